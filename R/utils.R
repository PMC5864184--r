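#' @importFrom stats median optimize p.adjust quantile rlnorm rnbinom rpois
#'   runif rnorm rmultinom dbinom dnbinom setNames aggregate
#' @importFrom utils head read.delim write.table
NULL

geometric_mean <- function(x) exp(mean(log(x)))

check_strand <- function(strand) {
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  strand
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
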