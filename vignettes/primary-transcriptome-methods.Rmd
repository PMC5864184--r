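---
title: "Methods: TSS detection, classification and differential promoter activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSS detection, classification and differential promoter activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primatx)
```

## The problem

Differential RNA sequencing (dRNA-seq) maps bacterial transcription start
sites (TSS) at single-nucleotide resolution by contrasting two libraries
prepared from the same RNA: a TEX-treated library, in which Terminator
5'-phosphate-dependent exonuclease has degraded processed transcripts so that
primary 5'-triphosphate ends are enriched, and a matched "minus" library that
sequences the left-over processed 5' ends. A genuine TSS shows a sharp pileup
of read 5' ends in the TEX library that is absent, or much weaker, in the
minus background. `primatx` implements the downstream analysis of such data
for a two-condition, two-replicate design: TSS calling, categorisation,
5'-UTR architecture, TSS-level differential promoter activity, CsrA/Rsm
binding-site scanning of 5'-UTRs, and flexible-genomic-island calling from
pairwise synteny — together with a synthetic-data generator that makes every
stage testable against a planted truth.

## TSS detection: replicate-assisted background subtraction

All TEX and MINUS libraries are first scaled to a common depth
(`scale_to_common_depth()`): library $i$ receives the factor
$f_i = \tilde N / N_i$ where $N_i$ is its total 5'-end count and $\tilde N$
the geometric mean over libraries. Geometric-mean scaling is simple,
invertible, and leaves the within-library rank order of positions unchanged.
A background library with no counts at all (possible in noise-free simulated
data) takes a neutral factor of 1, since its scaled counts vanish anyway.

For each replicate, every position whose **raw** TEX count reaches
`min_height` (default 10 reads) is evaluated as

$$\mathrm{enrichment} = \frac{f_\mathrm{TEX}\, y_\mathrm{TEX}}
  {f_\mathrm{MINUS}\, y_\mathrm{MINUS} + c},$$

with pseudocount $c = 1$ guarding against empty background. A position
becomes a candidate for a condition according to `replicate_rule`:

* `both` (default) — enrichment $\ge$ `min_enrichment` (default 2) in both
  replicates;
* `any` — in at least one replicate;
* `any_strong` — in both, or in a single replicate at
  `strong_enrichment` (default 5).

The default is the conservative choice: replicate agreement is what
suppresses spurious single-library pileups. Requiring the raw (not scaled)
count to reach `min_height` makes the floor interpretable in sequencing
reads.

Because read 5' ends jitter by a few nucleotides, candidates within
`cluster_distance` (default 5 nt) of the previous cluster member are chained
into one cluster whose representative is the member with the largest summed
TEX count across replicates; ties resolve to the 5'-most member. Detection
runs per condition and the two condition sets are then unioned, merging
calls within `cluster_distance` across conditions (representative from the
higher-count condition) while recording which conditions each TSS was active
in. Per-condition sets plus their union are exactly the shape of a primary
transcriptome census table.

## TSS categories

Each TSS collects every category whose rule fires; the reported category is
the highest-precedence member of that multi-label set
(gTSS > iTSS > aTSS > nTSS), and the full set is retained so users can
re-rank:

* **gTSS** — same strand, 1 to `gtss_window` (default 200, boundary
  inclusive) nt upstream of a protein-coding gene's start codon. The
  distance is measured to the first base of the annotated CDS; where gene
  and CDS rows disagree we use the CDS start.
* **iTSS** — same strand, inside an annotated gene body.
* **aTSS** — opposite strand, inside a gene body extended by `atss_flank`
  (default 50) nt on both sides.
* **nTSS** — within the same window upstream of an ncRNA-class feature
  (tRNA, rRNA, sRNA, other ncRNA) on the same strand, or in an intergenic
  region where no rule fires.

gTSS takes precedence because gene-leading promoters are the analytic
currency of everything downstream (5'-UTRs, promoter activity, CsrA sites).
The optional *coverage extension* (`use_coverage_extension`) admits a gTSS
beyond the 200-nt window when pooled RNA-seq coverage is at least
`coverage_floor` (default 5) at **every** base between the TSS and the start
codon — this is how 5'-UTRs longer than the window can exist. It is off by
default because it requires the extra RNA-seq track.

5'-UTR statistics are computed over gTSS records only: median length,
leaderless count, long-UTR count. The leaderless threshold
(`leaderless_max`, default 10 nt) is a genuinely open definition — published
censuses report leaderless counts without defining the cutoff — so it is
config-exposed; `long_utr_min` defaults to 200 nt, the complement of the
gTSS window.

## Differential promoter activity

Per-TSS tag counts sum the raw TEX 5'-end counts within `count_window`
(default 5, matching the cluster distance) nt of the TSS on its strand;
where windows overlap, each position is assigned to the nearer TSS (ties to
the 5'-most) so no tag is counted twice.

Between-library normalisation is the trimmed mean of M-values, implemented
from the published formula: M- and A-values against a reference library (the
one whose upper quartile of scaled counts is closest to the mean upper
quartile) on features nonzero in both, double trimming (30% on M, 5% on A),
inverse-asymptotic-variance weighting, factors rescaled to geometric mean 1.

The model is negative binomial with one common dispersion $\varphi$,
estimated by conditional maximum likelihood after mean-scaling counts to a
common effective library size. This mean-scaling replaces quantile-adjusted
pseudo-count equalisation; it is a documented approximation, so mild
divergence from quantile-adjusted estimators is expected. Matching the
original study design, all four samples can be pooled into one pseudo-group
for estimation — conservative when true fold changes exist, since planted
changes inflate the pooled dispersion (visible in the package's own fixture:
pooled estimates run above the generating $\varphi$).

Each TSS is tested with an exact NB test conditioning on its total count
after size equalisation: with $n_A$ and $n_B$ samples per group the group
sums are NB with sizes $n_A/\varphi$ and $n_B/\varphi$, and the two-sided
p-value sums the conditional probabilities of all splits no more likely than
the observed one (small-probabilities convention), capped at 1. At
$\varphi = 0$ this reduces to a binomial exact test. Calls combine
Benjamini–Hochberg FDR < 0.05 with $|\mathrm{logFC}| \ge 1$, where logFC is
computed from normalised condition means with a prior count of 0.5 for
stability at zeros.

## CsrA sites and IUPAC motifs

CsrA/Rsm binding sites in 5'-UTRs are matched with the anchored pattern
`GGA[ACGT]{4,70}GGA[ACGT]{2,12}$`: two GGA cores, an inner spacer of
4–70 nt, and 2–12 nt from the second core to the end of the scanned
sequence. The `$` anchor is interpreted as the end of the supplied 5'-UTR
(the base before the start codon), placing the second core near the
ribosome-binding region; `cds_extension` lets users append coding sequence
when they want to emulate scans running into the gene. One hit per sequence
is reported (the leftmost matching suffix), all valid spacer decompositions
are enumerated, and additional `A(N)GGA` occurrences are counted as
supporting evidence. Externally predicted target tables can be merged
through `read_external_csra_targets()`; the external prediction algorithms
themselves are out of scope.

`scan_iupac_motif()` is a deliberately generic utility (degenerate IUPAC
codes, mismatch tolerance, both strands, TSS-anchored coordinates) for
scanning promoter windows with user-supplied motifs; de novo motif
discovery is out of scope.

## Flexible genomic islands

Synteny anchors are alignment hits of at least `anchor_min_length`
(default 1 kb) and `anchor_min_identity` (default 70%) — these two values
are this package's operational definition, config-exposed, since the
break rule itself only fixes the island threshold. Anchors are chained by
the heaviest (alignment-length-weighted) subject-monotone subsequence along
the query, in either orientation, so off-diagonal repeats cannot rescue
synteny. Every maximal query interval of at least `min_island_length`
(default 10 kb) without an anchored base is reported as a flexible genomic
island. Conserved proteins are flagged from best BLAST hits with all-strict
thresholds: e-value < 1e-5, coverage > 80%, identity > 30%.

## The synthetic-data generator

The generator emulates the data-generating process the detector assumes:

* a single 200-kb replicon with uniform base composition and 150
  non-overlapping genes (lengths ~ N(900, 200) clipped at 150 bp, 5%
  ncRNA classes) — large enough for ~200 TSSs with realistic intergenic
  space, small enough that the whole pipeline runs in seconds;
* 200 planted TSSs with category mix 59/27/6/8% (gTSS/iTSS/aTSS/nTSS) and
  lognormal 5'-UTR lengths with median 63 nt, each placed so the classifier
  assigns exactly the intended category (placements are resampled until
  self-consistent, which in particular truncates planted gTSS UTRs at the
  200-nt window; longer UTRs are exercised separately through the
  coverage-extension path);
* per-TSS mean expression lognormal with median 50 tags and sdlog 0.5 — a
  central 95% range of roughly 19–133 tags, chosen so that the bulk of
  planted sites sits above the 10-read calling floor while the weak tail
  still probes it;
* TEX tag counts NB with common dispersion 0.2, spread by a positional
  jitter kernel (80% at the TSS, 15% at ±1, 5% at ±2 nt);
* MINUS background as 10% leakage of the TSS signal plus a Poisson
  processed-site background (2 sites per kb, shared positions across
  libraries, per-library Poisson counts around lognormal site intensities)
  — the simplest model producing the TEX/MINUS contrast;
* 15% of TSSs carry a planted log2 fold change of ±1, ±2 or ±3 between
  conditions;
* a pooled RNA-seq track with plateau coverage from each gene-leading TSS
  to its gene end, supporting coverage-extension classification.

Planted TSSs keep a minimal same-strand spacing of 25 nt so that jittered
clusters remain separable; everything is deterministic in the seed.

What the generator does **not** emulate: sequence-dependent library biases,
operon structure and reinitiation, partial TEX digestion of abundant
processed ends (background appears in MINUS only, never in TEX), rRNA
contamination, and condition-dependent background composition. Recovery
rates on synthetic data therefore bound what the algorithms can do when
their model holds; they do not certify performance on real libraries, where
threshold tuning against the minus background remains the user's
responsibility.

## Numerical and edge-case choices

* Coordinates are 1-based inclusive throughout (GFF3 convention); bedGraph
  input/output converts from/to 0-based half-open intervals at the boundary.
  The TSS is the first transcribed base; for minus-strand genes the gene
  start is the feature's end coordinate.
* Cluster representatives and consolidation ties resolve to the 5'-most
  position, making outputs deterministic.
* The exact test rounds the two scaled group sums independently before
  conditioning, which keeps label swaps exactly symmetric.
* The dispersion optimiser works on $\log \varphi$ over $[10^{-6}, 10]$;
  degenerate all-equal counts land at the lower clip.
* TMM returns factor 1 when every usable M-value is below $10^{-6}$ in
  magnitude (pure depth shifts).
* Overlapping bedGraph intervals on one strand are rejected as ambiguous
  rather than summed.
* Census percentages are rounded to 2 decimals; an empty census subset
  reports blank (NA) percentages rather than dividing by zero.

## Problem sizes used in the tests

The shipped suite runs the full pipeline on the 200-kb/200-TSS default
fixture, compares the classifier against a brute-force rule evaluator on
1000 random mini-genomes, checks the exact test against full enumeration for
totals up to 200 and against a null simulation of 5 × 2000 features, and the
CsrA scanner against a naive suffix enumerator on 10,000 random 80-mers.
These sizes were chosen to give the property checks real coverage while the
whole suite stays fast enough to run on every change.

## Known limitations

* The detector calls single positions, not promoter boxes; −10/−35 motif
  calling and sigma-factor assignment are out of scope.
* Only a 2 × 2 (condition × replicate) design is supported end-to-end;
  `replicate_rule = "any"` admits single-replicate designs for detection
  only.
* The common-dispersion model has no tagwise shrinkage; strongly
  heterogeneous dispersions will be averaged over.
* fGI calling assumes one query replicon against one reference; island
  typing (additive vs replacement) is not attempted.
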