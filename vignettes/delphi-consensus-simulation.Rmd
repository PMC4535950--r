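---
title: "Measuring Delphi consensus and its dependence on survey design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Delphi consensus and its dependence on survey design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delphisim)
```

## The model

A Delphi panel of `r` experts rates `n` questions on the integer scale
`1..q` (default `q = 10`) over `T` rounds (default 3).  `delphisim`
simulates the panel as follows.

**Round 1.** Every score is drawn i.i.d. from the discrete uniform
distribution on `1..q`: the panel starts maximally uninformed, with no
prior structure.  This is the strongest assumption of the whole model — in
real surveys first-round ratings are rarely uniform — and it is what makes
the later rounds interpretable: any agreement that emerges is produced
entirely by the convergence mechanism, not smuggled in through the initial
conditions.

**Cluster identification.** Opinions in a dissensual panel typically pile
up in a few regions of the scale rather than at a single point.  For each
item we find those regions as intervals of at most `v` consecutive scale
points (default `v = 3`): every interval of width `1..v` is a candidate,
candidates are ranked by how many ratings they hold (ties broken toward
wider intervals, then toward the lower end of the scale), and a
candidate is kept when it is disjoint from everything already kept and
holds at least `p * r_mode` ratings, where `r_mode` is the count in the
best window and `p` (default 0.5) is the secondary-cluster threshold.
Values of `p` below 0.5 let marginal outlying groups count as clusters and
capture converging experts; we therefore treat 0.5 as the sensible lower
bound and the default.

**Convergence.** Between rounds every expert moves toward the arithmetic
mean of the cluster *nearest to their current rating* under the Group
Conformity Index `β`:

    new = round( β * mean_cluster + (1 − β) * old )

`β = 0` reproduces a panel of immovable experts; `β = 1` a panel that
adopts the local group position outright.  Nearness is measured from the
rating to the cluster's score *interval* (distance zero inside it), not to
its mean.  We chose interval distance deliberately: distances between
integer ratings and integer interval bounds are integers, so the
exactly-midway case between two clusters is a routine occurrence that
needs a rule — it goes to the more populous cluster, and to the lower one
if the counts also tie.  Had distance been measured to the (generically
fractional) cluster means, exact ties would almost never arise and any
midway rule would be dead code; a convergence model whose stated
tie-break can essentially never fire struck us as the wrong reading of
the mechanism.  Experts already inside a cluster still tighten toward its
mean, which is what lets a mono-clustered item reach unanimity under
`β = 1`.

## The nine indices

On the final-round matrix the package computes, per item and study-wide
(the unweighted mean over items): the De Moivre unanimity indicator (DM),
pairwise agreement (PWA), clustered pairwise agreement (CPWA), its
extremities version confined to scores 1–3 and 8–10 (XCPWA), the modal
share (M), the modal-cluster share (CM) and the interquartile range (IQR);
plus Fleiss' and Conger's kappas (KF, KC), which are defined jointly over
all items and are therefore reported study-wide only — averaging
single-item kappas would be a different (and noisier) statistic.  Clusters
feeding CPWA and CM are re-identified from the final round itself, the
matrix the indices describe.

Two numerical conventions matter:

* **Quantiles for the IQR** interpolate linearly between order statistics
  at rank `1 + (r − 1) m / 100` (the default type-7 rule of
  `stats::quantile()`).  The IQR of four ratings (1,2,3,4) is thus 1.5,
  of (2,2,2,9) 1.75.  Ordinal data admit many quantile conventions; one
  must be fixed for results to be reproducible to the last digit, and
  this is the one every reader of R output already knows.
* **Degenerate kappas.** When every expert gives the same single rating
  everywhere, observed and chance agreement are both 1 and the kappa
  ratio is 0/0.  We return 1: perfect agreement should read as full
  consensus, not as undefined.

Rounding in the convergence update is half-away-from-zero (all quantities
are positive, so effectively half-up), and updated scores are clamped to
`[1, q]`.  Modal ties in M and CM break toward the lower score/cluster;
the reported share is unaffected either way.

## The dependency experiments

To measure how much a consensus index reflects the survey rather than the
panel's substance, `run_sweep()` varies exactly one characteristic —
questions over 6..40, experts over 6..50, or GCI over 0, 0.1, …, 1 — with
the other two fixed at the baseline of 12 questions, 20 experts and
GCI 0.5.  Each grid point is simulated 1000 times; the per-condition
summary is the median of the 1000 study-wide values (even counts average
the two central order statistics); and the index's *dependency* is the
range of those medians, max − min.  The IQR's dependency is divided by
`q − 1 = 9` so all nine dependencies share the 0–1 scale.  The GCI grid
step of 0.1 and the unit steps of the count grids are our choice: fine
enough to bracket the extreme medians, cheap enough that a full
three-sweep reproduction runs in seconds through the compiled core.

Replicate seeds derive deterministically from (master seed, swept value,
replicate id) through a Lehmer-style modular hash kept below 2^31.  Two
consequences worth stating: no RNG stream is shared between replicates,
and because the condition id is the swept *value* rather than its grid
position, permuting the grid permutes the per-condition medians and leaves
every dependency bit-identical.

The headline findings these experiments compute (at 1000 replicates, and
checked by the test suite at that resolution) are rank orders, which are
more robust than third decimals: the question count moves no index beyond
the second decimal; panel size matters most for the IQR and the two modal
indices; and panel conformity dominates everything, with the kappas and
PWA at the top and XCPWA and the IQR nearly indifferent.  A practitioner
reading a kappa from a real Delphi should know it is, in part, a
measurement of panel flexibility.

## Two engines, one model

The documented R functions (`identify_clusters()`, `advance_round()`,
`run_study()`, the `index_*()` family) are the reference implementation.
The Monte-Carlo loops call a compiled core (`Rcpp`) that replays the same
model operation for operation — the same `unif_rand()` stream, the same
candidate ordering, the same IEEE expression shapes — so a seed produces
the same study through either path; the test suite asserts agreement to
within 1e-12 across configurations.  `run_condition(engine = "r")` selects
the reference path when compiled code is under suspicion.

## What the generator does and does not emulate

The generator reproduces the mechanics of a clustered-convergence Delphi:
uniform first-round opinion, interval clustering, conformity-weighted
movement, a fixed number of rounds.  It deliberately does not model
qualitative feedback between rounds (which cannot be reduced to a
non-random rule), expert dropout, per-expert heterogeneous conformity
("fuzzy" conformity is a natural extension), radical opinion jumps to a
distant cluster, or non-uniform priors.  Passing tests therefore show
that the indices behave as analysed *under these mechanics*; they do not
certify how any index behaves on a real panel whose first round is already
structured.

## Known limitations

* With 12 items the study-wide DM median is quantized in steps of 1/12,
  so its dependency values move in 0.083 jumps; small modelling
  differences (or Monte-Carlo noise at low replicate counts) shift DM by
  a whole step where smoother indices move by 0.005.
* Several micro-decisions of the convergence model — the candidate
  enumeration order, tie-breaks among equal-count windows, the exact
  secondary threshold — are under-determined by the mechanism's verbal
  description.  We fixed each one deterministically and test them against
  independent brute-force oracles, but other reasonable choices shift the
  stochastic results by a few hundredths, which is why rank orders, not
  decimals, are the right reading of the dependency tables.
* Threshold comparisons (`count >= p * r_mode`) use a 1e-9 slack so that
  exact fractional products do not flip on floating-point representation.
* The IQR index is the one statistic whose value depends on a quantile
  convention; on small panels (r < 10) different conventions disagree by
  up to a scale point, and any comparison of IQR values across studies
  should state the convention used.
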