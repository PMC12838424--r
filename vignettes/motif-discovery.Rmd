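---
title: "De novo discovery of methylated motifs from modification fraction tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo discovery of methylated motifs from modification fraction tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Nanopore modification callers emit, for every adenine of a reference genome
and on each strand, an estimate of the *fraction of modified bases* — the
share of reads in which that adenine appears methylated. Two properties of
these tracks shape everything downstream. First, the caller makes systematic
false calls in particular sequence contexts, which an unmodified negative
control reproduces; subtracting the control removes them. Second, the raw
signal cannot localise a modification more precisely than an interval of
roughly five bases, so single-base signals appear smeared over their
neighbourhood. The package turns such a pair of tracks into a recognition
motif: it extracts the most strongly modified fixed-width regions, runs a
two-strand ZOOPS EM motif search over them, and then profiles the motif
back on the genome (mean modified fraction per context, flanking-base
extension ladder, methylation-aware restriction digestion as an orthogonal
check). A companion module reproduces the mass-spectrometric reasoning used
to characterise chemically modified nucleosides, and a small quality module
handles per-read Phred statistics.

```{r}
library(modmotif)
```

## The synthetic data generator

No public dataset is required: the generator plants a methylation motif in
a random genome and emulates the caller's output.

* `simulate_genome(length, gc, seed)` draws i.i.d. bases; the default study
  dataset is 200 kb at GC 0.5.
* `simulate_tracks(g, config)` covers every strand-resolved adenine
  (plus-strand A positions on `+`, T positions — minus-strand adenines — on
  `-`). The modified base of every motif occurrence (default `ATC`, modified
  base at offset 0, on both strands) draws its fraction from Beta(8, 2)
  (mean 0.8); all other adenines, and every adenine of the control, draw
  from Beta(1, 19) (mean 0.05). The caller's positional uncertainty is
  emulated by a geometric blur: a planted site with fraction *f* raises each
  covered same-strand neighbour at distance *d* ≤ 2 to
  max(current, *f* · 0.5^*d*), i.e. a ~5-base footprint matching the
  caller's stated localisation limit. The max-combination keeps fractions in
  [0, 1].
* `simulate_read_qscores(n, library, seed)` draws per-read mean quality
  scores from truncated normals — N(7.5, 1.5²) for native DNA, N(11.5, 2²)
  for PCR-amplified DNA, truncated to [1, 30] — centring the native median
  at Q7.5 and the PCR median near Q11.5.

The Beta noise model and its shapes are a modelling choice, not a measured
property of any instrument: callers report no parametric error model for
fraction estimates, so a bounded, right-shaped two-parameter family with
means 0.8/0.05 was fixed once and exposed in `sim_config()`. What the
generator deliberately does **not** model: read-level errors, coverage
variation (every adenine is covered), off-target methylase activity, and
chained correlations between neighbouring site estimates. Passing the
pipeline on this data therefore shows that the *analysis chain* recovers a
planted context under realistic noise and blur — not that any particular
caller is accurate on real reads.

Everything is deterministic given `seed`; each stage seeds its own stream,
so regenerating a track does not depend on whether the genome was simulated
in the same session.

## Window extraction

`differential_track()` computes max(0, test − control) per covered
position, treating a missing control value as 0 and keeping test-missing
positions missing. `top_windows()` scores **every** candidate start: the
score of a window is the sum of non-missing differential fractions on both
strands across its bases (missing contributes 0). With a fixed width, sum
and mean rank identically; the sum keeps missingness explicit. Selection is
greedy in descending score with ties broken toward the smaller start, under
a pairwise-disjointness constraint so that the extracted sequences are
independent evidence for the motif search; both strands pool into one score
because strand is recovered later by the two-strand motif model. Window
scores are rounded at 1e-9 before ranking so that windows with equal sums
tie exactly regardless of floating-point summation order. If fewer than
`k` positive-scoring disjoint windows exist the function returns what there
is, with a warning.

## The two-strand ZOOPS EM

Each extracted sequence is assumed to contain **zero or one** motif site
(ZOOPS). The model has a width-*w* position weight matrix θ, a fixed
0-order background *b* estimated from the input base composition (with a
1-count smoothing so no base has probability zero), and a site prior λ.
For a sequence of length *L* there are *m* = *L* − *w* + 1 site starts per
strand; the likelihood mixes "no site" (weight 1 − λ) with each (start,
strand) placement (weight λ/2*m*), a site being scored by the PWM on its
strand and the remainder of the sequence by the background:

$$P(s) = (1-\lambda)\prod_{i} b_{s_i} \;+\; \sum_{j,\sigma} \frac{\lambda}{2m}
  \; P(s \mid \text{site at } j, \sigma).$$

The E-step computes each sequence's posterior over these states; the M-step
re-estimates θ from posterior-weighted site counts with a pseudocount of
0.25 per base, and λ as the mean posterior probability of containing a
site. Iteration stops when the log-likelihood gain falls below 1e-6 (cap
500 iterations); the log-likelihood is non-decreasing within a start (the
standard EM guarantee — asserted by the tests on every fixture). Ten seeded
restarts are run, each initialising θ from a randomly chosen width-*w*
subsequence (0.7 on the observed base, 0.1 elsewhere) with λ = 0.5, and the
best final likelihood wins.

Two degeneracies deserve a note:

* **Orientation.** With the two-strand search, reverse-complementing the
  PWM and swapping every site's strand leaves the likelihood unchanged, so
  which orientation EM reaches depends only on the initialisation. The
  fitted model is therefore canonicalised to the orientation whose
  consensus is lexicographically smaller (`ATC` rather than `GAT`), making
  results deterministic and comparable across runs. The per-sequence strand
  assignments and the `n_rc` count flip with it.
* **Periodicity.** On a perfectly periodic input such as `ATCATCATCA`
  repeats, rotations of the motif with the same base multiset (`ATC`,
  `TCA`) are exactly equally likely; the reported one depends on the
  restart that wins. Real window sets have random flanks and do not show
  this.

Maximum-posterior site assignments break ties toward the earliest state in
a fixed order (no site, then plus starts ascending, then minus), so output
is reproducible. `consensus()` takes the per-position argmax with ties in
the order A < C < G < T; `information_content()` gives per-position bits
relative to the background, the sequence-logo column heights.

Because the discovered core may sit inside wider windows, `scan_motif_widths()`
fits all widths 3–8 and ranks them by BIC, −2·loglik + (3*w* + 1)·log *n*
(three free parameters per PWM column plus λ). On the planted dataset the
extra columns of wider models buy almost no likelihood against random
flanks, so width 3 wins; BIC was chosen over a raw likelihood comparison
precisely to encode that penalty explicitly.

## Motif-anchored genome statistics

`scan_sites()` finds all (possibly overlapping) occurrences of an IUPAC
pattern; minus-strand occurrences are occurrences of the reverse complement
on the plus strand, reported with their plus-strand footprint. A palindromic
pattern yields one record per strand per locus, and each strand contributes
its own observation to mean-fraction statistics — the two strands' adenines
are chemically distinct bases. Footprints containing `N` never match.
`motif_mean_fraction()` averages the (differential or raw) fraction at the
modified base across all loci, counting missing as 0, consistent with the
window scores. `extension_ladder()` grows the core one position at a time
up- and downstream, one concrete base at a distance with `N` in between,
so at each distance the four base-specific rows partition the core's loci
(exactly, away from the genome ends — a core occurrence closer to an end
than the extension distance has nothing to extend into). A flat row of
means says the planted methylation ignores that flanking position; on the
default dataset the four upstream d=1 means agree within well under 0.05,
the tolerance the tests use for "no preference".

`digest()` performs methylation-aware in-silico restriction digestion. The
shipped DpnI profile cuts fully methylated GATC (blunt, after base 2: GA^TC)
and optionally the hemi-contexts CATC/GATG as secondary sites. "Fully
methylated" means the site's adenine is methylated on **both** strands;
secondary, non-palindromic sites cut on single-strand methylation and only
when `include_secondary` is set — their partial activity is a flag, not a
probability, because no quantification is available. A palindromic locus is
one duplex site: the fragment boundary is placed at the top-strand cut. A
linear genome with *c* cuts yields *c* + 1 fragments, a circular one with
*c* ≥ 1 cuts yields *c*; fragment lengths always sum to the genome length
(property-tested over 1,000 random genomes).

## Mass annotation

`monoisotopic_mass()` uses the IUPAC monoisotopic element masses
(C 12, H 1.0078250319, N 14.0030740052, O 15.9949146221, P 30.97376151);
adducts add or remove one proton (1.00728 Da), all species being singly
charged. `explain_peak()` enumerates base × (no delta + delta library)
compositions within an explicit tolerance of an observed m/z —
tolerances are never hidden in rounding because printed instrument values
carry calibration offsets: the defaults are 0.005 Da for four-decimal peaks
and 0.03 Da for two-decimal peaks. `explain_fragments()` tries single and
depth-2 chained neutral losses from a precursor. The shipped delta
`pentosyl` (C5H8O4) encodes only the net composition of a glycosidically
bound pentose with an additional oxygen; no structural claim is attached,
since how the hydroxyl is carried is unresolved. One annotation caveat: an
isolation mass printed to two decimals can sit several hundredths of a Da
from the true species (precursor isolation windows are wide), so the
stage-5 analysis script falls back to the opposite ionisation mode when a
peak finds no candidate in its stated mode.

## Read quality

`qscore_to_error_percent(q)` is the Phred closed form 100·10^(−q/10); Q7 ≈
20% wrongly called bases, Q13 ≈ 5%. Per-read means are computed in
error-probability space (convert per-base Q to error probabilities,
average, convert back), the convention of nanopore tooling — an arithmetic
mean of Q would overstate accuracy, and the choice is documented here
because it is not universal. Quartiles use linear interpolation (type 7),
fixed for determinism.

## Problem sizes and numerical choices

The default study dataset is a 200 kb genome: large enough to carry ~6,000
planted sites (so 100 disjoint top windows are guaranteed and motif
statistics are tight) while a full simulate–discover cycle stays below a
second. The test suite runs the whole pipeline across 100 generator seeds
for the consensus-stability check and uses 2–60 kb genomes elsewhere.
Other fixed numerical choices: EM convergence at 1e-6 log-likelihood gain;
PWM pseudocount 0.25 (a quarter-count per base, the scale motif finders
conventionally use); λ clamped to
[1e-12, 1 − 1e-12] so degenerate all-site or no-site fits keep finite
likelihoods; bedGraph fractions serialized at full double precision so
write–read round-trips are exact.

## Known limitations

* The window score ignores coverage: every covered position counts equally,
  and there is no significance model behind "top 100" — it mirrors a fixed
  extraction depth, not a statistical threshold.
* The EM fits a single motif; multiple co-occurring motifs, OOPS/ANR site
  models and position priors are out of scope.
* The digestion model is all-or-nothing per site; partial digestion
  kinetics and band intensities are not modelled.
* The mass module annotates compositions, not structures, and fixes charge
  at ±1.
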