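---
title: "Structural profiling of archaeal promoters: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural profiling of archaeal promoters: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promstruct)
```

## The problem

Archaeal promoters are bound by a compact eukaryote-like machinery: TBP on
a TATA box near −28, TFB on the BRE immediately upstream, TFE contacting
the proximal promoter element (PPE) near −10 and the initiator (INR) at
+1. A substantial fraction of transcription units shows no recognizable
TATA at the sequence level, yet the physical properties of the region —
how easily the duplex melts, bends and curves — retain a promoter
signature. `promstruct` operationalizes that idea: sequences anchored at
an experimentally mapped TSS are converted into per-position structural
profiles, averaged TSS-aligned, and compared between promoter classes or
against un-annotated upstream DNA.

## Coordinate convention

There is no position 0: the TSS base is +1 and the base 5′ of it is −1. A
1000-nt TSS-centered record spans −500..+500 and the 100-nt core promoter
spans −80..+20 (TSS at 0-based offset 80). Dinucleotide step values are
anchored to the 5′ base of the step (a length-n record yields n−1
values); pentamer curvature is anchored to the window's center base (n−4
values). Anchoring is a convention the source data do not dictate; the
5′/center choice keeps the TATA signal at its literature coordinates and
is stated in every output header. Ambiguous bases (`N`) encode as missing
values rather than errors, and per-position means carry an explicit
count of contributing sequences, so edge positions and missing windows
remain auditable.

## Parameter tables

Three dinucleotide scales are shipped as plain TSV
(`inst/extdata/dinucleotide_properties.tsv`): nearest-neighbor melting
enthalpy and duplex stability (kcal/mol-bp, both negative) and
bendability (degrees, positive; TA = 6.74° is the extreme step). The
table is transcribed *verbatim* from its printed source, including a
European decimal comma read as a dot (AC enthalpy −8.5) and several
complement-asymmetric pairs (e.g. stability CC −1.28 vs GG −1.84,
enthalpy AG −8.2 vs CT −7.8). Physically, duplex scales should be
complement-symmetric; because the original analysis used the printed
values, no symmetrization is applied, and validation reports asymmetric
pairs as warnings (`step_table(..., warn_asymmetry = TRUE)`), never as
errors.

Intrinsic curvature uses gel-mobility wedge angles: per-step roll and
tilt (from the published wedge magnitudes and directions; the classic AA
wedge is 7.2° at direction −154°) with crystallographic twist angles,
shipped in `inst/extdata/bmht_wedge_angles.tsv`. Complementary steps
carry equal roll and opposite tilt by construction. Curvature of a k-mer
is the magnitude of the sum of the step wedge vectors, each rotated in
the plane by the accumulated twist, divided by the number of steps
(degrees per step, window-length comparable). This planar wedge-vector
sum is the standard simplification of the full 3-D path reconstruction;
phase invariance, linear scaling in the wedge magnitudes and agreement
with a brute-force vector construction are pinned by tests. The encoder
evaluates curvature over pentanucleotide windows via a precomputed
1024-entry lookup (`build_pentamer_table()`); a user-supplied wedge or
pentamer table (one 5-mer and one value per row) overrides the packaged
one everywhere, so the geometry is testable independently of any
particular angle set, and no exact numeric agreement with any external
precomputed lookup is claimed.

## Motif classification

The TATA-conserved / TATA-degenerated split uses the degenerate
consensuses reported for the three model archaea (`TATA_MOTIFS`):
`SYTTWWAA` (*H. volcanii*), `VYTTWWAA` (*T. kodakarensis*) and
`KVRWAAA VYTTWWWW` (*S. solfataricus*). The last is a BRE+TATA
combination printed as two words; it is treated as a single 15-mer with
no spacer (the BRE abuts the TATA), with a `gap` option because the
original text does not state whether the space is a separator or a
spacer. Matching is restricted to starts in a TSS-relative window,
default −40..−20, covering the reported median TATA distances (30, 31
and 35 bp upstream in the three organisms); among multiple matches the
one closest to −28 is kept, ties broken upstream, preserving
zero-or-one-occurrence semantics. Motif *discovery* is out of scope —
the classifier consumes any user IUPAC pattern.

## Statistics

Group comparisons follow the nonparametric route justified by a
Shapiro–Wilk screen: the two-sample Mann–Whitney U test and the
Kruskal–Wallis test, backed by the base-R implementations. The U test
uses the exact permutation distribution when `n·m ≤ 400` and no ties are
present, otherwise the normal approximation with tie correction and *no*
continuity correction — so the two-group Kruskal–Wallis p is identical in
the tie-free case, a relationship the tests pin. Degenerate all-tied
input returns U = nm/2 and p = 1 rather than a 0/0. No multiple-testing
correction is applied; raw p-values are reported.

## The synthetic generator

Every stage is testable without downloads through a seeded generator.
The background model is i.i.d. with strand-symmetric base probabilities
parameterized by a single AT fraction — the minimal model consistent
with treating GC% as the compositional covariate. Presets carry the
published compositions of the three organisms (1000-nt windows: AT
0.338 / 0.493 / 0.655; cores: 0.400 / 0.568 / 0.711). A degenerate TATA
motif is planted with configurable probability (default 0.5), its
midpoint at −28 with ±2 nt uniform jitter, and every planted position is
recorded as ground truth. Optionally (`promoter_elements()`) the three
flanking elements are planted too: BRE (`AA` at −34/−33, jitter ±1), an
AT-rich PPE (`WWWW` near −10, jitter ±2) and a pyrimidine–purine
initiator (`YR` at −1/+1, fixed). Real TSS-aligned profiles show signal
at all four sites; a TATA-only synthetic promoter leaves the reference
profile flat over most of the core, which understates what a reference
built from real promoters contains. The elements are off by default so
that single-motif studies stay minimal.

What the generator does *not* emulate: dinucleotide autocorrelation,
repeats, operon structure, coding bias, or organism-specific skews.
Passing tests therefore demonstrate the machinery (coordinates,
encoding, averaging, matching, scoring) under a clean compositional
null, not performance on real genomes.

## Upstream scanning

The reference profile is the per-sequence-weighted mean of each feature
over pooled core-promoter sets (a per-set weighting flag exists for
unbalanced pools). A candidate sequence is encoded per feature and a
100-nt window slides one position at a time; the per-feature score is
the Pearson correlation between the window's values and the reference
(pairwise-complete over non-missing positions; windows with fewer than
50 usable positions are skipped), and the combined score is the mean of
the feature correlations. Correlation is used rather than a distance so
features with different units combine without scaling constants; the
score is invariant to affine rescaling of any feature.

Significance is judged against the sequence's own composition: the best
combined score is compared with the best scores of shuffled copies
(default 100 draws). Because a best-of-all-windows statistic is
extreme-value distributed, a plain standard score against the null
maxima is anticonservative in its right tail (for a Gumbel, the
probability above mean + 3 sd is ≈1.2% rather than the normal 0.13%);
the null maxima are therefore summarized by a method-of-moments Gumbel
fit and `z` is the normal quantile of the fitted upper-tail probability
of the observed best score — approximately standard normal under the
null, tail included. The uncalibrated standard score is retained as
`z_raw`. The z > 3 cutoff quoted in examples is a convention, not a
claim about what signal strength constitutes a promoter.

Detection power depends strongly on background composition. In GC-rich
(halophile-like, AT ≈ 0.34–0.40) settings a planted promoter core is
structurally distinctive and the best-offset error concentrates at zero.
In AT-rich (AT ≥ 0.5–0.7) backgrounds TATA-like structure occurs
throughout the sequence and localization saturates — consistent with the
observation that the AT-richest of the three organisms has TATA-like
motifs in ~80% of its promoters while the GC-richest has them in ~2%.
This is a genuine limitation of correlation scanning against a mostly
flat reference, not an implementation artifact.

## Study sizes and numerical choices

The packaged studies use: 500 promoters (length 1000, AT 0.655, TATA
`VYTTWWWW` at −28 ± 2 in 50%) for the classification and profile-peak
study; a reference from 500 GC-rich cores with full architecture; 200
upstream regions (400 nt, AT 0.338) with 3′-flush promoter inserts for
localization; 1000 shuffled regions with 50 null draws each for z
calibration; and 2000 null simulations (n = 20 per group) for the rank
test's type-I error. These sizes give the binomial checks a 3-standard-
error margin while keeping a full run around a minute. Ties in the
sliding-correlation argmax are resolved to the first (5′-most) offset;
zero-variance windows score `NA`; shuffling uses a private RNG stream so
callers' seeds are never disturbed.

## Known limitations

* The i.i.d. background understates the spatial autocorrelation of real
  genomes; z calibration on real upstream sets should be re-checked
  against organism-matched shuffles (the machinery for that is built in).
* The wedge-angle set determines curvature values; other parameter sets
  (e.g. crystallography-derived) would change magnitudes, though the
  geometry and invariants are parameter-independent.
* Scanning is single-strand, as upstream exports are pre-oriented; no
  reverse-complement pass is made.
* The classifier records at most one motif occurrence per sequence; dense
  tandem TATA-like runs in AT-rich genomes are collapsed to the
  occurrence nearest −28.
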