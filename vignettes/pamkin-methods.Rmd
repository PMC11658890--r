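---
title: "Methods: PAM depletion profiling and exponential cleavage kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PAM depletion profiling and exponential cleavage kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamkin)
```

pamkin implements the two computational analyses behind in vitro
characterization of Cas9 PAM specificity and DNA unwinding: a
library-depletion statistic over a randomized PAM space, and
single-exponential fits to cleavage and 2-aminopurine (2AP) progress
curves. This vignette explains the models, the tunable parameters and the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## The depletion assay and its statistic

A plasmid library carries a 5'-TTTTNNNN-3' PAM cassette on the non-target
strand: four randomized positions, labeled -5 to -8 in the 5' to 3'
direction, giving 256 possible PAMs embedded in a constant 206-bp
amplicon. A targeting ribonucleoprotein cleaves library members whose PAM
it recognizes; cleaved members fail to amplify, so recognized PAMs are
*depleted* in the sequenced pool relative to an untreated library. A
non-targeting guide controls for everything except recognition.

The analysis chain is:

1. **Extraction** (`extract_pams`). Each read and its reverse complement
   are scanned with a regular expression for
   `upstream_anchor N{4} downstream_anchor`, where the anchors are the
   constant sequence immediately flanking the cassette (12 bp each by
   default, exact match). A read counts only on a *unique* hit across both
   orientations with unambiguous bases in the cassette; everything else
   contributes to total depth only. Anchor uniqueness within the designed
   fragment is verified when the library spec is constructed.
2. **Normalization** (`normalize_frequencies`).
   `freq(p) = (count(p) + c) / (matched + 256 c)` with pseudocount
   `c = 1` by default. The pseudocount keeps fully depleted PAMs at a
   finite frequency so their log2 fold change is defined; frequencies are
   computed over matched reads (reads that failed extraction carry no PAM
   information). Frequencies sum to 1 by construction.
3. **log2 fold change** (`log2_fold_change`), per PAM, versus the pooled
   untreated reference.
4. **Significance threshold** (`depletion_threshold`). The apparent
   depletion a non-targeting control shows is pure noise (sampling,
   amplification). All non-targeting log2 fold changes are pooled and a
   Gaussian null is fitted; the threshold is the one-sided lower bound
   `mean - z * sd` at confidence 0.999999 (`z ~ 4.7534`). A PAM is called
   depleted only if its log2FC falls *strictly below* this bound — the
   strict inequality means a degenerate all-zero null calls nothing. Two
   points here were genuinely open: whether the null should use pooled
   values or per-sample maxima (pooled chosen: it uses all the control
   information and has a defensible closed form; the per-sample-maximum
   reading is not recoverable and would need an extreme-value model), and
   whether a parametric bound is appropriate at all (an empirical
   alternative, threshold = minimum observed non-targeting log2FC, is
   available via `threshold_method = "empirical"`).
5. **Logo and consensus** (`logo_matrix`, `consensus_call`). Over the
   significant set, each position's base frequencies are unweighted shares
   (weighting by depletion magnitude, `-log2FC`, is an option);
   information content is `2 + sum f log2 f` bits, uncorrected — the set
   summarized is a fixed motif set, not a sample, so no small-sample
   correction is applied. The IUPAC consensus admits at each position
   every base with frequency >= `inclusion_fraction` (default 0.25: any
   base at or above the uniform background share contributes), mapping
   the subset to its ambiguity code. A constricted recognizer that
   removes CAAA and CTAA therefore reads out as `CWAA`; one that removes
   all C-initial PAMs reads out as `CNNN`.

## Kinetic models and the nd rule

Cleavage time courses (fraction cleaved from gel densitometry,
`fraction_cleaved = cleaved / (cleaved + uncleaved)`) follow

  Y = Ymax (1 - exp(-k t)),  0 <= Ymax <= 1, k > 0 (per minute),

and 2AP unwinding traces follow

  Y = Y0 + Ymax (1 - exp(-k t)),  Ymax >= 0, k > 0 (per second),

with Y0 *fixed* to the mean of the matched blank (non-targeting complex on
the same substrate), not fitted. Fits are bounded nonlinear least squares
(`minpack.lm::nlsLM`). A rate is reported "nd" (not determined) when the
fitted amplitude is at or below the assay floor — Ymax <= 0.05 cleaved
fraction, Ymax <= 100 AU fluorescence; the boundary itself is nd. Below
these floors the progress curve is indistinguishable from baseline drift
and k is meaningless however well it optimizes.

Numerical choices:

* **Initialization**: Ymax0 = max observed (minus the blank for 2AP);
  k0 = 1 / t*, where t* is the first time the trace crosses half of
  Ymax0. On non-convergence, five restarts with log-spaced k0 over
  10^-3..10^2 times the guess; the best converged RSS wins. Persistent
  non-convergence returns an nd-flagged result with a diagnostic message,
  never an error.
* **Replicate handling**: cleavage fits pool all replicate points into
  one fit (for balanced designs this estimates the same curve as fitting
  the replicate mean at each time point, which is how such data are
  usually processed in a GUI); 2AP fits are per replicate, and
  `aggregate_replicates` reports mean ± sample SD (n-1) of the non-nd
  replicate rates, annotating aggregates that lost replicates to nd.
  Both modes are available for both models via `mode =`.
* **The t = 0 point** enters as measured (a substrate-only lane may have
  nonzero background), not forced to zero.
* **Units**: rates are per the course's time unit; converting a course
  from minutes to seconds divides the fitted k by exactly 60
  (`convert_time_unit`).

`fold_change` is the plain ratio of two non-nd rates; it refuses nd
inputs rather than propagating a meaningless number.

## What the simulators emulate — and what they do not

`simulate_pam_library_reads` draws each sample's reads multinomially over
the 256 PAMs with survival weight `1 - p(cleave)` for targeting samples
(1 for untreated and non-targeting), renormalized; the recognition model
is an ordered list of IUPAC rules (first match wins) plus a default
probability. A model that cleaves everything is rejected ("library fully
depleted"). Reads are the full 206-bp insert, single-ended, constant
quality; an optional fraction is emitted reverse-complemented (default 0)
and an optional uniform substitution rate is available (default 0). The
generator emits a ground-truth table (true weights, expected counts) the
extraction stage can be audited against, and a fixed seed reproduces
byte-identical FASTQ.

Deliberately *not* modeled: PCR jackpots and duplicate structure (the
amplification of survivors is collapsed into the one multinomial draw —
this matches the frequency-level statistics the analysis consumes, but
means the simulator cannot probe duplicate-sensitive artifacts), index
hopping, adapter read-through, quality-dependent errors, partial
cleavage during the incubation, or any real-instrument noise spectrum.
Passing the planted-recovery tests therefore shows the *analysis chain*
is correct under its own statistical assumptions, not that those
assumptions absorb every pathology of a real sequencing run.

The kinetic generators evaluate the fitting models exactly and add i.i.d.
Gaussian noise (clipped to [0, 1] for fractions); real densitometry noise
is heteroscedastic and real 2AP traces drift, so the estimator-quality
numbers (median relative error of k under noise SD 0.02, three
replicates) are a best case.

The library's default flank sequences are a fixed synthetic 206-bp design
(the amplicon length and the 20-bp constant region 3' of the cassette
follow the assay's fragment design; the remaining constant sequence is
arbitrary but fixed), since only the geometry — not the base identity —
matters to extraction.

## Problem sizes and test design

The test suite simulates at depths chosen to make the statistics sharp
but the run fast: 2x10^4–10^5 reads per sample for pipeline recovery,
20 seeds for the multi-seed recovery and false-positive properties
(count-level simulation, the same multinomial draw the FASTQ writer
consumes), 40 seeds for the uniformity chi-square property, and 100 noisy
draws for estimator quality. Oracles are independent implementations: a
position-by-position scanner for extraction, a 200x200 grid search for
the fit objective, and closed forms for everything with one.

## Limitations

* The Gaussian null on pooled non-targeting log2FC is a modeling choice;
  with very few control samples its tail quantile at 0.999999 leans
  heavily on normality. The empirical threshold is the robust fallback.
* Only single-exponential kinetics are supported — no biphasic fits, no
  global fitting across magnesium concentrations.
* PAM length is configurable but the statistics assume the full 4^L
  space is enumerable; L beyond ~8 is impractical.
* Extraction requires exact anchor matches; heavily error-laden reads
  will simply drop out (visible as matched/total in the run log).
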