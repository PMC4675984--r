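---
title: "Models and methods behind bruuv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bruuv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bruuv)
```

`bruuv` analyses nascent-RNA sequencing from cells briefly irradiated
with UVC light before metabolic labeling. UVC introduces
transcription-blocking lesions (CPDs and 6-4 photoproducts) essentially
uniformly, at about 1 per 100 kb of transcribed strand per J/m².
Polymerases stall at lesions while initiation continues, so read density
is redistributed toward 5′ ends; transcripts held by stalled polymerases
are also protected from 3′→5′ exosome decay, which enriches labile
species such as eRNA. This vignette documents the statistical models, the
tunable parameters, the simulator, and the numerical and design choices.

## Coordinates and containers

All coordinates are 0-based half-open internally; GTF (1-based closed) is
converted on read, BED is native. A strand-aware TSS is `start` on `+`
and `end − 1` on `−`, and "upstream" is always strand-relative. Binned
coverage is a dense tibble of fixed-width bins (`bruuv_track`); bin *i*
covers `[i·w, (i+1)·w)`. Reads contribute to bins by overlapped fraction
(a 52-bp read straddling a border splits proportionally), conserving read
mass; a `five_prime` mode assigns whole reads to the bin holding the
strand-aware 5′ end, for cap-anchored assays where only that base is
informative. RPKM over an interval is overlapping read mass divided by
(interval kb × library millions), with partial bins pro-rated — exact for
bin-aligned intervals, a uniform-within-bin approximation otherwise.

## TSS merging

Isoforms of a gene with identical TSSs collapse to one entry; TSSs closer
than 1 kb (`merge_distance`, strict inequality so starts exactly 1 kb
apart stay distinct — the caller's resolution is "1 kb or more")
are clustered by single linkage and represented by the most upstream
member. Single linkage means chains merge: TSSs at 0, 900 and 1800 bp
form one entry. The operation is idempotent, and merged entries within a
gene are numbered in genomic order (`<gene>.<k>`).

## The TSS activity model

For each merged entry the signal in `bin_width` = 250 bp bins spanning
`upstream_bp` = `downstream_bp` = 5000 bp around the TSS is extracted,
oriented 5′→3′. Rows are quantile-normalized **across windows** — the
hidden-state emissions must be comparable between genes, and the
reference is the per-rank mean of row-sorted values, with ties given the
mean of the reference values they span — and then passed row-wise through
a *gamma-equivalent z-score*: a gamma distribution is fitted by the
method of moments (shape m²/v, scale v/m, after adding a pseudocount of
half the smallest positive value so zeros sit on the support), and each
value is mapped through the fitted CDF to a standard-normal quantile,
with the CDF clamped to [10⁻⁶, 1−10⁻⁶]. The transform is strictly
monotone away from the clamp and, because the moment fit rescales with
the data, invariant to uniform positive scaling. The phrase
"gamma-equivalent z-score" admits more than one reading; the
probability-integral transform through a fitted gamma is the simplest,
and a plain z-score is available via `gamma_mode = "plain_z"`.

The hidden chain has two states — state 1 before the TSS (low signal),
state 2 after (high) — with the *only* allowed transition 1→2 at
probability `p_transition` = 10⁻⁵ per step. Design choices the model
statement leaves open, fixed here for determinism:

* the chain starts in state 1 with probability 1 (a pre-TSS state must
  precede a TSS), but a path may switch before the first emission, so all
  n + 1 monotone paths compete;
* state 2 is absorbing (`log P(stay) = 0`); staying in state 1 costs
  `log(1 − p)`;
* emissions are Gaussian on the normalized signal, with mean/sd taken
  from each window's own training flanks — 5–2 kb upstream for state 1,
  2–5 kb downstream for state 2 (bins fully inside the range); a pooled
  mode (`pooled_emissions`) trains one pair across all windows instead;
* standard deviations are floored at `sd_floor` = 0.1 normalized units so
  constant flanks cannot produce degenerate likelihood spikes;
* exact ties between switch positions break toward the most upstream
  switch.

Viterbi decoding reduces to a closed-form scan over the n + 1 monotone
paths (the tests verify it against explicit enumeration). A TSS is
**active** when the first state-2 bin *starts* within
`activity_window_bp` = 500 bp of the TSS — the bin start, not midpoint,
is used, which is one of the rule's possible readings and is flagged as
such. All-zero windows are reported inactive rather than erroring. The
`grocap` preset changes only configuration (±500 bp windows, 50-bp bins,
training flanks −500..−100 and 0..+500 bp) for narrow 5′-cap peaks; the
code path is identical.

Because quantile normalization pools ranks across windows, the caller is
meant to run on a genome-wide annotation; with only a handful of windows
the rank-mean reference is degenerate and calls at the resolution limit
become noise-sensitive. The resolution measurement in the acceptance
script therefore always includes a background population of ordinary
single-TSS genes (60 by default) alongside the probe pair, and takes the
majority call over 15 replicate noise realizations per separation.

## The UV-enhancement model

Paired mock/UV tracks are smoothed per chromosome with a Daubechies-4
wavelet (soft universal threshold σ√(2 ln n), σ from the MAD of the
finest detail coefficients; smoothing precedes depth scaling, following
the stated order of operations), then scaled to common depth by
`min(totals)/own total`, so the baseline probability that a read is from
the UV sample is 0.5 by construction. Each bin's reads are Bernoulli
trials for "UV origin"; the observable is `f_UV = uv/(uv + mock)` on
scaled counts, with scaled counts rounded half-up to integer trial counts
for the emission model (the source material does not say how fractional
normalized counts were handled; rounding keeps the trials interpretable).
Bins with zero trials carry no information: their log-emission is 0 in
both states, the Viterbi state coasts across them on the self-transition
prior, and they are excluded from reported peaks.

The UV-repressed (UVR) state is trained on genes with mock RPKM ≥
`rpkm_min` = 0.25 and length > `tss_exclusion_bp` = 20 kb: for each such
gene the bins fully inside the gene and more than 20 kb downstream of the
TSS are pooled into a cumulative fraction `sum(uv)/sum(uv + mock)`
("cumulative … of each gene" is read as pooling a gene's bins; a
per-bin-mean alternative sits behind `training = "per_bin_mean"`). The
mean and variance of these per-gene fractions moment-match a beta
distribution (`c = m(1−m)/v − 1`, `α = mc`, `β = (1−m)c`; the variance
must sit strictly between 0 and the Bernoulli bound `m(1−m)`), giving a
beta-binomial emission for UVR; genes whose pooled fraction is exactly 0
or 1 carry no usable overdispersion information and are dropped with a
warning. The UV-enhanced (UVE) state is the UVR beta *reflected* about
1/2 — shapes swapped, so `logpmf(k, n, reflect(p)) = logpmf(n−k, n, p)`
exactly. Decoding uses a symmetric two-state Viterbi with transition
probability `p_transition` = 0.005 and uniform initial distribution (the
model statement fixes only the transition probability; symmetry and the
uniform start are the neutral completions). Maximal runs of UVE-state
bins with data become peaks, annotated with mean f_UV and RPKM in both
scaled tracks; peaks overlapping any gene or supplied transcription-unit
interval by ≥ 1 bp are non-intergenic. Gene annotations enter only
through training, so peaks can be found anywhere.

Segmentation runs on strand-combined tracks by default — eRNA is
bidirectional, so the pooled signal is the relevant quantity — and the
wavelet family/threshold (db4, universal soft, reflective padding to a
periodic transform length) are fixed in code for reproducibility since
the method statement names none.

## Descriptive analyses

* **Aggregate profiles**: genes ≥ 60 kb (the accompanying figure legend
  says 50 kb; both are one argument away) and ≥ 1 RPKM in the reference
  (mock) sample, aligned at the TSS; the per-offset value is the median
  across genes of per-bin RPKM, optionally divided bin-wise by the
  reference profile (the reference against itself is the unit profile).
* **Heat maps**: same filters, 1-kb bins from −2 kb to +60 kb, each row
  min-max scaled to [0, 1] (constant rows → 0), rows sorted by descending
  scaled signal over the first 5 kb.
* **First-5-kb fold change**: RPKM over the strand-aware first 5 kb per
  sample, `fold = (b + c)/(a + c)` with pseudocount `c` = 0.25 RPKM to
  stabilize low-expression ratios (our choice; the fold is exactly
  antisymmetric under swapping samples). Genes shorter than 5 kb fall
  back to full length and are flagged; a whole-gene mode serves the
  non-UV side of a comparison.
* **Nearest gene**: peak midpoint to gene TSS distance, strand-agnostic —
  the TSS, not the gene-body edge, because promoter–enhancer pairing is
  the claim being summarized; ties go to the lexicographically smaller
  id. Changes are correlated with plain Pearson on log2 fold changes.
* **Downsampling CV**: multivariate hypergeometric subsampling (without
  replacement, including an unassigned-read category) at each requested
  depth, 10 replicates; per-gene CV = sd/mean of RPKM across replicates.
  The coefficient of variation is sd/mean — the conventional definition —
  even though the source text inverts the phrase once. At full depth
  every draw is the library itself and the CV is exactly 0.

## The simulator

`sim_genome()` lays out non-overlapping genes (default 60; lengths
uniform 20–120 kb, gaps 30–80 kb, alternating strands, log-normal
expression weights with sdlog 0.5) with enhancers at gap midpoints —
intergenic by construction. `simulate_paired_tracks()` gives expected
genic density `e_g · exp(−λx)` at strand offset *x*, the survival of a
polymerase past Poisson lesions of intensity λ = rate × dose
(rate 10⁻⁵/bp/J, i.e. 1 per 100 kb per J/m²), integrated in closed form
per bin; the mock sample uses dose 0. This marginalizes lesion placement
analytically; an `explicit` mode instead conditions on one drawn lesion
set per gene (reads uniform up to the first lesion), whose expectation
equals the survival form — kept for validation, the marginal form for
speed. Enhancers add symmetric triangular kernels of half-width 1 kb
(matching the visual width scale of enhancer-anchored aggregate signal,
not an asserted value), with amplitude `base_amp` = 0.5 in mock —
eRNA is weakly captured without UV — and `base_amp × s` under UV, default
stabilization `s` = 5; no quantitative stabilization factor is stated
anywhere, so `s` is a free parameter, and it acts only at positive dose
because protection requires stalled polymerases. Reads are drawn
multinomially to the requested depth (default 10⁶ per track at 250-bp
bins), so track totals are exact and depth-scaling tests are sharp. The
truth object records lesions, TSSs, and enhancer element intervals
(center ± 500 bp — the element proper; the kernel is the wider RNA
spread). `simulate_tss_step_track()` builds the canonical caller test
signal: Poisson background (default 20 counts/bin) plus `effect_sd` = 5
baseline-standard-deviations of extra intensity downstream of each
active TSS.

What the simulator does *not* emulate: mappability and GC structure,
replicate-level biological variance, PROMPT-like divergent promoter
transcription (available but off by default in spirit — no divergent
kernel is placed), UV-induced changes of initiation itself, and
transcription-coupled repair kinetics. Passing tests therefore show the
callers recover the modelled redistribution and stabilization structure,
not that they are robust to every artefact of real libraries.

## Numerical choices and degenerate inputs

* Wavelet transform: orthogonal periodic pyramid with the 8-tap
  Daubechies-4 filters; inputs are reflect-padded to a multiple of
  2^level (level = min(4, ⌊log2 n⌋) by default) and truncated after
  reconstruction; results are clamped at 0. Perfect reconstruction is
  exact to machine precision (tested).
* Beta-binomial pmf via log-gamma (`lchoose + lbeta`), `n = 0 → log 1`.
* Rounding of scaled counts is half-up, not banker's.
* Zero-variance windows abort the gamma transform with a clear error;
  the TSS pipeline catches all-zero windows and reports them inactive.
* Empty training sets (no qualifying gene) abort UVE training with
  "cannot train UVR state" rather than guessing parameters.
* RPKM requires positive library totals; zero-total tracks error.

## Problem sizes

The shipped tests and the acceptance script run entirely on simulated
data sized for a desk machine: single chromosomes of a few Mb, 40–200
gene windows per caller run, 10⁵–10⁶ reads per track, 150–200 seeded
replicates for Poisson-process statistics, and exhaustive HMM-path
enumeration up to length 16. These sizes were chosen so every check
re-runs in minutes while keeping Monte-Carlo standard errors well inside
the asserted tolerances.

## Known limitations

* The monotone two-state caller sees exactly one switch per window, so
  when two active TSSs closer than ~2 kb share a window, the elevated
  plateau between them belongs to whichever state is nearer in z-space
  and the switch position at the second TSS is noise-sensitive; this is
  intrinsic to the model, and it is why the resolution quantity is
  measured as a majority over replicates.
* Quantile normalization assumes many windows; do not run the TSS caller
  on a handful of genes.
* The beta fit needs at least 3 training genes with informative pooled
  fractions; sparse annotations or very high doses (deep bodies entirely
  empty) degrade it.
* bedGraph import treats record scores as read mass spread uniformly
  over the record; tracks written by other tools at other resolutions
  are re-binned under that assumption.
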