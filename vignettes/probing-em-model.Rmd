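---
title: "The drop-off model behind dropem: counting, reactivity and the two-channel Poisson EM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The drop-off model behind dropem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dropem)
```

## The measurement

Chemical structure probing marks flexible or single-stranded nucleotides of
an RNA with an adduct (SHAPE reagents such as 1M7/NAI on the 2'-OH of any
base; DMS on N1 of adenosine and N3 of cytosine). Reverse transcriptase
falls off the template one nucleotide 3' of the adduct, so when randomly
primed cDNA is paired-end sequenced, the 5' end of read 1 records where RT
stopped and the mate records where the primer annealed. For each
nucleotide `x` we count the reads stopping there (`d_x`) and the reads
covering it (`n_x`), and define the RT drop-off rate as `d_x / n_x`.

Two matched libraries — the *channels* — are made per sample: one from
chemically treated RNA, one from solvent-only control RNA. The control
captures everything that makes RT stop anyway: natural base modifications,
strong secondary structure, sequence-dependent pausing.

### Coordinate and counting conventions

`count_stops()` uses 1-based, closed transcript coordinates. The drop-off
event of a fragment whose read-1 5' end aligns at position `q` is booked at
`p = q - 1` (the adduct position); the offset is a parameter so the
`p = q` dialect used by some pipelines can be reproduced. A fragment
contributes coverage at every position from its stop `p` through its
priming-site end, inclusive: that is the set of template positions the
polymerase actually traversed, and the most direct reading of "reads
covering that nucleotide" for paired-end data. Antisense fragments are
discarded (and tallied), as are secondary, supplementary and duplicate
alignments and mapping quality below 10 — defaults chosen as ordinary
short-read hygiene, all exposed as arguments. An optional 3'-end exclusion
window (default 0) suppresses stops that cannot be distinguished from
random-priming artifacts; every read-1 5' end is otherwise treated as a
drop-off event, including reads truncated by sequencing length, which at
typical fragment sizes are a small, channel-symmetric contamination that
the control channel absorbs.

## Reactivity

`reactivity()` computes, at each position with at least `min_coverage`
(default 20) reads in both channels,

```
raw[x] = max(0, ln(r_T[x] + eps) - ln(r_C[x] + eps)),   eps = 1e-4
```

where `r_T`, `r_C` are the channel drop-off rates. The log-difference is
the default transform in the structure-seq family of pipelines; a plain
rate difference is available via `transform = "raw"`. The pseudocount
`eps` keeps zero rates finite and is recorded in output headers. Profiles
are then 2–8% normalized — the profile is divided by the mean of the
values between the 2nd and 8th percentile from the top, after discarding
the top 2% as outliers — so that a typical highly reactive nucleotide
scores about 1, and finally capped (default 3) so a handful of extreme
sites cannot dominate downstream color scales. Positions failing the
coverage floor are excluded from the normalization reference set and
reported as missing, never as zero. A profile that is zero everywhere
(e.g. treated identical to control) has no usable normalization reference
and raises an error rather than returning a silently rescaled vector.

## The two-channel Poisson mixture

A reactivity value does not say whether a treated-channel excess is
statistically surprising given the local coverage. The caller models the
counts directly. Both channels are assumed to mix two RNA-wide per-read
drop-off regimes, a background rate `lambda_low` and a strong-stop rate
`lambda_high`, approximately constant along the molecule. Each nucleotide
belongs to one of three classes, distinguished by which regime each
channel sees:

| class | treated | control | meaning |
|-------|---------|---------|---------|
| U | `lambda_low` | `lambda_low` | unmodified background |
| H | `lambda_high` | `lambda_high` | natural strong stop (not caused by the chemical) |
| M | `lambda_high` | `lambda_low` | chemically modified |

Counts are Poisson with coverage as exposure:
`d ~ Poisson(lambda * n)`, independently across channels given the class.
The fourth conceivable combination (low treated, high control) is
deliberately absent — nothing in the experiment generates it, and
positions resembling it are absorbed by U/H. With mixture weights
`pi = (pi_U, pi_H, pi_M)` the per-position likelihood is the three-term
mixture, and `tcpem_fit()` maximizes the total log-likelihood by EM:

* **E-step** (`tcpem_e_step`): class posteriors
  `gamma_x(k) \propto pi_k Pois(d_x^T; lambda_k^T n_x^T) Pois(d_x^C; lambda_k^C n_x^C)`,
  computed entirely in log space (log-gamma Poisson terms, log-sum-exp
  normalization), so large counts cannot overflow.
* **M-step** (`tcpem_m_step`): weights are posterior means; the rates are
  closed-form weighted ratios — `lambda_low` pools U-class counts from
  both channels with M-class control counts over the matching
  posterior-weighted coverage, `lambda_high` pools H-class counts from
  both channels with M-class treated counts. If the ordering
  `lambda_high >= lambda_low` is violated the rates are swapped and the
  U/H weights relabelled, which also makes the fit invariant to
  initializing with the two rates interchanged.

Positions with zero coverage in either channel carry no information about
the channel contrast; they are excluded from fitting and reported as
*uncalled* (missing), never as unmodified. A class whose posterior mass
vanishes keeps its previous rate and has its weight floored at `1e-12`
rather than producing a 0/0.

### Initialization, convergence, determinism

Initialization is deterministic: `lambda_low` and `lambda_high` start at
the 25th and 99th percentile of the pooled per-position drop-off rates
(floored at `1e-6`), weights at `(0.90, 0.05, 0.05)`. EM stops when the
relative log-likelihood change drops below `tol` (default `1e-8`) or after
`max_iter` (default 1000) iterations. The log-likelihood trace is stored;
a decrease beyond a `1e-8` relative slack is treated as an internal error
and aborts, because exact EM can never decrease the objective — silent
tolerance of a falling trace would hide implementation faults. No random
restarts are used by default: on simulated data matching the model the
likelihood surface has not shown multimodality that the quantile
initialization fails to escape.

Class weights are estimated by default; `fix_weights = TRUE` keeps them at
their initial values for users who prefer a fixed prior over classes.

### Calling

`call_modified()` declares a nucleotide modified when its M-class
posterior is **strictly** greater than the threshold (default 0.90) — a
posterior of exactly 0.90 is not called. Thresholding `1 - P(U)` instead
of `P(M)` is available via the `statistic` argument for users who want
"anything but background"; the default contrasts modified specifically
against both background and natural stops.

## The simulator

`simulate_pair()` draws directly from the generative model above: i.i.d.
class labels with `P(M)` set so the expected number of modified positions
is `round(L * mod_density)` and `P(H) = frac_high_both`; per-position,
per-channel coverage from a negative binomial (default mean 500,
dispersion 5 — the conventional overdispersed model of sequencing depth),
or fixed coverage; Poisson stop counts given class and coverage. The
default modification density is 1/150, the middle of the 1-per-100–300
nucleotide adduct density that probing reactions are titrated to; the
default rates `lambda_low = 0.002`, `lambda_high = 0.02` put roughly 1
background stop and 10 strong stops per 500x-covered position, a
realistic contrast for deeply sequenced rRNA libraries. `mod_bases`
restricts modified positions to specific bases (e.g. `c("A", "C")` for a
DMS-like probe). A single scenario seed drives every draw through fixed
per-stage sub-seeds, so output is bit-reproducible.

`simulate_alignments()` materializes a simulated pair as plain-text SAM:
each stop becomes a properly paired fragment whose read-1 5' end sits one
nucleotide 3' of the stop and whose mate marks the priming site, with
fragment lengths from a truncated normal (default 150 ± 30 nt). Because
fragment-span coverage is determined by the drawn fragment lengths, the
function returns an updated truth whose coverage is recomputed from the
emitted fragments (and whose stops at the final position, which cannot be
encoded as an alignment, are dropped); `count_stops()` on the SAM output
reproduces that truth bit-exactly, which is the round-trip identity the
test suite asserts.

### What the simulator does and does not emulate

It reproduces the statistical skeleton the caller assumes: constant
high/low rates, channel symmetry at U and H positions, overdispersed
coverage, realistic modification density. It deliberately omits
position-specific background variation (real RT pausing has a continuum of
propensities shared between replicates, not two discrete regimes),
3'-coverage decay from RT processivity (available as nothing — probing
samples are selected for little decay over ~200 nt, so the default is
flat coverage), sequencing and alignment errors, and base-composition
effects on background. Consequently, passing tests demonstrate
correctness of the algorithms under their own model, and recovery/error
rates on data of matched structure — not performance on real libraries,
where the constant-background assumption is only approximate. One visible
consequence: replicate drop-off-rate correlations on simulated data are
moderate, because background positions are pure Poisson noise with no
shared propensity, whereas real replicates share sequence-driven pausing
and correlate highly.

## Comparing samples

A position differs between two samples when it is called at the 0.90
posterior threshold in one and not the other; no second-stage test is
layered on top, keeping "statistically significant difference" anchored in
the per-sample posteriors. `compare_calls()` partitions positions into
`both / a_only / b_only / neither / undefined`, where `undefined` marks
positions lacking data in either sample — reported separately from
`neither` so absence of evidence is not read as evidence of no
modification. Per-region aggregation over user-supplied annotations
(native 1-based closed TSV, or BED with the 0-based half-open conversion
done explicitly at import) and an optional per-region Fisher exact
contrast are provided as diagnostics only.

## Worked example

```{r example}
scn <- simulation_scenario(length = 3000, mod_density = 1 / 150,
                           lambda_low = 0.002, lambda_high = 0.02,
                           seed = 42)
truth <- simulate_pair(scn)
fit <- tcpem_fit(truth$pair)
fit

calls <- call_modified(fit, threshold = 0.90)
table(truth = truth$class_labels, called = calls$called)

prof <- reactivity(truth$pair)
summary(prof$reactivity[prof$defined])
```

## Problem sizes and numerical choices

The shipped tests and the acceptance script use transcripts of 500–5000 nt
at coverages of 50–10000, 10–20 seeds per scenario — sizes at which EM
converges in well under a second per fit and every stochastic check is
stable across reruns. Tolerances: posterior rows sum to 1 within `1e-9`;
enumeration oracles are matched to `1e-10` relative; the EM trace is
monotone within `1e-8` relative slack. Ties at the calling threshold are
resolved by the strict inequality. Degenerate inputs (all-zero profiles,
empty tracks, vanishing classes, zero-coverage positions) raise errors or
are masked as missing, as described above, rather than propagating NaN.

## Limitations

Point-estimate EM only — no posterior uncertainty on the rates; no
positional smoothing (each nucleotide is classified independently); no
per-base priors; single-transcript analysis (run transcripts
independently); no mutation-signal (MaP) extraction; and calling power
degrades gracefully but substantially below ~200x coverage, as the
coverage-sensitivity sweep in the test suite quantifies.
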