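---
title: "Task-transfer CSP for motor-imagery EEG: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Task-transfer CSP for motor-imagery EEG: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transfercsp)
```

## The problem

A motor-imagery brain-computer interface (MI-BCI) decodes which movement a
user is imagining from sensorimotor-rhythm EEG. Imagining a limb movement
desynchronizes the mu (8–12 Hz) and beta (13–30 Hz) rhythms over the
contralateral sensorimotor cortex (event-related desynchronization, ERD)
and often synchronizes them ipsilaterally (ERS). Classical decoders need
tens of calibration trials per command; every *new* command therefore
costs the user another long recording session. One way to enlarge the
command set cheaply is to use *combinations* of already-trained commands
(left hand + feet, right hand + feet, both hands) and to reuse the data
recorded for the single-limb commands: the scalp projections of the
underlying sources are largely shared, so spatial filters learned on the
old tasks transfer to the combined tasks. This package implements that
transfer scheme end to end, together with the baselines it is judged
against and a synthetic generator that stands in for real recordings.

## Common spatial patterns

For a two-class problem, a single-trial recording is a matrix $X \in
\mathbb{R}^{N\times G}$ ($N$ channels, $G$ samples). The class-average
normalized covariance is

$$R_c=\frac{1}{K}\sum_{i=1}^{K}\frac{X_c^i {X_c^i}^{\!\top}}
{\operatorname{trace}(X_c^i {X_c^i}^{\!\top})},$$

where the per-trial trace normalization removes global amplitude
differences between trials. With $R = R_1 + R_2 = U\Lambda U^{\top}$, the
whitening transform $P=\Lambda^{-1/2}U^{\top}$ gives $PRP^{\top}=I$; the
whitened class-1 covariance $S_1 = PR_1P^{\top} = B\Lambda_1 B^{\top}$ and
its complement satisfy $\Lambda_1+\Lambda_2=I$, so the orthonormal $B$
simultaneously diagonalizes both classes. The filter bank is
$W = B^{\top}P$, rows sorted by decreasing $\lambda$: the first rows pass
class-1 variance and suppress class 2, the last rows the reverse. The
*pattern* paired with filter $j$ — the physiologically interpretable scalp
projection — is column $j$ of $W^{-1}$.

On the whitening exponent: writing the transform with $\Lambda^{-1}$
instead of $\Lambda^{-1/2}$ breaks both $PRP^{\top}=I$ and
$\Lambda_1+\Lambda_2=I$; only the square-root form makes the
construction consistent, and that is what `csp_filters()` implements.
Both identities are verified to $10^{-8}$ in the test suite over random
symmetric positive definite pairs.

`csp_filters()` retains **all** $N$ rows. Reduction to the few filters
actually used happens later — in `select_transfer_filters()` for the
transfer path, or by taking the $m$ first and last rows in the plain CSP
baseline — because the transfer step needs the full bank to choose from.

## Fisher-ratio transfer

Filters built from the source task are not all useful for the target
task. Each target training trial is projected through the full source
bank ($Z = WX$) and summarized by normalized log-variance features

$$f_p=\log\!\frac{\operatorname{var}_p}{\sum_{q=1}^{2m}\operatorname{var}_q},$$

the same transform the classifier uses, so that screening and inference
see the same feature space. Each feature dimension (each filter) is
scored with the Fisher ratio

$$J^k=\frac{S^k_{between}}{S^k_{within}},\qquad
S^k_{between}=\sum_i \frac{n_i}{n}(m_i^k-m^k)^2,\qquad
S^k_{within}=\frac{1}{n}\sum_i\sum_{x\in\omega_i}(x^k-m_i^k)^2 .$$

The bank is split into its high-eigenvalue and low-eigenvalue halves and
the `k_per_group` best-scoring filters are kept *from each half*
(default 2, i.e. four transferred filters). Balanced selection preserves
the CSP symmetry — each class keeps filters tuned to it. An unbalanced
"overall top-$2k$" variant exists (`mode = "overall"`) because the
balanced and unbalanced readings of the selection rule are both
defensible; the balanced one is the default as the more specific
prescription. Ties in $J$ are broken toward eigenvalue extremity
$|\lambda - 0.5|$, i.e. toward source-domain discriminability, then by
bank order, making selection fully deterministic. In an odd-sized bank
the middle filter ($\lambda$ nearest 0.5) belongs to neither group and is
never selected.

When source and target coincide and `k_per_group = m`, selection returns
the $m$ first and last filters and the pipeline reduces exactly to the
plain CSP baseline — transfer CSP is a strict generalization, and the
test suite asserts identical predictions in that case.

## Classification

Features are z-scored by training statistics (log-variance features have
very unequal scales across filters; the RBF kernel is not affine
invariant — the original formulation is silent on this, and without it
small-sample tuning is unstable). An RBF-kernel SVM is tuned by
stratified 5-fold cross-validation over $C\in\{10^{-1},\dots,10^{3}\}$
and kernel width $\gamma\in\{10^{-2},\dots,10^{2}\}/d$ (5 × 5
logarithmic grid, $d$ = feature dimension), then refit on all training
data. With 2–4 trials per class tuning degrades to leave-one-out with a
warning; a singleton class is an error. Fold assignment derives from an
explicit seed, so fits are reproducible.

## Evaluation protocol

`inverted_cv()` implements the scarce-calibration protocol: the target
session is split into 12 stratified folds and the model is trained on a
*single* fold — 5 trials per class for a 60-per-class session — and
tested on the other 11/12; the split is reshuffled 5 times, giving 60
accuracy values per method. Stratification is adopted (it is what makes
"5 per class per fold" exact); fold shuffling is seeded per repetition.
If the per-class counts do not divide the requested fold count, the
nearest divisor is used with a warning rather than unbalanced folds.

Three methods run on identical splits: `transfer_csp`, the `csp`
baseline (filters re-estimated from each tiny training fold), and the
`psd` baseline (Welch log band power 8–30 Hz at C3, Cz, C4 plus their
mean — four features and no spatial filtering). Welch uses 1 s Hann
segments at 50% overlap; band powers are rectangle-rule integrals of the
one-sided density. The default analysis window for covariances and
features is the post-cue segment $[0, 2)$ s: trials are epoched from
−0.5 s to keep the baseline interval available, but pre-cue samples
carry no task signal and are excluded from covariance estimation (the
epoching convention leaves this open; the choice is configurable via
`window=`).

## The synthetic generator

Real MI recordings of this kind are not redistributable, so
`simulate_session()` plants known structure instead: instantaneous
linear mixing — CSP's own generative assumption, which is what makes
recovery tests meaningful. Three band-limited (8–30 Hz) unit-variance
Gaussian sources project through fixed Gaussian-bump scalp columns
peaking near C3, C4 and Cz. From the cue onward a class scales its
sources' band variance: left-hand imagery takes the C4 source to
$1-d$ and the C3 source to $1+d$ (depth $d$ = `erd_depth`), mirrored for
the right hand; feet imagery takes Cz to $1-d$; combined commands
multiply their components' factors elementwise — the mechanism that
makes single-task filters transferable. The pre-cue half second is
always unmodulated. The background is one 1/f source per channel, each
projecting as a Gaussian bump at a random scalp location (spatially
smooth and full rank, a crude stand-in for distributed cortical activity
under volume conduction), plus 1 µV white sensor noise, with a mean
background RMS of 10 µV. `snr_db` fixes, per task source, the 8–30 Hz
power ratio of source over background *at that source's peak channel* in
the unmodulated state — a deliberately conservative definition, since
spatial filtering can pool the source's energy across channels. An
optional frontal < 4 Hz component emulates ocular artifacts
(`eog_amplitude`, off by default: the ICA cleaning step used on real
data is out of scope, so fixtures are generated artifact-free). One
session seed expands into per-(class, trial) substreams, so a trial's
content depends only on its class and index, not on the order classes
are listed.

Defaults are a 64-channel, 500 Hz montage, 2.5 s trials (−0.5 to 2 s
around the cue), 60 trials per class — a typical laboratory session.
Per-class effect sizes have no published reference values; the defaults
`snr_db = 10`, `erd_depth = 0.6` were fixed once to give clearly planted
but not noiseless structure, before any downstream results were
inspected at those values.

What the generator does **not** emulate matters for interpreting green
tests: sessions are stationary (no drift, no fatigue), artifact-free by
default, exactly band-limited, and Gaussian. On such data a covariance
estimated from even 5 trials × 1000 samples per class is already decent,
so the small-sample breakdown of plain CSP — the regime where transfer
helps most on real recordings, where low-quality sessions gain upwards
of ten accuracy points — is strongly attenuated here: at moderate SNR
both spatial methods sit near ceiling and the plain CSP baseline can
edge out the transfer pipeline by a point or two. Passing recovery and
ordering tests on this generator therefore demonstrates correctness of
the machinery, not the real-data advantage of transfer over
re-estimation.

## Numerical choices

* **Shrinkage**: class covariances enter `csp_filters()` as
  $(1-\gamma)R_c+\gamma\,\frac{\operatorname{tr}R_c}{N}I$ with
  $\gamma=10^{-6}$; if the composite covariance is still numerically
  singular, $\gamma$ is raised a hundredfold at a time (to at most
  $10^{-2}$, with warnings) before giving up with the condition number.
* **Sign convention**: each filter row is scaled so its
  largest-magnitude coefficient is positive; eigenvector signs are
  otherwise arbitrary and would make results flip between runs.
* **Equal eigenvalues** keep the LAPACK output order (stable,
  deterministic).
* **Windows are half-open**: an epoch $[t_{min}, t_{max})$ at rate $f_s$
  has exactly $(t_{max}-t_{min})f_s$ samples; the 12 folds of the
  protocol then train on exactly 5 trials per class.
* **Variance** in the feature transform is the population ($1/G$)
  variance about the row mean.
* **Band-pass**: 4th-order Butterworth, 8–30 Hz, applied
  forward–backward (zero phase) so the baseline window is not delayed;
  verified to pass 15 Hz within 1 dB and attenuate 2 Hz and 50–60 Hz by
  over 20 dB.
* **Bad-channel interpolation** averages the 4 nearest good neighbours
  from montage geometry by default; the neighbourhood map is overridable
  since "surrounding channels" is montage-specific.
* **Re-referencing** from left mastoid to linked mastoids is the exact
  algebra $x \mapsto x-\tfrac{1}{2}\mathrm{RM}$ and is deliberately
  guarded against double application via the record's reference field.
* **EDF export** quantizes to 16 bits per channel range; round trips are
  exact to about $3\times10^{-5}$ of the per-channel amplitude, and the
  true (non-record-aligned) sample count is preserved in the header's
  recording-identification field.

## Problem sizes used by the test suite

Unit tests run on 16-channel, 250 Hz sessions with 12 trials per class —
small enough to iterate quickly, large enough for planted structure to
dominate sampling noise. The end-to-end checks use one full-size session
(64 channels, 500 Hz, 60 trials per class) for recovery and protocol
arithmetic, ten such sessions at `snr_db = 0, erd_depth = 0.5` (three
protocol repetitions each) for the method-ordering comparison, and one
unmodulated session for the chance-level control with a 99% binomial
interval over the 120 distinct target trials. These sizes are the
package's chosen operating points for its own validation; the generator
makes larger studies a one-line change.

## Known limitations

* Binary tasks only (pairwise decoding, as in the underlying scheme);
  multiclass use means one-vs-one orchestration by the caller.
* No ICA/EOG cleaning and no trial screening: real recordings must be
  cleaned upstream.
* The montage is schematic (unit-disc rings): adequate for neighbour
  maps and lateralization plots, not for source localization.
* The generator's stationarity means transfer-vs-CSP comparisons on
  synthetic data understate the transfer method's real-data advantage
  (see above).
* `eog_amplitude > 0` contaminates frontal channels but the package
  ships no remover; it exists to exercise robustness, not realism.
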