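---
title: "Deep kernel learning for fingerprint prediction: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep kernel learning for fingerprint prediction: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fpkit)
```

# The problem and the model

An MS/MS spectrum of a small molecule is a list of fragment masses with
intensities. The prediction target is a molecular fingerprint: thousands of
binary labels, each marking the presence of a substructure or property in
the (2D) molecular structure. Because stereoisomers fragment almost
identically, the unit of identity throughout the package is the 2D
structure key, and the cardinal evaluation rule is *structure-disjoint*
splitting: no structure may contribute data to both training and
evaluation (`structure_disjoint_folds()`).

Spectral libraries contain many replicate spectra per structure — in
public libraries the spread runs from a handful to nearly a hundred. Two
preprocessing treatments reflect this. Merged compounds
(`merge_spectra()`) pool all spectra of one structure measured on the same
instrument with the same adduct. Unmerged compounds (`unmerged_records()`)
keep every replicate as its own training example, down-weighted by
$1/\sqrt{\text{count}}$ (`compute_sample_weights()`): the square root
credits repeated measurement with extra information while preventing
heavily re-measured structures from dominating the loss.

## Kernels

The native spectral kernel is the probability product kernel: each
spectrum is a Gaussian mixture over the mass axis with one component per
peak, weight proportional to intensity (normalized to sum 1), and common
bandwidth $\sigma_m$; the kernel is $\int p_a(x)\,p_b(x)\,dx$, which for
mixtures is

$$k(a,b) = \sum_{i,j} w_i w'_j \,
\frac{\exp\!\big(-(m_i - m'_j)^2 / 4\sigma_m^2\big)}{\sqrt{4\pi\sigma_m^2}}.$$

`sigma_m` defaults to 0.01 Da — the scale of high-resolution mass accuracy
at a few hundred Da; it is the one spectral-kernel parameter a user should
revisit for low-resolution data. The compiled Gram evaluator
(`src/ppk.cpp`) skips peak pairs further apart than $12\sigma_m$, a
truncation at machine precision (relative contribution
$\le e^{-36}$); the exported `ppk()` keeps the exact closed form and the
test suite compares the two routes.

Fragmentation-tree kernels — responsible for much of the search
performance of production systems — are deliberately out of scope as
*computations*: they enter as precomputed matrices
(`kernel_spec(type = "precomputed")`, TSV exchange format).
`combine_kernels()` cosine-normalizes each square kernel and forms a
convex combination; weights default to uniform because the alignment-based
weight optimization of the production system is defined in its own right —
a centered-kernel-alignment fitter (`alignment_weights()`) is provided as
an optional strategy, and weights are always user-overridable.

## Nyström embedding

With landmark kernel block $K_{AA} = U \Sigma U^\top$, the projection
$\Gamma = U_r \Sigma_r^{-1/2}$ maps kernel rows against the landmarks to
features $\hat X = K \Gamma$ with $\hat X \hat X^\top \approx K$, exact on
the landmark block. The implicit $K_{AA}^{-1}$ of the textbook derivation
is numerically unsafe for near-singular kernel blocks, so
`fit_projection()` uses pseudo-inverse semantics: eigenpairs with
$\lambda < 10^{-10}\,\lambda_{\max}$ (relative floor, configurable) are
discarded. Eigendecomposition runs on the symmetrized matrix
$(K + K^\top)/2$; asymmetry beyond $10^{-8}$ is an error, not silently
repaired. The landmark set is simply the full merged training compound
list; subsampling is possible but off by default.

## Predictor heads

**Nyström SVM** (`train_nystrom_svm()`): one linear SVM per label on the
embedding, trained jointly by minibatch SGD on the per-compound-weighted
hinge loss plus $(1/C)\lVert w \rVert^2$. Plain SGD with a fixed learning
rate ($10^{-3}$ default) and zero initialization, so `epochs = 0` is the
zero model and a fixed seed reproduces training bit for bit. The standard
hinge (not squared) keeps the head equivalent in kind to the classical
kernel SVM it replaces. $C$ defaults to 1; `tune_svm_C()` implements a
per-label grid $\{0.125, 0.5, 2, 8\}$ (bracketing 1) on an inner
validation split for users who want the nested-selection behaviour —
exercised in the unit tests but off the default path for runtime reasons.
Decision values map to posteriors by per-label Platt scaling
(`fit_platt()`: regularized targets $(N_+ + 1)/(N_+ + 2)$, $1/(N_- + 2)$,
Newton iterations with backtracking). Labels with a single training class
cannot be calibrated and become constant predictors at the smoothed prior
$(N_+ + 1)/(N + 2)$.

**Primal→dual export** (`primal_to_dual()`): multiplying $\Gamma$ with the
learned primal weights gives support-vector coefficients over the
landmarks, so prediction can run exactly like a classical kernel SVM.
"Centering" the coefficient matrix is interpreted as subtracting each
label's column mean; the induced term is carried through the intercept via
the row sum of the kernel vector, and the binding contract is the
invariant: dual decision values equal primal ones within $10^{-6}$.

**Deep kernel** (`train_deep_kernel()`): a multilayer perceptron on the
same embedding. Production defaults, all overridable via
`train_config()`: hidden layers 2500 and 8000 (wider second layer —
enlarging the first was found unhelpful at production scale), ReLU
activations, 50% dropout on hidden activations (inverted dropout; no batch
normalization — dropout alone worked best), $\ell_2$ only on the output
layer with $\lambda = 10^{-7}$, sigmoid outputs with sigmoid
cross-entropy, Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), learning rate
$10^{-3}$, minibatch 200, 25 epochs. Hidden weights use scaled-uniform
fan-in initialization; the output layer starts at zero so an untrained
model predicts 0.5 everywhere. Training consumes randomness only through
the R RNG under the config seed, making runs bit-reproducible.

**Spectrum DNN** (`train_spectrum_dnn()`): the non-kernel baseline. A
spectrum becomes two concatenated sparse bin vectors
(`bin_spectrum_features()`): raw $m/z$ bins and precursor-minus-$m/z$ bins
(which align neutral losses across precursors), bin width 0.005 Da,
values $\sqrt{\text{relative intensity}}$, collisions resolved by maximum
(robust when one fragment splits across bins); plus the molecular formula
vector normalized by per-element training standard deviations
(`formula_feature_vector()`; zero-variance elements are dropped as
uninformative). The exact production feature count additionally depended
on unpublished mass-range trimming, so the binning here is explicitly
configurable (`bin_width`, `max_mass`) and the default axis length is a
choice, not a reproduction.

## Evaluation and database search

Per-label MCC and bookmaker informedness (BM) and per-compound Tanimoto,
with predictions binarized at 0.5 (the production threshold is
unpublished; 0.5 is the canonical choice for calibrated probabilities).
Undefined metric values (a zero confusion-matrix marginal) are a value
state, excluded from means and reported as counts. Labels with fewer than
10 positive *evaluation* examples are pooled into one pseudo-label before
scoring (micro averaging); counting positives on the evaluation side is
deliberate, since that is where the metric becomes unstable. Two all-zero
fingerprints compare as Tanimoto 1 with a warning — identical empty sets;
no real fingerprint is all-zero.

Candidate ranking scores a query's predicted probability vector against
each candidate's binary fingerprint. The default is the per-label
log-likelihood $\sum_i f_i \log p_i + (1-f_i)\log(1-p_i)$ — a diagonal
(independence) approximation of the covariance-aware scoring used in
production, which needs label-covariance estimates this package does not
compute; the scoring slot accepts arbitrary functions as a plugin point.
The probabilistic Tanimoto $\sum p_i f_i / \sum (p_i + f_i - p_i f_i)$ is
provided as the alternative; it uses the full probability vector rather
than thresholding (the literature is ambiguous between the two readings;
the thresholded variant is available through `tanimoto_compound()`).
Probabilities are clamped to $[10^{-4}, 1 - 10^{-4}]$ before any
logarithm. Tie handling is pessimistic: the correct candidate ranks below
every candidate scoring greater than or equal to it, so identification
rates at $k$ (`identification_rate()`) are never flattered by ties.

# The synthetic benchmark: what it does and does not establish

`fixture_config()` / `generate_benchmark()` produce a desk-scale world
with the *statistical* structure the pipeline assumes:

- each label owns `fragments_per_label` (default 3) characteristic
  fragment masses, drawn once per fixture; structures carrying the label
  emit those peaks with probability 0.95 — the generative stand-in for
  substructure-determined fragmentation chemistry;
- label prevalences are drawn from $[0.15, 0.5]$, so labels are common
  enough to be learnable at 300 structures while spanning a realistic
  imbalance range;
- replicate counts follow a truncated geometric with mean 5 (max 100),
  mimicking the heavy-tailed 3-to-85 replicate spread of real libraries;
- replicates are degraded by `simulate_noise()`: 20% peak dropout (never
  the base peak), log-normal intensity jitter (sd 0.3), and noise peaks
  (20% of the peak count) whose masses are drawn from peaks of *other*
  spectra — uniform random masses would be trivially artificial — with
  intensities below the 25th percentile. The upstream noise model's exact
  parameters are unpublished; these defaults were chosen once as
  plausible run-quality degradation and are not tuned;
- candidate sets contain the true fingerprint plus decoys at Hamming
  distance 5 — bit-flip decoys keep cheminformatics out of the test path,
  at the cost of decoys that are not chemically realizable structures.

What a green end-to-end test establishes: the pipeline wiring is correct —
kernels separate structures by shared fragments, the embedding preserves
that geometry, both heads learn label-fragment associations from weighted,
merged or replicate data, and the scorer recovers the true structure. What
it does not establish: performance on real spectra (no fragmentation
chemistry, isotopes, adducts, instrument effects), absolute metric levels
comparable to published full-scale numbers, or the value of
fragmentation-tree kernels (absent here).

The acceptance thresholds on this fixture (deep kernel mean MCC > 0.5,
Nyström SVM > 0.4, top-1 identification rate > 0.6, deep kernel BM above
SVM BM) are fixture-calibrated properties, not reproductions of published
values.

# Scaled-down training configuration

Production hyperparameters assume ~156k training compounds, i.e. hundreds
of SGD updates per epoch. The 300-structure fixture would see two updates
per epoch at minibatch 200, so the fixture runs scale the configuration
rather than the algorithm: minibatch 20, 50 epochs (restoring the update
count to the low thousands), hidden layers 250/800 (one tenth of
production, preserving the narrow-then-wide shape), with dropout rate,
$\lambda$, learning rate and optimizer unchanged. This is a deliberate,
fixed choice made on update-count grounds; the acceptance suite uses it
verbatim.

For the noise-robustness comparison, the "trained with noisy replicates"
model uses *unmerged* replicates with $1/\sqrt{\text{count}}$ weights —
merging first would average the noise away and train on cleaner-than-query
spectra, defeating the comparison; the contrast model trains on one clean
spectrum per structure. Both are evaluated on the same held-out spectra,
clean and noise-degraded. At desk scale the robustness gap between the two
training treatments is real but small (a few thousandths of mean MCC over
a degradation of ~0.1); the test asserts its direction under a fixed seed
and makes no claim about its magnitude.

# Numerical choices and degenerate inputs

- Peak agglomeration during merging: single linkage within 10 ppm on the
  sorted mass axis; merged $m/z$ is the intensity-weighted mean, merged
  intensity the maximum. A $(1 + 10^{-9})$ relative slack keeps
  exactly-at-tolerance pairs on the merge side.
- Spectrum cleanup (`remove_noise_peaks()`): drop below 0.1% relative
  intensity, cap at the 500 most intense peaks; both configurable — the
  referenced cleanup procedure is not fully specified.
- Kernel PSD policy: eigenvalues down to $-10^{-8}\lambda_{\max}$ are
  tolerated as numerical noise; anything worse raises an error rather than
  being clipped silently.
- Eigenvalue ties in `fit_projection()` are broken by solver order; the
  resulting sign/order ambiguity of $\Gamma$ never affects
  $\hat X \hat X^\top$, which is what every contract quantifies over.
- All randomness flows through explicit seeds (`withr::with_seed`), so no
  function disturbs the caller's RNG state.
- Serialization is plain text (TSV for kernels/fingerprints/candidates,
  JSON for projections and configs): no R HDF5 binding is assumed to be
  present, and text artifacts diff cleanly.

# Known limitations

- No fragmentation-tree computation, no fingerprint computation from
  structures, no structure standardization, no mzML reader, no negative
  ion mode: these are input-side concerns of the surrounding ecosystem.
- The dense MLP is plain R matrix arithmetic — adequate for desk scale
  and exactness testing, not for the 28000-landmark production regime.
- The log-likelihood scorer ignores label correlations; production
  covariance scoring is known to behave differently precisely where the
  deep kernel's label-coupling helps.
- Positive-mode, single-adduct assumptions are baked into the fixture
  generator, not into the data model.
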