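---
title: "Methods: descriptor encodings, kernel SVM, and balanced resampling evaluation"
author: "protclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: descriptor encodings, kernel SVM, and balanced resampling evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`protclass` is a toolkit for two-class protein classification from sequence
alone, of the kind used to discriminate insecticide-resistance-associated
proteins (cytochrome P450 detoxification enzymes; the target proteins of
knockdown resistance, dieldrin resistance, and organophosphate/carbamate
insensitivity) from proteins with no such role. It implements:

* five descriptor families — amino acid composition (AAC, 20 features),
  di-peptide composition (DPC, 400), pseudo amino acid composition (PAAC,
  20 + λ), composition–transition–distribution (CTD, 21 per attribute), and
  autocorrelation over physicochemical amino acid indices (ACF, M·n);
* a binary support vector machine with linear, polynomial, RBF and sigmoid
  kernels, trained by solving the dual problem
  max Σαᵢ − ½ ΣΣ αᵢαⱼyᵢyⱼK(xᵢ,xⱼ) s.t. 0 ≤ αᵢ ≤ c, Σαᵢyᵢ = 0
  with sequential minimal optimization, plus Platt sigmoid probability
  calibration;
* the balanced-resampling evaluation protocols used in this literature:
  many balanced sample sets (all positives + an equal-size uniform draw of
  negatives), k-fold cross-validation or leave-one-out within each, and
  aggregation of Sn, Sp, Ac, Pre, MCC and trapezoidal AUC-ROC as mean ± sd;
* a first-order Markov generator of labeled synthetic datasets, so the whole
  pipeline is testable without any external database.

# Descriptor conventions

Feature order is frozen so trained models are portable: residues in
alphabetical one-letter order `ACDEFGHIKLMNPQRSTVWY`; di-peptides in nested
alphabetical order; CTD attribute-then-block (C, T, D); ACF index-major then
lag. Every feature matrix carries a fingerprint (hash of scheme, parameters
and feature names) that a model records at training time and insists on at
prediction time.

**AAC** — residue counts divided by length L; sums to 1. **DPC** — counts of
the L−1 overlapping ordered pairs divided by L−1; sums to 1.

**PAAC** uses Chou's three classical properties (hydrophobicity,
hydrophilicity, side-chain mass), each standardized to zero mean and unit
*population* standard deviation over the 20 residues (denominator 20 —
Chou's convention; the sample-sd alternative would only rescale Θ by a
constant). The tier-j correlation factor is
θⱼ = mean over positions of Θ(Rᵢ, Rᵢ₊ⱼ), with Θ(a,b) the mean squared
difference of the standardized properties. The encoded vector is
(f₁,…,f₂₀, wθ₁,…,wθ_λ) / (1 + w Σθⱼ) with f the *normalized* residue
frequencies, so the vector sums to 1. A "raw count" reading of f would make
the pseudo components vanish as 1/L for long sequences, contrary to the
cited construction, so the normalized convention is used. Defaults: λ = 1,
w = 0.05.

**CTD** uses a seven-attribute Dubchak-style set (hydrophobicity, normalized
van der Waals volume, polarity, polarizability, charge, secondary-structure
propensity, solvent accessibility), each partitioning the residues into
three groups. Per attribute: 3 composition fractions, 3 unordered
adjacent-pair transition frequencies (divided by L−1), and 15 distribution
values — the chain position (1-based, as percent of L) of the first,
25th-, 50th-, 75th-percentile and last occurrence of each group, the
k-percentile index being max(1, ⌈fraction × group count⌉). Groups absent
from a sequence contribute zeros for their five distribution slots.
The source literature prints the dimension formula "L + L(L−1)/2 + 5L" with
L apparently the sequence length, which is dimensionally inconsistent; with
L = number of groups (3) it gives the standard 21 per attribute, which is
what is implemented.

**ACF** standardizes each amino acid index (same population-sd convention)
and records, for lag d = 1..n, the average product of the standardized
profile at positions i and i+d, divided by L−d. Standardization makes both
θⱼ and ACF invariant to affine rescaling of the raw property tables, which
the test suite asserts. Default order n = 1, matching the usable-index count
M = 531 printed for the full collection: the publicly distributed index
collection could not be redistributed here, so the packaged snapshot
(`synthetic_aaindex_snapshot()`) is a clearly-labelled deterministic
synthetic stand-in with the same structure — 544 entries of which 13 carry
missing values and are excluded at load, leaving 531. It exercises the ACF
machinery and its dimension contract; it carries no physicochemical meaning.
`load_aaindex()` reads real AAindex1 flat files when one is available.

Minimum lengths are enforced per scheme (AAC ≥ 1, DPC/CTD ≥ 2,
PAAC ≥ λ+1, ACF ≥ n+1) with scheme-specific errors; the FASTA reader does
not pre-filter by length because the minimum depends on the scheme.

# Classifier

The SMO solver follows Platt's working-set heuristics with a deterministic
scan order (no randomized fallback), a KKT tolerance of 1e−3, and an exact
update for each violating pair. Pairs with non-positive curvature
(η = K₁₁+K₂₂−2K₁₂ ≤ 0) are skipped: exact for the positive-definite kernels,
a safe approximation for the indefinite sigmoid kernel. The intercept is
recovered at the end from the KKT conditions — the mean over free support
vectors, or the midpoint of the feasible interval implied by the bound
multipliers when no free vector exists (the midpoint matters: with heavily
overlapping classes every multiplier can sit at the bound, and an
edge-of-interval intercept skews sensitivity against specificity).

**Kernel scale.** The default γ for the RBF/polynomial/sigmoid kernels is
1/(d · Var(X)) with Var pooled over all entries of the training matrix (the
libsvm/scikit-learn "scale" heuristic), not 1/d. Descriptor vectors are
normalized, so entries live on scale ~1/d and distances shrink accordingly;
with γ = 1/d every RBF kernel value is ≈ 1, the Gram matrix is effectively
constant and the classifier degenerates (observed directly: chance-level
accuracy on data with a planted recoverable signal). γ, r and the degree
remain fully configurable; c defaults to 1 and no silent tuning is done.

**Probabilities.** The decision value f(x) = Σ yᵢαᵢK(x,xᵢ) + b is mapped to
a probability of the positive class by a Platt sigmoid fitted on the
training decision values (robust Newton iteration with the usual
(N₊+1)/(N₊+2) target caps). Two consequences worth knowing: the attainable
probability is capped below 1 by the class counts, and points exactly on the
margin (f = ±1) get less extreme probabilities than points beyond it.
Labels always follow the sign of f (a tie at exactly 0 predicts +1 and is
reported); if the calibrated probability ever disagrees with the sign at the
0.5 threshold the discrepancy is counted and reported, never silently
reconciled.

Models persist to a single versioned JSON file with all doubles written as
C99 hex-float literals, so a reloaded model reproduces decision values
bit-exactly; files from other format versions are refused.

# Evaluation protocol

`balanced_sample_sets()` draws each set as all positives plus an equal-size
uniform draw of negatives without replacement (independently across sets).
`kfold_split()` partitions with sizes differing by at most one; stratified
splitting (the default for balanced sets) keeps the class ratio within one
instance per fold. Encoding happens once per dataset — every descriptor is a
per-sequence map, so no fold information can leak through it — and each
fold is scored by a model trained strictly on the other folds.

Metrics use the standard confusion-count formulas; any metric with a zero
denominator is *undefined* (NA), excluded from aggregation and counted,
because coercing it to 0 would bias means. AUC is the trapezoidal area under
the ROC curve swept over distinct score thresholds (ties grouped), which
equals the Mann–Whitney estimate of P(score₊ > score₋) with ties counted
one half; the tests assert that equality to 1e−9. The headline aggregate is
the mean and sample sd over all fold×set values; mean and sd over per-set
means are reported alongside, since published ± figures are sometimes one
and sometimes the other.

# The synthetic generator and what a green test establishes

Sequences are first-order Markov chains: initial residue from the stationary
weights, successors from a row-stochastic transition matrix; lengths uniform
on [50, 400] by default (loosely echoing real protein lengths). Two presets
define the test worlds:

* `leucine_enriched_preset()` — i.i.d. classes where positives have elevated
  leucine and depressed cysteine/tryptophan, the composition shape reported
  for resistance-associated protein families. The signal is AAC-visible.
* `dipeptide_planted_preset()` — both classes share the uniform stationary
  composition; the positive class doubles P(L→L) (0.05 → 0.10) and
  compensates on P(L→V), symmetrically for the V row, which preserves the
  uniform stationary distribution *exactly*. The signal lives in di-peptide
  space: DPC can see it, mean composition cannot. This is precisely the
  contrast needed to assert, directionally, the published finding that DPC
  outperforms AAC.

Two statistical subtleties surfaced by the acceptance suite are worth
recording. First, when one fixed finite pool of positives is resampled into
many balanced sets, cross-validation legitimately generalizes to that pool's
collective sampling fingerprint: even with identical class generators,
pool-based CV accuracy sits measurably above 0.5 at n = 128. That is a
property of the resampling design, not fold leakage (fold hygiene is
asserted separately by ID tracking), so the null-calibration test draws a
*fresh* signal-free dataset per sample set, for which accuracy is
statistically indistinguishable from 0.5. Second, on the di-peptide-planted
world, AAC-based CV comes out slightly *below* chance: the planted clumping
leaves mean composition flat but inflates the per-sequence L/V count
variance, and SVMs cross-validated on variance-only structure exhibit mild
anti-learning. The acceptance assertion for AAC is therefore "within 0.05 of
chance", while DPC must exceed chance by three standard errors over 20
sample sets *and* beat AAC paired on the same sets.

What a green suite does **not** establish: the generator has no domain
architecture, no phylogenetic correlation between sequences, and no
redundancy structure, so absolute accuracies on it say nothing about
accuracies on curated resistance datasets; only structural and directional
claims transfer.

# Limitations and open choices

* The headline accuracies of the source study (Tables of ~0.9 accuracy on
  curated resistance data) require its third-party datasets and are out of
  scope here; nothing in the package claims to reproduce them.
* The ACF order n actually used in the original experiments is unstated;
  n = 1 is the default, matching the printed 531-length feature vector.
* Whether hyperparameters were tuned per dataset is unstated; defaults are
  fixed and reproducible, and any tuning is left to the user.
* The printed RBF form carries a spurious leading minus and the printed CTD
  dimension formula conflates sequence length with group count; both are
  implemented in their standard positive-definite / 21-per-attribute forms.
* LOOCV with a singleton class would leave degenerate training sets and is
  refused rather than silently skipped.
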