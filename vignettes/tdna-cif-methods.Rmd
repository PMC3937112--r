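---
title: "Function logos and CIF phyloclassification: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Function logos and CIF phyloclassification: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRNAcif)
```

This vignette is the package's account of its science: the estimator
behind function logos, the classifiers built on them, what the synthetic
generator does and does not emulate, and the choices made where the
design was genuinely open.

## 1. The function-logo estimator

Input is a set of structurally aligned tRNA gene (tDNA) sequences over
Sprinzl coordinates, each labeled with one of 22 functional classes. A
*feature* is a nucleotide at a Sprinzl position, or an ordered nucleotide
pair at one of the canonical stem pairings (acceptor 1:72–7:66, D
10:25–13:22, anticodon 27:43–31:39, T 49:65–53:61). Gaps and ambiguity
codes yield no features, and a paired feature requires both member
columns ungapped.

For a taxon set, the estimator (`function_logo()`) computes for every
feature $f$ with sample size $n_f$:

* the background $P(C)$ — the empirical class frequencies of the taxon
  set, *not* a uniform prior. tRNA class sampling is structurally biased
  (gene copy numbers differ by class), and a uniform background would
  convert that bias into spurious information;
* the class posterior $P(C\mid f)$ — empirical class frequencies among
  the tDNAs carrying $f$;
* corrected information
  $I(f) = \max\{0,\; H(P(C)) - H(P(C\mid f)) - e(n_f)\}$ in bits;
* letter heights $h(f,c) = I(f)\, w(c\mid f)$ with normalized odds
  $w(c\mid f) \propto P(c\mid f)/P(c)$ (classes absent from the
  background are excluded from the normalization).

Heights are non-negative and sum exactly to $I(f)$ over classes (the
"stack conservation" identity, asserted throughout the test suite). A
**CIF set** is the letters at or above a height threshold
(`extract_cifs()`); threshold 0 means "strictly positive".

### The small-sample correction

Plug-in information is biased upward: with few carriers, the empirical
posterior looks concentrated even under the null. The default correction
(`correction = "mc"`) subtracts the Monte-Carlo estimate of that bias —
the expected entropy deficit $e(n) = H(P(C)) -
\mathbb{E}[H(\hat{P}_n)]$ of $n$ i.i.d. class draws from the background,
estimated from `mc_reps = 1000` seeded multinomial replicates and cached
per distinct $n$ (the cache is keyed by background, replicate count and
seed, so results are reproducible whether or not the cache is warm). Two
consequences worth knowing:

* $e(1) = H(P(C))$ exactly, so singleton features carry zero corrected
  information — the estimator cannot be fooled by one observation;
* the corrected statistic is approximately mean-zero under the null but
  retains a heavy right tail at very small $n$ (a feature seen twice in
  the same class keeps ≈ 1 bit). Significance for individual letters is
  therefore available separately via `permutation_pvalue()`, which
  shuffles class labels and recomputes the identical height statistic.

`correction = "none"` gives the uncorrected estimator, used by the
brute-force equivalence tests.

### Numerical choices

Entropies are in bits throughout; `0 log 0 = 0`; negative corrected
information clamps to 0; the odds normalization excludes classes with
zero background mass (their posterior mass is necessarily zero too).
Empty taxon sets (a leave-one-out fold that removes the only genome)
yield an all-zero logo rather than an error, so degenerate folds score
as "no evidence".

## 2. Classifiers

**Binary (`score_binary()`, `loocv_binary()`).** A genome is the multiset
of its tDNAs; its score against logos $A, B$ is the *mean* over tDNAs of
the summed height differences $h_A(f, c_t) - h_B(f, c_t)$ over the
features each tDNA presents at its own class. The mean (rather than the
raw sum) makes scores comparable across genomes whose tRNA complements
range from under 20 to over 110 genes; the score is invariant to
duplicating every gene, and exactly antisymmetric under swapping logos.
Training genomes are scored with their own contribution removed from
their side's logo (LOOCV); no correction is applied for unequal
training-set sizes, so a much larger side biases scores toward itself —
users should read score distributions side by side, as
`class_breakout()` does per functional class.

**Profile controls (`build_profiles()`, `score_profile()`).** The
total-sequence control scores a tDNA of class $c$ by
$\log_2 r_A(c) - \log_2 r_B(c) + \sum_f \ell(f)$ with
$q_T(f\mid c)$ the per-position state frequency among class-$c$ tDNAs of
taxon set $T$ and $r_T(c)$ the class frequency. The four treatments of
features unobserved in a training set are isolated behind one `method`
switch so any one can be corrected independently: `zero` (undefined
terms contribute 0), `skip` (undefined terms are dropped and the
remaining terms averaged, so they neither dilute nor zero-pad),
`pseudo` (Laplace smoothing, `(count + k)/(n_c + 4k)`), `small` (zero
frequencies replaced by `eps`, default `1/(2 max n_c)`, strictly below
any observable frequency). Base-2 logs keep profile scores on the same
bits scale as the logos. Profiles use single-nucleotide features only: a
total-sequence model that also scored stem pairs would count those sites
twice.

**Multiway (`multiway_fit()`, `train_mlp()`, `bootstrap_support()`).**
Each genome gets one CIF-match score per clade (its own clade's logo
rebuilt without it), and the labeled score vectors train a single-hidden-
layer perceptron: standardized inputs, `ceiling((inputs + classes)/2)`
logistic hidden units, softmax outputs, weight decay `1e-4`, at most 500
optimizer iterations, seeded initialization (backend: `nnet`). The
perceptron is the simplest nonlinear model able to use the dependence
structure among clade scores; ten-fold stratified cross-validation
reports generalization alongside the final all-data fit (both are
exposed, labeled, in the fit object). Site bootstrap draws Sprinzl
columns with replacement — all tDNAs of a replicate see the same column
multiset, paired features ride their 5' member — and reports the
percentage of replicates predicting each clade. The 0.5-bit height
filter (`apply_height_filter()`) truncates logos, recomputes all
training vectors and retrains before bootstrapping, probing whether
classifications rest on many small letters or a few strong CIFs.
Argmax ties break deterministically by clade order.

**Composition diagnostics.** `base_composition()` counts A/C/G/T over
ungapped residues by clade or genome (+0.5 smoothing for zero counts so
log-ratios stay defined); `clr()` is the centered log-ratio (natural log
by default — the base rescales all vectors by one constant and cannot
change UPGMA topology; it is recorded as an attribute); Euclidean
distance on CLR vectors is the Aitchison distance, invariant to count
rescaling; `upgma()` is average-linkage clustering returning an
ultrametric `phylo` tree on the half-distance scale, with ties broken by
label order.

## 3. The synthetic generator

`generate_tdna()` emulates the structure the classifiers exploit, not
tRNA biology in full. Genes are instantiated from class template
sequences (gaps copied verbatim; the default template gaps the -1
position and the insertion/variable-arm columns). Sites come in two
kinds:

* **conserved** sites keep the template base, apart from a minor-allele
  rate (`polymorphism`, default 0.10) and random substitutions
  (`background_noise`, default 0.02), replacements drawn to match the
  clade's `gc_bias`;
* **variable** sites are drawn i.i.d. per gene from the clade's
  gc-biased composition.

Variable sites are what gives each clade a realized base composition
near its target: compositional variation in real genomes is
clade-correlated but class-uninformative, and modeling it as per-gene
compositional sampling reproduces exactly that — profiles and
composition vectors see strong clade signal there while function logos
see none. The polymorphism floor at conserved sites serves a statistical
purpose: it keeps every feature's sample size out of the tiny-$n$ regime
where the corrected estimator's null tail reaches the CIF extraction
threshold, so planted-feature recovery is a clean measurement of the
estimator rather than of rare noise coincidences.

Planted CIFs are imposed on genes of their class with probability
`cif_fidelity` *after* the noise layers, so fidelity is exact by
construction. `converge_composition()` drives named genomes A+T-rich by
rewriting G/C to A/T with probability `at_shift` at unprotected sites;
protecting the planted CIF positions (the default) models the
observation that identity elements resist compositional drift, and an
unprotected mode exposes the failure regime.

What the generator does **not** emulate: phylogenetic covariance within
clades (genomes are exchangeable draws), tree-structured substitution
processes, stem covariation (paired sites are sampled independently),
isoacceptor/anticodon structure within classes, and real within-class
template divergence. Passing tests therefore demonstrate correctness of
the estimators and classifiers under the stated generative model — they
do not certify performance on real tDNA collections, where class
structure is richer and clade signal weaker.

### The default benchmark

`benchmark_config()` fixes the study conditions used by the tests and
the acceptance script: 7 clades × 10 genomes, 4 gene copies of each of
the 22 classes per genome (88 tRNA genes per genome, within the
20–110 range seen in real bacteria), 3 planted CIFs per clade at
distinct unpaired conserved positions in 3 distinct classes, fidelity
0.95, noise 0.02, and per-clade G+C targets 0.60/0.30/0.55/0.58/0.62/
0.53/0.57 — six clades spanning the 53–62% range typical of
Alphaproteobacteria plus one A+T-rich clade (C2) standing in for a
compositionally converged lineage. Planted positions sit at loop
(unpaired) coordinates: identity elements concentrate at such positions
in real tRNAs, and keeping stems fully variable keeps paired-feature
sample sizes saturated (see above). The convergence experiment draws 10
fresh genomes from clade C1's specification, applies
`converge_composition(at_shift = 0.5)` with planted positions
protected, and asks (a) whether composition clustering joins them to
C2, (b) whether the multiway classifier still returns them to C1 while
the `zero` profile control does not, and (c) whether binary CIF scores
keep their sign. These problem sizes run the whole acceptance suite in
well under a minute on one CPU; they were chosen as the smallest sizes
at which per-feature sample sizes stay out of the small-$n$ null tail.

## 4. Open design points, resolved

* *CIF membership condition.* Whether a CIF requires strict positivity,
  a height threshold, or a significance test is left parametric:
  `extract_cifs(threshold_bits)` covers all readings (0 = strictly
  positive), and `permutation_pvalue()` supplies significance
  separately.
* *Exact small-sample correction.* The Monte-Carlo expected-entropy
  subtraction is the package's declared correction; an exact convolution
  backend would slot in behind the same `correction` argument.
* *Profile missing-data semantics.* The four treatments follow their
  names' plain readings (above). Note one structural fact: `zero` and
  `skip` score the same feature subset, so their feature terms always
  agree in sign; `skip` differs by removing the dilution of the
  unscoreable features from the per-tDNA average.
* *Mean versus total genome scores.* Per-genome means are canonical
  everywhere (binary, profile, multiway), for comparability across
  widely varying tRNA complement sizes.
* *Probabilities from fold models or the final model.* Both are kept:
  `$mlp$cv$probabilities` holds the held-out fold predictions,
  `predict()` uses the all-data fit.

## 5. Known limitations

* The MC correction is stochastic; logo heights carry Monte-Carlo noise
  of order a few millibits at the default `mc_reps = 1000` (seeded, so
  reproducible).
* The corrected estimator's null tail at very small feature sample
  sizes means CIF lists from sparse real datasets should be filtered by
  sample size or permutation significance, not height alone.
* Binary scores are not probabilities and are biased toward the larger
  training set; the multiway classifier's probabilities are conditional
  on its seven-clade world and cannot flag "none of the above".
* UPGMA assumes ultrametricity; it is used here as a descriptive
  diagnostic of compositional similarity, not as a phylogeny estimate.
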