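---
title: "Methods: family-level modeling of TF base preference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: family-level modeling of TF base preference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(familycode)
```

This vignette is the package's own account of its methods: the model, its
assumptions, the tunable parameters, the numerical choices, and the places
where the design was genuinely open and a decision had to be made.

## Binding models and their embedding

A binding model for one TF is a position-specific affinity matrix (PSAM):
relative affinities $w_{jb} \in [0,1]$ per DNA position $j$ and base $b$
(order A, C, G, T throughout), with the preferred base at 1; equivalently a
matrix of dimensionless free-energy penalties $\Delta\Delta G_{jb}/RT =
-\ln w_{jb}$ with the preferred base at 0. Both containers validate these
conventions on construction.

Each PSAM column is normalized to frequencies $f_b = w_b / \sum_{b'} w_{b'}$
and mapped to $v = f \, T$ with vertex matrix

$$T = \begin{pmatrix} 1&1&1 \\ 1&-1&-1 \\ -1&1&-1 \\ -1&-1&1 \end{pmatrix},$$

whose rows are strict preferences for A, C, G, T. Because the rows of $T$
sum to zero, frequencies reconstructed by the inverse map
$f_b = (1 + \langle v, t_b\rangle)/4$ always sum to one, and the mapping is
exactly invertible on the simplex. Points near a face or vertex are
insensitive to the precise magnitude of large penalties — which is the
reason the family-level statistics operate in this space rather than on raw
$\Delta\Delta G/RT$ values, whose disfavored-base entries are the noisiest
part of any fitted binding model.

The assumption this embedding encodes is that *base preference at one DNA
position is a point on the frequency simplex*; correlations between DNA
positions are not modeled (each position gets its own model), matching the
position-independence assumption of the PSAM representation itself.

### Regularization of exterior points

Shift vectors between two embedded points can leave the tetrahedron. An
exterior point (some reconstructed $f_b < 0$) is moved along the straight
line to the vertex of its least-preferred base until the reconstructed
relative affinity of that base equals the floor (0.01 by default), and the
step is repeated until the point is interior. Numerical choices:

* the interior test is $f_b \ge -10^{-12}$, absorbing float noise;
* the relative affinity along the line is evaluated pointwise
  ($w_b = f_b / \max f$, with the maximum recomputed at each trial point,
  since the identity of the preferred base can change along the line) and
  the crossing is found by monotone bisection to $|w_b - 0.01| < 10^{-10}$;
* ties for "least-preferred base" resolve in A, C, G, T order;
* an interior point is never moved, which makes the operation idempotent;
* ten passes are allowed before a numeric-fault error; two is the most ever
  observed.

### The $\Delta\Delta\Delta G/RT$ convention

The inverse map turns a regularized shift endpoint into frequencies; we
convert them to signed energies as $-\ln(4 f_b)$, which is zero for a null
shift and negative for bases that gain preference. This normalization was
genuinely open: a row-max normalization would produce only non-negative
values, but mutant effects are signed. The $-\ln(4f)$ reading is pinned by
the forward worked example (a $+0.5$ shift along $x$ gives
$(-0.405, -0.405, 0.693, 0.693)$). Note one consequence: the convention is
*antisymmetric only to first order* — reversing a shift flips every sign
exactly, but magnitudes agree only up to $O(\|shift\|^2)$, since
$-\ln(1+x) \ne \ln(1-x)$. Tests assert the sign-flip property and the
first-order bound rather than exact antisymmetry.

## Association mapping

For every (residue position, DNA position) pair, a MANOVA asks whether the
mean tetrahedral position differs between amino-acid groups, using the
Pillai–Bartlett trace $V = \mathrm{tr}\,[H (H+E)^{-1}]$ of the
between-group ($H$) and within-group ($E$) SSCP matrices and the standard
F approximation with $s = \min(p, g-1)$. Implementation notes:

* The test is computed from the SSCP matrices directly. When the total
  scatter is rank-deficient (a cloud confined to a plane or line — possible
  for highly stereotyped positions) the test proceeds in the spanned
  subspace with the reduced $p$; a 1-D cloud then reduces exactly to the
  one-way ANOVA. A cloud of identical points is an error.
* Groups of size one are allowed (they contribute to $H$, not $E$); cells
  with fewer than two groups or no residual degrees of freedom are `NA`.
* Gap characters form their own group only when at least two TFs share the
  gap (`min_gap_group`); otherwise gapped TFs are dropped from that cell.
* Multiple testing is Bonferroni over all non-`NA` cells, with the
  significance level `alpha = 0.001` by default.

For reverse-complement-symmetric (palindromic) binding models the p-value
columns for positions $-k$ and $+k$ are identical: complementing the bases
is a signed coordinate permutation ($\mathrm{diag}(-1,-1,1)$), which is
orthogonal, and the MANOVA is invariant under orthogonal maps of the
response.

## The SVD-regression model

Per DNA position, the $n \times 3$ cloud $M$ of training-TF points is
centered ($\mu$) and decomposed, $M - \mu = U D V^\top$. The columns of $V$
are a data-driven coordinate frame; the per-TF scores are $S = (M-\mu)V$.
SVD signs are arbitrary, so each column of $V$ is flipped to make its
largest-magnitude entry positive — determinism matters because predictions
must be invariant to training-set order. A cloud of identical points is
accepted ($D = 0$, $V = I$): the degenerate family then predicts its shared
PSAM for any query, a useful exactness fixture.

For each principal component:

1. every residue position is ranked by the p-value of a one-way ANOVA of
   the scores against amino-acid identity (closed-form sums of squares;
   verified against `stats::aov`); positions with fewer than two groups
   are ineligible;
2. features enter by forward selection. A feature's predictor is the
   *leave-self-out* group mean of the scores of all other TFs sharing the
   query's amino acid (singleton groups encode as 0, the grand mean of the
   centered scores). Coefficients come from ordinary least squares without
   intercept. Each candidate is admitted while the extra-sum-of-squares
   F-test against the current model stays below `selection_alpha`
   (default 0.05); candidates that leave the design rank-deficient
   (perfectly linked residues) are skipped without counting as the stop.

Two points here were genuinely open. First, whether the *first* feature is
tested at all: we gate it against the empty model at the same threshold, so
that as `selection_alpha` goes to zero the model collapses to the centroid
predictor — without the gate that limit would be unreachable. Second, the
leave-self-out encoding is not cosmetic: it makes each feature's predictor
exactly uncorrelated with the response under the null hypothesis, keeping
the per-feature F-test honest. What it cannot remove is selection bias
*across* features — the top-ranked of many candidate residues passes the
gate far more often than the nominal level on pure-noise families. Users
should read a single marginally selected feature accordingly; the planted
determinants that matter are selected with p-values many orders of
magnitude below the threshold.

At prediction time the group-mean tables use the full training sample (the
self-exclusion applies only while fitting coefficients). A query amino acid
unseen at a selected position is encoded as a weighted mean of the observed
group means with weight $\propto 1/(B_{aa} - B_{aa'})$ under BLOSUM62;
non-positive differences (possible for near-identical substitutions)
receive the largest finite positive weight, and gaps use the unweighted
mean, since BLOSUM has no gap scores. Predicted scores are mapped back via
$v = \mu + V s$, inverse-embedded, floored at 0.01, and logged to energies.

### Mutant mode

For a set of point mutations the mutated residue positions become the only,
mandatory features — no ranking, no selection — and the coefficients are
refit on the full training set (reusing wild-type-fit coefficients would be the
alternative; refitting is the self-consistent choice given that forced
features were typically not in the selected set). Wild type and mutant are then encoded, mapped into the
tetrahedron, and their per-position shift converted to
$\Delta\Delta\Delta G/RT$ as above. Effects planted at disjoint DNA
positions combine near-additively; exact additivity is not expected because
the energy conversion is nonlinear in the shift.

## Baselines and evaluation

* **Closest paralog** transfers the model of the training TF with the
  smallest Levenshtein distance (unaligned sequences; ties break by
  lexicographic id).
* **Similarity regression** scores training TFs by pretrained per-position
  weights times a binary identity profile. Descriptions of this scheme
  are ambiguous about the optimization direction (a weighted identity is
  naturally maximized); the package defaults to transferring the
  *best-matching* neighbor and exposes a `direction` flag. Weight vectors trained on a different profile HMM are
  reconciled with `insert_gap_columns()` (e.g. two gap columns after match
  position 34 for bHLH).
* **LOOCV** holds out each TF, optionally excluding training TFs within a
  Hamming-distance threshold of the held-out sequence (information-leakage
  control), and compares predicted with observed $\Delta\Delta G/RT$.
  Aggregate R²/RMSD pool all (TF, position, base) entries — the natural
  choice when per-TF entry counts are equal — and per-TF metrics are also
  reported.
* **Bootstrap t-test**: "bootstrap t" admits several reasonable
  definitions; implemented as a paired bootstrap of squared prediction
  errors ($B = 10{,}000$, explicit seed, centered resampling for the null,
  add-one two-sided p-value). The Wilcoxon mode is the standard paired
  signed-rank test.

## The synthetic family generator

The generator emulates the statistical structure the model exploits: group
structure in the tetrahedron driven by amino-acid identity at determinant
residues.

* Determinant columns assign amino acids in a balanced factorial pattern
  (strides equal to the product of earlier group counts) so multiple
  determinants are uncorrelated by construction; background columns are
  i.i.d. over an 8-letter alphabet, mimicking the moderate per-column
  diversity of real family alignments (a full 20-letter i.i.d. column would
  be *more* diverse than real alignments and fill the family with
  uninformative singleton groups).
* Each TF's point at a determinant DNA position is its group's target plus
  isotropic Gaussian noise (sd 0.05 by default, in tetrahedral units),
  rejection-sampled to stay interior; non-determinant positions scatter
  around a per-position anchor drawn near the centroid. Family noise lives
  in tetrahedral space because that is where the model's assumptions live;
  *replicate* noise (for concordance ceilings) is added in energy space to
  non-preferred bases instead, mimicking assay noise, with the row minimum
  re-zeroed.
* Default scale: 50 TFs, alignment length 20, 6 DNA positions, one Arg/Val
  determinant at residue 13 controlling DNA position 3 (an echo of the
  major-groove contact residue of bHLH proteins). These sizes keep a full
  20-seed recovery study — association scan, LOOCV, mutant prediction per
  seed — comfortably within a few minutes on one core.

What passing tests on these families shows: the estimator recovers planted
determinants, group targets and mutant shifts at realistic noise. What it
does not show: robustness to misaligned binding frames, to correlated
determinants (epistasis), to phylogenetic non-independence of the training
TFs, or to binding-model bias shared across a family — none of which the
generator emulates.

## Known limitations

* One model per DNA position: inter-position dependencies in the binding
  site are out of scope, as in the PSAM representation itself.
* The regression is linear in group-mean encodings; strongly epistatic
  residue pairs would need interaction features.
* Forward selection controls each step's F-test, not family-wise error
  across candidate features (see above).
* $\Delta\Delta\Delta G/RT$ values inherit the $-\ln(4f)$ convention's
  second-order asymmetry for large shifts.
* Profile-HMM alignment of new sequences is deliberately external: the
  package consumes pre-aligned rows (FASTA/Stockholm/A2M) so that results
  are reproducible without network access or an aligner on the path.
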