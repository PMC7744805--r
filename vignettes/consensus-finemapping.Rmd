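---
title: "Methods: consensus fine-mapping with context-free and tissue-specific scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus fine-mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`finecons` prioritizes candidate causal variants at GWAS-associated loci by
combining three sources of evidence: linkage disequilibrium with the queried
marker, genic context, and functional-impact scores — both context-free
(one score per variant) and tissue-specific. This vignette documents the
statistical machinery, the design decisions behind it, and what the
synthetic test bed does and does not establish.

## LD proxy expansion

The causal allele at an associated locus is usually not the genotyped
marker but a variant in high LD with it. Given a phased haplotype panel
(VCF with `|`-separated genotypes; each diploid sample contributes two
haplotype rows), LD between two sites is the classical composite measure

$$r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)}, \qquad D = p_{AB} - p_A p_B,$$

computed exactly from haplotype allele frequencies; it equals the squared
Pearson correlation of the two binary allele-indicator columns. Because the
panel is phased by precondition, no EM phasing is implemented. $r^2$ is
undefined (an error, deliberately distinct from $r^2 = 0$) at monomorphic
sites.

Proxy search parameters (`ld_config()`):

* `r2_threshold` (default **0.5**) — the conventional cut for declaring a
  proxy. The comparison is closed (`>=`) by default; the strict/closed
  choice is a flag because the boundary case, while measure-zero on real
  data, must be deterministic.
* `window_bp` (default **500 kb**, the LDlink convention) — flank searched
  on each side of the index variant. 100 kb and 50 kb are common presets
  when matching score-lookup windows.
* `maf_min` (default 0) — minor-allele-frequency floor for candidates.

Allele handling: if the panel's ref/alt are swapped relative to the query
the haplotype coding is flipped with a warning; strand-ambiguous swaps
(A/T, C/G) are rejected rather than guessed. Output records are sorted by
descending $r^2$, then ascending distance, then position, with the
self-record ($r^2 = 1$, distance 0) first — fully deterministic.

## Gene-model annotation

Variants are classified against a refGene-style transcript table (UCSC
0-based half-open coordinates; all internal interval arithmetic uses the
same convention, converting at the VCF/refGene boundaries only). Each
transcript yields a per-transcript category; a variant hitting several
transcripts takes the highest-precedence one:

> exonic = splicing > ncRNA_exonic > UTR5 > UTR3 > intronic >
> ncRNA_intronic > upstream = downstream > intergenic

This mirrors the convention of the widely used annotators so that one
variant gets exactly one category. Remaining ties break on alphabetical
gene symbol, then transcript id. Choices a user can move:

* `splice_window_bp` (default **2**) — the first/last bases of an intron
  called "splicing"; applied to coding transcripts (non-coding introns are
  `ncRNA_intronic` throughout, as the category set has no ncRNA splicing
  class).
* `flank_bp` (default **1000**) — distance outside a transcript called
  upstream/downstream; beyond it, intergenic.

Intergenic, upstream and downstream records carry the signed distance to
the nearest transcription start site (txStart on `+`, txEnd on `-`), in
transcription orientation (negative = upstream of the TSS); equidistant
genes tie-break alphabetically. Coding consequence (synonymous / missense /
nonsense) is computed only when a reference FASTA is supplied, by
translating the affected codon before and after substitution with the
standard genetic code, reverse-complemented for minus-strand transcripts;
a stop-gain is "nonsense", and any other amino-acid change (including
stop-loss, which has no category of its own) is "missense". A variant
whose stated reference allele disagrees with the FASTA is an error, never a
silent fix.

## Semi-supervised tissue-specific scoring

The tissue-specific scorer fits, per tissue, the penalized objective

$$\hat f = \arg\min_f \; \sum_{i=1}^{m} \ell_p\!\left(Y_i, f(X_i)\right)
  \;+\; \gamma \sum_{i=1}^{l} \left(\hat Y^{u}_i - f(X_i)\right)^2,$$

where $\ell_p$ is the logistic negative log-likelihood on $m$ labeled
variants plus an elastic-net penalty
$\lambda(\alpha \lVert\beta\rVert_1 + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2)$,
and the second term anchors predictions for $l$ unlabeled variants to
scores $\hat Y^u \in [0,1]$ from a prior unsupervised method (supplied as
input, never recomputed here).

Design decisions, made where the formulation leaves room:

* **Scale of $f$ in the anchor term.** The linear predictor is passed
  through the logistic link before comparison with the anchors, so both
  loss terms live on $[0,1]$ probabilities; anchors are probabilities and
  the labeled term is logistic, so this keeps the two terms commensurable.
* **Raw sums.** Both sums are unnormalized; `normalize_terms = TRUE`
  divides them by $m$ and $l$ for users who want $\gamma$ to be
  scale-free in the set sizes. Off by default, matching the objective as
  written above.
* **Standardization.** Features are standardized internally (labeled-set
  mean and population sd — the glmnet convention) before penalization,
  and coefficients are reported on the original scale. Degenerate constant
  features get unit scale.

**Optimization.** The smooth part (logistic loss + ridge + anchor) plus the
L1 term is minimized by monotone FISTA: proximal gradient steps with
Nesterov momentum, backtracking line search on a local Lipschitz estimate,
and a restart whenever the objective would rise, so the accepted objective
sequence is non-increasing by construction. Initialization is the zero
vector; there is no randomness in the optimizer, so fits are exactly
reproducible. Convergence (relative objective change below `tol`, default
1e-10) is reported honestly in the `converged` flag, not assumed. Note the
anchor term makes the objective non-convex in general (squared loss through
a sigmoid); the monotone scheme converges to a stationary point, and the
zero start makes the solution deterministic.

**Tuning $\gamma$** (`tune_gamma()`): stratified k-fold cross-validation on
the labeled set, refitting with the full unlabeled set each time and
scoring held-out labeled variants by AUROC (the Mann–Whitney rank
statistic; ties count half). The grid element with the highest mean AUROC
wins; ties go to the *smallest* $\gamma$, preferring the less
assumption-laden model. Fold assignment is a seeded, per-class round-robin
deal, so tuning is deterministic given the seed. Folds whose test split
lacks both classes are an error, not a silent skip. Default grid in the
pipeline configuration: 0, 0.1, 1, 10; default $\lambda = 1$ (raw-sum
scale) and $\alpha = 0.5$.

## Consensus of context-free methods

Each method column of the score matrix ranks the $n$ variants with rank 1 =
most functional, after applying the column's direction flag (methods on an
inverted scale must be flagged `lower`); ties receive average ranks and
missing scores give missing ranks. The consensus statistic per variant is
the mean of its available ranks,
$\text{AverageRanking}_i = \sum_{j=1}^m R_{ij} / m$; by default a variant
must be ranked by *all* methods to enter downstream ordering
(`min_methods = m`, relaxable), because missingness is real in published
score panels and silently averaging two ranks against eleven misleads.

**Significance.** The p-value attached to an average ranking is this
package's own choice (the quantity is standard; the test attached to it is
not): a one-sided permutation test whose null permutes each method's rank
column independently, with the plus-one estimator
$p_i = (1 + \#\{\text{perm } \le \text{obs}\})/(n_{\text{perm}} + 1)$ and
Benjamini–Hochberg adjustment across variants. One-sided means
"more functional (smaller average rank) than chance". The test suite
checks calibration under a fully null table; because per-decile counts on a
single 50-variant table are binomially noisy (sd ≈ 4%), the check pools
p-values over 20 seeded replicate tables, where the ±5-point decile band
detects systematic miscalibration rather than sampling noise.

**Concordance.** Cross-method agreement is the Pearson correlation of rank
columns over shared variants (for complete data this equals Spearman on the
raw scores, and the implementation's Spearman helper is exactly that:
Pearson on tie-averaged ranks, pairwise-complete, requiring ≥ 3 pairs and
erroring on constant input). Pairs sharing fewer than 3 variants yield a
missing entry with a warning.

**Tissue-maximum profile.** Per variant, the set of tissues within
`tie_tol` (default 1e-9, i.e., exact ties only — configurable because
upstream scores may arrive rounded) of the row maximum, classified as
`unique_to_group`, `shared_with_group`, or `outside_group` against a
user-supplied tissue group. The three classes partition the variant set.

**Consensus prioritization.** A variant passes when (a) its target-tissue
score is in the top $\lceil qn \rceil$ of all variants and (b) it is in the
top $\lceil qn \rceil$ of at least $\lceil \text{fraction} \cdot m \rceil$
method columns; defaults $q = 0.05$, fraction $= 0.5$. The cut is
count-based on tie-averaged ranks, not a score percentile, so small $n$
behaves deterministically (a tie straddling the boundary excludes the tied
set rather than arbitrarily admitting part of it). The looser
"top 10% in a majority of methods" variant is the same rule with
$q = 0.10$.

## The synthetic test bed

The generators are pure functions of a `sim_config()` (one master seed
expands into per-component substreams, so reconfiguring one component does
not perturb the others' draws). Defaults describe the simulated study:
200 haplotypes × 40 sites in blocks of 10 with within-block $r^2 \approx
0.8$; 11 context-free methods with inter-method correlation 0.6 and 127
tissue columns; 50 labeled + 2000 unlabeled training variants over 20
features with 5 nonzero coefficients and anchor noise sd 0.05; planted
consensus hits occupying the top 5%.

* **Haplotypes** get block LD by copy-with-flip from a block founder: with
  flip probability $\varepsilon$ per copy the expected correlation between
  two copies is $(1-2\varepsilon)^2$, so the flip rate is solved in closed
  form from the $r^2$ target — no coalescent machinery, no recombination
  maps, no demography. This produces the matrix structure the LD stage
  assumes, not population-genetic realism.
* **Gene models** are isolated transcripts (inter-transcript gaps larger
  than twice the upstream/downstream flank) whose per-position category is
  computable by direct layout arithmetic — the construction oracle the
  annotation tests compare against.
* **Score matrices** share a latent per-variant functionality; each column
  is $\sqrt{\rho}\,z + \sqrt{1-\rho}\,\epsilon$, hitting the target
  inter-column correlation $\rho$ in expectation. Planted hits are then
  raised above each method column's background maximum and above the whole
  tissue matrix in the target-tissue column, making the planted set the
  exact top quantile by construction — recoverable with sensitivity and
  specificity 1 when the prioritization rule is correct, which is the
  point of the construction.
* **Training data** are i.i.d. normal features with a sparse true
  coefficient vector, Bernoulli labels, and anchors equal to true
  probabilities plus clipped Gaussian noise, with a held-out labeled set
  from the same truth for out-of-sample AUROC.

Passing tests on this bed shows the algebra and the contracts are right —
the r² matches count-table enumeration, the classifier matches planted
truth, the optimizer honors its limits, the prioritization rule recovers
what was planted. It does **not** show that real GWAS loci will be
prioritized correctly: real LD is not block-diagonal, real score panels
have heavier missingness and tail dependence, and real anchors are far
noisier than 0.05 sd.

## Degenerate inputs and numerical conventions

* Monomorphic sites: error from `pairwise_r2` ("undefined"), skipped as
  proxy candidates.
* Single-class labels, empty gamma grids, folds losing a class: errors.
* All-missing score columns: error; missing entries are tracked, never
  imputed.
* Indels are parsed and flagged but excluded from LD and coding stages.
* Chromosomes absent from the gene model annotate as intergenic with a
  warning (gene NA), not an error — panels routinely cover fewer contigs
  than gene models.
* Score TSVs are serialized with 17 significant digits so write-then-read
  round-trips exactly; output files carry the configuration hash and no
  timestamps, so identical configurations produce byte-identical outputs.

## Scale of the shipped checks

The test suite and acceptance script run the full pipeline on the default
synthetic study (10 index variants expanding to ~40 candidates, 11 methods,
127 tissues, 999-permutation consensus p-values in the calibration checks
and 199 in the end-to-end fixture) and the scorer's recovery simulation at
m = 50, l = 2000, p = 20 over 10 seeded replicates — sizes chosen so the
statistical assertions (AUROC gains, calibration bands, exact recovery)
have the power they need while a complete run stays in the minutes range
on one CPU.

## Known limitations

* LD is computed within one panel; no cross-population comparison or
  population-structure correction, and no D′ or haplotype-block calling.
* The annotator knows nothing of splice strength, conservation or protein
  domains; "splicing" is a positional convention.
* The anchor method (the source of $\hat Y^u$) is an input; if its scores
  are biased for a tissue, large $\gamma$ inherits the bias — the AUROC
  tuning mitigates but cannot remove this.
* The permutation null treats method rank columns as independent, which is
  conservative for positively correlated methods ranking the same signal.
* No liftover between genome builds; the gene model is trusted as given
  and its file hash is recorded in outputs.
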