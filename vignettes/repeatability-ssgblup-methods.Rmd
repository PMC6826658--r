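---
title: "Methods: repeatability-model genetic evaluation with pedigree and genomic information"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeatability-model genetic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The model

Everything in this package is organised around the single-trait
repeatability animal model for repeated-measure traits (the motivating
application is repeated ejaculate measurements of sperm-morphology
abnormality percentages on AI-station boars):

$$\mathbf{y} = \mathbf{Xb} + \mathbf{Za} + \mathbf{Wp}
  + \beta_{\mathrm{age}}\,\mathrm{Age} + \beta_{\mathrm{intv}}\,\mathrm{Intv}
  + \mathbf{e}$$

where $\mathbf{y}$ holds the repeated records, $\mathbf{b}$ the
year-season classes, $\mathbf{a} \sim N(0, \mathbf{K}\sigma^2_a)$ the
additive genetic values with relationship matrix $\mathbf{K}$,
$\mathbf{p} \sim N(0, \mathbf{I}\sigma^2_p)$ the per-boar permanent
environmental effects, Age (months) and Intv (collection interval,
days) fixed covariates, and
$\mathbf{e} \sim N(0, \mathbf{I}\sigma^2_e)$ the residuals. The three
evaluation variants differ only in $\mathbf{K}$:

* **BLUP**: $\mathbf{K} = \mathbf{A}$, the pedigree numerator
  relationship matrix;
* **GBLUP**: $\mathbf{K} = \mathbf{G} =
  \mathbf{ZZ}'/\sum_i 2p_i(1-p_i)$ over the genotyped animals, with
  genotype codes centred at $2p_i$ (VanRaden);
* **ssGBLUP**: all animals, through
  $\mathbf{H}^{-1} = \mathbf{A}^{-1} +
  \begin{bmatrix} 0 & 0 \\ 0 & \mathbf{G}_w^{-1} - \mathbf{A}_{22}^{-1}
  \end{bmatrix}$ with the blend
  $\mathbf{G}_w = 0.9\,\mathbf{G} + 0.1\,\mathbf{A}_{22}$.

Derived summaries are the heritability
$h^2 = \sigma^2_a/(\sigma^2_a+\sigma^2_p+\sigma^2_e)$ and the
repeatability $r = (\sigma^2_a+\sigma^2_p)/(\sigma^2_a+\sigma^2_p+\sigma^2_e)$.

# Pedigree machinery

`build_A()` uses the tabular recurrence; `inbreeding_coefficients()`
uses the Meuwissen–Luo ancestor recursion, which never forms dense
$\mathbf{A}$; `build_A_inverse()` applies Henderson's rules with
Mendelian-sampling variances $d_i = 0.5 - 0.25(F_s + F_d)$ by default.
A flag reproduces the classical no-inbreeding approximation, because
evaluation software differs on this point and both variants are useful
for comparisons. Unknown parents contribute as the population mean
(no unknown-parent groups; nothing in the target data structure calls
for them). `extract_A22()` obtains the genotyped-animal submatrix
without dense $\mathbf{A}$ by sparse Cholesky solves against
$\mathbf{A}^{-1}$ — one solve per genotyped animal.

# Genotype handling

Quality control runs in a fixed, auditable order — individual call
rate $\ge 0.90$, SNP call rate $\ge 0.90$, folded MAF $\ge 0.01$,
exact-test HWE $p \ge 10^{-5}$ — each filter applied to the matrix the
previous one left behind; the QC report records removals per step so
order effects stay visible. The HWE test is the conditional exact test
on heterozygote counts (a chi-square variant is available). Remaining
missing genotypes are set to heterozygote (code 1), the pragmatic
choice for panels with per-mille missingness where position-unknown
SNPs rule out LD-based imputation.

Two deliberate choices in `build_G()`:

* the centring frequency $p_i$ is the **unfolded** observed frequency
  of the counted allele, not the folded MAF. Folding would break the
  $-2p, 1-2p, 2-2p$ centring for loci where the counted allele is the
  major one, and would destroy the allele-swap invariance the test
  suite asserts. A `fold = TRUE` flag exists for sensitivity checks.
* frequencies are computed after the heterozygote fill (the fill is a
  QC-stage operation, so the matrix entering `build_G()` is complete);
  supplying external frequencies is supported via `freq_source`.

$\mathbf{G}_w^{-1}$ and $\mathbf{A}_{22}^{-1}$ use a symmetric
Cholesky factorisation with a logged $10^{-8}$ diagonal jitter
fallback; with the default blend weight 0.9 the jitter path should
never trigger on real-scale data.

# Solving the mixed-model equations

`solve_mme()` assembles Henderson's equations with
$\lambda_a = \sigma^2_e/\sigma^2_a$, $\lambda_p =
\sigma^2_e/\sigma^2_p$ and factorises the sparse symmetric coefficient
matrix. Prediction error variances come from the animal-block diagonal
of the coefficient-matrix inverse (exact column solves, no
approximation), and reliabilities are $1 - \mathrm{PEV}/\sigma^2_a$.
Covariates are centred for conditioning; slopes are reported on the
original scale. Year-season is a single concatenated class factor; the
reference class is dropped for full rank, and constant covariates are
dropped with a warning rather than left to produce singular systems.

# AI-REML

`ai_reml()` / `ai_reml_bivariate()` share one engine that handles $t$
traits with a common record structure ($t \in \{1, 2\}$ in the exposed
interfaces). All restricted-likelihood quantities are computed through
mixed-model-equation identities — the dense phenotypic covariance
$\mathbf{V}$ is never formed:

* $-2\ell = n\log|\Sigma_e| + q\log|\Sigma_a| + t\log|\mathbf{K}|
  + q_p\log|\Sigma_p| + \log|\mathbf{C}| + \mathbf{y}'\mathbf{Py}$,
  an exact identity verified in the tests against the dense formula;
* score traces use $\mathrm{tr}(\mathbf{K}^{-1}\mathbf{C}^{aa})$-type
  blocks of the inverse coefficient matrix;
* the average-information matrix is the Gram matrix
  $\tfrac12 \mathbf{f}_i'\mathbf{P}\mathbf{f}_j$ of the working
  variates $\mathbf{f}_i = \mathbf{V}_i\mathbf{Py}$, obtained by
  re-solving the same factorised system with each $\mathbf{f}_i$ as
  data. Because it is a Gram matrix it is positive semi-definite, so
  the AI direction is an ascent direction.

Updates are AI steps with step halving; when no fraction of the AI
step is admissible the engine falls back to an EM-REML step, which is
monotone by construction (the M-step uses
$E[\mathbf{u}'\mathbf{K}^{-1}\mathbf{u}\,|\,\mathbf{y}]$ and
$E[\mathbf{e}_j'\mathbf{e}_k\,|\,\mathbf{y}] =
\hat{\mathbf{e}}_j'\hat{\mathbf{e}}_k +
\mathrm{tr}((\mathbf{DC}^{-1}\mathbf{D}')_{jk})$). Covariance matrices
are projected onto the PSD cone with an eigenvalue floor of
$10^{-8}\max_j \mathrm{var}(y_j)$, so boundary estimates are pinned
slightly inside the cone and flagged; their standard errors are marked
unreliable. Convergence requires a relative parameter change below
$10^{-8}$ or a likelihood change below $10^{-9}$; parameters pinned at
the floor are excluded from the parameter criterion. Two further stops
handle boundary fits, which otherwise crawl along the cone with minute
EM gains: three consecutive likelihood changes below $10^{-7}$, or a
total $-2\log L$ improvement below $0.01$ over the last ten
iterations (a change far below any statistical resolution, so the
estimates it forgoes move only in the third or fourth decimal).
Initial values are $0.3/0.2/0.5$ of the phenotypic variance for
$\sigma^2_a/\sigma^2_p/\sigma^2_e$ unless supplied.

One structural decision: `estimate_variance_components()` restricts
the animal effect to the phenotyped animals, using the corresponding
submatrix of $\mathbf{A}$. The restricted likelihood depends on the
relationship matrix only through that submatrix, so this
marginalisation is exact, and it keeps the coefficient matrix dense
and small (about $2q + p$ with $q$ phenotyped boars), which is what
makes replicated desk-scale REML cheap. The pedigree-wide sparse MME
path is kept for BLUP solving, where predictions for unphenotyped
relatives are the point.

Genetic correlations are estimated by pairwise bivariate fits rather
than one joint five-trait fit: pairwise runs are numerically robust at
desk scale, and a full multi-trait fit adds nothing the pairwise table
does not already give for a correlation table. The bivariate engine
assumes the two traits share the record structure (both measured on
each ejaculate), which is how the simulator generates them.

# De-regressed proofs

`drp_pipeline()` fits the pedigree BLUP once per trait on the full
data (DRPs are the fixed evaluation currency; they are never
re-computed inside validation folds), converts PEVs to reliabilities,
forms parent averages `PA = (EBV_s + EBV_d)/2` with
`r2_PA = (r2_s + r2_d)/4`, and applies the Garrick
information-splitting recipe to remove both shrinkage and the
parent-average contribution. Animals failing the preconditions
(`r2_i > r2_PA`, `r2_PA < 0.5`, both parents known) are excluded with
reason codes, never clamped. The heritability entering the recipe is
the AI-REML estimate from the same data. Weights for weighted
downstream analyses are computed and stored (genomic proportion
parameter `c_genomic`, default 0.5) but deliberately unused by the
predictive-ability correlations, which are plain Pearson.

A property worth knowing: because every `Z'Z` term in the recipe
carries a factor $\lambda$, the DRP reliability depends only on
`r2_i` and `r2_PA`, not on $h^2$.

# Validation designs

`make_cv_folds()` builds repeated 5-fold partitions of the genotyped
animals (sizes differing by at most one; repeat $r$ seeded with
`seed + r`). `run_scenario()` masks the test animals' records and
refits with raw phenotypes as the response — using DRPs as the
response and a simplified model would discard information, so DRPs
serve only as the benchmark on the correlation side. For GBLUP only
genotyped training animals contribute records; for ssGBLUP every
non-test animal does. Variance components are estimated once on the
full data and held fixed across folds. `forward_split()` trains on the
older generations and tests on the newest two, reporting the
pedigree/genotyped/phenotyped counts on each side; the forward test
set for predictive ability is the genotyped new-generation animals
holding a valid DRP, and the eligibility counts are logged because
that intersection, not the full genotyped test set, is what a
correlation can use.

The cross-validation standard error is reported as the SD across all
fold-level correlations divided by $\sqrt{k \cdot \mathrm{repeats}}$;
the convention is recorded in the output.

# The synthetic-data generator

The generator's defaults emulate the structure of a large Duroc AI
station dataset: a 12-generation pedigree of ~5,300 animals (444
founders, 220 dams and 44 sires per generation, litters of two with
sexes balanced within litter so mating pools cannot run dry by
chance), ~1,300 phenotyped boars averaging 22.6 records each, 16
year-season classes, about a third of the animals genotyped on a
36k-SNP panel with 0.14% missing genotypes, and the five
sperm-abnormality traits with their published variance components and
genetic correlation matrix (`sperm_trait_params()`; the correlation
matrix is numerically positive definite as printed, smallest
eigenvalue 0.035).

True breeding values are pedigree-polygenic: founders are drawn from
$N(0, \Sigma_a)$ and descendants as parent average plus a Mendelian
sampling deviation with covariance $0.5(1 - (F_s + F_d)/2)\Sigma_a$,
which makes $\mathbf{A}$ the exact covariance of the truths — the
right null model for testing an $\mathbf{A}$-based estimator. An
optional markers mode draws SNP effects instead, for marker-based
recovery checks. Loci are unlinked (gene dropping with independent
segregation); none of the implemented analyses uses linkage. Record
counts are zero-truncated Poisson; year-season classes are uniform;
boars enter at 8–16 months and age by their collection intervals
(3 + Poisson(4) days); year-season effect SDs default to the residual
SD, and the age and interval slopes default to 0.01 and 0.005 residual
SDs per unit — values chosen once as plausible nuisance-effect sizes,
all overridable.

What the generator does *not* emulate: selection (matings are
random), overlapping generations, the measurement process behind the
abnormality percentages (records are Gaussian, not bounded
percentages), genotyping error, and linkage disequilibrium. Passing
recovery tests therefore demonstrates correctness of the estimation
machinery under the model's own assumptions, not robustness to the
ways real station data violate them.

# Problem sizes and reproducibility

The parameter-recovery experiments (tests and `scripts/acceptance.R`)
run ~1,000 phenotyped boars with ~20 records each on a ~2,650-animal,
12-generation pedigree — about 20,000 records per replicate, 10
replicates per single-trait target and 5 for the bivariate target.
These sizes keep a full recovery study in the tens of minutes on one
core while leaving Monte-Carlo error around 0.01 on a mean
heritability. The pipeline demo configuration
(`pipeline_demo_sim()`: ~800 animals, 300 boars, 1,200 SNPs) exercises
every stage end to end in minutes. All randomness flows from explicit
integer seeds: identical configuration plus seed reproduces every
table byte for byte.

# Known limitations

* The bivariate engine requires the two traits to share the record
  structure; traits with partially disjoint recording would need a
  missing-data extension.
* At the recovery scale (~1,000 boars, 15 records), the bivariate
  genetic-correlation estimate of a near-unity correlation involving a
  very low-heritability trait is noticeably noisy (replicate SD around
  0.05–0.1) and can sit slightly inside the boundary on average; the
  acceptance run therefore averages replicates.
* Reliabilities use $1 - \mathrm{PEV}/\sigma^2_a$ without the
  $(1+F_i)$ adjustment, matching the convention the de-regression
  recipe expects.
* No unknown-parent groups, metafounders, dominance, or weighted
  ssGBLUP; the blend weight is a single scalar.
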