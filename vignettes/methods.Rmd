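---
title: "Test-day random regression models and EBV association scans: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Test-day random regression models and EBV association scans: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rrmgwas)
```

This vignette is the package's own account of its models, the synthetic
data they are exercised on, and the numerical choices that were open.

## 1. The test-day model

A test-day record of cow $l$ at days in milk (DIM) $t$ is modelled as

$$y = \mathrm{HTD}_i + \mathrm{Age}_j + \mathrm{Season}_k +
      \sum_{m=0}^{M} a_{lm}\,\varphi_m(\omega) +
      \sum_{m=0}^{M} p_{lm}\,\varphi_m(\omega) + e,$$

where $\omega = 2(t - 5)/(305 - 5) - 1$ standardizes DIM onto
$[-1, 1]$ and $\varphi_m$ are Legendre polynomials. We use the
*normalized* form $\varphi_m = \sqrt{(2m+1)/2}\,P_m$ — the common
convention in test-day models, chosen here because it keeps the
coefficient covariances on comparable scales; the model class is
invariant to this choice (it only reparameterizes $G$ and $P$).

The fixed effects are herd–test-date (HTD), calving-month × age class,
and calving-year × season class (calendar quarters by default; the
class systems are configurable because no canonical binning exists).
The additive coefficients $a_l \in \mathbb{R}^{M+1}$ have
$\mathrm{Var}(a) = G \otimes A$ with $A$ the pedigree numerator
relationship matrix; the permanent-environment coefficients are
i.i.d. with $\mathrm{Var}(p) = P \otimes I$; residuals are homogeneous,
$\mathrm{Var}(e) = I\sigma^2_e$. Heterogeneous residual classes,
multi-trait fits and genomic (single-step) relationship matrices are
out of scope; fits are single-trait.

Derived quantities are quadratic forms in the basis:
$v_a(t) = \varphi(t)^\top G \varphi(t)$,
$h^2(t) = v_a / (v_a + v_{pe} + \sigma^2_e)$,
$r(t_1,t_2) = \varphi_1^\top G \varphi_2 / \sqrt{v_a(t_1) v_a(t_2)}$,
and the DIM-specific EBV $\varphi(t)^\top \hat a_l$. Because
$\hat G$ is kept positive semi-definite, estimated correlation grids
are valid correlation matrices by construction.

### Basis order

The basis order is fully generic in the code with default 5, the order
typically selected for full-lactation curves. The bundled analysis
scripts and the validation experiments use order 2: at a few hundred to
a thousand cows the higher-order coefficients are weakly identified,
and order 2 keeps every experiment comfortably inside a desktop run
while exercising exactly the same code paths.

## 2. Pedigree algebra

`nrm()` uses the tabular method; `inbreeding()` computes $F$ by
back-tracing ancestor contributions through the $A = LDL^\top$
factorization (no dense matrix is formed), and `nrm_inverse()` applies
Henderson's rules with inbreeding-corrected Mendelian-sampling
variances $d_i$, so $\log|A| = \sum_i \log d_i$ is available for the
restricted likelihood at no extra cost.

A finite `max_generations` cap truncates each animal's ancestor
pedigree at that depth (parents = depth 1); truncated ancestors are
treated as unrelated non-inbred founders, and $F$ is recomputed inside
the truncated sub-pedigree. This mirrors the practice of computing
inbreeding "going back $g$ generations"; the treatment of truncated
founders is an explicit decision since no standard is defined.

## 3. REML

`reml_fit()` assembles Henderson's mixed-model equations in
$R^{-1}$-form with ridge terms $A^{-1} \otimes G^{-1}$ and
$I \otimes P^{-1}$. The permanent-environment equations are block
diagonal per cow and are absorbed analytically; the remaining
fixed+additive system is factorized densely (Cholesky), which is exact
and fast up to a few thousand animals — the intended scale of the
package. Iterations are EM-REML updates:

* $\hat G \leftarrow \tfrac1q \sum_{ij} A^{-1}_{ij}
  (\hat a_i \hat a_j^\top + C^{a_i a_j})$, and analogously for $P$
  from the per-cow inverse blocks;
* $\hat\sigma^2_e \leftarrow (y^\top y - \hat\theta^\top W^\top y)/(n -
  \mathrm{rank}(X))$,

which are monotone in the restricted likelihood. Because plain EM can
crawl when $G$ and $P$ are weakly separated, each iteration also
proposes an average-information (AI) Newton step computed from the same
factorization (the AI traces reduce to sparse contractions via
$\Sigma^{-1}(A \otimes E)\Sigma^{-1} = A^{-1} \otimes G^{-1} E G^{-1}$).
The AI step is accepted only if the restricted likelihood does not
decrease (with step halving on failure), otherwise the EM update is
taken — so the monotone-likelihood property holds over accepted
iterations unconditionally, which the tests assert. Convergence is
declared at a relative parameter change below `tol` (default $10^{-6}$,
maximum 500 iterations); covariance estimates are projected onto the
PSD cone with a small relative eigenvalue floor ($10^{-8}$), and a
boundary collapse (a component heading to zero faster than the system
can be factorized) retreats halfway rather than aborting.
Non-convergence is reported through `converged = FALSE`, not an error.

Fixed-effect levels that are exactly confounded are an error in
`build_mme()` (named in the message); `reml_fit()` instead drops
aliased columns, the generalized-inverse convention of animal-model
software, because small simulated HTD cells occasionally alias by
chance.

## 4. The synthetic population

The generator is the package's study system, not a test fixture; its
defaults define the conditions every experiment runs under.

* **Pedigree** — either a nested design (dams tracked, one sire per dam
  and generation, so dam families are full sibs) or a classical
  paternal half-sib design (sires only, dams unknown). The final
  generation is all female: the recorded cow cohort.
* **Genotypes** — founder alleles at frequencies uniform in
  `maf_range`, gene-dropped through the pedigree with independent loci
  spread over `n_chrom` chromosomes. Independence of loci means no
  linkage disequilibrium: association signals are confined to the
  causal markers themselves, which is what the planted-truth tests
  need. It is also the main respect in which the simulation is easier
  than real data — fine-mapping ambiguity, LD decay and imputation
  noise are absent, so passing tests say nothing about those.
* **True curves** — additive coefficients sampled by the pedigree
  recursion $a_i = \tfrac12(a_s + a_d) + m_i$,
  $m_i \sim N(0, d_i G)$, which realizes $\mathrm{Var}(a) = A \otimes
  G$ exactly without forming $A$; permanent-environment coefficients
  i.i.d. $N(0, P)$. Optionally part of the intercept variance
  (`qtl_prop`, default 0.3) is reassigned to `n_qtl` planted markers so
  association scans have known truth; the polygenic remainder keeps
  $G$ intact in expectation because gene-dropped dosages themselves
  carry the $A$ structure.
* **Records** — milk yield, fat %, protein % and SCS are simulated as
  primary traits (milk-yield-scale components multiplied by
  `trait_var_scale`); fat and protein yield are *derived* by the
  component-yield formulas plus 0.01 kg/d measurement noise, and the
  somatic cell count is the inverse SCS transform — so the derivation
  step of the QC module is exercised nontrivially. Defaults give
  phenotypes matching typical first-lactation descriptive statistics
  (MY $\approx 28 \pm 8$ kg/d, FP $\approx 3.6 \pm 0.9$\,\%, SCS
  $\approx 2.8 \pm 1.9$).
* **Calving design** — cows calve in cohorts spaced in multiples of
  the 30-day test interval across two years. This makes herd-test-date
  cells mix cohorts (so season stays estimable next to HTD) and places
  several calving months in each season (so the month-age classes do
  not determine the season class). True fixed effects are i.i.d.
  normal per level with configurable SDs (defaults 2/1/1 kg on the
  milk-yield scale).
* **Reproducibility** — one integer seed; per-stage sub-seeds are
  derived deterministically, so each stage is a pure function of
  (config, seed).

The record- and cow-level inclusion criteria implement the standard
DHI edits: age at first calving 19–37 months, DIM 5–305, milk 1–65
kg, fat 0.5–8.5%, protein 0.5–7.5%, all inclusive; SCC strictly below
2{,}000 (thousand cells/mL), because "less than 2 million" is an open
bound; at least three surviving tests per cow, one before DIM 45;
calving before December 2019. SCC is carried in 1,000 cells/mL (the
DHI convention), making the score transform $\log_2(\mathrm{SCC}/100)
+ 3$ equal 3 at 100. Age at first calving is a calendar-month
difference with the day of month ignored.

## 5. Association scans

Responses are DIM-specific EBVs $\varphi(t)^\top \hat a$ at the five
lactation stages TD7/TD35/TD50/TD140/TD280 (early, peak, mid, late).
Deregression of EBVs is deliberately not applied; the trajectory value
is the implemented definition of the response.

* **QC** — samples with call rate < 0.95, then SNPs with call rate
  < 0.90, Hardy–Weinberg exact-test $p < 10^{-6}$, or MAF < 0.05. The
  HWE test is the conditional exact test given allele counts (sum of
  probabilities of heterozygote counts no more probable than observed),
  computed via log-factorials; the test suite checks it against an
  independent recurrence-based enumeration for every configuration up
  to $n = 50$.
* **GRM** — VanRaden method 1, $ZZ^\top / (2\sum p_j(1-p_j))$, with
  per-SNP mean imputation of missing dosages. PCA is the
  eigendecomposition of the GRM; the top three components are fitted
  as covariates in both scans.
* **MLM** — P3D: the variance ratio $\delta = \sigma^2_e/\sigma^2_a$
  is estimated once by REML under the no-marker null through the
  spectral decomposition of the GRM, then every marker is tested by
  weighted least squares in the rotated basis with a $t$-test
  ($n - c - 1$ df) that re-estimates the residual scale per marker —
  so forcing $\sigma^2_a = 0$ reduces the scan *exactly* to per-marker
  OLS, an oracle identity the tests exploit. P3D shows the documented
  mild conservatism (genomic $\lambda \approx 0.9$–$1.0$ on true
  nulls).
* **FarmCPU-style scan** — alternates a fixed-effect scan (every
  marker tested with the current pseudo-QTNs as covariates; markers
  sharing a bin with a pseudo-QTN are tested leaving those QTNs out)
  with pseudo-QTN reselection: markers are ranked by p-value within
  genomic bins, and the bin-size/count combination
  (bins $\{0.5, 5, 50\}$ Mb, counts $\{5, 10, 20, 50\}$ capped at
  $n/10$) that maximizes the restricted likelihood of the random model
  $y = \mu + u + e$, $u \sim N(0, 2K\sigma^2_u)$ with $K$ built from
  the candidate QTNs, is kept. Iteration stops when the pseudo-QTN set
  repeats or after 10 rounds; if no marker reaches $0.01/m$ in the
  first scan the GLM results are returned with a warning. These
  internals follow the published method's defaults. On small,
  family-structured EBV responses the conditional tests are visibly
  anti-conservative in $\lambda$ terms (a known property of multi-locus
  scans); the package therefore validates the procedure by type-I
  error on true nulls (where it reduces to the calibrated GLM) and by
  power on planted QTL, not by $\lambda$.
* **Significance** — fixed thresholds $5\times10^{-8}$ (genome-wide)
  and $5\times10^{-6}$ (suggestive); no FDR procedure. The genomic
  inflation factor is median-based,
  $\lambda = \mathrm{median}(\chi^2_1(1-p))/0.4549$.

## 6. Annotation

Significant SNPs are extended 150 kb up- and downstream (clipped at
position 1; 1-based inclusive coordinates throughout, with BED input
shifted on read). Genes are reported when their interval intersects
the window, with the nearest gene and its distance reported for empty
windows. QTL intervals of 1 Mb or larger are discarded; a trait-DIM
cell counts each significant SNP once per QTL class it touches (a SNP
overlapping several classes counts in each; several QTL of one class
still count once). Interval arithmetic is delegated to
GenomicRanges, and every overlap path is cross-checked against a
brute-force all-pairs oracle in the tests.

## 7. Validation experiments and their scale

The acceptance suite (`tests/testthat/test-acceptance.R`) runs, per
design choice:

* pedigree algebra against memoized-recursion oracles on ten random
  pedigrees up to 50 animals, including the full-sib-mating $F = 0.25$
  case and a pedigree whose only inbreeding loop sits at generation 4
  (invisible at a 3-generation cap);
* order-0 REML against closed-form balanced one-way ANOVA estimators
  (tolerance $10^{-6}$), with the likelihood trace asserted monotone;
* order-2 parameter recovery at 800 cows (80 paternal half-sib
  families of 10; 10 test days each). A design study across candidate
  pedigrees showed the single-replicate sampling SD of $\hat h^2(t)$
  at this size is 0.03–0.06, so recovery is judged on the mean curve
  over five replicate simulate+fit runs with fixed seeds against the
  analytic truth at ±0.05, and the estimated correlation surface must
  reproduce the adjacent-greater-than-distant ordering of the truth;
* MLM calibration on three replicate nulls of 1,000 samples × 2,000
  truly null markers (the polygenic background is drawn from a
  disjoint set of independent loci — drawing it from the tested panel
  makes every marker causal and $\lambda$ then measures real signal,
  about 1.10 at these sizes, rather than miscalibration): mean
  $\lambda \in [0.9, 1.1]$, mean type-I error inside its 95% binomial
  interval, per-replicate KS uniformity at $\alpha = 0.01$;
* FarmCPU power: a planted QTL explaining 10% of the response variance
  must reach $5\times10^{-8}$ in at least 18 of 20 replicates;
* the HWE exhaustive sweep, hand-counted filter fixtures, brute-force
  overlap oracles, and a bit-for-bit double run of the full pipeline.

The full default suite completes in roughly a quarter hour on one CPU.

## 8. Known limitations

No linkage disequilibrium, no genotype imputation errors, no
heterogeneous residuals, no multi-parity records, no selection in the
simulated pedigrees (matings are random), and dense factorization
limits REML to a few thousand animals. Real-data peculiarities the
simulator does not emulate — lactation-curve shape families
(Wilmink/Ali–Schaeffer), heat-stress responses, non-normal SCS tails —
mean that passing tests demonstrate correctness of the algorithms
under the stated model, not robustness to violations of it.
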