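---
title: "Methods: dominant-model association and Bayesian-network relevance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dominant-model association and Bayesian-network relevance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`dopanet` analyses candidate-gene case-control panels of SNPs and VNTRs —
its running example is an 11-marker dopaminergic panel (COMT, ANKK1, DRD2,
DRD4, SLC6A3) typed in a heroin-dependence cohort of 303 cases and 555
controls — with two complementary layers:

1. a **frequentist single-marker and haplotype layer**: dominant-model
   chi-square association with odds ratios, Hardy-Weinberg diagnostics,
   Bonferroni correction, exact 2x2 tests, stratified two-locus tables,
   EM haplotype frequencies, pairwise LD and a haplotype likelihood-ratio
   test; and
2. a **Bayesian-network based Bayesian multilevel analysis (BN-BMLA)
   layer** that treats every dominant-coded marker and the phenotype as
   nodes of a discrete Bayesian network, samples the posterior over
   network structures, and summarizes which variables are *strongly
   relevant* to the phenotype via Markov blanket posteriors.

This vignette documents the models, the tunable parameters, the numerical
policies, and what the synthetic-data generator does and does not emulate.

# The dominant coding

Every analysis operates on carrier status: a marker with grouping allele
$g$ codes a genotype as 1 when at least one copy of $g$ is present. For
biallelic SNPs $g$ is the control-stratum minor allele; for multi-allelic
VNTRs it is the second most frequent repeat allele (7-repeat of the DRD4
exon-3 VNTR, 9-repeat of the SLC6A3 40 bp VNTR, the 2-repeat intron-8
allele and the non-duplicated "1" allele of the 120 bp promoter
duplication). Frequency ties are broken lexicographically so the coding is
deterministic. Missing genotypes propagate as `NA` and each downstream
stage handles them by available-case or complete-case analysis — marker
panels genotyped with different success rates therefore keep their
per-marker `N`, which is why missingness is representable in the dataset
container rather than dropped at load time. A genotype with only one
readable allele is treated as missing.

# Single-marker layer

**Association.** Each marker yields a 2x2 carrier-by-phenotype table
tested with the Pearson chi-square (1 df) *without* continuity correction;
the odds ratio is the cross-product ratio with a Wald 95% interval on the
log scale, $\exp(\log \mathrm{OR} \pm z_{0.975}\sqrt{\sum 1/n_{ij}})$.
Tables with an empty cell report the degenerate OR with a `zero_cell` flag
rather than a silent 0.5 continuity correction — published reference
tables contain no zero cells, so no correction convention can be inferred
from them, and flagging keeps the choice with the analyst.

**Hardy-Weinberg.** The HWE statistic is the Pearson goodness of fit of
the three carrier classes against $p^2, 2pq, q^2$ at the sample allele
frequency. The reference df is selectable: the conventional test uses 1 df
(three classes minus one estimated frequency), but the package defaults to
2 df because the reference tables it reproduces were computed under that
convention (verified numerically: the printed values are
$e^{-\chi^2/2}$). Both modes share the same statistic, and the 1-df
p-value never exceeds the 2-df p-value, which the test suite asserts. For
VNTRs the test applies to the collapsed pseudo-biallelic classes
(grouping allele vs pooled others) — the same two-allele system the
dominant model uses.

**Exact 2x2 tests.** Two exact variants are exposed. `fisher_exact_2x2`
is Fisher's rule (sum of hypergeometric tables *at most as probable* as
observed). `exact_pearson_2x2` is the exact conditional Pearson test (sum
of tables whose chi-square statistic is *at least* the observed one), the
variant that common commercial statistics suites print as "Exact Sig.
(2-sided)" and the one under which the package's stratified reference
table reproduces; it is therefore the default in
`stratified_association()`. The two rules differ only in how they order
the tail.

**Multiplicity.** `bonferroni_adjust()` flags $p <$ `alpha`$/m$; with the
11-marker panel at $\alpha = 0.05$ the threshold is $0.0045$.

# Haplotype and LD layer

**EM.** `em_haplotype_frequencies()` runs a multinomial EM over the
phase-ambiguous expansions of each multilocus genotype ($2^{h-1}$
unordered haplotype pairs for $h$ heterozygous loci). Initialization is
the deterministic *phase-uniform expansion* (each compatible pair equally
weighted), chosen over random restarts because the 2-3 locus case-control
likelihoods handled here are unimodal in practice and reproducibility is
worth more than restart insurance. Convergence is declared when the
largest frequency change drops below `tol` = 1e-8 (cap `max_iter` = 1e4);
the log-likelihood is asserted non-decreasing at every iteration and a
decrease raises an error rather than a warning. Subjects missing any
involved marker are excluded from that marker subset's analysis.

**LD.** For a marker pair with focal (grouping) alleles A and B,
$D = p_{AB} - p_A p_B$, $D' = D / D_{\max}$ with the usual sign-dependent
bound, and $r^2 = D^2 / (p_A p_a p_B p_b)$. A monomorphic locus leaves
the statistics undefined and flagged instead of silently zero.

**Haplotype association.** The likelihood-ratio test compares
stratum-specific against shared haplotype frequencies,
$\mathrm{LRT} = 2(\ell_{\text{cases}} + \ell_{\text{controls}} -
\ell_{\text{pooled}})$, with df equal to the number of haplotypes whose
pooled EM frequency exceeds $10^{-6}$, minus one — numerically-zero
haplotypes carry no likelihood dimension and counting them would inflate
the df. On phase-known data this LRT equals the multinomial G-test on the
observable haplotype counts, which the suite uses as an oracle.

# BN-BMLA layer

**Model.** All dominant-coded markers and the phenotype are discrete
nodes of a Bayesian network. For variable $i$ with $r_i$ states and a
parent configuration $j$, the Cooper-Herskovits (K2) marginal likelihood
under a uniform Dirichlet parameter prior is, in log space,

$$\log P(D \mid G) = \sum_i \sum_j \Big[ \ln\Gamma(r_i) -
\ln\Gamma(N_{ij} + r_i) + \sum_k \ln\Gamma(N_{ijk} + 1) \Big].$$

The structure prior is uniform over DAGs satisfying the maximum-parent
bound; the Cooper-Herskovits prior governs parameters, not structures, so
uniformity is the natural default. The phenotype is an ordinary node with
no direction constraint — Markov blanket semantics are direction-agnostic.

**Sampling.** `structure_mcmc()` is a Metropolis-Hastings random walk
whose proposals are single-edge additions, deletions and reversals drawn
uniformly from the currently valid moves, with the Hastings
neighborhood-size correction $|N(G)|/|N(G')|$. Acyclicity is enforced by
reachability checks and family scores are cached by (variable,
parent-set) key, so each step costs two move enumerations and at most two
score lookups. Full-scale defaults mirror a production analysis —
$8\times10^6$ steps, $10^6$ burn-in, 5 maximum parents, thinning 100 —
while tests and examples use $10^4$-$10^6$ steps, which the calibration
checks below show is ample at 4-12 variables. The sampler consumes R's
RNG stream, so a `set.seed`-style seed makes runs bit-reproducible.

**Relevance summaries.** From the sampled structures the package reports
the Markov blanket membership posterior MBM$(Y, X_i)$ (fraction of
structures whose blanket of $Y$ — parents, children, children's other
parents — contains $X_i$), the exact-set posterior MBS$(Y)$, and directed
edge posteriors. The accounting identity
$\mathrm{MBM}(X_i) = \sum_{S \ni X_i} \mathrm{MBS}(S)$ holds exactly on
every sample collection and is asserted in the tests.

**Interaction and redundancy.** For a predictor pair,
$R = P(\text{both} \in \mathrm{MB}) / P(\text{exactly one} \in
\mathrm{MB})$, with $IR = \ln R$ and $RR = -\ln R$; $R > 1$ flags an
interaction, $R < 1$ a redundancy, and a redundancy ratio of e.g. 1.201
means solitary membership is $e^{1.201} \approx 3.32$ times as probable
as joint membership. The denominator choice "exactly one" is the
operational reading of solitary membership; an alternative
`"independence"` variant ($R = P(\text{both})/(\mathrm{MBM}_i \cdot
\mathrm{MBM}_j)$) is exposed because the two differ only in magnitude,
not in which side of 1 they fall on in the motifs studied here.
Degenerate numerators/denominators are flagged (`infinite`, `undefined`)
rather than corrected.

**Exact oracle.** `exhaustive_posterior()` enumerates every DAG on at
most 5 variables (29,281 at 5 nodes before the parent bound), weights by
the CH score with log-sum-exp normalization, and returns the same summary
object. It exists so the MCMC can be validated against an exact answer;
the suite requires MBM agreement within 0.01 on seeded 4-variable
datasets at $6\times10^5$ steps.

**Relevance tree.** The dendrogram of jointly relevant subsets starts at
the empty model with posterior 1.0 and greedily extends each node by the
variable with the highest joint-membership posterior
$P(S \subseteq \mathrm{MB}(Y))$, pruning below a floor (default 0.01).
Child posteriors can never exceed their parent's (conjunction
monotonicity), which the tests walk the tree to verify.

**Missing data.** The BN stage defaults to complete-case analysis across
the modeled variables; a `"category"` mode treats missingness as an own
state for analysts who prefer to keep partially typed subjects. Neither
mode imputes.

# The synthetic-data generator

`simulation_config()` describes a population, `simulate_dataset()` draws
case-control samples from it by rejection — the retrospective sampling
scheme of a case-control design, chosen over inverting the logistic model
because it is simple and exact. Components:

* **LD blocks**: two haplotypes per subject per block;
  `two_locus_haplotypes()` constructs the 4-haplotype table analytically
  from the marginals and a requested $D'$, so generated pools reproduce
  the requested $D'$ to within numerical round-off.
* **Independent markers**: allele draws at specified frequencies, with an
  optional inbreeding coefficient $F$ (duplicate one allele with
  probability $F$) for controlled HWE deviation.
* **Mediation edges**: a downstream marker drawn with different
  grouping-allele frequency in carriers vs non-carriers of an upstream
  marker, inducing a marker-to-marker dependency whose only path to the
  phenotype runs through the mediator.
* **Disease model**: logistic in the dominant codes, with optional
  pairwise interaction terms. Effect modification (an effect present only
  in one stratum of another marker) is encoded as a cancelling
  interaction term; mediation and effect modification are separate
  mechanisms because they exercise different analysis findings
  (an indirect network edge vs a stratified odds ratio).

`study_simulation_config()` fixes the defaults to the reference study's
conditions: quotas of 303 cases and 555 controls, the 11-marker panel at
its control-stratum allele frequencies, two tightly linked SNP pairs
(TaqIA~TaqIB and DRD4 -615~-616, both $D' = 0.98$), a TaqIB dominant
log-odds of $\ln 1.61$ (TaqIA associates only through LD, which is what
makes the pair redundant in the network layer), and the promoter motif in
which the -521 C allele is protective ($\ln(1/1.77)$) only in
non-carriers of the -615 G allele. Missingness defaults to 0; tests that
need varying per-marker `N` set it explicitly.

**What the generator does not emulate:** population history (LD is
specified per block, not emergent), between-block LD (the third DRD2
marker, TaqID, is drawn independently although the real panel shows
asymmetric linkage to its neighbours), population stratification,
genotyping error, and informative missingness. Passing tests on this
generator therefore demonstrate calibration and recovery under the stated
statistical structure, not robustness to the confounders of real cohort
data.

# Numerical policies and degenerate inputs

* All network scores and posterior normalizations are in log space
  (log-sum-exp); the EM guards zero-support genotypes.
* Allele pairs are unordered and canonicalized at construction, so token
  order never influences any statistic (asserted by tests).
* Monomorphic markers: HWE returns $p = 1$ flagged; LD is flagged
  undefined; the minor allele of a monomorphic column is the absent
  allele at frequency 0.
* Frequency ties in minor-allele determination break lexicographically.
* Empty strata, all-missing markers, self-parenting, oversized
  enumeration requests and unattainable simulation quotas raise errors
  naming the offending input.

# Problem sizes used by the checks

The test suite and the acceptance script run, per design: exhaustive
enumeration up to 5 variables; MCMC-vs-exact calibration at 4 variables,
$n = 400$, $6\times10^5$ steps; mediation and redundancy motif recovery
over 10 seeds at $n = 2000$ subjects and $4\times10^4$ steps; EM recovery
at $n = 2000$; and 500 null replicates at $n = 500$ for the type-I error
of the dominant test. These sizes were chosen so each property is
measured with comfortable Monte-Carlo margin while the whole suite stays
interactive.

# Known limitations

* The haplotype LRT uses the standard case-control haplotype likelihood;
  specialized software differs in its treatment of rare haplotypes and
  partially missing genotypes, so third-party haplotype p-values are not
  expected to reproduce digit-for-digit.
* The exhaustive oracle stops at 5 variables; beyond that only MCMC
  (with its Monte-Carlo error) is available, and no exact large-panel
  averaging (e.g. order-based dynamic programming) is implemented.
* No covariate adjustment and no additive/recessive/genotypic models:
  the analysis layer is deliberately scoped to the dominant model.
* VCF/PLINK import is out of scope for this version; the delimited-text
  format plus marker configuration is the only adapter.
* One printed control-stratum HWE entry and one VNTR row of the package's
  reference association table are internally inconsistent with their own
  published class counts; the reproduction tests cover every row that
  recomputes and the remaining two are documented exclusions.
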