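# dopanet

Case-control association and Bayesian-network relevance analysis for
candidate-gene panels of SNPs and VNTRs, built around an 11-marker
dopaminergic panel (COMT, ANKK1, DRD2, DRD4, SLC6A3) typed in a
heroin-dependence cohort of 303 cases and 555 controls. It is aimed at
statistical geneticists who want the classical single-marker and haplotype
toolchain and a systems-level relevance analysis in one reproducible
pipeline.

Two layers share one dominant (carrier) coding — each marker is 1 when the
genotype carries its grouping allele (the control-stratum minor allele for
SNPs, the second most frequent repeat for VNTRs):

* **Frequentist layer.** Per marker: Pearson chi-square on the 2x2
  carrier-by-phenotype table (1 df, no continuity correction), odds ratio
  OR = (case_carrier * control_noncarrier) / (case_noncarrier *
  control_carrier) with Wald 95% CI, Hardy-Weinberg goodness-of-fit
  diagnostics (selectable df), Bonferroni correction (alpha/m), exact 2x2
  tests (Fisher and exact Pearson), stratified two-locus tables, EM
  haplotype frequencies from unphased genotypes, pairwise LD (D, D', r^2)
  and a case-control haplotype likelihood-ratio test.
* **BN-BMLA layer.** Markers + phenotype are nodes of a discrete Bayesian
  network scored with the Cooper-Herskovits (K2) marginal likelihood,

  log P(D|G) = sum_i sum_j [ lnGamma(r_i) − lnGamma(N_ij + r_i) +
  sum_k lnGamma(N_ijk + 1) ],

  sampled by Metropolis-Hastings structure MCMC (add/delete/reverse edge
  moves, Hastings neighborhood correction, bounded in-degree, uniform
  structure prior). Reported: Markov blanket membership posteriors
  MBM(Y, X_i), exact blanket-set posteriors MBS(Y), edge posteriors, a
  consensus network and a relevance dendrogram, plus pairwise
  interaction/redundancy ratios R = P(both in MB) / P(exactly one in MB),
  IR = ln R, RR = −ln R. An exhaustive-enumeration oracle (≤ 5 variables)
  validates the sampler.

A synthetic-data module generates case-control panels with configurable
LD blocks, HWE deviation, logistic disease models, epistasis and
mediation structure, so the whole pipeline is testable end to end.

## Worked example

The package embeds the published per-marker genotype counts of its
reference cohort as fixtures, plus a small simulated example dataset
under `inst/extdata` (`example_genotypes.tsv` + `example_markers.yaml`).

```r
library(dopanet)

# single-marker layer on the published count tables
fx <- table1_fixture()
dominant_association(fx$TaqIB$case, fx$TaqIB$control)
#> <association> TaqIB: chi2=9.046 p=0.002633 OR=1.61 (1.18-2.20)

scan <- single_marker_scan(fx)   # 11 markers, Bonferroni at 0.05/11
scan[scan$bonferroni_significant, c("marker", "p", "odds_ratio")]
#>   marker       p odds_ratio
#> 3  TaqIB 0.00263       1.61
```

The TaqIB minor-allele carriers are over-represented among cases
(OR 1.61, 95% CI 1.18-2.20); at the family-wise threshold 0.05/11 =
0.0045 it is the only marker that survives correction.

```r
# simulate the study conditions and run the network layer
cfg <- study_simulation_config(n_cases = 303, n_controls = 555)
sim <- simulate_dataset(cfg, seed = 1)
round(ld_matrix(sim, c("TaqIA", "TaqIB", "TaqID"))$d_prime, 3)
#>        TaqIA  TaqIB  TaqID
#> TaqIA  1.000  0.995 -0.161
#> TaqIB  0.995  1.000 -0.109
#> TaqID -0.161 -0.109  1.000

smp <- structure_mcmc(dominant_code(sim), steps = 2e5, burn_in = 2e4,
                      seed = 1, thin = 100)
rel <- relevance_posteriors(smp)
ir <- interaction_redundancy(rel, "TaqIA", "TaqIB")
sprintf("TaqIA/TaqIB R = %.3f, RR = %.3f", ir$R, ir$RR)
#> "TaqIA/TaqIB R = 0.087, RR = 2.438"
```

The two simulated TaqI SNPs were generated in tight LD (D' = 0.98;
recovered here as 0.995), and the network layer sees them as redundant:
RR > 0 says that exactly one of the pair sitting in the phenotype's
Markov blanket is far more probable than both — carrying the same signal,
they compete rather than cooperate. `run_pipeline()` sequences all stages
and writes TSV/JSON/DOT outputs stamped with the seed and a configuration
hash; `inst/exec/dopanet` wraps it for shell use.

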