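#' Two-locus haplotype frequencies at a requested D'
#'
#' Analytic construction of the four haplotype frequencies of two biallelic
#' loci with marginal allele frequencies `p1`, `p2` (for the "A" and "B"
#' alleles) and standardized linkage disequilibrium `D' = D / Dmax`. Because
#' `Dmax` is the feasibility bound for the requested sign of D, any
#' `|D'| <= 1` yields a valid (non-negative) frequency table, and
#' recomputing D' from the table recovers the request exactly.
#'
#' @param p1,p2 Allele frequencies in (0, 1).
#' @param d_prime Standardized LD coefficient in `[-1, 1]`.
#' @return Named numeric vector `c(AB, Ab, aB, ab)` summing to 1.
#' @export
two_locus_haplotypes <- function(p1, p2, d_prime) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, abs(d_prime) <= 1)
  dmax <- if (d_prime >= 0) min(p1 * (1 - p2), (1 - p1) * p2)
          else min(p1 * p2, (1 - p1) * (1 - p2))
  D <- d_prime * dmax
  h <- c(AB = p1 * p2 + D, Ab = p1 * (1 - p2) - D,
         aB = (1 - p1) * p2 - D, ab = (1 - p1) * (1 - p2) + D)
  # guard tiny negative round-off
  h[h < 0 & h > -1e-12] <- 0
  h / sum(h)
}

#' Simulation configuration for synthetic case-control genotype data
#'
#' Describes a population of unlinked marker blocks and a logistic disease
#' model on the dominant codes, from which case-control samples are drawn
#' by rejection. Each component:
#'
#' * `markers`: named list of [marker_definition()]s; each must also appear
#'   in `freqs` unless it belongs to an LD block or a mediation edge.
#' * `freqs`: named list of allele-frequency vectors (named by allele label,
#'   summing to 1) for independently drawn markers.
#' * `fis`: optional named numeric of inbreeding coefficients (default 0;
#'   positive values inflate homozygosity, i.e. a specified HWE deviation).
#' * `ld_blocks`: list of blocks; a block is `list(markers = c(m1, m2),
#'   d_prime = ...)` for two biallelic markers (the block haplotype table is
#'   built with [two_locus_haplotypes()] on the grouping-allele
#'   frequencies), or `list(markers = ..., haplotypes = <matrix>,
#'   hap_freqs = <vector>)` with explicit haplotype rows of allele labels.
#' * `disease_model`: `list(baseline = <log-odds>, beta = <named log-ORs on
#'   dominant codes>, interactions = list(list(markers = c(mi, mj),
#'   beta = ...)))`.
#' * `mediation`: list of `list(from, to, freq_carrier, freq_noncarrier)`
#'   edges: marker `to` (biallelic) is drawn with grouping-allele frequency
#'   `freq_carrier` in carriers of `from`'s grouping allele and
#'   `freq_noncarrier` otherwise, inducing a marker -> marker dependency.
#' * `missing_rate`: per-cell probability a genotype is masked (default 0).
#'
#' @param markers Named list of [marker_definition()]s.
#' @param n_cases,n_controls Sample quotas (> 0).
#' @param freqs Named list of allele frequency vectors.
#' @param fis Named numeric of inbreeding coefficients.
#' @param ld_blocks List of LD block specifications.
#' @param disease_model Logistic disease model specification.
#' @param mediation List of mediation edges.
#' @param missing_rate Missingness probability in `[0, 1)`.
#' @param seed Default RNG seed used by [simulate_dataset()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(markers, n_cases, n_controls,
                              freqs = list(), fis = numeric(),
                              ld_blocks = list(),
                              disease_model = list(baseline = 0,
                                                   beta = numeric(),
                                                   interactions = list()),
                              mediation = list(),
                              missing_rate = 0, seed = NULL) {
  stopifnot(n_cases > 0, n_controls > 0,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(names(markers)))
    names(markers) <- vapply(markers, `[[`, "", "name")
  for (f in freqs) {
    stopifnot(all(f > 0), abs(sum(f) - 1) < 1e-9)
  }
  block_markers <- unlist(lapply(ld_blocks, `[[`, "markers"))
  mediated <- vapply(mediation, `[[`, "", "to")
  covered <- c(names(freqs), block_markers, mediated)
  missing_spec <- setdiff(names(markers), covered)
  if (length(missing_spec))
    stop("no frequency/block/mediation specification for marker(s): ",
         paste(missing_spec, collapse = ", "))
  if (anyDuplicated(c(block_markers, mediated)))
    stop("a marker may appear in at most one LD block or mediation edge")
  dm <- utils::modifyList(list(baseline = 0, beta = numeric(),
                               interactions = list()), disease_model)
  structure(list(markers = markers, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), freqs = freqs,
                 fis = fis, ld_blocks = ld_blocks, disease_model = dm,
                 mediation = mediation, missing_rate = missing_rate,
                 seed = seed),
            class = "simulation_config")
}

block_hap_table <- function(block, cfg) {
  mk <- cfg$markers[block$markers]
  if (!is.null(block$haplotypes)) {
    stopifnot(abs(sum(block$hap_freqs) - 1) < 1e-9)
    return(list(haps = block$haplotypes, freqs = block$hap_freqs))
  }
  stopifnot(length(mk) == 2L)
  g1 <- mk[[1L]]$grouping_allele; o1 <- setdiff(mk[[1L]]$alleles, g1)[1L]
  g2 <- mk[[2L]]$grouping_allele; o2 <- setdiff(mk[[2L]]$alleles, g2)[1L]
  p1 <- if (!is.null(block$p1)) block$p1 else cfg$freqs[[mk[[1L]]$name]][g1]
  p2 <- if (!is.null(block$p2)) block$p2 else cfg$freqs[[mk[[2L]]$name]][g2]
  h <- two_locus_haplotypes(as.numeric(p1), as.numeric(p2), block$d_prime)
  list(haps = matrix(c(g1, g1, o1, o1, g2, o2, g2, o2), 4, 2,
                     dimnames = list(NULL, c(mk[[1L]]$name, mk[[2L]]$name))),
       freqs = unname(h))
}

draw_independent <- function(marker, f, fis, n) {
  alle <- names(f)
  a1 <- sample(alle, n, replace = TRUE, prob = f)
  a2 <- sample(alle, n, replace = TRUE, prob = f)
  if (fis > 0) {
    dup <- stats::runif(n) < fis   # with prob F copy one allele: inflates hom
    a2[dup] <- a1[dup]
  }
  paste(a1, a2, sep = "/")
}

simulate_batch <- function(cfg, n) {
  p <- length(cfg$markers)
  geno <- matrix(NA_character_, n, p,
                 dimnames = list(NULL, names(cfg$markers)))
  for (blk in cfg$ld_blocks) {
    ht <- block_hap_table(blk, cfg)
    i1 <- sample.int(length(ht$freqs), n, replace = TRUE, prob = ht$freqs)
    i2 <- sample.int(length(ht$freqs), n, replace = TRUE, prob = ht$freqs)
    for (m in colnames(ht$haps))
      geno[, m] <- paste(ht$haps[i1, m], ht$haps[i2, m], sep = "/")
  }
  block_markers <- unlist(lapply(cfg$ld_blocks, `[[`, "markers"))
  mediated <- vapply(cfg$mediation, `[[`, "", "to")
  for (m in setdiff(names(cfg$freqs), c(block_markers, mediated))) {
    fis <- if (m %in% names(cfg$fis)) cfg$fis[[m]] else 0
    geno[, m] <- draw_independent(cfg$markers[[m]], cfg$freqs[[m]], fis, n)
  }
  for (med in cfg$mediation) {
    src <- cfg$markers[[med$from]]
    carrier <- vapply(split_tokens(geno[, med$from]),
                      function(pair) src$grouping_allele %in% pair, TRUE)
    mk <- cfg$markers[[med$to]]
    g <- mk$grouping_allele; o <- setdiff(mk$alleles, g)[1L]
    pg <- ifelse(carrier, med$freq_carrier, med$freq_noncarrier)
    a1 <- ifelse(stats::runif(n) < pg, g, o)
    a2 <- ifelse(stats::runif(n) < pg, g, o)
    geno[, med$to] <- paste(a1, a2, sep = "/")
  }
  geno
}

batch_dominant <- function(cfg, geno) {
  out <- matrix(0L, nrow(geno), ncol(geno),
                dimnames = dimnames(geno))
  for (m in names(cfg$markers)) {
    g <- cfg$markers[[m]]$grouping_allele
    out[, m] <- vapply(split_tokens(geno[, m]),
                       function(p) as.integer(g %in% p), 0L)
  }
  out
}

#' Simulate a case-control genotype dataset
#'
#' Draws subjects from the population model of a [simulation_config()] (two
#' haplotypes per subject within each LD block, independent or mediated
#' markers otherwise), assigns disease status from the logistic model on the
#' dominant codes, and fills the case and control quotas by rejection - the
#' retrospective sampling scheme of a case-control design. Cases occupy the
#' first rows of the result. Missingness is applied after phenotype
#' assignment so the disease model always acts on complete genotypes.
#'
#' @param cfg A [simulation_config()].
#' @param seed RNG seed (defaults to `cfg$seed`); identical seeds give
#'   identical datasets.
#' @param max_batches Upper bound on rejection batches before an
#'   unattainable-quota error.
#' @return A [genotype_dataset()].
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed, max_batches = 200L) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  dm <- cfg$disease_model
  need_case <- cfg$n_cases; need_ctrl <- cfg$n_controls
  batch_n <- max(1000L, 2L * (need_case + need_ctrl))
  cases <- list(); ctrls <- list()
  got_case <- 0L; got_ctrl <- 0L
  for (b in seq_len(max_batches)) {
    geno <- simulate_batch(cfg, batch_n)
    x <- batch_dominant(cfg, geno)
    eta <- rep(dm$baseline, batch_n)
    for (m in names(dm$beta)) eta <- eta + dm$beta[[m]] * x[, m]
    for (ia in dm$interactions)
      eta <- eta + ia$beta * x[, ia$markers[1L]] * x[, ia$markers[2L]]
    y <- stats::rbinom(batch_n, 1L, stats::plogis(eta))
    if (got_case < need_case) {
      take <- which(y == 1L)[seq_len(min(sum(y == 1L), need_case - got_case))]
      if (length(take)) {
        cases[[length(cases) + 1L]] <- geno[take, , drop = FALSE]
        got_case <- got_case + length(take)
      }
    }
    if (got_ctrl < need_ctrl) {
      take <- which(y == 0L)[seq_len(min(sum(y == 0L), need_ctrl - got_ctrl))]
      if (length(take)) {
        ctrls[[length(ctrls) + 1L]] <- geno[take, , drop = FALSE]
        got_ctrl <- got_ctrl + length(take)
      }
    }
    if (got_case >= need_case && got_ctrl >= need_ctrl) break
  }
  if (got_case < need_case || got_ctrl < need_ctrl)
    stop("case/control quotas not reached after ", max_batches,
         " batches; disease model may give near-degenerate probabilities")
  geno <- rbind(do.call(rbind, cases), do.call(rbind, ctrls))
  phen <- rep(c(1L, 0L), c(need_case, need_ctrl))
  if (cfg$missing_rate > 0) {
    mask <- matrix(stats::runif(length(geno)) < cfg$missing_rate,
                   nrow(geno), ncol(geno))
    geno[mask] <- NA_character_
  }
  genotype_dataset(sprintf("S%05d", seq_len(nrow(geno))), phen, geno,
                   cfg$markers)
}

#' Default simulation emulating the study population
#'
#' A [simulation_config()] whose defaults reproduce the statistical
#' structure assumed by the analysis: the 11-marker dopaminergic panel
#' ([study_markers()]) at the control-stratum allele frequencies of the
#' reference cohort, quotas of 303 cases and 555 controls, two strongly
#' linked SNP pairs (TaqIA~TaqIB and DRD4 -615~-616, both at D' = 0.98),
#' markers in Hardy-Weinberg proportions, and a dominant-model disease
#' model carrying the cohort's headline effects: TaqIB log-OR ln(1.61)
#' (TaqIA associates only through LD), and the promoter effect-modification
#' motif in which the -521 C allele is protective (log-OR ln(1/1.77)) only
#' in non-carriers of the -615 G allele, encoded as a cancelling
#' -615 x -521 interaction term.
#'
#' @param n_cases,n_controls Sample quotas.
#' @param seed Default seed carried by the configuration.
#' @return A [simulation_config()].
#' @export
study_simulation_config <- function(n_cases = 303, n_controls = 555,
                                    seed = NULL) {
  mk <- study_markers()
  freqs <- list(
    COMT        = c(G = 0.47, A = 0.53),
    TaqIA       = c(T = 0.17, C = 0.83),
    TaqIB       = c(A = 0.14, G = 0.86),
    TaqID       = c(C = 0.40, T = 0.60),
    DRD4_521    = c(C = 0.47, T = 0.53),
    DRD4_615    = c(G = 0.13, A = 0.87),
    DRD4_616    = c(G = 0.48, C = 0.52),
    DRD4_120dup = c("1" = 0.17, "2" = 0.83),
    DRD4_48bp   = c("2" = 0.08, "3" = 0.03, "4" = 0.62, "5" = 0.02,
                    "6" = 0.01, "7" = 0.22, "8" = 0.02),
    DAT_40bp    = c("6" = 0.01, "8" = 0.02, "9" = 0.28, "10" = 0.68,
                    "11" = 0.01),
    DAT_int8    = c("2" = 0.22, "3" = 0.78))
  simulation_config(
    markers = mk, n_cases = n_cases, n_controls = n_controls,
    freqs = freqs,
    ld_blocks = list(
      list(markers = c("TaqIA", "TaqIB"), d_prime = 0.98),
      list(markers = c("DRD4_615", "DRD4_616"), d_prime = 0.98)),
    disease_model = list(
      baseline = -1.0,
      beta = c(TaqIB = log(1.61), DRD4_521 = log(1 / 1.77)),
      interactions = list(
        list(markers = c("DRD4_615", "DRD4_521"), beta = log(1.77)))),
    missing_rate = 0, seed = seed)
}
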