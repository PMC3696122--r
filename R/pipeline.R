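# End-to-end orchestration: run the association, LD/haplotype and BN-BMLA
# stages over a dataset (loaded or simulated) and write the report bundle.

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

stamp <- function(df, hash, seed) {
  attr(df, "config_hash") <- hash
  attr(df, "seed") <- seed
  df
}

write_stamped_tsv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%s", hash,
                     if (is.null(seed)) "NA" else seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Sequences the package's stages over one dataset: the single-marker
#' dominant-model scan (association table with HWE diagnostics and the
#' Bonferroni flag), control-stratum minor allele frequencies, an optional
#' stratified two-marker analysis, the pairwise D' / r2 LD matrices,
#' haplotype likelihood-ratio tests for requested marker sets, and the
#' BN-BMLA stage (structure MCMC, relevance posteriors, pairwise
#' interaction/redundancy, consensus network and relevance tree). Every
#' written file embeds the configuration hash and seed; outputs are
#' deterministic given the seed.
#'
#' @param ds A [genotype_dataset()] (e.g. from [load_dataset()] or
#'   [simulate_dataset()]).
#' @param out_dir Output directory (created if needed); `NULL` skips all
#'   file output and only returns the bundle.
#' @param seed Seed for the stochastic stages.
#' @param hwe_df Degrees of freedom for HWE diagnostics.
#' @param stratify Optional `c(effect_marker, stratifier_marker)` pair for
#'   the stratified stage.
#' @param stratify_exposure Exposure orientation for the stratified stage,
#'   see [stratified_association()].
#' @param haplo_sets List of marker-name vectors for haplotype LRTs.
#' @param ld_markers Markers for the LD matrix (default: biallelic ones).
#' @param bn Logical: run the BN-BMLA stage.
#' @param bn_steps,bn_burn_in,bn_max_parents,bn_thin MCMC controls, see
#'   [structure_mcmc()].
#' @param edge_threshold Consensus-network edge posterior threshold.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return Invisibly, a list bundle: `association`, `maf`, `stratified`,
#'   `ld`, `haplotypes`, `relevance`, `consensus_dot`, `tree`, `log`.
#' @export
run_pipeline <- function(ds, out_dir = NULL, seed = 1L, hwe_df = 2,
                         stratify = NULL,
                         stratify_exposure = "present",
                         haplo_sets = list(),
                         ld_markers = NULL, bn = TRUE, bn_steps = 1e5,
                         bn_burn_in = 1e4, bn_max_parents = 5,
                         bn_thin = 100, edge_threshold = 0.35,
                         alpha = 0.05) {
  stopifnot(inherits(ds, "genotype_dataset"))
  cfg <- list(markers = names(ds$markers), seed = seed, hwe_df = hwe_df,
              stratify = stratify, haplo_sets = haplo_sets, bn = bn,
              bn_steps = bn_steps, bn_burn_in = bn_burn_in,
              bn_max_parents = bn_max_parents, bn_thin = bn_thin,
              edge_threshold = edge_threshold, alpha = alpha)
  hash <- config_hash(cfg)
  log_lines <- sprintf("pipeline start: %d subjects, %d markers, seed=%d, config=%s",
                       length(ds$subjects), length(ds$markers), seed, hash)
  bundle <- list(config_hash = hash, seed = seed)
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e)))
    log_lines <<- c(log_lines, sprintf("stage %-12s %.2fs", stage,
                                       proc.time()[["elapsed"]] - t0))
    out
  }

  bundle$association <- tick("assoc", single_marker_scan(ds, hwe_df, alpha))
  bundle$maf <- tick("maf", {
    data.frame(
      marker = names(ds$markers),
      minor_allele = vapply(names(ds$markers), function(m)
        minor_allele(ds, m, "controls")$allele, ""),
      maf_controls = vapply(names(ds$markers), function(m)
        minor_allele(ds, m, "controls")$frequency, 0),
      maf_cases = vapply(names(ds$markers), function(m)
        minor_allele(ds, m, "cases")$frequency, 0),
      row.names = NULL, stringsAsFactors = FALSE)
  })
  if (!is.null(stratify)) {
    bundle$stratified <- tick("stratified",
      stratified_association(ds, stratify[1L], stratify[2L],
                             exposure = stratify_exposure))
  }
  bundle$ld <- tick("ld", ld_matrix(ds, ld_markers))
  if (length(haplo_sets)) {
    bundle$haplotypes <- tick("haplo",
      lapply(haplo_sets, function(ms) haplotype_association_lrt(ds, ms)))
  }
  if (bn) {
    bundle$relevance <- tick("bmla", {
      bc <- dominant_code(ds)
      smp <- structure_mcmc(bc, steps = bn_steps, burn_in = bn_burn_in,
                            max_parents = bn_max_parents, seed = seed,
                            thin = bn_thin)
      relevance_posteriors(smp)
    })
    bundle$consensus_dot <- export_consensus_network(bundle$relevance,
                                                     edge_threshold)
    bundle$tree <- build_relevance_tree(bundle$relevance)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stamped_tsv(bundle$association,
                      file.path(out_dir, "association.tsv"), hash, seed)
    write_stamped_tsv(bundle$maf, file.path(out_dir, "maf.tsv"), hash, seed)
    dp <- as.data.frame(bundle$ld$d_prime)
    dp <- cbind(marker = rownames(bundle$ld$d_prime), dp)
    write_stamped_tsv(dp, file.path(out_dir, "ld_dprime.tsv"), hash, seed)
    if (!is.null(bundle$stratified)) {
      sdf <- do.call(rbind, lapply(names(bundle$stratified), function(nm) {
        s <- bundle$stratified[[nm]]
        data.frame(stratum = nm, p = s$p, odds_ratio = s$odds_ratio,
                   ci_low = s$ci_low, ci_high = s$ci_high, n = s$n,
                   stringsAsFactors = FALSE)
      }))
      write_stamped_tsv(sdf, file.path(out_dir, "stratified.tsv"), hash, seed)
    }
    if (!is.null(bundle$haplotypes)) {
      hdf <- do.call(rbind, lapply(seq_along(bundle$haplotypes), function(i) {
        h <- bundle$haplotypes[[i]]
        cbind(set = paste(haplo_sets[[i]], collapse = "~"), h$table,
              chi2 = h$chi2, df = h$df, p = h$p)
      }))
      write_stamped_tsv(hdf, file.path(out_dir, "haplotypes.tsv"), hash, seed)
    }
    if (!is.null(bundle$relevance)) {
      rel <- bundle$relevance
      jsonlite::write_json(
        list(config_hash = hash, seed = seed, target = rel$target,
             mbm = as.list(rel$mbm),
             mbs = rel$mbs[, c("set", "prob")],
             diagnostics = rel$diagnostics),
        file.path(out_dir, "relevance.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      mdf <- data.frame(marker = names(rel$mbm), mbm = as.numeric(rel$mbm),
                        stringsAsFactors = FALSE)
      write_stamped_tsv(mdf, file.path(out_dir, "mbm.tsv"), hash, seed)
      export_consensus_network(rel, edge_threshold,
                               file.path(out_dir, "consensus.dot"))
      export_relevance_tree(bundle$tree,
                            file.path(out_dir, "relevance_tree.dot"))
    }
    log_lines <- c(log_lines, sprintf("outputs written to %s", out_dir))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  bundle$log <- log_lines
  invisible(bundle)
}
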