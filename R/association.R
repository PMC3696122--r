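#' Genotype class counts for a marker and stratum
#'
#' Available-case counts of the dominant-coding carrier classes for one
#' marker: homozygous for the grouping allele, heterozygous carrier, and
#' non-carrier. Missing genotypes are excluded (per-marker available-case
#' analysis, so N varies across markers when genotyping success differs).
#'
#' @param ds A [genotype_dataset()].
#' @param marker Marker name.
#' @param stratum `"controls"`, `"cases"` or `"all"`.
#' @return A [genotype_counts_table()] of type `"genotypic"`.
#' @export
genotype_counts <- function(ds, marker,
                            stratum = c("controls", "cases", "all")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  stratum <- match.arg(stratum)
  if (!marker %in% names(ds$markers)) stop("unknown marker: ", marker)
  idx <- stratum_index(ds, stratum)
  tok <- ds$genotypes[idx, marker]
  tok <- tok[!is.na(tok)]
  if (!length(tok)) stop("all genotypes missing for '", marker,
                         "' in stratum '", stratum, "'")
  g <- ds$markers[[marker]]$grouping_allele
  ncopies <- vapply(split_tokens(tok), function(p) sum(p == g), 0L)
  cnt <- c(sum(ncopies == 2L), sum(ncopies == 1L), sum(ncopies == 0L))
  names(cnt) <- c(paste0(g, "/", g), paste0(g, "/other"), "other/other")
  genotype_counts_table(marker, stratum, cnt, "genotypic")
}

#' Minor allele frequency from genotype class counts
#'
#' For genotypic 3-class counts, the grouping-allele frequency
#' `(2*hom + het) / (2N)`.
#'
#' @param counts A [genotype_counts_table()] of type `"genotypic"`.
#' @return Numeric frequency.
#' @export
maf_from_counts <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$type != "genotypic")
    stop("allele frequency needs the 3 genotypic classes")
  unname((2 * counts$counts[1L] + counts$counts[2L]) / (2 * counts$N))
}

#' Hardy-Weinberg goodness-of-fit test
#'
#' Pearson goodness-of-fit of observed genotype class counts against the
#' Hardy-Weinberg expectations computed from the sample allele frequency.
#' For multi-allelic VNTRs the test is applied to the collapsed
#' pseudo-biallelic classes (grouping allele vs pooled others), the same
#' two-allele grouping under which the dominant model operates.
#'
#' The degrees of freedom are selectable. The conventional biallelic HWE
#' test has 1 df (3 classes, 1 estimated allele frequency); `df = 2` skips
#' the estimated-parameter adjustment and is the convention under which the
#' package's reference tables were produced, so it is the default for
#' reproduction work. Both modes share the identical chi-square statistic.
#'
#' @param counts A [genotype_counts_table()] of type `"genotypic"` ordered
#'   (hom, het, non-carrier).
#' @param df Degrees of freedom for the chi-square reference, 1 or 2.
#' @return List with `chi2`, `p`, `df`, allele frequency `p_allele`, and
#'   `monomorphic` flag (monomorphic samples return `p = 1` by convention).
#' @export
hwe_test <- function(counts, df = 2) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$type != "genotypic")
    stop("HWE test needs the 3 genotypic classes (hom/het/non-carrier)")
  if (!df %in% c(1, 2)) stop("df must be 1 or 2")
  if (counts$N == 0L) stop("empty genotype counts")
  obs <- as.numeric(counts$counts)
  p <- (2 * obs[1L] + obs[2L]) / (2 * counts$N)
  if (p == 0 || p == 1)
    return(list(chi2 = 0, p = 1, df = df, p_allele = p, monomorphic = TRUE))
  expd <- counts$N * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chi2 <- sum((obs - expd)^2 / expd)
  list(chi2 = chi2, p = stats::pchisq(chi2, df, lower.tail = FALSE),
       df = df, p_allele = p, monomorphic = FALSE)
}

dominant_collapse <- function(counts) {
  # (present, absent) from genotypic or dominant counts
  if (counts$type == "genotypic")
    c(present = unname(counts$counts[1L] + counts$counts[2L]),
      absent = unname(counts$counts[3L]))
  else
    c(present = unname(counts$counts[1L]), absent = unname(counts$counts[2L]))
}

wald_ci_or <- function(tab, conf = 0.95) {
  # tab: 2x2, rows case/control, cols exposed/unexposed
  zero <- any(tab == 0)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (zero)
    return(list(or = or, ci = c(NA_real_, NA_real_), zero_cell = TRUE))
  se <- sqrt(sum(1 / tab))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(or = or, ci = exp(log(or) + c(-1, 1) * z * se), zero_cell = FALSE)
}

#' Dominant-model case-control association for one marker
#'
#' Builds the 2x2 carrier-by-phenotype table (presence/absence of the
#' grouping allele x case/control) and tests it with the Pearson chi-square
#' (1 df, no continuity correction). The odds ratio is
#' `(case_present * control_absent) / (case_absent * control_present)` with
#' a Wald 95% confidence interval on the log scale. Hardy-Weinberg
#' diagnostics for both strata are attached when genotypic counts are
#' supplied. Tables with a zero cell report the (possibly infinite) OR with
#' a `zero_cell` flag rather than applying a continuity correction.
#'
#' @param case_counts,control_counts [genotype_counts_table()] objects for
#'   the same marker.
#' @param hwe_df Degrees of freedom for the attached HWE diagnostics.
#' @param conf Confidence level for the Wald interval.
#' @return An object of class `association_result`: marker, 2x2 `table`,
#'   `chi2`, `p`, `odds_ratio`, `ci_low`, `ci_high`, `hwe_p_control`,
#'   `hwe_p_case`, `zero_cell`.
#' @export
dominant_association <- function(case_counts, control_counts,
                                 hwe_df = 2, conf = 0.95) {
  stopifnot(inherits(case_counts, "genotype_counts"),
            inherits(control_counts, "genotype_counts"))
  if (case_counts$marker != control_counts$marker)
    stop("case and control counts are for different markers")
  ca <- dominant_collapse(case_counts)
  co <- dominant_collapse(control_counts)
  tab <- rbind(case = ca, control = co)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  w <- wald_ci_or(tab, conf)
  hw <- function(cnt) if (cnt$type == "genotypic") hwe_test(cnt, hwe_df)$p
                      else NA_real_
  structure(
    list(marker = case_counts$marker, table = tab,
         chi2 = unname(chi$statistic), p = chi$p.value,
         odds_ratio = w$or, ci_low = w$ci[1L], ci_high = w$ci[2L],
         hwe_p_case = hw(case_counts), hwe_p_control = hw(control_counts),
         zero_cell = w$zero_cell),
    class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("<association> %s: chi2=%.3f p=%.4g OR=%.2f (%.2f-%.2f)%s\n",
              x$marker, x$chi2, x$p, x$odds_ratio, x$ci_low, x$ci_high,
              if (isTRUE(x$zero_cell)) " [zero cell]" else ""))
  invisible(x)
}

degenerate_margin <- function(tab) any(rowSums(tab) == 0) || any(colSums(tab) == 0)

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value by hypergeometric enumeration, summing the
#' probabilities of all tables (with the observed margins) at most as
#' probable as the observed one.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value; degenerate margins return 1.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (degenerate_margin(tab)) return(1)
  stats::fisher.test(tab)$p.value
}

#' Exact Pearson chi-square test for a 2x2 table
#'
#' Exact conditional version of the Pearson chi-square test: enumerates the
#' hypergeometric distribution of the (1,1) cell given the margins and sums
#' the probabilities of all tables whose Pearson statistic is at least the
#' observed one. This is the "exact (2-sided)" variant reported by common
#' statistics suites for sparse tables, and differs slightly from Fisher's
#' probability-ordering rule.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided exact p-value; degenerate margins return 1.
#' @export
exact_pearson_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (degenerate_margin(tab)) return(1)
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); N <- sum(tab)
  ks <- max(0, c1 - r2):min(c1, r1)
  chi2_of <- function(a) {
    t2 <- matrix(c(a, c1 - a, r1 - a, r2 - c1 + a), 2, 2)
    e <- outer(c(r1, r2), colSums(t2)) / N
    sum((t2 - e)^2 / e)
  }
  obs <- chi2_of(tab[1, 1])
  pr <- stats::dhyper(ks, r1, r2, c1)
  sum(pr[vapply(ks, chi2_of, 0) >= obs - 1e-7])
}

#' Association of one marker within strata of another
#'
#' Stratifies subjects by the dominant code of `stratifier_marker` and, in
#' each stratum, cross-tabulates the dominant code of `effect_marker`
#' against phenotype; subjects missing either marker are excluded
#' (complete-case on the pair). Each stratum reports the exact p-value
#' (exact Pearson by default), the odds ratio and its Wald CI. The
#' `exposure` argument selects which carrier class of the effect marker is
#' treated as exposed; the published promoter-SNP table orients the
#' non-carrier (TT) class as the risk class, i.e. `exposure = "absent"`.
#'
#' @param ds A [genotype_dataset()].
#' @param effect_marker,stratifier_marker Marker names.
#' @param exposure `"present"` or `"absent"`: carrier class of the effect
#'   marker counted as exposed.
#' @param exact `"pearson"` (exact Pearson, default) or `"fisher"`.
#' @return List of per-stratum results (`stratifier_absent`,
#'   `stratifier_present`), each with `table`, `p`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `n`. Empty strata are omitted with a warning.
#' @export
stratified_association <- function(ds, effect_marker, stratifier_marker,
                                   exposure = c("present", "absent"),
                                   exact = c("pearson", "fisher")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  exposure <- match.arg(exposure)
  exact <- match.arg(exact)
  bc <- dominant_code(ds)
  x <- bc[, effect_marker]
  s <- bc[, stratifier_marker]
  y <- ds$phenotype
  keep <- !is.na(x) & !is.na(s)
  x <- x[keep]; s <- s[keep]; y <- y[keep]
  out <- list()
  for (lv in c(0L, 1L)) {
    nm <- if (lv == 0L) "stratifier_absent" else "stratifier_present"
    idx <- s == lv
    if (!any(idx)) {
      warning("stratum ", nm, " is empty; omitted")
      next
    }
    exposed <- if (exposure == "present") x[idx] == 1L else x[idx] == 0L
    tab <- rbind(case    = c(sum(exposed & y[idx] == 1L), sum(!exposed & y[idx] == 1L)),
                 control = c(sum(exposed & y[idx] == 0L), sum(!exposed & y[idx] == 0L)))
    colnames(tab) <- c("exposed", "unexposed")
    out[[nm]] <- c(assoc_2x2(tab, exact = exact), list(n = sum(idx)))
  }
  out
}

#' Exact association summary for a 2x2 case-control table
#'
#' @param tab 2x2 matrix, rows case/control, columns exposed/unexposed.
#' @param exact `"pearson"` or `"fisher"` exact p-value variant.
#' @param conf Confidence level for the Wald OR interval.
#' @return List with `table`, `p`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `zero_cell`.
#' @export
assoc_2x2 <- function(tab, exact = c("pearson", "fisher"), conf = 0.95) {
  exact <- match.arg(exact)
  tab <- as.matrix(tab)
  p <- if (exact == "pearson") exact_pearson_2x2(tab) else fisher_exact_2x2(tab)
  w <- wald_ci_or(tab, conf)
  list(table = tab, p = p, odds_ratio = w$or,
       ci_low = w$ci[1L], ci_high = w$ci[2L], zero_cell = w$zero_cell)
}

#' Bonferroni correction for a family of tests
#'
#' Family-wise threshold `alpha / m` for `m` tests; a p-value is flagged
#' when strictly below the threshold (an 11-marker panel at `alpha = 0.05`
#' gives the threshold 0.0045).
#'
#' @param p_values Numeric vector of uncorrected p-values.
#' @param alpha Family-wise error rate.
#' @return List with `threshold`, `flags` (logical, named as `p_values`)
#'   and `m`.
#' @export
bonferroni_adjust <- function(p_values, alpha = 0.05) {
  stopifnot(length(p_values) >= 1L, is.numeric(p_values))
  threshold <- alpha / length(p_values)
  list(threshold = threshold, flags = p_values < threshold,
       m = length(p_values))
}

#' Dominant-model association scan over all markers
#'
#' Runs [genotype_counts()], [hwe_test()] and [dominant_association()] for
#' every marker of a dataset (or over a list of published count fixtures)
#' and applies the Bonferroni correction across the panel. This is the
#' single-marker analysis table: genotype class counts per stratum, HWE
#' diagnostics, dominant-model chi-square p, OR with 95% CI, and the
#' family-wise significance flag.
#'
#' @param x A [genotype_dataset()], or a list of fixture entries as
#'   returned by [table1_fixture()].
#' @param hwe_df Degrees of freedom for HWE diagnostics (see [hwe_test()]).
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return A data.frame with one row per marker: counts summary, HWE
#'   p-values, `chi2`, `p`, `odds_ratio`, `ci_low`, `ci_high`,
#'   `bonferroni_significant`; the threshold is attached as attribute
#'   `bonferroni_threshold`.
#' @export
single_marker_scan <- function(x, hwe_df = 2, alpha = 0.05) {
  if (inherits(x, "genotype_dataset")) {
    fixture <- lapply(names(x$markers), function(m)
      list(marker = m,
           control = genotype_counts(x, m, "controls"),
           case = genotype_counts(x, m, "cases")))
    names(fixture) <- names(x$markers)
  } else fixture <- x
  res <- lapply(fixture, function(f)
    dominant_association(f$case, f$control, hwe_df = hwe_df))
  p <- vapply(res, `[[`, 0, "p")
  bf <- bonferroni_adjust(p, alpha)
  out <- data.frame(
    marker = vapply(res, `[[`, "", "marker"),
    n_case = vapply(fixture, function(f) f$case$N, 0L),
    n_control = vapply(fixture, function(f) f$control$N, 0L),
    hwe_p_control = vapply(res, `[[`, 0, "hwe_p_control"),
    hwe_p_case = vapply(res, `[[`, 0, "hwe_p_case"),
    chi2 = vapply(res, `[[`, 0, "chi2"),
    p = p,
    odds_ratio = vapply(res, `[[`, 0, "odds_ratio"),
    ci_low = vapply(res, `[[`, 0, "ci_low"),
    ci_high = vapply(res, `[[`, 0, "ci_high"),
    bonferroni_significant = bf$flags,
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "bonferroni_threshold") <- bf$threshold
  out
}
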