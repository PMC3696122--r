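# Haplotype EM over phase-ambiguous multilocus genotypes, LD statistics,
# and the case-control haplotype likelihood-ratio test.

# Expand one multilocus genotype (list of per-locus allele pairs) into its
# compatible unordered haplotype pairs. h heterozygous loci -> 2^(h-1)
# distinct pairs (1 when fully homozygous).
compatible_pairs <- function(pairs) {
  L <- length(pairs)
  het <- which(vapply(pairs, function(p) p[1L] != p[2L], TRUE))
  base1 <- vapply(pairs, `[`, "", 1L)
  base2 <- vapply(pairs, `[`, "", 2L)
  if (!length(het))
    return(list(list(h1 = paste(base1, collapse = "~"),
                     h2 = paste(base2, collapse = "~"))))
  out <- list()
  seen <- character()
  # fix the first het locus's assignment to avoid double counting
  n_free <- length(het) - 1L
  for (code in 0:(2^n_free - 1L)) {
    h1 <- base1; h2 <- base2
    if (n_free > 0) {
      bits <- as.integer(intToBits(code))[seq_len(n_free)]
      flip <- het[-1L][bits == 1L]
      tmp <- h1[flip]; h1[flip] <- h2[flip]; h2[flip] <- tmp
    }
    k1 <- paste(h1, collapse = "~"); k2 <- paste(h2, collapse = "~")
    key <- paste(sort(c(k1, k2)), collapse = "|")
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- list(h1 = k1, h2 = k2)
    }
  }
  out
}

# Tabulate distinct multilocus genotypes of the complete-case subjects and
# attach their compatible haplotype-pair expansions.
genotype_expansion <- function(ds, markers, subset = NULL) {
  tok <- ds$genotypes[, markers, drop = FALSE]
  if (!is.null(subset)) tok <- tok[subset, , drop = FALSE]
  complete <- stats::complete.cases(tok)
  tok <- tok[complete, , drop = FALSE]
  if (!nrow(tok))
    stop("no subjects with complete genotypes for markers: ",
         paste(markers, collapse = ", "))
  key <- apply(tok, 1L, paste, collapse = " ")
  counts <- table(key)
  genos <- lapply(names(counts), function(k) {
    toks <- strsplit(k, " ", fixed = TRUE)[[1L]]
    pairs <- split_tokens(toks)
    compatible_pairs(pairs)
  })
  hap_labels <- sort(unique(unlist(lapply(genos, function(g)
    unlist(lapply(g, function(pq) c(pq$h1, pq$h2)))))))
  idx <- lapply(genos, function(g)
    lapply(g, function(pq) c(match(pq$h1, hap_labels),
                             match(pq$h2, hap_labels))))
  list(counts = as.numeric(counts), pairs = idx, haps = hap_labels,
       n = sum(counts))
}

em_core <- function(exp_data, tol, max_iter) {
  H <- length(exp_data$haps)
  n <- exp_data$n
  # phase-uniform init: each compatible pair of each genotype equally likely
  f <- numeric(H)
  for (gi in seq_along(exp_data$pairs)) {
    prs <- exp_data$pairs[[gi]]
    w <- exp_data$counts[gi] / length(prs)
    for (pq in prs) { f[pq[1L]] <- f[pq[1L]] + w; f[pq[2L]] <- f[pq[2L]] + w }
  }
  f <- f / (2 * n)
  ll_trace <- numeric()
  for (iter in seq_len(max_iter)) {
    new_f <- numeric(H)
    ll <- 0
    for (gi in seq_along(exp_data$pairs)) {
      prs <- exp_data$pairs[[gi]]
      w <- vapply(prs, function(pq) {
        mult <- if (pq[1L] == pq[2L]) 1 else 2
        mult * f[pq[1L]] * f[pq[2L]]
      }, 0)
      pg <- sum(w)
      if (pg <= 0) { # genotype with all-zero current support: re-seed evenly
        w <- rep(1 / length(prs), length(prs)); pg <- .Machine$double.xmin
      } else w <- w / pg
      ll <- ll + exp_data$counts[gi] * log(pg)
      for (j in seq_along(prs)) {
        pq <- prs[[j]]
        add <- exp_data$counts[gi] * w[j]
        new_f[pq[1L]] <- new_f[pq[1L]] + add
        new_f[pq[2L]] <- new_f[pq[2L]] + add
      }
    }
    new_f <- new_f / (2 * n)
    if (length(ll_trace) && ll < ll_trace[length(ll_trace)] - 1e-9)
      stop("EM log-likelihood decreased; numerical fault")
    ll_trace <- c(ll_trace, ll)
    delta <- max(abs(new_f - f))
    f <- new_f
    if (delta < tol) break
  }
  list(freqs = f, loglik = ll_trace[length(ll_trace)], iterations = iter,
       ll_trace = ll_trace)
}

#' EM haplotype frequency estimation from unphased genotypes
#'
#' Multinomial EM over the phase-ambiguous expansions of the observed
#' multilocus genotypes: the E-step distributes each genotype over its
#' compatible haplotype pairs in proportion to current frequency products,
#' the M-step re-estimates frequencies from expected haplotype counts.
#' Initialization is the deterministic phase-uniform expansion, so results
#' are reproducible without random restarts. Subjects missing any involved
#' marker are excluded (complete-case per marker subset). The
#' log-likelihood is checked to be non-decreasing at every iteration.
#'
#' @param ds A [genotype_dataset()].
#' @param markers Character vector of >= 2 marker names.
#' @param tol Convergence tolerance on the max absolute frequency change.
#' @param max_iter Iteration cap.
#' @param subset Optional logical/integer subject subset (used internally
#'   for per-stratum fits).
#' @return An object of class `haplotype_model`: `markers`, `haplotypes`
#'   (labels joined with `"~"`), `freqs`, `loglik`, `iterations`, `n`
#'   (complete subjects).
#' @export
em_haplotype_frequencies <- function(ds, markers, tol = 1e-8,
                                     max_iter = 10000L, subset = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"), length(markers) >= 2L)
  missing_m <- setdiff(markers, names(ds$markers))
  if (length(missing_m)) stop("unknown marker(s): ",
                              paste(missing_m, collapse = ", "))
  ed <- genotype_expansion(ds, markers, subset)
  fit <- em_core(ed, tol, max_iter)
  structure(list(markers = markers, haplotypes = ed$haps,
                 freqs = stats::setNames(fit$freqs, ed$haps),
                 loglik = fit$loglik, iterations = fit$iterations,
                 n = ed$n),
            class = "haplotype_model")
}

#' @export
print.haplotype_model <- function(x, ...) {
  cat(sprintf("<haplotype_model> %s: n=%d, loglik=%.3f (%d EM iterations)\n",
              paste(x$markers, collapse = "~"), x$n, x$loglik, x$iterations))
  shown <- sort(x$freqs, decreasing = TRUE)
  shown <- shown[shown > 1e-4]
  for (h in names(shown)) cat(sprintf("  %-12s %.4f\n", h, shown[h]))
  invisible(x)
}

#' Pairwise linkage-disequilibrium statistics
#'
#' From a two-locus haplotype frequency table: the covariance
#' `D = p_AB - p_A * p_B` of the allele indicators, the range-standardized
#' `D' = D / Dmax`, and the squared correlation
#' `r2 = D^2 / (p_A p_a p_B p_b)`. The "A"/"B" alleles are the focal
#' alleles passed by the caller (conventionally each marker's grouping
#' allele). A monomorphic locus leaves the statistics undefined and sets
#' the `monomorphic` flag.
#'
#' @param hap_freqs Named haplotype frequency vector with `"a1~a2"` labels
#'   (as produced by [em_haplotype_frequencies()] on two markers), or a
#'   `haplotype_model` for a marker pair.
#' @param allele1,allele2 Focal allele label at each locus.
#' @return An object of class `ld_result`: `D`, `d_prime`, `r2`, focal
#'   allele frequencies `p1`, `p2`, `monomorphic`.
#' @export
ld_stats <- function(hap_freqs, allele1, allele2) {
  if (inherits(hap_freqs, "haplotype_model")) {
    stopifnot(length(hap_freqs$markers) == 2L)
    hap_freqs <- hap_freqs$freqs
  }
  labs <- strsplit(names(hap_freqs), "~", fixed = TRUE)
  a1 <- vapply(labs, `[`, "", 1L)
  a2 <- vapply(labs, `[`, "", 2L)
  pA <- sum(hap_freqs[a1 == allele1])
  pB <- sum(hap_freqs[a2 == allele2])
  pAB <- sum(hap_freqs[a1 == allele1 & a2 == allele2])
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(structure(list(D = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                          p1 = pA, p2 = pB, monomorphic = TRUE),
                     class = "ld_result"))
  D <- pAB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else if (D < 0) min(pA * pB, (1 - pA) * (1 - pB))
          else 1
  structure(list(D = D, d_prime = D / dmax,
                 r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)),
                 p1 = pA, p2 = pB, monomorphic = FALSE),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  if (x$monomorphic) cat("<ld_result> monomorphic locus; LD undefined\n")
  else cat(sprintf("<ld_result> D=%.4f D'=%.3f r2=%.3f\n",
                   x$D, x$d_prime, x$r2))
  invisible(x)
}

#' Pairwise D'/r2 matrix over a set of markers
#'
#' Runs the two-locus EM for every marker pair and evaluates [ld_stats()]
#' with each marker's grouping allele as the focal allele.
#'
#' @param ds A [genotype_dataset()].
#' @param markers Marker names (default: all biallelic markers).
#' @return List of matrices `d_prime` and `r2` (symmetric, unit diagonal).
#' @export
ld_matrix <- function(ds, markers = NULL) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (is.null(markers))
    markers <- names(ds$markers)[vapply(ds$markers, function(m)
      length(m$alleles) == 2L, TRUE)]
  k <- length(markers)
  dp <- matrix(1, k, k, dimnames = list(markers, markers))
  r2 <- dp
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    hm <- em_haplotype_frequencies(ds, c(markers[i], markers[j]))
    ld <- ld_stats(hm, ds$markers[[markers[i]]]$grouping_allele,
                   ds$markers[[markers[j]]]$grouping_allele)
    dp[i, j] <- dp[j, i] <- ld$d_prime
    r2[i, j] <- r2[j, i] <- ld$r2
  }
  list(d_prime = dp, r2 = r2)
}

#' Case-control haplotype likelihood-ratio association test
#'
#' Fits the haplotype EM separately in cases, controls, and pooled, and
#' compares stratum-specific against shared haplotype frequencies:
#' `LRT = 2 * (ll_cases + ll_controls - ll_pooled)`, referred to a
#' chi-square whose df is the number of haplotypes with pooled frequency
#' above `freq_floor`, minus one (numerically zero haplotypes carry no
#' likelihood dimension).
#'
#' @param ds A [genotype_dataset()].
#' @param markers Marker names (>= 2).
#' @param freq_floor Pooled frequency below which a haplotype is not
#'   counted toward the df.
#' @param tol,max_iter EM controls, see [em_haplotype_frequencies()].
#' @return List with `chi2`, `df`, `p` and `table` (a data.frame of
#'   haplotype frequencies: pooled, cases, controls).
#' @export
haplotype_association_lrt <- function(ds, markers, freq_floor = 1e-6,
                                      tol = 1e-8, max_iter = 10000L) {
  stopifnot(inherits(ds, "genotype_dataset"))
  fit_all  <- em_haplotype_frequencies(ds, markers, tol, max_iter)
  fit_case <- em_haplotype_frequencies(ds, markers, tol, max_iter,
                                       subset = ds$phenotype == 1L)
  fit_ctrl <- em_haplotype_frequencies(ds, markers, tol, max_iter,
                                       subset = ds$phenotype == 0L)
  chi2 <- max(0, 2 * (fit_case$loglik + fit_ctrl$loglik - fit_all$loglik))
  df <- sum(fit_all$freqs > freq_floor) - 1L
  haps <- fit_all$haplotypes
  tab <- data.frame(
    haplotype = haps,
    freq_pooled = as.numeric(fit_all$freqs[haps]),
    freq_cases = as.numeric(fit_case$freqs[match(haps, fit_case$haplotypes)]),
    freq_controls = as.numeric(fit_ctrl$freqs[match(haps, fit_ctrl$haplotypes)]),
    stringsAsFactors = FALSE)
  tab$freq_cases[is.na(tab$freq_cases)] <- 0
  tab$freq_controls[is.na(tab$freq_controls)] <- 0
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), table = tab)
}
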