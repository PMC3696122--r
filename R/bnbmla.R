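# Bayesian-network based Bayesian multilevel analysis (BN-BMLA):
# structure-posterior sampling, Markov blanket relevance posteriors,
# interaction/redundancy ratios, consensus network and relevance tree.

prepare_bn_data <- function(data, missing = c("complete", "category")) {
  missing <- match.arg(missing)
  X <- unclass(data)
  storage.mode(X) <- "integer"
  if (missing == "complete") {
    keep <- stats::complete.cases(X)
    if (!any(keep)) stop("no complete cases across the modeled variables")
    X <- X[keep, , drop = FALSE]
  } else {
    # missing becomes its own category, one past the observed maximum
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- max(X[!nas, j], 0L) + 1L
    }
  }
  r <- pmax(apply(X, 2L, max) + 1L, 2L)
  list(X = X, r = as.integer(r))
}

#' Cooper-Herskovits log marginal likelihood of one family
#'
#' The K2 closed-form score of a discrete variable given a parent set under
#' a uniform Dirichlet parameter prior: over parent configurations j with
#' child cardinality r, `sum_j [lgamma(r) - lgamma(N_j + r) +
#' sum_k lgamma(N_jk + 1)]`. Computed in log space. An empty dataset scores
#' 0 (vacuous product); complete cases across the involved columns are
#' used.
#'
#' @param data A [dominant_code()] matrix (or any integer-coded matrix of
#'   categories starting at 0).
#' @param variable Column name of the child variable.
#' @param parent_set Character vector of parent column names (possibly
#'   empty).
#' @return Log marginal likelihood (numeric scalar).
#' @export
ch_log_marginal_likelihood <- function(data, variable, parent_set = character()) {
  vars <- colnames(data)
  if (!variable %in% vars) stop("unknown variable: ", variable)
  if (variable %in% parent_set)
    stop("variable '", variable, "' cannot be in its own parent set")
  bad <- setdiff(parent_set, vars)
  if (length(bad)) stop("unknown parent(s): ", paste(bad, collapse = ", "))
  cols <- c(variable, parent_set)
  X <- unclass(data)[, cols, drop = FALSE]
  storage.mode(X) <- "integer"
  X <- X[stats::complete.cases(X), , drop = FALSE]
  if (nrow(X) == 0L) return(0)
  r <- as.integer(pmax(apply(X, 2L, max) + 1L, 2L))
  cpp_family_score(X, r, 0L, seq_along(parent_set))
}

#' Markov blanket of a target in a DAG
#'
#' Parents of the target, its children, and the children's other parents:
#' the variable set that renders the target conditionally independent of
#' everything else in the network.
#'
#' @param g Square 0/1 adjacency matrix with dimnames; `g[u, v] = 1` means
#'   the edge u -> v.
#' @param target Variable name.
#' @return Character vector of blanket members (possibly empty).
#' @export
markov_blanket <- function(g, target) {
  vars <- colnames(g)
  if (!target %in% vars) stop("target '", target, "' not in graph")
  parents <- vars[g[, target] == 1]
  children <- vars[g[target, ] == 1]
  spouses <- unlist(lapply(children, function(ch) vars[g[, ch] == 1]))
  setdiff(unique(c(parents, children, spouses)), target)
}

#' Sample DAG structures by Metropolis-Hastings MCMC
#'
#' Random walk over directed acyclic graphs on the dominant-coded markers
#' plus the phenotype target, under the Cooper-Herskovits score and a
#' uniform structure prior on DAGs respecting the maximum-parent bound.
#' Moves are single-edge additions, deletions and reversals chosen
#' uniformly among the currently valid moves, with the Hastings
#' neighborhood-size correction. Family scores are cached. The sampler is
#' reproducible given `seed`. Defaults for a full-scale analysis are 8e6
#' steps with 1e6 burn-in, 5 maximum parents and thinning 100; exploratory
#' runs scale `steps`/`burn_in` down.
#'
#' @param data A [dominant_code()] matrix (markers + target column).
#' @param target Target column name.
#' @param steps Total MCMC steps.
#' @param burn_in Steps discarded before sampling begins.
#' @param max_parents In-degree bound per node.
#' @param seed RNG seed.
#' @param thin Keep every `thin`-th post-burn-in structure.
#' @param missing `"complete"` (complete-case across modeled variables) or
#'   `"category"` (missingness becomes an own category).
#' @return An object of class `bn_samples`: flattened adjacency sample
#'   matrix, per-sample Markov blanket masks, variable names, target, and
#'   MCMC diagnostics (steps, burn-in, thinning, acceptance rate, seed,
#'   score-cache size).
#' @export
structure_mcmc <- function(data, target = "phenotype", steps = 1e5,
                           burn_in = 1e4, max_parents = 5, seed = NULL,
                           thin = 100,
                           missing = c("complete", "category")) {
  vars <- colnames(data)
  if (!target %in% vars) stop("target '", target, "' not in data")
  pd <- prepare_bn_data(data, missing)
  if (!is.null(seed)) set.seed(seed)
  t_idx <- match(target, vars) - 1L
  res <- cpp_structure_mcmc(pd$X, pd$r, t_idx, steps, burn_in,
                            as.integer(max_parents), as.integer(thin))
  structure(
    list(samples = res$samples, mb_masks = res$mb_masks, vars = vars,
         target = target,
         diagnostics = list(steps = steps, burn_in = burn_in, thin = thin,
                            max_parents = max_parents,
                            n_samples = res$n_samples,
                            acceptance_rate = res$acceptance_rate,
                            final_log_score = res$final_log_score,
                            cache_size = res$cache_size, seed = seed,
                            n_subjects = nrow(pd$X))),
    class = "bn_samples")
}

#' @export
print.bn_samples <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<bn_samples> %d structures over %d variables (target '%s')\n",
    as.integer(d$n_samples), length(x$vars), x$target))
  cat(sprintf("  %g steps (%g burn-in, thin %d), acceptance %.2f\n",
              d$steps, d$burn_in, d$thin, d$acceptance_rate))
  invisible(x)
}

#' Extract one sampled DAG as an adjacency matrix
#'
#' @param samples A `bn_samples` object.
#' @param i Sample index.
#' @return p x p 0/1 adjacency matrix with variable dimnames.
#' @export
sample_structure <- function(samples, i) {
  p <- length(samples$vars)
  matrix(samples$samples[i, ], p, p, byrow = TRUE,
         dimnames = list(samples$vars, samples$vars))
}

mask_to_set <- function(mask, vars) vars[bitwAnd(bitwShiftR(mask,
  seq_along(vars) - 1L), 1L) == 1L]

relevance_summary_new <- function(vars, target, mbm, mbs_df, edge_post,
                                  diagnostics) {
  ord <- order(-mbs_df$prob)
  mbs_df <- mbs_df[ord, , drop = FALSE]
  rownames(mbs_df) <- NULL
  structure(list(vars = vars, target = target, mbm = mbm, mbs = mbs_df,
                 edge_posteriors = edge_post, diagnostics = diagnostics),
            class = "relevance_summary")
}

#' Markov blanket relevance posteriors from structure samples
#'
#' Estimates, from a collection of sampled DAGs, the Markov blanket
#' membership posterior MBM(Y, X_i) (fraction of structures whose blanket
#' of the target contains X_i), the Markov blanket set posterior MBS(Y)
#' (fraction whose blanket equals each observed set exactly) and the
#' directed edge posteriors. The accounting identity
#' `MBM(X_i) = sum over sets containing X_i of MBS` holds exactly on any
#' sample collection.
#'
#' @param samples A `bn_samples` object from [structure_mcmc()].
#' @return An object of class `relevance_summary` with `mbm` (named
#'   vector), `mbs` (data.frame: `set` label, `mask`, `prob`),
#'   `edge_posteriors` (matrix) and the MCMC diagnostics.
#' @export
relevance_posteriors <- function(samples) {
  stopifnot(inherits(samples, "bn_samples"))
  n <- length(samples$mb_masks)
  if (!n) stop("empty sample collection")
  vars <- samples$vars
  p <- length(vars)
  preds <- setdiff(vars, samples$target)
  tab <- table(samples$mb_masks)
  masks <- as.integer(names(tab))
  probs <- as.numeric(tab) / n
  mbm <- vapply(match(preds, vars), function(j)
    sum(probs[bitwAnd(masks, bitwShiftL(1L, j - 1L)) != 0L]), 0)
  names(mbm) <- preds
  sets <- vapply(masks, function(m) {
    s <- mask_to_set(m, vars)
    if (length(s)) paste(s, collapse = ",") else "{}"
  }, "")
  edge_post <- matrix(colMeans(samples$samples), p, p, byrow = TRUE,
                      dimnames = list(vars, vars))
  relevance_summary_new(vars, samples$target, mbm,
                        data.frame(set = sets, mask = masks, prob = probs,
                                   stringsAsFactors = FALSE),
                        edge_post, samples$diagnostics)
}

#' @export
print.relevance_summary <- function(x, ...) {
  cat(sprintf("<relevance_summary> target '%s'\n", x$target))
  cat("  MBM posteriors:\n")
  m <- sort(x$mbm, decreasing = TRUE)
  for (v in names(m)) cat(sprintf("    %-14s %.3f\n", v, m[v]))
  cat(sprintf("  top MBS atoms (of %d observed):\n", nrow(x$mbs)))
  for (i in seq_len(min(5L, nrow(x$mbs))))
    cat(sprintf("    {%s} %.3f\n", x$mbs$set[i], x$mbs$prob[i]))
  invisible(x)
}

#' Exact relevance posteriors by exhaustive DAG enumeration
#'
#' Enumerates every DAG on at most 5 variables under the maximum-parent
#' bound, weights each by its Cooper-Herskovits score (uniform structure
#' prior, log-sum-exp normalization), and returns the exact analogue of
#' [relevance_posteriors()]. Serves as the independent oracle against
#' which the structure MCMC is validated.
#'
#' @param data A [dominant_code()] matrix.
#' @param target Target column name.
#' @param max_parents In-degree bound.
#' @param missing See [structure_mcmc()].
#' @return A `relevance_summary`; diagnostics carry `n_dags` and
#'   `log_evidence`.
#' @export
exhaustive_posterior <- function(data, target = "phenotype",
                                 max_parents = 5,
                                 missing = c("complete", "category")) {
  vars <- colnames(data)
  if (!target %in% vars) stop("target '", target, "' not in data")
  if (length(vars) > 5L)
    stop("exhaustive enumeration is limited to 5 variables; use structure_mcmc()")
  pd <- prepare_bn_data(data, missing)
  res <- cpp_exhaustive(pd$X, pd$r, match(target, vars) - 1L,
                        as.integer(min(max_parents, length(vars) - 1L)))
  preds <- setdiff(vars, target)
  mbm <- stats::setNames(res$mbm[match(preds, vars)], preds)
  sets <- vapply(res$mbs_masks, function(m) {
    s <- mask_to_set(m, vars)
    if (length(s)) paste(s, collapse = ",") else "{}"
  }, "")
  dimnames(res$edge_posteriors) <- list(vars, vars)
  relevance_summary_new(
    vars, target, mbm,
    data.frame(set = sets, mask = res$mbs_masks, prob = res$mbs_probs,
               stringsAsFactors = FALSE),
    res$edge_posteriors,
    list(method = "exhaustive", n_dags = res$n_dags,
         log_evidence = res$log_evidence, n_subjects = nrow(pd$X)))
}

joint_mb_prob <- function(summary, members) {
  if (!length(members)) return(1)
  vars <- summary$vars
  bits <- sum(bitwShiftL(1L, match(members, vars) - 1L))
  sum(summary$mbs$prob[bitwAnd(summary$mbs$mask, bits) == bits])
}

#' Pairwise interaction / redundancy scores
#'
#' For two predictors, compares the posterior probability that both belong
#' to the target's Markov blanket against the probability that exactly one
#' does: `R = P(both in MB) / P(exactly one in MB)`. `R > 1` indicates an
#' interaction (the pair tends to be needed jointly), `R < 1` a redundancy
#' (either one suffices). The Interaction Ratio is `IR = ln R` and the
#' Redundancy Ratio `RR = -ln R`; a redundancy of RR means the
#' exactly-one configuration is `exp(RR)` times as probable as joint
#' membership. The `"independence"` variant divides joint membership by
#' the product of the marginal memberships instead. Degenerate
#' denominators/numerators are flagged and yield infinite or undefined
#' ratios rather than an error.
#'
#' @param summary A `relevance_summary`.
#' @param x_i,x_j Predictor names (distinct, neither the target).
#' @param method `"exclusive"` (default, exactly-one denominator) or
#'   `"independence"`.
#' @return List with `R`, `IR`, `RR`, the component probabilities
#'   (`p_both`, `p_only_i`, `p_only_j`, and for the default method
#'   `p_exactly_one`), and `flag` (`"ok"`, `"infinite"` or `"undefined"`).
#' @export
interaction_redundancy <- function(summary, x_i, x_j,
                                   method = c("exclusive", "independence")) {
  stopifnot(inherits(summary, "relevance_summary"))
  method <- match.arg(method)
  if (x_i == x_j) stop("x_i and x_j must differ")
  if (summary$target %in% c(x_i, x_j)) stop("the target is not a predictor")
  vars <- summary$vars
  bi <- bitwShiftL(1L, match(x_i, vars) - 1L)
  bj <- bitwShiftL(1L, match(x_j, vars) - 1L)
  has_i <- bitwAnd(summary$mbs$mask, bi) != 0L
  has_j <- bitwAnd(summary$mbs$mask, bj) != 0L
  pr <- summary$mbs$prob
  p_both <- sum(pr[has_i & has_j])
  p_only_i <- sum(pr[has_i & !has_j])
  p_only_j <- sum(pr[!has_i & has_j])
  denom <- if (method == "exclusive") p_only_i + p_only_j
           else (p_both + p_only_i) * (p_both + p_only_j)
  if (p_both == 0 && denom == 0) {
    R <- NaN; flag <- "undefined"
  } else if (denom == 0) {
    R <- Inf; flag <- "infinite"
  } else {
    R <- p_both / denom
    flag <- if (p_both == 0) "zero" else "ok"
  }
  out <- list(R = R, IR = log(R), RR = -log(R), p_both = p_both,
              p_only_i = p_only_i, p_only_j = p_only_j, flag = flag,
              method = method)
  if (method == "exclusive") out$p_exactly_one <- p_only_i + p_only_j
  out
}

#' Relevance tree (dendrogram of jointly relevant variable subsets)
#'
#' Builds the hierarchy of variable subsets by joint Markov blanket
#' membership posterior: the root is the empty model with probability 1.0,
#' and each node's children extend its subset by one variable, ranked by
#' `P(all members in MB(Y))` and pruned below a probability floor. By
#' conjunction monotonicity every child's posterior is at most its
#' parent's.
#'
#' @param summary A `relevance_summary`.
#' @param depth Maximum tree depth (number of variables in the deepest
#'   subset).
#' @param prob_floor Prune subsets whose joint posterior falls below this.
#' @param max_children Cap on children per node (most probable first).
#' @return A nested structure of class `relevance_tree`; each node is
#'   `list(set, prob, children)`.
#' @export
build_relevance_tree <- function(summary, depth = 3, prob_floor = 0.01,
                                 max_children = 5) {
  stopifnot(inherits(summary, "relevance_summary"))
  preds <- setdiff(summary$vars, summary$target)
  grow <- function(set, prob, level) {
    node <- list(set = set, prob = prob, children = list())
    if (level >= depth) return(node)
    cand <- setdiff(preds, set)
    if (!length(cand)) return(node)
    probs <- vapply(cand, function(v)
      joint_mb_prob(summary, c(set, v)), 0)
    keep <- probs >= prob_floor
    cand <- cand[keep]; probs <- probs[keep]
    ord <- order(-probs, cand)
    cand <- utils::head(cand[ord], max_children)
    probs <- utils::head(probs[ord], max_children)
    node$children <- mapply(function(v, pp) grow(c(set, v), pp, level + 1L),
                            cand, probs, SIMPLIFY = FALSE)
    node
  }
  structure(grow(character(), 1, 0L), class = "relevance_tree")
}

#' @export
print.relevance_tree <- function(x, ...) {
  rec <- function(node, indent) {
    label <- if (length(node$set)) node$set[length(node$set)] else "(empty)"
    cat(sprintf("%s%s (%.3f)\n", strrep("  ", indent), label, node$prob))
    for (ch in node$children) rec(ch, indent + 1L)
  }
  rec(unclass(x), 0L)
  invisible(x)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\"', x, fixed = TRUE), '"')

#' Export the consensus network as a DOT graph
#'
#' Retains the directed edges whose posterior probability exceeds the
#' threshold; edge weights (and pen widths) carry the posterior, and the
#' target node is highlighted.
#'
#' @param summary A `relevance_summary`.
#' @param edge_threshold Keep edges with posterior strictly above this.
#' @param path Optional file to write the DOT document to.
#' @return The DOT document as a character scalar (invisibly if `path` is
#'   given); attribute `edges` holds the retained edge data.frame.
#' @export
export_consensus_network <- function(summary, edge_threshold = 0.35,
                                     path = NULL) {
  stopifnot(inherits(summary, "relevance_summary"))
  ep <- summary$edge_posteriors
  keep <- which(ep > edge_threshold, arr.ind = TRUE)
  edges <- data.frame(
    from = rownames(ep)[keep[, 1L]], to = colnames(ep)[keep[, 2L]],
    posterior = ep[keep], stringsAsFactors = FALSE)
  lines <- c("digraph consensus {",
             "  rankdir=LR;",
             paste0("  ", dot_quote(summary$target),
                    " [style=filled, fillcolor=black, fontcolor=white];"))
  if (nrow(edges)) {
    lines <- c(lines, sprintf("  %s -> %s [weight=%d, penwidth=%.2f, label=\"%.2f\"];",
                              dot_quote(edges$from), dot_quote(edges$to),
                              pmax(1L, as.integer(round(10 * edges$posterior))),
                              0.5 + 4 * edges$posterior, edges$posterior))
  }
  lines <- c(lines, "}")
  doc <- paste(lines, collapse = "\n")
  attr(doc, "edges") <- edges
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}

#' Export a relevance tree as a DOT dendrogram
#'
#' @param tree A `relevance_tree`.
#' @param path Optional output file.
#' @return DOT document (invisibly if `path` is given).
#' @export
export_relevance_tree <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "relevance_tree"))
  lines <- c("digraph relevance_tree {", "  rankdir=LR;")
  counter <- new.env()
  counter$i <- 0L
  rec <- function(node) {
    counter$i <- counter$i + 1L
    id <- paste0("n", counter$i)
    label <- if (length(node$set)) node$set[length(node$set)] else "empty model"
    lines <<- c(lines, sprintf("  %s [label=\"%s\\n(%.3g)\"];", id, label,
                               node$prob))
    for (ch in node$children) {
      cid <- rec(ch)
      lines <<- c(lines, sprintf("  %s -> %s;", id, cid))
    }
    id
  }
  rec(unclass(tree))
  lines <- c(lines, "}")
  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
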