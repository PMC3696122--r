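test_that("the Cooper-Herskovits score matches its closed form", {
  d <- matrix(c(0L, 1L), 2, 1, dimnames = list(NULL, "x"))
  # (r-1)! / (N+r-1)! * prod(n_k!) = 1/6 = integral of theta(1-theta)
  expect_equal(ch_log_marginal_likelihood(d, "x"), log(1 / 6),
               tolerance = 1e-12)
  # empty data scores zero (vacuous product)
  d0 <- matrix(integer(), 0, 1, dimnames = list(NULL, "x"))
  expect_equal(ch_log_marginal_likelihood(d0, "x"), 0)
  expect_error(ch_log_marginal_likelihood(d, "x", "x"), "own parent")
})

test_that("the network score decomposes into per-family scores", {
  set.seed(4)
  n <- 60
  A <- rbinom(n, 1, 0.5)
  B <- rbinom(n, 1, plogis(1.5 * A - 0.5))
  C <- rbinom(n, 1, plogis(-1 + 2 * B))
  X <- cbind(A = A, B = B, C = C)
  # chain A -> B -> C scored family-by-family against the oracle
  total <- ch_log_marginal_likelihood(X, "A") +
    ch_log_marginal_likelihood(X, "B", "A") +
    ch_log_marginal_likelihood(X, "C", "B")
  oracle <- ch_oracle(X, "A", character()) + ch_oracle(X, "B", "A") +
    ch_oracle(X, "C", "B")
  expect_equal(total, oracle, tolerance = 1e-10)
  # and with a two-parent family
  expect_equal(ch_log_marginal_likelihood(X, "C", c("A", "B")),
               ch_oracle(X, "C", c("A", "B")), tolerance = 1e-10)
})

test_that("Markov blankets collect parents, children and spouses", {
  vars <- c("A", "B", "C", "Y")
  g <- matrix(0L, 4, 4, dimnames = list(vars, vars))
  expect_equal(markov_blanket(g, "Y"), character())
  g_chain <- g; g_chain["A", "B"] <- 1L; g_chain["B", "Y"] <- 1L
  expect_equal(markov_blanket(g_chain, "Y"), "B")
  # v-structure Y -> C <- A: the spouse A enters the blanket
  g_v <- g; g_v["Y", "C"] <- 1L; g_v["A", "C"] <- 1L
  expect_setequal(markov_blanket(g_v, "Y"), c("C", "A"))
  expect_error(markov_blanket(g, "nope"), "not in graph")
})

test_that("exhaustive enumeration matches a hand-computed 2-variable posterior", {
  set.seed(11)
  x <- rbinom(30, 1, 0.5)
  y <- rbinom(30, 1, plogis(2 * x - 1))
  X <- cbind(x = x, phenotype = y)
  ex <- exhaustive_posterior(X, "phenotype", max_parents = 1)
  expect_equal(ex$diagnostics$n_dags, 3)
  # three DAGs: empty, x->y, y->x; scores by the closed form
  s_x <- ch_oracle(X, "x", character())
  s_y <- ch_oracle(X, "phenotype", character())
  s_xy <- ch_oracle(X, "phenotype", "x")
  s_yx <- ch_oracle(X, "x", "phenotype")
  w <- exp(c(s_x + s_y, s_x + s_xy, s_y + s_yx) -
             max(s_x + s_y, s_x + s_xy, s_y + s_yx))
  w <- w / sum(w)
  expect_equal(unname(ex$mbm["x"]), w[2L] + w[3L], tolerance = 1e-10)
  empty_atom <- ex$mbs$prob[ex$mbs$set == "{}"]
  expect_equal(empty_atom, w[1L], tolerance = 1e-10)
})

test_that("enumeration counts DAGs correctly and respects the parent bound", {
  X <- matrix(rbinom(40, 1, 0.5), 10, 4,
              dimnames = list(NULL, c("a", "b", "c", "phenotype")))
  expect_equal(exhaustive_posterior(X, "phenotype",
                                    max_parents = 3)$diagnostics$n_dags, 543)
  # bounding parents strictly shrinks the space
  expect_lt(exhaustive_posterior(X, "phenotype",
                                 max_parents = 1)$diagnostics$n_dags, 543)
  X5 <- cbind(X, e = rbinom(10, 1, 0.5))
  expect_equal(exhaustive_posterior(X5, "phenotype",
                                    max_parents = 4)$diagnostics$n_dags, 29281)
  expect_error(exhaustive_posterior(cbind(X5, f = 1L), "phenotype"),
               "structure_mcmc")
})

test_that("a strong pairwise dependence is detected with high posterior", {
  set.seed(2)
  n <- 1000
  x <- rbinom(n, 1, 0.4)
  y <- rbinom(n, 1, plogis(-1 + 2.5 * x))
  X <- cbind(x = x, phenotype = y)
  smp <- structure_mcmc(X, steps = 2e4, burn_in = 2e3, max_parents = 1,
                        seed = 3, thin = 10)
  rel <- relevance_posteriors(smp)
  expect_gt(rel$mbm["x"], 0.95)
})

test_that("independent variables leave the empty structure modal", {
  set.seed(6)
  n <- 1000
  X <- cbind(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.3),
             phenotype = rbinom(n, 1, 0.4))
  smp <- structure_mcmc(X, steps = 5e4, burn_in = 5e3, max_parents = 2,
                        seed = 7, thin = 10)
  # modal sampled structure is the empty graph
  freq <- table(apply(smp$samples, 1L, paste, collapse = ""))
  expect_equal(names(which.max(freq)), strrep("0", 9L))
  # and matches the exhaustive posterior within Monte-Carlo error
  ex <- exhaustive_posterior(X, "phenotype", max_parents = 2)
  rel <- relevance_posteriors(smp)
  for (v in names(rel$mbm)) {
    se <- sqrt(ex$mbm[v] * (1 - ex$mbm[v]) / nrow(smp$samples))
    expect_lt(abs(rel$mbm[v] - ex$mbm[v]), max(6 * se, 0.02))
  }
})

test_that("the sampler is reproducible given a seed", {
  X <- cbind(a = rbinom(50, 1, 0.5), phenotype = rbinom(50, 1, 0.5))
  s1 <- structure_mcmc(X, steps = 5e3, burn_in = 500, seed = 5, thin = 5)
  s2 <- structure_mcmc(X, steps = 5e3, burn_in = 500, seed = 5, thin = 5)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$mb_masks, s2$mb_masks)
})

test_that("relevance posteriors honour the accounting identities", {
  vars <- c("i", "j", "k", "phenotype")
  sets <- list(c("i", "j"), c("i", "j"), "i", "i", "i", "j", "j", "j",
               character(), character())
  smp <- mb_sample_collection(sets, vars)
  rel <- relevance_posteriors(smp)
  expect_equal(unname(rel$mbm["i"]), 0.5)
  expect_equal(unname(rel$mbm["j"]), 0.5)
  expect_equal(unname(rel$mbm["k"]), 0)
  # mbm(X) = sum of mbs atoms containing X, exactly
  for (v in c("i", "j", "k")) {
    bit <- bitwShiftL(1L, match(v, vars) - 1L)
    expect_equal(unname(rel$mbm[v]),
                 sum(rel$mbs$prob[bitwAnd(rel$mbs$mask, bit) != 0L]))
  }
  expect_equal(sum(rel$mbs$prob), 1)
  # identical samples collapse to a single atom
  rel1 <- relevance_posteriors(
    mb_sample_collection(list(c("i", "k"), c("i", "k")), vars))
  expect_equal(nrow(rel1$mbs), 1L)
  expect_equal(rel1$mbs$prob, 1)
  expect_true(all(rel1$mbm %in% c(0, 1)))
})

test_that("interaction/redundancy ratios count blanket co-membership", {
  vars <- c("i", "j", "phenotype")
  sets <- c(rep(list(c("i", "j")), 2), rep(list("i"), 3), rep(list("j"), 3),
            rep(list(character()), 2))
  rel <- relevance_posteriors(mb_sample_collection(sets, vars))
  ir <- interaction_redundancy(rel, "i", "j")
  expect_equal(ir$R, 2 / 6, tolerance = 1e-12)
  expect_equal(ir$RR, log(3), tolerance = 1e-12)
  expect_equal(ir$IR, -ir$RR)
  expect_equal(ir$p_exactly_one, 0.6)
  # always co-occurring pair: denominator collapses
  rel2 <- relevance_posteriors(
    mb_sample_collection(rep(list(c("i", "j")), 4), vars))
  ir2 <- interaction_redundancy(rel2, "i", "j")
  expect_equal(ir2$R, Inf)
  expect_equal(ir2$flag, "infinite")
  expect_error(interaction_redundancy(rel, "i", "i"), "differ")
  expect_error(interaction_redundancy(rel, "i", "phenotype"), "target")
})

test_that("the relevance tree is rooted at 1.0 and decreases along edges", {
  vars <- c("i", "j", "k", "phenotype")
  sets <- c(rep(list(c("i", "j")), 2), rep(list("i"), 3), rep(list("j"), 3),
            rep(list(character()), 2))
  rel <- relevance_posteriors(mb_sample_collection(sets, vars))
  tree <- build_relevance_tree(rel, depth = 3, prob_floor = 0.01)
  expect_equal(tree$prob, 1)
  expect_equal(length(tree$set), 0L)
  walk <- function(node) {
    for (ch in node$children) {
      expect_lte(ch$prob, node$prob + 1e-12)
      walk(ch)
    }
  }
  walk(tree)
  # the {i, j} node carries the joint membership posterior 0.2
  probs <- unlist(lapply(tree$children, function(ch)
    lapply(ch$children, function(g) g$prob)))
  expect_true(any(abs(probs - 0.2) < 1e-12))
})

test_that("consensus network export thresholds edge posteriors", {
  set.seed(2)
  x <- rbinom(400, 1, 0.4)
  y <- rbinom(400, 1, plogis(-1 + 2.5 * x))
  X <- cbind(x = x, phenotype = y)
  rel <- relevance_posteriors(
    structure_mcmc(X, steps = 1e4, burn_in = 1e3, seed = 9, thin = 10))
  empty <- export_consensus_network(rel, edge_threshold = 1.1)
  expect_equal(nrow(attr(empty, "edges")), 0L)
  full <- export_consensus_network(rel, edge_threshold = 0)
  observed <- sum(rel$edge_posteriors > 0)
  expect_equal(nrow(attr(full, "edges")), observed)
  expect_equal(sort(attr(full, "edges")$posterior),
               sort(rel$edge_posteriors[rel$edge_posteriors > 0]))
  expect_match(full, "digraph")
})
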