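# Shared fixtures built in code.

toy_markers <- function() {
  list(
    A = marker_definition("A", "GENE1", "SNP", c("C", "T"), "T"),
    B = marker_definition("B", "GENE2", "SNP", c("A", "G"), "A"),
    V = marker_definition("V", "GENE3", "VNTR", c("2", "4", "7"), "7"))
}

# dataset from explicit genotype tokens (list: marker -> character vector)
toy_dataset <- function(tokens, phenotype, markers = NULL) {
  if (is.null(markers)) markers <- toy_markers()[names(tokens)]
  geno <- do.call(cbind, tokens)
  colnames(geno) <- names(tokens)
  genotype_dataset(sprintf("S%03d", seq_along(phenotype)), phenotype,
                   geno, markers)
}

# phase-known sampling from a two-locus haplotype pool; returns a dataset
# whose two markers are drawn as independent haplotype pairs per subject
pool_dataset <- function(n, hap_freqs, phenotype = NULL, seed = NULL,
                         markers = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(markers))
    markers <- list(
      M1 = marker_definition("M1", "G1", "SNP", c("a", "A"), "A"),
      M2 = marker_definition("M2", "G2", "SNP", c("b", "B"), "B"))
  haps <- do.call(rbind, strsplit(names(hap_freqs), "~", fixed = TRUE))
  i1 <- sample.int(length(hap_freqs), n, TRUE, prob = hap_freqs)
  i2 <- sample.int(length(hap_freqs), n, TRUE, prob = hap_freqs)
  geno <- cbind(paste(haps[i1, 1L], haps[i2, 1L], sep = "/"),
                paste(haps[i1, 2L], haps[i2, 2L], sep = "/"))
  colnames(geno) <- vapply(markers, `[[`, "", "name")
  if (is.null(phenotype)) phenotype <- rep(0L, n)
  genotype_dataset(sprintf("S%05d", seq_len(n)), phenotype, geno, markers)
}

# hand-built structure-sample collection from Markov blanket member sets
mb_sample_collection <- function(sets, vars, target = "phenotype") {
  p <- length(vars)
  masks <- vapply(sets, function(s) {
    if (!length(s)) return(0L)
    sum(bitwShiftL(1L, match(s, vars) - 1L))
  }, 0L)
  structure(
    list(samples = matrix(0L, length(sets), p * p),
         mb_masks = as.integer(masks), vars = vars, target = target,
         diagnostics = list(n_samples = length(sets))),
    class = "bn_samples")
}

# independent CH family score, straight from the closed form
ch_oracle <- function(X, child, parents) {
  X <- X[stats::complete.cases(X[, c(child, parents), drop = FALSE]), ,
         drop = FALSE]
  r <- max(X[, child]) + 1L
  r <- max(r, 2L)
  key <- if (length(parents))
    apply(X[, parents, drop = FALSE], 1L, paste, collapse = "|")
  else rep("", nrow(X))
  s <- 0
  for (k in unique(key)) {
    nk <- table(factor(X[key == k, child], levels = 0:(r - 1L)))
    s <- s + lgamma(r) - lgamma(sum(nk) + r) + sum(lgamma(nk + 1))
  }
  s
}
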