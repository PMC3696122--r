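#' Genotype count container
#'
#' Per-marker, per-stratum genotype class counts. `type = "genotypic"` holds
#' the three carrier classes of the dominant coding (homozygous for the
#' grouping allele, heterozygous, non-carrier) and supports Hardy-Weinberg
#' testing; `type = "dominant"` holds the two collapsed classes
#' (carrier/non-carrier) as published for multi-allelic VNTRs.
#'
#' @param marker Marker name.
#' @param stratum `"controls"`, `"cases"` or `"all"`.
#' @param counts Named non-negative integer vector: 3 classes ordered
#'   (hom, het, non-carrier) for `"genotypic"`, 2 classes ordered
#'   (present, absent) for `"dominant"`.
#' @param type `"genotypic"` or `"dominant"`.
#' @return An object of class `genotype_counts` with field `N`.
#' @export
genotype_counts_table <- function(marker, stratum, counts,
                                  type = c("genotypic", "dominant")) {
  type <- match.arg(type)
  counts <- as.integer(counts0 <- counts)
  names(counts) <- names(counts0)
  if (any(counts < 0)) stop("genotype counts must be non-negative")
  need <- if (type == "genotypic") 3L else 2L
  if (length(counts) != need)
    stop("expected ", need, " classes for type '", type, "'")
  structure(list(marker = marker, stratum = stratum, counts = counts,
                 type = type, N = sum(counts)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> %s [%s, %s] N=%d: %s\n", x$marker,
              x$stratum, x$type, x$N,
              paste(names(x$counts), x$counts, sep = "=", collapse = ", ")))
  invisible(x)
}

#' The 11-marker dopaminergic study panel
#'
#' Marker definitions for the candidate-gene panel analysed throughout the
#' package: 7 SNPs (COMT Val158Met; ANKK1 TaqIA; DRD2 TaqIB and TaqID; the
#' DRD4 promoter SNPs -521 C/T, -615 A/G, -616 C/G) and 4 length
#' polymorphisms (DRD4 120 bp duplication and exon-3 48 bp VNTR; SLC6A3
#' 40 bp VNTR and intron-8 VNTR). Grouping alleles follow the dominant-model
#' convention: the control-stratum minor allele for SNPs, the second most
#' frequent repeat allele for VNTRs (7-repeat, 9-repeat, 2-repeat, and the
#' non-duplicated "1" allele).
#'
#' @return Named list of [marker_definition()] objects.
#' @export
study_markers <- function() {
  m <- list(
    marker_definition("COMT",        "COMT",   "SNP",  c("A", "G"), "G"),
    marker_definition("TaqIA",       "ANKK1",  "SNP",  c("C", "T"), "T"),
    marker_definition("TaqIB",       "DRD2",   "SNP",  c("A", "G"), "A"),
    marker_definition("TaqID",       "DRD2",   "SNP",  c("C", "T"), "C"),
    marker_definition("DRD4_521",    "DRD4",   "SNP",  c("C", "T"), "C"),
    marker_definition("DRD4_615",    "DRD4",   "SNP",  c("A", "G"), "G"),
    marker_definition("DRD4_616",    "DRD4",   "SNP",  c("C", "G"), "G"),
    marker_definition("DRD4_120dup", "DRD4",   "VNTR", c("1", "2"), "1"),
    marker_definition("DRD4_48bp",   "DRD4",   "VNTR", as.character(2:8), "7"),
    marker_definition("DAT_40bp",    "SLC6A3", "VNTR", c("6", "8", "9", "10", "11"), "9"),
    marker_definition("DAT_int8",    "SLC6A3", "VNTR", c("2", "3"), "2"))
  names(m) <- vapply(m, `[[`, "", "name")
  m
}

#' Published per-marker genotype counts (case-control reference table)
#'
#' The per-marker, per-stratum genotype class counts published for the
#' Hungarian heroin-dependence cohort (303 cases, 555 enrolled controls;
#' per-marker N varies with genotyping success). SNP rows carry the three
#' genotype classes ordered (hom-minor, het, hom-major); VNTR rows carry the
#' two published dominant classes ordered (present, absent). These counts
#' are marginal per marker - they carry no joint structure - and serve as
#' reproduction fixtures for the single-marker layer.
#'
#' @return Named list; each element has `marker`, `control` and `case`
#'   [genotype_counts_table()] entries.
#' @export
table1_fixture <- function() {
  snp <- function(name, ctrl, case, labels) {
    list(marker = name,
         control = genotype_counts_table(name, "controls",
                                         stats::setNames(ctrl, labels), "genotypic"),
         case = genotype_counts_table(name, "cases",
                                      stats::setNames(case, labels), "genotypic"))
  }
  vntr <- function(name, ctrl, case, labels) {
    list(marker = name,
         control = genotype_counts_table(name, "controls",
                                         stats::setNames(ctrl, labels), "dominant"),
         case = genotype_counts_table(name, "cases",
                                      stats::setNames(case, labels), "dominant"))
  }
  out <- list(
    COMT        = snp("COMT",     c(125, 275, 155), c(75, 152, 75),
                      c("GG", "AG", "AA")),
    TaqIA       = snp("TaqIA",    c(17, 148, 366),  c(18, 100, 176),
                      c("TT", "CT", "CC")),
    TaqIB       = snp("TaqIB",    c(12, 123, 388),  c(13, 88, 180),
                      c("AA", "AG", "GG")),
    TaqID       = snp("TaqID",    c(78, 239, 178),  c(56, 138, 95),
                      c("CC", "CT", "TT")),
    DRD4_521    = snp("DRD4_521", c(111, 278, 140), c(61, 134, 107),
                      c("CC", "CT", "TT")),
    DRD4_615    = snp("DRD4_615", c(4, 128, 395),   c(5, 80, 215),
                      c("GG", "AG", "AA")),
    DRD4_616    = snp("DRD4_616", c(120, 271, 143), c(62, 164, 76),
                      c("GG", "CG", "CC")),
    DRD4_120dup = vntr("DRD4_120dup", c(161, 392), c(92, 211),
                       c("1-present", "1-absent")),
    DRD4_48bp   = vntr("DRD4_48bp",   c(204, 337), c(106, 195),
                       c("7-present", "7-absent")),
    DAT_40bp    = vntr("DAT_40bp",    c(262, 275), c(128, 164),
                       c("9-present", "9-absent")),
    DAT_int8    = vntr("DAT_int8",    c(199, 343), c(106, 195),
                       c("2-present", "2-absent")))
  out
}

#' Published stratified two-SNP count tables (DRD4 -615 x -521)
#'
#' The published combined-effect table for the two DRD4 promoter SNPs:
#' subjects are stratified by carrier status of the -615 G allele, and within
#' each stratum the -521 C/T dominant classes are cross-tabulated against
#' phenotype. Each stratum is a 2x2 integer matrix with rows
#' `case`/`control` and columns `exposed` (C-absent, i.e. TT) /
#' `unexposed` (C-present), matching the published orientation in which the
#' TT genotype is the risk class.
#'
#' @return List with 2x2 matrices `g_absent` and `g_present`.
#' @export
table4_fixture <- function() {
  dn <- list(c("case", "control"), c("TT", "C-present"))
  list(
    g_absent  = matrix(c(91, 114, 124, 275), 2, 2, dimnames = dn),
    g_present = matrix(c(14, 23, 71, 109),  2, 2, dimnames = dn))
}

#' Expand genotype class counts into a single-marker dataset
#'
#' Turns a pair of genotypic count tables (controls, cases) into an
#' individual-level [genotype_dataset()] with one marker, enabling
#' count-level fixtures to flow through the individual-level code paths.
#' Only `type = "genotypic"` counts can be expanded (the two dominant
#' classes do not determine the carrier genotypes).
#'
#' @param marker A [marker_definition()].
#' @param control_counts,case_counts [genotype_counts_table()] objects of
#'   type `"genotypic"` ordered (hom, het, non-carrier).
#' @return A [genotype_dataset()] with cases first, then controls.
#' @export
counts_to_dataset <- function(marker, control_counts, case_counts) {
  stopifnot(inherits(control_counts, "genotype_counts"),
            inherits(case_counts, "genotype_counts"))
  if (control_counts$type != "genotypic" || case_counts$type != "genotypic")
    stop("only genotypic (3-class) counts can be expanded to individuals")
  g <- marker$grouping_allele
  other <- setdiff(marker$alleles, g)[1L]
  toks <- c(paste(g, g, sep = "/"), paste(sort(c(g, other))[1L],
            sort(c(g, other))[2L], sep = "/"), paste(other, other, sep = "/"))
  expand <- function(cnt) rep(toks, times = cnt$counts)
  tok <- c(expand(case_counts), expand(control_counts))
  phen <- rep(c(1L, 0L), c(case_counts$N, control_counts$N))
  geno <- matrix(tok, ncol = 1, dimnames = list(NULL, marker$name))
  genotype_dataset(sprintf("S%05d", seq_along(tok)), phen, geno,
                   stats::setNames(list(marker), marker$name))
}
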