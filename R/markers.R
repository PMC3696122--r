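#' Define a genetic marker
#'
#' A marker is either a biallelic SNP or a multi-allelic length polymorphism
#' (VNTR). The `grouping_allele` is the allele whose carrier status defines
#' the dominant (presence/absence) coding used throughout the association and
#' network layers; for SNPs this is conventionally the minor allele in the
#' control stratum, for VNTRs the second most frequent repeat allele.
#'
#' @param name Marker name, unique within a study (e.g. `"TaqIB"`).
#' @param gene Gene symbol the marker belongs to (e.g. `"DRD2"`).
#' @param kind `"SNP"` or `"VNTR"`.
#' @param alleles Character vector of allele labels: two bases for a SNP,
#'   repeat-count labels for a VNTR. At least two.
#' @param grouping_allele Allele whose presence (>= 1 copy) codes as 1 in the
#'   dominant model. Must be one of `alleles`.
#' @param missing_code Token representing a missing genotype in text files.
#' @return An object of class `marker_definition`.
#' @examples
#' marker_definition("TaqIB", "DRD2", "SNP", c("A", "G"), "A")
#' @export
marker_definition <- function(name, gene = "", kind = c("SNP", "VNTR"),
                              alleles, grouping_allele,
                              missing_code = "./.") {
  kind <- match.arg(kind)
  alleles <- as.character(alleles)
  grouping_allele <- as.character(grouping_allele)
  if (length(alleles) < 2L)
    stop("marker '", name, "': at least two alleles are required")
  if (anyDuplicated(alleles))
    stop("marker '", name, "': duplicated allele labels")
  if (kind == "SNP" && length(alleles) != 2L)
    stop("marker '", name, "': a SNP must have exactly two alleles")
  if (!grouping_allele %in% alleles)
    stop("marker '", name, "': grouping_allele '", grouping_allele,
         "' is not in the allele universe")
  structure(
    list(name = as.character(name), gene = as.character(gene), kind = kind,
         alleles = alleles, grouping_allele = grouping_allele,
         missing_code = missing_code),
    class = "marker_definition")
}

#' @export
print.marker_definition <- function(x, ...) {
  cat(sprintf("<marker> %s (%s, %s) alleles: %s; dominant coding on '%s'\n",
              x$name, x$gene, x$kind, paste(x$alleles, collapse = "/"),
              x$grouping_allele))
  invisible(x)
}

normalize_token <- function(token, marker) {
  # canonical unordered pair: alleles ordered by their position in the
  # marker's allele universe, joined by "/"
  idx <- match(token, marker$alleles)
  paste(marker$alleles[sort(idx)], collapse = "/")
}

split_tokens <- function(tokens) strsplit(tokens, "/", fixed = TRUE)

#' Construct a genotype dataset
#'
#' Container for an individual-level case-control genotype table: one row per
#' subject, a binary phenotype (1 = case, 0 = control) and one column per
#' marker holding unordered allele pairs as `"a/b"` tokens (`NA` = missing).
#' Pairs are stored in a canonical allele order so that `"7/4"` and `"4/7"`
#' are the same genotype.
#'
#' @param subjects Character vector of subject identifiers.
#' @param phenotype Integer/logical vector, 1 for cases, 0 for controls.
#' @param genotypes Character matrix, subjects x markers, of `"a/b"` tokens
#'   (or `NA`); column names must match marker names.
#' @param markers List of [marker_definition()] objects.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(subjects, phenotype, genotypes, markers) {
  subjects <- as.character(subjects)
  phenotype <- as.integer(phenotype)
  if (length(phenotype) != length(subjects))
    stop("phenotype length (", length(phenotype),
         ") does not match subject count (", length(subjects), ")")
  if (!all(phenotype %in% c(0L, 1L)))
    stop("phenotype must be binary (0 = control, 1 = case)")
  marker_names <- unname(vapply(markers, `[[`, "", "name"))
  if (anyDuplicated(marker_names)) stop("marker names must be unique")
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes)) ||
      !identical(unname(colnames(genotypes)), marker_names))
    stop("genotype matrix columns must match marker names, in order")
  if (nrow(genotypes) != length(subjects))
    stop("genotype matrix has ", nrow(genotypes), " rows for ",
         length(subjects), " subjects")
  names(markers) <- marker_names
  # validate and canonicalize tokens
  for (m in marker_names) {
    tok <- genotypes[, m]
    ok <- !is.na(tok)
    if (!any(ok)) next
    parts <- split_tokens(tok[ok])
    bad_len <- lengths(parts) != 2L
    if (any(bad_len))
      stop("malformed genotype token for marker '", m, "', subject '",
           subjects[ok][which(bad_len)[1L]], "': '",
           tok[ok][which(bad_len)[1L]], "'")
    alle <- unlist(parts, use.names = FALSE)
    unknown <- !alle %in% markers[[m]]$alleles
    if (any(unknown)) {
      row_idx <- ceiling(which(unknown)[1L] / 2)
      stop("unknown allele '", alle[unknown][1L], "' for marker '", m,
           "', subject '", subjects[ok][row_idx], "'")
    }
    genotypes[ok, m] <- vapply(parts, normalize_token, "", marker = markers[[m]])
  }
  structure(
    list(subjects = subjects, phenotype = phenotype,
         genotypes = genotypes, markers = markers),
    class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("<genotype_dataset> %d subjects (%d cases, %d controls), %d markers\n",
              length(x$subjects), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), length(x$markers)))
  cat("  markers:", paste(names(x$markers), collapse = ", "), "\n")
  invisible(x)
}

parse_phenotype <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("1", "case", "cases", "affected")] <- 1L
  out[x %in% c("0", "control", "controls", "unaffected")] <- 0L
  if (anyNA(out))
    stop("phenotype values must be 0/1 or case/control; offending value: '",
         x[which(is.na(out))[1L]], "' (row ", which(is.na(out))[1L], ")")
  out
}

#' Read a marker configuration file
#'
#' The configuration is a YAML or JSON list; each entry carries `name`,
#' `gene`, `kind`, `alleles`, `grouping_allele` and optionally
#' `missing_code`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of [marker_definition()] objects.
#' @export
read_marker_config <- function(path) {
  if (!file.exists(path)) stop("marker config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
         else yaml::read_yaml(path)
  lapply(raw, function(m) {
    marker_definition(
      name = m$name, gene = if (is.null(m$gene)) "" else m$gene,
      kind = m$kind, alleles = unlist(m$alleles),
      grouping_allele = m$grouping_allele,
      missing_code = if (is.null(m$missing_code)) "./." else m$missing_code)
  })
}

#' Load a genotype dataset from delimited text
#'
#' Reads a TSV/CSV genotype table (`subject_id`, `phenotype`, one column per
#' marker; genotype tokens `"a/b"`) together with a marker configuration
#' file, validates every allele against the marker's allele universe and
#' returns a [genotype_dataset()]. Row order is preserved; the configured
#' missing token becomes `NA`.
#'
#' @param genotype_path Path to the genotype table (TSV by default; `.csv`
#'   extension switches to comma separation).
#' @param marker_config_path Path to the marker configuration (YAML/JSON),
#'   see [read_marker_config()].
#' @return A [genotype_dataset()].
#' @export
load_dataset <- function(genotype_path, marker_config_path) {
  if (!file.exists(genotype_path))
    stop("genotype file not found: ", genotype_path)
  markers <- read_marker_config(marker_config_path)
  sep <- if (tolower(tools::file_ext(genotype_path)) == "csv") "," else "\t"
  tab <- utils::read.table(genotype_path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "phenotype", vapply(markers, `[[`, "", "name"))
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("genotype table is missing columns: ", paste(miss, collapse = ", "))
  geno <- as.matrix(tab[, vapply(markers, `[[`, "", "name"), drop = FALSE])
  for (m in markers) geno[geno[, m$name] == m$missing_code, m$name] <- NA
  genotype_dataset(tab$subject_id, parse_phenotype(tab$phenotype),
                   geno, markers)
}

#' Write a genotype dataset to delimited text
#'
#' Inverse of [load_dataset()]: emits `subject_id`, `phenotype` and one
#' canonical `"a/b"` token column per marker; missing genotypes are written
#' as each marker's missing token.
#'
#' @param ds A [genotype_dataset()].
#' @param path Output path (TSV; `.csv` extension switches to commas).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  geno <- ds$genotypes
  for (m in ds$markers) geno[is.na(geno[, m$name]), m$name] <- m$missing_code
  tab <- data.frame(subject_id = ds$subjects, phenotype = ds$phenotype,
                    geno, check.names = FALSE, stringsAsFactors = FALSE)
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dominant (carrier) binary coding of a genotype dataset
#'
#' Codes each marker as 1 if the genotype carries at least one copy of the
#' marker's `grouping_allele`, 0 otherwise; missing genotypes propagate as
#' `NA`. The phenotype is appended as the final target column, giving the
#' discretized matrix that both the dominant-model association tests and the
#' BN-BMLA layer consume.
#'
#' @param ds A [genotype_dataset()].
#' @param target Name for the appended phenotype column.
#' @return An integer matrix of 0/1/`NA`, subjects x (markers + target), of
#'   class `binary_coded`, with attribute `target`.
#' @export
dominant_code <- function(ds, target = "phenotype") {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (target %in% names(ds$markers))
    stop("target column name collides with a marker name")
  out <- matrix(NA_integer_, nrow = length(ds$subjects),
                ncol = length(ds$markers) + 1L,
                dimnames = list(ds$subjects, c(names(ds$markers), target)))
  for (m in ds$markers) {
    tok <- ds$genotypes[, m$name]
    ok <- !is.na(tok)
    if (any(ok)) {
      parts <- split_tokens(tok[ok])
      out[ok, m$name] <- vapply(parts, function(p)
        as.integer(m$grouping_allele %in% p), 0L)
    }
  }
  out[, target] <- ds$phenotype
  structure(out, target = target, class = c("binary_coded", class(out)))
}

stratum_index <- function(ds, stratum = c("controls", "cases", "all")) {
  stratum <- match.arg(stratum)
  idx <- switch(stratum,
                controls = ds$phenotype == 0L,
                cases    = ds$phenotype == 1L,
                all      = rep(TRUE, length(ds$phenotype)))
  if (!any(idx)) stop("stratum '", stratum, "' is empty")
  idx
}

#' Allele frequencies and the minor allele of a marker
#'
#' Counts alleles over the 2N non-missing chromosomes of the requested
#' stratum. The minor allele is the second most frequent allele (for a
#' biallelic SNP, the rarer one); frequency ties are broken by lexicographic
#' allele order so the result is deterministic.
#'
#' @param ds A [genotype_dataset()].
#' @param marker Marker name.
#' @param stratum `"controls"` (default, the stratum in which study minor
#'   alleles are conventionally defined), `"cases"` or `"all"`.
#' @return A list with `allele` (the minor allele), `frequency`, and the
#'   full `frequencies` table.
#' @export
minor_allele <- function(ds, marker,
                         stratum = c("controls", "cases", "all")) {
  stopifnot(inherits(ds, "genotype_dataset"))
  if (!marker %in% names(ds$markers)) stop("unknown marker: ", marker)
  idx <- stratum_index(ds, stratum)
  tok <- ds$genotypes[idx, marker]
  tok <- tok[!is.na(tok)]
  if (!length(tok)) stop("no non-missing genotypes for '", marker,
                         "' in stratum '", match.arg(stratum), "'")
  alle <- unlist(split_tokens(tok), use.names = FALSE)
  counts <- table(factor(alle, levels = ds$markers[[marker]]$alleles))
  freqs <- counts / sum(counts)
  # order: decreasing frequency, lexicographic within ties
  ord <- order(-as.numeric(freqs), names(freqs))
  minor <- names(freqs)[ord][2L]
  list(allele = minor, frequency = as.numeric(freqs[minor]),
       frequencies = freqs)
}
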