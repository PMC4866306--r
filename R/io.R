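# Plain-TSV interchange formats and VCF import. TSV is the native format:
# the emulated study's data are spreadsheet supplements, not standard
# genomics containers. write/read round-trips are the identity (bit-exact for
# integers and ids; reals at >= 12 significant digits).

parse_error <- function(file, msg, line = NA, column = NA) {
  loc <- if (!is.na(line)) sprintf(" (line %s%s)", line,
                                   if (!is.na(column)) paste0(", column ", column) else "")
         else ""
  abort(sprintf("%s: %s%s", file, msg, loc), class = "dgp_parse_error")
}

check_columns <- function(d, required, file) {
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    parse_error(file, sprintf("missing column(s): %s",
                              paste(missing, collapse = ", ")))
  }
}

#' Write and read the genotype table
#'
#' `genotypes.tsv` has one row per hybrid (`hybrid_id` column) and one column
#' per site, values in `{0, 1, 2}`.
#'
#' @param G Dosage matrix with hybrid row names and site column names.
#' @param path File path.
#' @return `read_genotypes()` returns the integer dosage matrix.
#' @export
write_genotypes <- function(G, path) {
  d <- as_tibble(G, rownames = "hybrid_id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(d, "hybrid_id", path)
  if (anyDuplicated(d$hybrid_id)) parse_error(path, "duplicate hybrid ids")
  G <- as.matrix(d[, -1, drop = FALSE])
  bad <- which(!(G %in% c(0, 1, 2)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(G))
    parse_error(path, sprintf("dosage value %s not in {0,1,2}", G[bad[1]]),
                line = rc[1] + 1L, column = colnames(G)[rc[2]])
  }
  storage.mode(G) <- "integer"
  rownames(G) <- d$hybrid_id
  G
}

#' Write and read the site map table
#'
#' `sites.tsv`: columns `site_id`, `chrom`, `pos_cM`.
#'
#' @param map Site map tibble.
#' @param path File path.
#' @export
write_sites <- function(map, path) {
  readr::write_tsv(map[, c("site_id", "chrom", "pos_cM")], path)
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(site_id = "c", chrom = "i",
                                               pos_cM = "d"))
  check_columns(d, c("site_id", "chrom", "pos_cM"), path)
  if (anyDuplicated(d$site_id)) parse_error(path, "duplicate site ids")
  d
}

#' Write and read the pedigree table
#'
#' `pedigree.tsv`: columns `hybrid_id`, `parent_a`, `parent_alpha`.
#'
#' @param ped Pedigree tibble.
#' @param path File path.
#' @export
write_pedigree <- function(ped, path) {
  readr::write_tsv(ped[, c("hybrid_id", "parent_a", "parent_alpha")], path)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, col_types = "ccc")
  check_columns(d, c("hybrid_id", "parent_a", "parent_alpha"), path)
  if (anyDuplicated(d$hybrid_id)) parse_error(path, "duplicate hybrid ids")
  d
}

#' Write and read the phenotype table
#'
#' `phenotypes.tsv`: long format with columns `hybrid_id`, `trait`,
#' `replicate`, `value`. An empty-but-headered file reads as an empty table.
#'
#' @param pheno Long phenotype tibble.
#' @param path File path.
#' @export
write_phenotypes <- function(pheno, path) {
  readr::write_tsv(pheno[, c("hybrid_id", "trait", "replicate", "value")], path)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, col_types = "ccid")
  check_columns(d, c("hybrid_id", "trait", "replicate", "value"), path)
  d
}

#' Write and read a GRM as a square TSV matrix
#'
#' `grm.tsv`: header of individual ids, one labelled row per individual.
#'
#' @param grm A `grm` object.
#' @param path File path.
#' @export
write_grm <- function(grm, path) {
  d <- as_tibble(grm$K, rownames = "hybrid_id")
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname write_grm
#' @export
read_grm <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(d, "hybrid_id", path)
  K <- as.matrix(d[, -1, drop = FALSE])
  rownames(K) <- d$hybrid_id
  structure(list(K = K, c = NA_real_, ids = d$hybrid_id), class = "grm")
}

#' Write and read prediction and result tables
#'
#' `predictions.tsv`: `hybrid_id`, `trait`, `fold`, `pred_mean`, `pred_sd`.
#' `results.tsv`: `trait`, `model`, `scenario`, `fold`, `r2`, `n_train`,
#' `mean_pred_sd`, `resid_sd`.
#'
#' @param d Tibble to write.
#' @param path File path.
#' @export
write_results <- function(d, path) {
  readr::write_tsv(d, path)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Import a genotype matrix from a VCF file
#'
#' Converts biallelic diploid `GT` fields to dosages: `0/0 -> 0`, `0/1` or
#' `1/0 -> 1`, `1/1 -> 2` (phased `|` separators are treated the same).
#' Multi-allelic records and records with any missing GT are skipped, with
#' the skip count reported.
#'
#' @param path VCF file path (requires the vcfR package).
#' @return An integer dosage matrix (individuals x sites) with a
#'   `n_skipped` attribute.
#' @export
import_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort_arg("VCF import requires the vcfR package")
  }
  if (!file.exists(path)) {
    abort(sprintf("cannot read VCF file: %s", path), class = "dgp_io_error")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("|", "/", gt, fixed = TRUE)
  dose[clean %in% c("0/0")] <- 0L
  dose[clean %in% c("0/1", "1/0")] <- 1L
  dose[clean %in% c("1/1")] <- 2L
  keep <- !multi & !apply(dose, 1, anyNA)
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    message(sprintf("import_vcf: skipped %d multi-allelic or incomplete record(s)",
                    n_skipped))
  }
  G <- t(dose[keep, , drop = FALSE])
  structure(G, n_skipped = n_skipped)
}

#' Write a simulated dataset to a directory of TSV tables
#'
#' Writes `genotypes.tsv`, `sites.tsv`, `pedigree.tsv`, `phenotypes.tsv` and
#' `truth.json` (realized per-trait heritabilities and the generator seed).
#'
#' @param data A `diallel_data`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_diallel_data <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(data$G, file.path(dir, "genotypes.tsv"))
  write_sites(data$map, file.path(dir, "sites.tsv"))
  write_pedigree(data$pedigree, file.path(dir, "pedigree.tsv"))
  write_phenotypes(data$phenotypes, file.path(dir, "phenotypes.tsv"))
  jsonlite::write_json(
    list(seed = data$seed, realized = data$truth),
    file.path(dir, "truth.json"), dataframe = "rows", auto_unbox = TRUE,
    digits = NA)
  invisible(dir)
}

#' Read a dataset directory written by [write_diallel_data()]
#'
#' @param dir Directory containing the TSV tables.
#' @return A `diallel_data`-like list (`G`, `map`, `pedigree`, `phenotypes`).
#' @export
read_diallel_data <- function(dir) {
  structure(list(
    G = read_genotypes(file.path(dir, "genotypes.tsv")),
    map = read_sites(file.path(dir, "sites.tsv")),
    pedigree = read_pedigree(file.path(dir, "pedigree.tsv")),
    phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv"))),
    class = "diallel_data")
}
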