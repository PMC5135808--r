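#' Construct a mutation cohort from a data frame
#'
#' A mutation cohort is a tibble of single-nucleotide somatic substitutions
#' (columns `chrom`, `pos`, `ref`, `alt`, `sample_id`, `cancer_type`) carrying
#' class `mutation_cohort`, deduplicated on the full record and sorted by
#' position so windowed recurrence queries can binary-search. Positions are
#' 1-based as called; interval inputs elsewhere in the package are 0-based
#' half-open and converted at query time.
#'
#' @param df data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `sample_id`; an optional `cancer_type` column is kept (filled with `NA`
#'   otherwise).
#' @param genome optional tibble `(chrom, length)` giving chromosome lengths,
#'   used to clip background windows at chromosome ends.
#' @return a `mutation_cohort` tibble.
#' @export
#' @examples
#' as_mutation_cohort(tibble::tibble(
#'   chrom = "chr1", pos = c(100, 100, 105), ref = "A", alt = "G",
#'   sample_id = c("s1", "s1", "s2")
#' ))
as_mutation_cohort <- function(df, genome = NULL) {
  assert_cols(df, c("chrom", "pos", "ref", "alt", "sample_id"), "mutation table")
  df <- as_tibble(df)
  if (!"cancer_type" %in% names(df)) df$cancer_type <- NA_character_
  df <- df[, c("chrom", "pos", "ref", "alt", "sample_id", "cancer_type")]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$ref <- toupper(as.character(df$ref))
  df$alt <- toupper(as.character(df$alt))
  df$sample_id <- as.character(df$sample_id)
  validate_mutations(df)
  df <- dplyr::distinct(df, .data$chrom, .data$pos, .data$ref, .data$alt,
    .data$sample_id,
    .keep_all = TRUE
  )
  df <- dplyr::arrange(df, .data$chrom, .data$pos)
  if (!is.null(genome)) {
    assert_cols(genome, c("chrom", "length"), "genome table")
    genome <- as_tibble(genome)[, c("chrom", "length")]
  }
  structure(df,
    genome = genome,
    class = c("mutation_cohort", class(tibble::tibble()))
  )
}

validate_mutations <- function(df) {
  if (nrow(df) == 0) rlang::abort("mutation table is empty")
  if (any(is.na(df$pos))) {
    rlang::abort(sprintf(
      "non-integer position at row %d", which(is.na(df$pos))[1]
    ))
  }
  if (any(df$pos < 1)) {
    rlang::abort(sprintf("position < 1 at row %d", which(df$pos < 1)[1]))
  }
  bad <- which(df$ref == df$alt)
  if (length(bad) > 0) {
    rlang::abort(sprintf("ref equals alt at row %d", bad[1]))
  }
  if (any(!nzchar(df$sample_id) | is.na(df$sample_id))) {
    rlang::abort("empty sample_id")
  }
  invisible(df)
}

#' @export
print.mutation_cohort <- function(x, ...) {
  cat(sprintf(
    "# mutation_cohort: %d records, %d samples, %d chromosome(s)\n",
    nrow(x), dplyr::n_distinct(x$sample_id), dplyr::n_distinct(x$chrom)
  ))
  NextMethod()
}

# per-chromosome sorted position vectors (duplicates kept: one entry per record)
cohort_index <- function(cohort) {
  split(cohort$pos, cohort$chrom)
}

cohort_genome <- function(cohort) attr(cohort, "genome")

#' Read a somatic mutation call table
#'
#' Reads a TSV with header columns `chrom`, `pos`, `ref`, `alt`, `sample`
#' (or `sample_id`). Only single-nucleotide substitutions are retained:
#' rows whose `ref` or `alt` is longer than one base (indels/MNVs) are
#' skipped with a warning, since downstream binding-site rescanning is
#' defined for point substitutions. Exact duplicate records are collapsed.
#'
#' @param path file path.
#' @param cancer_type label stored with every record.
#' @param genome optional `(chrom, length)` tibble (see
#'   [as_mutation_cohort()]).
#' @param strip_chr_prefix strip a leading `"chr"` from chromosome names.
#' @return a `mutation_cohort` tibble.
#' @export
read_mutations <- function(path, cancer_type = NA_character_, genome = NULL,
                           strip_chr_prefix = FALSE) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(df) == 0) rlang::abort(sprintf("empty mutation file: %s", path))
  if ("sample" %in% names(df) && !"sample_id" %in% names(df)) {
    df <- dplyr::rename(df, sample_id = "sample")
  }
  assert_cols(df, c("chrom", "pos", "ref", "alt", "sample_id"), path)
  pos <- suppressWarnings(as.integer(df$pos))
  if (any(is.na(pos))) {
    rlang::abort(sprintf(
      "malformed position '%s' at line %d of %s",
      df$pos[which(is.na(pos))[1]], which(is.na(pos))[1] + 1L, path
    ))
  }
  df$pos <- pos
  is_snv <- nchar(df$ref) == 1 & nchar(df$alt) == 1 &
    toupper(df$ref) %in% c(DNA_BASES, "N") & toupper(df$alt) %in% DNA_BASES
  if (any(!is_snv)) {
    rlang::warn(sprintf(
      "skipping %d non-SNV row(s) in %s", sum(!is_snv), path
    ))
    df <- df[is_snv, , drop = FALSE]
    if (nrow(df) == 0) rlang::abort(sprintf("no SNV rows in %s", path))
  }
  if (strip_chr_prefix) df$chrom <- sub("^chr", "", df$chrom)
  df$cancer_type <- as.character(cancer_type)
  as_mutation_cohort(df, genome = genome)
}

#' Write a mutation cohort to TSV
#'
#' @param cohort a `mutation_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(cohort, path) {
  out <- as_tibble(cohort)
  names(out)[names(out) == "sample_id"] <- "sample"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Remove mutations at known germline variant positions
#'
#' Drops every record whose `(chrom, pos)` appears in the known-variant set
#' (e.g. 1000 Genomes positions). Matching is by position only, not allele:
#' a somatic call sitting exactly on a catalogued polymorphic site is treated
#' as a likely residual germline variant regardless of the allele observed.
#'
#' @param cohort a `mutation_cohort`.
#' @param known_sites data frame with columns `chrom`, `pos` (1-based).
#' @return the filtered `mutation_cohort`; the number of removed records is
#'   reported via `message()` and stored in attribute `n_removed`.
#' @export
filter_germline <- function(cohort, known_sites) {
  genome <- cohort_genome(cohort)
  if (is.null(known_sites) || nrow(known_sites) == 0) {
    out <- cohort
    attr(out, "n_removed") <- 0L
    return(out)
  }
  assert_cols(known_sites, c("chrom", "pos"), "known-variant table")
  keep <- !(site_key(cohort) %in% site_key(known_sites))
  n_removed <- sum(!keep)
  rlang::inform(sprintf("filter_germline: removed %d record(s)", n_removed))
  out <- as_tibble(cohort)[keep, , drop = FALSE]
  out <- structure(out,
    genome = genome,
    class = c("mutation_cohort", class(tibble::tibble()))
  )
  attr(out, "n_removed") <- n_removed
  out
}
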