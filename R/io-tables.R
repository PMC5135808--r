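#' Read a network edge list
#'
#' Reads a two-column TSV of gene identifiers (regulator then target when
#' `directed = TRUE`). Self-loops are dropped and duplicate edges collapsed;
#' undirected edges are stored once in canonical (sorted) orientation and
#' treated symmetrically by all graph queries.
#'
#' @param path TSV file with columns `from`, `to` (header optional: a header
#'   line named `from`/`to` is detected, otherwise the first row is data).
#' @param directed logical; is the network directed?
#' @return an `edge_list` tibble with columns `from`, `to` and attribute
#'   `directed`.
#' @export
read_edge_list <- function(path, directed = FALSE) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^from\\tto", first)
  df <- utils::read.table(path,
    header = has_header, sep = "\t",
    stringsAsFactors = FALSE, colClasses = "character"
  )
  if (ncol(df) < 2) rlang::abort(sprintf("fewer than 2 columns in %s", path))
  as_edge_list(stats::setNames(df[, 1:2], c("from", "to")), directed = directed)
}

#' Construct an edge list from a data frame
#'
#' @param df data frame with columns `from`, `to`.
#' @param directed logical.
#' @return an `edge_list` tibble.
#' @export
as_edge_list <- function(df, directed = FALSE) {
  assert_cols(df, c("from", "to"), "edge list")
  df <- as_tibble(df)[, c("from", "to")]
  df$from <- as.character(df$from)
  df$to <- as.character(df$to)
  df <- df[df$from != df$to, , drop = FALSE]
  if (!directed) {
    swap <- df$from > df$to
    tmp <- df$from[swap]
    df$from[swap] <- df$to[swap]
    df$to[swap] <- tmp
  }
  df <- dplyr::distinct(df)
  structure(df,
    directed = directed,
    class = c("edge_list", class(tibble::tibble()))
  )
}

#' Write an edge list to TSV
#'
#' @param net an `edge_list`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  readr::write_tsv(as_tibble(net), path, progress = FALSE)
  invisible(path)
}

# nodes adjacent to `node`: outgoing only when directed
neighbors_of <- function(net, node) {
  if (attr(net, "directed")) {
    unique(net$to[net$from %in% node])
  } else {
    unique(c(net$to[net$from %in% node], net$from[net$to %in% node]))
  }
}

#' Read an enhancer-promoter pair table
#'
#' TSV columns: `chrom`, `start`, `end`, `gene`, `cell_type`, `score`
#' (header required). Intervals are 0-based half-open enhancer coordinates.
#'
#' @param path TSV file.
#' @return a tibble of EP pairs.
#' @export
read_ep_pairs <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(), end = readr::col_double(),
      gene = readr::col_character(), cell_type = readr::col_character(),
      score = readr::col_double()
    ), progress = FALSE
  )
  assert_cols(df, c("chrom", "start", "end", "gene", "cell_type", "score"), path)
  if (any(df$start < 0 | df$end <= df$start)) {
    rlang::abort("invalid enhancer interval")
  }
  df
}

#' Read a DHS-correlation map table
#'
#' TSV columns: `chrom`, `start`, `end`, `gene`, `max_corr` (header
#' required). `max_corr` is the maximum distal-proximal DNase tag-density
#' correlation across cell types, in \[-1, 1\].
#'
#' @param path TSV file.
#' @return a tibble of DHS-correlation entries.
#' @export
read_dhs_map <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_double(), end = readr::col_double(),
      gene = readr::col_character(), max_corr = readr::col_double()
    ), progress = FALSE
  )
  assert_cols(df, c("chrom", "start", "end", "gene", "max_corr"), path)
  if (any(abs(df$max_corr) > 1)) rlang::abort("max_corr outside [-1, 1]")
  df
}

#' Read a BED file of intervals
#'
#' First three columns chrom/start/end (0-based half-open), no header.
#' Extra columns are ignored.
#'
#' @param path BED file.
#' @return a tibble `(chrom, start, end)`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path,
    header = FALSE, sep = "", stringsAsFactors = FALSE
  )
  if (ncol(df) < 3) rlang::abort(sprintf("fewer than 3 columns in %s", path))
  tibble(
    chrom = as.character(df[[1]]),
    start = as.numeric(df[[2]]),
    end = as.numeric(df[[3]])
  )
}

#' Read a GWAS SNP catalog
#'
#' TSV columns: `chrom`, `pos` (1-based), optional `trait`.
#'
#' @param path TSV file.
#' @return a tibble of SNP positions.
#' @export
read_gwas_catalog <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  assert_cols(df, c("chrom", "pos"), path)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df
}

#' Read a gene expression matrix with tumor/normal status
#'
#' The file is a TSV whose first column is `gene_id` and remaining columns
#' are samples; the first data row must be named `__status__` in `gene_id`
#' and carry `tumor`/`normal` for each sample column.
#'
#' @param path TSV file.
#' @return a list with `values` (genes x samples numeric matrix) and
#'   `status` (factor of `"tumor"`/`"normal"` per sample column).
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      .default = readr::col_character()
    ), progress = FALSE
  )
  assert_cols(df, "gene_id", path)
  if (df$gene_id[1] != "__status__") {
    rlang::abort("first data row must be the __status__ row")
  }
  status <- factor(as.character(df[1, -1]), levels = c("tumor", "normal"))
  if (any(is.na(status))) rlang::abort("status must be tumor or normal")
  vals <- as.matrix(df[-1, -1])
  storage.mode(vals) <- "double"
  rownames(vals) <- df$gene_id[-1]
  if (any(!is.finite(vals))) rlang::abort("non-finite expression value")
  list(values = vals, status = status)
}

#' Write an expression matrix in the package's TSV layout
#'
#' @param expr list with `values` and `status` (see
#'   [read_expression_matrix()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  hdr <- c("gene_id", colnames(expr$values))
  status_row <- c("__status__", as.character(expr$status))
  body <- cbind(rownames(expr$values), format(expr$values, digits = 10, trim = TRUE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = "\t"), con)
  writeLines(paste(status_row, collapse = "\t"), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a genome FASTA into named sequences
#'
#' Minimal single-letter FASTA reader for the toy genomes this package
#' scans; sequences are returned as upper-case strings named by the first
#' word of each header.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) rlang::abort(sprintf("no FASTA records in %s", path))
  starts <- hdr + 1
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    toupper(paste(lines[starts[i]:ends[i]], collapse = ""))
  }, character(1))
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @param width line width (default 70).
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    idx <- seq(1, nchar(s), by = width)
    writeLines(substring(s, idx, pmin(idx + width - 1, nchar(s))), con)
  }
  invisible(path)
}
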