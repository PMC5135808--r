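#' Construct a position weight matrix
#'
#' @param tf_id transcription factor identifier.
#' @param matrix numeric matrix, one row per motif position, columns
#'   `A`,`C`,`G`,`T`; each row must sum to 1 (within 1e-9). Motifs shorter
#'   than 4 positions are rejected.
#' @param background base frequencies (default uniform).
#' @return a `pwm` object.
#' @export
new_pwm <- function(tf_id, matrix, background = rep(0.25, 4)) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 4) rlang::abort("PWM must have 4 columns (A,C,G,T)")
  colnames(matrix) <- DNA_BASES
  if (nrow(matrix) < 4) rlang::abort("PWM must have length >= 4")
  if (any(matrix < 0)) rlang::abort("negative PWM probability")
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
    rlang::abort("PWM rows must sum to 1")
  }
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-9) {
    rlang::abort("background must be 4 frequencies summing to 1")
  }
  structure(
    list(
      tf_id = as.character(tf_id), matrix = matrix,
      background = stats::setNames(as.numeric(background), DNA_BASES)
    ),
    class = "pwm"
  )
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("# pwm: %s, length %d\n", x$tf_id, nrow(x$matrix)))
  print(round(x$matrix, 3))
  invisible(x)
}

pwm_length <- function(pwm) nrow(pwm$matrix)

# counts -> probabilities with a pseudocount spread by background
normalize_counts <- function(counts, background, pseudocount) {
  counts <- sweep(counts, 2, background * pseudocount * 4, "+")
  counts / rowSums(counts)
}

#' Read TRANSFAC-format motifs
#'
#' Minimal TRANSFAC matrix parser: records delimited by `//`, identifier
#' from the `ID` (fallback `AC`) line, count rows are numbered lines with
#' four numeric columns ordered A C G T. Counts are converted to
#' probabilities with a small pseudocount so no base has probability zero.
#'
#' @param path TRANSFAC file.
#' @param pseudocount added to each row before normalization (default 0.1,
#'   split by background frequency).
#' @return named list of `pwm` objects.
#' @export
read_transfac <- function(path, pseudocount = 0.1) {
  lines <- readLines(path)
  recs <- split(lines, cumsum(grepl("^//", lines)))
  pwms <- list()
  for (rec in recs) {
    idl <- grep("^ID\\s+", rec, value = TRUE)
    if (length(idl) == 0) idl <- grep("^AC\\s+", rec, value = TRUE)
    if (length(idl) == 0) next
    tf_id <- sub("^\\S+\\s+", "", idl[1])
    rows <- grep("^\\s*\\d+\\s+", rec, value = TRUE)
    if (length(rows) < 4) next
    counts <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][2:5])
    }))
    if (any(is.na(counts))) {
      rlang::abort(sprintf("malformed TRANSFAC count row for %s", tf_id))
    }
    mat <- normalize_counts(counts, rep(0.25, 4), pseudocount)
    pwms[[tf_id]] <- new_pwm(tf_id, mat)
  }
  if (length(pwms) == 0) rlang::abort(sprintf("no motifs parsed from %s", path))
  pwms
}

#' Read MEME-format motifs
#'
#' Minimal MEME text parser: `MOTIF <id>` headers followed by a
#' `letter-probability matrix:` block of whitespace-separated rows over
#' A/C/G/T. A `Background letter frequencies` line, if present, sets the
#' background for every motif.
#'
#' @param path MEME file.
#' @return named list of `pwm` objects.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  background <- rep(0.25, 4)
  bgi <- grep("^Background letter frequencies", lines)
  if (length(bgi) > 0 && bgi[1] < length(lines)) {
    toks <- strsplit(trimws(lines[bgi[1] + 1]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks[seq(2, length(toks), by = 2)]))
    keys <- toks[seq(1, length(toks), by = 2)]
    if (!any(is.na(vals)) && setequal(keys, DNA_BASES)) {
      background <- vals[match(DNA_BASES, keys)]
    }
  }
  starts <- grep("^MOTIF\\s+", lines)
  if (length(starts) == 0) rlang::abort(sprintf("no motifs parsed from %s", path))
  pwms <- list()
  for (i in seq_along(starts)) {
    tf_id <- strsplit(trimws(sub("^MOTIF\\s+", "", lines[starts[i]])), "\\s+")[[1]][1]
    to <- if (i < length(starts)) starts[i + 1] - 1 else length(lines)
    block <- lines[starts[i]:to]
    mi <- grep("letter-probability matrix", block)
    if (length(mi) == 0) next
    rows <- character()
    for (j in seq(mi[1] + 1, length(block))) {
      if (!grepl("^\\s*[0-9.eE+-]+(\\s+[0-9.eE+-]+){3}\\s*$", block[j])) break
      rows <- c(rows, block[j])
    }
    mat <- do.call(rbind, lapply(rows, function(r) {
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    }))
    pwms[[tf_id]] <- new_pwm(tf_id, mat, background = background)
  }
  if (length(pwms) == 0) rlang::abort(sprintf("no motifs parsed from %s", path))
  pwms
}

#' Write motifs in minimal MEME format
#'
#' @param pwms named list of `pwm` objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "Background letter frequencies",
    paste(rbind(DNA_BASES, format(pwms[[1]]$background, digits = 6)),
      collapse = " "
    ), ""
  ), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$tf_id), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      nrow(p$matrix)
    ), con)
    writeLines(apply(format(p$matrix, digits = 6), 1, paste, collapse = " "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read a FIMO-style motif match table
#'
#' TSV with header columns `motif_id`, `sequence_name`, `start`, `stop`,
#' `strand`, `score`, `p-value` (as the FIMO program emits). Lets
#' precomputed external scans substitute for the built-in scanner at the
#' binding-site scoring layer.
#'
#' @param path TSV file.
#' @return a tibble with columns `tf_id`, `sequence_name`, `start`, `stop`,
#'   `strand`, `score`, `p_value`.
#' @export
read_fimo_tsv <- function(path) {
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    check.names = FALSE, comment.char = "#"
  )
  need <- c("motif_id", "sequence_name", "start", "stop", "strand", "score", "p-value")
  assert_cols(df, need, path)
  out <- tibble(
    tf_id = as.character(df$motif_id),
    sequence_name = as.character(df$sequence_name),
    start = as.integer(df$start),
    stop = as.integer(df$stop),
    strand = as.character(df$strand),
    score = as.numeric(df$score),
    p_value = as.numeric(df[["p-value"]])
  )
  if (any(out$p_value <= 0 | out$p_value > 1)) {
    rlang::abort("FIMO p-values must lie in (0, 1]")
  }
  out
}
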