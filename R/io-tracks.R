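#' Construct a signal track
#'
#' A signal track is a tibble of 0-based half-open intervals
#' (`chrom`, `start`, `end`, `value`) that do not overlap within a
#' chromosome, sorted by position, carrying class `signal_track` and a
#' `track_name` attribute. Used for DNase/histone ChIP signal, conservation
#' scores and replication-timing fractions alike.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `value`.
#' @param name track label.
#' @return a `signal_track` tibble.
#' @export
as_signal_track <- function(df, name = "track") {
  assert_cols(df, c("chrom", "start", "end", "value"), "signal track")
  df <- as_tibble(df)[, c("chrom", "start", "end", "value")]
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start)
  df$end <- as.numeric(df$end)
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) rlang::abort("non-finite track value")
  if (any(df$start < 0) || any(df$end <= df$start)) {
    rlang::abort("intervals must satisfy 0 <= start < end")
  }
  df <- dplyr::arrange(df, .data$chrom, .data$start)
  overlap <- vapply(split(df, df$chrom), function(t) {
    n <- nrow(t)
    n > 1 && any(t$start[-1] < t$end[-n])
  }, logical(1))
  if (any(overlap)) {
    rlang::abort("overlapping intervals within a chromosome")
  }
  structure(df,
    track_name = name,
    class = c("signal_track", class(tibble::tibble()))
  )
}

#' Read a bedGraph signal track
#'
#' Expects four whitespace-separated columns: chrom, start, end, value,
#' with 0-based half-open coordinates and no header.
#'
#' @param path bedGraph file.
#' @param name track label (defaults to the file stem).
#' @return a `signal_track` tibble.
#' @export
read_signal_track <- function(path, name = NULL) {
  name <- name %||% sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path,
    header = FALSE, sep = "", stringsAsFactors = FALSE,
    col.names = c("chrom", "start", "end", "value"),
    colClasses = c("character", "numeric", "numeric", "character")
  )
  val <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(val))) {
    rlang::abort(sprintf(
      "non-numeric value '%s' at line %d of %s",
      df$value[which(is.na(val))[1]], which(is.na(val))[1], path
    ))
  }
  df$value <- val
  as_signal_track(df, name = name)
}

#' Write a signal track as bedGraph
#'
#' @param track a `signal_track`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signal_track <- function(track, path) {
  out <- as.data.frame(track)
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Look up track signal at mutation positions
#'
#' Returns the value of the interval containing each 1-based position, or 0
#' where no interval covers it. With `halfwidth > 0` the mean of per-base
#' values over `pos +/- halfwidth` is returned instead (uncovered bases
#' count as 0).
#'
#' @param track a `signal_track`.
#' @param sites data frame with columns `chrom`, `pos` (1-based).
#' @param halfwidth averaging half-width in bp (default 0: single base).
#' @return numeric vector, one value per row of `sites`.
#' @export
signal_at <- function(track, sites, halfwidth = 0) {
  assert_cols(sites, c("chrom", "pos"), "sites")
  if (halfwidth > 0) {
    vals <- vapply(seq_len(nrow(sites)), function(i) {
      ps <- (sites$pos[i] - halfwidth):(sites$pos[i] + halfwidth)
      ps <- ps[ps >= 1]
      mean(signal_at(track, tibble(chrom = sites$chrom[i], pos = ps)))
    }, numeric(1))
    return(vals)
  }
  out <- numeric(nrow(sites))
  by_chrom <- split(seq_len(nrow(sites)), sites$chrom)
  trk <- split(as_tibble(track), track$chrom)
  for (ch in names(by_chrom)) {
    t <- trk[[ch]]
    if (is.null(t) || nrow(t) == 0) next
    idx <- by_chrom[[ch]]
    pos0 <- sites$pos[idx] - 1 # to 0-based
    j <- findInterval(pos0, t$start)
    hit <- j > 0 & pos0 < t$end[pmax(j, 1)]
    out[idx[hit]] <- t$value[j[hit]]
  }
  out
}
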