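# internal helpers shared across modules

# composite key identifying one mutation record
mutation_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, df$sample_id, sep = ":")
}

# site-level key (position only)
site_key <- function(df) paste(df$chrom, df$pos, sep = ":")

# derive a child seed from a run seed; stays below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% .Machine$integer.max)
}

assert_cols <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# 1-based inclusive window [pos - floor(w/2), pos + ceil(w/2) - 1]:
# even windows are left-heavy and always contain pos
window_bounds <- function(pos, w) {
  lo <- pos - floor(w / 2)
  hi <- pos + ceiling(w / 2) - 1
  list(lo = lo, hi = hi)
}

DNA_BASES <- c("A", "C", "G", "T")

revcomp <- function(s) {
  chartr("ACGTNacgtn", "TGCANtgcan", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}
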