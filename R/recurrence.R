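#' Poisson upper-tail recurrence p-value
#'
#' Probability of observing `x` or more mutations in a window of `w` bp when
#' mutations arrive as a homogeneous Poisson process with local rate `p` per
#' bp: `P(X >= x)` with `X ~ Poisson(w * p)`. Computed via the survival
#' function `1 - F(x - 1)`, which is numerically stable down to p-values of
#' order 1e-300.
#'
#' @param x observed recurrence count(s), `>= 0`.
#' @param w recurrence window size in bp, `>= 1`.
#' @param p background mutation rate per bp, `>= 0`.
#' @return numeric vector of upper-tail probabilities.
#' @export
#' @examples
#' recurrence_pvalue(1, 10, 0.001) # 1 - exp(-0.01)
#' recurrence_pvalue(0, 10, 0.001) # always 1
recurrence_pvalue <- function(x, w, p) {
  if (any(x < 0) || any(w < 1) || any(p < 0)) {
    rlang::abort("recurrence_pvalue requires x >= 0, w >= 1, p >= 0")
  }
  lambda <- w * p
  stats::ppois(x - 1, lambda, lower.tail = FALSE)
}

# count cohort records with pos in [lo, hi] per focal site (vectorized per
# chromosome through binary search on the sorted position index)
count_in_windows <- function(cohort, chrom, lo, hi) {
  idx <- cohort_index(cohort)
  out <- integer(length(chrom))
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ps <- idx[[ch]]
    if (is.null(ps)) next
    out[sel] <- findInterval(hi[sel], ps) -
      findInterval(lo[sel] - 1L, ps)
  }
  out
}

#' Raw recurrence count in a window
#'
#' Counts cohort mutation records (all samples, any allele) whose position
#' lies in the `w`-bp window centered on each focal position. The window on
#' position `pos` covers 1-based `[pos - floor(w/2), pos + ceil(w/2) - 1]`,
#' so even window sizes are left-heavy and always contain `pos`; the focal
#' record itself is counted when present in the cohort.
#'
#' @param cohort a `mutation_cohort` to count against (e.g. the pan-cancer
#'   set).
#' @param focal data frame of focal sites with columns `chrom`, `pos`.
#' @param w window size in bp (default 10).
#' @return `focal` as a tibble with an added integer column `x`.
#' @export
count_raw_recurrence <- function(cohort, focal, w = 10) {
  if (w < 1) rlang::abort("w must be >= 1")
  if (nrow(cohort) == 0) rlang::abort("cohort is empty")
  assert_cols(focal, c("chrom", "pos"), "focal sites")
  b <- window_bounds(focal$pos, w)
  out <- as_tibble(focal)
  out$x <- count_in_windows(cohort, focal$chrom, b$lo, b$hi)
  out
}

#' Local background mutation rate
#'
#' Counts cohort mutations in the `B`-bp window centered on each focal
#' position (same centering convention as [count_raw_recurrence()]), clips
#' the window to `[1, chromosome length]`, and estimates the per-bp rate as
#' `n_bg / effective_B` where `effective_B` is the clipped width. Chromosome
#' lengths come from the cohort's `genome` attribute; without one, only the
#' lower end is clipped.
#'
#' @param cohort a `mutation_cohort`.
#' @param focal data frame with columns `chrom`, `pos`.
#' @param B background window size in bp (default 1e4); must exceed the
#'   recurrence window it will be paired with.
#' @param w recurrence window the background must contain (used only for
#'   validation; default 10).
#' @param exclude_core drop the recurrence window's mutations and width from
#'   the background estimate (default `FALSE`: the background includes the
#'   core window, which is simpler and slightly conservative).
#' @return `focal` as a tibble with added columns `n_bg`, `bg_width`, `p`.
#' @export
background_rate <- function(cohort, focal, B = 1e4, w = 10,
                            exclude_core = FALSE) {
  if (B <= w) rlang::abort("background window B must exceed recurrence window w")
  if (nrow(cohort) == 0) rlang::abort("cohort is empty")
  assert_cols(focal, c("chrom", "pos"), "focal sites")
  b <- window_bounds(focal$pos, B)
  lo <- pmax(b$lo, 1)
  hi <- b$hi
  genome <- cohort_genome(cohort)
  if (!is.null(genome)) {
    len <- genome$length[match(focal$chrom, genome$chrom)]
    hi <- ifelse(is.na(len), hi, pmin(hi, len))
  }
  n_bg <- count_in_windows(cohort, focal$chrom, lo, hi)
  width <- hi - lo + 1
  if (exclude_core) {
    cb <- window_bounds(focal$pos, w)
    n_bg <- n_bg - count_in_windows(cohort, focal$chrom, pmax(cb$lo, 1), cb$hi)
    width <- width - (cb$hi - pmax(cb$lo, 1) + 1)
  }
  out <- as_tibble(focal)
  out$n_bg <- n_bg
  out$bg_width <- width
  out$p <- n_bg / width
  out
}

#' Score a set of focal mutations for recurrence significance
#'
#' For each focal mutation: the raw recurrence count `x` in the `w`-bp
#' window, the local background rate `p` from the `B`-bp window, the Poisson
#' mean `lambda = w * p`, and the upper-tail p-value `P(X >= x)`. The
#' background cohort is typically the larger pan-cancer set while `focal`
#' holds the cancer-type-specific candidates; passing the same cohort twice
#' scores a cohort against itself.
#'
#' @param cohort a `mutation_cohort` supplying both recurrence and
#'   background counts.
#' @param focal data frame of candidate mutations (columns `chrom`, `pos`,
#'   and any identifying columns, which are carried through). Defaults to
#'   the cohort itself.
#' @param w recurrence window in bp (default 10).
#' @param B background window in bp (default 1e4).
#' @param exclude_core see [background_rate()].
#' @return a tibble of recurrence records: the focal columns plus `w`, `x`,
#'   `B`, `n_bg`, `p`, `lambda`, `p_value`.
#' @export
score_cohort <- function(cohort, focal = cohort, w = 10, B = 1e4,
                         exclude_core = FALSE) {
  out <- count_raw_recurrence(cohort, focal, w = w)
  bg <- background_rate(cohort, focal, B = B, w = w, exclude_core = exclude_core)
  out$w <- as.integer(w)
  out$B <- B
  out$n_bg <- bg$n_bg
  out$bg_width <- bg$bg_width
  out$p <- bg$p
  out$lambda <- w * bg$p
  out$p_value <- recurrence_pvalue(out$x, w, bg$p)
  out
}

#' Build a true/false labeled training set from recurrence records
#'
#' The true set holds the records passing the recurrence threshold: raw
#' model, `x >= threshold`; significance model, `p_value < threshold`. The
#' false set is a seeded uniform sample, without replacement, of
#' `ratio * n_true` records from the non-recurrent pool — records with raw
#' count exactly 1 whose p-value is not below the significance cutoff.
#'
#' @param records output of [score_cohort()].
#' @param model `"significance"` (default) or `"raw"`.
#' @param threshold p-value cutoff (significance model, default 5e-6) or
#'   minimum raw count (raw model).
#' @param ratio false:true size ratio (default 3).
#' @param seed RNG seed for the false-set draw.
#' @param sig_cutoff p-value bound defining "non-recurrent" for the false
#'   pool (defaults to `threshold` under the significance model, 5e-6 under
#'   the raw model).
#' @return a tibble of the selected records with a logical `label` column
#'   (`TRUE` = recurrent); attributes `model`, `params`, `seed` record the
#'   provenance. If fewer than `ratio * n_true` non-recurrent records exist,
#'   all are used with a warning.
#' @export
build_labeled_set <- function(records, model = c("significance", "raw"),
                              threshold = NULL, ratio = 3, seed = 1,
                              sig_cutoff = NULL) {
  model <- match.arg(model)
  assert_cols(records, c("x", "p_value"), "recurrence records")
  if (is.null(threshold)) threshold <- if (model == "significance") 5e-6 else 4
  if (is.null(sig_cutoff)) {
    sig_cutoff <- if (model == "significance") threshold else 5e-6
  }
  is_true <- if (model == "significance") {
    records$p_value < threshold
  } else {
    records$x >= threshold
  }
  n_true <- sum(is_true)
  if (n_true == 0) {
    rlang::abort("no records pass the recurrence threshold: empty true set")
  }
  pool <- which(!is_true & records$x == 1 & records$p_value >= sig_cutoff)
  n_false <- ratio * n_true
  if (length(pool) < n_false) {
    rlang::warn(sprintf(
      "only %d non-recurrent records available for a false set of %d; using all",
      length(pool), n_false
    ))
    n_false <- length(pool)
  }
  false_idx <- withr::with_seed(seed, sample(pool, n_false, replace = FALSE))
  out <- dplyr::bind_rows(
    dplyr::mutate(records[is_true, , drop = FALSE], label = TRUE),
    dplyr::mutate(records[false_idx, , drop = FALSE], label = FALSE)
  )
  structure(as_tibble(out),
    model = model,
    params = list(threshold = threshold, ratio = ratio, sig_cutoff = sig_cutoff),
    seed = seed
  )
}
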