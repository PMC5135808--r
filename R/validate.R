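#' Select the top-k mutations by a scoring method
#'
#' Orders scored mutations by the chosen method — raw model: highest
#' recurrence count first; significance model: smallest p-value first;
#' forest votes: highest vote proportion first — and returns the first `k`.
#' Ties break by `(chrom, pos)` so selections are deterministic.
#'
#' @param scored tibble carrying `chrom`, `pos`, and the method's score
#'   column (`x`, `p_value`, or `vote`).
#' @param method one of `"raw"`, `"significance"`, `"forest_votes"`.
#' @param k number of mutations to select; must not exceed the rows
#'   available.
#' @return the selected rows as a tibble with a `method` column, ordered by
#'   the method's score.
#' @export
select_top <- function(scored, method = c("raw", "significance", "forest_votes"),
                       k) {
  method <- match.arg(method)
  if (k > nrow(scored)) {
    rlang::abort(sprintf("k = %d exceeds the %d scored mutations", k, nrow(scored)))
  }
  score_col <- switch(method,
    raw = "x", significance = "p_value", forest_votes = "vote"
  )
  assert_cols(scored, c("chrom", "pos", score_col), "scored mutations")
  s <- scored[[score_col]]
  if (method == "significance") s <- -s # smaller p first
  ord <- order(-s, scored$chrom, scored$pos)
  out <- as_tibble(scored)[ord[seq_len(k)], , drop = FALSE]
  out$method <- method
  out
}

#' Recheck recurrence of selected mutations against a new cohort
#'
#' A selected mutation's recurrence is "revealed" when at least one mutation
#' of the added cohort lies within the check window centered on it (same
#' left-heavy centering as the recurrence module). The new cohort must be
#' disjoint from the training cohort: any shared sample id errors as a
#' leakage guard.
#'
#' @param selection output of [select_top()].
#' @param new_cohort a `mutation_cohort` of added samples.
#' @param check_window window size in bp (conventionally 10 or 100).
#' @param training_samples character vector of training-cohort sample ids
#'   for the disjointness guard (optional but recommended).
#' @return a one-row tibble: `method`, `k`, `window`, `revealed` (count of
#'   selected mutations with recurrence revealed).
#' @export
recheck_recurrence <- function(selection, new_cohort, check_window = 10,
                               training_samples = NULL) {
  if (!is.null(training_samples)) {
    overlap <- intersect(unique(new_cohort$sample_id), training_samples)
    if (length(overlap) > 0) {
      rlang::abort(sprintf(
        "new cohort shares %d sample(s) with the training cohort",
        length(overlap)
      ))
    }
  }
  counts <- count_raw_recurrence(new_cohort, selection, w = check_window)$x
  tibble(
    method = selection$method[1] %||% NA_character_,
    k = nrow(selection),
    window = check_window,
    revealed = sum(counts >= 1)
  )
}

#' Compare selection methods by recurrence revealed in a new cohort
#'
#' Runs [select_top()] and [recheck_recurrence()] for each requested method
#' and window, producing the per-method revealed counts for a
#' sample-addition comparison.
#'
#' @param scored tibble with `chrom`, `pos` and the score columns used by
#'   the methods (`x`, `p_value`, `vote` as applicable).
#' @param new_cohort a `mutation_cohort` of added samples.
#' @param k number selected per method.
#' @param methods methods to compare (default all three).
#' @param windows check windows in bp (default `c(10, 100)`).
#' @param training_samples see [recheck_recurrence()].
#' @return a tibble with one row per method x window: `method`, `k`,
#'   `window`, `revealed`.
#' @export
validation_report <- function(scored, new_cohort, k,
                              methods = c("raw", "significance", "forest_votes"),
                              windows = c(10, 100),
                              training_samples = NULL) {
  purrr::map_dfr(methods, function(m) {
    sel <- select_top(scored, m, k)
    purrr::map_dfr(windows, function(w) {
      recheck_recurrence(sel, new_cohort, w, training_samples = training_samples)
    })
  })
}
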