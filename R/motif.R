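# Motif scanning with exact p-values.
#
# Scores are log2 likelihood ratios against the background, quantized to a
# fixed bin width so the null distribution of a window score under the
# background model can be computed exactly by dynamic programming
# (per-position convolution of the four quantized base scores). The p-value
# of a match is the exact probability that a random background window
# scores at least as high — the same null the FIMO program uses.

# floor for log2(p/bg) when a PWM entry is zero
LOG_RATIO_FLOOR <- -20

# integer-quantized per-position score matrix (L x 4)
pwm_int_scores <- function(pwm, bin = 1e-3) {
  s <- log2(sweep(pwm$matrix, 2, pwm$background, "/"))
  s[!is.finite(s)] <- LOG_RATIO_FLOOR
  s <- pmax(s, LOG_RATIO_FLOOR)
  matrix(as.integer(round(s / bin)), nrow = nrow(s), dimnames = dimnames(s))
}

# exact null distribution of the window score under the background:
# list(min = minimum integer score, prob = P(score = min + 0:(K-1)),
# surv = P(score >= min + 0:(K-1)))
pwm_null_dist <- function(pwm, bin = 1e-3) {
  s <- pwm_int_scores(pwm, bin)
  bg <- pwm$background
  lo <- sum(apply(s, 1, min))
  hi <- sum(apply(s, 1, max))
  probs <- numeric(hi - lo + 1)
  # running distribution over partial sums, anchored at its own minimum
  cur <- 1
  cur_min <- 0L
  for (i in seq_len(nrow(s))) {
    row <- s[i, ]
    rmin <- min(row)
    width <- length(cur) + (max(row) - rmin)
    nxt <- numeric(width)
    for (b in 1:4) {
      off <- row[b] - rmin
      idx <- seq_along(cur) + off
      nxt[idx] <- nxt[idx] + cur * bg[b]
    }
    cur <- nxt
    cur_min <- cur_min + rmin
  }
  probs[(cur_min - lo + 1):(cur_min - lo + length(cur))] <- cur
  surv <- rev(cumsum(rev(probs)))
  list(min = lo, prob = probs, surv = surv, bin = bin)
}

# P(random window score >= k) for integer score k
null_pvalue <- function(null, k) {
  i <- k - null$min + 1
  if (i <= 1) return(1)
  if (i > length(null$surv)) return(0)
  null$surv[i]
}

# integer score of each L-window of seq (character vector of bases);
# N scores 0 at its position
score_windows <- function(int_scores, bases) {
  L <- nrow(int_scores)
  n <- length(bases)
  if (n < L) rlang::abort("sequence shorter than motif")
  base_idx <- match(bases, DNA_BASES) # NA for N
  per_pos <- matrix(0L, nrow = n, ncol = L)
  for (j in 1:L) {
    v <- int_scores[j, base_idx]
    v[is.na(v)] <- 0L
    per_pos[, j] <- v
  }
  n_win <- n - L + 1
  out <- integer(n_win)
  for (j in 1:L) out <- out + per_pos[j:(j + n_win - 1), j]
  out
}

#' Best motif match in a sequence
#'
#' Scans every offset of `sequence` on both strands with a position weight
#' matrix, scoring each window by its quantized log2 likelihood ratio
#' against the background, and returns the best match with its exact
#' p-value: the probability that a random background window scores at least
#' as high, computed by dynamic programming over the discretized
#' per-position score distribution. `N` bases score as background
#' (log-ratio 0). Ties prefer the + strand, then the smallest start.
#'
#' @param pwm a `pwm` object.
#' @param sequence a single DNA string (bases `A`,`C`,`G`,`T`,`N`).
#' @param bin score quantization bin width in log2 units (default 1e-3).
#' @param null optional precomputed null distribution (from an internal
#'   cache); recomputed when `NULL`.
#' @return a one-row tibble: `tf_id`, `start` (1-based on `sequence`),
#'   `strand`, `score` (log2 likelihood ratio), `p_value`.
#' @export
#' @examples
#' pwm <- new_pwm("toy", matrix(rep(c(1, 0, 0, 0), 4), ncol = 4, byrow = TRUE))
#' scan_best_match(pwm, "GGAAAAGG") # consensus AAAA, p = 0.25^4
scan_best_match <- function(pwm, sequence, bin = 1e-3, null = NULL) {
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- pwm_length(pwm)
  if (length(bases) < L) rlang::abort("sequence shorter than motif")
  s <- pwm_int_scores(pwm, bin)
  fwd <- score_windows(s, bases)
  # - strand: score the reverse complement of each window, i.e. scan with
  # the reverse-complemented matrix
  s_rc <- s[rev(seq_len(L)), c("T", "G", "C", "A"), drop = FALSE]
  colnames(s_rc) <- DNA_BASES
  rev_ <- score_windows(s_rc, bases)
  best_f <- which.max(fwd)
  best_r <- which.max(rev_)
  if (fwd[best_f] >= rev_[best_r]) {
    k <- fwd[best_f]
    start <- best_f
    strand <- "+"
  } else {
    k <- rev_[best_r]
    start <- best_r
    strand <- "-"
  }
  if (is.null(null)) null <- pwm_null_dist(pwm, bin)
  tibble(
    tf_id = pwm$tf_id, start = as.integer(start), strand = strand,
    score = k * bin, p_value = null_pvalue(null, k)
  )
}

#' Classify a motif change from wild-type and mutant match p-values
#'
#' A motif gain means only the mutant sequence passes the match threshold;
#' a loss means only the wild type does; both passing or both failing is no
#' change.
#'
#' @param p_wt best match p-value on the wild-type sequence, in (0, 1\].
#' @param p_mut best match p-value on the mutant sequence.
#' @param alpha match threshold (default 1e-4); must lie in (0, 1).
#' @return character vector over `"gain"`, `"loss"`, `"none"`.
#' @export
classify_change <- function(p_wt, p_mut, alpha = 1e-4) {
  if (alpha <= 0 || alpha >= 1) rlang::abort("alpha must lie in (0, 1)")
  if (any(p_wt <= 0 | p_wt > 1) || any(p_mut <= 0 | p_mut > 1)) {
    rlang::abort("p-values must lie in (0, 1]")
  }
  dplyr::case_when(
    p_mut < alpha & p_wt >= alpha ~ "gain",
    p_wt < alpha & p_mut >= alpha ~ "loss",
    TRUE ~ "none"
  )
}

# decision layer shared by the built-in scanner and the FIMO-table path:
# per_tf has one row per TF with p_wt, p_mut; region_best is the best
# region-wide wild-type match (tf_id, p_value)
decide_tfbs <- function(per_tf, region_best, alpha) {
  chg <- classify_change(per_tf$p_wt, per_tf$p_mut, alpha)
  changed <- which(chg != "none")
  if (length(changed) > 0) {
    lw <- -log10(per_tf$p_wt[changed])
    lm <- -log10(per_tf$p_mut[changed])
    pick <- changed[which.max(abs(lw - lm))]
    lw1 <- -log10(per_tf$p_wt[pick])
    lm1 <- -log10(per_tf$p_mut[pick])
    tibble(
      diff_Log_Pval_FIMO = lw1 - lm1,
      avg_Log_Pval_FIMO = (lw1 + lm1) / 2,
      Gain_or_Loss = if (chg[pick] == "gain") 1 else -1,
      bound_tf = per_tf$tf_id[pick]
    )
  } else {
    tibble(
      diff_Log_Pval_FIMO = 0,
      avg_Log_Pval_FIMO = -log10(region_best$p_value),
      Gain_or_Loss = 0,
      bound_tf = region_best$tf_id
    )
  }
}

#' Binding-site change scores for candidate mutations
#'
#' For each mutation, every PWM is rescanned over the windows overlapping
#' the mutated base in the wild-type and the mutant sequence (the scan
#' region is the mutation's DHS interval from [assign_targets()]). If any
#' PWM gains or loses a match at threshold `alpha`, the changed PWM with the
#' largest absolute log10 p-value difference defines the scores:
#' `diff_Log_Pval_FIMO = (-log10 p_wt) - (-log10 p_mut)` (positive for a
#' loss), `avg_Log_Pval_FIMO` their mean, `Gain_or_Loss` +1/-1, and
#' `bound_tf` that TF. With no motif change, `diff` and `Gain_or_Loss` are
#' 0, `avg` is `-log10` of the best wild-type match p-value over the whole
#' DHS region and all PWMs, and `bound_tf` is the TF attaining it.
#'
#' @param assigned output of [assign_targets()] (needs `chrom`, `pos`,
#'   `ref`, `alt`, `dhs_start`, `dhs_end`).
#' @param pwms named list of `pwm` objects.
#' @param genome named character vector of chromosome sequences.
#' @param alpha motif match p-value threshold (default 1e-4).
#' @param bin score quantization bin (default 1e-3).
#' @return `assigned` with added columns `diff_Log_Pval_FIMO`,
#'   `avg_Log_Pval_FIMO`, `Gain_or_Loss`, `bound_tf`.
#' @export
tfbs_scores <- function(assigned, pwms, genome, alpha = 1e-4, bin = 1e-3) {
  if (length(pwms) == 0) rlang::abort("no PWMs loaded")
  assert_cols(
    assigned, c("chrom", "pos", "ref", "alt", "dhs_start", "dhs_end"),
    "assigned mutations"
  )
  nulls <- lapply(pwms, pwm_null_dist, bin = bin)
  res <- vector("list", nrow(assigned))
  for (i in seq_len(nrow(assigned))) {
    chrom <- assigned$chrom[i]
    if (!chrom %in% names(genome)) {
      rlang::abort(sprintf("no genome sequence for chromosome %s", chrom))
    }
    chrom_seq <- genome[[chrom]]
    lo <- max(assigned$dhs_start[i] + 1, 1) # to 1-based inclusive
    hi <- min(assigned$dhs_end[i], nchar(chrom_seq))
    region_wt <- substr(chrom_seq, lo, hi)
    off <- assigned$pos[i] - lo + 1
    if (off < 1 || off > nchar(region_wt)) {
      rlang::abort(sprintf("mutation %s:%d outside its DHS region", chrom, assigned$pos[i]))
    }
    region_mut <- region_wt
    substr(region_mut, off, off) <- assigned$alt[i]

    per_tf <- purrr::map_dfr(names(pwms), function(tf) {
      L <- pwm_length(pwms[[tf]])
      w_lo <- max(1, off - L + 1)
      w_hi <- min(nchar(region_wt), off + L - 1)
      if (w_hi - w_lo + 1 < L) {
        return(tibble(tf_id = tf, p_wt = 1, p_mut = 1))
      }
      wt <- scan_best_match(pwms[[tf]], substr(region_wt, w_lo, w_hi),
        bin = bin, null = nulls[[tf]]
      )
      mu <- scan_best_match(pwms[[tf]], substr(region_mut, w_lo, w_hi),
        bin = bin, null = nulls[[tf]]
      )
      tibble(tf_id = tf, p_wt = max(wt$p_value, 1e-300), p_mut = max(mu$p_value, 1e-300))
    })

    region_best <- purrr::map_dfr(names(pwms), function(tf) {
      if (nchar(region_wt) < pwm_length(pwms[[tf]])) {
        return(tibble(tf_id = tf, p_value = 1))
      }
      m <- scan_best_match(pwms[[tf]], region_wt, bin = bin, null = nulls[[tf]])
      tibble(tf_id = tf, p_value = max(m$p_value, 1e-300))
    })
    region_best <- region_best[which.min(region_best$p_value), , drop = FALSE]

    res[[i]] <- decide_tfbs(per_tf, region_best, alpha)
  }
  dplyr::bind_cols(as_tibble(assigned), dplyr::bind_rows(res))
}

#' Binding-site change scores from precomputed FIMO tables
#'
#' Replaces the built-in scanner with externally computed FIMO matches at
#' the scoring layer: for each mutation the best wild-type and mutant match
#' p-value per TF, plus the best wild-type region-wide match, feed the same
#' gain/loss decision as [tfbs_scores()].
#'
#' @param assigned output of [assign_targets()].
#' @param wt_matches,mut_matches FIMO-style tibbles (see [read_fimo_tsv()])
#'   whose `sequence_name` is the mutation key
#'   (`chrom:pos:ref:alt:sample_id`), scanned over the mutation-overlapping
#'   windows of the wild-type and mutant sequence respectively.
#' @param region_matches FIMO-style tibble of wild-type matches over each
#'   mutation's whole DHS region.
#' @param alpha match threshold (default 1e-4).
#' @return as [tfbs_scores()].
#' @export
tfbs_scores_from_fimo <- function(assigned, wt_matches, mut_matches,
                                  region_matches, alpha = 1e-4) {
  keys <- mutation_key(assigned)
  res <- vector("list", nrow(assigned))
  for (i in seq_along(keys)) {
    wt <- wt_matches[wt_matches$sequence_name == keys[i], ]
    mu <- mut_matches[mut_matches$sequence_name == keys[i], ]
    tfs <- union(wt$tf_id, mu$tf_id)
    per_tf <- purrr::map_dfr(tfs, function(tf) {
      tibble(
        tf_id = tf,
        p_wt = min(c(wt$p_value[wt$tf_id == tf], 1)),
        p_mut = min(c(mu$p_value[mu$tf_id == tf], 1))
      )
    })
    reg <- region_matches[region_matches$sequence_name == keys[i], ]
    if (nrow(reg) == 0) {
      region_best <- tibble(tf_id = NA_character_, p_value = 1)
    } else {
      region_best <- tibble(
        tf_id = reg$tf_id[which.min(reg$p_value)],
        p_value = min(reg$p_value)
      )
    }
    if (nrow(per_tf) == 0) per_tf <- tibble(tf_id = character(), p_wt = numeric(), p_mut = numeric())
    res[[i]] <- decide_tfbs(per_tf, region_best, alpha)
  }
  dplyr::bind_cols(as_tibble(assigned), dplyr::bind_rows(res))
}
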