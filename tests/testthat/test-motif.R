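degenerate_pwm <- function(consensus, tf_id = "deg") {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix(0, length(bases), 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(bases)) m[i, bases[i]] <- 1
  new_pwm(tf_id, m)
}

random_pwm <- function(L, tf_id, seed) {
  set.seed(seed)
  m <- matrix(rgamma(L * 4, 1), L, 4)
  new_pwm(tf_id, m / rowSums(m))
}

test_that("consensus matches of a degenerate PWM have p-value 0.25^L", {
  for (L in c(4, 6, 8)) {
    set.seed(L)
    consensus <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    pwm <- degenerate_pwm(consensus)
    hit <- scan_best_match(pwm, paste0("GG", consensus, "AA"))
    expect_equal(hit$p_value, 0.25^L, tolerance = 1e-12)
    expect_equal(hit$start, 3L)
    expect_equal(hit$strand, "+")
  }
})

test_that("a uniform PWM scores every window 0 with p-value 1", {
  pwm <- new_pwm("flat", matrix(0.25, 5, 4))
  hit <- scan_best_match(pwm, "ACGTACGTAC")
  expect_equal(hit$score, 0)
  expect_equal(hit$p_value, 1)
})

test_that("scanner p-values equal exhaustive enumeration for motifs up to length 6", {
  battery <- list(
    random_pwm(4, "r4", 101),
    random_pwm(5, "r5", 102),
    random_pwm(6, "r6", 103),
    degenerate_pwm("ACGTAC", "d6"),
    new_pwm("mix6", {
      m <- matrix(0.1 / 3, 6, 4)
      diag_idx <- cbind(1:6, c(1, 2, 3, 4, 1, 2))
      m[diag_idx] <- 0.9
      m / rowSums(m)
    })
  )
  set.seed(77)
  for (pwm in battery) {
    for (rep in 1:3) {
      seq <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
      hit <- scan_best_match(pwm, seq)
      expect_equal(hit$p_value, oracle_enum_pvalue(pwm, hit$score),
        tolerance = 1e-12,
        label = sprintf("pwm %s rep %d", pwm$tf_id, rep)
      )
    }
  }
})

test_that("scanning is strand symmetric", {
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  set.seed(55)
  for (rep in 1:5) {
    pwm <- random_pwm(6, "s", 200 + rep)
    seq <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    a <- scan_best_match(pwm, seq)
    b <- scan_best_match(pwm, rc(seq))
    expect_equal(a$score, b$score)
    expect_equal(a$p_value, b$p_value)
  }
})

test_that("motif change classification follows the gain/loss rule and is antisymmetric", {
  expect_equal(classify_change(1e-6, 0.5, 1e-4), "loss")
  expect_equal(classify_change(0.5, 1e-6, 1e-4), "gain")
  expect_equal(classify_change(1e-6, 1e-6, 1e-4), "none")
  expect_equal(classify_change(0.5, 0.5, 1e-4), "none")
  # boundary: p == alpha does not pass
  expect_equal(classify_change(1e-4, 1e-6, 1e-4), "gain")
  set.seed(3)
  pw <- 10^runif(50, -8, 0)
  pm <- 10^runif(50, -8, 0)
  ab <- classify_change(pw, pm)
  ba <- classify_change(pm, pw)
  swap <- c(gain = "loss", loss = "gain", none = "none")
  expect_equal(ba, unname(swap[ab]))
  expect_error(classify_change(0.5, 0.5, 1.5), "alpha")
  expect_error(classify_change(0, 0.5), "p-values")
})

test_that("binding-site scores carry the stated arithmetic and branch rules", {
  # changed site with p_wt = 1e-6, p_mut = 1e-2: diff = 4, avg = 4
  out <- regrecur:::decide_tfbs(
    tibble::tibble(tf_id = "TF1", p_wt = 1e-6, p_mut = 1e-2),
    tibble::tibble(tf_id = "TF9", p_value = 1e-3),
    alpha = 1e-4
  )
  expect_equal(out$diff_Log_Pval_FIMO, 4)
  expect_equal(out$avg_Log_Pval_FIMO, 4)
  expect_equal(out$Gain_or_Loss, -1)
  expect_equal(out$bound_tf, "TF1")

  # no change: region-wide best supplies avg and the bound TF
  out2 <- regrecur:::decide_tfbs(
    tibble::tibble(tf_id = "TF1", p_wt = 0.3, p_mut = 0.2),
    tibble::tibble(tf_id = "TF9", p_value = 1e-3),
    alpha = 1e-4
  )
  expect_equal(out2$diff_Log_Pval_FIMO, 0)
  expect_equal(out2$Gain_or_Loss, 0)
  expect_equal(out2$avg_Log_Pval_FIMO, 3)
  expect_equal(out2$bound_tf, "TF9")

  # multiple changed PWMs: the largest |diff| wins
  out3 <- regrecur:::decide_tfbs(
    tibble::tibble(
      tf_id = c("TFa", "TFb"),
      p_wt = c(1e-5, 1e-8), p_mut = c(1e-3, 1e-2)
    ),
    tibble::tibble(tf_id = "TF9", p_value = 1e-3),
    alpha = 1e-4
  )
  expect_equal(out3$bound_tf, "TFb")
  expect_equal(out3$diff_Log_Pval_FIMO, 6)
})

test_that("a consensus-destroying substitution is detected as a motif loss", {
  consensus <- "ACGTACGT"
  pwm <- list(STRONG = regrecur:::consensus_pwm("STRONG", consensus))
  genome <- c(chrX = paste0(strrep("T", 20), consensus, strrep("T", 20)))
  asn <- tibble::tibble(
    chrom = "chrX", pos = 24L, ref = "T", alt = "G", sample_id = "s1",
    gene_id = "G1", dhs_start = 10, dhs_end = 38
  )
  out <- tfbs_scores(asn, pwm, genome, alpha = 1e-4)
  expect_equal(out$Gain_or_Loss, -1)
  expect_gt(out$diff_Log_Pval_FIMO, 0)
  expect_equal(out$bound_tf, "STRONG")

  # the reverse substitution on the damaged genome is a gain
  genome_mut <- genome
  substr(genome_mut[["chrX"]], 24, 24) <- "G"
  asn2 <- asn
  asn2$ref <- "G"
  asn2$alt <- "T"
  out2 <- tfbs_scores(asn2, pwm, genome_mut, alpha = 1e-4)
  expect_equal(out2$Gain_or_Loss, 1)
  expect_lt(out2$diff_Log_Pval_FIMO, 0)
})

test_that("no-change and changed branches hold jointly on the tiny fixture", {
  res <- tiny_bundle$resources
  asn <- suppressMessages(assign_targets(
    tiny_labeled, res$ep_pairs, res$dhs_map, res$dhs_peaks
  ))
  out <- tfbs_scores(asn, res$pwms, res$genome_seq)
  expect_true(all(out$Gain_or_Loss %in% c(-1, 0, 1)))
  expect_true(all(out$diff_Log_Pval_FIMO[out$Gain_or_Loss == 0] == 0))
  # every planted hotspot mutation in the set shows a motif loss
  key <- paste(out$chrom, out$pos, out$ref, out$alt, out$sample_id, sep = ":")
  hs <- tiny_bundle$truth$hotspot_id[match(key, tiny_bundle$truth$key)]
  expect_true(all(out$Gain_or_Loss[!is.na(hs)] == -1))
})

test_that("the FIMO-table path reproduces the built-in scanner's scores", {
  res <- tiny_bundle$resources
  asn <- suppressMessages(assign_targets(
    tiny_labeled[seq_len(10), ], res$ep_pairs, res$dhs_map, res$dhs_peaks
  ))
  builtin <- tfbs_scores(asn, res$pwms, res$genome_seq)

  # reconstruct FIMO-style tables from the scanner itself, then feed them
  # through the ingestion path: the decision layer must agree bit for bit
  keys <- paste(asn$chrom, asn$pos, asn$ref, asn$alt, asn$sample_id, sep = ":")
  rows <- list(wt = NULL, mut = NULL, reg = NULL)
  for (i in seq_len(nrow(asn))) {
    chrom_seq <- res$genome_seq[[asn$chrom[i]]]
    lo <- asn$dhs_start[i] + 1
    hi <- min(asn$dhs_end[i], nchar(chrom_seq))
    region_wt <- substr(chrom_seq, lo, hi)
    off <- asn$pos[i] - lo + 1
    region_mut <- region_wt
    substr(region_mut, off, off) <- asn$alt[i]
    for (tf in names(res$pwms)) {
      L <- nrow(res$pwms[[tf]]$matrix)
      w_lo <- max(1, off - L + 1)
      w_hi <- min(nchar(region_wt), off + L - 1)
      wt <- scan_best_match(res$pwms[[tf]], substr(region_wt, w_lo, w_hi))
      mu <- scan_best_match(res$pwms[[tf]], substr(region_mut, w_lo, w_hi))
      rg <- scan_best_match(res$pwms[[tf]], region_wt)
      fimo_row <- function(m) {
        tibble::tibble(
          tf_id = tf, sequence_name = keys[i], start = m$start,
          stop = m$start + L - 1, strand = m$strand, score = m$score,
          p_value = max(m$p_value, 1e-300)
        )
      }
      rows$wt <- rbind(rows$wt, fimo_row(wt))
      rows$mut <- rbind(rows$mut, fimo_row(mu))
      rows$reg <- rbind(rows$reg, fimo_row(rg))
    }
  }
  external <- tfbs_scores_from_fimo(asn, rows$wt, rows$mut, rows$reg)
  expect_equal(
    external[, c("diff_Log_Pval_FIMO", "avg_Log_Pval_FIMO", "Gain_or_Loss", "bound_tf")],
    builtin[, c("diff_Log_Pval_FIMO", "avg_Log_Pval_FIMO", "Gain_or_Loss", "bound_tf")]
  )
})
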