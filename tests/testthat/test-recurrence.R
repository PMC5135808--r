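test_that("window counts match the stated centering convention", {
  co <- toy_cohort(c(996, 1000, 1004, 1005))
  # w=10 on pos 1000 covers [995, 1004]: 996, 1000, 1004 fall inside
  expect_equal(
    count_raw_recurrence(co, tibble::tibble(chrom = "chr1", pos = 1000), w = 10)$x,
    3L
  )
  # focal not in cohort, nothing nearby
  expect_equal(
    count_raw_recurrence(co, tibble::tibble(chrom = "chr1", pos = 5000), w = 10)$x,
    0L
  )
  # degenerate w=1 counts only the exact position
  expect_equal(
    count_raw_recurrence(co, tibble::tibble(chrom = "chr1", pos = c(1000, 1001)), w = 1)$x,
    c(1L, 0L)
  )
  expect_error(count_raw_recurrence(co, tibble::tibble(chrom = "chr1", pos = 1), w = 0))
})

test_that("window counting agrees with a naive full scan on random queries", {
  sim <- simulate_cohort(
    sim_config(tibble::tibble(chrom = c("cA", "cB"), length = c(5e4, 5e4)),
      n_samples = 6, background_rate = 2e-3,
      hotspots = tibble::tibble(
        chrom = "cA", pos = 2500L,
        multiplicity = 5L, max_spread = 2L
      )
    ),
    seed = 9
  )
  co <- sim$cohort
  raw <- as.data.frame(co)
  set.seed(21)
  queries <- tibble::tibble(
    chrom = sample(c("cA", "cB"), 1000, replace = TRUE),
    pos = sample.int(5e4, 1000, replace = TRUE),
    w = sample(c(1, 5, 10, 20), 1000, replace = TRUE)
  )
  for (w in unique(queries$w)) {
    q <- queries[queries$w == w, ]
    got <- count_raw_recurrence(co, q, w = w)$x
    want <- vapply(seq_len(nrow(q)), function(i) {
      oracle_window_count(raw, q$chrom[i], q$pos[i], w)
    }, numeric(1))
    expect_equal(got, as.integer(want))
  }
})

test_that("background rate estimates clip at chromosome ends and renormalize", {
  genome <- tibble::tibble(chrom = "chr1", length = 2e4)
  co <- toy_cohort(seq(5500, 14500, length.out = 10), genome = genome)

  # 10 mutations uniformly inside the 10 kbp window [5000, 14999]
  mid <- background_rate(co, tibble::tibble(chrom = "chr1", pos = 10000), B = 1e4, w = 10)
  expect_equal(mid$p, 10 / 1e4)

  # clipping at the left end: pos 100, B=1000 -> window [1, 599], width 599
  left <- background_rate(co, tibble::tibble(chrom = "chr1", pos = 100), B = 1000, w = 10)
  expect_equal(left$bg_width, 599)
  # clipping at the right end: pos 19900 on a 20 kbp chromosome
  right <- background_rate(co, tibble::tibble(chrom = "chr1", pos = 19900), B = 1000, w = 10)
  expect_equal(right$bg_width, 20000 - (19900 - 500) + 1)

  # empty neighborhood -> rate 0
  far <- toy_cohort(100, genome = genome)
  none <- background_rate(far, tibble::tibble(chrom = "chr1", pos = 9000), B = 1000, w = 10)
  expect_equal(none$p, 0)

  expect_error(background_rate(co, tibble::tibble(chrom = "chr1", pos = 100), B = 10, w = 10), "exceed")
})

test_that("background counts match naive scans on random queries", {
  sim <- simulate_cohort(
    sim_config(tibble::tibble(chrom = "cA", length = 5e4),
      n_samples = 6, background_rate = 2e-3,
      hotspots = tibble::tibble(
        chrom = character(), pos = integer(),
        multiplicity = integer(), max_spread = integer()
      )
    ),
    seed = 10
  )
  raw <- as.data.frame(sim$cohort)
  set.seed(22)
  q <- tibble::tibble(chrom = "cA", pos = sample.int(5e4, 500, replace = TRUE))
  got <- background_rate(sim$cohort, q, B = 1000, w = 10)
  want <- vapply(seq_len(nrow(q)), function(i) {
    oracle_window_count(raw, q$chrom[i], q$pos[i], 1000)
  }, numeric(1))
  expect_equal(got$n_bg, as.integer(want))
})

test_that("Poisson tail p-values are exact, stable and monotone", {
  expect_equal(recurrence_pvalue(0, 10, 0.5), 1)
  expect_equal(recurrence_pvalue(1, 10, 0.001), 1 - exp(-0.01), tolerance = 1e-12)
  # lambda = 1e-3, x = 4: 1 - e^-l (1 + l + l^2/2 + l^3/6)
  expect_equal(recurrence_pvalue(4, 10, 1e-4), 4.162e-14,
    tolerance = 1e-3
  )
  expect_equal(
    recurrence_pvalue(4, 10, 1e-4),
    oracle_pois_tail(4, 1e-3),
    tolerance = 1e-9
  )
  # extreme tails stay representable
  expect_gt(recurrence_pvalue(50, 10, 1e-5), 0)
  expect_lt(recurrence_pvalue(50, 10, 1e-5), 1e-250)

  # monotone non-increasing in x, non-decreasing in lambda
  lam <- c(1e-4, 1e-2, 0.5, 2)
  for (l in lam) {
    pv <- recurrence_pvalue(0:20, 1, l)
    expect_true(all(diff(pv) <= 0))
  }
  for (x in c(1, 3, 7)) {
    pv <- vapply(lam, function(l) recurrence_pvalue(x, 1, l), numeric(1))
    expect_true(all(diff(pv) >= 0))
  }
  expect_error(recurrence_pvalue(-1, 10, 0.1))
  expect_error(recurrence_pvalue(1, 10, -0.1))
})

test_that("cohort scoring flags planted hotspots and stays calibrated under the null", {
  # single-mutation cohort scores itself
  one <- toy_cohort(500, genome = tibble::tibble(chrom = "chr1", length = 1e4))
  r1 <- score_cohort(one, w = 10, B = 1e3)
  expect_equal(r1$x, 1L)
  expect_equal(r1$p_value, recurrence_pvalue(1, 10, r1$p))

  # planted hotspot: 5 mutations within 4 bp over a ~1e-3/bp background
  genome <- tibble::tibble(chrom = "chr1", length = 2e4)
  set.seed(31)
  bg_pos <- sort(sample.int(2e4, 20))
  co <- as_mutation_cohort(tibble::tibble(
    chrom = "chr1",
    pos = c(bg_pos, 10000, 10001, 10002, 10003, 10004),
    ref = "A", alt = "G",
    sample_id = paste0("s", 1:25)
  ), genome = genome)
  hot <- score_cohort(co, tibble::tibble(chrom = "chr1", pos = 10002), w = 10, B = 1e4)
  expect_gte(hot$x, 5)
  expect_lt(hot$p_value, 5e-6)

  # null calibration on a hotspot-free cohort (~10,000 records, pooled
  # density 5e-4/bp so the 10-bp Poisson mean is ~5e-3)
  null_sim <- simulate_cohort(
    sim_config(tibble::tibble(chrom = "cN", length = 2e7),
      n_samples = 10, background_rate = 5e-5,
      hotspots = tibble::tibble(
        chrom = character(), pos = integer(),
        multiplicity = integer(), max_spread = integer()
      )
    ),
    seed = 13
  )
  # cohort records against a well-estimated background (wide window):
  # the stringent cutoff admits at most ~1e-4 of the null
  rec <- score_cohort(null_sim$cohort, w = 10, B = 1e6)
  expect_lte(mean(rec$p_value < 5e-6), 1e-4)
  # random genomic sites: the empirical rate below alpha = 1e-2 stays at
  # alpha's order of magnitude (conservative because counts are discrete)
  set.seed(14)
  probe <- tibble::tibble(chrom = "cN", pos = sample.int(2e7, 10000))
  pr <- score_cohort(null_sim$cohort, probe, w = 10, B = 1e4)
  rate <- mean(pr$p_value < 1e-2)
  expect_lt(rate, 1.5e-2)
  expect_gt(rate, 5e-4)
})

test_that("labeled sets honor the 3x ratio, determinism and degenerate cases", {
  rec <- tiny_records
  ls <- suppressWarnings(build_labeled_set(rec, "significance", 5e-6, seed = 7))
  expect_equal(sum(!ls$label), min(
    3 * sum(ls$label),
    sum(rec$x == 1 & rec$p_value >= 5e-6)
  ))
  expect_equal(
    as.data.frame(ls),
    as.data.frame(suppressWarnings(build_labeled_set(rec, "significance", 5e-6, seed = 7)))
  )
  ls2 <- suppressWarnings(build_labeled_set(rec, "significance", 5e-6, seed = 8))
  expect_false(identical(
    as.data.frame(ls[!ls$label, ]),
    as.data.frame(ls2[!ls2$label, ])
  ))
  # true and false sets never intersect
  key <- paste(ls$chrom, ls$pos, ls$ref, ls$alt, ls$sample_id, sep = ":")
  expect_equal(anyDuplicated(key), 0)
  # raw model works off the count column
  lr <- suppressWarnings(build_labeled_set(rec, "raw", 4, seed = 7))
  expect_true(all(lr$x[lr$label] >= 4))
  expect_true(all(lr$x[!lr$label] == 1))
  # impossible threshold errors
  expect_error(build_labeled_set(rec, "significance", 1e-300, seed = 1), "empty true set")
})
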