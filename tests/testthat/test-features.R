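test_that("DEG scores follow x/(x+1) of the t-test p-value", {
  # identical groups: p = 1 -> score 0
  expect_equal(deg_score(c(5, 5, 5), c(5, 5, 5)), 0)
  # analytically forced point: p = 0.1 -> x = 1 -> 0.5
  x <- -log10(0.1)
  expect_equal(x / (x + 1), 0.5)
  # hand-computed pooled t-test oracle
  tum <- c(10, 10.1, 9.9)
  nor <- c(0, 0.1, -0.1)
  n1 <- 3; n2 <- 3
  sp2 <- ((n1 - 1) * var(tum) + (n2 - 1) * var(nor)) / (n1 + n2 - 2)
  tstat <- (mean(tum) - mean(nor)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_oracle <- 2 * pt(-abs(tstat), df = n1 + n2 - 2)
  xo <- -log10(max(p_oracle, 1e-300))
  expect_equal(deg_score(tum, nor), xo / (xo + 1), tolerance = 1e-12)
  expect_error(deg_score(c(1), c(1, 2)), ">= 2")
})

test_that("DEG score decreases in the p-value and stays within [0, 1)", {
  set.seed(12)
  ps <- numeric(30)
  scores <- numeric(30)
  for (i in 1:30) {
    shift <- runif(1, 0, 5)
    a <- rnorm(5)
    b <- rnorm(5) + shift
    ps[i] <- t.test(a, b, var.equal = TRUE)$p.value
    scores[i] <- deg_score(a, b)
  }
  ord <- order(ps)
  expect_true(all(diff(scores[ord]) <= 1e-12))
  expect_true(all(scores >= 0 & scores < 1))
})

test_that("regulatory-network DEG sums follow directed reachability", {
  chain <- as_edge_list(tibble::tibble(
    from = c("g", "a", "b", "c"), to = c("a", "b", "c", "d")
  ), directed = TRUE)
  deg <- tibble::tibble(gene_id = c("a", "b", "c", "d", "g"), deg_score = 0.1)
  expect_equal(regnet_deg_score(chain, "g", deg, hops = 3), 0.3)
  expect_equal(regnet_deg_score(chain, "g", deg, hops = 4), 0.4)

  cyc <- as_edge_list(tibble::tibble(from = c("g", "a"), to = c("a", "g")),
    directed = TRUE
  )
  deg2 <- tibble::tibble(gene_id = "a", deg_score = 0.4)
  expect_equal(regnet_deg_score(cyc, "g", deg2, hops = 3), 0.4)

  # absent source
  expect_equal(regnet_deg_score(chain, "zz", deg, hops = 3), 0)

  # monotone in hops on random graphs, and equal to the igraph oracle
  skip_if_not_installed("igraph")
  set.seed(41)
  for (rep in 1:10) {
    nodes <- sprintf("n%02d", 1:25)
    net <- as_edge_list(tibble::tibble(
      from = sample(nodes, 60, replace = TRUE),
      to = sample(nodes, 60, replace = TRUE)
    ), directed = TRUE)
    degs <- tibble::tibble(gene_id = nodes, deg_score = runif(25))
    src <- sample(nodes, 5)
    for (g in src) {
      expect_equal(
        regnet_deg_score(net, g, degs, hops = 3),
        oracle_regnet_deg(net, g, degs, 3),
        tolerance = 1e-12
      )
    }
    h <- vapply(1:4, function(k) regnet_deg_score(net, src[1], degs, hops = k), numeric(1))
    expect_true(all(diff(h) >= -1e-12))
  }
})

test_that("cancer gene scores count exact-distance neighbors", {
  net <- as_edge_list(tibble::tibble(
    from = c("g", "g", "x"), to = c("A", "B", "c")
  ), directed = FALSE)
  expect_equal(cgs(net, "g", c("A"), 1), 1L)
  path <- as_edge_list(tibble::tibble(from = c("g", "x"), to = c("x", "c")),
    directed = FALSE
  )
  expect_equal(cgs(path, "g", "c", 1), 0L)
  expect_equal(cgs(path, "g", "c", 2), 1L)
  expect_equal(cgs(path, "isolated", "c", 1), 0L)

  skip_if_not_installed("igraph")
  set.seed(42)
  for (rep in 1:10) {
    nodes <- sprintf("n%02d", 1:30)
    net <- as_edge_list(tibble::tibble(
      from = sample(nodes, 200, replace = TRUE),
      to = sample(nodes, 200, replace = TRUE)
    ), directed = FALSE)
    cancer <- sample(nodes, 8)
    for (g in sample(nodes, 5)) {
      for (lev in 1:2) {
        expect_equal(
          cgs(net, g, cancer, lev),
          oracle_cgs(net, g, cancer, lev),
          label = sprintf("rep %d gene %s level %d", rep, g, lev)
        )
      }
      l1 <- cgs(net, g, cancer, 1)
      l2 <- cgs(net, g, cancer, 2)
      expect_lte(l1 + l2, length(cancer))
      # cumulative reading covers both rings
      expect_equal(cgs(net, g, cancer, 2, cumulative = TRUE), l1 + l2)
    }
  }
})

test_that("GWAS distances use same-chromosome minima with a sentinel", {
  cat <- tibble::tibble(chrom = c("chr1", "chr1", "chr2"), pos = c(90, 250, 5))
  m <- tibble::tibble(chrom = c("chr1", "chr1", "chr3"), pos = c(90, 100, 7))
  d <- distance_to_gwas(m, cat)
  expect_equal(d, c(0, 10, 2.5e8))
  expect_error(distance_to_gwas(m, cat[0, ]), "empty")
})

test_that("early-to-late replication ratios follow (G1B+S1)/(S4+G2)", {
  expect_equal(early_late_ratio(1, 1, 1, 1), 1)
  expect_equal(early_late_ratio(2, 1, 1, 0.5), 2)
  expect_equal(early_late_ratio(0, 0, 1, 1), 0)
  expect_equal(early_late_ratio(1, 1, 0, 0), 100)
  expect_error(early_late_ratio(-1, 0, 1, 1), "non-negative")
})

test_that("track lookups match a linear scan on random positions", {
  set.seed(8)
  starts <- sort(sample.int(1e5, 300)) * 2
  track <- as_signal_track(tibble::tibble(
    chrom = sample(c("c1", "c2"), 300, replace = TRUE),
    start = starts, end = starts + 1,
    value = round(runif(300), 4)
  ))
  q <- tibble::tibble(
    chrom = sample(c("c1", "c2", "c3"), 1000, replace = TRUE),
    pos = sample.int(2e5 + 10, 1000, replace = TRUE)
  )
  got <- signal_at(track, q)
  want <- vapply(seq_len(nrow(q)), function(i) {
    oracle_signal_at(track, q$chrom[i], q$pos[i])
  }, numeric(1))
  expect_equal(got, want)
})

test_that("assembled feature tables carry exactly the 35-feature schema", {
  res <- tiny_bundle$resources
  asn <- suppressMessages(assign_targets(
    tiny_labeled, res$ep_pairs, res$dhs_map, res$dhs_peaks
  ))
  scored <- tfbs_scores(asn, res$pwms, res$genome_seq)
  ft <- assemble_features(scored, res)
  feats <- setdiff(
    names(ft),
    c("chrom", "pos", "ref", "alt", "sample_id", "cancer_type", "label", "gene_id")
  )
  expect_identical(feats, feature_schema())
  expect_equal(length(feature_schema()), 35)
  m <- as.matrix(ft[, feature_schema()])
  expect_true(all(is.finite(m)))
  expect_true(all(ft$tfbs.Gain_or_Loss %in% c(-1, 0, 1)))
  expect_true(all(ft$genetic.Distance.to.GWAS >= 0))

  # a missing track errors naming the track
  broken <- res
  broken$tracks$`origin.H4K20me1` <- NULL
  expect_error(assemble_features(scored, broken), "origin.H4K20me1")
})

test_that("feature branch rules: region-best TF feeds tf.* scores when nothing changes", {
  res <- tiny_bundle$resources
  asn <- suppressMessages(assign_targets(
    tiny_labeled, res$ep_pairs, res$dhs_map, res$dhs_peaks
  ))
  scored <- tfbs_scores(asn, res$pwms, res$genome_seq)
  ft <- assemble_features(scored, res)
  nochange <- which(scored$Gain_or_Loss == 0 & !is.na(scored$bound_tf))
  if (length(nochange) > 0) {
    expect_true(all(ft$tfbs.diff_Log_Pval_FIMO[nochange] == 0))
    # the bound TF's own scores appear in the tf.* block
    i <- nochange[1]
    tf <- scored$bound_tf[i]
    deg <- deg_table(res$expression)
    val <- deg$deg_score[match(tf, deg$gene_id)]
    expect_equal(ft$tf.DEG_score[i], ifelse(is.na(val), 0, val))
  }
})
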