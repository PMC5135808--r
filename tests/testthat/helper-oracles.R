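# Independent oracles used across the suite. Each reimplements the checked
# quantity by the most transparent route available (term summation, full
# enumeration, naive scanning, O(n^2) counting) without touching the code
# paths under test.

# Poisson upper tail P(X >= x) by term-by-term pmf summation in log space
oracle_pois_tail <- function(x, lambda) {
  if (x == 0) return(1)
  if (lambda == 0) return(0)
  k <- x
  logterm <- -lambda + k * log(lambda) - lgamma(k + 1)
  total <- 0
  repeat {
    t <- exp(logterm)
    total <- total + t
    k <- k + 1
    logterm <- logterm + log(lambda) - log(k)
    if ((t < total * 1e-17 && k > lambda + x + 10) || k > x + 1e5) break
  }
  total
}

# naive full-scan window count on a plain mutation table
oracle_window_count <- function(tbl, chrom, pos, w) {
  lo <- pos - floor(w / 2)
  hi <- pos + ceiling(w / 2) - 1
  sum(tbl$chrom == chrom & tbl$pos >= lo & tbl$pos <= hi)
}

# exhaustive single-strand enumeration p-value for a PWM match score,
# using the same quantization rule as the scanner but recomputed here
oracle_enum_pvalue <- function(pwm, observed_score, bin = 1e-3) {
  s <- log2(sweep(pwm$matrix, 2, pwm$background, "/"))
  s[!is.finite(s)] <- -20
  s <- pmax(s, -20)
  q <- matrix(as.integer(round(s / bin)), nrow = nrow(s))
  L <- nrow(q)
  combos <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- integer(nrow(combos))
  for (j in 1:L) scores <- scores + q[j, combos[, j]]
  k <- as.integer(round(observed_score / bin))
  mean(scores >= k)
}

# O(n^2) concordance AUC with half-credit for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# igraph-based count of cancer genes at exact (or cumulative) distance
oracle_cgs <- function(net, gene, cancer_genes, level, cumulative = FALSE) {
  g <- igraph::graph_from_data_frame(as.data.frame(net),
    directed = attr(net, "directed")
  )
  if (!gene %in% igraph::V(g)$name) return(0L)
  d <- igraph::distances(g, v = gene, mode = "all")[1, ]
  ring <- if (cumulative) {
    names(d)[d >= 1 & d <= level]
  } else {
    names(d)[d == level]
  }
  length(intersect(ring, cancer_genes))
}

# igraph-based downstream DEG sum within `hops` directed steps
oracle_regnet_deg <- function(net, gene, deg, hops) {
  g <- igraph::graph_from_data_frame(as.data.frame(net), directed = TRUE)
  if (!gene %in% igraph::V(g)$name) return(0)
  d <- igraph::distances(g, v = gene, mode = "out")[1, ]
  down <- setdiff(names(d)[d >= 1 & d <= hops], gene)
  lookup <- stats::setNames(deg$deg_score, deg$gene_id)
  sum(lookup[intersect(down, names(lookup))])
}

# linear-scan track lookup
oracle_signal_at <- function(track, chrom, pos) {
  hit <- track$chrom == chrom & track$start < pos & pos <= track$end
  if (any(hit)) track$value[which(hit)[1]] else 0
}

# small deterministic cohort builder for unit tests
toy_cohort <- function(pos, chrom = "chr1", sample_id = NULL, genome = NULL) {
  n <- length(pos)
  as_mutation_cohort(tibble::tibble(
    chrom = chrom, pos = pos, ref = "A", alt = "G",
    sample_id = sample_id %||% paste0("s", seq_len(n))
  ), genome = genome)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
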