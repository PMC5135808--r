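#' The 35-feature schema
#'
#' Names and order of the feature panel: six target-gene scores, the same
#' six for the bound TF, three binding-site scores, six cancer-cell
#' epigenetic signals, three genetic signals, and eleven cell-of-origin
#' epigenetic signals.
#'
#' @return character vector of the 35 feature names, in canonical order.
#' @export
feature_schema <- function() {
  gene_scores <- c(
    "HumanNet.CGS_L1", "HumanNet.CGS_L2",
    "InteractNet.CGS_L1", "InteractNet.CGS_L2",
    "RegNet.DEG_score", "DEG_score"
  )
  c(
    paste0("target.", gene_scores),
    paste0("tf.", gene_scores),
    paste0("tfbs.", c("diff_Log_Pval_FIMO", "avg_Log_Pval_FIMO", "Gain_or_Loss")),
    paste0("cancer.", c(
      "DnaseSig", "H3K27ac", "H3K27me3", "H3K36me3", "H3K4me3", "H3K9me3"
    )),
    paste0("genetic.", c("Distance.to.GWAS", "Early.to.late_Rate", "PhastCons")),
    paste0("origin.", c(
      "DnaseSig", "H3K27ac", "H3K27me3", "H3K36me3", "H3K4me1", "H3K4me2",
      "H3K4me3", "H3K79me2", "H3K9ac", "H3K9me3", "H4K20me1"
    ))
  )
}

# track labels expected in the resources$tracks list
cancer_track_names <- function() {
  c("DnaseSig", "H3K27ac", "H3K27me3", "H3K36me3", "H3K4me3", "H3K9me3")
}
origin_track_names <- function() {
  c(
    "DnaseSig", "H3K27ac", "H3K27me3", "H3K36me3", "H3K4me1", "H3K4me2",
    "H3K4me3", "H3K79me2", "H3K9ac", "H3K9me3", "H4K20me1"
  )
}

#' Differential expression score for one gene
#'
#' A two-sample t-test compares tumor against normal expression; with
#' `x = -log10(p)` the score is `x / (x + 1)`, a monotone map of the
#' p-value onto `[0, 1)`. The p-value is clamped below at 1e-300.
#'
#' @param tumor_values,normal_values numeric vectors, each of length >= 2.
#' @param welch use the Welch t-test instead of the pooled-variance Student
#'   test (default `FALSE`).
#' @return a single score in `[0, 1)`.
#' @export
#' @examples
#' deg_score(c(10, 10.1, 9.9), c(0, 0.1, -0.1))
deg_score <- function(tumor_values, normal_values, welch = FALSE) {
  if (length(tumor_values) < 2 || length(normal_values) < 2) {
    rlang::abort("deg_score needs >= 2 values per group")
  }
  if (stats::sd(tumor_values) == 0 && stats::sd(normal_values) == 0) {
    # degenerate constant groups: no evidence of change
    p <- 1
  } else {
    p <- stats::t.test(tumor_values, normal_values, var.equal = !welch)$p.value
  }
  p <- max(p, 1e-300)
  x <- -log10(p)
  x / (x + 1)
}

#' Differential expression scores for every gene in a matrix
#'
#' @param expr list with `values` (genes x samples matrix) and `status`
#'   (factor `"tumor"`/`"normal"` per sample), as from
#'   [read_expression_matrix()].
#' @param welch see [deg_score()].
#' @return a tibble `(gene_id, deg_score)`.
#' @export
deg_table <- function(expr, welch = FALSE) {
  tum <- expr$status == "tumor"
  if (sum(tum) < 2 || sum(!tum) < 2) {
    rlang::abort("need >= 2 tumor and >= 2 normal samples")
  }
  scores <- apply(expr$values, 1, function(v) {
    deg_score(v[tum], v[!tum], welch = welch)
  })
  tibble(gene_id = rownames(expr$values), deg_score = unname(scores))
}

# distinct nodes reachable from source in 1..hops directed steps
reachable_downstream <- function(regnet, source, hops) {
  frontier <- source
  seen <- character()
  for (h in seq_len(hops)) {
    frontier <- setdiff(neighbors_of(regnet, frontier), c(seen, source))
    if (length(frontier) == 0) break
    seen <- c(seen, frontier)
  }
  seen
}

#' Regulatory-network differential expression score
#'
#' Sum of the DEG scores of all distinct genes reachable within `hops`
#' directed steps downstream of each source gene (the source itself is
#' excluded; genes absent from the DEG table contribute 0; cycles are
#' visited once).
#'
#' @param regnet a directed `edge_list` (regulator -> target).
#' @param genes character vector of source genes (gene or TF ids).
#' @param deg a DEG tibble `(gene_id, deg_score)` from [deg_table()].
#' @param hops maximum downstream distance (default 3).
#' @return numeric vector of scores, one per source gene; 0 for genes
#'   absent from the network.
#' @export
regnet_deg_score <- function(regnet, genes, deg, hops = 3) {
  if (hops < 1) rlang::abort("hops must be >= 1")
  if (!attr(regnet, "directed")) {
    rlang::abort("regnet_deg_score requires a directed network")
  }
  lookup <- stats::setNames(deg$deg_score, deg$gene_id)
  vapply(genes, function(g) {
    down <- reachable_downstream(regnet, g, hops)
    if (length(down) == 0) return(0)
    sum(lookup[down], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Cancer gene score: cancer genes at graph distance 1 or 2
#'
#' Counts known cancer genes at shortest-path distance exactly `level` from
#' each source gene in an undirected interaction network; the source never
#' counts itself. With `cumulative = TRUE` the count covers distances
#' `1..level` instead.
#'
#' @param network an undirected `edge_list`.
#' @param genes character vector of source genes.
#' @param cancer_genes character vector of known cancer genes.
#' @param level 1 or 2.
#' @param cumulative count distances `<= level` (default `FALSE`: exactly
#'   `level`).
#' @return integer vector of counts; 0 for isolated or absent genes.
#' @export
cgs <- function(network, genes, cancer_genes, level = 1, cumulative = FALSE) {
  if (!level %in% c(1, 2)) rlang::abort("level must be 1 or 2")
  vapply(genes, function(g) {
    d1 <- setdiff(neighbors_of(network, g), g)
    ring <- if (level == 1) {
      d1
    } else {
      d2 <- setdiff(neighbors_of(network, d1), c(d1, g))
      if (cumulative) union(d1, d2) else d2
    }
    length(intersect(ring, cancer_genes))
  }, integer(1), USE.NAMES = FALSE)
}

#' Distance to the nearest cancer-associated GWAS SNP
#'
#' Minimum absolute distance in bp from each mutation to a catalog SNP on
#' the same chromosome; chromosomes with no catalog SNP report the
#' `sentinel` distance.
#'
#' @param mutations data frame with columns `chrom`, `pos`.
#' @param catalog GWAS tibble `(chrom, pos)`; must be non-empty.
#' @param sentinel distance reported when the chromosome has no SNP
#'   (default 2.5e8, the order of the largest chromosome).
#' @return numeric vector of distances in bp.
#' @export
distance_to_gwas <- function(mutations, catalog, sentinel = 2.5e8) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    rlang::abort("empty GWAS catalog")
  }
  by_chrom <- split(catalog$pos, catalog$chrom)
  vapply(seq_len(nrow(mutations)), function(i) {
    ps <- by_chrom[[mutations$chrom[i]]]
    if (is.null(ps)) return(sentinel)
    min(abs(mutations$pos[i] - ps))
  }, numeric(1))
}

#' Replication-timing early-to-late ratio
#'
#' `(G1B + S1) / (S4 + G2)` over normalized replication signals of the four
#' cell-cycle fractions; a zero denominator reports the configured cap.
#'
#' @param g1b,s1,s4,g2 non-negative numeric vectors (recycled).
#' @param cap value reported when `S4 + G2 = 0` (default 100).
#' @return numeric vector of ratios.
#' @export
#' @examples
#' early_late_ratio(2, 1, 1, 0.5) # 2
early_late_ratio <- function(g1b, s1, s4, g2, cap = 100) {
  if (any(c(g1b, s1, s4, g2) < 0)) {
    rlang::abort("replication fractions must be non-negative")
  }
  den <- s4 + g2
  ifelse(den == 0, cap, (g1b + s1) / den)
}

# six gene-level scores for a vector of genes (NA gene -> all zero)
gene_score_block <- function(genes, resources, config) {
  uniq <- unique(genes[!is.na(genes)])
  if (length(uniq) == 0) {
    block <- matrix(0, nrow = length(genes), ncol = 6)
  } else {
    deg <- resources$deg %||% deg_table(resources$expression, welch = config$deg_welch)
    lookup <- stats::setNames(deg$deg_score, deg$gene_id)
    tab <- tibble(
      gene = uniq,
      HumanNet.CGS_L1 = as.numeric(cgs(resources$humannet, uniq,
        resources$cancer_genes, 1,
        cumulative = config$cgs_cumulative
      )),
      HumanNet.CGS_L2 = as.numeric(cgs(resources$humannet, uniq,
        resources$cancer_genes, 2,
        cumulative = config$cgs_cumulative
      )),
      InteractNet.CGS_L1 = as.numeric(cgs(resources$interactnet, uniq,
        resources$cancer_genes, 1,
        cumulative = config$cgs_cumulative
      )),
      InteractNet.CGS_L2 = as.numeric(cgs(resources$interactnet, uniq,
        resources$cancer_genes, 2,
        cumulative = config$cgs_cumulative
      )),
      RegNet.DEG_score = regnet_deg_score(resources$regnet, uniq, deg, hops = 3),
      DEG_score = unname(ifelse(is.na(lookup[uniq]), 0, lookup[uniq]))
    )
    m <- match(genes, tab$gene)
    block <- as.matrix(tab[, -1])[m, , drop = FALSE]
    block[is.na(block)] <- 0
  }
  colnames(block) <- c(
    "HumanNet.CGS_L1", "HumanNet.CGS_L2", "InteractNet.CGS_L1",
    "InteractNet.CGS_L2", "RegNet.DEG_score", "DEG_score"
  )
  as_tibble(block)
}

#' Assemble the 35-feature table for scored candidate mutations
#'
#' Fills every feature of [feature_schema()] for each mutation: the six
#' target-gene scores for its assigned gene; the same six for the bound TF
#' (zero when no TF was identified); the three binding-site scores; the
#' cancer-cell and cell-of-origin track signals at the site; and the three
#' genetic signals (GWAS distance, replication early-to-late ratio,
#' conservation).
#'
#' @param scored output of [tfbs_scores()]: assigned mutations with the
#'   binding-site score columns.
#' @param resources named list with elements `humannet`, `interactnet`
#'   (undirected `edge_list`s), `regnet` (directed `edge_list`),
#'   `cancer_genes` (character), `expression` (or a precomputed `deg`
#'   tibble), `gwas` (tibble `chrom`,`pos`), `reptiming` (named list of
#'   four `signal_track`s `G1B`,`S1`,`S4`,`G2`), `phastcons` (a
#'   `signal_track`), `tracks` (named list with elements `cancer.<mark>`
#'   and `origin.<mark>` `signal_track`s for the full mark panel).
#' @param config a [regrecur_config()] list.
#' @return a tibble: the identifying columns of `scored` (`chrom`, `pos`,
#'   `ref`, `alt`, `sample_id`, and `label`/`gene_id` when present) followed
#'   by the 35 feature columns in schema order.
#' @export
assemble_features <- function(scored, resources, config = regrecur_config()) {
  assert_cols(scored, c(
    "chrom", "pos", "gene_id",
    "diff_Log_Pval_FIMO", "avg_Log_Pval_FIMO", "Gain_or_Loss", "bound_tf"
  ), "scored mutations")
  needed <- c(
    paste0("cancer.", cancer_track_names()),
    paste0("origin.", origin_track_names())
  )
  missing <- setdiff(needed, names(resources$tracks))
  if (length(missing) > 0) {
    rlang::abort(sprintf(
      "missing configured track(s): %s", paste(missing, collapse = ", ")
    ))
  }
  for (frac in c("G1B", "S1", "S4", "G2")) {
    if (!frac %in% names(resources$reptiming)) {
      rlang::abort(sprintf("missing replication-timing fraction %s", frac))
    }
  }

  sites <- scored[, c("chrom", "pos")]
  target_block <- gene_score_block(scored$gene_id, resources, config)
  names(target_block) <- paste0("target.", names(target_block))
  tf_block <- gene_score_block(scored$bound_tf, resources, config)
  names(tf_block) <- paste0("tf.", names(tf_block))

  tfbs_block <- tibble(
    tfbs.diff_Log_Pval_FIMO = scored$diff_Log_Pval_FIMO,
    tfbs.avg_Log_Pval_FIMO = scored$avg_Log_Pval_FIMO,
    tfbs.Gain_or_Loss = scored$Gain_or_Loss
  )

  hw <- config$signal_halfwidth
  track_block <- purrr::map_dfc(needed, function(nm) {
    stats::setNames(
      tibble(v = signal_at(resources$tracks[[nm]], sites, halfwidth = hw)), nm
    )
  })

  rt <- lapply(c("G1B", "S1", "S4", "G2"), function(f) {
    signal_at(resources$reptiming[[f]], sites, halfwidth = hw)
  })
  genetic_block <- tibble(
    genetic.Distance.to.GWAS = distance_to_gwas(sites, resources$gwas,
      sentinel = config$gwas_sentinel
    ),
    genetic.Early.to.late_Rate = early_late_ratio(rt[[1]], rt[[2]], rt[[3]], rt[[4]],
      cap = config$elr_cap
    ),
    genetic.PhastCons = signal_at(resources$phastcons, sites, halfwidth = hw)
  )

  id_cols <- intersect(
    c("chrom", "pos", "ref", "alt", "sample_id", "cancer_type", "label", "gene_id"),
    names(scored)
  )
  out <- dplyr::bind_cols(
    as_tibble(scored)[, id_cols],
    target_block, tf_block, tfbs_block,
    track_block[, paste0("cancer.", cancer_track_names())],
    genetic_block,
    track_block[, paste0("origin.", origin_track_names())]
  )
  stopifnot(identical(
    setdiff(names(out), id_cols), feature_schema()
  ))
  out
}
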