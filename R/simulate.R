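# Synthetic fixture generation: mutation cohorts with planted hotspots plus
# every resource table/track the pipeline consumes, at toy-genome scale.
#
# The generator realizes the statistical structure the analysis assumes — a
# homogeneous Poisson mutation background plus recurrent sites shared across
# samples — and, through the effect model, a feature-label association whose
# strength controls the achievable classification performance.

#' Simulation configuration
#'
#' @param genome tibble `(chrom, length)` of the toy genome.
#' @param n_samples number of cohort samples.
#' @param background_rate background mutations per bp per sample.
#' @param hotspots tibble `(chrom, pos, multiplicity, max_spread)`; each
#'   hotspot contributes `multiplicity` mutations in distinct samples within
#'   `pos +/- max_spread`. Multiplicity must be >= 2 and positions within
#'   genome bounds.
#' @param n_genes,n_tfs,n_cancer_genes gene-universe sizes.
#' @param effect effect model: list with elements `track` (signal added to
#'   tracks at hotspot bins), `expr` (expression shift of hotspot target
#'   genes in tumor samples), `reptiming` (early-fraction shift at hotspot
#'   bins), `gwas` (plant catalog SNPs near hotspots), `network` (wire
#'   cancer genes adjacent to hotspot target genes). `effect_model("null")`
#'   zeroes all of them.
#' @return a `sim_config` list.
#' @export
sim_config <- function(genome, n_samples, background_rate, hotspots,
                       n_genes = 100, n_tfs = 8, n_cancer_genes = 20,
                       effect = effect_model("default")) {
  if (background_rate <= 0) rlang::abort("background_rate must be positive")
  if (nrow(hotspots) > 0) {
    if (any(hotspots$multiplicity < 2)) {
      rlang::abort("hotspot multiplicity must be >= 2")
    }
    if (any(hotspots$multiplicity > n_samples)) {
      rlang::abort("hotspot multiplicity exceeds n_samples")
    }
    len <- genome$length[match(hotspots$chrom, genome$chrom)]
    if (any(is.na(len)) ||
      any(hotspots$pos - hotspots$max_spread < 1) ||
      any(hotspots$pos + hotspots$max_spread > len)) {
      rlang::abort("hotspot positions must lie within genome bounds")
    }
  }
  structure(
    list(
      genome = as_tibble(genome), n_samples = n_samples,
      background_rate = background_rate, hotspots = as_tibble(hotspots),
      n_genes = n_genes, n_tfs = n_tfs, n_cancer_genes = n_cancer_genes,
      effect = effect
    ),
    class = "sim_config"
  )
}

#' Effect models for the simulator
#'
#' `"default"` plants a moderate, multi-feature association between
#' hotspot-linked mutations and their features (the regime in which a
#' forest separates true from false well above chance); `"null"` removes
#' every feature-label association while keeping the data shapes identical.
#'
#' @param preset `"default"` or `"null"`.
#' @return an effect-model list (see [sim_config()]).
#' @export
effect_model <- function(preset = c("default", "null")) {
  preset <- match.arg(preset)
  if (preset == "null") {
    list(track = 0, expr = 0, reptiming = 0, gwas = FALSE, network = FALSE)
  } else {
    list(track = 3, expr = 2, reptiming = 1.5, gwas = TRUE, network = TRUE)
  }
}

# jittered-grid hotspot positions: deterministic spacing, seeded jitter
place_hotspots <- function(genome, n, multiplicities, spread, seed) {
  if (n == 0) {
    return(tibble(
      chrom = character(), pos = integer(),
      multiplicity = integer(), max_spread = integer()
    ))
  }
  per_chrom <- diff(round(seq(0, n, length.out = nrow(genome) + 1)))
  withr::with_seed(seed, {
    out <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
      k <- per_chrom[i]
      if (k == 0) return(NULL)
      step <- genome$length[i] / (k + 1)
      pos <- round(step * seq_len(k) + stats::runif(k, -step / 4, step / 4))
      tibble(chrom = genome$chrom[i], pos = as.integer(pos))
    })
    out$multiplicity <- as.integer(sample(multiplicities, n, replace = TRUE))
    out$max_spread <- as.integer(spread)
    out
  })
}

#' Generate a random toy genome sequence
#'
#' Uniform random bases per chromosome; hotspot loci are later overwritten
#' with TF consensus sites by [simulate_resources()].
#'
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @return named character vector of chromosome sequences.
#' @export
simulate_genome <- function(config, seed = 1) {
  withr::with_seed(seed, {
    seqs <- vapply(seq_len(nrow(config$genome)), function(i) {
      paste(sample(DNA_BASES, config$genome$length[i], replace = TRUE),
        collapse = ""
      )
    }, character(1))
    names(seqs) <- config$genome$chrom
    seqs
  })
}

#' Simulate a mutation cohort with planted hotspots
#'
#' Background mutations arrive as a homogeneous Poisson process per sample
#' (`background_rate` per bp); each hotspot contributes `multiplicity`
#' mutations in distinct samples within `pos +/- max_spread`. Reference
#' alleles follow the genome sequence when one is supplied; alternates are
#' drawn uniformly from the other bases.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @param genome_seq optional named character vector of chromosome
#'   sequences (for consistent `ref` alleles).
#' @param cancer_type label for the generated records.
#' @return list with `cohort` (a `mutation_cohort`) and `truth` (tibble
#'   `key`, `hotspot_id`: `NA` for background mutations).
#' @export
simulate_cohort <- function(config, seed = 1, genome_seq = NULL,
                            cancer_type = "SIM") {
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  withr::with_seed(seed, {
    bg <- purrr::map_dfr(seq_len(nrow(config$genome)), function(i) {
      len <- config$genome$length[i]
      n <- stats::rpois(
        config$n_samples,
        len * config$background_rate
      )
      tibble(
        chrom = config$genome$chrom[i],
        pos = as.integer(ceiling(stats::runif(sum(n)) * len)),
        sample_id = rep(samples, n),
        hotspot_id = NA_integer_
      )
    })
    hs <- purrr::map_dfr(seq_len(nrow(config$hotspots)), function(j) {
      h <- config$hotspots[j, ]
      tibble(
        chrom = h$chrom,
        pos = as.integer(h$pos + sample(-h$max_spread:h$max_spread,
          h$multiplicity,
          replace = TRUE
        )),
        sample_id = sample(samples, h$multiplicity, replace = FALSE),
        hotspot_id = j
      )
    })
    all <- dplyr::bind_rows(bg, hs)
    if (is.null(genome_seq)) {
      all$ref <- sample(DNA_BASES, nrow(all), replace = TRUE)
    } else {
      all$ref <- substring(
        genome_seq[all$chrom],
        all$pos, all$pos
      )
    }
    all$alt <- vapply(all$ref, function(r) {
      sample(setdiff(DNA_BASES, r), 1)
    }, character(1), USE.NAMES = FALSE)
    all$cancer_type <- cancer_type
  })
  truth <- tibble(key = mutation_key(all), hotspot_id = all$hotspot_id)
  truth <- dplyr::distinct(truth, .data$key, .keep_all = TRUE)
  cohort <- as_mutation_cohort(
    all[, c("chrom", "pos", "ref", "alt", "sample_id", "cancer_type")],
    genome = config$genome
  )
  list(cohort = cohort, truth = truth)
}

# near-consensus PWM: prob `major` on the consensus base per position
consensus_pwm <- function(tf_id, consensus, major = 0.85) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  mat <- matrix((1 - major) / 3, nrow = length(bases), ncol = 4,
    dimnames = list(NULL, DNA_BASES)
  )
  for (i in seq_along(bases)) mat[i, bases[i]] <- major
  new_pwm(tf_id, mat)
}

# binned baseline track over the genome, elevated at hotspot bins
make_track <- function(genome, hotspots, name, bin_bp, base_fun, boost) {
  df <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = bin_bp)
    tibble(
      chrom = genome$chrom[i], start = starts,
      end = pmin(starts + bin_bp, genome$length[i]),
      value = base_fun(length(starts))
    )
  })
  if (boost != 0 && nrow(hotspots) > 0) {
    for (j in seq_len(nrow(hotspots))) {
      hit <- df$chrom == hotspots$chrom[j] &
        df$start < hotspots$pos[j] & hotspots$pos[j] <= df$end
      df$value[hit] <- df$value[hit] + boost
    }
  }
  as_signal_track(df, name = name)
}

#' Simulate every resource the feature pipeline consumes
#'
#' Generates, consistently with the planted hotspots: a genome sequence
#' with TF consensus sites straddling hotspot positions; PWMs for those
#' TFs; EP pairs and DHS peaks covering the hotspots (plus random distal
#' coverage, and a DHS-correlation map for fallback mapping); tumor/normal
#' expression in which hotspot target genes are differentially expressed; a
#' directed regulatory network and two undirected interaction networks in
#' which cancer genes sit adjacent to hotspot target genes; a GWAS catalog
#' with SNPs near hotspots; replication-timing fractions with an elevated
#' early-to-late ratio at hotspots; the 17-mark signal-track panel and a
#' conservation track, all hotspot-enriched per the effect model.
#'
#' @param config a `sim_config`.
#' @param seed RNG seed.
#' @return list with `genome_seq`, `pwms`, `ep_pairs`, `dhs_map`,
#'   `dhs_peaks`, `expression`, `regnet`, `humannet`, `interactnet`,
#'   `cancer_genes`, `gwas`, `reptiming`, `phastcons`, `tracks`, and the
#'   ground-truth `hotspot_genes` table.
#' @export
simulate_resources <- function(config, seed = 1) {
  genome <- config$genome
  hs <- config$hotspots
  eff <- config$effect
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  tfs <- sprintf("TF%02d", seq_len(config$n_tfs))

  genome_seq <- simulate_genome(config, derive_seed(seed, 1))

  withr::with_seed(derive_seed(seed, 2), {
    # TF consensus strings and hotspot wiring
    consensus <- vapply(tfs, function(t) {
      paste(sample(DNA_BASES, 8, replace = TRUE), collapse = "")
    }, character(1))
    pwms <- lapply(seq_along(tfs), function(i) {
      consensus_pwm(tfs[i], consensus[i])
    })
    names(pwms) <- tfs

    if (nrow(hs) > 0) {
      hs_gene <- genes[(seq_len(nrow(hs)) - 1) %% config$n_genes + 1]
      hs_tf <- tfs[(seq_len(nrow(hs)) - 1) %% config$n_tfs + 1]
      # plant each hotspot's TF consensus at [pos-3, pos+4] so every member
      # mutation (within +/- max_spread <= 2) falls inside the site
      for (j in seq_len(nrow(hs))) {
        s <- genome_seq[[hs$chrom[j]]]
        substr(s, hs$pos[j] - 3, hs$pos[j] + 4) <- consensus[hs_tf[j]]
        genome_seq[[hs$chrom[j]]] <- s
      }
    } else {
      hs_gene <- character()
      hs_tf <- character()
    }
    hotspot_genes <- dplyr::bind_cols(hs, tibble(gene_id = hs_gene, tf_id = hs_tf))

    # enhancer-promoter pairs: one enhancer per hotspot plus random distal
    # enhancers for ~40% of the genome's background mutations
    n_extra <- max(4, round(sum(genome$length) / 2000))
    extra_chrom <- sample(genome$chrom, n_extra, replace = TRUE)
    extra_start <- vapply(extra_chrom, function(ch) {
      ceiling(stats::runif(1) * (genome$length[genome$chrom == ch] - 400))
    }, numeric(1), USE.NAMES = FALSE)
    ep_pairs <- dplyr::bind_rows(
      if (nrow(hs) > 0) {
        tibble(
          chrom = hs$chrom, start = pmax(hs$pos - 50, 0), end = hs$pos + 50,
          gene = hs_gene, cell_type = "SIM",
          score = stats::runif(nrow(hs), 0.6, 1)
        )
      },
      tibble(
        chrom = extra_chrom, start = extra_start, end = extra_start + 200,
        gene = sample(genes, n_extra, replace = TRUE), cell_type = "SIM",
        score = stats::runif(n_extra, 0.2, 0.9)
      )
    )

    # DHS-correlation map: distal intervals covering another slice of the
    # genome, for fallback mapping
    n_dhs <- max(4, round(sum(genome$length) / 4000))
    dhs_chrom <- sample(genome$chrom, n_dhs, replace = TRUE)
    dhs_start <- vapply(dhs_chrom, function(ch) {
      ceiling(stats::runif(1) * (genome$length[genome$chrom == ch] - 400))
    }, numeric(1), USE.NAMES = FALSE)
    dhs_map <- tibble(
      chrom = dhs_chrom, start = dhs_start, end = dhs_start + 200,
      gene = sample(genes, n_dhs, replace = TRUE),
      max_corr = stats::runif(n_dhs, 0.2, 0.99)
    )

    dhs_peaks <- dplyr::bind_rows(
      if (nrow(hs) > 0) {
        tibble(chrom = hs$chrom, start = pmax(hs$pos - 60, 0), end = hs$pos + 60)
      },
      tibble(chrom = dhs_chrom, start = dhs_start, end = dhs_start + 200)
    )

    # expression: hotspot target genes shifted in tumor samples
    n_t <- 6
    n_n <- 6
    vals <- matrix(stats::rnorm(config$n_genes * (n_t + n_n), 5, 1),
      nrow = config$n_genes,
      dimnames = list(genes, c(sprintf("T%02d", 1:n_t), sprintf("N%02d", 1:n_n)))
    )
    de_genes <- unique(hs_gene)
    vals[de_genes, 1:n_t] <- vals[de_genes, 1:n_t] + eff$expr
    expression <- list(
      values = vals,
      status = factor(rep(c("tumor", "normal"), c(n_t, n_n)),
        levels = c("tumor", "normal")
      )
    )

    # networks over genes + TFs
    nodes <- c(genes, tfs)
    cancer_genes <- sample(setdiff(genes, de_genes), config$n_cancer_genes)
    rand_edges <- function(m) {
      tibble(
        from = sample(nodes, m, replace = TRUE),
        to = sample(nodes, m, replace = TRUE)
      )
    }
    wire <- function(anchored) {
      df <- rand_edges(2 * length(nodes))
      if (eff$network && length(anchored) > 0) {
        df <- dplyr::bind_rows(df, tibble(
          from = rep(anchored, each = 2),
          to = sample(cancer_genes, 2 * length(anchored), replace = TRUE)
        ))
      }
      df
    }
    anchored <- unique(c(de_genes, if (eff$network) hs_tf))
    humannet <- as_edge_list(wire(anchored), directed = FALSE)
    interactnet <- as_edge_list(wire(anchored), directed = FALSE)
    # regulatory network: random wiring plus a chain through the DE genes so
    # hotspot targets reach other DE genes downstream
    reg_edges <- rand_edges(2 * length(nodes))
    if (length(de_genes) > 1) {
      reg_edges <- dplyr::bind_rows(reg_edges, tibble(
        from = de_genes, to = de_genes[c(2:length(de_genes), 1)]
      ))
    }
    if (eff$network && length(hs_tf) > 0) {
      reg_edges <- dplyr::bind_rows(reg_edges, tibble(
        from = hs_tf, to = hs_gene
      ))
    }
    regnet <- as_edge_list(reg_edges, directed = TRUE)

    # GWAS catalog: near-hotspot SNPs plus uniform background SNPs
    n_snp <- max(10, round(sum(genome$length) / 5e4))
    snp_chrom <- sample(genome$chrom, n_snp, replace = TRUE)
    gwas <- dplyr::bind_rows(
      if (eff$gwas && nrow(hs) > 0) {
        tibble(
          chrom = hs$chrom,
          pos = as.integer(hs$pos + sample(c(-1, 1), nrow(hs), replace = TRUE) *
            sample(100:500, nrow(hs), replace = TRUE))
        )
      },
      tibble(
        chrom = snp_chrom,
        pos = as.integer(ceiling(stats::runif(n_snp) *
          genome$length[match(snp_chrom, genome$chrom)]))
      )
    )

    # track panel, conservation, replication fractions
    track_names <- c(
      paste0("cancer.", cancer_track_names()),
      paste0("origin.", origin_track_names())
    )
    tracks <- lapply(track_names, function(nm) {
      make_track(genome, hs, nm, 500,
        function(n) round(stats::rlnorm(n, 0, 0.5), 4),
        boost = eff$track
      )
    })
    names(tracks) <- track_names
    phastcons <- make_track(genome, hs, "PhastCons", 500,
      function(n) round(stats::runif(n, 0, 0.3), 4),
      boost = 0
    )
    reptiming <- list(
      G1B = make_track(genome, hs, "G1B", 500,
        function(n) round(stats::runif(n, 0.5, 1.5), 4),
        boost = eff$reptiming
      ),
      S1 = make_track(genome, hs, "S1", 500,
        function(n) round(stats::runif(n, 0.5, 1.5), 4),
        boost = eff$reptiming
      ),
      S4 = make_track(genome, hs, "S4", 500,
        function(n) round(stats::runif(n, 0.5, 1.5), 4),
        boost = 0
      ),
      G2 = make_track(genome, hs, "G2", 500,
        function(n) round(stats::runif(n, 0.5, 1.5), 4),
        boost = 0
      )
    )
  })

  list(
    genome_seq = genome_seq, pwms = pwms, ep_pairs = ep_pairs,
    dhs_map = dhs_map, dhs_peaks = dhs_peaks, expression = expression,
    regnet = regnet, humannet = humannet, interactnet = interactnet,
    cancer_genes = cancer_genes, gwas = gwas, reptiming = reptiming,
    phastcons = phastcons, tracks = tracks, hotspot_genes = hotspot_genes
  )
}

#' Build a complete fixture bundle
#'
#' Generates a mutation cohort plus every resource for one of three study
#' presets, optionally writing all artifacts to disk with a manifest.
#' Presets: `tiny` — 1 chromosome x 100 kbp, 5 samples, 3 hotspots (fast
#' end-to-end runs); `default` — 2 chromosomes x 1 Mbp, 20 samples, 114
#' hotspots of multiplicity 4-7 (mirrors the reference true-set size);
#' `null` — the default genome with no hotspots and a null effect model.
#'
#' @param preset `"tiny"`, `"default"`, or `"null"`.
#' @param seed RNG seed (default 42).
#' @param dir optional directory; when given, every artifact is written
#'   there and the returned bundle gains a `manifest` tibble of paths.
#' @return list with `config`, `cohort`, `truth`, `resources`, and
#'   optionally `manifest`.
#' @export
make_fixture_bundle <- function(preset = c("tiny", "default", "null"),
                                seed = 42, dir = NULL) {
  preset <- match.arg(preset)
  config <- switch(preset,
    tiny = {
      genome <- tibble(chrom = "chr1", length = 1e5)
      sim_config(
        genome,
        n_samples = 8, background_rate = 6e-4,
        hotspots = place_hotspots(genome, 3, 4:6, 2, derive_seed(seed, 91)),
        n_genes = 30, n_tfs = 4, n_cancer_genes = 8
      )
    },
    default = {
      genome <- tibble(chrom = c("chr1", "chr2"), length = c(1e6, 1e6))
      sim_config(
        genome,
        n_samples = 20, background_rate = 2.5e-4,
        hotspots = place_hotspots(genome, 114, 4:7, 2, derive_seed(seed, 92)),
        n_genes = 200, n_tfs = 10, n_cancer_genes = 30
      )
    },
    null = {
      genome <- tibble(chrom = c("chr1", "chr2"), length = c(1e6, 1e6))
      sim_config(
        genome,
        n_samples = 20, background_rate = 2.5e-4,
        hotspots = place_hotspots(genome, 0, integer(), 2, seed),
        n_genes = 200, n_tfs = 10, n_cancer_genes = 30,
        effect = effect_model("null")
      )
    }
  )
  resources <- simulate_resources(config, seed = derive_seed(seed, 10))
  sim <- simulate_cohort(config,
    seed = derive_seed(seed, 20),
    genome_seq = resources$genome_seq
  )
  bundle <- list(
    config = config, cohort = sim$cohort, truth = sim$truth,
    resources = resources
  )
  if (!is.null(dir)) {
    bundle$manifest <- write_fixture_bundle(bundle, dir)
  }
  bundle
}

# write every artifact of a bundle under `dir`; returns the manifest tibble
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- bundle$resources
  paths <- c(
    mutations = write_mutations(bundle$cohort, file.path(dir, "mutations.tsv")),
    genome = write_genome_fasta(res$genome_seq, file.path(dir, "genome.fa")),
    pwms = write_meme(res$pwms, file.path(dir, "motifs.meme")),
    ep_pairs = {
      readr::write_tsv(res$ep_pairs, file.path(dir, "ep_pairs.tsv"), progress = FALSE)
      file.path(dir, "ep_pairs.tsv")
    },
    dhs_map = {
      readr::write_tsv(res$dhs_map, file.path(dir, "dhs_map.tsv"), progress = FALSE)
      file.path(dir, "dhs_map.tsv")
    },
    dhs_peaks = {
      utils::write.table(res$dhs_peaks, file.path(dir, "dhs_peaks.bed"),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
      )
      file.path(dir, "dhs_peaks.bed")
    },
    expression = write_expression_matrix(res$expression, file.path(dir, "expression.tsv")),
    regnet = write_edge_list(res$regnet, file.path(dir, "regnet.tsv")),
    humannet = write_edge_list(res$humannet, file.path(dir, "humannet.tsv")),
    interactnet = write_edge_list(res$interactnet, file.path(dir, "interactnet.tsv")),
    gwas = {
      readr::write_tsv(res$gwas, file.path(dir, "gwas.tsv"), progress = FALSE)
      file.path(dir, "gwas.tsv")
    },
    truth = {
      readr::write_tsv(bundle$truth, file.path(dir, "truth.tsv"), progress = FALSE)
      file.path(dir, "truth.tsv")
    },
    hotspots = {
      readr::write_tsv(res$hotspot_genes, file.path(dir, "hotspots.tsv"),
        progress = FALSE
      )
      file.path(dir, "hotspots.tsv")
    }
  )
  track_paths <- vapply(names(res$tracks), function(nm) {
    write_signal_track(res$tracks[[nm]], file.path(dir, paste0("track_", nm, ".bedgraph")))
  }, character(1))
  rep_paths <- vapply(names(res$reptiming), function(nm) {
    write_signal_track(res$reptiming[[nm]], file.path(dir, paste0("reptiming_", nm, ".bedgraph")))
  }, character(1))
  pc_path <- write_signal_track(res$phastcons, file.path(dir, "phastcons.bedgraph"))
  manifest <- tibble(
    artifact = c(
      names(paths), paste0("track_", names(track_paths)),
      paste0("reptiming_", names(rep_paths)), "phastcons"
    ),
    path = c(paths, track_paths, rep_paths, pc_path)
  )
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
  manifest
}

#' Simulate a labeled feature table directly
#'
#' Draws the 35-feature profile for `n_true` recurrent and `n_false`
#' non-recurrent mutations from per-feature latent Gaussians, where true
#' rows are shifted by the per-feature standardized effect sizes before a
#' monotone map onto each feature's natural scale (counts for the CGS
#' features, `{-1,0,1}` for Gain_or_Loss, positive distances for the GWAS
#' feature, `[0,1)` for the DEG scores, and so on). This samples the
#' feature-label association directly, bypassing the genome-level
#' machinery, and is the substrate for classifier calibration studies.
#'
#' @param n_true,n_false class sizes (defaults 114 and 342, the reference
#'   training-set geometry).
#' @param effect `"default"`, `"null"`, or a named numeric vector of
#'   standardized shifts over [feature_schema()] names.
#' @param n_samples sample ids are dealt uniformly over this many cohort
#'   samples (default 20).
#' @param seed RNG seed.
#' @return a labeled feature table: `chrom`, `pos`, `sample_id`, `label`,
#'   plus the 35 feature columns.
#' @export
simulate_feature_table <- function(n_true = 114, n_false = 342,
                                   effect = "default", n_samples = 20,
                                   seed = 1) {
  feats <- feature_schema()
  shifts <- feature_effect_sizes(effect)
  n <- n_true + n_false
  label <- rep(c(TRUE, FALSE), c(n_true, n_false))
  withr::with_seed(seed, {
    z <- matrix(stats::rnorm(n * length(feats)),
      nrow = n,
      dimnames = list(NULL, feats)
    )
    z <- z + outer(as.numeric(label), shifts[feats])
    vals <- vapply(feats, function(f) feature_transform(f, z[, f]), numeric(n))
    sample_id <- sprintf("S%03d", sample.int(n_samples, n, replace = TRUE))
  })
  dplyr::bind_cols(
    tibble(
      chrom = "chr1", pos = seq_len(n) * 100L,
      sample_id = sample_id, label = label
    ),
    as_tibble(vals)
  )
}

# default standardized effect sizes per feature: the strongest signal on
# chromatin accessibility, network and expression scores of the target
# gene, and proximity to risk loci, echoing which feature families carry
# the association; conservation carries none
feature_effect_sizes <- function(effect) {
  feats <- feature_schema()
  if (is.character(effect) && length(effect) == 1) {
    if (effect == "null") {
      return(stats::setNames(rep(0, length(feats)), feats))
    }
    s <- stats::setNames(rep(0.25, length(feats)), feats)
    s[c("cancer.DnaseSig", "origin.DnaseSig")] <- 0.8
    s[c(
      "target.InteractNet.CGS_L1", "target.InteractNet.CGS_L2",
      "target.RegNet.DEG_score", "target.DEG_score"
    )] <- 0.6
    s["genetic.Distance.to.GWAS"] <- -0.6 # true rows sit closer to risk loci
    s[c(
      "cancer.H3K27me3", "cancer.H3K9me3", "origin.H3K4me1",
      "origin.H3K36me3", "target.HumanNet.CGS_L1", "target.HumanNet.CGS_L2"
    )] <- 0.4
    s["tfbs.avg_Log_Pval_FIMO"] <- 0.4
    s[c("genetic.PhastCons", "tfbs.diff_Log_Pval_FIMO", "tfbs.Gain_or_Loss")] <- 0
    return(s)
  }
  missing <- setdiff(feats, names(effect))
  if (length(missing) > 0) {
    rlang::abort("effect vector must name every feature")
  }
  effect[feats]
}

# map a latent standard-normal value onto the feature's natural scale
feature_transform <- function(feature, z) {
  if (grepl("CGS_L[12]$", feature)) {
    return(pmax(0, round(2 + 1.5 * z)))
  }
  if (feature == "tfbs.Gain_or_Loss") {
    return(ifelse(z > 1.2, 1, ifelse(z < -1.2, -1, 0)))
  }
  if (feature == "genetic.Distance.to.GWAS") {
    return(round(exp(11 + z)))
  }
  if (grepl("DEG_score$", feature)) {
    return(stats::plogis(z) * 0.999)
  }
  if (feature == "genetic.PhastCons") {
    return(stats::plogis(2 * z - 2))
  }
  if (feature == "genetic.Early.to.late_Rate") {
    return(exp(0.5 * z))
  }
  if (feature == "tfbs.diff_Log_Pval_FIMO") {
    return(z)
  }
  if (feature == "tfbs.avg_Log_Pval_FIMO") {
    return(pmax(0, 2 + z))
  }
  exp(z) # signal tracks: lognormal
}
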