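#' Map mutations to target genes via enhancer-promoter pairs
#'
#' A mutation maps to the gene of an enhancer interval containing it
#' (0-based half-open intervals; a 1-based position `pos` is contained when
#' `start < pos <= end`). When several enhancers overlap, the pair with the
#' highest score wins; ties break by smallest interval, then lexicographic
#' gene id.
#'
#' @param mutations data frame with columns `chrom`, `pos`.
#' @param ep_pairs EP-pair tibble (see [read_ep_pairs()]).
#' @return character vector of gene ids, `NA` where no enhancer covers the
#'   mutation.
#' @export
map_by_ep <- function(mutations, ep_pairs) {
  assert_cols(mutations, c("chrom", "pos"), "mutations")
  pick_containing(
    mutations, ep_pairs,
    order_cols = function(d) {
      order(-d$score, d$end - d$start, d$gene)
    }
  )
}

#' Map mutations to target genes via the DHS-correlation map
#'
#' Among map entries whose distal DHS contains the mutation, the gene with
#' the largest maximum cross-cell-type DHS correlation wins; ties break by
#' lexicographic gene id.
#'
#' @param mutations data frame with columns `chrom`, `pos`.
#' @param dhs_map DHS-correlation tibble (see [read_dhs_map()]).
#' @return character vector of gene ids, `NA` where no entry covers the
#'   mutation.
#' @export
map_by_dhs_corr <- function(mutations, dhs_map) {
  assert_cols(mutations, c("chrom", "pos"), "mutations")
  pick_containing(
    mutations, dhs_map,
    order_cols = function(d) order(-d$max_corr, d$gene)
  )
}

# shared containment + tie-break: returns gene per mutation (NA if none)
pick_containing <- function(mutations, intervals, order_cols) {
  out <- rep(NA_character_, nrow(mutations))
  if (nrow(intervals) == 0) return(out)
  by_chrom <- split(seq_len(nrow(intervals)), intervals$chrom)
  for (i in seq_len(nrow(mutations))) {
    rows <- by_chrom[[mutations$chrom[i]]]
    if (is.null(rows)) next
    d <- intervals[rows, , drop = FALSE]
    hit <- d$start < mutations$pos[i] & mutations$pos[i] <= d$end
    if (!any(hit)) next
    d <- d[hit, , drop = FALSE]
    out[i] <- d$gene[order_cols(d)[1]]
  }
  out
}

#' Assign target genes to candidate mutations
#'
#' Enhancer-promoter mapping is attempted first; mutations not covered by
#' any EP pair fall back to the DHS-correlation map. Mutations mapping to no
#' gene are excluded — the pipeline analyses regulatory mutations only — and
#' the exclusion count is reported. For downstream binding-site rescanning
#' each assignment also carries a scan region `dhs_start`/`dhs_end`: the DHS
#' peak containing the mutation when `dhs_peaks` is given, otherwise the
#' matched enhancer/DHS interval itself.
#'
#' @param mutations data frame of candidate mutations (columns `chrom`,
#'   `pos`, others carried through).
#' @param ep_pairs EP-pair tibble.
#' @param dhs_map DHS-correlation tibble.
#' @param dhs_peaks optional BED tibble of DHS peaks (`chrom`, `start`,
#'   `end`).
#' @return a tibble of the mapped mutations with added columns `gene_id`,
#'   `source` (`"EP"` or `"DHS_CORR"`), `dhs_start`, `dhs_end` (0-based
#'   half-open). Errors if nothing maps.
#' @export
assign_targets <- function(mutations, ep_pairs, dhs_map, dhs_peaks = NULL) {
  assert_cols(mutations, c("chrom", "pos"), "mutations")
  mutations <- as_tibble(mutations)
  ep_gene <- map_by_ep(mutations, ep_pairs)
  dhs_gene <- map_by_dhs_corr(mutations, dhs_map)
  gene <- ifelse(is.na(ep_gene), dhs_gene, ep_gene)
  source <- ifelse(is.na(ep_gene),
    ifelse(is.na(dhs_gene), NA_character_, "DHS_CORR"), "EP"
  )
  n_excluded <- sum(is.na(gene))
  rlang::inform(sprintf(
    "assign_targets: %d of %d mutation(s) mapped to a gene (%d excluded)",
    sum(!is.na(gene)), length(gene), n_excluded
  ))
  keep <- !is.na(gene)
  if (!any(keep)) rlang::abort("no regulatory mutations: nothing mapped to a gene")
  out <- mutations[keep, , drop = FALSE]
  out$gene_id <- gene[keep]
  out$source <- source[keep]

  # scan region: containing DHS peak, else the matched regulatory interval
  reg <- scan_region_for(out, ep_pairs, dhs_map)
  if (!is.null(dhs_peaks) && nrow(dhs_peaks) > 0) {
    for (i in seq_len(nrow(out))) {
      hit <- dhs_peaks$chrom == out$chrom[i] &
        dhs_peaks$start < out$pos[i] & out$pos[i] <= dhs_peaks$end
      if (any(hit)) {
        j <- which(hit)[1]
        reg$start[i] <- dhs_peaks$start[j]
        reg$end[i] <- dhs_peaks$end[j]
      }
    }
  }
  out$dhs_start <- reg$start
  out$dhs_end <- reg$end
  attr(out, "n_excluded") <- n_excluded
  out
}

# the interval that produced each assignment (per its source map)
scan_region_for <- function(assigned, ep_pairs, dhs_map) {
  start <- numeric(nrow(assigned))
  end <- numeric(nrow(assigned))
  for (i in seq_len(nrow(assigned))) {
    src <- if (assigned$source[i] == "EP") ep_pairs else dhs_map
    hit <- src$chrom == assigned$chrom[i] &
      src$start < assigned$pos[i] & assigned$pos[i] <= src$end &
      src$gene == assigned$gene_id[i]
    j <- which(hit)[1]
    start[i] <- src$start[j]
    end[i] <- src$end[j]
  }
  list(start = start, end = end)
}
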