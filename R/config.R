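#' Pipeline configuration defaults
#'
#' Returns the flat list of tunable parameters used across the pipeline.
#' Values supplied in `...` override the defaults; unknown names error.
#'
#' @param ... named overrides of any default below.
#'
#' @details Defaults:
#' \describe{
#'   \item{w}{recurrence window size in bp (10).}
#'   \item{B}{background window size in bp (1e4).}
#'   \item{p_cutoff}{recurrence significance cutoff (5e-6).}
#'   \item{raw_cutoff}{raw recurrence count cutoff (4).}
#'   \item{false_ratio}{false:true training-set size ratio (3).}
#'   \item{motif_alpha}{motif match p-value threshold (1e-4).}
#'   \item{motif_bin}{log-ratio quantization bin for the scanner null (1e-3).}
#'   \item{gwas_sentinel}{distance reported when a chromosome has no
#'     catalog SNP (2.5e8 bp).}
#'   \item{elr_cap}{early-to-late ratio cap when S4+G2 = 0 (100).}
#'   \item{deg_welch}{use Welch instead of pooled-variance t-test (FALSE).}
#'   \item{cgs_cumulative}{count cancer genes at distance <= level rather
#'     than exactly level (FALSE).}
#'   \item{signal_halfwidth}{half-width in bp for averaging track signal
#'     around the site; 0 = single-base lookup (0).}
#'   \item{exclude_core_from_background}{drop the recurrence window's
#'     mutations and width from the background estimate (FALSE).}
#'   \item{strip_chr_prefix}{strip a leading "chr" from chromosome names on
#'     read (FALSE).}
#'   \item{n_trees}{random forest size (1000).}
#' }
#'
#' @return a named list of parameters.
#' @export
#' @examples
#' cfg <- regrecur_config(w = 20, p_cutoff = 3e-6)
#' cfg$w
regrecur_config <- function(...) {
  cfg <- list(
    w = 10,
    B = 1e4,
    p_cutoff = 5e-6,
    raw_cutoff = 4,
    false_ratio = 3,
    motif_alpha = 1e-4,
    motif_bin = 1e-3,
    gwas_sentinel = 2.5e8,
    elr_cap = 100,
    deg_welch = FALSE,
    cgs_cumulative = FALSE,
    signal_halfwidth = 0,
    exclude_core_from_background = FALSE,
    strip_chr_prefix = FALSE,
    n_trees = 1000
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0 || is.null(names(over)) || any(names(over) == "")) {
      rlang::abort(paste0(
        "unknown configuration key(s): ",
        paste(bad, collapse = ", ")
      ))
    }
    cfg[names(over)] <- over
  }
  cfg
}
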