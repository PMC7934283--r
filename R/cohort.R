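# Cohort-level descriptions: binned distributions of maxLen, pair count and
# complementary ratio, plus Pearson correlations of pair count and maxLen
# against circRNA length.

#' Histogram with explicit under-/overflow bins
#'
#' Left-closed, right-open bins on the given edges; the last bin is closed
#' on both sides. Values below the first edge or above the last are counted
#' in explicit underflow/overflow bins, so counts always conserve mass.
#'
#' @param values Numeric vector (finite).
#' @param edges Strictly increasing numeric bin edges (>= 2).
#' @return List with `edges`, `counts` (length `length(edges) - 1`),
#'   `underflow`, `overflow`.
#' @examples
#' bin_histogram(c(10, 10, 15, 25), c(10, 15, 20, 25))  # counts 2, 1, 1
#' @export
bin_histogram <- function(values, edges) {
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE))
    stop("`edges` must be at least two strictly increasing numbers")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  counts <- tabulate(idx[idx >= 1L & idx <= nb], nbins = nb)
  list(edges = edges, counts = counts,
       underflow = sum(idx == 0L),
       overflow = sum(idx > nb))
}

#' Pearson correlation with two-sided p-value
#'
#' Standard Pearson product-moment correlation; the p-value comes from the
#' t-distribution with n - 2 degrees of freedom (two-sided). Constant input
#' is rejected rather than returning NaN.
#'
#' @param x,y Equal-length numeric vectors, n >= 3, both non-constant.
#' @return List with `r`, `p`, `n`.
#' @examples
#' pearson_corr(c(1, 2, 3), c(2, 4, 6))  # r = 1
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) stop("need n >= 3 for a correlation")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("`x` and `y` must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant input")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Cohort-level ICBPS summary
#'
#' Assembles the standard cohort panels from per-circRNA profiles: binned
#' distributions of maxLen (restricted to circRNAs with maxLen >= 10 nt),
#' pair count and complementary ratio; Pearson correlations of pair count
#' vs circRNA length (restricted to circ_len <= `len_cap`) and of maxLen vs
#' circRNA length (unrestricted); and the fraction of circRNAs carrying at
#' least one pair. Correlations are computed on the circRNAs that carry
#' pairs (set `with_pairs_only = FALSE` to use all profiles) and are skipped
#' with a warning when fewer than 3 points remain.
#'
#' @param profiles Profile data frame (rows from [build_profile]).
#' @param max_len_edges,n_pairs_edges,cr_edges Histogram bin edges.
#' @param len_cap Length cap in nt for the pair-count correlation
#'   (default 10,000).
#' @param with_pairs_only Restrict correlations to circRNAs with
#'   `n_pairs >= 1` (default TRUE).
#' @return An object of class `icbps_cohort_summary`: histograms,
#'   correlations (`NULL` where refused), `fraction_with_pairs` (percent)
#'   and the subset sizes used.
#' @export
summarize_cohort <- function(profiles,
                             max_len_edges = seq(10, 200, by = 5),
                             n_pairs_edges = c(1, 2, 5, 10, 20, 50),
                             cr_edges = seq(0, 100, by = 5),
                             len_cap = 10000L,
                             with_pairs_only = TRUE) {
  if (!is.data.frame(profiles) || nrow(profiles) == 0L)
    stop("`profiles` must be a non-empty data frame")
  hml <- bin_histogram(profiles$max_len[profiles$max_len >= 10], max_len_edges)
  hnp <- bin_histogram(profiles$n_pairs[profiles$n_pairs >= 1], n_pairs_edges)
  hcr <- bin_histogram(profiles$cr_percent, cr_edges)
  sub <- if (with_pairs_only) profiles[profiles$n_pairs >= 1L, , drop = FALSE]
         else profiles
  corr_of <- function(px, py, what) {
    if (nrow(px) < 3L) {
      warning("fewer than 3 circRNAs for the ", what,
              " correlation; skipped")
      return(NULL)
    }
    tryCatch(pearson_corr(px[[py[1L]]], px[[py[2L]]]),
             error = function(e) {
               warning(what, " correlation skipped: ", conditionMessage(e))
               NULL
             })
  }
  len_sub <- sub[sub$circ_len <= len_cap, , drop = FALSE]
  structure(list(
    n_profiles = nrow(profiles),
    hist_max_len = hml,
    hist_n_pairs = hnp,
    hist_cr = hcr,
    corr_n_pairs_len = corr_of(len_sub, c("n_pairs", "circ_len"),
                               "pair-count vs length"),
    corr_max_len_len = corr_of(sub, c("max_len", "circ_len"),
                               "maxLen vs length"),
    n_corr_n_pairs = nrow(len_sub),
    n_corr_max_len = nrow(sub),
    fraction_with_pairs = fraction_percent(sum(profiles$n_pairs >= 1L),
                                           nrow(profiles)),
    n_el_circ = sum(profiles$is_el_circ),
    len_cap = len_cap,
    with_pairs_only = with_pairs_only
  ), class = "icbps_cohort_summary")
}

#' @export
print.icbps_cohort_summary <- function(x, ...) {
  cat(sprintf("ICBPS cohort summary: %d circRNAs (%d el-circRNAs > 5,000 nt)\n",
              x$n_profiles, x$n_el_circ))
  cat(sprintf("  with >= 1 reported pair: %.2f%%\n", x$fraction_with_pairs))
  fmt_corr <- function(cc, nm) {
    if (is.null(cc)) cat(sprintf("  %s: not computed\n", nm))
    else cat(sprintf("  %s: r = %.3f, p = %.3g, n = %d\n", nm, cc$r, cc$p,
                     cc$n))
  }
  fmt_corr(x$corr_n_pairs_len,
           sprintf("pair count vs circ_len (<= %d nt)", x$len_cap))
  fmt_corr(x$corr_max_len_len, "maxLen vs circ_len")
  invisible(x)
}
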