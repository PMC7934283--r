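# Per-circRNA ICBPS summary statistics. The complementary ratio (CR) is the
# fraction of the circle occupied by the longest internal duplex:
# CR = 2 * maxLen / circLen * 100%. circRNAs longer than 5,000 nt are
# flagged as extremely long (el-circRNAs).

#' Complementary ratio
#'
#' CR = 2 * `max_len` / `circ_len` * 100, the percentage of a circRNA's
#' length occupied by its longest internal complementary duplex (both arms).
#'
#' @param max_len Length in nt of the longest ICBPS arm (0 if none).
#' @param circ_len Total circRNA length in nt.
#' @return CR in percent (0-100), full precision; round to 2 decimals for
#'   reporting. Vectorized.
#' @examples
#' round(complementary_ratio(123, 6071), 2)  # 4.05
#' complementary_ratio(0, 500)               # 0
#' complementary_ratio(250, 500)             # 100
#' @export
complementary_ratio <- function(max_len, circ_len) {
  if (any(circ_len < 1L)) stop("`circ_len` must be >= 1")
  if (any(max_len < 0L)) stop("`max_len` must be >= 0")
  if (any(max_len > circ_len / 2))
    stop("`max_len` exceeds circ_len/2: two disjoint arms cannot fit")
  2 * max_len / circ_len * 100
}

# arm table of a pairs data frame: one row per arm (two per pair)
.arms_of <- function(pairs) {
  if (nrow(pairs) == 0L)
    return(data.frame(pair = integer(0L), start = integer(0L),
                      end = integer(0L)))
  data.frame(pair = rep(seq_len(nrow(pairs)), 2L),
             start = c(pairs$q_start, pairs$p_start),
             end = c(pairs$q_end, pairs$p_end))
}

#' Classify pairing-pattern topology of a circRNA's ICBPS set
#'
#' Two qualitative patterns beyond the simple two-arm duplex:
#' `multi_partner` -- one (shared) arm segment is complementary to two or
#' more distinct partner segments: some arm of one pair intersects an arm of
#' another pair while the two partner arms do not intersect each other.
#' `overlapping_complements` -- any two distinct pairs have intersecting
#' arms at all (complementary segments lying close together or overlapping
#' on the same chain).
#'
#' @param pairs Pairs data frame (see [find_icbps_pointer]), one circRNA.
#' @param circ_len Total circRNA length in nt (arm intervals are circular).
#' @return A list with logical elements `multi_partner` and
#'   `overlapping_complements`.
#' @export
classify_patterns <- function(pairs, circ_len) {
  n <- nrow(pairs)
  if (n <= 1L)
    return(list(multi_partner = FALSE, overlapping_complements = FALSE))
  multi <- FALSE
  overl <- FALSE
  arm <- function(i, side) {
    if (side == 1L) c(pairs$q_start[i], pairs$q_end[i])
    else c(pairs$p_start[i], pairs$p_end[i])
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    for (si in 1:2) for (sj in 1:2) {
      a <- arm(i, si); b <- arm(j, sj)
      if (circular_intersects(a[1L], a[2L], b[1L], b[2L], circ_len)) {
        overl <- TRUE
        pa <- arm(i, 3L - si); pb <- arm(j, 3L - sj)
        if (!circular_intersects(pa[1L], pa[2L], pb[1L], pb[2L], circ_len))
          multi <- TRUE
      }
    }
    if (multi) break
  }
  list(multi_partner = multi, overlapping_complements = overl)
}

#' Build a per-circRNA ICBPS profile
#'
#' Filters a circRNA's maximal pairs to arm length >= `threshold` and
#' summarises: pair count, maximum and median arm length, complementary
#' ratio, el-circRNA flag (circ_len > 5,000 nt, strict) and pairing-pattern
#' flags. The median of an even number of arm lengths is the mean of the two
#' central values.
#'
#' @param record A [circ_record] (or sequence string) the pairs came from.
#' @param pairs Pairs data frame from [find_icbps_pointer] /
#'   [find_icbps_bruteforce] on `record`.
#' @param threshold Reporting threshold in nt (default 20; cohort analyses
#'   conventionally profile pairs >= 20 nt out of candidates >= 10 nt).
#' @return One-row data frame: `circ_id`, `circ_len`, `n_pairs`, `max_len`,
#'   `median_len` (NA when no pair survives), `cr_percent` (full precision),
#'   `is_el_circ`, `multi_partner`, `overlapping_complements`.
#' @examples
#' rec <- circ_record("toy", strrep("ACGGT", 120))
#' build_profile(rec, empty_pairs(), threshold = 20)
#' @export
build_profile <- function(record, pairs, threshold = 20L) {
  rec <- as_circ_record(record)
  keep <- pairs[pairs$length >= threshold, , drop = FALSE]
  n_pairs <- nrow(keep)
  max_len <- if (n_pairs) max(keep$length) else 0L
  med_len <- if (n_pairs) stats::median(as.numeric(keep$length)) else NA_real_
  pat <- classify_patterns(keep, rec$circ_len)
  data.frame(circ_id = rec$id,
             circ_len = rec$circ_len,
             n_pairs = n_pairs,
             max_len = max_len,
             median_len = med_len,
             cr_percent = complementary_ratio(max_len, rec$circ_len),
             is_el_circ = rec$circ_len > 5000L,
             multi_partner = pat$multi_partner,
             overlapping_complements = pat$overlapping_complements,
             stringsAsFactors = FALSE)
}

#' Percentage of a count over a total
#'
#' Small reporting helper used by the cohort summaries: `100 * k / n`,
#' rounded.
#'
#' @param k Count (numerator).
#' @param n Total (denominator, > 0).
#' @param digits Decimals to round to (default 2).
#' @return Percentage on the 0-100 scale.
#' @examples
#' fraction_percent(6155, 140790)  # 4.37
#' @export
fraction_percent <- function(k, n, digits = 2L) {
  if (any(n <= 0)) stop("`n` must be positive")
  round(100 * k / n, digits)
}
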