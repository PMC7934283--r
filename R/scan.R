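# ICBPS scanner. An ICBPS pair is two disjoint segments ("arms") of one
# circRNA whose sequences are exact antiparallel Watson-Crick reverse
# complements (no G.U wobble, no mismatches). The scanner reports every
# MAXIMAL pair: a pair that cannot be extended at either end in its pairing
# register without breaking the match or the disjointness of the arms.
#
# Algorithm: for every anchor position the min_len window (pointer pair:
# window start and end) is looked up in a hash of reverse-complement k-mers;
# every disjoint occurrence fixes a pairing register, and the window is then
# grown to its maximal extent in that register, first rightwards then
# leftwards, subject to exact complementarity and arm disjointness. Duplicate
# discoveries of the same maximal pair (one per anchor inside its arms) are
# collapsed. In wrap mode the same machinery runs on the tripled sequence
# with circular disjointness, so arms may cross the backsplice junction;
# coordinates are mapped back onto the circle and rotational duplicates
# removed.

#' Scanner configuration
#'
#' @param min_len Minimum arm length in nt (default 10, the candidate
#'   threshold; cohort analyses conventionally report pairs >= 20 nt).
#' @param wrap Logical; if `TRUE` arms may cross the backsplice junction
#'   (scan on the circle), if `FALSE` (default) the scan is linear on the
#'   given linearization.
#' @param max_pairs Abort with an error if more candidate pairs than this are
#'   found in one record (guards against pathological self-complementary
#'   repeats such as long AT microsatellites).
#' @return An object of class `scan_config`.
#' @examples
#' scan_config(min_len = 20)
#' @export
scan_config <- function(min_len = 10L, wrap = FALSE, max_pairs = 10000L) {
  min_len <- as.integer(min_len)
  max_pairs <- as.integer(max_pairs)
  if (is.na(min_len) || min_len < 2L)
    stop("`min_len` must be an integer >= 2")
  if (!is.logical(wrap) || length(wrap) != 1L || is.na(wrap))
    stop("`wrap` must be TRUE or FALSE")
  if (is.na(max_pairs) || max_pairs < 1L)
    stop("`max_pairs` must be a positive integer")
  structure(list(min_len = min_len, wrap = wrap, max_pairs = max_pairs),
            class = "scan_config")
}

#' Empty ICBPS pairs table
#'
#' The shared pairs schema with zero rows; coordinates are 1-based
#' inclusive and `q_end`/`p_end` may exceed the circRNA length for
#' junction-crossing arms.
#'
#' @return Zero-row pairs data frame.
#' @export
empty_pairs <- function() {
  data.frame(circ_id = character(0L),
             q_start = integer(0L), q_end = integer(0L),
             p_start = integer(0L), p_end = integer(0L),
             length = integer(0L),
             q_wraps = logical(0L), p_wraps = logical(0L),
             stringsAsFactors = FALSE)
}

# assemble, canonicalize (upstream arm first), dedupe and sort raw matches;
# qs/ps are 1-based arm starts on the circle, L arm lengths
.pairs_df <- function(id, qs, ps, L, n) {
  if (length(qs) == 0L) return(empty_pairs())
  swap <- ps < qs
  tmp <- qs[swap]; qs[swap] <- ps[swap]; ps[swap] <- tmp
  keep <- !duplicated(paste(qs, ps, L, sep = ":"))
  qs <- qs[keep]; ps <- ps[keep]; L <- L[keep]
  ord <- order(qs, ps)
  qs <- qs[ord]; ps <- ps[ord]; L <- L[ord]
  data.frame(circ_id = rep(id, length(qs)),
             q_start = qs, q_end = qs + L - 1L,
             p_start = ps, p_end = ps + L - 1L,
             length = L,
             q_wraps = qs + L - 1L > n,
             p_wraps = ps + L - 1L > n,
             stringsAsFactors = FALSE)
}

# hash from k-mer string to integer positions
.kmer_index <- function(kmers, positions) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(kmers)) {
    key <- kmers[i]
    env[[key]] <- c(env[[key]], positions[i])
  }
  env
}

#' Find all maximal ICBPS pairs (pointer scan)
#'
#' Detects every maximal internal complementary base-pairing sequence pair
#' in one circRNA: two disjoint arms, each the exact reverse complement of
#' the other, of length at least `min_len`. Pairs are reported once, in
#' canonical orientation (upstream arm first), sorted by arm starts.
#' Positions holding N never participate in a pair.
#'
#' @param record A [circ_record], or a single (optionally named) sequence
#'   string.
#' @param config A [scan_config].
#' @return A data frame with one row per maximal pair: `circ_id`, `q_start`,
#'   `q_end`, `p_start`, `p_end`, `length`, `q_wraps`, `p_wraps`.
#'   Coordinates are 1-based inclusive; for junction-crossing arms (wrap
#'   mode) the end exceeds the circRNA length and the wrap flag is set.
#'   Records shorter than `2 * min_len` yield an empty table.
#' @examples
#' s <- paste0(strrep("A", 20), "GATTACAGATTACA",
#'             strrep("A", 20), reverse_complement("GATTACAGATTACA"))
#' find_icbps_pointer(c(demo = s), scan_config(min_len = 10))
#' @seealso [find_icbps_bruteforce] for the independent quadratic oracle.
#' @export
find_icbps_pointer <- function(record, config = scan_config()) {
  rec <- as_circ_record(record)
  k <- config$min_len
  n <- rec$circ_len
  if (n < 2L * k) return(empty_pairs())
  if (config$wrap) .scan_wrap(rec, k, config$max_pairs)
  else .scan_linear(rec, k, config$max_pairs)
}

.scan_linear <- function(rec, k, max_pairs) {
  s <- rec$sequence
  n <- rec$circ_len
  enc <- .encode(s)
  pairc <- .PAIR_CODE[enc]            # code each position pairs with (0 = N)
  starts <- 1L:(n - k + 1L)
  kmers <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  idx <- .kmer_index(kmers[ok], starts[ok])
  rck <- .rc_kmers(kmers, k)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  qs <- integer(0L); ps <- integer(0L); Ls <- integer(0L)
  npairs <- 0L
  for (a in starts[ok]) {
    partners <- idx[[rck[a]]]
    if (is.null(partners)) next
    for (p0 in partners) {
      if (abs(p0 - a) < k) next      # seed windows themselves must be disjoint
      q <- a; p <- p0; L <- k
      # grow query right / partner left in this register
      while (q + L <= n && p > 1L &&
             enc[p - 1L] == pairc[q + L] &&
             (q + L + 1L <= p - 1L || p + L <= q)) {
        p <- p - 1L; L <- L + 1L
      }
      # grow query left / partner right
      while (q > 1L && p + L <= n &&
             enc[p + L] == pairc[q - 1L] &&
             (q - 1L + L + 1L <= p || p + L + 1L <= q - 1L)) {
        q <- q - 1L; L <- L + 1L
      }
      key <- if (q < p) paste(q, p, L, sep = ":") else paste(p, q, L, sep = ":")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      npairs <- npairs + 1L
      if (npairs > max_pairs)
        stop(sprintf(paste0("record '%s': more than %d ICBPS pairs; the ",
                            "sequence is dominated by self-complementary ",
                            "repeats (raise `max_pairs` to force reporting)"),
                     rec$id, max_pairs))
      qs[npairs] <- q; ps[npairs] <- p; Ls[npairs] <- L
    }
  }
  .pairs_df(rec$id, qs, ps, Ls, n)
}

# circular disjointness of arms starting at 0-based circle positions a0/b0,
# both of length L: the forward distance between the starts must be >= L in
# both directions (this also implies 2 * L <= n)
.circ_disjoint <- function(a0, b0, L, n) {
  ((b0 - a0) %% n) >= L && ((a0 - b0) %% n) >= L
}

.scan_wrap <- function(rec, k, max_pairs) {
  s <- rec$sequence
  n <- rec$circ_len
  s3 <- paste0(s, s, s)
  enc <- .encode(s3)
  pairc <- .PAIR_CODE[enc]
  # one representative per circular k-mer occurrence, in the middle copy
  starts <- (n + 1L):(2L * n)
  kmers <- substring(s3, starts, starts + k - 1L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  idx <- .kmer_index(kmers[ok], starts[ok])
  rck <- .rc_kmers(kmers, k)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  qs <- integer(0L); ps <- integer(0L); Ls <- integer(0L)
  npairs <- 0L
  for (a in starts[ok]) {
    partners <- idx[[rck[a - n]]]
    if (is.null(partners)) next
    for (p0 in partners) {
      if (!.circ_disjoint((a - 1L) %% n, (p0 - 1L) %% n, k, n)) next
      q <- a; p <- p0; L <- k
      while (p > 1L && q + L <= 3L * n &&
             enc[p - 1L] == pairc[q + L] &&
             .circ_disjoint((q - 1L) %% n, (p - 2L) %% n, L + 1L, n)) {
        p <- p - 1L; L <- L + 1L
      }
      while (q > 1L && p + L <= 3L * n &&
             enc[p + L] == pairc[q - 1L] &&
             .circ_disjoint((q - 2L) %% n, (p - 1L) %% n, L + 1L, n)) {
        q <- q - 1L; L <- L + 1L
      }
      qc <- (q - 1L) %% n + 1L
      pc <- (p - 1L) %% n + 1L
      key <- if (qc < pc) paste(qc, pc, L, sep = ":")
             else paste(pc, qc, L, sep = ":")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      npairs <- npairs + 1L
      if (npairs > max_pairs)
        stop(sprintf(paste0("record '%s': more than %d ICBPS pairs; the ",
                            "sequence is dominated by self-complementary ",
                            "repeats (raise `max_pairs` to force reporting)"),
                     rec$id, max_pairs))
      qs[npairs] <- qc; ps[npairs] <- pc; Ls[npairs] <- L
    }
  }
  .pairs_df(rec$id, qs, ps, Ls, n)
}
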