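# Brute-force ICBPS oracle. Independent of the pointer scan: it materialises
# the full pairing matrix M[i, j] = "position j carries the base that pairs
# with position i" and decomposes it along anti-diagonals. All base pairings
# of one register (one pairing frame) lie on one anti-diagonal i + j = d, and
# the mirror map i -> d - i sends each maximal run of TRUE entries onto
# another run (or onto itself). A pair of distinct mirror runs is exactly one
# maximal ICBPS pair (arm = whole run); a self-mirrored run is a near-
# palindromic stretch whose maximal disjoint pair takes floor(run/2) from
# each end, the two arms abutting at the centre. This enumerates precisely
# the maximal pairs with disjoint arms, with same-register containments never
# produced. Quadratic in memory; intended for records up to ~2,000 nt.

#' Find all maximal ICBPS pairs (brute-force oracle)
#'
#' Exhaustive reference implementation with the same output contract as
#' [find_icbps_pointer]: every maximal pair of disjoint, exactly
#' reverse-complementary arms of length at least `min_len`, canonical
#' orientation, sorted. Quadratic cost; use for validation on records up to
#' roughly 2,000 nt.
#'
#' @inheritParams find_icbps_pointer
#' @return A data frame with the schema of [find_icbps_pointer].
#' @examples
#' s <- paste0("GATTACAGAT", reverse_complement("GATTACAGAT"))
#' find_icbps_bruteforce(c(toy = s), scan_config(min_len = 10))
#' @export
find_icbps_bruteforce <- function(record, config = scan_config()) {
  rec <- as_circ_record(record)
  k <- config$min_len
  n <- rec$circ_len
  if (n < 2L * k) return(empty_pairs())
  enc <- .encode(rec$sequence)
  pairc <- .PAIR_CODE[enc]
  M <- outer(pairc, enc, "==")       # M[i, j]: j pairs with i
  hits <- if (config$wrap) .oracle_wrap(M, n, k) else .oracle_linear(M, n, k)
  if (nrow(hits) > config$max_pairs)
    stop(sprintf(paste0("record '%s': more than %d ICBPS pairs; the ",
                        "sequence is dominated by self-complementary ",
                        "repeats (raise `max_pairs` to force reporting)"),
                 rec$id, config$max_pairs))
  .pairs_df(rec$id, hits$q + 1L, hits$p + 1L, hits$L, n)
}

# TRUE runs of a logical vector as (start, length), 0-based starts
.true_runs <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  list(start = starts[keep], len = r$lengths[keep])
}

.oracle_linear <- function(M, n, k) {
  q <- integer(0L); p <- integer(0L); L <- integer(0L); m <- 0L
  for (d in 0L:(2L * n - 2L)) {
    lo <- max(0L, d - n + 1L)
    hi <- min(d, n - 1L)
    if (hi - lo + 1L < 2L * k) next
    ii <- lo:hi
    v <- M[cbind(ii + 1L, d - ii + 1L)]
    runs <- .true_runs(v)
    for (r in seq_along(runs$start)) {
      a <- lo + runs$start[r]
      len <- runs$len[r]
      b <- a + len - 1L
      ma <- d - b                    # mirror run start
      if (ma == a) {                 # self-mirrored (near-palindromic) run
        arm <- len %/% 2L
        if (arm >= k) {
          m <- m + 1L; q[m] <- a; p[m] <- d - a - arm + 1L; L[m] <- arm
        }
      } else if (a < ma) {           # distinct mirror runs, process once
        if (len >= k) {
          m <- m + 1L; q[m] <- a; p[m] <- ma; L[m] <- len
        }
      }
    }
  }
  data.frame(q = q, p = p, L = L)
}

.oracle_wrap <- function(M, n, k) {
  q <- integer(0L); p <- integer(0L); L <- integer(0L); m <- 0L
  for (d in 0L:(n - 1L)) {
    ii <- 0L:(n - 1L)
    v <- M[cbind(ii + 1L, (d - ii) %% n + 1L)]
    if (all(v)) {
      # fully self-complementary register (e.g. an AT microsatellite): the
      # maximal pairs are the half-circle splits whose two residual gaps are
      # both < 2 nt (otherwise the pair could still be extended); enumerate
      # candidates and keep the geometrically valid ones
      for (arm in unique(c(n %/% 2L, (n - 1L) %/% 2L, n %/% 2L - 1L))) {
        if (arm < k) next
        for (a in ii) {
          pp <- (d - a - arm + 1L) %% n
          g1 <- (pp - a - arm) %% n
          g2 <- (a - pp - arm) %% n
          if (g1 <= 1L && g2 <= 1L && .circ_disjoint(a, pp, arm, n)) {
            m <- m + 1L; q[m] <- a; p[m] <- pp; L[m] <- arm
          }
        }
      }
      next
    }
    runs <- .true_runs(v)
    nr <- length(runs$start)
    if (nr == 0L) next
    # merge a run wrapping over the linearization point of the diagonal
    if (v[1L] && v[n]) {
      first <- which(runs$start == 0L)
      last <- which(runs$start + runs$len == n)
      runs$start[last] <- runs$start[last] - n   # negative start, wraps
      runs$len[last] <- runs$len[last] + runs$len[first]
      runs$start <- runs$start[-first]
      runs$len <- runs$len[-first]
    }
    for (r in seq_along(runs$start)) {
      a <- runs$start[r] %% n
      len <- runs$len[r]
      b0 <- runs$start[r] + len - 1L
      ma <- (d - b0) %% n            # mirror run start
      if (ma == a) {
        arm <- len %/% 2L
        if (arm >= k) {
          m <- m + 1L; q[m] <- a; p[m] <- (d - a - arm + 1L) %% n; L[m] <- arm
        }
      } else {
        if (len >= k) {              # emitted from both runs; deduped later
          m <- m + 1L; q[m] <- a; p[m] <- ma; L[m] <- len
        }
      }
    }
  }
  data.frame(q = q, p = p, L = L)
}
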