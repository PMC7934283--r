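# Synthetic circRNA cohorts with known ICBPS ground truth. Records are
# i.i.d. random-composition backbones into which reverse-complement arm
# pairs are planted: A/A' topology (one arm, one partner) or B/B'/B''
# (one arm complementary to several disjoint partners). A cleanliness step
# rejects records containing any complementary match beyond the planted
# truth, so scanner recall/precision can be measured exactly. Optional
# MRE/ORF-like intervals are planted to overlap a truth arm with a stated
# probability.

#' Planting specification for one arm family
#'
#' @param arm_len Arm length in nt (>= 10; shorter segments are below the
#'   candidate threshold and are not ICBPS).
#' @param n_partners 1 for the plain A/A' duplex topology, >= 2 to plant one
#'   arm with several disjoint reverse-complement partners (B/B'/B'').
#' @param separation Gap in nt between the arm and its partner (A/A' only);
#'   `NULL` (default) places partners at random disjoint positions.
#' @param allow_wrap Allow planted arms to cross the backsplice junction
#'   (default FALSE, matching the scanner's default linear mode).
#' @param per_record_prob Probability that a given record receives this
#'   planting (default 1).
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(arm_len, n_partners = 1L, separation = NULL,
                       allow_wrap = FALSE, per_record_prob = 1) {
  arm_len <- as.integer(arm_len)
  n_partners <- as.integer(n_partners)
  if (is.na(arm_len) || arm_len < 10L)
    stop("`arm_len` must be an integer >= 10")
  if (is.na(n_partners) || n_partners < 1L)
    stop("`n_partners` must be an integer >= 1")
  if (!is.null(separation)) {
    separation <- as.integer(separation)
    if (n_partners != 1L)
      stop("`separation` is only meaningful for n_partners = 1")
    if (is.na(separation) || separation < 1L)
      stop("`separation` must be a positive integer")
  }
  if (per_record_prob < 0 || per_record_prob > 1)
    stop("`per_record_prob` must be in [0, 1]")
  structure(list(arm_len = arm_len, n_partners = n_partners,
                 separation = separation, allow_wrap = isTRUE(allow_wrap),
                 per_record_prob = per_record_prob),
            class = "plant_spec")
}

#' Annotation planting plan
#'
#' @param overlap_prob Probability that a record's first MRE-like interval
#'   intersects a planted arm (the remaining MREs are placed clear of all
#'   arms so the realized overlap status is driven by this one interval).
#' @param n_mre Number of MRE-like intervals per record (default 1).
#' @param mre_len Length range in nt for MRE-like intervals (default 7-22).
#' @param n_orf Number of ORF-like intervals per record (default 0).
#' @param orf_len Length range in nt for ORF-like intervals; realized
#'   lengths are multiples of 3, >= 60 (default 60-300).
#' @param orf_overlap_prob As `overlap_prob`, for the first ORF (default 0).
#' @return An object of class `annotation_plan`.
#' @export
annotation_plan <- function(overlap_prob = 0.5, n_mre = 1L,
                            mre_len = c(7L, 22L), n_orf = 0L,
                            orf_len = c(60L, 300L), orf_overlap_prob = 0) {
  if (overlap_prob < 0 || overlap_prob > 1 ||
      orf_overlap_prob < 0 || orf_overlap_prob > 1)
    stop("overlap probabilities must be in [0, 1]")
  structure(list(overlap_prob = overlap_prob, n_mre = as.integer(n_mre),
                 mre_len = as.integer(mre_len), n_orf = as.integer(n_orf),
                 orf_len = as.integer(orf_len),
                 orf_overlap_prob = orf_overlap_prob),
            class = "annotation_plan")
}

#' Specification of a synthetic circRNA cohort
#'
#' @param n_records Number of circRNAs to generate.
#' @param circ_len Fixed length(s) in nt (recycled); overrides
#'   `length_range` when given.
#' @param length_range Range in nt from which lengths are drawn (log-uniform
#'   by default, mirroring the right-skewed length distribution of circRNA
#'   databases).
#' @param log_uniform Draw lengths log-uniformly (default TRUE).
#' @param el_circ_fraction Fraction of records forced to el-circRNA length
#'   (> 5,000 nt; drawn log-uniformly from 5,001 nt up to at least
#'   10,000 nt).
#' @param gc Background GC content (default 0.5; complementary-match base
#'   rates depend strongly on composition).
#' @param plantings List of [plant_spec] objects.
#' @param annotations An [annotation_plan], or `NULL` for none.
#' @param seed Integer RNG seed; the cohort is a deterministic function of
#'   the spec.
#' @param clean Cleanliness check: `"oracle"` (exact, records <= 2,000 nt),
#'   `"screen"` (shared reverse-complement k-mer screen, conservative for
#'   exact matches >= k, any length), `"auto"` (oracle up to 2,000 nt, then
#'   screen; default) or `"none"`.
#' @param clean_min_len Match length k above which a record is rejected as
#'   unclean (default 10, the candidate threshold).
#' @param max_tries Resampling attempts per record before giving up.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_records, circ_len = NULL,
                           length_range = c(200L, 2000L), log_uniform = TRUE,
                           el_circ_fraction = 0, gc = 0.5,
                           plantings = list(), annotations = NULL,
                           seed = 1L,
                           clean = c("auto", "oracle", "screen", "none"),
                           clean_min_len = 10L, max_tries = 50L) {
  n_records <- as.integer(n_records)
  if (is.na(n_records) || n_records < 0L)
    stop("`n_records` must be a non-negative integer")
  if (gc <= 0 || gc >= 1) stop("`gc` must be in (0, 1)")
  if (el_circ_fraction < 0 || el_circ_fraction > 1)
    stop("`el_circ_fraction` must be in [0, 1]")
  if (!is.null(circ_len)) circ_len <- as.integer(circ_len)
  if (inherits(plantings, "plant_spec")) plantings <- list(plantings)
  if (!all(vapply(plantings, inherits, logical(1L), "plant_spec")))
    stop("`plantings` must be a list of plant_spec objects")
  if (!is.null(annotations) && !inherits(annotations, "annotation_plan"))
    stop("`annotations` must be an annotation_plan or NULL")
  structure(list(n_records = n_records, circ_len = circ_len,
                 length_range = as.integer(length_range),
                 log_uniform = isTRUE(log_uniform),
                 el_circ_fraction = el_circ_fraction, gc = gc,
                 plantings = plantings, annotations = annotations,
                 seed = as.integer(seed), clean = match.arg(clean),
                 clean_min_len = as.integer(clean_min_len),
                 max_tries = as.integer(max_tries)),
            class = "synthetic_spec")
}

.rand_bases <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# does S contain a duplicated k-mer or a k-mer whose reverse complement
# also occurs in S? either would let planted copies interact
.arm_unsafe <- function(S, k) {
  l <- nchar(S)
  if (l < k) return(FALSE)
  km <- substring(S, 1L:(l - k + 1L), k:l)
  any(duplicated(km)) || any(.rc_kmers(km, k) %in% km)
}

.rand_arm <- function(arm_len, gc, k, tries = 200L) {
  for (i in seq_len(tries)) {
    S <- paste(.rand_bases(arm_len, gc), collapse = "")
    if (!.arm_unsafe(S, k)) return(S)
  }
  stop("could not draw an arm sequence free of internal k-mer structure")
}

# sample `m` non-overlapping interval starts of length `len` on 1..n
# (linear; with wrap the last `len - 1` start positions are also allowed),
# avoiding `occupied` (two-column matrix of start/end, end may exceed n)
.place_arms <- function(n, len, m, occupied, wrap = FALSE,
                        tries = 300L) {
  hi <- if (wrap) n else n - len + 1L
  if (hi < 1L) return(NULL)
  for (t in seq_len(tries)) {
    starts <- sort(sample.int(hi, m))
    ends <- starts + len - 1L
    cand <- rbind(occupied, cbind(starts, ends))
    ok <- TRUE
    if (nrow(cand) > 1L) {
      for (i in 1L:(nrow(cand) - 1L)) for (j in (i + 1L):nrow(cand)) {
        if (circular_intersects(cand[i, 1L], cand[i, 2L],
                                cand[j, 1L], cand[j, 2L], n)) ok <- FALSE
      }
    }
    if (ok) return(starts)
  }
  # deterministic fallback: tile free positions left to right (linear only)
  if (!wrap && m * len + sum(pmin(occupied[, 2L], n) - occupied[, 1L] + 1L)
      <= n) {
    starts <- integer(0L); s <- 1L
    while (length(starts) < m && s + len - 1L <= n) {
      e <- s + len - 1L
      clash <- nrow(occupied) > 0L &&
        any(circular_intersects(s, e, occupied[, 1L], occupied[, 2L], n))
      if (!clash) { starts <- c(starts, s); s <- e + 1L }
      else s <- s + 1L
    }
    if (length(starts) == m) return(starts)
  }
  NULL
}

# write `content` into chars at 1-based circular position `start`
.write_at <- function(chars, start, content, n) {
  cc <- strsplit(content, "", fixed = TRUE)[[1L]]
  pos <- ((start - 1L + seq_along(cc) - 1L) %% n) + 1L
  chars[pos] <- cc
  chars
}

#' Plant one arm with one or more reverse-complement partners
#'
#' Overwrites disjoint stretches of `record` with a random arm sequence S
#' and `n_partners` copies of its reverse complement, producing
#' `n_partners` ground-truth ICBPS pairs that share the S arm (A/A'
#' topology for one partner, B/B'/B'' for several). Uses the current RNG
#' state.
#'
#' @param record A [circ_record] or sequence string.
#' @param arm_len Arm length in nt (>= 10).
#' @param n_partners Number of partner copies (>= 1).
#' @param separation Optional exact gap in nt between arm and partner
#'   (single-partner only).
#' @param allow_wrap Allow planted arms to cross the junction.
#' @param gc Base composition used when drawing the arm sequence.
#' @param clean_min_len k-mer scale on which the arm itself is kept free of
#'   internal repeat/self-complement structure.
#' @param occupied Optional two-column matrix of already-occupied intervals
#'   (1-based inclusive) that the new arms must not touch; used when
#'   planting several arm families into one record.
#' @return List with `record` (mutated [circ_record]) and `truth` (pairs
#'   data frame with an extra `topology` column, `"A"` or `"B"`).
#' @examples
#' set.seed(1)
#' plant_multi_partner(circ_record("x", strrep("ACGGTTA", 72)), 20, 2)$truth
#' @export
plant_multi_partner <- function(record, arm_len, n_partners = 1L,
                                separation = NULL, allow_wrap = FALSE,
                                gc = 0.5, clean_min_len = 10L,
                                occupied = NULL) {
  rec <- as_circ_record(record)
  n <- rec$circ_len
  arm_len <- as.integer(arm_len)
  n_partners <- as.integer(n_partners)
  if (is.null(occupied)) occupied <- matrix(integer(0L), 0L, 2L)
  if ((n_partners + 1L) * arm_len > n)
    stop(sprintf("cannot fit %d disjoint arms of %d nt in %d nt",
                 n_partners + 1L, arm_len, n))
  S <- .rand_arm(arm_len, gc, clean_min_len)
  chars <- strsplit(rec$sequence, "", fixed = TRUE)[[1L]]
  if (!is.null(separation)) {
    separation <- as.integer(separation)
    if (2L * arm_len + separation > n)
      stop("record too short for the requested separation")
    hi <- n - (2L * arm_len + separation) + 1L
    starts <- NULL
    for (t in 1:300) {
      q <- sample.int(hi, 1L)
      cand <- c(q, q + arm_len + separation)
      clash <- nrow(occupied) > 0L &&
        any(circular_intersects(rep(cand, each = nrow(occupied)),
                                rep(cand + arm_len - 1L,
                                    each = nrow(occupied)),
                                rep(occupied[, 1L], 2L),
                                rep(occupied[, 2L], 2L), n))
      if (!clash) { starts <- cand; break }
    }
    if (is.null(starts))
      stop("could not place the separated arm pair clear of occupied ",
           "intervals")
  } else {
    starts <- .place_arms(n, arm_len, n_partners + 1L, occupied,
                          wrap = allow_wrap)
    if (is.null(starts))
      stop("could not place the requested arms disjointly")
    # the shared arm takes a random one of the placed slots
    starts <- sample(starts)
  }
  arm_start <- starts[1L]
  partner_starts <- starts[-1L]
  chars <- .write_at(chars, arm_start, S, n)
  rcS <- reverse_complement(S)
  for (ps in partner_starts) chars <- .write_at(chars, ps, rcS, n)
  truth <- do.call(rbind, lapply(partner_starts, function(ps) {
    a <- sort(c(arm_start, ps))
    data.frame(circ_id = rec$id,
               q_start = a[1L], q_end = a[1L] + arm_len - 1L,
               p_start = a[2L], p_end = a[2L] + arm_len - 1L,
               length = arm_len,
               q_wraps = a[1L] + arm_len - 1L > n,
               p_wraps = a[2L] + arm_len - 1L > n,
               topology = if (n_partners >= 2L) "B" else "A",
               stringsAsFactors = FALSE)
  }))
  truth <- truth[order(truth$q_start, truth$p_start), , drop = FALSE]
  rownames(truth) <- NULL
  list(record = circ_record(rec$id, paste(chars, collapse = "")),
       truth = truth)
}

# conservative cleanliness screen: every shared k-mer between the sequence
# and its reverse complement must be explained by a truth pair (window
# inside one arm, partner window inside the other arm, same register)
.screen_clean <- function(seq, truth, k, n, wrap = FALSE) {
  s <- if (wrap) paste0(seq, substr(seq, 1L, k - 1L)) else seq
  last <- nchar(s) - k + 1L
  if (last < 1L) return(TRUE)
  starts <- 1L:last
  kmers <- substring(s, starts, starts + k - 1L)
  idx <- .kmer_index(kmers, starts)
  rck <- .rc_kmers(kmers, k)
  reg <- truth$q_start + truth$p_start + truth$length
  contained <- function(x, lo, hi) x >= lo & x + k - 1L <= hi
  for (a in starts) {
    partners <- idx[[rck[a]]]
    for (p in partners) {
      if (p <= a || p - a < k) next
      expl <- (contained(a, truth$q_start, truth$q_end) &
                 contained(p, truth$p_start, truth$p_end) &
                 a + p + k == reg) |
              (contained(a, truth$p_start, truth$p_end) &
                 contained(p, truth$q_start, truth$q_end) &
                 a + p + k == reg)
      if (!any(expl)) return(FALSE)
    }
  }
  TRUE
}

.truth_key <- function(df) paste(df$q_start, df$p_start, df$length, sep = ":")

.record_clean <- function(rec, truth, spec) {
  k <- spec$clean_min_len
  wrap <- nrow(truth) > 0L && any(truth$q_wraps | truth$p_wraps)
  mode <- spec$clean
  if (mode == "none") return(TRUE)
  if (mode == "auto") mode <- if (rec$circ_len <= 2000L) "oracle" else "screen"
  if (mode == "oracle") {
    found <- find_icbps_bruteforce(rec, scan_config(k, wrap = wrap,
                                                    max_pairs = 10000L))
    setequal(.truth_key(found), .truth_key(truth)) &&
      nrow(found) == nrow(truth)
  } else {
    # screen is exact-match conservative but only supports linear plantings
    if (wrap) stop("the k-mer cleanliness screen requires linear plantings")
    # the screen checks that observed matches are explained; additionally
    # verify every truth duplex is intact in the sequence
    for (i in seq_len(nrow(truth))) {
      a1 <- substr(rec$sequence, truth$q_start[i], truth$q_end[i])
      a2 <- substr(rec$sequence, truth$p_start[i], truth$p_end[i])
      if (!identical(a2, reverse_complement(a1))) return(FALSE)
    }
    .screen_clean(rec$sequence, truth, k, rec$circ_len)
  }
}

.empty_truth <- function() {
  cbind(empty_pairs(), data.frame(topology = character(0L),
                                  stringsAsFactors = FALSE))
}

#' Generate a synthetic circRNA cohort with known ICBPS ground truth
#'
#' Deterministic given the spec's seed. Each record is resampled until the
#' cleanliness check confirms that the only complementary matches of length
#' >= `clean_min_len` are the planted ones, so the truth table is exhaustive
#' and scanner recall/precision against it are exact.
#'
#' @param spec A [synthetic_spec].
#' @return List of class `icbps_cohort_sim`: `records` (named character
#'   vector of sequences), `truth` (pairs data frame with `topology`),
#'   `annotations` (data frame with realized `overlaps_arm` status, or
#'   `NULL`), and `spec`.
#' @examples
#' spec <- synthetic_spec(2, circ_len = 300,
#'                        plantings = list(plant_spec(20)), seed = 7)
#' sim <- generate_cohort(spec)
#' sim$truth
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$seed)
  nr <- spec$n_records
  if (nr == 0L)
    return(structure(list(records = stats::setNames(character(0L),
                                                    character(0L)),
                          truth = .empty_truth(), annotations = NULL,
                          spec = spec),
                     class = "icbps_cohort_sim"))
  lens <- .draw_lengths(spec, nr)
  records <- character(nr)
  ids <- sprintf("sim_%04d", seq_len(nr))
  truth_all <- vector("list", nr)
  for (i in seq_len(nr)) {
    got <- NULL
    for (t in seq_len(spec$max_tries)) {
      cand <- .build_record(ids[i], lens[i], spec)
      if (.record_clean(cand$record, cand$truth, spec)) { got <- cand; break }
    }
    if (is.null(got))
      stop(sprintf("record %s: no clean realization in %d tries (planted ",
                   ids[i], spec$max_tries),
           "arms too dense for the requested length/composition?")
    records[i] <- got$record$sequence
    truth_all[[i]] <- got$truth
  }
  names(records) <- ids
  truth <- do.call(rbind, truth_all)
  if (is.null(truth) || nrow(truth) == 0L) truth <- .empty_truth()
  rownames(truth) <- NULL
  ann <- NULL
  if (!is.null(spec$annotations)) {
    ann <- do.call(rbind, lapply(seq_len(nr), function(i) {
      plant_annotations(circ_record(ids[i], records[i]),
                        truth[truth$circ_id == ids[i], , drop = FALSE],
                        spec$annotations)
    }))
    rownames(ann) <- NULL
  }
  structure(list(records = records, truth = truth, annotations = ann,
                 spec = spec),
            class = "icbps_cohort_sim")
}

.draw_lengths <- function(spec, nr) {
  if (!is.null(spec$circ_len)) return(rep_len(spec$circ_len, nr))
  r <- spec$length_range
  lens <- if (spec$log_uniform)
    round(exp(stats::runif(nr, log(r[1L]), log(r[2L]))))
  else round(stats::runif(nr, r[1L], r[2L]))
  n_el <- round(spec$el_circ_fraction * nr)
  if (n_el > 0L) {
    el_hi <- max(10000L, r[2L])
    which_el <- sample.int(nr, n_el)
    lens[which_el] <- round(exp(stats::runif(n_el, log(5001), log(el_hi))))
  }
  as.integer(lens)
}

.build_record <- function(id, len, spec) {
  rec <- circ_record(id, paste(.rand_bases(len, spec$gc), collapse = ""))
  truth <- .empty_truth()
  for (ps in spec$plantings) {
    if (stats::runif(1L) > ps$per_record_prob) next
    occ <- cbind(c(truth$q_start, truth$p_start),
                 c(truth$q_end, truth$p_end))
    planted <- plant_multi_partner(rec, ps$arm_len, ps$n_partners,
                                   separation = ps$separation,
                                   allow_wrap = ps$allow_wrap, gc = spec$gc,
                                   clean_min_len = spec$clean_min_len,
                                   occupied = occ)
    rec <- planted$record
    truth <- rbind(truth, planted$truth)
  }
  truth <- truth[order(truth$q_start, truth$p_start), , drop = FALSE]
  rownames(truth) <- NULL
  list(record = rec, truth = truth)
}

#' Plant MRE/ORF-like annotation intervals on one record
#'
#' The first interval of each kind intersects a randomly chosen planted arm
#' with the plan's overlap probability and is otherwise placed clear of all
#' arms; additional intervals are always placed clear, so the realized
#' per-record overlap status is exactly the first interval's draw. Uses the
#' current RNG state.
#'
#' @param record A [circ_record].
#' @param truth Truth pairs data frame for this record (may be empty, in
#'   which case no interval can overlap an arm).
#' @param plan An [annotation_plan].
#' @return Annotation data frame: `circ_id`, `start`, `end` (1-based
#'   inclusive), `kind`, `source`, and the realized `overlaps_arm` flag.
#' @export
plant_annotations <- function(record, truth, plan) {
  stopifnot(inherits(plan, "annotation_plan"))
  rec <- as_circ_record(record)
  n <- rec$circ_len
  arms <- .arms_of(truth)
  place_one <- function(l, want_overlap) {
    if (want_overlap && nrow(arms)) {
      a <- arms[sample.int(nrow(arms), 1L), ]
      lo <- max(1L, a$start - l + 1L)
      hi <- min(min(a$end, n), n - l + 1L)
      if (lo > hi) return(NULL)
      s <- if (lo == hi) lo else sample(lo:hi, 1L)
      return(c(s, s + l - 1L))
    }
    for (t in 1:500) {
      s <- sample.int(n - l + 1L, 1L)
      if (nrow(arms) == 0L ||
          !any(circular_intersects(s, s + l - 1L, arms$start, arms$end, n)))
        return(c(s, s + l - 1L))
    }
    NULL
  }
  rows <- list()
  add_kind <- function(kind, count, lens, p_overlap) {
    for (j in seq_len(count)) {
      l <- if (length(lens) == 1L) lens else sample(lens, 1L)
      want <- j == 1L && stats::runif(1L) < p_overlap
      iv <- place_one(l, want)
      if (is.null(iv))
        stop("could not place a ", kind, " interval on record ", rec$id)
      realized <- nrow(arms) > 0L &&
        any(circular_intersects(iv[1L], iv[2L], arms$start, arms$end, n))
      rows[[length(rows) + 1L]] <<- data.frame(
        circ_id = rec$id, start = iv[1L], end = iv[2L], kind = kind,
        source = "synthetic", overlaps_arm = realized,
        stringsAsFactors = FALSE)
    }
  }
  if (plan$n_mre > 0L)
    add_kind("MRE", plan$n_mre, plan$mre_len[1L]:plan$mre_len[2L],
             plan$overlap_prob)
  if (plan$n_orf > 0L)
    add_kind("ORF", plan$n_orf,
             seq.int(max(60L, plan$orf_len[1L]), max(60L, plan$orf_len[2L]),
                     by = 3L),
             plan$orf_overlap_prob)
  if (length(rows) == 0L)
    return(data.frame(circ_id = character(0L), start = integer(0L),
                      end = integer(0L), kind = character(0L),
                      source = character(0L), overlaps_arm = logical(0L),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
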