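# Interval algebra on circular coordinates, and intersection of ICBPS arms
# with MRE / ORF / region annotations. All in-memory intervals are 1-based
# inclusive; an interval crossing the backsplice junction is written with
# end > circ_len (it wraps around to end - circ_len).

#' Do two arcs on a circle share at least one nucleotide?
#'
#' Intervals are 1-based inclusive with `start` in `1..circ_len`; a
#' junction-crossing arc has `end > circ_len`. Abutting arcs do not
#' intersect. Vectorized; symmetric and invariant under joint rotation.
#'
#' @param a_start,a_end First arc.
#' @param b_start,b_end Second arc.
#' @param circ_len Circumference in nt.
#' @return Logical.
#' @examples
#' circular_intersects(101, 150, 141, 160, 1000)  # TRUE, 10 nt shared
#' circular_intersects(101, 150, 151, 200, 1000)  # FALSE, abutting
#' circular_intersects(951, 1020, 11, 30, 1000)   # TRUE, across junction
#' @export
circular_intersects <- function(a_start, a_end, b_start, b_end, circ_len) {
  ok <- function(s, e) all(s >= 1L & s <= circ_len & e >= s &
                           (e - s + 1L) <= circ_len)
  if (!ok(a_start, a_end) || !ok(b_start, b_end))
    stop("invalid circular interval: need 1 <= start <= circ_len, ",
         "start <= end, length <= circ_len")
  lin <- function(as, ae, bs, be) as <= be & bs <= ae
  lin(a_start, a_end, b_start, b_end) |
    lin(a_start, a_end, b_start + circ_len, b_end + circ_len) |
    lin(a_start + circ_len, a_end + circ_len, b_start, b_end)
}

#' Overlap of ICBPS arms with annotations on one circRNA
#'
#' A circRNA "overlaps" an annotation kind (e.g. MRE, ORF) if any arm of any
#' reported pair intersects any annotation of that kind by at least 1 nt.
#' `n_overlap_events` counts every intersecting (arm, annotation)
#' combination.
#'
#' @param pairs Pairs data frame for a single circRNA.
#' @param annotations Annotation data frame for the same circRNA: columns
#'   `circ_id`, `start`, `end` (1-based inclusive, end > circ_len wraps),
#'   `kind` (e.g. `"MRE"`, `"ORF"`), `source`.
#' @param circ_len Total circRNA length in nt.
#' @return One-row data frame: `circ_id`, `overlaps_mre`, `overlaps_orf`,
#'   `overlaps_both`, `n_overlap_events`.
#' @export
summarize_overlaps <- function(pairs, annotations, circ_len) {
  ids <- unique(c(pairs$circ_id, annotations$circ_id))
  if (length(ids) > 1L)
    stop("`pairs` and `annotations` mix several circ_ids: ",
         paste(ids, collapse = ", "))
  id <- if (length(ids)) ids else NA_character_
  arms <- .arms_of(pairs)
  hit_kind <- character(0L)
  n_events <- 0L
  if (nrow(arms) && nrow(annotations)) {
    for (ai in seq_len(nrow(arms))) {
      hits <- circular_intersects(arms$start[ai], arms$end[ai],
                                  annotations$start, annotations$end,
                                  circ_len)
      n_events <- n_events + sum(hits)
      hit_kind <- c(hit_kind, toupper(annotations$kind[hits]))
    }
  }
  mre <- "MRE" %in% hit_kind
  orf <- "ORF" %in% hit_kind
  data.frame(circ_id = id, overlaps_mre = mre, overlaps_orf = orf,
             overlaps_both = mre && orf, n_overlap_events = n_events,
             stringsAsFactors = FALSE)
}

# cohort driver: one summarize_overlaps row per circRNA in `profiles`
.overlap_table <- function(pairs, annotations, profiles) {
  out <- lapply(seq_len(nrow(profiles)), function(i) {
    id <- profiles$circ_id[i]
    row <- summarize_overlaps(pairs[pairs$circ_id == id, , drop = FALSE],
                              annotations[annotations$circ_id == id, ,
                                          drop = FALSE],
                              profiles$circ_len[i])
    row$circ_id <- id
    row
  })
  do.call(rbind, out)
}

#' Fraction of circRNAs carrying ICBPS, by group label
#'
#' For each label in `metadata` (e.g. the parental-gene region a circRNA was
#' transcribed from), reports how many circRNAs carry at least one ICBPS
#' pair with arm length >= `threshold`. Profiles must have been built at a
#' base threshold no larger than `threshold` so that `max_len` is
#' informative.
#'
#' @param profiles Profile data frame (rows from [build_profile]).
#' @param metadata Data frame with columns `circ_id` and `region_label`
#'   (additional columns such as `chromosome` are ignored). circRNAs absent
#'   from `metadata` are counted under label `"unknown"` with a warning.
#' @param threshold Arm-length threshold in nt (default 20).
#' @return Data frame: `label`, `n_total`, `n_with_icbps`, `fraction`
#'   (percent, 2 decimals), one row per label, sorted by label.
#' @examples
#' prof <- data.frame(circ_id = c("a", "b"), circ_len = c(500, 600),
#'                    n_pairs = c(1, 0), max_len = c(25, 0))
#' meta <- data.frame(circ_id = c("a", "b"), region_label = "3'-UTR")
#' group_fraction_with_icbps(prof, meta)
#' @export
group_fraction_with_icbps <- function(profiles, metadata, threshold = 20L) {
  if (nrow(profiles) == 0L)
    return(data.frame(label = character(0L), n_total = integer(0L),
                      n_with_icbps = integer(0L), fraction = numeric(0L)))
  lab <- metadata$region_label[match(profiles$circ_id, metadata$circ_id)]
  if (anyNA(lab)) {
    warning(sum(is.na(lab)),
            " circRNA(s) missing from metadata; counted as \"unknown\"")
    lab[is.na(lab)] <- "unknown"
  }
  with_icbps <- profiles$max_len >= threshold
  out <- do.call(rbind, lapply(sort(unique(lab)), function(l) {
    sel <- lab == l
    data.frame(label = l, n_total = sum(sel),
               n_with_icbps = sum(with_icbps[sel]),
               fraction = fraction_percent(sum(with_icbps[sel]), sum(sel)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
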