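# High-level interface: scan a whole cohort and return a classed result
# holding the pairs table (candidates >= min_len) and the per-circRNA
# profiles (reported at >= report_threshold).

#' Scan circRNAs for internal complementary base-pairing sequences
#'
#' The main entry point. Runs the maximal-pair scanner on every record and
#' summarises each circRNA into a profile (pair count, maxLen, medianLen,
#' complementary ratio, el-circRNA and pattern flags). Candidate pairs are
#' detected at `min_len` (default 10 nt) and profiles are reported at
#' `report_threshold` (default 20 nt), the conventional analysis threshold.
#'
#' @param x Sequences: a named character vector, a FASTA file path, a
#'   `Biostrings` XStringSet, a [circ_record], or a simulated cohort from
#'   [generate_cohort].
#' @param min_len Minimum candidate arm length in nt (>= 2).
#' @param report_threshold Arm length in nt above which pairs enter the
#'   profiles (>= `min_len`).
#' @param wrap Allow arms to cross the backsplice junction (default FALSE).
#' @param max_pairs Per-record cap on reported pairs (see [scan_config]).
#' @param engine `"pointer"` (default) or `"bruteforce"` (exact reference
#'   scanner, quadratic; small records only).
#' @return Object of class `icbps_result`: list with `pairs` (all maximal
#'   pairs >= `min_len`, all records), `profiles` (one row per scanned
#'   record), `skipped` (records dropped with their failure reason) and
#'   `config`. Records shorter than `2 * min_len` are profiled with zero
#'   pairs after a warning; records failing normalization are skipped with
#'   a warning.
#' @examples
#' set.seed(42)
#' sim <- generate_cohort(synthetic_spec(3, circ_len = 400,
#'                                       plantings = list(plant_spec(25)),
#'                                       seed = 3))
#' res <- icbps_scan(sim)
#' res$profiles[, c("circ_id", "n_pairs", "max_len", "cr_percent")]
#' @export
icbps_scan <- function(x, min_len = 10L, report_threshold = 20L,
                       wrap = FALSE, max_pairs = 10000L,
                       engine = c("pointer", "bruteforce")) {
  engine <- match.arg(engine)
  if (report_threshold < min_len)
    stop("`report_threshold` must be >= `min_len`")
  seqs <- .as_sequences(x)
  cfg <- scan_config(min_len = min_len, wrap = wrap, max_pairs = max_pairs)
  scan_fun <- if (engine == "pointer") find_icbps_pointer
              else find_icbps_bruteforce
  pairs_l <- list(); prof_l <- list()
  skipped <- data.frame(circ_id = character(0L), reason = character(0L),
                        stringsAsFactors = FALSE)
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    rec <- tryCatch(circ_record(id, seqs[[i]]), error = function(e) {
      warning("record '", id, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(rec)) {
      skipped <- rbind(skipped, data.frame(circ_id = id,
                                           reason = "normalization error",
                                           stringsAsFactors = FALSE))
      next
    }
    if (rec$circ_len < 2L * cfg$min_len)
      warning("record '", id, "' is shorter than 2 * min_len; ",
              "no pair can fit", call. = FALSE)
    pr <- scan_fun(rec, cfg)
    pairs_l[[length(pairs_l) + 1L]] <- pr
    prof_l[[length(prof_l) + 1L]] <- build_profile(rec, pr,
                                                   report_threshold)
  }
  pairs <- if (length(pairs_l)) do.call(rbind, pairs_l) else empty_pairs()
  profiles <- if (length(prof_l)) do.call(rbind, prof_l)
              else build_profile(circ_record("none", "ACGT"),
                                 empty_pairs())[0L, ]
  rownames(pairs) <- NULL
  rownames(profiles) <- NULL
  structure(list(pairs = pairs, profiles = profiles, skipped = skipped,
                 config = list(min_len = cfg$min_len,
                               report_threshold = as.integer(report_threshold),
                               wrap = cfg$wrap, max_pairs = cfg$max_pairs,
                               engine = engine)),
            class = "icbps_result")
}

.as_sequences <- function(x) {
  if (inherits(x, "icbps_cohort_sim")) return(x$records)
  if (inherits(x, "circ_record")) return(stats::setNames(x$sequence, x$id))
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(out))
    return(out)
  }
  if (is.character(x)) {
    if (length(x) == 1L && is.null(names(x)) && file.exists(x) &&
        !grepl("^[ACGTUNacgtun]+$", x))
      return(read_circ_fasta(x))
    if (is.null(names(x)))
      names(x) <- sprintf("seq%d", seq_along(x))
    return(x)
  }
  stop("cannot interpret `x` as circRNA sequences")
}

#' @export
print.icbps_result <- function(x, ...) {
  cat(sprintf("ICBPS scan: %d circRNA(s), %s mode, min_len %d nt, ",
              nrow(x$profiles), if (x$config$wrap) "wrap" else "linear",
              x$config$min_len),
      sprintf("profiles at >= %d nt\n", x$config$report_threshold), sep = "")
  cat(sprintf("  candidate pairs: %d;  circRNAs with reported pairs: %d\n",
              nrow(x$pairs), sum(x$profiles$n_pairs >= 1L)))
  if (nrow(x$skipped))
    cat(sprintf("  skipped records: %d\n", nrow(x$skipped)))
  if (nrow(x$profiles)) {
    cat("\nProfiles:\n")
    show <- utils::head(x$profiles, 10L)
    show$cr_percent <- round(show$cr_percent, 2L)
    print(show, row.names = FALSE)
    if (nrow(x$profiles) > 10L)
      cat(sprintf("  ... and %d more\n", nrow(x$profiles) - 10L))
  }
  invisible(x)
}

#' Cohort summary of a scan result
#'
#' @param object An `icbps_result`.
#' @param annotations Optional annotation data frame (or file path) for
#'   overlap analysis.
#' @param metadata Optional metadata data frame (or file path) for
#'   per-label fractions.
#' @param ... Passed to [summarize_cohort].
#' @return A list of class `summary.icbps_result`; see [run_summarize].
#' @export
summary.icbps_result <- function(object, annotations = NULL,
                                 metadata = NULL, ...) {
  out <- run_summarize(object$profiles, pairs = object$pairs,
                       annotations = annotations, metadata = metadata,
                       threshold = object$config$report_threshold)
  class(out) <- "summary.icbps_result"
  out
}

#' @export
print.summary.icbps_result <- function(x, ...) {
  print(x$cohort)
  if (!is.null(x$overlap_fractions))
    cat(sprintf("  arm/annotation overlap: MRE %.2f%%, ORF %.2f%%, both %.2f%%\n",
                x$overlap_fractions$mre, x$overlap_fractions$orf,
                x$overlap_fractions$both))
  if (!is.null(x$groups)) {
    cat("  per-label ICBPS fractions:\n")
    print(x$groups, row.names = FALSE)
  }
  invisible(x)
}

#' Diagnostic panels for a scan result
#'
#' Four base-graphics panels: the maxLen distribution, the pair-count
#' distribution, the complementary-ratio distribution, and pair count
#' against circRNA length.
#'
#' @param x An `icbps_result`.
#' @param ... Ignored.
#' @return `x`, invisibly.
#' @export
plot.icbps_result <- function(x, ...) {
  p <- x$profiles
  op <- graphics::par(mfrow = c(2L, 2L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  hp <- p[p$n_pairs >= 1L, , drop = FALSE]
  if (nrow(hp)) {
    graphics::hist(hp$max_len, breaks = 20L, main = "maxLen of ICBPS",
                   xlab = "maxLen (nt)", col = "grey80")
    graphics::hist(hp$n_pairs, breaks = 20L, main = "pairs per circRNA",
                   xlab = "n pairs", col = "grey80")
    graphics::hist(p$cr_percent, breaks = 20L,
                   main = "complementary ratio", xlab = "CR (%)",
                   col = "grey80")
    graphics::plot(hp$circ_len, hp$n_pairs, pch = 16L,
                   col = grDevices::adjustcolor("steelblue", 0.6),
                   xlab = "circ_len (nt)", ylab = "n pairs",
                   main = "pair count vs length")
  } else {
    graphics::plot.new()
    graphics::title("no circRNA with reported pairs")
  }
  invisible(x)
}
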