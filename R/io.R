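# File formats. FASTA in/out goes through Biostrings. Tabular outputs are
# TSV (UTF-8, Unix newlines, mandatory header); all coordinates in pairs,
# truth and profiles tables are 1-based inclusive, with end > circ_len
# flagging a junction-crossing interval. Annotation files on disk are
# BED-like and 0-based half-open (converted on read/write); standard
# 6-column BED with the kind in the name field is also accepted.

#' Read circRNA sequences from a (multi-)FASTA file
#'
#' @param path FASTA file; record ids are the header tokens up to the first
#'   whitespace.
#' @return Named character vector of raw sequences (not yet normalized).
#' @export
read_circ_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write circRNA sequences to FASTA
#'
#' @param records Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_circ_fasta <- function(records, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(records), path)
  invisible(path)
}

.write_tsv <- function(df, path, logical_cols = character(0L),
                       formats = list()) {
  out <- df
  for (cl in logical_cols) out[[cl]] <- as.integer(out[[cl]])
  for (cl in names(formats))
    out[[cl]] <- ifelse(is.na(df[[cl]]), "NA",
                        sprintf(formats[[cl]], df[[cl]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path, required) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", path, "' lacks required column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write / read an ICBPS pairs table
#'
#' Columns `circ_id`, `q_start`, `q_end`, `p_start`, `p_end`, `length`,
#' `q_wraps`, `p_wraps` (wrap flags stored as 0/1); coordinates 1-based
#' inclusive, deterministic row order. A `topology` column (ground-truth
#' tables) is carried through when present.
#'
#' @param pairs Pairs data frame.
#' @param path TSV file.
#' @return `path` (write) or the pairs data frame (read).
#' @export
write_pairs_tsv <- function(pairs, path) {
  .write_tsv(pairs, path, logical_cols = c("q_wraps", "p_wraps"))
}

#' @rdname write_pairs_tsv
#' @export
read_pairs_tsv <- function(path) {
  df <- .read_tsv(path, c("circ_id", "q_start", "q_end", "p_start", "p_end",
                          "length", "q_wraps", "p_wraps"))
  df$q_wraps <- as.logical(df$q_wraps)
  df$p_wraps <- as.logical(df$p_wraps)
  df$circ_id <- as.character(df$circ_id)
  df
}

#' Write / read a per-circRNA profiles table
#'
#' `cr_percent` is written with 2 decimals and `median_len` with 1 decimal
#' (the reporting precisions); flags are stored as 0/1.
#'
#' @param profiles Profiles data frame (rows from [build_profile]).
#' @param path TSV file.
#' @return `path` (write) or the profiles data frame (read).
#' @export
write_profiles_tsv <- function(profiles, path) {
  .write_tsv(profiles, path,
             logical_cols = c("is_el_circ", "multi_partner",
                              "overlapping_complements"),
             formats = list(cr_percent = "%.2f", median_len = "%.1f"))
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  df <- .read_tsv(path, c("circ_id", "circ_len", "n_pairs", "max_len",
                          "median_len", "cr_percent", "is_el_circ",
                          "multi_partner", "overlapping_complements"))
  for (cl in c("is_el_circ", "multi_partner", "overlapping_complements"))
    df[[cl]] <- as.logical(df[[cl]])
  df$circ_id <- as.character(df$circ_id)
  df
}

#' Read annotation intervals (BED-like TSV or 6-column BED)
#'
#' Accepts either the package's BED-like TSV (header `circ_id`, `start`,
#' `end`, `kind`, `source`; 0-based half-open, wrap encoded as
#' end > circ_len) or headerless standard 6-column BED with the kind in the
#' name field. Coordinates are converted to 1-based inclusive in memory.
#'
#' @param path Annotation file.
#' @return Data frame: `circ_id`, `start`, `end` (1-based inclusive),
#'   `kind`, `source`.
#' @export
read_annotations <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^circ_id\t", first)) {
    df <- .read_tsv(path, c("circ_id", "start", "end", "kind"))
    if (is.null(df$source)) df$source <- NA_character_
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 4L)
      stop("headerless annotation file must be >= 4-column BED")
    df <- data.frame(circ_id = df[[1L]], start = df[[2L]], end = df[[3L]],
                     kind = df[[4L]], source = "bed",
                     stringsAsFactors = FALSE)
  }
  if (any(df$end <= df$start))
    stop("annotation intervals must satisfy end > start (0-based half-open)")
  df$start <- as.integer(df$start) + 1L   # to 1-based inclusive
  df$end <- as.integer(df$end)
  df$circ_id <- as.character(df$circ_id)
  df
}

#' Write annotation intervals as BED-like TSV (0-based half-open)
#'
#' @param annotations Data frame with 1-based inclusive `start`/`end`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_annotations_tsv <- function(annotations, path) {
  out <- annotations[, c("circ_id", "start", "end", "kind", "source")]
  out$start <- out$start - 1L
  .write_tsv(out, path)
}

#' Read a per-circRNA metadata table
#'
#' TSV with header columns `circ_id`, `region_label` and optionally
#' `chromosome`.
#'
#' @param path Metadata TSV.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  df <- .read_tsv(path, c("circ_id", "region_label"))
  df$circ_id <- as.character(df$circ_id)
  df
}

#' Scan a FASTA file of circRNAs and write pairs/profiles tables
#'
#' Streams the records of `fasta` through [icbps_scan]; malformed records
#' (alphabet errors) are reported as warnings and skipped, records shorter
#' than `2 * min_len` are profiled with zero pairs after a warning.
#'
#' @param fasta Input FASTA path.
#' @param out_pairs,out_profiles Optional output TSV paths.
#' @inheritParams icbps_scan
#' @return The [icbps_scan] result, invisibly.
#' @export
run_scan <- function(fasta, out_pairs = NULL, out_profiles = NULL,
                     min_len = 10L, report_threshold = 20L, wrap = FALSE,
                     max_pairs = 10000L) {
  res <- icbps_scan(read_circ_fasta(fasta), min_len = min_len,
                    report_threshold = report_threshold, wrap = wrap,
                    max_pairs = max_pairs)
  if (!is.null(out_pairs)) write_pairs_tsv(res$pairs, out_pairs)
  if (!is.null(out_profiles)) write_profiles_tsv(res$profiles, out_profiles)
  invisible(res)
}

#' Simulate a synthetic cohort and write FASTA / truth / annotation files
#'
#' @param out_fasta Output FASTA path.
#' @param out_truth Optional truth-pairs TSV path (pairs schema plus
#'   `topology`).
#' @param out_annotations Optional BED-like annotations TSV path.
#' @param spec A [synthetic_spec]; alternatively give `spec_file`.
#' @param spec_file JSON (or YAML, if the yaml package is installed) file
#'   whose top-level fields are [synthetic_spec] arguments; `plantings` is
#'   a list of [plant_spec] argument sets and `annotations` an
#'   [annotation_plan] argument set.
#' @param seed Optional override of the spec's seed.
#' @return The generated cohort (class `icbps_cohort_sim`), invisibly.
#' @export
run_simulate <- function(out_fasta, out_truth = NULL, out_annotations = NULL,
                         spec = NULL, spec_file = NULL, seed = NULL) {
  if (is.null(spec)) {
    if (is.null(spec_file)) stop("give either `spec` or `spec_file`")
    spec <- .spec_from_file(spec_file)
  }
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  sim <- generate_cohort(spec)
  write_circ_fasta(sim$records, out_fasta)
  if (!is.null(out_truth)) {
    .write_tsv(sim$truth, out_truth, logical_cols = c("q_wraps", "p_wraps"))
  }
  if (!is.null(out_annotations) && !is.null(sim$annotations))
    write_annotations_tsv(sim$annotations, out_annotations)
  invisible(sim)
}

.spec_from_file <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML specs requires the yaml package; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!is.null(cfg$plantings))
    cfg$plantings <- lapply(cfg$plantings, function(p)
      do.call(plant_spec, p))
  if (!is.null(cfg$annotations))
    cfg$annotations <- do.call(annotation_plan, cfg$annotations)
  do.call(synthetic_spec, cfg)
}

#' Summarise a profiles table (plus optional annotations and metadata)
#'
#' Reads a profiles TSV and assembles the cohort summary; when a pairs
#' table and annotations are given the per-circRNA overlap table and cohort
#' overlap fractions are added, and when metadata is given the per-label
#' ICBPS fractions are added. Optionally writes the whole summary as JSON.
#'
#' @param profiles Profiles TSV path (or data frame).
#' @param pairs Optional pairs TSV path (or data frame); required for
#'   overlap analysis.
#' @param annotations Optional annotation file path (or data frame).
#' @param metadata Optional metadata TSV path (or data frame).
#' @param out_json Optional output JSON path.
#' @param threshold Arm-length threshold for the per-label fractions.
#' @return List with elements `cohort` ([summarize_cohort] result) and,
#'   when inputs allow, `overlap` (per-circRNA table), `overlap_fractions`
#'   (cohort percentages) and `groups` (per-label fractions). Invisibly
#'   when `out_json` is written.
#' @export
run_summarize <- function(profiles, pairs = NULL, annotations = NULL,
                          metadata = NULL, out_json = NULL,
                          threshold = 20L) {
  prof <- if (is.character(profiles)) read_profiles_tsv(profiles)
          else profiles
  out <- list(cohort = summarize_cohort(prof))
  if (!is.null(annotations) && !is.null(pairs)) {
    ann <- if (is.character(annotations)) read_annotations(annotations)
           else annotations
    prs <- if (is.character(pairs)) read_pairs_tsv(pairs) else pairs
    ov <- .overlap_table(prs, ann, prof)
    out$overlap <- ov
    out$overlap_fractions <- list(
      mre = fraction_percent(sum(ov$overlaps_mre), nrow(ov)),
      orf = fraction_percent(sum(ov$overlaps_orf), nrow(ov)),
      both = fraction_percent(sum(ov$overlaps_both), nrow(ov)))
  } else if (!is.null(annotations) && is.null(pairs)) {
    message("annotations given without a pairs table; overlap analysis ",
            "omitted")
  }
  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) read_metadata(metadata) else metadata
    out$groups <- group_fraction_with_icbps(prof, md, threshold)
  }
  if (!is.null(out_json)) {
    ser <- out
    ser$cohort <- unclass(ser$cohort)
    jsonlite::write_json(ser, out_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", null = "null")
    return(invisible(out))
  }
  out
}
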