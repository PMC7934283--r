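# Nucleotide alphabet handling. Internally every sequence is an uppercase
# DNA-alphabet string over {A,C,G,T,N}; U on input is folded into T so RNA-
# and DNA-style records behave identically. Integer encoding is used by the
# scanner: A=1, C=2, G=3, T=4, N=5. .PAIR_CODE[x] is the code of the base
# that Watson-Crick pairs with code x; N maps to 0, which equals no code, so
# positions holding N can never participate in a match.

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)
.PAIR_CODE <- c(4L, 3L, 2L, 1L, 0L)

#' Normalize a nucleotide sequence
#'
#' Uppercases, maps U to T, and validates that only A, C, G, T and N remain.
#'
#' @param raw A single character string (DNA or RNA alphabet, any case).
#' @return The normalized sequence as a single uppercase DNA-alphabet string.
#' @examples
#' normalize_sequence("acgu")   # "ACGT"
#' normalize_sequence("ACGTN")  # unchanged
#' @export
normalize_sequence <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw))
    stop("`raw` must be a single non-NA character string")
  s <- chartr("U", "T", toupper(raw))
  bad <- regexpr("[^ACGTN]", s)
  if (bad > 0L)
    stop(sprintf("invalid character '%s' at position %d",
                 substr(s, bad, bad), bad))
  s
}

#' Reverse complement of nucleotide sequences
#'
#' Returns the antiparallel Watson-Crick complement. Input is normalized
#' first (U is treated as T); N maps to N. Vectorized over `seq`.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGT")     # its own reverse complement
#' reverse_complement("GAUUACA") # same result as for "GATTACA"
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    s <- normalize_sequence(s)
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# integer encoding of a normalized sequence
.encode <- function(s) {
  unname(.BASE_CODE[strsplit(s, "", fixed = TRUE)[[1L]]])
}

# vectorized reverse complement of equal-length k-mer strings (no validation)
.rc_kmers <- function(kmers, k) {
  if (length(kmers) == 0L) return(character(0L))
  comp <- chartr("ACGTN", "TGCAN", kmers)
  do.call(paste0, lapply(k:1L, function(i) substring(comp, i, i)))
}

#' Construct a circRNA record
#'
#' A circRNA record holds an identifier and the linearized sequence of a
#' circular RNA (written 5' to 3' starting at the backsplice junction).
#'
#' @param id Single character identifier.
#' @param sequence Nucleotide sequence; normalized on construction.
#' @return An object of class `circ_record` with elements `id`, `sequence`
#'   (normalized) and `circ_len` (total length in nt).
#' @examples
#' circ_record("circ1", "ACGUACGU")
#' @export
circ_record <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id))
    stop("`id` must be a single non-empty string")
  sequence <- normalize_sequence(sequence)
  structure(list(id = id, sequence = sequence, circ_len = nchar(sequence)),
            class = "circ_record")
}

#' @export
print.circ_record <- function(x, ...) {
  prev <- if (x$circ_len > 40L) paste0(substr(x$sequence, 1L, 40L), "...")
          else x$sequence
  cat(sprintf("circRNA record '%s': %d nt\n  %s\n", x$id, x$circ_len, prev))
  invisible(x)
}

as_circ_record <- function(x) {
  if (inherits(x, "circ_record")) return(x)
  if (is.character(x) && length(x) == 1L) {
    id <- if (!is.null(names(x)) && nzchar(names(x))) names(x) else "seq1"
    return(circ_record(id, unname(x)))
  }
  stop("expected a `circ_record` or a single (optionally named) sequence string")
}
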