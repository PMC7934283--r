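# shared fixture builders (everything generated in code, fixed seeds)

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# canonical identity of a pairs table, for set comparisons
pair_key <- function(df) {
  paste(df$circ_id, df$q_start, df$p_start, df$length, sep = ":")
}

# a background string with no complementary match >= min_len, by rejection
# against the brute-force oracle
clean_background <- function(n, min_len = 10L, gc = 0.5, tries = 100L) {
  for (i in seq_len(tries)) {
    s <- random_seq(n, gc)
    if (nrow(find_icbps_bruteforce(c(bg = s), scan_config(min_len))) == 0L)
      return(s)
  }
  stop("no clean background found")
}

# rotate the linearization point of a circular sequence by `off` nt
rotate_seq <- function(s, off) {
  n <- nchar(s)
  off <- off %% n
  if (off == 0L) return(s)
  paste0(substr(s, off + 1L, n), substr(s, 1L, off))
}
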