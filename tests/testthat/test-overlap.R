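test_that("circular intersection handles overlap, abutment and wrap", {
  expect_true(circular_intersects(101, 150, 141, 160, 1000))
  expect_false(circular_intersects(101, 150, 151, 200, 1000))
  expect_true(circular_intersects(951, 1020, 11, 30, 1000))
  expect_false(circular_intersects(951, 1020, 21, 40, 1000))
  expect_error(circular_intersects(0, 10, 1, 5, 100), "invalid")
  expect_error(circular_intersects(1, 120, 1, 5, 100), "invalid")
})

test_that("circular intersection agrees with per-position membership", {
  members <- function(s, e, n) ((s:e - 1L) %% n) + 1L
  set.seed(71)
  for (i in 1:200) {
    n <- sample(20:200, 1)
    s1 <- sample(n, 1); l1 <- sample(n, 1); e1 <- s1 + l1 - 1L
    s2 <- sample(n, 1); l2 <- sample(n, 1); e2 <- s2 + l2 - 1L
    expect_identical(
      circular_intersects(s1, e1, s2, e2, n),
      length(intersect(members(s1, e1, n), members(s2, e2, n))) > 0L,
      info = sprintf("n=%d [%d,%d] vs [%d,%d]", n, s1, e1, s2, e2))
  }
})

test_that("circular intersection is symmetric and rotation invariant", {
  set.seed(73)
  for (i in 1:50) {
    n <- sample(50:500, 1)
    s1 <- sample(n, 1); e1 <- s1 + sample(n, 1) - 1L
    s2 <- sample(n, 1); e2 <- s2 + sample(n, 1) - 1L
    base <- circular_intersects(s1, e1, s2, e2, n)
    expect_identical(circular_intersects(s2, e2, s1, e1, n), base)
    off <- sample(n, 1) - 1L
    rot <- function(s, e) {
      ns <- ((s - 1L + off) %% n) + 1L
      c(ns, ns + (e - s))
    }
    a <- rot(s1, e1); b <- rot(s2, e2)
    expect_identical(circular_intersects(a[1], a[2], b[1], b[2], n), base)
  }
})

test_that("per-circRNA overlap summary counts events and kinds", {
  pairs <- data.frame(circ_id = "c", q_start = 100L, q_end = 130L,
                      p_start = 400L, p_end = 430L, length = 31L,
                      q_wraps = FALSE, p_wraps = FALSE)
  ann <- data.frame(circ_id = "c", start = 111L, end = 118L, kind = "MRE",
                    source = "t")
  out <- summarize_overlaps(pairs, ann, 1000)
  expect_true(out$overlaps_mre)
  expect_false(out$overlaps_orf)
  expect_false(out$overlaps_both)
  expect_identical(out$n_overlap_events, 1L)

  none <- summarize_overlaps(pairs, ann[0, ], 1000)
  expect_false(none$overlaps_mre)
  expect_identical(none$n_overlap_events, 0L)

  both <- rbind(ann, data.frame(circ_id = "c", start = 420L, end = 600L,
                                kind = "ORF", source = "t"))
  out2 <- summarize_overlaps(pairs, both, 1000)
  expect_true(out2$overlaps_both)
  expect_identical(out2$n_overlap_events, 2L)

  ann$circ_id <- "other"
  expect_error(summarize_overlaps(pairs, ann, 1000), "mix")
})

test_that("per-label ICBPS fractions are counted per group", {
  prof <- data.frame(circ_id = sprintf("c%02d", 1:10),
                     circ_len = 500L,
                     n_pairs = c(rep(1L, 6), rep(0L, 4)),
                     max_len = c(rep(25L, 6), rep(0L, 4)))
  meta <- data.frame(circ_id = prof$circ_id, region_label = "A")
  out <- group_fraction_with_icbps(prof, meta, threshold = 20)
  expect_identical(out$n_total, 10L)
  expect_identical(out$n_with_icbps, 6L)
  expect_equal(out$fraction, 60)

  empty <- group_fraction_with_icbps(prof[0, ], meta)
  expect_identical(nrow(empty), 0L)

  expect_warning(
    out2 <- group_fraction_with_icbps(prof, meta[1:5, ], threshold = 20),
    "unknown")
  expect_setequal(out2$label, c("A", "unknown"))
  expect_identical(sum(out2$n_total), 10L)
})

test_that("group fractions recover per-label planting rates", {
  set.seed(79)
  n_per <- 150L
  plant_rate <- c(X = 0.8, Y = 0.2)
  prof <- do.call(rbind, lapply(names(plant_rate), function(l) {
    with_pairs <- runif(n_per) < plant_rate[[l]]
    data.frame(circ_id = paste0(l, seq_len(n_per)), circ_len = 500L,
               n_pairs = as.integer(with_pairs),
               max_len = ifelse(with_pairs, 25L, 0L))
  }))
  meta <- data.frame(circ_id = prof$circ_id,
                     region_label = substr(prof$circ_id, 1, 1))
  out <- group_fraction_with_icbps(prof, meta, threshold = 20)
  # binomial 99% CI around the planting rates
  for (l in names(plant_rate)) {
    p <- plant_rate[[l]]
    half <- 2.576 * sqrt(p * (1 - p) / n_per) * 100
    expect_lt(abs(out$fraction[out$label == l] - 100 * p), half)
  }
})
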