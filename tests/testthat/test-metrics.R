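test_that("complementary ratio matches its definition and guards geometry", {
  expect_equal(round(complementary_ratio(123, 6071), 2), 4.05)
  expect_equal(complementary_ratio(0, 500), 0)
  expect_equal(complementary_ratio(250, 500), 100)
  expect_error(complementary_ratio(251, 500), "disjoint arms")
  expect_error(complementary_ratio(10, 0), "circ_len")
  # strictly increasing in max_len at fixed circ_len
  cr <- complementary_ratio(0:50, 100)
  expect_true(all(diff(cr) > 0))
})

test_that("profiles aggregate filtered pairs correctly", {
  mk_pairs <- function(lens, gap = 50L) {
    # stack non-overlapping arm pairs along the sequence
    starts <- cumsum(c(1L, head(lens, -1) + gap))
    p_starts <- 300L + cumsum(c(0L, head(lens, -1) + gap))
    data.frame(circ_id = "c", q_start = starts,
               q_end = starts + lens - 1L, p_start = p_starts,
               p_end = p_starts + lens - 1L, length = lens,
               q_wraps = FALSE, p_wraps = FALSE)
  }
  rec <- circ_record("c", strrep("A", 600))
  p <- build_profile(rec, mk_pairs(c(20L, 21L, 30L)), threshold = 20)
  expect_identical(p$n_pairs, 3L)
  expect_identical(p$max_len, 30L)
  expect_equal(p$median_len, 21)
  expect_equal(p$cr_percent, 10)
  expect_false(p$is_el_circ)

  p2 <- build_profile(rec, mk_pairs(c(12L, 15L)), threshold = 20)
  expect_identical(p2$n_pairs, 0L)
  expect_identical(p2$max_len, 0L)
  expect_true(is.na(p2$median_len))
  expect_equal(p2$cr_percent, 0)

  # even pair count: median is the mean of the central two
  p3 <- build_profile(rec, mk_pairs(c(20L, 22L, 27L, 40L)), threshold = 20)
  expect_equal(p3$median_len, 24.5)
})

test_that("the el-circRNA boundary is strict at 5,000 nt", {
  at <- build_profile(circ_record("a", random_seq(5000)), empty_pairs())
  above <- build_profile(circ_record("b", random_seq(5001)), empty_pairs())
  expect_false(at$is_el_circ)
  expect_true(above$is_el_circ)
})

test_that("pattern classification separates shared arms from mere overlap", {
  pr <- function(qs, qe, ps, pe) {
    data.frame(circ_id = "c", q_start = qs, q_end = qe, p_start = ps,
               p_end = pe, length = qe - qs + 1L, q_wraps = FALSE,
               p_wraps = FALSE)
  }
  shared <- rbind(pr(10, 30, 100, 120), pr(10, 30, 200, 220))
  out <- classify_patterns(shared, 500)
  expect_true(out$multi_partner)
  expect_true(out$overlapping_complements)

  disjoint <- rbind(pr(10, 30, 100, 120), pr(300, 320, 400, 420))
  out2 <- classify_patterns(disjoint, 500)
  expect_false(out2$multi_partner)
  expect_false(out2$overlapping_complements)

  # shared arm whose partners flank it: canonical roles differ per pair
  flank <- rbind(pr(50, 70, 200, 220), pr(200, 220, 400, 420))
  out3 <- classify_patterns(flank, 500)
  expect_true(out3$multi_partner)

  expect_false(classify_patterns(pr(10, 30, 100, 120), 500)$multi_partner)
})

test_that("threshold monotonicity: higher thresholds never add pairs", {
  set.seed(67)
  sim <- generate_cohort(synthetic_spec(5, circ_len = 600,
                                        plantings = list(plant_spec(24)),
                                        seed = 67))
  res <- icbps_scan(sim, min_len = 10)
  for (i in seq_len(nrow(res$profiles))) {
    rec <- circ_record(res$profiles$circ_id[i],
                       sim$records[[res$profiles$circ_id[i]]])
    prs <- res$pairs[res$pairs$circ_id == rec$id, ]
    np <- vapply(c(10L, 15L, 20L, 25L),
                 function(t) build_profile(rec, prs, t)$n_pairs, integer(1))
    expect_true(all(diff(np) <= 0))
  }
})

test_that("fraction_percent reports rounded cohort percentages", {
  expect_equal(fraction_percent(6155, 140790), 4.37)
  expect_equal(fraction_percent(1, 3, digits = 4), 33.3333)
  expect_error(fraction_percent(1, 0), "positive")
})
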