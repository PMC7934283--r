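test_that("cohort generation is a deterministic function of spec and seed", {
  spec <- synthetic_spec(5, circ_len = 400,
                         plantings = list(plant_spec(20)),
                         annotations = annotation_plan(overlap_prob = 0.5),
                         seed = 103)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_false(identical(
    a$records,
    generate_cohort(synthetic_spec(5, circ_len = 400,
                                   plantings = list(plant_spec(20)),
                                   seed = 104))$records))
  # generation must not disturb the caller's RNG stream
  set.seed(1); before <- runif(3)
  set.seed(1); invisible(generate_cohort(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("an empty spec yields an empty cohort", {
  sim <- generate_cohort(synthetic_spec(0, seed = 1))
  expect_length(sim$records, 0L)
  expect_identical(nrow(sim$truth), 0L)
})

test_that("truth pairs are real and clean cohorts contain nothing else", {
  spec <- synthetic_spec(10, circ_len = 500,
                         plantings = list(plant_spec(25)), seed = 107)
  sim <- generate_cohort(spec)
  expect_identical(nrow(sim$truth), 10L)
  for (id in names(sim$records)) {
    found <- find_icbps_bruteforce(c(sim$records[id]), scan_config(10))
    expect_identical(pair_key(found),
                     pair_key(sim$truth[sim$truth$circ_id == id, ]))
  }
})

test_that("the k-mer cleanliness screen agrees with the oracle's verdict", {
  # screen-mode cohorts must also be oracle-clean at the same k
  spec <- synthetic_spec(6, circ_len = 600,
                         plantings = list(plant_spec(22)), seed = 109,
                         clean = "screen", clean_min_len = 10)
  sim <- generate_cohort(spec)
  for (id in names(sim$records)) {
    found <- find_icbps_bruteforce(c(sim$records[id]), scan_config(10))
    expect_identical(pair_key(found),
                     pair_key(sim$truth[sim$truth$circ_id == id, ]))
  }
})

test_that("multi-partner planting yields shared-arm truth and feasibility errors", {
  set.seed(113)
  base <- circ_record("x", random_seq(500))
  out <- plant_multi_partner(base, 20, 2)
  expect_identical(nrow(out$truth), 2L)
  expect_identical(unique(out$truth$topology), "B")
  # the two pairs share one arm
  arms <- c(paste(out$truth$q_start, out$truth$q_end),
            paste(out$truth$p_start, out$truth$p_end))
  expect_identical(length(unique(arms)), 3L)

  single <- plant_multi_partner(base, 20, 1)
  expect_identical(unique(single$truth$topology), "A")
  expect_identical(nrow(single$truth), 1L)

  expect_silent(plant_multi_partner(circ_record("y", random_seq(120)),
                                    25, 2, clean_min_len = 25))
  expect_error(plant_multi_partner(circ_record("z", random_seq(70)), 25, 2),
               "cannot fit")
})

test_that("exact separation planting honours the requested gap", {
  set.seed(127)
  out <- plant_multi_partner(circ_record("x", random_seq(300)), 20, 1,
                             separation = 37)
  expect_identical(out$truth$p_start - out$truth$q_end - 1L, 37L)
})

test_that("planted annotations realize the requested overlap probability exactly at 0 and 1", {
  set.seed(131)
  rec <- circ_record("x", random_seq(400))
  planted <- plant_multi_partner(rec, 20, 1)
  always <- plant_annotations(planted$record, planted$truth,
                              annotation_plan(overlap_prob = 1, n_mre = 2))
  expect_true(always$overlaps_arm[1])
  expect_false(any(always$overlaps_arm[-1]))   # extras stay clear of arms

  never <- plant_annotations(planted$record, planted$truth,
                             annotation_plan(overlap_prob = 0))
  expect_false(any(never$overlaps_arm))

  orfs <- plant_annotations(planted$record, planted$truth,
                            annotation_plan(overlap_prob = 0, n_mre = 0,
                                            n_orf = 2,
                                            orf_overlap_prob = 1))
  expect_identical(unique(orfs$kind), "ORF")
  expect_true(all((orfs$end - orfs$start + 1L) %% 3L == 0L))
  expect_true(all(orfs$end - orfs$start + 1L >= 60L))
})

test_that("spec validation rejects impossible or malformed requests", {
  expect_error(plant_spec(8), "arm_len")
  expect_error(plant_spec(20, 0), "n_partners")
  expect_error(plant_spec(20, 2, separation = 10), "n_partners = 1")
  expect_error(synthetic_spec(3, gc = 1.2), "gc")
  expect_error(synthetic_spec(3, plantings = list(1)), "plant_spec")
  expect_error(annotation_plan(overlap_prob = 2), "probabilities")
  # arms cannot fit: generator gives up with a spec error
  expect_error(generate_cohort(
    synthetic_spec(1, circ_len = 50, plantings = list(plant_spec(30)),
                   seed = 1)), "cannot fit")
})

test_that("el-circRNA fraction forces lengths above 5,000 nt", {
  # no plantings: cleanliness is irrelevant here and unattainable at
  # el-circRNA scale, where chance decamer matches are expected
  spec <- synthetic_spec(10, length_range = c(300, 1000),
                         el_circ_fraction = 0.3, seed = 137, clean = "none")
  sim <- generate_cohort(spec)
  lens <- nchar(sim$records)
  expect_identical(sum(lens > 5000), 3L)
})
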