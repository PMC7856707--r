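test_that("pair scores are the sums of the configured weights", {
  cfg <- link_config()
  s <- make_surgery()
  # every field agrees, admission one day after the procedure: 7+5+15+10+2
  i <- make_icu(icu_adm_date = s$procedure_date + 1)
  expect_equal(score_pair(s, i, cfg)$score, 39)
  # identity missing on the ICU side contributes 0: 10 + 2
  i2 <- make_icu(surname = "", forename = "", mrn = "",
                 slk = build_slk(s$surname, s$forename, s$dob, s$sex))
  expect_equal(score_pair(s, i2, cfg)$score, 12)
  # identity agrees but the dates are 3 days apart: 37 - 40, below cutoff
  i3 <- make_icu(icu_adm_date = s$procedure_date + 3)
  ps <- score_pair(s, i3, cfg)
  expect_equal(ps$score, -3)
  expect_lt(ps$score, cfg$cutoff)
  # everything disagrees, dates equal: -3-2-5-2+2
  i4 <- make_icu(surname = "OTHER", forename = "NAME", mrn = "7654321",
                 dob = as.Date("1960-01-01"))
  expect_equal(score_pair(s, i4, cfg)$score, -10)
})

test_that("field outcomes are symmetric and missing-aware", {
  cfg <- link_config()
  s <- make_surgery(mrn = "")
  i <- make_icu()
  ps <- score_pair(s, i, cfg)
  expect_equal(ps$outcome_mrn, "missing")
  expect_equal(ps$outcome_surname, "agree")
  # names compare under the same normalization as the linkage key
  s2 <- make_surgery(surname = "o'brien", forename = "mary anne")
  i2 <- make_icu(surname = "OBRIEN", forename = "MARYANNE",
                 slk = build_slk("OBRIEN", "MARYANNE", s2$dob, "M"))
  ps2 <- score_pair(s2, i2, cfg)
  expect_equal(ps2$outcome_surname, "agree")
  expect_equal(ps2$outcome_forename, "agree")
  expect_equal(ps2$outcome_slk, "agree")
})

test_that("greedy assignment reproduces the hand-worked toy example", {
  scored <- data.frame(
    surgery_id = c("s1", "s1", "s2"),
    icu_id = c("i1", "i2", "i2"),
    score = c(39, 17, 39))
  got <- assign_pairs(scored, cutoff = 1)
  expect_setequal(paste(got$surgery_id, got$icu_id),
                  c("s1 i1", "s2 i2"))
})

test_that("ties break by date proximity then lexicographic ids", {
  scored <- data.frame(
    surgery_id = c("s1", "s1"), icu_id = c("i1", "i2"),
    score = c(12, 12), date_delta_days = c(2L, 0L))
  expect_equal(assign_pairs(scored, 1)$icu_id, "i2")
  scored$date_delta_days <- c(1L, 1L)
  expect_equal(assign_pairs(scored, 1)$icu_id, "i1")
})

test_that("raising the cutoff never accepts more pairs", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:6, 1)
    scored <- expand.grid(surgery_id = paste0("s", 1:n),
                          icu_id = paste0("i", 1:m),
                          stringsAsFactors = FALSE)
    scored$score <- runif(nrow(scored), -5, 15)
    sizes <- vapply(c(-5, 0, 1, 5, 10),
                    function(ct) nrow(assign_pairs(scored, ct)), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("records with no candidate inside the caliper stay unmatched", {
  s <- rbind_records(make_surgery("S1"),
                     make_surgery("S2", procedure_date = as.Date("2018-09-01")))
  i <- make_icu("I1")  # admission matches only S1
  res <- link_probabilistic(s, i)
  expect_equal(res$pairs$surgery_id, "S1")
  expect_equal(res$unmatched_surgery, "S2")
  expect_length(res$unmatched_icu, 0)
})

test_that("the SLK-plus-date configuration equals a single-stage plan", {
  cfg <- link_config(fields = c("slk", "date"))
  plan <- stage_plan("slk_date", stages = list(c("SLK", "ICUAdmDt")),
                     tolerant = TRUE)
  for (seed in 1:2) {
    sim <- generate_registries(small_params(n_surgery = 250,
                                            n_icu_nonsurgical = 600),
                               error_model(), seed = seed)
    prob <- link_probabilistic(sim$surgery, sim$icu, cfg)
    det <- run_stages(sim$surgery, sim$icu, plan)
    expect_setequal(paste(prob$pairs$surgery_id, prob$pairs$icu_id),
                    paste(det$pairs$surgery_id, det$pairs$icu_id))
  }
})

test_that("linkage results are one-to-one and cover the surgery registry", {
  sim <- generate_registries(small_params(), error_model(), seed = 3)
  res <- link_probabilistic(sim$surgery, sim$icu)
  expect_false(anyDuplicated(res$pairs$surgery_id) > 0)
  expect_false(anyDuplicated(res$pairs$icu_id) > 0)
  expect_setequal(c(res$pairs$surgery_id, res$unmatched_surgery),
                  sim$surgery$record_id)
  expect_setequal(c(res$pairs$icu_id, res$unmatched_icu),
                  sim$icu$record_id)
})
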