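test_that("the shipped plans reproduce the published stage hierarchies", {
  p2 <- stage_plan("strategy2")
  p4 <- stage_plan("strategy4")
  expect_length(p2$stages, 9)
  expect_length(p4$stages, 12)
  fields2 <- lapply(p2$stages, `[[`, "required_fields")
  expect_equal(fields2[[1]],
               c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt", "Age", "Sex"))
  expect_equal(fields2[[4]],
               c("ICUAdmDt", "ICUDisDt", "HospAdmDt", "Age", "Sex"))
  expect_equal(fields2[[9]], c("ICUAdmDt", "ICUDisDt", "HospAdmDt"))
  fields4 <- lapply(p4$stages, `[[`, "required_fields")
  expect_equal(fields4[[1]],
               c("SLK", "ICUAdmDt", "ICUDisDt", "HospAdmDt", "HospDisDt",
                 "Age", "Sex"))
  expect_equal(fields4[[4]], c("SLK", "ICUAdmDt"))
  expect_equal(fields4[[12]],
               c("SLK", "ICUDisDt", "HospAdmDt", "HospDisDt", "Age", "Sex"))
  # no SLK anywhere in the non-identifying plan
  expect_false(any(vapply(fields2, function(f) "SLK" %in% f, logical(1))))
  # stage 1 tight, later stages loosened
  expect_false(p2$stages[[1]]$tolerant)
  expect_true(all(vapply(p2$stages[-1], `[[`, logical(1), "tolerant")))
})

test_that("stage agreement honours exactness, tolerance and the caliper", {
  s <- make_surgery()
  i <- make_icu()
  full <- list(required_fields = c("ICUAdmDt", "ICUDisDt", "HospAdmDt",
                                   "HospDisDt", "Age", "Sex"),
               tolerant = FALSE)
  expect_true(stage_agree(s, i, full))
  # a 1-day discrepancy in hospital discharge fails tight, passes loosened
  i2 <- make_icu(hosp_dis_date = i$hosp_dis_date + 1)
  expect_false(stage_agree(s, i2, full))
  expect_true(stage_agree(s, i2, modifyList(full, list(tolerant = TRUE))))
  # admission 3 days after the procedure is beyond the caliper at any stage
  i3 <- make_icu(icu_adm_date = s$procedure_date + 3,
                 icu_dis_date = s$icu_dis_date,
                 hosp_adm_date = s$hosp_adm_date,
                 hosp_dis_date = s$hosp_dis_date)
  expect_false(stage_agree(s, i3, modifyList(full, list(tolerant = TRUE))))
  # the intrinsic post-operative delay is allowed even at the tight stage
  i4 <- make_icu(icu_adm_date = s$procedure_date + 2,
                 icu_dis_date = s$icu_dis_date,
                 hosp_adm_date = s$hosp_adm_date,
                 hosp_dis_date = s$hosp_dis_date)
  expect_true(stage_agree(s, i4, full))
  # a missing field on either side fails any stage requiring it
  s_na <- make_surgery(icu_dis_date = as.Date(NA))
  expect_false(stage_agree(s_na, i, full))
})

test_that("records are recovered at the first stage omitting their errors", {
  # single-field corruptions beyond tolerance, against the 9-stage plan:
  # each lands at the first stage that does not require the broken field
  cases <- list(
    list(break_fields = "Sex", stage = 2),
    list(break_fields = "Age", stage = 3),
    list(break_fields = "HospDisDt", stage = 4),
    list(break_fields = "HospAdmDt", stage = 5),
    list(break_fields = "ICUDisDt", stage = 6),
    list(break_fields = "ICUAdmDt", stage = 7),
    list(break_fields = c("Age", "Sex"), stage = 8),
    list(break_fields = c("HospDisDt", "Age", "Sex"), stage = 9))
  plan <- stage_plan("strategy2")
  s <- make_surgery()
  for (case in cases) {
    args <- list(icu_adm_date = s$procedure_date,
                 icu_dis_date = s$icu_dis_date,
                 hosp_adm_date = s$hosp_adm_date,
                 hosp_dis_date = s$hosp_dis_date)
    if ("Sex" %in% case$break_fields) args$sex <- "F"
    if ("Age" %in% case$break_fields) args$age <- s$age + 5L
    if ("HospDisDt" %in% case$break_fields)
      args$hosp_dis_date <- s$hosp_dis_date + 5
    if ("HospAdmDt" %in% case$break_fields)
      args$hosp_adm_date <- s$hosp_adm_date + 5
    if ("ICUDisDt" %in% case$break_fields)
      args$icu_dis_date <- s$icu_dis_date + 5
    if ("ICUAdmDt" %in% case$break_fields)
      args$icu_adm_date <- s$procedure_date + 5
    i <- do.call(make_icu, args)
    res <- run_stages(s, i, plan)
    expect_equal(res$pairs$stage, case$stage,
                 label = paste("broken:", paste(case$break_fields, collapse = "+")))
  }
})

test_that("SLK stages rescue date errors and vice versa in the 12-stage plan", {
  plan <- stage_plan("strategy4")
  s <- make_surgery()
  # all administrative dates broken: only SLK + admission date remain
  i <- make_icu(icu_dis_date = s$icu_dis_date + 9,
                hosp_adm_date = s$hosp_adm_date - 7,
                hosp_dis_date = s$hosp_dis_date + 8)
  expect_equal(run_stages(s, i, plan)$pairs$stage, 4)
  # admission date broken, everything else intact: the only stage without
  # ICUAdmDt is the last
  i2 <- make_icu(icu_adm_date = s$procedure_date + 6,
                 icu_dis_date = s$icu_dis_date,
                 hosp_adm_date = s$hosp_adm_date,
                 hosp_dis_date = s$hosp_dis_date)
  expect_equal(run_stages(s, i2, plan)$pairs$stage, 12)
})

test_that("tied multi-candidate agreement defers; closest agreement wins", {
  # two surgery records identical in every stage field against one ICU
  # record: an irresolvable tie, so neither is matched at that stage
  s <- rbind_records(make_surgery("S1"), make_surgery("S2"))
  i <- make_icu("I1")
  res <- run_stages(s, i, stage_plan("strategy2"))
  expect_equal(nrow(res$pairs), 0)
  expect_setequal(res$unmatched_surgery, c("S1", "S2"))
  # but among candidates agreeing at the same loosened stage, the strictly
  # closer one is preferred over the looser one
  s2 <- make_surgery("S1")
  i2 <- rbind_records(
    make_icu("I1", icu_adm_date = s2$procedure_date,
             icu_dis_date = s2$icu_dis_date,
             hosp_adm_date = s2$hosp_adm_date,
             hosp_dis_date = s2$hosp_dis_date + 1),
    make_icu("I2", icu_adm_date = s2$procedure_date + 1,
             icu_dis_date = s2$icu_dis_date + 2,
             hosp_adm_date = s2$hosp_adm_date,
             hosp_dis_date = s2$hosp_dis_date + 2))
  res2 <- run_stages(s2, i2, stage_plan("strategy2"))
  expect_equal(res2$pairs$icu_id, "I1")
  expect_gt(res2$pairs$stage, 1)
})

test_that("staged linkage is sequentially exclusive and auditable", {
  sim <- generate_registries(small_params(n_surgery = 250,
                                          n_icu_nonsurgical = 600),
                             error_model(), seed = 9)
  for (plan_name in c("strategy2", "strategy4")) {
    plan <- stage_plan(plan_name)
    res <- run_stages(sim$surgery, sim$icu, plan)
    expect_false(anyDuplicated(res$pairs$surgery_id) > 0)
    expect_false(anyDuplicated(res$pairs$icu_id) > 0)
    # every accepted pair agrees at its recorded stage
    for (k in seq_len(nrow(res$pairs))) {
      s <- sim$surgery[sim$surgery$record_id == res$pairs$surgery_id[k], ]
      i <- sim$icu[sim$icu$record_id == res$pairs$icu_id[k], ]
      expect_true(stage_agree(s, i, plan$stages[[res$pairs$stage[k]]]))
    }
  }
})
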