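test_that("a result equal to the gold standard scores perfectly", {
  sim <- generate_registries(small_params(), error_model_zero(), seed = 13)
  res <- link_strategy(sim$surgery, sim$icu, "strategy1")
  ev <- evaluate_linkage(res, sim$gold)
  expect_equal(ev$n_false_positive, 0)
  expect_equal(ev$n_false_negative, 0)
  expect_equal(ev$match_rate_pct, 100.0)
})

test_that("match-rate percentages follow from their counts at one decimal", {
  # 1151/1242 = 92.673% -> 92.7; 1202/1242 = 96.779% -> 96.8;
  # 1211/1242 = 97.504% -> 97.5
  expect_equal(match_rate_pct(1151, 1242), 92.7)
  expect_equal(match_rate_pct(1202, 1242), 96.8)
  expect_equal(match_rate_pct(1211, 1242), 97.5)
  expect_equal(match_rate_pct(0, 10), 0)
  expect_equal(match_rate_pct(10, 10), 100)
  expect_error(match_rate_pct(11, 10))
})

test_that("percentages round half away from zero", {
  expect_equal(round_half_up(92.65, 1), 92.7)
  expect_equal(round_half_up(0.05, 1), 0.1)
  expect_equal(round_half_up(-0.05, 1), -0.1)
  expect_equal(round_half_up(58.536, 1), 58.5)
})

test_that("the 2x2 chi-square equals the closed-form Pearson statistic", {
  pearson <- function(k1, n1, k2, n2) {
    a <- as.numeric(k1); b <- as.numeric(n1 - k1)
    c <- as.numeric(k2); d <- as.numeric(n2 - k2)
    N <- a + b + c + d
    N * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  }
  set.seed(31)
  for (rep in 1:25) {
    n1 <- sample(20:2000, 1); n2 <- sample(20:2000, 1)
    k1 <- sample(1:(n1 - 1), 1); k2 <- sample(1:(n2 - 1), 1)
    got <- compare_match_rates(k1, n1, k2, n2)
    expect_equal(got$statistic, pearson(k1, n1, k2, n2), tolerance = 1e-10)
    expect_equal(got$df, 1)
  }
  # identical proportions: statistic 0, p = 1
  same <- compare_match_rates(50, 80, 50, 80)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(compare_match_rates(0, 10, 0, 10), "degenerate")
})

test_that("accounting identities hold on noisy runs", {
  sim <- generate_registries(small_params(n_surgery = 250,
                                          n_icu_nonsurgical = 600),
                             error_model(), seed = 17)
  for (st in c("strategy1", "strategy2", "strategy3", "strategy4")) {
    ev <- evaluate_linkage(link_strategy(sim$surgery, sim$icu, st), sim$gold)
    expect_equal(ev$n_matched_true + ev$n_false_positive, ev$n_pairs)
    expect_equal(ev$n_matched_true + ev$n_false_negative, ev$n_eligible)
  }
})

test_that("percent (count) cells format as printed tables do", {
  expect_equal(fmt_pct_n(24, 41), "58.5 (24)")
  expect_equal(fmt_pct_n(273, 1242), "22.0 (273)")
  expect_equal(fmt_pct_n(0, 41), "0.0 (0)")
})

test_that("identical cohorts give null comparisons", {
  sim <- generate_registries(small_params(), error_model(), seed = 23)
  cohorts <- list(a = sim$surgery, b = sim$surgery)
  tab <- compare_cohorts(cohorts)
  expect_true(all(tab$a == tab$b))
  p <- tab$p_value[!is.na(tab$p_value)]
  expect_true(all(p >= 0.99))
  expect_true(any(tab$test == "t-test"))
  expect_true(any(tab$test == "Wilcoxon rank-sum"))
})

test_that("multi-group comparisons use ANOVA and Kruskal-Wallis", {
  sim <- generate_registries(small_params(), error_model(), seed = 29)
  half <- seq_len(nrow(sim$surgery)) %% 3
  cohorts <- split(sim$surgery, half)
  names(cohorts) <- c("g1", "g2", "g3")
  tab <- compare_cohorts(cohorts)
  expect_true(any(tab$test == "ANOVA"))
  expect_true(any(tab$test == "Kruskal-Wallis"))
  expect_true(all(c("g1", "g2", "g3") %in% names(tab)))
})

test_that("degenerate zero-variance groups report NA rather than failing", {
  a <- rbind_records(make_surgery("S1"), make_surgery("S2"))
  b <- rbind_records(make_surgery("S3"), make_surgery("S4"))
  tab <- compare_cohorts(list(a = a, b = b))
  expect_true(is.na(tab$p_value[tab$characteristic == "Age (mean, sd)"]))
})

test_that("unmatched patients skew younger and higher-risk than matched", {
  # direction of the matched-vs-unmatched contrast the generator emulates
  age_gap <- c(); risk_ratio <- c()
  for (seed in 1:3) {
    sim <- generate_registries(cohort_params(), error_model(), seed = seed)
    res <- link_strategy(sim$surgery, sim$icu, "strategy1")
    unmatched <- sim$surgery[sim$surgery$record_id %in% res$unmatched_surgery, ]
    matched <- sim$surgery[sim$surgery$record_id %in% res$pairs$surgery_id, ]
    age_gap <- c(age_gap, mean(matched$age) - mean(unmatched$age))
    risk_ratio <- c(risk_ratio, stats::median(unmatched$risk_of_death) /
                                stats::median(matched$risk_of_death))
  }
  expect_gt(mean(age_gap), 4)
  expect_gt(mean(risk_ratio), 2)
})
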