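# Review sampling, simulated chart review, PPV and confirmation rates.

codes <- default_codes()

mk_classified <- function(n, stratum = "text_sclc_only") {
  data.frame(patient_id = seq_len(n), group = 1L, index_code = "LC01",
             index_date = D("2005-06-01"), stratum = stratum,
             is_expected_case = TRUE)
}

test_that("review sampling is exact at the boundaries and deterministic", {
  cl <- mk_classified(40)
  expect_equal(draw_review_sample(cl, "text_sclc_only", 40, 1),
               1:40)  # whole stratum
  expect_equal(draw_review_sample(cl, "text_sclc_only", 0, 1), integer())
  expect_error(draw_review_sample(cl, "text_sclc_only", 41, 1),
               class = "sclcehr_parameter_error")
  s1 <- draw_review_sample(cl, "text_sclc_only", 10, 99)
  s2 <- draw_review_sample(cl, "text_sclc_only", 10, 99)
  expect_identical(s1, s2)
  expect_equal(length(s1), 10)
  expect_true(all(s1 %in% 1:40))
})

test_that("inclusion frequency matches simple random sampling", {
  cl <- mk_classified(40)
  n_draws <- 400
  hits <- integer(40)
  for (s in seq_len(n_draws)) {
    ids <- draw_review_sample(cl, "text_sclc_only", 10, s)
    hits[ids] <- hits[ids] + 1
  }
  p <- 10 / 40
  se <- sqrt(p * (1 - p) / n_draws)
  expect_true(all(abs(hits / n_draws - p) < 3.5 * se))
})

review_fixture <- function() {
  p <- rbind(mk_patient(1L), mk_patient(2L), mk_patient(3L), mk_patient(4L))
  ev <- do.call(rbind, lapply(1:4, annual_visits))
  truth <- data.frame(
    patient_id = 1:4,
    true_disease = c("SCLC", "NSCLC", "SCLC", "OTHER_LUNG"),
    true_onset_date = D(c("2005-03-01", "2006-01-01", "1999-06-01",
                          "2007-01-01")),
    true_stage = c("extensive", "unknown", "limited", "unknown"),
    true_death_date = D(NA))
  b <- mini_bundle(p, ev, truth = truth)
  fu <- data.frame(patient_id = 1:4, start_date = D("2000-01-01"),
                   end_date = D("2014-12-31"), end_reason = "study_end",
                   person_days = 5478L)
  list(bundle = b, fu = fu)
}

test_that("review maps truth to confirmation and exclusion reasons", {
  fx <- review_fixture()
  out <- as.data.frame(review_cases(1:4, fx$bundle, fx$fu))
  expect_equal(out$confirmed, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$exclusion_reason,
               c("none", "nsclc", "prevalent", "other_location"))
  # patient 3 is a true SCLC whose onset precedes follow-up: prevalent
  expect_error(review_cases(99L, fx$bundle, fx$fu),
               class = "sclcehr_linkage_error")
})

test_that("error-free review equals the truth set exactly", {
  b <- generate_bundle(sim_config(n_patients = 30000, seed = 41))
  asc <- ascertain_sclc(b)
  cases <- asc$classifications[asc$classifications$is_expected_case, ]
  out <- review_cases(cases$patient_id, b, asc$followups)
  tr <- as.data.frame(b$truth)
  fu <- as.data.frame(asc$followups)
  want <- merge(merge(data.frame(patient_id = cases$patient_id), tr),
                fu[, c("patient_id", "start_date")])
  want_confirmed <- want$patient_id[want$true_disease == "SCLC" &
                                      !is.na(want$true_onset_date) &
                                      want$true_onset_date >= want$start_date]
  expect_setequal(out$patient_id[out$confirmed], want_confirmed)
})

test_that("PPV point estimates and exact intervals are correct", {
  p <- ppv_estimate(n_confirmed = 381, n_reviewed = 400)
  expect_equal(round(100 * p$ppv, 1), 95.2)
  p1 <- ppv_estimate(n_confirmed = 296, n_reviewed = 300)
  expect_equal(round(100 * p1$ppv, 1), 98.7)
  p2 <- ppv_estimate(n_confirmed = 85, n_reviewed = 100)
  expect_equal(round(100 * p2$ppv, 1), 85.0)
  p0 <- ppv_estimate(n_confirmed = 0, n_reviewed = 25)
  expect_equal(p0$ppv, 0)
  expect_equal(p0$ci_low, 0)
  expect_error(ppv_estimate(n_confirmed = 0, n_reviewed = 0),
               class = "sclcehr_parameter_error")

  # cross-check Clopper-Pearson against stats::binom.test
  for (xn in list(c(381, 400), c(296, 300), c(85, 100), c(1, 20),
                  c(0, 18), c(18, 18))) {
    ours <- clopper_pearson(xn[1], xn[2])
    ref <- stats::binom.test(xn[1], xn[2])$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-12)
  }
})

test_that("confirmation rates divide confirmed by reviewed per stratum", {
  mk_out <- function(conf, n) {
    data.frame(patient_id = seq_len(n), reviewed = rep(TRUE, n),
               confirmed = seq_len(n) <= conf,
               exclusion_reason = ifelse(seq_len(n) <= conf, "none",
                                         "nsclc"))
  }
  r <- confirmation_rates(list(both = mk_out(1, 20),
                               sclc_only = mk_out(18, 18),
                               lung = mk_out(0, 18)))
  expect_equal(unname(r), c(0.05, 1, 0))
  expect_error(confirmation_rates(list(empty = mk_out(0, 0))),
               class = "sclcehr_parameter_error")
})

test_that("sampled PPV is an unbiased estimator of population precision", {
  b <- generate_bundle(sim_config(n_patients = 60000, seed = 43))
  asc <- ascertain_sclc(b)
  cl <- asc$classifications
  pool <- cl[cl$stratum %in% c("text_sclc_only", "text_lung"), ]
  out_all <- review_cases(pool$patient_id, b, asc$followups)
  pop_ppv <- mean(out_all$confirmed)
  confirmed <- out_all$confirmed[match(pool$patient_id, out_all$patient_id)]
  n <- 25
  est <- numeric(250)
  for (s in seq_len(250)) {
    set.seed(s)
    est[s] <- mean(confirmed[sample(length(confirmed), n)])
  }
  se_mean <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - pop_ppv), 3 * se_mean + 1e-9)
})

test_that("Clopper-Pearson intervals reach nominal coverage", {
  set.seed(101)
  p_true <- 0.3
  n <- 20
  x <- rbinom(2000, n, p_true)
  cover <- vapply(x, function(xi) {
    ci <- clopper_pearson(xi, n)
    ci["low"] <= p_true && p_true <= ci["high"]
  }, logical(1))
  expect_gte(mean(cover), 0.95)
})

test_that("stratified PPV splits outcomes by the given strata", {
  fx <- review_fixture()
  out <- review_cases(1:4, fx$bundle, fx$fu)
  sp <- stratified_ppv(out, c("a", "a", "b", "b"))
  expect_equal(sp$a$n_reviewed, 2)
  expect_equal(sp$a$ppv, 0.5)
  expect_equal(sp$b$ppv, 0)
})

test_that("exclusion reasons tally over unconfirmed patients", {
  fx <- review_fixture()
  out <- review_cases(1:4, fx$bundle, fx$fu)
  tal <- exclusion_tally(out)
  expect_equal(tal[["nsclc"]], 1L)
  expect_equal(tal[["prevalent"]], 1L)
  expect_equal(tal[["other_location"]], 1L)
  expect_equal(sum(tal), 3L)
})
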