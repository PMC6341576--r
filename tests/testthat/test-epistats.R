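# Incidence rates, one-year mortality, the product-limit estimator and the
# baseline characterisation rules.

codes <- default_codes()

test_that("incidence rates and log-normal intervals reproduce known values", {
  r <- incidence_rate(2938, 29028641)
  expect_equal(round(r$rate, 2), 1.01)
  r0 <- incidence_rate(0, 1e5)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci_low, 0)
  expect_equal(r0$ci_high, 3.69 / 1e5 * 10000)
  expect_error(incidence_rate(10, 0), class = "sclcehr_parameter_error")

  # one-year mortality rate of 1998 deaths over 20,073 person-months
  rm <- incidence_rate(1998, 20073, scale = 100, unit = "person-months")
  expect_equal(round(rm$rate, 2), 9.95)
  expect_lt(abs(rm$ci_low - 9.53), 0.02)
  expect_lt(abs(rm$ci_high - 10.39), 0.02)
})

test_that("rates are invariant to the person-time unit", {
  days <- 1234567
  ry <- incidence_rate(100, days / 365, scale = 10000)
  rm <- incidence_rate(100, days / 30.4375, scale = 10000 * 365 / 30.4375)
  expect_equal(ry$rate, rm$rate, tolerance = 1e-10)
})

# Engineered one-year mortality records matching published stratum totals:
# deaths get equal follow-up within a stratum, survivors a full 12 months.
engineered_records <- function(n, deaths, person_months, sex, age_band) {
  surv <- n - deaths
  t_death <- (person_months - surv * 12) / deaths
  data.frame(patient_id = seq_len(n), sex = sex, age_band = age_band,
             time_months = c(rep(t_death, deaths), rep(12, surv)),
             event = c(rep(TRUE, deaths), rep(FALSE, surv)))
}

test_that("the mortality summary reproduces stratum arithmetic", {
  males <- engineered_records(1468, 1081, 9787, "M", "60-69")
  females <- engineered_records(1372, 917, 10287, "F", "70-79")
  rec <- rbind(males, females)
  rec$patient_id <- seq_len(nrow(rec))
  tab <- as.data.frame(mortality_summary(rec))
  tot <- tab[tab$stratum == "total", ]
  expect_equal(tot$at_risk, 2840)
  expect_equal(tot$deaths, 1998)
  expect_equal(round(tot$crude_pct, 1), 70.4)
  expect_equal(round(tot$rate, 2), 9.95)
  m <- tab[tab$stratum == "M", ]
  expect_equal(round(m$rate, 2), 11.05)
  expect_lt(abs(m$ci_low - 10.41), 0.02)
  expect_lt(abs(m$ci_high - 11.72), 0.02)
  # stratified deaths and person-time sum to the totals
  expect_equal(sum(tab$deaths[tab$stratum %in% c("M", "F")]), tot$deaths)
  expect_equal(sum(tab$person_months[tab$stratum %in% c("M", "F")]),
               tot$person_months)
  expect_equal(sum(tab$deaths[tab$stratum %in%
                                c("<60", "60-69", "70-79", ">=80")]),
               tot$deaths)
})

test_that("a single patient dying at six months gives rate 16.67", {
  rec <- data.frame(patient_id = 1L, sex = "M", age_band = "60-69",
                    time_months = 6, event = TRUE)
  tab <- as.data.frame(mortality_summary(rec))
  tot <- tab[tab$stratum == "total", ]
  expect_equal(tot$deaths, 1)
  expect_equal(tot$person_months, 6)
  expect_equal(round(tot$rate, 2), 16.67)
})

test_that("the product-limit estimator handles simple exact cases", {
  km <- km_estimate(data.frame(time_months = 1:4, event = TRUE))
  expect_equal(km_survival_at(km, 2.5), 0.5)
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(attr(km, "median_survival"), 2)

  km2 <- km_estimate(data.frame(time_months = c(1, 5, 9), event = FALSE))
  expect_equal(nrow(km2), 0)
  expect_equal(km_survival_at(km2, 12), 1)
  expect_true(is.na(attr(km2, "median_survival")))

  expect_error(km_estimate(data.frame(time_months = -1, event = TRUE)),
               class = "sclcehr_parameter_error")
})

# Independent risk-set enumeration oracle.
km_oracle <- function(t, e, at) {
  s <- 1
  for (tt in sort(unique(t[e]))) {
    if (tt > at) break
    s <- s * (1 - sum(e & t == tt) / sum(t >= tt))
  }
  s
}

test_that("the estimator equals a brute-force risk-set oracle", {
  set.seed(71)
  t <- round(runif(500, 0, 12), 1)
  e <- runif(500) < 0.6
  km <- km_estimate(data.frame(time_months = t, event = e))
  for (tt in km$time) {
    expect_equal(km_survival_at(km, tt), km_oracle(t, e, tt),
                 tolerance = 1e-12)
  }
  # and at arbitrary times between event times
  for (tt in c(0, 0.05, 3.33, 11.99, 12)) {
    expect_equal(km_survival_at(km, tt), km_oracle(t, e, tt),
                 tolerance = 1e-12)
  }
})

test_that("the estimator agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(72)
  t <- round(runif(300, 0.1, 12), 2)
  e <- runif(300) < 0.7
  km <- km_estimate(data.frame(time_months = t, event = e))
  sf <- survival::survfit(survival::Surv(t, e) ~ 1)
  sf_at <- summary(sf, times = km$time)$surv
  expect_equal(km$survival, sf_at, tolerance = 1e-12)
})

test_that("without censoring, 1 - S(12) is the crude cumulative mortality", {
  set.seed(73)
  t <- pmin(rexp(400, 1 / 8), 12)
  e <- t < 12
  km <- km_estimate(data.frame(time_months = t, event = e))
  expect_equal(1 - km_survival_at(km, 12), mean(e), tolerance = 1e-12)
})

test_that("survival records truncate at 12 months and censor at record end", {
  p <- rbind(
    mk_patient(1L, status = "died", reg_end = "2005-09-01",
               death = "2005-09-01"),                      # dies at 3 months
    mk_patient(2L),                                        # alive, full year
    mk_patient(3L, reg_end = "2005-10-01"),                # data stop: censor
    mk_patient(4L, status = "died", reg_end = "2007-08-01",
               death = "2007-08-01"))                      # dies after a year
  ev <- do.call(rbind, lapply(1:4, function(i)
    annual_visits(i, "1995-06-01", "2004-06-01")))
  b <- mini_bundle(p, ev)
  cases <- data.frame(patient_id = 1:4, final_event_date = D("2005-06-01"))
  rec <- as.data.frame(survival_records(b, cases))
  expect_equal(nrow(rec), 4)
  expect_equal(rec$event, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(rec$time_months[1], 92 / 30.4375)
  expect_equal(rec$time_months[2], 12)
  expect_equal(rec$time_months[3], 122 / 30.4375)
  expect_equal(rec$time_months[4], 12)  # death beyond the follow-up year
})

test_that("medication counts as current iff supply reaches the prior year", {
  dx <- D("2005-06-01")
  p <- mk_patient(1L)
  rx <- data.frame(
    patient_id = 1L,
    issue_date = c(dx - 30, dx - 400),
    drug_class = c("opioid", "nsaid"),
    supply_days = c(60L, 5L))
  b <- mini_bundle(p, annual_visits(1L), prescriptions = rx)
  tab <- as.data.frame(baseline_table(
    b, data.frame(patient_id = 1L, final_event_date = dx), codes))
  med <- tab[tab$variable == "medication", ]
  expect_equal(med$n[med$category == "opioid"], 1L)  # supply spans diagnosis
  expect_equal(med$n[med$category == "nsaid"], 0L)   # ended 395 days before
})

test_that("baseline flags equal a brute-force per-rule scan", {
  b <- generate_bundle(sim_config(n_patients = 20000, seed = 47))
  asc <- ascertain_sclc(b)
  cases <- as.data.frame(asc$classifications[
    asc$classifications$is_expected_case, ])
  expect_gt(nrow(cases), 3)
  tab <- as.data.frame(baseline_table(b, cases, codes))
  ev <- as.data.frame(b$events)
  rx <- as.data.frame(b$prescriptions)
  cl <- as.data.frame(codes)

  # comorbidity: any code before diagnosis
  for (lab in c("copd", "hypertension")) {
    cc <- cl$code[cl$category == "comorbidity" & cl$label == lab]
    n_oracle <- 0
    for (i in seq_len(nrow(cases))) {
      pe <- ev[ev$patient_id == cases$patient_id[i] & ev$code == cc, ]
      if (any(pe$event_date <= cases$final_event_date[i])) {
        n_oracle <- n_oracle + 1
      }
    }
    expect_equal(tab$n[tab$variable == "comorbidity" &
                         tab$category == lab], n_oracle, label = lab)
  }

  # smoking: status closest before diagnosis
  cur <- 0
  for (i in seq_len(nrow(cases))) {
    pe <- ev[ev$patient_id == cases$patient_id[i] &
               ev$code %in% c("SMOK_NON", "SMOK_CURR", "SMOK_FORMER") &
               ev$event_date <= cases$final_event_date[i], ]
    if (nrow(pe) && pe$code[which.max(as.integer(pe$event_date))] ==
        "SMOK_CURR") cur <- cur + 1
  }
  expect_equal(tab$n[tab$variable == "smoking" &
                       tab$category == "current"], cur)

  # medication: most recent supply reaching the year before diagnosis
  n_op <- 0
  for (i in seq_len(nrow(cases))) {
    pr <- rx[rx$patient_id == cases$patient_id[i] &
               rx$drug_class == "opioid" &
               rx$issue_date <= cases$final_event_date[i], ]
    if (nrow(pr) && any(pr$issue_date + pr$supply_days >=
                          cases$final_event_date[i] - 365)) n_op <- n_op + 1
  }
  expect_equal(tab$n[tab$variable == "medication" &
                       tab$category == "opioid"], n_op)
})
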