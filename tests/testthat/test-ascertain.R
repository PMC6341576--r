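# Index detection, cross-code confirmation, stratum classification,
# confirmation-rate extrapolation and event-date backdating.

codes <- default_codes()
ps <- default_patterns()

fu_one <- function(id = 1L, start = "2000-01-01", end = "2014-12-31") {
  data.frame(patient_id = id, start_date = D(start), end_date = D(end),
             end_reason = "study_end",
             person_days = as.integer(D(end) - D(start)))
}

test_that("the earliest cancer code fixes group and index date", {
  p <- mk_patient(1L)
  ev <- rbind(annual_visits(1L),
              mk_events(1L, c("2005-01-10", "2005-02-09"),
                        c("SCC01", "LC01")))
  b <- mini_bundle(p, ev)
  idx <- detect_index(b, fu_one(end = "2005-01-10"), codes)
  expect_equal(idx$group, 2L)
  expect_equal(idx$index_date, D("2005-01-10"))

  # tie on the same first day: the SCC code wins
  ev2 <- rbind(annual_visits(2L),
               mk_events(2L, c("2005-01-10", "2005-01-10"),
                         c("LC01", "SCC01")))
  b2 <- mini_bundle(mk_patient(2L), ev2)
  idx2 <- detect_index(b2, fu_one(2L, end = "2005-01-10"), codes)
  expect_equal(idx2$group, 2L)
})

test_that("codes outside follow-up never assign a group", {
  p <- mk_patient(1L)
  ev <- rbind(annual_visits(1L), mk_events(1L, "1999-06-01", "LC01"))
  b <- mini_bundle(p, ev)
  idx <- detect_index(b, fu_one(start = "2000-01-01"), codes)
  expect_equal(nrow(idx), 0)
})

test_that("group sizes match an independent per-patient scan", {
  b <- generate_bundle(small_sim(n = 20000, seed = 23))
  fu <- eligible_cohort(b, codes)
  idx <- as.data.frame(detect_index(b, fu, codes))
  ev <- as.data.frame(b$events)
  lung <- codes$code[codes$category == "lung_cancer"]
  scc <- codes$code[codes$category == "scc"]
  groups <- integer()
  for (i in seq_len(nrow(fu))) {
    pe <- ev[ev$patient_id == fu$patient_id[i] &
               ev$code %in% c(lung, scc), ]
    pe <- pe[pe$event_date >= fu$start_date[i] &
               pe$event_date <= fu$end_date[i], ]
    if (!nrow(pe)) next
    first <- pe[pe$event_date == min(pe$event_date), ]
    g <- if (any(first$code %in% scc)) 2L else 1L
    groups <- c(groups, g)
  }
  expect_equal(sum(idx$group == 1L), sum(groups == 1L))
  expect_equal(sum(idx$group == 2L), sum(groups == 2L))
})

test_that("cross-code confirmation matches exhaustive offset enumeration", {
  for (offset in seq(-120, 120, by = 10)) {
    ev <- rbind(annual_visits(1L),
                mk_events(1L, "2005-06-01", "LC01"),
                mk_events(1L, format(D("2005-06-01") + offset), "SCC01"))
    b <- mini_bundle(mk_patient(1L), ev)
    fu <- fu_one(start = "2000-01-01",
                 end = format(min(D("2005-06-01"), D("2005-06-01") + offset)))
    idx <- detect_index(b, fu, codes)
    cc <- cross_code(idx, b, codes, 90L)
    expect_identical(cc$cross_code, abs(offset) <= 90,
                     label = paste("offset", offset))
  }
  # boundary day itself
  for (offset in c(-91, -90, 90, 91)) {
    ev <- rbind(annual_visits(1L),
                mk_events(1L, "2005-06-01", "LC01"),
                mk_events(1L, format(D("2005-06-01") + offset), "SCC01"))
    b <- mini_bundle(mk_patient(1L), ev)
    fu <- fu_one(end = format(min(D("2005-06-01"), D("2005-06-01") + offset)))
    cc <- cross_code(detect_index(b, fu, codes), b, codes, 90L)
    expect_identical(cc$cross_code, abs(offset) <= 90,
                     label = paste("offset", offset))
  }
})

test_that("flag combinations map to the documented strata", {
  mk_cl <- function(group, cross, sclc, non, lung) {
    a <- data.frame(patient_id = 1L, group = group, index_code = "X",
                    index_date = D("2005-06-01"))
    cf <- data.frame(patient_id = 1L, cross_code = cross)
    tf <- data.frame(patient_id = 1L, has_sclc_text = sclc,
                     has_non_text = non, has_lung_text = lung)
    classify_cases(a, cf, tf)
  }
  cases <- list(
    list(1L, TRUE, FALSE, FALSE, FALSE, "cross_code_confirmed", TRUE),
    list(1L, FALSE, TRUE, FALSE, FALSE, "text_sclc_only", TRUE),
    list(1L, FALSE, FALSE, TRUE, FALSE, "text_non_only", FALSE),
    list(1L, FALSE, TRUE, TRUE, FALSE, "text_both", FALSE),
    list(1L, FALSE, FALSE, FALSE, FALSE, "no_text", FALSE),
    list(2L, TRUE, FALSE, FALSE, FALSE, "cross_code_confirmed", TRUE),
    list(2L, FALSE, FALSE, FALSE, TRUE, "text_lung", TRUE),
    list(2L, FALSE, FALSE, FALSE, FALSE, "no_text", FALSE)
  )
  for (cs in cases) {
    cl <- mk_cl(cs[[1]], cs[[2]], cs[[3]], cs[[4]], cs[[5]])
    expect_equal(cl$stratum, cs[[6]],
                 label = paste(unlist(cs[1:5]), collapse = "/"))
    expect_equal(cl$is_expected_case, cs[[7]])
  }
})

test_that("strata partition each group exactly", {
  b <- generate_bundle(sim_config(n_patients = 30000, seed = 29))
  asc <- ascertain_sclc(b)
  cl <- as.data.frame(asc$classifications)
  sc <- asc$counts
  expect_equal(sc$n_cross1 + sc$n_text_sclc_only + sc$n_text_non_only +
                 sc$n_text_both + sum(cl$group == 1 & cl$stratum == "no_text"),
               sc$n_group1)
  expect_equal(sc$n_cross2 + sc$n_text_lung +
                 sum(cl$group == 2 & cl$stratum == "no_text"),
               sc$n_group2)
  expect_false(any(cl$stratum == "text_lung" & cl$group == 1))
  expect_false(any(cl$stratum %in%
                     c("text_sclc_only", "text_non_only", "text_both") &
                     cl$group == 2))
})

test_that("extrapolation reproduces hand-computable cases", {
  sc <- make_step_counts(24508, 733, 364, 137, 2000, 4166, 353, 437)
  out <- extrapolate_cases(sc, c(sclc_only = 1, both = 0.05, lung = 1))
  expect_equal(out$term_both, 18)        # 0.05 * 353 = 17.65, half away
  expect_equal(out$expected_cases_total, 2956)
  expect_equal(out$expected_cases_final, 2938)

  # identity rates: total is the sum of all contributing strata
  out1 <- extrapolate_cases(sc, c(sclc_only = 1, both = 1, lung = 1))
  expect_equal(out1$expected_cases_total, 364 + 2000 + 353 + 137 + 437)

  expect_error(extrapolate_cases(sc, c(sclc_only = 1.2, both = 0, lung = 1)),
               class = "sclcehr_parameter_error")
})

test_that("extrapolation equals an independently coded formula", {
  # second implementation, written separately from the package's
  round2 <- function(x) trunc(x + sign(x) * 0.5)
  oracle <- function(cnt, r) {
    terms <- c(round2(r[1] * cnt$n_text_sclc_only),
               round2(r[2] * cnt$n_text_both),
               round2(r[3] * cnt$n_text_lung))
    tot <- cnt$n_cross1 + cnt$n_cross2 + sum(terms)
    c(tot, tot - terms[2])
  }
  set.seed(77)
  for (i in 1:100) {
    g1 <- sample(100:30000, 1); g2 <- sample(10:1000, 1)
    x1 <- sample(0:min(500, g1), 1); x2 <- sample(0:min(200, g2), 1)
    rest1 <- g1 - x1; rest2 <- g2 - x2
    so <- sample(0:(rest1 %/% 3), 1); no <- sample(0:(rest1 %/% 3), 1)
    bo <- sample(0:(rest1 %/% 3), 1); lu <- sample(0:rest2, 1)
    r <- round(runif(3), 3)
    sc <- make_step_counts(g1, g2, x1, x2, so, no, bo, lu)
    out <- extrapolate_cases(sc, c(sclc_only = r[1], both = r[2],
                                   lung = r[3]))
    expect_equal(c(out$expected_cases_total, out$expected_cases_final),
                 oracle(sc, r))
  }
})

test_that("backdating picks the earliest related record in the lookback", {
  ev <- mk_events(1L, c("2005-04-26", "2005-05-12", "2005-03-01"),
                  c("SYMP_COUGH", "PROC_CXR", "VISIT"))
  # cough 36 days before the recorded code, X-ray 20 days before
  d <- backdate_event_date(ev, codes, "2005-06-01", 90)
  expect_equal(d, D("2005-04-26"))
  # no related events: the recorded date stands
  d2 <- backdate_event_date(mk_events(1L, "2005-05-01", "VISIT"), codes,
                            "2005-06-01")
  expect_equal(d2, D("2005-06-01"))
  # events beyond the lookback or after the recorded date are ignored
  ev3 <- mk_events(1L, c("2005-01-01", "2005-06-10"),
                   c("SYMP_COUGH", "PROC_CXR"))
  expect_equal(backdate_event_date(ev3, codes, "2005-06-01", 90),
               D("2005-06-01"))
})

test_that("backdating equals a brute-force filtered minimum", {
  rel <- codes$code[codes$category %in% c("symptom", "procedure", "surgery")]
  all_codes <- c(rel, "VISIT", "COM_MI", "LC01")
  set.seed(55)
  for (i in 1:60) {
    k <- sample(1:8, 1)
    rec <- D("2010-06-01")
    ev <- mk_events(1L, format(rec + sample(-150:30, k, TRUE)),
                    sample(all_codes, k, TRUE))
    lb <- sample(c(30, 90, 120), 1)
    got <- backdate_event_date(ev, codes, rec, lb)
    cand <- ev$event_date[ev$code %in% rel &
                            ev$event_date >= rec - lb &
                            ev$event_date <= rec]
    want <- if (length(cand)) min(cand) else rec
    expect_equal(got, want)
    expect_lte(as.integer(got), as.integer(rec))  # never later
  }
})
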