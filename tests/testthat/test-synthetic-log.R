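test_that("demand_model validates its fields and names the offender", {
  expect_s3_class(demand_model(), "demand_model")
  expect_error(demand_model(arrival_rate = -1), "arrival_rate")
  expect_error(demand_model(service_mean = 0), "service_mean")
  expect_error(demand_model(p_delegation = 1.2), "p_delegation")
  expect_error(demand_model(service_cv = 2), "service_cv")  # exponential cv fixed at 1
  expect_equal(demand_model(service_distribution = "deterministic")$service_cv, 0)
  expect_equal(demand_model(service_distribution = "lognormal",
                            service_cv = 0.5)$service_cv, 0.5)
})

test_that("generated logs satisfy the record invariants", {
  log <- generate_log(default_demand(), horizon_days = 120, seed = 11)
  expect_s3_class(log, "tep_log")
  expect_true(all(diff(log$arrival_time) > 0))
  expect_true(all(log$arrival_time >= 0 & log$arrival_time < 120 * 1440))
  expect_true(all(log$service_duration > 0))
  expect_true(all(log$nrs_pain %in% 0:10))
  expect_false(anyDuplicated(log$call_id) > 0)
})

test_that("degenerate generator settings behave as specified", {
  empty <- generate_log(demand_model(arrival_rate = 0), horizon_days = 365,
                        seed = 1)
  expect_equal(nrow(empty), 0)
  all_deleg <- generate_log(demand_model(p_delegation = 1), 60, seed = 2)
  expect_true(all(all_deleg$medication_delegated))
  det <- generate_log(demand_model(service_distribution = "deterministic"),
                      60, seed = 3)
  expect_true(all(det$service_duration == 24.6))
  expect_error(generate_log(default_demand(), horizon_days = 0, seed = 1),
               "horizon_days")
})

test_that("a year at the calibrated rate lands in the Poisson 99% band", {
  # qpois(c(.005, .995), 3.96 * 365) = [1348, 1544]
  log <- generate_log(default_demand(), horizon_days = 365, seed = 7)
  expect_gte(nrow(log), 1348)
  expect_lte(nrow(log), 1544)
})

test_that("same seed reproduces a byte-identical log; streams are split", {
  m <- default_demand()
  a <- generate_log(m, 90, seed = 42)
  b <- generate_log(m, 90, seed = 42)
  expect_identical(a, b)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_log(a, f1); write_log(b, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # changing attribute probabilities must not perturb arrivals or services
  m2 <- demand_model(p_delegation = 0.9, p_no_transport = 0.01)
  c_ <- generate_log(m2, 90, seed = 42)
  expect_identical(a$arrival_time, c_$arrival_time)
  expect_identical(a$service_duration, c_$service_duration)
})

test_that("long-horizon estimates recover the configured parameters", {
  # seed-averaged law-of-large-numbers check: 20 seeds x 10 years
  m <- default_demand()
  est <- vapply(1:20, function(s) {
    log <- generate_log(m, horizon_days = 3650, seed = s)
    r <- estimate_rates(log, 3650)
    gaps <- diff(log$arrival_time)
    c(r$arrival_rate, r$service_mean, mean(gaps))
  }, numeric(3))
  expect_lt(abs(mean(est[1, ]) / 3.96 - 1), 0.02)
  expect_lt(abs(mean(est[2, ]) / 24.6 - 1), 0.02)
  expect_lt(abs(mean(est[3, ]) / (1440 / 3.96) - 1), 0.02)
})

test_that("attribute frequencies converge to configured probabilities", {
  m <- default_demand()
  log <- generate_log(m, horizon_days = 3650, seed = 99)
  n <- nrow(log)
  band <- function(p) 2.576 * sqrt(p * (1 - p) / n)  # binomial 99% band
  expect_lt(abs(mean(log$medication_delegated) - m$p_delegation),
            band(m$p_delegation))
  expect_lt(abs(mean(log$transport_avoided) - m$p_no_transport),
            band(m$p_no_transport))
  expect_lt(abs(mean(log$nrs_pain >= 7) - m$p_nrs_ge7), band(m$p_nrs_ge7))
  # within-bin NRS shape: severe cases sit in 7..10, others in 0..6
  expect_true(all(log$nrs_pain[log$nrs_pain >= 7] %in% 7:10))
})

test_that("generate_cohort yields exactly n records with the same structure", {
  coh <- generate_cohort(default_demand(), n = 500, seed = 5)
  expect_equal(nrow(coh), 500)
  expect_true(all(diff(coh$arrival_time) > 0))
  expect_identical(coh, generate_cohort(default_demand(), n = 500, seed = 5))
})

test_that("logs round-trip through CSV and JSONL field-for-field", {
  log <- generate_log(default_demand(), 30, seed = 13)
  log$nrs_pain[1] <- NA  # missing value must be preserved
  for (fmt in c("csv", "jsonl")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_log(log, f, format = fmt)
    back <- read_log(f)
    expect_equal(as.data.frame(back), as.data.frame(log), tolerance = 0)
    expect_true(is.na(back$nrs_pain[1]))
  }
})

test_that("an empty log round-trips as a header-only CSV", {
  empty <- generate_log(demand_model(arrival_rate = 0), 10, seed = 1)
  f <- withr::local_tempfile(fileext = ".csv")
  write_log(empty, f)
  expect_equal(length(readLines(f)), 1)  # header only
  expect_equal(nrow(read_log(f)), 0)
})

test_that("malformed rows raise a parse error naming the line", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("call_id,arrival_time,service_duration,medication_delegated,transport_avoided,nrs_pain",
               "C1,1.5,10,true,false,3",
               "C2,oops,10,true,false,"), f)
  expect_error(read_log(f), "line 3")
  writeLines(c("bad,header"), f)
  expect_error(read_log(f), "line 1")
})

test_that("estimate_rates handles empty and populated logs", {
  m <- default_demand()
  log <- generate_log(m, 365, seed = 21)
  est <- estimate_rates(log, 365)
  expect_equal(est$arrival_rate, nrow(log) / 365)
  expect_false(est$undefined)
  empty <- generate_log(demand_model(arrival_rate = 0), 10, seed = 1)
  est0 <- estimate_rates(empty, 10)
  expect_equal(est0$arrival_rate, 0)
  expect_true(est0$undefined)
  expect_true(is.na(est0$service_mean))
})
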