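test_that("offered load follows the per-day / minutes convention", {
  expect_equal(offered_load(0, 24.6), 0)
  expect_equal(offered_load(3.96, 24.6), 3.96 * 24.6 / 1440)
  expect_equal(offered_load(20 * 3.96, 24.6), 1.3530)
  expect_error(offered_load(-1, 24.6), "arrival_rate")
  expect_error(offered_load(1, 0), "service_mean")
})

test_that("Erlang B recursion matches the factorial-sum oracle", {
  for (a in c(0.1, 1, 5)) {
    for (k in 0:20) {
      expect_equal(erlang_b(k, a), erlang_b_sum(k, a), tolerance = 1e-12,
                   label = sprintf("B(%d, %g)", k, a))
    }
  }
  expect_equal(erlang_b(0, 3), 1)           # recursion base
  expect_equal(erlang_b(1, 1), 0.5)         # a / (1 + a)
  expect_equal(erlang_b(2, 1.3530), 0.28005484, tolerance = 5e-8)
  expect_lt(erlang_b(10000, 9999), 1)       # stable at large k
})

test_that("Erlang C matches its oracle and the M/M/1 identity", {
  expect_equal(as.numeric(erlang_c(1, 0.3)), 0.3)  # C = rho for k = 1
  expect_equal(as.numeric(erlang_c(3, 1.3530)), erlang_c_sum(3, 1.3530),
               tolerance = 1e-12)
  expect_equal(as.numeric(erlang_c(3, 1.3530)), 0.18703, tolerance = 1e-4)
  expect_equal(as.numeric(erlang_c(5, 1.3530)), 0.013377, tolerance = 1e-4)
  sat <- erlang_c(2, 2.5)
  expect_equal(as.numeric(sat), 1)
  expect_true(attr(sat, "saturated"))
})

test_that("Erlang probabilities are ordered and monotone", {
  for (a in c(0.07, 1.35, 4.5)) {
    ks <- seq.int(floor(a) + 1, floor(a) + 8)
    b <- vapply(ks, erlang_b, numeric(1), a = a)
    c_ <- vapply(ks, function(k) as.numeric(erlang_c(k, a)), numeric(1))
    expect_true(all(c_ >= b))            # waiting dominates blocking
    expect_true(all(diff(b) < 0))        # strictly decreasing in k
    expect_true(all(diff(c_) < 0))
  }
  for (k in c(2L, 5L)) {
    as <- seq(0.1, k - 0.1, length.out = 8)
    c_ <- vapply(as, function(a) as.numeric(erlang_c(k, a)), numeric(1))
    b <- vapply(as, function(a) erlang_b(k, a), numeric(1))
    expect_true(all(diff(c_) > 0))       # strictly increasing in load
    expect_true(all(diff(b) > 0))
  }
})

test_that("performance measures satisfy the exact queueing identities", {
  m <- default_demand()
  for (k in 1:4) {
    p <- performance(k, m)
    lambda_min <- m$arrival_rate / 1440
    expect_equal(p$L, lambda_min * p$W)        # Little's law
    expect_equal(p$Lq, lambda_min * p$Wq)
    expect_equal(p$W, p$Wq + m$service_mean)
    expect_equal(p$utilization, p$offered_load / k)
    expect_equal(p$idle_fraction, 1 - p$utilization)
  }
})

test_that("single calibrated unit idles more than 90% of the time", {
  p <- performance(1, default_demand())
  expect_equal(p$idle_fraction, 1 - 3.96 * 24.6 / 1440)  # 0.93235
  expect_gt(p$idle_fraction, 0.90)
  expect_equal(p$p_wait, p$offered_load)  # M/M/1: C = rho
})

test_that("limits behave: empty system and saturation", {
  quiet <- performance(1, demand_model(arrival_rate = 1e-9))
  expect_lt(quiet$p_wait, 1e-9)
  expect_gt(quiet$idle_fraction, 1 - 1e-9)
  sat <- performance(1, demand_model(arrival_rate = 100, service_mean = 24.6))
  expect_true(sat$saturated)
  expect_equal(sat$p_wait, 1)
  expect_true(is.infinite(sat$Wq) && is.infinite(sat$Lq))
  expect_equal(sat$idle_fraction, 0)
})

test_that("min_servers finds the smallest compliant staffing", {
  m <- default_demand()
  expect_equal(min_servers(m, 0.05), 2)  # C(1) = rho = 0.0677 > 0.05
  m20 <- aggregate_demand(m, 20)
  expect_equal(min_servers(m20, 0.05), 5)
  # target -> 1 gives bare stability
  expect_equal(min_servers(m20, 0.999), floor(offered_load(m20$arrival_rate,
                                                           m20$service_mean)) + 1)
  expect_error(min_servers(m, 0), "target_p_wait")
  expect_error(min_servers(m, 1), "target_p_wait")
})

test_that("min_servers is monotone in load and in the target", {
  m <- default_demand()
  k_by_D <- vapply(c(1, 5, 10, 20, 40), function(D)
    min_servers(aggregate_demand(m, D), 0.05), numeric(1))
  expect_true(all(diff(k_by_D) >= 0))
  k_by_t <- vapply(c(0.3, 0.1, 0.05, 0.01, 0.001), function(t)
    min_servers(aggregate_demand(m, 20), t), numeric(1))
  expect_true(all(diff(k_by_t) >= 0))  # tighter target never needs fewer
})

test_that("max_arrival_rate matches the k = 1 closed form and is monotone", {
  # k = 1: C = rho, so lambda_max = target * 1440 / E[S]
  expect_equal(max_arrival_rate(1, 24.6, 0.05), 0.05 * 1440 / 24.6,
               tolerance = 1e-8)
  expect_equal(max_arrival_rate(1, 24.6, 0.5), 0.5 * 1440 / 24.6,
               tolerance = 1e-8)
  rates <- vapply(1:6, max_arrival_rate, numeric(1),
                  service_mean = 24.6, target_p_wait = 0.05)
  expect_true(all(diff(rates) > 0))
})

test_that("min_servers and max_arrival_rate are mutually consistent", {
  m <- default_demand()
  for (D in c(1, 5, 20)) {
    for (target in c(0.05, 0.2)) {
      mD <- aggregate_demand(m, D)
      a <- offered_load(mD$arrival_rate, mD$service_mean)
      k <- min_servers(mD, target)
      expect_lte(as.numeric(erlang_c(k, a)), target)
      if (k > 1 && a < k - 1)
        expect_gt(as.numeric(erlang_c(k - 1, a)), target)
      # the found k supports at least this demand at the same target
      expect_gte(max_arrival_rate(k, mD$service_mean, target) * (1 + 1e-9),
                 mD$arrival_rate)
    }
  }
})

test_that("max_supported_units floors the supportable pooled demand", {
  expect_equal(max_supported_units(1, 0.1, 24.6, 0.05), 29)  # floor(2.927/0.1)
  expect_equal(max_supported_units(1, 10, 24.6, 0.05), 0)    # unit too heavy
  n1 <- max_supported_units(3, 0.1, 24.6, 0.05)
  n2 <- max_supported_units(3, 0.2, 24.6, 0.05)
  expect_true(n2 >= floor(n1 / 2) - 1 && n2 <= ceiling(n1 / 2))
  expect_error(max_supported_units(1, 0, 24.6, 0.05), "per_unit_rate")
})

test_that("rate estimates from a generated log match the queue inputs", {
  m <- default_demand()
  log <- generate_log(m, horizon_days = 3650, seed = 4)
  est <- estimate_rates(log, 3650)
  expect_lt(abs(est$arrival_rate / 3.96 - 1), 0.02)
  expect_lt(abs(est$service_mean / 24.6 - 1), 0.02)
})
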