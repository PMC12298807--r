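#' Discrete-event simulation of a k-server FIFO queue
#'
#' Simulates one sample path of the TEP queue fed by a demand model:
#' Poisson arrivals, i.i.d. service durations from the configured family
#' (so non-exponential service gives an M/G/k run), `k` servers,
#' infinite buffer, FIFO dispatch to the earliest-free server. Used to
#' cross-validate the closed-form M/M/k results and to extend them.
#'
#' Waiting times follow the multi-server Lindley recursion: an arrival
#' starts service at the maximum of its arrival epoch and the earliest
#' server-free epoch. Statistics are collected only over
#' `[warmup_days, horizon_days]`: per-arrival statistics (`p_wait`,
#' `mean_wait`) over arrivals inside the window, time-averaged
#' statistics (`mean_queue_length`, `server_busy_fraction`) by exact
#' integration of the piecewise-constant queue-length and busy-server
#' processes over the window.
#'
#' @param model A [demand_model()].
#' @param k Number of servers (integer >= 1).
#' @param horizon_days Simulated horizon in days; must exceed
#'   `warmup_days`.
#' @param warmup_days Warm-up period discarded before statistics
#'   collection (default 7 days).
#' @param seed Integer seed; identical seeds give identical sample
#'   paths.
#' @return A list with `p_wait`, `mean_wait` (min),
#'   `mean_queue_length`, `server_busy_fraction`, `n_arrivals` (in the
#'   measurement window), and `arrival_rate_hat` (per day).
#' @examples
#' simulate_queue(demand_model(), k = 1, horizon_days = 60, seed = 42)
#' @export
simulate_queue <- function(model, k, horizon_days, warmup_days = 7, seed) {
  assert_demand_model(model)
  stop_if_invalid(is.numeric(k), length(k) == 1, !is.na(k), k >= 1,
                  k == floor(k), field = "k",
                  msg = "'k' must be a positive integer")
  stop_if_invalid(is.numeric(warmup_days), length(warmup_days) == 1,
                  !is.na(warmup_days), warmup_days >= 0,
                  field = "warmup_days",
                  msg = "'warmup_days' must be non-negative")
  stop_if_invalid(is.numeric(horizon_days), length(horizon_days) == 1,
                  !is.na(horizon_days), horizon_days > warmup_days,
                  field = "horizon_days",
                  msg = "'horizon_days' must exceed 'warmup_days'")
  seeds <- split_seed(seed, 2L)
  horizon_min <- horizon_days * MINUTES_PER_DAY
  warmup_min <- warmup_days * MINUTES_PER_DAY
  t <- sample_arrivals(model$arrival_rate, horizon_min, seeds[1])
  n <- length(t)
  s <- sample_services(model, n, seeds[2])
  start <- numeric(n)
  if (n) {
    free <- numeric(k)  # next-free epoch per server
    for (i in seq_len(n)) {
      j <- which.min(free)
      start[i] <- max(t[i], free[j])
      free[j] <- start[i] + s[i]
    }
  }
  window <- horizon_min - warmup_min
  in_win <- t >= warmup_min
  waits <- start - t
  # exact time integrals of the queue-length and busy-server processes
  overlap <- function(from, to) {
    pmax(0, pmin(to, horizon_min) - pmax(from, warmup_min))
  }
  lq_time <- sum(overlap(t, start))
  busy_time <- sum(overlap(start, start + s))
  n_win <- sum(in_win)
  list(
    p_wait = if (n_win) mean(waits[in_win] > 1e-9) else 0,
    mean_wait = if (n_win) mean(waits[in_win]) else 0,
    mean_queue_length = lq_time / window,
    server_busy_fraction = busy_time / (k * window),
    n_arrivals = n_win,
    arrival_rate_hat = n_win / (window / MINUTES_PER_DAY))
}

#' Replicated simulation with confidence intervals
#'
#' Runs [simulate_queue()] on `n_reps` independent replications (seeds
#' derived from one root seed, verified distinct) and pools the
#' post-warm-up estimates: the pooled value of each measure is the
#' arithmetic mean of the replication estimates, with a 95\% confidence
#' half-width from the Student-t distribution on the replication means.
#'
#' @inheritParams simulate_queue
#' @param n_reps Number of independent replications (>= 2, default 50).
#' @param root_seed Integer root seed for the replication seeds.
#' @return An object of class `simulation_result`: a list with
#'   `replications`, `horizon_days`, `warmup_days`, `estimates` (a
#'   data frame, one row per replication), `pooled` (named means) and
#'   `half_width` (named 95\% CI half-widths).
#' @examples
#' r <- replicate_queue(demand_model(), k = 1, n_reps = 5,
#'                      horizon_days = 60, root_seed = 7)
#' r$pooled["p_wait"]
#' @export
replicate_queue <- function(model, k, n_reps = 50, horizon_days,
                            warmup_days = 7, root_seed) {
  stop_if_invalid(is.numeric(n_reps), length(n_reps) == 1, !is.na(n_reps),
                  n_reps >= 2, n_reps == floor(n_reps), field = "n_reps",
                  msg = "'n_reps' must be an integer >= 2")
  seeds <- split_seed(root_seed, n_reps)  # sampled without replacement
  stopifnot(!anyDuplicated(seeds))
  rows <- lapply(seeds, function(sd)
    as.data.frame(simulate_queue(model, k, horizon_days, warmup_days, sd)))
  est <- do.call(rbind, rows)
  est$seed <- seeds
  measures <- c("p_wait", "mean_wait", "mean_queue_length",
                "server_busy_fraction", "arrival_rate_hat")
  pooled <- vapply(measures, function(m) mean(est[[m]]), numeric(1))
  hw <- vapply(measures, function(m) {
    stats::qt(0.975, n_reps - 1) * stats::sd(est[[m]]) / sqrt(n_reps)
  }, numeric(1))
  structure(
    list(replications = as.integer(n_reps),
         horizon_days = horizon_days,
         warmup_days = warmup_days,
         servers = as.integer(k),
         estimates = est,
         pooled = pooled,
         half_width = hw),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("DES result: %d replications x %.4g days (warm-up %.4g days), k = %d\n",
              x$replications, x$horizon_days, x$warmup_days, x$servers))
  for (m in names(x$pooled))
    cat(sprintf("  %-22s %.5f +/- %.5f\n", m, x$pooled[m], x$half_width[m]))
  invisible(x)
}
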