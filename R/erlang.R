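#' Offered load in Erlangs
#'
#' The offered load of the TEP queue, `a = lambda * E[S]`, with the
#' arrival rate given per day and the mean service time in minutes
#' (1 day = 1440 min). Utilization of a k-server system is `rho = a / k`.
#'
#' @param arrival_rate Arrivals per day (>= 0).
#' @param service_mean Mean service time in minutes (> 0).
#' @return Offered load in Erlangs.
#' @examples
#' offered_load(3.96, 24.6)       # single district: about 0.068 Erlang
#' offered_load(20 * 3.96, 24.6)  # 20 districts:    about 1.35 Erlang
#' @export
offered_load <- function(arrival_rate, service_mean) {
  stop_if_invalid(is.numeric(arrival_rate), all(!is.na(arrival_rate)),
                  all(arrival_rate >= 0), field = "arrival_rate",
                  msg = "'arrival_rate' must be non-negative")
  stop_if_invalid(is.numeric(service_mean), all(!is.na(service_mean)),
                  all(service_mean > 0), field = "service_mean",
                  msg = "'service_mean' must be positive")
  arrival_rate * service_mean / MINUTES_PER_DAY
}

#' Erlang B blocking probability
#'
#' Blocking probability of an M/M/k/k loss system with offered load `a`,
#' computed by the numerically stable recursion
#' `B(0, a) = 1`, `B(k, a) = a B(k-1, a) / (k + a B(k-1, a))`.
#' Stable for `k` up to at least 1e4 (each step stays in (0, 1]).
#'
#' @param k Number of servers (integer >= 0).
#' @param a Offered load in Erlangs (>= 0).
#' @return The blocking probability `B(k, a)`.
#' @examples
#' erlang_b(1, 1)  # a / (1 + a) = 0.5
#' @export
erlang_b <- function(k, a) {
  stop_if_invalid(is.numeric(k), length(k) == 1, !is.na(k), k >= 0,
                  k == floor(k), field = "k",
                  msg = "'k' must be a non-negative integer")
  stop_if_invalid(is.numeric(a), length(a) == 1, !is.na(a), a >= 0,
                  field = "a", msg = "'a' must be non-negative")
  b <- 1
  if (k >= 1) for (i in seq_len(k)) b <- a * b / (i + a * b)
  b
}

#' Erlang C waiting probability
#'
#' Probability that an arriving case finds all `k` servers busy and must
#' wait, in an M/M/k queue with infinite buffer and FIFO discipline:
#' `C(k, a) = k B(k, a) / (k - a (1 - B(k, a)))`. This is the quantity a
#' service-level target such as "delayed physician contact below 5%"
#' bounds. For an unstable system (`a >= k`) the probability is 1 and the
#' result carries a `saturated` attribute instead of raising an error, so
#' scenario sweeps never abort.
#'
#' @inheritParams erlang_b
#' @return The waiting probability, with attribute `saturated` set to
#'   `TRUE` when `a >= k`.
#' @examples
#' erlang_c(1, 0.0677)  # for k = 1 this equals the utilization
#' erlang_c(5, 1.353)   # 20 districts pooled on 5 TEP positions
#' @export
erlang_c <- function(k, a) {
  stop_if_invalid(is.numeric(k), length(k) == 1, !is.na(k), k >= 1,
                  k == floor(k), field = "k",
                  msg = "'k' must be a positive integer")
  stop_if_invalid(is.numeric(a), length(a) == 1, !is.na(a), a >= 0,
                  field = "a", msg = "'a' must be non-negative")
  if (a >= k) return(structure(1, saturated = TRUE))
  b <- erlang_b(k, a)
  structure(k * b / (k - a * (1 - b)), saturated = FALSE)
}

#' Closed-form performance of a k-server TEP queue
#'
#' Steady-state M/M/k (infinite buffer, FIFO) performance measures for a
#' demand model: offered load, utilization, Erlang B and C, the
#' per-server long-run idle fraction `1 - rho`, expected queue length
#' and number in system (`Lq`, `L`), and expected waiting and sojourn
#' times (`Wq`, `W`, minutes). Little's law (`L = lambda W`,
#' `Lq = lambda Wq`) holds exactly by construction.
#'
#' For a saturated system (`a >= k`) the waiting measures are infinite
#' and the result is flagged via `saturated = TRUE`.
#'
#' @param k Number of servers (TEP positions), integer >= 1.
#' @param model A [demand_model()].
#' @return An object of class `performance_measures`: a list with fields
#'   `servers`, `offered_load`, `utilization`, `erlang_b`, `p_wait`,
#'   `idle_fraction`, `Lq`, `L`, `Wq`, `W`, `saturated`.
#' @examples
#' performance(1, demand_model())  # idle fraction about 93%
#' @export
performance <- function(k, model) {
  assert_demand_model(model)
  a <- offered_load(model$arrival_rate, model$service_mean)
  lambda_min <- model$arrival_rate / MINUTES_PER_DAY
  mu_min <- 1 / model$service_mean
  rho <- a / k
  c_ <- erlang_c(k, a)
  saturated <- isTRUE(attr(c_, "saturated"))
  if (saturated) {
    wq <- Inf
  } else {
    wq <- as.numeric(c_) / (k * mu_min - lambda_min)
  }
  w <- wq + model$service_mean
  structure(
    list(servers = as.integer(k),
         offered_load = a,
         utilization = rho,
         erlang_b = erlang_b(k, a),
         p_wait = as.numeric(c_),
         idle_fraction = max(0, 1 - rho),
         Lq = lambda_min * wq,
         L = lambda_min * w,
         Wq = wq,
         W = w,
         saturated = saturated),
    class = "performance_measures")
}

#' @export
print.performance_measures <- function(x, ...) {
  cat(sprintf("M/M/%d performance%s\n", x$servers,
              if (x$saturated) " [SATURATED]" else ""))
  cat(sprintf("  offered load a = %.4f Erlang, utilization rho = %.4f, idle = %.2f%%\n",
              x$offered_load, x$utilization, 100 * x$idle_fraction))
  cat(sprintf("  P(wait) = %.4f (Erlang C), Erlang B = %.4f\n",
              x$p_wait, x$erlang_b))
  cat(sprintf("  Wq = %.3f min, W = %.3f min, Lq = %.4f, L = %.4f\n",
              x$Wq, x$W, x$Lq, x$L))
  invisible(x)
}

#' @export
as.data.frame.performance_measures <- function(x, ...) {
  data.frame(servers = x$servers, offered_load = x$offered_load,
             utilization = x$utilization, erlang_b = x$erlang_b,
             p_wait = x$p_wait, idle_fraction = x$idle_fraction,
             Lq = x$Lq, L = x$L, Wq = x$Wq, W = x$W,
             saturated = x$saturated)
}

#' Minimal number of servers meeting a waiting-probability target
#'
#' Smallest `k` with a stable queue (`a < k`) and Erlang C waiting
#' probability at or below the target, found by a linear scan upward
#' from the stability bound. The target is inclusive (`C <= target`),
#' the standard service-level convention.
#'
#' @param model A [demand_model()].
#' @param target_p_wait Waiting-probability target in (0, 1).
#' @return Integer number of servers.
#' @examples
#' min_servers(demand_model(), 0.05)                       # 2
#' min_servers(aggregate_demand(demand_model(), 20), 0.05) # 5
#' @export
min_servers <- function(model, target_p_wait) {
  assert_demand_model(model)
  stop_if_invalid(is.numeric(target_p_wait), length(target_p_wait) == 1,
                  !is.na(target_p_wait), target_p_wait > 0,
                  target_p_wait < 1, field = "target_p_wait",
                  msg = "'target_p_wait' must be in (0, 1)")
  a <- offered_load(model$arrival_rate, model$service_mean)
  k <- max(1L, as.integer(floor(a)) + 1L)
  while (a >= k || as.numeric(erlang_c(k, a)) > target_p_wait)
    k <- k + 1L
  k
}

#' Maximal arrival rate supportable at a waiting-probability target
#'
#' Largest arrival rate (per day) for which `k` servers keep the Erlang
#' C waiting probability at or below the target, found by bisection on
#' the offered load (Erlang C is strictly increasing in the load) to a
#' relative tolerance of 1e-9.
#'
#' @param k Number of servers (integer >= 1).
#' @param service_mean Mean service time in minutes.
#' @param target_p_wait Waiting-probability target in (0, 1).
#' @return Maximal arrival rate in cases per day; non-decreasing in `k`.
#' @examples
#' max_arrival_rate(1, 24.6, 0.05)  # = 0.05 * 1440 / 24.6 since C = rho at k = 1
#' @export
max_arrival_rate <- function(k, service_mean, target_p_wait) {
  stop_if_invalid(is.numeric(k), length(k) == 1, !is.na(k), k >= 1,
                  k == floor(k), field = "k",
                  msg = "'k' must be a positive integer")
  stop_if_invalid(is.numeric(service_mean), length(service_mean) == 1,
                  !is.na(service_mean), service_mean > 0,
                  field = "service_mean",
                  msg = "'service_mean' must be positive")
  stop_if_invalid(is.numeric(target_p_wait), length(target_p_wait) == 1,
                  !is.na(target_p_wait), target_p_wait > 0,
                  target_p_wait < 1, field = "target_p_wait",
                  msg = "'target_p_wait' must be in (0, 1)")
  lo <- 0
  hi <- k  # C -> 1 as a -> k, so the root lies in (0, k)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (as.numeric(erlang_c(k, mid)) <= target_p_wait) lo <- mid else hi <- mid
    if (hi - lo <= 1e-9 * max(1, lo)) break
  }
  lo * MINUTES_PER_DAY / service_mean
}

#' Maximal number of demand units supportable by k servers
#'
#' Given a per-unit arrival rate (e.g. the TEP call rate generated by
#' one ambulance or one district), the largest integer number of units
#' whose pooled demand still meets the waiting-probability target:
#' `floor(max_arrival_rate / per_unit_rate)`. The per-unit rate is a
#' free parameter: published capacity statements of the form "one TEP
#' supports N ambulances" depend on it.
#'
#' @inheritParams max_arrival_rate
#' @param per_unit_rate TEP cases per day generated by one unit (> 0).
#' @return Integer count of supportable units.
#' @export
max_supported_units <- function(k, per_unit_rate, service_mean,
                                target_p_wait) {
  stop_if_invalid(is.numeric(per_unit_rate), length(per_unit_rate) == 1,
                  !is.na(per_unit_rate), per_unit_rate > 0,
                  field = "per_unit_rate",
                  msg = "'per_unit_rate' must be positive")
  lam <- max_arrival_rate(k, service_mean, target_p_wait)
  as.integer(floor(lam / per_unit_rate + 1e-9))
}
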