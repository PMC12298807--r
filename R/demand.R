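#' Demand model for a tele-emergency physician (TEP) service
#'
#' Bundles the parameters that drive both the synthetic call-log generator
#' and the queueing analysis: the arrival rate of TEP consultations, the
#' service-time distribution, and the case-mix probabilities. Rates are
#' configured per day; all internal computation uses minutes with
#' 1 day = 1440 min.
#'
#' Defaults are calibrated to a rural German district TEP deployment:
#' 3.96 consultations per day with a mean consultation length of 24.6
#' minutes, 17.8\% of cases with delegated medication, 24.3\% resolved
#' without hospital transport, and 12.3\% with severe pain (NRS >= 7).
#'
#' @param arrival_rate Mean number of TEP consultations per day (lambda).
#'   Must be non-negative.
#' @param service_mean Mean consultation duration in minutes (E[S]).
#'   Must be positive.
#' @param service_distribution Service-time family: `"exponential"`
#'   (the M/M/k assumption), `"lognormal"` or `"deterministic"`. The
#'   non-exponential families are intended for M/G/k sensitivity runs
#'   with the discrete-event simulator.
#' @param service_cv Coefficient of variation of the service time. Fixed
#'   at 1 for the exponential family and 0 for the deterministic family;
#'   configurable (default 1) for the lognormal family.
#' @param p_delegation Probability that a case involves delegated
#'   medication.
#' @param p_no_transport Probability that a case is resolved without
#'   hospital transport.
#' @param p_nrs_ge7 Probability that a case reports severe pain
#'   (numerical rating scale >= 7).
#' @return An object of class `demand_model`.
#' @examples
#' m <- demand_model()
#' offered_load(m$arrival_rate, m$service_mean)
#' @export
demand_model <- function(arrival_rate = 3.96,
                         service_mean = 24.6,
                         service_distribution = c("exponential", "lognormal",
                                                  "deterministic"),
                         service_cv = NULL,
                         p_delegation = 0.178,
                         p_no_transport = 0.243,
                         p_nrs_ge7 = 0.123) {
  service_distribution <- match.arg(service_distribution)
  stop_if_invalid(is.numeric(arrival_rate), length(arrival_rate) == 1,
                  !is.na(arrival_rate), arrival_rate >= 0,
                  field = "arrival_rate",
                  msg = "'arrival_rate' must be a single non-negative number")
  stop_if_invalid(is.numeric(service_mean), length(service_mean) == 1,
                  !is.na(service_mean), service_mean > 0,
                  field = "service_mean",
                  msg = "'service_mean' must be a single positive number")
  for (p in c("p_delegation", "p_no_transport", "p_nrs_ge7")) {
    v <- get(p)
    stop_if_invalid(is.numeric(v), length(v) == 1, !is.na(v),
                    v >= 0, v <= 1, field = p,
                    msg = sprintf("'%s' must be a probability in [0, 1]", p))
  }
  cv <- switch(service_distribution,
    exponential = {
      if (!is.null(service_cv) && !isTRUE(all.equal(service_cv, 1)))
        stop("'service_cv' is fixed at 1 for the exponential family",
             call. = FALSE)
      1
    },
    deterministic = {
      if (!is.null(service_cv) && !isTRUE(all.equal(service_cv, 0)))
        stop("'service_cv' is fixed at 0 for the deterministic family",
             call. = FALSE)
      0
    },
    lognormal = {
      cv <- if (is.null(service_cv)) 1 else service_cv
      stop_if_invalid(is.numeric(cv), length(cv) == 1, !is.na(cv), cv > 0,
                      field = "service_cv",
                      msg = "'service_cv' must be positive for the lognormal family")
      cv
    })
  structure(
    list(arrival_rate = arrival_rate,
         service_mean = service_mean,
         service_distribution = service_distribution,
         service_cv = cv,
         p_delegation = p_delegation,
         p_no_transport = p_no_transport,
         p_nrs_ge7 = p_nrs_ge7),
    class = "demand_model")
}

#' @export
print.demand_model <- function(x, ...) {
  cat("TEP demand model\n")
  cat(sprintf("  arrival rate : %.4g cases/day\n", x$arrival_rate))
  cat(sprintf("  service time : %s, mean %.4g min (cv %.3g)\n",
              x$service_distribution, x$service_mean, x$service_cv))
  cat(sprintf("  case mix     : delegation %.1f%%, no transport %.1f%%, NRS>=7 %.1f%%\n",
              100 * x$p_delegation, 100 * x$p_no_transport,
              100 * x$p_nrs_ge7))
  invisible(x)
}

# internal: validation helper that names the offending field
stop_if_invalid <- function(..., field, msg) {
  ok <- vapply(list(...), isTRUE, logical(1))
  if (!all(ok)) stop(msg, " (field: ", field, ")", call. = FALSE)
  invisible(TRUE)
}

is_demand_model <- function(x) inherits(x, "demand_model")

assert_demand_model <- function(model) {
  if (!is_demand_model(model))
    stop("'model' must be a demand_model object", call. = FALSE)
  invisible(model)
}

#' Scale a demand model to several homogeneous districts
#'
#' Superposition of independent Poisson streams: D districts with
#' per-district rate lambda yield an aggregate Poisson stream of rate
#' D * lambda with the same service-time and case-mix structure.
#'
#' @param model A [demand_model()].
#' @param districts Number of districts D (positive integer).
#' @return A `demand_model` with `arrival_rate` multiplied by `districts`.
#' @export
aggregate_demand <- function(model, districts) {
  assert_demand_model(model)
  stop_if_invalid(is.numeric(districts), length(districts) == 1,
                  !is.na(districts), districts >= 1,
                  districts == floor(districts),
                  field = "districts",
                  msg = "'districts' must be a positive integer")
  model$arrival_rate <- model$arrival_rate * districts
  model
}

MINUTES_PER_DAY <- 1440
DAYS_PER_YEAR <- 365
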