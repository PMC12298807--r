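#' Evaluate a TEP deployment scenario for D districts
#'
#' Composes the demand, queueing and cost modules into the
#' decentral-versus-central comparison. Districts are homogeneous:
#' superposition of D independent Poisson streams gives aggregate rate
#' `D * lambda`.
#'
#' Two deployment modes are modeled:
#' \describe{
#'   \item{`central`}{One shared TEP center serves all D districts. It
#'     is staffed with the minimal number of 24/7 positions meeting the
#'     waiting-probability target ([min_servers()]), unless `servers`
#'     overrides the staffing. Costs come from `central_cost_model` at
#'     that staffing and the expected annual caseload
#'     `D * lambda * 365`, shared equally across districts.}
#'   \item{`decentral`}{Each district runs its own standalone single-
#'     position unit (k = 1 by design, matching how a standalone
#'     district unit is operated, whether or not k = 1 meets the
#'     target); the per-district cost is the standalone annual cost.}
#' }
#' The reduction column always compares the scenario's per-district
#' cost against the standalone decentralized baseline, i.e. the annual
#' cost of one k = 1 unit under `baseline_cost_model` at the
#' per-district caseload.
#'
#' The expected caseload (not a simulated draw) prices variable costs,
#' keeping scenario results deterministic.
#'
#' @param per_district_model A [demand_model()] for one district.
#' @param districts Number of participating districts D (integer >= 1).
#' @param target_p_wait Waiting-probability target (default 0.05).
#' @param central_cost_model [cost_model()] of the shared center
#'   (default [default_cost_model()]).
#' @param baseline_cost_model [cost_model()] of a standalone district
#'   unit (default [default_cost_model()]).
#' @param servers Optional staffing override for the central mode.
#' @param mode `"central"` (shared center, default) or `"decentral"`
#'   (one unit per district).
#' @return An object of class `scenario_result`: a list with
#'   `districts`, `mode`, `aggregate_arrival_rate`, `servers`,
#'   `performance` (a `performance_measures` object), `cases_per_year`,
#'   `total_cost`, `cost_per_district`, `reduction_vs_standalone`.
#' @examples
#' run_scenario(demand_model(), districts = 20)
#' @export
run_scenario <- function(per_district_model, districts,
                         target_p_wait = 0.05,
                         central_cost_model = default_cost_model(),
                         baseline_cost_model = default_cost_model(),
                         servers = NULL,
                         mode = c("central", "decentral")) {
  mode <- match.arg(mode)
  assert_demand_model(per_district_model)
  agg <- aggregate_demand(per_district_model, districts)
  lambda <- per_district_model$arrival_rate
  baseline_single <- annual_cost(baseline_cost_model, 1,
                                 lambda * DAYS_PER_YEAR)
  if (mode == "central") {
    k <- if (is.null(servers)) min_servers(agg, target_p_wait)
         else as.integer(servers)
    perf <- performance(k, agg)
    cases <- agg$arrival_rate * DAYS_PER_YEAR
    total <- annual_cost(central_cost_model, k, cases)
    per_district <- cost_per_district(total, districts)
  } else {
    k <- 1L
    perf <- performance(1L, per_district_model)
    cases <- agg$arrival_rate * DAYS_PER_YEAR
    per_district <- baseline_single
    total <- baseline_single * districts
  }
  structure(
    list(districts = as.integer(districts),
         mode = mode,
         aggregate_arrival_rate = agg$arrival_rate,
         servers = k,
         performance = perf,
         cases_per_year = cases,
         total_cost = total,
         cost_per_district = per_district,
         reduction_vs_standalone = cost_reduction(baseline_single,
                                                  per_district)),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("%s scenario, D = %d districts\n",
              if (x$mode == "central") "Centralized" else "Decentralized",
              x$districts))
  cat(sprintf("  aggregate demand %.3f cases/day, k = %d position(s), P(wait) = %.4f\n",
              x$aggregate_arrival_rate, x$servers, x$performance$p_wait))
  cat(sprintf("  total cost %s EUR/year, per district %s EUR/year (%.1f%% vs standalone)\n",
              format(round(x$total_cost), big.mark = ","),
              format(round(x$cost_per_district), big.mark = ","),
              x$reduction_vs_standalone))
  invisible(x)
}

#' @export
as.data.frame.scenario_result <- function(x, ...) {
  data.frame(districts = x$districts, mode = x$mode,
             aggregate_arrival_rate = x$aggregate_arrival_rate,
             servers = x$servers, p_wait = x$performance$p_wait,
             utilization = x$performance$utilization,
             idle_fraction = x$performance$idle_fraction,
             Wq = x$performance$Wq,
             cases_per_year = x$cases_per_year,
             total_cost = x$total_cost,
             cost_per_district = x$cost_per_district,
             reduction_vs_standalone = x$reduction_vs_standalone,
             stringsAsFactors = FALSE)
}

#' Cost curve over the number of participating districts
#'
#' Evaluates the centralized scenario for every D in 1..D_max and
#' appends the decentralized total for comparison, yielding the cost
#' functions of the central and decentral deployment options as a
#' function of the number of districts joining the shared center.
#'
#' @inheritParams run_scenario
#' @param D_max Largest number of districts (integer >= 1).
#' @return A data frame, one row per D, with the columns of
#'   [as.data.frame.scenario_result()] plus `decentral_total_cost`.
#' @examples
#' sweep_districts(demand_model(), D_max = 20)
#' @export
sweep_districts <- function(per_district_model, D_max,
                            target_p_wait = 0.05,
                            central_cost_model = default_cost_model(),
                            baseline_cost_model = default_cost_model()) {
  stop_if_invalid(is.numeric(D_max), length(D_max) == 1, !is.na(D_max),
                  D_max >= 1, D_max == floor(D_max), field = "D_max",
                  msg = "'D_max' must be a positive integer")
  lambda <- per_district_model$arrival_rate
  baseline_single <- annual_cost(baseline_cost_model, 1,
                                 lambda * DAYS_PER_YEAR)
  rows <- lapply(seq_len(D_max), function(D) {
    r <- as.data.frame(run_scenario(per_district_model, D, target_p_wait,
                                    central_cost_model,
                                    baseline_cost_model))
    r$decentral_total_cost <- baseline_single * D
    r
  })
  do.call(rbind, rows)
}

#' Sensitivity sweep over demand and target parameters
#'
#' Evaluates the centralized scenario over the Cartesian product of the
#' supplied arrival rates, service means and waiting-probability
#' targets, at a fixed district count. Returns a long-format table, one
#' row per grid point.
#'
#' @inheritParams run_scenario
#' @param arrival_rates Vector of per-district arrival rates (per day).
#' @param service_means Vector of mean service times (minutes).
#' @param targets Vector of waiting-probability targets.
#' @param districts Number of districts held fixed across the grid.
#' @return A data frame with the grid columns and the scenario
#'   projection for each point.
#' @export
sensitivity <- function(per_district_model = demand_model(),
                        arrival_rates = per_district_model$arrival_rate,
                        service_means = per_district_model$service_mean,
                        targets = 0.05,
                        districts = 20,
                        central_cost_model = default_cost_model(),
                        baseline_cost_model = default_cost_model()) {
  stop_if_invalid(all(arrival_rates >= 0), field = "arrival_rates",
                  msg = "'arrival_rates' must be non-negative")
  stop_if_invalid(all(service_means > 0), field = "service_means",
                  msg = "'service_means' must be positive")
  stop_if_invalid(all(targets > 0), all(targets < 1), field = "targets",
                  msg = "'targets' must be in (0, 1)")
  grid <- expand.grid(arrival_rate = arrival_rates,
                      service_mean = service_means,
                      target_p_wait = targets,
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0) stop("empty sensitivity grid", call. = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    m <- per_district_model
    m$arrival_rate <- grid$arrival_rate[i]
    m$service_mean <- grid$service_mean[i]
    r <- as.data.frame(run_scenario(m, districts, grid$target_p_wait[i],
                                    central_cost_model,
                                    baseline_cost_model))
    cbind(grid[i, , drop = FALSE], r[setdiff(names(r), "mode")],
          row.names = NULL)
  })
  do.call(rbind, rows)
}
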