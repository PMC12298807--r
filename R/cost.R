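#' Cost components and full-cost models
#'
#' A cost model is a collection of components of three kinds, following
#' the full-cost accounting of a 24/7 TEP operation:
#' \describe{
#'   \item{`fixed`}{EUR per year, independent of capacity and caseload
#'     (e.g. office infrastructure, administration).}
#'   \item{`jump_fixed`}{EUR per staffed 24/7 server position per year;
#'     steps up with each additional position (e.g. staff salaries,
#'     telemedicine equipment, licences).}
#'   \item{`variable`}{EUR per handled case.}
#' }
#' Annual cost is additive over components; amounts are kept exact
#' (integer EUR components stay integers) and rounded only at report
#' time.
#'
#' @param label Component label.
#' @param kind One of `"fixed"`, `"jump_fixed"`, `"variable"`.
#' @param amount Non-negative amount; the unit follows the kind.
#' @return `cost_component()` returns a one-row data frame;
#'   `cost_model()` an object of class `cost_model`.
#' @examples
#' cm <- cost_model(
#'   cost_component("infrastructure & administration", "fixed", 148876),
#'   cost_component("staff, equipment, licences", "jump_fixed", 548073))
#' annual_cost(cm, servers = 1, cases_per_year = 3.96 * 365)
#' @export
cost_component <- function(label, kind = c("fixed", "jump_fixed", "variable"),
                           amount) {
  kind <- match.arg(kind)
  stop_if_invalid(is.character(label), length(label) == 1, nzchar(label),
                  field = "label", msg = "'label' must be a non-empty string")
  stop_if_invalid(is.numeric(amount), length(amount) == 1, !is.na(amount),
                  amount >= 0, field = "amount",
                  msg = "'amount' must be non-negative")
  data.frame(label = label, kind = kind, amount = amount,
             stringsAsFactors = FALSE)
}

#' @rdname cost_component
#' @param ... For `cost_model()`: components built with
#'   `cost_component()`, or a single data frame with columns `label`,
#'   `kind`, `amount`.
#' @param currency Currency code (informational; default `"EUR"`).
#' @export
cost_model <- function(..., currency = "EUR") {
  parts <- list(...)
  if (length(parts) == 1 && is.data.frame(parts[[1]]))
    components <- parts[[1]]
  else
    components <- do.call(rbind, parts)
  if (is.null(components) || nrow(components) == 0)
    stop("a cost model needs at least one component (field: components)",
         call. = FALSE)
  if (!all(c("label", "kind", "amount") %in% names(components)))
    stop("components need columns label, kind, amount (field: components)",
         call. = FALSE)
  bad <- !components$kind %in% c("fixed", "jump_fixed", "variable")
  if (any(bad))
    stop("unknown component kind: ", components$kind[bad][1],
         " (field: kind)", call. = FALSE)
  if (any(is.na(components$amount)) || any(components$amount < 0))
    stop("component amounts must be non-negative (field: amount)",
         call. = FALSE)
  structure(list(components = components, currency = currency),
            class = "cost_model")
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf("Cost model (%s), %d components\n", x$currency,
              nrow(x$components)))
  unit <- c(fixed = "/year", jump_fixed = "/position/year",
            variable = "/case")
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  %-12s %12s %s%s\n", x$components$kind[i],
                format(x$components$amount[i], big.mark = ","),
                x$currency, unit[[x$components$kind[i]]]))
  invisible(x)
}

#' Default decentralized TEP cost configuration
#'
#' The full-cost configuration of one decentralized 24/7 TEP unit:
#' EUR 148,876 per year fixed (office infrastructure, administration)
#' plus EUR 548,073 per staffed 24/7 server position per year (staff
#' salaries, telemedicine equipment, licences), summing to EUR 696,949
#' at one position. The published accounts do not split the second
#' figure between per-case variable and jump-fixed parts, so the default
#' books it entirely as one jump-fixed component; `variable_share`
#' re-splits it as a per-case amount at the reference caseload of
#' 3.96 cases/day if a different allocation is wanted.
#'
#' @param variable_share Fraction of the EUR 548,073 block booked as
#'   per-case variable cost (default 0, i.e. all jump-fixed).
#' @return A [cost_model()].
#' @export
default_cost_model <- function(variable_share = 0) {
  stop_if_invalid(is.numeric(variable_share), length(variable_share) == 1,
                  !is.na(variable_share), variable_share >= 0,
                  variable_share <= 1, field = "variable_share",
                  msg = "'variable_share' must be in [0, 1]")
  fixed <- cost_component("office infrastructure & administration",
                          "fixed", 148876)
  block <- 548073
  ref_cases <- 3.96 * DAYS_PER_YEAR
  if (variable_share == 0) {
    cost_model(fixed,
               cost_component("staff, telemedicine equipment, licences",
                              "jump_fixed", block))
  } else if (variable_share == 1) {
    cost_model(fixed,
               cost_component("per-case operating cost", "variable",
                              block / ref_cases))
  } else {
    cost_model(fixed,
               cost_component("staff, telemedicine equipment, licences",
                              "jump_fixed", block * (1 - variable_share)),
               cost_component("per-case operating cost", "variable",
                              block * variable_share / ref_cases))
  }
}

#' Annual full cost of operating a TEP service
#'
#' Sum of all components: fixed amounts, jump-fixed amounts times the
#' number of staffed 24/7 server positions, and variable amounts times
#' the annual caseload. No rounding is applied; round at report time.
#'
#' @param model A [cost_model()].
#' @param servers Number of staffed 24/7 server positions (integer
#'   >= 1).
#' @param cases_per_year Annual caseload (>= 0).
#' @return Annual cost in the model's currency.
#' @export
annual_cost <- function(model, servers, cases_per_year) {
  if (!inherits(model, "cost_model"))
    stop("'model' must be a cost_model object", call. = FALSE)
  stop_if_invalid(is.numeric(servers), length(servers) == 1,
                  !is.na(servers), servers >= 1,
                  servers == floor(servers), field = "servers",
                  msg = "'servers' must be an integer >= 1")
  stop_if_invalid(is.numeric(cases_per_year), length(cases_per_year) == 1,
                  !is.na(cases_per_year), cases_per_year >= 0,
                  field = "cases_per_year",
                  msg = "'cases_per_year' must be non-negative")
  comp <- model$components
  amt <- comp$amount
  sum(amt[comp$kind == "fixed"]) +
    sum(amt[comp$kind == "jump_fixed"]) * servers +
    sum(amt[comp$kind == "variable"]) * cases_per_year
}

#' Per-district share of a total annual cost
#'
#' @param total Total annual cost (EUR).
#' @param districts Number of districts sharing it (integer >= 1).
#' @return `total / districts`.
#' @examples
#' cost_per_district(1146000, 20)  # 57,300
#' @export
cost_per_district <- function(total, districts) {
  stop_if_invalid(is.numeric(total), length(total) == 1, !is.na(total),
                  field = "total", msg = "'total' must be a number")
  stop_if_invalid(is.numeric(districts), length(districts) == 1,
                  !is.na(districts), districts >= 1,
                  districts == floor(districts), field = "districts",
                  msg = "'districts' must be an integer >= 1")
  total / districts
}

#' Percentage cost reduction versus a baseline
#'
#' `100 * (1 - scenario / baseline)`: positive when the scenario is
#' cheaper than the baseline.
#'
#' @param baseline_per_district Baseline per-district annual cost (> 0).
#' @param scenario_per_district Scenario per-district annual cost.
#' @return Reduction in percent.
#' @examples
#' cost_reduction(696949, 57300)  # about 91.8%
#' @export
cost_reduction <- function(baseline_per_district, scenario_per_district) {
  stop_if_invalid(is.numeric(baseline_per_district),
                  length(baseline_per_district) == 1,
                  !is.na(baseline_per_district), baseline_per_district > 0,
                  field = "baseline_per_district",
                  msg = "'baseline_per_district' must be positive")
  stop_if_invalid(is.numeric(scenario_per_district),
                  length(scenario_per_district) == 1,
                  !is.na(scenario_per_district),
                  field = "scenario_per_district",
                  msg = "'scenario_per_district' must be a number")
  100 * (1 - scenario_per_district / baseline_per_district)
}
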