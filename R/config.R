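#' Default run configuration
#'
#' The complete configuration of a planning run as a nested list with
#' one section per module: `demand` (arrival and service parameters,
#' case mix), `queue` (staffing and the waiting-probability target),
#' `simulation` (replications, horizon, warm-up), `costs` (currency and
#' components), `scenario` (district counts) and `run` (seed, horizon
#' for log generation, output directory). Configuration files are YAML
#' with exactly these sections; unknown keys are rejected so typos
#' cannot silently fall back to defaults.
#'
#' @return A nested list of defaults.
#' @export
default_config <- function() {
  list(
    demand = list(
      arrival_rate = 3.96,
      service_mean = 24.6,
      service_distribution = "exponential",
      service_cv = 1,
      p_delegation = 0.178,
      p_no_transport = 0.243,
      p_nrs_ge7 = 0.123),
    queue = list(
      servers = 1L,
      target_p_wait = 0.05),
    simulation = list(
      n_reps = 50L,
      horizon_days = 365,
      warmup_days = 7),
    costs = list(
      currency = "EUR",
      components = list(
        list(label = "office infrastructure & administration",
             kind = "fixed", amount = 148876),
        list(label = "staff, telemedicine equipment, licences",
             kind = "jump_fixed", amount = 548073))),
    scenario = list(
      districts = 20L,
      d_max = 20L),
    run = list(
      seed = 1L,
      horizon_days = 365,
      output_dir = "."))
}

#' Read a run configuration from a YAML file
#'
#' Values in the file override the defaults section by section; any key
#' not present in [default_config()] raises an error naming it.
#'
#' @param path Path to a YAML configuration file; `NULL` returns the
#'   defaults unchanged.
#' @return A validated configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("config file must be a YAML mapping", call. = FALSE)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown config section: ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (section in names(user)) {
    if (section == "costs") {
      bad <- setdiff(names(user$costs), c("currency", "components"))
      if (length(bad))
        stop("unknown config key: costs.", bad[1], call. = FALSE)
      cfg$costs[names(user$costs)] <- user$costs
      next
    }
    bad <- setdiff(names(user[[section]]), names(cfg[[section]]))
    if (length(bad))
      stop("unknown config key: ", section, ".", bad[1], call. = FALSE)
    cfg[[section]][names(user[[section]])] <- user[[section]]
  }
  cfg
}

#' Build model objects from a configuration
#'
#' @param cfg A configuration list from [read_config()].
#' @return `config_demand_model()` returns a [demand_model()];
#'   `config_cost_model()` a [cost_model()].
#' @export
config_demand_model <- function(cfg) {
  d <- cfg$demand
  demand_model(arrival_rate = d$arrival_rate,
               service_mean = d$service_mean,
               service_distribution = d$service_distribution,
               service_cv = if (identical(d$service_distribution,
                                          "lognormal")) d$service_cv,
               p_delegation = d$p_delegation,
               p_no_transport = d$p_no_transport,
               p_nrs_ge7 = d$p_nrs_ge7)
}

#' @rdname config_demand_model
#' @export
config_cost_model <- function(cfg) {
  comps <- do.call(rbind, lapply(cfg$costs$components, function(x)
    cost_component(x$label, x$kind, x$amount)))
  cost_model(comps, currency = cfg$costs$currency)
}

# internal: stable hash of a configuration for run logging
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}
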