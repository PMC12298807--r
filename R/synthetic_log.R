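#' Generate a synthetic TEP call log
#'
#' Simulates a consultation log with the statistical structure the
#' economic model assumes: homogeneous Poisson arrivals, i.i.d. service
#' durations from the configured family, and i.i.d. Bernoulli case
#' attributes. Each record carries an identifier, the arrival time in
#' minutes since the start of the horizon, the service duration in
#' minutes, and three case-mix attributes.
#'
#' The root seed is split into independent sub-streams for arrivals,
#' service durations and case attributes, so changing an attribute
#' probability (or adding attributes) never perturbs the arrival times.
#'
#' @param model A [demand_model()].
#' @param horizon_days Length of the simulated horizon in days (> 0).
#' @param seed Integer root seed; the same `(model, horizon_days, seed)`
#'   triple always yields a byte-identical log.
#' @return A `data.frame` of class `tep_log` with columns `call_id`,
#'   `arrival_time` (min), `service_duration` (min),
#'   `medication_delegated`, `transport_avoided` (logical) and
#'   `nrs_pain` (integer 0--10, `NA` allowed).
#' @examples
#' log <- generate_log(demand_model(), horizon_days = 30, seed = 1)
#' head(log)
#' @export
generate_log <- function(model, horizon_days, seed) {
  assert_demand_model(model)
  stop_if_invalid(is.numeric(horizon_days), length(horizon_days) == 1,
                  !is.na(horizon_days), horizon_days > 0,
                  field = "horizon_days",
                  msg = "'horizon_days' must be a single positive number")
  seeds <- split_seed(seed, 3L)
  horizon_min <- horizon_days * MINUTES_PER_DAY
  arrival_time <- sample_arrivals(model$arrival_rate, horizon_min, seeds[1])
  n <- length(arrival_time)
  service_duration <- sample_services(model, n, seeds[2])
  attrs <- sample_attributes(model, n, seeds[3])
  out <- data.frame(
    call_id = if (n) sprintf("C%06d", seq_len(n)) else character(0),
    arrival_time = arrival_time,
    service_duration = service_duration,
    medication_delegated = attrs$medication_delegated,
    transport_avoided = attrs$transport_avoided,
    nrs_pain = attrs$nrs_pain,
    stringsAsFactors = FALSE)
  class(out) <- c("tep_log", "data.frame")
  out
}

#' Generate a synthetic cohort of exactly n case records
#'
#' Like [generate_log()] but with a fixed number of cases rather than a
#' fixed horizon: arrival times are the first `n` points of the Poisson
#' process. Useful for calibration checks of the case-mix fractions at a
#' prescribed cohort size.
#'
#' @inheritParams generate_log
#' @param n Number of case records to generate (positive integer).
#' @return A `tep_log` data frame with `n` rows.
#' @export
generate_cohort <- function(model, n, seed) {
  assert_demand_model(model)
  stop_if_invalid(is.numeric(n), length(n) == 1, !is.na(n), n >= 1,
                  n == floor(n), field = "n",
                  msg = "'n' must be a positive integer")
  stop_if_invalid(model$arrival_rate > 0, field = "arrival_rate",
                  msg = "'arrival_rate' must be positive to generate a fixed-size cohort")
  seeds <- split_seed(seed, 3L)
  rate_per_min <- model$arrival_rate / MINUTES_PER_DAY
  arrival_time <- local({
    set.seed(seeds[1])
    cumsum(stats::rexp(n, rate = rate_per_min))
  })
  service_duration <- sample_services(model, n, seeds[2])
  attrs <- sample_attributes(model, n, seeds[3])
  out <- data.frame(
    call_id = sprintf("C%06d", seq_len(n)),
    arrival_time = arrival_time,
    service_duration = service_duration,
    medication_delegated = attrs$medication_delegated,
    transport_avoided = attrs$transport_avoided,
    nrs_pain = attrs$nrs_pain,
    stringsAsFactors = FALSE)
  class(out) <- c("tep_log", "data.frame")
  out
}

# internal: derive independent sub-stream seeds from one root seed
split_seed <- function(seed, n) {
  stop_if_invalid(is.numeric(seed), length(seed) == 1, !is.na(seed),
                  seed == floor(seed), field = "seed",
                  msg = "'seed' must be a single integer")
  set.seed(as.integer(seed %% .Machine$integer.max))
  sample.int(.Machine$integer.max, n)
}

# internal: Poisson arrival epochs on [0, horizon_min)
sample_arrivals <- function(rate_per_day, horizon_min, seed) {
  if (rate_per_day == 0) return(numeric(0))
  rate_per_min <- rate_per_day / MINUTES_PER_DAY
  set.seed(seed)
  expected <- horizon_min * rate_per_min
  times <- numeric(0)
  last <- 0
  repeat {
    chunk <- max(100L, ceiling(expected + 10 * sqrt(expected)))
    gaps <- stats::rexp(chunk, rate = rate_per_min)
    times <- c(times, last + cumsum(gaps))
    last <- times[length(times)]
    if (last >= horizon_min) break
    expected <- (horizon_min - last) * rate_per_min
  }
  times[times < horizon_min]
}

# internal: i.i.d. service durations with the configured family and mean
sample_services <- function(model, n, seed) {
  if (n == 0) return(numeric(0))
  set.seed(seed)
  m <- model$service_mean
  switch(model$service_distribution,
    exponential = stats::rexp(n, rate = 1 / m),
    deterministic = rep(m, n),
    lognormal = {
      sdlog <- sqrt(log(1 + model$service_cv^2))
      meanlog <- log(m) - sdlog^2 / 2
      stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
    })
}

# internal: Bernoulli case attributes; NRS drawn uniformly within the
# severe {7..10} or non-severe {0..6} bin
sample_attributes <- function(model, n, seed) {
  if (n == 0)
    return(list(medication_delegated = logical(0),
                transport_avoided = logical(0),
                nrs_pain = integer(0)))
  set.seed(seed)
  medication_delegated <- stats::runif(n) < model$p_delegation
  transport_avoided <- stats::runif(n) < model$p_no_transport
  severe <- stats::runif(n) < model$p_nrs_ge7
  nrs <- integer(n)
  nrs[severe] <- sample(7:10, sum(severe), replace = TRUE)
  nrs[!severe] <- sample(0:6, sum(!severe), replace = TRUE)
  list(medication_delegated = medication_delegated,
       transport_avoided = transport_avoided,
       nrs_pain = nrs)
}

LOG_COLUMNS <- c("call_id", "arrival_time", "service_duration",
                 "medication_delegated", "transport_avoided", "nrs_pain")

# internal: structural validation of a call log
assert_tep_log <- function(records) {
  if (!is.data.frame(records) || !all(LOG_COLUMNS %in% names(records)))
    stop("'records' must be a call-log data frame with columns ",
         paste(LOG_COLUMNS, collapse = ", "), call. = FALSE)
  if (nrow(records)) {
    if (any(is.na(records$arrival_time)) || any(records$arrival_time < 0))
      stop("arrival_time must be non-negative (field: arrival_time)",
           call. = FALSE)
    if (any(diff(records$arrival_time) < 0))
      stop("arrival_time must be non-decreasing (field: arrival_time)",
           call. = FALSE)
    if (any(is.na(records$service_duration)) ||
        any(records$service_duration <= 0))
      stop("service_duration must be positive (field: service_duration)",
           call. = FALSE)
    nrs <- records$nrs_pain[!is.na(records$nrs_pain)]
    if (any(nrs < 0 | nrs > 10 | nrs != floor(nrs)))
      stop("nrs_pain must be an integer in 0..10 or missing (field: nrs_pain)",
           call. = FALSE)
  }
  invisible(records)
}

#' Write a TEP call log to disk
#'
#' Serializes a call log as CSV (comma-delimited, header row, UTF-8,
#' times as decimal minutes) or JSONL (one JSON object per line).
#' Numeric fields are written with 17 significant digits so that
#' [read_log()] round-trips field-for-field, and a missing `nrs_pain` is
#' written as an empty CSV field / JSON `null`.
#'
#' @param records A call-log data frame as returned by [generate_log()].
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_log <- function(records, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  assert_tep_log(records)
  n <- nrow(records)
  num <- function(x) sprintf("%.17g", x)
  if (format == "csv") {
    lines <- paste(LOG_COLUMNS, collapse = ",")
    if (n) {
      body <- paste(
        records$call_id,
        num(records$arrival_time),
        num(records$service_duration),
        ifelse(records$medication_delegated, "true", "false"),
        ifelse(records$transport_avoided, "true", "false"),
        ifelse(is.na(records$nrs_pain), "",
               as.character(records$nrs_pain)),
        sep = ",")
      lines <- c(lines, body)
    }
  } else {
    lines <- if (n) {
      vapply(seq_len(n), function(i) {
        sprintf(
          '{"call_id":"%s","arrival_time":%s,"service_duration":%s,"medication_delegated":%s,"transport_avoided":%s,"nrs_pain":%s}',
          records$call_id[i],
          num(records$arrival_time[i]),
          num(records$service_duration[i]),
          if (records$medication_delegated[i]) "true" else "false",
          if (records$transport_avoided[i]) "true" else "false",
          if (is.na(records$nrs_pain[i])) "null"
          else as.character(records$nrs_pain[i]))
      }, character(1))
    } else character(0)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a TEP call log from disk
#'
#' Inverse of [write_log()]; the format is inferred from the file
#' content (a leading `{` marks JSONL). Malformed rows raise a parse
#' error naming the offending line.
#'
#' @param path Path to a CSV or JSONL call log.
#' @return A `tep_log` data frame.
#' @export
read_log <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  jsonl <- length(lines) > 0 && grepl("^\\s*\\{", lines[1])
  if (jsonl) {
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e)
                        stop("parse error at line ", i, ": ",
                             conditionMessage(e), call. = FALSE))
      if (!all(LOG_COLUMNS[-6] %in% names(rec)))
        stop("parse error at line ", i, ": missing fields", call. = FALSE)
      rec$nrs_pain <- if (is.null(rec$nrs_pain)) NA_integer_
                      else as.integer(rec$nrs_pain)
      rec
    })
    out <- data.frame(
      call_id = vapply(recs, function(r) as.character(r$call_id), ""),
      arrival_time = vapply(recs, function(r) as.numeric(r$arrival_time), 0),
      service_duration = vapply(recs, function(r) as.numeric(r$service_duration), 0),
      medication_delegated = vapply(recs, function(r) as.logical(r$medication_delegated), NA),
      transport_avoided = vapply(recs, function(r) as.logical(r$transport_avoided), NA),
      nrs_pain = vapply(recs, function(r) r$nrs_pain, NA_integer_),
      stringsAsFactors = FALSE)
  } else {
    if (length(lines) == 0 || lines[1] != paste(LOG_COLUMNS, collapse = ","))
      stop("parse error at line 1: expected header '",
           paste(LOG_COLUMNS, collapse = ","), "'", call. = FALSE)
    body <- lines[-1]
    fields <- strsplit(body, ",", fixed = TRUE)
    parse_num <- function(s, i, what) {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) stop("parse error at line ", i + 1L,
                         ": invalid ", what, call. = FALSE)
      v
    }
    parse_bool <- function(s, i, what) {
      if (s %in% c("true", "TRUE", "True")) return(TRUE)
      if (s %in% c("false", "FALSE", "False")) return(FALSE)
      stop("parse error at line ", i + 1L, ": invalid ", what, call. = FALSE)
    }
    n <- length(body)
    out <- data.frame(
      call_id = character(n), arrival_time = numeric(n),
      service_duration = numeric(n), medication_delegated = logical(n),
      transport_avoided = logical(n), nrs_pain = rep(NA_integer_, n),
      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      f <- fields[[i]]
      # a trailing empty nrs_pain field is dropped by strsplit
      if (length(f) == 5 && endsWith(body[i], ",")) f <- c(f, "")
      if (length(f) != 6)
        stop("parse error at line ", i + 1L, ": expected 6 fields, got ",
             length(f), call. = FALSE)
      out$call_id[i] <- f[1]
      out$arrival_time[i] <- parse_num(f[2], i, "arrival_time")
      out$service_duration[i] <- parse_num(f[3], i, "service_duration")
      out$medication_delegated[i] <- parse_bool(f[4], i, "medication_delegated")
      out$transport_avoided[i] <- parse_bool(f[5], i, "transport_avoided")
      out$nrs_pain[i] <- if (f[6] == "") NA_integer_
                         else as.integer(parse_num(f[6], i, "nrs_pain"))
    }
  }
  assert_tep_log(out)
  class(out) <- c("tep_log", "data.frame")
  out
}

#' Estimate demand parameters from a call log
#'
#' Point estimates of the arrival rate (records per day of horizon) and
#' the mean service duration, i.e. the empirical quantities a planning
#' study would extract from an EMS IT system.
#'
#' @param log A call-log data frame.
#' @param horizon_days Observation horizon in days (> 0).
#' @return A list with `arrival_rate` (per day), `service_mean` (min;
#'   `NA` for an empty log) and `undefined` (`TRUE` when the log is
#'   empty, so the service mean is undefined).
#' @export
estimate_rates <- function(log, horizon_days) {
  assert_tep_log(log)
  stop_if_invalid(is.numeric(horizon_days), length(horizon_days) == 1,
                  !is.na(horizon_days), horizon_days > 0,
                  field = "horizon_days",
                  msg = "'horizon_days' must be a single positive number")
  n <- nrow(log)
  list(arrival_rate = n / horizon_days,
       service_mean = if (n) mean(log$service_duration) else NA_real_,
       undefined = n == 0)
}
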