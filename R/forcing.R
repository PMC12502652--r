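#' Read a mesocosm experiment from CSV
#'
#' Loads the four-table CSV schema: `tanks.csv` (tank_id, population,
#' treatment), `sensors.csv` (tank_id, timestamp, variable, value; ISO-8601
#' timestamps), `counts.csv` (tank_id, day, replicate, count in cells mL^-1)
#' and `samples.csv` (tank_id, day, PC, PN, PP, chl_a, TDN, TDP, SRP).
#' The schema is documented in `inst/extdata/schema.md`.
#'
#' @param dir Directory containing the four CSV files.
#' @return List of class `experiment_dataset` with elements `tanks`,
#'   `sensors`, `counts`, `samples`.  Sensor timestamps are parsed to POSIXct
#'   (UTC) and a `day` column is derived relative to the earliest sensor date
#'   (Day 0 = inoculation day).
#' @export
read_experiment <- function(dir) {
  files <- c(tanks = "tanks.csv", sensors = "sensors.csv",
             counts = "counts.csv", samples = "samples.csv")
  missing <- files[!file.exists(file.path(dir, files))]
  if (length(missing))
    stop("experiment directory lacks: ", paste(missing, collapse = ", "))
  ds <- lapply(files, function(f)
    utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE))
  ds$sensors$timestamp <- parse_timestamp(ds$sensors$timestamp)
  day0 <- min(as.Date(ds$sensors$timestamp))
  ds$sensors$day <- as.integer(as.Date(ds$sensors$timestamp) - day0)
  attr(ds, "day0") <- day0
  class(ds) <- "experiment_dataset"
  ds
}

parse_timestamp <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (anyNA(out))
    stop("unparseable ISO-8601 timestamp(s), e.g. ", x[which(is.na(out))[1]])
  out
}

parse_hhmm <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  as.integer(parts[1]) * 60L + as.integer(parts[2])
}

#' Sampling-window means of sensor series
#'
#' Reduces a 10-minute-cadence sensor stream to one value per (tank, day,
#' variable): the arithmetic mean of readings whose local time falls in the
#' closed-open window (default 07:00-09:00, the morning grab-sampling
#' window).  The number of contributing readings is returned alongside.
#'
#' @param sensors Sensor table with columns `tank_id`, `timestamp` (POSIXct
#'   or ISO-8601 string), `variable`, `value`, and optionally `day`.
#' @param window Character vector `c(start, end)` in `"HH:MM"`; readings with
#'   `start <= time < end` contribute.
#' @return data.frame with columns `tank_id`, `day`, `variable`, `value`
#'   (window mean) and `n_readings`.
#' @export
window_means <- function(sensors, window = c("07:00", "09:00")) {
  ts <- sensors$timestamp
  if (!inherits(ts, "POSIXct")) ts <- parse_timestamp(ts)
  if (!("day" %in% names(sensors))) {
    day0 <- min(as.Date(ts))
    sensors$day <- as.integer(as.Date(ts) - day0)
  }
  lt <- as.POSIXlt(ts, tz = "UTC")
  mins <- lt$hour * 60L + lt$min
  lo <- parse_hhmm(window[1]); hi <- parse_hhmm(window[2])
  keep <- mins >= lo & mins < hi
  s <- sensors[keep, , drop = FALSE]
  if (!nrow(s))
    return(data.frame(tank_id = character(), day = integer(),
                      variable = character(), value = numeric(),
                      n_readings = integer()))
  agg <- stats::aggregate(value ~ tank_id + day + variable, data = s,
                          FUN = mean)
  n <- stats::aggregate(value ~ tank_id + day + variable, data = s,
                        FUN = length)
  names(n)[names(n) == "value"] <- "n_readings"
  out <- merge(agg, n, by = c("tank_id", "day", "variable"))
  out[order(out$tank_id, out$day, out$variable), , drop = FALSE]
}

#' Morning-window mean for a single day
#'
#' Convenience wrapper around [window_means()] for one day.  Days with zero
#' readings in the window yield an `NA` value with a warning (never a silent
#' zero).
#'
#' @inheritParams window_means
#' @param day Integer experiment day.
#' @return data.frame with one row per (tank, variable) present on that day.
#' @export
morning_window_mean <- function(sensors, day, window = c("07:00", "09:00")) {
  wm <- window_means(sensors, window)
  out <- wm[wm$day == day, , drop = FALSE]
  if (!nrow(out)) {
    warning("no sensor readings in window ", window[1], "-", window[2],
            " on day ", day)
    return(data.frame(tank_id = character(), day = integer(),
                      variable = character(), value = numeric(),
                      n_readings = integer()))
  }
  rownames(out) <- NULL
  out
}

#' Specific growth rate from successive cell counts
#'
#' The exponential-growth estimator `mu = ln(C_f / C_i) / dt` (d^-1) between
#' an initial and final cell count.
#'
#' @param C_i,C_f Initial and final cell counts (cells mL^-1), > 0.
#'   Vectorised.
#' @param dt Elapsed time between the counts, days, > 0.
#' @return Specific growth rate(s), d^-1.
#' @export
#' @examples
#' growth_rate(1e8, 2e8, 1)  # ln(2)
growth_rate <- function(C_i, C_f, dt = 1) {
  if (any(!is.finite(C_i)) || any(C_i <= 0) ||
      any(!is.finite(C_f)) || any(C_f <= 0)) {
    bad <- which(!is.finite(C_i) | C_i <= 0 | !is.finite(C_f) | C_f <= 0)[1]
    stop("cell counts must be > 0 (record ", bad, ": C_i = ", C_i[bad],
         ", C_f = ", C_f[bad], ")")
  }
  if (any(!is.finite(dt)) || any(dt <= 0))
    stop("dt must be > 0")
  log(C_f / C_i) / dt
}

#' Growth intervals from a count table
#'
#' Averages triplicate counts per (tank, day), then forms consecutive-day
#' intervals with `dt` equal to the actual day difference and computes the
#' interval growth rate with [growth_rate()].
#'
#' @param counts Count table with columns `tank_id`, `day`, `count`
#'   (cells mL^-1); replicates are averaged.
#' @return data.frame with columns `tank_id`, `day_start`, `day_end`, `C_i`,
#'   `C_f`, `dt`, `mu`.
#' @export
growth_intervals <- function(counts) {
  m <- stats::aggregate(count ~ tank_id + day, data = counts, FUN = mean)
  out <- do.call(rbind, lapply(split(m, m$tank_id), function(d) {
    d <- d[order(d$day), ]
    if (nrow(d) < 2L) return(NULL)
    i <- seq_len(nrow(d) - 1L)
    data.frame(tank_id = d$tank_id[i], day_start = d$day[i],
               day_end = d$day[i + 1L], C_i = d$count[i],
               C_f = d$count[i + 1L], dt = d$day[i + 1L] - d$day[i],
               mu = growth_rate(d$count[i], d$count[i + 1L],
                                d$day[i + 1L] - d$day[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Assemble per-(tank, day) forcing records
#'
#' Joins morning-window sensor means (temperature, irradiance), count-derived
#' growth rates and the nutrient limitation policy into the forcing table the
#' cell model consumes.  The growth rate for day `d` is the forward interval
#' rate starting at `d`; the final sampled day carries its backward interval.
#' Days missing temperature or irradiance are excluded, each with a logged
#' reason (attribute `"exclusions"` and a message).
#'
#' @param sensors,counts Tables as in [read_experiment()].
#' @param samples Optional sample table; dissolved nutrients (`TDN`, `SRP`)
#'   are carried through and used by the ratio-based limitation policy.
#' @param tanks Optional tank metadata (`tank_id`, `population`,
#'   `treatment`), joined onto the result.
#' @param window Sampling window passed to [window_means()].
#' @param limitation_policy `"P_limited"` (constant, the default — the
#'   experimental design fixed phosphorus limitation a priori) or
#'   `"DIN_SRP"`: P-limited where dissolved N:P exceeds `din_srp_threshold`.
#' @param din_srp_threshold Molar dissolved N:P threshold for `"DIN_SRP"`.
#' @param quiet Suppress the exclusion message.
#' @return data.frame with columns `tank_id` (+ `population`, `treatment` if
#'   `tanks` given), `day`, `T_C`, `I`, `mu`, `limitation`; attribute
#'   `"exclusions"` is a data.frame of excluded (tank, day, reason).
#' @export
build_forcing <- function(sensors, counts, samples = NULL, tanks = NULL,
                          window = c("07:00", "09:00"),
                          limitation_policy = c("P_limited", "DIN_SRP"),
                          din_srp_threshold = 16, quiet = FALSE) {
  limitation_policy <- match.arg(limitation_policy)
  wm <- window_means(sensors, window)
  temp <- wm[wm$variable == "temperature", c("tank_id", "day", "value")]
  names(temp)[3] <- "T_C"
  irr <- wm[wm$variable == "irradiance", c("tank_id", "day", "value")]
  names(irr)[3] <- "I"

  gi <- growth_intervals(counts)
  mu_tab <- do.call(rbind, lapply(split(gi, gi$tank_id), function(d) {
    d <- d[order(d$day_start), ]
    data.frame(tank_id = d$tank_id[c(seq_len(nrow(d)), nrow(d))],
               day = c(d$day_start, d$day_end[nrow(d)]),
               mu = c(d$mu, d$mu[nrow(d)]))
  }))

  base <- merge(mu_tab, temp, by = c("tank_id", "day"), all.x = TRUE)
  base <- merge(base, irr, by = c("tank_id", "day"), all.x = TRUE)

  miss_T <- is.na(base$T_C); miss_I <- is.na(base$I)
  excl <- base[miss_T | miss_I, c("tank_id", "day")]
  if (nrow(excl)) {
    excl$reason <- ifelse(miss_T[miss_T | miss_I] & miss_I[miss_T | miss_I],
                          "missing temperature and irradiance",
                          ifelse(miss_T[miss_T | miss_I],
                                 "missing temperature", "missing irradiance"))
    if (!quiet)
      message("build_forcing: excluded ", nrow(excl), " tank-day record(s); ",
              "see attr(x, 'exclusions')")
  } else {
    excl <- data.frame(tank_id = character(), day = integer(),
                       reason = character())
  }
  out <- base[!(miss_T | miss_I), , drop = FALSE]

  if (limitation_policy == "P_limited" || is.null(samples)) {
    out$limitation <- "P_limited"
  } else {
    nut <- samples[, c("tank_id", "day", "TDN", "SRP")]
    out <- merge(out, nut, by = c("tank_id", "day"), all.x = TRUE)
    ratio <- out$TDN / out$SRP
    out$limitation <- ifelse(!is.na(ratio) & ratio <= din_srp_threshold,
                             "N_limited", "P_limited")
    out$TDN <- NULL; out$SRP <- NULL
  }
  if (!is.null(tanks))
    out <- merge(tanks, out, by = "tank_id")
  out <- out[order(out$tank_id, out$day), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- excl
  out
}
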