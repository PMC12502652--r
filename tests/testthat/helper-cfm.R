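# Shared fixture builders (all data generated in code).

# Minute-resolution sensor rows for one tank/variable/day.
sensor_rows <- function(tank_id, day, times, values, variable = "temperature",
                        date0 = as.Date("2021-06-01")) {
  data.frame(
    tank_id = tank_id,
    timestamp = as.POSIXct(paste0(format(date0 + day), "T", times),
                           format = "%Y-%m-%dT%H:%M", tz = "UTC"),
    variable = variable,
    value = values
  )
}

# A complete 2-tank, 3-day sensor + count fixture with readings at 07:00
# and 08:30 each day.
tiny_fixture <- function(drop_irradiance_day = NULL) {
  sensors <- NULL
  for (tk in c("A", "B")) for (d in 0:2) {
    sensors <- rbind(
      sensors,
      sensor_rows(tk, d, c("07:00", "08:30"), c(20 + d, 21 + d),
                  "temperature"),
      if (is.null(drop_irradiance_day) || d != drop_irradiance_day ||
          tk != "A")
        sensor_rows(tk, d, c("07:00", "08:30"), c(100, 300), "irradiance")
    )
  }
  counts <- expand.grid(tank_id = c("A", "B"), day = 0:2, replicate = 1:3,
                        stringsAsFactors = FALSE)
  counts$count <- 1000 * 2^counts$day * c(0.9, 1.0, 1.1)[counts$replicate]
  list(sensors = sensors, counts = counts)
}

# Random feasible forcing draws under the community profile.
random_forcings <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(T_C = runif(n, 15, 30), I = runif(n, 50, 800),
             mu = runif(n, 0, 0.8))
}

small_config <- function(...) {
  experiment_config(replicates = 1, n_tanks = 4, days = 5,
                    storm_days = c(3, 4), ...)
}
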