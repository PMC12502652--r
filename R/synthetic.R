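#' Configuration of the synthetic mesocosm experiment
#'
#' Captures the design of the 12-tank warming experiment the generator
#' emulates: 2 populations (eukaryote monoculture / mixed community) x 2
#' treatments (heated / reference) x 3 replicates, 14 days (Day 0 =
#' inoculation), heated tanks offset +4.5 degC from Day 1 (linear ramp during
#' Day 0), an ambient daily-mean climatology spanning 18.6-21.5 degC with the
#' warmest day on Day 8 and the coldest on Day 11, a storm-driven low-light
#' event on days 9-11, and a phosphorus-limited nutrient addition at molar
#' N:P = 100.
#'
#' @param n_tanks Number of tanks (must equal 2 x 2 x `replicates`).
#' @param replicates Replicate tanks per treatment x population cell.
#' @param days Final experiment day; days run 0..`days`.
#' @param heat_offset Heating above ambient, degC, applied from Day 1.
#' @param ambient_T_min,ambient_T_max Ambient daily-mean climatology bounds,
#'   degC.
#' @param storm_days Integer days of the low-irradiance storm event.
#' @param storm_light_factor Multiplier in (0, 1] applied to storm-day
#'   irradiance.
#' @param init_PO4 Initial dissolved phosphate, umol P L^-1.
#' @param init_NO3 Initial dissolved nitrate, umol N L^-1; default derived as
#'   `init_PO4 * supply_NP_molar`.
#' @param supply_NP_molar Molar N:P of the nutrient addition (> 1, a
#'   P-limited design).
#' @param mu_max_ref Maximum specific growth rate at 20 degC, d^-1.
#' @param Q10_growth Q10 of the maximum growth rate.
#' @param mortality Background loss rate, d^-1 (drives the post-peak crash).
#' @param K_P Half-saturation of growth on dissolved P, umol L^-1.
#' @param I_half_growth Light scale of the growth light factor
#'   `1 - exp(-I / I_half_growth)`, umol photons m^-2 s^-1.
#' @param quota_C,quota_N,quota_P Per-cell element quotas, mol cell^-1, used
#'   for nutrient drawdown and particulate concentrations.
#' @param inoculum Initial cell density, cells mL^-1.
#' @param diel_T_amp Amplitude of the diel water-temperature sinusoid, degC.
#' @param anomaly_sd,anomaly_phi Std. dev. and AR(1) coefficient of the
#'   day-to-day ambient temperature anomaly (part of the noise model).
#' @param sensor_sd_T,sensor_sd_I Per-reading sensor noise (degC; umol
#'   photons m^-2 s^-1).
#' @param I_max Clear-sky noon irradiance, umol photons m^-2 s^-1.
#' @param cloud_range Range of the daily cloudiness factor on ordinary days.
#' @param count_cv,stoich_cv,nutrient_cv Lognormal CVs of triplicate counts,
#'   stoichiometry observations, and nutrient measurements.
#' @param sample_every Cadence (days) of stoichiometry/nutrient sampling.
#' @param cadence_min Sensor cadence, minutes.
#' @param start_date Calendar date of Day 0 (ISO), used for timestamps only.
#' @param noise Master switch: `FALSE` silences every stochastic component
#'   (sensor noise, climatology anomaly, cloudiness draws, count and sample
#'   noise), leaving the deterministic design.
#' @param seed Integer seed governing all stochastic components via derived
#'   per-stage substreams.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(n_tanks = 12, replicates = 3, days = 14,
                              heat_offset = 4.5,
                              ambient_T_min = 18.6, ambient_T_max = 21.5,
                              storm_days = c(9, 10, 11),
                              storm_light_factor = 0.25,
                              init_PO4 = 2.5, init_NO3 = NULL,
                              supply_NP_molar = 100,
                              mu_max_ref = 1.0, Q10_growth = 2,
                              mortality = 0.15, K_P = 0.1,
                              I_half_growth = 150,
                              quota_C = 1.5e-13, quota_N = 2.5e-14,
                              quota_P = 5e-15,
                              inoculum = 1000,
                              diel_T_amp = 0.8, anomaly_sd = 0.3,
                              anomaly_phi = 0.6,
                              sensor_sd_T = 0.05, sensor_sd_I = 10,
                              I_max = 1500, cloud_range = c(0.55, 0.95),
                              count_cv = 0.05, stoich_cv = 0.05,
                              nutrient_cv = 0.02,
                              sample_every = 3, cadence_min = 10,
                              start_date = "2021-06-01",
                              noise = TRUE, seed = 42) {
  if (is.null(init_NO3)) init_NO3 <- init_PO4 * supply_NP_molar
  cfg <- as.list(environment())
  if (cfg$n_tanks != 4L * cfg$replicates)
    stop("n_tanks must equal 2 populations x 2 treatments x replicates")
  if (cfg$heat_offset <= 0) stop("heat_offset must be > 0")
  if (cfg$ambient_T_min >= cfg$ambient_T_max)
    stop("ambient_T_min must be < ambient_T_max")
  if (cfg$supply_NP_molar <= 1)
    stop("supply_NP_molar must be > 1 (phosphorus-limited design)")
  if (cfg$storm_light_factor <= 0 || cfg$storm_light_factor > 1)
    stop("storm_light_factor must lie in (0, 1]")
  if (cfg$days < 1) stop("days must be >= 1")
  class(cfg) <- "experiment_config"
  cfg
}

substream <- function(seed, k) {
  as.integer((as.numeric(seed) %% 20000000) * 100 + k)
}

#' Tank design table
#'
#' @param cfg An [experiment_config()].
#' @return data.frame `tank_id`, `population`, `treatment`, `replicate`.
#' @export
tank_design <- function(cfg) {
  d <- expand.grid(replicate = seq_len(cfg$replicates),
                   treatment = c("reference", "heated"),
                   population = c("eukaryote", "mixed"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d$tank_id <- sprintf("T%02d", seq_len(nrow(d)))
  d[c("tank_id", "population", "treatment", "replicate")]
}

ambient_climatology <- function(cfg) {
  rng <- cfg$ambient_T_max - cfg$ambient_T_min
  xa <- c(0, 8, 11, 14) / 14 * cfg$days
  ya <- cfg$ambient_T_min + rng * c(0.7, 1, 0, 0.5)
  stats::approx(xa, ya, xout = 0:cfg$days, rule = 2)$y
}

day_times <- function(cfg) seq(0L, 1439L, by = cfg$cadence_min)

sensor_timestamps <- function(cfg) {
  d0 <- as.POSIXct(paste0(cfg$start_date, " 00:00:00"), tz = "UTC")
  mins <- day_times(cfg)
  rep(0:cfg$days, each = length(mins)) * 86400 + rep(mins, cfg$days + 1) * 60 + d0
}

#' Generate water-temperature sensor series
#'
#' Ambient daily means follow the climatology trend (warmest Day 8, coldest
#' Day 11, spanning the configured envelope), plus a seeded AR(1) anomaly
#' clipped to the envelope when noise is on.  A diel sinusoid (peak 16:00,
#' zero daily mean on the even sensor grid) and per-reading sensor noise are
#' added on top.  Heated tanks sit `heat_offset` above ambient from Day 1,
#' ramping linearly from zero across Day 0.  Replicate tanks share the
#' ambient signal and differ only by sensor noise.
#'
#' @param cfg An [experiment_config()].
#' @param seed Optional override of `cfg$seed`.
#' @return Sensor table: `tank_id`, `timestamp`, `day`, `variable`
#'   (`"temperature"`), `value` (degC).
#' @export
generate_temperature <- function(cfg, seed = cfg$seed) {
  design <- tank_design(cfg)
  trend <- ambient_climatology(cfg)
  if (cfg$noise && cfg$anomaly_sd > 0) {
    set.seed(substream(seed, 1L))
    eps <- stats::rnorm(cfg$days + 1, 0, cfg$anomaly_sd)
    anom <- Reduce(function(a, e) cfg$anomaly_phi * a + e, eps, accumulate = TRUE)
    daily <- pmin(pmax(trend + anom, cfg$ambient_T_min), cfg$ambient_T_max)
  } else daily <- trend

  mins <- day_times(cfg)
  diel <- cfg$diel_T_amp * sin(2 * pi * (mins / 1440 - 10 / 24))
  ts <- sensor_timestamps(cfg)
  day_idx <- rep(0:cfg$days, each = length(mins))
  ambient_inst <- daily[day_idx + 1L] + rep(diel, cfg$days + 1)
  frac <- rep(mins, cfg$days + 1) / 1440
  offset_inst <- ifelse(day_idx >= 1, cfg$heat_offset, cfg$heat_offset * frac)

  set.seed(substream(seed, 2L))
  out <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    base <- ambient_inst +
      if (design$treatment[i] == "heated") offset_inst else 0
    noise <- if (cfg$noise && cfg$sensor_sd_T > 0)
      stats::rnorm(length(base), 0, cfg$sensor_sd_T) else 0
    data.frame(tank_id = design$tank_id[i], timestamp = ts, day = day_idx,
               variable = "temperature", value = base + noise)
  }))
  rownames(out) <- NULL
  out
}

daily_cloud_factors <- function(cfg, seed) {
  nd <- cfg$days + 1
  if (cfg$noise) {
    set.seed(substream(seed, 3L))
    cl <- stats::runif(nd, cfg$cloud_range[1], cfg$cloud_range[2])
  } else cl <- rep(mean(cfg$cloud_range), nd)
  cl[1] <- 1  # Day 0: clearest day of the run
  storm <- intersect(cfg$storm_days, 0:cfg$days)
  cl[storm + 1L] <- cl[storm + 1L] * cfg$storm_light_factor
  cl
}

#' Generate irradiance sensor series
#'
#' Clear-sky diel sinusoid (06:00-18:00) times a daily cloudiness factor.
#' Day 0 is forced clear (factor 1, the brightest day); storm days are
#' multiplied by `storm_light_factor`, placing the darkest day inside the
#' storm window.  Cloudiness is shared weather across tanks; sensor noise is
#' per tank and clipped at zero.
#'
#' @inheritParams generate_temperature
#' @return Sensor table: `tank_id`, `timestamp`, `day`, `variable`
#'   (`"irradiance"`), `value` (umol photons m^-2 s^-1, >= 0).
#' @export
generate_irradiance <- function(cfg, seed = cfg$seed) {
  design <- tank_design(cfg)
  cl <- daily_cloud_factors(cfg, seed)
  mins <- day_times(cfg)
  hours <- mins / 60
  diel <- pmax(0, sin(pi * (hours - 6) / 12))
  ts <- sensor_timestamps(cfg)
  day_idx <- rep(0:cfg$days, each = length(mins))
  base0 <- cfg$I_max * cl[day_idx + 1L] * rep(diel, cfg$days + 1)

  set.seed(substream(seed, 4L))
  out <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    v <- base0
    if (cfg$noise && cfg$sensor_sd_I > 0) {
      pos <- v > 0
      v[pos] <- pmax(0, v[pos] + stats::rnorm(sum(pos), 0, cfg$sensor_sd_I))
    }
    data.frame(tank_id = design$tank_id[i], timestamp = ts, day = day_idx,
               variable = "irradiance", value = v)
  }))
  rownames(out) <- NULL
  out
}

#' Generate bloom dynamics, counts and stoichiometry samples
#'
#' Simulates a phosphorus-limited bloom and crash per tank on a daily step:
#' gross growth is logistic-style, `mu_max_ref` scaled by a Q10 temperature
#' factor, a saturating light factor and Monod uptake on dissolved P; new
#' biomass draws dissolved P and N down against fixed cell quotas, with
#' uptake fluxes stopping at machine zero (carrying capacity by P
#' exhaustion); a constant background mortality produces the post-peak
#' crash.  This growth engine is deliberately simpler than, and independent
#' of, the steady-state cell model — only the stoichiometry *observations*
#' are model-derived truth: on sampling days, true N:C, P:C and Chl:C are
#' computed by [steady_state_allocation()] under the realized morning-window
#' forcing (eukaryote profile for the monoculture, community profile for the
#' mixed tanks) and perturbed by lognormal measurement noise, so the full
#' pipeline admits round-trip validation.
#'
#' @inheritParams generate_temperature
#' @param temperature,irradiance Sensor tables from [generate_temperature()]
#'   and [generate_irradiance()].
#' @return List with `counts` (triplicate, cells mL^-1), `samples`
#'   (particulate C/N/P in umol L^-1, chl-a in ug L^-1, dissolved TDN, TDP,
#'   SRP in umol L^-1), and `truth` (per tank-day: true cells, dissolved
#'   nutrients, cumulative uptake, realized growth rate, true stoichiometry).
#' @export
generate_bloom <- function(cfg, temperature, irradiance, seed = cfg$seed) {
  design <- tank_design(cfg)
  dayT <- stats::aggregate(value ~ tank_id + day, data = temperature, FUN = mean)
  dayI <- stats::aggregate(value ~ tank_id + day, data = irradiance, FUN = mean)
  sensors <- rbind(temperature, irradiance)
  wm <- window_means(sensors)
  morT <- wm[wm$variable == "temperature", ]
  morI <- wm[wm$variable == "irradiance", ]

  conv_P <- cfg$quota_P * 1e9  # umol L-1 per (cell mL-1)
  conv_N <- cfg$quota_N * 1e9
  profiles <- list(eukaryote = cell_parameters_profile("eukaryote"),
                   mixed = cell_parameters_profile("community"))
  sample_days <- seq(0, cfg$days, by = cfg$sample_every)

  truth <- NULL
  for (i in seq_len(nrow(design))) {
    tk <- design$tank_id[i]
    Td <- dayT$value[dayT$tank_id == tk][order(dayT$day[dayT$tank_id == tk])]
    Id <- dayI$value[dayI$tank_id == tk][order(dayI$day[dayI$tank_id == tk])]
    nd <- cfg$days + 1
    cells <- numeric(nd); Pd <- numeric(nd); Nd <- numeric(nd)
    upP <- numeric(nd); upN <- numeric(nd)
    cells[1] <- cfg$inoculum; Pd[1] <- cfg$init_PO4; Nd[1] <- cfg$init_NO3
    for (d in seq_len(cfg$days)) {
      mu_g <- cfg$mu_max_ref * cfg$Q10_growth^((Td[d] - 20) / 10) *
        (1 - exp(-Id[d] / cfg$I_half_growth)) * Pd[d] / (Pd[d] + cfg$K_P)
      pot <- cells[d] * (expm1(mu_g))
      allowed <- min(pot, Pd[d] / conv_P, Nd[d] / conv_N)
      cells[d + 1] <- (cells[d] + allowed) * exp(-cfg$mortality)
      Pd[d + 1] <- max(0, Pd[d] - allowed * conv_P)
      Nd[d + 1] <- max(0, Nd[d] - allowed * conv_N)
      upP[d + 1] <- upP[d] + allowed * conv_P
      upN[d + 1] <- upN[d] + allowed * conv_N
    }
    mu_net <- c(log(cells[-1] / cells[-nd]), log(cells[nd] / cells[nd - 1]))

    mT <- morT$value[morT$tank_id == tk][order(morT$day[morT$tank_id == tk])]
    mI <- morI$value[morI$tank_id == tk][order(morI$day[morI$tank_id == tk])]
    prm <- profiles[[design$population[i]]]
    NCt <- PCt <- Chlt <- numeric(nd)
    for (d in seq_len(nd)) {
      st <- steady_state_allocation(mT[d], mI[d], max(0, mu_net[d]), prm,
                                    tank_id = tk, day = d - 1L)
      NCt[d] <- st$stoichiometry$NC
      PCt[d] <- st$stoichiometry$PC
      Chlt[d] <- st$stoichiometry$ChlC
    }
    truth <- rbind(truth, data.frame(
      tank_id = tk, population = design$population[i],
      treatment = design$treatment[i], day = 0:cfg$days,
      cells = cells, TDP = Pd, TDN = Nd,
      uptake_P = upP, uptake_N = upN, mu = mu_net,
      NC = NCt, PC_ratio = PCt, ChlC = Chlt))
  }

  lnoise <- function(n, cv) {
    if (!cfg$noise || cv <= 0) return(rep(1, n))
    sd <- sqrt(log(1 + cv^2))
    exp(stats::rnorm(n, -sd^2 / 2, sd))
  }

  set.seed(substream(seed, 5L))
  counts <- do.call(rbind, lapply(1:3, function(r)
    data.frame(tank_id = truth$tank_id, day = truth$day, replicate = r,
               count = truth$cells * lnoise(nrow(truth), cfg$count_cv))))
  counts <- counts[order(counts$tank_id, counts$day, counts$replicate), ]
  rownames(counts) <- NULL

  set.seed(substream(seed, 6L))
  s <- truth[truth$day %in% sample_days, ]
  n <- nrow(s)
  C_conc <- s$cells * cfg$quota_C * 1e9 * lnoise(n, cfg$stoich_cv)
  NC_obs <- s$NC * lnoise(n, cfg$stoich_cv)
  PC_obs <- s$PC_ratio * lnoise(n, cfg$stoich_cv)
  samples <- data.frame(
    tank_id = s$tank_id, day = s$day,
    PC = C_conc, PN = C_conc * NC_obs, PP = C_conc * PC_obs,
    chl_a = s$ChlC * C_conc * (893.5 / 55) * lnoise(n, cfg$stoich_cv),
    TDN = s$TDN * lnoise(n, cfg$nutrient_cv),
    TDP = s$TDP * lnoise(n, cfg$nutrient_cv),
    SRP = 0.85 * s$TDP * lnoise(n, cfg$nutrient_cv))
  rownames(samples) <- NULL

  list(counts = counts, samples = samples, truth = truth)
}

#' Generate a complete synthetic mesocosm experiment
#'
#' Runs the temperature, irradiance and bloom generators and assembles the
#' in-memory dataset in the layout [read_experiment()] produces.
#'
#' @inheritParams generate_temperature
#' @return List of class `experiment_dataset`: `tanks`, `sensors`, `counts`,
#'   `samples`, plus the generator `truth` table and the `config`.
#' @export
#' @examples
#' cfg <- experiment_config(days = 3, replicates = 1, n_tanks = 4)
#' ds <- generate_experiment(cfg)
#' table(ds$tanks$treatment, ds$tanks$population)
generate_experiment <- function(cfg, seed = cfg$seed) {
  temperature <- generate_temperature(cfg, seed)
  irradiance <- generate_irradiance(cfg, seed)
  bloom <- generate_bloom(cfg, temperature, irradiance, seed)
  ds <- list(tanks = tank_design(cfg),
             sensors = rbind(temperature, irradiance),
             counts = bloom$counts, samples = bloom$samples,
             truth = bloom$truth, config = cfg)
  attr(ds, "day0") <- as.Date(cfg$start_date)
  class(ds) <- "experiment_dataset"
  ds
}

#' Write a synthetic experiment to CSV
#'
#' Emits the four-file schema consumed by [read_experiment()] plus a
#' `manifest.json` recording the full configuration, seed and per-file MD5
#' checksums, sufficient for byte-identical regeneration via
#' [regenerate_experiment()].  A self-check validates the written schema.
#'
#' @inheritParams generate_temperature
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the manifest as a list.
#' @export
write_experiment <- function(cfg, seed = cfg$seed, out_dir) {
  ds <- generate_experiment(cfg, seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sensors <- ds$sensors
  sensors$timestamp <- format(sensors$timestamp, "%Y-%m-%dT%H:%M:%S",
                              tz = "UTC")
  write_one <- function(d, f) {
    utils::write.csv(d, file.path(out_dir, f), row.names = FALSE,
                     quote = FALSE)
  }
  write_one(ds$tanks, "tanks.csv")
  write_one(sensors[c("tank_id", "timestamp", "variable", "value")],
            "sensors.csv")
  write_one(ds$counts, "counts.csv")
  write_one(ds$samples, "samples.csv")

  check <- read_experiment(out_dir)
  stopifnot(nrow(check$tanks) == cfg$n_tanks,
            all(c("tank_id", "timestamp", "variable", "value", "day") %in%
                  names(check$sensors)),
            all(check$counts$count >= 0))

  files <- c("tanks.csv", "sensors.csv", "counts.csv", "samples.csv")
  manifest <- list(
    package = "cfmphyto",
    seed = seed,
    config = unclass(cfg),
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Regenerate an experiment from its manifest
#'
#' @param manifest_path Path to a `manifest.json` written by
#'   [write_experiment()].
#' @param out_dir Directory to write the regenerated CSVs to.
#' @return Invisibly, the new manifest.
#' @export
regenerate_experiment <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfg_list <- m$config
  cfg_list$init_NO3 <- as.numeric(cfg_list$init_NO3)
  cfg <- do.call(experiment_config, cfg_list)
  write_experiment(cfg, seed = m$seed, out_dir = out_dir)
}
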