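test_that("default design is 2 populations x 2 treatments x 3 replicates", {
  cfg <- experiment_config()
  d <- tank_design(cfg)
  expect_identical(nrow(d), 12L)
  expect_identical(unname(as.vector(table(d$treatment, d$population))),
                   rep(3L, 4))
  expect_identical(anyDuplicated(d$tank_id), 0L)
})

test_that("config validation enforces the experimental design", {
  expect_error(experiment_config(n_tanks = 10), "2 populations")
  expect_error(experiment_config(heat_offset = 0), "heat_offset")
  expect_error(experiment_config(ambient_T_min = 25), "ambient_T_min")
  expect_error(experiment_config(supply_NP_molar = 1), "supply_NP_molar")
  expect_error(experiment_config(storm_light_factor = 0), "storm_light_factor")
})

test_that("heated tanks sit the configured offset above reference from Day 1", {
  cfg <- experiment_config()
  tt <- generate_temperature(cfg)
  des <- tank_design(cfg)
  dm <- stats::aggregate(value ~ tank_id + day, tt, mean)
  dm <- merge(dm, des[c("tank_id", "treatment")])
  trt <- stats::aggregate(value ~ day + treatment, dm, mean)
  diffs <- trt$value[trt$treatment == "heated"] -
    trt$value[trt$treatment == "reference"]
  expect_true(all(abs(diffs[-1] - cfg$heat_offset) < 0.05))
  expect_lt(diffs[1], cfg$heat_offset)  # Day 0: ramp still in progress

  # noiseless run reproduces the offset exactly
  cfg0 <- experiment_config(noise = FALSE)
  tt0 <- generate_temperature(cfg0)
  dm0 <- stats::aggregate(value ~ tank_id + day, tt0, mean)
  dm0 <- merge(dm0, des[c("tank_id", "treatment")])
  trt0 <- stats::aggregate(value ~ day + treatment, dm0, mean)
  diffs0 <- trt0$value[trt0$treatment == "heated"] -
    trt0$value[trt0$treatment == "reference"]
  expect_equal(diffs0[-1], rep(cfg$heat_offset, cfg$days), tolerance = 1e-9)
})

test_that("ambient daily means span the configured climatology envelope", {
  cfg <- experiment_config(noise = FALSE)
  tt <- generate_temperature(cfg)
  des <- tank_design(cfg)
  ref <- des$tank_id[des$treatment == "reference"]
  dm <- stats::aggregate(value ~ day, tt[tt$tank_id %in% ref, ], mean)
  expect_equal(max(dm$value), cfg$ambient_T_max, tolerance = 1e-9)
  expect_equal(min(dm$value), cfg$ambient_T_min, tolerance = 1e-9)
  expect_identical(dm$day[which.max(dm$value)], 8L)   # warmest day
  expect_identical(dm$day[which.min(dm$value)], 11L)  # coldest (storm) day
  # with noise on, the anomaly is clipped to the envelope
  ttn <- generate_temperature(experiment_config())
  dmn <- stats::aggregate(value ~ day, ttn[ttn$tank_id %in% ref, ], mean)
  expect_true(all(dmn$value <= cfg$ambient_T_max + 0.05))
  expect_true(all(dmn$value >= cfg$ambient_T_min - 0.05))
})

test_that("irradiance is darkest during the storm and brightest on Day 0", {
  cfg <- experiment_config()
  ir <- generate_irradiance(cfg)
  expect_true(all(ir$value >= 0))
  dm <- stats::aggregate(value ~ day, ir, mean)
  expect_true(dm$day[which.min(dm$value)] %in% cfg$storm_days)
  expect_identical(dm$day[which.max(dm$value)], 0L)
  # a neutral storm factor leaves storm days indistinguishable (noiseless)
  cfg1 <- experiment_config(storm_light_factor = 1, noise = FALSE)
  dm1 <- stats::aggregate(value ~ day, generate_irradiance(cfg1), mean)
  expect_equal(diff(range(dm1$value[-1])), 0, tolerance = 1e-9)
})

test_that("generators are byte-deterministic under a fixed seed", {
  cfg <- experiment_config()
  expect_identical(generate_temperature(cfg, seed = 5),
                   generate_temperature(cfg, seed = 5))
  expect_identical(generate_irradiance(cfg, seed = 5),
                   generate_irradiance(cfg, seed = 5))
  a <- generate_experiment(small_config(seed = 5))
  b <- generate_experiment(small_config(seed = 5))
  expect_identical(a$counts, b$counts)
  expect_identical(a$samples, b$samples)
  c2 <- generate_experiment(small_config(seed = 6))
  expect_false(identical(a$counts$count, c2$counts$count))
})

test_that("bloom dynamics: heated tanks peak higher; P limitation persists", {
  ds <- generate_experiment(experiment_config())
  tr <- ds$truth
  mx <- stats::aggregate(cells ~ treatment, tr, max)
  expect_gt(mx$cells[mx$treatment == "heated"],
            mx$cells[mx$treatment == "reference"])
  # bloom and crash: a peak strictly inside the horizon for every tank
  for (tk in unique(tr$tank_id)) {
    cells <- tr$cells[tr$tank_id == tk]
    pk <- which.max(cells)
    expect_true(pk > 1 && pk < length(cells))
    expect_lt(cells[length(cells)], max(cells))
  }
  # dissolved N:P never drops to the limitation threshold
  expect_true(all(tr$TDN / pmax(tr$TDP, 1e-12) > 16))
  expect_true(all(tr$TDP >= 0) && all(tr$TDN >= 0))
})

test_that("nutrient drawdown balances cumulative biomass uptake", {
  cfg <- experiment_config(noise = FALSE)
  tr <- generate_experiment(cfg)$truth
  expect_equal(cfg$init_PO4 - tr$TDP, tr$uptake_P, tolerance = 1e-9)
  expect_equal(cfg$init_NO3 - tr$TDN, tr$uptake_N, tolerance = 1e-9)
})

test_that("temperature-neutral growth makes treatments identical (noiseless)", {
  cfg <- experiment_config(Q10_growth = 1, noise = FALSE)
  tr <- generate_experiment(cfg)$truth
  h <- tr$cells[tr$tank_id == "T04"]  # heated eukaryote
  r <- tr$cells[tr$tank_id == "T01"]  # reference eukaryote
  expect_equal(h, r, tolerance = 1e-12)
})

test_that("write_experiment emits the schema and regenerates byte-identically", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- small_config(seed = 3)
  m1 <- write_experiment(cfg, out_dir = dir1)
  expect_setequal(list.files(dir1),
                  c("tanks.csv", "sensors.csv", "counts.csv", "samples.csv",
                    "manifest.json"))
  m2 <- regenerate_experiment(file.path(dir1, "manifest.json"), dir2)
  expect_identical(m1$files, m2$files)  # md5-identical regeneration
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("a one-day horizon still yields a well-formed dataset", {
  dir <- tempfile()
  cfg <- experiment_config(replicates = 1, n_tanks = 4, days = 1,
                           storm_days = integer(0), sample_every = 1)
  write_experiment(cfg, out_dir = dir)
  ds <- read_experiment(dir)
  expect_identical(sort(unique(ds$counts$day)), c(0L, 1L))
  fo <- build_forcing(ds$sensors, ds$counts, tanks = ds$tanks, quiet = TRUE)
  expect_identical(nrow(fo), 8L)  # 4 tanks x 2 days
  unlink(dir, recursive = TRUE)
})
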