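test_that("light response is saturating-exponential with the right limits", {
  p <- cell_parameters(Pmax_ref = 6, a_I = 0.01)
  expect_identical(light_limited_photosynthesis(0, p), 0)
  expect_equal(light_limited_photosynthesis(1e6, p), 6, tolerance = 1e-6 / 6)
  expect_equal(light_limited_photosynthesis(100, p), 3.79272335297135,
               tolerance = 1e-12)
  I <- seq(0, 2000, by = 50)
  expect_true(all(diff(light_limited_photosynthesis(I, p)) >= 0))
  expect_true(all(light_limited_photosynthesis(I, p) <= 6))
  expect_error(light_limited_photosynthesis(-1, p), ">= 0")
})

test_that("maintenance respiration follows the Q10 law", {
  p <- cell_parameters(Rm_ref = 0.1, Q10_R = 2)
  expect_equal(maintenance_respiration(p$T_ref, p), 0.1)
  expect_equal(maintenance_respiration(p$T_ref + 10, p), 0.2)
  # +4.5 K, the experimental heating offset
  expect_equal(maintenance_respiration(p$T_ref + 4.5, p), 0.13660402567544,
               tolerance = 1e-12)
  T_K <- seq(280, 310, by = 1)
  expect_true(all(diff(maintenance_respiration(T_K, p)) > 0))
  expect_error(maintenance_respiration(-5, p), "> 0 K")
})

test_that("biosynthetic capacity follows the Arrhenius law", {
  p <- cell_parameters(k_bio_ref = 2, Ea_bio = 70000, T_ref = 293.15)
  expect_equal(biosynthetic_capacity(293.15, p), 2)
  p0 <- cell_parameters(k_bio_ref = 2, Ea_bio = 0)
  expect_equal(biosynthetic_capacity(280, p0), 2)
  expect_equal(biosynthetic_capacity(310, p0), 2)
  expect_equal(biosynthetic_capacity(297.65, p), 3.08750124953295,
               tolerance = 1e-12)
  T_K <- seq(280, 310, by = 1)
  expect_true(all(diff(biosynthetic_capacity(T_K, p)) > 0))
})

test_that("zero growth with zero maintenance leaves only structure", {
  p <- cell_parameters(Rm_ref = 0)
  st <- steady_state_allocation(20, 300, 0, p)
  expect_identical(st$stoichiometry$ChlC, 0)
  expect_identical(unname(st$pool_C["biosynthetic"]), 0)
  expect_identical(unname(st$pool_N["biosynthetic"]), 0)
  expect_identical(unname(st$pool_P["biosynthetic"]), 0)
  skeleton <- p$N_store / p$comp["n_store", "NC"]
  expect_equal(unname(st$pool_C["C_storage"]), 1 - p$C_ess - skeleton)
})

test_that("allocation fractions conserve each element and P storage is absent", {
  p <- cell_parameters()
  fo <- random_forcings(50, seed = 11)
  for (i in seq_len(nrow(fo))) {
    st <- tryCatch(steady_state_allocation(fo$T_C[i], fo$I[i], fo$mu[i], p),
                   cfm_infeasible = function(e) NULL)
    if (is.null(st)) next
    expect_equal(unname(rowSums(st$allocation)), c(1, 1, 1),
                 tolerance = 1e-9)
    expect_identical(unname(st$allocation["P", "N_storage"]), 0)
    expect_identical(unname(st$allocation["P", "C_storage"]), 0)
    expect_true(all(st$allocation >= 0 & st$allocation <= 1))
    expect_equal(st$stoichiometry$NP,
                 st$stoichiometry$NC / st$stoichiometry$PC)
  }
})

test_that("essential and N-storage pools are invariant to forcing", {
  p <- cell_parameters_profile("eukaryote")
  a <- steady_state_allocation(16, 100, 0.1, p)
  b <- steady_state_allocation(28, 600, 0.6, p)
  expect_identical(a$pool_C[["essential"]], b$pool_C[["essential"]])
  expect_identical(a$pool_N[["essential"]], b$pool_N[["essential"]])
  expect_identical(a$pool_P[["essential"]], b$pool_P[["essential"]])
  expect_identical(a$pool_C[["N_storage"]], b$pool_C[["N_storage"]])
  expect_identical(a$pool_N[["N_storage"]], p$N_store)
})

test_that("mechanistic monotonicities hold across both profiles", {
  for (prof in c("community", "eukaryote")) {
    p <- cell_parameters_profile(prof)
    sw_T <- sweep_allocation(seq(15, 30, by = 1), 300, 0.3, p)
    expect_true(all(sw_T$feasible))
    expect_true(all(diff(sw_T$NP) > 0))                # warmer -> higher N:P
    expect_true(all(diff(sw_T$C_biosynthetic) < 0))    # fewer enzymes needed
    sw_I <- sweep_allocation(20, seq(25, 1000, by = 25), 0.4, p)
    expect_true(all(diff(sw_I$C_photosynthetic) < 0))  # light-harvesting down
    expect_true(all(diff(sw_I$C_C_storage) > 0))       # storage takes the slack
    sw_mu <- sweep_allocation(20, 300, seq(0, 0.8, by = 0.1), p)
    expect_true(all(diff(sw_mu$C_biosynthetic) > 0))
  }
})

test_that("Chl:C approaches its closed-form limit at saturating light", {
  p <- cell_parameters()
  mu <- 0.4; T_C <- 22
  st <- steady_state_allocation(T_C, 1e6, mu, p)
  lim <- (mu * (1 + p$E_bio) +
            maintenance_respiration(celsius_to_kelvin(T_C), p)) / p$Pmax_ref
  expect_equal(st$stoichiometry$ChlC, lim, tolerance = 1e-6)
})

test_that("infeasible carbon budgets raise a named error, never clamp", {
  p <- cell_parameters()
  expect_error(
    steady_state_allocation(15, 30, 3, p, tank_id = "T07", day = 9),
    class = "cfm_infeasible")
  err <- tryCatch(steady_state_allocation(15, 30, 3, p, tank_id = "T07",
                                          day = 9),
                  cfm_infeasible = identity)
  expect_match(conditionMessage(err), "T07")
  expect_match(conditionMessage(err), "9")
  # zero light with positive demand is also infeasible
  expect_error(steady_state_allocation(20, 0, 0.2, p),
               class = "cfm_infeasible")
})

test_that("N:P is flagged undefined, not fabricated, when P:C is zero", {
  comp <- default_composition()
  comp[c("rna", "dna", "thylakoid"), "PC"] <- 0
  p <- cell_parameters(comp = comp)
  st <- steady_state_allocation(20, 300, 0.3, p)
  expect_identical(st$stoichiometry$PC, 0)
  expect_true(is.na(st$stoichiometry$NP))
})

test_that("sweep rows equal independent single-point calls", {
  p <- cell_parameters()
  sw <- sweep_allocation(c(16, 24), c(100, 500), c(0.2, 0.5), p)
  expect_identical(nrow(sw), 8L)
  for (i in seq_len(nrow(sw))) {
    st <- steady_state_allocation(sw$T_C[i], sw$I[i], sw$mu[i], p)
    expect_identical(sw$NC[i], st$stoichiometry$NC)
    expect_identical(sw$PC[i], st$stoichiometry$PC)
    expect_identical(sw$C_biosynthetic[i],
                     unname(st$allocation["C", "biosynthetic"]))
  }
  one <- sweep_allocation(20, 300, 0.3, p)
  st <- steady_state_allocation(20, 300, 0.3, p)
  expect_identical(one$NP, st$stoichiometry$NP)
})

test_that("sweep flags infeasible grid points without aborting", {
  p <- cell_parameters()
  sw <- sweep_allocation(20, 300, c(0.2, 5, 0.4), p)
  expect_identical(sw$feasible, c(TRUE, FALSE, TRUE))
  expect_true(is.na(sw$NC[2]))
  expect_false(anyNA(sw$NC[c(1, 3)]))
})

test_that("parameter validation rejects ill-formed inputs", {
  expect_error(cell_parameters(C_ess = 1.2), "C_ess")
  expect_error(cell_parameters(k_bio_ref = -1), "strictly positive")
  comp <- default_composition(); comp["protein", "PC"] <- 0.1
  expect_error(cell_parameters(comp = comp), "protein")
  expect_error(steady_state_allocation(60, 300, 0.3, cell_parameters()),
               "0-45")
  expect_error(steady_state_allocation(20, 300, -0.1, cell_parameters()),
               ">= 0")
})

test_that("shipped profiles load and differ as documented", {
  com <- cell_parameters_profile("community")
  euk <- cell_parameters_profile("eukaryote")
  expect_gt(euk$Rm_ref, com$Rm_ref)  # raised maintenance consumption
  expect_identical(com$k_bio_ref, euk$k_bio_ref)
  expect_error(cell_parameters_profile("diatom"), "unknown")
})
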