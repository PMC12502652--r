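POOLS <- c("biosynthetic", "photosynthetic", "C_storage", "N_storage",
           "essential")
ELEMENTS <- c("C", "N", "P")

#' Steady-state macromolecular allocation and stoichiometry
#'
#' Core of CFM-Phyto-T.  Given temperature, irradiance and specific growth
#' rate, solves the steady-state carbon balance of a coarse-grained cell and
#' returns the allocation of C, N and P across five functional pools
#' (biosynthetic, photosynthetic, C storage, N storage, essential) together
#' with the resulting elemental stoichiometry.
#'
#' The carbon budget, expressed as fractions of total cell carbon, is closed
#' as follows.  The chlorophyll quota is set by the requirement that light-
#' limited photosynthesis pays for growth, biosynthetic overhead and
#' maintenance respiration:
#' `ChlC = (mu * (1 + E_bio) + Rm(T)) / P_chl(I)`.
#' The photosynthetic pool is chlorophyll plus associated protein and
#' thylakoid membrane, `ChlC * (1 + f_pp + f_thy)`.  The biosynthetic pool
#' (ribosomes/RNA plus biosynthetic protein) scales with growth demand,
#' `mu / k_bio(T)`, split internally by the fixed RNA share `f_rna`.  The
#' essential pool is the constant `C_ess` (DNA share `f_dna_ess`), and the
#' nitrogen store contributes a carbon skeleton `N_store / NC(n_store)`.
#' Carbon storage takes the remainder; a negative remainder means the forcing
#' cannot be sustained and raises an infeasibility error naming the record.
#'
#' Nitrogen and phosphorus per pool follow from the biomolecule composition
#' table.  Under phosphorus limitation no phosphorus is ever allocated to
#' storage: storage pools carry carbon and nitrogen only.
#'
#' @param T_C Water temperature, degrees Celsius (0-45).
#' @param I Irradiance, umol photons m^-2 s^-1, >= 0.
#' @param mu Specific growth rate, d^-1, >= 0.  The steady-state model
#'   describes a growing, balanced cell; negative (crash-phase) rates are a
#'   domain error here and are clamped upstream by [predict_stoichiometry()].
#' @param params A [cell_parameters()] object.
#' @param limitation Nutrient regime; one of `"P_limited"` (default),
#'   `"N_limited"`, `"replete"`.  This model version resolves no phosphorus
#'   storage in any regime, matching its phosphorus-limited design.
#' @param tank_id,day Optional labels reported in infeasibility errors.
#'
#' @return An object of class `cfm_state`: a list with
#'   \item{allocation}{3 x 5 numeric matrix of fractional allocation, rows
#'     `C`, `N`, `P`, columns the five pools; each row sums to 1.}
#'   \item{stoichiometry}{list with `NC`, `PC`, `NP` (mol mol^-1) and `ChlC`
#'     (chlorophyll-pool carbon per total carbon).  `NP` is `NA` when
#'     `PC == 0`.}
#'   \item{pool_C,pool_N,pool_P}{named per-pool element content, per unit
#'     total cell carbon.}
#' @export
#' @examples
#' st <- steady_state_allocation(20, 300, 0.5, cell_parameters())
#' st$stoichiometry$NP
#' rowSums(st$allocation)
steady_state_allocation <- function(T_C, I, mu, params,
                                    limitation = "P_limited",
                                    tank_id = NA, day = NA) {
  validate_cell_parameters(params)
  if (!is.finite(T_C) || T_C < 0 || T_C > 45)
    stop("temperature must lie in 0-45 degC (got ", T_C, ")")
  if (!is.finite(I) || I < 0) stop("irradiance must be >= 0")
  if (!is.finite(mu) || mu < 0)
    stop("growth rate must be >= 0 for the steady-state model (got ", mu, ")")
  limitation <- match.arg(limitation, c("P_limited", "N_limited", "replete"))

  T_K <- celsius_to_kelvin(T_C)
  cm <- params$comp
  P_chl <- light_limited_photosynthesis(I, params)
  Rm <- maintenance_respiration(T_K, params)
  k_bio <- biosynthetic_capacity(T_K, params)

  demand <- mu * (1 + params$E_bio) + Rm
  if (demand <= 0) {
    chl_C <- 0
  } else if (P_chl <= 0) {
    infeasible_stop(tank_id, day,
                    "no photosynthesis possible (I = 0) with positive carbon demand")
  } else {
    chl_C <- demand / P_chl
  }

  photo_C <- chl_C * (1 + params$f_pp + params$f_thy)
  bio_C <- mu / k_bio
  rna_C <- params$f_rna * bio_C
  bprot_C <- (1 - params$f_rna) * bio_C
  ess_C <- params$C_ess
  dna_C <- params$f_dna_ess * ess_C
  eprot_C <- (1 - params$f_dna_ess) * ess_C
  nstore_C <- if (cm["n_store", "NC"] > 0)
    params$N_store / cm["n_store", "NC"] else 0
  cstore_C <- 1 - photo_C - bio_C - ess_C - nstore_C
  if (cstore_C < 0)
    infeasible_stop(tank_id, day, sprintf(
      "carbon demand exceeds budget: photosynthetic %.4f + biosynthetic %.4f + essential %.4f + N-store skeleton %.4f > 1",
      photo_C, bio_C, ess_C, nstore_C))

  pool_C <- c(biosynthetic = bio_C, photosynthetic = photo_C,
              C_storage = cstore_C, N_storage = nstore_C, essential = ess_C)
  pool_N <- c(
    biosynthetic = bprot_C * cm["protein", "NC"] + rna_C * cm["rna", "NC"],
    photosynthetic = chl_C * cm["chlorophyll", "NC"] +
      chl_C * params$f_pp * cm["protein", "NC"] +
      chl_C * params$f_thy * cm["thylakoid", "NC"],
    C_storage = cstore_C * cm["carb_store", "NC"],
    N_storage = params$N_store,
    essential = dna_C * cm["dna", "NC"] + eprot_C * cm["protein", "NC"]
  )
  # No phosphorus storage in this (phosphorus-limited) model version.
  pool_P <- c(
    biosynthetic = rna_C * cm["rna", "PC"],
    photosynthetic = chl_C * params$f_thy * cm["thylakoid", "PC"],
    C_storage = cstore_C * cm["carb_store", "PC"],
    N_storage = 0,
    essential = dna_C * cm["dna", "PC"]
  )

  NC <- sum(pool_N)
  PC <- sum(pool_P)
  NP <- if (PC > 0) NC / PC else NA_real_

  alloc <- rbind(
    C = pool_C / sum(pool_C),
    N = if (NC > 0) pool_N / NC else rep(NA_real_, 5L),
    P = if (PC > 0) pool_P / PC else rep(NA_real_, 5L)
  )
  colnames(alloc) <- POOLS

  out <- list(
    allocation = alloc,
    stoichiometry = list(NC = NC, PC = PC, NP = NP, ChlC = chl_C),
    pool_C = pool_C, pool_N = pool_N, pool_P = pool_P,
    forcing = list(T_C = T_C, I = I, mu = mu, limitation = limitation)
  )
  class(out) <- "cfm_state"
  out
}

infeasible_stop <- function(tank_id, day, msg) {
  where <- if (!is.na(tank_id) || !is.na(day))
    sprintf(" [tank %s, day %s]", tank_id, day) else ""
  stop(errorCondition(paste0("infeasible forcing", where, ": ", msg),
                      class = c("cfm_infeasible", "error")))
}

#' @export
print.cfm_state <- function(x, ...) {
  s <- x$stoichiometry
  cat("CFM-Phyto-T steady state",
      sprintf("(T = %g degC, I = %g, mu = %g d-1, %s)\n",
              x$forcing$T_C, x$forcing$I, x$forcing$mu, x$forcing$limitation))
  cat(sprintf("  N:C = %.4f  P:C = %.5f  N:P = %s  Chl:C = %.4f\n",
              s$NC, s$PC, ifelse(is.na(s$NP), "undefined", sprintf("%.2f", s$NP)),
              s$ChlC))
  cat("  C allocation (%):\n")
  print(round(100 * x$allocation["C", ], 1))
  invisible(x)
}

state_row <- function(st) {
  a <- st$allocation
  s <- st$stoichiometry
  vals <- c(NC = s$NC, PC = s$PC, NP = s$NP, ChlC = s$ChlC)
  for (e in ELEMENTS)
    for (p in POOLS)
      vals[paste(e, p, sep = "_")] <- a[e, p]
  as.data.frame(as.list(vals))
}

empty_state_row <- function() {
  nm <- c("NC", "PC", "NP", "ChlC",
          as.vector(outer(ELEMENTS, POOLS, paste, sep = "_")))
  as.data.frame(as.list(stats::setNames(rep(NA_real_, length(nm)), nm)))
}

#' Evaluate the cell model on a grid of forcings
#'
#' Runs [steady_state_allocation()] at every combination of the supplied
#' temperature, irradiance and growth-rate values.  Infeasible combinations
#' are flagged per row (`feasible = FALSE`, results `NA`), never aborting the
#' sweep.
#'
#' @param T_C,I,mu Numeric vectors of temperatures (degC), irradiances and
#'   growth rates (d^-1); the grid is their Cartesian product.
#' @inheritParams steady_state_allocation
#' @return data.frame with one row per grid point: the forcing columns, a
#'   `feasible` flag, stoichiometry (`NC`, `PC`, `NP`, `ChlC`) and allocation
#'   fractions in columns `<element>_<pool>`.
#' @export
#' @examples
#' sw <- sweep_allocation(c(15, 20, 25), 300, 0.3, cell_parameters())
#' sw$NP
sweep_allocation <- function(T_C, I, mu, params, limitation = "P_limited") {
  if (!length(T_C) || !length(I) || !length(mu))
    stop("all grids must be non-empty")
  grid <- expand.grid(T_C = T_C, I = I, mu = mu,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    st <- tryCatch(
      steady_state_allocation(grid$T_C[i], grid$I[i], grid$mu[i], params,
                              limitation = limitation),
      cfm_infeasible = function(e) NULL)
    if (is.null(st)) cbind(feasible = FALSE, empty_state_row())
    else cbind(feasible = TRUE, state_row(st))
  })
  cbind(grid, do.call(rbind, rows))
}

#' Predict stoichiometry and allocation for a forcing table
#'
#' Applies the steady-state model to each row of a forcing table (one row per
#' tank-day, as produced by [build_forcing()]).  Negative growth rates (bloom
#' crash) are clamped to zero before evaluation, since the steady-state model
#' describes a growing cell; the clamping is recorded in `mu_model`.
#'
#' @param forcing data.frame with columns `tank_id`, `day`, `T_C`, `I`, `mu`
#'   and optionally `limitation` and `population`.
#' @param params Either a single [cell_parameters()] object used for all rows,
#'   or a named list of such objects keyed by the values of
#'   `forcing$population` (e.g. `list(eukaryote = ..., mixed = ...)`).
#' @return data.frame: forcing identifiers, `mu_model`, `feasible`,
#'   stoichiometry and `<element>_<pool>` allocation columns.
#' @export
predict_stoichiometry <- function(forcing, params) {
  need <- c("tank_id", "day", "T_C", "I", "mu")
  if (!all(need %in% names(forcing)))
    stop("forcing must have columns ", paste(need, collapse = ", "))
  lim <- if ("limitation" %in% names(forcing)) forcing$limitation
         else rep("P_limited", nrow(forcing))
  per_pop <- !inherits(params, "cell_parameters")
  if (per_pop && !("population" %in% names(forcing)))
    stop("per-population parameters given but forcing lacks a 'population' column")
  rows <- lapply(seq_len(nrow(forcing)), function(i) {
    p <- if (per_pop) params[[forcing$population[i]]] else params
    if (is.null(p))
      stop("no parameters for population '", forcing$population[i], "'")
    mu_model <- max(0, forcing$mu[i])
    st <- tryCatch(
      steady_state_allocation(forcing$T_C[i], forcing$I[i], mu_model, p,
                              limitation = lim[i],
                              tank_id = forcing$tank_id[i],
                              day = forcing$day[i]),
      cfm_infeasible = function(e) NULL)
    if (is.null(st)) cbind(mu_model = mu_model, feasible = FALSE,
                           empty_state_row())
    else cbind(mu_model = mu_model, feasible = TRUE, state_row(st))
  })
  id_cols <- intersect(c("tank_id", "population", "treatment", "day",
                         "T_C", "I", "mu"), names(forcing))
  out <- cbind(forcing[id_cols], do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Long-format allocation table
#'
#' Reshapes a prediction table ([predict_stoichiometry()] output) into tidy
#' long format: one row per (tank, day, element, pool) with the fractional
#' allocation, the layout used for the allocation CSV output.
#'
#' @param pred Prediction table from [predict_stoichiometry()].
#' @return data.frame with columns `tank_id`, `day`, `element`, `pool`,
#'   `fraction`.
#' @export
allocation_long <- function(pred) {
  out <- do.call(rbind, lapply(ELEMENTS, function(e) {
    do.call(rbind, lapply(POOLS, function(p) {
      data.frame(tank_id = pred$tank_id, day = pred$day,
                 element = e, pool = p,
                 fraction = pred[[paste(e, p, sep = "_")]])
    }))
  }))
  out <- out[order(out$tank_id, out$day, out$element, out$pool), ]
  rownames(out) <- NULL
  out
}
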