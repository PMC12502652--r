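#' Regress observed stoichiometry on model predictions
#'
#' Ordinary least squares of observed N:C or P:C on the model prediction,
#' with intercept, pairs matched on (tank, day) — the 1:1-plot regression
#' used to judge model-observation agreement.  Observed ratios are formed
#' from particulate concentrations (`PN/PC`, `PP/PC`) when not already
#' present.
#'
#' @param pred Prediction table from [predict_stoichiometry()] (columns
#'   `tank_id`, `day`, `NC`, `PC`).
#' @param obs Sample table with `tank_id`, `day` and either ratio columns
#'   (`NC`, `PC_ratio`) or particulate concentrations (`PC`, `PN`, `PP`).
#' @param ratio `"NC"` or `"PC"`: which ratio to compare.
#' @return Object of class `cfm_regression`: `slope`, `intercept`, `R2`,
#'   `n`, `residuals` (per matched tank-day), `unmatched` (obs rows without
#'   a prediction), and the underlying `lm` fit.
#' @export
regress_model_vs_observed <- function(pred, obs, ratio = c("NC", "PC")) {
  ratio <- match.arg(ratio)
  obs_ratio <- if (ratio == "NC") {
    if ("NC" %in% names(obs)) obs$NC else obs$PN / obs$PC
  } else {
    if ("PC_ratio" %in% names(obs)) obs$PC_ratio else obs$PP / obs$PC
  }
  o <- data.frame(tank_id = obs$tank_id, day = obs$day, observed = obs_ratio)
  p <- data.frame(tank_id = pred$tank_id, day = pred$day,
                  predicted = pred[[ratio]])
  m <- merge(o, p, by = c("tank_id", "day"))
  m <- m[is.finite(m$observed) & is.finite(m$predicted), ]
  unmatched <- o[!paste(o$tank_id, o$day) %in% paste(m$tank_id, m$day), ]
  if (nrow(m) < 3L)
    stop("need >= 3 matched (tank, day) pairs for regression; have ", nrow(m))
  fit <- stats::lm(observed ~ predicted, data = m)
  sm <- summary(fit)
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- 0  # constant response: no variance explained
  out <- list(slope = unname(stats::coef(fit)["predicted"]),
              intercept = unname(stats::coef(fit)["(Intercept)"]),
              R2 = r2, n = nrow(m),
              residuals = data.frame(tank_id = m$tank_id, day = m$day,
                                     observed = m$observed,
                                     predicted = m$predicted,
                                     residual = stats::resid(fit)),
              unmatched = unmatched, ratio = ratio, fit = fit)
  class(out) <- "cfm_regression"
  out
}

#' @export
print.cfm_regression <- function(x, ...) {
  cat(sprintf("Model vs observed %s: n = %d\n", x$ratio, x$n))
  cat(sprintf("  observed = %.4f + %.4f * predicted,  R^2 = %.3f\n",
              x$intercept, x$slope, x$R2))
  if (nrow(x$unmatched))
    cat("  unmatched observation rows:", nrow(x$unmatched), "\n")
  invisible(x)
}

#' Two-factor fixed-effects ANOVA
#'
#' Standard two-way ANOVA (via [stats::aov()]) of a per-tank summary value
#' against two crossed factors, with interaction when every cell is
#' replicated.  Empty design cells are an explicit error.
#'
#' @param data data.frame holding the response and both factors.
#' @param response,factor_a,factor_b Column names; defaults match the
#'   treatment x population design (`value ~ treatment * population`).
#' @return Object of class `cfm_anova`: data.frame of terms with `df`,
#'   `sum_sq`, `F`, `p`, plus the residual row; attribute `"aov"` holds the
#'   fit.
#' @export
two_factor_anova <- function(data, response = "value",
                             factor_a = "treatment",
                             factor_b = "population") {
  need <- c(response, factor_a, factor_b)
  if (!all(need %in% names(data)))
    stop("data must have columns ", paste(need, collapse = ", "))
  A <- factor(data[[factor_a]]); B <- factor(data[[factor_b]])
  if (nlevels(A) < 2L || nlevels(B) < 2L)
    stop("each factor needs >= 2 levels")
  tab <- table(A, B)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1, ]
    stop("empty design cell: ", factor_a, " = ", levels(A)[empty[1]], ", ",
         factor_b, " = ", levels(B)[empty[2]])
  }
  replicated <- all(tab > 1L)
  d <- data.frame(y = data[[response]], A = A, B = B)
  form <- if (replicated) y ~ A * B else y ~ A + B
  fit <- stats::aov(form, data = d)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  label <- c(A = factor_a, B = factor_b,
             `A:B` = paste0(factor_a, ":", factor_b),
             Residuals = "residuals")[terms]
  Fval <- s$`F value`
  if (stats::var(d$y) == 0)  # constant response: nothing explained, F = 0
    Fval[!is.na(Fval)] <- 0
  out <- data.frame(term = unname(label), df = as.integer(s$Df),
                    sum_sq = s$`Sum Sq`, F = Fval, p = s$`Pr(>F)`)
  attr(out, "aov") <- fit
  class(out) <- c("cfm_anova", "data.frame")
  out
}

#' Summarise a pipeline run
#'
#' Builds the report tables of a completed run: per-tank-day stoichiometry
#' comparison, per-day allocation fractions in long format, and the
#' chlorophyll predicted-vs-observed comparison with an order-of-magnitude
#' agreement flag.  With empty observations a predictions-only report is
#' returned.
#'
#' @param pred Prediction table from [predict_stoichiometry()].
#' @param obs Sample table (may have zero rows).
#' @return List of class `cfm_report`: `stoichiometry` (matched pred/obs
#'   ratios), `allocation` (long per-(tank, day, element, pool) fractions),
#'   `chlorophyll` (predicted vs observed ug L^-1 where observable) and
#'   `chl_same_order` (logical flag, `NA` without observations).
#' @export
summarize_run <- function(pred, obs = NULL) {
  alloc <- allocation_long(pred[pred$feasible, , drop = FALSE])
  stoich <- pred[c("tank_id", "day", "NC", "PC", "NP", "ChlC", "feasible")]
  names(stoich)[names(stoich) == "NC"] <- "NC_pred"
  names(stoich)[names(stoich) == "PC"] <- "PC_pred"
  chl <- NULL; chl_flag <- NA
  if (!is.null(obs) && nrow(obs)) {
    o <- data.frame(tank_id = obs$tank_id, day = obs$day,
                    NC_obs = obs$PN / obs$PC, PC_obs = obs$PP / obs$PC,
                    chl_a_obs = obs$chl_a, C_conc = obs$PC)
    stoich <- merge(stoich, o, by = c("tank_id", "day"), all.x = TRUE)
    chl <- merge(pred[c("tank_id", "day", "ChlC")],
                 o[c("tank_id", "day", "chl_a_obs", "C_conc")],
                 by = c("tank_id", "day"))
    # chlorophyll mass from chlorophyll-pool carbon: 893.5 g chl-a per 55 mol C
    chl$chl_a_pred <- chl$ChlC * chl$C_conc * (893.5 / 55)
    ok <- is.finite(chl$chl_a_pred) & is.finite(chl$chl_a_obs) &
      chl$chl_a_obs > 0
    if (any(ok)) {
      r <- stats::median(chl$chl_a_pred[ok]) / stats::median(chl$chl_a_obs[ok])
      chl_flag <- r >= 0.1 && r <= 10
    }
  }
  out <- list(stoichiometry = stoich, allocation = alloc,
              chlorophyll = chl, chl_same_order = chl_flag)
  class(out) <- "cfm_report"
  out
}

#' @export
print.cfm_report <- function(x, ...) {
  cat("CFM-Phyto-T run report\n")
  cat("  stoichiometry rows:", nrow(x$stoichiometry), "\n")
  cat("  allocation rows:   ", nrow(x$allocation), "\n")
  if (!is.null(x$chlorophyll))
    cat("  chlorophyll pred/obs same order of magnitude:", x$chl_same_order,
        "\n")
  invisible(x)
}
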