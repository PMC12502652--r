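#' Cellular parameters for CFM-Phyto-T
#'
#' Constructs and validates the full set of physiological constants used by
#' the steady-state allocation model.  All rates are per day, temperatures in
#' Kelvin, composition ratios in mol mol^-1.  Defaults correspond to the
#' `"community"` profile shipped in `inst/extdata/parameters.yaml`.
#'
#' @param Pmax_ref Maximum chlorophyll-carbon-specific carbon fixation rate
#'   (d^-1).
#' @param a_I Light saturation coefficient ((umol photons m^-2 s^-1)^-1).
#' @param E_bio Dimensionless carbon cost (excretion overhead) per unit growth.
#' @param Rm_ref Maintenance carbohydrate consumption rate at `T_ref` (d^-1).
#' @param Q10_R Temperature sensitivity (Q10) of maintenance respiration.
#' @param k_bio_ref Biosynthetic capacity at `T_ref` (d^-1): growth rate
#'   produced per unit biosynthetic-pool carbon fraction.
#' @param Ea_bio Activation energy of biosynthesis (J mol^-1).
#' @param T_ref Reference temperature (K).
#' @param f_pp Photosynthetic-protein carbon per unit chlorophyll carbon.
#' @param f_thy Thylakoid-membrane carbon per unit chlorophyll carbon.
#' @param C_ess Essential-pool carbon fraction of total cell carbon, in (0, 1).
#' @param N_store Nitrogen storage per unit total cell carbon
#'   (mol N (mol C)^-1); may be zero.
#' @param f_rna RNA share of biosynthetic-pool carbon, in [0, 1).
#' @param f_dna_ess DNA share of essential-pool carbon, in [0, 1).
#' @param comp Biomolecule composition table: a data.frame with rownames
#'   `protein`, `rna`, `dna`, `chlorophyll`, `thylakoid`, `carb_store`,
#'   `n_store` and numeric columns `NC` and `PC` (mol mol^-1).
#'
#' @return An object of class `cell_parameters` (a validated named list).
#' @seealso [cell_parameters_profile()], [steady_state_allocation()]
#' @export
#' @examples
#' p <- cell_parameters()
#' p$k_bio_ref
cell_parameters <- function(Pmax_ref = 25, a_I = 0.01, E_bio = 0.25,
                            Rm_ref = 0.1, Q10_R = 2, k_bio_ref = 2,
                            Ea_bio = 70000, T_ref = 293.15,
                            f_pp = 1.5, f_thy = 0.4, C_ess = 0.15,
                            N_store = 0.01, f_rna = 0.35, f_dna_ess = 0.1,
                            comp = default_composition()) {
  p <- list(Pmax_ref = Pmax_ref, a_I = a_I, E_bio = E_bio, Rm_ref = Rm_ref,
            Q10_R = Q10_R, k_bio_ref = k_bio_ref, Ea_bio = Ea_bio,
            T_ref = T_ref, f_pp = f_pp, f_thy = f_thy, C_ess = C_ess,
            N_store = N_store, f_rna = f_rna, f_dna_ess = f_dna_ess,
            comp = comp)
  class(p) <- "cell_parameters"
  validate_cell_parameters(p)
  p
}

#' Default biomolecule composition table
#'
#' Per-biomolecule N:C and P:C ratios (mol mol^-1) used to translate pool
#' carbon into nitrogen and phosphorus content.  Protein, chlorophyll and the
#' carbohydrate store carry no phosphorus; the carbohydrate store carries no
#' nitrogen; the thylakoid membrane carries a small phospholipid P:C.
#'
#' @return data.frame with rownames naming the biomolecule classes and columns
#'   `NC`, `PC`.
#' @export
default_composition <- function() {
  data.frame(
    NC = c(protein = 0.27, rna = 0.38, dna = 0.39, chlorophyll = 0.0727,
           thylakoid = 0, carb_store = 0, n_store = 0.5),
    PC = c(protein = 0, rna = 0.105, dna = 0.105, chlorophyll = 0,
           thylakoid = 0.024, carb_store = 0, n_store = 0)
  )
}

comp_classes <- c("protein", "rna", "dna", "chlorophyll", "thylakoid",
                  "carb_store", "n_store")

validate_cell_parameters <- function(p) {
  stopifnot(inherits(p, "cell_parameters"))
  num <- c("Pmax_ref", "a_I", "E_bio", "Rm_ref", "Q10_R", "k_bio_ref",
           "Ea_bio", "T_ref", "f_pp", "f_thy", "C_ess", "N_store",
           "f_rna", "f_dna_ess")
  for (f in num) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("cell_parameters: field '", f, "' must be a finite scalar")
  }
  pos <- c("Pmax_ref", "a_I", "Q10_R", "k_bio_ref", "T_ref",
           "f_pp", "f_thy")
  bad <- pos[vapply(pos, function(f) p[[f]] <= 0, logical(1))]
  if (length(bad))
    stop("cell_parameters: fields must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (p$E_bio < 0 || p$Ea_bio < 0 || p$Rm_ref < 0)
    stop("cell_parameters: E_bio, Ea_bio and Rm_ref must be non-negative")
  if (p$N_store < 0)
    stop("cell_parameters: N_store must be >= 0")
  if (p$C_ess <= 0 || p$C_ess >= 1)
    stop("cell_parameters: C_ess must lie in (0, 1)")
  if (p$f_rna < 0 || p$f_rna >= 1 || p$f_dna_ess < 0 || p$f_dna_ess >= 1)
    stop("cell_parameters: f_rna and f_dna_ess must lie in [0, 1)")
  cm <- p$comp
  if (!is.data.frame(cm) || !all(comp_classes %in% rownames(cm)) ||
      !all(c("NC", "PC") %in% colnames(cm)))
    stop("cell_parameters: comp must be a data.frame with rows ",
         paste(comp_classes, collapse = ", "), " and columns NC, PC")
  if (any(cm$NC < 0) || any(cm$PC < 0))
    stop("cell_parameters: comp entries must be non-negative")
  if (cm["protein", "PC"] != 0 || cm["chlorophyll", "PC"] != 0 ||
      cm["carb_store", "PC"] != 0)
    stop("cell_parameters: P:C of protein, chlorophyll and carb_store must be 0")
  if (cm["carb_store", "NC"] != 0)
    stop("cell_parameters: N:C of carb_store must be 0")
  invisible(p)
}

#' Load a shipped parameter profile
#'
#' Two calibrations ship with the package: `"community"` (original average-
#' community constants) and `"eukaryote"` (raised maintenance carbohydrate
#' consumption and larger essential pool, for a Raphidocelis-like green alga).
#'
#' @param profile Profile name, `"community"` or `"eukaryote"`.
#' @param file Optional path to an alternative YAML parameter file with the
#'   same layout as the shipped `parameters.yaml`.
#' @return A [cell_parameters()] object.
#' @export
#' @examples
#' euk <- cell_parameters_profile("eukaryote")
#' euk$Rm_ref
cell_parameters_profile <- function(profile = c("community", "eukaryote"),
                                    file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "parameters.yaml", package = "cfmphyto",
                        mustWork = TRUE)
  cfg <- yaml::read_yaml(file, merge.precedence = "override")
  profile <- if (length(profile) > 1L) profile[1L] else profile
  if (is.null(cfg$profiles[[profile]]))
    stop("unknown parameter profile '", profile, "'; available: ",
         paste(names(cfg$profiles), collapse = ", "))
  raw <- cfg$profiles[[profile]]
  comp_raw <- raw$comp
  comp <- data.frame(
    NC = vapply(comp_classes, function(b) as.numeric(comp_raw[[b]]$NC), 0),
    PC = vapply(comp_classes, function(b) as.numeric(comp_raw[[b]]$PC), 0),
    row.names = comp_classes
  )
  args <- raw[setdiff(names(raw), "comp")]
  args <- lapply(args, as.numeric)
  args$comp <- comp
  do.call(cell_parameters, args)
}

#' @export
print.cell_parameters <- function(x, ...) {
  cat("CFM-Phyto-T cell parameters\n")
  cat(sprintf("  photosynthesis: Pmax_ref = %g d-1, a_I = %g\n",
              x$Pmax_ref, x$a_I))
  cat(sprintf("  maintenance:    Rm_ref = %g d-1, Q10_R = %g\n",
              x$Rm_ref, x$Q10_R))
  cat(sprintf("  biosynthesis:   k_bio_ref = %g d-1, Ea_bio = %g J mol-1, f_rna = %g\n",
              x$k_bio_ref, x$Ea_bio, x$f_rna))
  cat(sprintf("  structure:      C_ess = %g, N_store = %g, f_pp = %g, f_thy = %g\n",
              x$C_ess, x$N_store, x$f_pp, x$f_thy))
  cat(sprintf("  reference T:    %g K\n", x$T_ref))
  invisible(x)
}
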