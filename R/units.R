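# Unit handling: the model works internally in g L^-1 for every species,
# while culture media and assay results are conventionally reported in mM.
# The bridge between the two is a per-nutrient molar mass table.

#' Nutrient identifiers
#'
#' The closed set of medium nutrients tracked by both models: sucrose
#' (`"S"`), fructose (`"F"`), glucose (`"G"`), ammonium (`"A"`), nitrate
#' (`"N"`) and phosphate (`"P"`). Dry mass (`"X"`) is a response but not a
#' nutrient.
#'
#' @format Character vector of length 6.
#' @export
NUTRIENT_IDS <- c("S", "F", "G", "A", "N", "P")

#' Molar mass table for medium nutrients
#'
#' Returns the molar masses [g mol^-1] used to convert between reported
#' millimolar concentrations and the internal g L^-1 scale. Defaults use the
#' free-ion species for the inorganic nutrients (NH4+ 18.04, NO3- 62.00,
#' PO4 94.97), not the parent salts of the medium recipe, because the assays
#' quantify the dissolved ions. Any entry can be overridden.
#'
#' @param ... Named overrides, e.g. `A = 80.04` to count ammonium as
#'   ammonium nitrate equivalents.
#' @return Named numeric vector over [NUTRIENT_IDS].
#' @examples
#' molar_masses()
#' molar_masses(P = 96.99) # H2PO4- convention
#' @export
molar_masses <- function(...) {
  mm <- c(S = 342.30, F = 180.16, G = 180.16, A = 18.04, N = 62.00, P = 94.97)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), NUTRIENT_IDS)
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown nutrient id(s) in molar mass override: ",
           paste(bad, collapse = ", "))
    }
    vals <- unlist(dots)
    if (any(vals <= 0)) stop("molar masses must be positive")
    mm[names(dots)] <- vals
  }
  mm
}

#' Convert a reported concentration (mM) to the internal scale (g/L)
#'
#' @param c_mM Concentration in mM (vectorised, must be >= 0).
#' @param nutrient A single nutrient id from [NUTRIENT_IDS].
#' @param mm Molar mass table, see [molar_masses()].
#' @return Concentration in g L^-1.
#' @examples
#' to_internal(88, "S") # 30.12 g/L sucrose
#' @export
to_internal <- function(c_mM, nutrient, mm = molar_masses()) {
  stopifnot(length(nutrient) == 1L)
  if (!nutrient %in% names(mm)) stop("unknown nutrient id: ", nutrient)
  if (any(c_mM < 0)) stop("concentrations must be non-negative")
  c_mM * mm[[nutrient]] / 1000
}

#' Convert an internal concentration (g/L) back to mM
#'
#' @param c_gL Concentration in g L^-1 (vectorised, must be >= 0).
#' @inheritParams to_internal
#' @return Concentration in mM.
#' @export
to_reported <- function(c_gL, nutrient, mm = molar_masses()) {
  stopifnot(length(nutrient) == 1L)
  if (!nutrient %in% names(mm)) stop("unknown nutrient id: ", nutrient)
  if (any(c_gL < 0)) stop("concentrations must be non-negative")
  c_gL * 1000 / mm[[nutrient]]
}

#' Hexose yield of sucrose hydrolysis
#'
#' Mass of each hexose (glucose or fructose) produced per unit mass of
#' sucrose hydrolysed: one mole of sucrose gives one mole of each hexose,
#' so the yield is the hexose/sucrose molar-mass ratio, about 0.526 g g^-1.
#'
#' @param mm Molar mass table.
#' @return Dimensionless mass yield (scalar).
#' @export
sucrose_hexose_yield <- function(mm = molar_masses()) {
  mm[["G"]] / mm[["S"]]
}
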