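#' Limiting equivalent ionic conductivities at 25 degrees C
#'
#' The shipped mobility table used by the Henderson liquid-junction
#' calculation: standard published limiting equivalent conductivities
#' (S cm2/equiv), including the organic anions of common pipette internals
#' (gluconate, HEPES) and EGTA treated by its dominant (2-) charge state
#' near pH 7.2. User-extensible: pass extra rows via `extra`.
#'
#' @param extra optional data.frame with columns `species`, `z`, `lambda`
#'   appended to (or overriding) the shipped table.
#' @return data.frame with columns `species`, `z` (signed integer charge),
#'   `lambda` (limiting equivalent conductivity).
#' @export
ion_mobility_table <- function(extra = NULL) {
  tab <- data.frame(
    species = c("K", "Na", "Li", "Cs", "H", "NH4", "Mg", "Ca",
                "Cl", "Br", "F", "HCO3", "H2PO4", "HPO4", "SO4", "NO3",
                "acetate", "gluconate", "HEPES", "MES", "EGTA", "OH",
                "glutamate", "methylsulfate"),
    z = c(1, 1, 1, 1, 1, 1, 2, 2,
          -1, -1, -1, -1, -1, -2, -2, -1,
          -1, -1, -1, -1, -2, -1,
          -1, -1),
    lambda = c(73.50, 50.11, 38.69, 77.30, 349.80, 73.50, 53.06, 59.50,
               76.35, 78.30, 55.40, 44.50, 33.00, 57.00, 80.00, 71.46,
               40.90, 24.30, 22.05, 26.80, 24.00, 198.00,
               26.00, 48.80),
    stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(all(c("species", "z", "lambda") %in% names(extra)))
    tab <- rbind(tab[!tab$species %in% extra$species, ], extra)
  }
  tab
}

#' Ionic composition of a solution
#'
#' @param ... named ionic concentrations in mM, e.g. `K = 144, Cl = 123`.
#'   Names must appear in the mobility table used downstream.
#' @return named numeric vector of class `solution_composition`.
#' @export
solution_composition <- function(...) {
  x <- c(...)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("all species must be named")
  if (any(x < 0)) stop("concentrations must be >= 0")
  structure(x, class = "solution_composition")
}

# fraction of HEPES in the anionic form at a given pH (pKa 7.48 at 25 C)
hepes_anion_fraction <- function(pH) 1 / (1 + 10^(7.48 - pH))

#' The study's pipette internal solution, as free ions
#'
#' K-gluconate 130, NaCl 7, MgCl2 2, HEPES 10, EGTA 0.1 mM (pH 7.2 with
#' KOH), dissociated into ionic species: HEPES contributes its anionic
#' fraction at pH 7.2 (with matching K+ from the KOH titration), EGTA is
#' carried as its dominant 2- species (again K-balanced), and Mg-ATP/GTP
#' are omitted from the junction calculation (their contribution is within
#' the +-1 mV scope of the method).
#'
#' @param pH internal pH (default 7.2).
#' @return a [solution_composition()].
#' @export
pipette_internal_solution <- function(pH = 7.2) {
  hep <- 10 * hepes_anion_fraction(pH)
  egta <- 0.1
  solution_composition(
    K = 130 + hep + 2 * egta,  # K-gluconate + KOH counter-ions
    Na = 7,
    Mg = 2,
    Cl = 7 + 2 * 2,            # NaCl + MgCl2
    gluconate = 130,
    HEPES = hep,
    EGTA = egta)
}

#' The study's standard aCSF, as free ions
#'
#' NaCl 119, KCl 2.5, NaH2PO4 1.25, NaHCO3 24, HEPES 5, glucose 12.5,
#' MgSO4 2, CaCl2 2 mM (glucose is neutral and drops out; HEPES again
#' enters by its anionic fraction, Na-balanced, at the carbogen-buffered
#' bath pH).
#'
#' @param pH bath pH (default 7.4).
#' @return a [solution_composition()].
#' @export
standard_acsf_solution <- function(pH = 7.4) {
  hep <- 5 * hepes_anion_fraction(pH)
  solution_composition(
    Na = 119 + 1.25 + 24 + hep,
    K = 2.5,
    Mg = 2,
    Ca = 2,
    Cl = 119 + 2 * 2,          # NaCl + CaCl2
    H2PO4 = 1.25,
    HCO3 = 24,
    SO4 = 2,
    HEPES = hep)
}

#' Henderson liquid junction potential
#'
#' Potential of the pipette (internal) solution relative to the bath
#' (external) solution at the liquid junction, by the Henderson equation at
#' 25 degrees C. The sign convention is the pipette-referenced correction:
#' negative for a K-gluconate internal against a NaCl-based bath (the
#' reading must be corrected by this amount).
#'
#' @param internal,external [solution_composition()]s (mM).
#' @param mobility mobility table from [ion_mobility_table()].
#' @return junction potential (mV).
#' @export
liquid_junction_potential <- function(internal, external,
                                      mobility = ion_mobility_table()) {
  species <- union(names(internal), names(external))
  if (!length(species)) stop("empty solutions")
  missing <- setdiff(species, mobility$species)
  if (length(missing))
    stop("no mobility entry for: ", paste(missing, collapse = ", "))
  idx <- match(species, mobility$species)
  z <- mobility$z[idx]
  lam <- mobility$lambda[idx]
  cA <- as.numeric(internal[species]); cA[is.na(cA)] <- 0  # pipette
  cB <- as.numeric(external[species]); cB[is.na(cB)] <- 0  # bath

  rtf <- 25.693  # RT/F at 25 C, mV
  s1 <- sum(sign(z) * lam * (cB - cA))
  s2 <- sum(abs(z) * lam * (cB - cA))
  sA <- sum(abs(z) * lam * cA)
  sB <- sum(abs(z) * lam * cB)
  if (s2 == 0 || sA == 0 || sB == 0) return(0)
  e_bath_minus_pip <- rtf * (s1 / s2) * log(sA / sB)
  -e_bath_minus_pip
}
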