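# Monoisotopic mass scale. Residue masses are the standard values for the 20
# proteinogenic amino-acid residues (i.e. amino acids minus water), to >= 9
# decimal places; small molecules are kept as package constants so every m/z
# in the package derives from one table.

.RESIDUE_MASSES <- c(
  G = 57.02146372376, A = 71.03711378471, S = 87.03202840427,
  P = 97.05276384885, V = 99.06841391407, T = 101.04767846841,
  C = 103.00918478471, L = 113.08406397713, I = 113.08406397713,
  N = 114.04292744114, D = 115.02694302383, Q = 128.05857750528,
  K = 128.09496301399, E = 129.04259308797, M = 131.04048508847,
  H = 137.05891185845, F = 147.06841391299, R = 156.10111102359,
  Y = 163.06332853255, W = 186.07931294986
)

.MASS_CONSTANTS <- c(
  water            = 18.010565,  # H2O, monoisotopic
  proton           = 1.007276,   # charge carrier
  ammonia          = 17.026549,  # NH3 neutral loss
  methanesulfenic  = 63.998301   # CH3SOH, diagnostic loss of Met sulfoxide
)

#' Monoisotopic residue masses
#'
#' Masses of the 20 standard amino-acid residues (amino acid minus water) in
#' daltons, named by one-letter code. Leucine and isoleucine are isobaric.
#'
#' @return Named numeric vector of length 20.
#' @examples
#' residueMasses()[["G"]]
#' @export
residueMasses <- function() .RESIDUE_MASSES

#' Small-molecule mass constants
#'
#' Monoisotopic masses (Da) of water, the proton charge carrier, ammonia and
#' methanesulfenic acid (CH3SOH, the ~64 Da neutral loss diagnostic for
#' methionine sulfoxide).
#'
#' @return Named numeric vector with elements \code{water}, \code{proton},
#'   \code{ammonia}, \code{methanesulfenic}.
#' @export
massConstants <- function() .MASS_CONSTANTS

# Modification registry. Deltas are monoisotopic; targets are residue letters
# (empty = any residue, terminus rule applies). The succinimide delta is
# exactly deamidation minus water: +0.984016 - 18.010565 = -17.026549.
.MOD_REGISTRY <- data.frame(
  name = c("none", "carbamidomethyl", "oxidation", "trioxidation",
           "deamidation", "succinimide", "succination", "methyl-ester",
           "acetylation"),
  delta = c(0.0, 57.021464, 15.994915, 47.984744, 0.984016, -17.026549,
            116.010959, 14.015650, 42.010565),
  targets = c("", "C", "M", "C", "N,Q", "N", "C", "D", ""),
  terminus = c("none", "none", "none", "none", "none", "none", "none",
               "none", "protein-N-term"),
  glyph = c("", "C***", "M**", "C**", "N**", "N=", "C=", "D~", "ac-"),
  stringsAsFactors = FALSE
)

#' Modification registry
#'
#' The fixed set of modification states handled by the mass core: artefactual
#' cysteine carbamidomethylation (the reduced-Cys proxy), Met sulfoxide,
#' Cys sulfonic acid (trioxidation), Asn/Gln deamidation, the succinimide
#' intermediate of deamidation, cysteine succination (2SC), aspartate methyl
#' ester (applied to the deamidated, D-encoded residue; net +14.999666 Da
#' relative to the original Asn), protein-N-terminal acetylation, and the
#' identity state \code{none}.
#'
#' @return A data.frame with columns \code{name}, \code{delta} (monoisotopic
#'   Da), \code{targets} (comma-separated residue letters; empty = any),
#'   \code{terminus} (\code{"none"} or \code{"protein-N-term"}) and
#'   \code{glyph} (report notation).
#' @examples
#' modRegistry()
#' modDelta("oxidation")
#' @export
modRegistry <- function() .MOD_REGISTRY

#' @rdname modRegistry
#' @param name Modification name as listed in \code{modRegistry()}.
#' @export
modDelta <- function(name) {
  i <- match(name, .MOD_REGISTRY$name)
  if (anyNA(i)) {
    stop("unknown modification name(s): ",
         paste(name[is.na(i)], collapse = ", "), call. = FALSE)
  }
  .MOD_REGISTRY$delta[i]
}

.modTargets <- function(name) {
  i <- match(name, .MOD_REGISTRY$name)
  strsplit(.MOD_REGISTRY$targets[i], ",", fixed = TRUE)[[1]]
}

.modTerminus <- function(name) {
  .MOD_REGISTRY$terminus[match(name, .MOD_REGISTRY$name)]
}

#' Convert between neutral mass and m/z
#'
#' Protonated-ion convention: \code{mz = (M + z * 1.007276) / z}. The proton
#' is the only charge carrier considered.
#'
#' @param mass Neutral monoisotopic mass in Da.
#' @param mz Observed or calculated m/z.
#' @param z Positive integer charge.
#' @return \code{mz()} returns m/z; \code{neutralMass()} inverts it exactly.
#' @examples
#' mz(857.410545, 2)
#' neutralMass(mz(857.410545, 2), 2)
#' @export
mz <- function(mass, z) {
  z <- .checkCharge(z)
  (mass + z * .MASS_CONSTANTS[["proton"]]) / z
}

#' @rdname mz
#' @export
neutralMass <- function(mz, z) {
  z <- .checkCharge(z)
  mz * z - z * .MASS_CONSTANTS[["proton"]]
}

.checkCharge <- function(z) {
  if (length(z) != 1L || !is.numeric(z) || is.na(z) || z < 1 ||
      z != round(z)) {
    stop("charge 'z' must be a single positive integer", call. = FALSE)
  }
  as.integer(z)
}

.residueMass <- function(letters) {
  m <- .RESIDUE_MASSES[letters]
  if (anyNA(m)) {
    stop("unknown residue letter(s): ",
         paste(unique(letters[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}
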