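#' @import methods
NULL

#' Peptidoform: a peptide interval with localized modifications
#'
#' A peptide drawn from a parent protein, located by 1-based inclusive
#' coordinates in the numbering that counts the initiator methionine, plus a
#' (possibly empty) set of localized modifications, at most one per position.
#'
#' @slot sequence Residue string (one-letter codes).
#' @slot start,end 1-based inclusive coordinates on the parent protein.
#' @slot mods data.frame with columns \code{position} (absolute coordinate)
#'   and \code{name} (a \code{modRegistry()} name).
#' @seealso [Peptidoform()], [peptidoformMass()], [fragmentLadder()]
#' @exportClass Peptidoform
setClass("Peptidoform", representation(
  sequence = "character", start = "integer", end = "integer",
  mods = "data.frame"))

setValidity("Peptidoform", function(object) {
  s <- object@sequence
  msgs <- character()
  if (length(s) != 1L || !nzchar(s)) {
    return("sequence must be a single non-empty string")
  }
  letters <- strsplit(s, "", fixed = TRUE)[[1]]
  if (!all(letters %in% names(.RESIDUE_MASSES))) {
    msgs <- c(msgs, paste0("unknown residue letter(s): ",
      paste(unique(setdiff(letters, names(.RESIDUE_MASSES))), collapse = ", ")))
  }
  if (object@end - object@start + 1L != nchar(s)) {
    msgs <- c(msgs, "end - start + 1 must equal sequence length")
  }
  m <- object@mods
  if (!all(c("position", "name") %in% names(m))) {
    return("mods must have columns 'position' and 'name'")
  }
  if (nrow(m)) {
    if (anyDuplicated(m$position)) {
      msgs <- c(msgs, "at most one modification per position")
    }
    if (any(m$position < object@start | m$position > object@end)) {
      msgs <- c(msgs, "modification position outside [start, end]")
    }
    bad <- !m$name %in% .MOD_REGISTRY$name
    if (any(bad)) {
      msgs <- c(msgs, paste0("unknown modification name(s): ",
                             paste(unique(m$name[bad]), collapse = ", ")))
    }
    ok <- !bad & m$position >= object@start & m$position <= object@end
    for (i in which(ok)) {
      tgt <- .modTargets(m$name[i])
      res <- letters[m$position[i] - object@start + 1L]
      if (.modTerminus(m$name[i]) == "protein-N-term") {
        # N-terminal rule: the mod must sit on the first residue of the
        # protein (position 1, or 2 when the initiator Met is removed).
        if (m$position[i] != object@start || object@start > 2L) {
          msgs <- c(msgs, paste0(m$name[i],
            " requires the protein N-terminal residue"))
        }
      } else if (length(tgt) && !res %in% tgt) {
        msgs <- c(msgs, paste0(m$name[i], " does not target residue '", res,
                               "' at position ", m$position[i]))
      }
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Protein with initiator-Met-aware numbering
#'
#' @slot id Identifier.
#' @slot description Free-text description.
#' @slot sequence Full residue string including the initiator Met.
#' @slot matureOffset 1 if the initiator Met is removed in the mature
#'   protein, else 0. Mature length = full length - matureOffset.
#' @seealso [Protein()], [digest()], [coverage()]
#' @exportClass Protein
setClass("Protein", representation(
  id = "character", description = "character", sequence = "character",
  matureOffset = "integer"))

setValidity("Protein", function(object) {
  if (length(object@sequence) != 1L || !nzchar(object@sequence)) {
    return("sequence must be a single non-empty string")
  }
  if (!object@matureOffset %in% c(0L, 1L)) {
    return("matureOffset must be 0 or 1")
  }
  letters <- strsplit(object@sequence, "", fixed = TRUE)[[1]]
  if (!all(letters %in% names(.RESIDUE_MASSES))) {
    return("sequence contains non-standard residue letters")
  }
  TRUE
})

#' Sequence coverage of a protein by observed peptides
#'
#' @slot proteinId Parent protein id.
#' @slot covered Sorted integer vector of covered mature positions
#'   (initiator-counting coordinates).
#' @slot percent Covered mature positions / mature length x 100.
#' @slot uncoveredRuns data.frame(start, end) intervals partitioning the
#'   uncovered part of the mature sequence.
#' @seealso [coverage()]
#' @exportClass CoverageMap
setClass("CoverageMap", representation(
  proteinId = "character", covered = "integer", percent = "numeric",
  uncoveredRuns = "data.frame"))

setValidity("CoverageMap", function(object) {
  if (object@percent < 0 || object@percent > 100) {
    return("percent must lie in [0, 100]")
  }
  TRUE
})

#' Per-site modified/reference intensity ratio summary
#'
#' One row of a site quantification table: the ratio of summed intensities
#' of evidence carrying the modification at the site over evidence carrying
#' the reference state, per technical replicate, with mean and sample SD.
#'
#' @slot site Absolute sequence position.
#' @slot modification,reference Modification-state names.
#' @slot cellLine Sample label the summary was computed for.
#' @slot replicateRatios Named numeric vector, one ratio per replicate with a
#'   defined (non-zero-denominator) ratio.
#' @slot mean,sd Mean and sample SD over the defined replicate ratios.
#' @slot flag \code{"normal"} or \code{"fully_modified"} (reference intensity
#'   zero in every replicate).
#' @seealso [siteRatio()], [buildRatioTable()]
#' @exportClass SiteQuantSummary
setClass("SiteQuantSummary", representation(
  site = "integer", modification = "character", reference = "character",
  cellLine = "character", replicateRatios = "numeric", mean = "numeric",
  sd = "numeric", flag = "character"))

setValidity("SiteQuantSummary", function(object) {
  if (!object@flag %in% c("normal", "fully_modified")) {
    return("flag must be 'normal' or 'fully_modified'")
  }
  TRUE
})

#' Centroided MS/MS peak list
#'
#' @slot precursorMz,precursorCharge Precursor ion coordinates.
#' @slot peaks Two-column numeric matrix (\code{mz}, \code{intensity}),
#'   sorted by m/z, intensities >= 0.
#' @slot title Scan title / id.
#' @seealso [readMGF()], [annotateSpectrum()]
#' @exportClass PeakList
setClass("PeakList", representation(
  precursorMz = "numeric", precursorCharge = "integer", peaks = "matrix",
  title = "character"))

setValidity("PeakList", function(object) {
  p <- object@peaks
  if (ncol(p) != 2L) return("peaks must be a two-column matrix (mz, intensity)")
  if (nrow(p)) {
    if (is.unsorted(p[, 1L])) return("peaks must be sorted by m/z")
    if (any(p[, 2L] < 0)) return("intensities must be >= 0")
  }
  TRUE
})

#' Fragment annotation of a peak list against a peptidoform
#'
#' @slot peptidoform The matched [Peptidoform-class].
#' @slot matches data.frame: \code{peak} (row index into the peak list),
#'   \code{series}, \code{index}, \code{charge}, \code{loss}, \code{theoMz},
#'   \code{ppm}. Each peak and each theoretical ion is used at most once.
#' @slot diagnostics List; \code{metoxNeutralLossFound} flags a matched
#'   backbone ion spanning a Met-sulfoxide with its \eqn{-}CH3SOH companion.
#' @slot fractionMatched Fraction of theoretical ions matched to a peak.
#' @slot precursorPpm Signed ppm error of the precursor.
#' @seealso [annotateSpectrum()]
#' @exportClass AnnotatedSpectrum
setClass("AnnotatedSpectrum", representation(
  peptidoform = "Peptidoform", matches = "data.frame", diagnostics = "list",
  fractionMatched = "numeric", precursorPpm = "numeric"))

#' Voltage protocol applied during a current recording
#'
#' Either a constant holding potential (default +10 mV) or a symmetric
#' triangular ramp 0 -> +Vmax -> 0 -> -Vmax -> 0 (default Vmax 50 mV, period
#' 100 s, i.e. 10 mHz).
#'
#' @slot kind \code{"constant"} or \code{"triangular"}.
#' @slot level Holding potential in mV (constant protocols).
#' @slot vmax,period Ramp amplitude (mV) and period (s).
#' @seealso [constantProtocol()], [triangularProtocol()], [protocolVoltage()]
#' @exportClass VoltageProtocol
setClass("VoltageProtocol", representation(
  kind = "character", level = "numeric", vmax = "numeric", period = "numeric"))

setValidity("VoltageProtocol", function(object) {
  if (!object@kind %in% c("constant", "triangular")) {
    return("kind must be 'constant' or 'triangular'")
  }
  if (object@kind == "triangular" && object@period <= 0) {
    return("period must be > 0 for triangular ramps")
  }
  TRUE
})

#' Sampled single-channel current trace
#'
#' @slot dt Sampling interval in seconds (uniform).
#' @slot current Current samples in pA.
#' @slot protocol The [VoltageProtocol-class] applied.
#' @slot labels Free-form condition labels (e.g. KCl molarity, DTT).
#' @seealso [simulateTrace()], [detectSteps()], [ivCurve()]
#' @exportClass CurrentTrace
setClass("CurrentTrace", representation(
  dt = "numeric", current = "numeric", protocol = "VoltageProtocol",
  labels = "list"))

setValidity("CurrentTrace", function(object) {
  if (object@dt <= 0) return("sampling interval must be > 0")
  if (object@protocol@kind == "triangular" &&
      length(object@current) * object@dt < object@protocol@period) {
    return("trace must span at least one protocol period")
  }
  TRUE
})

#' Gating step amplitudes and conductance summary
#'
#' @slot amplitudes Signed step amplitudes (pA) between successive levels.
#' @slot histogram List with \code{edges} and \code{counts} over absolute
#'   amplitudes; counts sum to the event count.
#' @slot modalConductance Modal event conductance in pS (modal absolute
#'   amplitude / |V|); \code{NA} when no events were found.
#' @slot voltage Holding potential in mV.
#' @seealso [detectSteps()]
#' @exportClass ConductanceSummary
setClass("ConductanceSummary", representation(
  amplitudes = "numeric", histogram = "list", modalConductance = "numeric",
  voltage = "numeric"))

setValidity("ConductanceSummary", function(object) {
  if (length(object@histogram$counts) &&
      sum(object@histogram$counts) != length(object@amplitudes)) {
    return("histogram counts must sum to the event count")
  }
  TRUE
})

#' Normalized conductance versus voltage curve
#'
#' @slot table data.frame with \code{Vm} (mV), \code{G} (nS) and \code{GG0}.
#' @slot g0 Reference conductance (mean G over |Vm| <= vRef), nS.
#' @slot vRef Reference band half-width in mV.
#' @seealso [voltageDependence()]
#' @exportClass VoltageDependenceCurve
setClass("VoltageDependenceCurve", representation(
  table = "data.frame", g0 = "numeric", vRef = "numeric"))
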