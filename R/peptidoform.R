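#' Construct a Peptidoform
#'
#' @param sequence Residue string (one-letter codes).
#' @param start,end 1-based inclusive coordinates on the parent protein, in
#'   the numbering that counts the initiator Met. Defaults place the peptide
#'   at positions 1..nchar(sequence).
#' @param mods Localized modifications: a data.frame with columns
#'   \code{position} (absolute coordinate) and \code{name}, or a named list
#'   / vector \code{c("26" = "oxidation")}, or NULL.
#' @return A validated [Peptidoform-class] object.
#' @examples
#' Peptidoform("GYGFGMVK", 21, 28, c("26" = "oxidation"))
#' @export
Peptidoform <- function(sequence, start = 1L, end = start + nchar(sequence) - 1L,
                        mods = NULL) {
  new("Peptidoform", sequence = as.character(sequence),
      start = as.integer(start), end = as.integer(end),
      mods = .asModsFrame(mods))
}

.asModsFrame <- function(mods) {
  if (is.null(mods) || (is.data.frame(mods) && !nrow(mods)) ||
      (!is.data.frame(mods) && !length(mods))) {
    return(data.frame(position = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.data.frame(mods)) {
    out <- data.frame(position = as.integer(mods$position),
                      name = as.character(mods$name),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(position = as.integer(names(mods)),
                      name = as.character(unlist(mods, use.names = FALSE)),
                      stringsAsFactors = FALSE)
  }
  out[order(out$position), , drop = FALSE]
}

#' @describeIn Peptidoform Residue string accessor.
#' @param x A Peptidoform.
#' @export
pepSequence <- function(x) x@sequence

#' @describeIn Peptidoform Start coordinate accessor.
#' @export
pepStart <- function(x) x@start

#' @describeIn Peptidoform End coordinate accessor.
#' @export
pepEnd <- function(x) x@end

#' @describeIn Peptidoform Modification table accessor.
#' @export
pepMods <- function(x) x@mods

setMethod("show", "Peptidoform", function(object) {
  cat(sprintf("Peptidoform %s (%d-%d)\n", object@sequence, object@start,
              object@end))
  if (nrow(object@mods)) {
    cat("  mods:", paste(sprintf("%d:%s", object@mods$position,
                                 object@mods$name), collapse = ", "), "\n")
  } else {
    cat("  mods: none\n")
  }
})

#' Peptidoform text dialect
#'
#' Round-trippable one-line notation \code{SEQUENCE/start-end[pos:mod,...]},
#' e.g. \code{"GYGFGMVK/21-28[26:oxidation]"}. The bracket part is omitted
#' for unmodified peptides.
#'
#' @param x A [Peptidoform-class] (format) or a single string (parse).
#' @return \code{formatPeptidoform()} a string; \code{parsePeptidoform()} a
#'   [Peptidoform-class].
#' @examples
#' parsePeptidoform("GYGFGMVK/21-28[26:oxidation]")
#' @export
formatPeptidoform <- function(x) {
  stopifnot(is(x, "Peptidoform"))
  base <- sprintf("%s/%d-%d", x@sequence, x@start, x@end)
  if (nrow(x@mods)) {
    base <- sprintf("%s[%s]", base, paste(
      sprintf("%d:%s", x@mods$position, x@mods$name), collapse = ","))
  }
  base
}

#' @rdname formatPeptidoform
#' @export
parsePeptidoform <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec(
    "^([A-Z]+)/([0-9]+)-([0-9]+)(\\[([^]]*)\\])?$", x))[[1]]
  if (!length(m)) stop("cannot parse peptidoform string: ", x, call. = FALSE)
  mods <- NULL
  if (nzchar(m[6L])) {
    parts <- strsplit(strsplit(m[6L], ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    mods <- data.frame(
      position = as.integer(vapply(parts, `[`, "", 1L)),
      name = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
  }
  Peptidoform(m[2L], as.integer(m[3L]), as.integer(m[4L]), mods)
}

#' Neutral monoisotopic mass and m/z of a peptidoform
#'
#' Sum of residue masses plus water plus the mass deltas of all localized
#' modifications. \code{peptidoformMz()} protonates: \code{(M + z p) / z}.
#'
#' @param p A [Peptidoform-class].
#' @param z Positive integer charge (for \code{peptidoformMz()}).
#' @return Mass in Da, or m/z.
#' @examples
#' peptidoformMz(Peptidoform("GYGFGMVK", 21, 28, c("26" = "oxidation")), 2)
#' @export
peptidoformMass <- function(p) {
  stopifnot(is(p, "Peptidoform"))
  validObject(p)
  letters <- strsplit(p@sequence, "", fixed = TRUE)[[1]]
  sum(.residueMass(letters)) + .MASS_CONSTANTS[["water"]] +
    sum(modDelta(p@mods$name))
}

#' @rdname peptidoformMass
#' @export
peptidoformMz <- function(p, z) mz(peptidoformMass(p), z)

#' b/y fragment-ion ladder with neutral-loss variants
#'
#' Emits all b_i and y_i ions (i = 1..n-1) at charges 1..\code{maxCharge}.
#' With \code{losses = TRUE} each backbone ion gains -H2O and -NH3 variants,
#' and ions spanning a Met-sulfoxide position additionally a -CH3SOH
#' (63.998301 Da) variant, the diagnostic companion of MetO. Singly charged
#' complementary pairs obey b_i + y_(n-i) = precursor(1+) + proton.
#'
#' @param p A [Peptidoform-class].
#' @param maxCharge Highest fragment charge to emit (default 1).
#' @param losses Emit neutral-loss variants (default TRUE).
#' @return data.frame with columns \code{series} ("b"/"y"), \code{index},
#'   \code{charge}, \code{loss} ("" for the backbone ion, else "H2O", "NH3"
#'   or "CH3SOH") and \code{mz}.
#' @examples
#' fragmentLadder(Peptidoform("GYGFGMVK", 21, 28, c("26" = "oxidation")))
#' @export
fragmentLadder <- function(p, maxCharge = 1L, losses = TRUE) {
  stopifnot(is(p, "Peptidoform"))
  validObject(p)
  maxCharge <- .checkCharge(maxCharge)
  letters <- strsplit(p@sequence, "", fixed = TRUE)[[1]]
  n <- length(letters)
  res <- .residueMass(letters)
  delta <- numeric(n)
  if (nrow(p@mods)) {
    delta[p@mods$position - p@start + 1L] <- modDelta(p@mods$name)
  }
  # relative positions carrying Met sulfoxide
  metox <- integer()
  if (nrow(p@mods)) {
    metox <- p@mods$position[p@mods$name == "oxidation" &
      letters[p@mods$position - p@start + 1L] == "M"] - p@start + 1L
  }
  prefix <- cumsum(res + delta)                 # neutral b-fragment masses
  suffix <- rev(cumsum(rev(res + delta))) + .MASS_CONSTANTS[["water"]]
  rows <- vector("list", 2L * (n - 1L))
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (series in c("b", "y")) {
      neutral <- if (series == "b") prefix[i] else suffix[n - i + 1L]
      spansMet <- if (series == "b") any(metox <= i) else any(metox >= n - i + 1L)
      lossSet <- ""
      if (losses) {
        lossSet <- c("", "H2O", "NH3", if (spansMet) "CH3SOH")
      }
      lossTable <- c(0, .MASS_CONSTANTS[["water"]],
                     .MASS_CONSTANTS[["ammonia"]],
                     .MASS_CONSTANTS[["methanesulfenic"]])
      names(lossTable) <- c("", "H2O", "NH3", "CH3SOH")
      lossMass <- unname(lossTable[match(lossSet, names(lossTable))])
      for (z in seq_len(maxCharge)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          series = series, index = i, charge = z, loss = lossSet,
          mz = (neutral - lossMass + z * .MASS_CONSTANTS[["proton"]]) / z,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  rownames(out) <- NULL
  out[order(out$series, out$index, out$charge, out$loss), , drop = FALSE]
}
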