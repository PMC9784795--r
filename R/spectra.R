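#' Construct a PeakList
#'
#' @param mz,intensity Numeric vectors of equal length; stored sorted by m/z.
#' @param precursorMz,precursorCharge Precursor coordinates.
#' @param title Scan title.
#' @return A [PeakList-class].
#' @export
PeakList <- function(mz, intensity, precursorMz = NA_real_,
                     precursorCharge = NA_integer_, title = "") {
  o <- order(mz)
  new("PeakList",
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      peaks = cbind(mz = as.numeric(mz)[o],
                    intensity = as.numeric(intensity)[o]),
      title = as.character(title))
}

#' @describeIn PeakList Peak matrix accessor (columns mz, intensity).
#' @param x A PeakList.
#' @export
peaks <- function(x) x@peaks

#' @describeIn PeakList Precursor m/z accessor.
#' @export
precursorMz <- function(x) x@precursorMz

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList '%s': %d peaks, precursor %.4f (%s+)\n",
              object@title, nrow(object@peaks), object@precursorMz,
              ifelse(is.na(object@precursorCharge), "?",
                     object@precursorCharge)))
})

#' Read / write MGF peak lists
#'
#' Minimal Mascot Generic Format codec: BEGIN IONS / TITLE= / PEPMASS= /
#' CHARGE=n+ / one "mz intensity" pair per line / END IONS. Unrecognized
#' header lines are ignored on read.
#'
#' @param path File path.
#' @param peakLists List of [PeakList-class] objects (for the writer).
#' @return \code{readMGF()} a list of [PeakList-class]; \code{writeMGF()}
#'   the path, invisibly.
#' @export
readMGF <- function(path) {
  lines <- readLines(path)
  starts <- grep("^BEGIN IONS", lines)
  ends <- grep("^END IONS", lines)
  if (length(starts) != length(ends)) {
    stop("malformed MGF: unbalanced BEGIN/END IONS", call. = FALSE)
  }
  lapply(seq_along(starts), function(i) {
    block <- lines[(starts[i] + 1L):(ends[i] - 1L)]
    title <- sub("^TITLE=", "", grep("^TITLE=", block, value = TRUE)[1])
    pepmass <- grep("^PEPMASS=", block, value = TRUE)
    pmz <- if (length(pepmass)) {
      as.numeric(strsplit(sub("^PEPMASS=", "", pepmass[1]), "\\s+")[[1]][1])
    } else NA_real_
    chg <- grep("^CHARGE=", block, value = TRUE)
    z <- if (length(chg)) {
      as.integer(sub("^CHARGE=([0-9]+)\\+?.*$", "\\1", chg[1]))
    } else NA_integer_
    dataLines <- block[grepl("^[0-9]", block)]
    if (length(dataLines)) {
      m <- do.call(rbind, lapply(strsplit(dataLines, "\\s+"), function(p) {
        as.numeric(p[1:2])
      }))
    } else {
      m <- matrix(numeric(), ncol = 2L)
    }
    PeakList(m[, 1L], m[, 2L], pmz, z,
             if (is.na(title)) sprintf("scan_%d", i) else title)
  })
}

#' @rdname readMGF
#' @export
writeMGF <- function(peakLists, path) {
  if (is(peakLists, "PeakList")) peakLists <- list(peakLists)
  con <- file(path, "w")
  on.exit(close(con))
  for (pl in peakLists) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", pl@title), con)
    if (!is.na(pl@precursorMz)) {
      writeLines(sprintf("PEPMASS=%.6f", pl@precursorMz), con)
    }
    if (!is.na(pl@precursorCharge)) {
      writeLines(sprintf("CHARGE=%d+", pl@precursorCharge), con)
    }
    if (nrow(pl@peaks)) {
      writeLines(sprintf("%.6f %.4f", pl@peaks[, 1L], pl@peaks[, 2L]), con)
    }
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Signed precursor mass error
#'
#' @param peakList A [PeakList-class] with a precursor m/z and charge.
#' @param p The candidate [Peptidoform-class].
#' @return Signed ppm error, observed minus calculated.
#' @examples
#' # 660.2664 observed vs 660.2663 calculated is about +0.15 ppm
#' @export
precursorCheck <- function(peakList, p) {
  stopifnot(is(peakList, "PeakList"))
  z <- peakList@precursorCharge
  if (is.na(z) || is.na(peakList@precursorMz)) {
    stop("peak list lacks precursor m/z or charge", call. = FALSE)
  }
  calc <- peptidoformMz(p, z)
  (peakList@precursorMz - calc) / calc * 1e6
}

#' Annotate an MS/MS peak list against a peptidoform's fragment ladder
#'
#' Greedy nearest-ppm matching between observed peaks and the theoretical
#' b/y ladder (with neutral-loss variants): candidate (peak, ion) pairs
#' within \code{tolPpm} are assigned best-|ppm| first, ties broken by lower
#' charge, then series b before y, then lower index; every peak and every
#' theoretical ion is used at most once. Neutral-loss variants are only
#' eligible once their backbone ion has been matched, which keeps diagnostic
#' flags off noise peaks. The Met-sulfoxide diagnostic is raised when a
#' matched backbone ion spanning a MetO site has its -CH3SOH (63.998301 Da)
#' companion matched at the same charge.
#'
#' A precursor mass mismatch beyond tolerance yields a warning, not a
#' failure (the annotation may still be informative).
#'
#' @param peakList A [PeakList-class].
#' @param p The [Peptidoform-class] to annotate against.
#' @param tolPpm Fragment match tolerance in ppm (default 10).
#' @param maxCharge Highest fragment charge considered (default 1).
#' @return An [AnnotatedSpectrum-class].
#' @export
annotateSpectrum <- function(peakList, p, tolPpm = 10, maxCharge = 1L) {
  stopifnot(is(peakList, "PeakList"), tolPpm > 0)
  validObject(p)
  ladder <- fragmentLadder(p, maxCharge = maxCharge, losses = TRUE)
  obs <- peakList@peaks[, 1L]
  emptyMatches <- data.frame(peak = integer(), series = character(),
                             index = integer(), charge = integer(),
                             loss = character(), theoMz = numeric(),
                             ppm = numeric(), stringsAsFactors = FALSE)
  ppmErr <- if (!is.na(peakList@precursorMz) &&
                !is.na(peakList@precursorCharge)) {
    precursorCheck(peakList, p)
  } else NA_real_
  if (!is.na(ppmErr) && abs(ppmErr) > tolPpm) {
    warning(sprintf("precursor m/z differs from calculated by %.1f ppm",
                    ppmErr), call. = FALSE)
  }
  if (!length(obs) || !nrow(ladder)) {
    return(new("AnnotatedSpectrum", peptidoform = p, matches = emptyMatches,
               diagnostics = list(metoxNeutralLossFound = FALSE),
               fractionMatched = 0, precursorPpm = ppmErr))
  }
  # all candidate pairs within tolerance
  cand <- do.call(rbind, lapply(seq_len(nrow(ladder)), function(i) {
    ppm <- (obs - ladder$mz[i]) / ladder$mz[i] * 1e6
    hit <- which(abs(ppm) <= tolPpm)
    if (!length(hit)) return(NULL)
    data.frame(peak = hit, ion = i, ppm = ppm[hit])
  }))
  matches <- emptyMatches
  if (!is.null(cand) && nrow(cand)) {
    ord <- order(abs(cand$ppm), ladder$charge[cand$ion],
                 ladder$series[cand$ion], ladder$index[cand$ion])
    cand <- cand[ord, , drop = FALSE]
    usedPeak <- logical(length(obs))
    usedIon <- logical(nrow(ladder))
    backboneMatched <- logical(nrow(ladder))  # by ladder row of the backbone
    pick <- integer()
    # two passes: backbone ions first, then loss variants gated on them
    for (pass in 1:2) {
      for (r in seq_len(nrow(cand))) {
        i <- cand$ion[r]
        isLoss <- nzchar(ladder$loss[i])
        if ((pass == 1L) == isLoss) next
        if (usedPeak[cand$peak[r]] || usedIon[i]) next
        if (isLoss) {
          bb <- which(ladder$series == ladder$series[i] &
                        ladder$index == ladder$index[i] &
                        ladder$charge == ladder$charge[i] &
                        ladder$loss == "")
          if (!any(usedIon[bb])) next
        }
        usedPeak[cand$peak[r]] <- TRUE
        usedIon[i] <- TRUE
        pick <- c(pick, r)
      }
    }
    if (length(pick)) {
      sel <- cand[pick, , drop = FALSE]
      matches <- data.frame(
        peak = sel$peak, series = ladder$series[sel$ion],
        index = ladder$index[sel$ion], charge = ladder$charge[sel$ion],
        loss = ladder$loss[sel$ion], theoMz = ladder$mz[sel$ion],
        ppm = sel$ppm, stringsAsFactors = FALSE)
      matches <- matches[order(matches$series, matches$index, matches$charge,
                               matches$loss), , drop = FALSE]
      rownames(matches) <- NULL
    }
  }
  # MetO diagnostic: matched backbone ion spanning a MetO site plus its
  # CH3SOH-loss companion at the same charge
  metox <- FALSE
  if (nrow(matches)) {
    lossHits <- matches[matches$loss == "CH3SOH", , drop = FALSE]
    for (i in seq_len(nrow(lossHits))) {
      hasBackbone <- any(matches$series == lossHits$series[i] &
                           matches$index == lossHits$index[i] &
                           matches$charge == lossHits$charge[i] &
                           matches$loss == "")
      if (hasBackbone) { metox <- TRUE; break }
    }
  }
  new("AnnotatedSpectrum", peptidoform = p, matches = matches,
      diagnostics = list(metoxNeutralLossFound = metox),
      fractionMatched = nrow(matches) / nrow(ladder),
      precursorPpm = ppmErr)
}

#' @describeIn annotateSpectrum Match table accessor.
#' @param x An AnnotatedSpectrum.
#' @export
spectrumMatches <- function(x) x@matches

#' @describeIn annotateSpectrum Fraction of theoretical ions matched.
#' @export
fractionMatched <- function(x) x@fractionMatched

#' @describeIn annotateSpectrum TRUE when the MetO 64 Da companion loss was
#'   observed for a matched backbone ion.
#' @export
metoxNeutralLossFound <- function(x) {
  isTRUE(x@diagnostics$metoxNeutralLossFound)
}

setMethod("show", "AnnotatedSpectrum", function(object) {
  cat(sprintf("AnnotatedSpectrum of %s: %d matches (%.0f%% of ladder)%s\n",
              formatPeptidoform(object@peptidoform), nrow(object@matches),
              100 * object@fractionMatched,
              if (metoxNeutralLossFound(object)) ", MetO loss found" else ""))
})

#' Write an annotation report TSV
#'
#' @param annotated An [AnnotatedSpectrum-class].
#' @param path Output path.
#' @export
writeAnnotationReport <- function(annotated, path) {
  utils::write.table(annotated@matches, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
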