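#' Voltage protocols
#'
#' \code{constantProtocol()} holds a fixed membrane potential (default
#' +10 mV, the single-channel conductance condition).
#' \code{triangularProtocol()} is the symmetric ramp 0 -> +Vmax -> 0 ->
#' -Vmax -> 0 used for voltage-dependence analysis (default 0 to +/-50 mV
#' at 10 mHz, i.e. a 100 s period).
#'
#' @param level Holding potential, mV.
#' @param vmax Ramp amplitude, mV.
#' @param period Ramp period, s.
#' @return A [VoltageProtocol-class].
#' @export
constantProtocol <- function(level = 10) {
  new("VoltageProtocol", kind = "constant", level = as.numeric(level),
      vmax = NA_real_, period = NA_real_)
}

#' @rdname constantProtocol
#' @export
triangularProtocol <- function(vmax = 50, period = 100) {
  new("VoltageProtocol", kind = "triangular", level = NA_real_,
      vmax = as.numeric(vmax), period = as.numeric(period))
}

#' Instantaneous protocol voltage
#'
#' @param protocol A [VoltageProtocol-class].
#' @param t Time points in seconds.
#' @return Voltage in mV at each time point.
#' @export
protocolVoltage <- function(protocol, t) {
  if (protocol@kind == "constant") {
    return(rep(protocol@level, length(t)))
  }
  ph <- (t / protocol@period) %% 1
  tri <- ifelse(ph < 0.25, 4 * ph, ifelse(ph < 0.75, 2 - 4 * ph, 4 * ph - 4))
  protocol@vmax * tri
}

#' Construct a CurrentTrace
#'
#' @param current Current samples, pA.
#' @param dt Sampling interval, s.
#' @param protocol A [VoltageProtocol-class].
#' @param labels Optional list of condition labels (KCl molarity, DTT, ...).
#' @return A [CurrentTrace-class].
#' @export
CurrentTrace <- function(current, dt, protocol = constantProtocol(),
                         labels = list()) {
  new("CurrentTrace", dt = as.numeric(dt), current = as.numeric(current),
      protocol = protocol, labels = labels)
}

#' @describeIn CurrentTrace Current vector accessor (pA).
#' @param x A CurrentTrace.
#' @export
traceCurrent <- function(x) x@current

#' @describeIn CurrentTrace Protocol accessor.
#' @export
traceProtocol <- function(x) x@protocol

setMethod("show", "CurrentTrace", function(object) {
  cat(sprintf("CurrentTrace: %d samples at %.4g s (%s protocol)\n",
              length(object@current), object@dt, object@protocol@kind))
})

#' Write / read a current trace CSV
#'
#' Plain-text dialect: commented header lines carrying the sampling
#' interval and protocol parameters, then a single \code{current} column.
#'
#' @param trace A [CurrentTrace-class].
#' @param path File path.
#' @return \code{readTrace()} a [CurrentTrace-class]; the writer returns the
#'   path invisibly.
#' @export
writeTrace <- function(trace, path) {
  p <- trace@protocol
  hdr <- c(sprintf("# dt %.10g", trace@dt), sprintf("# kind %s", p@kind),
           if (p@kind == "constant") sprintf("# level %.10g", p@level)
           else c(sprintf("# vmax %.10g", p@vmax),
                  sprintf("# period %.10g", p@period)))
  writeLines(c(hdr, "current", sprintf("%.6f", trace@current)), path)
  invisible(path)
}

#' @rdname writeTrace
#' @export
readTrace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) {
    hit <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(hit)) return(NA_character_)
    sub(paste0("^# ", key, " "), "", hit[1])
  }
  kind <- getv("kind")
  proto <- if (identical(kind, "constant")) {
    constantProtocol(as.numeric(getv("level")))
  } else {
    triangularProtocol(as.numeric(getv("vmax")), as.numeric(getv("period")))
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "current" & nzchar(body)]
  CurrentTrace(as.numeric(body), as.numeric(getv("dt")), proto)
}

#' Detect gating steps and summarize single-channel conductance
#'
#' Median-filters the trace (default 5 ms window), finds change points
#' where the filtered level jumps by more than \code{minStep} pA, segments
#' the trace into levels and reports the signed step amplitudes between
#' successive levels. The modal conductance is the modal absolute step
#' amplitude divided by |V| (Ohm's law; a 4.5 pA step at +10 mV is 450 pS).
#' Constant baseline offsets cancel in the amplitudes.
#'
#' @param trace A [CurrentTrace-class] under a constant-voltage protocol.
#' @param minStep Minimum step amplitude to call an event, pA.
#' @param filterMs Median filter window, ms (default 5).
#' @param binWidth Amplitude histogram bin width, pA (default 0.2).
#' @return A [ConductanceSummary-class].
#' @export
detectSteps <- function(trace, minStep = 0.5, filterMs = 5, binWidth = 0.2) {
  stopifnot(is(trace, "CurrentTrace"))
  if (trace@protocol@kind != "constant") {
    stop("detectSteps requires a constant-voltage protocol", call. = FALSE)
  }
  v <- trace@protocol@level
  if (v == 0) stop("undefined conductance at 0 mV", call. = FALSE)
  x <- trace@current
  n <- length(x)
  w <- max(3L, round(filterMs * 1e-3 / trace@dt))
  if (w %% 2L == 0L) w <- w + 1L
  filt <- if (n > w) stats::runmed(x, w) else x
  lag <- max(1L, (w - 1L) %/% 2L)
  # change score: level difference across a 2*lag window
  d <- filt[seq_len(n - 2L * lag) + 2L * lag] - filt[seq_len(n - 2L * lag)]
  hot <- abs(d) > minStep
  amplitudes <- numeric()
  if (any(hot)) {
    # cluster consecutive hot samples; the change point is the |d| maximum
    runs <- rle(hot)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    cps <- integer()
    for (i in which(runs$values)) {
      seg <- starts[i]:ends[i]
      cps <- c(cps, seg[which.max(abs(d[seg]))] + lag)
    }
    bounds <- c(0L, cps, n)
    levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
      lo <- bounds[i] + 1L
      hi <- bounds[i + 1L]
      # trim the filter-smeared edges of each segment where possible
      if (hi - lo + 1L > 4L * lag) { lo <- lo + lag; hi <- hi - lag }
      stats::median(filt[lo:hi])
    }, 0)
    amplitudes <- diff(levels)
    amplitudes <- amplitudes[abs(amplitudes) >= minStep]
  }
  hist <- amplitudeHistogram(abs(amplitudes), binWidth)
  modal <- NA_real_
  if (length(amplitudes)) {
    top <- which.max(hist$counts)
    inBin <- abs(amplitudes) >= hist$edges[top] &
      abs(amplitudes) < hist$edges[top + 1L]
    modal <- stats::median(abs(amplitudes)[inBin]) / abs(v) * 1000  # pS
  }
  new("ConductanceSummary", amplitudes = amplitudes, histogram = hist,
      modalConductance = modal, voltage = v)
}

#' Amplitude histogram
#'
#' @param amplitudes Event amplitudes, pA.
#' @param binWidth Bin width, pA.
#' @return List with \code{edges} (length counts + 1) and \code{counts}.
#' @export
amplitudeHistogram <- function(amplitudes, binWidth = 0.2) {
  if (!length(amplitudes)) return(list(edges = numeric(), counts = integer()))
  lo <- floor(min(amplitudes) / binWidth) * binWidth
  hi <- ceiling((max(amplitudes) + binWidth / 2) / binWidth) * binWidth
  edges <- seq(lo, hi, by = binWidth)
  counts <- vapply(seq_len(length(edges) - 1L), function(i) {
    sum(amplitudes >= edges[i] & amplitudes < edges[i + 1L])
  }, 0L)
  list(edges = edges, counts = counts)
}

#' @describeIn detectSteps Modal conductance accessor (pS).
#' @param x A ConductanceSummary.
#' @export
modalConductance <- function(x) x@modalConductance

#' @describeIn detectSteps Step amplitude accessor (pA).
#' @export
stepAmplitudes <- function(x) x@amplitudes

setMethod("show", "ConductanceSummary", function(object) {
  cat(sprintf("ConductanceSummary: %d events at %+g mV; modal %.0f pS\n",
              length(object@amplitudes), object@voltage,
              object@modalConductance))
})

#' Current-voltage curve from a triangular ramp
#'
#' Pairs every current sample with the instantaneous ramp voltage and
#' averages within voltage bins over all ramp cycles in the trace.
#'
#' @param trace A [CurrentTrace-class] under a triangular protocol spanning
#'   at least one period.
#' @param binWidth Voltage bin width, mV (default 1).
#' @return data.frame with columns \code{Vm} (bin center, mV) and \code{I}
#'   (mean current, pA), sorted by Vm.
#' @export
ivCurve <- function(trace, binWidth = 1) {
  stopifnot(is(trace, "CurrentTrace"))
  if (trace@protocol@kind != "triangular") {
    stop("ivCurve requires a triangular ramp protocol", call. = FALSE)
  }
  n <- length(trace@current)
  t <- (seq_len(n) - 1L) * trace@dt
  v <- protocolVoltage(trace@protocol, t)
  bin <- round(v / binWidth) * binWidth
  # report the mean voltage actually sampled in each bin, not the bin
  # center: keeps a noiseless ohmic trace exactly ohmic after binning
  vAgg <- tapply(v, bin, mean)
  iAgg <- tapply(trace@current, bin, mean)
  out <- data.frame(Vm = as.numeric(vAgg), I = as.numeric(iAgg))
  out <- out[order(out$Vm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalized conductance versus voltage (G/G0)
#'
#' Converts an I-V curve to chord conductance G = I/Vm (nS, from pA/mV) on
#' bins with |Vm| above \code{eps}, normalizes by G0 = mean conductance in
#' the low-voltage reference band |Vm| <= \code{vRef} (the conventional
#' open-state reference), and returns G/G0 per bin. For an ohmic channel the
#' curve is identically 1; voltage-gated closure bends it down at high |Vm|.
#'
#' @param iv data.frame from [ivCurve()].
#' @param vRef Reference band half-width, mV (default 10).
#' @param eps Bins with |Vm| <= eps are dropped (chord conductance is
#'   undefined at 0 mV); default 0.5 mV.
#' @return A [VoltageDependenceCurve-class].
#' @export
voltageDependence <- function(iv, vRef = 10, eps = 0.5) {
  stopifnot(all(c("Vm", "I") %in% names(iv)))
  sub <- iv[abs(iv$Vm) > eps, , drop = FALSE]
  if (!nrow(sub)) stop("no bins outside |Vm| <= eps", call. = FALSE)
  g <- sub$I / sub$Vm   # pA/mV = nS
  refBand <- abs(sub$Vm) <= vRef
  if (!any(refBand)) {
    stop("no bins in the reference band |Vm| <= ", vRef, call. = FALSE)
  }
  g0 <- mean(g[refBand])
  if (g0 == 0) stop("zero reference conductance", call. = FALSE)
  new("VoltageDependenceCurve",
      table = data.frame(Vm = sub$Vm, G = g, GG0 = g / g0), g0 = g0,
      vRef = vRef)
}

#' @describeIn voltageDependence G/G0 table accessor.
#' @param x A VoltageDependenceCurve.
#' @export
gOverG0 <- function(x) x@table

#' @describeIn voltageDependence Reference conductance accessor (nS).
#' @export
referenceConductance <- function(x) x@g0

setMethod("show", "VoltageDependenceCurve", function(object) {
  cat(sprintf("VoltageDependenceCurve: %d bins, G0 = %.3g nS (|Vm| <= %g mV)\n",
              nrow(object@table), object@g0, object@vRef))
})
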