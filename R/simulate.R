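# Synthetic-data generators. They produce every input the analysis stages
# consume -- evidence tables with planted modified/reference intensity
# ratios, MS/MS peak lists built from fragment ladders, and gating current
# traces with planted conductances -- so the whole pipeline is testable
# without instrument data. All draws go through withr::with_seed: a given
# seed yields bit-identical output.

#' Configuration for the evidence-table simulator
#'
#' Defaults mirror the study conditions: 3 technical replicates and
#' multiplicative lognormal intensity noise with CV 0.05.
#'
#' @param protein Parent [Protein-class]; planted sites must be covered by
#'   a tryptic peptide of the protein.
#' @param sites data.frame with columns \code{site}, \code{mod}, \code{ref}
#'   (state names from [modRegistry()]; ref \code{"none"} = unmodified),
#'   \code{ratio} (true modified/reference intensity ratio, >= 0) and
#'   optionally \code{fullyModified} (logical: emit no reference rows).
#' @param replicates Number of technical replicates (default 3).
#' @param baseIntensity Reference-state expected intensity (arbitrary
#'   units, default 1e6).
#' @param cv Coefficient of variation of the lognormal intensity noise
#'   (default 0.05; 0 = noise-free).
#' @param cellLine Sample label stamped on every row.
#' @param seed Mandatory integer seed.
#' @return A validated config (list, class \code{"EvidenceSimConfig"}).
#' @export
evidenceSimConfig <- function(protein, sites, replicates = 3L,
                              baseIntensity = 1e6, cv = 0.05,
                              cellLine = "NSC34", seed) {
  stopifnot(is(protein, "Protein"), is.data.frame(sites))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(sites$fullyModified)) sites$fullyModified <- FALSE
  stopifnot(all(c("site", "mod", "ref", "ratio") %in% names(sites)),
            all(sites$ratio >= 0), cv >= 0, replicates >= 1)
  peps <- digest(protein, "trypsin", maxMissed = 3L)
  for (s in sites$site) {
    if (!any(peps$start <= s & peps$end >= s)) {
      stop("site ", s, " is not covered by any tryptic peptide",
           call. = FALSE)
    }
  }
  structure(list(protein = protein, sites = sites,
                 replicates = as.integer(replicates),
                 baseIntensity = baseIntensity, cv = cv,
                 cellLine = cellLine, seed = as.integer(seed)),
            class = "EvidenceSimConfig")
}

# smallest covering tryptic peptide with fewest missed cleavages
.coveringPeptide <- function(peps, site) {
  hit <- peps[peps$start <= site & peps$end >= site, , drop = FALSE]
  hit <- hit[order(hit$missed, hit$end - hit$start), , drop = FALSE]
  hit[1L, ]
}

#' Simulate an evidence table with planted intensity ratios
#'
#' For each planted site and replicate, draws one shared peptide-level
#' abundance A (lognormal around \code{baseIntensity}) and emits reference
#' rows with expected intensity A and modified rows with expected intensity
#' \code{ratio} x A, split across charge states 2+ and 3+ so that ratio
#' estimators must pool charges. Each row gets independent multiplicative
#' lognormal noise with the configured CV; with \code{cv = 0} the planted
#' ratio is recovered exactly. \code{fullyModified} sites emit no reference
#' rows at all.
#'
#' @param cfg An [evidenceSimConfig()].
#' @return Evidence data.frame (see [readEvidence()] for columns).
#' @export
simulateEvidence <- function(cfg) {
  stopifnot(inherits(cfg, "EvidenceSimConfig"))
  sdlog <- if (cfg$cv > 0) sqrt(log(1 + cfg$cv^2)) else 0
  peps <- digest(cfg$protein, "trypsin", maxMissed = 3L)
  withr::with_seed(cfg$seed, {
    rows <- list()
    k <- 0L
    for (i in seq_len(nrow(cfg$sites))) {
      st <- cfg$sites[i, ]
      pep <- .coveringPeptide(peps, st$site)
      noise <- function() if (sdlog > 0) stats::rlnorm(1L, 0, sdlog) else 1
      for (r in seq_len(cfg$replicates)) {
        A <- cfg$baseIntensity * noise()
        for (charge in c(2L, 3L)) {
          share <- if (charge == 2L) 0.7 else 0.3
          modStr <- sprintf("%d:%s", st$site, st$mod)
          k <- k + 1L
          rows[[k]] <- data.frame(
            Sequence = pep$sequence, Start = pep$start, End = pep$end,
            Modifications = modStr, Charge = charge,
            CellLine = cfg$cellLine, Replicate = r,
            RT_min = round(20 + st$site * 0.05, 2),
            Intensity = st$ratio * A * share * noise(),
            stringsAsFactors = FALSE)
          if (!isTRUE(st$fullyModified)) {
            refStr <- if (st$ref == "none") "" else
              sprintf("%d:%s", st$site, st$ref)
            k <- k + 1L
            rows[[k]] <- data.frame(
              Sequence = pep$sequence, Start = pep$start, End = pep$end,
              Modifications = refStr, Charge = charge,
              CellLine = cfg$cellLine, Replicate = r,
              RT_min = round(20 + st$site * 0.05, 2),
              Intensity = A * share * noise(),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Simulate an MS/MS peak list from a peptidoform's fragment ladder
#'
#' Plants every ion of \code{fragmentLadder(p)} (backbone plus neutral-loss
#' variants, so a Met-sulfoxide peptidoform carries its 63.998301 Da
#' companion peaks), applies uniform m/z jitter within
#' \code{+/- jitterPpm}, and adds uniform random noise peaks.
#'
#' @param p A [Peptidoform-class].
#' @param jitterPpm Half-width of the uniform m/z jitter, ppm (default 0).
#' @param nNoisePeaks Number of uniform noise peaks to add (default 0).
#' @param seed Mandatory integer seed.
#' @param precursorCharge Charge for the reported precursor (default 2).
#' @param maxCharge Highest fragment charge planted (default 1).
#' @return A [PeakList-class].
#' @export
simulateSpectrum <- function(p, jitterPpm = 0, nNoisePeaks = 0L, seed,
                             precursorCharge = 2L, maxCharge = 1L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  validObject(p)
  ladder <- fragmentLadder(p, maxCharge = maxCharge, losses = TRUE)
  withr::with_seed(as.integer(seed), {
    jit <- if (jitterPpm > 0) {
      stats::runif(nrow(ladder), -jitterPpm, jitterPpm)
    } else numeric(nrow(ladder))
    mzv <- ladder$mz * (1 + jit * 1e-6)
    intensity <- ifelse(nzchar(ladder$loss), 30, 100)
    if (nNoisePeaks > 0L) {
      lo <- min(mzv); hi <- max(mzv)
      mzv <- c(mzv, stats::runif(nNoisePeaks, lo, hi))
      intensity <- c(intensity, stats::runif(nNoisePeaks, 1, 10))
    }
    PeakList(mzv, intensity, precursorMz = peptidoformMz(p, precursorCharge),
             precursorCharge = precursorCharge,
             title = formatPeptidoform(p))
  })
}

#' Configuration for the gating-trace simulator
#'
#' A Markov gating model: one fully open level (default 450 pS, the
#' wild-type single-channel conductance in 1 M KCl), optional conducting
#' substates with occupancies, a closed level, and a voltage-dependent
#' closure rate (logistic in |Vm|). With the default zero closure rate the
#' channel is ohmic, the wild-type-like flat-G/G0 regime.
#'
#' @param gOpen Open-state conductance, pS (default 450).
#' @param substates data.frame(conductance, occupancy): conducting substates
#'   and the fraction of conducting time spent in each; the open state gets
#'   the remaining occupancy (occupancies over all conducting levels sum
#'   to 1).
#' @param closureVHalf,closureSlope Logistic closure-rate law parameters:
#'   rate = \code{closureMaxRate} / (1 + exp(-(|Vm| - vHalf)/slope)).
#' @param closureMaxRate Maximal closure rate, 1/s (default 0: no gating).
#' @param reopenRate Closed-to-open rate, 1/s.
#' @param switchRate Rate of re-drawing the conducting level, 1/s.
#' @param gClosed Closed-state conductance, pS (default 0).
#' @param noiseSd Gaussian current noise SD, pA.
#' @param samplingHz Sampling rate, Hz.
#' @param seed Mandatory integer seed.
#' @return A validated config (list, class \code{"GatingSimConfig"}).
#' @export
gatingSimConfig <- function(gOpen = 450, substates = NULL,
                            closureVHalf = 30, closureSlope = 5,
                            closureMaxRate = 0, reopenRate = 20,
                            switchRate = 5, gClosed = 0, noiseSd = 0.1,
                            samplingHz = 1000, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(substates)) {
    substates <- data.frame(conductance = numeric(), occupancy = numeric())
  }
  stopifnot(gOpen >= 0, all(substates$conductance >= 0),
            all(substates$occupancy >= 0), sum(substates$occupancy) <= 1,
            noiseSd >= 0, samplingHz > 0)
  levels <- rbind(
    data.frame(conductance = gOpen, occupancy = 1 - sum(substates$occupancy)),
    substates)
  structure(list(levels = levels, closureVHalf = closureVHalf,
                 closureSlope = closureSlope,
                 closureMaxRate = closureMaxRate, reopenRate = reopenRate,
                 switchRate = switchRate, gClosed = gClosed,
                 noiseSd = noiseSd, samplingHz = samplingHz,
                 seed = as.integer(seed)),
            class = "GatingSimConfig")
}

#' Simulate a gating current trace
#'
#' Discrete-time Markov switching at the sampling rate between the closed
#' level and the conducting levels of the config, with closure probability
#' increasing with |Vm| through the logistic closure law. The current is
#' I = G_state x V(t) / 1000 (pS x mV -> pA) plus Gaussian noise.
#'
#' @param cfg A [gatingSimConfig()].
#' @param protocol A [VoltageProtocol-class].
#' @param duration Trace duration, s.
#' @return A [CurrentTrace-class].
#' @export
simulateTrace <- function(cfg, protocol = constantProtocol(),
                          duration = 10) {
  stopifnot(inherits(cfg, "GatingSimConfig"))
  dt <- 1 / cfg$samplingHz
  n <- max(2L, round(duration / dt))
  t <- (seq_len(n) - 1L) * dt
  v <- protocolVoltage(protocol, t)
  closeRate <- cfg$closureMaxRate /
    (1 + exp(-(abs(v) - cfg$closureVHalf) / cfg$closureSlope))
  pClose <- 1 - exp(-closeRate * dt)
  pOpen <- 1 - exp(-cfg$reopenRate * dt)
  pSwitch <- 1 - exp(-cfg$switchRate * dt)
  occ <- cfg$levels$occupancy
  gLev <- cfg$levels$conductance
  withr::with_seed(cfg$seed, {
    drawLevel <- function() sample.int(length(gLev), 1L, prob = occ)
    state <- drawLevel()   # index into conducting levels; 0L = closed
    g <- numeric(n)
    u <- stats::runif(n)
    for (i in seq_len(n)) {
      if (state == 0L) {
        if (u[i] < pOpen) state <- drawLevel()
      } else {
        if (u[i] < pClose[i]) {
          state <- 0L
        } else if (u[i] < pClose[i] + pSwitch * (length(gLev) > 1L)) {
          state <- drawLevel()
        }
      }
      g[i] <- if (state == 0L) cfg$gClosed else gLev[state]
    }
    current <- g * v / 1000 +
      if (cfg$noiseSd > 0) stats::rnorm(n, 0, cfg$noiseSd) else 0
    CurrentTrace(current, dt, protocol,
                 labels = list(KCl = "1 M", simulated = TRUE))
  })
}
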