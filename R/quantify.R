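#' Modified/reference intensity ratio at one site
#'
#' The ratio statistic behind a site quantification table row: within each
#' technical replicate, the summed intensity of all evidence rows whose
#' peptidoform carries \code{mod} at \code{site}, divided by the summed
#' intensity of rows carrying the reference state there, pooling over charge
#' states and over the different peptides covering the site. A row counts
#' toward the reference only when the site is explicitly in the reference
#' form (e.g. carbamidomethylated for Cys, unmodified for Met/Asn); rows not
#' covering the site are ignored.
#'
#' Replicates with zero reference intensity have an undefined ratio: they
#' are dropped with a warning when other replicates still define one, and
#' when the reference is absent from every replicate the site is flagged
#' \code{fully_modified} (the "totally oxidized" rendering).
#'
#' @param evidence Evidence data.frame (see [readEvidence()]).
#' @param site Absolute sequence position (initiator-Met-counting).
#' @param mod Modification name at the site (a [modRegistry()] name).
#' @param ref Reference state name; \code{"none"} means unmodified at the
#'   site.
#' @param cellLine Optional label to subset evidence before computing.
#' @return A [SiteQuantSummary-class].
#' @examples
#' ev <- data.frame(Sequence = "GYGFGMVK", Start = 21, End = 28,
#'   Modifications = c("26:oxidation", ""), Charge = 2, CellLine = "NSC34",
#'   Replicate = 1, RT_min = 30, Intensity = c(10, 1))
#' siteRatio(ev, 26, "oxidation")
#' @export
siteRatio <- function(evidence, site, mod, ref = "none", cellLine = NULL) {
  validateEvidence(evidence)
  site <- as.integer(site)
  if (!is.null(cellLine)) {
    evidence <- evidence[evidence$CellLine == cellLine, , drop = FALSE]
  }
  state <- .siteState(evidence, site)
  keep <- !is.na(state)
  evidence <- evidence[keep, , drop = FALSE]
  state <- state[keep]
  if (!nrow(evidence)) {
    stop("no evidence covers site ", site, call. = FALSE)
  }
  reps <- sort(unique(evidence$Replicate))
  num <- vapply(reps, function(r) {
    sum(evidence$Intensity[state == mod & evidence$Replicate == r])
  }, 0)
  den <- vapply(reps, function(r) {
    sum(evidence$Intensity[state == ref & evidence$Replicate == r])
  }, 0)
  defined <- den > 0
  flag <- "normal"
  if (!any(defined)) {
    flag <- "fully_modified"
    ratios <- stats::setNames(numeric(), character())
  } else {
    if (any(!defined)) {
      warning("reference intensity zero in replicate(s) ",
              paste(reps[!defined], collapse = ", "),
              "; ratio undefined there, excluded", call. = FALSE)
    }
    ratios <- stats::setNames((num / den)[defined],
                              as.character(reps[defined]))
  }
  new("SiteQuantSummary", site = site, modification = mod, reference = ref,
      cellLine = if (is.null(cellLine)) NA_character_ else cellLine,
      replicateRatios = ratios,
      mean = if (length(ratios)) mean(ratios) else NA_real_,
      sd = if (length(ratios) > 1L) stats::sd(ratios)
           else if (length(ratios) == 1L) NA_real_ else NA_real_,
      flag = flag)
}

#' @describeIn siteRatio Replicate ratio accessor.
#' @param x A SiteQuantSummary.
#' @export
replicateRatios <- function(x) x@replicateRatios

#' @describeIn siteRatio Mean ratio accessor (NA when fully modified).
#' @export
ratioMean <- function(x) x@mean

#' @describeIn siteRatio Sample-SD accessor.
#' @export
ratioSd <- function(x) x@sd

#' @describeIn siteRatio TRUE when the reference state was absent from all
#'   replicates.
#' @export
isFullyModified <- function(x) x@flag == "fully_modified"

setMethod("show", "SiteQuantSummary", function(object) {
  lab <- sprintf("site %d %s/%s", object@site, object@modification,
                 object@reference)
  if (!is.na(object@cellLine)) lab <- paste(lab, object@cellLine)
  if (object@flag == "fully_modified") {
    cat(lab, ": fully modified (no reference intensity)\n")
  } else {
    cat(sprintf("%s: mean %.3g, sd %.3g over %d replicate(s)\n", lab,
                object@mean, object@sd, length(object@replicateRatios)))
  }
})

#' Deamidation percentage at one site
#'
#' 100 x deamidated / (deamidated + unmodified) summed intensity at the
#' site, pooled over replicates and charge states (a deam/norm ratio of 0.1
#' corresponds to 10\% of molecules deamidated, the site-occupancy reading).
#'
#' @inheritParams siteRatio
#' @return Percentage in [0, 100].
#' @export
deamidationPercent <- function(evidence, site, cellLine = NULL) {
  validateEvidence(evidence)
  site <- as.integer(site)
  if (!is.null(cellLine)) {
    evidence <- evidence[evidence$CellLine == cellLine, , drop = FALSE]
  }
  state <- .siteState(evidence, site)
  if (!any(!is.na(state))) {
    stop("no evidence covers site ", site, call. = FALSE)
  }
  deam <- sum(evidence$Intensity[!is.na(state) & state == "deamidation"])
  norm <- sum(evidence$Intensity[!is.na(state) & state == "none"])
  if (deam + norm == 0) {
    stop("no deamidated or unmodified intensity at site ", site,
         call. = FALSE)
  }
  100 * deam / (deam + norm)
}

#' Site-ratio table over many sites and cell lines
#'
#' Applies [siteRatio()] to each requested (site, mod, ref) triple for every
#' cell line present in the evidence, in deterministic order (site, then
#' modification, then cell line).
#'
#' @param evidence Evidence data.frame.
#' @param sites data.frame with columns \code{site}, \code{mod}, \code{ref}.
#' @return data.frame with one row per site x cell line: \code{site},
#'   \code{mod}, \code{ref}, \code{cellLine}, \code{n} (defined replicates),
#'   \code{mean}, \code{sd}, \code{flag}.
#' @export
buildRatioTable <- function(evidence, sites) {
  if (!nrow(sites) || !nrow(evidence)) {
    return(data.frame(site = integer(), mod = character(), ref = character(),
                      cellLine = character(), n = integer(), mean = numeric(),
                      sd = numeric(), flag = character(),
                      stringsAsFactors = FALSE))
  }
  validateEvidence(evidence)
  lines <- sort(unique(evidence$CellLine))
  sites <- sites[order(sites$site, sites$mod), , drop = FALSE]
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(sites))) {
    for (cl in lines) {
      sub <- evidence[evidence$CellLine == cl, , drop = FALSE]
      covers <- any(sub$Start <= sites$site[i] & sub$End >= sites$site[i])
      if (!covers) next
      sq <- siteRatio(sub, sites$site[i], sites$mod[i], sites$ref[i])
      k <- k + 1L
      rows[[k]] <- data.frame(
        site = sq@site, mod = sq@modification, ref = sq@reference,
        cellLine = cl, n = length(sq@replicateRatios), mean = sq@mean,
        sd = sq@sd, flag = sq@flag, stringsAsFactors = FALSE)
    }
  }
  out <- if (k) do.call(rbind, rows) else
    data.frame(site = integer(), mod = character(), ref = character(),
               cellLine = character(), n = integer(), mean = numeric(),
               sd = numeric(), flag = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Render a ratio table in report style
#'
#' Two-decimal rounding for display only (underlying values keep full
#' precision); fully modified sites render as a dash, the "totally
#' oxidized" convention.
#'
#' @param table Output of [buildRatioTable()].
#' @return Character matrix-like data.frame ready for printing / TSV export.
#' @export
formatRatioTable <- function(table) {
  data.frame(
    site = table$site, mod = table$mod, ref = table$ref,
    cellLine = table$cellLine,
    mean = ifelse(table$flag == "fully_modified", "-",
                  formatC(table$mean, format = "fg", digits = 2)),
    sd = ifelse(table$flag == "fully_modified", "-",
                formatC(table$sd, format = "fg", digits = 2)),
    note = ifelse(table$flag == "fully_modified", "fully modified", ""),
    stringsAsFactors = FALSE)
}
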