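# Evidence tables: one row per identified peptidoform x charge x replicate
# with its summed intensity. The TSV dialect mirrors a search-engine
# evidence export reduced to the columns the ratio statistics need.

.EVIDENCE_COLS <- c("Sequence", "Start", "End", "Modifications", "Charge",
                    "CellLine", "Replicate", "RT_min", "Intensity")

#' Read / write evidence tables
#'
#' Tab-separated, one row per observed peptidoform x charge x replicate.
#' Required columns: \code{Sequence}, \code{Start}, \code{End},
#' \code{Modifications} (semicolon-separated \code{pos:name} list, empty for
#' unmodified), \code{Charge}, \code{CellLine}, \code{Replicate},
#' \code{RT_min}, \code{Intensity}. Extra columns are kept as-is.
#'
#' @param path File path.
#' @return \code{readEvidence()} a data.frame; writers return the path
#'   invisibly.
#' @export
readEvidence <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing <- setdiff(.EVIDENCE_COLS, names(ev))
  if (length(missing)) {
    stop("evidence table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ev$Modifications[is.na(ev$Modifications)] <- ""
  validateEvidence(ev)
  ev
}

#' @rdname readEvidence
#' @param evidence Evidence data.frame.
#' @export
writeEvidence <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname readEvidence
#' @export
validateEvidence <- function(evidence) {
  stopifnot(is.data.frame(evidence))
  missing <- setdiff(.EVIDENCE_COLS, names(evidence))
  if (length(missing)) {
    stop("evidence table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(evidence$Intensity < 0)) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  if (any(evidence$Start > evidence$End)) {
    stop("Start must be <= End", call. = FALSE)
  }
  invisible(evidence)
}

# parse "pos:name;pos:name" -> data.frame(position, name); "" -> 0 rows
.parseModString <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(position = integer(), name = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(position = as.integer(vapply(parts, `[`, "", 1L)),
             name = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
}

.formatModString <- function(mods) {
  if (!nrow(mods)) return("")
  paste(sprintf("%d:%s", mods$position, mods$name), collapse = ";")
}

# state of `site` in one evidence row: NA if the row does not cover the
# site, "none" if covered and unmodified there, else the modification name
.siteState <- function(evidence, site) {
  state <- rep(NA_character_, nrow(evidence))
  covers <- evidence$Start <= site & evidence$End >= site
  state[covers] <- "none"
  hit <- which(covers & grepl(paste0("(^|;)", site, ":"),
                              evidence$Modifications))
  for (i in hit) {
    m <- .parseModString(evidence$Modifications[i])
    state[i] <- m$name[m$position == site]
  }
  state
}
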