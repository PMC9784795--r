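#' Construct a Protein
#'
#' @param id Identifier.
#' @param sequence Full residue string including the initiator Met.
#' @param description Optional description.
#' @param matureOffset 1 if the initiator Met is removed during maturation
#'   (the mature chain then starts at position 2), else 0.
#' @return A validated [Protein-class].
#' @examples
#' Protein("P1", "MAKR", matureOffset = 1)
#' @export
Protein <- function(id, sequence, description = "", matureOffset = 1L) {
  new("Protein", id = as.character(id), description = as.character(description),
      sequence = toupper(as.character(sequence)),
      matureOffset = as.integer(matureOffset))
}

#' @describeIn Protein Full sequence accessor.
#' @param x A Protein.
#' @export
proteinSequence <- function(x) x@sequence

#' @describeIn Protein Identifier accessor.
#' @export
proteinId <- function(x) x@id

#' @describeIn Protein Mature chain length (full length minus matureOffset).
#' @export
matureLength <- function(x) nchar(x@sequence) - x@matureOffset

setMethod("show", "Protein", function(object) {
  cat(sprintf("Protein %s: %d aa (mature %d, offset %d)\n", object@id,
              nchar(object@sequence), matureLength(object),
              object@matureOffset))
  if (nzchar(object@description)) cat(" ", object@description, "\n")
})

#' Read proteins from FASTA
#'
#' @param path FASTA file path.
#' @param matureOffset Applied to every record (default 1: initiator Met
#'   removed in the mature protein).
#' @return List of [Protein-class] objects, named by id.
#' @export
readProteinFasta <- function(path, matureOffset = 1L) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  out <- lapply(seq_along(aa), function(i) {
    Protein(ids[i], as.character(aa[[i]]), desc[i], matureOffset)
  })
  names(out) <- ids
  out
}

#' @rdname readProteinFasta
#' @param proteins List of [Protein-class] objects.
#' @export
writeProteinFasta <- function(proteins, path) {
  seqs <- Biostrings::AAStringSet(vapply(proteins, proteinSequence, ""))
  names(seqs) <- vapply(proteins, function(p) {
    if (nzchar(p@description)) paste(p@id, p@description) else p@id
  }, "")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Bundled synthetic VDAC3-like reference protein
#'
#' A 283-residue synthetic stand-in for the mouse VDAC3 channel constructed
#' to match all published peptide coordinates and residue landmarks used by
#' this package (Met at 1/26/155, Cys at 2/8/36/65/122/229, Asn215, Tyr225,
#' the Arg119-Arg120 tryptic dipeptide, the blocked Arg251-Pro252 bond;
#' mature length 282). Segments between the published peptides are invented;
#' it is a test fixture, not the database sequence.
#'
#' @return A [Protein-class] with \code{matureOffset = 1}.
#' @examples
#' vdac3Fixture()
#' @export
vdac3Fixture <- function() {
  path <- system.file("extdata", "vdac3_synthetic.fasta",
                      package = "VDACmods", mustWork = TRUE)
  readProteinFasta(path, matureOffset = 1L)[[1L]]
}

.PROTEASES <- list(
  trypsin      = list(cleaveAfter = c("K", "R"), blockBefore = "P"),
  chymotrypsin = list(cleaveAfter = c("F", "W", "Y", "L"), blockBefore = "P")
)

.cleavageSites <- function(letters, rule) {
  # positions i (1-based, within the digested chain) after which the
  # protease cleaves; Keil rules: no cleavage before proline
  n <- length(letters)
  i <- which(letters %in% rule$cleaveAfter)
  i <- i[i < n]
  i[!letters[i + 1L] %in% rule$blockBefore]
}

#' In-silico protease digestion
#'
#' Digests the mature chain (the initiator Met, when absent from the mature
#' protein, is never part of a peptide) with trypsin (cleave after K/R, not
#' before P) or chymotrypsin (high specificity: after F/W/Y/L, not before
#' P), emitting every peptide with 0..\code{maxMissed} missed cleavages.
#' Coordinates are reported in the full, initiator-Met-counting numbering,
#' so the N-terminal peptide of a mature protein starts at position 2.
#' Peptides of any length are emitted; filtering is the caller's concern.
#'
#' @param protein A [Protein-class].
#' @param enzyme \code{"trypsin"} or \code{"chymotrypsin"}.
#' @param maxMissed Maximum missed cleavages (default 3).
#' @return data.frame with columns \code{sequence}, \code{start}, \code{end},
#'   \code{missed}, sorted by start then length; deterministic.
#' @examples
#' digest(Protein("P1", "MAKR"), "trypsin", maxMissed = 0)
#' @export
digest <- function(protein, enzyme = c("trypsin", "chymotrypsin"),
                   maxMissed = 3L) {
  stopifnot(is(protein, "Protein"))
  enzyme <- match.arg(enzyme)
  maxMissed <- as.integer(maxMissed)
  stopifnot(maxMissed >= 0L)
  off <- protein@matureOffset
  chain <- substr(protein@sequence, off + 1L, nchar(protein@sequence))
  letters <- strsplit(chain, "", fixed = TRUE)[[1]]
  n <- length(letters)
  bounds <- c(0L, .cleavageSites(letters, .PROTEASES[[enzyme]]), n)
  nb <- length(bounds)
  rows <- list()
  k <- 0L
  for (i in seq_len(nb - 1L)) {
    for (m in 0:maxMissed) {
      j <- i + 1L + m
      if (j > nb) break
      k <- k + 1L
      rows[[k]] <- c(bounds[i] + 1L, bounds[j], m)
    }
  }
  mat <- do.call(rbind, rows)
  out <- data.frame(
    sequence = substring(chain, mat[, 1L], mat[, 2L]),
    start = mat[, 1L] + off, end = mat[, 2L] + off, missed = mat[, 3L],
    stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end - out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert digest rows to Peptidoform objects
#'
#' @param peptides A digest data.frame (\code{sequence}, \code{start},
#'   \code{end} columns).
#' @return List of unmodified [Peptidoform-class] objects.
#' @export
asPeptidoforms <- function(peptides) {
  lapply(seq_len(nrow(peptides)), function(i) {
    Peptidoform(peptides$sequence[i], peptides$start[i], peptides$end[i])
  })
}

#' Classify peptides as isoform-unique or shared
#'
#' A peptide string is unique iff it occurs as a substring of exactly one of
#' the supplied isoform sequences (anywhere, not only at tryptic
#' boundaries); such peptides distinguish isoforms sharing most of their
#' sequence.
#'
#' @param peptides Character vector of peptide sequences.
#' @param proteins List of [Protein-class] objects (at least 2), or a named
#'   character vector of sequences.
#' @return data.frame with columns \code{peptide} and \code{status}
#'   (\code{"shared"}, \code{"unique-to-<id>"}, or \code{"absent"} when the
#'   peptide occurs in none of the sequences).
#' @export
uniquePeptides <- function(peptides, proteins) {
  if (is.list(proteins)) {
    seqs <- vapply(proteins, proteinSequence, "")
    names(seqs) <- vapply(proteins, proteinId, "")
  } else {
    seqs <- proteins
  }
  if (length(seqs) < 2L) stop("need at least two isoform sequences",
                              call. = FALSE)
  peptides <- unique(peptides)
  hits <- vapply(peptides, function(p) {
    sum(vapply(seqs, function(s) grepl(p, s, fixed = TRUE), NA))
  }, 0L)
  status <- rep("shared", length(peptides))
  status[hits == 0L] <- "absent"
  one <- hits == 1L
  if (any(one)) {
    owner <- vapply(peptides[one], function(p) {
      names(seqs)[which(vapply(seqs, function(s) grepl(p, s, fixed = TRUE),
                               NA))]
    }, "")
    status[one] <- paste0("unique-to-", owner)
  }
  data.frame(peptide = peptides, status = status, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Sequence coverage of a protein by observed peptides
#'
#' Takes the union of observed peptide intervals, intersects it with the
#' mature chain, and reports the covered fraction of the mature length (the
#' denominator convention behind "279 of 282 residues").
#'
#' @param protein A [Protein-class].
#' @param observed Observed peptides: a data.frame with \code{start}/\code{end}
#'   columns, or a list of [Peptidoform-class] objects.
#' @return A [CoverageMap-class].
#' @examples
#' coverage(Protein("P1", "MAKRGG"), data.frame(start = 2, end = 4))
#' @export
coverage <- function(protein, observed) {
  stopifnot(is(protein, "Protein"))
  if (is.list(observed) && !is.data.frame(observed)) {
    observed <- data.frame(
      start = vapply(observed, pepStart, 1L),
      end = vapply(observed, pepEnd, 1L))
  }
  n <- nchar(protein@sequence)
  off <- protein@matureOffset
  matureRange <- IRanges::IRanges(off + 1L, n)
  if (nrow(observed)) {
    if (any(observed$start < 1L | observed$end > n |
            observed$start > observed$end)) {
      stop("observed peptide interval out of protein bounds", call. = FALSE)
    }
    ir <- IRanges::reduce(IRanges::IRanges(observed$start, observed$end))
    covered <- IRanges::intersect(ir, matureRange)
  } else {
    covered <- IRanges::IRanges()
  }
  uncovered <- IRanges::setdiff(matureRange, covered)
  pct <- 100 * sum(IRanges::width(covered)) / matureLength(protein)
  new("CoverageMap", proteinId = protein@id,
      covered = as.integer(sort(unlist(lapply(seq_along(covered), function(i) {
        seq(IRanges::start(covered)[i], IRanges::end(covered)[i])
      })))),
      percent = pct,
      uncoveredRuns = data.frame(start = IRanges::start(uncovered),
                                 end = IRanges::end(uncovered)))
}

#' @describeIn coverage Covered percentage accessor.
#' @param x A CoverageMap.
#' @export
coveragePercent <- function(x) x@percent

#' @describeIn coverage Uncovered interval accessor.
#' @export
uncoveredRuns <- function(x) x@uncoveredRuns

setMethod("show", "CoverageMap", function(object) {
  cat(sprintf("CoverageMap of %s: %.1f%% (%d positions covered)\n",
              object@proteinId, object@percent, length(object@covered)))
  if (nrow(object@uncoveredRuns)) {
    cat("  uncovered:", paste(sprintf("%d-%d", object@uncoveredRuns$start,
                                      object@uncoveredRuns$end),
                              collapse = ", "), "\n")
  }
})

#' Write a peptide report TSV
#'
#' @param peptides digest() output, optionally with a \code{status} column
#'   from [uniquePeptides()].
#' @param path Output path.
#' @export
writePeptideReport <- function(peptides, path) {
  utils::write.table(peptides, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
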