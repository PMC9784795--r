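#' Validated end-to-end run configuration
#'
#' Collects and validates everything one PTM-mapping run needs before any
#' stage executes: input paths, enzyme settings, the sites of interest, the
#' output directory and the seed. The validated configuration is persisted
#' alongside the outputs for provenance.
#'
#' @param fasta Path to the protein FASTA.
#' @param evidence Path to the evidence TSV (see [readEvidence()]).
#' @param sites Sites of interest: a data.frame with columns \code{site},
#'   \code{mod}, \code{ref}, or the path of a YAML file holding a list of
#'   such records.
#' @param enzyme \code{"trypsin"} or \code{"chymotrypsin"}.
#' @param maxMissed Missed-cleavage ceiling for the digest report.
#' @param outDir Output directory (created if needed).
#' @param seed Integer seed recorded for provenance.
#' @return A list of class \code{"RunConfig"}.
#' @export
runConfig <- function(fasta, evidence, sites, enzyme = "trypsin",
                      maxMissed = 3L, outDir = tempfile("ptmrun"),
                      seed = 1L) {
  for (path in c(fasta, evidence)) {
    if (!file.exists(path)) {
      stop("input file not found: ", path, call. = FALSE)
    }
  }
  if (is.character(sites)) {
    if (!file.exists(sites)) {
      stop("input file not found: ", sites, call. = FALSE)
    }
    raw <- yaml::read_yaml(sites)
    sites <- do.call(rbind, lapply(raw, function(x) {
      data.frame(site = as.integer(x$site), mod = x$mod,
                 ref = if (is.null(x$ref)) "none" else x$ref,
                 stringsAsFactors = FALSE)
    }))
  }
  stopifnot(is.data.frame(sites),
            all(c("site", "mod", "ref") %in% names(sites)))
  enzyme <- match.arg(enzyme, c("trypsin", "chymotrypsin"))
  structure(list(fasta = fasta, evidence = evidence, sites = sites,
                 enzyme = enzyme, maxMissed = as.integer(maxMissed),
                 outDir = outDir, seed = as.integer(seed)),
            class = "RunConfig")
}

#' Run the digest -> coverage -> quantify pipeline
#'
#' Orchestrates the analysis stages over one run configuration and writes
#' deterministic report files: \code{peptides.tsv} (the digest with
#' isoform-uniqueness status when several proteins are supplied),
#' \code{coverage.txt}, \code{ratio_table.tsv} (full precision),
#' \code{ratio_report.tsv} (rendered) and \code{config.yaml} (provenance).
#' Stage failures propagate with the stage name prefixed; re-running the
#' same configuration reproduces the reports byte for byte.
#'
#' @param cfg A [runConfig()].
#' @return Invisibly, a named list of output file paths.
#' @export
runPtmPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  proteins <- stage("read-fasta", readProteinFasta(cfg$fasta))
  protein <- proteins[[1L]]
  evidence <- stage("read-evidence", readEvidence(cfg$evidence))

  peptides <- stage("digest", digest(protein, cfg$enzyme, cfg$maxMissed))
  if (length(proteins) > 1L) {
    status <- stage("uniqueness",
                    uniquePeptides(peptides$sequence, proteins))
    peptides$status <- status$status[match(peptides$sequence,
                                           status$peptide)]
  }
  pepPath <- file.path(cfg$outDir, "peptides.tsv")
  writePeptideReport(peptides, pepPath)

  cov <- stage("coverage", coverage(
    protein, data.frame(start = evidence$Start, end = evidence$End)))
  covPath <- file.path(cfg$outDir, "coverage.txt")
  writeLines(c(
    sprintf("protein\t%s", proteinId(protein)),
    sprintf("mature_length\t%d", matureLength(protein)),
    sprintf("covered\t%d", length(cov@covered)),
    sprintf("percent\t%.1f", coveragePercent(cov)),
    sprintf("uncovered\t%s", paste(
      sprintf("%d-%d", uncoveredRuns(cov)$start, uncoveredRuns(cov)$end),
      collapse = ","))), covPath)

  ratios <- stage("quantify",
                  suppressWarnings(buildRatioTable(evidence, cfg$sites)))
  ratioPath <- file.path(cfg$outDir, "ratio_table.tsv")
  utils::write.table(ratios, ratioPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  reportPath <- file.path(cfg$outDir, "ratio_report.tsv")
  utils::write.table(formatRatioTable(ratios), reportPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cfgPath <- file.path(cfg$outDir, "config.yaml")
  yaml::write_yaml(list(
    fasta = cfg$fasta, evidence = cfg$evidence, enzyme = cfg$enzyme,
    maxMissed = cfg$maxMissed, seed = cfg$seed,
    sites = lapply(seq_len(nrow(cfg$sites)), function(i) {
      as.list(cfg$sites[i, ])
    })), cfgPath)

  invisible(list(peptides = pepPath, coverage = covPath,
                 ratios = ratioPath, report = reportPath,
                 config = cfgPath))
}
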