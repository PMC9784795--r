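# Shared fixtures, built in code.

# peptidoform rows printed in the site-quantification tables: sequence,
# coordinates, localized mods, charge and printed m/z (verified against the
# mass scale to +/- 0.001)
tableMzCases <- function() {
  list(
    list(seq = "GYGFGMVK", start = 21, mods = c("26" = "oxidation"),
         z = 2, mz = 437.7103),
    list(seq = "GYGFGMVK", start = 21, mods = NULL, z = 2, mz = 429.7128),
    list(seq = "SCSGVEFSTSGHAYTDTGK", start = 35,
         mods = c("36" = "trioxidation"), z = 2, mz = 991.4079),
    list(seq = "SCSGVEFSTSGHAYTDTGK", start = 35,
         mods = c("36" = "carbamidomethyl"), z = 2, mz = 995.9260),
    list(seq = "YKVCNYGLTFTQK", start = 62,
         mods = c("65" = "trioxidation"), z = 2, mz = 806.8877),
    list(seq = "YKVCNYGLTFTQK", start = 62,
         mods = c("65" = "carbamidomethyl"), z = 2, mz = 811.4060),
    list(seq = "YKVCNYGLTFTQK", start = 62,
         mods = c("65" = "succination"), z = 3, mz = 560.9367),
    list(seq = "DCFSLGSNVDIDFSGPTIYGWAVLAFEGWLAGYQMSFDTAK", start = 121,
         mods = c("122" = "carbamidomethyl", "155" = "oxidation"),
         z = 3, mz = 1518.0315),
    list(seq = "DCFSLGSNVDIDFSGPTIYGWAVLAFEGWLAGYQMSFDTAK", start = 121,
         mods = c("122" = "carbamidomethyl"), z = 3, mz = 1512.6995),
    list(seq = "GFGMVKIDL", start = 23, mods = c("26" = "oxidation"),
         z = 2, mz = 498.2657),
    list(seq = "GFGMVKIDL", start = 23, mods = NULL, z = 2, mz = 490.2682),
    list(seq = "QMSFDTAKSKL", start = 154, mods = c("155" = "oxidation"),
         z = 2, mz = 636.3192),
    list(seq = "QMSFDTAKSKL", start = 154, mods = NULL, z = 2, mz = 628.3217),
    list(seq = "KLDCRTSL", start = 226, mods = c("229" = "trioxidation"),
         z = 2, mz = 492.2455),
    list(seq = "KLDCRTSL", start = 226, mods = c("229" = "carbamidomethyl"),
         z = 2, mz = 496.7638),
    list(seq = "WNTDNTLGTEISWENK", start = 75,
         mods = c("76" = "deamidation"), z = 2, mz = 954.9344),
    list(seq = "WNTDNTLGTEISWENK", start = 75, mods = NULL, z = 2,
         mz = 954.4424),
    list(seq = "LTLDTIFVPNTGK", start = 97,
         mods = c("106" = "deamidation"), z = 2, mz = 710.3904),
    list(seq = "LTLDTIFVPNTGK", start = 97, mods = NULL, z = 2,
         mz = 709.8984),
    list(seq = "LSQNNFALGYK", start = 164,
         mods = c("167" = "deamidation"), z = 2, mz = 628.3197),
    list(seq = "LSQNNFALGYK", start = 164, mods = NULL, z = 2, mz = 627.8277),
    list(seq = "LSQNNFALGYK", start = 164,
         mods = c("167" = "succinimide"), z = 2, mz = 619.3144),
    list(seq = "IETSINLAWTAGSNNTR", start = 202,
         mods = c("215" = "deamidation"), z = 2, mz = 924.9582),
    list(seq = "IETSINLAWTAGSNNTR", start = 202, mods = NULL, z = 2,
         mz = 924.4662),
    list(seq = "VNNASLIGLGYTQTLRPGVK", start = 237,
         mods = c("238" = "deamidation"), z = 3, mz = 701.3920),
    list(seq = "VNNASLIGLGYTQTLRPGVK", start = 237, mods = NULL, z = 3,
         mz = 701.0640),
    list(seq = "VNNASLIGLGYTQTLRPGVK", start = 237,
         mods = c("238" = "succinimide"), z = 2, mz = 1042.5788),
    list(seq = "VNNASLIGLGYTQTLRPGVK", start = 237, mods = NULL, z = 2,
         mz = 1051.0924),
    list(seq = "CNTPTYCDLGK", start = 2,
         mods = c("2" = "trioxidation", "8" = "carbamidomethyl"),
         z = 2, mz = 660.2663)
  )
}

caseToPeptidoform <- function(cs) {
  Peptidoform(cs$seq, cs$start, cs$start + nchar(cs$seq) - 1L, cs$mods)
}

# minimal evidence frame builder
makeEvidence <- function(..., cellLine = "NSC34") {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(Sequence = r$seq, Start = r$start,
               End = r$start + nchar(r$seq) - 1L,
               Modifications = if (is.null(r$mods)) "" else r$mods,
               Charge = if (is.null(r$z)) 2L else r$z,
               CellLine = cellLine,
               Replicate = if (is.null(r$rep)) 1L else r$rep,
               RT_min = 30, Intensity = r$int, stringsAsFactors = FALSE)
  }))
}

# independent mass oracle: direct residue-by-residue summation, written
# separately from the package's vectorized path
oracleMass <- function(seq, deltas = 0) {
  masses <- c(G = 57.02146372376, A = 71.03711378471, S = 87.03202840427,
              P = 97.05276384885, V = 99.06841391407, T = 101.04767846841,
              C = 103.00918478471, L = 113.08406397713, I = 113.08406397713,
              N = 114.04292744114, D = 115.02694302383, Q = 128.05857750528,
              K = 128.09496301399, E = 129.04259308797, M = 131.04048508847,
              H = 137.05891185845, F = 147.06841391299, R = 156.10111102359,
              Y = 163.06332853255, W = 186.07931294986)
  total <- 18.010565
  for (ch in strsplit(seq, "")[[1]]) total <- total + masses[[ch]]
  total + sum(deltas)
}
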