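test_that("residue mass table and constants are on the standard scale", {
  m <- residueMasses()
  expect_length(m, 20)
  expect_true(all(m > 0))
  expect_equal(names(which.min(m)), "G")
  cst <- massConstants()
  expect_equal(cst[["water"]], 18.010565, tolerance = 1e-5)
  expect_equal(cst[["proton"]], 1.007276, tolerance = 1e-5)
  expect_equal(cst[["ammonia"]], 17.026549, tolerance = 1e-5)
  expect_equal(cst[["methanesulfenic"]], 63.998301, tolerance = 1e-5)
})

test_that("modification registry holds exactly the nine states", {
  reg <- modRegistry()
  expected <- c(none = 0.0, carbamidomethyl = 57.021464,
                oxidation = 15.994915, trioxidation = 47.984744,
                deamidation = 0.984016, succinimide = -17.026549,
                succination = 116.010959, `methyl-ester` = 14.015650,
                acetylation = 42.010565)
  expect_setequal(reg$name, names(expected))
  expect_equal(modDelta(names(expected)), unname(expected))
  expect_false(anyDuplicated(reg$name) > 0)
  # succinimide is deamidation followed by dehydration, exactly
  expect_equal(modDelta("deamidation") - massConstants()[["water"]],
               modDelta("succinimide"))
  # methyl ester on the deamidated residue is +14.999666 net from Asn
  expect_equal(modDelta("deamidation") + modDelta("methyl-ester"),
               14.999666)
})

test_that("neutral mass sums residues, water and modification deltas", {
  expect_equal(peptidoformMass(Peptidoform("G")), 75.03203,
               tolerance = 1e-5)
  p <- Peptidoform("GYGFGMVK", 21, 28, c("26" = "oxidation"))
  expect_equal(peptidoformMass(p), oracleMass("GYGFGMVK", 15.994915),
               tolerance = 1e-9)
  # succinimide subtracts exactly 17.026549 from the unmodified form
  ps <- Peptidoform("LSQNNFALGYK", 164, 174, c("167" = "succinimide"))
  p0 <- Peptidoform("LSQNNFALGYK", 164, 174)
  expect_equal(peptidoformMass(ps), peptidoformMass(p0) - 17.026549)
  expect_error(peptidoformMass(Peptidoform("GXK")), "residue")
})

test_that("mass additivity: adding a mod shifts mass by exactly its delta", {
  cases <- list(
    c(seq = "YKVCNYGLTFTQK", pos = 65, mod = "succination"),
    c(seq = "IETSINLAWTAGSNNTR", pos = 215, mod = "deamidation"),
    c(seq = "SCSGVEFSTSGHAYTDTGK", pos = 36, mod = "trioxidation"))
  starts <- c(62, 202, 35)
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    base <- Peptidoform(cs[["seq"]], starts[i])
    withMod <- Peptidoform(cs[["seq"]], starts[i],
      mods = stats::setNames(cs[["mod"]], cs[["pos"]]))
    expect_equal(peptidoformMass(withMod) - peptidoformMass(base),
                 modDelta(cs[["mod"]]), tolerance = 1e-12)
  }
})

test_that("m/z round trip is exact and rejects bad charges", {
  for (M in c(75.03203, 857.410545, 4551.07)) {
    for (z in 1:4) {
      expect_equal(neutralMass(mz(M, z), z), M, tolerance = 1e-9)
    }
  }
  expect_equal(mz(100, 1), 101.007276)
  expect_error(mz(100, 0), "charge")
  expect_error(mz(100, -2), "charge")
})

test_that("all printed table m/z values are reproduced within 0.001", {
  for (cs in tableMzCases()) {
    p <- caseToPeptidoform(cs)
    expect_lt(abs(peptidoformMz(p, cs$z) - cs$mz), 0.001,
              label = sprintf("|calc - printed| for %s (%d+)",
                              formatPeptidoform(p), cs$z))
  }
})

test_that("deamidation shifts any 2+ m/z by +0.492008", {
  for (cs in list(c("WNTDNTLGTEISWENK", 75, 76),
                  c("IETSINLAWTAGSNNTR", 202, 215),
                  c("LSQNNFALGYK", 164, 168))) {
    s <- cs[1]; st <- as.integer(cs[2]); pos <- as.integer(cs[3])
    base <- peptidoformMz(Peptidoform(s, st), 2)
    deam <- peptidoformMz(
      Peptidoform(s, st, mods = stats::setNames("deamidation", pos)), 2)
    expect_equal(deam - base, 0.492008, tolerance = 1e-6)
  }
})

test_that("peptidoform validity enforces targeting and one mod per site", {
  expect_error(Peptidoform("GYGFGMVK", 21, 28, c("26" = "trioxidation")),
               "target")
  expect_error(Peptidoform("GYGFGMVK", 21, 28,
    data.frame(position = c(26, 26), name = c("oxidation", "none"))),
    "one modification")
  expect_error(Peptidoform("GYGFGMVK", 21, 28, c("40" = "oxidation")),
               "outside")
  expect_error(Peptidoform("GYGFGMVK", 21, 29), "length")
  # protein-N-terminal acetylation allowed only at position 1 or 2
  expect_s4_class(Peptidoform("CNTPTYCDLGK", 2, 12, c("2" = "acetylation")),
                  "Peptidoform")
  expect_error(Peptidoform("LSQNNFALGYK", 164, 174,
                           c("164" = "acetylation")), "N-terminal")
})

test_that("peptidoform text dialect round-trips", {
  for (cs in tableMzCases()[c(1, 7, 29)]) {
    p <- caseToPeptidoform(cs)
    q <- parsePeptidoform(formatPeptidoform(p))
    expect_equal(formatPeptidoform(q), formatPeptidoform(p))
    expect_equal(peptidoformMass(q), peptidoformMass(p))
  }
  expect_error(parsePeptidoform("not a peptidoform"), "parse")
})

test_that("fragment ladder emits n-1 b and y ions per charge plus losses", {
  p <- Peptidoform("GYGFGMVK", 21, 28, c("26" = "oxidation"))
  n <- nchar("GYGFGMVK")
  bare <- fragmentLadder(p, maxCharge = 2, losses = FALSE)
  expect_equal(nrow(bare), 2 * (n - 1) * 2)
  expect_true(all(bare$index >= 1 & bare$index <= n - 1))
  lad <- fragmentLadder(p, maxCharge = 1, losses = TRUE)
  # every y ion spans MetO at relative position 6, so y3..y7 carry CH3SOH;
  # b ions from b6 onward do too
  metForB <- lad$series == "b" & lad$index >= 6
  metForY <- lad$series == "y" & lad$index >= 3
  carriers <- unique(lad[metForB | metForY, c("series", "index")])
  withLoss <- unique(lad[lad$loss == "CH3SOH", c("series", "index")])
  expect_equal(nrow(merge(carriers, withLoss)), nrow(carriers))
  # and no CH3SOH variant for fragments not spanning the MetO
  expect_false(any(lad$loss == "CH3SOH" & lad$series == "b" & lad$index < 6))
})

test_that("b/y complementarity holds against independent prefix sums", {
  p <- Peptidoform("GYGFGMVK", 21, 28, c("26" = "oxidation"))
  lad <- fragmentLadder(p, maxCharge = 1, losses = FALSE)
  n <- nchar(pepSequence(p))
  prec1 <- peptidoformMz(p, 1)
  for (i in seq_len(n - 1)) {
    b <- lad$mz[lad$series == "b" & lad$index == i]
    y <- lad$mz[lad$series == "y" & lad$index == n - i]
    expect_equal(b + y, prec1 + 1.007276, tolerance = 1e-6)
  }
  # b ions against residue-by-residue oracle sums
  letters <- strsplit("GYGFGMVK", "")[[1]]
  acc <- 0
  for (i in seq_len(n - 1)) {
    acc <- acc + oracleMass(letters[i]) - 18.010565 +
      if (i == 6) 15.994915 else 0
    expect_equal(lad$mz[lad$series == "b" & lad$index == i],
                 acc + 1.007276, tolerance = 1e-9)
  }
})

test_that("MetO companion offset equals methanesulfenic acid at 1/z", {
  p <- Peptidoform("GYGFGMVK", 21, 28, c("26" = "oxidation"))
  lad <- fragmentLadder(p, maxCharge = 2, losses = TRUE)
  y7 <- lad[lad$series == "y" & lad$index == 7, ]
  for (z in 1:2) {
    off <- y7$mz[y7$loss == "" & y7$charge == z] -
      y7$mz[y7$loss == "CH3SOH" & y7$charge == z]
    expect_equal(off, 63.998301 / z, tolerance = 1e-9)
  }
})
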