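test_that("noise-free planted ratios are recovered exactly", {
  ev <- do.call(rbind, lapply(1:3, function(r) makeEvidence(
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 100,
         rep = r),
    list(seq = "GYGFGMVK", start = 21, int = 10, rep = r))))
  sq <- siteRatio(ev, 26, "oxidation")
  expect_equal(ratioMean(sq), 10)
  expect_equal(ratioSd(sq), 0)
  expect_equal(unname(replicateRatios(sq)), c(10, 10, 10))
  expect_false(isFullyModified(sq))
})

test_that("ratios pool charge states and peptides covering the site", {
  # MetO at 26 observed on the tryptic and the chymotryptic peptide at 2+/3+
  ev <- makeEvidence(
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 6, z = 2),
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 4, z = 3),
    list(seq = "GFGMVKIDL", start = 23, mods = "26:oxidation", int = 10),
    list(seq = "GYGFGMVK", start = 21, int = 3, z = 2),
    list(seq = "GFGMVKIDL", start = 23, int = 1, z = 3),
    # a peptide not covering the site is ignored
    list(seq = "LSQNNFALGYK", start = 164, int = 999))
  sq <- siteRatio(ev, 26, "oxidation")
  expect_equal(ratioMean(sq), 20 / 4)
})

test_that("mean and sample SD summarize replicate ratios", {
  ev <- do.call(rbind, Map(function(r, num) makeEvidence(
    list(seq = "SCSGVEFSTSGHAYTDTGK", start = 35, mods = "36:trioxidation",
         int = num, rep = r),
    list(seq = "SCSGVEFSTSGHAYTDTGK", start = 35,
         mods = "36:carbamidomethyl", int = 100, rep = r)),
    1:3, c(7, 8, 9)))
  sq <- siteRatio(ev, 36, "trioxidation", ref = "carbamidomethyl")
  expect_equal(ratioMean(sq), 0.08)
  expect_equal(ratioSd(sq), stats::sd(c(0.07, 0.08, 0.09)))
})

test_that("all-modified evidence is flagged fully modified", {
  ev <- makeEvidence(
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 50),
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 70,
         rep = 2))
  sq <- siteRatio(ev, 26, "oxidation")
  expect_true(isFullyModified(sq))
  expect_true(is.na(ratioMean(sq)))
  expect_length(replicateRatios(sq), 0)
})

test_that("replicates with zero reference are excluded with a warning", {
  ev <- makeEvidence(
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 10),
    list(seq = "GYGFGMVK", start = 21, int = 5),
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 10,
         rep = 2))
  expect_warning(sq <- siteRatio(ev, 26, "oxidation"), "excluded")
  expect_equal(ratioMean(sq), 2)
  expect_named(replicateRatios(sq), "1")
})

test_that("ratios are scale invariant", {
  ev <- do.call(rbind, lapply(1:3, function(r) makeEvidence(
    list(seq = "YKVCNYGLTFTQK", start = 62, mods = "65:succination",
         int = 30 + r, rep = r),
    list(seq = "YKVCNYGLTFTQK", start = 62, mods = "65:carbamidomethyl",
         int = 100 - r, rep = r))))
  sq1 <- siteRatio(ev, 65, "succination", ref = "carbamidomethyl")
  ev2 <- ev
  ev2$Intensity <- ev2$Intensity * 1e4
  sq2 <- siteRatio(ev2, 65, "succination", ref = "carbamidomethyl")
  expect_equal(replicateRatios(sq1), replicateRatios(sq2))
  expect_equal(ratioMean(sq1), ratioMean(sq2))
})

test_that("siteRatio(mod, ref) and siteRatio(ref, mod) are reciprocal", {
  ev <- do.call(rbind, lapply(1:3, function(r) makeEvidence(
    list(seq = "IETSINLAWTAGSNNTR", start = 202, mods = "215:deamidation",
         int = 11 * r, rep = r),
    list(seq = "IETSINLAWTAGSNNTR", start = 202, int = 95 + r, rep = r))))
  fwd <- siteRatio(ev, 215, "deamidation", ref = "none")
  # reciprocal direction: reference becomes the modified state
  ev2 <- ev
  bwd <- siteRatio(ev2, 215, "none", ref = "deamidation")
  expect_equal(replicateRatios(fwd) * replicateRatios(bwd),
               stats::setNames(rep(1, 3), 1:3))
})

test_that("deamidation percentage follows pooled intensities", {
  ev <- makeEvidence(
    list(seq = "IETSINLAWTAGSNNTR", start = 202, mods = "215:deamidation",
         int = 1),
    list(seq = "IETSINLAWTAGSNNTR", start = 202, int = 9))
  expect_equal(deamidationPercent(ev, 215), 10)
  # zero deamidated intensity -> 0 percent
  ev0 <- makeEvidence(list(seq = "IETSINLAWTAGSNNTR", start = 202, int = 9))
  expect_equal(deamidationPercent(ev0, 215), 0)
  expect_error(deamidationPercent(ev, 76), "covers")
})

test_that("deamidation percent recovers a planted 1% under lognormal noise", {
  cfg <- evidenceSimConfig(vdac3Fixture(),
    data.frame(site = 215, mod = "deamidation", ref = "none", ratio = 1 / 99),
    replicates = 3, cv = 0.05, seed = 20260930)
  ev <- simulateEvidence(cfg)
  expect_equal(deamidationPercent(ev, 215), 1, tolerance = 0.2)
  expect_lt(abs(deamidationPercent(ev, 215) - 1), 0.2)
})

test_that("the mean-ratio estimator is unbiased as replicates grow", {
  cfg <- evidenceSimConfig(vdac3Fixture(),
    data.frame(site = 26, mod = "oxidation", ref = "none", ratio = 10.1),
    replicates = 100, cv = 0.05, seed = 7, cellLine = "NSC34")
  ev <- simulateEvidence(cfg)
  sq <- siteRatio(ev, 26, "oxidation")
  expect_equal(ratioMean(sq), 10.1, tolerance = 0.02)
})

test_that("buildRatioTable is deterministic, ordered and cell-line aware", {
  sites <- data.frame(site = c(65, 26), mod = c("succination", "oxidation"),
                      ref = c("carbamidomethyl", "none"),
                      stringsAsFactors = FALSE)
  evA <- do.call(rbind, lapply(1:3, function(r) makeEvidence(
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 101,
         rep = r),
    list(seq = "GYGFGMVK", start = 21, int = 10, rep = r),
    list(seq = "YKVCNYGLTFTQK", start = 62, mods = "65:succination",
         int = 30, rep = r),
    list(seq = "YKVCNYGLTFTQK", start = 62, mods = "65:carbamidomethyl",
         int = 100, rep = r), cellLine = "NSC34")))
  evB <- do.call(rbind, lapply(1:3, function(r) makeEvidence(
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 55,
         rep = r), cellLine = "NSC34-SOD1G93A")))
  tab <- buildRatioTable(rbind(evA, evB), sites)
  expect_equal(tab$site, c(26, 26, 65))
  expect_equal(tab$cellLine, c("NSC34", "NSC34-SOD1G93A", "NSC34"))
  expect_equal(tab$mean[1], 10.1)
  expect_equal(tab$flag[2], "fully_modified")
  expect_equal(tab$mean[3], 0.3)
  expect_identical(tab, buildRatioTable(rbind(evA, evB), sites))
  # empty input -> empty table
  expect_equal(nrow(buildRatioTable(evA[0, ], sites)), 0)
})

test_that("formatted table renders fully modified rows as a dash", {
  tab <- data.frame(site = c(26L, 36L), mod = c("oxidation", "trioxidation"),
                    ref = c("none", "carbamidomethyl"),
                    cellLine = c("G93A", "NSC34"), n = c(0L, 3L),
                    mean = c(NA, 0.0823), sd = c(NA, 0.011),
                    flag = c("fully_modified", "normal"))
  out <- formatRatioTable(tab)
  expect_equal(out$mean, c("-", "0.082"))
  expect_equal(out$note[1], "fully modified")
})

test_that("evidence TSV round trip preserves all columns", {
  ev <- makeEvidence(
    list(seq = "GYGFGMVK", start = 21, mods = "26:oxidation", int = 12.5),
    list(seq = "GYGFGMVK", start = 21, int = 3))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeEvidence(ev, tmp)
  back <- readEvidence(tmp)
  expect_equal(back, ev)
  # reader tolerates extra columns, rejects missing ones
  ev$Extra <- "x"
  writeEvidence(ev, tmp)
  expect_equal(readEvidence(tmp)$Extra, c("x", "x"))
  bad <- ev[, setdiff(names(ev), "Intensity")]
  writeEvidence(bad, tmp)
  expect_error(readEvidence(tmp), "Intensity")
})
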