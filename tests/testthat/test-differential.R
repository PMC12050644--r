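test_that("subject fold changes are day14 minus baseline PAI per subject", {
  hs <- handStudy(tgtEffect = c(lotion = log10(0.5), lotion_ff = log10(1.9)),
                  nSubjects = 3L)
  pe <- quantifyProteins(hs$peptides, hs$design)
  dl <- subjectLogFoldChanges(pe, "lotion")
  df <- subjectLogFoldChanges(pe, "lotion_ff")
  expect_equal(unname(dl["TGT", ]), rep(log10(0.5), 3), tolerance = 1e-12)
  expect_equal(unname(df["TGT", ]), rep(log10(1.9), 3), tolerance = 1e-12)
  expect_equal(unname(dl["STD", ]), rep(0, 3), tolerance = 1e-12)
  expect_error(subjectLogFoldChanges(pe, "placebo"), "arm")
})

test_that("a subject missing day14 loses only its own fold change", {
  hs <- handStudy(nSubjects = 3L)
  gone <- hs$design$sample_id[hs$design$subject_id == "S02" &
                                hs$design$arm == "lotion" &
                                hs$design$timepoint == "day14"]
  pep <- hs$peptides[!(hs$peptides$sample_id == gone &
                         hs$peptides$protein_id == "TGT"), ]
  pe <- quantifyProteins(pep, hs$design)
  dl <- subjectLogFoldChanges(pe, "lotion")
  expect_true(is.na(dl["TGT", "S02"]))
  expect_false(anyNA(dl["TGT", c("S01", "S03")]))
  expect_false(anyNA(dl["STD", ]))
})

test_that("arm fold change is the mean log fold change, reported with n", {
  delta <- rbind(A = c(log10(2), log10(8)), B = c(0, 0), C = c(NA, NA))
  colnames(delta) <- c("s1", "s2")
  expect_warning(fc <- armFoldChange(delta), "no subject")
  expect_equal(fc$lfc[fc$protein_id == "A"], 2 * log10(2))
  expect_equal(fc$fc[fc$protein_id == "A"], 4, tolerance = 1e-12)
  expect_equal(fc$fc[fc$protein_id == "B"], 1)
  expect_false("C" %in% fc$protein_id)
  expect_identical(fc$n, c(2L, 2L))
  # the printed-fold convention: lfc 0.2788 is a 1.9-fold change
  expect_equal(10^0.2788, 1.9, tolerance = 1e-3)
})

test_that("between-arm tests recover a film-only effect at the exact floor", {
  eff <- data.frame(protein_id = "P_SBSN", arm = "lotion_ff",
                    delta_pai = log10(2), stringsAsFactors = FALSE)
  cfg <- cleanConfig(noiseSd = 0.001, nSubjects = 8L, effects = eff,
                     baselineOutliers = data.frame())
  st <- generateStudy(cfg)
  pe <- quantifyProteins(st$peptides, st$design)
  btw <- testBetweenArmChanges(subjectLogFoldChanges(pe, "lotion"),
                               subjectLogFoldChanges(pe, "lotion_ff"))
  expect_equal(btw$table$p_value[btw$table$protein_id == "P_SBSN"], 2 / 256)
})

test_that("identical arms are untestable with p = 1", {
  hs <- handStudy(nSubjects = 4L)
  pe <- quantifyProteins(hs$peptides, hs$design)
  btw <- testBetweenArmChanges(subjectLogFoldChanges(pe, "lotion"),
                               subjectLogFoldChanges(pe, "lotion_ff"))
  expect_true(all(btw$table$p_value == 1))
  expect_true(all(btw$table$untestable))
})

test_that("quadrants follow the strict sign rule", {
  expect_identical(classifyQuadrant(0.3, 0.2), "up_up")
  expect_identical(classifyQuadrant(-0.2, -0.3), "down_down")
  expect_identical(classifyQuadrant(-0.1, 0.4), "up_ff_down_lotion")
  expect_identical(classifyQuadrant(0.1, -0.4), "up_lotion_down_ff")
  expect_identical(classifyQuadrant(0, 0.5), "boundary")
  expect_identical(classifyQuadrant(0.5, 0), "boundary")
  expect_true(is.na(classifyQuadrant(NA, 1)))
  # partition: every defined pair lands in exactly one class
  set.seed(2)
  x <- rnorm(500); y <- rnorm(500)
  x[1:5] <- 0
  q <- classifyQuadrant(x, y)
  expect_identical(sum(table(q)), 500L)
})

test_that("fold-change ratios divide film by lotion folds", {
  expect_equal(foldChangeRatio(1.9, 0.5), 3.8)
  expect_equal(foldChangeRatio(2, 1), 2)
  expect_equal(foldChangeRatio(1.5, 1.5), 1)
  expect_error(foldChangeRatio(1, 0), "fc_lotion")
})

test_that("scatter summary reproduces the textbook correlation", {
  rec <- data.frame(lfc_lotion = c(0.1, 0.2, -0.1, 0.4, 0),
                    lfc_ff = c(0.15, 0.1, -0.2, 0.5, 0.05))
  sc <- scatterSummary(rec, nBins = 10)
  l2 <- function(x) x / log10(2)
  manual <- sum((l2(rec$lfc_lotion) - mean(l2(rec$lfc_lotion))) *
                  (l2(rec$lfc_ff) - mean(l2(rec$lfc_ff)))) /
    sqrt(sum((l2(rec$lfc_lotion) - mean(l2(rec$lfc_lotion)))^2) *
           sum((l2(rec$lfc_ff) - mean(l2(rec$lfc_ff)))^2))
  expect_equal(sc$pearson_r, manual, tolerance = 1e-12)
  expect_identical(sum(sc$counts_lotion), 5L)
  expect_identical(sum(sc$counts_ff), 5L)
  # perfect concordance / anticoncordance
  expect_equal(scatterSummary(data.frame(lfc_lotion = 1:4 / 10,
                                         lfc_ff = 1:4 / 10))$pearson_r, 1)
  expect_equal(scatterSummary(data.frame(lfc_lotion = 1:4 / 10,
                                         lfc_ff = -(1:4) / 10))$pearson_r, -1)
  flat <- data.frame(lfc_lotion = c(0.1, 0.1), lfc_ff = c(0, 1))
  expect_true(scatterSummary(flat)$degenerate)
})

test_that("the differential table is internally consistent", {
  st <- generateStudy(generatorConfig(nProteins = 60, seed = 23))
  pe <- quantifyProteins(st$peptides, st$design)
  f <- applyConcordanceFilter(baselineDifferences(pe))
  rec <- differentialAnalysis(pe, proteins = f$retained)
  expect_setequal(rec$protein_id, f$retained)
  expect_true(all(rec$fc_lotion > 0 & rec$fc_ff > 0, na.rm = TRUE))
  expect_equal(rec$fc_ratio, rec$fc_ff / rec$fc_lotion, tolerance = 1e-12)
  expect_identical(rec$significant, !is.na(rec$q_value) & rec$q_value < 0.05)
  both <- !is.na(rec$lfc_lotion) & !is.na(rec$lfc_ff)
  expect_identical(sum(table(rec$quadrant[both])), sum(both))
  pi0 <- attr(rec, "pi0")
  expect_named(pi0, c("between_arm", "lotion", "ff"))
  expect_true(all(pi0 > 0 & pi0 <= 1))
})
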