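test_that("identical baseline arms give zero differences and unit folds", {
  hs <- handStudy()
  pe <- quantifyProteins(hs$peptides, hs$design)
  d <- baselineDifferences(pe)
  expect_equal(d$diff_pai, rep(0, nrow(d)), tolerance = 1e-12)
  expect_equal(d$fold, rep(1, nrow(d)), tolerance = 1e-12)
})

test_that("planted baseline offsets pass through as folds at zero noise", {
  out <- data.frame(protein_id = "P_HBB", delta_pai = log10(3.8),
                    stringsAsFactors = FALSE)
  cfg <- cleanConfig(baselineOutliers = out, effects = data.frame())
  st <- generateStudy(cfg)
  pe <- quantifyProteins(st$peptides, st$design)
  d <- baselineDifferences(pe)
  expect_equal(d$fold[d$protein_id == "P_HBB"], 3.8, tolerance = 1e-9)
  expect_equal(d$diff_pai[d$protein_id == "P_HBB"], log10(3.8), tolerance = 1e-9)
})

test_that("proteins unobserved at baseline in an arm are flagged insufficient", {
  hs <- handStudy(nSubjects = 3L)
  pep <- hs$peptides
  drop <- hs$design$sample_id[hs$design$arm == "lotion" &
                                hs$design$timepoint == "baseline"][1:2]
  pep <- pep[!(pep$protein_id == "TGT" & pep$sample_id %in% drop), ]
  pe <- quantifyProteins(pep, hs$design)
  d <- baselineDifferences(pe, minSubjects = 2L)
  expect_true(is.na(d$diff_pai[d$protein_id == "TGT"]))
  expect_true(d$insufficient[d$protein_id == "TGT"])
  f <- applyConcordanceFilter(d)
  expect_identical(f$insufficient, "TGT")
})

test_that("the count rule retains floor(retention * P) proteins", {
  mk <- function(absd) data.frame(
    protein_id = sprintf("P%03d", seq_along(absd)), diff_pai = absd,
    abs_diff = abs(absd), fold = 10^abs(absd), stringsAsFactors = FALSE)
  # paper-scale worked example: 172 -> 163 retained, 9 excluded
  set.seed(1)
  d172 <- mk(rnorm(172, 0, 0.05))
  f <- applyConcordanceFilter(d172)
  expect_length(f$retained, 163L)
  expect_identical(nrow(f$excluded), 9L)
  # all-equal differences: still a count-based split
  dEq <- mk(rep(0.1, 20))
  fEq <- applyConcordanceFilter(dEq)
  expect_length(fEq$retained, 19L)
  expect_identical(nrow(fEq$excluded), 1L)
  # deterministic tie-break: lexicographically last accession excluded
  expect_identical(fEq$excluded$protein_id, "P020")
  # one planted large difference among 20 -> exactly it is excluded
  d20 <- mk(c(rep(0.01, 19), 2))
  f20 <- applyConcordanceFilter(d20)
  expect_identical(f20$excluded$protein_id, "P020")
  expect_length(f20$retained, 19L)
})

test_that("filter invariants hold across random difference tables", {
  set.seed(42)
  for (i in 1:25) {
    P <- sample(5:200, 1)
    d <- data.frame(protein_id = sprintf("P%04d", seq_len(P)),
                    diff_pai = rnorm(P, 0, 0.2), stringsAsFactors = FALSE)
    d$abs_diff <- abs(d$diff_pai); d$fold <- 10^d$abs_diff
    ret <- runif(1, 0.5, 1)
    f <- applyConcordanceFilter(d, retention = ret)
    expect_identical(length(f$retained) + nrow(f$excluded), P)
    expect_identical(length(f$retained), as.integer(floor(ret * P)))
    if (nrow(f$excluded) && length(f$retained)) {
      maxRet <- max(d$abs_diff[d$protein_id %in% f$retained])
      expect_true(all(d$abs_diff[d$protein_id %in% f$excluded$protein_id] >=
                        maxRet - 1e-12))
    }
  }
  expect_error(applyConcordanceFilter(d, retention = 0), "retention")
  expect_error(applyConcordanceFilter(d, retention = 1.2), "retention")
})

test_that("planted outliers are exactly the excluded set on clean studies", {
  cfg <- generatorConfig(seed = 17, missingRate = 0)
  st <- generateStudy(cfg)
  pe <- quantifyProteins(st$peptides, st$design)
  f <- applyConcordanceFilter(baselineDifferences(pe))
  planted <- sort(st$truth$protein_id[st$truth$kind == "baseline_outlier"])
  expect_identical(sort(f$excluded$protein_id), planted)
})

test_that("retention 1 excludes nothing", {
  hs <- handStudy()
  pe <- quantifyProteins(hs$peptides, hs$design)
  f <- applyConcordanceFilter(baselineDifferences(pe), retention = 1)
  expect_identical(nrow(f$excluded), 0L)
  expect_length(f$retained, 2L)
})
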