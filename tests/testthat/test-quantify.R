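test_that("PPI is the per-sample sum of observed peptide intensities", {
  pep <- data.frame(
    peptide_id = c("a", "b", "c", "a", "c"),
    protein_id = c("P1", "P1", "P2", "P1", "P2"),
    sample_id = c("S1", "S1", "S1", "S2", "S2"),
    intensity = c(100, 50, 30, 70, 10), stringsAsFactors = FALSE)
  ppi <- computePPI(pep)
  expect_equal(ppi["P1", "S1"], 150)
  expect_equal(ppi["P2", "S1"], 30)
  expect_equal(ppi["P1", "S2"], 70)
  # single-term sum
  expect_equal(computePPI(pep[1, ])["P1", "S1"], 100)
  # all peptides of P1 unobserved in S3 -> missing, not zero
  pep3 <- rbind(pep, data.frame(peptide_id = "c", protein_id = "P2",
                                sample_id = "S3", intensity = 5))
  ppi3 <- computePPI(pep3)
  expect_true(is.na(ppi3["P1", "S3"]))
  expect_equal(ppi3["P2", "S3"], 5)
})

test_that("invalid peptide records are rejected with the record named", {
  pep <- data.frame(peptide_id = c("a", "b"), protein_id = "P1",
                    sample_id = "S1", intensity = c(10, -1))
  expect_error(computePPI(pep), "b")
  pep$intensity <- c(10, Inf)
  expect_error(computePPI(pep), "b")
  dup <- data.frame(peptide_id = "a", protein_id = "P1",
                    sample_id = "S1", intensity = c(1, 2))
  expect_error(computePPI(dup), "duplicate")
})

test_that("standard protein selection maximises total PPI over complete proteins", {
  m <- rbind(A = c(10, 10), B = c(100, NA), C = c(30, 40))
  colnames(m) <- c("S1", "S2")
  # B has the largest total but is not observed everywhere
  expect_identical(selectStandardProtein(m), "C")
  expect_identical(selectStandardProtein(m["A", , drop = FALSE]), "A")
  # exact tie -> lexicographically smallest accession
  tie <- rbind(Zb = c(5, 5), Aa = c(4, 6))
  colnames(tie) <- c("S1", "S2")
  expect_identical(selectStandardProtein(tie), "Aa")
  none <- rbind(A = c(1, NA), B = c(NA, 1)); colnames(none) <- c("S1", "S2")
  expect_error(selectStandardProtein(none), "standard")
})

test_that("generator studies select the boosted standard protein", {
  st <- generateStudy(generatorConfig(nProteins = 40, nSubjects = 3, seed = 21))
  pe <- quantifyProteins(st$peptides, st$design)
  expect_identical(standardProtein(pe), "P_K1C10")
})

test_that("weights are ratios to the reference-sample standard PPI", {
  m <- rbind(STD = c(200, 100), X = c(1, 2)); colnames(m) <- c("S1", "S2")
  w <- computeWeights(m, "STD")
  expect_equal(unname(w$wt), c(1, 0.5))
  expect_identical(w$referenceSample, "S1")
  expect_equal(w$wt[[w$referenceSample]], 1)
  eq <- rbind(STD = c(7, 7, 7)); colnames(eq) <- c("S1", "S2", "S3")
  expect_equal(unname(computeWeights(eq, "STD")$wt), c(1, 1, 1))
  bad <- rbind(STD = c(5, 0)); colnames(bad) <- c("S1", "S2")
  expect_error(computeWeights(bad, "STD"), "S2")
})

test_that("PAI is log10 of weight-normalised PPI with missingness propagated", {
  m <- rbind(P = c(1000, 50, NA)); colnames(m) <- c("S1", "S2", "S3")
  wt <- c(S1 = 1, S2 = 0.5, S3 = 1)
  pai <- computePAI(m, wt)
  expect_equal(pai["P", "S1"], 3)
  expect_equal(pai["P", "S2"], 2)
  expect_true(is.na(pai["P", "S3"]))
})

test_that("PAI of the standard protein at the reference equals log10 PPI there", {
  st <- generateStudy(generatorConfig(nProteins = 20, nSubjects = 3, seed = 4))
  pe <- quantifyProteins(st$peptides, st$design)
  ref <- referenceSample(pe)
  expect_equal(paiMatrix(pe)[standardProtein(pe), ref],
               log10(ppiMatrix(pe)[standardProtein(pe), ref]))
})

test_that("scaling one sample's peptides leaves PAI unchanged", {
  st <- generateStudy(generatorConfig(nProteins = 25, nSubjects = 3, seed = 31))
  pe0 <- quantifyProteins(st$peptides, st$design)
  ref <- referenceSample(pe0)
  # rescale the lowest-weight sample: a 3x boost cannot dethrone the reference
  victim <- names(which.min(sampleWeights(pe0)))
  scalePep <- function(c) {
    p <- st$peptides
    p$intensity[p$sample_id == victim] <- p$intensity[p$sample_id == victim] * c
    p
  }
  # default max-rule reference: invariance whenever the reference persists
  for (c in c(0.1, 3)) {
    peC <- quantifyProteins(scalePep(c), st$design)
    expect_identical(referenceSample(peC), ref)
    expect_lt(max(abs(paiMatrix(peC) - paiMatrix(pe0)), na.rm = TRUE), 1e-9)
  }
  # held reference: invariance for any c, including 1e6
  peA <- quantifyProteins(st$peptides, st$design, referenceSample = ref)
  for (c in c(0.1, 3, 1e6)) {
    peC <- quantifyProteins(scalePep(c), st$design, referenceSample = ref)
    expect_lt(max(abs(paiMatrix(peC) - paiMatrix(peA)), na.rm = TRUE), 1e-9)
  }
})

test_that("noise-free generator output yields identical PPI across replicate samples", {
  cfg <- cleanConfig(effects = data.frame(), baselineOutliers = data.frame())
  st <- generateStudy(cfg)
  pe <- quantifyProteins(st$peptides, st$design)
  ppi <- ppiMatrix(pe)
  # with no noise, scale or effects every sample sees the same signal
  expect_equal(max(apply(ppi, 1, function(r) diff(range(r)))), 0,
               tolerance = 1e-9)
})

test_that("quantifyProteins validates design and sample consistency", {
  st <- generateStudy(generatorConfig(nProteins = 10, nSubjects = 2, seed = 2))
  badDesign <- st$design
  badDesign$arm[1] <- "placebo"
  expect_error(quantifyProteins(st$peptides, badDesign), "arm")
  expect_error(quantifyProteins(st$peptides, st$design[-1, ]), "absent")
})
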