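test_that("grouped validation runs the machinery per specificity group", {
  set.seed(301)
  full <- fixturePsms(sprintf("FULLPEP%03dK", 1:40), 10^runif(40, -5, 0),
                      isDecoy = runif(40) < 0.3,
                      spectra = sprintf("f%03d", 1:40))
  semi <- fixturePsms(sprintf("SEMIPEP%03dK", 1:30), 10^runif(30, -5, 0),
                      isDecoy = runif(30) < 0.3,
                      spectra = sprintf("s%03d", 1:30),
                      specificity = "semi_n")
  val <- validateSemiEnzymatic(rbind(full, semi), windowSize = 9)
  expect_setequal(unique(val$peptides$validation_group), c("full", "semi"))

  # the full group's q-values equal a standalone run on the full subset
  alone <- computePeptideQvalues(
    collapseToPeptides(sanitizePsms(combinePep(full, windowSize = 9))))
  got <- val$peptides[val$peptides$validation_group == "full", ]
  got <- got[match(alone$peptide, got$peptide), ]
  expect_equal(got$q_value, alone$q_value)

  # semi PSMs never leak into the full group
  expect_false(any(grepl("SEMI",
                         val$peptides$peptide[val$peptides$validation_group ==
                                                "full"])))
})

test_that("cleavage-site verdicts follow the stated precedence", {
  # protein with tryptic sites at 10 (K) and 34 (K); predicted CS 25
  s <- paste0(paste(rep("A", 9), collapse = ""), "K",
              paste(rep("G", 23), collapse = ""), "K",
              paste(rep("L", 20), collapse = ""), "K",
              paste(rep("S", 5), collapse = ""))
  cs <- 25L
  correct <- classifyCleavageSites(s, cs, "Sec(SPI)", semiStarts = cs,
                                   fullStarts = c(11L, 35L))
  expect_equal(correct$verdict, "correct")

  refined <- classifyCleavageSites(s, cs, "Sec(SPI)", semiStarts = cs + 2L,
                                   fullStarts = c(11L, 35L))
  expect_equal(refined$verdict, "refined")
  expect_equal(refined$refined_cs, cs + 2L)

  # correct beats refined when both kinds of evidence exist
  both <- classifyCleavageSites(s, cs, "Sec(SPI)",
                                semiStarts = c(cs, cs + 2L),
                                fullStarts = c(11L, 35L))
  expect_equal(both$verdict, "correct")

  # a fully enzymatic peptide >= 3 residues upstream contradicts the CS
  wrong <- classifyCleavageSites(s, cs, "Sec(SPI)", semiStarts = integer(0),
                                 fullStarts = cs - 4L)
  expect_equal(wrong$verdict, "incorrect")
  # boundary: exactly CS - 3 still counts as upstream evidence
  expect_equal(classifyCleavageSites(s, cs, "Sec(SPI)", integer(0),
                                     cs - 3L)$verdict, "incorrect")
  expect_equal(classifyCleavageSites(s, cs, "Sec(SPI)", integer(0),
                                     cs - 2L)$verdict, "no_call")

  # lipid-anchored pathways cannot be probed by semi-tryptic peptides
  lip <- classifyCleavageSites(s, cs, "Tat(lipobox)", integer(0), integer(0))
  expect_equal(lip$verdict, "unclassifiable")

  # no tryptic C-terminus reachable within 5-50 residues of the CS
  sNo <- paste0(paste(rep("A", 9), collapse = ""), "K",
                paste(rep("G", 80), collapse = ""))
  expect_equal(classifyCleavageSites(sNo, 15L, "Sec(SPI)", integer(0),
                                     integer(0))$verdict, "unclassifiable")

  expect_error(classifyCleavageSites(s, 1000L, "Sec(SPI)", integer(0),
                                     integer(0)), "outside")
})

test_that("planted cleavage-site cases are recovered end to end", {
  st <- simulateStudy(120, nDatasets = 1, presentFraction = 0.75, seed = 17,
                      csCases = c(correct = 3, refined = 6, incorrect = 2,
                                  sparse = 2),
                      refinedDeltas = c(1L, -1L, 2L, -2L, 3L, -3L))
  db <- generateDecoys(st$db, "trypsin", seed = 17)
  ev <- plantSignalPeptideEvidence(db, st$truth, seed = 17)
  val <- validateSemiEnzymatic(ev$psms, windowSize = 9)
  cs <- st$truth@plantedCs
  calls <- callCleavageSites(db, data.frame(accession = cs$accession,
                                            pathway = cs$pathway,
                                            predicted_cs = cs$cs),
                             val)
  m <- merge(calls, cs, by = "accession")
  expected <- c(correct = "correct", refined = "refined",
                incorrect = "incorrect", sparse = "no_call")
  expect_equal(m$verdict, unname(expected[m$case]))
  ref <- m[m$case == "refined", ]
  expect_equal(ref$refined_cs, ref$cs + ref$delta)
  # the sparse case is excluded purely by the five-PSM rule
  expect_true(all(m$n_semi_psms[m$case == "sparse"] < 5))
})

test_that("excluded datasets and semi-heavy proteins drop out of CS calls", {
  st <- simulateStudy(100, nDatasets = 1, presentFraction = 0.8, seed = 19,
                      csCases = c(correct = 2, refined = 0, incorrect = 0,
                                  sparse = 0))
  db <- generateDecoys(st$db, "trypsin", seed = 19)
  ev <- plantSignalPeptideEvidence(db, st$truth, seed = 19,
                                   datasetId = "DS01")
  val <- validateSemiEnzymatic(ev$psms, windowSize = 9)
  cs <- st$truth@plantedCs
  pred <- data.frame(accession = cs$accession, pathway = cs$pathway,
                     predicted_cs = cs$cs)
  # excluding the only evidence dataset leaves no supporting evidence
  none <- callCleavageSites(db, pred, val, excludeDatasets = "DS01")
  expect_true(all(none$n_semi_psms == 0))
  expect_false(any(none$verdict %in% c("correct", "refined", "incorrect")))

  # TatLipo predictions override Tat(SPI) rows for the same protein
  pred2 <- rbind(pred,
                 data.frame(accession = cs$accession[1],
                            pathway = c("Tat(SPI)", "Tat(lipobox)"),
                            predicted_cs = cs$cs[1]))
  calls2 <- callCleavageSites(db, pred2, val)
  sub <- calls2[calls2$accession == cs$accession[1], ]
  expect_false("Tat(SPI)" %in% sub$pathway)
  expect_true("Tat(lipobox)" %in% sub$pathway)
})
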