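test_that("study generation allocates roles exactly and deterministically", {
  st <- simulateStudy(100, nDatasets = 3, presentFraction = 0.6,
                      duplicateFraction = 0.05, spuriousFraction = 0.1,
                      seed = 21)
  # exact allocation: 100 entries, 5 duplicate members, 10 spurious
  expect_equal(nrow(dbEntries(st$db)), 95L)
  expect_equal(sum(dbEntries(st$db)$is_spurious), 10L)
  expect_equal(countedSize(st$db), 85L)
  # exactly 60% of counted proteins present in every dataset draw
  pres <- st$truth@proteinPresence
  perDs <- tapply(pres$present, pres$dataset_id, sum)
  expect_true(all(perDs == round(0.6 * countedSize(st$db))))

  # non-integral allocations are refused
  expect_error(simulateStudy(100, presentFraction = 0.333, seed = 1),
               "not an integer")

  # same seed reproduces the study byte for byte
  st2 <- simulateStudy(100, nDatasets = 3, presentFraction = 0.6,
                       duplicateFraction = 0.05, spuriousFraction = 0.1,
                       seed = 21)
  f1 <- tempfile(); f2 <- tempfile()
  writeProteinDb(st$db, f1); writeProteinDb(st2$db, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(st$truth@proteinPresence, st2$truth@proteinPresence)
  unlink(c(f1, f2))

  expect_error(simulateStudy(40, seed = 1), "at least 51")
})

test_that("planted islands are recorded and absent from every dataset", {
  st <- simulateStudy(120, nDatasets = 2, presentFraction = 0.5, seed = 8,
                      plantIslands = data.frame(replicon_id = "rep1",
                                                start = 10L, length = 30L))
  expect_equal(st$truth@plantedIslands$length, 30L)
  e <- dbEntries(st$db, targetsOnly = TRUE)
  e <- e[order(e$gene_index), ]
  runAcc <- e$accession[e$gene_index %in% 10:39]
  pres <- st$truth@proteinPresence
  expect_false(any(pres$present[pres$accession %in% runAcc]))
})

test_that("PSM simulation labels matches and respects the decoy split", {
  st <- simulateStudy(120, nDatasets = 1, presentFraction = 0.75, seed = 2)
  db <- generateDecoys(st$db, "trypsin", seed = 2)
  sim <- simulatePsmTables(db, st$truth, nTrue = 400, nFalse = 200, seed = 2)
  psms <- sim$psms
  lab <- sim$truth@psmLabels
  expect_equal(nrow(lab), nrow(psms))
  expect_setequal(lab$spectrum_id, psms$spectrum_id)

  lbl <- lab$label[match(psms$spectrum_id, lab$spectrum_id)]
  expect_equal(sum(lbl == "true_match"), 400L)
  expect_equal(sum(lbl == "false_match"), 200L)
  # true matches never hit decoys; false matches split about evenly
  expect_false(any(psms$is_decoy[lbl == "true_match"]))
  nDecoy <- sum(psms$is_decoy[lbl == "false_match"])
  expect_gt(nDecoy, qbinom(0.001, 200, 0.5))
  expect_lt(nDecoy, qbinom(0.999, 200, 0.5))
  # true FDR of the unfiltered target list is computable from the labels
  tgt <- psms[!psms$is_decoy, ]
  fdr <- mean(lbl[!psms$is_decoy] == "false_match")
  expect_equal(fdr, sum(!psms$is_decoy & lbl == "false_match") / nrow(tgt))

  # true matches are drawn from present proteins only
  pres <- st$truth@proteinPresence
  presentAcc <- pres$accession[pres$present]
  expect_true(all(psms$accessions[lbl == "true_match"] %in% presentAcc))

  # requesting more true peptides than available fails
  expect_error(simulatePsmTables(db, st$truth, nTrue = 1e6, nFalse = 0,
                                 seed = 2), "exceeds")
})

test_that("engine overlap is biased toward true matches", {
  st <- simulateStudy(120, nDatasets = 1, presentFraction = 0.75, seed = 4)
  db <- generateDecoys(st$db, "trypsin", seed = 4)
  sim <- simulatePsmTables(db, st$truth, nTrue = 800, nFalse = 400,
                           overlapBias = 0.4, seed = 4)
  lbl <- sim$truth@psmLabels$label[match(sim$psms$spectrum_id,
                                         sim$truth@psmLabels$spectrum_id)]
  nEng <- lengths(strsplit(sim$psms$engine_ids, ";"))
  expect_gt(mean(nEng[lbl == "true_match"]), mean(nEng[lbl == "false_match"]))
})

test_that("false-match PEPs are exchangeable between targets and decoys", {
  st <- simulateStudy(150, nDatasets = 1, presentFraction = 0.8, seed = 6)
  db <- generateDecoys(st$db, "trypsin", seed = 6)
  sim <- simulatePsmTables(db, st$truth, nTrue = 100, nFalse = 4000, seed = 6)
  lbl <- sim$truth@psmLabels$label[match(sim$psms$spectrum_id,
                                         sim$truth@psmLabels$spectrum_id)]
  false <- sim$psms[lbl == "false_match", ]
  bestPep <- vapply(strsplit(false$engine_peps, ";"), function(kv)
    min(as.numeric(sub(".*=", "", kv))), numeric(1))
  ks <- suppressWarnings(stats::ks.test(bestPep[false$is_decoy],
                                        bestPep[!false$is_decoy]))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted cleavage-site evidence realizes each case", {
  st <- simulateStudy(100, nDatasets = 1, presentFraction = 0.8, seed = 13,
                      csCases = c(correct = 2, refined = 2, incorrect = 1,
                                  sparse = 1))
  db <- generateDecoys(st$db, "trypsin", seed = 13)
  ev <- plantSignalPeptideEvidence(db, st$truth, seed = 13)
  cs <- st$truth@plantedCs
  for (i in seq_len(nrow(cs))) {
    mine <- ev$psms[ev$psms$accessions == cs$accession[i], ]
    seqi <- dbEntries(db)$sequence[dbEntries(db)$accession == cs$accession[i]]
    starts <- vapply(mine$peptide, function(p)
      as.integer(regexpr(p, seqi, fixed = TRUE)), integer(1))
    semi <- mine$specificity == "semi_n"
    if (cs$case[i] == "correct") {
      expect_equal(sum(semi & starts == cs$cs[i]), 6L)
    } else if (cs$case[i] == "refined") {
      expect_equal(sum(semi & starts == cs$cs[i] + cs$delta[i]), 6L)
      expect_lte(abs(cs$delta[i]), 3L)
    } else if (cs$case[i] == "incorrect") {
      expect_equal(sum(semi), 0L)
      expect_true(any(!semi & starts == cs$cs[i] - 3L))
    } else if (cs$case[i] == "sparse") {
      expect_equal(sum(semi & starts == cs$cs[i]), 4L)
    }
    # every planted protein keeps at least as many full as semi peptides
    expect_gte(length(unique(mine$peptide[!semi])),
               length(unique(mine$peptide[semi])))
  }
})

test_that("truth records round-trip losslessly through JSON", {
  st <- simulateStudy(80, nDatasets = 2, presentFraction = 0.5, seed = 3,
                      csCases = c(correct = 1, refined = 1, incorrect = 0,
                                  sparse = 0))
  db <- generateDecoys(st$db, "trypsin", seed = 3)
  sim <- simulatePsmTables(db, st$truth, nTrue = 50, nFalse = 20, seed = 3)
  path <- tempfile(fileext = ".json")
  writeTruth(sim$truth, path)
  back <- readTruth(path)
  expect_equal(back@psmLabels, sim$truth@psmLabels)
  expect_equal(back@proteinPresence, sim$truth@proteinPresence)
  expect_equal(back@plantedCs$cs, sim$truth@plantedCs$cs)
  expect_equal(back@params$seed, sim$truth@params$seed)
  unlink(path)
})
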