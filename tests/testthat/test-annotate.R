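# Annotation workflow: abundance ranking, coverage, sarafotoxin parsing,
# toxin selection, stringency filters and the novel screen.

test_that("abundance ranking produces fractions and dense ranks", {
  ab <- rankAbundance(c(a = 50, b = 30, c = 20))
  expect_equal(ab$fraction, c(0.5, 0.3, 0.2))
  expect_equal(ab$rank, 1:3)
  tie <- rankAbundance(c(b = 10, a = 10, c = 5))
  expect_equal(tie$rank, c(1L, 1L, 2L))
  expect_identical(tie$id[1:2], c("a", "b"))  # id order on ties
  expect_error(rankAbundance(c(a = 0, b = 0)), "all-zero")
  set.seed(23)
  for (i in 1:100) {
    x <- stats::setNames(stats::rpois(20, 30), paste0("t", 1:20))
    x[1] <- x[1] + 1
    expect_equal(sum(rankAbundance(x)$fraction), 1, tolerance = 1e-9)
  }
})

test_that("cumulative coverage returns the minimal transcript count", {
  uni <- rankAbundance(stats::setNames(rep(10, 10), paste0("t", 1:10)))
  expect_equal(cumulativeCoverage(uni, 0.8)$nTranscripts, 8L)
  ab <- rankAbundance(c(a = 60, b = 30, c = 10))
  expect_equal(cumulativeCoverage(ab, 0.8)$nTranscripts, 2L)
  expect_error(cumulativeCoverage(ab, 1.2), "targetFraction")
  # inverse property: top k reaches the target, top k-1 does not
  set.seed(24)
  for (i in 1:50) {
    x <- stats::setNames(stats::rpois(30, 20) + 1, paste0("t", 1:30))
    ab <- rankAbundance(x)
    tgt <- stats::runif(1, 0.2, 0.95)
    k <- cumulativeCoverage(ab, tgt)$nTranscripts
    expect_gte(sum(ab$fraction[seq_len(k)]), tgt - 1e-12)
    if (k > 1) expect_lt(sum(ab$fraction[seq_len(k - 1)]), tgt)
  }
})

test_that("sarafotoxin precursors are parsed into mature cassettes", {
  ft <- templateFeatures(getTset())
  p1 <- parseSarafotoxinPrecursor(ft$protein[ft$id == "tpl_srtx_01"])
  expect_equal(nchar(p1$peptides), c(24, 24, 24))
  expect_true(all(substring(p1$peptides, 22) == "DEP"))
  p2 <- parseSarafotoxinPrecursor(ft$protein[ft$id == "tpl_srtx_02"])
  expect_equal(sort(nchar(p2$peptides)), c(21, 24))
  expect_true(all(nchar(p1$peptides) >= 21 & nchar(p1$peptides) <= 25))
  # a hand-built short cassette excises at exactly the 21-mer core
  core <- paste0("C", "NDQHW", "C", strrep("Q", 14))
  prec <- paste0("MFLNQ", "KR", core, "WNQ")
  p3 <- parseSarafotoxinPrecursor(prec)
  expect_identical(p3$peptides, core)
  expect_warning(parseSarafotoxinPrecursor("MAAAAAAA"), "no sarafotoxin")
})

test_that("keyword plus reciprocal best hit confirms planted toxins", {
  panel <- toxinPanel()
  prots <- familyProteins("3FTx")[1:3]
  sel <- selectToxinCandidates(prots, panel)
  expect_true(all(sel$keywordHit & sel$rbhConfirmed))
  expect_true(all(sel$family == "3FTx"))
  hk <- familyProteins("housekeeping")[1:3]
  selHk <- selectToxinCandidates(hk, panel)
  expect_true(all(is.na(selHk$topHit)))
  expect_false(any(selHk$keywordHit))
  expect_error(selectToxinCandidates(prots, panel,
                                     keywords = character()),
               "keyword")
})

test_that("a keyword hit without a reciprocal partner is not confirmed", {
  panel <- toxinPanel()
  base <- as.character(panel[["TP_crisp_01"]])
  near <- venomscan:::withSeed(5, venomscan:::mutateFree(base, 0.02))
  far <- venomscan:::withSeed(6, venomscan:::mutateFree(base, 0.15))
  sel <- selectToxinCandidates(
    Biostrings::AAStringSet(c(qNear = near, qFar = far)), panel)
  expect_true(sel$keywordHit[sel$id == "qFar"])  # keyword matches
  expect_false(sel$rbhConfirmed[sel$id == "qFar"])  # but qNear owns the RBH
  expect_true(sel$rbhConfirmed[sel$id == "qNear"])
})

test_that("stringency filters exclude with reasons unless relaxed", {
  rec <- S4Vectors::DataFrame(
    id = c("t1", "t2", "t3", "t4"),
    verdict = rep("known_toxin", 4),
    family = c("3FTx", "3FTx", "3FTx", "sarafotoxin"),
    exclusionReason = NA_character_, relaxed = FALSE)
  truncated <- c(t1 = FALSE, t2 = FALSE, t3 = FALSE, t4 = TRUE)
  ambiguous <- c(t1 = FALSE, t2 = TRUE, t3 = FALSE, t4 = FALSE)
  signalOk <- c(t1 = TRUE, t2 = TRUE, t3 = FALSE, t4 = TRUE)
  out <- suppressWarnings(
    applyStringencyFilters(rec, truncated, ambiguous, signalOk,
                           relaxFamilies = "sarafotoxin"))
  expect_identical(out$verdict,
                   c("known_toxin", "excluded", "excluded", "known_toxin"))
  expect_identical(out$exclusionReason[2], "ambiguous_positions")
  expect_identical(out$exclusionReason[3], "no_signal_peptide")
  expect_true(out$relaxed[4])
  expect_warning(
    applyStringencyFilters(rec, truncated, ambiguous, signalOk,
                           relaxFamilies = "sarafotoxin"),
    "truncated")
})

test_that("the workflow on templates reaches the expected verdicts", {
  ann <- getTemplateAnnotation()
  rec <- ann$records
  tr <- truthTable(getTset())
  expected <- stats::setNames(tr$expectedVerdict, tr$id)
  # every annotated transcript gets exactly one verdict
  expect_true(all(rec$verdict %in% c("known_toxin", "novel_candidate",
                                     "non_toxin", "excluded")))
  # planted toxins are confirmed with the right family
  tox <- rec[expected[rec$id] == "known_toxin", ]
  expect_true(all(tox$verdict == "known_toxin"))
  fam <- stats::setNames(tr$family, tr$id)
  expect_identical(unname(fam[tox$id]),
                   ifelse(tox$family == "sarafotoxin", "SRTX",
                          tox$family))
  # all novel secreted isoforms pass the orphan screen
  nov <- rec[expected[rec$id] == "novel_candidate", ]
  expect_true(all(nov$verdict == "novel_candidate"))
  # the abundant signal-negative orphan is rejected with evidence recorded
  orph <- rec[rec$id == "tpl_orph_01", ]
  expect_identical(orph$verdict, "non_toxin")
  expect_false(orph$signalPeptide)
  expect_lte(orph$abundanceRank, 2L)
  # no housekeeping transcript is called a known toxin
  bg <- rec[fam[rec$id] %in% c("housekeeping", "TE_like", "other"), ]
  expect_false(any(bg$verdict == "known_toxin"))
})

test_that("the novel screen requires abundance and applies its gates", {
  ann <- getTemplateAnnotation()
  expect_error(detectNovelCandidates(ann$records,
                                     signalOk = logical(),
                                     cysCount = integer(),
                                     abundance = NULL),
               "abundance")
  # a panel-matching secreted protein is never called novel
  rec <- ann$records
  expect_false(any(rec$verdict == "novel_candidate" &
                     !is.na(rec$topHit)))
  # rank gate: rerun the screen with topRank = 1 and expect fewer calls
  tight <- annotateTranscriptome(
    templates(getTset())[truthTable(getTset())$rank <= 60],
    stats::setNames(round(truthTable(getTset())$fraction * 1e5),
                    truthTable(getTset())$id)[
                      truthTable(getTset())$rank <= 60],
    toxinPanel(), novel = novelParams(topRank = 1))
  expect_lte(sum(tight$records$verdict == "novel_candidate"), 1)
})

test_that("annotation reports are written as TSV plus JSON run log", {
  ann <- getTemplateAnnotation()
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  writeAnnotationReport(ann, tsv, js)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(ann$records))
  log <- jsonlite::read_json(js)
  expect_equal(log$evalueMax, 1e-5)
})
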