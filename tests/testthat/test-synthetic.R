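# Synthetic transcriptome generator: truth structure, determinism, and
# read-sampling behaviour.

test_that("truth table is normalised and families are planted as designed", {
  tset <- getTset()
  tr <- truthTable(tset)
  ft <- templateFeatures(tset)
  expect_equal(sum(tr$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(tr$family == "3FTx"), 13)
  expect_true(all(ft$cysCountMature[tr$family == "3FTx"] == 10))
  expect_true(all(ft$matureLength[tr$family == "novel_secreted"] == 173))
  expect_true(all(ft$cysCountMature[tr$family == "novel_secreted"] == 2))
  # sarafotoxin precursors carry at least two tandem cassettes
  for (id in tr$id[tr$family == "SRTX"]) {
    p <- parseSarafotoxinPrecursor(ft$protein[ft$id == id])
    expect_gte(length(p$peptides), 2)
  }
  # the 57 top-weight templates carry a majority of the weight
  expect_gt(sum(sort(tr$fraction, decreasing = TRUE)[1:57]), 0.5)
})

test_that("generation is deterministic for a fixed seed", {
  t1 <- generateTranscriptome(seed = 42)
  t2 <- generateTranscriptome(seed = 42)
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  writeTemplates(t1, f1)
  writeTemplates(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
  t3 <- generateTranscriptome(seed = 43)
  expect_false(identical(as.character(templates(t1)),
                         as.character(templates(t3))))
})

test_that("invalid generator configurations are rejected", {
  expect_error(transcriptomeConfig(n3FTx = -1), "non-negative")
  expect_error(transcriptomeConfig(nHousekeeping = 10000), "repertoire")
  expect_error(librarySpec(errorRate = 0.2), "errorRate")
})

test_that("every planted secreted template passes the signal predictor", {
  tset <- getTset()
  ft <- templateFeatures(tset)
  sec <- !is.na(ft$signalLength)
  sig <- predictSignalPeptide(stats::setNames(ft$protein[sec],
                                              ft$id[sec]))
  expect_true(all(sig$accepted))
  expect_true(all(sig$cleavageSite == ft$signalLength[sec]))
})

test_that("error-free reads are exact substrings of their template", {
  tset <- getTset()
  lib <- simulateReads(tset, librarySpec(nReads = 300, errorRate = 0,
                                         seed = 3))
  prov <- provenance(lib)
  tpl <- as.character(templates(tset))
  for (i in seq_len(length(readSeqs(lib)))) {
    r <- as.character(readSeqs(lib)[[i]])
    if (prov$strand[i] == "-")
      r <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(r)))
    expect_identical(r, substring(tpl[[prov$template[i]]], prov$start[i],
                                  prov$start[i] + nchar(r) - 1))
  }
})

test_that("an empty library request warns and returns zero reads", {
  expect_warning(lib <- simulateReads(getTset(),
                                      librarySpec(nReads = 0)),
                 "empty")
  expect_length(readSeqs(lib), 0)
})

test_that("top-57 read share tracks the multinomial expectation", {
  tset <- getTset()
  lib <- simulateReads(tset, librarySpec(mode = "non_normalized",
                                         nReads = 10000, seed = 7))
  tr <- truthTable(tset)
  counts <- table(factor(provenance(lib)$template, levels = tr$id))
  top <- order(tr$fraction, decreasing = TRUE)[1:57]
  empirical <- sum(counts[top]) / sum(counts)
  expected <- sum(tr$fraction[top])
  expect_lt(abs(empirical - expected), 0.05)
})

test_that("normalization flattens the library (lower Gini)", {
  tset <- getTset()
  tr <- truthTable(tset)
  libN <- simulateReads(tset, librarySpec(mode = "normalized",
                                          nReads = 20000, seed = 9))
  libU <- simulateReads(tset, librarySpec(mode = "non_normalized",
                                          nReads = 20000, seed = 9))
  cN <- as.numeric(table(factor(provenance(libN)$template,
                                levels = tr$id)))
  cU <- as.numeric(table(factor(provenance(libU)$template,
                                levels = tr$id)))
  gN <- venomscan:::giniCoefficient(cN)
  gU <- venomscan:::giniCoefficient(cU)
  expect_lt(gN, gU)
  # and the internal Gini agrees with the mean-absolute-difference oracle
  expect_equal(gU, oracleGini(cU), tolerance = 1e-12)
})

test_that("non-normalized sampling converges to the truth fractions", {
  tset <- getTset()
  tr <- truthTable(tset)
  counts <- table(factor(provenance(getLib())$template, levels = tr$id))
  gof <- suppressWarnings(
    stats::chisq.test(as.numeric(counts), p = tr$fraction))
  expect_gt(gof$p.value, 0.01)
})

test_that("FASTQ output round-trips through a standard reader", {
  lib <- simulateReads(getTset(), librarySpec(nReads = 50, seed = 2))
  fq <- tempfile(fileext = ".fastq")
  writeReadLibrary(lib, fq)
  back <- Biostrings::readDNAStringSet(fq, format = "fastq")
  expect_identical(as.character(back), as.character(readSeqs(lib)))
})
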