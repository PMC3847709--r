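# Six-frame ORF discovery, signal-peptide heuristic and cysteine profile.

codonsFor <- function(aa) {
  # deterministic back-translation (first codon per residue)
  cod <- split(names(Biostrings::GENETIC_CODE), Biostrings::GENETIC_CODE)
  paste(vapply(strsplit(aa, "")[[1]], function(a) cod[[a]][1],
               character(1)), collapse = "")
}

test_that("the 60-aa minimum length boundary is enforced", {
  aa59 <- paste0("M", strrep("K", 58))
  seq59 <- paste0("CC", codonsFor(aa59), "TAA", "CC")
  expect_equal(nrow(findOrfs(seq59)), 0)
  aa60 <- paste0("M", strrep("K", 59))
  seq60 <- paste0("CC", codonsFor(aa60), "TAA", "CC")
  orfs <- findOrfs(seq60)
  expect_equal(nrow(orfs), 1)
  expect_identical(orfs$aa[1], aa60)
})

test_that("sequences without a start codon yield no ORFs", {
  expect_equal(nrow(findOrfs(strrep("CCT", 100), minLen = 5)), 0)
  expect_equal(nrow(findOrfs("AC")), 0)  # shorter than a codon
})

test_that("reverse-complementing the input preserves the protein set", {
  set.seed(11)
  for (i in 1:20) {
    s <- randomDNA(400)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(s)))
    a <- findOrfs(s, minLen = 20)
    b <- findOrfs(rc, minLen = 20)
    expect_setequal(a$aa, b$aa)
    # strand labels flip between the two orientations
    flip <- c(`+` = "-", `-` = "+")
    expect_setequal(paste(a$aa, substr(a$frame, 1, 1)),
                    paste(b$aa, flip[substr(b$frame, 1, 1)]))
  }
})

test_that("truncated ORFs are flagged and excluded by default", {
  aa <- paste0("M", strrep("L", 70))
  noStop <- paste0("CCTT", codonsFor(aa))  # runs off the 3' end
  expect_equal(nrow(findOrfs(noStop, minLen = 60)), 0)
  tr <- findOrfs(noStop, minLen = 60, includeTruncated = TRUE)
  expect_true(all(tr$truncated))
  ns <- tr[!is.na(tr$truncReason) & tr$truncReason == "no_stop", ]
  expect_equal(nrow(ns), 1)
  expect_identical(ns$aa[1], aa)
})

test_that("ORF finding matches the brute-force enumeration oracle", {
  set.seed(21)
  for (i in 1:25) {
    s <- randomDNA(500)
    got <- findOrfs(s, minLen = 20)
    want <- oracleOrfs(s, minLen = 20)
    expect_setequal(got$aa, vapply(want, `[[`, character(1), "aa"))
  }
})

test_that("generator signal peptides are accepted, decoys rejected", {
  ft <- templateFeatures(getTset())
  sec <- which(!is.na(ft$signalLength))[1]
  sig <- predictSignalPeptide(ft$protein[sec])
  expect_true(sig$accepted)
  expect_equal(sig$cleavageSite, 19L)
  expect_false(predictSignalPeptide(strrep("G", 100))$accepted)
  short <- predictSignalPeptide(strrep("L", 20))
  expect_false(short$evaluable)
  expect_false(short$accepted)
})

test_that("signal prediction is pure and has a low false-positive rate on shuffles", {
  ft <- templateFeatures(getTset())
  mat <- substring(ft$protein[ft$id == "tpl_novel_01"], 20)
  a <- predictSignalPeptide(mat)
  b <- predictSignalPeptide(mat)
  expect_identical(as.data.frame(a), as.data.frame(b))
  set.seed(77)
  ch <- strsplit(mat, "")[[1]]
  shuffles <- vapply(1:1000, function(i)
    paste(sample(ch), collapse = ""), character(1))
  fp <- mean(predictSignalPeptide(shuffles)$accepted)
  expect_lte(fp, 0.05)
})

test_that("cysteine profiling counts and locates cysteines exactly", {
  ft <- templateFeatures(getTset())
  tr <- truthTable(getTset())
  p <- ft$protein[tr$family == "3FTx"][1]
  prof <- cysteineProfile(p, matureStart = 20L)
  expect_equal(prof$count, 10)
  expect_equal(cysteineProfile(strrep("A", 50))$count, 0)
  set.seed(31)
  for (i in 1:200) {
    s <- randomProtein(sample(30:120, 1))
    ms <- sample(nchar(s), 1)
    prof <- cysteineProfile(s, ms)
    naive <- unlist(gregexpr("C", substring(s, ms), fixed = TRUE))
    naive <- naive[naive > 0]
    expect_equal(prof$positions, as.integer(naive))
    expect_equal(prof$count, length(naive))
  }
})
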