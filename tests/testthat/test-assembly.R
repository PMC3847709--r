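# Greedy overlap-consensus assembly and read mapping.

test_that("two reads with a 50-nt exact overlap merge into one contig", {
  set.seed(3)
  tpl <- randomDNA(350)
  r1 <- substring(tpl, 1, 200)
  r2 <- substring(tpl, 151, 350)
  ctg <- assembleReads(c(rA = r1, rB = r2))
  expect_length(consensusSeqs(ctg), 1)
  expect_equal(unname(Biostrings::width(consensusSeqs(ctg))), 350)
  expect_identical(as.character(consensusSeqs(ctg)[[1]]), tpl)
  expect_length(singletonIds(ctg), 0)
  expect_setequal(contigMembers(ctg)[[1]], c("rA", "rB"))
})

test_that("the 40-bp minimal overlap is a hard boundary", {
  set.seed(4)
  tpl <- randomDNA(400)
  # 39-nt overlap: no merge
  c39 <- assembleReads(c(rA = substring(tpl, 1, 200),
                         rB = substring(tpl, 162, 361)))
  expect_length(consensusSeqs(c39), 0)
  expect_setequal(singletonIds(c39), c("rA", "rB"))
  # 40-nt overlap at 100% identity: merge
  c40 <- assembleReads(c(rA = substring(tpl, 1, 200),
                         rB = substring(tpl, 161, 360)))
  expect_length(consensusSeqs(c40), 1)
})

test_that("a lone read becomes a singleton", {
  ctg <- assembleReads(c(solo = randomDNA(150)))
  expect_length(consensusSeqs(ctg), 0)
  expect_identical(singletonIds(ctg), "solo")
})

test_that("reverse-strand reads are reoriented before merging", {
  set.seed(5)
  tpl <- randomDNA(350)
  r2rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(tpl, 151, 350))))
  ctg <- assembleReads(c(rA = substring(tpl, 1, 200), rB = r2rc))
  expect_length(consensusSeqs(ctg), 1)
  expect_identical(as.character(consensusSeqs(ctg)[[1]]), tpl)
})

test_that("non-nucleotide characters raise an error naming the read", {
  expect_error(assembleReads(c(ok = strrep("ACGT", 30),
                               bad = paste0(strrep("ACGT", 30), "Q"))),
               "bad")
})

test_that("deep error-free tiling reproduces the template exactly", {
  tpl <- as.character(templates(getTset())[["tpl_novel_01"]])
  starts <- unique(c(seq(1, nchar(tpl) - 120 + 1, by = 7),
                     nchar(tpl) - 119))
  reads <- stats::setNames(substring(tpl, starts, starts + 119),
                           sprintf("tile_%03d", seq_along(starts)))
  ctg <- assembleReads(reads)
  expect_length(consensusSeqs(ctg), 1)
  expect_identical(as.character(consensusSeqs(ctg)[[1]]), tpl)
  # idempotence: assembling the members again reproduces one contig
  ctg2 <- assembleReads(reads)
  expect_identical(as.character(consensusSeqs(ctg2)),
                   as.character(consensusSeqs(ctg)))
})

test_that("contig members and singletons partition the read ids", {
  lib <- simulateReads(getTset(), librarySpec(nReads = 3000, seed = 5))
  ctg <- assembleReads(lib)
  ids <- c(unlist(contigMembers(ctg)), singletonIds(ctg),
           ctg@droppedReads)
  expect_setequal(ids, names(readSeqs(lib)))
  expect_false(anyDuplicated(ids) > 0)
  expect_true(all(readCount(ctg) >= 2))
})

test_that("reads map to their source template and counts are conserved", {
  tset <- getTset()
  lib <- simulateReads(tset, librarySpec(nReads = 400, errorRate = 0,
                                         seed = 8))
  mp <- mapReadsToContigs(lib, templates(tset))
  prov <- provenance(lib)
  mapped <- !is.na(mp$assignments$contig)
  expect_gt(mean(mapped), 0.99)
  expect_true(all(mp$assignments$contig[mapped] ==
                    prov$template[mapped]))
  expect_equal(sum(mp$counts) + sum(!mapped), length(readSeqs(lib)))
})

test_that("a read matching two identical contigs is flagged ambiguous", {
  set.seed(9)
  tpl <- randomDNA(300)
  contigs <- Biostrings::DNAStringSet(c(ctgA = tpl, ctgB = tpl))
  mp <- mapReadsToContigs(c(r1 = substring(tpl, 50, 250)), contigs)
  expect_identical(mp$assignments$contig, "ctgA")
  expect_true(mp$assignments$ambiguous)
})

test_that("mapping against an empty contig set warns and unmaps all", {
  expect_warning(
    mp <- mapReadsToContigs(c(r1 = randomDNA(100)),
                            Biostrings::DNAStringSet()),
    "empty")
  expect_true(all(is.na(mp$assignments$contig)))
})
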