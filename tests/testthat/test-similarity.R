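# Local alignment, E-values, best-hit logic and clustering.

test_that("self-alignment has identity 1 and E-values scale with db size", {
  s <- randomProtein(40)
  r <- alignPair(s, s)
  expect_equal(r$identity, 1)
  expect_equal(r$alnLength, 40L)
  r1 <- alignPair(s, s, dbSize = 1000)
  r2 <- alignPair(s, s, dbSize = 2000)
  expect_equal(r2$evalue / r1$evalue, 2)
  # E-value strictly decreasing in score for fixed lengths
  sc <- scoringScheme()
  ev <- venomscan:::karlinAltschulE(c(50, 60, 70), 100, 1000, sc)
  expect_true(all(diff(ev) < 0))
})

test_that("ambiguous X residues are scored zero", {
  expect_equal(alignPair("CWC", "CWC")$rawScore, 29)
  expect_equal(alignPair("CXC", "CWC")$rawScore, 18)
  expect_error(alignPair("", "AAA"), "amino-acid")
  expect_error(alignPair("AB-", "AAA"), "amino-acid")
})

test_that("scores match the exhaustive DP oracle on random pairs", {
  set.seed(12)
  for (i in 1:30) {
    a <- randomProtein(sample(8:30, 1))
    b <- randomProtein(sample(8:30, 1))
    expect_equal(alignPair(a, b)$rawScore, oracleSW(a, b))
  }
})

test_that("all-vs-all search equals a brute-force pairwise oracle", {
  set.seed(13)
  base <- randomProtein(60)
  seqs <- stats::setNames(c(
    vapply(1:5, function(i) {
      x <- strsplit(base, "")[[1]]
      pos <- sample(60, 6)
      for (p in pos) x[p] <- sample(setdiff(LETTERS[LETTERS %in%
        strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]], x[p]), 1)
      paste(x, collapse = "")
    }, character(1)),
    vapply(1:5, function(i) randomProtein(60), character(1))),
    sprintf("u%02d", 1:10))
  hits <- searchAllVsAll(seqs, seqs, evalueMax = 1e-3)
  dbSize <- sum(nchar(seqs))
  sc <- scoringScheme()
  # oracle: score every ordered pair with the R DP and filter
  want <- list()
  for (q in names(seqs)) for (s in names(seqs)) {
    if (q == s) next
    sco <- oracleSW(seqs[[q]], seqs[[s]])
    ev <- venomscan:::karlinAltschulE(sco, nchar(seqs[[q]]), dbSize, sc)
    if (ev <= 1e-3)
      want[[paste(q, s)]] <- c(score = sco, evalue = ev)
  }
  expect_setequal(paste(hits$query, hits$subject), names(want))
  for (k in seq_len(nrow(hits))) {
    w <- want[[paste(hits$query[k], hits$subject[k])]]
    expect_equal(hits$rawScore[k], unname(w["score"]))
    expect_equal(hits$evalue[k], unname(w["evalue"]))
  }
})

test_that("an empty panel warns and returns no hits", {
  expect_warning(h <- searchAllVsAll(c(a = "MKWW"),
                                     Biostrings::AAStringSet()),
                 "empty panel")
  expect_equal(nrow(h), 0)
})

test_that("a query identical to a panel member tops its hit list", {
  set.seed(14)
  panel <- stats::setNames(vapply(1:6, function(i) randomProtein(50),
                                  character(1)), sprintf("p%d", 1:6))
  hits <- searchAllVsAll(c(q = panel[["p3"]]), panel, evalueMax = 1e-3)
  expect_identical(hits$subject[1], "p3")
})

test_that("reciprocal best hits form a symmetric partial matching", {
  prots <- familyProteins("3FTx")
  panel <- toxinPanel()
  rbh <- reciprocalBestHits(prots, panel)
  # engineered bijection: every isoform pairs with its own panel ortholog
  expect_equal(nrow(rbh), 13)
  expect_identical(sub("tpl_", "TP_", rbh$idA), rbh$idB)
  expect_false(anyDuplicated(rbh$idA) > 0)
  expect_false(anyDuplicated(rbh$idB) > 0)
  # symmetry under swapping the two sets
  rbh2 <- reciprocalBestHits(panel, prots)
  expect_setequal(paste(rbh$idA, rbh$idB), paste(rbh2$idB, rbh2$idA))
})

test_that("unresolved top-hit ties are excluded from RBH", {
  set.seed(15)
  a <- randomProtein(60)
  setA <- c(qa = a)
  setB <- c(b1 = a, b2 = a)  # two identical best subjects
  expect_message(rbh <- reciprocalBestHits(setA, setB), "ties")
  expect_equal(nrow(rbh), 0)
})

test_that("greedy non-redundant clustering collapses duplicates only", {
  set.seed(16)
  s <- randomProtein(80)
  dup <- c(a = s, b = s, c = s)
  cl <- clusterNonredundant(dup)
  expect_length(cl$representatives, 1)
  expect_setequal(cl$members[[1]], c("a", "b", "c"))
  # two dissimilar families stay apart at 0.9 identity
  fam2 <- c(x1 = s, x2 = randomProtein(80))
  cl2 <- clusterNonredundant(fam2, 0.9)
  expect_length(cl2$representatives, 2)
  # idempotence: re-clustering representatives is a fixed point
  cl3 <- clusterNonredundant(cl2$representatives, 0.9)
  expect_identical(names(cl3$representatives),
                   names(cl2$representatives))
  expect_error(clusterNonredundant(dup, 1.5), "identityThreshold")
})
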