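# Similarity networks: edge filtering, components, group classification,
# export.

toyHits <- function(df) {
  n <- nrow(df)
  S4Vectors::DataFrame(query = df$q, subject = df$s,
                       rawScore = rep(100, n), identity = rep(0.9, n),
                       alnLength = rep(50L, n), evalue = df$e)
}

test_that("edges respect the E-value ceiling and drop self-pairs", {
  hits <- toyHits(data.frame(q = c("a", "b", "c"), s = c("b", "c", "c"),
                             e = c(1e-30, 1e-15, 1e-40)))
  g <- buildSimilarityGraph(hits, 1e-20, nodes = c("a", "b", "c"))
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1)
  expect_setequal(as.vector(el), c("a", "b"))
  expect_error(buildSimilarityGraph(hits, -1), "positive")
  # threshold below every hit: edgeless, all singletons
  g0 <- buildSimilarityGraph(hits, 1e-50, nodes = c("a", "b", "c"))
  p0 <- connectedComponentsPartition(g0)
  expect_length(p0$components, 0)
  expect_setequal(p0$singletons, c("a", "b", "c"))
})

test_that("directional hits collapse to the minimum E-value", {
  hits <- toyHits(data.frame(q = c("a", "b"), s = c("b", "a"),
                             e = c(1e-25, 1e-5)))
  g <- buildSimilarityGraph(hits, 1e-20)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$evalue, 1e-25)
})

test_that("components partition the nodes deterministically", {
  hits <- toyHits(data.frame(q = c("a", "b"), s = c("b", "c"),
                             e = c(1e-30, 1e-30)))
  g <- buildSimilarityGraph(hits, 1e-20, nodes = c("a", "b", "c", "d"))
  p <- connectedComponentsPartition(g)
  expect_equal(p$components, list(c("a", "b", "c")))
  expect_identical(p$singletons, "d")
})

test_that("components agree with a union-find oracle on random graphs", {
  set.seed(18)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    ne <- sample(0:(2 * n), 1)
    edges <- cbind(sample(nodes, ne, TRUE), sample(nodes, ne, TRUE))
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
    hits <- toyHits(data.frame(q = edges[, 1], s = edges[, 2],
                               e = rep(1e-30, nrow(edges))))
    g <- buildSimilarityGraph(hits, 1e-20, nodes = nodes)
    p <- connectedComponentsPartition(g)
    got <- c(p$components, as.list(p$singletons))
    want <- oracleComponents(nodes, edges)
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("tightening the threshold refines the partition", {
  set.seed(19)
  nodes <- sprintf("n%02d", 1:30)
  ne <- 40
  hits <- toyHits(data.frame(q = sample(nodes, ne, TRUE),
                             s = sample(nodes, ne, TRUE),
                             e = 10^-runif(ne, 5, 40)))
  hits <- hits[hits$query != hits$subject, ]
  gLoose <- buildSimilarityGraph(hits, 1e-10, nodes = nodes)
  gTight <- buildSimilarityGraph(hits, 1e-20, nodes = nodes)
  pl <- connectedComponentsPartition(gLoose)
  pt <- connectedComponentsPartition(gTight)
  looseOf <- character()
  for (k in seq_along(pl$components))
    looseOf[pl$components[[k]]] <- paste0("C", k)
  looseOf[pl$singletons] <- pl$singletons
  for (comp in pt$components)
    expect_length(unique(looseOf[comp]), 1)
})

test_that("planted 3FTx isoforms split into 4 groups plus a singleton", {
  prots <- familyProteins("3FTx")
  hits <- searchAllVsAll(prots, prots, evalueMax = 1)
  g <- buildSimilarityGraph(hits, 1e-20, nodes = names(prots),
                            origin = stats::setNames(
                              rep("query", length(prots)), names(prots)))
  p <- connectedComponentsPartition(g)
  expect_equal(lengths(p$components), c(4, 4, 2, 2))
  expect_length(p$singletons, 1)
  groups <- classifyQueryGroups(
    p, stats::setNames(rep("query", length(prots)), names(prots)))
  expect_equal(sort(unique(groups$group[!groups$singleton])),
               c("G1", "G2", "G3", "G4"))
  expect_true(groups$singleton[groups$id == p$singletons])
  # engineered cluster labels agree with the recovered groups
  cl <- templateFeatures(getTset())
  cl <- stats::setNames(cl$cluster, cl$id)[groups$id]
  tab <- table(cl[!groups$singleton], groups$group[!groups$singleton])
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("components containing panel members inherit the family name", {
  origin <- c(q1 = "query", q2 = "query", p1 = "panel")
  part <- list(components = list(c("p1", "q1", "q2")),
               singletons = character())
  cls <- classifyQueryGroups(part, origin,
                             panelFamilies = c(p1 = "lipocalin"))
  expect_true(all(cls$family == "lipocalin"))
  expect_true(all(cls$group == "G1"))
})

test_that("graph export round-trips and SIF lines count edges", {
  hits <- toyHits(data.frame(q = c("a", "b"), s = c("b", "c"),
                             e = c(1e-30, 1e-25)))
  g <- buildSimilarityGraph(hits, 1e-20, nodes = c("a", "b", "c", "d"),
                            origin = c(a = "query", b = "query",
                                       c = "panel", d = "query"))
  p <- connectedComponentsPartition(g)
  base <- file.path(tempdir(), "net_test")
  paths <- exportGraph(g, p, base)
  g2 <- igraph::read_graph(paste0(base, ".graphml"), format = "graphml")
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  el2 <- apply(igraph::as_edgelist(g2), 1,
               function(x) paste(sort(x), collapse = "-"))
  el1 <- apply(igraph::as_edgelist(g), 1,
               function(x) paste(sort(x), collapse = "-"))
  expect_setequal(el1, el2)
  sif <- readLines(paste0(base, ".sif"))
  expect_equal(sum(grepl(" sim ", sif)), igraph::ecount(g))
  expect_equal(length(sif), igraph::ecount(g) + 1)  # + isolated node d
  # edgeless graph still exports valid files
  g0 <- buildSimilarityGraph(toyHits(data.frame(q = character(),
                                                s = character(),
                                                e = numeric())),
                             1e-10, nodes = c("x", "y"))
  p0 <- connectedComponentsPartition(g0)
  paths0 <- exportGraph(g0, p0, file.path(tempdir(), "net_empty"))
  expect_true(all(file.exists(paths0)))
})
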