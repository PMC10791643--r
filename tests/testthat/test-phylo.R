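test_that("global alignment matches the quadratic DP oracle", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  pa <- pairwiseAlignGlobal("MK", "MK")
  expect_equal(pa$score, b62["M", "M"] + b62["K", "K"])
  expect_identical(pa$aligned_a, "MK")
  pa2 <- pairwiseAlignGlobal("MK", "M")
  expect_identical(nchar(pa2$aligned_b), 2L)
  expect_match(pa2$aligned_b, "-")
  set.seed(17)
  for (k in 1:50) {
    a <- random_protein(sample(5:100, 1))
    b <- random_protein(sample(5:100, 1))
    mine <- pairwiseAlignGlobal(a, b)
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
      type = "global", scoreOnly = TRUE)
    expect_equal(mine$score, oracle)
    expect_identical(gsub("-", "", mine$aligned_a), a)
    expect_identical(gsub("-", "", mine$aligned_b), b)
  }
})

test_that("progressive alignment handles identity and single insertions", {
  pa <- progressiveAlign(c(a = "MKLV", b = "MKLV", c = "MKLV"))
  expect_true(all(pa$rows == "MKLV"))
  pa2 <- progressiveAlign(c(a = "MKTTLV", b = "MKTLV", c = "MKTLV"))
  expect_identical(unname(nchar(pa2$rows)), rep(6L, 3))
  expect_identical(sum(grepl("-", pa2$rows)), 2L)
  # ungapping recovers every input
  set.seed(3)
  seqs <- setNames(vapply(1:5, function(i) random_protein(60), ""),
                   paste0("s", 1:5))
  pa3 <- progressiveAlign(seqs)
  expect_identical(gsub("-", "", pa3$rows), seqs)
})

test_that("progressive alignment beats a center-star baseline on sum of pairs", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  sp_score <- function(rows) {
    n <- length(rows)
    tot <- 0
    ch <- lapply(rows, function(r) strsplit(r, "")[[1]])
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      a <- ch[[i]]; b <- ch[[j]]
      for (k in seq_along(a)) {
        tot <- tot + if (a[k] == "-" && b[k] == "-") 0
        else if (a[k] == "-" || b[k] == "-") -4
        else b62[a[k], b[k]]
      }
    }
    tot
  }
  center_star <- function(seqs) {
    # align everything to the first sequence, pad greedily
    rows <- progressiveAlign(seqs[c(1, 2)])$rows
    for (k in 3:length(seqs)) {
      merged <- progressiveAlign(c(seqs[1], seqs[k]))$rows
      rows <- c(rows, merged[2])
    }
    w <- max(nchar(rows))
    vapply(rows, function(r) paste0(r, strrep("-", w - nchar(r))), "")
  }
  set.seed(23)
  wins <- 0
  for (k in 1:20) {
    base <- paste0("M", random_protein(49))
    triple <- setNames(c(mutate_protein(base, 0.2),
                         mutate_protein(base, 0.25),
                         mutate_protein(base, 0.3)), c("x", "y", "z"))
    mine <- sp_score(progressiveAlign(triple)$rows)
    star <- sp_score(center_star(triple))
    if (mine >= star) wins <- wins + 1
  }
  expect_gte(wins, 20)
})

test_that("alignment distances follow the closed forms", {
  rows <- c(a = "AAAA", b = "AAAT")
  D <- alignmentDistance(rows, "p")
  expect_equal(D["a", "b"], 0.25)
  Dp <- alignmentDistance(rows, "poisson")
  expect_equal(Dp["a", "b"], -log(0.75))
  expect_equal(alignmentDistance(c(a = "MKL", b = "MKL"))["a", "b"], 0)
  # symmetry and zero diagonal on random gapped alignments
  set.seed(2)
  seqs <- setNames(vapply(1:5, function(i) random_protein(80), ""),
                   paste0("t", 1:5))
  D2 <- alignmentDistance(progressiveAlign(seqs))
  expect_equal(D2, t(D2))
  expect_equal(unname(diag(D2)), rep(0, 5))
  # monotone correction
  ps <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(-log(1 - ps)) > 0))
  expect_error(alignmentDistance(c(a = "AAAA", b = "TTTT"), "poisson"),
               class = "edc_parameter_error")
})

test_that("neighbor joining is exact on additive matrices", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  D <- ape::cophenetic.phylo(tr)
  phy <- neighborJoining(D)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), phy)), 0)
  expect_equal(ape::cophenetic.phylo(phy)[rownames(D), colnames(D)], D)
  # 3-taxon closed form
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p3 <- neighborJoining(D3)
  cp <- ape::cophenetic.phylo(p3)[rownames(D3), colnames(D3)]
  expect_equal(cp, D3)
  # random additive matrices: topology and path lengths recovered
  set.seed(31)
  for (k in 1:20) {
    ra <- random_additive(sample(5:8, 1))
    phy <- neighborJoining(ra$D)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ra$tree), phy)), 0)
    expect_equal(ape::cophenetic.phylo(phy)[rownames(ra$D), colnames(ra$D)],
                 ra$D, tolerance = 1e-8)
  }
  expect_error(neighborJoining(matrix(0, 2, 2)),
               class = "edc_parameter_error")
})

test_that("bootstrap supports are reproducible and sane", {
  set.seed(41)
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.4,(C:0.2,D:0.2):0.4,(E:0.5,F:0.5):0.1);")
  anc <- sampleLowComplexityProtein(generatorProfile("S100"), 150, seed = 2)
  lp <- evolveDomain(anc, tr, 1.0, seed = 6)
  aln <- progressiveAlign(lp)
  b1 <- bootstrapSupport(aln, n_replicates = 40, seed = 5)
  b2 <- bootstrapSupport(aln, n_replicates = 40, seed = 5)
  expect_identical(b1$node.label, b2$node.label)
  sup <- attr(b1, "supports")
  expect_true(all(sup >= 0 & sup <= 1))
  # invariance to the order of alignment rows
  b3 <- bootstrapSupport(aln$rows[c(3, 1, 6, 2, 5, 4)],
                         n_replicates = 40, seed = 5)
  expect_equal(sort(attr(b3, "supports")), sort(sup))
  # columns with no variance across a clean split support it fully
  rows <- c(A = strrep("AR", 30), B = strrep("AR", 30),
            C = strrep("LV", 30), D = strrep("LV", 30))
  bs <- bootstrapSupport(rows, n_replicates = 30, seed = 1)
  expect_equal(unname(attr(bs, "supports")), 1)
})

test_that("outgroup rooting and supported groups behave as specified", {
  tr <- neighborJoining(random_additive(5)$D)
  og <- tr$tip.label[1]
  rooted <- rootWithOutgroup(tr, og)
  expect_true(ape::is.rooted(rooted))
  # root bipartition: outgroup alone on one side
  root_children <- rooted$edge[rooted$edge[, 1] ==
                                 length(rooted$tip.label) + 1, 2]
  expect_true(any(root_children == which(rooted$tip.label == og)))
  # unrooting recovers the original topology
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(rooted), tr)), 0)
  expect_error(rootWithOutgroup(tr, "nope"), class = "edc_parameter_error")
  # supports of 1 everywhere: every clade is a group; 0: only singletons
  rooted$node.label <- rep("1", rooted$Nnode)
  g1 <- phyloGroups(rooted, 0.9)
  expect_gt(length(g1), length(rooted$tip.label))
  rooted$node.label <- rep("0", rooted$Nnode)
  g0 <- phyloGroups(rooted, 0.9)
  expect_identical(length(g0), length(rooted$tip.label))
})
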