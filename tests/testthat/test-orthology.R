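test_that("reciprocal best hits match exhaustive enumeration and handle ties", {
  # identical sets pair up with themselves
  set.seed(51)
  prots <- setNames(vapply(1:5, function(i) random_protein(60), ""),
                    paste0("p", 1:5))
  rbh <- reciprocalBestHits(prots, prots)
  expect_identical(rbh$a, rbh$b)
  expect_identical(nrow(rbh), 5L)
  # random score matrices, including engineered ties
  for (k in 1:25) {
    S <- matrix(sample(1:50, 25, TRUE), 5, 5,
                dimnames = list(paste0("a", 1:5), paste0("b", 1:5)))
    if (k %% 3 == 0) S[1, 1:2] <- max(S) + 1    # tie for a1's best
    mine <- reciprocalBestHits(scores = S)
    oracle <- rbh_oracle(S)
    expect_identical(paste(mine$a, mine$b),
                     paste(oracle$a, oracle$b))
    if (k %% 3 == 0) {
      expect_false("a1" %in% mine$a)
      expect_true("a1" %in% attr(mine, "ambiguous"))
    }
  }
  # symmetry: swapping loci transposes the pair list
  S <- matrix(sample(1:100, 30), 5, 6,
              dimnames = list(paste0("a", 1:5), paste0("b", 1:6)))
  f <- reciprocalBestHits(scores = S)
  r <- reciprocalBestHits(scores = t(S))
  expect_identical(sort(paste(f$a, f$b)), sort(paste(r$b, r$a)))
})

test_that("local synteny counts shared neighbors orientation-aware", {
  ord <- data.frame(symbol = c("u1", "u2", "u3", "g", "d1", "d2", "d3"),
                    strand = "+", stringsAsFactors = FALSE)
  expect_identical(localSyntenyScore("g", "g", ord, ord, window = 3), 6L)
  # a gene moved somewhere with no shared neighbors scores zero
  alien <- data.frame(symbol = c("x1", "x2", "g", "x3", "x4"),
                      strand = "+", stringsAsFactors = FALSE)
  expect_identical(localSyntenyScore("g", "g", ord, alien, window = 3), 0L)
  # inverted gene: neighborhoods compared after side swap
  inv <- data.frame(symbol = c("d3", "d2", "d1", "g", "u3", "u2", "u1"),
                    strand = c(rep("-", 7)), stringsAsFactors = FALSE)
  expect_identical(localSyntenyScore("g", "g", ord, inv, window = 3), 6L)
})

test_that("ortholog calls demand two concordant evidence streams", {
  oa <- data.frame(symbol = c("n1", "a", "n2"), strand = "+")
  ob <- data.frame(symbol = c("n1", "b", "n2"), strand = "+")
  rbh <- data.frame(a = "a", b = "b", stringsAsFactors = FALSE)
  # RBH + synteny
  calls <- callOrthologs(rbh, oa, ob, genes_a = "a", genes_b = "b")
  expect_identical(calls$relation, "one_to_one")
  expect_match(calls$evidence, "reciprocal_best")
  expect_match(calls$evidence, "synteny")
  # RBH alone (no shared neighbors, no groups) is not sufficient
  ob2 <- data.frame(symbol = c("x1", "b", "x2"), strand = "+")
  calls2 <- callOrthologs(rbh, oa, ob2, genes_a = "a", genes_b = "b")
  expect_identical(calls2$relation, "none")
  # RBH + exclusive supported pair clade rescues the call
  grp <- list(c("a:a", "b:b"))
  calls3 <- callOrthologs(rbh, oa, ob2, phylo_groups = grp,
                          genes_a = "a", genes_b = "b")
  expect_identical(calls3$relation, "one_to_one")
  expect_match(calls3$evidence, "phylo_group")
})

test_that("a multi-member supported clade forces a co-ortholog group call", {
  oa <- data.frame(symbol = c("n1", "fam", "n2"), strand = "+")
  ob <- data.frame(symbol = c("n1", "fam1", "fam2", "fam3", "n2"),
                   strand = "+")
  rbh <- data.frame(a = "fam", b = "fam1", stringsAsFactors = FALSE)
  grp <- list(c("a:fam", "b:fam1", "b:fam2", "b:fam3"))
  calls <- callOrthologs(rbh, oa, ob, phylo_groups = grp,
                         genes_a = "fam", genes_b = c("fam1", "fam2", "fam3"))
  expect_identical(calls$relation, "co_ortholog_group")
  expect_identical(calls$gene_b, "fam1,fam2,fam3")
  # never one_to_one inside a >2-member supported clade, despite RBH
  expect_false(any(calls$relation == "one_to_one"))
})

test_that("identical gene orders give one segment and no events", {
  ord <- data.frame(symbol = c("S100A9", "g1", "g2", "g3", "S100A11"),
                    strand = c("+", "+", "-", "+", "+"))
  rep <- detectLocusRearrangement(ord, ord)
  expect_identical(rep$n_segments, 1L)
  expect_identical(nrow(rep$events), 0L)
})

test_that("a split with spacers is reported with flank assignment", {
  oa <- data.frame(symbol = c("S100A9", "g1", "g2", "g3", "g4", "S100A11"),
                   strand = "+")
  ob <- data.frame(symbol = c("S100A9", "g1", "g2", "x1", "x2",
                              "g3", "g4", "S100A11"),
                   strand = "+")
  rep <- detectLocusRearrangement(oa, ob)
  expect_identical(rep$n_segments, 2L)
  expect_identical(rep$events$type, "split")
  expect_identical(rep$events$after_symbol, "g2")
  expect_identical(rep$events$before_symbol, "g3")
  expect_identical(unname(rep$flank_assignment["S100A9"]), 1)
  expect_identical(unname(rep$flank_assignment["S100A11"]), 2)
})

test_that("split plus segment reversal adds an inversion event", {
  oa <- data.frame(symbol = c("S100A9", "g1", "g2", "g3", "g4", "S100A11"),
                   strand = "+")
  oc <- data.frame(symbol = c("S100A9", "g1", "g2", "x1", "x2",
                              "S100A11", "g4", "g3"),
                   strand = c(rep("+", 5), "-", "-", "-"))
  rep <- detectLocusRearrangement(oa, oc)
  expect_identical(sort(rep$events$type), c("inversion", "split"))
  inv <- rep$events[rep$events$type == "inversion", ]
  expect_identical(inv$after_symbol, "g3")
  expect_identical(inv$before_symbol, "S100A11")
})

test_that("events place on the species tree by Dollo parsimony", {
  oa <- data.frame(symbol = c("S100A9", "g1", "g2", "g3", "S100A11"),
                   strand = "+")
  split_ord <- data.frame(symbol = c("S100A9", "g1", "x1", "g2", "g3",
                                     "S100A11"), strand = "+")
  tree <- "((spA:1,spB:1):1,(spC:1,spD:1):1);"
  reports <- list(spC = detectLocusRearrangement(oa, split_ord),
                  spD = detectLocusRearrangement(oa, split_ord))
  placed <- placeEventsOnTree(reports, tree)
  expect_identical(placed$clade, "spC,spD")
  placed1 <- placeEventsOnTree(reports["spD"], tree)
  expect_identical(placed1$clade, "spD")
})
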