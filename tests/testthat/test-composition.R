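test_that("amino-acid percentages are exact and exclude non-standard symbols", {
  cv <- aaComposition(c(g = "GGGG", u = "ACDE", m = "GSGSGSGSQQ"))
  expect_equal(unname(cv["g", "G"]), 100)
  expect_equal(sum(cv["g", ] > 0), 1)
  expect_equal(unname(cv["u", c("A", "C", "D", "E")]), rep(25, 4))
  expect_equal(unname(cv["m", c("G", "S", "Q")]), c(40, 40, 20))
  expect_equal(unname(rowSums(cv)), rep(100, 3))
  # X and * drop out of numerator and denominator
  cv2 <- aaComposition(c(x = "GGXX**GG"))
  expect_equal(unname(cv2[1, "G"]), 100)
  expect_identical(unname(attr(cv2, "length")), 4L)
})

test_that("composition is invariant under k-fold concatenation", {
  set.seed(5)
  for (k in 1:5) {
    p <- random_protein(sample(30:80, 1))
    expect_equal(aaComposition(c(a = p))[1, ],
                 aaComposition(c(a = strrep(p, 3)))[1, ])
  }
})

test_that("C-terminal segment slicing respects the boundary contract", {
  p <- random_protein(100)
  expect_identical(sftpCtermSegment(p, 90), substring(p, 91, 100))
  expect_error(sftpCtermSegment(p, 100), class = "edc_parameter_error")
  expect_error(sftpCtermSegment(p, 0), class = "edc_parameter_error")
})

test_that("hierarchical clustering matches a brute-force average-linkage oracle", {
  set.seed(9)
  for (k in 1:5) {
    n <- sample(4:8, 1)
    prots <- setNames(vapply(seq_len(n), function(i)
      random_protein(60), ""), paste0("p", seq_len(n)))
    cv <- aaComposition(prots)
    cl <- hierarchicalCluster(cv)
    expect_equal(sort(cl$hc$height), average_linkage_oracle(cv))
  }
  # two identical vectors merge at height zero
  cv <- aaComposition(c(a = "GGSS", b = "GGSS", c = "QQEE"))
  cl <- hierarchicalCluster(cv)
  expect_equal(min(cl$hc$height), 0)
})

test_that("well-separated pairs split at the top and order does not matter", {
  cv <- aaComposition(c(a1 = strrep("GS", 30), a2 = strrep("GGS", 20),
                        b1 = strrep("QE", 30), b2 = strrep("QQE", 20)))
  cl <- hierarchicalCluster(cv)
  g <- compositionGroups(cl, 2)
  expect_identical(g[["a1"]], g[["a2"]])
  expect_identical(g[["b1"]], g[["b2"]])
  expect_false(g[["a1"]] == g[["b1"]])
  cl2 <- hierarchicalCluster(cv[c(3, 1, 4, 2), ])
  expect_identical(compositionGroups(cl2, 2), g)
  expect_match(asNewick(cl), "^\\(")
})

test_that("nearest-centroid assignment reproduces the named groups", {
  v <- aaComposition(c(x = paste0(strrep("G", 35), strrep("S", 30),
                                  strrep("A", 35))))[1, ]
  expect_identical(as.character(assignCompositionGroup(v)),
                   "GS-rich (loricrin-like)")
  v2 <- aaComposition(c(x = paste0(strrep("Q", 30), strrep("E", 25),
                                   strrep("A", 45))))[1, ]
  expect_identical(as.character(assignCompositionGroup(v2)),
                   "QE-rich (involucrin-like)")
  # a uniform vector reports its (deterministic, lexicographic) winner
  u <- setNames(rep(5, 20), colnames(defaultCompositionProfiles()))
  res <- assignCompositionGroup(u)
  expect_identical(as.character(res),
                   names(which.min(attr(res, "distance"))))
})

test_that("tandem repeats are detected with exact period and span", {
  rep4 <- strrep("QSHS", 10)
  rr <- detectTandemRepeats(rep4)
  expect_true(4 %in% rr$period)
  expect_equal(rr$identity[rr$period == 4], 1.0)
  # random segments should not report at stringent identity
  set.seed(13)
  fp <- 0
  for (k in 1:100) {
    r <- detectTandemRepeats(random_protein(200), min_identity = 0.8)
    if (nrow(r)) fp <- fp + 1
  }
  expect_identical(fp, 0)
  # planted noisy decamer repeats recover period 10
  seg <- sampleLowComplexityProtein(generatorProfile("QE"), 300,
                                    repeat_spec = list(unit = 10,
                                                       mutation = 0.05),
                                    seed = 4)
  rr2 <- detectTandemRepeats(seg, min_identity = 0.7)
  expect_true(10 %in% rr2$period)
  expect_error(detectTandemRepeats("QS"), class = "edc_parameter_error")
})
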