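test_that("six-frame translation follows the code table on both strands", {
  tr <- sixFrameTranslate("ATGAAATAA")
  expect_identical(tr[["+0"]], "MK*")
  expect_identical(sixFrameTranslate("TTACATTTTCAT")[["-0"]], "MKM*")
  expect_identical(sixFrameTranslate("ATGANA")[["+0"]], "MX")
  expect_identical(unname(nchar(sixFrameTranslate(""))), rep(0L, 6))
})

test_that("an exactly encoded query yields a perfect hit on either strand", {
  q <- "MKWVTFISLLFLFSSAYS"
  dna <- encode_protein(q)
  h <- seededSearch(q, dna, searchParams(min_score = 20))
  expect_length(h, 1)
  expect_identical(h[[1]]@identity, 1)
  expect_identical(h[[1]]@strand, "+")
  expect_equal(h[[1]]@score, sw_oracle(q, dna))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
  h2 <- seededSearch(q, rc, searchParams(min_score = 20))
  expect_identical(h2[[1]]@strand, "-")
  expect_equal(h2[[1]]@score, h[[1]]@score)
})

test_that("low-complexity queries are never filtered out", {
  q <- strrep("S", 20)
  dna <- encode_protein(q)
  h <- seededSearch(q, dna, searchParams(min_score = 20))
  expect_gte(length(h), 1)
  expect_identical(h[[1]]@identity, 1)
})

test_that("query shorter than the seed length is a parameter error", {
  expect_error(seededSearch("MK", random_dna(300)),
               class = "edc_parameter_error")
})

test_that("guaranteed-seed scores equal the quadratic local oracle", {
  set.seed(101)
  sp <- searchParams(neighborhood_threshold = -Inf, min_score = 1)
  for (k in 1:25) {
    q <- random_protein(sample(20:150, 1))
    dna <- random_dna(sample(120:600, 1), c("A", "C", "G", "T", "N"))
    h <- seededSearch(q, dna, sp)
    mine <- if (length(h)) h[[1]]@score else 0
    expect_equal(mine, max(sw_oracle(q, dna), 0))
  }
})

test_that("gene models are built with exact ORF boundaries", {
  set.seed(7)
  prot <- paste0("M", random_protein(299))
  cds <- paste0(encode_protein(prot), "TAA")
  dna <- paste0(random_dna(400), "AG", random_dna(48), cds, random_dna(300))
  h <- seededSearch(prot, dna, searchParams(min_score = 50))
  m <- buildGeneModel(h[[1]], dna, gene_id = "t")
  ce <- codingExons(m)
  expect_identical(nrow(ce), 1L)
  expect_identical(unname(ce[1, ]), c(450, 450 + nchar(cds)))
  expect_identical(proteinSeq(m), prot)
  expect_identical(nrow(exons(m)), 2L)     # acceptor AG implies a 5' exon
  expect_identical(sum(m@coding), 1L)
  expect_false("missing_utr_exon" %in% m@flags)
})

test_that("a planted intron yields a 3-exon model with the spliced protein", {
  set.seed(8)
  j <- 31L
  prot <- paste0("M", random_protein(149))
  cds <- paste0(encode_protein(prot), "TGA")
  cds1 <- substring(cds, 1, 3 * j)
  cds2 <- substring(cds, 3 * j + 1, nchar(cds))
  intron <- paste0("GT", random_dna(146), "AG")
  dna <- paste0(random_dna(300), "AG", random_dna(20),
                cds1, intron, cds2, random_dna(250))
  h <- seededSearch(prot, dna, searchParams(min_score = 50))
  m <- buildGeneModel(h[[1]], dna, query = prot,
                      query_meta = list(class = "S100A", junction = j))
  expect_identical(sum(m@coding), 2L)
  expect_identical(nrow(exons(m)), 3L)
  expect_identical(proteinSeq(m), prot)
  expect_identical(m@junction, j)
})

test_that("classification is a pure function of exon structure and length", {
  mk <- function(n_coding, plen, junction = NA_integer_) {
    ex <- cbind(seq(0, by = 2000, length.out = n_coding),
                seq(1000, by = 2000, length.out = n_coding))
    new("GeneModel", gene_id = "x", gene_symbol = "x", seqid = "c",
        strand = "+", exons = ex, coding = rep(TRUE, n_coding),
        gene_class = "unknown", pseudogene_evidence = character(),
        metadata = list(), protein = strrep("A", plen), score = 1,
        source_query = "q", flags = character(),
        junction = junction)
  }
  expect_identical(classifyGeneType(mk(1, 312)), "SEDC")
  expect_identical(classifyGeneType(mk(2, 105, 60L)), "S100A")
  expect_identical(classifyGeneType(mk(2, 2800, 93L)), "SFTP")
  expect_identical(classifyGeneType(mk(3, 400)), "unknown")
  expect_identical(classifyGeneType(mk(5, 400)), "PGLYRP")
})

test_that("pseudogene flags recover planted stops and frameshifts", {
  set.seed(21)
  ref <- paste0("M", random_protein(199))
  cds <- paste0(encode_protein(ref), "TAA")
  flank5 <- paste0(random_dna(280), "AG", random_dna(18))
  flank3 <- random_dna(300)
  build <- function(cds_mut) {
    dna <- paste0(flank5, cds_mut, flank3)
    h <- seededSearch(ref, dna, searchParams(min_score = 50))
    buildGeneModel(h[[1]], dna)
  }
  # intact
  expect_identical(detectPseudogene(build(cds), ref), character(0))
  # stop planted at codon 40
  cds_stop <- cds
  substr(cds_stop, 118, 120) <- "TAA"
  expect_identical(detectPseudogene(build(cds_stop), ref),
                   "premature_stop")
  # 1-nt deletion at codon 90
  cds_fs <- paste0(substring(cds, 1, 268), substring(cds, 270))
  expect_identical(detectPseudogene(build(cds_fs), ref), "frameshift")
  expect_error(detectPseudogene(build(cds), ""),
               class = "edc_parameter_error")
})

test_that("iterative discovery finds two-step homologs in round two", {
  set.seed(33)
  A <- paste0("M", random_protein(179))
  B <- mutate_protein(A, 0.25)
  C <- mutate_protein(B, 0.45)       # too diverged from A directly
  dna <- paste0(random_dna(400), "AG", random_dna(30),
                encode_protein(B), "TAA",
                random_dna(1500), "AG", random_dna(30),
                encode_protein(C), "TAA", random_dna(400))
  sp <- searchParams(min_score = 320)
  direct <- seededSearch(C, dna, sp, query_id = "c-direct")
  # scenario sanity: A alone cannot reach C at this threshold
  a_hits <- seededSearch(A, dna, sp, query_id = "a")
  expect_identical(length(a_hits), 1L)
  one_round <- iterativeDiscovery(c(qA = A), dna, sp, max_rounds = 1)
  expect_identical(length(one_round), 1L)
  two_round <- iterativeDiscovery(c(qA = A), dna, sp, max_rounds = 4)
  expect_identical(length(two_round), 2L)
  # determinism: identical output on a rerun
  again <- iterativeDiscovery(c(qA = A), dna, sp, max_rounds = 4)
  expect_identical(lapply(two_round, exons), lapply(again, exons))
  # no same-strand overlaps in the report
  fps <- t(vapply(two_round, edcscan:::.modelFootprint, numeric(2)))
  o <- order(fps[, 1])
  expect_true(all(fps[o, 2][-nrow(fps)] <= fps[o, 1][-1] |
                    vapply(two_round, function(m) m@strand, "")[o][-nrow(fps)] !=
                    vapply(two_round, function(m) m@strand, "")[o][-1]))
})
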