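test_that("FASTA reading uppercases, tokenizes ids and keeps descriptions", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x some note", "acgt"), f)
  s <- readFasta(f)
  expect_identical(unname(s[["x"]]), "ACGT")
  expect_identical(unname(attr(s, "description")[["x"]]), "some note")

  writeLines(c(">a", "AC", "GT", ">b meta=1", "TT"), f)
  s <- readFasta(f)
  expect_identical(as.vector(s), c("ACGT", "TT"))
  expect_identical(names(s), c("a", "b"))
})

test_that("malformed FASTA raises a format error naming the line", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c("ACGT", "TTTT"), f)
  err <- tryCatch(readFasta(f), error = identity)
  expect_s3_class(err, "edc_format_error")
  expect_match(conditionMessage(err), "line 1")
  file.create(f)
  writeLines(character(), f)
  expect_error(readFasta(f), class = "edc_format_error")
})

test_that("FASTA round-trips losslessly", {
  f <- withr::local_tempfile(fileext = ".fa")
  seqs <- c(p1 = random_protein(150), p2 = random_protein(7))
  attr(seqs, "description") <- c(p1 = "class=SFTP junction=93", p2 = "")
  writeFasta(seqs, f)
  back <- readFasta(f)
  expect_identical(unname(back), unname(seqs))
  expect_identical(unname(attr(back, "description")[["p1"]]),
                   "class=SFTP junction=93")
})

test_that("GFF3 round-trips annotations with coordinate conversion", {
  a <- geneAnnotation("g1", rbind(c(10, 60), c(100, 400)),
                      c(FALSE, TRUE), "chr1", "+", gene_class = "SEDC")
  b <- geneAnnotation("g2", rbind(c(500, 560), c(600, 750), c(800, 1000)),
                      c(FALSE, TRUE, TRUE), "chr1", "-",
                      gene_class = "SFTP",
                      pseudogene_evidence = "premature_stop")
  f <- withr::local_tempfile(fileext = ".gff3")
  writeGff3(list(a, b), f)
  back <- readGff3(f)
  expect_length(back, 2)
  expect_equal(unname(back[[1]]@exons), unname(a@exons))
  expect_identical(back[[1]]@coding, a@coding)
  expect_identical(back[[2]]@gene_class, "SFTP")
  expect_identical(back[[2]]@pseudogene_evidence, "premature_stop")
  # the 1-based inclusive file convention: internal exon (10, 60) must
  # appear as 11..60 on disk
  lines <- readLines(f)
  expect_true(any(grepl("\texon\t11\t60\t", lines)))
})

test_that("exon end before start is rejected", {
  expect_error(
    geneAnnotation("bad", rbind(c(100, 50)), TRUE, "chr1"),
    "start must be <")
})

test_that("core region extraction returns the interval between flanks", {
  mk <- function(sym, s, e, chr = "chr1")
    geneAnnotation(sym, rbind(c(s, e)), TRUE, chr, gene_symbol = sym)
  chr <- random_dna(60000)
  ann <- list(mk("S100A9", 1000, 2000), mk("LOR", 10000, 11000),
              mk("S100A11", 50000, 51000))
  reg <- extractCoreRegion(ann, c(chr1 = chr))
  expect_identical(start(reg), 2000)
  expect_identical(end(reg), 50000)
  expect_identical(reg@sequence, substring(chr, 2001, 50000))
  expect_identical(reg@metadata$orientation, "forward")
  # invariance to annotation order
  reg2 <- extractCoreRegion(rev(ann), c(chr1 = chr))
  expect_identical(reg2@start, reg@start)
  expect_identical(reg2@end, reg@end)
  # reversed genomic order of the flanks: same interval, flagged
  ann_rev <- list(mk("S100A11", 1000, 2000), mk("S100A9", 50000, 51000))
  reg3 <- extractCoreRegion(ann_rev, c(chr1 = chr))
  expect_identical(reg3@start, 2000)
  expect_identical(reg3@metadata$orientation, "reversed")
})

test_that("missing or split flanks raise their dedicated conditions", {
  mk <- function(sym, s, e, chr = "chr1")
    geneAnnotation(sym, rbind(c(s, e)), TRUE, chr, gene_symbol = sym)
  chr <- c(chr1 = random_dna(3000), chr2 = random_dna(3000))
  expect_error(extractCoreRegion(list(mk("S100A9", 10, 20)), chr),
               class = "edc_locus_incomplete")
  err <- tryCatch(extractCoreRegion(list(mk("S100A9", 10, 20)), chr),
                  error = identity)
  expect_match(conditionMessage(err), "S100A11")
  expect_error(
    extractCoreRegion(list(mk("S100A9", 10, 20),
                           mk("S100A11", 100, 200, "chr2")), chr),
    class = "edc_locus_split")
})
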