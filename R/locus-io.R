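#' Read a FASTA file
#'
#' Sequences are uppercased; record ids are the first whitespace-delimited
#' token of the header. The remainder of each header is kept in the
#' \code{"description"} attribute (used to carry query metadata such as
#' \code{class=SFTP junction=93}).
#'
#' @param path path to a FASTA file.
#' @return Named character vector of sequences, with a
#'   \code{"description"} attribute (named character vector).
#' @examples
#' f <- tempfile(fileext = ".fa")
#' writeLines(c(">x some note", "acgt"), f)
#' readFasta(f)
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) .stopf("edc_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank))
    .stopf("edc_format_error", "FASTA format error at line 1: empty file")
  first <- nonblank[1]
  if (!startsWith(lines[first], ">"))
    .stopf("edc_format_error",
           "FASTA format error at line %d: expected '>' header", first)
  hdr <- which(startsWith(lines, ">"))
  for (k in seq_along(hdr)) {
    if (!nzchar(trimws(substring(lines[hdr[k]], 2))))
      .stopf("edc_format_error",
             "FASTA format error at line %d: empty header", hdr[k])
    to <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    body <- lines[seq(hdr[k] + 1, length.out = max(0, to - hdr[k]))]
    if (!any(nzchar(trimws(body))))
      .stopf("edc_format_error",
             "FASTA format error at line %d: record has no sequence", hdr[k])
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  full <- names(seqs)
  ids <- vapply(strsplit(full, "\\s+"), `[`, "", 1)
  desc <- vapply(full, function(h) {
    sub("^\\S+\\s*", "", h)
  }, "", USE.NAMES = FALSE)
  names(seqs) <- ids
  attr(seqs, "description") <- setNames(desc, ids)
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector; an optional \code{"description"}
#'   attribute is appended to headers.
#' @param path output path.
#' @param width line wrap width.
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(seqs, path, width = 70) {
  desc <- attr(seqs, "description")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    d <- if (!is.null(desc) && !is.na(desc[id]) && nzchar(desc[id]))
      paste0(" ", desc[id]) else ""
    writeLines(paste0(">", id, d), con)
    s <- seqs[[i]]
    starts <- seq(1, max(1, nchar(s)), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# ---- GFF3 ----------------------------------------------------------------

#' Write gene annotations to GFF3
#'
#' Emits gene/mRNA/exon/CDS features, converting the package's 0-based
#' half-open coordinates to the 1-based inclusive file convention. Every
#' gene row carries a \code{gene_class} attribute and, where applicable,
#' \code{pseudogene_evidence}.
#'
#' @param annotations list of \linkS4class{GeneAnnotation} (or
#'   \linkS4class{GeneModel}) objects.
#' @param path output path.
#' @param seqlengths optional named vector of sequence lengths.
#' @return Invisibly, \code{path}.
#' @export
writeGff3 <- function(annotations, path, seqlengths = NULL) {
  rows <- list()
  for (a in annotations) {
    ex <- a@exons
    g0 <- min(ex[, 1]); g1 <- max(ex[, 2])
    mid <- paste0(a@gene_id, ".t1")
    rows[[length(rows) + 1]] <- data.frame(
      seqid = a@seqid, type = "gene", start = g0 + 1, end = g1,
      strand = a@strand, ID = a@gene_id, Parent = NA_character_,
      Name = a@gene_symbol, gene_class = a@gene_class,
      pseudogene_evidence = if (length(a@pseudogene_evidence))
        paste(a@pseudogene_evidence, collapse = ",") else NA_character_,
      phase = NA_integer_, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      seqid = a@seqid, type = "mRNA", start = g0 + 1, end = g1,
      strand = a@strand, ID = mid, Parent = a@gene_id,
      Name = NA_character_, gene_class = NA_character_,
      pseudogene_evidence = NA_character_, phase = NA_integer_,
      stringsAsFactors = FALSE)
    # CDS phase: cumulative coding length in transcript order
    tx_order <- if (a@strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
    phase_of <- rep(NA_integer_, nrow(ex))
    acc <- 0
    for (k in tx_order) {
      if (a@coding[k]) {
        phase_of[k] <- (3 - (acc %% 3)) %% 3
        acc <- acc + (ex[k, 2] - ex[k, 1])
      }
    }
    for (k in seq_len(nrow(ex))) {
      rows[[length(rows) + 1]] <- data.frame(
        seqid = a@seqid, type = "exon", start = ex[k, 1] + 1, end = ex[k, 2],
        strand = a@strand, ID = NA_character_, Parent = mid,
        Name = NA_character_, gene_class = NA_character_,
        pseudogene_evidence = NA_character_, phase = NA_integer_,
        stringsAsFactors = FALSE)
      if (a@coding[k]) {
        rows[[length(rows) + 1]] <- data.frame(
          seqid = a@seqid, type = "CDS", start = ex[k, 1] + 1,
          end = ex[k, 2], strand = a@strand, ID = NA_character_,
          Parent = mid, Name = NA_character_, gene_class = NA_character_,
          pseudogene_evidence = NA_character_, phase = phase_of[k],
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqid,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- ifelse(is.na(df$Parent), "", df$Parent)
  S4Vectors::mcols(gr)$Name <- df$Name
  S4Vectors::mcols(gr)$gene_class <- df$gene_class
  S4Vectors::mcols(gr)$pseudogene_evidence <- df$pseudogene_evidence
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  # drop the date header line: artifacts must be run-to-run identical
  lines <- readLines(path, warn = FALSE)
  writeLines(lines[!startsWith(lines, "##date")], path)
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Inverse of \code{\link{writeGff3}} on the feature subset the package
#' emits (gene/mRNA/exon/CDS). Coordinates are converted back to 0-based
#' half-open. CDS features outside their parent gene's bounds, or features
#' with end < start, raise a validation error.
#'
#' @param path path to a GFF3 file.
#' @return List of \linkS4class{GeneAnnotation} objects, sorted by
#'   (seqid, start).
#' @export
readGff3 <- function(path) {
  if (!file.exists(path)) .stopf("edc_io_error", "file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   .stopf("edc_format_error", "GFF3 parse error in %s: %s",
                          path, conditionMessage(e)))
  df <- as.data.frame(gr)
  df$Parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) as.character(p[[1]]) else "", "")
  genes <- df[df$type == "gene", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    mrna <- df[df$type == "mRNA" & df$Parent == g$ID, , drop = FALSE]
    mids <- if (nrow(mrna)) mrna$ID else g$ID
    ex <- df[df$type == "exon" & df$Parent %in% mids, , drop = FALSE]
    cds <- df[df$type == "CDS" & df$Parent %in% mids, , drop = FALSE]
    if (nrow(cds)) {
      if (any(cds$start < g$start | cds$end > g$end))
        .stopf("edc_validation_error",
               "CDS outside parent gene bounds for gene %s", g$ID)
    }
    if (!nrow(ex)) ex <- cds
    exm <- cbind(start = ex$start - 1, end = ex$end)
    o <- order(exm[, 1])
    exm <- exm[o, , drop = FALSE]
    coding <- vapply(seq_len(nrow(exm)), function(k)
      any(cds$start - 1 == exm[k, 1] & cds$end == exm[k, 2]), TRUE)
    cls <- if (!is.null(g$gene_class) && !is.na(g$gene_class))
      g$gene_class else "unknown"
    pe <- if (!is.null(g$pseudogene_evidence) &&
              !is.na(g$pseudogene_evidence) && nzchar(g$pseudogene_evidence))
      strsplit(g$pseudogene_evidence, ",")[[1]] else character()
    sym <- if (!is.null(g$Name) && !is.na(g$Name)) g$Name else g$ID
    out[[length(out) + 1]] <- geneAnnotation(
      gene_id = g$ID, exons = exm, coding = coding,
      seqid = as.character(g$seqnames), strand = as.character(g$strand),
      gene_symbol = sym, gene_class = cls, pseudogene_evidence = pe)
  }
  ord <- order(vapply(out, function(a) a@seqid, ""),
               vapply(out, function(a) min(a@exons), 0))
  out[ord]
}

#' Extract the EDC core region between two flanking marker genes
#'
#' The EDC core is the interval strictly between the two flanking genes
#' (by default the S100A9 and S100A11 orthologs): from the end of the
#' upstream gene to the start of the downstream gene in sequence
#' coordinates. The flanks themselves are reported in the region metadata,
#' not included in the interval.
#'
#' @param annotations list of \linkS4class{GeneAnnotation}.
#' @param sequence named character vector of chromosome sequences (or a
#'   single unnamed sequence).
#' @param flank5_symbol,flank3_symbol gene symbols of the flanking marker
#'   genes (defaults follow the EDC core convention; the same machinery
#'   applies to other loci, e.g. the caspase-14 cluster, by overriding
#'   them).
#' @return A \linkS4class{GenomicRegion} whose metadata records both flank
#'   annotations and an \code{orientation} field: \code{"forward"} when the
#'   5' flank is genomically left of the 3' flank, \code{"reversed"}
#'   otherwise.
#' @section Errors: a missing flank raises a condition of class
#'   \code{edc_locus_incomplete} naming the absent flank; flanks on
#'   different sequences raise \code{edc_locus_split} carrying both seqids
#'   (a genuine biological signal: a split locus, as in marsupials).
#' @export
extractCoreRegion <- function(annotations, sequence,
                              flank5_symbol = "S100A9",
                              flank3_symbol = "S100A11") {
  syms <- vapply(annotations, geneSymbol, "")
  hit5 <- which(syms == flank5_symbol)
  hit3 <- which(syms == flank3_symbol)
  if (length(hit5) != 1)
    .stopf("edc_locus_incomplete",
           "locus incomplete: flank %s %s", flank5_symbol,
           if (length(hit5)) "present more than once" else "missing",
           data = list(flank = flank5_symbol))
  if (length(hit3) != 1)
    .stopf("edc_locus_incomplete",
           "locus incomplete: flank %s %s", flank3_symbol,
           if (length(hit3)) "present more than once" else "missing",
           data = list(flank = flank3_symbol))
  a5 <- annotations[[hit5]]; a3 <- annotations[[hit3]]
  if (a5@seqid != a3@seqid)
    .stopf("edc_locus_split",
           "locus split: %s on %s, %s on %s", flank5_symbol, a5@seqid,
           flank3_symbol, a3@seqid,
           data = list(flank5_seqid = a5@seqid, flank3_seqid = a3@seqid))
  s5 <- c(min(a5@exons), max(a5@exons))
  s3 <- c(min(a3@exons), max(a3@exons))
  if (s5[1] <= s3[1]) {
    left <- s5; right <- s3; orientation <- "forward"
  } else {
    left <- s3; right <- s5; orientation <- "reversed"
  }
  if (is.null(names(sequence)) && length(sequence) == 1)
    names(sequence) <- a5@seqid
  if (!a5@seqid %in% names(sequence))
    .stopf("edc_io_error", "no sequence provided for %s", a5@seqid)
  chr <- sequence[[a5@seqid]]
  st <- left[2]; en <- right[1]
  genomicRegion(a5@seqid, st, en, "+",
                substring(chr, st + 1, en),
                metadata = list(flank5 = a5, flank3 = a3,
                                orientation = orientation))
}
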