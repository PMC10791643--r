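#' GenomicRegion: a located stretch of genomic sequence
#'
#' Coordinates are 0-based, half-open throughout the package; conversion to
#' the 1-based inclusive convention happens only at the GFF3 boundary.
#'
#' @slot seqid sequence (chromosome/scaffold) identifier.
#' @slot start,end 0-based half-open interval on \code{seqid}.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot sequence DNA over \code{A,C,G,T,N}, length \code{end - start}.
#' @slot metadata free-form list (flank identities, orientation flags, ...).
#' @exportClass GenomicRegion
setClass("GenomicRegion",
  representation(seqid = "character", start = "numeric", end = "numeric",
                 strand = "character", sequence = "character",
                 metadata = "list"),
  prototype(strand = "+", metadata = list()))

setValidity("GenomicRegion", function(object) {
  msg <- character()
  if (!(object@strand %in% c("+", "-")))
    msg <- c(msg, "strand must be '+' or '-'")
  if (object@start < 0 || object@start >= object@end)
    msg <- c(msg, "need 0 <= start < end")
  if (nchar(object@sequence) != object@end - object@start)
    msg <- c(msg, "sequence length must equal end - start")
  if (grepl("[^ACGTN]", object@sequence))
    msg <- c(msg, "sequence must be over {A,C,G,T,N}")
  if (length(msg)) msg else TRUE
})

#' Construct a GenomicRegion
#'
#' @param seqid sequence identifier.
#' @param start,end 0-based half-open coordinates.
#' @param strand \code{"+"} or \code{"-"}.
#' @param sequence DNA string of length \code{end - start} (uppercased).
#' @param metadata optional list of free-form metadata.
#' @return A \linkS4class{GenomicRegion}.
#' @examples
#' genomicRegion("chr1", 0, 4, "+", "ACGT")
#' @export
genomicRegion <- function(seqid, start, end, strand = "+", sequence,
                          metadata = list()) {
  new("GenomicRegion", seqid = as.character(seqid), start = as.numeric(start),
      end = as.numeric(end), strand = strand,
      sequence = toupper(as.character(sequence)), metadata = metadata)
}

#' Gene annotation: exon-structured gene with class and evidence labels
#'
#' @slot gene_id unique identifier.
#' @slot gene_symbol gene symbol (used for synteny matching).
#' @slot seqid sequence identifier the exons live on.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons two-column matrix of 0-based half-open (start, end) rows,
#'   sorted by start, non-overlapping.
#' @slot coding logical per exon: does the exon carry coding sequence.
#' @slot gene_class one of SEDC, SFTP, S100A, PGLYRP, unknown.
#' @slot pseudogene_evidence subset of {premature_stop, frameshift}.
#' @slot metadata free-form list.
#' @exportClass GeneAnnotation
setClass("GeneAnnotation",
  representation(gene_id = "character", gene_symbol = "character",
                 seqid = "character", strand = "character",
                 exons = "matrix", coding = "logical",
                 gene_class = "character",
                 pseudogene_evidence = "character", metadata = "list"),
  prototype(gene_class = "unknown", pseudogene_evidence = character(),
            metadata = list()))

setValidity("GeneAnnotation", function(object) {
  msg <- character()
  ex <- object@exons
  if (ncol(ex) != 2) return("exons must be a 2-column matrix")
  if (nrow(ex) != length(object@coding))
    msg <- c(msg, "coding flags must match exon count")
  if (nrow(ex) > 1) {
    if (is.unsorted(ex[, 1]))
      msg <- c(msg, "exons must be sorted by start")
    if (any(ex[-nrow(ex), 2] > ex[-1, 1]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  if (any(ex[, 1] >= ex[, 2])) msg <- c(msg, "exon start must be < end")
  if (!(object@gene_class %in%
        c("SEDC", "SFTP", "S100A", "PGLYRP", "unknown")))
    msg <- c(msg, "invalid gene_class")
  if (length(msg)) msg else TRUE
})

#' Construct a GeneAnnotation
#'
#' @param gene_id unique identifier.
#' @param exons two-column matrix (0-based half-open starts/ends).
#' @param coding logical vector, one flag per exon.
#' @param seqid sequence identifier.
#' @param strand \code{"+"} or \code{"-"}.
#' @param gene_symbol symbol; defaults to \code{gene_id}.
#' @param gene_class SEDC, SFTP, S100A, PGLYRP or unknown.
#' @param pseudogene_evidence character subset of
#'   \code{c("premature_stop", "frameshift")}.
#' @param metadata free-form list.
#' @return A \linkS4class{GeneAnnotation}.
#' @export
geneAnnotation <- function(gene_id, exons, coding, seqid, strand = "+",
                           gene_symbol = gene_id, gene_class = "unknown",
                           pseudogene_evidence = character(),
                           metadata = list()) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  new("GeneAnnotation", gene_id = gene_id, gene_symbol = gene_symbol,
      seqid = seqid, strand = strand, exons = exons,
      coding = as.logical(coding), gene_class = gene_class,
      pseudogene_evidence = pseudogene_evidence, metadata = metadata)
}

#' Translated homology hit
#'
#' Footprint coordinates are 0-based half-open positions on the forward
#' strand of the searched region; \code{frame} is the offset (0, 1, 2)
#' within the reading strand.
#'
#' @slot query_id query protein identifier.
#' @slot seqid target sequence identifier.
#' @slot strand strand of the reading frame.
#' @slot frame frame offset 0, 1 or 2 on the reading strand.
#' @slot t_start,t_end genomic footprint (forward-strand coordinates).
#' @slot q_start,q_end 0-based half-open span on the query protein.
#' @slot score raw substitution-matrix alignment score.
#' @slot identity fraction identical of aligned residue pairs.
#' @slot qidx,tidx aligned residue indices (-1 marks a gap), query and
#'   frame-translation coordinates respectively.
#' @slot aa_t_start start of the footprint in frame-translation residues.
#' @exportClass TranslatedHit
setClass("TranslatedHit",
  representation(query_id = "character", seqid = "character",
                 strand = "character", frame = "integer",
                 t_start = "numeric", t_end = "numeric",
                 q_start = "integer", q_end = "integer",
                 score = "numeric", identity = "numeric",
                 qidx = "integer", tidx = "integer",
                 aa_t_start = "integer"))

#' Gene model: a discovered gene with protein and evidence
#'
#' Extends \linkS4class{GeneAnnotation} with the encoded protein, the raw
#' search score, the query that seeded it, and builder flags
#' (\code{incomplete}, \code{missing_utr_exon}).
#'
#' @slot protein predicted protein (no terminal stop).
#' @slot score alignment score of the supporting hit.
#' @slot source_query id of the query protein that found the gene.
#' @slot flags builder status flags.
#' @slot junction length (aa) of the first coding exon for 2-exon models.
#' @exportClass GeneModel
setClass("GeneModel", contains = "GeneAnnotation",
  representation(protein = "character", score = "numeric",
                 source_query = "character", flags = "character",
                 junction = "integer"),
  prototype(flags = character(), junction = NA_integer_))

#' Locus simulation scenario
#'
#' @slot name scenario name.
#' @slot seed base RNG seed; same seed gives byte-identical output.
#' @slot tree species tree (Newick text) with branch lengths.
#' @slot roster data.frame of gene families: columns \code{family},
#'   \code{class}, \code{profile}, \code{length}, \code{strand}, plus
#'   optional \code{disruption} ("", "premature_stop", "frameshift"),
#'   \code{copies} (species-specific duplication spec, e.g. "spB:3"),
#'   \code{divergence} (expected per-site substitution probability between
#'   the two most distant leaves).
#' @slot rearrangements data.frame of events: \code{type} (split or
#'   inversion), \code{edge} (leaf set "spC+spD" defining the clade whose
#'   stem carries the event), \code{after_family} (breakpoint).
#' @slot params list: intergenic length range, intron length range,
#'   repeat specs, etc.
#' @exportClass LocusScenario
setClass("LocusScenario",
  representation(name = "character", seed = "numeric", tree = "character",
                 roster = "data.frame", rearrangements = "data.frame",
                 params = "list"))

setValidity("LocusScenario", function(object) {
  msg <- character()
  need <- c("family", "class", "profile", "length", "strand")
  if (!all(need %in% names(object@roster)))
    msg <- c(msg, paste("roster needs columns:", paste(need, collapse = ", ")))
  if (nrow(object@rearrangements) &&
      !all(object@rearrangements$after_family %in%
           c(object@roster$family, "")))
    msg <- c(msg, "rearrangement breakpoint families must exist in roster")
  if (nrow(object@rearrangements) &&
      !all(object@rearrangements$type %in% c("split", "inversion")))
    msg <- c(msg, "rearrangement type must be split or inversion")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GenomicRegion", function(object) {
  cat(sprintf("GenomicRegion %s:%.0f-%.0f(%s), %.0f bp\n", object@seqid,
              object@start, object@end, object@strand,
              object@end - object@start))
})

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("%s %s (%s) %s:%s(%s) exons=%d coding=%d%s\n",
              class(object), object@gene_id, object@gene_class,
              object@seqid,
              paste0(min(object@exons), "-", max(object@exons)),
              object@strand, nrow(object@exons), sum(object@coding),
              if (length(object@pseudogene_evidence))
                paste0(" [", paste(object@pseudogene_evidence,
                                   collapse = ","), "]") else ""))
})

setMethod("show", "LocusScenario", function(object) {
  cat(sprintf("LocusScenario '%s': %d families, %d rearrangement event(s), seed %.0f\n",
              object@name, nrow(object@roster),
              nrow(object@rearrangements), object@seed))
})

#' @describeIn genomicRegion width of a region
#' @param x a GenomicRegion
#' @importMethodsFrom BiocGenerics start end strand width
#' @export
setMethod("width", "GenomicRegion", function(x) x@end - x@start)

#' @describeIn genomicRegion 0-based start
#' @export
setMethod("start", "GenomicRegion", function(x) x@start)

#' @describeIn genomicRegion half-open end
#' @export
setMethod("end", "GenomicRegion", function(x) x@end)

#' @describeIn genomicRegion strand
#' @export
setMethod("strand", "GenomicRegion", function(x) x@strand)

#' Accessors for gene annotations and models
#'
#' @param x a \linkS4class{GeneAnnotation} or \linkS4class{GeneModel}.
#' @return \code{geneId}, \code{geneSymbol}, \code{geneClass} return single
#'   strings; \code{exons} the exon matrix; \code{codingExons} the coding
#'   subset; \code{proteinSeq} the encoded protein; \code{pseudogeneFlags}
#'   the evidence flags.
#' @name gene-accessors
NULL

#' @rdname gene-accessors
#' @export
geneId <- function(x) x@gene_id

#' @rdname gene-accessors
#' @export
geneSymbol <- function(x) x@gene_symbol

#' @rdname gene-accessors
#' @export
geneClass <- function(x) x@gene_class

#' @rdname gene-accessors
#' @export
exons <- function(x) x@exons

#' @rdname gene-accessors
#' @export
codingExons <- function(x) x@exons[x@coding, , drop = FALSE]

#' @rdname gene-accessors
#' @export
proteinSeq <- function(x) x@protein

#' @rdname gene-accessors
#' @export
pseudogeneFlags <- function(x) x@pseudogene_evidence
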