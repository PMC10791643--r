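#' Six-frame translation
#'
#' Translates a DNA sequence in all six reading frames under the standard
#' genetic code. Stop codons are rendered as \code{"*"}; codons containing
#' \code{N} translate to \code{X} unless the code resolves them uniquely
#' is not attempted -- any fuzzy codon becomes \code{X}. Reverse frames
#' translate the reverse complement.
#'
#' @param dna DNA string over \code{A,C,G,T,N}.
#' @return Character vector of six translations named \code{"+0","+1","+2",
#'   "-0","-1","-2"}; the frame number is the offset into the reading
#'   strand.
#' @examples
#' sixFrameTranslate("ATGAAATAA")[["+0"]]  # "MK*"
#' @export
sixFrameTranslate <- function(dna) {
  dna <- toupper(dna)
  out <- character(6)
  names(out) <- c("+0", "+1", "+2", "-0", "-1", "-2")
  for (strand in c("+", "-")) {
    s <- if (strand == "+") dna else .revCompChr(dna)
    for (f in 0:2) {
      out[paste0(strand, f)] <- .translateFrame(s, f)
    }
  }
  out
}

# translate one frame of an already-oriented strand sequence
.translateFrame <- function(s, frame) {
  L <- nchar(s)
  n_codons <- (L - frame) %/% 3
  if (n_codons <= 0) return("")
  sub <- substring(s, frame + 1, frame + 3 * n_codons)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     if.fuzzy.codon = "X"))
}

# translate a CDS nucleotide string (dropping any trailing partial codon);
# keeps internal '*' so callers can inspect disruptions
.translateCds <- function(nt) .translateFrame(toupper(nt), 0L)
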