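#' Amino-acid composition of proteins
#'
#' Computes the percentage of each of the 20 standard amino acids.
#' Non-standard symbols (\code{X}, \code{*}, \code{B}, \code{Z}, ...) are
#' excluded from both numerator and denominator. Percentages are used
#' rather than counts so that proteins of very different lengths (a
#' 100-residue LCE and a multi-thousand-residue SFTP tail) live in the
#' same 20-dimensional space.
#'
#' @param proteins character vector of protein sequences (named; a single
#'   unnamed sequence gets id \code{"protein"}).
#' @return Numeric matrix with one row per protein and 20 columns (one
#'   per standard residue, alphabetical); rows sum to 100. The counted
#'   residue totals are attached as attribute \code{"length"}.
#' @examples
#' aaComposition(c(p1 = "GGGG", p2 = "ACDE"))
#' @export
aaComposition <- function(proteins) {
  std <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  if (is.null(names(proteins)))
    names(proteins) <- if (length(proteins) == 1) "protein"
                       else paste0("protein", seq_along(proteins))
  m <- matrix(0, length(proteins), length(std),
              dimnames = list(names(proteins), std))
  lens <- integer(length(proteins))
  for (i in seq_along(proteins)) {
    ch <- strsplit(toupper(proteins[[i]]), "")[[1]]
    ch <- ch[ch %in% std]
    if (!length(ch))
      .stopf("edc_parameter_error",
             "protein %s has no standard residues", names(proteins)[i])
    tb <- table(factor(ch, levels = std))
    lens[i] <- length(ch)
    m[i, ] <- 100 * as.numeric(tb) / length(ch)
  }
  attr(m, "length") <- setNames(lens, names(proteins))
  m
}

#' Carboxy-terminal segment of an S100 fused-type protein
#'
#' Returns the residues strictly after the S100 domain, the low-complexity
#' tail whose composition (not alignment) carries the evolutionary signal.
#'
#' @param protein protein sequence.
#' @param s100_end 1-based position of the last S100-domain residue;
#'   must satisfy \code{0 < s100_end < nchar(protein)}.
#' @return The C-terminal segment (character string).
#' @export
sftpCtermSegment <- function(protein, s100_end) {
  n <- nchar(protein)
  if (is.na(s100_end) || s100_end <= 0 || s100_end >= n)
    .stopf("edc_parameter_error",
           "S100 boundary %s outside protein (length %d)",
           as.character(s100_end), n)
  substring(protein, s100_end + 1, n)
}

#' Locate the S100 domain boundary by alignment to a reference domain
#'
#' Aligns a reference S100 domain locally against the protein and returns
#' the 1-based end position of the aligned span, i.e. the boundary to
#' feed \code{\link{sftpCtermSegment}}.
#'
#' @param protein protein sequence.
#' @param reference reference S100-domain sequence.
#' @return Integer position, or \code{NA} if no alignment scores above
#'   zero.
#' @export
s100DomainEnd <- function(protein, reference) {
  al <- cpp_local_align(.aaEncode(reference), .aaEncode(protein),
                        .subMatrix(), 11, 1)
  if (is.null(al$tend)) return(NA_integer_)
  as.integer(al$tend)
}

#' Hierarchical clustering of composition vectors
#'
#' Agglomerative clustering of 20-dimensional amino-acid percentage
#' vectors. Input rows are ordered by protein id before clustering so the
#' result is invariant to input order.
#'
#' @param vectors matrix from \code{\link{aaComposition}} (>= 2 rows).
#' @param metric distance metric, default \code{"euclidean"}.
#' @param linkage agglomeration method, default \code{"average"}.
#' @return Object of class \code{"composition_clust"}: a list with the
#'   \code{hclust} tree (\code{$hc}), the parameters, and the input ids;
#'   \code{\link{compositionGroups}} cuts it, \code{\link{asNewick}}
#'   serialises it.
#' @export
hierarchicalCluster <- function(vectors, metric = "euclidean",
                                linkage = "average") {
  if (nrow(vectors) < 2)
    .stopf("edc_parameter_error", "need at least 2 composition vectors")
  vectors <- vectors[order(rownames(vectors)), , drop = FALSE]
  d <- dist(vectors, method = metric)
  hc <- hclust(d, method = linkage)
  structure(list(hc = hc, metric = metric, linkage = linkage,
                 ids = rownames(vectors)),
            class = "composition_clust")
}

#' @export
print.composition_clust <- function(x, ...) {
  cat(sprintf("Composition clustering of %d proteins (%s distance, %s linkage)\n",
              length(x$ids), x$metric, x$linkage))
  invisible(x)
}

#' Cut a composition dendrogram into k groups
#'
#' @param clustering result of \code{\link{hierarchicalCluster}}.
#' @param k number of groups.
#' @return Named integer vector of group memberships.
#' @export
compositionGroups <- function(clustering, k) {
  cutree(clustering$hc, k = k)
}

#' Serialise a composition dendrogram as Newick with merge heights
#'
#' @param clustering result of \code{\link{hierarchicalCluster}}.
#' @return Newick string (branch lengths reproduce merge heights).
#' @export
asNewick <- function(clustering) {
  phy <- ape::as.phylo(clustering$hc)
  ape::write.tree(phy)
}

#' Default composition-group centroids
#'
#' Four centroid profiles encoding the characteristic enrichments of the
#' major SEDC composition groups: glycine/serine-rich (loricrin-like),
#' glutamine/glutamate-rich (involucrin-like), G/S/C/P-rich (LCE-like)
#' and P/C/Q-rich (SPRR-like). Each centroid is a 20-dimensional
#' percentage vector; residues not listed share the remainder uniformly.
#'
#' @return Matrix of four rows (named groups) by 20 residue columns,
#'   each row summing to 100.
#' @export
defaultCompositionProfiles <- function() {
  std <- colnames(aaComposition("ACDEFGHIKLMNPQRSTVWY"))
  mk <- function(spec) {
    v <- setNames(rep(0, 20), std)
    v[names(spec)] <- spec
    rest <- setdiff(std, names(spec))
    v[rest] <- (100 - sum(spec)) / length(rest)
    v
  }
  rbind(
    "GS-rich (loricrin-like)"   = mk(c(G = 35, S = 25, C = 5)),
    "QE-rich (involucrin-like)" = mk(c(Q = 30, E = 25, L = 8)),
    "GSCP-rich (LCE-like)"      = mk(c(G = 18, S = 18, C = 12, P = 12)),
    "PCQ-rich (SPRR-like)"      = mk(c(P = 20, C = 15, Q = 15, K = 8)))
}

#' Assign a composition vector to the nearest centroid group
#'
#' @param vector single composition vector (20 percentages, named by
#'   residue) or 1-row matrix.
#' @param profiles centroid matrix, rows named by group
#'   (\code{\link{defaultCompositionProfiles}} by default).
#' @param metric distance metric (matching the clustering metric).
#' @return The winning group label, with attributes \code{"distance"}
#'   (distances to every centroid) and \code{"tie"} (TRUE when the
#'   minimum is shared; ties resolve to the lexicographically smallest
#'   label).
#' @export
assignCompositionGroup <- function(vector,
                                   profiles = defaultCompositionProfiles(),
                                   metric = "euclidean") {
  v <- as.numeric(vector)
  if (length(v) != ncol(profiles))
    .stopf("edc_parameter_error", "composition vector must have %d entries",
           ncol(profiles))
  d <- apply(profiles, 1, function(p)
    if (metric == "euclidean") sqrt(sum((p - v)^2)) else sum(abs(p - v)))
  dmin <- min(d)
  winners <- sort(names(d)[abs(d - dmin) < 1e-9])
  structure(winners[1], distance = d, tie = length(winners) > 1)
}

#' Detect tandem quasi-repeats in a protein segment
#'
#' Periods are found by self-comparison: the segment is compared with
#' itself shifted by p residues, and a period is reported when the
#' shifted identity reaches \code{min_identity} over at least
#' \code{min_copies} copies. Multiples of a true period also qualify; the
#' smallest reported period is the fundamental one.
#'
#' @param segment protein segment (length >= 2 * \code{min_period}).
#' @param protein_id id recorded in the report.
#' @param min_period,max_period period search range (residues).
#' @param min_copies minimum number of repeat copies spanned.
#' @param min_identity minimum shifted self-identity.
#' @return data.frame with columns \code{protein_id}, \code{period},
#'   \code{start}, \code{end} (1-based repeat span), \code{identity};
#'   zero rows when nothing qualifies. The detection method is recorded
#'   in attribute \code{"method"}.
#' @export
detectTandemRepeats <- function(segment, protein_id = "segment",
                                min_period = 2, max_period = NULL,
                                min_copies = 3, min_identity = 0.8) {
  n <- nchar(segment)
  if (n < 2 * min_period)
    .stopf("edc_parameter_error",
           "segment (%d aa) shorter than 2 * min_period", n)
  if (is.null(max_period)) max_period <- n %/% min_copies
  ch <- strsplit(segment, "")[[1]]
  rows <- list()
  for (p in seq(min_period, max(min_period, max_period))) {
    if (n < p * min_copies) break
    eq <- ch[seq_len(n - p)] == ch[seq(p + 1, n)]
    ident <- mean(eq)
    if (ident >= min_identity) {
      w <- which(eq)
      rows[[length(rows) + 1]] <- data.frame(
        protein_id = protein_id, period = p,
        start = w[1], end = min(n, w[length(w)] + p),
        identity = ident, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(protein_id = character(), period = integer(),
                         start = integer(), end = integer(),
                         identity = numeric(), stringsAsFactors = FALSE)
  attr(out, "method") <- "shifted-self-identity"
  out
}
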