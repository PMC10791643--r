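#' Reciprocal best hits between two protein sets
#'
#' A pair (a, b) is reported iff b is a's unique best-scoring partner and
#' a is b's unique best-scoring partner. Score ties for the best partner
#' disqualify the gene (no reciprocal best hit; the ambiguity is
#' reported).
#'
#' @param proteins_a,proteins_b named character vectors of protein
#'   sequences, or \code{NULL} when \code{scores} is supplied.
#' @param scores optional precomputed score matrix (rows = set A,
#'   columns = set B); by default global alignment scores are computed.
#' @param scorer \code{"global"} (affine global alignment score) or a
#'   function(a, b) returning a score.
#' @return data.frame with columns \code{a}, \code{b}; ambiguous (tied)
#'   genes are listed in attribute \code{"ambiguous"}.
#' @export
reciprocalBestHits <- function(proteins_a = NULL, proteins_b = NULL,
                               scores = NULL, scorer = "global") {
  if (is.null(scores)) {
    stopifnot(!is.null(proteins_a), !is.null(proteins_b))
    fn <- if (is.function(scorer)) scorer else .globalScore
    scores <- matrix(0, length(proteins_a), length(proteins_b),
                     dimnames = list(names(proteins_a),
                                     names(proteins_b)))
    for (i in seq_along(proteins_a))
      for (j in seq_along(proteins_b))
        scores[i, j] <- fn(proteins_a[[i]], proteins_b[[j]])
  }
  an <- rownames(scores); bn <- colnames(scores)
  best_b_of_a <- vector("list", nrow(scores))
  for (i in seq_len(nrow(scores)))
    best_b_of_a[[i]] <- which(scores[i, ] == max(scores[i, ]))
  best_a_of_b <- vector("list", ncol(scores))
  for (j in seq_len(ncol(scores)))
    best_a_of_b[[j]] <- which(scores[, j] == max(scores[, j]))
  pairs <- list(); ambiguous <- character()
  for (i in seq_len(nrow(scores))) {
    bb <- best_b_of_a[[i]]
    if (length(bb) != 1) { ambiguous <- c(ambiguous, an[i]); next }
    aa <- best_a_of_b[[bb]]
    if (length(aa) != 1) { ambiguous <- c(ambiguous, bn[bb]); next }
    if (aa == i)
      pairs[[length(pairs) + 1]] <- data.frame(a = an[i], b = bn[bb],
                                               stringsAsFactors = FALSE)
  }
  out <- if (length(pairs)) do.call(rbind, pairs)
         else data.frame(a = character(), b = character(),
                         stringsAsFactors = FALSE)
  attr(out, "ambiguous") <- unique(ambiguous)
  out
}

# ordered gene table (symbol, strand) from an annotation list
.geneOrder <- function(annotations) {
  if (is.data.frame(annotations)) return(annotations)
  df <- data.frame(
    symbol = vapply(annotations, geneSymbol, ""),
    strand = vapply(annotations, function(a) a@strand, ""),
    seqid = vapply(annotations, function(a) a@seqid, ""),
    start = vapply(annotations, function(a) min(a@exons), 0),
    stringsAsFactors = FALSE)
  df[order(df$seqid, df$start), , drop = FALSE]
}

#' Shared-neighbor (local synteny) score for a gene pair
#'
#' Counts gene symbols shared between the neighborhoods of the two genes
#' (up to \code{window} genes on each side), orientation-aware: when the
#' two genes lie on opposite strands relative to their loci, the left and
#' right neighborhoods of the second locus are swapped before comparison.
#'
#' @param gene_a,gene_b gene symbols.
#' @param annotations_a,annotations_b annotation lists (or precomputed
#'   order data.frames with \code{symbol} and \code{strand} columns).
#' @param window neighborhood size per side.
#' @return Integer shared-neighbor count (maximum \code{2 * window}).
#' @export
localSyntenyScore <- function(gene_a, gene_b, annotations_a,
                              annotations_b, window = 3) {
  oa <- .geneOrder(annotations_a)
  ob <- .geneOrder(annotations_b)
  ia <- which(oa$symbol == gene_a)
  ib <- which(ob$symbol == gene_b)
  if (length(ia) != 1 || length(ib) != 1)
    .stopf("edc_parameter_error",
           "genes must be present exactly once in their loci")
  nb <- function(ord, i) {
    left <- ord$symbol[seq_len(i - 1)]
    left <- tail(left, window)
    right <- ord$symbol[seq(i + 1, length.out = min(window,
                                                    nrow(ord) - i))]
    list(left = left, right = right)
  }
  na_ <- nb(oa, ia); nb_ <- nb(ob, ib)
  inverted <- oa$strand[ia] != ob$strand[ib]
  if (inverted) nb_ <- list(left = rev(nb_$right), right = rev(nb_$left))
  length(intersect(na_$left, nb_$left)) +
    length(intersect(na_$right, nb_$right))
}

#' Call orthology between the genes of two loci
#'
#' Combines three evidence streams -- reciprocal best hits, shared local
#' synteny, and supported phylogenetic groups -- under the rule that no
#' single criterion suffices. A one-to-one call requires a reciprocal
#' best hit plus concordant synteny (>= \code{synteny_threshold}) or a
#' minimal supported phylogenetic group containing exactly the two genes.
#' A gene whose minimal supported cross-locus group contains more than
#' two members is called a co-ortholog group over that group, never
#' one-to-one. Phylogenetic evidence is optional ("if available"): when
#' no groups are supplied, calls rest on RBH + synteny alone.
#'
#' @param rbh data.frame from \code{\link{reciprocalBestHits}}.
#' @param annotations_a,annotations_b annotation lists or order
#'   data.frames (for synteny).
#' @param phylo_groups optional list of leaf sets
#'   (\code{\link{phyloGroups}}); leaves are locus-qualified gene
#'   symbols, \code{"a:<symbol>"} for locus A and \code{"b:<symbol>"}
#'   for locus B, so the same symbol in both loci stays
#'   distinguishable.
#' @param genes_a,genes_b gene symbol vectors; default all genes of the
#'   respective locus order.
#' @param synteny_threshold minimum shared-neighbor count.
#' @param window synteny window.
#' @return data.frame with columns \code{gene_a}, \code{gene_b} (comma
#'   separated for groups), \code{relation} (\code{one_to_one},
#'   \code{co_ortholog_group}, \code{none}) and \code{evidence} (comma
#'   separated subset of phylo_group, synteny, reciprocal_best).
#' @export
callOrthologs <- function(rbh, annotations_a, annotations_b,
                          phylo_groups = NULL, genes_a = NULL,
                          genes_b = NULL, synteny_threshold = 2,
                          window = 3) {
  oa <- .geneOrder(annotations_a)
  ob <- .geneOrder(annotations_b)
  if (is.null(genes_a)) genes_a <- oa$symbol
  if (is.null(genes_b)) genes_b <- ob$symbol
  rbh_of <- setNames(rbh$b, rbh$a)
  # phylo group leaves are locus-qualified ("a:<symbol>" / "b:<symbol>")
  # so the same symbol in both loci stays distinguishable
  qa <- paste0("a:", genes_a); qb <- paste0("b:", genes_b)
  minimalGroup <- function(g) {
    # smallest supported group containing g and at least one cross gene
    if (is.null(phylo_groups)) return(NULL)
    cand <- Filter(function(s) paste0("a:", g) %in% s &&
                     length(intersect(s, qa)) >= 1 &&
                     length(intersect(s, qb)) >= 1, phylo_groups)
    if (!length(cand)) return(NULL)
    cand[[order(vapply(cand, length, 0))[1]]]
  }
  rows <- list()
  for (g in genes_a) {
    grp <- minimalGroup(g)
    if (!is.null(grp) && length(intersect(grp, c(qa, qb))) > 2) {
      partners <- sort(sub("^b:", "", intersect(grp, qb)))
      ev <- "phylo_group"
      if (g %in% names(rbh_of) && rbh_of[[g]] %in% partners)
        ev <- c(ev, "reciprocal_best")
      rows[[length(rows) + 1]] <- data.frame(
        gene_a = g, gene_b = paste(partners, collapse = ","),
        relation = "co_ortholog_group",
        evidence = paste(ev, collapse = ","), stringsAsFactors = FALSE)
      next
    }
    if (g %in% names(rbh_of)) {
      b <- rbh_of[[g]]
      ev <- "reciprocal_best"
      syn <- tryCatch(localSyntenyScore(g, b, oa, ob, window),
                      error = function(e) 0)
      if (syn >= synteny_threshold) ev <- c(ev, "synteny")
      pair_group <- !is.null(grp) &&
        length(intersect(grp, c(qa, qb))) == 2 && paste0("b:", b) %in% grp
      if (pair_group) ev <- c(ev, "phylo_group")
      if (syn >= synteny_threshold || pair_group) {
        rows[[length(rows) + 1]] <- data.frame(
          gene_a = g, gene_b = b, relation = "one_to_one",
          evidence = paste(ev, collapse = ","), stringsAsFactors = FALSE)
        next
      }
    }
    rows[[length(rows) + 1]] <- data.frame(
      gene_a = g, gene_b = "", relation = "none", evidence = "",
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Detect locus splits and orientation changes between two gene orders
#'
#' Decomposes the shared gene content of two loci into maximal
#' common-order segments (allowing whole-segment reversal), then reports
#' the breakpoints, each segment's relative orientation, and which
#' segment retains which flanking marker gene. Genes private to one locus
#' (e.g. non-EDC spacer genes inserted at a split) are ignored for
#' segment building but delimit breakpoints.
#'
#' @param order_a,order_b gene orders: data.frames with \code{symbol} and
#'   \code{strand} columns (or annotation lists).
#' @param flanks character vector of the two flanking marker symbols
#'   (5' flank first).
#' @return List of class \code{"rearrangement_report"} with elements
#'   \code{segments} (list of data.frames with the paired positions and
#'   an \code{orientation} attribute), \code{events} (data.frame of
#'   split/inversion events with breakpoint symbols), \code{breakpoints},
#'   and \code{flank_assignment}.
#' @export
detectLocusRearrangement <- function(order_a, order_b,
                                     flanks = c("S100A9", "S100A11")) {
  oa <- .geneOrder(order_a)
  ob <- .geneOrder(order_b)
  shared <- intersect(oa$symbol, ob$symbol)
  a_idx <- which(oa$symbol %in% shared)
  pos_in_a <- setNames(seq_along(a_idx), oa$symbol[a_idx])
  b_shared <- which(ob$symbol %in% shared)
  segs <- list()
  cur <- NULL
  dirn <- 0
  gap_before <- FALSE
  prev_b <- NULL
  for (bi in seq_along(ob$symbol)) {
    sym <- ob$symbol[bi]
    if (!(sym %in% shared)) {
      if (!is.null(cur)) gap_before <- TRUE
      next
    }
    pa <- pos_in_a[[sym]]
    extend <- FALSE
    if (!is.null(cur) && !gap_before) {
      step <- pa - prev_b
      if (dirn == 0 && abs(step) == 1) { dirn <- step; extend <- TRUE }
      else if (dirn != 0 && step == dirn) extend <- TRUE
    }
    if (extend) {
      cur <- rbind(cur, data.frame(symbol = sym, a_pos = pa, b_pos = bi,
                                   stringsAsFactors = FALSE))
    } else {
      if (!is.null(cur)) segs[[length(segs) + 1]] <-
          list(genes = cur, dir = dirn)
      cur <- data.frame(symbol = sym, a_pos = pa, b_pos = bi,
                        stringsAsFactors = FALSE)
      dirn <- 0
    }
    prev_b <- pa
    gap_before <- FALSE
  }
  if (!is.null(cur)) segs[[length(segs) + 1]] <- list(genes = cur,
                                                      dir = dirn)
  # orientation per segment: +1 traverses locus A forward, -1 reversed;
  # strand agreement is the tie-break for single-gene segments
  seg_dfs <- lapply(segs, function(s) {
    d <- s$dir
    if (d == 0) {
      sym <- s$genes$symbol[1]
      d <- if (oa$strand[oa$symbol == sym][1] ==
               ob$strand[ob$symbol == sym][1]) 1 else -1
    }
    structure(s$genes, orientation = if (d > 0) "same" else "inverted")
  })
  # reference orientation: the segment holding the 5' flank
  flank_seg <- vapply(flanks, function(f)
    which(vapply(seg_dfs, function(s) f %in% s$symbol, TRUE))[1],
    0)
  ref_or <- if (!is.na(flank_seg[1]))
    attr(seg_dfs[[flank_seg[1]]], "orientation") else "same"
  # events are keyed in locus-A coordinates so the same ancestral event
  # detected in different species carries the same breakpoint symbols
  events <- list()
  if (length(seg_dfs) > 1) {
    by_a <- order(vapply(seg_dfs, function(s) min(s$a_pos), 0))
    for (k in seq_len(length(by_a) - 1)) {
      left <- seg_dfs[[by_a[k]]]; right <- seg_dfs[[by_a[k + 1]]]
      events[[length(events) + 1]] <- data.frame(
        type = "split",
        after_symbol = left$symbol[which.max(left$a_pos)],
        before_symbol = right$symbol[which.min(right$a_pos)],
        stringsAsFactors = FALSE)
    }
  }
  for (k in seq_along(seg_dfs)) {
    if (attr(seg_dfs[[k]], "orientation") != ref_or) {
      s <- seg_dfs[[k]]
      events[[length(events) + 1]] <- data.frame(
        type = "inversion",
        after_symbol = s$symbol[which.min(s$a_pos)],
        before_symbol = s$symbol[which.max(s$a_pos)],
        stringsAsFactors = FALSE)
    }
  }
  events_df <- if (length(events)) do.call(rbind, events)
               else data.frame(type = character(),
                               after_symbol = character(),
                               before_symbol = character(),
                               stringsAsFactors = FALSE)
  breakpoints <- if (length(seg_dfs) > 1)
    lapply(seq_len(length(seg_dfs) - 1), function(k) {
      left <- seg_dfs[[k]]; right <- seg_dfs[[k + 1]]
      list(a = c(after = left$symbol[nrow(left)],
                 before = right$symbol[1]),
           b = c(after = ob$symbol[max(left$b_pos)],
                 before = ob$symbol[min(right$b_pos)]))
    }) else list()
  structure(list(
    segments = seg_dfs,
    events = events_df,
    breakpoints = breakpoints,
    flank_assignment = setNames(flank_seg, flanks),
    n_segments = length(seg_dfs)),
    class = "rearrangement_report")
}

#' @export
print.rearrangement_report <- function(x, ...) {
  cat(sprintf("Rearrangement report: %d segment(s), %d event(s)\n",
              x$n_segments, nrow(x$events)))
  if (nrow(x$events)) print(x$events)
  invisible(x)
}

#' Place rearrangement events on a species tree by Dollo parsimony
#'
#' Each event is assigned to the edge above the smallest clade containing
#' every species that exhibits it (the rearranged state is assumed to
#' arise once and never revert).
#'
#' @param reports named list of \code{\link{detectLocusRearrangement}}
#'   reports, one per species compared against the same reference locus.
#' @param tree species tree (\code{"phylo"} or Newick text) containing
#'   the report names as tips.
#' @return data.frame with columns \code{type}, \code{clade}
#'   (comma-separated species above whose stem edge the event sits) and
#'   \code{species} (which species exhibit it).
#' @export
placeEventsOnTree <- function(reports, tree) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  evkey <- function(e) paste(e$type, e$after_symbol, e$before_symbol)
  all_ev <- list()
  for (sp in names(reports)) {
    ev <- reports[[sp]]$events
    for (k in seq_len(nrow(ev))) {
      key <- evkey(ev[k, ])
      if (is.null(all_ev[[key]]))
        all_ev[[key]] <- list(row = ev[k, ], species = character())
      all_ev[[key]]$species <- c(all_ev[[key]]$species, sp)
    }
  }
  rows <- list()
  for (key in names(all_ev)) {
    sp <- all_ev[[key]]$species
    clade <- if (length(sp) == 1) sp
    else {
      node <- ape::getMRCA(tree, sp)
      sort(.cladeTips(tree, node))
    }
    rows[[length(rows) + 1]] <- data.frame(
      type = all_ev[[key]]$row$type,
      after_symbol = all_ev[[key]]$row$after_symbol,
      before_symbol = all_ev[[key]]$row$before_symbol,
      clade = paste(sort(clade), collapse = ","),
      species = paste(sort(sp), collapse = ","),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(type = character(), after_symbol = character(),
                      before_symbol = character(), clade = character(),
                      species = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
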