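#' Parameters for the translated seed-and-extend search
#'
#' Defaults follow common translated-search practice: BLOSUM62, gap open
#' 11 / extend 1, word length 3 with a word-score (neighborhood) threshold
#' of 11. There is deliberately no low-complexity filter anywhere in the
#' search: the proteins this package targets are low-complexity by nature,
#' and masking them is exactly what must not happen. Raw alignment scores
#' replace E-values (a single locus has no database-size semantics); hits
#' below \code{min_score} are not reported.
#'
#' @param seed_length word length k for seeding.
#' @param neighborhood_threshold minimum word score for a seed match;
#'   \code{-Inf} guarantees a seed at every position (full sensitivity,
#'   used by the search-oracle equivalence checks).
#' @param min_score minimum raw score of a reported hit.
#' @param gap_open,gap_ext affine gap penalties (a gap of length L costs
#'   \code{gap_open + L * gap_ext}).
#' @param x_drop reserved extension-pruning margin; \code{Inf} (the
#'   default) extends exhaustively within each seeded window.
#' @param max_hsps maximum number of distinct alignments reported per
#'   seeded window.
#' @param two_hit_dist maximum diagonal distance between two word hits
#'   for a seed to be confirmed (the classic two-hit rule; ignored in
#'   guaranteed-seed mode).
#' @param ungapped_trigger minimum ungapped X-drop extension score for a
#'   confirmed seed to open a gapped extension window (0 disables the
#'   ungapped stage).
#' @param ungapped_xdrop X-drop margin of the ungapped extension.
#' @param window_gap seed clusters further apart than this (residues, on
#'   the frame translation) open separate extension windows.
#' @param window_margin residues added around a seed cluster when carving
#'   the extension window.
#' @return Named list of parameters.
#' @export
searchParams <- function(seed_length = 3, neighborhood_threshold = 11,
                         min_score = 60, gap_open = 11, gap_ext = 1,
                         x_drop = Inf, max_hsps = 10, two_hit_dist = 40,
                         ungapped_trigger = 40, ungapped_xdrop = 16,
                         window_gap = 300, window_margin = 30) {
  list(seed_length = as.integer(seed_length),
       neighborhood_threshold = neighborhood_threshold,
       min_score = min_score, gap_open = gap_open, gap_ext = gap_ext,
       x_drop = x_drop, max_hsps = as.integer(max_hsps),
       two_hit_dist = as.integer(two_hit_dist),
       ungapped_trigger = ungapped_trigger,
       ungapped_xdrop = ungapped_xdrop,
       window_gap = as.integer(window_gap),
       window_margin = as.integer(window_margin))
}

# six strand/frame translations of a region, pre-encoded; cached by callers
.frameTable <- function(region_seq) {
  tr <- sixFrameTranslate(region_seq)
  lapply(seq_along(tr), function(i) {
    nm <- names(tr)[i]
    list(strand = substring(nm, 1, 1),
         frame = as.integer(substring(nm, 2, 2)),
         aa = tr[[i]], enc = .aaEncode(tr[[i]]))
  })
}

# map an aa interval [ts, te) in frame (strand, f) of a region of length L
# to forward-strand nucleotide coordinates (0-based half-open)
.aaToGenomic <- function(ts, te, strand, frame, L) {
  if (strand == "+") c(frame + 3 * ts, frame + 3 * te)
  else c(L - frame - 3 * te, L - frame - 3 * ts)
}

#' Translated homology search by seeding and gapped extension
#'
#' Finds local alignments of a protein query against all six reading
#' frames of a genomic region. Word seeds (length \code{seed_length},
#' word score >= \code{neighborhood_threshold}) trigger gapped affine
#' extension within a window around each seed cluster; extension within a
#' window is exhaustive, so with a guaranteed seed the reported score
#' equals the optimal local alignment score against that frame's
#' translation. No low-complexity masking is ever applied.
#'
#' @param query protein sequence (character string).
#' @param region \linkS4class{GenomicRegion} or plain DNA string.
#' @param params see \code{\link{searchParams}}.
#' @param query_id identifier recorded on hits.
#' @param frames optional precomputed frame table (internal reuse).
#' @param strands restrict search to these strands (default both).
#' @return List of \linkS4class{TranslatedHit}, sorted by score
#'   (descending), ties broken by leftmost genomic start then query id.
#'   Overlapping hits from the same query are merged to the best-scoring
#'   one.
#' @export
seededSearch <- function(query, region, params = searchParams(),
                         query_id = "query", frames = NULL,
                         strands = c("+", "-")) {
  if (nchar(query) < params$seed_length)
    .stopf("edc_parameter_error",
           "query (%d aa) shorter than seed length %d",
           nchar(query), params$seed_length)
  region_seq <- if (is(region, "GenomicRegion")) region@sequence
                else toupper(region)
  seqid <- if (is(region, "GenomicRegion")) region@seqid else "region"
  L <- nchar(region_seq)
  if (is.null(frames)) frames <- .frameTable(region_seq)
  qenc <- .aaEncode(query)
  qlen <- length(qenc)
  sub <- .subMatrix()
  maskIdx <- length(.aaLetters()) - 1L
  hits <- list()
  for (fr in frames) {
    if (!(fr$strand %in% strands)) next
    tlen <- length(fr$enc)
    if (tlen < params$seed_length) next
    wins <- cpp_seed_windows(qenc, fr$enc, sub, params$seed_length,
                             params$neighborhood_threshold,
                             params$two_hit_dist,
                             is.finite(params$neighborhood_threshold),
                             params$window_gap, params$window_margin,
                             params$ungapped_trigger,
                             params$ungapped_xdrop)
    if (!nrow(wins)) next
    for (ci in seq_len(nrow(wins))) {
      w0 <- wins[ci, 1]; w1 <- wins[ci, 2]
      tw <- fr$enc[(w0 + 1):w1]
      for (rep in seq_len(params$max_hsps)) {
        res <- cpp_local_align(qenc, tw, sub, params$gap_open,
                               params$gap_ext)
        if (res$score < params$min_score) break
        qi <- res$qidx; ti <- res$tidx
        both <- qi >= 0 & ti >= 0
        matches <- sum(qenc[qi[both] + 1] == tw[ti[both] + 1])
        ident <- matches / length(qi)
        ts <- w0 + res$tstart; te <- w0 + res$tend
        g <- .aaToGenomic(ts, te, fr$strand, fr$frame, L)
        hits[[length(hits) + 1]] <- new("TranslatedHit",
          query_id = query_id, seqid = seqid, strand = fr$strand,
          frame = fr$frame, t_start = g[1], t_end = g[2],
          q_start = res$qstart, q_end = res$qend,
          score = res$score, identity = ident,
          qidx = as.integer(qi),
          tidx = as.integer(ifelse(ti >= 0, ti + w0, -1L)),
          aa_t_start = as.integer(ts))
        tw[(res$tstart + 1):res$tend] <- maskIdx
      }
    }
  }
  .mergeHits(hits)
}

# keep best-scoring hit among same-strand hits whose genomic footprints
# overlap substantially; deterministic order: score desc, leftmost, query
.mergeHits <- function(hits, overlap_frac = 0.25) {
  if (!length(hits)) return(list())
  o <- order(-vapply(hits, function(h) h@score, 0),
             vapply(hits, function(h) h@t_start, 0),
             vapply(hits, function(h) h@query_id, ""))
  hits <- hits[o]
  kept <- list()
  for (h in hits) {
    dup <- FALSE
    for (k in kept) {
      if (k@strand != h@strand || k@seqid != h@seqid) next
      ov <- min(k@t_end, h@t_end) - max(k@t_start, h@t_start)
      shorter <- min(k@t_end - k@t_start, h@t_end - h@t_start)
      if (ov > overlap_frac * shorter) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1]] <- h
  }
  kept
}
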