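#' Parameters for gene-model construction
#'
#' @param max_orf_extension maximum distance (nt) the open reading frame
#'   is extended beyond a hit when searching for start/stop codons.
#' @param splice_donor,splice_acceptor canonical splice dinucleotides;
#'   only the GT--AG dialect is modelled.
#' @param upstream_scan_window window (nt) upstream of the start codon
#'   scanned for an acceptor AG implying a 5' non-coding exon.
#' @param junction_window slack (nt) around the query-implied exon
#'   junction when searching for splice sites of 2-coding-exon genes.
#' @param intron_range admissible intron length range (nt).
#' @param flank_window sequence (nt) kept around a hit when re-locating
#'   the partner coding exon of a 2-exon gene.
#' @return Named parameter list.
#' @export
modelParams <- function(max_orf_extension = 9000, splice_donor = "GT",
                        splice_acceptor = "AG", upstream_scan_window = 200,
                        junction_window = 45, intron_range = c(50, 10000),
                        flank_window = 20000) {
  list(max_orf_extension = max_orf_extension, splice_donor = splice_donor,
       splice_acceptor = splice_acceptor,
       upstream_scan_window = upstream_scan_window,
       junction_window = junction_window, intron_range = intron_range,
       flank_window = flank_window)
}

# parse 'class=SFTP junction=93' style metadata tokens from a FASTA
# description string
.parseQueryMeta <- function(desc) {
  out <- list(class = NA_character_, junction = NA_integer_)
  if (is.null(desc) || is.na(desc) || !nzchar(desc)) return(out)
  toks <- strsplit(trimws(desc), "\\s+")[[1]]
  kv <- strsplit(toks, "=", fixed = TRUE)
  for (p in kv) {
    if (length(p) != 2) next
    if (p[1] == "class") out$class <- p[2]
    if (p[1] == "junction") out$junction <- as.integer(p[2])
  }
  out
}

# hit footprint in strand-oriented coordinates of the full region
.hitStrandCoords <- function(hit, L) {
  if (hit@strand == "+") c(hit@t_start, hit@t_end)
  else c(L - hit@t_end, L - hit@t_start)
}

# collect in-frame ATG positions walking upstream from pos (stopping at a
# stop codon or the extension limit) and return the one closest to the
# position the query alignment projects for the start codon; ties go to
# the more upstream candidate
.chooseStart <- function(S, pos, expected, max_ext) {
  cand <- integer()
  p <- pos
  lim <- max(pos %% 3, pos - max_ext)
  while (p >= lim) {
    cod <- substring(S, p + 1, p + 3)
    if (cod %in% c("TAA", "TAG", "TGA")) break
    if (cod == "ATG") cand <- c(cand, p)
    p <- p - 3
  }
  if (!length(cand)) return(NA_integer_)
  cand[order(abs(cand - expected), cand)][1]
}

# scan downstream (in-frame) from pos for the first stop codon; returns
# position after the stop codon, or NA
.scanStop <- function(S, pos, max_ext) {
  L <- nchar(S)
  p <- pos
  lim <- min(L - 3, pos + max_ext)
  while (p <= lim) {
    cod <- substring(S, p + 1, p + 3)
    if (cod %in% c("TAA", "TAG", "TGA")) return(p + 3)
    p <- p + 3
  }
  NA_integer_
}

# nearest occurrence of dinucleotide `dn` ending at a position b with
# b %% 3 == phase, searched within [lo, hi]; returns end position b or NA
.nearestDinuc <- function(S, dn, center, window, phase, after = FALSE) {
  lo <- max(2, center - window)
  hi <- min(nchar(S), center + window)
  cand <- integer()
  for (b in seq(lo, hi)) {
    if (b %% 3 == phase && substring(S, b - 1, b) == dn)
      cand <- c(cand, b)
  }
  if (!length(cand)) return(NA_integer_)
  cand[order(abs(cand - center), cand)][1]
}

# expected strand-oriented nt position of query aa position q (0-based)
# extrapolated from a hit's alignment
.projectQueryPos <- function(hit, q, L) {
  qi <- hit@qidx; ti <- hit@tidx
  both <- which(qi >= 0 & ti >= 0)
  qa <- qi[both]; ta <- ti[both]
  # anchor on the aligned pair closest to q
  k <- which.min(abs(qa - q))
  aa_t <- ta[k] + (q - qa[k])
  if (hit@strand == "+") hit@frame + 3 * aa_t
  else {
    # ti holds frame-translation indices of the reverse strand, which are
    # already strand-oriented positions
    hit@frame + 3 * aa_t
  }
}

#' Build an exon-structured gene model from a translated hit
#'
#' Extends the hit to the nearest in-frame start codon upstream and stop
#' codon downstream. For queries annotated as 2-coding-exon genes (SFTP /
#' S100A, \code{class=}/\code{junction=} metadata), a GT..AG intron is
#' sought at the position homologous to the query's coding-exon junction
#' (phase-0 junctions are assumed). A 5' non-coding exon is modelled as
#' the acceptor-AG-to-ATG stretch when an AG lies within
#' \code{upstream_scan_window} of the start codon; otherwise the model is
#' flagged \code{missing_utr_exon}. Models that lack a start or stop
#' codon within the extension window are flagged \code{incomplete}, never
#' silently truncated.
#'
#' @param hit a \linkS4class{TranslatedHit}.
#' @param region the searched \linkS4class{GenomicRegion} or DNA string.
#' @param params see \code{\link{modelParams}}.
#' @param query the query protein sequence (needed for 2-exon models).
#' @param query_meta list with \code{class} and \code{junction} (aa length
#'   of the query's first coding exon), as parsed from query FASTA
#'   descriptions.
#' @param search_params passed to the internal exon re-location search.
#' @param gene_id identifier for the resulting model.
#' @return A \linkS4class{GeneModel}.
#' @export
buildGeneModel <- function(hit, region, params = modelParams(),
                           query = NULL, query_meta = list(),
                           search_params = searchParams(),
                           gene_id = "gene") {
  region_seq <- if (is(region, "GenomicRegion")) region@sequence
                else toupper(region)
  seqid <- if (is(region, "GenomicRegion")) region@seqid else "region"
  L <- nchar(region_seq)
  S <- if (hit@strand == "+") region_seq else .revCompChr(region_seq)
  two_exon <- !is.null(query_meta$class) && !is.na(query_meta$class) &&
    query_meta$class %in% c("SFTP", "S100A") &&
    !is.null(query_meta$junction) && !is.na(query_meta$junction) &&
    !is.null(query)
  if (two_exon) {
    m <- .buildTwoExonModel(hit, S, L, params, query,
                            query_meta$junction, search_params)
  } else {
    m <- .buildSingleExonModel(hit, S, L, params)
  }
  .finishModel(m, hit, S, L, seqid, params, gene_id)
}

# single coding exon: in-frame ORF extension around the hit; the start
# codon is the in-frame ATG closest to the position homologous to the
# query's first residue
.buildSingleExonModel <- function(hit, S, L, params) {
  sc <- .hitStrandCoords(hit, L)
  h0 <- sc[1]
  flags <- character()
  expected <- .projectQueryPos(hit, 0L, L)
  atg <- .chooseStart(S, h0, expected, params$max_orf_extension)
  if (is.na(atg)) { flags <- c(flags, "incomplete"); atg <- h0 }
  stop_end <- .scanStop(S, atg, params$max_orf_extension +
                          (sc[2] - atg))
  if (is.na(stop_end)) { flags <- c(flags, "incomplete"); stop_end <- sc[2] }
  list(coding = list(c(atg, stop_end)), atg = atg, flags = flags,
       junction = NA_integer_)
}

# two coding exons separated by a GT..AG intron at the query's junction
.buildTwoExonModel <- function(hit, S, L, params, query, junction,
                               search_params) {
  j <- as.integer(junction)
  qlen <- nchar(query)
  if (j <= 0 || j >= qlen)
    return(.buildSingleExonModel(hit, S, L, params))
  sc <- .hitStrandCoords(hit, L)
  w0 <- max(0, sc[1] - params$flank_window)
  w1 <- min(L, sc[2] + params$flank_window)
  sub_seq <- substring(S, w0 + 1, w1)
  q1 <- substring(query, 1, j)
  q2 <- substring(query, j + 1, qlen)
  sp <- search_params
  sp$min_score <- min(sp$min_score, 40)
  h1 <- seededSearch(q1, sub_seq, sp, query_id = "exon1", strands = "+")
  h2 <- seededSearch(q2, sub_seq, sp, query_id = "exon2", strands = "+")
  if (!length(h1) || !length(h2)) {
    m <- .buildSingleExonModel(hit, S, L, params)
    m$flags <- unique(c(m$flags, "incomplete"))
    return(m)
  }
  # anchor on the triggering hit so tandem gene copies in the window do
  # not hijack the model: prefer exon hits overlapping it, then pair the
  # nearest compatible upstream first-exon hit
  oh <- c(sc[1] - w0, sc[2] - w0)
  pickNear <- function(hs) {
    ovl <- vapply(hs, function(h)
      min(h@t_end, oh[2]) - max(h@t_start, oh[1]), 0)
    if (any(ovl > 0)) hs[[which(ovl > 0)[1]]] else hs[[1]]
  }
  h2 <- pickNear(h2)
  cand1 <- Filter(function(h)
    h@t_end <= h2@t_start + 9 &&
      h2@t_start - h@t_end <= params$intron_range[2] + 3 * j + 100, h1)
  h1 <- if (length(cand1)) cand1[[1]] else pickNear(h1)
  flags <- character()
  # second exon: acceptor AG at the projected start of query residue j
  e2 <- .projectQueryPos(h2, 0L, nchar(sub_seq))
  ag <- .nearestDinuc(sub_seq, params$splice_acceptor, e2,
                      params$junction_window, e2 %% 3)
  if (is.na(ag)) { flags <- c(flags, "missing_acceptor"); ag <- e2 }
  cds2_start <- ag
  stop_end <- .scanStop(sub_seq, cds2_start, params$max_orf_extension)
  if (is.na(stop_end)) {
    flags <- c(flags, "incomplete")
    stop_end <- min(nchar(sub_seq), h2@t_end - w0)
  }
  # first exon: ATG upstream, donor GT at the projected junction
  sc1 <- c(h1@t_start, h1@t_end)
  atg <- .chooseStart(sub_seq, sc1[1],
                      .projectQueryPos(h1, 0L, nchar(sub_seq)),
                      params$max_orf_extension)
  if (is.na(atg)) { flags <- c(flags, "incomplete"); atg <- sc1[1] }
  d <- .projectQueryPos(h1, j, nchar(sub_seq))
  gt <- .nearestDinuc(sub_seq, params$splice_donor, d + 2,
                      params$junction_window, (d + 2) %% 3)
  donor <- if (is.na(gt)) { flags <- c(flags, "missing_donor"); d }
           else gt - 2
  intron_len <- cds2_start - donor
  if (intron_len < params$intron_range[1] ||
      intron_len > params$intron_range[2])
    flags <- c(flags, "unusual_intron")
  if (donor <= atg || cds2_start <= donor) {
    m <- .buildSingleExonModel(hit, S, L, params)
    m$flags <- unique(c(m$flags, "incomplete"))
    return(m)
  }
  list(coding = list(c(w0 + atg, w0 + donor),
                     c(w0 + cds2_start, w0 + stop_end)),
       atg = w0 + atg, flags = flags,
       junction = as.integer((donor - atg) / 3))
}

# shared tail: UTR exon scan, translation, coordinate conversion
.finishModel <- function(m, hit, S, L, seqid, params, gene_id) {
  coding <- m$coding
  flags <- m$flags
  atg <- m$atg
  # 5' non-coding exon: nearest acceptor AG upstream of the start codon;
  # the AG-to-ATG stretch is modelled as the non-coding exon
  utr <- NULL
  if (atg > 2) {
    ws <- max(1, atg - params$upstream_scan_window + 1)  # 1-based
    seg <- substring(S, ws, atg)  # ends right before the ATG
    pos <- gregexpr(params$splice_acceptor, seg, fixed = TRUE)[[1]]
    if (pos[1] != -1) {
      starts0 <- ws + pos  # 0-based exon start right after each AG
      starts0 <- starts0[starts0 < atg]
      if (length(starts0)) utr <- c(max(starts0), atg)
    }
  }
  if (is.null(utr)) flags <- c(flags, "missing_utr_exon")
  cds_nt <- paste(vapply(coding, function(e)
    substring(S, e[1] + 1, e[2]), ""), collapse = "")
  prot <- .translateCds(cds_nt)
  prot <- sub("\\*$", "", prot)
  exon_list <- c(if (!is.null(utr)) list(utr), coding)
  coding_flags <- c(if (!is.null(utr)) FALSE, rep(TRUE, length(coding)))
  # convert strand coordinates to forward-region coordinates
  fwd <- lapply(exon_list, function(e) {
    if (hit@strand == "+") e else c(L - e[2], L - e[1])
  })
  o <- order(vapply(fwd, `[`, 0, 1))
  exm <- do.call(rbind, fwd)[o, , drop = FALSE]
  colnames(exm) <- c("start", "end")
  coding_flags <- coding_flags[o]
  # genomic context used by pseudogene detection: for 2-coding-exon
  # models the intron is spliced out (it would otherwise mimic a
  # frameshift) and the second exon runs on into downstream genomic
  # sequence so indels that truncated the model stay detectable
  if (length(coding) == 1) {
    ctx0 <- max(0, coding[[1]][1] - 3000)
    ctx1 <- min(L, coding[[1]][2] + 3000)
    ctx <- substring(S, ctx0 + 1, ctx1)
  } else {
    e1 <- coding[[1]]; e2 <- coding[[2]]
    ctx0 <- max(0, e1[1] - 999)  # keep the first exon's frame phase
    ctx <- paste0(substring(S, ctx0 + 1, e1[2]),
                  substring(S, e2[1] + 1, min(L, e2[2] + 3000)))
  }
  new("GeneModel", gene_id = gene_id, gene_symbol = gene_id,
      seqid = seqid, strand = hit@strand, exons = exm,
      coding = coding_flags, gene_class = "unknown",
      pseudogene_evidence = character(),
      metadata = list(context = ctx,
                      context_offset = ctx0, cds_seq = cds_nt),
      protein = prot, score = hit@score, source_query = hit@query_id,
      flags = unique(flags), junction = m$junction)
}

#' Classify a gene model into the four EDC gene classes
#'
#' Classification is a pure function of coding-exon count and protein
#' length: one coding exon is an SEDC gene; two coding exons encode either
#' an S100A protein or, when the segment after the S100 domain reaches
#' \code{sftp_min_cterm_len} residues, an S100 fused-type protein (SFTP);
#' more than three coding exons is PGLYRP-like; exactly three is left
#' unknown.
#'
#' @param model a \linkS4class{GeneModel} (or
#'   \linkS4class{GeneAnnotation} with a protein length supplied via
#'   \code{protein_length}).
#' @param sftp_min_cterm_len minimum post-S100-domain length (aa) for the
#'   SFTP call.
#' @param protein_length optional override of the protein length.
#' @return One of \code{"SEDC"}, \code{"SFTP"}, \code{"S100A"},
#'   \code{"PGLYRP"}, \code{"unknown"}.
#' @export
classifyGeneType <- function(model, sftp_min_cterm_len = 300,
                             protein_length = NULL) {
  nc <- sum(model@coding)
  if (nc < 1)
    .stopf("edc_parameter_error", "model has no coding exon")
  if (nc == 1) return("SEDC")
  if (nc == 3) return("unknown")
  if (nc >= 4) return("PGLYRP")
  plen <- if (!is.null(protein_length)) protein_length
          else if (is(model, "GeneModel")) nchar(model@protein)
          else sum(model@exons[model@coding, 2] -
                     model@exons[model@coding, 1]) %/% 3
  j <- if (is(model, "GeneModel") && !is.na(model@junction)) model@junction
       else {
         ce <- model@exons[model@coding, , drop = FALSE]
         first <- if (model@strand == "+") 1 else nrow(ce)
         as.integer((ce[first, 2] - ce[first, 1]) %/% 3)
       }
  if (plen - j >= sftp_min_cterm_len) "SFTP" else "S100A"
}

#' Flag pseudogenes by comparison with an intact reference protein
#'
#' A model is flagged \code{premature_stop} when an in-frame stop codon
#' interrupts the reading frame before 90\% of the reference protein
#' length is covered, and \code{frameshift} when covering the reference
#' requires a change of reading frame across the locus (the signature of
#' an indel of length not divisible by 3). Both flags can in principle
#' co-occur; an intact gene yields an empty set.
#'
#' @param model a \linkS4class{GeneModel} built by
#'   \code{\link{buildGeneModel}} (its genomic context travels with it).
#' @param reference intact reference protein of the same family.
#' @param coverage_threshold fraction of the reference that must be
#'   accounted for by a single reading frame before the gene is
#'   considered frame-intact.
#' @return Character vector: subset of
#'   \code{c("premature_stop", "frameshift")}.
#' @export
detectPseudogene <- function(model, reference, coverage_threshold = 0.9) {
  if (is.null(reference) || !nzchar(reference))
    .stopf("edc_parameter_error", "reference protein is empty")
  ctx <- model@metadata$context
  if (is.null(ctx))
    .stopf("edc_parameter_error", "model carries no genomic context")
  rlen <- nchar(reference)
  renc <- .aaEncode(chartr("*", "X", reference))
  sub <- .subMatrix()
  res <- lapply(0:2, function(f) {
    tr <- .translateFrame(ctx, f)
    if (!nzchar(tr)) return(NULL)
    tenc <- .aaEncode(tr)
    al <- cpp_local_align(renc, tenc, sub, 11, 1)
    if (is.null(al$qstart)) return(NULL)
    stop_idx <- match("*", .aaLetters()) - 1L
    qi <- al$qidx; ti <- al$tidx
    both <- which(qi >= 0 & ti >= 0)
    # stops well inside the aligned stretch (not ragged ends); the
    # strict variant trims further, for the two-frame case where the
    # extension overshoots an indel into shifted sequence
    inner <- both[seq_along(both) > 5 &
                    seq_along(both) <= length(both) - 5]
    deep <- both[seq_along(both) > 15 &
                   seq_along(both) <= length(both) - 15]
    list(cov = c(al$qstart, al$qend), score = al$score,
         has_stop = any(tenc[ti[inner] + 1] == stop_idx),
         has_stop_deep = any(tenc[ti[deep] + 1] == stop_idx))
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res)) return(character())
  covlen <- vapply(res, function(r) diff(r$cov), 0)
  best <- which.max(covlen)
  flags <- character()
  if (covlen[best] >= coverage_threshold * rlen) {
    if (res[[best]]$has_stop) flags <- c(flags, "premature_stop")
    return(flags)
  }
  # single frame does not cover the reference: look for a two-frame split
  if (length(res) >= 2) {
    o <- order(-covlen)
    a <- res[[o[1]]]; b <- res[[o[2]]]
    un <- max(a$cov[2], b$cov[2]) - min(a$cov[1], b$cov[1])
    ov <- max(0, min(a$cov[2], b$cov[2]) - max(a$cov[1], b$cov[1]))
    joint <- covlen[o[1]] + covlen[o[2]] - ov
    # frame-shifted low-complexity sequence keeps scoring weakly, so the
    # two frames' coverage intervals can overlap around the indel
    if (joint >= 0.85 * rlen && un >= 0.85 * rlen && ov <= 0.35 * rlen) {
      flags <- c(flags, "frameshift")
      if (a$has_stop_deep || b$has_stop_deep)
        flags <- c(flags, "premature_stop")
      return(flags)
    }
  }
  if (res[[best]]$has_stop) flags <- c(flags, "premature_stop")
  flags
}

#' Iterative gene discovery over a genomic region
#'
#' Runs the translated search with an initial protein query set, builds
#' gene models from the hits, then feeds newly discovered intact proteins
#' back as queries until a round adds no new non-overlapping model (or
#' \code{max_rounds} is reached). The output never contains two models
#' overlapping on the same strand: the higher-scoring model wins, ties
#' broken by leftmost coordinate then query id.
#'
#' @param queries named character vector of query proteins; FASTA
#'   descriptions (attribute \code{"description"}) may carry
#'   \code{class=}/\code{junction=} metadata used for 2-exon gene
#'   building.
#' @param region \linkS4class{GenomicRegion} or DNA string.
#' @param params search parameters (\code{\link{searchParams}}).
#' @param model_params builder parameters (\code{\link{modelParams}}).
#' @param max_rounds maximum number of search rounds.
#' @param min_protein_len minimum length for a discovered protein to be
#'   recycled as a query.
#' @return List of \linkS4class{GeneModel} sorted by genomic start, with
#'   deterministic ids \code{g001, g002, ...} and \code{gene_class}
#'   assigned by \code{\link{classifyGeneType}}. The number of rounds run
#'   is attached as attribute \code{"rounds"}.
#' @export
iterativeDiscovery <- function(queries, region, params = searchParams(),
                               model_params = modelParams(),
                               max_rounds = 5, min_protein_len = 30) {
  stopifnot(length(queries) >= 1)
  region_seq <- if (is(region, "GenomicRegion")) region@sequence
                else toupper(region)
  frames <- .frameTable(region_seq)
  desc <- attr(queries, "description")
  meta <- lapply(names(queries), function(id)
    .parseQueryMeta(if (!is.null(desc)) desc[id] else NULL))
  names(meta) <- names(queries)
  models <- list()
  pending <- names(queries)
  all_queries <- queries
  rounds <- 0L
  while (length(pending) && rounds < max_rounds) {
    rounds <- rounds + 1L
    # collect this round's hits from every pending query, then build
    # models in global score order so the strongest evidence defines
    # each locus before weaker cross-family hits can
    round_hits <- list()
    for (qid in pending) {
      q <- all_queries[[qid]]
      if (nchar(q) < params$seed_length) next
      hits <- seededSearch(q, region, params, query_id = qid,
                           frames = frames)
      round_hits <- c(round_hits, hits)
    }
    if (length(round_hits)) {
      o <- order(-vapply(round_hits, function(h) h@score, 0),
                 vapply(round_hits, function(h) h@t_start, 0),
                 vapply(round_hits, function(h) h@query_id, ""))
      round_hits <- round_hits[o]
    }
    new_models <- list()
    for (h in round_hits) {
      if (.coveredByModels(h, c(models, new_models))) next
      qid <- h@query_id
      m <- buildGeneModel(h, region, model_params,
                          query = all_queries[[qid]],
                          query_meta = meta[[qid]],
                          search_params = params)
      # discard stub models whose coding region collapsed to a sliver
      ce <- m@exons[m@coding, , drop = FALSE]
      if (sum(ce[, 2] - ce[, 1]) < 3 * min_protein_len) next
      new_models[[length(new_models) + 1]] <- m
    }
    added <- .mergeModels(models, new_models)
    if (!length(added$new)) break
    models <- added$all
    # recycle newly discovered intact proteins as next-round queries
    pending <- character()
    for (m in added$new) {
      p <- m@protein
      if (!nzchar(p) || grepl("*", p, fixed = TRUE)) next
      if (nchar(p) < min_protein_len) next
      qid <- paste0("disc_", length(all_queries) + 1L)
      all_queries[[qid]] <- p
      cls <- classifyGeneType(m)
      meta[[qid]] <- list(class = cls, junction = m@junction)
      pending <- c(pending, qid)
    }
  }
  models <- .sortModels(models)
  for (i in seq_along(models)) {
    models[[i]]@gene_id <- sprintf("g%03d", i)
    models[[i]]@gene_symbol <- models[[i]]@gene_id
    models[[i]]@gene_class <- classifyGeneType(models[[i]])
  }
  attr(models, "rounds") <- rounds
  models
}

.modelFootprint <- function(m) {
  ce <- m@exons[m@coding, , drop = FALSE]
  c(min(ce[, 1]), max(ce[, 2]))
}

.coveredByModels <- function(hit, models, frac = 0.5,
                             shadow_ratio = 1.5) {
  for (m in models) {
    fp <- .modelFootprint(m)
    ov <- min(fp[2], hit@t_end) - max(fp[1], hit@t_start)
    if (ov <= frac * (hit@t_end - hit@t_start)) next
    if (m@strand == hit@strand) return(TRUE)
    if (m@score >= shadow_ratio * hit@score) return(TRUE)
  }
  FALSE
}

# merge candidate models into the accepted set: same-strand overlapping
# models collapse to the best-scoring one (ties: leftmost, then query
# id); a model heavily overlapped by a much stronger opposite-strand
# model is its reverse-frame shadow (low-complexity coding sequence
# aligns to its own reverse complement) and is dropped too
.mergeModels <- function(existing, candidates, frac = 0.3,
                         shadow_frac = 0.5, shadow_ratio = 1.5) {
  pool <- c(existing, candidates)
  if (!length(pool)) return(list(all = list(), new = list()))
  o <- order(-vapply(pool, function(m) m@score, 0),
             vapply(pool, function(m) .modelFootprint(m)[1], 0),
             vapply(pool, function(m) m@source_query, ""))
  pool <- pool[o]
  kept <- list()
  for (m in pool) {
    fp <- .modelFootprint(m)
    dup <- FALSE
    for (k in kept) {
      if (k@seqid != m@seqid) next
      kfp <- .modelFootprint(k)
      ov <- min(fp[2], kfp[2]) - max(fp[1], kfp[1])
      if (k@strand == m@strand) {
        if (ov > frac * min(fp[2] - fp[1], kfp[2] - kfp[1])) {
          dup <- TRUE; break
        }
      } else {
        if (ov > shadow_frac * (fp[2] - fp[1]) &&
            k@score >= shadow_ratio * m@score) {
          dup <- TRUE; break
        }
      }
    }
    if (!dup) kept[[length(kept) + 1]] <- m
  }
  # suppress residual fragments: a much weaker model lying within
  # `merge_gap` nt of a strong one (either strand) is the leftover piece
  # or reverse-frame echo of the same (typically disrupted) gene, not an
  # independent gene; the score ratio protects genuine close neighbors
  merge_gap <- 1000; frag_ratio <- 0.3
  drop <- rep(FALSE, length(kept))
  for (i in seq_along(kept)) {
    if (drop[i]) next
    for (j in seq_along(kept)) {
      if (i == j || drop[j]) next
      a <- kept[[i]]; b <- kept[[j]]
      if (a@seqid != b@seqid) next
      if (b@score > frag_ratio * a@score) next
      fa <- .modelFootprint(a); fb <- .modelFootprint(b)
      gap <- max(fa[1], fb[1]) - min(fa[2], fb[2])
      if (gap <= merge_gap) drop[j] <- TRUE
    }
  }
  kept <- kept[!drop]
  old_keys <- vapply(existing, .modelKey, "")
  new <- Filter(function(m) !(.modelKey(m) %in% old_keys), kept)
  list(all = kept, new = new)
}

.modelKey <- function(m) {
  fp <- .modelFootprint(m)
  sprintf("%s:%s:%.0f-%.0f", m@seqid, m@strand, fp[1], fp[2])
}

.sortModels <- function(models) {
  if (!length(models)) return(models)
  o <- order(vapply(models, function(m) min(m@exons), 0),
             vapply(models, function(m) max(m@exons), 0))
  models[o]
}
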