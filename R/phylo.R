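#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment under BLOSUM62 with affine gap costs
#' (a gap of length L costs \code{gap_open + L * gap_ext}); terminal gaps
#' are penalised. Traceback is deterministic (match preferred over
#' insertion over deletion).
#'
#' @param a,b protein sequences.
#' @param gap_open,gap_ext affine gap penalties.
#' @return List with \code{aligned_a}, \code{aligned_b} (gapped strings of
#'   equal length) and \code{score}.
#' @export
pairwiseAlignGlobal <- function(a, b, gap_open = 11, gap_ext = 1) {
  if (!nzchar(a) || !nzchar(b))
    .stopf("edc_parameter_error", "sequences must be non-empty")
  ea <- .aaEncode(a); eb <- .aaEncode(b)
  res <- cpp_global_align(ea, eb, .subMatrix(), gap_open, gap_ext)
  aa <- .aaLetters()
  gapped <- function(enc, idx) {
    out <- rep("-", length(idx))
    out[idx >= 0] <- aa[enc[idx[idx >= 0] + 1] + 1]
    paste(out, collapse = "")
  }
  ga <- gapped(ea, res$qidx)
  gb <- gapped(eb, res$tidx)
  list(aligned_a = ga, aligned_b = gb, score = res$score)
}

# global alignment score only (no traceback); used by RBH scoring
.globalScore <- function(a, b, gap_open = 11, gap_ext = 1) {
  cpp_global_score(.aaEncode(a), .aaEncode(b), .subMatrix(),
                   gap_open, gap_ext)
}

# ---- progressive multiple alignment -------------------------------------

# k-mer distance between two sequences: 1 - shared kmers / possible kmers
.kmerDistance <- function(a, b, k = 3) {
  km <- function(s) {
    n <- nchar(s)
    if (n < k) return(character())
    substring(s, 1:(n - k + 1), k:n)
  }
  ka <- km(a); kb <- km(b)
  if (!length(ka) || !length(kb)) return(1)
  shared <- sum(pmin(table(ka)[intersect(names(table(ka)),
                                         names(table(kb)))],
                     table(kb)[intersect(names(table(ka)),
                                         names(table(kb)))]))
  1 - shared / min(length(ka), length(kb))
}

# profile-profile global alignment (Gotoh) with sum-of-pairs column
# scores; profiles are character matrices (rows = sequences, "-" = gap)
.profileAlign <- function(A, B, gap_open = 11, gap_ext = 1) {
  sub <- .subMatrix()
  aa <- .aaLetters()
  gapScore <- -4  # residue-vs-gap contribution inside column scoring
  encCol <- function(M, j) {
    ch <- M[, j]
    i <- match(ch, aa)
    i[ch == "-"] <- NA
    i
  }
  n <- ncol(A); m <- ncol(B)
  Aenc <- lapply(seq_len(n), function(j) encCol(A, j))
  Benc <- lapply(seq_len(m), function(j) encCol(B, j))
  colScore <- function(ca, cb) {
    tot <- 0; cnt <- 0
    for (x in ca) for (y in cb) {
      if (is.na(x) && is.na(y)) next
      tot <- tot + if (is.na(x) || is.na(y)) gapScore else sub[x, y]
      cnt <- cnt + 1
    }
    if (cnt == 0) 0 else tot / cnt
  }
  NEG <- -1e12
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  PM <- matrix(0L, n + 1, m + 1); PX <- PM; PY <- PM
  M[1, 1] <- 0
  for (i in 2:(n + 1)) { X[i, 1] <- -gap_open - gap_ext * (i - 1)
                         PX[i, 1] <- if (i == 2) 1L else 2L }
  for (j in 2:(m + 1)) { Y[1, j] <- -gap_open - gap_ext * (j - 1)
                         PY[1, j] <- if (j == 2) 1L else 2L }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- colScore(Aenc[[i - 1]], Benc[[j - 1]])
      xo <- M[i - 1, j] - gap_open - gap_ext
      xe <- X[i - 1, j] - gap_ext
      if (xo >= xe) { X[i, j] <- xo; PX[i, j] <- 1L }
      else { X[i, j] <- xe; PX[i, j] <- 2L }
      yo <- M[i, j - 1] - gap_open - gap_ext
      ye <- Y[i, j - 1] - gap_ext
      if (yo >= ye) { Y[i, j] <- yo; PY[i, j] <- 1L }
      else { Y[i, j] <- ye; PY[i, j] <- 2L }
      best <- M[i - 1, j - 1]; from <- 1L
      if (X[i - 1, j - 1] > best) { best <- X[i - 1, j - 1]; from <- 2L }
      if (Y[i - 1, j - 1] > best) { best <- Y[i - 1, j - 1]; from <- 3L }
      M[i, j] <- best + s; PM[i, j] <- from
    }
  }
  i <- n + 1; j <- m + 1
  st <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  pathA <- integer(); pathB <- integer()
  while (i > 1 || j > 1) {
    if (st == 1) {
      pathA <- c(i - 1, pathA); pathB <- c(j - 1, pathB)
      from <- PM[i, j]; i <- i - 1; j <- j - 1; st <- from
    } else if (st == 2) {
      pathA <- c(i - 1, pathA); pathB <- c(0L, pathB)
      from <- PX[i, j]; i <- i - 1; st <- if (from == 1L) 1L else 2L
    } else {
      pathA <- c(0L, pathA); pathB <- c(j - 1, pathB)
      from <- PY[i, j]; j <- j - 1; st <- if (from == 1L) 1L else 3L
    }
  }
  out <- matrix("-", nrow(A) + nrow(B), length(pathA))
  rownames(out) <- c(rownames(A), rownames(B))
  for (k in seq_along(pathA)) {
    if (pathA[k] > 0) out[seq_len(nrow(A)), k] <- A[, pathA[k]]
    if (pathB[k] > 0) out[nrow(A) + seq_len(nrow(B)), k] <- B[, pathB[k]]
  }
  out
}

#' Progressive multiple sequence alignment
#'
#' Builds a guide tree from k-mer distances (average linkage) and merges
#' sequence profiles in guide-tree order with sum-of-pairs profile
#' alignment. Deterministic for a given input set (rows are returned in
#' input order).
#'
#' @param sequences named character vector (>= 2 sequences).
#' @param gap_open,gap_ext affine gap penalties.
#' @return List with \code{rows} (named character vector of gapped
#'   sequences, equal lengths) and \code{ncol}.
#' @export
progressiveAlign <- function(sequences, gap_open = 11, gap_ext = 1) {
  ns <- length(sequences)
  if (ns < 2)
    .stopf("edc_parameter_error", "need at least 2 sequences")
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_len(ns))
  if (ns == 2) {
    pa <- pairwiseAlignGlobal(sequences[[1]], sequences[[2]],
                              gap_open, gap_ext)
    rows <- setNames(c(pa$aligned_a, pa$aligned_b), names(sequences))
    return(list(rows = rows, ncol = nchar(pa$aligned_a)))
  }
  D <- matrix(0, ns, ns, dimnames = list(names(sequences),
                                         names(sequences)))
  for (i in seq_len(ns - 1)) for (j in seq(i + 1, ns)) {
    D[i, j] <- D[j, i] <- .kmerDistance(sequences[[i]], sequences[[j]])
  }
  hc <- hclust(as.dist(D), method = "average")
  profiles <- lapply(seq_len(ns), function(i) {
    m <- matrix(strsplit(sequences[[i]], "")[[1]], nrow = 1)
    rownames(m) <- names(sequences)[i]
    m
  })
  merged <- vector("list", ns - 1)
  for (k in seq_len(ns - 1)) {
    pick <- function(idx) if (idx < 0) profiles[[-idx]] else merged[[idx]]
    merged[[k]] <- .profileAlign(pick(hc$merge[k, 1]),
                                 pick(hc$merge[k, 2]),
                                 gap_open, gap_ext)
  }
  final <- merged[[ns - 1]]
  final <- final[names(sequences), , drop = FALSE]
  rows <- setNames(apply(final, 1, paste, collapse = ""),
                   names(sequences))
  list(rows = rows, ncol = ncol(final))
}

# ---- distances, NJ, bootstrap, rooting ----------------------------------

#' Pairwise distances from a multiple alignment
#'
#' p-distance (mismatches over pairwise comparable, i.e. both-ungapped,
#' columns) or its Poisson correction \eqn{-\ln(1 - p)}.
#'
#' @param alignment result of \code{\link{progressiveAlign}}, or a named
#'   character vector of equal-length gapped sequences.
#' @param correction \code{"p"} or \code{"poisson"}.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
alignmentDistance <- function(alignment, correction = c("p", "poisson")) {
  correction <- match.arg(correction)
  rows <- if (is.list(alignment)) alignment$rows else alignment
  n <- length(rows)
  if (n < 2) .stopf("edc_parameter_error", "need >= 2 rows")
  if (length(unique(nchar(rows))) != 1)
    .stopf("edc_parameter_error", "alignment rows differ in length")
  chs <- lapply(rows, function(r) strsplit(r, "")[[1]])
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    a <- chs[[i]]; b <- chs[[j]]
    ok <- a != "-" & b != "-"
    if (!any(ok))
      .stopf("edc_parameter_error",
             "no comparable columns between %s and %s",
             names(rows)[i], names(rows)[j])
    p <- mean(a[ok] != b[ok])
    d <- if (correction == "p") p else {
      if (p >= 1)
        .stopf("edc_parameter_error",
               "p-distance %.3f not Poisson-correctable", p)
      -log(1 - p)
    }
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' Neighbor-joining tree estimation
#'
#' Standard neighbor-joining agglomeration from a symmetric distance
#' matrix. Tie-breaking in the Q-matrix minimisation is by smallest
#' (i, j) index pair, so the result is deterministic. Negative branch
#' lengths are clamped to zero; the original values are kept in the
#' attribute \code{"negative_branches"}.
#'
#' @param D symmetric distance matrix (>= 3 taxa) with labels.
#' @return Unrooted \code{ape} \code{"phylo"} tree.
#' @export
neighborJoining <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 3) .stopf("edc_parameter_error", "need >= 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(n))
  if (max(abs(D - t(D))) > 1e-8)
    .stopf("edc_parameter_error", "distance matrix must be symmetric")
  labels <- rownames(D)
  negatives <- numeric(0)
  clamp <- function(x) { if (x < 0) negatives <<- c(negatives, x); max(x, 0) }
  # build with placeholder tip names so Newick metacharacters (colons
  # etc.) in labels survive the round-trip, then restore
  ph <- sprintf("tx%d", seq_along(labels))
  nwk <- ph
  Dm <- D
  while (nrow(Dm) > 3) {
    m <- nrow(Dm)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- Dm[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    vj <- Dm[i, j] - vi
    joined <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], clamp(vi),
                      nwk[j], clamp(vj))
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    nwk <- c(nwk[keep], joined)
  }
  # final 3-node star: closed-form branch lengths
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  v <- c((d12 + d13 - d23) / 2, (d12 + d23 - d13) / 2,
         (d13 + d23 - d12) / 2)
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nwk[1], clamp(v[1]),
                 nwk[2], clamp(v[2]), nwk[3], clamp(v[3]))
  phy <- ape::read.tree(text = txt)
  phy$tip.label <- labels[match(phy$tip.label, ph)]
  attr(phy, "negative_branches") <- negatives
  phy
}

# canonical string for the bipartition induced by an internal edge:
# the side not containing tip 1, sorted
.bipartitions <- function(phy) {
  out <- character()
  unrooted <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  parts <- ape::prop.part(unrooted)
  labs <- attr(parts, "labels")
  ref <- min(labs)  # fixed reference: tip order varies between trees
  for (p in parts) {
    side <- labs[p]
    other <- setdiff(labs, side)
    if (length(side) <= 1 || length(other) <= 1) next
    key_side <- if (ref %in% side) other else side
    out <- c(out, paste(sort(key_side), collapse = "|"))
  }
  unique(out)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the
#' distance/NJ tree per replicate, and reports for each internal edge of
#' the point-estimate tree the fraction of replicates containing the same
#' bipartition.
#'
#' @param alignment result of \code{\link{progressiveAlign}} or a named
#'   character vector of gapped rows (>= 4).
#' @param n_replicates number of bootstrap replicates (default 100).
#' @param seed RNG seed; a fixed seed makes supports reproducible.
#' @param correction distance correction passed to
#'   \code{\link{alignmentDistance}}.
#' @return The point-estimate unrooted \code{"phylo"} tree with a
#'   \code{node.label} vector of supports in [0, 1] (empty label for the
#'   root/trivial nodes) and attribute \code{"supports"} (named by
#'   bipartition).
#' @export
bootstrapSupport <- function(alignment, n_replicates = 100, seed = 1,
                             correction = "p") {
  rows <- if (is.list(alignment)) alignment$rows else alignment
  if (length(rows) < 4)
    .stopf("edc_parameter_error", "need >= 4 aligned sequences")
  chs <- do.call(rbind, lapply(rows, function(r) strsplit(r, "")[[1]]))
  rownames(chs) <- names(rows)
  ncols <- ncol(chs)
  point <- neighborJoining(alignmentDistance(rows, correction))
  target <- .bipartitions(point)
  counts <- setNames(numeric(length(target)), target)
  .withSeed(seed, {
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(ncols, ncols, replace = TRUE)
      rep_rows <- setNames(apply(chs[, cols, drop = FALSE], 1,
                                 paste, collapse = ""), names(rows))
      rep_tree <- tryCatch(
        neighborJoining(alignmentDistance(rep_rows, correction)),
        error = function(e) NULL)
      if (is.null(rep_tree)) next
      bp <- .bipartitions(rep_tree)
      hit <- target %in% bp
      counts[hit] <- counts[hit] + 1
    }
  })
  supports <- counts / n_replicates
  point <- .annotateSupports(point, supports)
  attr(point, "supports") <- supports
  point
}

# write supports onto node labels of the (unrooted) point tree
.annotateSupports <- function(phy, supports) {
  n <- length(phy$tip.label)
  phy$node.label <- rep("", phy$Nnode)
  ref <- min(phy$tip.label)
  for (node in seq(n + 1L, n + phy$Nnode)) {
    tips <- .cladeTips(phy, node)
    if (length(tips) <= 1 || length(tips) >= n - 1) next
    other <- setdiff(phy$tip.label, tips)
    key <- if (ref %in% tips)
      paste(sort(other), collapse = "|")
    else paste(sort(tips), collapse = "|")
    if (key %in% names(supports))
      phy$node.label[node - n] <- format(supports[[key]], digits = 3)
  }
  phy
}

.cladeTips <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(phy$tip.label[node])
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  unlist(lapply(kids, .cladeTips, phy = phy))
}

#' Root a tree with an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant edge.
#'
#' @param tree an \code{ape} \code{"phylo"} tree (node labels carrying
#'   bootstrap supports are preserved).
#' @param outgroup tip label of the outgroup.
#' @return Rooted \code{"phylo"} tree.
#' @export
rootWithOutgroup <- function(tree, outgroup) {
  if (!(outgroup %in% tree$tip.label))
    .stopf("edc_parameter_error", "outgroup '%s' not in tree", outgroup)
  tip <- which(tree$tip.label == outgroup)
  pend <- which(tree$edge[, 2] == tip)
  half <- tree$edge.length[pend] / 2
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  # split the outgroup pendant edge at its midpoint
  tip_r <- which(rooted$tip.label == outgroup)
  pend_r <- which(rooted$edge[, 2] == tip_r)
  root_node <- length(rooted$tip.label) + 1L
  root_edges <- which(rooted$edge[, 1] == root_node)
  other <- setdiff(root_edges, pend_r)
  if (rooted$edge[pend_r, 1] == root_node) {
    moved <- rooted$edge.length[pend_r] - half
    rooted$edge.length[pend_r] <- half
    rooted$edge.length[other] <- rooted$edge.length[other] + moved
  }
  rooted
}

#' Supported phylogenetic groups from a rooted tree
#'
#' Returns the clades whose subtending edge carries bootstrap support at
#' or above the threshold, plus all trivial singleton groups. These leaf
#' sets are the phylogenetic evidence stream of the orthology caller.
#'
#' @param rooted_tree rooted \code{"phylo"} with node labels holding
#'   supports (as written by \code{\link{bootstrapSupport}}).
#' @param support_threshold minimum support (default 0.9).
#' @return List of character vectors (leaf sets), singletons first, then
#'   clades by decreasing size.
#' @export
phyloGroups <- function(rooted_tree, support_threshold = 0.9) {
  n <- length(rooted_tree$tip.label)
  groups <- as.list(sort(rooted_tree$tip.label))
  clades <- list()
  if (!is.null(rooted_tree$node.label)) {
    for (k in seq_len(rooted_tree$Nnode)) {
      lab <- rooted_tree$node.label[k]
      if (is.na(lab) || !nzchar(lab)) next
      sup <- suppressWarnings(as.numeric(lab))
      if (is.na(sup) || sup < support_threshold) next
      tips <- sort(.cladeTips(rooted_tree, n + k))
      if (length(tips) > 1) clades[[length(clades) + 1]] <- tips
    }
  }
  clades <- clades[order(-vapply(clades, length, 0),
                         vapply(clades, function(x)
                           paste(x, collapse = "|"), ""))]
  c(groups, clades)
}
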