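# Shared fixtures and independent oracles used across the suite.

std_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(std_aa, n, TRUE), collapse = "")

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, TRUE), collapse = "")
}

# back-translate deterministically (first codon of each residue)
encode_protein <- function(p) {
  tab <- Biostrings::GENETIC_CODE
  inv <- split(names(tab), tab)
  paste(vapply(strsplit(p, "")[[1]], function(r) inv[[r]][1], ""),
        collapse = "")
}

# independent local-alignment oracle: best score of the query against
# any of the six frame translations (Biostrings dynamic programming)
sw_oracle <- function(query, dna) {
  data("BLOSUM62", package = "Biostrings",
       envir = environment())
  b62 <- get("BLOSUM62", envir = environment())
  max(vapply(sixFrameTranslate(dna), function(tr) {
    if (!nzchar(tr)) return(0)
    Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(tr),
      substitutionMatrix = b62, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
  }, 0))
}

# brute-force average-linkage agglomeration recomputed from definitions
average_linkage_oracle <- function(X) {
  n <- nrow(X)
  clusters <- lapply(seq_len(n), identity)
  D <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); bd <- Inf
    for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
      d <- mean(D[clusters[[i]], clusters[[j]], drop = FALSE])
      if (d < bd - 1e-12) { bd <- d; best <- c(i, j) }
    }
    heights <- c(heights, bd)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

# random tree with positive branch lengths and its additive matrix
random_additive <- function(n) {
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1.5)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# exhaustive best-pair enumeration oracle for reciprocal best hits
rbh_oracle <- function(S) {
  out <- list()
  for (i in seq_len(nrow(S))) {
    bi <- which(S[i, ] == max(S[i, ]))
    if (length(bi) != 1) next
    bj <- which(S[, bi] == max(S[, bi]))
    if (length(bj) == 1 && bj == i)
      out[[length(out) + 1]] <- c(rownames(S)[i], colnames(S)[bi])
  }
  if (!length(out)) return(data.frame(a = character(), b = character()))
  as.data.frame(do.call(rbind, out)) |>
    stats::setNames(c("a", "b"))
}

# closed-form probability that a site differs between two leaves under
# the simulator's substitution process (composition of per-branch
# 20-state transition matrices of the form aI + bJ)
path_diff_oracle <- function(rate, lens) {
  a <- 1; b <- 0
  for (l in lens) {
    q <- 1 - exp(-rate * l)
    a2 <- 1 - q - q / 19; b2 <- q / 19
    ab <- c(a * a2, a * b2 + b * a2 + 20 * b * b2)
    a <- ab[1]; b <- ab[2]
  }
  1 - (a + b)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  (a - expected) / (maxi - expected)
}

# mutate a protein to a given per-site substitution probability
mutate_protein <- function(p, rate) {
  s <- strsplit(p, "")[[1]]
  mut <- stats::runif(length(s)) < rate
  mut[1] <- FALSE
  s[mut] <- vapply(s[mut], function(r) sample(setdiff(std_aa, r), 1), "")
  paste(s, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
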