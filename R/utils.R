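#' @useDynLib edcscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats hclust dist as.dist cutree runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

.pkgCache <- new.env(parent = emptyenv())

# residue alphabet fixed to the BLOSUM62 row order, plus a terminal
# sentinel used to mask already-reported alignment footprints
.aaLetters <- function() {
  if (is.null(.pkgCache$aa)) {
    data("BLOSUM62", package = "Biostrings", envir = .pkgCache)
    .pkgCache$aa <- c(rownames(.pkgCache$BLOSUM62), "#")
  }
  .pkgCache$aa
}

# integer substitution matrix extended with the mask sentinel '#'
# (score -1000 against everything, so masked stretches never re-align)
.subMatrix <- function() {
  if (is.null(.pkgCache$sub)) {
    aa <- .aaLetters()
    n <- length(aa)
    m <- matrix(-1000, n, n, dimnames = list(aa, aa))
    b <- .pkgCache$BLOSUM62
    m[rownames(b), colnames(b)] <- b
    m["#", ] <- -1000
    m[, "#"] <- -1000
    storage.mode(m) <- "integer"
    .pkgCache$sub <- m
  }
  .pkgCache$sub
}

# encode an amino-acid string as 0-based integers into .aaLetters();
# unknown characters (U, O, ...) fall back to X
.aaEncode <- function(x) {
  aa <- .aaLetters()
  ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  i <- match(ch, aa)
  i[is.na(i)] <- match("X", aa)
  as.integer(i - 1L)
}

.aaDecode <- function(idx) {
  aa <- .aaLetters()
  paste(aa[idx + 1L], collapse = "")
}

# evaluate expr under a fixed RNG state, restoring the caller's state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# derive a stream-specific child seed; kept well inside 32-bit range
.childSeed <- function(seed, stream) {
  s <- (as.numeric(seed) * 48271 + as.numeric(stream) * 7919) %% 2147483587
  as.integer(s)
}

.revCompChr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.stopf <- function(class, fmt, ..., data = list()) {
  msg <- sprintf(fmt, ...)
  cond <- structure(class = c(class, "error", "condition"),
                    list(message = msg, call = sys.call(-1), data = data))
  stop(cond)
}
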