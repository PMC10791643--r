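#' Residue sampling profiles used by the locus simulator
#'
#' Probability profiles over the 20 standard residues for the major EDC
#' composition classes (glycine/serine-rich, glutamine/glutamate-rich,
#' G/S/C/P-rich, P/C/Q-rich), a generic globular profile used for S100
#' domains, and a neutral profile for non-EDC spacer genes.
#'
#' @param name profile name: one of \code{"GS"}, \code{"QE"},
#'   \code{"GSCP"}, \code{"PCQ"}, \code{"S100"}, \code{"NEDC"}.
#' @return Named numeric vector of 20 probabilities summing to 1.
#' @export
generatorProfile <- function(name) {
  std <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  mk <- function(spec) {
    v <- setNames(rep(0, 20), std)
    v[names(spec)] <- spec
    rest <- setdiff(std, names(spec))
    v[rest] <- (1 - sum(spec)) / length(rest)
    v
  }
  switch(name,
    GS   = mk(c(G = 0.35, S = 0.25, C = 0.05)),
    QE   = mk(c(Q = 0.30, E = 0.25, L = 0.08)),
    GSCP = mk(c(G = 0.18, S = 0.18, C = 0.12, P = 0.12)),
    PCQ  = mk(c(P = 0.20, C = 0.15, Q = 0.15, K = 0.08)),
    S100 = mk(c(E = 0.10, K = 0.09, L = 0.09, F = 0.06, D = 0.07)),
    NEDC = mk(c()),
    .stopf("edc_parameter_error", "unknown profile '%s'", name))
}

#' Sample a low-complexity protein from a composition profile
#'
#' Residues are drawn i.i.d. from the profile; when \code{repeat_spec} is
#' given, a repeat unit is sampled once and tandem-copied with a per-copy
#' per-site mutation rate, emulating the quasi-repetitive organisation of
#' SFTP carboxy-terminal domains.
#'
#' @param profile named probability vector over the 20 residues (sums
#'   to 1), e.g. from \code{\link{generatorProfile}}.
#' @param length protein length (>= 20); with \code{repeat_spec} the
#'   result is trimmed/extended to this length.
#' @param repeat_spec optional list with \code{unit} (residues per
#'   repeat), and \code{mutation} (per-site per-copy substitution
#'   probability).
#' @param seed RNG seed (same seed, same protein).
#' @return Protein string.
#' @export
sampleLowComplexityProtein <- function(profile, length, repeat_spec = NULL,
                                       seed = 1) {
  if (abs(sum(profile) - 1) > 1e-6)
    .stopf("edc_parameter_error", "profile must sum to 1")
  if (length < 20)
    .stopf("edc_parameter_error", "length must be >= 20")
  std <- names(profile)
  .withSeed(seed, {
    if (is.null(repeat_spec)) {
      paste(sample(std, length, replace = TRUE, prob = profile),
            collapse = "")
    } else {
      unit <- sample(std, repeat_spec$unit, replace = TRUE,
                     prob = profile)
      copies <- ceiling(length / repeat_spec$unit)
      out <- character(0)
      for (k in seq_len(copies)) {
        cp <- unit
        mut <- runif(length(cp)) < repeat_spec$mutation
        if (any(mut))
          cp[mut] <- vapply(cp[mut], function(r)
            sample(setdiff(std, r), 1), "")
        out <- c(out, cp)
      }
      paste(out[seq_len(length)], collapse = "")
    }
  })
}

#' Evolve a protein along a tree by i.i.d. substitutions
#'
#' Each site substitutes on a branch of length l with probability
#' \code{1 - exp(-rate * l)}, replaced by a uniform draw from the other
#' 19 residues.
#'
#' @param ancestor ancestral protein (length >= 50 recommended).
#' @param tree \code{"phylo"} object or Newick text with branch lengths.
#' @param rate substitution rate per site per unit branch length.
#' @param seed RNG seed.
#' @param fix_first keep the initiator residue unchanged (default TRUE,
#'   so planted genes always start with M).
#' @return Named character vector of per-leaf proteins.
#' @export
evolveDomain <- function(ancestor, tree, rate, seed = 1,
                         fix_first = TRUE) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  std <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  n <- length(tree$tip.label)
  root <- n + 1L
  seqs <- vector("list", n + tree$Nnode)
  seqs[[root]] <- strsplit(ancestor, "")[[1]]
  .withSeed(seed, {
    ord <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(ord$edge))) {
      par <- ord$edge[e, 1]; child <- ord$edge[e, 2]
      bl <- ord$edge.length[e]
      s <- seqs[[par]]
      p <- 1 - exp(-rate * bl)
      mut <- runif(length(s)) < p
      if (fix_first) mut[1] <- FALSE
      if (any(mut))
        s[mut] <- vapply(s[mut], function(r)
          sample(setdiff(std, r), 1), "")
      seqs[[child]] <- s
    }
  })
  out <- vapply(seq_len(n), function(i)
    paste(seqs[[i]], collapse = ""), "")
  setNames(out, tree$tip.label)
}

# probability that a site differs between two leaves connected by a path
# of branch lengths `lens` under the evolveDomain substitution process
.pathDiffProb <- function(rate, lens) {
  a <- 1; b <- 0  # transition matrix aI + bJ over 20 states
  for (l in lens) {
    q <- 1 - exp(-rate * l)
    a2 <- 1 - q - q / 19; b2 <- q / 19
    ab <- c(a * a2, a * b2 + b * a2 + 20 * b * b2)
    a <- ab[1]; b <- ab[2]
  }
  1 - (a + b)
}

# rate such that the two most distant leaves differ at `target` of sites
.calibrateRate <- function(tree, target) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  pl <- max(ape::cophenetic.phylo(tree))
  f <- function(r) .pathDiffProb(r, pl) - target
  stats::uniroot(f, c(1e-6, 100))$root
}

# ---- DNA-level helpers ---------------------------------------------------

.randDNA <- function(n) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.codonTable <- function() {
  if (is.null(.pkgCache$codons)) {
    gc <- Biostrings::GENETIC_CODE
    .pkgCache$codons <- split(names(gc), gc)
  }
  .pkgCache$codons
}

# back-translate a protein with uniform synonymous codon choice
.backTranslate <- function(protein) {
  tab <- .codonTable()
  ch <- strsplit(protein, "")[[1]]
  paste(vapply(ch, function(r) {
    cods <- tab[[r]]
    if (is.null(cods))
      .stopf("edc_parameter_error", "cannot back-translate residue '%s'", r)
    if (length(cods) == 1) cods else sample(cods, 1)
  }, ""), collapse = "")
}

.mutateProtein <- function(protein, p, fix_first = TRUE) {
  std <- sort(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                "N", "P", "Q", "R", "S", "T", "V", "W", "Y"))
  s <- strsplit(protein, "")[[1]]
  mut <- runif(length(s)) < p
  if (fix_first) mut[1] <- FALSE
  if (any(mut))
    s[mut] <- vapply(s[mut], function(r) sample(setdiff(std, r), 1), "")
  paste(s, collapse = "")
}

# build the DNA block for one gene entry (strand-local layout, then
# reverse-complemented for minus-strand genes); truth exons carry only
# the non-coding first exon plus the exact CDS intervals
.plantGeneSeq <- function(entry, params) {
  two_exon <- entry$class %in% c("SFTP", "S100A")
  prot <- entry$protein
  j <- entry$junction
  e1 <- .randDNA(params$e1nc_len)
  i1 <- paste0("GT", .randDNA(sample(seq(params$intron_range[1],
                                         params$intron_range[2]), 1) - 4),
               "AG")
  utr5 <- .randDNA(params$utr5_len)
  stopc <- sample(c("TAA", "TAG", "TGA"), 1)
  cds <- paste0(.backTranslate(prot), stopc)
  if (two_exon) {
    cds1 <- substring(cds, 1, 3 * j)
    cds2 <- substring(cds, 3 * j + 1, nchar(cds))
    i2 <- paste0("GT", .randDNA(sample(seq(params$intron_range[1],
                                           params$intron_range[2]), 1) - 4),
                 "AG")
  } else {
    cds1 <- cds; cds2 <- ""; i2 <- ""
  }
  # disruptions hit the last coding exon at ~45% of its codons
  dis <- entry$disruption
  if (!is.na(dis) && nzchar(dis)) {
    target <- if (two_exon) cds2 else cds1
    k <- max(2, floor(0.45 * (nchar(target) / 3)))
    if (dis == "premature_stop") {
      substr(target, 3 * (k - 1) + 1, 3 * k) <- "TAA"
    } else if (dis == "frameshift") {
      target <- paste0(substring(target, 1, 3 * (k - 1)),
                       substring(target, 3 * (k - 1) + 2, nchar(target)))
    }
    if (two_exon) cds2 <- target else cds1 <- target
  }
  utr3 <- .randDNA(params$utr3_len)
  parts <- c(e1, i1, utr5, cds1, if (two_exon) c(i2, cds2), utr3)
  block <- paste(parts, collapse = "")
  off <- cumsum(c(0, nchar(parts)))
  # strand-local exon intervals: exon1 (non-coding) + exact CDS exon(s);
  # parts boundaries: off[k] is the start of parts[k] (0-based)
  ex <- rbind(c(0, nchar(e1)),
              c(off[4], off[5]))
  coding <- c(FALSE, TRUE)
  if (two_exon) {
    ex <- rbind(ex, c(off[6], off[7]))
    coding <- c(coding, TRUE)
  }
  Lb <- nchar(block)
  if (entry$strand == "-") {
    block <- .revCompChr(block)
    ex <- cbind(Lb - ex[, 2], Lb - ex[, 1])
    o <- order(ex[, 1])
    ex <- ex[o, , drop = FALSE]
    coding <- coding[o]
  }
  colnames(ex) <- c("start", "end")
  list(block = block, exons = ex, coding = coding,
       cds_translation = .translateCds(paste0(cds1, cds2)))
}

#' Construct a locus simulation scenario
#'
#' @param name scenario name.
#' @param seed base RNG seed.
#' @param tree species tree as Newick text (branch lengths required).
#' @param roster gene-family table; see \linkS4class{LocusScenario}.
#' @param rearrangements event table (may be empty).
#' @param params overrides for layout parameters (intergenic_range,
#'   intron_range, e1nc_len, utr5_len, utr3_len, spacer_genes,
#'   copy_divergence, flank_divergence, query_species).
#' @return A \linkS4class{LocusScenario}.
#' @export
locusScenario <- function(name, seed, tree, roster,
                          rearrangements = NULL, params = list()) {
  defaults <- list(intergenic_range = c(4000, 7000),
                   intron_range = c(150, 400),
                   e1nc_len = 60, utr5_len = 30, utr3_len = 40,
                   spacer_genes = 3, copy_divergence = 0.04,
                   flank_divergence = 0.10, query_species = NULL)
  params <- utils::modifyList(defaults, params)
  if (is.null(rearrangements))
    rearrangements <- data.frame(type = character(), edge = character(),
                                 after_family = character(),
                                 stringsAsFactors = FALSE)
  for (col in c("disruption", "copies"))
    if (is.null(roster[[col]])) roster[[col]] <- ""
  if (is.null(roster$repeat_unit)) roster$repeat_unit <- 12L
  new("LocusScenario", name = name, seed = as.numeric(seed), tree = tree,
      roster = roster, rearrangements = rearrangements, params = params)
}

#' Bundled simulation scenarios
#'
#' Three named scenarios drive the package's validation suite:
#' \describe{
#'   \item{fig1_locus}{a ~200 kb two-species EDC-like locus: two S100A
#'     flanking marker genes, 20 SEDC and 4 SFTP families at per-family
#'     divergences giving 60--80\% protein identity between the query
#'     species and the target species, with 5 genes disrupted in the
#'     target (3 premature stops, 2 frameshifts).}
#'   \item{fig2_rearrangement}{four species; the locus is split after one
#'     family on the stem edge of one clade (non-EDC spacer genes appear
#'     at the split) and the second segment is additionally inverted on a
#'     nested edge.}
#'   \item{fig5_sftp_expansion}{two species; one SFTP family expands to 3
#'     tandem copies in the second lineage, the classic co-orthology
#'     situation.}
#' }
#'
#' @param name scenario name.
#' @param seed optional seed override (defaults are fixed per scenario).
#' @return A \linkS4class{LocusScenario}.
#' @export
edcScenario <- function(name = c("fig1_locus", "fig2_rearrangement",
                                 "fig5_sftp_expansion"), seed = NULL) {
  name <- match.arg(name)
  if (name == "fig1_locus") {
    profs <- rep(c("GS", "QE", "GSCP", "PCQ"), 5)
    roster <- data.frame(
      family = c(sprintf("sedc%02d", 1:20), sprintf("sftp%d", 1:4)),
      class = c(rep("SEDC", 20), rep("SFTP", 4)),
      profile = c(profs, "GS", "QE", "GSCP", "PCQ"),
      length = c(round(seq(120, 420, length.out = 20)),
                 93 + c(357, 457, 552, 657)),
      strand = rep(c("+", "-"), 12),
      divergence = round(seq(0.20, 0.40, length.out = 24), 3),
      disruption = "", copies = "",
      repeat_unit = c(rep(12L, 20), 10L, 12L, 15L, 20L),
      stringsAsFactors = FALSE)
    roster$disruption[roster$family %in%
                        c("sedc03", "sedc13", "sftp2")] <- "tsp:premature_stop"
    roster$disruption[roster$family %in%
                        c("sedc08", "sedc18")] <- "tsp:frameshift"
    sc <- locusScenario("fig1_locus", seed %||% 20240116,
                        "(qsp:0.5,tsp:0.5);", roster,
                        params = list(intergenic_range = c(4000, 7000)))
  } else if (name == "fig2_rearrangement") {
    roster <- data.frame(
      family = c(sprintf("sedc%02d", 1:10), "sftp1", "sftp2"),
      class = c(rep("SEDC", 10), "SFTP", "SFTP"),
      profile = c(rep(c("GS", "QE", "GSCP", "PCQ"), length.out = 10),
                  "GS", "QE"),
      length = c(rep(120L, 10), 420L, 420L),
      strand = rep(c("+", "-"), 6),
      divergence = 0.12, disruption = "", copies = "",
      repeat_unit = 12L, stringsAsFactors = FALSE)
    ev <- data.frame(type = c("split", "inversion"),
                     edge = c("spC+spD", "spD"),
                     after_family = c("sedc05", ""),
                     stringsAsFactors = FALSE)
    sc <- locusScenario("fig2_rearrangement", seed %||% 20240217,
                        "((spA:0.3,spB:0.3):0.15,(spC:0.24,spD:0.24):0.21);",
                        roster, ev,
                        params = list(intergenic_range = c(300, 800),
                                      intron_range = c(100, 200)))
  } else {
    roster <- data.frame(
      family = c(sprintf("sedc%02d", 1:6), "sftpA", "sftpB", "sftpC"),
      class = c(rep("SEDC", 6), rep("SFTP", 3)),
      profile = c(rep(c("GS", "QE", "GSCP"), 2), "GS", "QE", "PCQ"),
      length = c(rep(150L, 6), rep(93L + 400L, 3)),
      strand = "+",
      divergence = 0.18, disruption = "",
      copies = c(rep("", 7), "spB:3", ""),
      repeat_unit = 12L, stringsAsFactors = FALSE)
    sc <- locusScenario("fig5_sftp_expansion", seed %||% 20240518,
                        "(spA:0.5,spB:0.5);", roster,
                        params = list(intergenic_range = c(800, 1500),
                                      intron_range = c(100, 250)))
  }
  sc
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# parse "sp:what" specs from roster columns
.parseSpec <- function(x) {
  if (is.na(x) || !nzchar(x)) return(NULL)
  p <- strsplit(x, ":", fixed = TRUE)[[1]]
  list(species = p[1], what = p[2])
}

#' Build a simulated EDC-like locus with full ground truth
#'
#' Lays out the scenario's gene families between two S100A flanking
#' marker genes for every species of the scenario tree: proteins are
#' sampled from class-specific composition profiles, evolved along the
#' tree at per-family calibrated rates, back-translated with uniform
#' synonymous codon choice, and embedded in i.i.d. intergenic DNA with
#' canonical GT..AG introns (phase 0). Disruption events plant premature
#' stops or 1-nt frameshifts; duplication events plant tandem copies;
#' split/inversion events rearrange the locus on the specified tree
#' edges, inserting non-EDC spacer genes at the split. Translating the
#' emitted truth CDS always reproduces the recorded translation (checked
#' on every build).
#'
#' @param scenario a \linkS4class{LocusScenario}
#'   (\code{\link{edcScenario}} for the bundled ones).
#' @return List of class \code{"edc_locus_sim"}: per-species
#'   \code{sequences} (one chromosome string each), \code{annotations}
#'   (lists of \linkS4class{GeneAnnotation}), \code{proteins} (intended
#'   intact proteins), \code{cds_proteins} (actual CDS translations),
#'   \code{orders}, \code{pseudogenes}, \code{orthology} map,
#'   \code{events}, the \code{query_set} (query-species proteins with
#'   class/junction metadata) and bookkeeping fields.
#' @export
buildLocus <- function(scenario) {
  stopifnot(is(scenario, "LocusScenario"))
  params <- scenario@params
  tree <- ape::read.tree(text = scenario@tree)
  species <- tree$tip.label
  qsp <- params$query_species %||% species[1]
  seed <- scenario@seed
  roster <- scenario@roster
  events <- scenario@rearrangements
  # extended family table: flanks + roster + (possibly) spacer families
  n_spacer <- if (nrow(events[events$type == "split", , drop = FALSE]))
    params$spacer_genes else 0
  fam <- rbind(
    data.frame(family = "S100A9", class = "S100A", profile = "S100",
               length = 100L, strand = "+",
               divergence = params$flank_divergence, disruption = "",
               copies = "", repeat_unit = 12L, stringsAsFactors = FALSE),
    roster[, c("family", "class", "profile", "length", "strand",
               "divergence", "disruption", "copies", "repeat_unit")],
    data.frame(family = "S100A11", class = "S100A", profile = "S100",
               length = 100L, strand = "+",
               divergence = params$flank_divergence, disruption = "",
               copies = "", repeat_unit = 12L, stringsAsFactors = FALSE))
  if (n_spacer > 0)
    fam <- rbind(fam, data.frame(
      family = sprintf("NEDC%d", seq_len(n_spacer)), class = "SEDC",
      profile = "NEDC", length = 150L, strand = "+", divergence = 0.05,
      disruption = "", copies = "", repeat_unit = 12L,
      stringsAsFactors = FALSE))
  # per-family ancestral proteins and per-leaf evolved proteins
  leafprot <- list(); junctions <- c(); copyprot <- list()
  for (fi in seq_len(nrow(fam))) {
    f <- fam[fi, ]
    fseed <- .childSeed(seed, fi)
    junction <- switch(f$class, SFTP = 93L, S100A = 60L, NA_integer_)
    anc <- if (f$class == "SFTP") {
      dom <- sampleLowComplexityProtein(generatorProfile("S100"), 93,
                                        seed = fseed)
      ct <- sampleLowComplexityProtein(
        generatorProfile(f$profile), f$length - 93,
        repeat_spec = list(unit = f$repeat_unit, mutation = 0.10),
        seed = .childSeed(fseed, 2))
      paste0(dom, ct)
    } else {
      sampleLowComplexityProtein(generatorProfile(f$profile), f$length,
                                 seed = fseed)
    }
    anc <- paste0("M", substring(anc, 2))
    rate <- .calibrateRate(tree, f$divergence)
    lp <- evolveDomain(anc, tree, rate, seed = .childSeed(fseed, 3))
    leafprot[[f$family]] <- lp
    junctions[f$family] <- junction
    cp <- .parseSpec(f$copies)
    if (!is.null(cp)) {
      ncp <- as.integer(cp$what)
      copyprot[[f$family]] <- .withSeed(.childSeed(fseed, 4), {
        setNames(lapply(seq_len(ncp), function(k)
          .mutateProtein(lp[[cp$species]], params$copy_divergence)),
          sprintf("%s_c%d", f$family, seq_len(ncp)))
      })
    }
  }
  # per-species gene entry lists (roster order), then rearrangements
  sim <- list(scenario = scenario@name, seed = seed,
              tree = scenario@tree, species = species,
              query_species = qsp, junctions = junctions,
              sequences = list(), annotations = list(), proteins = list(),
              cds_proteins = list(), orders = list(),
              pseudogenes = list(), orthology = NULL, events = NULL)
  orth_rows <- list(); event_rows <- list()
  spacer_fams <- if (n_spacer > 0) sprintf("NEDC%d", seq_len(n_spacer))
                 else character()
  core_fams <- setdiff(fam$family, spacer_fams)
  for (si in seq_along(species)) {
    sp <- species[si]
    entries <- list()
    for (fi in seq_len(nrow(fam))) {
      f <- fam[fi, ]
      if (f$family %in% spacer_fams) next
      cp <- .parseSpec(f$copies)
      dis <- .parseSpec(f$disruption)
      dtype <- if (!is.null(dis) && dis$species == sp) dis$what else ""
      if (!is.null(cp) && cp$species == sp) {
        for (k in seq_len(as.integer(cp$what))) {
          sym <- sprintf("%s_c%d", f$family, k)
          entries[[length(entries) + 1]] <- list(
            family = f$family, symbol = sym, class = f$class,
            strand = f$strand, protein = copyprot[[f$family]][[sym]],
            junction = junctions[[f$family]], disruption = "")
        }
      } else {
        entries[[length(entries) + 1]] <- list(
          family = f$family, symbol = f$family, class = f$class,
          strand = f$strand, protein = leafprot[[f$family]][[sp]],
          junction = junctions[[f$family]], disruption = dtype)
      }
    }
    # rearrangement events affecting this species (splits first)
    ev_sp <- events[order(events$type != "split"), , drop = FALSE]
    split_at <- NA_integer_
    for (ei in seq_len(nrow(ev_sp))) {
      e <- ev_sp[ei, ]
      clade <- strsplit(e$edge, "+", fixed = TRUE)[[1]]
      if (!(sp %in% clade)) next
      if (e$type == "split") {
        idx <- max(which(vapply(entries, function(x)
          x$family == e$after_family, TRUE)))
        spacers <- lapply(spacer_fams, function(nf) list(
          family = nf, symbol = nf, class = "SEDC", strand = "+",
          protein = leafprot[[nf]][[sp]], junction = NA_integer_,
          disruption = ""))
        before_fam <- entries[[idx + 1]]$family
        entries <- c(entries[seq_len(idx)], spacers,
                     entries[seq(idx + 1, length(entries))])
        split_at <- idx + length(spacers)
        event_rows[[length(event_rows) + 1]] <- data.frame(
          type = "split", species = sp, after_family = e$after_family,
          before_family = before_fam, edge = e$edge,
          stringsAsFactors = FALSE)
      } else if (e$type == "inversion") {
        if (is.na(split_at)) next  # inversions only follow a split
        seg <- seq(split_at + 1, length(entries))
        inv <- rev(entries[seg])
        inv <- lapply(inv, function(x) {
          x$strand <- if (x$strand == "+") "-" else "+"; x })
        entries[seg] <- inv
        event_rows[[length(event_rows) + 1]] <- data.frame(
          type = "inversion", species = sp,
          after_family = entries[[split_at + 1]]$family,
          before_family = entries[[length(entries)]]$family,
          edge = e$edge, stringsAsFactors = FALSE)
      }
    }
    # assemble chromosome
    chrom <- paste0(sp, "_chr")
    ann <- list(); prot <- c(); cdsp <- c(); pg <- list()
    .withSeed(.childSeed(seed, 5000 + si), {
      parts <- character(); pos <- 0
      for (en in entries) {
        ig <- .randDNA(sample(seq(params$intergenic_range[1],
                                  params$intergenic_range[2]), 1))
        parts <- c(parts, ig); pos <- pos + nchar(ig)
        planted <- .plantGeneSeq(en, params)
        gid <- paste(sp, en$symbol, sep = "_")
        exm <- planted$exons + pos
        flags <- if (nzchar(en$disruption)) en$disruption else character()
        ann[[length(ann) + 1]] <- geneAnnotation(
          gene_id = gid, exons = exm, coding = planted$coding,
          seqid = chrom, strand = en$strand, gene_symbol = en$symbol,
          gene_class = en$class, pseudogene_evidence = flags,
          metadata = list(family = en$family,
                          junction = en$junction))
        prot[gid] <- en$protein
        cdsp[gid] <- planted$cds_translation
        pg[[gid]] <- flags
        parts <- c(parts, planted$block)
        pos <- pos + nchar(planted$block)
      }
      tailig <- .randDNA(sample(seq(params$intergenic_range[1],
                                    params$intergenic_range[2]), 1))
      parts <- c(parts, tailig)
      sim$sequences[[sp]] <- paste(parts, collapse = "")
    })
    sim$annotations[[sp]] <- ann
    sim$proteins[[sp]] <- prot
    sim$cds_proteins[[sp]] <- cdsp
    sim$pseudogenes[[sp]] <- pg
    sim$orders[[sp]] <- data.frame(
      symbol = vapply(entries, function(x) x$symbol, ""),
      strand = vapply(entries, function(x) x$strand, ""),
      family = vapply(entries, function(x) x$family, ""),
      stringsAsFactors = FALSE)
    for (en in entries)
      orth_rows[[length(orth_rows) + 1]] <- data.frame(
        family = en$family, species = sp, symbol = en$symbol,
        gene_id = paste(sp, en$symbol, sep = "_"),
        stringsAsFactors = FALSE)
  }
  sim$orthology <- do.call(rbind, orth_rows)
  sim$events <- if (length(event_rows)) do.call(rbind, event_rows)
                else data.frame(type = character(), species = character(),
                                after_family = character(),
                                before_family = character(),
                                edge = character(),
                                stringsAsFactors = FALSE)
  # query set: query-species roster proteins with class/junction metadata
  qs <- c(); qdesc <- c()
  for (fi in seq_len(nrow(roster))) {
    f <- roster[fi, ]
    qs[f$family] <- leafprot[[f$family]][[qsp]]
    qdesc[f$family] <- if (f$class %in% c("SFTP", "S100A"))
      sprintf("class=%s junction=%d", f$class, junctions[[f$family]])
    else sprintf("class=%s", f$class)
  }
  attr(qs, "description") <- qdesc
  sim$query_set <- qs
  class(sim) <- "edc_locus_sim"
  .checkLocusSim(sim)
  sim
}

#' @export
print.edc_locus_sim <- function(x, ...) {
  cat(sprintf("Simulated locus '%s' (seed %.0f): %d species, %d genes each\n",
              x$scenario, x$seed, length(x$species),
              length(x$annotations[[1]])))
  invisible(x)
}

# structural self-check run on every build: truth CDS translates to the
# recorded protein, splice sites are canonical GT..AG, SEDC genes have
# exactly one coding exon
.checkLocusSim <- function(sim) {
  for (sp in sim$species) {
    chr <- sim$sequences[[sp]]
    for (a in sim$annotations[[sp]]) {
      ce <- a@exons[a@coding, , drop = FALSE]
      segs <- vapply(seq_len(nrow(ce)), function(k)
        substring(chr, ce[k, 1] + 1, ce[k, 2]), "")
      cds <- paste(segs, collapse = "")
      if (a@strand == "-") cds <- .revCompChr(cds)
      tr <- .translateCds(cds)
      if (!identical(tr, sim$cds_proteins[[sp]][[a@gene_id]]))
        stop("simulator self-check failed: CDS translation mismatch for ",
             a@gene_id)
      if (a@gene_class == "SEDC" && sum(a@coding) != 1)
        stop("simulator self-check failed: SEDC exon structure for ",
             a@gene_id)
      if (sum(a@coding) == 2) {
        # canonical splice check around the internal coding intron
        iv <- if (a@strand == "+") {
          c(ce[1, 2], ce[2, 1])
        } else c(ce[1, 2], ce[2, 1])
        donor_acceptor <- substring(chr, c(iv[1] + 1, iv[2] - 1),
                                    c(iv[1] + 2, iv[2]))
        if (a@strand == "-")
          donor_acceptor <- rev(vapply(donor_acceptor, .revCompChr, ""))
        if (!identical(unname(donor_acceptor), c("GT", "AG")))
          stop("simulator self-check failed: non-canonical splice for ",
               a@gene_id)
      }
    }
  }
  invisible(TRUE)
}
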