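#' Assemble a pipeline run configuration
#'
#' Defaults mirror the package's stage-level defaults; a YAML config file
#' may override them, and direct arguments override the file. Unknown
#' keys are rejected so typos cannot silently fall back to defaults.
#'
#' @param config_file optional YAML file of overrides.
#' @param ... direct overrides (highest precedence).
#' @return Named list of class \code{"edc_config"}.
#' @export
edcConfig <- function(config_file = NULL, ...) {
  defaults <- list(
    scenario = "fig1_locus",
    seed = NULL,                 # NULL: use the scenario's fixed seed
    outdir = "edcscan_run",
    min_score = 90,
    seed_length = 3,
    neighborhood_threshold = 11,
    max_rounds = 4,
    sftp_min_cterm_len = 300,
    synteny_threshold = 2,
    synteny_window = 3,
    bootstrap_replicates = 100,
    support_threshold = 0.9,
    cluster_metric = "euclidean",
    cluster_linkage = "average",
    flank5 = "S100A9",
    flank3 = "S100A11",
    overwrite = FALSE)
  cfg <- defaults
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown))
      .stopf("edc_parameter_error", "unknown config key(s) from %s: %s",
             src, paste(unknown, collapse = ", "))
    utils::modifyList(cfg, over)
  }
  if (!is.null(config_file)) {
    if (!file.exists(config_file))
      .stopf("edc_io_error", "config file not found: %s", config_file)
    cfg <- apply_over(cfg, yaml::read_yaml(config_file), config_file)
  }
  over <- list(...)
  if (length(over)) cfg <- apply_over(cfg, over, "arguments")
  structure(cfg, class = "edc_config")
}

.stageNames <- c("simulate", "find-genes", "classify", "compose",
                 "cluster", "phylo", "ortho", "compare-loci")

.stageDir <- function(cfg, stage) {
  d <- file.path(cfg$outdir, stage)
  if (dir.exists(d) && length(list.files(d)) && !isTRUE(cfg$overwrite))
    .stopf("edc_io_error",
           "stage directory %s already holds artifacts (outputs are write-once per run directory)",
           d)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, null = "null")
  path
}

.writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.needState <- function(state, what, stage) {
  if (is.null(state[[what]]))
    .stopf("edc_io_error",
           "stage '%s' is missing its input artifact '%s'; run the producing stage first",
           stage, what)
  state[[what]]
}

#' Run one pipeline stage
#'
#' Stages: \code{simulate} (build the scenario locus and write
#' FASTA/GFF3/truth), \code{find-genes} (iterative translated discovery
#' on the target locus core region), \code{classify} (gene classes and
#' pseudogene flags), \code{compose} (composition vectors and SFTP
#' C-terminal segments), \code{cluster} (hierarchical composition
#' clustering), \code{phylo} (S100-domain alignment, NJ + bootstrap,
#' outgroup rooting, supported groups), \code{ortho} (RBH + synteny +
#' phylo-group orthology calls), \code{compare-loci} (gene-order
#' rearrangement report) and \code{full} (the whole chain). Every stage
#' writes its artifacts plus a manifest into
#' \code{<outdir>/<stage>/}; on error, partial outputs of the failing
#' stage are removed.
#'
#' @param name stage name.
#' @param config an \code{\link{edcConfig}}.
#' @param state in-memory state from earlier stages (as returned by this
#'   function); stages chained by \code{\link{runPipeline}} pass it
#'   automatically.
#' @return The updated state (invisible), with stage outputs under their
#'   stage names.
#' @export
runStage <- function(name, config = edcConfig(), state = NULL) {
  if (!(name %in% c(.stageNames, "full")))
    .stopf("edc_parameter_error", "unknown stage '%s'", name)
  if (name == "full") {
    for (s in .stageNames) state <- runStage(s, config, state)
    manifest <- list(
      pipeline = "edcscan full",
      stages = .stageNames,
      parameters = unclass(config),
      seed = state$sim$seed,
      scenario = config$scenario)
    .writeJson(manifest, file.path(config$outdir, "manifest.json"))
    return(invisible(state))
  }
  if (is.null(state)) state <- list()
  d <- .stageDir(config, name)
  ok <- FALSE
  on.exit(if (!ok) unlink(d, recursive = TRUE))
  state <- switch(name,
    "simulate" = .stageSimulate(config, state, d),
    "find-genes" = .stageFindGenes(config, state, d),
    "classify" = .stageClassify(config, state, d),
    "compose" = .stageCompose(config, state, d),
    "cluster" = .stageCluster(config, state, d),
    "phylo" = .stagePhylo(config, state, d),
    "ortho" = .stageOrtho(config, state, d),
    "compare-loci" = .stageCompareLoci(config, state, d))
  .writeJson(list(stage = name, parameters = unclass(config)),
             file.path(d, "stage_manifest.json"))
  ok <- TRUE
  invisible(state)
}

#' Run the full pipeline
#'
#' @param config an \code{\link{edcConfig}}.
#' @return Pipeline state (invisible); artifacts under
#'   \code{config$outdir}.
#' @export
runPipeline <- function(config = edcConfig()) {
  runStage("full", config)
}

.stageSimulate <- function(cfg, state, d) {
  sc <- edcScenario(cfg$scenario, seed = cfg$seed)
  sim <- buildLocus(sc)
  for (sp in sim$species) {
    writeFasta(setNames(sim$sequences[sp], paste0(sp, "_chr")),
               file.path(d, paste0(sp, "_genome.fa")))
    writeGff3(sim$annotations[[sp]],
              file.path(d, paste0(sp, "_truth.gff3")))
    writeFasta(sim$proteins[[sp]],
               file.path(d, paste0(sp, "_proteins.fa")))
  }
  writeFasta(sim$query_set, file.path(d, "query_set.fa"))
  truth <- list(species = sim$species, tree = sim$tree,
                query_species = sim$query_species,
                orders = sim$orders,
                events = sim$events,
                orthology = sim$orthology,
                pseudogenes = sim$pseudogenes)
  .writeJson(truth, file.path(d, "truth.json"))
  state$sim <- sim
  state
}

# species whose loci are searched: every species except the query one
.targetSpecies <- function(sim) setdiff(sim$species, sim$query_species)

.stageFindGenes <- function(cfg, state, d) {
  sim <- .needState(state, "sim", "find-genes")
  params <- searchParams(min_score = cfg$min_score,
                         seed_length = cfg$seed_length,
                         neighborhood_threshold = cfg$neighborhood_threshold)
  state$models <- list(); state$core <- list()
  for (sp in .targetSpecies(sim)) {
    core <- extractCoreRegion(sim$annotations[[sp]],
                              setNames(sim$sequences[sp],
                                       paste0(sp, "_chr")),
                              cfg$flank5, cfg$flank3)
    models <- iterativeDiscovery(sim$query_set, core, params,
                                 max_rounds = cfg$max_rounds)
    state$core[[sp]] <- core
    state$models[[sp]] <- models
    writeGff3(models, file.path(d, paste0(sp, "_models.gff3")))
    prots <- setNames(vapply(models, proteinSeq, ""),
                      vapply(models, geneId, ""))
    writeFasta(prots[nzchar(prots)],
               file.path(d, paste0(sp, "_predicted_proteins.fa")))
  }
  state
}

.stageClassify <- function(cfg, state, d) {
  sim <- .needState(state, "sim", "classify")
  models <- .needState(state, "models", "classify")
  rows <- list()
  for (sp in names(models)) {
    for (i in seq_along(models[[sp]])) {
      m <- models[[sp]][[i]]
      m@gene_class <- classifyGeneType(
        m, sftp_min_cterm_len = cfg$sftp_min_cterm_len)
      # reference for pseudogene flagging: the seeding query, or (for
      # models seeded by a recycled discovery) the closest query protein
      ref <- if (m@source_query %in% names(sim$query_set))
        sim$query_set[[m@source_query]]
      else {
        sc <- vapply(sim$query_set, .globalScore, 0, b = m@protein)
        sim$query_set[[which.max(sc)]]
      }
      m@pseudogene_evidence <- detectPseudogene(m, ref)
      models[[sp]][[i]] <- m
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, gene_id = geneId(m), gene_class = geneClass(m),
        pseudogene = paste(pseudogeneFlags(m), collapse = ","),
        protein_length = nchar(proteinSeq(m)),
        source_query = m@source_query, stringsAsFactors = FALSE)
    }
    writeGff3(models[[sp]], file.path(d, paste0(sp, "_classified.gff3")))
  }
  .writeTsv(do.call(rbind, rows), file.path(d, "gene_classes.tsv"))
  state$models <- models
  state
}

.stageCompose <- function(cfg, state, d) {
  models <- .needState(state, "models", "compose")
  comp <- list(); cterm <- list()
  for (sp in names(models)) {
    prots <- setNames(vapply(models[[sp]], proteinSeq, ""),
                      vapply(models[[sp]], geneId, ""))
    prots <- prots[nzchar(prots)]
    cv <- aaComposition(prots)
    df <- data.frame(protein_id = rownames(cv),
                     length = attr(cv, "length"), cv, check.names = FALSE)
    .writeTsv(df, file.path(d, paste0(sp, "_composition.tsv")))
    comp[[sp]] <- cv
    segs <- c()
    for (m in models[[sp]]) {
      if (geneClass(m) == "SFTP" && !is.na(m@junction) &&
          m@junction < nchar(proteinSeq(m)))
        segs[geneId(m)] <- sftpCtermSegment(proteinSeq(m), m@junction)
    }
    if (length(segs))
      writeFasta(segs, file.path(d, paste0(sp, "_sftp_cterm.fa")))
    cterm[[sp]] <- segs
  }
  state$composition <- comp
  state$cterm <- cterm
  state
}

.stageCluster <- function(cfg, state, d) {
  comp <- .needState(state, "composition", "cluster")
  state$clusterings <- list()
  for (sp in names(comp)) {
    if (nrow(comp[[sp]]) < 2) next
    cl <- hierarchicalCluster(comp[[sp]], metric = cfg$cluster_metric,
                              linkage = cfg$cluster_linkage)
    writeLines(asNewick(cl), file.path(d, paste0(sp, "_dendrogram.nwk")))
    state$clusterings[[sp]] <- cl
  }
  state
}

# S100 domains of the query locus (a) and each target locus (b), labels
# locus-qualified for the orthology caller
.s100Domains <- function(sim, models_sp) {
  doms <- c()
  q <- sim$query_species
  for (fam in names(sim$query_set)) {
    j <- sim$junctions[[fam]]
    if (is.na(j)) next
    doms[paste0("a:", fam)] <- substring(sim$query_set[[fam]], 1, j)
  }
  for (m in models_sp) {
    if (sum(m@coding) == 2 && !is.na(m@junction))
      doms[paste0("b:", geneId(m))] <-
        substring(proteinSeq(m), 1, m@junction)
  }
  # outgroup: the query-species S100A11 flank
  og <- sim$proteins[[q]][[paste(q, "S100A11", sep = "_")]]
  doms["a:S100A11"] <- substring(og, 1, sim$junctions[["S100A11"]])
  doms
}

.stagePhylo <- function(cfg, state, d) {
  sim <- .needState(state, "sim", "phylo")
  models <- .needState(state, "models", "phylo")
  state$phylo <- list()
  for (sp in names(models)) {
    doms <- .s100Domains(sim, models[[sp]])
    if (length(doms) < 4) next
    aln <- progressiveAlign(doms)
    writeFasta(aln$rows, file.path(d, paste0(sp, "_s100_alignment.fa")))
    tr <- bootstrapSupport(aln, n_replicates = cfg$bootstrap_replicates,
                           seed = .childSeed(sim$seed, 77))
    rooted <- rootWithOutgroup(tr, "a:S100A11")
    ape::write.tree(rooted, file.path(d, paste0(sp, "_s100_tree.nwk")))
    groups <- phyloGroups(rooted, cfg$support_threshold)
    .writeJson(groups, file.path(d, paste0(sp, "_phylo_groups.json")))
    state$phylo[[sp]] <- list(tree = rooted, groups = groups)
  }
  state
}

# provisional symbols for discovered genes: the family of their best
# query, so synteny can see shared neighborhoods
.provisionalOrder <- function(models_sp, rbh) {
  sym <- setNames(rbh$a, rbh$b)
  data.frame(
    symbol = vapply(models_sp, function(m) {
      gid <- geneId(m)
      if (gid %in% names(sym)) sym[[gid]] else gid
    }, ""),
    strand = vapply(models_sp, function(m) m@strand, ""),
    stringsAsFactors = FALSE)
}

.stageOrtho <- function(cfg, state, d) {
  sim <- .needState(state, "sim", "ortho")
  models <- .needState(state, "models", "ortho")
  state$ortho <- list()
  for (sp in names(models)) {
    a_prots <- sim$query_set
    b_prots <- setNames(vapply(models[[sp]], proteinSeq, ""),
                        vapply(models[[sp]], geneId, ""))
    b_prots <- b_prots[nzchar(b_prots)]
    rbh <- reciprocalBestHits(a_prots, b_prots)
    order_a <- data.frame(
      symbol = names(a_prots),
      strand = vapply(names(a_prots), function(f) {
        i <- match(f, sim$orders[[sim$query_species]]$symbol)
        if (is.na(i)) "+" else sim$orders[[sim$query_species]]$strand[i]
      }, ""), stringsAsFactors = FALSE)
    # one consistent provisional naming for discovered genes (their best
    # query's family), applied to the order, the RBH pairs and the
    # phylo-group labels alike
    order_b <- .provisionalOrder(models[[sp]], rbh)
    gid2sym <- setNames(order_b$symbol,
                        vapply(models[[sp]], geneId, ""))
    rbh$b <- ifelse(rbh$b %in% names(gid2sym), gid2sym[rbh$b], rbh$b)
    groups <- if (!is.null(state$phylo[[sp]]))
      lapply(state$phylo[[sp]]$groups, function(s) {
        gid <- sub("^b:", "", s)
        ifelse(startsWith(s, "b:") & gid %in% names(gid2sym),
               paste0("b:", gid2sym[gid]), s)
      }) else NULL
    calls <- callOrthologs(rbh, order_a, order_b, phylo_groups = groups,
                           synteny_threshold = cfg$synteny_threshold,
                           window = cfg$synteny_window)
    .writeTsv(calls, file.path(d, paste0(sp, "_orthology_calls.tsv")))
    state$ortho[[sp]] <- calls
  }
  state
}

.stageCompareLoci <- function(cfg, state, d) {
  sim <- .needState(state, "sim", "compare-loci")
  q <- sim$query_species
  order_a <- sim$orders[[q]]
  reports <- list()
  for (sp in .targetSpecies(sim)) {
    rep <- detectLocusRearrangement(order_a, sim$orders[[sp]],
                                    flanks = c(cfg$flank5, cfg$flank3))
    reports[[sp]] <- rep
    .writeJson(list(
      n_segments = rep$n_segments,
      events = rep$events,
      flank_assignment = as.list(rep$flank_assignment)),
      file.path(d, paste0(sp, "_rearrangement.json")))
  }
  if (length(reports) >= 1) {
    placed <- placeEventsOnTree(reports, sim$tree)
    .writeTsv(placed, file.path(d, "events_on_tree.tsv"))
    state$events_placed <- placed
  }
  state$rearrangements <- reports
  state
}
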