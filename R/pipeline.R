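## End-to-end orchestration: similarity searches, family clustering, unique
## proteins, RBH core sets, replicon/origin/COG profiles and Ka/Ks analysis,
## with a summary report of the headline tables.

#' Run the full comparative pipeline
#'
#' Chains the stages over a set of genomes: an all-vs-all search for family
#' clustering (BLOSUM62 graph at `family_evalue`, MCL), unique-protein
#' detection (`exclusive_evalue`), a second search under the stricter
#' orthology scoring (BLOSUM80), reciprocal-best-hit orthologue groups and
#' core sets (with an ancestral core when `outgroup_id` is given), replicon
#' and origin composition profiles, COG tabulation, and NG86 Ka/Ks with the
#' consistent-replicon regression. Deterministic given identical inputs.
#'
#' @param genomes named list of [Genome-class] (ingroup plus, optionally,
#'   the outgroup).
#' @param outgroup_id id of the outgroup genome in `genomes`, or NULL.
#' @param family_scheme,ortho_scheme scoring schemes for the two searches.
#' @param family_evalue MCL graph inclusion threshold.
#' @param exclusive_evalue unique-protein threshold (strict `<`).
#' @param mcl [mclParams()].
#' @param thresholds [orthologyThresholds()] for RBH.
#' @param mode group assembly mode, `"clique"` or `"component"`.
#' @param search_method `"kmer"` or `"exact"`, see [allVsAll()].
#' @param hits_family,hits_ortho optional precomputed hit tables (e.g. from
#'   [readHitTable()]); when supplied the corresponding search is skipped.
#' @param kaks run the Ka/Ks stage (the slowest part).
#' @return list with elements `partition`, `venn`, `uniques`, `rbh`,
#'   `groups_ingroup`, `core`, `report` and, when requested, `kaks`
#'   (per-pair table) and `regression` (per consistency class).
#' @export
runPipeline <- function(genomes, outgroup_id = NULL,
                        family_scheme = scoringScheme("BLOSUM62"),
                        ortho_scheme = scoringScheme("BLOSUM80"),
                        family_evalue = 1e-7, exclusive_evalue = 1e-6,
                        mcl = mclParams(), thresholds = orthologyThresholds(),
                        mode = c("clique", "component"),
                        search_method = c("kmer", "exact"),
                        hits_family = NULL, hits_ortho = NULL,
                        kaks = TRUE) {
  mode <- match.arg(mode)
  search_method <- match.arg(search_method)
  gids <- vapply(genomes, genomeId, character(1))
  names(genomes) <- gids
  ingroup <- genomes[setdiff(gids, outgroup_id)]
  in_ids <- names(ingroup)

  if (is.null(hits_family))
    hits_family <- allVsAll(ingroup, family_scheme, method = search_method)
  if (is.null(hits_ortho))
    hits_ortho <- allVsAll(genomes, ortho_scheme, method = search_method)

  ## families
  all_genes <- unlist(lapply(ingroup, function(g) g@genes$gene_id),
                      use.names = FALSE)
  graph <- buildGraph(hits_family, all_genes, evalue_cutoff = family_evalue)
  clusters <- mclCluster(graph, mcl)
  partition <- partitionFamilies(clusters, ingroup)
  venn <- vennCounts(partition)
  uniques <- uniqueProteins(hits_family, ingroup,
                            exclusive_evalue = exclusive_evalue)

  ## orthology
  gmap <- geneGenomeMap(genomes)
  rbh_in <- rbhAllPairs(
    hits_ortho[gmap[hits_ortho$query] %in% in_ids &
               gmap[hits_ortho$subject] %in% in_ids, , drop = FALSE],
    ingroup, thresholds)
  groups_in <- assembleGroups(rbh_in, in_ids, gmap, mode = mode)
  groups_all <- NULL
  if (!is.null(outgroup_id)) {
    rbh_all <- rbhAllPairs(hits_ortho, genomes, thresholds)
    groups_all <- assembleGroups(rbh_all, names(genomes), gmap, mode = mode)
  }
  core <- coreSets(groups_in, groups_all, in_ids,
                   outgroup_id %||% character())

  ## profiles
  repart <- lapply(ingroup, function(g) repliconRepartition(groups_in, g))
  origin <- originComposition(groups_in, ingroup)
  cog <- if (!is.null(outgroup_id)) cogTabulate(core, genomes) else NULL

  res <- list(
    hits_family = hits_family, hits_ortho = hits_ortho,
    partition = partition, venn = venn, uniques = uniques,
    rbh = rbh_in, groups_ingroup = groups_in, core = core,
    report = list(
      replicon_summaries = lapply(genomes, repliconSummary),
      extrachromosomal = vapply(genomes, extrachromosomalFraction,
                                numeric(1)),
      venn = venn,
      unique_repartition = lapply(uniques, `[[`, "repartition"),
      core_repartition = repart,
      core_fraction = vapply(in_ids, function(g)
        coreFraction(nrow(groups_in), nrow(genomes[[g]]@genes)), integer(1)),
      origin_composition = origin,
      cog_table = cog))

  if (kaks && nrow(groups_in) >= 3L) {
    classes <- consistentSubset(groups_in, ingroup)
    kk <- coreKaks(groups_in, ingroup, classes)
    reg <- lapply(split(kk, kk$class), function(p)
      if (sum(p$status == "ok") >= 3L) kaksRegression(p) else NULL)
    res$kaks <- kk
    res$kaks_classes <- classes
    res$regression <- reg[!vapply(reg, is.null, logical(1))]
  }
  res
}
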