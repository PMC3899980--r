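## Reciprocal-best-hit orthology across N genomes, core-set construction
## (ingroup core and ancestral core with an outgroup), replicon/origin
## profiles and COG tabulation.

#' Orthology acceptance thresholds
#'
#' Defaults follow the strict criterion used for core-genome construction:
#' e-value at most 1e-12 under BLOSUM80 scoring, aligned region covering at
#' least 75% of both sequences, and positives amounting to at least 35% of
#' both sequence lengths.
#'
#' @param max_evalue e-value ceiling for both directional best hits.
#' @param min_aln_region minimum aligned fraction; applied to both query and
#'   subject coverage unless `coverage_on = "query"`.
#' @param min_similarity minimum similar residues as a fraction of both
#'   sequence lengths.
#' @param similarity_on `"positives"` (positive-scoring pairs, the default)
#'   or `"identities"`.
#' @param coverage_on `"both"` or `"query"` (single-sided).
#' @return list of class `OrthologyThresholds`.
#' @export
orthologyThresholds <- function(max_evalue = 1e-12, min_aln_region = 0.75,
                                min_similarity = 0.35,
                                similarity_on = c("positives", "identities"),
                                coverage_on = c("both", "query")) {
  stopifnot(max_evalue > 0, min_aln_region > 0, min_aln_region <= 1,
            min_similarity > 0, min_similarity <= 1)
  structure(list(max_evalue = max_evalue, min_aln_region = min_aln_region,
                 min_similarity = min_similarity,
                 similarity_on = match.arg(similarity_on),
                 coverage_on = match.arg(coverage_on)),
            class = "OrthologyThresholds")
}

## does each hit row satisfy the thresholds?
.hitQualifies <- function(h, lengths, th) {
  miss <- setdiff(unique(c(h$query, h$subject)), names(lengths))
  if (length(miss)) stopf("missing length for gene '%s'", miss[1])
  sim <- if (th$similarity_on == "positives") {
    if (anyNA(h$positives))
      stopf("hit table lacks positives; use similarity_on = 'identities'")
    h$positives
  } else round(h$pident * h$length / 100)
  cov_ok <- if (th$coverage_on == "both") h$qcov >= th$min_aln_region &
    h$scov >= th$min_aln_region else h$qcov >= th$min_aln_region
  h$evalue <= th$max_evalue & cov_ok &
    sim >= th$min_similarity * lengths[h$query] &
    sim >= th$min_similarity * lengths[h$subject]
}

## best hit per query among hits into one genome (bitscore desc, evalue asc,
## subject id lex)
.bestHits <- function(h) {
  if (!nrow(h)) return(h)
  ord <- order(h$query, -h$bitscore, h$evalue, h$subject)
  h <- h[ord, , drop = FALSE]
  h[!duplicated(h$query), , drop = FALSE]
}

#' Reciprocal best hits between two genomes
#'
#' A pair (a, b) is reported iff b is a's best hit in genome B, a is b's
#' best hit in genome A, and both directional hits satisfy the thresholds
#' (e-value, aligned-region and similarity floors on both sequences).
#'
#' @param hits_ab,hits_ba directed hit tables A -> B and B -> A.
#' @param lengths named vector of protein lengths (residues).
#' @param thresholds an [orthologyThresholds()] list.
#' @return data.frame with columns `a`, `b` and `total_bitscore` (sum of the
#'   two directional bit scores), sorted by `a`.
#' @export
rbhPairs <- function(hits_ab, hits_ba, lengths,
                     thresholds = orthologyThresholds()) {
  best_ab <- .bestHits(hits_ab)
  best_ba <- .bestHits(hits_ba)
  if (!nrow(best_ab) || !nrow(best_ba))
    return(data.frame(a = character(), b = character(),
                      total_bitscore = numeric()))
  fwd <- setNames(best_ab$subject, best_ab$query)
  rev <- setNames(best_ba$subject, best_ba$query)
  recip <- names(fwd)[!is.na(rev[fwd]) & rev[fwd] == names(fwd)]
  ok_ab <- best_ab[.hitQualifies(best_ab, lengths, thresholds), ]
  ok_ba <- best_ba[.hitQualifies(best_ba, lengths, thresholds), ]
  recip <- recip[recip %in% ok_ab$query & fwd[recip] %in% ok_ba$query]
  res <- data.frame(a = recip, b = unname(fwd[recip]),
                    total_bitscore =
                      ok_ab$bitscore[match(recip, ok_ab$query)] +
                      ok_ba$bitscore[match(unname(fwd[recip]), ok_ba$query)],
                    stringsAsFactors = FALSE)
  res[order(res$a), , drop = FALSE]
}

#' Reciprocal best hits for every genome pair
#'
#' Convenience wrapper splitting one global hit table by ordered genome pair
#' and calling [rbhPairs()] on each unordered pair.
#'
#' @param hits global hit table from [allVsAll()].
#' @param genomes list of [Genome-class].
#' @param thresholds an [orthologyThresholds()] list.
#' @return named list `"A|B"` (sorted ids) -> RBH data.frame.
#' @export
rbhAllPairs <- function(hits, genomes, thresholds = orthologyThresholds()) {
  gmap <- geneGenomeMap(genomes)
  lens <- unlist(lapply(genomes, function(g)
    setNames(Biostrings::width(g@proteins), names(g@proteins))))
  names(lens) <- sub("^[^.]*\\.", "", names(lens))
  qg <- gmap[hits$query]; sg <- gmap[hits$subject]
  gids <- vapply(genomes, genomeId, character(1))
  out <- list()
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (i >= j) next
    a <- gids[i]; b <- gids[j]
    key <- paste(sort(c(a, b)), collapse = "|")
    out[[key]] <- rbhPairs(hits[qg == a & sg == b, , drop = FALSE],
                           hits[qg == b & sg == a, , drop = FALSE],
                           lens, thresholds)
    ## orient columns to the sorted order
    if (sort(c(a, b))[1] != a)
      out[[key]] <- data.frame(a = out[[key]]$b, b = out[[key]]$a,
                               total_bitscore = out[[key]]$total_bitscore,
                               stringsAsFactors = FALSE)
  }
  out
}

#' Assemble N-way orthologue groups from pairwise RBH sets
#'
#' In `clique` mode (default) a group is a tuple with exactly one gene per
#' genome in which *every* genome pair is an RBH pair; in `component` mode a
#' connected component of the union RBH graph qualifies when it contains
#' exactly one gene per genome. Extraction is greedy in descending total bit
#' score (then lexicographic seed id) and each gene joins at most one group.
#'
#' @param rbh named list `"A|B"` -> RBH data.frame ([rbhAllPairs()]).
#' @param genome_ids character vector of the genome ids to span.
#' @param genome_of named gene id -> genome id map.
#' @param mode `"clique"` or `"component"`.
#' @return data.frame: `group` id plus one gene-id column per genome.
#' @export
assembleGroups <- function(rbh, genome_ids, genome_of,
                           mode = c("clique", "component")) {
  mode <- match.arg(mode)
  gids <- sort(genome_ids)
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (i < j && !paste(gids[i], gids[j], sep = "|") %in% names(rbh))
      stopf("missing RBH set for genome pair %s|%s", gids[i], gids[j])
  }
  partner <- list()   # partner[[X]][[Y]][gene in X] -> gene in Y
  for (key in names(rbh)) {
    xy <- strsplit(key, "|", fixed = TRUE)[[1]]
    df <- rbh[[key]]
    partner[[xy[1]]][[xy[2]]] <- setNames(df$b, df$a)
    partner[[xy[2]]][[xy[1]]] <- setNames(df$a, df$b)
  }
  groups <- if (mode == "clique") {
    .cliqueGroups(partner, gids, rbh)
  } else {
    .componentGroups(rbh, gids, genome_of)
  }
  if (!length(groups))
    return(cbind(data.frame(group = character()),
                 as.data.frame(matrix(character(), 0, length(gids),
                                      dimnames = list(NULL, gids)))))
  df <- as.data.frame(do.call(rbind, groups), stringsAsFactors = FALSE)
  names(df) <- gids
  ## deterministic order by first genome's member
  df <- df[order(df[[1]]), , drop = FALSE]
  rownames(df) <- NULL
  cbind(data.frame(group = sprintf("OG%04d", seq_len(nrow(df))),
                   stringsAsFactors = FALSE), df)
}

.cliqueGroups <- function(partner, gids, rbh) {
  first <- gids[1]
  seeds <- sort(names(partner[[first]][[gids[2]]]))
  ## greedy order: descending total bit score over the seed's pairs with the
  ## first genome, then lexicographic
  sc <- rbh[[paste(gids[1], gids[2], sep = "|")]]
  seed_score <- setNames(sc$total_bitscore, sc$a)[seeds]
  seeds <- seeds[order(-seed_score, seeds)]
  used <- character()
  groups <- list()
  for (a in seeds) {
    tuple <- setNames(character(length(gids)), gids)
    tuple[first] <- a
    ok <- TRUE
    for (g in gids[-1]) {
      p <- partner[[first]][[g]][a]
      if (is.na(p)) { ok <- FALSE; break }
      tuple[g] <- p
    }
    if (!ok) next
    for (i in seq_along(gids)) for (j in seq_along(gids)) {
      if (!ok || i >= j) next
      p <- partner[[gids[i]]][[gids[j]]][tuple[gids[i]]]
      if (is.na(p) || p != tuple[gids[j]]) ok <- FALSE
    }
    if (ok && !any(tuple %in% used)) {
      groups[[length(groups) + 1L]] <- tuple
      used <- c(used, tuple)
    }
  }
  groups
}

.componentGroups <- function(rbh, gids, genome_of) {
  edges <- do.call(rbind, lapply(rbh, function(df) df[, c("a", "b")]))
  if (is.null(edges) || !nrow(edges)) return(list())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  vs <- igraph::V(g)$name
  groups <- list()
  for (ci in seq_len(comp$no)) {
    mem <- sort(vs[comp$membership == ci])
    gg <- unname(genome_of[mem])
    if (length(mem) == length(gids) && setequal(gg, gids)) {
      tuple <- setNames(mem[match(gids, gg)], gids)
      groups[[length(groups) + 1L]] <- tuple
    }
  }
  groups
}

#' Construct ingroup-core and ancestral-core sets
#'
#' The ingroup core is the orthologue groups spanning every ingroup genome;
#' the ancestral core comes from the same procedure run with the outgroup
#' genome added. Reports how many ingroup-core groups are absent from the
#' ancestral core (matching groups by their member in the first ingroup
#' genome).
#'
#' @param groups_ingroup groups over the ingroup ([assembleGroups()]).
#' @param groups_with_outgroup groups over ingroup + outgroup, or NULL.
#' @param ingroup_ids,outgroup_id genome ids.
#' @return a [CoreSets-class]; its summary is printed by `show`.
#' @export
coreSets <- function(groups_ingroup, groups_with_outgroup = NULL,
                     ingroup_ids, outgroup_id = character()) {
  ingroup_ids <- sort(ingroup_ids)
  if (!all(ingroup_ids %in% names(groups_ingroup)))
    stopf("genome-set mismatch: ingroup groups lack %s",
          paste(setdiff(ingroup_ids, names(groups_ingroup)), collapse = ", "))
  anc <- groups_with_outgroup
  if (is.null(anc)) {
    anc <- groups_ingroup[0, , drop = FALSE]
  } else if (length(outgroup_id) &&
             !all(c(ingroup_ids, outgroup_id) %in% names(anc))) {
    stopf("genome-set mismatch between ingroup and outgroup group tables")
  }
  new("CoreSets", ingroup_core = groups_ingroup, ancestral_core = anc,
      ingroup_ids = ingroup_ids, outgroup_id = outgroup_id)
}

#' @describeIn coreSets number of ingroup-core groups missing from the
#'   ancestral core (matched via the first ingroup genome's member).
#' @param x a [CoreSets-class].
#' @export
coreAbsentFromAncestral <- function(x) {
  ref <- x@ingroup_ids[1]
  sum(!x@ingroup_core[[ref]] %in% x@ancestral_core[[ref]])
}

#' Core-genome fraction of a proteome
#'
#' `round(100 * core_size / proteome_size)`, half-up.
#'
#' @param core_size number of core orthologue groups.
#' @param proteome_size total proteins encoded by the genome.
#' @return integer percentage.
#' @examples
#' coreFraction(2328, 6185)   # 38
#' coreFraction(2328, 7846)   # 30
#' @export
coreFraction <- function(core_size, proteome_size) {
  stopifnot(core_size >= 0, proteome_size > 0)
  as.integer(roundHalfUp(100 * core_size / proteome_size))
}

#' Replicon repartition of core genes in one genome
#'
#' Fraction of a genome's core-group members carried by each of its
#' replicons; fractions sum to 1.
#'
#' @param groups group table from [assembleGroups()].
#' @param genome a [Genome-class] whose id is a column of `groups`.
#' @return named numeric vector over the genome's replicons.
#' @export
repliconRepartition <- function(groups, genome) {
  gid <- genomeId(genome)
  if (!gid %in% names(groups)) stopf("groups carry no column for genome %s", gid)
  genes <- groups[[gid]]
  repl <- genome@genes$replicon[match(genes, genome@genes$gene_id)]
  if (anyNA(repl)) stopf("group member absent from genome %s", gid)
  tab <- table(factor(repl, levels = genome@replicons$name))
  setNames(as.numeric(tab) / length(genes), genome@replicons$name)
}

#' Origin composition of core groups
#'
#' Each group is labelled by majority vote over its members' origin
#' annotations (ties give `unassigned`); returns the fractions of groups per
#' label.
#'
#' @param groups group table from [assembleGroups()].
#' @param genomes list of [Genome-class] covering the group columns.
#' @return named fractions over `ancestral`, `HGT`, `unassigned`
#'   (summing to 1).
#' @export
originComposition <- function(groups, genomes) {
  origin_of <- unlist(lapply(genomes, function(g)
    setNames(g@genes$origin, g@genes$gene_id)))
  names(origin_of) <- sub("^[^.]*\\.", "", names(origin_of))
  gcols <- intersect(names(groups), vapply(genomes, genomeId, character(1)))
  lab <- apply(groups[, gcols, drop = FALSE], 1, function(mem) {
    v <- origin_of[unlist(mem)]
    v <- v[!is.na(v)]
    if (!length(v)) return("unassigned")
    tt <- sort(table(v), decreasing = TRUE)
    if (length(tt) > 1L && tt[1] == tt[2]) "unassigned" else names(tt)[1]
  })
  tab <- table(factor(lab, levels = c("ancestral", "HGT", "unassigned")))
  setNames(as.numeric(tab) / nrow(groups), names(tab))
}

#' COG tabulation of core groups
#'
#' Counts orthologue groups per COG functional category for (a) the
#' ancestral core and (b) the ingroup-core groups absent from the ancestral
#' core, using the annotation of one reference genome's member per group
#' (when a member lists several comma-separated letters the first is used).
#' Optionally adds a per-category two-sided Fisher exact comparison with
#' Benjamini-Hochberg correction.
#'
#' @param core a [CoreSets-class].
#' @param genomes named list of [Genome-class].
#' @param reference id of the reference genome (must span all groups).
#' @param fisher add the optional enrichment test (off by default; the
#'   primary output is raw counts).
#' @return data.frame with rows for the 20 COG letters plus `none`, columns
#'   `ancestral_core` and `ingroup_only` (and test columns when requested).
#' @export
cogTabulate <- function(core, genomes, reference = core@ingroup_ids[1],
                        fisher = FALSE) {
  if (!reference %in% names(core@ingroup_core))
    stopf("reference genome %s absent from the groups", reference)
  gen <- genomes[[reference]]
  cog_of <- setNames(gen@genes$cog_letter, gen@genes$gene_id)
  firstLetter <- function(x) {
    x <- sub(",.*$", "", x)
    ifelse(is.na(x) | x == "", NA_character_, substr(x, 1, 1))
  }
  anc_ref <- core@ancestral_core[[reference]]
  only_ref <- setdiff(core@ingroup_core[[reference]], anc_ref)
  lv <- c(.COG_LETTERS, "none")
  cnt <- function(ids) {
    l <- firstLetter(cog_of[ids])
    l[is.na(l)] <- "none"
    table(factor(l, levels = lv))
  }
  out <- data.frame(cog = lv,
                    ancestral_core = as.integer(cnt(anc_ref)),
                    ingroup_only = as.integer(cnt(only_ref)),
                    stringsAsFactors = FALSE)
  if (fisher) {
    tot <- colSums(out[, 2:3])
    p <- vapply(seq_len(nrow(out)), function(i) {
      stats::fisher.test(matrix(c(out$ancestral_core[i],
                                  tot[1] - out$ancestral_core[i],
                                  out$ingroup_only[i],
                                  tot[2] - out$ingroup_only[i]), 2))$p.value
    }, numeric(1))
    out$p_value <- p
    out$p_adj <- stats::p.adjust(p, method = "BH")
  }
  out
}
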