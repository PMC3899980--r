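## Protein families: similarity graph from the hit table, Markov clustering
## (implemented here: column-stochastic normalisation, expansion by matrix
## squaring, inflation by entrywise powering, iteration to idempotence),
## genome-membership (Venn) partition and unique-protein reports.

#' MCL parameters
#'
#' @param inflation entrywise power applied after each expansion; > 1.
#' @param expansion matrix power of the expansion step.
#' @param prune_threshold entries below this are dropped (then columns are
#'   renormalised) to keep the matrix sparse.
#' @param max_iters iteration cap; exceeding it is a diagnostic error.
#' @param convergence_eps converged when the largest absolute change of any
#'   matrix entry falls below this.
#' @return list of class `MCLParams`.
#' @export
mclParams <- function(inflation = 1.2, expansion = 2L, prune_threshold = 1e-5,
                      max_iters = 200L, convergence_eps = 1e-6) {
  stopifnot(inflation > 1, expansion >= 2L, prune_threshold >= 0,
            max_iters >= 1L, convergence_eps > 0)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iters = as.integer(max_iters),
                 convergence_eps = convergence_eps),
            class = "MCLParams")
}

#' Build the protein similarity graph
#'
#' Undirected graph over all genes with an edge wherever some hit in either
#' direction reaches `evalue_cutoff`; the edge weight is
#' `min(200, -log10(E))` of the best e-value over both directions (capped so
#' E = 0 has finite weight). Genes without hits become isolated vertices.
#'
#' @param hits hit table ([allVsAll()] / [readHitTable()]).
#' @param genes character vector of all gene ids (the vertex set; genes
#'   absent from any hit must still be clustered as singletons).
#' @param evalue_cutoff inclusion threshold on E.
#' @param include_self_genome keep hits between genes of the same genome
#'   (in-paralogs); requires `genome_of` when disabled.
#' @param genome_of named gene id -> genome id map, only used when
#'   `include_self_genome = FALSE`.
#' @return an [igraph::graph] with vertex names and edge `weight`.
#' @export
buildGraph <- function(hits, genes, evalue_cutoff = 1e-7,
                       include_self_genome = TRUE, genome_of = NULL) {
  h <- hits[hits$evalue <= evalue_cutoff, c("query", "subject", "evalue")]
  if (!include_self_genome) {
    if (is.null(genome_of))
      stopf("genome_of is required when dropping self-genome hits")
    h <- h[genome_of[h$query] != genome_of[h$subject], ]
  }
  if (nrow(h)) {
    a <- pmin(h$query, h$subject)
    b <- pmax(h$query, h$subject)
    w <- pmin(200, -log10(pmax(h$evalue, 1e-300)))
    w[h$evalue == 0] <- 200
    best <- tapply(w, paste(a, b, sep = "\r"), max)
    ab <- strsplit(names(best), "\r", fixed = TRUE)
    edges <- data.frame(from = vapply(ab, `[`, character(1), 1L),
                        to = vapply(ab, `[`, character(1), 2L),
                        weight = as.numeric(best), stringsAsFactors = FALSE)
    edges <- edges[edges$from != edges$to & edges$weight > 0, ]
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = sort(unique(genes)))
  g
}

#' Markov clustering
#'
#' From-scratch MCL on a weighted undirected graph. Self-loops equal to each
#' node's maximum incident edge weight (1 for isolated nodes) are added, the
#' adjacency matrix is made column-stochastic, and expansion (matrix power)
#' alternates with inflation (entrywise power + renormalisation) with
#' pruning, until the matrix change falls below `convergence_eps`. Clusters
#' are read off the attractor structure: attractor rows (positive diagonal)
#' are merged when they attract each other, and every node joins the
#' attractor with the largest weight in its column (ties broken towards the
#' lexicographically smallest attractor). Nodes are processed in
#' lexicographic order, so the result is deterministic. The computation runs
#' per connected component.
#'
#' @param graph an [igraph::graph] from [buildGraph()].
#' @param params an `MCLParams` list, see [mclParams()].
#' @return named list: cluster id (`"C0001"`, ...) -> member gene ids;
#'   clusters are ordered by their lexicographically smallest member.
#' @export
mclCluster <- function(graph, params = mclParams()) {
  nodes <- sort(igraph::V(graph)$name)
  if (!length(nodes)) stopf("graph is empty")
  graph <- igraph::permute(graph, match(igraph::V(graph)$name,
                                        nodes))
  comp <- igraph::components(graph)
  clusters <- list()
  for (ci in seq_len(comp$no)) {
    members <- nodes[comp$membership == ci]
    sub <- igraph::induced_subgraph(graph, members)
    m <- igraph::as_adjacency_matrix(sub, attr = if (igraph::ecount(sub))
      "weight" else NULL, sparse = TRUE)
    m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
    clusters <- c(clusters, .mclCore(m, params))
  }
  ## order deterministically by smallest member and label
  firsts <- vapply(clusters, min, character(1))
  clusters <- clusters[order(firsts)]
  names(clusters) <- sprintf("C%04d", seq_along(clusters))
  clusters
}

## MCL iteration on one (sparse) adjacency matrix with named dimnames
.mclCore <- function(adj, params) {
  nm <- rownames(adj)
  n <- length(nm)
  if (n == 1L) return(list(nm))
  m <- methods::as(adj, "CsparseMatrix")
  loops <- apply(m, 2, max)
  loops[loops <= 0] <- 1
  diag(m) <- loops
  norml <- function(x) {
    cs <- Matrix::colSums(x)
    x %*% Matrix::Diagonal(x = 1 / cs)
  }
  m <- norml(m)
  for (it in seq_len(params$max_iters)) {
    old <- m
    ex <- m
    for (k in seq_len(params$expansion - 1L)) ex <- ex %*% m
    ex <- methods::as(ex, "CsparseMatrix")
    ex@x <- ex@x^params$inflation
    ex@x[ex@x < params$prune_threshold] <- 0
    ex <- Matrix::drop0(ex)
    m <- norml(ex)
    if (max(abs(m - old)) < params$convergence_eps) {
      return(.readClusters(as.matrix(m), nm, params$prune_threshold))
    }
  }
  stopf("MCL did not converge within %d iterations", params$max_iters)
}

## interpret the idempotent matrix: attractors and their basins
.readClusters <- function(m, nm, eps) {
  att <- which(diag(m) > eps)
  if (!length(att)) att <- which.max(diag(m))
  ## merge attractors that attract each other (overlapping systems)
  owner <- seq_along(att)
  for (i in seq_along(att)) for (j in seq_along(att)) {
    if (i < j && (m[att[i], att[j]] > eps || m[att[j], att[i]] > eps)) {
      o <- owner[j]; owner[owner == o] <- owner[i]
    }
  }
  assign_to <- integer(length(nm))
  for (j in seq_along(nm)) {
    w <- m[att, j]
    if (all(w <= eps)) {
      ## unattached column (numerical corner); give it its own best row
      assign_to[j] <- owner[which.max(w)]
    } else {
      best <- max(w)
      cand <- which(w >= best - 1e-12)
      assign_to[j] <- owner[cand[1L]]   # rows sorted, so ties -> smallest
    }
  }
  lapply(split(nm, assign_to), sort)
}

#' Partition clusters into families and singletons
#'
#' Clusters with at least two members become protein families (whatever
#' their genome composition, so paralog-only families are possible);
#' single-member clusters are recorded per genome as singletons.
#'
#' @param clusters named list from [mclCluster()].
#' @param genomes list of [Genome-class] (supplies the gene -> genome map).
#' @return a [FamilyPartition-class].
#' @export
partitionFamilies <- function(clusters, genomes) {
  gmap <- geneGenomeMap(genomes)
  sizes <- lengths(clusters)
  fams <- clusters[sizes >= 2L]
  names(fams) <- sprintf("FAM%04d", seq_along(fams))
  singles <- unlist(clusters[sizes == 1L], use.names = FALSE)
  gids <- vapply(genomes, genomeId, character(1))
  singletons <- lapply(setNames(gids, gids), function(g)
    sort(singles[gmap[singles] == g]))
  profile <- lapply(fams, function(mem) sort(unique(unname(gmap[mem]))))
  new("FamilyPartition", families = fams, singletons = singletons,
      membership_profile = profile, genome_of = gmap)
}

#' Family counts per genome-subset region
#'
#' Counts families whose genome membership profile equals each of the
#' `2^n - 1` genome subsets, together with per-genome singleton counts (the
#' parenthesised numbers of a pan-genome Venn diagram). Region counts sum to
#' the number of families.
#'
#' @param partition a [FamilyPartition-class].
#' @return list with `regions` (named integer vector keyed by
#'   `"G1+G2"`-style subset strings), `singletons` (named integer) and
#'   `n_families`.
#' @export
vennCounts <- function(partition) {
  gids <- sort(names(partition@singletons))
  if (length(gids) < 2L) stopf("need at least two genomes")
  subsets <- unlist(lapply(seq_along(gids), function(k)
    utils::combn(gids, k, paste, collapse = "+", simplify = TRUE)))
  key <- vapply(partition@membership_profile, paste, character(1),
                collapse = "+")
  counts <- table(factor(key, levels = subsets))
  list(regions = setNames(as.integer(counts), subsets),
       singletons = lengths(partition@singletons)[gids],
       n_families = length(partition@families))
}

#' Percentage of shared families
#'
#' `round(100 * shared / total)` with half-up rounding.
#'
#' @param shared_count,total_count non-negative counts, `total_count > 0`.
#' @return integer percentage.
#' @examples
#' percentShared(2600, 5575)   # 47
#' @export
percentShared <- function(shared_count, total_count) {
  stopifnot(total_count > 0, shared_count >= 0,
            shared_count <= total_count)
  as.integer(roundHalfUp(100 * shared_count / total_count))
}

#' Strain-unique proteins and their replicon repartition
#'
#' A gene is unique to its genome iff it has no hit in any *other* genome at
#' `E < exclusive_evalue` (hits within its own genome are ignored). For each
#' genome the unique set and its distribution over replicons (fractions
#' summing to 1) are returned.
#'
#' @param hits hit table.
#' @param genomes list of [Genome-class].
#' @param exclusive_evalue exclusivity threshold (strict).
#' @return list per genome: `genes` (character) and `repartition` (named
#'   fractions over that genome's replicons).
#' @export
uniqueProteins <- function(hits, genomes, exclusive_evalue = 1e-6) {
  gmap <- geneGenomeMap(genomes)
  cross <- hits$evalue < exclusive_evalue &
    gmap[hits$query] != gmap[hits$subject]
  has_hit <- unique(hits$query[cross])
  out <- list()
  for (g in genomes) {
    gt <- g@genes
    uniq <- sort(setdiff(gt$gene_id, has_hit))
    repl <- factor(gt$replicon[match(uniq, gt$gene_id)],
                   levels = g@replicons$name)
    rep_frac <- if (length(uniq)) as.numeric(table(repl)) / length(uniq)
                else rep(NA_real_, nrow(g@replicons))
    out[[genomeId(g)]] <- list(
      genes = uniq,
      repartition = setNames(rep_frac, g@replicons$name))
  }
  out
}
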