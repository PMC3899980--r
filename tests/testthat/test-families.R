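mkGraph <- function(edges, genes) {
  ## edges: data.frame(query, subject, evalue) both directions not required
  hits <- data.frame(query = edges$query, subject = edges$subject,
                     evalue = edges$evalue)
  buildGraph(hits, genes)
}

test_that("graph construction applies the cutoff and best-evalue max rule", {
  genes <- c("a", "b", "c")
  g <- mkGraph(data.frame(query = "a", subject = "b", evalue = 1e-3), genes)
  expect_equal(igraph::ecount(g), 0)          # above cutoff: no edges
  expect_equal(igraph::vcount(g), 3)

  g <- mkGraph(data.frame(query = c("a", "b"), subject = c("b", "a"),
                          evalue = c(1e-30, 1e-9)), genes)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 30)       # better of the two directions
  ## zero e-value is capped
  g <- mkGraph(data.frame(query = "a", subject = "b", evalue = 0), genes)
  expect_equal(igraph::E(g)$weight, 200)
})

test_that("MCL separates disjoint cliques and keeps isolated nodes", {
  tri <- function(v) data.frame(query = v[c(1, 2, 3)], subject = v[c(2, 3, 1)],
                                evalue = 1e-20)
  g <- mkGraph(rbind(tri(c("a", "b", "c")), tri(c("x", "y", "z"))),
               c("a", "b", "c", "x", "y", "z", "lone"))
  cl <- mclCluster(g, mclParams(inflation = 2))
  expect_true(samePartition(cl, list(c("a", "b", "c"), c("x", "y", "z"),
                                     "lone")))
})

test_that("MCL output matches the dense reference on random graphs", {
  set.seed(77)
  for (rep in 1:12) {
    n <- sample(8:30, 1)
    nm <- sprintf("n%02d", 1:n)
    p <- runif(1, 0.1, 0.35)
    adj <- matrix(0, n, n, dimnames = list(nm, nm))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (runif(1) < p) adj[i, j] <- adj[j, i] <- round(runif(1, 0.5, 30), 2)
    }
    el <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    hits <- data.frame(query = nm[el[, 1]], subject = nm[el[, 2]],
                       evalue = 10^(-adj[el]))
    g <- buildGraph(hits, nm, evalue_cutoff = 1)
    infl <- sample(c(1.4, 2, 3), 1)
    got <- mclCluster(g, mclParams(inflation = infl))
    want <- mclOracle(adj, infl)
    expect_true(samePartition(got, want), info = paste("rep", rep))
  }
})

test_that("MCL always returns a partition and never merges components", {
  set.seed(42)
  sim <- smallSim()
  genomes <- ingroupOf(sim)
  hits <- allVsAll(genomes, scoringScheme("BLOSUM62"))
  genes <- unlist(lapply(genomes, function(g) geneTable(g)$gene_id),
                  use.names = FALSE)
  g <- buildGraph(hits, genes)
  comp <- igraph::components(g)$membership
  for (infl in c(1.2, 2)) {
    cl <- mclCluster(g, mclParams(inflation = infl))
    mem <- unlist(cl, use.names = FALSE)
    expect_setequal(mem, genes)                 # no node lost or duplicated
    expect_equal(anyDuplicated(mem), 0L)
    for (v in cl)                               # clusters within components
      expect_length(unique(comp[v]), 1L)
  }
})

test_that("non-convergence raises a diagnostic error", {
  ## a path graph is not idempotent after one expansion/inflation round
  path <- data.frame(query = c("a", "b"), subject = c("b", "c"),
                     evalue = c(1e-20, 1e-10))
  g <- mkGraph(path, c("a", "b", "c"))
  expect_error(mclCluster(g, mclParams(max_iters = 1L)), "converge")
})

test_that("families partition into >=2-member clusters plus singletons", {
  sim <- smallSim()
  genomes <- ingroupOf(sim)
  hits <- allVsAll(genomes, scoringScheme("BLOSUM62"))
  genes <- unlist(lapply(genomes, function(g) geneTable(g)$gene_id),
                  use.names = FALSE)
  part <- partitionFamilies(mclCluster(buildGraph(hits, genes)), genomes)
  expect_true(all(lengths(familyMembers(part)) >= 2))
  expect_setequal(c(unlist(familyMembers(part), use.names = FALSE),
                    unlist(familySingletons(part), use.names = FALSE)),
                  genes)
  ## at default divergence, the true families are recovered
  truefams <- trueFamilies(sim$truth)
  expect_gte(mean(familyKeys(truefams) %in% familyKeys(familyMembers(part))),
             0.95)
})

test_that("venn regions conserve totals", {
  sim <- smallSim()
  genomes <- ingroupOf(sim)
  hits <- allVsAll(genomes, scoringScheme("BLOSUM62"))
  genes <- unlist(lapply(genomes, function(g) geneTable(g)$gene_id),
                  use.names = FALSE)
  part <- partitionFamilies(mclCluster(buildGraph(hits, genes)), genomes)
  v <- vennCounts(part)
  expect_equal(sum(v$regions), v$n_families)
  expect_length(v$regions, 2^4 - 1)
  ## the core families land in the centre region
  expect_gte(v$regions[["G1+G2+G3+G4"]], 40)
  expect_equal(unname(v$singletons),
               unname(lengths(familySingletons(part))[names(v$singletons)]))
})

test_that("a family spanning one genome has a single-genome profile", {
  fams <- list(FAM0001 = c("G1_a", "G1_b"), FAM0002 = c("G1_c", "G2_a"))
  part <- new("FamilyPartition", families = fams,
              singletons = list(G1 = character(), G2 = "G2_b"),
              membership_profile = list(FAM0001 = "G1",
                                        FAM0002 = c("G1", "G2")),
              genome_of = c(G1_a = "G1", G1_b = "G1", G1_c = "G1",
                            G2_a = "G2", G2_b = "G2"))
  v <- vennCounts(part)
  expect_equal(v$regions[["G1"]], 1L)
  expect_equal(v$regions[["G1+G2"]], 1L)
  expect_equal(v$regions[["G2"]], 0L)
})

test_that("shared-family percentages round half-up", {
  expect_equal(percentShared(2600, 5575), 47L)
  expect_equal(percentShared(4136, 5575), 74L)
  expect_equal(percentShared(0, 10), 0L)
  expect_equal(percentShared(10, 10), 100L)
  expect_equal(percentShared(1, 200), 1L)      # 0.5 rounds up
  expect_error(percentShared(5, 0))
})

test_that("unique proteins are exactly the no-cross-hit genes", {
  sim <- smallSim()
  genomes <- ingroupOf(sim)
  hits <- allVsAll(genomes, scoringScheme("BLOSUM62"))
  uq <- uniqueProteins(hits, genomes)
  tr <- sim$truth
  found <- unlist(lapply(uq, `[[`, "genes"), use.names = FALSE)
  truly <- names(tr@family_of)[grepl("^U_", tr@family_of) &
                               !grepl("^OUT", names(tr@family_of))]
  expect_true(all(truly %in% found))
  expect_equal(sum(grepl("^F", tr@family_of[found])), 0)  # no core gene
  for (g in names(uq)) {
    if (length(uq[[g]]$genes))
      expect_equal(sum(uq[[g]]$repartition), 1)
  }
  ## two identical genomes -> zero uniques
  sim0 <- generatePanGenome(smallConfig(branch_sub_rate = 0,
                                        n_unique_per_genome = 0L,
                                        seed = 21L,
                                        replicon_plan = {
                                          p <- smallPlan()
                                          p$target_gene_count <- c(27L, 12L, 6L)
                                          p
                                        }))
  gg <- sim0$genomes[c("G1", "G2")]
  h0 <- allVsAll(gg, scoringScheme("BLOSUM62"))
  uq0 <- uniqueProteins(h0, gg)
  expect_equal(lengths(lapply(uq0, `[[`, "genes")),
               c(G1 = 0L, G2 = 0L))
})
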