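# hand-built hit rows for threshold tests
mkHit <- function(q, s, evalue = 1e-30, bitscore = 500, qcov = 1, scov = 1,
                  positives = 100, pident = 90, len = 100) {
  data.frame(query = q, subject = s, pident = pident, length = len,
             mismatches = 5L, gapopen = 0L, qstart = 1L, qend = len,
             sstart = 1L, send = len, evalue = evalue, bitscore = bitscore,
             positives = positives, qcov = qcov, scov = scov,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best hits respect every threshold", {
  lens <- c(a1 = 100L, a2 = 100L, b1 = 100L, b2 = 100L)
  th <- orthologyThresholds()
  ## clean reciprocal pair
  ab <- mkHit("a1", "b1")
  ba <- mkHit("b1", "a1")
  expect_equal(rbhPairs(ab, ba, lens, th)$a, "a1")
  ## coverage failure on one side excludes the pair
  expect_equal(nrow(rbhPairs(mkHit("a1", "b1", qcov = 0.70), ba, lens, th)), 0)
  ## e-value above the ceiling excludes
  expect_equal(nrow(rbhPairs(mkHit("a1", "b1", evalue = 1e-10), ba, lens, th)), 0)
  ## similarity below 35% of either length excludes
  expect_equal(nrow(rbhPairs(mkHit("a1", "b1", positives = 30), ba, lens, th)), 0)
  lens2 <- c(a1 = 100L, b1 = 400L)
  expect_equal(nrow(rbhPairs(mkHit("a1", "b1", positives = 100),
                             mkHit("b1", "a1", positives = 100), lens2, th)), 0)
  ## reciprocity: a1's best is b1, but b1's best is a2, so only the
  ## mutually-best pair (a2, b1) survives
  ab2 <- rbind(mkHit("a1", "b1"), mkHit("a2", "b1", bitscore = 400))
  ba2 <- rbind(mkHit("b1", "a2", bitscore = 600), mkHit("b1", "a1"))
  got <- rbhPairs(ab2, ba2, lens, th)
  expect_equal(got$a, "a2")
  expect_equal(got$b, "b1")
  ## missing length is an error
  expect_error(rbhPairs(mkHit("a9", "b1"), mkHit("b1", "a9"), lens, th),
               "missing length")
})

test_that("RBH is symmetric and monotone in the thresholds", {
  sim <- smallSim()
  genomes <- ingroupOf(sim)[c("G1", "G2")]
  hits <- allVsAll(genomes, scoringScheme("BLOSUM80"))
  gmap <- geneGenomeMap(genomes)
  lens <- unlist(lapply(genomes, function(g)
    setNames(Biostrings::width(proteinSeqs(g)), names(proteinSeqs(g)))))
  names(lens) <- sub("^[^.]*\\.", "", names(lens))
  hab <- hits[gmap[hits$query] == "G1" & gmap[hits$subject] == "G2", ]
  hba <- hits[gmap[hits$query] == "G2" & gmap[hits$subject] == "G1", ]
  th <- orthologyThresholds()
  p1 <- rbhPairs(hab, hba, lens, th)
  p2 <- rbhPairs(hba, hab, lens, th)
  expect_setequal(paste(p1$a, p1$b), paste(p2$b, p2$a))
  expect_gt(nrow(p1), 0)
  ## raising any threshold never increases the pair count
  for (tighter in list(orthologyThresholds(max_evalue = 1e-40),
                       orthologyThresholds(min_aln_region = 0.95),
                       orthologyThresholds(min_similarity = 0.8))) {
    expect_lte(nrow(rbhPairs(hab, hba, lens, tighter)), nrow(p1))
  }
})

test_that("clique and component assembly modes differ as specified", {
  gmap <- c(a1 = "A", b1 = "B", c1 = "C")
  full <- list("A|B" = data.frame(a = "a1", b = "b1", total_bitscore = 10),
               "A|C" = data.frame(a = "a1", b = "c1", total_bitscore = 10),
               "B|C" = data.frame(a = "b1", b = "c1", total_bitscore = 10))
  g <- assembleGroups(full, c("A", "B", "C"), gmap, mode = "clique")
  expect_equal(nrow(g), 1)
  expect_equal(unlist(g[1, c("A", "B", "C")], use.names = FALSE),
               c("a1", "b1", "c1"))

  chain <- full
  chain[["A|C"]] <- data.frame(a = character(), b = character(),
                               total_bitscore = numeric())
  expect_equal(nrow(assembleGroups(chain, c("A", "B", "C"), gmap,
                                   mode = "clique")), 0)
  expect_equal(nrow(assembleGroups(chain, c("A", "B", "C"), gmap,
                                   mode = "component")), 1)
  expect_error(assembleGroups(full[1:2], c("A", "B", "C"), gmap), "missing RBH")
})

test_that("groups and core sets are recovered on synthetic data", {
  sim <- smallSim()
  res <- smallRun()
  og <- sim$truth@ortho_groups
  gid4 <- paste0("G", 1:4)
  expect_gte(mean(tupleKeys(og, gid4) %in%
                  tupleKeys(res$groups_ingroup, gid4)), 0.95)
  ## clique-mode member sets are a subset of component-mode member sets
  gmap <- geneGenomeMap(sim$genomes)
  comp <- assembleGroups(res$rbh, gid4, gmap, mode = "component")
  expect_true(all(tupleKeys(res$groups_ingroup, gid4) %in%
                  tupleKeys(comp, gid4)))
  ## HGT-pool families reach the ingroup core but never the ancestral core
  anc_keys <- tupleKeys(res$core@ancestral_core, gid4)
  azo_keys <- tupleKeys(res$groups_ingroup, gid4)
  hgt_keys <- tupleKeys(og[!og$in_anc, ], gid4)
  expect_true(all(hgt_keys %in% azo_keys))
  expect_false(any(hgt_keys %in% anc_keys))
  expect_gte(nrow(res$groups_ingroup), nrow(res$core@ancestral_core))
  ## ancestral-core groups restricted to the ingroup appear in the ingroup core
  expect_true(all(anc_keys %in% azo_keys))
})

test_that("zero-divergence core size equals the configured family count", {
  sim <- generatePanGenome(smallConfig(branch_sub_rate = 0, seed = 31L))
  res <- runPipeline(ingroupOf(sim), kaks = FALSE)
  expect_equal(nrow(res$groups_ingroup), 40L)
})

test_that("outgroup identical to an ingroup genome reproduces the ingroup core", {
  sim <- generatePanGenome(smallConfig(seed = 17L))
  genomes <- ingroupOf(sim)
  ## duplicate G1 as a fake outgroup
  g1 <- genomes$G1
  dup <- g1
  dup@id <- "OUT"
  dup@genes$gene_id <- sub("^G1", "OUT", dup@genes$gene_id)
  dup@genes$genome_id <- "OUT"
  names(dup@proteins) <- sub("^G1", "OUT", names(dup@proteins))
  names(dup@cds) <- sub("^G1", "OUT", names(dup@cds))
  res <- runPipeline(c(genomes, list(OUT = dup)), outgroup_id = "OUT",
                     kaks = FALSE)
  gid4 <- paste0("G", 1:4)
  expect_setequal(tupleKeys(res$core@ancestral_core, gid4),
                  tupleKeys(res$groups_ingroup, gid4))
  expect_equal(coreAbsentFromAncestral(res$core), 0)
})

test_that("core fractions and repartitions behave", {
  expect_equal(coreFraction(2328, 6185), 38L)
  expect_equal(coreFraction(2328, 7846), 30L)
  expect_equal(coreFraction(0, 10), 0L)
  sim <- smallSim()
  res <- smallRun()
  for (g in ingroupOf(sim)) {
    rr <- repliconRepartition(res$groups_ingroup, g)
    expect_equal(sum(rr), 1)
  }
})

test_that("origin composition uses a majority vote with ties unassigned", {
  mkg <- function(id, origins) {
    n <- length(origins)
    gids <- sprintf("%s_g%02d", id, 1:n)
    new("Genome", id = id,
        replicons = data.frame(name = "chromosome", length_bp = 1000L,
                               gc_percent = 60, orf_count = n,
                               replication_class = "oriC",
                               rrna_count = NA_integer_,
                               trna_count = NA_integer_),
        genes = data.frame(gene_id = gids, genome_id = id,
                           replicon = "chromosome",
                           start = seq(1, by = 30, length.out = n),
                           end = seq(9, by = 30, length.out = n),
                           strand = "+", cog_letter = "J", origin = origins,
                           essential = FALSE),
        proteins = Biostrings::AAStringSet(setNames(rep("MKV", n), gids)),
        cds = Biostrings::DNAStringSet(setNames(rep("ATGAAAGTT", n), gids)))
  }
  gs <- list(A = mkg("A", c("ancestral", "ancestral")),
             B = mkg("B", c("HGT", "ancestral")),
             C = mkg("C", c("ancestral", "HGT")),
             D = mkg("D", c("ancestral", "HGT")))
  groups <- data.frame(group = c("OG1", "OG2"),
                       A = c("A_g01", "A_g02"), B = c("B_g01", "B_g02"),
                       C = c("C_g01", "C_g02"), D = c("D_g01", "D_g02"),
                       stringsAsFactors = FALSE)
  oc <- originComposition(groups, gs)
  ## OG1: 3 ancestral + 1 HGT -> ancestral; OG2: 2-2 tie -> unassigned
  expect_equal(unname(oc), c(0.5, 0, 0.5))
  expect_equal(sum(oc), 1)
})

test_that("COG tabulation conserves group counts", {
  sim <- smallSim()
  res <- smallRun()
  tab <- cogTabulate(res$core, sim$genomes)
  expect_equal(sum(tab$ancestral_core), nrow(res$core@ancestral_core))
  expect_equal(sum(tab$ingroup_only), coreAbsentFromAncestral(res$core))
  ## the reference genome's letters are the family letters, so the recovered
  ## non-"none" counts match the truth annotation exactly
  g1 <- geneTable(sim$genomes$G1)
  fam_letter <- setNames(g1$cog_letter, g1$gene_id)
  anc_ref <- res$core@ancestral_core$G1
  want <- table(factor(ifelse(is.na(fam_letter[anc_ref]), "none",
                              fam_letter[anc_ref]),
                       levels = tab$cog))
  expect_equal(tab$ancestral_core, as.integer(want))
  expect_error(cogTabulate(res$core, sim$genomes, reference = "nope"),
               "reference")
  tf <- cogTabulate(res$core, sim$genomes, fisher = TRUE)
  expect_true(all(tf$p_adj >= tf$p_value - 1e-12, na.rm = TRUE))
})
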