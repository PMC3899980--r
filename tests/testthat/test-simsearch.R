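test_that("self-alignment scores the diagonal sum at 100% identity", {
  sc <- scoringScheme("BLOSUM62")
  s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
  al <- localAlign(s, s, sc)
  expected <- sum(diag(sc@matrix[strsplit(s, "")[[1]], strsplit(s, "")[[1]]]))
  expect_equal(al$score, expected)
  expect_equal(al$identities, nchar(s))
  expect_equal(al$positives, nchar(s))
  expect_equal(al$mismatches, 0L)
})

test_that("alignment is symmetric and rejects bad input", {
  sc <- scoringScheme("BLOSUM62")
  a <- "HEAGAWGHEE"; b <- "PAWHEAE"
  expect_equal(localAlign(a, b, sc)$score, localAlign(b, a, sc)$score)
  expect_error(localAlign("", b, sc), "empty")
  expect_error(localAlign("MKB2", b, sc), "unknown residue")
  expect_silent(localAlign("MKXV", b, sc))   # X allowed, scored 0
})

test_that("local alignment equals the brute-force DP oracle on random pairs", {
  sc <- scoringScheme("BLOSUM62")
  aa <- rownames(sc@matrix)[1:20]
  set.seed(101)
  for (k in 1:40) {
    a <- paste(sample(aa, sample(5:50, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aa, sample(5:50, 1), replace = TRUE), collapse = "")
    expect_equal(localAlign(a, b, sc)$score,
                 swOracleScore(a, b, sc@matrix, sc@gap_open, sc@gap_extend),
                 info = paste(a, b))
  }
})

test_that("lambda calibration matches closed forms and published values", {
  ## +1 diagonal / -1 off-diagonal with uniform frequencies:
  ## (1/20) e^l + (19/20) e^-l = 1  =>  l = log 19
  aa <- names(pancore:::.RR_FREQS)
  m <- matrix(-1L, 21, 21, dimnames = list(c(aa, "X"), c(aa, "X")))
  diag(m) <- 1L
  m["X", ] <- 0L; m[, "X"] <- 0L
  sch <- scoringScheme("BLOSUM62",
                       background_freqs = setNames(rep(1, 20), aa))
  sch@matrix <- m
  lam <- calibrateLambda(sch)
  expect_equal(lam, log(19), tolerance = 1e-7)

  ## doubling every score halves lambda
  sch2 <- sch
  sch2@matrix <- m * 2L
  expect_equal(calibrateLambda(sch2), lam / 2, tolerance = 1e-7)

  ## BLOSUM62 with standard background frequencies: widely tabulated
  ## ungapped value ~0.3176
  expect_equal(calibrateLambda(scoringScheme("BLOSUM62")), 0.3176,
               tolerance = 0.05)

  ## all-positive matrix has no valid lambda
  sch3 <- sch
  sch3@matrix <- abs(m)
  expect_error(calibrateLambda(sch3), "non-negative")
})

test_that("e-values scale correctly and match direct evaluation", {
  sc <- scoringScheme("BLOSUM62")
  e1 <- hitEvalue(100, 300, 1e6, sc)$evalue
  e2 <- hitEvalue(100, 300, 2e6, sc)$evalue
  expect_equal(e2, 2 * e1)
  ## E strictly decreasing in S
  expect_lt(hitEvalue(101, 300, 1e6, sc)$evalue, e1)
  ## S with lambda*S = log(K m n) gives E = 1
  s_star <- log(sc@kappa * 300 * 1e6) / sc@lambda
  expect_equal(hitEvalue(s_star, 300, 1e6, sc)$evalue, 1)
  ## fixed toy inputs against the closed form
  sc2 <- sc; sc2@lambda <- 0.32; sc2@kappa <- 0.14
  got <- hitEvalue(100, 300, 1e6, sc2)
  expect_equal(got$evalue, 0.14 * 300 * 1e6 * exp(-0.32 * 100))
  expect_equal(got$bitscore, (0.32 * 100 - log(0.14)) / log(2))
  sc2@lambda <- NA_real_
  expect_error(hitEvalue(100, 300, 1e6, sc2), "not calibrated")
})

test_that("all-vs-all finds copies across identical proteomes", {
  sim <- generatePanGenome(smallConfig(branch_sub_rate = 0,
                                       n_accessory_families = 0L,
                                       n_unique_per_genome = 0L,
                                       seed = 9L,
                                       replicon_plan = {
                                         p <- smallPlan()
                                         p$target_gene_count <- c(26L, 10L, 4L)
                                         p
                                       }))
  genomes <- sim$genomes[c("G1", "G2")]
  hits <- allVsAll(genomes, scoringScheme("BLOSUM62"))
  og <- sim$truth@ortho_groups
  ## every protein's best cross-genome hit is its identical copy
  gmap <- geneGenomeMap(genomes)
  cross <- hits[gmap[hits$query] == "G1" & gmap[hits$subject] == "G2", ]
  best <- cross[!duplicated(cross$query), ]   # already ranked by bitscore
  expect_equal(unname(setNames(best$subject, best$query)[og$G1]), og$G2)
  expect_true(all(best$pident[match(og$G1, best$query)] == 100))
})

test_that("hit tables round-trip bit-exactly and 12-column input works", {
  sim <- smallSim()
  genomes <- ingroupOf(sim)[1:2]
  hits <- allVsAll(genomes, scoringScheme("BLOSUM62"))
  f <- withr::local_tempfile()
  writeHitTable(hits, f)
  back <- readHitTable(f)
  expect_equal(back, hits, ignore_attr = TRUE)

  ## plain 12-column input with coverage recomputation
  f2 <- withr::local_tempfile()
  write.table(format(hits[, 1:12], digits = 17, scientific = NA,
                     trim = TRUE),
              f2, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  lens <- unlist(lapply(genomes, function(g)
    setNames(Biostrings::width(proteinSeqs(g)), names(proteinSeqs(g)))))
  names(lens) <- sub("^[^.]*\\.", "", names(lens))
  back12 <- readHitTable(f2, lengths = lens)
  expect_equal(back12$qcov, hits$qcov, tolerance = 1e-12)
  expect_equal(back12$scov, hits$scov, tolerance = 1e-12)
  expect_true(all(is.na(back12$positives)))
  expect_error(readHitTable(f2), "length table")
})

test_that("search output is reproducible and kmer prefilter agrees with exact mode", {
  sim <- generatePanGenome(smallConfig(n_core_families = 12L,
                                       n_accessory_families = 2L,
                                       n_unique_per_genome = 2L,
                                       seed = 13L,
                                       replicon_plan = {
                                         p <- smallPlan()
                                         p$target_gene_count <- c(9L, 4L, 2L)
                                         p
                                       },
                                       essential_plan = c(chromosome = 2L,
                                                          p1 = 1L, p2 = 1L)))
  genomes <- ingroupOf(sim)
  h1 <- allVsAll(genomes, scoringScheme("BLOSUM62"))
  h2 <- allVsAll(genomes, scoringScheme("BLOSUM62"))
  expect_identical(h1, h2)
  hx <- allVsAll(genomes, scoringScheme("BLOSUM62"), method = "exact")
  ## every strong hit found by exact mode survives the prefilter
  strong <- hx[hx$evalue <= 1e-7, ]
  key <- function(h) paste(h$query, h$subject)
  expect_true(all(key(strong) %in% key(h1)))
  expect_equal(h1[match(key(strong), key(h1)), "bitscore"], strong$bitscore)
})
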