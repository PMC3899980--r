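test_that("codon alignment threads CDS through protein alignments", {
  ## identical gene
  ca <- codonAlign(c("MKV", "MKV"), "ATGAAAGTTTAA", "ATGAAAGTT")
  expect_equal(length(ca), 3L)
  est <- ng86(ca)
  expect_equal(est$Ka, 0); expect_equal(est$Ks, 0)
  expect_true(is.na(est$omega))
  expect_equal(est$status, "ok")

  ## one gap column drops one codon
  ca <- codonAlign(c("MKV", "M-V"), "ATGAAAGTT", "ATGGTT")
  expect_equal(length(ca), 2L)

  ## translation mismatch names the codon
  expect_error(codonAlign(c("MKV", "MKV"), "ATGAAAGTT", "ATGCCCGTT"),
               "codon 2")
  expect_error(codonAlign(c("MKV", "MK"), "ATGAAAGTT", "ATGAAA"),
               "equal-length")
})

test_that("site counting conserves S + N = 3L", {
  set.seed(5)
  tabs <- pancore:::codonTables()
  sense <- which(tabs$aa != "*")
  for (k in 1:25) {
    L <- sample(1:40, 1)
    ca <- new("CodonAlignment", codons_a = sample(sense, L, TRUE),
              codons_b = sample(sense, L, TRUE))
    est <- ng86(ca)
    expect_equal(est$S + est$N, 3 * L)
    ## Sd + Nd equals the observed nucleotide differences
    trip <- function(i) cbind((i - 1) %/% 16, ((i - 1) %/% 4) %% 4,
                              (i - 1) %% 4)
    ndiff <- sum(trip(ca@codons_a) != trip(ca@codons_b))
    expect_equal(est$Sd + est$Nd, ndiff, tolerance = 1e-9)
    expect_gte(est$Sd, 0); expect_gte(est$Nd, 0)
  }
})

test_that("synonymous-only divergence gives Ka = 0 and the JC-corrected Ks", {
  ## 100 GGT codons with 5 changed to GGC (all synonymous)
  a <- strrep("GGT", 100)
  b <- paste0(strrep("GGC", 5), strrep("GGT", 95))
  est <- ng86(codonAlign(c(strrep("G", 100), strrep("G", 100)), a, b))
  expect_equal(est$Ka, 0)
  ## independent enumeration: GGT and GGC both have exactly one synonymous
  ## site (third position), so pS = 5/100
  o <- ng86Oracle("GGT", "GGC")
  expect_equal(o$S, 1); expect_equal(o$Sd, 1)
  pS <- 5 / 100
  expect_equal(est$Ks, -0.75 * log(1 - 4 * pS / 3))
  expect_equal(est$status, "ok")
})

test_that("single codon pair TTT/TTC saturates", {
  est <- ng86(new("CodonAlignment",
                  codons_a = pancore:::.cdsToCodons("TTT"),
                  codons_b = pancore:::.cdsToCodons("TTC")))
  expect_equal(est$S, 1 / 3)
  expect_equal(est$Sd, 1)
  expect_equal(est$pS, 3)
  expect_equal(est$status, "saturated")
  expect_true(is.na(est$Ks))
})

test_that("ng86 matches the enumeration oracle on sampled codon pairs", {
  tabs <- pancore:::codonTables()
  sense <- which(tabs$aa != "*")
  set.seed(99)
  pick <- cbind(sample(sense, 150, TRUE), sample(sense, 150, TRUE))
  for (k in seq_len(nrow(pick))) {
    ca <- new("CodonAlignment", codons_a = pick[k, 1], codons_b = pick[k, 2])
    est <- ng86(ca)
    o <- ng86Oracle(tabs$codons[pick[k, 1]], tabs$codons[pick[k, 2]])
    expect_equal(est$S, o$S, info = paste(pick[k, ], collapse = "/"))
    expect_equal(est$Sd, o$Sd, info = paste(pick[k, ], collapse = "/"))
    expect_equal(est$Nd, o$Nd, info = paste(pick[k, ], collapse = "/"))
  }
})

test_that("Ka and Ks grow with branch length until saturation", {
  rates <- c(0.01, 0.05, 0.15, 0.3)
  ks <- ka <- numeric(length(rates))
  for (i in seq_along(rates)) {
    sim <- generatePanGenome(smallConfig(branch_sub_rate = rates[i],
                                         omega_core = 0.3, seed = 8L))
    og <- sim$truth@ortho_groups
    est <- do.call(rbind, lapply(1:15, function(j)
      groupKaks(unlist(og[j, paste0("G", 1:4)]), sim$genomes)$pairs))
    ks[i] <- mean(est$Ks, na.rm = TRUE)
    ka[i] <- mean(est$Ka, na.rm = TRUE)
  }
  expect_true(all(diff(ks) > 0))
  expect_true(all(diff(ka) > 0))
})

test_that("consistent-replicon subset splits groups correctly", {
  sim <- smallSim()
  res <- smallRun()
  cls <- consistentSubset(res$groups_ingroup, ingroupOf(sim))
  expect_setequal(cls$group, res$groups_ingroup$group)
  ## compare against truth replicons (core families are homed consistently,
  ## so no recovered group should be mixed)
  tr <- sim$truth
  want <- vapply(seq_len(nrow(res$groups_ingroup)), function(i) {
    repl <- tr@replicon_of[unlist(res$groups_ingroup[i, paste0("G", 1:4)])]
    if (all(repl == "chromosome")) "chromosomal_all"
    else if (all(repl != "chromosome")) "nonchromosomal_all" else "mixed"
  }, character(1))
  expect_equal(cls$class, want)
  expect_false(any(cls$class == "mixed"))

  ## a hand-mixed group
  mixed <- res$groups_ingroup[1, ]
  chrom_grp <- which(want == "chromosomal_all")[1]
  non_grp <- which(want == "nonchromosomal_all")[1]
  mixed$G1 <- res$groups_ingroup$G1[chrom_grp]
  for (g in c("G2", "G3", "G4")) mixed[[g]] <- res$groups_ingroup[[g]][non_grp]
  expect_equal(consistentSubset(mixed, ingroupOf(sim))$class, "mixed")
})

test_that("regression recovers exact linear relations and flags degeneracy", {
  ks <- seq(0.1, 1, by = 0.1)
  r <- kaksRegression(data.frame(Ks = ks, Ka = 0.5 * ks))
  expect_equal(r$slope, 0.5, tolerance = 1e-10)
  expect_equal(r$intercept, 0, tolerance = 1e-10)
  expect_equal(r$r_squared, 1)
  expect_equal(r$fraction_negative, 1)

  r0 <- kaksRegression(data.frame(Ks = ks, Ka = 0))
  expect_equal(r0$slope, 0, tolerance = 1e-12)
  expect_true(is.na(r0$r_squared))

  expect_error(kaksRegression(data.frame(Ks = 1:2, Ka = 1:2)), "fewer than 3")

  ## saturated points are excluded and counted
  pts <- data.frame(Ks = c(ks, 2), Ka = c(0.5 * ks, NA),
                    status = c(rep("ok", 10), "saturated"))
  r2 <- kaksRegression(pts)
  expect_equal(r2$n_points, 10)
  expect_equal(r2$n_excluded, 1)
})

test_that("group means exclude saturated and undefined pairs", {
  sim <- smallSim()
  og <- sim$truth@ortho_groups
  gk <- groupKaks(unlist(og[1, paste0("G", 1:4)]), sim$genomes)
  expect_equal(nrow(gk$pairs), 6L)
  expect_equal(unname(gk$mean[["n_pairs_used"]]),
               sum(gk$pairs$status == "ok"))
  expect_equal(unname(gk$mean[["Ks"]]),
               mean(gk$pairs$Ks[gk$pairs$status == "ok"]))
})
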