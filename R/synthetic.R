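## Synthetic multi-replicon pan-genome generator with known ground truth.
##
## Families descend from per-family ancestral CDS; each genome's copy is the
## ancestor pushed through a codon-aware nucleotide substitution process in
## which synonymous proposals are always accepted, nonsynonymous proposals are
## accepted with probability omega, and proposals creating internal stops are
## rejected. Horizontally acquired (HGT) families come from a separate pool
## with shifted GC that the outgroup genome never carries; strain-unique genes
## are random sequences with no ancestry.

NT <- c("T", "C", "A", "G")

## transition partner under the TCAG coding: T<->C, A<->G
.TS_PARTNER <- c(2L, 1L, 4L, 3L)

#' Default replicon plan of the synthetic generator
#'
#' Six replicons per genome (one oriC chromosome, five repABC replicons) with
#' gene capacities that place the bulk of the core on the chromosome and the
#' large chromids, and the accessory/unique complement mostly outside the
#' chromosome, mirroring a multi-replicon alpha-proteobacterial genome.
#'
#' @return data.frame with columns `name`, `replication_class`,
#'   `target_gene_count`, `target_gc`.
#' @export
defaultRepliconPlan <- function() {
  data.frame(
    name = c("chromosome", "p1", "p2", "p3", "p4", "p6"),
    replication_class = c("oriC", rep("repABC", 5L)),
    target_gene_count = c(425L, 140L, 80L, 35L, 45L, 25L),
    target_gc = c(0.600, 0.600, 0.595, 0.590, 0.600, 0.570),
    stringsAsFactors = FALSE
  )
}

#' Construct a simulation configuration
#'
#' All arguments have defaults that describe the study conditions the package
#' is exercised under: four related genomes of 750 genes over six replicons,
#' 600 core families (65% chromosomal), 200 accessory families each carried by
#' two genomes, 50 strain-unique genes per genome, 22% HGT core families with
#' GC depressed by 0.05, and core genes diverging under purifying selection
#' (omega 0.2) at 0.05 proposed substitutions per site per branch.
#'
#' @param n_genomes number of ingroup genomes.
#' @param outgroup add a deep-branch outgroup genome (id `"OUT"`) carrying
#'   only the non-HGT core families.
#' @param replicon_plan see [defaultRepliconPlan()].
#' @param n_core_families,n_accessory_families,n_unique_per_genome counts.
#' @param core_chromosomal_fraction fraction of core families homed on the
#'   chromosome.
#' @param hgt_fraction,unassigned_fraction origin composition of the core.
#' @param hgt_gc_offset signed GC shift of HGT genes.
#' @param mean_gene_len_codons mean gene length (codons).
#' @param branch_sub_rate expected proposed substitutions/site per branch.
#' @param omega_core,omega_accessory acceptance probability of nonsynonymous
#'   proposals (the true dN/dS).
#' @param indel_rate_accessory per-copy probability of a short in-frame indel
#'   in accessory genes.
#' @param tstv transition/transversion rate ratio of the proposal kernel.
#' @param outgroup_rate_mult branch-length multiplier for the outgroup.
#' @param essential_plan named integer vector of essential core-gene counts
#'   per replicon.
#' @param seed integer RNG seed.
#' @return a validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_core_families = 20L, n_accessory_families = 6L,
#'                  n_unique_per_genome = 4L,
#'                  replicon_plan = data.frame(
#'                    name = c("chromosome", "p1"),
#'                    replication_class = c("oriC", "repABC"),
#'                    target_gene_count = c(18L, 9L),
#'                    target_gc = c(0.6, 0.58)),
#'                  essential_plan = c(chromosome = 4L, p1 = 2L))
#' @export
simConfig <- function(n_genomes = 4L,
                      outgroup = FALSE,
                      replicon_plan = defaultRepliconPlan(),
                      n_core_families = 600L,
                      core_chromosomal_fraction = 0.65,
                      n_accessory_families = 200L,
                      n_unique_per_genome = 50L,
                      hgt_fraction = 0.22,
                      unassigned_fraction = 0.04,
                      hgt_gc_offset = -0.05,
                      mean_gene_len_codons = 250L,
                      branch_sub_rate = 0.05,
                      omega_core = 0.2,
                      omega_accessory = 0.4,
                      indel_rate_accessory = 0.1,
                      tstv = 1,
                      outgroup_rate_mult = 3,
                      essential_plan = c(chromosome = 60L, p1 = 8L,
                                         p2 = 3L, p4 = 2L),
                      seed = 42L) {
  new("SimConfig",
      n_genomes = as.integer(n_genomes),
      outgroup = outgroup,
      replicon_plan = replicon_plan,
      n_core_families = as.integer(n_core_families),
      core_chromosomal_fraction = core_chromosomal_fraction,
      n_accessory_families = as.integer(n_accessory_families),
      n_unique_per_genome = as.integer(n_unique_per_genome),
      hgt_fraction = hgt_fraction,
      unassigned_fraction = unassigned_fraction,
      hgt_gc_offset = hgt_gc_offset,
      mean_gene_len_codons = as.integer(mean_gene_len_codons),
      branch_sub_rate = branch_sub_rate,
      omega_core = omega_core,
      omega_accessory = omega_accessory,
      indel_rate_accessory = indel_rate_accessory,
      tstv = tstv,
      outgroup_rate_mult = outgroup_rate_mult,
      essential_plan = setNames(as.integer(essential_plan),
                                names(essential_plan)),
      seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## low-level sequence machinery (integer nt codes 1..4 = T,C,A,G)
## ---------------------------------------------------------------------------

codonIndex <- function(n1, n2, n3) 16L * (n1 - 1L) + 4L * (n2 - 1L) + n3

## codon index -> aa for the bacterial/standard code (identical codon->aa map)
.aaByCodon <- function() {
  if (!is.null(.pancoreCache$aa64)) return(.pancoreCache$aa64)
  codons <- apply(expand.grid(n3 = NT, n2 = NT, n1 = NT,
                              stringsAsFactors = FALSE)[, 3:1], 1, paste,
                  collapse = "")
  gc <- Biostrings::getGeneticCode("11")
  .pancoreCache$aa64 <- unname(gc[codons])
  .pancoreCache$codons64 <- codons
  .pancoreCache$aa64
}

## sample L codons (as nt-code vector of length 3L) at a target GC fraction,
## never emitting stop codons
sampleCodons <- function(n_codons, gc) {
  aa <- .aaByCodon()
  pnt <- c(T = (1 - gc) / 2, C = gc / 2, A = (1 - gc) / 2, G = gc / 2)
  grid <- expand.grid(n3 = 1:4, n2 = 1:4, n1 = 1:4)[, 3:1]
  w <- pnt[grid$n1] * pnt[grid$n2] * pnt[grid$n3]
  w[aa == "*"] <- 0
  idx <- sample.int(64L, n_codons, replace = TRUE, prob = w / sum(w))
  as.integer(t(cbind((idx - 1L) %/% 16L + 1L,
                     ((idx - 1L) %/% 4L) %% 4L + 1L,
                     (idx - 1L) %% 4L + 1L)))
}

## codon-aware substitution process. x: nt-code vector (multiple of 3).
## Proposals are uniform over sites; the replacement base is drawn with the
## transition partner weighted `tstv` against each transversion's 1.
evolveCDS <- function(x, n_prop, omega, tstv) {
  aa <- .aaByCodon()
  L <- length(x)
  if (n_prop == 0L || L == 0L) return(x)
  for (k in seq_len(n_prop)) {
    pos <- sample.int(L, 1L)
    cur <- x[pos]
    alt <- setdiff(1:4, cur)
    wts <- ifelse(alt == .TS_PARTNER[cur], tstv, 1)
    newnt <- alt[sample.int(3L, 1L, prob = wts)]
    c0 <- pos - (pos - 1L) %% 3L
    old_codon <- codonIndex(x[c0], x[c0 + 1L], x[c0 + 2L])
    tmp <- x[c0:(c0 + 2L)]
    tmp[(pos - 1L) %% 3L + 1L] <- newnt
    new_codon <- codonIndex(tmp[1L], tmp[2L], tmp[3L])
    if (aa[new_codon] == "*") next                      # reject stops
    if (aa[new_codon] != aa[old_codon] && runif(1) > omega) next
    x[pos] <- newnt
  }
  x
}

## short in-frame indel: delete or duplicate 1-3 codons
applyIndel <- function(x, gc) {
  L3 <- length(x) %/% 3L
  k <- sample.int(3L, 1L)
  if (L3 <= k + 21L || runif(1) < 0.5) {      # insertion
    at <- sample.int(L3 - 1L, 1L)
    ins <- sampleCodons(k, gc)
    append(x, ins, after = 3L * at)
  } else {                                     # deletion
    at <- sample.int(L3 - k - 1L, 1L)
    x[-((3L * at + 1L):(3L * at + 3L * k))]
  }
}

ntToString <- function(x) paste(NT[x], collapse = "")

translateNt <- function(x) {
  aa <- .aaByCodon()
  idx <- codonIndex(x[seq(1, length(x), 3)],
                    x[seq(2, length(x), 3)],
                    x[seq(3, length(x), 3)])
  paste(aa[idx], collapse = "")
}

## largest-remainder apportionment of `total` slots with per-bin caps
apportion <- function(total, weights, caps) {
  n <- length(weights)
  out <- integer(n)
  if (total == 0L) return(out)
  if (sum(caps) < total)
    stopf("configuration error: %d genes exceed a capacity of %d",
          total, sum(caps))
  w <- weights / sum(weights)
  raw <- pmin(caps, w * total)
  out <- as.integer(floor(raw))
  frac <- raw - out
  ord <- order(-frac, seq_len(n))
  i <- 1L
  while (sum(out) < total) {
    j <- ord[(i - 1L) %% n + 1L]
    if (out[j] < caps[j]) out[j] <- out[j] + 1L
    i <- i + 1L
  }
  out
}

## balanced assignment of accessory families to genome pairs: each family is
## carried by exactly two genomes and every genome carries the same number
balancedPairs <- function(n_families, genome_ids) {
  need <- setNames(rep(2L * n_families / length(genome_ids), length(genome_ids)),
                   genome_ids)
  pairs <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    ord <- order(-need, names(need))
    a <- names(need)[ord[1L]]; b <- names(need)[ord[2L]]
    pairs[[f]] <- sort(c(a, b))
    need[a] <- need[a] - 1L; need[b] <- need[b] - 1L
  }
  pairs
}

.COG_LETTERS <- c("J", "K", "L", "D", "V", "T", "M", "N", "U", "O",
                  "C", "E", "F", "G", "H", "I", "P", "Q", "R", "S")
.COG_WEIGHTS <- c(4, 6, 4, 1, 1, 5, 5, 2, 2, 3, 5, 8, 2, 6, 3, 3, 5, 3, 9, 8)

## ---------------------------------------------------------------------------
## generator
## ---------------------------------------------------------------------------

#' Generate a synthetic multi-replicon pan-genome
#'
#' Simulates `n_genomes` related genomes (plus an optional deep-branch
#' outgroup) according to a [SimConfig-class]: core families shared by all
#' genomes and homed on a consistent replicon, accessory families carried by
#' two genomes each, strain-unique random genes, HGT families with shifted GC
#' drawn from a pool absent in the outgroup, and per-gene annotation (COG
#' letter, origin label, essential flag, coordinates). Identical
#' configurations (including the seed) give identical output.
#'
#' @param config a [SimConfig-class], see [simConfig()].
#' @return a list with elements `genomes` (named list of [Genome-class],
#'   ingroup plus `OUT` when an outgroup was requested), `truth`
#'   (a [SyntheticTruth-class]) and `config`.
#' @examples
#' cfg <- simConfig(n_core_families = 30L, n_accessory_families = 10L,
#'                  n_unique_per_genome = 5L, mean_gene_len_codons = 80L,
#'                  replicon_plan = data.frame(
#'                    name = c("chromosome", "p1", "p2"),
#'                    replication_class = c("oriC", "repABC", "repABC"),
#'                    target_gene_count = c(24L, 11L, 5L),
#'                    target_gc = c(0.60, 0.60, 0.57)),
#'                  essential_plan = c(chromosome = 5L, p1 = 2L))
#' sim <- generatePanGenome(cfg)
#' sim$genomes[[1]]
#' @export
generatePanGenome <- function(config) {
  validObject(config)
  set.seed(config@seed)
  plan <- config@replicon_plan
  gids <- sprintf("G%d", seq_len(config@n_genomes))
  n_core <- config@n_core_families
  n_acc <- config@n_accessory_families
  n_uni <- config@n_unique_per_genome

  acc_per <- if (n_acc > 0L) 2L * n_acc / config@n_genomes else 0L
  if (acc_per != round(acc_per))
    stopf("configuration error: 2 * n_accessory_families must be divisible by n_genomes")
  acc_per <- as.integer(acc_per)
  if (sum(plan$target_gene_count) != n_core + acc_per + n_uni)
    stopf(paste("configuration error: replicon_plan totals %d genes but the",
                "composition implies %d (core %d + accessory %d + unique %d)"),
          sum(plan$target_gene_count), n_core + acc_per + n_uni,
          n_core, acc_per, n_uni)

  ## --- core family structure -----------------------------------------------
  fam_ids <- sprintf("F%04d", seq_len(n_core))
  n_hgt <- as.integer(round(config@hgt_fraction * n_core))
  n_un <- as.integer(round(config@unassigned_fraction * n_core))
  origin_fam <- setNames(rep("ancestral", n_core), fam_ids)
  origin_fam[sample.int(n_core, n_hgt + n_un)] <-
    rep(c("HGT", "unassigned"), c(n_hgt, n_un))

  n_chrom_core <- as.integer(round(config@core_chromosomal_fraction * n_core))
  chrom_name <- plan$name[plan$replication_class == "oriC"]
  if (n_chrom_core > plan$target_gene_count[plan$name == chrom_name])
    stopf("configuration error: %d chromosomal core genes exceed the chromosome capacity",
          n_chrom_core)
  chrom_fams <- sort(sample(fam_ids, n_chrom_core))
  home <- setNames(rep(chrom_name, n_core), fam_ids)
  noncore_fams <- setdiff(fam_ids, chrom_fams)
  chromid_names <- intersect(
    plan$name[plan$replication_class == "repABC"],
    names(config@essential_plan)[config@essential_plan > 0L])
  if (!length(chromid_names))
    chromid_names <- plan$name[plan$replication_class == "repABC"]
  caps_chromid <- plan$target_gene_count[match(chromid_names, plan$name)]
  alloc <- apportion(length(noncore_fams), caps_chromid, caps_chromid)
  home[noncore_fams] <- rep(chromid_names, alloc)

  ## essential flags live on core families, per replicon
  ess_fams <- character()
  for (r in names(config@essential_plan)) {
    cand <- fam_ids[home == r]
    k <- config@essential_plan[[r]]
    if (k > length(cand))
      stopf("configuration error: essential_plan asks %d genes on %s but only %d core families are homed there",
            k, r, length(cand))
    ess_fams <- c(ess_fams, head(cand, k))
  }

  mean_len <- config@mean_gene_len_codons
  fam_len <- pmax(60L, as.integer(round(rnorm(n_core, mean_len, 0.2 * mean_len))))
  names(fam_len) <- fam_ids

  gcOf <- function(repl, is_hgt) {
    gc <- plan$target_gc[match(repl, plan$name)]
    if (is_hgt) gc <- min(0.95, max(0.05, gc + config@hgt_gc_offset))
    gc
  }
  core_anc <- lapply(fam_ids, function(f)
    sampleCodons(fam_len[[f]], gcOf(home[[f]], origin_fam[[f]] == "HGT")))
  names(core_anc) <- fam_ids

  ## --- accessory family structure ------------------------------------------
  acc_ids <- sprintf("A%04d", seq_len(n_acc))
  acc_pairs <- balancedPairs(n_acc, gids)
  names(acc_pairs) <- acc_ids
  acc_len <- pmax(60L, as.integer(round(rnorm(n_acc, mean_len, 0.2 * mean_len))))
  names(acc_len) <- acc_ids
  acc_origin <- setNames(sample(c("HGT", "ancestral", "unassigned"), n_acc,
                                replace = TRUE, prob = c(0.5, 0.25, 0.25)),
                         acc_ids)
  acc_anc <- lapply(acc_ids, function(f)
    sampleCodons(acc_len[[f]],
                 gcOf(plan$name[nrow(plan)], acc_origin[[f]] == "HGT")))
  names(acc_anc) <- acc_ids

  ## COG letters are a family property (recovered downstream via any member)
  all_fam <- c(fam_ids, acc_ids)
  cog_fam <- setNames(sample(.COG_LETTERS, length(all_fam), replace = TRUE,
                             prob = .COG_WEIGHTS), all_fam)
  cog_fam[runif(length(all_fam)) < 0.2] <- NA_character_

  ## --- evolve copies, genome by genome -------------------------------------
  mut <- function(anc, rate, omega) {
    evolveCDS(anc, rpois(1L, rate * length(anc)), omega, config@tstv)
  }
  rate <- config@branch_sub_rate

  truth_family <- truth_origin <- truth_replicon <- character()
  truth_omega <- numeric()
  ortho <- as.data.frame(matrix(NA_character_, n_core, config@n_genomes,
                                dimnames = list(NULL, gids)))
  ortho$family <- fam_ids
  ortho$in_anc <- origin_fam[fam_ids] != "HGT"

  genomes <- list()
  for (g in gids) {
    ## replicon slot allocation for this genome
    core_per_rep <- table(factor(home, levels = plan$name))
    rem <- plan$target_gene_count - as.integer(core_per_rep)
    if (any(rem < 0))
      stopf("configuration error: core allocation exceeds capacity on %s",
            paste(plan$name[rem < 0], collapse = ", "))
    is_chrom <- plan$replication_class == "oriC"
    acc_chrom <- min(rem[is_chrom], as.integer(round(0.2 * acc_per)))
    acc_rep <- integer(nrow(plan))
    acc_rep[is_chrom] <- acc_chrom
    acc_rep[!is_chrom] <- apportion(acc_per - acc_chrom,
                                    pmax(rem[!is_chrom], 0L),
                                    rem[!is_chrom])
    uni_rep <- rem - acc_rep
    if (any(uni_rep < 0) || sum(uni_rep) != n_uni)
      stopf("configuration error: unique genes do not fill the plan on genome %s", g)

    my_acc <- acc_ids[vapply(acc_pairs, function(p) g %in% p, logical(1))]

    ## build the gene roster: (id placeholder, family, class, replicon)
    roster <- list()
    for (ri in seq_len(nrow(plan))) {
      r <- plan$name[ri]
      fams_here <- fam_ids[home == r]
      take_acc <- head(my_acc, acc_rep[ri])
      my_acc <- setdiff(my_acc, take_acc)
      roster[[r]] <- data.frame(
        family = c(fams_here, take_acc,
                   sprintf("U_%s_%s_%02d", g, r, seq_len(uni_rep[ri]))),
        class = rep(c("core", "accessory", "unique"),
                    c(length(fams_here), length(take_acc), uni_rep[ri])),
        replicon = r, stringsAsFactors = FALSE)
    }
    roster <- do.call(rbind, roster)
    rownames(roster) <- NULL

    ## sequences
    seqs <- vector("list", nrow(roster))
    for (i in seq_len(nrow(roster))) {
      f <- roster$family[i]
      seqs[[i]] <- switch(roster$class[i],
        core = mut(core_anc[[f]], rate, config@omega_core),
        accessory = {
          s <- mut(acc_anc[[f]], rate, config@omega_accessory)
          if (runif(1) < config@indel_rate_accessory)
            s <- applyIndel(s, plan$target_gc[match(roster$replicon[i], plan$name)])
          s
        },
        unique = sampleCodons(
          pmax(60L, as.integer(round(rnorm(1, mean_len, 0.2 * mean_len)))),
          plan$target_gc[match(roster$replicon[i], plan$name)]))
    }

    gene_ids <- sprintf("%s_g%04d", g, seq_len(nrow(roster)))
    uni_origin <- sample(c("ancestral", "HGT", "unassigned"),
                         sum(roster$class == "unique"), replace = TRUE,
                         prob = c(0.2, 0.35, 0.45))
    origin <- ifelse(roster$class == "core", origin_fam[roster$family],
              ifelse(roster$class == "accessory", acc_origin[roster$family],
                     NA))
    origin[roster$class == "unique"] <- uni_origin
    cog <- ifelse(roster$class == "unique",
                  ifelse(runif(nrow(roster)) < 0.6, NA_character_,
                         sample(.COG_LETTERS, nrow(roster), replace = TRUE)),
                  cog_fam[roster$family])
    omega_true <- ifelse(roster$class == "core", config@omega_core,
                  ifelse(roster$class == "accessory", config@omega_accessory,
                         NA_real_))

    genomes[[g]] <- .assembleGenome(g, plan, roster, gene_ids, seqs,
                                    origin, cog,
                                    essential = roster$family %in% ess_fams)

    truth_family <- c(truth_family, setNames(roster$family, gene_ids))
    truth_origin <- c(truth_origin, setNames(origin, gene_ids))
    truth_replicon <- c(truth_replicon, setNames(roster$replicon, gene_ids))
    truth_omega <- c(truth_omega, setNames(omega_true, gene_ids))
    ortho[[g]] <- gene_ids[match(fam_ids, roster$family)]
  }

  ## --- outgroup -------------------------------------------------------------
  if (config@outgroup) {
    og <- "OUT"
    keep <- fam_ids[origin_fam != "HGT"]
    oplan <- data.frame(name = "chromosome", replication_class = "oriC",
                        target_gene_count = length(keep),
                        target_gc = plan$target_gc[plan$replication_class == "oriC"],
                        stringsAsFactors = FALSE)
    roster <- data.frame(family = keep, class = "core",
                         replicon = "chromosome", stringsAsFactors = FALSE)
    seqs <- lapply(keep, function(f)
      mut(core_anc[[f]], rate * config@outgroup_rate_mult, config@omega_core))
    gene_ids <- sprintf("%s_g%04d", og, seq_along(keep))
    genomes[[og]] <- .assembleGenome(og, oplan, roster, gene_ids, seqs,
                                     origin = rep("ancestral", length(keep)),
                                     cog = cog_fam[keep],
                                     essential = rep(FALSE, length(keep)))
    truth_family <- c(truth_family, setNames(keep, gene_ids))
    truth_origin <- c(truth_origin, setNames(rep("ancestral", length(keep)), gene_ids))
    truth_replicon <- c(truth_replicon, setNames(rep("chromosome", length(keep)), gene_ids))
    truth_omega <- c(truth_omega, setNames(rep(config@omega_core, length(keep)), gene_ids))
    ortho[[og]] <- gene_ids[match(fam_ids, truth_family[gene_ids])]
  }

  truth <- new("SyntheticTruth",
               family_of = truth_family,
               ortho_groups = ortho,
               origin_of = truth_origin,
               omega_of = truth_omega,
               replicon_of = truth_replicon)
  list(genomes = genomes, truth = truth, config = config)
}

## build a Genome object from a roster and nt-code sequences
.assembleGenome <- function(gid, plan, roster, gene_ids, seqs, origin, cog,
                            essential) {
  n <- nrow(roster)
  start <- end <- integer(n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  repl_len <- setNames(integer(nrow(plan)), plan$name)
  repl_gc <- setNames(numeric(nrow(plan)), plan$name)
  for (r in plan$name) {
    sel <- which(roster$replicon == r)
    cursor <- 0L
    for (i in sel) {
      gap <- sample(20:200, 1L)
      start[i] <- cursor + gap + 1L
      end[i] <- start[i] + length(seqs[[i]]) + 3L - 1L   # includes stop codon
      cursor <- end[i]
    }
    repl_len[r] <- cursor + sample(20:200, 1L)
    nt_all <- unlist(seqs[sel], use.names = FALSE)
    repl_gc[r] <- if (length(nt_all)) 100 * mean(nt_all %in% c(2L, 4L)) else 50
  }
  cds_str <- vapply(seqs, ntToString, character(1))
  prot_str <- vapply(seqs, translateNt, character(1))
  genes <- data.frame(
    gene_id = gene_ids, genome_id = gid, replicon = roster$replicon,
    start = start, end = end, strand = strand,
    cog_letter = unname(cog), origin = unname(origin),
    essential = essential, stringsAsFactors = FALSE)
  new("Genome", id = gid,
      replicons = data.frame(
        name = plan$name, length_bp = unname(repl_len),
        gc_percent = round(unname(repl_gc), 2),
        orf_count = as.integer(table(factor(roster$replicon,
                                            levels = plan$name))),
        replication_class = plan$replication_class,
        rrna_count = NA_integer_, trna_count = NA_integer_,
        stringsAsFactors = FALSE),
      genes = genes,
      proteins = Biostrings::AAStringSet(setNames(prot_str, gene_ids)),
      cds = Biostrings::DNAStringSet(setNames(cds_str, gene_ids)))
}

## ---------------------------------------------------------------------------
## truth and config serialization
## ---------------------------------------------------------------------------

#' Write the ground truth of a simulation to TSV files
#'
#' Emits `genes.tsv` (gene_id, family, origin, omega, replicon) and
#' `ortho_groups.tsv` (family, in_anc, one column per genome) under
#' `dir/truth/`. [readTruth()] restores an identical object.
#'
#' @param truth a [SyntheticTruth-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeTruth <- function(truth, dir) {
  td <- file.path(dir, "truth")
  dir.create(td, recursive = TRUE, showWarnings = FALSE)
  ids <- names(truth@family_of)
  genes <- data.frame(gene_id = ids,
                      family = unname(truth@family_of[ids]),
                      origin = unname(truth@origin_of[ids]),
                      omega = unname(truth@omega_of[ids]),
                      replicon = unname(truth@replicon_of[ids]))
  p1 <- file.path(td, "genes.tsv")
  p2 <- file.path(td, "ortho_groups.tsv")
  write.table(genes, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth@ortho_groups, p2, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(p1, p2))
}

#' Read back a ground truth written by [writeTruth()]
#' @param dir the directory passed to [writeTruth()].
#' @return a [SyntheticTruth-class].
#' @export
readTruth <- function(dir) {
  genes <- read.delim(file.path(dir, "truth", "genes.tsv"),
                      stringsAsFactors = FALSE)
  og <- read.delim(file.path(dir, "truth", "ortho_groups.tsv"),
                   stringsAsFactors = FALSE)
  new("SyntheticTruth",
      family_of = setNames(genes$family, genes$gene_id),
      ortho_groups = og,
      origin_of = setNames(genes$origin, genes$gene_id),
      omega_of = setNames(genes$omega, genes$gene_id),
      replicon_of = setNames(genes$replicon, genes$gene_id))
}

#' Serialize a simulation configuration to JSON
#' @param config a [SimConfig-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeSimConfig <- function(config, path) {
  sl <- methods::slotNames(config)
  obj <- lapply(setNames(sl, sl), function(s) slot(config, s))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
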