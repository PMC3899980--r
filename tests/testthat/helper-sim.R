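# Shared simulation fixtures. The small configuration keeps module tests
# fast; the full default-scale run (used by the recovery tests) is computed
# once per session and memoised.

.fixtures <- new.env(parent = emptyenv())

smallPlan <- function() {
  data.frame(name = c("chromosome", "p1", "p2"),
             replication_class = c("oriC", "repABC", "repABC"),
             target_gene_count = c(32L, 12L, 6L),
             target_gc = c(0.60, 0.60, 0.57),
             stringsAsFactors = FALSE)
}

smallConfig <- function(...) {
  args <- list(n_core_families = 40L, n_accessory_families = 10L,
               n_unique_per_genome = 5L, mean_gene_len_codons = 100L,
               replicon_plan = smallPlan(),
               essential_plan = c(chromosome = 5L, p1 = 2L, p2 = 1L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(simConfig, args)
}

smallSim <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- generatePanGenome(smallConfig(outgroup = TRUE))
  .fixtures$small
}

# small simulation + pipeline with outgroup, shared across test files
smallRun <- function() {
  if (is.null(.fixtures$small_run))
    .fixtures$small_run <- runPipeline(smallSim()$genomes, outgroup_id = "OUT",
                                       kaks = FALSE)
  .fixtures$small_run
}

# full default-scale simulation + pipeline (the study conditions)
defaultRun <- function() {
  if (is.null(.fixtures$big)) {
    sim <- generatePanGenome(simConfig(outgroup = TRUE))
    res <- runPipeline(sim$genomes, outgroup_id = "OUT")
    .fixtures$big <- list(sim = sim, res = res)
  }
  .fixtures$big
}

ingroupOf <- function(sim) sim$genomes[names(sim$genomes) != "OUT"]

tupleKeys <- function(df, cols) {
  apply(df[, cols, drop = FALSE], 1, function(v) paste(sort(v), collapse = ","))
}

familyKeys <- function(l) {
  sort(vapply(l, function(v) paste(sort(v), collapse = ","), character(1)))
}

trueFamilies <- function(truth, drop_outgroup = TRUE) {
  sel <- grepl("^(F|A)", truth@family_of)
  if (drop_outgroup) sel <- sel & !grepl("^OUT", names(truth@family_of))
  split(names(truth@family_of)[sel], truth@family_of[sel])
}
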