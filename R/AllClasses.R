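## S4 classes for the pan-genome pipeline.

setOldClass("data.frame")

## ---------------------------------------------------------------------------
## SimConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic pan-genome generator
#'
#' A `SimConfig` holds every knob of the codon-level simulator: the number of
#' ingroup genomes, an optional deep-branch outgroup, the per-replicon gene
#' plan, family counts, origin (ancestral / HGT) structure, the GC shift of
#' horizontally acquired genes, and the selection regime (dN/dS acceptance
#' probabilities) under which core and accessory genes diverge.
#'
#' @slot n_genomes number of ingroup genomes.
#' @slot outgroup logical; add one deep-branch genome carrying only the
#'   ancestral (non-HGT) core families, for ancestral-core tests.
#' @slot replicon_plan data.frame with columns `name`,
#'   `replication_class` (`"oriC"` or `"repABC"`), `target_gene_count`,
#'   `target_gc` (fraction); identical plan for every ingroup genome;
#'   exactly one `oriC` replicon.
#' @slot n_core_families,n_accessory_families,n_unique_per_genome family and
#'   strain-unique gene counts.
#' @slot core_chromosomal_fraction fraction of core families homed on the
#'   chromosome (consistently across genomes).
#' @slot hgt_fraction fraction of core families labelled HGT; these are drawn
#'   from a separate ancestral pool absent from the outgroup.
#' @slot unassigned_fraction fraction of core families with unresolved origin.
#' @slot hgt_gc_offset signed GC shift (fraction) applied to HGT genes.
#' @slot mean_gene_len_codons mean gene length in codons (sd = 20% of mean,
#'   floor 60 codons).
#' @slot branch_sub_rate expected proposed nucleotide changes per site on each
#'   genome's branch from the family ancestor.
#' @slot omega_core,omega_accessory dN/dS: probability that a proposed
#'   nonsynonymous change is accepted (synonymous changes are always accepted,
#'   changes creating internal stops always rejected).
#' @slot indel_rate_accessory per-gene probability of a short in-frame indel
#'   in accessory gene copies (core genes never receive indels).
#' @slot tstv transition/transversion rate ratio of the proposal kernel.
#'   The default of 1 keeps the mutation opportunity uniform across the
#'   synonymous/nonsynonymous site classes that Nei-Gojobori counting assumes,
#'   so `omega_core` is, by construction, the quantity the estimator targets;
#'   see the methods vignette.
#' @slot outgroup_rate_mult branch-length multiplier for the outgroup genome.
#' @slot essential_plan named integer vector: number of essential-flagged core
#'   genes per replicon (essential genes are what qualifies a repABC replicon
#'   as a chromid).
#' @slot seed integer RNG seed; identical configs give byte-identical output.
#' @seealso [simConfig()] for the user constructor with defaults,
#'   [generatePanGenome()] for the generator.
#' @exportClass SimConfig
setClass("SimConfig", representation(
  n_genomes = "integer",
  outgroup = "logical",
  replicon_plan = "data.frame",
  n_core_families = "integer",
  core_chromosomal_fraction = "numeric",
  n_accessory_families = "integer",
  n_unique_per_genome = "integer",
  hgt_fraction = "numeric",
  unassigned_fraction = "numeric",
  hgt_gc_offset = "numeric",
  mean_gene_len_codons = "integer",
  branch_sub_rate = "numeric",
  omega_core = "numeric",
  omega_accessory = "numeric",
  indel_rate_accessory = "numeric",
  tstv = "numeric",
  outgroup_rate_mult = "numeric",
  essential_plan = "integer",
  seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  rp <- object@replicon_plan
  need <- c("name", "replication_class", "target_gene_count", "target_gc")
  if (!all(need %in% names(rp)))
    msg <- c(msg, paste("replicon_plan must have columns",
                        paste(need, collapse = ", ")))
  else {
    if (sum(rp$replication_class == "oriC") != 1L)
      msg <- c(msg, "replicon_plan must contain exactly one oriC replicon")
    if (!all(rp$replication_class %in% c("oriC", "repABC")))
      msg <- c(msg, "replication_class must be oriC or repABC")
    if (any(rp$target_gene_count <= 0))
      msg <- c(msg, "target_gene_count must be positive")
    if (any(rp$target_gc <= 0 | rp$target_gc >= 1))
      msg <- c(msg, "target_gc must be in (0,1)")
    if (anyDuplicated(rp$name)) msg <- c(msg, "replicon names must be unique")
  }
  fr <- c(core_chromosomal_fraction = object@core_chromosomal_fraction,
          hgt_fraction = object@hgt_fraction,
          unassigned_fraction = object@unassigned_fraction,
          indel_rate_accessory = object@indel_rate_accessory)
  bad <- names(fr)[fr < 0 | fr > 1]
  if (length(bad))
    msg <- c(msg, paste(paste(bad, collapse = ", "), "must be in [0,1]"))
  if (object@hgt_fraction + object@unassigned_fraction > 1)
    msg <- c(msg, "hgt_fraction + unassigned_fraction must be <= 1")
  if (object@n_genomes < 2L) msg <- c(msg, "n_genomes must be >= 2")
  if (object@n_core_families < 1L) msg <- c(msg, "n_core_families must be positive")
  if (object@n_unique_per_genome < 0L) msg <- c(msg, "n_unique_per_genome must be >= 0")
  if (object@mean_gene_len_codons < 60L)
    msg <- c(msg, "mean_gene_len_codons must be >= 60")
  if (object@omega_core < 0 || object@omega_accessory < 0)
    msg <- c(msg, "omega values must be >= 0")
  if (object@branch_sub_rate < 0) msg <- c(msg, "branch_sub_rate must be >= 0")
  if (object@tstv <= 0) msg <- c(msg, "tstv must be positive")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## SyntheticTruth
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic pan-genome
#'
#' Records, for every generated gene, its true family, origin label, true
#' dN/dS and replicon, plus the true one-gene-per-genome orthologue tuples
#' (with the outgroup member and ancestral-core flag where an outgroup was
#' simulated). Downstream recovery tests compare pipeline output against
#' these records.
#'
#' @slot family_of named character: gene id -> true family id.
#' @slot ortho_groups data.frame: one row per core family, one column per
#'   genome holding that genome's member gene id, plus `family`, `in_anc`
#'   (belongs to the ancestral core) and, when simulated, the outgroup column.
#' @slot origin_of named character: gene id -> ancestral / HGT / unassigned.
#' @slot omega_of named numeric: gene id -> true dN/dS.
#' @slot replicon_of named character: gene id -> replicon name.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth", representation(
  family_of = "character",
  ortho_groups = "data.frame",
  origin_of = "character",
  omega_of = "numeric",
  replicon_of = "character"
))

setValidity("SyntheticTruth", function(object) {
  ids <- names(object@family_of)
  if (is.null(ids)) return("family_of must be a named vector")
  for (s in c("origin_of", "omega_of", "replicon_of")) {
    if (!setequal(names(slot(object, s)), ids))
      return(sprintf("%s must cover exactly the genes of family_of", s))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Genome
## ---------------------------------------------------------------------------

#' A bacterial genome partitioned over replicons
#'
#' Container for one strain: the ordered replicon table (size, GC, ORF count,
#' replication class, optional rRNA/tRNA counts), the per-gene annotation
#' table, and the protein and CDS sequences as `AAStringSet` / `DNAStringSet`
#' keyed by gene id. CDS are stored without the terminal stop codon; gene
#' coordinates are 1-based inclusive.
#'
#' @slot id strain identifier.
#' @slot replicons data.frame with columns `name`, `length_bp`, `gc_percent`,
#'   `orf_count`, `replication_class`, `rrna_count`, `trna_count`
#'   (counts may be NA when unknown).
#' @slot genes data.frame with columns `gene_id`, `genome_id`, `replicon`,
#'   `start`, `end`, `strand`, `cog_letter`, `origin`, `essential`.
#' @slot proteins [Biostrings::AAStringSet] named by gene id.
#' @slot cds [Biostrings::DNAStringSet] named by gene id, length 3 x protein
#'   length.
#' @seealso [readGenome()], [writeGenome()], [repliconSummary()]
#' @exportClass Genome
setClass("Genome", representation(
  id = "character",
  replicons = "data.frame",
  genes = "data.frame",
  proteins = "AAStringSet",
  cds = "DNAStringSet"
))

setValidity("Genome", function(object) {
  g <- object@genes
  r <- object@replicons
  msg <- character()
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (sum(r$replication_class == "oriC") != 1L)
    msg <- c(msg, "exactly one replicon must have replication_class oriC")
  if (any(r$length_bp <= 0)) msg <- c(msg, "replicon length_bp must be > 0")
  if (any(r$gc_percent < 0 | r$gc_percent > 100, na.rm = TRUE))
    msg <- c(msg, "gc_percent must lie in [0,100]")
  if (anyDuplicated(g$gene_id)) msg <- c(msg, "duplicate gene ids")
  if (!all(g$replicon %in% r$name))
    msg <- c(msg, "every gene's replicon must exist in the replicon table")
  if (any(g$start > g$end)) msg <- c(msg, "gene start must be <= end")
  if (!setequal(names(object@proteins), g$gene_id) ||
      !setequal(names(object@cds), g$gene_id))
    msg <- c(msg, "proteins and cds must be keyed by exactly the gene ids")
  else {
    pl <- setNames(Biostrings::width(object@proteins),
                   names(object@proteins))[g$gene_id]
    cl <- setNames(Biostrings::width(object@cds),
                   names(object@cds))[g$gene_id]
    if (any(cl != 3L * pl))
      msg <- c(msg, "cds length must equal 3 x protein length (stop trimmed)")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Genome-class strain identifier
#' @param x,object a `Genome`
#' @export
genomeId <- function(x) x@id

#' @describeIn Genome-class per-gene annotation table
#' @export
geneTable <- function(x) x@genes

#' @describeIn Genome-class replicon table
#' @export
repliconTable <- function(x) x@replicons

#' @describeIn Genome-class protein sequences (`AAStringSet`)
#' @export
proteinSeqs <- function(x) x@proteins

#' @describeIn Genome-class CDS sequences (`DNAStringSet`, stop trimmed)
#' @export
cdsSeqs <- function(x) x@cds

#' @describeIn Genome-class name of the oriC replicon
#' @export
chromosomeName <- function(x) {
  x@replicons$name[x@replicons$replication_class == "oriC"]
}

setMethod("show", "Genome", function(object) {
  cat(sprintf("Genome %s: %d genes on %d replicons (%s bp)\n",
              object@id, nrow(object@genes), nrow(object@replicons),
              format(sum(object@replicons$length_bp), big.mark = ",")))
  cat("  replicons:", paste(object@replicons$name, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## ScoringScheme
## ---------------------------------------------------------------------------

#' Protein scoring scheme with Karlin-Altschul statistics
#'
#' Bundles a BLOSUM substitution matrix, affine gap penalties, residue
#' background frequencies and the ungapped Karlin-Altschul parameters
#' (`lambda`, `K`) that turn raw local-alignment scores into bit scores and
#' e-values via E = K m n exp(-lambda S).
#'
#' @slot matrix_name `"BLOSUM62"` or `"BLOSUM80"`.
#' @slot matrix integer substitution matrix over the 20 residues plus `X`
#'   (scored 0 against everything).
#' @slot gap_open,gap_extend positive gap penalties; a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @slot lambda nats per score unit, the positive root of
#'   sum_ij p_i p_j exp(lambda s_ij) = 1 for the ungapped matrix.
#' @slot kappa the Karlin-Altschul K parameter.
#' @slot background_freqs the 20 residue frequencies (sum to 1).
#' @seealso [scoringScheme()], [calibrateLambda()], [hitEvalue()]
#' @exportClass ScoringScheme
setClass("ScoringScheme", representation(
  matrix_name = "character",
  matrix = "matrix",
  gap_open = "numeric",
  gap_extend = "numeric",
  lambda = "numeric",
  kappa = "numeric",
  background_freqs = "numeric"
))

setValidity("ScoringScheme", function(object) {
  p <- object@background_freqs
  if (length(p) != 20L || abs(sum(p) - 1) > 1e-6)
    return("background_freqs must be 20 fractions summing to 1")
  if (object@gap_open <= 0 || object@gap_extend <= 0)
    return("gap penalties must be positive")
  m <- object@matrix
  aa <- names(p)
  if (!all(aa %in% rownames(m))) return("matrix must cover the 20 residues")
  if (!isTRUE(all.equal(m[aa, aa], t(m[aa, aa]))))
    return("matrix must be symmetric")
  if (length(object@lambda) == 1L && !is.na(object@lambda)) {
    if (object@lambda <= 0) return("lambda must be positive")
    res <- sum(outer(p, p) * exp(object@lambda * m[aa, aa])) - 1
    if (abs(res) > 1e-6)
      return("lambda does not satisfy the Karlin-Altschul identity")
  }
  TRUE
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf("ScoringScheme %s: gap %g/%g, lambda %.4f, K %.3f\n",
              object@matrix_name, object@gap_open, object@gap_extend,
              object@lambda, object@kappa))
})

## ---------------------------------------------------------------------------
## FamilyPartition
## ---------------------------------------------------------------------------

#' Protein families from Markov clustering
#'
#' The partition of all input proteins into families (clusters with at least
#' two members) and per-genome singletons, together with each family's genome
#' membership profile.
#'
#' @slot families named list: family id -> member gene ids (>= 2 members).
#' @slot singletons named list: genome id -> gene ids in no family.
#' @slot membership_profile named list: family id -> sorted genome ids.
#' @slot genome_of named character: gene id -> genome id.
#' @seealso [partitionFamilies()], [vennCounts()]
#' @exportClass FamilyPartition
setClass("FamilyPartition", representation(
  families = "list",
  singletons = "list",
  membership_profile = "list",
  genome_of = "character"
))

setValidity("FamilyPartition", function(object) {
  fam <- unlist(object@families, use.names = FALSE)
  sing <- unlist(object@singletons, use.names = FALSE)
  if (any(lengths(object@families) < 2L))
    return("families must have >= 2 members")
  if (anyDuplicated(c(fam, sing)))
    return("families and singletons must partition the genes")
  if (!setequal(names(object@families), names(object@membership_profile)))
    return("membership_profile must cover exactly the families")
  TRUE
})

setMethod("show", "FamilyPartition", function(object) {
  cat(sprintf(
    "FamilyPartition: %d families (%d genes), %d singletons over %d genomes\n",
    length(object@families), length(unlist(object@families, use.names = FALSE)),
    length(unlist(object@singletons, use.names = FALSE)),
    length(object@singletons)))
})

#' @describeIn FamilyPartition-class list of member gene ids per family
#' @param x a `FamilyPartition`
#' @export
familyMembers <- function(x) x@families

#' @describeIn FamilyPartition-class per-genome singleton gene ids
#' @export
familySingletons <- function(x) x@singletons

## ---------------------------------------------------------------------------
## CoreSets
## ---------------------------------------------------------------------------

#' Core-genome orthologue group collections
#'
#' Holds the ingroup core (orthologue groups shared by every ingroup genome)
#' and the ancestral core (groups additionally shared with the outgroup),
#' each as a data.frame with a `group` id column and one gene-id column per
#' genome.
#'
#' @slot ingroup_core data.frame of groups over the ingroup genomes.
#' @slot ancestral_core data.frame of groups over ingroup + outgroup.
#' @slot ingroup_ids,outgroup_id character: the genome ids involved.
#' @seealso [coreSets()], [assembleGroups()]
#' @exportClass CoreSets
setClass("CoreSets", representation(
  ingroup_core = "data.frame",
  ancestral_core = "data.frame",
  ingroup_ids = "character",
  outgroup_id = "character"
))

setMethod("show", "CoreSets", function(object) {
  cat(sprintf("CoreSets: %d ingroup-core groups (%s)",
              nrow(object@ingroup_core),
              paste(object@ingroup_ids, collapse = ", ")))
  if (length(object@outgroup_id))
    cat(sprintf("; %d ancestral-core groups (+%s)",
                nrow(object@ancestral_core), object@outgroup_id))
  cat("\n")
})

## ---------------------------------------------------------------------------
## CodonAlignment
## ---------------------------------------------------------------------------

#' A gap-free pairing of codon columns from two CDS
#'
#' Built by threading the two coding sequences through a protein alignment
#' ([codonAlign()]); gapped columns are dropped so both members are exactly
#' 3L nucleotides for L codon columns. Codons are stored as indices 1..64
#' in TCAG order.
#'
#' @slot codons_a,codons_b integer vectors of codon indices (1..64).
#' @seealso [codonAlign()], [ng86()]
#' @exportClass CodonAlignment
setClass("CodonAlignment", representation(
  codons_a = "integer",
  codons_b = "integer"
))

setValidity("CodonAlignment", function(object) {
  if (length(object@codons_a) != length(object@codons_b))
    return("both sequences must have the same codon length")
  tab <- codonTables()
  if (any(tab$aa[object@codons_a] == "*") || any(tab$aa[object@codons_b] == "*"))
    return("internal stop codons are not allowed")
  TRUE
})

setMethod("length", "CodonAlignment", function(x) length(x@codons_a))

setMethod("show", "CodonAlignment", function(object) {
  nd <- sum(object@codons_a != object@codons_b)
  cat(sprintf("CodonAlignment: %d codons, %d differing\n",
              length(object@codons_a), nd))
})
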