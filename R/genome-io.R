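## Reading/writing genomes and annotation tables; replicon-level statistics;
## chromosome / chromid / plasmid classification.
##
## File dialect: protein FASTA (<id>.faa), CDS FASTA (<id>.fna, terminal stop
## codon included), per-gene annotation TSV (<id>.annot.tsv) with 1-based
## inclusive coordinates, and a replicon metadata TSV (<id>.replicons.tsv)
## carrying size/GC/replication-class so a genome round-trips losslessly.

#' GC content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous bases are excluded from both
#' the numerator and the denominator.
#'
#' @param x character vector, `DNAString` or `DNAStringSet`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @examples
#' gcContent("ATGC")   # 0.5
#' gcContent("AANN")   # 0 over the 2 counted bases
#' @export
gcContent <- function(x) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(x)
  if (is(x, "DNAString")) x <- Biostrings::DNAStringSet(list(x))
  if (any(Biostrings::width(x) == 0L)) stopf("empty sequence")
  af <- Biostrings::alphabetFrequency(x, baseOnly = TRUE)
  counted <- rowSums(af[, c("A", "C", "G", "T"), drop = FALSE])
  if (any(counted == 0L)) stopf("sequence with no unambiguous bases")
  unname(rowSums(af[, c("G", "C"), drop = FALSE]) / counted)
}

#' Write a genome to FASTA + TSV files
#'
#' Emits `<id>.faa`, `<id>.fna` (CDS with a terminal TAA stop codon),
#' `<id>.annot.tsv` and `<id>.replicons.tsv` under `dir`.
#'
#' @param genome a [Genome-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the four paths.
#' @seealso [readGenome()]
#' @export
writeGenome <- function(genome, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- genome@id
  paths <- file.path(dir, paste0(id, c(".faa", ".fna", ".annot.tsv",
                                       ".replicons.tsv")))
  Biostrings::writeXStringSet(genome@proteins, paths[1])
  withstop <- Biostrings::DNAStringSet(paste0(as.character(genome@cds), "TAA"))
  names(withstop) <- names(genome@cds)
  Biostrings::writeXStringSet(withstop, paths[2])
  write.table(genome@genes, paths[3], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(genome@replicons, paths[4], sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' Read a genome from FASTA + TSV files
#'
#' Ids must be consistent across the three files; CDS may carry a terminal
#' stop codon, which is trimmed. Every record is validated (coordinates,
#' CDS/protein length agreement, translation) and violations are reported
#' with the offending gene id.
#'
#' @param faa_path protein FASTA.
#' @param fna_path CDS FASTA (ids matching `faa_path`).
#' @param annot_path annotation TSV with columns `gene_id`, `genome_id`,
#'   `replicon`, `start`, `end`, `strand`, `cog_letter`, `origin`,
#'   `essential`.
#' @param repl_path optional replicon metadata TSV; when absent, replicon
#'   sizes are inferred from the gene coordinates and the replicon with the
#'   largest span is taken as the oriC chromosome.
#' @return a [Genome-class].
#' @export
readGenome <- function(faa_path, fna_path, annot_path, repl_path = NULL) {
  prot <- Biostrings::readAAStringSet(faa_path)
  cds <- Biostrings::readDNAStringSet(fna_path)
  names(prot) <- sub("\\s.*$", "", names(prot))
  names(cds) <- sub("\\s.*$", "", names(cds))
  annot <- read.delim(annot_path, stringsAsFactors = FALSE)
  annot$cog_letter <- as.character(annot$cog_letter)
  annot$origin <- as.character(annot$origin)

  if (anyDuplicated(annot$gene_id))
    stopf("format error: duplicate gene id '%s' in %s",
          annot$gene_id[duplicated(annot$gene_id)][1], annot_path)
  if (anyDuplicated(names(prot)) || anyDuplicated(names(cds)))
    stopf("format error: duplicate sequence ids in FASTA input")
  miss <- setdiff(annot$gene_id, names(prot))
  if (length(miss))
    stopf("format error: missing protein for gene '%s'", miss[1])
  miss <- setdiff(annot$gene_id, names(cds))
  if (length(miss))
    stopf("format error: missing CDS for gene '%s'", miss[1])
  bad <- annot$gene_id[annot$start > annot$end]
  if (length(bad))
    stopf("format error: end < start for gene '%s'", bad[1])

  prot <- prot[annot$gene_id]
  cds <- cds[annot$gene_id]
  pl <- Biostrings::width(prot)
  cl <- Biostrings::width(cds)
  has_stop <- cl == 3L * pl + 3L
  ok_len <- has_stop | cl == 3L * pl
  if (!all(ok_len))
    stopf("format error: CDS length %d does not match protein length %d for gene '%s'",
          cl[!ok_len][1], pl[!ok_len][1], annot$gene_id[!ok_len][1])
  if (any(has_stop)) {
    last <- as.character(Biostrings::subseq(cds[has_stop],
                                            start = cl[has_stop] - 2L))
    notstop <- !last %in% c("TAA", "TAG", "TGA")
    if (any(notstop))
      stopf("format error: CDS of gene '%s' is 3L+3 nt but does not end in a stop codon",
            annot$gene_id[has_stop][notstop][1])
    cds[has_stop] <- Biostrings::subseq(cds[has_stop], start = 1L,
                                        end = cl[has_stop] - 3L)
  }
  tr <- Biostrings::translate(cds, genetic.code = Biostrings::getGeneticCode("11"),
                              no.init.codon = TRUE, if.fuzzy.codon = "X")
  mismatch <- as.character(tr) != as.character(prot)
  if (any(mismatch))
    stopf("format error: CDS of gene '%s' does not translate to its protein",
          annot$gene_id[mismatch][1])

  gid <- unique(annot$genome_id)
  if (length(gid) != 1L)
    stopf("format error: annotation mixes genome ids (%s)",
          paste(gid, collapse = ", "))

  if (!is.null(repl_path)) {
    repl <- read.delim(repl_path, stringsAsFactors = FALSE)
    for (cc in c("length_bp", "orf_count", "rrna_count", "trna_count"))
      if (cc %in% names(repl)) repl[[cc]] <- as.integer(repl[[cc]])
    if ("gc_percent" %in% names(repl))
      repl$gc_percent <- as.numeric(repl$gc_percent)
  } else {
    spans <- vapply(split(annot$end, annot$replicon), max, numeric(1))
    repl <- data.frame(
      name = names(spans),
      length_bp = as.integer(spans),
      gc_percent = NA_real_,
      orf_count = as.integer(table(annot$replicon)[names(spans)]),
      replication_class = ifelse(seq_along(spans) == which.max(spans),
                                 "oriC", "repABC"),
      rrna_count = NA_integer_, trna_count = NA_integer_,
      stringsAsFactors = FALSE)
  }
  new("Genome", id = gid, replicons = repl, genes = annot,
      proteins = prot, cds = cds)
}

#' Replicon summary statistics
#'
#' One row per replicon (size, GC, ORF count, rRNA/tRNA when known, category
#' from [classifyReplicon()]) plus a `TOTAL` row whose size and count columns
#' are exact column sums (GC is the length-weighted mean).
#'
#' @param genome a [Genome-class].
#' @param gc_tolerance GC-closeness tolerance (percentage points) forwarded
#'   to the replicon classifier.
#' @return data.frame with a trailing `TOTAL` row.
#' @export
repliconSummary <- function(genome, gc_tolerance = 1.5) {
  cls <- classifyReplicons(genome, gc_tolerance = gc_tolerance)
  r <- genome@replicons
  out <- data.frame(
    replicon = r$name, size_bp = r$length_bp, gc_percent = r$gc_percent,
    orf_count = r$orf_count, rrna = r$rrna_count, trna = r$trna_count,
    category = cls$category, stringsAsFactors = FALSE)
  total <- data.frame(
    replicon = "TOTAL", size_bp = sum(r$length_bp),
    gc_percent = roundHalfUp(sum(r$gc_percent * r$length_bp) /
                             sum(r$length_bp), 2),
    orf_count = sum(r$orf_count),
    rrna = if (anyNA(r$rrna_count)) NA_integer_ else sum(r$rrna_count),
    trna = if (anyNA(r$trna_count)) NA_integer_ else sum(r$trna_count),
    category = NA_character_, stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Extra-chromosomal genome fraction
#'
#' Percentage of the genome (in bp) carried by replicons other than the oriC
#' chromosome, rounded half-up to one decimal.
#'
#' @param x a [Genome-class], or a numeric vector of replicon sizes.
#' @param chromosome for the numeric method: index or name of the chromosome
#'   entry (default 1).
#' @return a percentage with one decimal.
#' @examples
#' extrachromosomalFraction(c(2900071, 1598241, 731389, 488405,
#'                            606415, 148687))   # 55.2
#' @export
setGeneric("extrachromosomalFraction",
           function(x, chromosome = 1L) standardGeneric("extrachromosomalFraction"))

#' @rdname extrachromosomalFraction
#' @export
setMethod("extrachromosomalFraction", "numeric", function(x, chromosome = 1L) {
  if (length(x) < 1L || any(x <= 0)) stopf("replicon sizes must be positive")
  chrom <- if (is.character(chromosome)) x[[chromosome]] else x[[chromosome]]
  roundHalfUp(100 * (sum(x) - chrom) / sum(x), 1)
})

#' @rdname extrachromosomalFraction
#' @export
setMethod("extrachromosomalFraction", "Genome", function(x, chromosome = 1L) {
  r <- x@replicons
  ic <- which(r$replication_class == "oriC")
  if (length(ic) != 1L) stopf("genome must have exactly one oriC replicon")
  extrachromosomalFraction(r$length_bp, chromosome = ic)
})

#' Classify one replicon as chromosome, chromid or plasmid
#'
#' An oriC replicon is the chromosome. A repABC replicon carrying at least
#' one essential gene is a chromid; with none it is a plasmid. GC closeness
#' to the chromosome (within `gc_tolerance` percentage points) is reported as
#' an advisory flag but does not decide the category, since published chromid
#' assignments keep replicons that fail it.
#'
#' @param replication_class `"oriC"` or `"repABC"`.
#' @param gc_percent the replicon's GC (percent).
#' @param chromosome_gc the chromosome's GC (percent).
#' @param essential_count number of essential genes on the replicon.
#' @param gc_tolerance advisory GC-closeness tolerance, percentage points.
#' @return list with `category` and logical `flags`
#'   (`plasmid_type_replication`, `has_essential`, `gc_close`).
#' @examples
#' classifyReplicon("repABC", 68.8, 68.4, essential_count = 40)$category
#' classifyReplicon("repABC", 67.1, 68.4, essential_count = 0)$category
#' @export
classifyReplicon <- function(replication_class, gc_percent, chromosome_gc,
                             essential_count, gc_tolerance = 1.5) {
  if (!replication_class %in% c("oriC", "repABC"))
    stopf("unknown replication class '%s'", replication_class)
  flags <- c(
    plasmid_type_replication = replication_class == "repABC",
    has_essential = isTRUE(essential_count >= 1L),
    gc_close = isTRUE(abs(gc_percent - chromosome_gc) <= gc_tolerance))
  category <- if (replication_class == "oriC") "chromosome"
              else if (flags[["has_essential"]]) "chromid" else "plasmid"
  list(category = category, flags = flags)
}

#' Classify every replicon of a genome
#'
#' Applies [classifyReplicon()] to each replicon, counting essential genes
#' from the annotation table.
#'
#' @param genome a [Genome-class].
#' @param gc_tolerance advisory GC tolerance in percentage points.
#' @return data.frame: `name`, `category` and the three criterion flags.
#' @export
classifyReplicons <- function(genome, gc_tolerance = 1.5) {
  r <- genome@replicons
  g <- genome@genes
  chrom_gc <- r$gc_percent[r$replication_class == "oriC"]
  ess <- vapply(r$name, function(nm)
    sum(g$essential[g$replicon == nm], na.rm = TRUE), numeric(1))
  res <- lapply(seq_len(nrow(r)), function(i)
    classifyReplicon(r$replication_class[i], r$gc_percent[i], chrom_gc,
                     ess[i], gc_tolerance))
  data.frame(
    name = r$name,
    category = vapply(res, `[[`, character(1), "category"),
    plasmid_type_replication = vapply(res, function(x)
      x$flags[["plasmid_type_replication"]], logical(1)),
    has_essential = vapply(res, function(x)
      x$flags[["has_essential"]], logical(1)),
    gc_close = vapply(res, function(x) x$flags[["gc_close"]], logical(1)),
    stringsAsFactors = FALSE)
}

#' Published multi-replicon genome statistics shipped with the package
#'
#' Replicon sizes, GC, ORF/rRNA/tRNA counts, replication class and chromid
#' status for the four Azospirillum strains CBG497, Sp245, 4B and B510
#' (unknown entries are NA). Useful as a worked example for the replicon
#' statistics functions.
#'
#' @return data.frame, one row per replicon.
#' @examples
#' tab <- exampleRepliconTable()
#' with(subset(tab, strain == "CBG497"),
#'      extrachromosomalFraction(size_bp, which(replication_class == "oriC")))
#' @export
exampleRepliconTable <- function() {
  read.delim(system.file("extdata", "azospirillum_replicons.tsv",
                         package = "pancore"),
             stringsAsFactors = FALSE)
}
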