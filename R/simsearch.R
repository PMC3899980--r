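## All-vs-all protein comparison: exact affine-gap local alignment scored with
## a BLOSUM matrix, Karlin-Altschul e-value statistics, and the standard
## 12-column tabular hit format (plus positives/coverage extension columns).
##
## The search itself is a shared-k-mer prefilter followed by exact local
## alignment of the surviving pairs; `method = "exact"` aligns every pair and
## is what the dynamic-programming oracle tests run against.

## Robinson & Robinson (1991) residue background frequencies
.RR_FREQS <- c(
  A = 78.05, R = 51.29, N = 44.87, D = 53.64, C = 19.25, Q = 42.64,
  E = 62.95, G = 73.77, H = 21.99, I = 51.42, L = 90.19, K = 57.44,
  M = 22.43, F = 38.56, P = 52.03, S = 71.20, T = 58.41, W = 13.30,
  Y = 32.16, V = 64.41)

## published ungapped K parameters
.KA_KAPPA <- c(BLOSUM62 = 0.134, BLOSUM80 = 0.177)

#' Construct a scoring scheme
#'
#' Loads the requested BLOSUM matrix (with `X` rescored to 0 against every
#' residue), attaches affine gap penalties, background residue frequencies
#' and the Karlin-Altschul parameters. `lambda` is calibrated from the matrix
#' by [calibrateLambda()] unless supplied.
#'
#' @param matrix_name `"BLOSUM62"` or `"BLOSUM80"`.
#' @param gap_open,gap_extend positive gap penalties (a gap of length L costs
#'   `gap_open + L * gap_extend`); defaults follow common practice for each
#'   matrix (11/1 for BLOSUM62, 10/1 for BLOSUM80).
#' @param lambda,kappa optional Karlin-Altschul parameter overrides.
#' @param background_freqs 20 residue frequencies (normalised internally).
#' @return a [ScoringScheme-class].
#' @examples
#' scoringScheme("BLOSUM80")
#' @export
scoringScheme <- function(matrix_name = c("BLOSUM62", "BLOSUM80"),
                          gap_open = NULL, gap_extend = 1,
                          lambda = NULL, kappa = NULL,
                          background_freqs = NULL) {
  matrix_name <- match.arg(matrix_name)
  mat <- getBlosum(matrix_name)
  p <- background_freqs %||% .RR_FREQS
  p <- p / sum(p)
  if (is.null(gap_open))
    gap_open <- if (matrix_name == "BLOSUM62") 11 else 10
  scheme <- new("ScoringScheme",
                matrix_name = matrix_name, matrix = mat,
                gap_open = gap_open, gap_extend = gap_extend,
                lambda = NA_real_,
                kappa = kappa %||% unname(.KA_KAPPA[matrix_name]),
                background_freqs = p)
  scheme@lambda <- lambda %||% calibrateLambda(scheme)
  validObject(scheme)
  scheme
}

## BLOSUM matrix restricted to the 20 residues + X (X scored 0)
getBlosum <- function(name) {
  key <- paste0("blosum_", name)
  if (!is.null(.pancoreCache[[key]])) return(.pancoreCache[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]]
  aa <- names(.RR_FREQS)
  m <- m[c(aa, "X"), c(aa, "X")]
  m["X", ] <- 0L
  m[, "X"] <- 0L
  .pancoreCache[[key]] <- m
  m
}

#' Calibrate the ungapped Karlin-Altschul lambda
#'
#' Finds the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s_ij) = 1` by bracketed root finding
#' (residual below 1e-9). Requires a negative expected matrix score.
#'
#' @param scheme a [ScoringScheme-class] (its `lambda` slot is ignored).
#' @return the calibrated lambda (nats per score unit).
#' @examples
#' abs(calibrateLambda(scoringScheme("BLOSUM62")) - 0.3176) < 0.01
#' @export
calibrateLambda <- function(scheme) {
  p <- scheme@background_freqs
  aa <- names(p)
  S <- scheme@matrix[aa, aa]
  pp <- outer(p, p)
  if (sum(pp * S) >= 0)
    stopf("expected matrix score is non-negative; no valid lambda exists")
  f <- function(l) sum(pp * exp(l * S)) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  r <- uniroot(f, c(1e-8, hi), tol = 1e-12)
  if (abs(f(r$root)) > 1e-9)
    stopf("lambda root finding did not converge")
  r$root
}

#' E-value and bit score of a local alignment score
#'
#' Karlin-Altschul statistics with the scheme's ungapped parameters:
#' `E = K * m * n * exp(-lambda * S)` and
#' `S' = (lambda * S - log K) / log 2`. No effective-length edge correction
#' is applied; `n` is the raw residue count of the searched database.
#'
#' @param score raw alignment score(s).
#' @param query_len query length m (residues).
#' @param db_residues database size n (total residues searched).
#' @param scheme a calibrated [ScoringScheme-class].
#' @return list with numeric `evalue` and `bitscore`.
#' @export
hitEvalue <- function(score, query_len, db_residues, scheme) {
  if (is.na(scheme@lambda)) stopf("scoring scheme is not calibrated")
  lam <- scheme@lambda; K <- scheme@kappa
  list(evalue = K * query_len * db_residues * exp(-lam * score),
       bitscore = (lam * score - log(K)) / log(2))
}

## ---------------------------------------------------------------------------
## alignment
## ---------------------------------------------------------------------------

.checkProtein <- function(x, what) {
  if (!nchar(x)) stopf("empty %s sequence", what)
  bad <- setdiff(strsplit(x, "")[[1]], c(names(.RR_FREQS), "X"))
  if (length(bad))
    stopf("unknown residue '%s' in %s sequence", bad[1], what)
}

#' Optimal local alignment of two proteins
#'
#' Exact Smith-Waterman alignment under affine gaps with the scheme's
#' substitution matrix; the traceback yields one optimal alignment.
#' `X` is accepted and scored 0 against everything.
#'
#' @param a,b protein sequences (character or `AAString`).
#' @param scheme a [ScoringScheme-class].
#' @return list with `score`, 1-based aligned spans (`q_start`, `q_end`,
#'   `s_start`, `s_end`), the gapped `aligned_a` / `aligned_b` strings,
#'   `aln_length`, `identities`, `positives`, `mismatches` and `gap_opens`.
#' @examples
#' sc <- scoringScheme("BLOSUM62")
#' localAlign("HEAGAWGHEE", "PAWHEAE", sc)$score
#' @export
localAlign <- function(a, b, scheme) {
  a <- as.character(a); b <- as.character(b)
  .checkProtein(a, "query"); .checkProtein(b, "subject")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scheme@matrix,
    gapOpening = scheme@gap_open, gapExtension = scheme@gap_extend)
  st <- .alignmentStats(as.character(Biostrings::pattern(pa)),
                        as.character(Biostrings::subject(pa)), scheme)
  c(list(score = score(pa),
         q_start = BiocGenerics::start(Biostrings::pattern(pa)),
         q_end = BiocGenerics::end(Biostrings::pattern(pa)),
         s_start = BiocGenerics::start(Biostrings::subject(pa)),
         s_end = BiocGenerics::end(Biostrings::subject(pa))),
    st)
}

## per-alignment column statistics from the gapped strings (vectorized)
.alignmentStats <- function(aligned_a, aligned_b, scheme) {
  mat <- scheme@matrix
  n <- length(aligned_a)
  ident <- pos <- mism <- gaps <- integer(n)
  ca_all <- strsplit(aligned_a, "")
  cb_all <- strsplit(aligned_b, "")
  for (i in seq_len(n)) {
    ca <- ca_all[[i]]; cb <- cb_all[[i]]
    nog <- ca != "-" & cb != "-"
    ident[i] <- sum(ca[nog] == cb[nog])
    pos[i] <- sum(mat[cbind(ca[nog], cb[nog])] > 0)
    mism[i] <- sum(nog) - ident[i]
    gaps[i] <- .countGapOpens(ca) + .countGapOpens(cb)
  }
  list(aligned_a = aligned_a, aligned_b = aligned_b,
       aln_length = nchar(aligned_a), identities = ident,
       positives = pos, mismatches = mism, gap_opens = gaps)
}

.countGapOpens <- function(chars) {
  g <- chars == "-"
  sum(g & !c(FALSE, head(g, -1L)))
}

## ---------------------------------------------------------------------------
## all-vs-all search
## ---------------------------------------------------------------------------

#' Map gene ids to genome ids
#' @param genomes list of [Genome-class].
#' @return named character vector gene id -> genome id.
#' @export
geneGenomeMap <- function(genomes) {
  ids <- unlist(lapply(genomes, function(g) g@genes$gene_id), use.names = FALSE)
  if (anyDuplicated(ids)) stopf("duplicate gene ids across genomes")
  setNames(rep(vapply(genomes, genomeId, character(1)),
               vapply(genomes, function(g) nrow(g@genes), integer(1))), ids)
}

## candidate unordered pairs sharing >= min_shared k-mers
.kmerCandidates <- function(seqs, k = 5L, min_shared = 2L, max_occ = 200L) {
  n <- length(seqs)
  chs <- as.character(seqs)
  kms <- lapply(chs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  ix <- rep.int(seq_len(n), lengths(kms))
  km <- unlist(kms, use.names = FALSE)
  grp <- split(ix, km)
  grp <- grp[lengths(grp) >= 2L & lengths(grp) <= max_occ]
  if (!length(grp)) return(matrix(integer(), 0L, 2L))
  pr <- lapply(grp, function(v) {
    m <- t(utils::combn(v, 2L))
    m
  })
  pr <- do.call(rbind, pr)
  key <- (pr[, 1L] - 1) * n + pr[, 2L]
  cnt <- table(key)
  keep <- as.numeric(names(cnt)[cnt >= min_shared])
  cbind(as.integer((keep - 1) %/% n + 1), as.integer((keep - 1) %% n + 1))
}

#' All-vs-all protein comparison
#'
#' Aligns protein pairs across (and within) the given genomes and returns a
#' hit table in the standard 12-column layout plus `positives`, `qcov` and
#' `scov`. Each unordered pair is aligned once; both directed hits are
#' emitted when they pass `min_report_evalue` (e-values differ by direction
#' because the database size n is the subject genome's proteome residue
#' count). Hits are ranked by bit score within each ordered genome pair and
#' query; self-hits of a gene against itself are excluded, hits between two
#' genes of the same genome are included.
#'
#' @param genomes list of [Genome-class] (at least two).
#' @param scheme a [ScoringScheme-class].
#' @param min_report_evalue report hits with E at or below this value.
#' @param method `"kmer"` (shared-k-mer prefilter, the default) or `"exact"`
#'   (align every pair).
#' @param kmer_k,kmer_min_shared prefilter: word size and the number of
#'   shared words required to align a pair.
#' @return data.frame hit table; see [writeHitTable()] for the column layout.
#' @export
allVsAll <- function(genomes, scheme = scoringScheme("BLOSUM62"),
                     min_report_evalue = 1e-4,
                     method = c("kmer", "exact"),
                     kmer_k = 5L, kmer_min_shared = 2L) {
  method <- match.arg(method)
  if (length(genomes) < 2L) stopf("need at least two genomes")
  gmap <- geneGenomeMap(genomes)
  prot <- do.call(c, unname(lapply(genomes, proteinSeqs)))
  prot <- prot[names(gmap)]
  lens <- Biostrings::width(prot)
  names(lens) <- names(prot)
  db_res <- tapply(lens, gmap[names(prot)], sum)

  pairs <- if (method == "exact") {
    n <- length(prot)
    t(utils::combn(seq_len(n), 2L))
  } else {
    .kmerCandidates(prot, k = kmer_k, min_shared = kmer_min_shared)
  }
  if (!nrow(pairs)) return(.emptyHitTable())

  out <- vector("list", ceiling(nrow(pairs) / 2000L))
  bi <- 0L
  for (off in seq(1L, nrow(pairs), by = 2000L)) {
    sel <- off:min(off + 1999L, nrow(pairs))
    ia <- pairs[sel, 1L]; ib <- pairs[sel, 2L]
    pa <- Biostrings::pairwiseAlignment(
      prot[ia], prot[ib], type = "local",
      substitutionMatrix = scheme@matrix,
      gapOpening = scheme@gap_open, gapExtension = scheme@gap_extend)
    st <- .alignmentStats(as.character(Biostrings::pattern(pa)),
                          as.character(Biostrings::subject(pa)), scheme)
    sc <- score(pa)
    qs <- BiocGenerics::start(Biostrings::pattern(pa))
    qe <- BiocGenerics::end(Biostrings::pattern(pa))
    ss <- BiocGenerics::start(Biostrings::subject(pa))
    se <- BiocGenerics::end(Biostrings::subject(pa))
    ids_a <- names(prot)[ia]; ids_b <- names(prot)[ib]
    la <- lens[ia]; lb <- lens[ib]
    fwd <- hitEvalue(sc, la, db_res[gmap[ids_b]], scheme)
    rev <- hitEvalue(sc, lb, db_res[gmap[ids_a]], scheme)
    mk <- function(q, s, qst, qen, sst, sen, ql, sl, ev) data.frame(
      query = q, subject = s,
      pident = round(100 * st$identities / pmax(st$aln_length, 1L), 2),
      length = st$aln_length, mismatches = st$mismatches,
      gapopen = st$gap_opens,
      qstart = qst, qend = qen, sstart = sst, send = sen,
      evalue = ev, bitscore = round(fwd$bitscore, 1),
      positives = st$positives,
      qcov = (qen - qst + 1) / ql, scov = (sen - sst + 1) / sl,
      stringsAsFactors = FALSE)
    h1 <- mk(ids_a, ids_b, qs, qe, ss, se, la, lb, fwd$evalue)
    h2 <- mk(ids_b, ids_a, ss, se, qs, qe, lb, la, rev$evalue)
    h <- rbind(h1[h1$evalue <= min_report_evalue & sc > 0, ],
               h2[h2$evalue <= min_report_evalue & sc > 0, ])
    bi <- bi + 1L
    out[[bi]] <- h
  }
  hits <- do.call(rbind, out[seq_len(bi)])
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  ord <- order(gmap[hits$query], gmap[hits$subject], hits$query,
               -hits$bitscore, hits$evalue, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

.emptyHitTable <- function() {
  data.frame(query = character(), subject = character(), pident = numeric(),
             length = integer(), mismatches = integer(), gapopen = integer(),
             qstart = integer(), qend = integer(), sstart = integer(),
             send = integer(), evalue = numeric(), bitscore = numeric(),
             positives = integer(), qcov = numeric(), scov = numeric(),
             stringsAsFactors = FALSE)
}

#' Write a hit table in tabular format
#'
#' The standard 12 tab-separated columns (query, subject, %identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore) followed by the extension columns `positives`, `qcov`
#' and `scov`. No header line. Numeric values are written with full
#' precision so the table round-trips bit-exactly.
#'
#' @param hits data.frame from [allVsAll()] or [readHitTable()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeHitTable <- function(hits, path) {
  fm <- hits
  for (cc in c("evalue", "qcov", "scov"))
    fm[[cc]] <- sprintf("%.17g", fm[[cc]])
  fm$pident <- sprintf("%.17g", fm$pident)
  fm$bitscore <- sprintf("%.17g", fm$bitscore)
  write.table(fm, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a tabular hit table
#'
#' Accepts the 15-column format written by [writeHitTable()] or a plain
#' 12-column file (e.g. from an external search tool), in which case
#' coverages are recomputed from a supplied length table and `positives`
#' is NA.
#'
#' @param path input file.
#' @param lengths named integer vector of sequence lengths, required for
#'   12-column input.
#' @return data.frame hit table.
#' @export
readHitTable <- function(path, lengths = NULL) {
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  cn <- c("query", "subject", "pident", "length", "mismatches", "gapopen",
          "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (ncol(raw) == 15L) {
    names(raw) <- c(cn, "positives", "qcov", "scov")
  } else if (ncol(raw) == 12L) {
    names(raw) <- cn
    if (is.null(lengths))
      stopf("12-column input requires a length table to recompute coverages")
    miss <- setdiff(unique(c(raw$query, raw$subject)), names(lengths))
    if (length(miss)) stopf("missing length for sequence '%s'", miss[1])
    raw$positives <- NA_integer_
    raw$qcov <- (raw$qend - raw$qstart + 1) / lengths[raw$query]
    raw$scov <- (raw$send - raw$sstart + 1) / lengths[raw$subject]
  } else {
    stopf("expected 12 or 15 tab-separated columns, found %d", ncol(raw))
  }
  raw
}

#' @importFrom BiocGenerics score start end
NULL
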