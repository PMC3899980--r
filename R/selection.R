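## Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, codon-alignment
## construction, the consistent-replicon core subset, and the Ka-vs-Ks
## regression / negative-selection classification.

## ---------------------------------------------------------------------------
## codon lookup tables (built once, cached)
## ---------------------------------------------------------------------------

## Per-codon synonymous site fractions and pathway-averaged synonymous /
## nonsynonymous difference counts for every codon pair. Site counting: each
## position contributes (number of synonymous non-stop one-step changes)/3,
## so S + N = 3L holds exactly and changes to stop codons never count as
## synonymous. Multi-difference codon pairs average the per-step counts over
## all substitution orderings; orderings passing through a stop codon are
## excluded (if every ordering is blocked, all orderings are used and steps
## through stops count as nonsynonymous).
codonTables <- function() {
  if (!is.null(.pancoreCache$ng86)) return(.pancoreCache$ng86)
  aa <- .aaByCodon()
  codons <- .pancoreCache$codons64
  syn_sites <- rep(NA_real_, 64L)
  nt_of <- function(idx) c((idx - 1L) %/% 16L + 1L,
                           ((idx - 1L) %/% 4L) %% 4L + 1L,
                           (idx - 1L) %% 4L + 1L)
  idx_of <- function(v) codonIndex(v[1L], v[2L], v[3L])
  for (c1 in 1:64) {
    if (aa[c1] == "*") next
    s <- 0
    v <- nt_of(c1)
    for (p in 1:3) for (nt in setdiff(1:4, v[p])) {
      w <- v; w[p] <- nt
      c2 <- idx_of(w)
      if (aa[c2] == "*") next
      if (aa[c2] == aa[c1]) s <- s + 1
    }
    syn_sites[c1] <- s / 3
  }
  sd <- nd <- matrix(NA_real_, 64L, 64L)
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  for (c1 in 1:64) for (c2 in 1:64) {
    if (aa[c1] == "*" || aa[c2] == "*") next
    if (c1 == c2) { sd[c1, c2] <- 0; nd[c1, c2] <- 0; next }
    v1 <- nt_of(c1); v2 <- nt_of(c2)
    dpos <- which(v1 != v2)
    paths <- perms[[as.character(length(dpos))]]
    walk <- function(ord, exclude_stops) {
      cur <- v1
      s <- n <- 0
      for (p in dpos[ord]) {
        nxt <- cur; nxt[p] <- v2[p]
        a1 <- aa[idx_of(cur)]; a2 <- aa[idx_of(nxt)]
        if (a2 == "*" && exclude_stops) return(NULL)
        if (a1 != "*" && a1 == a2) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    }
    res <- lapply(paths, walk, exclude_stops = TRUE)
    res <- res[!vapply(res, is.null, logical(1))]
    if (!length(res)) res <- lapply(paths, walk, exclude_stops = FALSE)
    m <- do.call(rbind, res)
    sd[c1, c2] <- mean(m[, 1L]); nd[c1, c2] <- mean(m[, 2L])
  }
  .pancoreCache$ng86 <- list(aa = aa, codons = codons, syn_sites = syn_sites,
                             sd = sd, nd = nd)
  .pancoreCache$ng86
}

## nucleotide string -> codon index vector (1..64); ambiguity is an error
.cdsToCodons <- function(x, what = "sequence") {
  if (!is.null(.pancoreCache$ntlut)) lut <- .pancoreCache$ntlut
  else {
    lut <- rep(NA_integer_, 128L)
    lut[utf8ToInt("T")] <- 1L; lut[utf8ToInt("C")] <- 2L
    lut[utf8ToInt("A")] <- 3L; lut[utf8ToInt("G")] <- 4L
    lut[utf8ToInt("t")] <- 1L; lut[utf8ToInt("c")] <- 2L
    lut[utf8ToInt("a")] <- 3L; lut[utf8ToInt("g")] <- 4L
    .pancoreCache$ntlut <- lut
  }
  v <- lut[utf8ToInt(as.character(x))]
  if (anyNA(v)) stopf("non-ACGT base in %s", what)
  if (length(v) %% 3L != 0L) stopf("%s length is not a multiple of 3", what)
  codonIndex(v[seq(1L, length(v), 3L)], v[seq(2L, length(v), 3L)],
             v[seq(3L, length(v), 3L)])
}

## ---------------------------------------------------------------------------
## codon alignment
## ---------------------------------------------------------------------------

#' Thread two CDS through a protein alignment
#'
#' Maps each aligned residue pair to its codon pair and drops gapped
#' columns, yielding a gap-free [CodonAlignment-class]. Each CDS must
#' translate to its (ungapped) protein in the alignment; a terminal stop
#' codon is trimmed first. Translation disagreements are reported with the
#' offending codon index.
#'
#' @param protein_alignment character vector of two equal-length gapped
#'   protein strings (or a list of two).
#' @param cds_a,cds_b the coding sequences (character / `DNAString`).
#' @return a [CodonAlignment-class].
#' @export
codonAlign <- function(protein_alignment, cds_a, cds_b) {
  pa <- unlist(protein_alignment)
  if (length(pa) != 2L || nchar(pa[1]) != nchar(pa[2]))
    stopf("protein_alignment must be two equal-length gapped strings")
  tabs <- codonTables()
  prep <- function(cds, aligned, what) {
    cod <- .cdsToCodons(cds, what)
    if (tabs$aa[cod[length(cod)]] == "*") cod <- cod[-length(cod)]
    res <- strsplit(aligned, "")[[1]]
    nog <- which(res != "-")
    if (length(nog) != length(cod))
      stopf("%s: %d codons do not match %d aligned residues",
            what, length(cod), length(nog))
    tr <- tabs$aa[cod]
    bad <- which(tr != res[nog] & res[nog] != "X" & tr != "X")
    if (length(bad))
      stopf("translation mismatch at codon %d of %s ('%s' vs residue '%s')",
            bad[1], what, tr[bad[1]], res[nog][bad[1]])
    full <- rep(NA_integer_, nchar(aligned))
    full[nog] <- cod
    full
  }
  fa <- prep(cds_a, pa[1], "cds_a")
  fb <- prep(cds_b, pa[2], "cds_b")
  keep <- !is.na(fa) & !is.na(fb)
  new("CodonAlignment", codons_a = fa[keep], codons_b = fb[keep])
}

## ---------------------------------------------------------------------------
## NG86
## ---------------------------------------------------------------------------

#' Nei-Gojobori (1986) Ka/Ks estimate
#'
#' Counts synonymous/nonsynonymous sites (averaged between the two
#' sequences) and pathway-averaged differences per codon pair, then applies
#' the Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)`. Proportions at or
#' above 3/4 cannot be corrected and yield status `"saturated"`; `S = 0` or
#' `N = 0` with differences present yields `"undefined"`. For identical
#' sequences Ka = Ks = 0 and omega is NA.
#'
#' @param alignment a [CodonAlignment-class].
#' @return one-row data.frame: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `Ks`,
#'   `Ka`, `omega`, `status`.
#' @examples
#' ca <- codonAlign(c("GG", "GG"), "GGTGGT", "GGCGGT")
#' ng86(ca)$Ks > 0
#' @export
ng86 <- function(alignment) {
  stopifnot(is(alignment, "CodonAlignment"))
  tabs <- codonTables()
  ca <- alignment@codons_a; cb <- alignment@codons_b
  L <- length(ca)
  S <- (sum(tabs$syn_sites[ca]) + sum(tabs$syn_sites[cb])) / 2
  N <- 3 * L - S
  Sd <- sum(tabs$sd[cbind(ca, cb)])
  Nd <- sum(tabs$nd[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  status <- "ok"
  if ((S == 0 || N == 0) && Sd + Nd > 0) status <- "undefined"
  if (pS >= 0.75 || pN >= 0.75) status <- "saturated"
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  Ks <- jc(pS); Ka <- jc(pN)
  omega <- if (status == "ok" && !is.na(Ks) && Ks > 0 && !is.na(Ka))
    Ka / Ks else NA_real_
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka, omega = omega, status = status,
             stringsAsFactors = FALSE)
}

## Ka/Ks for one gene pair given raw CDS; equal-length in-frame pairs with
## matching translations are threaded directly, otherwise the proteins are
## globally aligned first.
pairKaks <- function(cds_a, cds_b) {
  tabs <- codonTables()
  strip <- function(cds, what) {
    cod <- .cdsToCodons(cds, what)
    if (tabs$aa[cod[length(cod)]] == "*") cod <- cod[-length(cod)]
    cod
  }
  coda <- strip(cds_a, "cds_a"); codb <- strip(cds_b, "cds_b")
  if (length(coda) == length(codb) &&
      !any(tabs$aa[coda] == "*") && !any(tabs$aa[codb] == "*")) {
    return(ng86(new("CodonAlignment", codons_a = coda, codons_b = codb)))
  }
  pa <- paste(tabs$aa[coda], collapse = "")
  pb <- paste(tabs$aa[codb], collapse = "")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb), type = "global",
    substitutionMatrix = getBlosum("BLOSUM62"),
    gapOpening = 10, gapExtension = 1)
  ng86(codonAlign(c(as.character(Biostrings::pattern(al)),
                    as.character(Biostrings::subject(al))),
                  cds_a, cds_b))
}

#' Ka/Ks over an orthologue group
#'
#' All pairwise NG86 estimates between the group's members plus their mean
#' (undefined and saturated pairs are excluded from the mean).
#'
#' @param group named character vector: genome id -> gene id (e.g. one row
#'   of an [assembleGroups()] table without the `group` column).
#' @param genomes named list of [Genome-class].
#' @return list with `pairs` (data.frame, one row per genome pair) and
#'   `mean` (named numeric: `Ks`, `Ka`, `omega`, `n_pairs_used`).
#' @export
groupKaks <- function(group, genomes) {
  gids <- names(group)
  cds <- lapply(gids, function(g) genomes[[g]]@cds[[group[[g]]]])
  names(cds) <- gids
  rows <- list()
  for (i in seq_along(gids)) for (j in seq_along(gids)) {
    if (i >= j) next
    est <- pairKaks(cds[[i]], cds[[j]])
    rows[[length(rows) + 1L]] <- cbind(
      data.frame(genome_a = gids[i], genome_b = gids[j],
                 gene_a = group[[gids[i]]], gene_b = group[[gids[j]]],
                 stringsAsFactors = FALSE), est)
  }
  pairs <- do.call(rbind, rows)
  ok <- pairs$status == "ok"
  mean_est <- c(
    Ks = mean(pairs$Ks[ok]), Ka = mean(pairs$Ka[ok]),
    omega = mean(pairs$omega[ok & is.finite(pairs$omega)]),
    n_pairs_used = sum(ok))
  list(pairs = pairs, mean = mean_est)
}

## ---------------------------------------------------------------------------
## core subsets and regression
## ---------------------------------------------------------------------------

#' Partition core groups by replicon consistency
#'
#' A group is `chromosomal_all` when every member lies on its genome's oriC
#' chromosome, `nonchromosomal_all` when none does, and `mixed` otherwise
#' (mixed groups are excluded from the Ka/Ks analysis).
#'
#' @param groups table from [assembleGroups()].
#' @param genomes named list of [Genome-class] covering the group columns.
#' @return data.frame with columns `group` and `class`.
#' @export
consistentSubset <- function(groups, genomes) {
  gcols <- intersect(names(groups), names(genomes))
  on_chrom <- sapply(gcols, function(g) {
    gen <- genomes[[g]]
    repl <- gen@genes$replicon[match(groups[[g]], gen@genes$gene_id)]
    repl == chromosomeName(gen)
  })
  on_chrom <- matrix(on_chrom, nrow = nrow(groups))
  k <- rowSums(on_chrom)
  cls <- ifelse(k == length(gcols), "chromosomal_all",
                ifelse(k == 0L, "nonchromosomal_all", "mixed"))
  data.frame(group = groups$group, class = cls, stringsAsFactors = FALSE)
}

#' Ka-vs-Ks regression and negative-selection share
#'
#' Ordinary least squares `Ka = slope * Ks + intercept` over the usable
#' points of one subset, with R-squared (NA when Ka has zero variance), the
#' fraction of points under the neutrality line (Ka < Ks), and the number of
#' excluded saturated/undefined points.
#'
#' @param points data.frame with columns `Ks`, `Ka` and optionally `status`
#'   (rows with status other than `"ok"` are excluded and counted).
#' @return list: `slope`, `intercept`, `r_squared`, `fraction_negative`,
#'   `n_points`, `n_excluded`.
#' @export
kaksRegression <- function(points) {
  excl <- if ("status" %in% names(points)) points$status != "ok" else
    rep(FALSE, nrow(points))
  usable <- !excl & is.finite(points$Ks) & is.finite(points$Ka)
  p <- points[usable, , drop = FALSE]
  if (nrow(p) < 3L) stopf("fewer than 3 usable points for regression")
  fit <- lm(Ka ~ Ks, data = p)
  r2 <- if (var(p$Ka) == 0) NA_real_ else {
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((p$Ka - mean(p$Ka))^2)
    1 - ss_res / ss_tot
  }
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = r2,
       fraction_negative = mean(p$Ka < p$Ks),
       n_points = nrow(p), n_excluded = sum(excl | !usable))
}

#' Pairwise Ka/Ks table for a set of core groups
#'
#' Runs [groupKaks()] over every group and binds the per-pair estimates,
#' carrying each group's id and (optionally) its replicon-consistency class.
#'
#' @param groups table from [assembleGroups()].
#' @param genomes named list of [Genome-class].
#' @param classes optional output of [consistentSubset()] to join.
#' @return data.frame of per-pair estimates with `group` (and `class`).
#' @export
coreKaks <- function(groups, genomes, classes = NULL) {
  gcols <- intersect(names(groups), names(genomes))
  out <- vector("list", nrow(groups))
  for (i in seq_len(nrow(groups))) {
    grp <- unlist(groups[i, gcols])
    gk <- groupKaks(grp, genomes)
    out[[i]] <- cbind(data.frame(group = groups$group[i],
                                 stringsAsFactors = FALSE), gk$pairs)
  }
  res <- do.call(rbind, out)
  if (!is.null(classes))
    res$class <- classes$class[match(res$group, classes$group)]
  res
}
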