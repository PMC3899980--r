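# Independent brute-force oracles. These are deliberately written as plain,
# unoptimised reference implementations, separate from the package's code
# paths, and are only ever used to check results on small instances.

# --- affine-gap Smith-Waterman by full dynamic programming ------------------
# gap of length L costs open + L * ext
swOracleScore <- function(a, b, mat, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)   # gap in b (consumes a)
  Iy <- matrix(NEG, n + 1, m + 1)   # gap in a (consumes b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + s, Ix[i - 1, j - 1] + s,
                     Iy[i - 1, j - 1] + s)
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# --- dense-matrix MCL reference --------------------------------------------
# same parameterisation as the package (self-loops = max incident weight,
# column-stochastic, expansion 2, inflation, convergence on max change) but
# dense base-R arithmetic and no pruning.
mclOracle <- function(adj, inflation) {
  nm <- rownames(adj)
  m <- as.matrix(adj)
  loops <- apply(m, 2, max)
  loops[loops <= 0] <- 1
  diag(m) <- loops
  m <- sweep(m, 2, colSums(m), "/")
  for (it in 1:5000) {
    old <- m
    m <- m %*% m
    m <- m^inflation
    m <- sweep(m, 2, colSums(m), "/")
    if (max(abs(m - old)) < 1e-9) break
  }
  att <- which(diag(m) > 1e-6)
  if (!length(att)) att <- which.max(diag(m))
  owner <- seq_along(att)
  for (i in seq_along(att)) for (j in seq_along(att)) {
    if (i < j && (m[att[i], att[j]] > 1e-6 || m[att[j], att[i]] > 1e-6)) {
      o <- owner[j]; owner[owner == o] <- owner[i]
    }
  }
  assign_to <- vapply(seq_along(nm), function(jj) {
    w <- m[att, jj]
    owner[which.max(w)]
  }, integer(1))
  unname(lapply(split(nm, assign_to), sort))
}

# compare two partitions (lists of member vectors) as sets of sets
samePartition <- function(p1, p2) {
  k1 <- sort(unname(vapply(p1, function(v) paste(sort(v), collapse = ","),
                           character(1))))
  k2 <- sort(unname(vapply(p2, function(v) paste(sort(v), collapse = ","),
                           character(1))))
  identical(k1, k2)
}

# --- per-codon NG86 enumeration oracle --------------------------------------
# explicit listing of one-step neighbours and substitution orderings,
# character-based, standard/bacterial genetic code from Biostrings
ng86Oracle <- function(codon_a, codon_b) {
  code <- as.list(Biostrings::GENETIC_CODE)
  nts <- c("T", "C", "A", "G")
  splitc <- function(x) strsplit(x, "")[[1]]
  synSites <- function(codon) {
    v <- splitc(codon)
    s <- 0
    for (p in 1:3) for (nt in setdiff(nts, v[p])) {
      w <- v; w[p] <- nt
      mut <- paste(w, collapse = "")
      if (code[[mut]] == "*") next
      if (code[[mut]] == code[[codon]]) s <- s + 1
    }
    s / 3
  }
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out <- c(out, list(c(v[i], rest)))
    out
  }
  va <- splitc(codon_a); vb <- splitc(codon_b)
  dpos <- which(va != vb)
  sd <- nd <- 0
  if (length(dpos)) {
    valid <- list()
    all_paths <- list()
    for (ord in perms(dpos)) {
      cur <- va; s <- 0; n <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur; nxt[p] <- vb[p]
        aa1 <- code[[paste(cur, collapse = "")]]
        aa2 <- code[[paste(nxt, collapse = "")]]
        if (aa2 == "*") blocked <- TRUE
        if (aa1 != "*" && aa1 == aa2) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      all_paths <- c(all_paths, list(c(s, n)))
      if (!blocked) valid <- c(valid, list(c(s, n)))
    }
    use <- if (length(valid)) valid else all_paths
    sd <- mean(vapply(use, `[`, numeric(1), 1))
    nd <- mean(vapply(use, `[`, numeric(1), 2))
  }
  S <- (synSites(codon_a) + synSites(codon_b)) / 2
  list(S = S, N = 3 - S, Sd = sd, Nd = nd)
}
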