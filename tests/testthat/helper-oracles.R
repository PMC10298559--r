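# Independent oracles, written from the definitions and kept free of the
# package's internal lookup tables.

.oracle_code <- local({
  gc <- Biostrings::GENETIC_CODE
  function(codon) unname(gc[[codon]])
})

# Brute-force NG86 for one codon pair: synonymous site fractions from the
# definition, difference counts by recursive enumeration of all minimal
# pathways (steps through stop codons count as nonsynonymous).
oracle_ng86_codon <- function(c1, c2) {
  bases <- c("A", "C", "G", "T")
  syn_frac <- function(cod) {
    aa <- .oracle_code(cod)
    s <- 0
    for (pos in 1:3) for (nb in setdiff(bases, substr(cod, pos, pos))) {
      mut <- cod
      substr(mut, pos, pos) <- nb
      if (.oracle_code(mut) == aa && aa != "*") s <- s + 1 / 3
    }
    s
  }
  walk <- function(cur, target) {
    dpos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(dpos) == 0) return(c(syn = 0, steps = 0, paths = 1))
    acc <- c(syn = 0, steps = 0, paths = 0)
    for (p in dpos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      sub <- walk(nxt, target)
      a1 <- .oracle_code(cur); a2 <- .oracle_code(nxt)
      syn_step <- as.numeric(a1 == a2 && a1 != "*" && a2 != "*")
      acc <- acc + c(syn = sub[["paths"]] * syn_step + sub[["syn"]],
                     steps = sub[["paths"]] + sub[["steps"]],
                     paths = sub[["paths"]])
    }
    acc
  }
  w <- walk(c1, c2)
  sd <- w[["syn"]] / w[["paths"]]
  nd <- w[["steps"]] / w[["paths"]] - sd
  list(S = (syn_frac(c1) + syn_frac(c2)) / 2, Sd = sd, Nd = nd)
}

oracle_ng86 <- function(seq_a, seq_b) {
  ca <- substring(seq_a, seq(1, nchar(seq_a), 3), seq(3, nchar(seq_a), 3))
  cb <- substring(seq_b, seq(1, nchar(seq_b), 3), seq(3, nchar(seq_b), 3))
  S <- 0; Sd <- 0; Nd <- 0; m <- 0
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    if (.oracle_code(ca[i]) == "*" || .oracle_code(cb[i]) == "*") next
    o <- oracle_ng86_codon(ca[i], cb[i])
    S <- S + o$S; Sd <- Sd + o$Sd; Nd <- Nd + o$Nd; m <- m + 1
  }
  N <- 3 * m - S
  pS <- Sd / S
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS,
       dS = if (pS >= 0.75) NA_real_ else -0.75 * log(1 - 4 / 3 * pS))
}

# Position-by-position transition/transversion tally.
oracle_k2p <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  pur <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  ts <- sum(a != b & pur[a] == pur[b])
  tv <- sum(a != b) - ts
  P <- ts / length(a); Q <- tv / length(a)
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Closed-form GLS ancestral states: conditional mean of the internal
# nodes given the tips under the Brownian covariance of the full node set.
oracle_gls_anc <- function(tree, z) {
  ntip <- length(tree$tip.label)
  nodes <- ntip + seq_len(tree$Nnode)
  Cfull <- ape::vcv.phylo(tree)                  # tips only
  # covariance including internal nodes via shared path lengths
  depth <- ape::node.depth.edgelength(tree)
  allids <- c(seq_len(ntip), nodes)
  n <- length(allids)
  Call <- matrix(0, n, n)
  anc_path <- function(i) {
    path <- i
    repeat {
      up <- tree$edge[tree$edge[, 2] == path[length(path)], 1]
      if (length(up) == 0) break
      path <- c(path, up)
    }
    path
  }
  paths <- lapply(allids, anc_path)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    Call[i, j] <- max(depth[shared])
  }
  tipsel <- seq_len(ntip)
  nodesel <- ntip + seq_len(tree$Nnode)
  root <- ntip + 1L
  mu <- rep(0, n)
  Ctt <- Call[tipsel, tipsel]
  Cnt <- Call[nodesel, tipsel, drop = FALSE]
  ones <- rep(1, ntip)
  z0 <- drop(ones %*% solve(Ctt, z)) / drop(ones %*% solve(Ctt, ones))
  est <- z0 + Cnt %*% solve(Ctt, z - z0)
  stats::setNames(drop(est), nodesel)
}

# Shared fixture: small ultrametric tree with a fixed seed.
make_ultra_tree <- function(n, seed = 1) {
  set.seed(seed)
  ape::rcoal(n)
}
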