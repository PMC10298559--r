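# Nei-Gojobori (1986) synonymous-rate estimation for codon-aligned coding
# pairs. Per-codon synonymous site fractions are averaged over both
# sequences; multi-hit codons are resolved by averaging over all minimal
# mutational pathways; single mutations that create a stop codon count as
# nonsynonymous. pS is corrected with the Jukes-Cantor formula
# dS = -(3/4) log(1 - (4/3) pS).

.codon_cache <- new.env(parent = emptyenv())

.codon_strings <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(t(outer(as.vector(t(outer(b, b, paste0))), b, paste0)))
}

# Per-codon synonymous site fractions and pathway-averaged difference
# counts for all 64 x 64 codon pairs, built once and cached. Stop codons
# get NA (pairs containing them are skipped by the caller).
.ng86_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)
  codons <- .codon_strings()
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  digits <- do.call(rbind, strsplit(codons, ""))
  bases <- c("A", "C", "G", "T")

  syn_sites <- rep(NA_real_, 64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") next
    s <- 0
    for (pos in 1:3) for (nb in bases) {
      if (nb == digits[i, pos]) next
      mut <- digits[i, ]; mut[pos] <- nb
      j <- .codon_index_chr(mut)
      if (aa[j] == aa[i]) s <- s + 1 / 3   # mutation to a stop is not equal
    }
    syn_sites[i] <- s
  }

  perms <- list(matrix(1L, 1, 1), rbind(1:2, 2:1),
                rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                      c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sd <- matrix(NA_real_, 64, 64)
  nd <- matrix(NA_real_, 64, 64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") next
    for (j in seq_len(64)) {
      if (aa[j] == "*") next
      dpos <- which(digits[i, ] != digits[j, ])
      k <- length(dpos)
      if (k == 0L) { sd[i, j] <- 0; nd[i, j] <- 0; next }
      pm <- perms[[k]]
      syn_tot <- 0
      for (p in seq_len(nrow(pm))) {
        cur <- digits[i, ]
        for (step in dpos[pm[p, ]]) {
          nxt <- cur; nxt[step] <- digits[j, step]
          a1 <- aa[.codon_index_chr(cur)]
          a2 <- aa[.codon_index_chr(nxt)]
          if (a1 == a2 && a1 != "*") syn_tot <- syn_tot + 1
          cur <- nxt
        }
      }
      sd[i, j] <- syn_tot / nrow(pm)
      nd[i, j] <- k - sd[i, j]
    }
  }
  .codon_cache$tab <- list(aa = aa, syn_sites = syn_sites, sd = sd, nd = nd)
  .codon_cache$tab
}

.codon_index_chr <- function(triplet) {
  v <- match(triplet, c("A", "C", "G", "T"))
  (v[1] - 1L) * 16L + (v[2] - 1L) * 4L + v[3]
}

# Vector of codon indices (1..64) for a nucleotide string; codons with any
# non-ACGT character get NA.
.codon_indices <- function(seq) {
  v <- match(strsplit(toupper(seq), "")[[1]], c("A", "C", "G", "T"))
  n <- length(v) %/% 3L
  m <- matrix(v[seq_len(3L * n)], nrow = 3L)
  idx <- (m[1, ] - 1L) * 16L + (m[2, ] - 1L) * 4L + m[3, ]
  idx
}

#' Construct a codon-aligned coding pair
#'
#' @param cds_a,cds_b codon-aligned nucleotide strings (equal length,
#'   divisible by 3).
#' @param id_a,id_b sequence identifiers.
#' @param species_a,species_b species labels.
#' @param kind `"te_pair"` or `"ortholog_pair"`.
#' @return list of class `coding_pair`.
#' @export
coding_pair <- function(cds_a, cds_b, id_a = "a", id_b = "b",
                        species_a = NA_character_, species_b = NA_character_,
                        kind = c("te_pair", "ortholog_pair")) {
  kind <- match.arg(kind)
  if (nchar(cds_a) != nchar(cds_b))
    stop("aligned sequences must have equal length")
  if (nchar(cds_a) %% 3L != 0L)
    stop("aligned length must be divisible by 3")
  structure(list(id_a = id_a, id_b = id_b, species_a = species_a,
                 species_b = species_b, aligned_cds_a = toupper(cds_a),
                 aligned_cds_b = toupper(cds_b), kind = kind,
                 aligned_nt = nchar(cds_a)),
            class = "coding_pair")
}

#' Nei-Gojobori dS for a codon-aligned pair
#'
#' Codons containing a gap or ambiguity character in either sequence, and
#' codons that are stops in either sequence, are skipped. Synonymous sites
#' `S` are averaged over both sequences; `S + N` equals three times the
#' number of compared codons. `pS = Sd / S` is Jukes-Cantor corrected to
#' `dS`; `pS >= 3/4` sets the `saturated` flag with `dS = NA`.
#'
#' @param pair a [coding_pair()], or a nucleotide string (then `cds_b` must
#'   be given).
#' @param cds_b optional second aligned sequence.
#' @return list with `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`, `dN`,
#'   `codons_compared`, `saturated`.
#' @export
ng86_ds <- function(pair, cds_b = NULL) {
  if (!inherits(pair, "coding_pair")) {
    if (is.null(cds_b)) stop("provide a coding_pair or two aligned strings")
    pair <- coding_pair(pair, cds_b)
  }
  tab <- .ng86_tables()
  ia <- .codon_indices(pair$aligned_cds_a)
  ib <- .codon_indices(pair$aligned_cds_b)
  ok <- !is.na(ia) & !is.na(ib) & tab$aa[ia] != "*" & tab$aa[ib] != "*"
  ia <- ia[ok]; ib <- ib[ok]
  m <- length(ia)
  if (m == 0L) stop("no comparable codons")
  S <- (sum(tab$syn_sites[ia]) + sum(tab$syn_sites[ib])) / 2
  N <- 3 * m - S
  if (S <= 0) stop("zero synonymous sites")
  Sd <- sum(tab$sd[cbind(ia, ib)])
  Nd <- sum(tab$nd[cbind(ia, ib)])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 / 3 * p)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN), codons_compared = m,
       saturated = pS >= 3 / 4)
}

#' Length-filter coding pairs ahead of dS estimation
#'
#' TE pairs are kept when their aligned length is strictly greater than
#' `min_te_nt` nucleotides; ortholog pairs when strictly greater than
#' `min_orth_aa` aligned amino acids.
#'
#' @param pairs data.frame with columns `kind` and `aligned_nt` (rows may
#'   carry any further columns, which are preserved).
#' @param min_te_nt nucleotide threshold for TE pairs (default 300).
#' @param min_orth_aa amino-acid threshold for ortholog pairs (default 300).
#' @return the filtered data.frame.
#' @export
length_filter_pairs <- function(pairs, min_te_nt = 300, min_orth_aa = 300) {
  keep <- ifelse(pairs$kind == "te_pair",
                 pairs$aligned_nt > min_te_nt,
                 pairs$aligned_nt / 3 > min_orth_aa)
  pairs[keep, , drop = FALSE]
}

#' Reciprocal-best-hit ortholog pairing
#'
#' Keeps the pair `(a, b)` when `b` is `a`'s best forward hit, `a` is `b`'s
#' best reverse hit, and both rows share the same single-copy marker
#' identifier (`shared_identifier` flag). Bitscore ties are broken by the
#' lexicographically smallest subject id, so the result is deterministic.
#'
#' @param score_table data.frame with columns `query`, `subject`,
#'   `bitscore`, `shared_identifier` (logical); rows are directed
#'   query-to-subject hits.
#' @return data.frame with columns `id_a`, `id_b` (`id_a < id_b`).
#' @export
reciprocal_best_pairs <- function(score_table) {
  st <- score_table[order(score_table$query, -score_table$bitscore,
                          score_table$subject), ]
  best <- st[!duplicated(st$query), ]
  bmap <- stats::setNames(best$subject, best$query)
  smap <- stats::setNames(best$shared_identifier, best$query)
  out <- list()
  for (q in names(bmap)) {
    s <- bmap[[q]]
    if (s %in% names(bmap) && bmap[[s]] == q && q < s &&
        isTRUE(smap[[q]]) && isTRUE(smap[[s]]))
      out[[length(out) + 1L]] <- data.frame(id_a = q, id_b = s,
                                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
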