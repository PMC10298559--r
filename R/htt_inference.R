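# Horizontal-TE-transfer calling: TE-pair dS against the per-species-pair
# ortholog dS null, per-subfamily transfer frequencies, collapsing of
# recently diverged species into lineages, and clustering of cross-lineage
# hits into a minimal set of independent transfer events.

#' Configuration for HTT detection and clustering
#'
#' @param quantile_q ortholog-dS quantile defining the transfer threshold
#'   (default 0.025, i.e. the bottom ~2.5 percent).
#' @param min_copy_fraction minimal copy length as a fraction of the
#'   consensus (default 0.8).
#' @param min_te_nt minimal aligned nucleotides for TE pairs (default 300).
#' @param min_orth_aa minimal aligned amino acids for ortholog pairs
#'   (default 300).
#' @param lineage_ds_fraction fraction of ortholog pairs below the maximal
#'   TE divergence beyond which a clade is collapsed (default 0.003).
#' @param lineage_age_my clades younger than this are always collapsed
#'   (default 40 My).
#' @return list of class `htt_config`.
#' @export
htt_config <- function(quantile_q = 0.025, min_copy_fraction = 0.8,
                       min_te_nt = 300, min_orth_aa = 300,
                       lineage_ds_fraction = 0.003, lineage_age_my = 40) {
  stopifnot(quantile_q >= 0, quantile_q <= 1,
            min_copy_fraction > 0, min_copy_fraction <= 1,
            lineage_ds_fraction >= 0, lineage_ds_fraction <= 1,
            lineage_age_my >= 0)
  structure(list(quantile_q = quantile_q,
                 min_copy_fraction = min_copy_fraction,
                 min_te_nt = min_te_nt, min_orth_aa = min_orth_aa,
                 lineage_ds_fraction = lineage_ds_fraction,
                 lineage_age_my = lineage_age_my),
            class = "htt_config")
}

#' Canonical key for an unordered species pair
#' @param a,b species labels (vectorised).
#' @return character vector `"x|y"` with `x <= y`.
#' @export
species_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Ortholog-dS quantile threshold
#'
#' Empirical `q`-quantile of the finite ortholog dS values, with linear
#' interpolation between order statistics at index `(n - 1) q` (R's type-7
#' convention).
#'
#' @param orth_ds numeric vector of ortholog dS values.
#' @param q quantile (default 0.025).
#' @return the threshold.
#' @export
ortholog_ds_threshold <- function(orth_ds, q = 0.025) {
  x <- orth_ds[is.finite(orth_ds)]
  if (length(x) == 0L) stop("no finite ortholog dS values")
  unname(stats::quantile(x, q, type = 7))
}

#' Call HTT candidate hits from TE-pair dS values
#'
#' For every species pair, TE pairs with dS strictly below that pair's
#' ortholog-dS quantile threshold are called as hits. SINE-class pairs are
#' excluded (no protein, no dS). A species pair with fewer than
#' `min_orth_n` finite ortholog values falls back, with a warning, to a
#' threshold computed from all ortholog values pooled; a species pair with
#' no orthologs at all is skipped with a warning.
#'
#' @param te_pairs data.frame with columns `copy_a`, `copy_b`, `species_a`,
#'   `species_b`, `subfamily`, `ds`.
#' @param orth_ds named list: species-pair key ([species_pair_key()]) to
#'   numeric vector of ortholog dS values.
#' @param config [htt_config()].
#' @param pooled force one pooled threshold for every species pair.
#' @param min_orth_n minimal per-pair ortholog sample size (default 40).
#' @return data.frame of hits (the qualifying rows of `te_pairs` plus a
#'   `threshold_used` column).
#' @export
call_htt <- function(te_pairs, orth_ds, config = htt_config(),
                     pooled = FALSE, min_orth_n = 40L) {
  q <- config$quantile_q
  tp <- te_pairs[te_class(te_pairs$subfamily) != "SINE" &
                   te_pairs$species_a != te_pairs$species_b, , drop = FALSE]
  pooled_vals <- unlist(orth_ds, use.names = FALSE)
  pooled_thr <- if (length(pooled_vals[is.finite(pooled_vals)]))
    ortholog_ds_threshold(pooled_vals, q) else NA_real_
  keys <- species_pair_key(tp$species_a, tp$species_b)
  thr <- rep(NA_real_, nrow(tp))
  for (k in unique(keys)) {
    vals <- orth_ds[[k]]
    vals <- vals[is.finite(vals)]
    if (pooled) {
      thr[keys == k] <- pooled_thr
    } else if (length(vals) == 0L) {
      warning("species pair ", k, " has no ortholog dS values; skipped")
    } else if (length(vals) < min_orth_n) {
      warning("species pair ", k, " has only ", length(vals),
              " ortholog dS values; using pooled threshold")
      thr[keys == k] <- pooled_thr
    } else {
      thr[keys == k] <- ortholog_ds_threshold(vals, q)
    }
  }
  hit <- !is.na(thr) & is.finite(tp$ds) & tp$ds < thr
  out <- tp[hit, , drop = FALSE]
  out$threshold_used <- thr[hit]
  rownames(out) <- NULL
  out
}

#' Transfer frequency per thousand copies
#'
#' `1000 * n_htt / copy_number`; vectorised. Values are returned unrounded;
#' use [format_htt_frequency()] for the conventional printed form.
#'
#' @param n_htt number of transfer events.
#' @param copy_number total copies of the subfamily (> 0).
#' @return numeric frequency per thousand copies.
#' @export
htt_frequency_per_thousand <- function(n_htt, copy_number) {
  if (any(copy_number <= 0)) stop("copy_number must be positive")
  1000 * n_htt / copy_number
}

#' Format a per-thousand frequency the way summary tables print it
#'
#' Values of at least 0.01 are shown with two decimals; smaller values are
#' truncated to two significant digits in scientific notation.
#'
#' @param x numeric frequencies.
#' @return character vector.
#' @export
format_htt_frequency <- function(x) {
  fmt1 <- function(v) {
    if (v == 0) return("0")
    if (v >= 0.01) return(sprintf("%.2f", round(v, 2)))
    e <- floor(log10(v))
    mant <- floor(v / 10^e * 10) / 10   # truncate, not round
    sprintf("%.1fe%+03d", mant, e)
  }
  vapply(x, fmt1, character(1))
}

#' Collapse recently diverged species into lineages
#'
#' Working bottom-up over the internal nodes of the guide tree, a clade is
#' collapsed into a single lineage when either (i) for every cross-species
#' pair inside it the fraction of ortholog dS values below
#' `max_te_divergence` exceeds `lineage_ds_fraction`, or (ii) the clade's
#' crown age is younger than `lineage_age_my`. Maximal qualifying clades
#' form the partition; species not inside any such clade become singleton
#' lineages. Pairs with no ortholog data fail criterion (i) (conservative:
#' less collapsing).
#'
#' @param guide_tree a `timetree` (see [read_newick_timetree()]).
#' @param orth_ds named list of ortholog dS vectors by species-pair key.
#' @param max_te_divergence highest nucleotide divergence observed among
#'   the TE pairs under scrutiny.
#' @param config [htt_config()].
#' @return object of class `lineage_partition`: list with `map` (named
#'   character: species to lineage id), `lineages` (list of species
#'   vectors), `crown_age` and `stem_age` (named numeric, per lineage).
#' @export
collapse_lineages <- function(guide_tree, orth_ds, max_te_divergence,
                              config = htt_config()) {
  stopifnot(inherits(guide_tree, "timetree"))
  tree <- guide_tree$tree
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  age <- guide_tree$node_age

  tips_below <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- tree$tip.label[i]
  ord <- tree$edge[order(ape::node.depth.edgelength(tree)[tree$edge[, 2]],
                         decreasing = TRUE), , drop = FALSE]
  for (r in seq_len(nrow(ord))) {
    p <- ord[r, 1]; ch <- ord[r, 2]
    tips_below[[p]] <- c(tips_below[[p]], tips_below[[ch]])
  }

  pair_ok <- function(a, b) {
    vals <- orth_ds[[species_pair_key(a, b)]]
    vals <- vals[is.finite(vals)]
    if (length(vals) == 0L) return(FALSE)
    mean(vals < max_te_divergence) > config$lineage_ds_fraction
  }
  clade_ok <- function(node) {
    if (age[node] < config$lineage_age_my) return(TRUE)
    tips <- tips_below[[node]]
    cmb <- utils::combn(sort(tips), 2)
    all(vapply(seq_len(ncol(cmb)),
               function(i) pair_ok(cmb[1, i], cmb[2, i]), logical(1)))
  }

  internal <- ntip + seq_len(nnode)
  ok <- stats::setNames(vapply(internal, clade_ok, logical(1)), internal)
  parent_of <- stats::setNames(tree$edge[, 1], tree$edge[, 2])
  root <- ntip + 1L
  maximal <- internal[vapply(internal, function(nd) {
    if (!ok[as.character(nd)]) return(FALSE)
    if (nd == root) return(TRUE)
    !ok[as.character(parent_of[as.character(nd)])]
  }, logical(1))]

  lineages <- list(); crown <- numeric(); stem <- numeric()
  assigned <- character()
  for (nd in maximal) {
    id <- paste0("L", length(lineages) + 1L)
    lineages[[id]] <- sort(tips_below[[nd]])
    crown[id] <- age[nd]
    stem[id] <- if (nd == root) age[nd] else age[parent_of[as.character(nd)]]
    assigned <- c(assigned, lineages[[id]])
  }
  for (sp in setdiff(sort(tree$tip.label), assigned)) {
    id <- paste0("L", length(lineages) + 1L)
    lineages[[id]] <- sp
    crown[id] <- 0
    tip_idx <- match(sp, tree$tip.label)
    stem[id] <- age[parent_of[as.character(tip_idx)]]
    assigned <- c(assigned, sp)
  }
  map <- character()
  for (id in names(lineages)) map[lineages[[id]]] <- id
  structure(list(map = map, lineages = lineages,
                 crown_age = crown, stem_age = stem),
            class = "lineage_partition")
}

#' Cluster cross-lineage HTT hits into minimal transfer events
#'
#' Hits within one lineage are discarded. Two hits are connected when they
#' join the same unordered lineage pair, share their TE subfamily, and on
#' each side the copies involved are mutually consistent with vertical
#' inheritance inside that lineage: identical copies always connect, and
#' distinct copies connect when their pairwise nucleotide divergence (K2P)
#' is below the lineage's vertical ceiling `2 r * stem age`. The stem age
#' (when the lineage split from its sister) bounds how diverged two
#' vertically inherited copies of one transferred element can be; copies
#' older than the crown but younger than the stem are legitimately
#' vertical. A missing divergence (`NA` from `te_nt_divergence`) blocks the
#' edge, which is conservative: more, smaller groups. Connected components
#' are the hit groups; their number is the minimal event count.
#'
#' @param hits data.frame of hits from [call_htt()].
#' @param partition a `lineage_partition` from [collapse_lineages()].
#' @param te_nt_divergence function of two copy ids returning their K2P
#'   nucleotide divergence, or `NA` when unavailable.
#' @param clock [clock_parameters()] for the vertical ceiling.
#' @return list of class `hit_groups`: `hits` (input rows between distinct
#'   lineages, with `group_id`), `groups` (one row per group: `group_id`,
#'   `lineage_a`, `lineage_b`, `subfamily`, `n_hits`), `n_events`.
#' @export
minimal_htt_events <- function(hits, partition, te_nt_divergence,
                               clock = clock_parameters()) {
  stopifnot(inherits(partition, "lineage_partition"))
  lin_a <- partition$map[hits$species_a]
  lin_b <- partition$map[hits$species_b]
  if (anyNA(lin_a) || anyNA(lin_b))
    stop("hit species missing from the lineage partition")
  cross <- lin_a != lin_b
  h <- hits[cross, , drop = FALSE]
  if (nrow(h) == 0L)
    return(structure(list(hits = h, groups = data.frame(), n_events = 0L),
                     class = "hit_groups"))
  la <- pmin(lin_a[cross], lin_b[cross])
  lb <- pmax(lin_a[cross], lin_b[cross])
  # copy on the la side / lb side of each hit
  ca <- ifelse(lin_a[cross] == la, h$copy_a, h$copy_b)
  cb <- ifelse(lin_a[cross] == la, h$copy_b, h$copy_a)
  rpy <- 2 * clock$rate_r * clock$generations_per_year * 1e6
  ceiling_of <- function(lin) rpy * partition$stem_age[[lin]]

  side_ok <- function(c1, c2, lin) {
    if (c1 == c2) return(TRUE)
    d <- te_nt_divergence(c1, c2)
    !is.na(d) && d < ceiling_of(lin)
  }
  n <- nrow(h)
  edges <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    if (la[i] != la[j] || lb[i] != lb[j]) next
    if (h$subfamily[i] != h$subfamily[j]) next
    if (side_ok(ca[i], ca[j], la[i]) && side_ok(cb[i], cb[j], lb[i]))
      edges[[length(edges) + 1L]] <- c(i, j)
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges))
    g <- igraph::add_edges(g, unlist(edges))
  comp <- igraph::components(g)$membership
  h$group_id <- paste0("G", comp)
  groups <- do.call(rbind, lapply(split(seq_len(n), comp), function(ix) {
    data.frame(group_id = paste0("G", comp[ix[1]]),
               lineage_a = la[ix[1]], lineage_b = lb[ix[1]],
               subfamily = h$subfamily[ix[1]], n_hits = length(ix),
               stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  structure(list(hits = h, groups = groups,
                 n_events = length(unique(comp))),
            class = "hit_groups")
}

#' Nucleotide-divergence lookup backed by a sequence table
#'
#' Builds the `te_nt_divergence` callback for [minimal_htt_events()] from a
#' named vector of copy sequences: K2P divergence of the pairwise alignment
#' (sequences here are equal-length and gap-free, as produced by the
#' synthetic generator), `NA` for unknown ids, unequal lengths, or
#' saturation.
#'
#' @param seqs named character vector of copy sequences.
#' @return function of two copy ids.
#' @export
te_divergence_from_seqs <- function(seqs) {
  function(id1, id2) {
    if (!id1 %in% names(seqs) || !id2 %in% names(seqs)) return(NA_real_)
    s1 <- seqs[[id1]]
    s2 <- seqs[[id2]]
    if (nchar(s1) != nchar(s2)) return(NA_real_)
    tryCatch(k2p_from_alignment(s1, s2)$K, error = function(e) NA_real_)
  }
}
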