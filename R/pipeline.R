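# Orchestration: chain simulate -> filter -> dS -> HTT detection ->
# clustering -> landscape -> phylogenetic signal -> ancestral states ->
# correlations, with every stage communicating through files and a run
# manifest recording config, seeds, hashes and row counts.

#' Ortholog dS values per species pair
#'
#' Computes Nei-Gojobori dS for every shared gene id of every species pair.
#' Genes failing the amino-acid length filter are skipped; saturated pairs
#' yield `NA`.
#'
#' @param orthologs list: species -> named character vector of aligned CDS.
#' @param min_orth_aa strict minimal aligned amino acids (default 0: keep
#'   all).
#' @return named list of numeric dS vectors, keyed by
#'   [species_pair_key()].
#' @export
ortholog_ds_table <- function(orthologs, min_orth_aa = 0) {
  sp <- sort(names(orthologs))
  out <- list()
  if (length(sp) < 2L) return(out)
  cmb <- utils::combn(sp, 2)
  for (i in seq_len(ncol(cmb))) {
    a <- cmb[1, i]; b <- cmb[2, i]
    genes <- intersect(names(orthologs[[a]]), names(orthologs[[b]]))
    ds <- vapply(genes, function(g) {
      ca <- orthologs[[a]][[g]]; cb <- orthologs[[b]][[g]]
      if (nchar(ca) / 3 <= min_orth_aa) return(NA_real_)
      tryCatch(ng86_ds(ca, cb)$dS, error = function(e) NA_real_)
    }, numeric(1))
    out[[species_pair_key(a, b)]] <- unname(ds)
  }
  out
}

#' Build cross-species TE coding pairs with dS
#'
#' Pairs copies of the same (non-SINE) subfamily across every species
#' pair, up to `max_pairs` per subfamily and species pair (taken in copy-id
#' order, deterministically), and computes Nei-Gojobori dS for each.
#'
#' @param copies annotated-copy data.frame (needs `copy_id`, `species`,
#'   `subfamily`).
#' @param copy_seqs named character vector of copy coding sequences.
#' @param max_pairs cap per (subfamily, species pair) cell (default 30).
#' @param min_te_nt strict minimal aligned nucleotides (default 0: keep
#'   all).
#' @return data.frame with columns `copy_a`, `copy_b`, `species_a`,
#'   `species_b`, `subfamily`, `aligned_nt`, `ds`.
#' @export
build_te_pairs <- function(copies, copy_seqs, max_pairs = 30,
                           min_te_nt = 0) {
  rows <- list()
  for (sf in sort(unique(copies$subfamily))) {
    if (te_class(sf) == "SINE") next
    sub <- copies[copies$subfamily == sf, , drop = FALSE]
    spp <- sort(unique(sub$species))
    if (length(spp) < 2L) next
    cmb <- utils::combn(spp, 2)
    for (i in seq_len(ncol(cmb))) {
      ids_a <- sort(sub$copy_id[sub$species == cmb[1, i]])
      ids_b <- sort(sub$copy_id[sub$species == cmb[2, i]])
      grid <- expand.grid(a = ids_a, b = ids_b, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      grid <- utils::head(grid[order(grid$a, grid$b), , drop = FALSE],
                          max_pairs)
      for (j in seq_len(nrow(grid))) {
        sa <- copy_seqs[[grid$a[j]]]; sb <- copy_seqs[[grid$b[j]]]
        if (nchar(sa) != nchar(sb) || nchar(sa) <= min_te_nt) next
        ds <- tryCatch(ng86_ds(sa, sb)$dS, error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          copy_a = grid$a[j], copy_b = grid$b[j],
          species_a = cmb[1, i], species_b = cmb[2, i],
          subfamily = sf, aligned_nt = nchar(sa), ds = ds,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(copy_a = character(), copy_b = character(),
                      species_a = character(), species_b = character(),
                      subfamily = character(), aligned_nt = integer(),
                      ds = numeric(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-subfamily HTT summary with class subtotals
#'
#' Builds the per-subfamily table of transfer counts, copy numbers and
#' frequency per thousand copies, then appends one subtotal row per TE
#' class and a grand total. Accepts either a precomputed counts table
#' (columns `subfamily`, `n_htt`, `copy_number`) or a hits data.frame plus
#' a per-subfamily copy-count table.
#'
#' @param hits data.frame of hits (with a `subfamily` column), or a counts
#'   table when `copy_counts` is `NULL`.
#' @param copy_counts data.frame with `subfamily` and `copy_number`.
#' @return data.frame with columns `subfamily`, `class`, `level`
#'   (`subfamily`, `class_total`, `grand_total`), `freq_per_thousand`,
#'   `freq_printed`, `n_htt`, `copy_number`.
#' @export
table6_summary <- function(hits, copy_counts = NULL) {
  if (is.null(copy_counts)) {
    stopifnot(all(c("subfamily", "n_htt", "copy_number") %in% names(hits)))
    counts <- hits
  } else {
    tab <- table(hits$subfamily)
    counts <- copy_counts
    counts$n_htt <- as.integer(tab[counts$subfamily])
    counts$n_htt[is.na(counts$n_htt)] <- 0L
  }
  counts$class <- te_class(counts$subfamily)
  counts$level <- "subfamily"
  cls <- stats::aggregate(counts[, c("n_htt", "copy_number")],
                          list(class = counts$class), sum)
  cls$subfamily <- paste0(cls$class, " (all)")
  cls$level <- "class_total"
  tot <- data.frame(subfamily = "Total", class = "All",
                    level = "grand_total", n_htt = sum(counts$n_htt),
                    copy_number = sum(counts$copy_number),
                    stringsAsFactors = FALSE)
  out <- rbind(counts[, c("subfamily", "class", "level", "n_htt",
                          "copy_number")],
               cls[, c("subfamily", "class", "level", "n_htt",
                       "copy_number")],
               tot)
  out$freq_per_thousand <- ifelse(
    out$copy_number > 0,
    htt_frequency_per_thousand(out$n_htt, pmax(out$copy_number, 1)), 0)
  out$freq_printed <- format_htt_frequency(out$freq_per_thousand)
  rownames(out) <- NULL
  out[, c("subfamily", "class", "level", "freq_per_thousand",
          "freq_printed", "n_htt", "copy_number")]
}

.default_config <- function() list(
  seed = 1, n_orthologs = 100, ortholog_length = 300, omega = 0.05,
  quantile_q = 0.025, min_copy_fraction = 0.8, min_te_nt = 300,
  min_orth_aa = 100, lineage_ds_fraction = 0.003, lineage_age_my = 40,
  bin_width = 0.01, rate_r = 2.9e-9, generations_per_year = 1,
  max_pairs = 30, n_perm = 199, trait = "All_pct")

#' Run the full synthetic-data analysis pipeline
#'
#' Simulates a dataset, applies the copy-length filter, computes TE-pair
#' and ortholog dS, calls and clusters HTT hits, writes the
#' copy-divergence landscape, phylogenetic-signal statistics, comparative
#' model fits with ancestral states for the TE load, and TE-load /
#' genome-size correlations. All stage outputs are TSV files under
#' `out_dir`; `manifest.json` records the configuration, seed, file
#' hashes and per-stage row counts, so a rerun with the same config is
#' byte-identical.
#'
#' @param config named list overriding the defaults (see
#'   `tehorizon:::.default_config`), or the path to a YAML file of the
#'   same; entries `tree`, `subfamilies`, `htt_events` are forwarded to
#'   [sim_scenario()].
#' @param out_dir output directory.
#' @return invisibly, a list with the main in-memory results
#'   (`dataset`, `hits`, `groups`, `landscape`, `signal`, `fits`,
#'   `ancestral`, `correlations`, `manifest`).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_config(), config)
  clock <- clock_parameters(cfg$rate_r, cfg$generations_per_year)
  hcfg <- htt_config(cfg$quantile_q, cfg$min_copy_fraction, cfg$min_te_nt,
                     cfg$min_orth_aa, cfg$lineage_ds_fraction,
                     cfg$lineage_age_my)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  counts <- list()

  scen_args <- list(clock = clock, n_orthologs = cfg$n_orthologs,
                    ortholog_length = cfg$ortholog_length,
                    omega = cfg$omega, seed = cfg$seed)
  for (nm in c("tree", "species_multiplier", "baseline_mb", "copy_weight",
               "kappa"))
    if (!is.null(cfg[[nm]])) scen_args[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$subfamilies))
    scen_args$subfamilies <- lapply(cfg$subfamilies, function(s)
      if (is.list(s) && !is.null(s$burst_sd_my)) s
      else do.call(te_subfamily, s))
  if (!is.null(cfg$htt_events))
    scen_args$htt_events <- lapply(cfg$htt_events, function(e)
      do.call(htt_event, e))
  scenario <- do.call(sim_scenario, scen_args)
  ds <- simulate_dataset(scenario, dir = file.path(out_dir, "data"))
  counts$copies_simulated <- nrow(ds$copies)

  cons_len <- stats::setNames(ds$consensus$length, ds$consensus$consensus_id)
  kept <- copy_length_filter(ds$copies, cons_len, cfg$min_copy_fraction)
  counts$copies_after_length_filter <- nrow(kept)

  te_pairs <- build_te_pairs(kept, ds$copy_seqs, max_pairs = cfg$max_pairs,
                             min_te_nt = cfg$min_te_nt)
  counts$te_pairs <- nrow(te_pairs)
  orth_ds <- ortholog_ds_table(ds$orthologs, min_orth_aa = cfg$min_orth_aa)
  counts$ortholog_pairs <- sum(lengths(orth_ds))

  hits <- call_htt(te_pairs, orth_ds, hcfg)
  counts$htt_hits <- nrow(hits)

  # "highest nucleotide divergence of TEs": a robust (90th percentile)
  # ceiling over the called hits, so the expected ~q fraction of
  # borderline deep calls cannot force the whole tree into one lineage
  # (override with config$max_te_divergence)
  max_te_div <- cfg$max_te_divergence %||% if (nrow(hits)) {
    divs <- vapply(seq_len(nrow(hits)), function(i)
      tryCatch(k2p_from_alignment(ds$copy_seqs[[hits$copy_a[i]]],
                                  ds$copy_seqs[[hits$copy_b[i]]])$K,
               error = function(e) NA_real_), numeric(1))
    unname(stats::quantile(divs, 0.9, na.rm = TRUE))
  } else 0
  partition <- collapse_lineages(ds$tree, orth_ds, max_te_div, hcfg)
  counts$lineages <- length(partition$lineages)
  groups <- minimal_htt_events(hits, partition,
                               te_divergence_from_seqs(ds$copy_seqs), clock)
  counts$hit_groups <- groups$n_events

  land <- landscape(kept, bin_width = cfg$bin_width, clock = clock)
  counts$landscape_bins <- nrow(land)

  copy_counts <- stats::aggregate(
    list(copy_number = rep(1L, nrow(ds$copies))),
    list(subfamily = ds$copies$subfamily), sum)
  t6 <- table6_summary(hits, copy_counts)

  gt <- ds$genome_table
  trait <- stats::setNames(gt[[cfg$trait]], gt$species)
  tt <- trait_tree(ds$tree, trait)
  lam <- pagel_lambda(tt)
  K <- blomberg_k(tt, n_perm = cfg$n_perm, seed = cfg$seed + 1)
  signal <- data.frame(statistic = c("lambda", "K"),
                       estimate = c(lam$estimate, K$estimate),
                       p_value = c(lam$p_value, K$p_value))
  fits <- lapply(c("BM", "OU", "EB", "WN"), function(m)
    fit_continuous(tt, m))
  names(fits) <- c("BM", "OU", "EB", "WN")
  fit_tab <- data.frame(model = names(fits),
                        logL = vapply(fits, `[[`, numeric(1), "logL"),
                        AICc = vapply(fits, `[[`, numeric(1), "AICc"))
  best <- names(fits)[which.min(fit_tab$AICc)]
  anc_fit <- if (best %in% c("BM", "EB")) fits[[best]] else fits$BM
  anc <- ancestral_ml(tt, anc_fit)
  node_tab <- data.frame(node = names(anc$node_states),
                         value = unname(anc$node_states))

  cors <- do.call(rbind, lapply(
    c(DNA = "DTE_pct", LTR = "LTR_pct", LINE = "LINE_pct",
      SINE = "SINE_pct", Total = "All_pct"), function(col) {
        pc <- pearson_correlation(gt$genome_size_mb, gt[[col]])
        data.frame(r = pc$r, p_value = pc$p_value, n = pc$n)
      }))
  cors <- cbind(class = c("DNA", "LTR", "LINE", "SINE", "Total"), cors)

  write_tables(list(
    te_pairs = te_pairs, htt_hits = hits, hit_groups = groups$groups,
    lineages = data.frame(species = names(partition$map),
                          lineage = unname(partition$map)),
    landscape = land, htt_summary = t6, signal = signal,
    model_fits = fit_tab, ancestral_nodes = node_tab,
    ancestral_branches = anc$branches, correlations = cors), out_dir)

  manifest <- list(
    package_version = as.character(utils::packageVersion("tehorizon")),
    config = cfg[order(names(cfg))], seed = cfg$seed,
    input_hashes = as.list(tools::md5sum(sort(ds$files))),
    row_counts = counts, best_model = best)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(dataset = ds, te_pairs = te_pairs, hits = hits,
                 groups = groups, partition = partition, landscape = land,
                 table6 = t6, signal = signal, fits = fits,
                 ancestral = anc, correlations = cors, manifest = manifest))
}
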