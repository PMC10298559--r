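# Synthetic multi-species TE / ortholog datasets with known truth:
# a timetree, clock-like ortholog coding sequences, TE subfamilies whose
# copies diverge from a per-species master in proportion to insertion age
# (burst age distributions), and injected horizontal transfers that make
# cross-species TE pairs anomalously similar.
#
# Coding sequences are built from the eight fourfold-degenerate codon
# families, so third positions are synonymous by construction and the
# synonymous clock is exact; first/second positions evolve at omega times
# the neutral rate with stop-creating changes rejected.

.BASES <- c("A", "C", "G", "T")
.TS_PARTNER <- c(3L, 4L, 1L, 2L)              # A<->G, C<->T
.TV_PARTNERS <- rbind(c(2L, 4L), c(1L, 3L), c(2L, 4L), c(1L, 3L))
# Fourfold-degenerate codon families whose first/second positions admit no
# synonymous single change (Leu CTN and Arg CGN are excluded: their
# first-position swaps to TTR/AGR are synonymous, which would put
# synonymous sites where the generator never places substitutions and
# dilute the realised dS below the clock expectation).
.FOURFOLD_PREFIX <- c("GT", "TC", "CC", "AC", "GC", "GG")
.STOPS <- c("TAA", "TAG", "TGA")

.seq_to_int <- function(s) match(strsplit(s, "")[[1]], .BASES)
.int_to_seq <- function(v) paste(.BASES[v], collapse = "")

# Exact endpoint sampling under Kimura's two-parameter process for an
# expected number of substitutions d per site; kappa is the
# transition/transversion rate ratio (alpha / 2 beta).
evolve_sites <- function(bases, d, kappa = 1) {
  if (d <= 0 || length(bases) == 0L) return(bases)
  bt <- d / (2 * (kappa + 1))                 # beta * t
  at <- kappa * d / (kappa + 1)               # alpha * t
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)
  n <- length(bases)
  u <- stats::runif(n)
  out <- bases
  is_ts <- u < p_ts
  is_tv <- !is_ts & u < p_ts + p_tv
  out[is_ts] <- .TS_PARTNER[bases[is_ts]]
  if (any(is_tv)) {
    pick <- 1L + (stats::runif(sum(is_tv)) < 0.5)
    out[is_tv] <- .TV_PARTNERS[cbind(bases[is_tv], pick)]
  }
  out
}

.codon_starts <- function(v) seq(1L, length(v), by = 3L)

.stop_codons_at <- function(v) {
  st <- .codon_starts(v)
  cod <- paste0(.BASES[v[st]], .BASES[v[st + 1L]], .BASES[v[st + 2L]])
  st[cod %in% .STOPS]
}

# Evolve an in-frame coding sequence: third positions at expected distance
# d_syn, first/second positions at d_ns, both under K2P(kappa). Codons that
# would become stops are reverted to their original state. With
# `exclusive = TRUE` (ortholog mode) first/second-position changes that
# happen to be synonymous are also reverted, so the realised synonymous
# divergence is carried by the third positions alone and the synonymous
# clock truth is exact.
evolve_coding <- function(v, d_syn, d_ns, kappa = 1, exclusive = FALSE) {
  pos3 <- seq(3L, length(v), by = 3L)
  pos12 <- setdiff(seq_along(v), pos3)
  out <- v
  out[pos3] <- evolve_sites(v[pos3], d_syn, kappa)
  out[pos12] <- evolve_sites(v[pos12], d_ns, kappa)
  stops <- .stop_codons_at(out)
  for (s in stops) out[s:(s + 2L)] <- v[s:(s + 2L)]
  if (exclusive) {
    st <- .codon_starts(out)
    ch12 <- st[out[st] != v[st] | out[st + 1L] != v[st + 1L]]
    if (length(ch12)) {
      gc <- Biostrings::GENETIC_CODE
      new_cod <- paste0(.BASES[out[ch12]], .BASES[out[ch12 + 1L]],
                        .BASES[out[ch12 + 2L]])
      ref_cod <- paste0(.BASES[v[ch12]], .BASES[v[ch12 + 1L]],
                        .BASES[out[ch12 + 2L]])
      syn <- unname(gc[new_cod]) == unname(gc[ref_cod])
      for (s in ch12[syn]) {
        out[s] <- v[s]
        out[s + 1L] <- v[s + 1L]
      }
    }
  }
  out
}

# Random in-frame coding sequence over the fourfold-degenerate codons.
random_coding_seq <- function(n_codons) {
  pre <- sample(.FOURFOLD_PREFIX, n_codons, replace = TRUE)
  third <- sample(.BASES, n_codons, replace = TRUE)
  .seq_to_int(paste0(paste0(pre, third), collapse = ""))
}

#' Describe one synthetic TE subfamily
#'
#' @param name `Class/Family` label, e.g. `"LINE/CR1"`.
#' @param copies_per_species baseline copy count per species.
#' @param burst_ages insertion-burst centres, My before present.
#' @param burst_sd_my spread of insertion ages around each burst (default 3).
#' @param consensus_codons master sequence length in codons (default 300).
#' @param species optional species labels carrying vertical copies of this
#'   subfamily (default `NULL`: all species); lineage-specific subfamilies
#'   restrict this set.
#' @return list describing the subfamily.
#' @export
te_subfamily <- function(name, copies_per_species = 40, burst_ages = 20,
                         burst_sd_my = 3, consensus_codons = 300,
                         species = NULL) {
  stopifnot(copies_per_species >= 0, all(burst_ages >= 0), burst_sd_my >= 0,
            consensus_codons > 0)
  list(name = normalize_te_class(name),
       copies_per_species = copies_per_species,
       burst_ages = burst_ages, burst_sd_my = burst_sd_my,
       consensus_codons = consensus_codons, species = species)
}

#' Describe one injected horizontal transfer event
#'
#' @param donor donor species label.
#' @param recipients recipient species label(s).
#' @param age_my event age, My before present; must not predate the
#'   donor-recipient divergence.
#' @param subfamily subfamily name (must exist in the scenario).
#' @param n_copies copies seeded per recipient species.
#' @return list describing the event.
#' @export
htt_event <- function(donor, recipients, age_my, subfamily, n_copies = 3) {
  stopifnot(age_my >= 0, n_copies >= 1)
  list(donor = donor, recipients = recipients, age_my = age_my,
       subfamily = normalize_te_class(subfamily), n_copies = n_copies)
}

# A nine-species noctuid-like timetree (clock-consistent ages chosen to
# resemble the clade: basal split 60 My, a 40-45 My stem lineage, two
# shallow radiations at 5-15 My).
.default_tree <- paste0(
  "(T_ni:60,((H_armigera:5,H_zea:5):50,((S_frugiperda:15,",
  "(S_exigua:10,S_litura:10):5):35,(B_fusca:45,",
  "(A_ipsilon:30,M_configurata:30):15):5):5):5);")

.default_subfamilies <- function() list(
  te_subfamily("LINE/CR1", 40, burst_ages = 30),
  te_subfamily("LINE/R1", 40, burst_ages = 6),
  te_subfamily("DNA/TcMar-Tc1", 30, burst_ages = 20, consensus_codons = 200),
  te_subfamily("DNA/Helitron", 50, burst_ages = c(35, 10)),
  te_subfamily("LTR/Gypsy", 20, burst_ages = 15, consensus_codons = 250),
  te_subfamily("SINE/B2", 30, burst_ages = 25, consensus_codons = 100))

#' Parameterise a synthetic multi-species TE / ortholog dataset
#'
#' @param tree Newick string or file (branch lengths in My); default: a
#'   nine-species noctuid-like timetree of height 60 My.
#' @param clock [clock_parameters()].
#' @param n_orthologs single-copy orthologous genes to simulate.
#' @param ortholog_length gene length in codons.
#' @param omega dN/dS: rate multiplier for first/second codon positions.
#' @param subfamilies list of [te_subfamily()] specs.
#' @param htt_events list of [htt_event()] specs (default none).
#' @param species_multiplier named numeric rescaling each species' copy
#'   counts (default: an even ramp over the tips, which makes TE load vary
#'   across species and correlates it with genome size by construction).
#' @param baseline_mb constant non-TE genome size in Mb.
#' @param copy_weight genomic weight of one simulated copy (a simulated
#'   copy stands for this many real copies when genome sizes and TE
#'   percentages are derived).
#' @param kappa transition/transversion rate ratio for TE copy evolution.
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(tree = .default_tree, clock = clock_parameters(),
                         n_orthologs = 100, ortholog_length = 300,
                         omega = 0.05, subfamilies = .default_subfamilies(),
                         htt_events = list(), species_multiplier = NULL,
                         baseline_mb = 250, copy_weight = 1000,
                         kappa = 2, seed = 1) {
  tt <- read_newick_timetree(tree)
  sp <- sort(tt$tree$tip.label)
  if (is.null(species_multiplier))
    species_multiplier <- stats::setNames(
      seq(0.6, 1.8, length.out = length(sp)), sp)
  stopifnot(all(sp %in% names(species_multiplier)),
            n_orthologs > 0, ortholog_length > 0, omega >= 0, kappa > 0)
  subfam_names <- vapply(subfamilies, `[[`, character(1), "name")
  if (anyDuplicated(subfam_names)) stop("duplicate subfamily names")
  for (sf in subfamilies)
    if (any(sf$burst_ages > tt$height))
      stop("burst age exceeds tree height for ", sf$name)
  for (ev in htt_events) {
    if (!ev$subfamily %in% subfam_names)
      stop("HTT event references unknown subfamily ", ev$subfamily)
    for (rcp in ev$recipients) {
      split <- mrca_age(tt, c(ev$donor, rcp))
      if (ev$age_my > split)
        stop(sprintf("HTT age %g My predates the %s-%s divergence (%g My)",
                     ev$age_my, ev$donor, rcp, split))
    }
  }
  structure(list(tree = tree, clock = clock, n_orthologs = n_orthologs,
                 ortholog_length = ortholog_length, omega = omega,
                 subfamilies = subfamilies, htt_events = htt_events,
                 species_multiplier = species_multiplier,
                 baseline_mb = baseline_mb, copy_weight = copy_weight,
                 kappa = kappa, seed = seed),
            class = "sim_scenario")
}

# Evolve a root sequence along the tree; `points` is a data.frame
# (species, age_my, key) of on-lineage sampling points (used to take the
# donor-lineage sequence at a horizontal-transfer date). Returns tip
# sequences, plus the point sequences by key.
.evolve_on_tree <- function(tt, root_seq, step_fn, points = NULL) {
  tree <- tt$tree
  ntip <- length(tree$tip.label)
  depth <- tt$node_depth
  age <- tt$node_age
  tips_below <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) tips_below[[i]] <- tree$tip.label[i]
  ord <- tree$edge[order(depth[tree$edge[, 2]], decreasing = TRUE), ,
                   drop = FALSE]
  for (r in seq_len(nrow(ord)))
    tips_below[[ord[r, 1]]] <- c(tips_below[[ord[r, 1]]],
                                 tips_below[[ord[r, 2]]])
  node_seq <- vector("list", ntip + tree$Nnode)
  node_seq[[ntip + 1L]] <- root_seq
  point_seq <- list()
  pre <- tree$edge[order(depth[tree$edge[, 2]]), , drop = FALSE]
  for (r in seq_len(nrow(pre))) {
    p <- pre[r, 1]; ch <- pre[r, 2]
    a_hi <- age[p]; a_lo <- age[ch]
    on_edge <- NULL
    if (!is.null(points) && nrow(points)) {
      sel <- points$species %in% tips_below[[ch]] &
        points$age_my >= a_lo & points$age_my < a_hi
      on_edge <- points[sel, , drop = FALSE]
      on_edge <- on_edge[order(-on_edge$age_my), , drop = FALSE]
    }
    cur <- node_seq[[p]]
    t_cur <- a_hi
    if (!is.null(on_edge) && nrow(on_edge)) {
      for (k in seq_len(nrow(on_edge))) {
        cur <- step_fn(cur, t_cur - on_edge$age_my[k])
        t_cur <- on_edge$age_my[k]
        key <- on_edge$key[k]
        if (is.null(point_seq[[key]])) point_seq[[key]] <- cur
      }
    }
    node_seq[[ch]] <- step_fn(cur, t_cur - a_lo)
  }
  tips <- stats::setNames(node_seq[seq_len(ntip)], tree$tip.label)
  list(tips = tips, points = point_seq)
}

#' Generate a synthetic dataset from a scenario
#'
#' Emits (optionally) per-species TE copy FASTA and RepeatMasker-style
#' `.out` files, a per-species consensus library, per-species ortholog
#' FASTA (identical gene ids across species: gap-free codon alignments),
#' the Newick tree, a genome-size/TE-load table, and the ground truth
#' (per-copy insertion ages and origins, per-event records, expected
#' ortholog dS per species pair).
#'
#' @param scenario a [sim_scenario()].
#' @param dir output directory, or `NULL` to skip writing files.
#' @return list of class `sim_dataset` with elements `tree` (a
#'   `timetree`), `copies` (annotated-copy data.frame), `copy_seqs`
#'   (named character), `consensus` (data.frame), `orthologs` (list:
#'   species -> named character vector of gene CDS), `genome_table`,
#'   `truth` (list `copies`, `events`, `expected_orth_ds`), `files`
#'   (paths, when `dir` was given), `scenario`.
#' @export
simulate_dataset <- function(scenario, dir = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  tt <- read_newick_timetree(scenario$tree)
  sp_all <- tt$tree$tip.label
  clock <- scenario$clock
  r_yr <- clock$rate_r * clock$generations_per_year
  mult <- scenario$species_multiplier

  # --- orthologs: third positions at the neutral rate, equal exchange
  # rates so the synonymous clock matches the estimator's correction;
  # first/second positions at omega times that.
  orth_step <- function(seq, dt_my)
    evolve_coding(seq, d_syn = r_yr * dt_my * 1e6,
                  d_ns = scenario$omega * r_yr * dt_my * 1e6, kappa = 1,
                  exclusive = TRUE)
  orthologs <- stats::setNames(
    replicate(length(sp_all), character(scenario$n_orthologs),
              simplify = FALSE), sp_all)
  gene_ids <- sprintf("gene%04d", seq_len(scenario$n_orthologs))
  for (g in seq_len(scenario$n_orthologs)) {
    res <- .evolve_on_tree(tt, random_coding_seq(scenario$ortholog_length),
                           orth_step)
    for (s in sp_all) orthologs[[s]][g] <- .int_to_seq(res$tips[[s]])
  }
  for (s in sp_all) names(orthologs[[s]]) <- gene_ids

  # --- TE masters evolve along the tree (neutral); HTT events sample the
  # donor lineage at the event date.
  te_step <- function(seq, dt_my)
    evolve_coding(seq, d_syn = r_yr * dt_my * 1e6,
                  d_ns = r_yr * dt_my * 1e6, kappa = scenario$kappa)
  events <- scenario$htt_events
  ev_id <- if (length(events)) sprintf("E%02d", seq_along(events)) else
    character()
  masters <- list()
  transfer_seq <- list()
  for (sf in scenario$subfamilies) {
    pts <- NULL
    sel <- which(vapply(events, function(e) e$subfamily == sf$name,
                        logical(1)))
    if (length(sel))
      pts <- data.frame(
        species = vapply(events[sel], `[[`, character(1), "donor"),
        age_my = vapply(events[sel], `[[`, numeric(1), "age_my"),
        key = ev_id[sel], stringsAsFactors = FALSE)
    res <- .evolve_on_tree(tt, random_coding_seq(sf$consensus_codons),
                           te_step, points = pts)
    masters[[sf$name]] <- res$tips
    for (k in names(res$points)) transfer_seq[[k]] <- res$points[[k]]
  }

  # --- copies: vertical (burst insertion ages) plus injected transfers.
  copy_rows <- list()
  copy_seqs <- character()
  truth_rows <- list()
  add_copy <- function(species, sf_name, seq_int, age, origin, event) {
    i <- length(copy_rows) + 1L
    copy_rows[[i]] <<- list(species = species, subfamily = sf_name,
                            seq = .int_to_seq(seq_int), age = age,
                            origin = origin, event = event)
  }
  for (sf in scenario$subfamilies) {
    sf_species <- if (is.null(sf$species)) sp_all else
      intersect(sp_all, sf$species)
    for (s in sf_species) {
      n <- max(0L, round(sf$copies_per_species * mult[[s]]))
      if (n == 0L) next
      bursts <- sf$burst_ages[sample.int(length(sf$burst_ages), n,
                                         replace = TRUE)]
      ages <- pmin(pmax(stats::rnorm(n, bursts, sf$burst_sd_my), 0),
                   tt$height)
      for (i in seq_len(n))
        add_copy(s, sf$name,
                 evolve_coding(masters[[sf$name]][[s]],
                               d_syn = 2 * r_yr * ages[i] * 1e6,
                               d_ns = 2 * r_yr * ages[i] * 1e6,
                               kappa = scenario$kappa),
                 ages[i], "vertical", NA_character_)
    }
  }
  for (j in seq_along(events)) {
    ev <- events[[j]]
    base <- transfer_seq[[ev_id[j]]]
    if (is.null(base))
      stop("internal: transfer point not sampled for event ", ev_id[j])
    for (rcp in ev$recipients) {
      ages <- stats::runif(ev$n_copies, 0, ev$age_my)
      for (i in seq_len(ev$n_copies))
        add_copy(rcp, ev$subfamily,
                 evolve_coding(base,
                               d_syn = r_yr * (ev$age_my + ages[i]) * 1e6,
                               d_ns = r_yr * (ev$age_my + ages[i]) * 1e6,
                               kappa = scenario$kappa),
                 ages[i], "htt", ev_id[j])
    }
  }

  # --- assemble the annotated-copy table with realised divergences.
  consensus <- do.call(rbind, lapply(scenario$subfamilies, function(sf) {
    data.frame(consensus_id = paste0(gsub("/", "_", sf$name), "__", sp_all),
               subfamily = sf$name, species = sp_all,
               sequence = vapply(masters[[sf$name]][sp_all], .int_to_seq,
                                 character(1)),
               stringsAsFactors = FALSE)
  }))
  consensus$length <- nchar(consensus$sequence)
  rownames(consensus) <- NULL
  cons_key <- stats::setNames(consensus$consensus_id,
                              paste(consensus$species, consensus$subfamily))

  n_copies <- length(copy_rows)
  copies <- data.frame(
    species = vapply(copy_rows, `[[`, character(1), "species"),
    subfamily = vapply(copy_rows, `[[`, character(1), "subfamily"),
    sequence = vapply(copy_rows, `[[`, character(1), "seq"),
    true_age_my = vapply(copy_rows, `[[`, numeric(1), "age"),
    origin = vapply(copy_rows, `[[`, character(1), "origin"),
    event_id = vapply(copy_rows, `[[`, character(1), "event"),
    stringsAsFactors = FALSE)
  copies$consensus_id <- cons_key[paste(copies$species, copies$subfamily)]
  copies$length <- nchar(copies$sequence)
  # lay copies per species along one synthetic scaffold
  copies <- copies[order(copies$species, copies$subfamily), , drop = FALSE]
  starts <- integer(n_copies)
  for (s in unique(copies$species)) {
    ix <- which(copies$species == s)
    ends <- cumsum(copies$length[ix] + 100L)
    starts[ix] <- ends - copies$length[ix] + 1L
  }
  copies$query_seq <- "scaf1"
  copies$start <- starts
  copies$end <- starts + copies$length - 1L
  copies$strand <- sample(c("+", "-"), n_copies, replace = TRUE)
  copies$copy_id <- paste0(copies$species, "|", copies$query_seq, ":",
                           copies$start, "-", copies$end, "|",
                           copies$consensus_id)
  cons_seq <- stats::setNames(consensus$sequence, consensus$consensus_id)
  copies$percent_divergence <- vapply(seq_len(n_copies), function(i) {
    k2p_from_alignment(copies$sequence[i],
                       cons_seq[[copies$consensus_id[i]]])$K
  }, numeric(1))
  rownames(copies) <- NULL
  copy_seqs <- stats::setNames(copies$sequence, copies$copy_id)

  # --- genome table: constant non-TE baseline plus weighted TE bases.
  gt <- do.call(rbind, lapply(sort(sp_all), function(s) {
    ix <- copies$species == s
    cls_bases <- vapply(c("DNA", "LTR", "LINE", "SINE", "Unknown"),
                        function(cl) sum(copies$length[ix][
                          te_class(copies$subfamily[ix]) == cl]) *
                          scenario$copy_weight, numeric(1))
    genome <- scenario$baseline_mb * 1e6 + sum(cls_bases)
    data.frame(species = s,
               DTE_pct = 100 * cls_bases[["DNA"]] / genome,
               LTR_pct = 100 * cls_bases[["LTR"]] / genome,
               LINE_pct = 100 * cls_bases[["LINE"]] / genome,
               SINE_pct = 100 * cls_bases[["SINE"]] / genome,
               UnC_pct = 100 * cls_bases[["Unknown"]] / genome,
               All_pct = 100 * sum(cls_bases) / genome,
               genome_size_mb = genome / 1e6, stringsAsFactors = FALSE)
  }))
  rownames(gt) <- NULL

  # --- truth.
  pairs <- utils::combn(sort(sp_all), 2)
  expected_orth_ds <- stats::setNames(
    vapply(seq_len(ncol(pairs)), function(i)
      2 * r_yr * 1e6 * mrca_age(tt, pairs[, i]), numeric(1)),
    species_pair_key(pairs[1, ], pairs[2, ]))
  truth <- list(
    copies = copies[, c("copy_id", "species", "subfamily", "true_age_my",
                        "origin", "event_id")],
    events = if (length(events)) data.frame(
      event_id = ev_id,
      donor = vapply(events, `[[`, character(1), "donor"),
      recipients = vapply(events, function(e)
        paste(e$recipients, collapse = ","), character(1)),
      age_my = vapply(events, `[[`, numeric(1), "age_my"),
      subfamily = vapply(events, `[[`, character(1), "subfamily"),
      n_copies = vapply(events, `[[`, numeric(1), "n_copies"),
      stringsAsFactors = FALSE) else data.frame(),
    expected_orth_ds = expected_orth_ds)

  out <- structure(list(tree = tt, copies = copies, copy_seqs = copy_seqs,
                        consensus = consensus, orthologs = orthologs,
                        genome_table = gt, truth = truth,
                        scenario = scenario, files = NULL),
                   class = "sim_dataset")
  if (!is.null(dir)) out$files <- .write_sim_dataset(out, dir)
  out
}

.write_sim_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  for (s in sort(unique(ds$copies$species))) {
    ix <- ds$copies$species == s
    fa <- file.path(dir, paste0("copies_", s, ".fa"))
    write_fasta(stats::setNames(ds$copies$sequence[ix],
                                ds$copies$copy_id[ix]), fa)
    outp <- file.path(dir, paste0(s, ".out"))
    write_repeatmasker_out(ds$copies[ix, , drop = FALSE], outp)
    files <- c(files, fa, outp)
  }
  cons <- file.path(dir, "consensus.fa")
  write_consensus_fasta(ds$consensus, cons)
  for (s in names(ds$orthologs)) {
    fa <- file.path(dir, paste0("orthologs_", s, ".fa"))
    write_fasta(ds$orthologs[[s]], fa)
    files <- c(files, fa)
  }
  nwk <- file.path(dir, "tree.nwk")
  ape::write.tree(ds$tree$tree, nwk)
  tabs <- write_tables(list(genome_table = ds$genome_table,
                            truth_copies = ds$truth$copies,
                            truth_events = ds$truth$events), dir)
  scen <- file.path(dir, "scenario.yaml")
  sc <- ds$scenario
  yaml::write_yaml(list(
    tree = sc$tree, seed = sc$seed, n_orthologs = sc$n_orthologs,
    ortholog_length = sc$ortholog_length, omega = sc$omega,
    baseline_mb = sc$baseline_mb, copy_weight = sc$copy_weight,
    kappa = sc$kappa,
    rate_r = sc$clock$rate_r,
    generations_per_year = sc$clock$generations_per_year,
    species_multiplier = as.list(sc$species_multiplier),
    subfamilies = sc$subfamilies,
    htt_events = sc$htt_events), scen)
  c(files, cons, nwk, tabs, scen)
}

#' Simulate independent codon-aligned coding pairs at a known distance
#'
#' Each pair descends from a random fourfold-codon ancestor; both lineages
#' evolve half the requested synonymous distance (and half the
#' nonsynonymous distance), so the pair's expected synonymous divergence is
#' exactly `d_syn`.
#'
#' @param n number of pairs.
#' @param codons gene length in codons.
#' @param d_syn total expected synonymous substitutions per synonymous site.
#' @param d_ns total expected nonsynonymous-position distance (default 0).
#' @param kappa transition/transversion rate ratio (default 1).
#' @param seed optional seed.
#' @return data.frame with columns `id`, `cds_a`, `cds_b`.
#' @export
sim_coding_pairs <- function(n, codons = 300, d_syn = 0.1, d_ns = 0,
                             kappa = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    anc <- random_coding_seq(codons)
    a <- evolve_coding(anc, d_syn / 2, d_ns / 2, kappa, exclusive = TRUE)
    b <- evolve_coding(anc, d_syn / 2, d_ns / 2, kappa, exclusive = TRUE)
    data.frame(id = sprintf("pair%04d", i), cds_a = .int_to_seq(a),
               cds_b = .int_to_seq(b), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sample a continuous trait under a comparative model
#'
#' Exact multivariate-normal sampling from the model's covariance
#' (`sigma2` times the structure used by [fit_continuous()]), mean `z0`.
#'
#' @param tree a `timetree`, phylo, or Newick string.
#' @param model `"BM"`, `"OU"`, `"EB"` or `"WN"`.
#' @param params list with `sigma2`, `z0`, and `a` (EB) or `alpha` (OU).
#' @param seed optional seed.
#' @return named numeric vector over the tips.
#' @export
simulate_trait <- function(tree, model = c("BM", "OU", "EB", "WN"),
                           params = list(sigma2 = 1, z0 = 0), seed = NULL) {
  model <- match.arg(model)
  tt <- if (inherits(tree, "timetree")) tree
        else if (inherits(tree, "phylo")) timetree_from_phylo(tree)
        else read_newick_timetree(tree)
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv.phylo(tt$tree)
  par <- params$a %||% params$alpha
  M <- .model_cov(C, tt$height, model, par)
  sigma2 <- params$sigma2 %||% 1
  z0 <- params$z0 %||% 0
  if (sigma2 == 0)
    return(stats::setNames(rep(z0, nrow(C)), rownames(C)))
  ch <- chol(sigma2 * M)
  stats::setNames(drop(z0 + t(ch) %*% stats::rnorm(nrow(C))), rownames(C))
}
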