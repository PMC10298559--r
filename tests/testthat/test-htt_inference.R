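mk_te_pairs <- function(ds, species_a = "A", species_b = "B",
                        subfamily = "LINE/CR1") {
  data.frame(copy_a = paste0("ca", seq_along(ds)),
             copy_b = paste0("cb", seq_along(ds)),
             species_a = species_a, species_b = species_b,
             subfamily = subfamily, ds = ds, stringsAsFactors = FALSE)
}

test_that("ortholog dS threshold follows the interpolated quantile", {
  expect_equal(ortholog_ds_threshold(1:100, 0.025), 3.475)
  expect_equal(ortholog_ds_threshold(rep(0.2, 50), 0.025), 0.2)
  expect_equal(ortholog_ds_threshold(c(5, 1, 3), 0), 1)
  expect_error(ortholog_ds_threshold(c(NA_real_, Inf)), "no finite")
})

test_that("hit calling is strict at the threshold and excludes SINEs", {
  orth <- list("A|B" = seq(0.05, 1, length.out = 100))
  thr <- ortholog_ds_threshold(orth[["A|B"]], 0.025)
  tp <- mk_te_pairs(c(0.01, thr, thr - 1e-9))
  hits <- call_htt(tp, orth)
  expect_equal(hits$ds, c(0.01, thr - 1e-9))
  expect_true(all(hits$threshold_used == thr))

  sine <- mk_te_pairs(0.01, subfamily = "SINE/B2")
  expect_equal(nrow(call_htt(sine, orth)), 0L)

  expect_warning(call_htt(mk_te_pairs(0.01, species_b = "C"), orth),
                 "no ortholog")
  expect_warning(
    hits2 <- call_htt(mk_te_pairs(0.01), list("A|B" = c(0.5, 0.6))),
    "pooled")
})

test_that("raising the quantile never loses hits", {
  set.seed(31)
  orth <- list("A|B" = stats::rchisq(500, 3) / 10)
  tp <- mk_te_pairs(stats::rchisq(300, 3) / 10)
  n_prev <- -1L
  for (q in c(0.01, 0.025, 0.05, 0.1, 0.25)) {
    n <- nrow(call_htt(tp, orth, htt_config(quantile_q = q)))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})

test_that("transfer frequency per thousand copies and its printed form", {
  expect_equal(round(htt_frequency_per_thousand(3, 1741), 2), 1.72)
  expect_equal(round(htt_frequency_per_thousand(12, 27452), 2), 0.44)
  expect_equal(htt_frequency_per_thousand(0, 1000), 0)
  expect_error(htt_frequency_per_thousand(1, 0), "positive")
  expect_equal(format_htt_frequency(c(1.7231, 0.00617688, 0.0012906)),
               c("1.72", "6.1e-03", "1.2e-03"))
})

test_that("lineage collapsing follows the age and dS criteria", {
  # two species diverged 10 My: collapsed by the age criterion alone
  tt <- read_newick_timetree("(A:10,B:10);")
  p <- collapse_lineages(tt, list(), max_te_divergence = 0.1)
  expect_equal(length(p$lineages), 1L)
  expect_equal(unname(p$map[c("A", "B")]), c("L1", "L1"))

  # two species diverged 100 My with no ortholog dS below the TE maximum
  tt2 <- read_newick_timetree("(A:100,B:100);")
  orth <- list("A|B" = seq(0.5, 1.2, length.out = 200))
  p2 <- collapse_lineages(tt2, orth, max_te_divergence = 0.3)
  expect_equal(length(p2$lineages), 2L)
  # same depth, but TEs as diverged as the orthologs: collapsed
  p3 <- collapse_lineages(tt2, orth, max_te_divergence = 1.0)
  expect_equal(length(p3$lineages), 1L)
})

test_that("lineage partition matches an exhaustive clade-checking oracle", {
  nwk <- "(((A:15,B:15):20,(C:30,D:30):5):45,(E:70,F:70):10);"
  tt <- read_newick_timetree(nwk)
  set.seed(41)
  sp <- c("A", "B", "C", "D", "E", "F")
  orth <- list()
  for (i in 1:5) for (j in (i + 1):6) {
    t_ij <- mrca_age(tt, sp[c(i, j)])
    orth[[species_pair_key(sp[i], sp[j])]] <-
      2 * 2.9e-9 * 1e6 * t_ij * stats::rlnorm(300, 0, 0.3)
  }
  cfg <- htt_config()
  maxdiv <- 0.25
  p <- collapse_lineages(tt, orth, maxdiv, cfg)

  # oracle: enumerate all clades, keep maximal qualifying ones
  clades <- list(c("A", "B"), c("C", "D"), c("A", "B", "C", "D"),
                 c("E", "F"), sp)
  ages <- vapply(clades, function(x) mrca_age(tt, x), numeric(1))
  ok <- vapply(seq_along(clades), function(k) {
    if (ages[k] < cfg$lineage_age_my) return(TRUE)
    cmb <- utils::combn(clades[[k]], 2)
    all(vapply(seq_len(ncol(cmb)), function(i) {
      v <- orth[[species_pair_key(cmb[1, i], cmb[2, i])]]
      mean(v < maxdiv) > cfg$lineage_ds_fraction
    }, logical(1)))
  }, logical(1))
  maximal <- clades[ok]
  maximal <- maximal[!vapply(seq_along(maximal), function(i)
    any(vapply(seq_along(maximal), function(j)
      i != j && all(maximal[[i]] %in% maximal[[j]]), logical(1))),
    logical(1))]
  got_sets <- unname(lapply(p$lineages, sort))
  exp_sets <- c(lapply(maximal, sort),
                as.list(setdiff(sp, unlist(maximal))))
  expect_setequal(vapply(got_sets, paste, character(1), collapse = ","),
                  vapply(exp_sets, paste, character(1), collapse = ","))

  # invariance to species input order (shuffled ortholog list)
  p_shuf <- collapse_lineages(tt, orth[sample(names(orth))], maxdiv, cfg)
  expect_equal(p_shuf$map[sort(names(p_shuf$map))],
               p$map[sort(names(p$map))])
})

test_that("hit clustering: shared copies merge, disjoint lineage pairs never do", {
  tt <- read_newick_timetree("((A:10,B:10):70,(C:20,D:20):60);")
  part <- collapse_lineages(tt, list(), max_te_divergence = 0)
  expect_equal(length(part$lineages), 2L)
  hits <- data.frame(
    copy_a = c("x1", "x1"), copy_b = c("y1", "y2"),
    species_a = "A", species_b = c("C", "D"),
    subfamily = "DNA/Mariner", ds = 0.01, threshold_used = 0.1,
    stringsAsFactors = FALSE)
  seqs <- c(x1 = "AAAA", y1 = "AAAA", y2 = "AAAT")
  gr <- minimal_htt_events(hits, part, te_divergence_from_seqs(seqs))
  expect_equal(gr$n_events, 1L)   # same copy on the A side, low div on CD

  # different subfamilies never merge
  hits2 <- hits; hits2$subfamily <- c("DNA/Mariner", "DNA/hAT")
  expect_equal(minimal_htt_events(hits2, part,
                                  te_divergence_from_seqs(seqs))$n_events, 2L)

  # unknown divergence blocks the edge (conservative)
  gr3 <- minimal_htt_events(hits, part,
                            te_divergence_from_seqs(seqs[c("x1", "y1")]))
  expect_equal(gr3$n_events, 2L)

  # disjoint lineage pairs on a 3-lineage tree never merge
  tt3 <- read_newick_timetree(
    "(((A:10,B:10):70,(C:20,D:20):60):20,(E:30,F:30):70);")
  part3 <- collapse_lineages(tt3, list(), max_te_divergence = 0)
  hits3 <- data.frame(
    copy_a = c("a1", "e1"), copy_b = c("c1", "c2"),
    species_a = c("A", "E"), species_b = c("C", "C"),
    subfamily = "DNA/Mariner", ds = 0.01, threshold_used = 0.1,
    stringsAsFactors = FALSE)
  seqs3 <- c(a1 = "AAAA", e1 = "AAAA", c1 = "AAAA", c2 = "AAAA")
  expect_equal(minimal_htt_events(hits3, part3,
                                  te_divergence_from_seqs(seqs3))$n_events,
               2L)
})

test_that("an ancestral transfer before a radiation clusters to one event", {
  nwk <- "(D:150,(R1:30,(R2:20,R3:20):10):120);"
  sc <- sim_scenario(
    tree = nwk, n_orthologs = 60, ortholog_length = 200,
    subfamilies = list(
      te_subfamily("DNA/Mariner", 3, burst_ages = 2, burst_sd_my = 1,
                   species = "D", consensus_codons = 200)),
    htt_events = list(htt_event("D", c("R1", "R2", "R3"), age_my = 50,
                                subfamily = "DNA/Mariner", n_copies = 3)),
    species_multiplier = c(D = 1, R1 = 1, R2 = 1, R3 = 1),
    seed = 77)
  ds <- simulate_dataset(sc)
  orth <- ortholog_ds_table(ds$orthologs)
  tp <- build_te_pairs(ds$copies, ds$copy_seqs, max_pairs = 1000)
  hits <- call_htt(tp, orth)
  cross <- hits[hits$species_a == "D" | hits$species_b == "D", ]
  expect_gte(nrow(cross), 9L)
  expect_setequal(setdiff(unique(c(cross$species_a, cross$species_b)), "D"),
                  c("R1", "R2", "R3"))

  maxdiv <- max(vapply(seq_len(nrow(tp)), function(i)
    tryCatch(k2p_from_alignment(ds$copy_seqs[[tp$copy_a[i]]],
                                ds$copy_seqs[[tp$copy_b[i]]])$K,
             error = function(e) NA_real_), numeric(1)), na.rm = TRUE)
  part <- collapse_lineages(ds$tree, orth, maxdiv)
  expect_equal(length(part$lineages), 2L)  # D vs the R radiation
  gr <- minimal_htt_events(hits, part,
                           te_divergence_from_seqs(ds$copy_seqs))
  expect_equal(gr$n_events, 1L)
})
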