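rm_header <- c(
  "   SW   perc perc perc  query      position in query           matching       repeat              position in repeat",
  "score   div. del. ins.  sequence    begin     end    (left)    repeat         class/family      begin  end (left)   ID",
  "")

rm_row <- function(query = "scaf1", begin = 100, end = 199, strand = "+",
                   name = "cons1", cf = "LINE/CR1", div = 10.5, id = 1) {
  sprintf(" 1000 %.1f 0.0 0.0 %s %d %d (0) %s %s %s 1 %d (0) %d",
          div, query, begin, end, strand, name, cf, end - begin + 1, id)
}

test_that("RepeatMasker parsing: coordinates, strand dialect, class filter", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(rm_header,
               rm_row(begin = 100, end = 199),
               rm_row(begin = 300, end = 450, strand = "C", cf = "DNA/hAT"),
               rm_row(begin = 500, end = 520, cf = "Simple_repeat"),
               rm_row(begin = 600, end = 900, cf = "-"),
               rm_row(begin = 1000, end = 1010, cf = "RC/Helitron")), f)
  copies <- read_repeatmasker_out(f, species = "spX")
  expect_equal(nrow(copies), 4L)          # Simple_repeat dropped
  expect_equal(copies$length[1], 100L)
  expect_equal(copies$strand[2], "-")
  expect_equal(copies$subfamily[3], "Unknown/Unknown")
  expect_equal(copies$subfamily[4], "DNA/Helitron")
  expect_equal(copies$percent_divergence[1], 0.105)
  expect_true(all(copies$species == "spX"))
})

test_that("malformed RepeatMasker rows are rejected with a line number", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(rm_header, rm_row(), "only three fields here"), f)
  expect_error(read_repeatmasker_out(f), "line 5")
  writeLines(c(rm_header,
               sub("100 199", "100 notanumber", rm_row())), f)
  expect_error(read_repeatmasker_out(f), "non-numeric")
})

test_that("parse/serialize round trip preserves every row", {
  f <- withr::local_tempfile(fileext = ".out")
  set.seed(42)
  rows <- vapply(1:20, function(i)
    rm_row(begin = i * 1000, end = i * 1000 + sample(50:900, 1),
           strand = sample(c("+", "C"), 1),
           cf = sample(c("LINE/CR1", "DNA/TcMar-Tc1", "LTR/Gypsy"), 1),
           div = round(stats::runif(1, 0, 40), 1), id = i), character(1))
  writeLines(c(rm_header, rows), f)
  x <- read_repeatmasker_out(f, species = "s")
  f2 <- withr::local_tempfile(fileext = ".out")
  write_repeatmasker_out(x, f2)
  y <- read_repeatmasker_out(f2, species = "s")
  expect_equal(y[c("start", "end", "strand", "subfamily",
                   "percent_divergence", "length")],
               x[c("start", "end", "strand", "subfamily",
                   "percent_divergence", "length")])
})

test_that("copy length filter is inclusive at the boundary and idempotent", {
  cons <- data.frame(consensus_id = "c1", length = 1000)
  mk <- function(lens) data.frame(
    copy_id = paste0("k", seq_along(lens)), consensus_id = "c1",
    length = lens, stringsAsFactors = FALSE)
  expect_equal(nrow(copy_length_filter(mk(800), cons)), 1L)
  expect_equal(nrow(copy_length_filter(mk(799), cons)), 0L)
  ladder <- mk(seq(100, 1000, by = 100))
  kept <- copy_length_filter(ladder, cons, 0.8)
  expect_equal(kept$length, c(800, 900, 1000))
  expect_identical(copy_length_filter(kept, cons, 0.8), kept)
  bad <- mk(500); bad$consensus_id <- "nope"
  expect_error(copy_length_filter(bad, cons), "nope")
})

test_that("library filter uses strict thresholds and matches a brute-force scan", {
  rec <- function(id, pid, e, cov) data.frame(
    query_id = id, subject_id = "prot", percent_identity = pid,
    e_value = e, query_coverage = cov, stringsAsFactors = FALSE)
  # identity exactly at the threshold is not a removal
  r <- library_filter(rbind(rec("q1", 30.0, 1e-6, 60),
                            rec("q2", 45, 1e-8, 75)))
  expect_equal(r$kept, "q1")
  expect_equal(r$removed, "q2")

  set.seed(99)
  recs <- data.frame(
    query_id = sample(paste0("q", 1:30), 100, replace = TRUE),
    subject_id = "p",
    percent_identity = stats::runif(100, 0, 100),
    e_value = 10^stats::runif(100, -12, 0),
    query_coverage = stats::runif(100, 0, 100), stringsAsFactors = FALSE)
  got <- library_filter(recs)
  brute <- sort(unique(recs$query_id[
    recs$percent_identity > 30 & recs$e_value < 1e-5 &
      recs$query_coverage > 50]))
  expect_equal(got$removed, brute)
  shuf <- library_filter(recs[sample(nrow(recs)), ])
  expect_equal(shuf, got)
})

test_that("timetree reading: heights, MRCA ages, ultrametricity check", {
  tt <- read_newick_timetree("((A:1,B:1):1,C:2);")
  expect_equal(tt$height, 2)
  expect_equal(mrca_age(tt, c("A", "B")), 1)
  expect_equal(mrca_age(tt, c("A", "C")), 2)
  expect_error(read_newick_timetree("(A:1,B:2);"), "ultrametric")

  # 9-taxon clock-consistent tree: MRCA times equal hand-summed path ages
  nwk <- paste0("(T_ni:60,((H_armigera:5,H_zea:5):50,((S_frugiperda:15,",
                "(S_exigua:10,S_litura:10):5):35,(B_fusca:45,",
                "(A_ipsilon:30,M_configurata:30):15):5):5):5);")
  tt9 <- read_newick_timetree(nwk)
  expect_equal(tt9$height, 60)
  expect_equal(mrca_age(tt9, c("H_armigera", "H_zea")), 5)
  expect_equal(mrca_age(tt9, c("S_exigua", "S_frugiperda")), 15)
  expect_equal(mrca_age(tt9, c("B_fusca", "A_ipsilon")), 45)
  expect_equal(mrca_age(tt9, c("T_ni", "B_fusca")), 60)
})

test_that("result tables round-trip through TSV", {
  d <- withr::local_tempdir()
  empty <- data.frame(a = character(), b = numeric())
  write_tables(list(empty = empty), d)
  expect_equal(nrow(read_tables(d)$empty), 0L)

  gt <- noctuid_genome_table()
  set.seed(5)
  rand <- data.frame(id = paste0("x", 1:8), v = stats::rnorm(8),
                     w = sample(100, 8), stringsAsFactors = FALSE)
  write_tables(list(genome = gt, rand = rand), d)
  back <- read_tables(d)
  expect_equal(back$genome, gt)
  expect_equal(back$rand, rand)

  p <- file.path(d, "genome.tsv")
  expect_equal(read_genome_table(p), gt)
})
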