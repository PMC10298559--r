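# Kimura 2-parameter divergence, copy-divergence landscapes, and the
# molecular-clock conversion between divergence and insertion age.

#' Neutral molecular clock parameters
#'
#' The default rate is the lepidopteran neutral mutation rate estimate
#' 2.9e-9 substitutions per site per generation, with one generation per
#' year, so that an insertion age in years is `K / (2 r)`.
#'
#' @param rate_r substitutions per site per generation (> 0).
#' @param generations_per_year generations per year (> 0).
#' @return list of class `clock_parameters`.
#' @export
clock_parameters <- function(rate_r = 2.9e-9, generations_per_year = 1) {
  stopifnot(rate_r > 0, generations_per_year > 0)
  structure(list(rate_r = rate_r,
                 generations_per_year = generations_per_year),
            class = "clock_parameters")
}

#' Kimura 2-parameter distance from site counts
#'
#' With transition proportion `P` and transversion proportion `Q`,
#' `K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q))`. The distance is undefined
#' (saturated) when `1 - 2P - Q <= 0` or `1 - 2Q <= 0`.
#'
#' @param compared_sites aligned, unambiguous sites compared.
#' @param transitions transition count.
#' @param transversions transversion count.
#' @return list with `K`, `P`, `Q`, `compared_sites`.
#' @export
k2p_from_counts <- function(compared_sites, transitions, transversions) {
  stopifnot(compared_sites > 0, transitions >= 0, transversions >= 0,
            transitions + transversions <= compared_sites)
  P <- transitions / compared_sites
  Q <- transversions / compared_sites
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop(errorCondition(
      sprintf("K2P distance saturated (P = %.4g, Q = %.4g)", P, Q),
      class = c("tehorizon_saturation", "error", "condition")))
  list(K = -0.5 * log(w1 * sqrt(w2)), P = P, Q = Q,
       compared_sites = compared_sites)
}

.PURINE <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)

#' Kimura 2-parameter distance from an aligned sequence pair
#'
#' Columns containing a gap or any non-ACGT character in either sequence
#' are excluded from the compared sites.
#'
#' @param seq_a,seq_b aligned nucleotide strings of equal length.
#' @return list as in [k2p_from_counts()].
#' @export
k2p_from_alignment <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  ok <- a %in% names(.PURINE) & b %in% names(.PURINE)
  if (!any(ok)) stop("no comparable (ACGT vs ACGT) columns")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  ts <- sum(diff & (.PURINE[a] == .PURINE[b]))
  tv <- sum(diff) - ts
  k2p_from_counts(length(a), ts, tv)
}

#' Convert a divergence into an insertion age
#'
#' `T = K / (2 r)` with `r` the neutral mutation rate per year
#' (`rate_r * generations_per_year`); the age is reported in millions of
#' years. With the default clock, `K = 0.10` gives 17.24 My.
#'
#' @param K substitutions per site (>= 0); vectorised.
#' @param clock [clock_parameters()].
#' @return age in My.
#' @export
divergence_to_age <- function(K, clock = clock_parameters()) {
  stopifnot(all(K >= 0))
  K / (2 * clock$rate_r * clock$generations_per_year) / 1e6
}

#' @rdname divergence_to_age
#' @param age_my age in millions of years.
#' @return for `age_to_divergence`, the divergence `K` expected under the
#'   clock.
#' @export
age_to_divergence <- function(age_my, clock = clock_parameters()) {
  stopifnot(all(age_my >= 0))
  age_my * 1e6 * 2 * clock$rate_r * clock$generations_per_year
}

#' Copy-divergence landscape
#'
#' Histograms annotated bases (and copy counts) by divergence bin for each
#' (species, subfamily) combination. Bins are half-open `[lo, hi)` with the
#' last bin closed; a parallel age axis is attached by converting bin
#' midpoints through the clock.
#'
#' @param copies data.frame of annotated copies (needs `species`,
#'   `subfamily`, `percent_divergence`, `length`).
#' @param bin_width divergence bin width (default 0.01).
#' @param clock [clock_parameters()] used for the age axis.
#' @return data.frame with columns `species`, `subfamily`, `bin_lo`,
#'   `bin_hi`, `age_mid_my`, `bases`, `copies`.
#' @export
landscape <- function(copies, bin_width = 0.01, clock = clock_parameters()) {
  stopifnot(bin_width > 0)
  if (nrow(copies) == 0L)
    return(data.frame(species = character(), subfamily = character(),
                      bin_lo = numeric(), bin_hi = numeric(),
                      age_mid_my = numeric(), bases = numeric(),
                      copies = integer()))
  div <- copies$percent_divergence
  stopifnot(all(div >= 0))
  nbins <- max(1L, floor(max(div) / bin_width + 1e-12) + 1L)
  idx <- pmin(floor(div / bin_width + 1e-12) + 1L, nbins)
  grp <- data.frame(species = copies$species, subfamily = copies$subfamily,
                    bin = idx, stringsAsFactors = FALSE)
  agg_b <- stats::aggregate(list(bases = as.numeric(copies$length)), grp, sum)
  agg_n <- stats::aggregate(list(copies = rep(1L, nrow(copies))), grp, sum)
  out <- merge(agg_b, agg_n, by = c("species", "subfamily", "bin"))
  out$bin_lo <- (out$bin - 1) * bin_width
  out$bin_hi <- out$bin * bin_width
  out$age_mid_my <- divergence_to_age((out$bin_lo + out$bin_hi) / 2, clock)
  out <- out[order(out$species, out$subfamily, out$bin_lo), ]
  rownames(out) <- NULL
  out[, c("species", "subfamily", "bin_lo", "bin_hi", "age_mid_my",
          "bases", "copies")]
}
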