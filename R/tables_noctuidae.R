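# Bundled reference tables for ten noctuid moth species, used as worked
# examples and as printed-table inputs to the summary statistics.

#' Per-species TE loads and genome sizes for ten noctuid species
#'
#' TE content (percent of genome) per class - DNA transposons (DTE), LTR
#' retrotransposons, LINEs, SINEs, unclassified (UnC) - the total TE
#' percentage, and assembly size in Mb, for ten noctuid moth species.
#'
#' @return data.frame with columns `species`, `DTE_pct`, `LTR_pct`,
#'   `LINE_pct`, `SINE_pct`, `UnC_pct`, `All_pct`, `genome_size_mb`.
#' @export
noctuid_genome_table <- function() {
  data.frame(
    species = c("Trichoplusia ni", "Helicoverpa armigera",
                "Helicoverpa zea", "Spodoptera exigua",
                "Spodoptera litura", "Spodoptera frugiperda",
                "Agrotis ipsilon", "Mamestra configurata",
                "Busseola fusca", "Heliothis virescens"),
    DTE_pct = c(4.59, 4.01, 4.82, 4.74, 5.87, 9.12, 11.8, 11.24, 12.1, 8.39),
    LTR_pct = c(2.63, 0.74, 1.07, 4.22, 2.4, 1.94, 2.08, 2.12, 3.16, 1.3),
    LINE_pct = c(4.99, 3.46, 4.05, 17.64, 14.81, 12.54, 13.81, 15.59,
                 20.16, 5.64),
    SINE_pct = c(2.25, 2.06, 2.63, 2.56, 3.39, 0.98, 3.16, 2.37, 6.11, 2.92),
    UnC_pct = c(1.4, 1.06, 1.19, 1.48, 2.51, 2.17, 3.42, 3.4, 3.57, 2.29),
    All_pct = c(15.86, 11.33, 13.76, 30.64, 28.98, 26.75, 34.27, 34.72,
                45.10, 20.54),
    genome_size_mb = c(367.2, 299.98, 306.41, 446.80, 428.03, 486.23,
                       486.92, 559.39, 490.17, 403.15),
    stringsAsFactors = FALSE)
}

#' Published per-subfamily HTT counts for the noctuid dataset
#'
#' Number of horizontal-transfer events and total copy number per TE
#' subfamily, as printed in the reference summary for the ten-species
#' noctuid dataset; input to [table6_summary()] and
#' [htt_frequency_per_thousand()].
#'
#' @return data.frame with columns `subfamily`, `n_htt`, `copy_number`.
#' @export
noctuid_htt_counts <- function() {
  data.frame(
    subfamily = c("LTR/Gypsy", "LTR/Copia", "LINE/RTE-RTE", "LINE/RTE-BovB",
                  "LINE/R1", "LINE/Proto2", "LINE/L2", "LINE/Dong-R4",
                  "LINE/CR1-Zenon", "LINE/CR1", "DNA/Zator", "DNA/TcMar-Tc1",
                  "DNA/TcMar-Mariner", "DNA/Helitron", "DNA/Maverick"),
    n_htt = c(1, 1, 10, 4, 3, 1, 6, 3, 1, 4, 1, 12, 5, 1, 3),
    copy_number = c(22547, 3978, 183155, 130583, 485681, 21637, 209382,
                    22186, 380795, 15874, 5418, 27452, 13007, 774822, 1741),
    stringsAsFactors = FALSE)
}
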