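# Readers/writers for the external formats the pipeline touches, plus the
# copy-level filters applied before any analysis.

#' Normalise a RepeatMasker class/family string
#'
#' Splits a `Class/Family` string into its class and family components and
#' maps it onto the controlled vocabulary `DNA`, `LINE`, `SINE`, `LTR`,
#' `Unknown`. Rolling-circle (`RC`) elements such as Helitron are treated as
#' DNA transposons; a trailing `?` (RepeatMasker's uncertainty marker) is
#' stripped; missing or unrecognised strings become `Unknown/Unknown`.
#'
#' @param x character vector of `Class/Family` strings.
#' @return character vector of normalised `Class/Family` strings.
#' @export
normalize_te_class <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "-"] <- "Unknown/Unknown"
  cls <- sub("/.*$", "", x)
  fam <- ifelse(grepl("/", x), sub("^[^/]*/", "", x), "Unknown")
  cls <- sub("\\?$", "", cls)
  fam <- sub("\\?$", "", fam)
  cls[cls == "RC"] <- "DNA"
  cls[!cls %in% c("DNA", "LINE", "SINE", "LTR")] <- "Unknown"
  fam[fam == ""] <- "Unknown"
  paste0(cls, "/", fam)
}

#' Extract the class component of a `Class/Family` subfamily string
#' @param subfamily character vector of `Class/Family` strings.
#' @return character vector of classes.
#' @export
te_class <- function(subfamily) sub("/.*$", "", normalize_te_class(subfamily))

#' Read a RepeatMasker `.out` annotation file
#'
#' Parses the classic 15-column whitespace-separated `.out` dialect (three
#' header lines, 1-based inclusive coordinates, strand `C` meaning minus).
#' Rows annotated as `Simple_repeat` or `Low_complexity` are dropped; rows
#' lacking a class/family string are kept as `Unknown/Unknown`. The percent
#' divergence column is stored as a fraction in `[0, 1]`.
#'
#' @param path path to a `.out` file.
#' @param species optional species label attached to every copy.
#' @return data.frame of annotated copies with columns `copy_id`, `species`,
#'   `query_seq`, `start`, `end`, `strand`, `subfamily`, `consensus_id`,
#'   `percent_divergence`, `length`.
#' @export
read_repeatmasker_out <- function(path, species = NA_character_) {
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("not a RepeatMasker .out file (fewer than 3 header lines): ", path)
  body_idx <- seq(4L, length.out = max(0L, length(lines) - 3L))
  rows <- vector("list", length(body_idx))
  keep <- logical(length(body_idx))
  for (i in seq_along(body_idx)) {
    ln <- body_idx[i]
    raw <- trimws(lines[ln])
    if (raw == "") next
    fields <- strsplit(raw, "[ \t]+")[[1]]
    if (length(fields) < 15L)
      stop(sprintf("malformed RepeatMasker row at line %d: expected >= 15 columns, got %d",
                   ln, length(fields)))
    begin <- suppressWarnings(as.integer(fields[6]))
    end <- suppressWarnings(as.integer(fields[7]))
    div <- suppressWarnings(as.numeric(fields[2]))
    if (is.na(begin) || is.na(end) || is.na(div))
      stop(sprintf("malformed RepeatMasker row at line %d: non-numeric coordinate or divergence", ln))
    cf <- fields[11]
    if (cf %in% c("Simple_repeat", "Low_complexity")) next
    strand <- if (fields[9] == "C") "-" else fields[9]
    rows[[i]] <- data.frame(
      query_seq = fields[5], start = begin, end = end, strand = strand,
      subfamily = normalize_te_class(cf), consensus_id = fields[10],
      percent_divergence = div / 100, stringsAsFactors = FALSE)
    keep[i] <- TRUE
  }
  out <- do.call(rbind, rows[keep])
  if (is.null(out))
    out <- data.frame(query_seq = character(), start = integer(),
                      end = integer(), strand = character(),
                      subfamily = character(), consensus_id = character(),
                      percent_divergence = numeric(), stringsAsFactors = FALSE)
  out$length <- out$end - out$start + 1L
  out$species <- species
  prefix <- if (is.na(species)) "" else paste0(species, "|")
  out$copy_id <- paste0(prefix, out$query_seq, ":", out$start, "-", out$end,
                        "|", out$consensus_id)
  out[, c("copy_id", "species", "query_seq", "start", "end", "strand",
          "subfamily", "consensus_id", "percent_divergence", "length")]
}

#' Write annotated copies back to RepeatMasker `.out` layout
#'
#' Inverse of [read_repeatmasker_out()]: emits a 3-line header and one
#' 15-column row per copy. Divergence is written with four decimals so that
#' a write/read cycle preserves it.
#'
#' @param copies data.frame as returned by [read_repeatmasker_out()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(copies, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in queryserie    matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin end     (left)   repeat    class/family   begin end  (left)  ID",
    "")
  rows <- sprintf("  250 %6.4f  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d",
                  copies$percent_divergence * 100, copies$query_seq,
                  copies$start, copies$end,
                  ifelse(copies$strand == "-", "C", "+"),
                  copies$consensus_id, copies$subfamily,
                  copies$length, seq_len(nrow(copies)))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a TE consensus library from FASTA
#'
#' Sequence names may follow the RepeatModeler convention
#' `name#Class/Family`; anything after the `#` is parsed as the subfamily,
#' otherwise the subfamily is `Unknown/Unknown`.
#'
#' @param path FASTA file of consensus sequences.
#' @return data.frame with columns `consensus_id`, `subfamily`, `sequence`,
#'   `length`.
#' @export
read_consensus_fasta <- function(path) {
  seqs <- read_fasta(path)
  ids <- names(seqs)
  has_cf <- grepl("#", ids, fixed = TRUE)
  subfam <- ifelse(has_cf, sub("^[^#]*#", "", ids), NA_character_)
  data.frame(consensus_id = sub("#.*$", "", ids),
             subfamily = normalize_te_class(subfam),
             sequence = unname(seqs),
             length = nchar(seqs), stringsAsFactors = FALSE)
}

#' Write a consensus library to FASTA
#' @param consensus data.frame as from [read_consensus_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensus, path) {
  seqs <- consensus$sequence
  names(seqs) <- paste0(consensus$consensus_id, "#", consensus$subfamily)
  write_fasta(seqs, path)
}

#' Read/write FASTA as a named character vector
#'
#' Thin wrappers around Biostrings kept so that every module handles plain
#' character vectors internally.
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 80L)
  invisible(path)
}

#' Filter TE copies by fractional length of their consensus
#'
#' Keeps exactly the copies whose length is at least `min_fraction` times
#' the length of the consensus they were annotated against (boundary
#' inclusive). Autonomous-copy selection ahead of protein/dS analysis.
#'
#' @param copies data.frame of annotated copies.
#' @param consensus data.frame with `consensus_id` and `length` columns, or a
#'   named numeric vector of consensus lengths.
#' @param min_fraction minimum length fraction in `(0, 1]`; default 0.8.
#' @return the filtered copies, original order preserved.
#' @export
copy_length_filter <- function(copies, consensus, min_fraction = 0.8) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  if (is.data.frame(consensus)) {
    lens <- stats::setNames(consensus$length, consensus$consensus_id)
  } else lens <- consensus
  clen <- lens[copies$consensus_id]
  if (anyNA(clen)) {
    bad <- unique(copies$consensus_id[is.na(clen)])
    stop("unresolvable consensus_id(s): ", paste(bad, collapse = ", "))
  }
  copies[copies$length >= min_fraction * clen, , drop = FALSE]
}

#' Flag library consensus sequences with non-TE protein hits
#'
#' A query is removed from the library when at least one of its alignment
#' records simultaneously exceeds all three thresholds (strict
#' inequalities): identity > `identity_min`, e-value < `evalue_max`,
#' query coverage > `coverage_min`.
#'
#' @param records data.frame with columns `query_id`, `subject_id`,
#'   `percent_identity`, `e_value`, `query_coverage`.
#' @param identity_min percent identity threshold (default 30).
#' @param evalue_max e-value threshold (default 1e-5).
#' @param coverage_min percent query coverage threshold (default 50).
#' @return list with character vectors `kept` and `removed` of query ids.
#' @export
library_filter <- function(records, identity_min = 30, evalue_max = 1e-5,
                           coverage_min = 50) {
  hit <- records$percent_identity > identity_min &
    records$e_value < evalue_max &
    records$query_coverage > coverage_min
  removed <- sort(unique(records$query_id[hit]))
  kept <- sort(setdiff(unique(records$query_id), removed))
  list(kept = kept, removed = removed)
}

#' Read a time-calibrated species tree from Newick
#'
#' Expects a single rooted tree with branch lengths in millions of years.
#' Ultrametricity is checked to a relative tolerance of `tol` times the
#' tree height; node times from the root and node ages before present are
#' computed.
#'
#' @param path Newick file, or a Newick string.
#' @param tol relative ultrametricity tolerance (default 1e-6).
#' @return an object of class `timetree`: list with elements `tree`
#'   (an `ape` phylo), `height`, `node_depth` (time from root, per node),
#'   `node_age` (My before present, per node).
#' @export
read_newick_timetree <- function(path, tol = 1e-6) {
  tree <- if (grepl("[(;]", path)) ape::read.tree(text = path)
          else ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick input")
  timetree_from_phylo(tree, tol = tol)
}

#' Build a `timetree` from an `ape` phylo object
#' @param tree a rooted phylo with branch lengths in My.
#' @param tol relative ultrametricity tolerance.
#' @return a `timetree` (see [read_newick_timetree()]).
#' @export
timetree_from_phylo <- function(tree, tol = 1e-6) {
  if (!ape::is.rooted(tree) && tree$Nnode > 1L)
    stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  ntip <- length(tree$tip.label)
  height <- max(depth[seq_len(ntip)])
  if (height <= 0) stop("tree has zero height")
  if (max(depth[seq_len(ntip)]) - min(depth[seq_len(ntip)]) > tol * height)
    stop(sprintf("tree is not ultrametric: tip depths span %.6g to %.6g",
                 min(depth[seq_len(ntip)]), max(depth[seq_len(ntip)])))
  structure(list(tree = tree, height = height, node_depth = depth,
                 node_age = height - depth), class = "timetree")
}

#' Age (My before present) of the MRCA of a set of tips
#' @param tt a `timetree`.
#' @param tips character vector of tip labels (length >= 1).
#' @return age in My (0 for a single tip).
#' @export
mrca_age <- function(tt, tips) {
  stopifnot(inherits(tt, "timetree"))
  tips <- match(tips, tt$tree$tip.label)
  if (anyNA(tips)) stop("unknown tip label")
  if (length(tips) == 1L) return(0)
  node <- ape::getMRCA(tt$tree, tips)
  tt$node_age[node]
}

#' Write a named list of result tables as TSV files
#'
#' Each element of `objects` is written to `<dir>/<name>.tsv`. The files
#' round-trip through [read_tables()] (numbers at full precision, no
#' quoting, no row names).
#'
#' @param objects named list of data.frames.
#' @param dir output directory (created if missing).
#' @return character vector of file paths, invisibly.
#' @export
write_tables <- function(objects, dir) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(objects))
  for (i in seq_along(objects)) {
    paths[i] <- file.path(dir, paste0(names(objects)[i], ".tsv"))
    utils::write.table(objects[[i]], paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}

#' @rdname write_tables
#' @return for `read_tables`, a named list of data.frames.
#' @export
read_tables <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  out <- lapply(files, function(f)
    utils::read.table(f, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE))
  names(out) <- sub("\\.tsv$", "", basename(files))
  out
}

#' Read a per-species genome-size / TE-load table
#'
#' TSV with columns `species`, `DTE_pct`, `LTR_pct`, `LINE_pct`, `SINE_pct`,
#' `UnC_pct`, `All_pct`, `genome_size_mb`. Percentages are validated to lie
#' in `[0, 100]` and the total column is checked against the class sum
#' within per-column rounding (0.05 per class column).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_genome_table <- function(path) {
  gt <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("species", "DTE_pct", "LTR_pct", "LINE_pct", "SINE_pct",
           "UnC_pct", "All_pct", "genome_size_mb")
  if (!all(req %in% names(gt)))
    stop("genome table missing columns: ",
         paste(setdiff(req, names(gt)), collapse = ", "))
  pct <- as.matrix(gt[, c("DTE_pct", "LTR_pct", "LINE_pct", "SINE_pct",
                          "UnC_pct", "All_pct")])
  if (any(pct < 0 | pct > 100)) stop("TE percentages must lie in [0, 100]")
  class_sum <- rowSums(pct[, 1:5, drop = FALSE])
  if (any(abs(class_sum - gt$All_pct) > 0.05 * 5 + 1e-9))
    warning("total TE percent differs from class sum beyond rounding for: ",
            paste(gt$species[abs(class_sum - gt$All_pct) > 0.25],
                  collapse = ", "))
  gt
}
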