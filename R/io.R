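# File formats. All data.frame interval representations in this package are
# 0-based half-open; conversion to the 1-based GRanges convention happens
# only at the rtracklayer/Biostrings boundary, in the two helpers below.

#' Convert a 0-based interval data frame to GRanges
#'
#' @param df Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `strand` and `name`.
#' @return A [GenomicRanges::GRanges] object.
#' @export
intervals_to_granges <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if ("strand" %in% names(df)) df$strand else "*"
  )
  if ("name" %in% names(df)) gr$name <- df$name
  gr
}

#' Convert GRanges to a 0-based interval data frame
#'
#' @param gr A [GenomicRanges::GRanges] object.
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open),
#'   `strand`, and `name` when present.
#' @export
granges_to_intervals <- function(gr) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (!is.null(gr$name)) df$name <- as.character(gr$name)
  df
}

#' Read a BED interval track
#'
#' Parses BED through [rtracklayer::import()] and returns the package's
#' 0-based half-open data frame representation. The optional BED name
#' column (e.g. a repeat family label) is kept as `name`.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom`, `start`, `end`, `strand` and
#'   optionally `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  granges_to_intervals(gr)
}

#' Write intervals as BED
#'
#' @param df Interval data frame (`chrom`, `start`, `end`, optional
#'   `strand`, `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  rtracklayer::export(intervals_to_granges(df), path, format = "BED")
  invisible(path)
}

#' Read a per-CpG bisulfite coverage table
#'
#' Expected columns: `chrom`, `pos` (0-based position of the cytosine),
#' `strand`, `methylated_reads`, `unmethylated_reads` -- the
#' Bismark-coverage information with explicit strand, one row per
#' strand-specific cytosine.
#'
#' @param path Path to a TSV file with a header row.
#' @return Data frame with the five columns above.
#' @export
read_coverage <- function(path) {
  cov <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  need <- c("chrom", "pos", "strand", "methylated_reads", "unmethylated_reads")
  missing <- setdiff(need, names(cov))
  if (length(missing)) {
    stop("coverage file ", path, " lacks columns: ", paste(missing, collapse = ", "))
  }
  if (any(cov$methylated_reads < 0) || any(cov$unmethylated_reads < 0)) {
    stop("negative read counts in ", path)
  }
  cov[need]
}

#' Write a per-CpG coverage table
#' @param cov Coverage data frame as returned by [read_coverage()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(cov, path) {
  data.table::fwrite(cov, path, sep = "\t")
  invisible(path)
}

#' Combine strand-specific CpG counts into dinucleotide sites
#'
#' A CpG dinucleotide carries a cytosine on each strand: the plus-strand C
#' at position p and the minus-strand C at p + 1. Reads from both strands
#' report the methylation state of the same site, so counts are summed and
#' keyed by the plus-strand C position.
#'
#' @param cov Strand-resolved coverage data frame ([read_coverage()]).
#' @return Data frame `chrom`, `pos`, `methylated_reads`,
#'   `unmethylated_reads`, one row per CpG dinucleotide.
#' @export
combine_strand_counts <- function(cov) {
  dt <- data.table::as.data.table(cov)
  dt[, key_pos := ifelse(strand == "-", pos - 1L, pos)]
  out <- dt[, .(
    methylated_reads = sum(methylated_reads),
    unmethylated_reads = sum(unmethylated_reads)
  ), by = .(chrom, pos = key_pos)]
  data.table::setorder(out, chrom, pos)
  as.data.frame(out)
}

#' Import a genome-alignment chain file
#'
#' Thin wrapper over [rtracklayer::import.chain()]. Chains map coordinates
#' from the reference ("target") genome to the query genome.
#'
#' @param path Path to a UCSC chain file.
#' @return An `rtracklayer::Chain` object.
#' @export
read_chain <- function(path) {
  rtracklayer::import.chain(path)
}

#' Project 0-based positions through a chain
#'
#' @param chain Chain from [read_chain()].
#' @param chrom Character vector of reference chromosomes.
#' @param pos Integer vector of 0-based reference positions.
#' @return Data frame with `chrom` and `pos` (0-based) in the query
#'   genome; both NA where the position does not map, or maps ambiguously
#'   to more than one locus.
#' @export
project_positions <- function(chain, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- data.frame(chrom = rep(NA_character_, length(pos)),
                    pos = rep(NA_integer_, length(pos)))
  if (!length(pos)) return(out)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = pos + 1L, width = 1L))
  hits <- suppressMessages(rtracklayer::liftOver(gr, chain))
  nhit <- S4Vectors::elementNROWS(hits)
  ok <- nhit == 1L
  if (any(ok)) {
    mapped <- unlist(hits[ok])
    out$chrom[ok] <- as.character(GenomicRanges::seqnames(mapped))
    out$pos[ok] <- GenomicRanges::start(mapped) - 1L
  }
  out
}

#' Fraction of each interval covered by chain alignment blocks
#'
#' @param chain Chain from [read_chain()].
#' @param df Interval data frame (`chrom`, `start`, `end`, 0-based).
#' @return Numeric vector of covered fractions in \[0, 1\].
#' @export
chain_covered_fraction <- function(chain, df) {
  if (!nrow(df)) return(numeric(0))
  gr <- intervals_to_granges(df)
  hits <- suppressMessages(rtracklayer::liftOver(gr, chain))
  mapped <- vapply(seq_along(hits), function(i) {
    sum(GenomicRanges::width(hits[[i]]))
  }, numeric(1))
  mapped / (df$end - df$start)
}

#' Read / write the synthetic-truth JSON
#'
#' @param path Path to a truth JSON file.
#' @return The truth list.
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname read_truth
#' @param truth Truth list as produced by [simulate_dataset()].
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
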