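# Pairwise segmental-duplication alignments and base-level coordinate maps.
#
# An alignment relates two duplicon copies: copy A is always given on the
# plus strand of its chromosome; the aligned copy-B sequence is stored in
# the orientation matching A, i.e. reverse-complemented when the relative
# orientation is "-". Column-level bookkeeping converts between alignment
# columns and 0-based genomic positions on each copy's plus strand.

#' Construct a duplicon alignment
#'
#' @param chrom_a,start_a,end_a Copy-A location (0-based half-open).
#' @param chrom_b,start_b,end_b Copy-B location.
#' @param strand_b Relative orientation of copy B (`"+"` or `"-"`).
#' @param seq_a,seq_b Gapped aligned sequences (equal length; `-` = gap).
#'   `seq_a` is the plus strand of copy A; `seq_b` is copy B oriented to
#'   match A (reverse complement of the plus strand when `strand_b == "-"`).
#' @param identity Optional declared identity; when NULL the empirical
#'   identity over both-aligned columns is used.
#' @param id Optional alignment identifier.
#' @return An object of class `duplicon_alignment`.
#' @export
duplicon_alignment <- function(chrom_a, start_a, end_a,
                               chrom_b, start_b, end_b,
                               strand_b, seq_a, seq_b,
                               identity = NULL, id = NULL) {
  stopifnot(strand_b %in% c("+", "-"), nchar(seq_a) == nchar(seq_b))
  ca <- strsplit(toupper(seq_a), "")[[1]]
  cb <- strsplit(toupper(seq_b), "")[[1]]
  if (sum(ca != "-") != end_a - start_a) {
    stop("copy-A sequence length does not match its interval")
  }
  if (sum(cb != "-") != end_b - start_b) {
    stop("copy-B sequence length does not match its interval")
  }
  if (any(ca == "-" & cb == "-")) stop("column gapped on both copies")
  both <- ca != "-" & cb != "-"
  emp_identity <- if (any(both)) mean(ca[both] == cb[both]) else 0
  structure(list(
    chrom_a = chrom_a, start_a = as.integer(start_a), end_a = as.integer(end_a),
    chrom_b = chrom_b, start_b = as.integer(start_b), end_b = as.integer(end_b),
    strand_b = strand_b,
    chars_a = ca, chars_b = cb,
    identity = if (is.null(identity)) emp_identity else identity,
    empirical_identity = emp_identity,
    id = id
  ), class = "duplicon_alignment")
}

#' @export
print.duplicon_alignment <- function(x, ...) {
  cat(sprintf(
    "duplicon_alignment %s: %s:%d-%d (+) ~ %s:%d-%d (%s), %d columns, identity %.3f\n",
    if (is.null(x$id)) "" else x$id,
    x$chrom_a, x$start_a, x$end_a, x$chrom_b, x$start_b, x$end_b,
    x$strand_b, length(x$chars_a), x$identity
  ))
  invisible(x)
}

#' Base-level coordinate map of an alignment
#'
#' One row per alignment column, giving the 0-based plus-strand genomic
#' position of the column on each copy (NA where the column is a gap on
#' that copy). For inverted alignments, `pos_b` decreases along columns.
#'
#' @param aln A `duplicon_alignment`.
#' @return Data frame with columns `pos_a` and `pos_b`.
#' @export
alignment_columns <- function(aln) {
  ng_a <- aln$chars_a != "-"
  ng_b <- aln$chars_b != "-"
  pos_a <- rep(NA_integer_, length(ng_a))
  pos_a[ng_a] <- aln$start_a + seq_len(sum(ng_a)) - 1L
  pos_b <- rep(NA_integer_, length(ng_b))
  if (aln$strand_b == "+") {
    pos_b[ng_b] <- aln$start_b + seq_len(sum(ng_b)) - 1L
  } else {
    pos_b[ng_b] <- aln$end_b - seq_len(sum(ng_b))
  }
  data.frame(pos_a = pos_a, pos_b = pos_b)
}

#' Project positions between the two copies of a duplicon
#'
#' Maps 0-based positions in one copy to the aligned position in the other,
#' honouring orientation. Positions whose alignment column is gapped in the
#' other copy return NA.
#'
#' @param aln A `duplicon_alignment`.
#' @param pos Integer vector of 0-based positions inside the source copy.
#' @param from Which copy `pos` refers to, `"a"` or `"b"`.
#' @return Integer vector of projected positions (NA at gap columns).
#' @export
project_position <- function(aln, pos, from = c("a", "b")) {
  from <- match.arg(from)
  cols <- alignment_columns(aln)
  src <- if (from == "a") cols$pos_a else cols$pos_b
  dst <- if (from == "a") cols$pos_b else cols$pos_a
  lo <- if (from == "a") aln$start_a else aln$start_b
  hi <- if (from == "a") aln$end_a else aln$end_b
  if (any(pos < lo | pos >= hi)) {
    stop(sprintf("position outside duplicon copy %s [%d, %d)", from, lo, hi))
  }
  dst[match(pos, src)]
}

#' Parse pairwise segmental-duplication alignments
#'
#' The format carries one record per duplicon: a header line
#' `>chrA:startA-endA strandA chrB:startB-endB strandB identity`
#' (coordinates 0-based half-open; strandA is always `+`), followed by two
#' sequence lines -- the gapped copy-A sequence and the gapped copy-B
#' sequence in A-matching orientation. Records failing the inclusion rule
#' for segmental duplications (alignment span of copy A greater than
#' `min_length`, identity above `min_identity`) are dropped with a warning
#' naming the offending line.
#'
#' @param path Path to an alignment file.
#' @param min_length Minimum copy-A span in bp (exclusive bound).
#' @param min_identity Minimum declared identity (exclusive bound).
#' @return List of `duplicon_alignment` objects.
#' @export
parse_duplication_alignments <- function(path, min_length = 1000,
                                         min_identity = 0.9) {
  lines <- readLines(path)
  hdr_idx <- grep("^>", lines)
  if (!length(hdr_idx)) stop("no alignment records in ", path)
  out <- vector("list", length(hdr_idx))
  kept <- 0L
  for (i in seq_along(hdr_idx)) {
    h <- hdr_idx[i]
    m <- regmatches(lines[h], regexec(
      "^>(\\S+):(\\d+)-(\\d+)\\s+([+-])\\s+(\\S+):(\\d+)-(\\d+)\\s+([+-])\\s+([0-9.]+)\\s*$",
      lines[h]
    ))[[1]]
    if (length(m) != 10 || m[5] != "+") {
      stop("malformed alignment header at line ", h, ": ", lines[h])
    }
    if (h + 2 > length(lines)) stop("truncated record at line ", h)
    aln <- duplicon_alignment(
      chrom_a = m[2], start_a = as.integer(m[3]), end_a = as.integer(m[4]),
      chrom_b = m[6], start_b = as.integer(m[7]), end_b = as.integer(m[8]),
      strand_b = m[9],
      seq_a = lines[h + 1], seq_b = lines[h + 2],
      identity = as.numeric(m[10]),
      id = sprintf("aln%04d", i)
    )
    if (aln$end_a - aln$start_a <= min_length) {
      warning(sprintf("line %d: alignment span %d bp <= %d bp, record dropped",
                      h, aln$end_a - aln$start_a, min_length))
      next
    }
    if (aln$identity <= min_identity) {
      warning(sprintf("line %d: identity %.3f <= %.2f, record dropped",
                      h, aln$identity, min_identity))
      next
    }
    kept <- kept + 1L
    out[[kept]] <- aln
  }
  out[seq_len(kept)]
}

#' Write duplicon alignments in the pairwise alignment format
#'
#' @param alignments List of `duplicon_alignment` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_duplication_alignments <- function(alignments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (aln in alignments) {
    writeLines(sprintf(">%s:%d-%d + %s:%d-%d %s %.4f",
                       aln$chrom_a, aln$start_a, aln$end_a,
                       aln$chrom_b, aln$start_b, aln$end_b,
                       aln$strand_b, aln$identity), con)
    writeLines(paste(aln$chars_a, collapse = ""), con)
    writeLines(paste(aln$chars_b, collapse = ""), con)
  }
  invisible(path)
}

# 0-based positions of CpG cytosines (plus strand) within [start, end)
cpg_positions <- function(genome, chrom, start, end) {
  seq <- Biostrings::subseq(genome[[chrom]], start = start + 1L, width = end - start)
  hits <- Biostrings::matchPattern("CG", seq)
  start + BiocGenerics::start(hits) - 1L
}

#' Enumerate paralogous CpG site pairs
#'
#' For every alignment, finds CpG dinucleotides in copy A whose aligned
#' positions in copy B also carry a CpG on B's own plus strand. CG is its
#' own reverse complement, so inverted alignments pair a CpG with a CpG;
#' in that case the plus-strand C of the B-copy site is the aligned
#' position of the A-copy G. Pairs whose C or G column is gapped, or whose
#' dinucleotide was destroyed by substitution in either copy, are not
#' reported.
#'
#' @param alignments List of `duplicon_alignment` objects.
#' @param genome Named [Biostrings::DNAStringSet] with both copies'
#'   chromosomes.
#' @return Data frame with `alignment_id`, `chrom_a`, `pos_a`, `chrom_b`,
#'   `pos_b` (0-based plus-strand C positions) and a canonical `pair_id`.
#' @export
find_paralogous_cpg_pairs <- function(alignments, genome) {
  res <- lapply(seq_along(alignments), function(i) {
    aln <- alignments[[i]]
    p <- cpg_positions(genome, aln$chrom_a, aln$start_a, aln$end_a)
    p <- p[p + 1L < aln$end_a]
    if (!length(p)) return(NULL)
    q1 <- project_position(aln, p, from = "a")
    q2 <- project_position(aln, p + 1L, from = "a")
    ok <- !is.na(q1) & !is.na(q2) & abs(q1 - q2) == 1L
    if (!any(ok)) return(NULL)
    p <- p[ok]; qc <- pmin(q1[ok], q2[ok])
    bseq <- genome[[aln$chrom_b]]
    din <- as.character(Biostrings::extractAt(
      bseq, IRanges::IRanges(start = qc + 1L, width = 2L)))
    keep <- toupper(din) == "CG"
    if (!any(keep)) return(NULL)
    data.frame(
      alignment_id = if (is.null(aln$id)) sprintf("aln%04d", i) else aln$id,
      chrom_a = aln$chrom_a, pos_a = p[keep],
      chrom_b = aln$chrom_b, pos_b = qc[keep],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(alignment_id = character(), chrom_a = character(),
                      pos_a = integer(), chrom_b = character(),
                      pos_b = integer(), stringsAsFactors = FALSE)
  }
  out$pair_id <- cpg_pair_id(out$chrom_a, out$pos_a, out$chrom_b, out$pos_b)
  out
}

#' Canonical identifier for a paralogous CpG pair
#' @param chrom_a,pos_a,chrom_b,pos_b Site coordinates (0-based C position).
#' @return Character vector of pair identifiers.
#' @export
cpg_pair_id <- function(chrom_a, pos_a, chrom_b, pos_b) {
  paste0(chrom_a, ":", pos_a, "|", chrom_b, ":", pos_b)
}

#' Attach methylation counts to paralogous CpG pairs
#'
#' Joins dinucleotide-combined coverage ([combine_strand_counts()]) onto
#' both members of every pair. Sites absent from the coverage table get
#' zero counts.
#'
#' @param pairs Pair table from [find_paralogous_cpg_pairs()].
#' @param coverage Combined coverage data frame (`chrom`, `pos`,
#'   `methylated_reads`, `unmethylated_reads`).
#' @return The pair table with `meth_a`, `unmeth_a`, `meth_b`, `unmeth_b`.
#' @export
attach_pair_counts <- function(pairs, coverage) {
  key <- function(chrom, pos) paste0(chrom, ":", pos)
  idx <- setNames(seq_len(nrow(coverage)), key(coverage$chrom, coverage$pos))
  ia <- idx[key(pairs$chrom_a, pairs$pos_a)]
  ib <- idx[key(pairs$chrom_b, pairs$pos_b)]
  grab <- function(col, i) ifelse(is.na(i), 0L, coverage[[col]][i])
  pairs$meth_a <- grab("methylated_reads", ia)
  pairs$unmeth_a <- grab("unmethylated_reads", ia)
  pairs$meth_b <- grab("methylated_reads", ib)
  pairs$unmeth_b <- grab("unmethylated_reads", ib)
  pairs
}
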