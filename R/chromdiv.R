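# Chromatin-feature divergence between duplicon copies: uniqueness-masked
# 500-bp window read counts, exact binomial discordance tests, and
# flanking read-depth profiles around discordant CpG sites.

# logical vector: is each 0-based position covered by the interval set?
positions_in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || !nrow(intervals)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (cc in unique(chrom)) {
    iv <- intervals[intervals$chrom == cc, , drop = FALSE]
    sel <- chrom == cc
    if (!nrow(iv)) next
    o <- order(iv$start)
    starts <- iv$start[o]; ends <- iv$end[o]
    idx <- findInterval(pos[sel], starts)
    hit <- idx >= 1 & pos[sel] < ends[pmax(idx, 1)]
    out[sel] <- hit
  }
  out
}

# 5'-most mapped position of each read (0-based)
read_five_prime <- function(reads) {
  ifelse(!is.null(reads$strand) & reads$strand == "-", reads$end - 1L, reads$start)
}

#' Build mappability-masked 500-bp window pairs for a duplicon
#'
#' Tiles copy A of the alignment with nonoverlapping windows of `size` bp
#' starting at the duplicon start (a trailing partial window is dropped)
#' and projects every window position onto copy B. A position enters the
#' window's mask only when its alignment column is ungapped and the
#' position is uniquely mappable in *both* copies -- positions that cannot
#' be uniquely mapped in either copy are ignored symmetrically.
#'
#' @param aln A `duplicon_alignment`.
#' @param mappability Interval data frame of uniquely mappable positions
#'   (0-based half-open); NULL treats the genome as fully mappable.
#' @param size Window size in bp.
#' @return List with `windows` (one row per window: `window_id`,
#'   `chrom_a`, `start_a`, `end_a`, `chrom_b`, `mask_size`) and `mask`
#'   (per masked position: `window_id`, `pos_a`, `pos_b`).
#' @export
make_window_pairs <- function(aln, mappability = NULL, size = 500) {
  len <- aln$end_a - aln$start_a
  n_win <- len %/% size
  if (n_win == 0) {
    return(list(
      windows = data.frame(window_id = character(), chrom_a = character(),
                           start_a = integer(), end_a = integer(),
                           chrom_b = character(), mask_size = integer()),
      mask = data.frame(window_id = character(), pos_a = integer(),
                        pos_b = integer())
    ))
  }
  cols <- alignment_columns(aln)
  cols <- cols[!is.na(cols$pos_a) & !is.na(cols$pos_b), , drop = FALSE]
  cols <- cols[cols$pos_a < aln$start_a + n_win * size, , drop = FALSE]
  if (!is.null(mappability)) {
    ok <- positions_in_intervals(rep(aln$chrom_a, nrow(cols)), cols$pos_a, mappability) &
      positions_in_intervals(rep(aln$chrom_b, nrow(cols)), cols$pos_b, mappability)
    cols <- cols[ok, , drop = FALSE]
  }
  win_of <- (cols$pos_a - aln$start_a) %/% size
  id <- sprintf("%s:%d:w%03d", aln$chrom_a, aln$start_a, seq_len(n_win) - 1L)
  mask <- data.frame(window_id = id[win_of + 1L],
                     pos_a = cols$pos_a, pos_b = cols$pos_b,
                     stringsAsFactors = FALSE)
  windows <- data.frame(
    window_id = id,
    chrom_a = aln$chrom_a,
    start_a = aln$start_a + (seq_len(n_win) - 1L) * size,
    end_a = aln$start_a + seq_len(n_win) * size,
    chrom_b = aln$chrom_b,
    mask_size = as.integer(table(factor(mask$window_id, levels = id))),
    stringsAsFactors = FALSE
  )
  list(windows = windows, mask = mask)
}

#' Count reads over masked window pairs
#'
#' A read is assigned to a window by its 5'-most mapped position; it is
#' counted for a copy when that position lies on a masked (jointly
#' mappable, ungapped) position of the window. Nonoverlapping windows and
#' single-position assignment conserve counts across a duplicon.
#'
#' @param window_pairs Result of [make_window_pairs()].
#' @param reads Read track data frame (`chrom`, `start`, `end`, optional
#'   `strand`), e.g. from [read_bed()].
#' @return The `windows` table with `count_a` and `count_b` columns.
#' @export
count_window_reads <- function(window_pairs, reads) {
  win <- window_pairs$windows
  mask <- window_pairs$mask
  p5 <- read_five_prime(reads)
  keyr <- paste0(reads$chrom, ":", p5)
  tab <- table(keyr)
  count_at <- function(chrom, pos) {
    v <- tab[paste0(chrom, ":", pos)]
    ifelse(is.na(v), 0L, as.integer(v))
  }
  widx <- match(mask$window_id, win$window_id)
  ca <- count_at(win$chrom_a[widx], mask$pos_a)
  cb <- count_at(win$chrom_b[widx], mask$pos_b)
  grp <- factor(mask$window_id, levels = win$window_id)
  sum_by <- function(x) {
    s <- tapply(x, grp, sum)
    as.integer(ifelse(is.na(s), 0L, s))
  }
  win$count_a <- sum_by(ca)
  win$count_b <- sum_by(cb)
  win
}

#' Binomial discordance test for window pairs
#'
#' Two-sided exact binomial test of the copy-A read count against the
#' window total at success probability 0.5 (both windows are drawn from
#' the same library, so no size normalisation applies). Windows with no
#' reads on either copy are untestable and get NA.
#'
#' @param windows Window table with `count_a`, `count_b`.
#' @return The table with a `p_value` column.
#' @export
test_window_discordance <- function(windows) {
  windows$p_value <- binom_exact_p(windows$count_a,
                                   windows$count_a + windows$count_b)
  windows
}

#' Call discordant windows
#'
#' A window pair is discordant when its Bonferroni-corrected binomial
#' p-value (corrected over the testable windows of the mark) is below
#' `alpha` *and* one copy has a read count of exactly zero -- restricting
#' calls to windows where the chromatin feature has been completely lost
#' on one copy.
#'
#' @param windows Window table from [test_window_discordance()].
#' @param alpha Corrected significance cutoff.
#' @return The table with `p_adjusted` and logical `discordant`.
#' @export
classify_discordant_windows <- function(windows, alpha = 0.05) {
  testable <- !is.na(windows$p_value)
  m <- sum(testable)
  windows$p_adjusted <- pmin(1, windows$p_value * m)
  windows$discordant <- testable &
    windows$p_adjusted < alpha &
    pmin(windows$count_a, windows$count_b) == 0
  windows
}

#' Read depth flanking the two copies of discordant CpG pairs
#'
#' For every discordant pair, counts reads (by 5' position) within `flank`
#' bp either side of the hypermethylated and hypomethylated copy's CpG,
#' then compares the two counts across pairs with a paired Wilcoxon
#' signed-rank test. Active-chromatin reads concentrating on the
#' hypomethylated copies yield a small p-value.
#'
#' @param pairs Discordant pair table with `hyper_copy` labels.
#' @param reads Read track data frame.
#' @param flank Flank in bp either side of the CpG position.
#' @return List with `per_pair` (`count_hyper`, `count_hypo` appended) and
#'   `p_value` (NA when no informative pair).
#' @export
flanking_read_profile <- function(pairs, reads, flank = 500) {
  p5 <- read_five_prime(reads)
  count_near <- function(chrom, pos) {
    vapply(seq_along(pos), function(i) {
      sum(reads$chrom == chrom[i] & p5 >= pos[i] - flank & p5 <= pos[i] + flank)
    }, numeric(1))
  }
  hyper_is_a <- pairs$hyper_copy == "a"
  hyper_chrom <- ifelse(hyper_is_a, pairs$chrom_a, pairs$chrom_b)
  hyper_pos <- ifelse(hyper_is_a, pairs$pos_a, pairs$pos_b)
  hypo_chrom <- ifelse(hyper_is_a, pairs$chrom_b, pairs$chrom_a)
  hypo_pos <- ifelse(hyper_is_a, pairs$pos_b, pairs$pos_a)
  pairs$count_hyper <- count_near(hyper_chrom, hyper_pos)
  pairs$count_hypo <- count_near(hypo_chrom, hypo_pos)
  d <- pairs$count_hyper - pairs$count_hypo
  p <- if (!nrow(pairs) || all(d == 0)) {
    if (nrow(pairs) && all(pairs$count_hyper == pairs$count_hypo) &&
        any(pairs$count_hyper > 0)) 1 else NA_real_
  } else {
    suppressWarnings(wilcox.test(pairs$count_hyper, pairs$count_hypo,
                                 paired = TRUE)$p.value)
  }
  list(per_pair = pairs, p_value = p)
}
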