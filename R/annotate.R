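# Genomic context of discordant versus concordant CpG sites: distances to
# annotation features, CpG island / shore classes, repeat and
# duplicon-junction proximity statistics, and flank-sequence export.

#' Distance from point sites to the nearest feature interval
#'
#' Edge-to-point distance: 0 when the position lies inside (or on the last
#' base of) a feature, otherwise the number of bases to the nearest
#' feature edge. Chromosomes without any feature give NA.
#'
#' @param chrom,pos Site coordinates (0-based positions).
#' @param track Feature interval data frame (`chrom`, `start`, `end`).
#' @return Numeric vector of distances (NA where no feature exists on the
#'   site's chromosome).
#' @export
distance_to_nearest <- function(chrom, pos, track) {
  chrom <- rep_len(chrom, length(pos))
  if (is.null(track) || !nrow(track)) return(rep(NA_real_, length(pos)))
  out <- rep(NA_real_, length(pos))
  for (cc in unique(chrom)) {
    iv <- track[track$chrom == cc, , drop = FALSE]
    sel <- which(chrom == cc)
    if (!nrow(iv)) next
    o <- order(iv$start)
    starts <- iv$start[o]; ends <- iv$end[o]
    for (i in sel) {
      p <- pos[i]
      inside <- any(p >= starts & p < ends)
      if (inside) {
        out[i] <- 0
      } else {
        dl <- suppressWarnings(min(p - ends[ends <= p] + 1))
        dr <- suppressWarnings(min(starts[starts > p] - p))
        out[i] <- min(dl, dr)
      }
    }
  }
  out
}

#' Classify CpG sites as island, shore or open sea
#'
#' Sites overlapping a CpG island are `island`; sites strictly closer than
#' `shore_width` bp to an island are `shore`; everything else is
#' `open_sea`. The three classes partition the input.
#'
#' @param chrom,pos Site coordinates.
#' @param islands CpG island interval data frame.
#' @param shore_width Shore distance bound in bp (strict upper bound).
#' @return Character vector of classes.
#' @export
classify_island_shore <- function(chrom, pos, islands, shore_width = 2000) {
  d <- distance_to_nearest(chrom, pos, islands)
  ifelse(is.na(d), "open_sea",
         ifelse(d == 0, "island",
                ifelse(d < shore_width, "shore", "open_sea")))
}

#' Repeat-class proximity at hyper- versus hypomethylated copies
#'
#' For each repeat class, compares the distance to the nearest element of
#' that class at the hypermethylated copy against the hypomethylated copy
#' of each discordant pair, using a paired Wilcoxon signed-rank test (the
#' paired analogue of the Mann-Whitney U test). A class is informative
#' only when present in the track and represented by at least two pairs
#' with a defined distance difference.
#'
#' @param pairs Discordant pair table with `hyper_copy` labels.
#' @param repeats Repeat track with a `name` column holding the class.
#' @param classes Repeat classes to test (default: all in the track).
#' @return Data frame with `class`, `n`, `median_hyper`, `median_hypo`,
#'   `p_value` (NA where untestable).
#' @export
repeat_proximity_test <- function(pairs, repeats, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(repeats$name))
  hyper_is_a <- pairs$hyper_copy == "a"
  hc <- ifelse(hyper_is_a, pairs$chrom_a, pairs$chrom_b)
  hp <- ifelse(hyper_is_a, pairs$pos_a, pairs$pos_b)
  lc <- ifelse(hyper_is_a, pairs$chrom_b, pairs$chrom_a)
  lp <- ifelse(hyper_is_a, pairs$pos_b, pairs$pos_a)
  rows <- lapply(classes, function(cl) {
    trk <- repeats[repeats$name == cl, , drop = FALSE]
    if (!nrow(trk)) {
      return(data.frame(class = cl, n = 0L, median_hyper = NA_real_,
                        median_hypo = NA_real_, p_value = NA_real_))
    }
    dh <- distance_to_nearest(hc, hp, trk)
    dl <- distance_to_nearest(lc, lp, trk)
    ok <- !is.na(dh) & !is.na(dl)
    p <- if (sum(ok) < 2) {
      NA_real_
    } else if (all(dh[ok] == dl[ok])) {
      1
    } else {
      suppressWarnings(wilcox.test(dh[ok], dl[ok], paired = TRUE)$p.value)
    }
    data.frame(class = cl, n = sum(ok),
               median_hyper = median(dh[ok]), median_hypo = median(dl[ok]),
               p_value = p)
  })
  do.call(rbind, rows)
}

#' Distance to duplicon junctions: discordant versus concordant sites
#'
#' Measures each site's distance to the nearest duplicated-region boundary
#' and compares the two groups with an unpaired two-sided Mann-Whitney
#' test.
#'
#' @param discordant,concordant Site tables (`chrom`, `pos`).
#' @param duplicons Duplicon interval data frame (`chrom`, `start`,
#'   `end`).
#' @return List with `median_discordant`, `median_concordant`, `p_value`
#'   (NA when a group is empty).
#' @export
junction_distance_test <- function(discordant, concordant, duplicons) {
  # junction = boundary base of a duplicated region
  bounds <- rbind(
    data.frame(chrom = duplicons$chrom, start = duplicons$start,
               end = duplicons$start + 1L),
    data.frame(chrom = duplicons$chrom, start = duplicons$end - 1L,
               end = duplicons$end)
  )
  dd <- distance_to_nearest(discordant$chrom, discordant$pos, bounds)
  dc <- distance_to_nearest(concordant$chrom, concordant$pos, bounds)
  dd <- dd[!is.na(dd)]; dc <- dc[!is.na(dc)]
  if (!length(dd) || !length(dc)) {
    return(list(median_discordant = NA_real_, median_concordant = NA_real_,
                p_value = NA_real_))
  }
  p <- suppressWarnings(wilcox.test(dd, dc)$p.value)
  list(median_discordant = median(dd), median_concordant = median(dc),
       p_value = p)
}

#' TSS distances for both copies of every pair
#'
#' @param pairs Pair table with a `discordant` column.
#' @param tss TSS track (`chrom`, `start`, `end`) or gene table with
#'   `chrom` and `tss` columns.
#' @return List with `table` (pairs plus `dist_a`, `dist_b`) and
#'   `fraction_discordant_distal`, the fraction of discordant pairs with
#'   both distances above 1 kb.
#' @export
tss_distance_table <- function(pairs, tss) {
  if ("tss" %in% names(tss)) {
    tss <- data.frame(chrom = tss$chrom, start = tss$tss, end = tss$tss + 1L)
  }
  pairs$dist_a <- distance_to_nearest(pairs$chrom_a, pairs$pos_a, tss)
  pairs$dist_b <- distance_to_nearest(pairs$chrom_b, pairs$pos_b, tss)
  disc <- pairs$discordant
  frac <- if (any(disc)) {
    mean(pairs$dist_a[disc] > 1000 & pairs$dist_b[disc] > 1000, na.rm = TRUE)
  } else {
    NA_real_
  }
  list(table = pairs, fraction_discordant_distal = frac)
}

#' Export flanking sequences around CpG sites as FASTA
#'
#' Writes one FASTA per group (typically the hypermethylated and
#' hypomethylated copies of discordant pairs) with the sequence `flank` bp
#' either side of each site, for motif discovery with external tools.
#' Sequences are truncated at chromosome ends and flagged in the header.
#'
#' @param sites Site table (`chrom`, `pos`, `group`).
#' @param genome Named [Biostrings::DNAStringSet].
#' @param flank Flank in bp either side of the site.
#' @param out_dir Output directory.
#' @param prefix File-name prefix (`<prefix>_<group>.fa`).
#' @return Named character vector of written paths (one per group).
#' @export
export_flank_fasta <- function(sites, genome, flank = 500, out_dir = ".",
                               prefix = "flanks") {
  stopifnot(all(c("chrom", "pos", "group") %in% names(sites)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in unique(sites$group)) {
    sub <- sites[sites$group == g, , drop = FALSE]
    seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(sub)), function(i) {
      len <- length(genome[[sub$chrom[i]]])
      s <- max(0L, sub$pos[i] - flank)
      e <- min(len, sub$pos[i] + flank + 1L)
      as.character(Biostrings::subseq(genome[[sub$chrom[i]]], s + 1L, e))
    }, character(1)))
    lens <- Biostrings::width(seqs)
    full <- 2L * flank + 1L
    names(seqs) <- sprintf("%s:%d-%d%s", sub$chrom,
                           pmax(0L, sub$pos - flank),
                           pmax(0L, sub$pos - flank) + lens,
                           ifelse(lens < full, " truncated", ""))
    path <- file.path(out_dir, paste0(prefix, "_", g, ".fa"))
    Biostrings::writeXStringSet(seqs, path)
    paths[g] <- path
  }
  paths
}
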