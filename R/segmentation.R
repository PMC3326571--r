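# Recursive change-point splitting of one ordered series. At each node the
# max-CUSUM statistic is located and its significance assessed by random
# permutation of the node's values; a split is kept when the permutation
# p-value is <= alpha, and both halves are revisited. Returns the indices k
# after which the series is cut.
find_breaks <- function(x, alpha, min_markers, nperm) {
  n <- length(x)
  if (n < 2 * min_markers) return(integer(0))
  mc <- .cusum_max(x, as.integer(min_markers))
  if (mc$k < 0 || mc$stat <= 1e-12) return(integer(0))
  p <- .cusum_perm_pvalue(x, as.integer(min_markers), mc$stat,
                          as.integer(nperm), alpha)
  if (p > alpha) return(integer(0))
  k <- mc$k
  c(find_breaks(x[seq_len(k)], alpha, min_markers, nperm),
    k,
    k + find_breaks(x[seq.int(k + 1, n)], alpha, min_markers, nperm))
}

# Turn per-probe positions plus break indices into abutting bp segments.
# Boundaries fall halfway between flanking probes; the outer extent is
# [first_pos - half_spacing + 1, last_pos + half_spacing].
breaks_to_segments <- function(chrom, pos, breaks) {
  n <- length(pos)
  half <- if (n > 1) stats::median(diff(pos)) / 2 else 5000
  cuts <- floor((pos[breaks] + pos[breaks + 1]) / 2)
  starts <- c(max(1, floor(pos[1] - half + 1)), cuts + 1)
  ends <- c(cuts, floor(pos[n] + half))
  idx_start <- c(1, breaks + 1)
  idx_end <- c(breaks, n)
  data.frame(chrom = chrom, start = starts, end = ends,
             .i0 = idx_start, .i1 = idx_end, stringsAsFactors = FALSE)
}

#' Segment a logR profile
#'
#' Partitions each chromosome's ordered logR series into segments of
#' constant mean by recursive change-point detection with permutation
#' p-values (a CBS-style procedure).
#'
#' @param sample probe data frame (`chrom`, `pos`, `logR`, ...), sorted.
#' @param alpha per-split significance level for the permutation test.
#' @param min_markers minimum markers per segment.
#' @param nperm permutations per split test; must satisfy
#'   `1/(nperm+1) <= alpha` for any split to be accepted.
#' @param seed optional seed making the permutation tests reproducible.
#' @return data frame `chrom`, `start`, `end`, `n_markers`, `mean_logr`.
#' @export
segment_logr <- function(sample, alpha = 0.001, min_markers = 5,
                         nperm = 999, seed = NULL) {
  stopifnot(all(c("chrom", "pos", "logR") %in% names(sample)))
  chroms <- unique(sample$chrom)
  with_seed(seed, {
    res <- lapply(chroms, function(ch) {
      s <- sample[sample$chrom == ch, , drop = FALSE]
      if (nrow(s) == 0) {
        warning("no probes on chromosome ", ch)
        return(NULL)
      }
      br <- find_breaks(s$logR, alpha, min_markers, nperm)
      seg <- breaks_to_segments(ch, s$pos, br)
      seg$n_markers <- seg$.i1 - seg$.i0 + 1
      seg$mean_logr <- vapply(seq_len(nrow(seg)), function(i)
        mean(s$logR[seg$.i0[i]:seg$.i1[i]]), numeric(1))
      seg$.i0 <- seg$.i1 <- NULL
      seg
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Mirror B-allele frequencies
#'
#' Reflects BAF about 0.5 into mBAF = max(BAF, 1 - BAF) for informative
#' (putatively heterozygous) probes. Probes whose BAF lies outside
#' `[hom_exclusion_band, 1 - hom_exclusion_band]` are flagged homozygous and
#' dropped.
#'
#' @param sample probe data frame with a `BAF` column.
#' @param hom_exclusion_band half-width of the homozygote exclusion zone at
#'   each end of the BAF scale.
#' @return data frame `chrom`, `pos`, `mbaf` over informative probes.
#' @export
mirror_baf <- function(sample, hom_exclusion_band = 0.05) {
  stopifnot("BAF" %in% names(sample))
  b <- sample$BAF
  keep <- !is.na(b) & b >= hom_exclusion_band & b <= 1 - hom_exclusion_band
  if (!any(keep)) {
    warning("all probes homozygous; empty mBAF series")
    return(data.frame(chrom = character(0), pos = numeric(0),
                      mbaf = numeric(0)))
  }
  data.frame(chrom = sample$chrom[keep], pos = sample$pos[keep],
             mbaf = pmax(b[keep], 1 - b[keep]), stringsAsFactors = FALSE)
}

#' Segment a mirrored-BAF series
#'
#' Change-point partition of the per-probe mBAF series of informative
#' probes; per-segment level is the median (robust to residual
#' homozygotes).
#'
#' @param mbaf data frame from [mirror_baf()].
#' @param alpha,min_markers,nperm,seed as in [segment_logr()].
#' @param min_het_markers if fewer informative probes than this exist on a
#'   chromosome, it is returned as a single low-confidence segment.
#' @return data frame `chrom`, `start`, `end`, `n_het_markers`,
#'   `mean_mbaf`, `low_confidence`.
#' @export
segment_baf <- function(mbaf, alpha = 0.001, min_markers = 5,
                        min_het_markers = 10, nperm = 999, seed = NULL) {
  stopifnot(all(c("chrom", "pos", "mbaf") %in% names(mbaf)))
  if (nrow(mbaf) == 0) stop("no informative probes")
  chroms <- unique(mbaf$chrom)
  with_seed(seed, {
    res <- lapply(chroms, function(ch) {
      s <- mbaf[mbaf$chrom == ch, , drop = FALSE]
      low <- nrow(s) < min_het_markers
      br <- if (low) integer(0) else find_breaks(s$mbaf, alpha, min_markers, nperm)
      seg <- breaks_to_segments(ch, s$pos, br)
      seg$n_het_markers <- seg$.i1 - seg$.i0 + 1
      seg$mean_mbaf <- vapply(seq_len(nrow(seg)), function(i)
        stats::median(s$mbaf[seg$.i0[i]:seg$.i1[i]]), numeric(1))
      seg$low_confidence <- low
      seg$.i0 <- seg$.i1 <- NULL
      seg
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}

#' Integrate logR and mBAF segmentations
#'
#' Forms the union of the two partitions' breakpoints per chromosome and
#' recomputes per-segment statistics over the sample's probes: `mean_logr`
#' as the mean of member logR values and `mean_mbaf` as the median mBAF of
#' informative probes (`NA` when a segment has none).
#'
#' @param logr_segs output of [segment_logr()].
#' @param baf_segs output of [segment_baf()].
#' @param sample the probe data frame both segmentations came from.
#' @param hom_exclusion_band passed to [mirror_baf()] for the re-aggregation.
#' @return data frame `chrom`, `start`, `end`, `n_markers`,
#'   `n_het_markers`, `mean_logr`, `mean_mbaf`.
#' @export
integrate_segments <- function(logr_segs, baf_segs, sample,
                               hom_exclusion_band = 0.05) {
  ch_l <- unique(logr_segs$chrom)
  ch_b <- unique(baf_segs$chrom)
  if (!setequal(ch_l, ch_b))
    stop("logR and BAF segmentations cover different chromosomes")
  mb <- mirror_baf(sample, hom_exclusion_band)
  res <- lapply(ch_l, function(ch) {
    a <- logr_segs[logr_segs$chrom == ch, , drop = FALSE]
    b <- baf_segs[baf_segs$chrom == ch, , drop = FALSE]
    L <- max(a$end, b$end)
    cuts <- sort(unique(c(a$start, b$start)))
    cuts <- cuts[cuts > 1]
    starts <- c(1, cuts)
    ends <- c(cuts - 1, L)
    s <- sample[sample$chrom == ch, , drop = FALSE]
    m <- mb[mb$chrom == ch, , drop = FALSE]
    out <- data.frame(chrom = ch, start = starts, end = ends,
                      stringsAsFactors = FALSE)
    out$n_markers <- out$n_het_markers <- 0L
    out$mean_logr <- out$mean_mbaf <- NA_real_
    for (i in seq_len(nrow(out))) {
      inseg <- s$pos >= out$start[i] & s$pos <= out$end[i]
      out$n_markers[i] <- sum(inseg)
      if (any(inseg)) out$mean_logr[i] <- mean(s$logR[inseg])
      hseg <- m$pos >= out$start[i] & m$pos <= out$end[i]
      out$n_het_markers[i] <- sum(hseg)
      if (any(hseg)) out$mean_mbaf[i] <- stats::median(m$mbaf[hseg])
    }
    out[out$n_markers > 0, , drop = FALSE]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# Weighted Epanechnikov kernel density evaluated on a grid; h is the kernel
# half-width (K(u) = 0.75 (1 - u^2) on |u| <= 1).
epan_density_grid <- function(x, w, h, grid) {
  w <- w / sum(w)
  vapply(grid, function(g) {
    u <- (g - x) / h
    sum(w * 0.75 * pmax(0, 1 - u^2)) / h
  }, numeric(1))
}

#' Centralize a segmented logR profile
#'
#' Shifts all segment means so that the dominant copy-number level sits at
#' logR 0. The dominant level is the mode of the marker-count-weighted
#' Epanechnikov density of segment means, located on a regularly spaced
#' grid; ties are broken toward the level covering more of the genome.
#'
#' @param segments data frame with `mean_logr` and `n_markers`.
#' @param bw kernel half-width on the logR scale.
#' @param grid_step spacing of the mode-search grid.
#' @return `segments` with shifted `mean_logr`; the shift applied is stored
#'   in `attr(, "shift")`.
#' @export
centralize <- function(segments, bw = 0.1, grid_step = 0.01) {
  stopifnot(nrow(segments) >= 1)
  x <- segments$mean_logr
  w <- segments$n_markers
  grid <- seq(floor((min(x) - bw) / grid_step) * grid_step,
              ceiling((max(x) + bw) / grid_step) * grid_step,
              by = grid_step)
  d <- epan_density_grid(x, w, bw, grid)
  top <- which(d >= max(d) - 1e-12)
  if (length(top) > 1) {
    cover <- vapply(grid[top], function(g)
      sum(w[abs(x - g) <= bw]), numeric(1))
    top <- top[which.max(cover)]
  }
  shift <- grid[top[1]]
  segments$mean_logr <- segments$mean_logr - shift
  attr(segments, "shift") <- shift
  segments
}
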