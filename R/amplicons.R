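#' Focal high-level amplicons of one sample
#'
#' Segments strictly larger than `min_size` bp with centralized mean logR
#' strictly above `min_logr`, carrying their mBAF when available.
#'
#' @param logr_segments centralized segments with `mean_logr` (and
#'   optionally `mean_mbaf`, `nA`, `nB`).
#' @param min_size minimum size in bp (strict; default 50 kb).
#' @param min_logr minimum mean logR (strict; default 0.7).
#' @return the qualifying rows with `kind = "focal"`.
#' @export
focal_amplicons <- function(logr_segments, min_size = 50000, min_logr = 0.7) {
  sz <- seg_lengths(logr_segments)
  out <- logr_segments[sz > min_size & logr_segments$mean_logr > min_logr, ,
                       drop = FALSE]
  if (nrow(out)) out$kind <- "focal"
  rownames(out) <- NULL
  out
}

#' Classify an amplification as monoallelic
#'
#' Monoallelic amplification places all added copies on one parental
#' chromosome: the minor allele stays at or below its ploidy-expected
#' share (`nB <= round(psi / 2)`) while the major allele carries the
#' amplification (`nA - nB >= 3`). Returns `NA` when no allelic
#' information exists.
#'
#' @param nA,nB allele-specific copy numbers of the event (may be `NA`).
#' @param psi tumor ploidy.
#' @return logical (vectorized), `NA` when the allele split is unknown.
#' @export
classify_monoallelic <- function(nA, nB, psi) {
  ifelse(is.na(nA) | is.na(nB), NA,
         nB <= round(psi / 2) & (nA - nB) >= 3)
}

#' Broad amplified events of one sample
#'
#' Merges adjacent qualifying segments and reports events strictly larger
#' than `min_size` bp whose total copy number strictly exceeds
#' `psi + cn_margin` (e.g. with ploidy 2.58 an event needs total CN above
#' 5.58). Each event carries the marker-weighted mean allele-specific
#' copy numbers of its member segments and a monoallelic classification.
#'
#' @param ascn_segments fitted segments (`total_cn`, `nA`, `nB`, ...).
#' @param psi tumor ploidy.
#' @param min_size minimum merged size in bp (strict; default 2 Mb).
#' @param cn_margin copies above ploidy required (default 3).
#' @return data frame of events with `kind = "broad"` and `monoallelic`.
#' @export
broad_amplified_events <- function(ascn_segments, psi, min_size = 2e6,
                                   cn_margin = 3) {
  seg <- ascn_segments
  qual <- !is.na(seg$total_cn) & seg$total_cn > psi + cn_margin
  if (!any(qual)) return(seg[0, c("chrom", "start", "end"), drop = FALSE])
  res <- list()
  for (ch in unique(seg$chrom[qual])) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    q <- !is.na(s$total_cn) & s$total_cn > psi + cn_margin
    r <- rle(q)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values)) {
      block <- s[starts[k]:ends[k], , drop = FALSE]
      w <- block$n_markers
      res[[length(res) + 1]] <- data.frame(
        chrom = ch, start = min(block$start), end = max(block$end),
        n_markers = sum(w),
        mean_logr = sum(w * block$mean_logr) / sum(w),
        nA = sum(w * block$nA) / sum(w),
        nB = sum(w * block$nB) / sum(w),
        total_cn = sum(w * block$total_cn) / sum(w),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  out <- out[seg_lengths(out) > min_size, , drop = FALSE]
  if (nrow(out)) {
    out$kind <- "broad"
    out$monoallelic <- classify_monoallelic(round(out$nA), round(out$nB), psi)
  }
  rownames(out) <- NULL
  out
}

#' Recurrent high-level amplicons across a cohort
#'
#' Builds per-probe coverage of amplification segments (centralized mean
#' logR strictly above `min_logr`) over the common grid, requires support
#' from at least `ceiling(min_fraction * n_samples)` samples, and reports
#' for each maximal supported run the minimal common overlap: the
#' sub-interval where coverage attains its maximum, intersected across the
#' supporting samples' segments. Coverage plateaus of equal height within
#' one run are reported separately.
#'
#' @param seg_list named list of per-sample centralized segment data frames.
#' @param genome the common [genome_model()].
#' @param min_logr amplification threshold on mean logR (strict; default 1).
#' @param min_fraction minimum fraction of samples (default 0.03).
#' @return data frame `chrom`, `start`, `end`, `n_supporting`, `samples`
#'   (comma-separated ids).
#' @export
recurrent_amplicons <- function(seg_list, genome, min_logr = 1,
                                min_fraction = 0.03) {
  if (!length(seg_list)) stop("empty cohort")
  ids <- names(seg_list)
  if (is.null(ids)) ids <- paste0("sample_", seq_along(seg_list))
  n <- length(seg_list)
  k <- ceiling(min_fraction * n)
  amp <- vapply(seg_list, function(s) {
    v <- to_grid(s, genome, "mean_logr")
    !is.na(v) & v > min_logr
  }, logical(nrow(genome$probes)))
  amp <- matrix(amp, nrow = nrow(genome$probes))
  cov <- rowSums(amp)
  half <- genome$probe_spacing / 2
  res <- list()
  for (ch in names(genome$chromosomes)) {
    idx <- which(genome$probes$chrom == ch)
    if (!length(idx)) next
    cv <- cov[idx]
    r <- rle(cv >= k & cv > 0)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (run in which(r$values)) {
      ri <- starts[run]:ends[run]
      m <- max(cv[ri])
      peak <- cv[ri] == m
      pr <- rle(peak)
      pends <- cumsum(pr$lengths)
      pstarts <- pends - pr$lengths + 1
      for (pl in which(pr$values)) {
        probes <- idx[ri[pstarts[pl]:pends[pl]]]
        support <- which(apply(amp[probes, , drop = FALSE], 2, all))
        # minimal overlap: intersect supporting samples' amp segments
        lo <- genome$probes$pos[probes[1]] - half + 1
        hi <- genome$probes$pos[probes[length(probes)]] + half
        for (s in support) {
          segs <- seg_list[[s]]
          segs <- segs[segs$chrom == ch & segs$mean_logr > min_logr, ,
                       drop = FALSE]
          csegs <- segs[segs$start <= genome$probes$pos[probes[1]] &
                          segs$end >= genome$probes$pos[probes[length(probes)]], ,
                        drop = FALSE]
          if (nrow(csegs)) {
            lo <- max(lo, min(csegs$start))
            hi <- min(hi, max(csegs$end))
          }
        }
        res[[length(res) + 1]] <- data.frame(
          chrom = ch, start = lo, end = hi,
          n_supporting = length(support),
          samples = paste(ids[support], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(res)) do.call(rbind, res)
         else data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), n_supporting = integer(0),
                         samples = character(0))
  rownames(out) <- NULL
  out
}
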