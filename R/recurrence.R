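#' Amplitude-weighted recurrence scores (G-scores)
#'
#' Per grid probe, the gain score is the sum over samples of the logR
#' excess above `gain_thr` (and symmetrically below `loss_thr` for losses).
#' Missing probes contribute 0.
#'
#' @param grid_matrix probes-by-samples matrix of centralized grid logR
#'   values (see [to_grid()]).
#' @param gain_thr,loss_thr score thresholds (defaults +0.12 / -0.12).
#' @return list with numeric vectors `gain` and `loss`.
#' @export
gscore <- function(grid_matrix, gain_thr = 0.12, loss_thr = -0.12) {
  m <- grid_matrix
  m[is.na(m)] <- 0
  list(gain = rowSums(pmax(m - gain_thr, 0)),
       loss = rowSums(pmax(loss_thr - m, 0)))
}

#' Permutation null distribution for G-scores
#'
#' Each permutation cyclically shifts every sample's per-probe contribution
#' vector by an independent random offset — preserving each sample's
#' within-genome segment structure while destroying cross-sample alignment —
#' and pools the resulting per-probe scores into one genome-wide null
#' distribution.
#'
#' @inheritParams gscore
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed.
#' @param direction `"gain"` or `"loss"`.
#' @return sorted numeric vector of null scores (length
#'   `n_perm * n_probes`).
#' @export
permutation_null <- function(grid_matrix, n_perm = 1000, seed = NULL,
                             gain_thr = 0.12, loss_thr = -0.12,
                             direction = c("gain", "loss")) {
  direction <- match.arg(direction)
  stopifnot(n_perm >= 100)
  m <- grid_matrix
  m[is.na(m)] <- 0
  contrib <- if (direction == "gain") pmax(m - gain_thr, 0)
             else pmax(loss_thr - m, 0)
  with_seed(seed, {
    null <- .gscore_perm_null(t(contrib), as.integer(n_perm))
    sort(null)
  })
}

#' Significantly recurrent regions with peel-off
#'
#' Per-probe empirical p-values (fraction of the pooled null at or above
#' the observed score) are corrected by Benjamini-Hochberg; contiguous
#' probes with q below `q_cut` form regions. After recording the top peak,
#' every sample's contribution within the peak region is removed, scores
#' and q-values are recomputed against the same null, and the procedure
#' iterates so that independent secondary peaks can surface.
#'
#' @inheritParams gscore
#' @param genome the common [genome_model()].
#' @param null sorted null scores from [permutation_null()].
#' @param direction `"gain"` or `"loss"`.
#' @param q_cut q-value cut-off (default 0.05).
#' @param max_peel maximum peel-off iterations per chromosome.
#' @return data frame `chrom`, `start`, `end`, `direction`, `peak_q`,
#'   `peak_score`, `n_samples`.
#' @export
significant_regions <- function(grid_matrix, genome, null,
                                direction = c("gain", "loss"),
                                gain_thr = 0.12, loss_thr = -0.12,
                                q_cut = 0.05, max_peel = 10) {
  direction <- match.arg(direction)
  m <- grid_matrix
  m[is.na(m)] <- 0
  contrib <- if (direction == "gain") pmax(m - gain_thr, 0)
             else pmax(loss_thr - m, 0)
  np <- nrow(contrib)
  stopifnot(np == nrow(genome$probes))
  half <- genome$probe_spacing / 2
  nn <- length(null)
  probe_q <- function(score) {
    # p = fraction of null >= observed (with +1 continuity)
    p <- (nn - findInterval(score - 1e-12, null) + 1) / (nn + 1)
    stats::p.adjust(p, method = "BH")
  }
  out <- list()
  iter_limit <- max_peel * length(genome$chromosomes)
  for (it in seq_len(iter_limit)) {
    score <- rowSums(contrib)
    q <- probe_q(score)
    sig <- q < q_cut & score > 0
    if (!any(sig)) break
    # regions = maximal runs of significant probes within a chromosome
    regions <- list()
    for (ch in names(genome$chromosomes)) {
      idx <- which(genome$probes$chrom == ch)
      if (!length(idx)) next
      r <- rle(sig[idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        probes <- idx[starts[k]:ends[k]]
        peak <- probes[which.max(score[probes])]
        regions[[length(regions) + 1]] <- list(
          chrom = ch, probes = probes,
          peak_q = min(q[probes]), peak_score = max(score[probes]),
          n_samples = sum(contrib[peak, ] > 0))
      }
    }
    top <- which.max(vapply(regions, `[[`, numeric(1), "peak_score"))
    rg <- regions[[top]]
    out[[length(out) + 1]] <- data.frame(
      chrom = rg$chrom,
      start = genome$probes$pos[rg$probes[1]] - half + 1,
      end = genome$probes$pos[rg$probes[length(rg$probes)]] + half,
      direction = direction, peak_q = rg$peak_q,
      peak_score = rg$peak_score, n_samples = rg$n_samples,
      stringsAsFactors = FALSE)
    # peel off: remove every sample's contribution inside the peak region
    contrib[rg$probes, ] <- 0
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), direction = character(0),
                         peak_q = numeric(0), peak_score = numeric(0),
                         n_samples = integer(0))
  rownames(res) <- NULL
  res
}
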