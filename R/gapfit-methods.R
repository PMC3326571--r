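#' @export
print.gap_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("GAP-style ASCN fit: degenerate (no detectable aberration); psi = 2\n")
  } else {
    cat(sprintf(
      "GAP-style ASCN fit: purity %.2f, ploidy %.2f, score %.3g, %d segments\n",
      x$purity, x$psi, x$fit_score, nrow(x$segments)))
  }
  invisible(x)
}

#' @export
coef.gap_fit <- function(object, ...) {
  c(purity = object$purity, ploidy = object$psi)
}

#' @export
summary.gap_fit <- function(object, ...) {
  seg <- object$segments
  lens <- seg_lengths(seg)
  tab <- table(factor(paste0("(", seg$nA, ",", seg$nB, ")")))
  out <- list(fit = object,
              genome_bp = sum(lens),
              n_segments = nrow(seg),
              state_table = tab)
  class(out) <- "summary.gap_fit"
  out
}

#' @export
print.summary.gap_fit <- function(x, ...) {
  print(x$fit)
  cat("Genome covered:", format(x$genome_bp, big.mark = ","), "bp in",
      x$n_segments, "segments\n")
  cat("ASCN states (nA,nB):\n")
  print(x$state_table)
  invisible(x)
}

#' Model-implied mBAF and logR for the fitted states
#'
#' The expected mBAF is the observable segment-level median, which includes
#' the upward fold bias mirroring imposes on near-balanced states (a
#' balanced state is observed near `0.5 + 0.675 sigma_baf`, not 0.5).
#'
#' @param object a [gap_fit()] object.
#' @param ... unused.
#' @return data frame with `expected_mbaf` and `expected_logr` per segment
#'   (`NA` where the allele split is unknown).
#' @export
predict.gap_fit <- function(object, ...) {
  seg <- object$segments
  p <- object$purity
  if (object$degenerate || is.na(p))
    return(data.frame(expected_mbaf = ifelse(seg$allele_unknown, NA, 0.5),
                      expected_logr = rep(0, nrow(seg))))
  em <- el <- rep(NA_real_, nrow(seg))
  known <- !seg$allele_unknown
  em[known] <- folded_mbaf(expected_mbaf(seg$nA[known], seg$nB[known], p),
                           object$sigma_baf)
  el <- log2(pmax(2 * (1 - p) + p * seg$total_cn, 1e-12)) -
    log2(2 * (1 - p) + p * object$psi) + object$baseline
  data.frame(expected_mbaf = em, expected_logr = el)
}

#' @export
residuals.gap_fit <- function(object, ...) {
  pr <- predict(object)
  data.frame(mbaf = object$segments$mean_mbaf - pr$expected_mbaf,
             logr = object$segments$mean_logr - pr$expected_logr)
}

#' Plot a fitted ASCN profile
#'
#' Scatter of per-segment mBAF against logR (point area proportional to
#' genome length), overlaid with the fitted lattice of allele-specific
#' copy-number states.
#'
#' @param x a [gap_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gap_fit <- function(x, ...) {
  seg <- x$segments
  graphics::plot(seg$mean_logr, seg$mean_mbaf,
                 cex = sqrt(seg_lengths(seg) / max(seg_lengths(seg))) * 3,
                 xlab = "segment mean logR", ylab = "segment mBAF",
                 ylim = c(0.45, 1.05), pch = 16,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  if (!x$degenerate && !is.na(x$purity)) {
    lat <- ascn_lattice(8)
    p <- x$purity
    keep <- !(lat$nA == 0 & lat$nB == 0 & p >= 1)
    lat <- lat[keep, ]
    lm_ <- expected_mbaf(lat$nA, lat$nB, p)
    ll <- log2(pmax(2 * (1 - p) + p * (lat$nA + lat$nB), 1e-12)) -
      log2(2 * (1 - p) + p * x$psi) + x$baseline
    graphics::points(ll, lm_, pch = 3, col = "red3")
    graphics::text(ll, lm_, labels = paste0(lat$nA, ",", lat$nB),
                   pos = 3, cex = 0.6, col = "red3")
  }
  invisible(x)
}

#' Simulate SNP-array samples from a fitted ASCN profile
#'
#' Draws new synthetic samples whose single aberrant clone carries the
#' fitted integer allele-specific copy numbers, at the fitted purity, using
#' the fit's own noise SD estimates. Useful for posterior-predictive style
#' checks of the fit.
#'
#' @param object a non-degenerate [gap_fit()] object.
#' @param nsim number of samples.
#' @param seed integer seed.
#' @param genome a [genome_model()] matching the fit's coordinates.
#' @param ... unused.
#' @return list of probe data frames.
#' @export
simulate.gap_fit <- function(object, nsim = 1, seed = NULL,
                             genome = default_genome(), ...) {
  if (object$degenerate || is.na(object$purity))
    stop("cannot simulate from a degenerate fit")
  seg <- object$segments
  seg$nA[seg$allele_unknown] <- seg$total_cn[seg$allele_unknown]
  seg$nB[seg$allele_unknown] <- 0L
  cl <- list(fraction = 1,
             segments = seg[, c("chrom", "start", "end", "nA", "nB")])
  lapply(seq_len(nsim), function(i) {
    simulate_tumor(object$purity, list(cl), genome,
                   sigma_logr = object$sigma_logr,
                   sigma_baf = object$sigma_baf,
                   seed = if (is.null(seed)) NULL else seed + i - 1,
                   sample_id = paste0("sim_from_fit_", i))$sample
  })
}
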