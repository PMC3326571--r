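#' Expected mirrored BAF of an ASCN state
#'
#' For a tumor with aberrant-cell fraction `p` in which the aberrant cells
#' carry `nA` copies of one parental allele and `nB` of the other, the
#' heterozygous-probe BAF is
#' `b = ((1 - p) + p nB) / (2 (1 - p) + p (nA + nB))` and the mirrored value
#' is `max(b, 1 - b)`.
#'
#' @param nA,nB major/minor allele copy numbers, `nA >= nB >= 0`.
#' @param p aberrant-cell fraction in (0, 1].
#' @return expected mBAF in \[0.5, 1\].
#' @examples
#' expected_mbaf(2, 0, 0.5)  # 0.75
#' @export
expected_mbaf <- function(nA, nB, p) {
  stopifnot(all(nA >= nB), all(nB >= 0), all(p > 0), all(p <= 1))
  denom <- 2 * (1 - p) + p * (nA + nB)
  if (any(denom <= 0))
    stop("state with no DNA (nA = nB = 0 at p = 1) has no defined BAF")
  b <- ((1 - p) + p * nB) / denom
  pmax(b, 1 - b)
}

#' Expected logR of an ASCN state
#'
#' `log2((2 (1 - p) + p (nA + nB)) / (2 (1 - p) + p psi))`: the log2 ratio of
#' the mixture's DNA content at the segment to the mixture's average content
#' for a tumor of ploidy `psi`.
#'
#' @inheritParams expected_mbaf
#' @param psi tumor ploidy (copies), > 0.
#' @return expected logR.
#' @examples
#' expected_logr(4, 0, 0.5, 2)  # log2(1.5)
#' @export
expected_logr <- function(nA, nB, p, psi) {
  stopifnot(all(psi > 0), all(nA >= nB), all(nB >= 0), all(p > 0), all(p <= 1))
  num <- 2 * (1 - p) + p * (nA + nB)
  den <- 2 * (1 - p) + p * psi
  if (any(den <= 0) || any(num < 0)) stop("invalid mixture DNA content")
  log2(pmax(num, 1e-12) / den)
}

# All (nA, nB) states with nA >= nB >= 0 and nA + nB <= max_total.
ascn_lattice <- function(max_total = 8) {
  g <- expand.grid(nA = 0:max_total, nB = 0:max_total)
  g <- g[g$nA >= g$nB & g$nA + g$nB <= max_total, ]
  rownames(g) <- NULL
  g
}

# Robust probe-level noise SD estimates from within-segment residuals.
# logR: pooled MAD about segment means. mBAF: per-segment MAD; mirroring
# folds the noise of balanced segments and deflates their MAD (to ~0.59
# sigma), while segments near the homozygote-exclusion boundary suffer
# truncation and homozygote leakage that inflate it. The maximum MAD over
# moderately imbalanced segments (median mBAF in [0.55, 0.85]), where the
# MAD is consistent for sigma, is therefore preferred; the maximum over
# all segments is the fallback.
estimate_noise <- function(segments, sample, hom_exclusion_band = 0.05) {
  mb <- mirror_baf(sample, hom_exclusion_band)
  rl <- numeric(0)
  mads <- meds <- numeric(0)
  for (i in seq_len(nrow(segments))) {
    sel <- sample$chrom == segments$chrom[i] &
      sample$pos >= segments$start[i] & sample$pos <= segments$end[i]
    if (sum(sel) >= 10)
      rl <- c(rl, sample$logR[sel] - mean(sample$logR[sel]))
    selb <- mb$chrom == segments$chrom[i] &
      mb$pos >= segments$start[i] & mb$pos <= segments$end[i]
    if (sum(selb) >= 30) {
      mads <- c(mads, stats::mad(mb$mbaf[selb]))
      meds <- c(meds, stats::median(mb$mbaf[selb]))
    }
  }
  mid <- mads[meds >= 0.55 & meds <= 0.85]
  sb <- if (length(mid)) max(mid) else if (length(mads)) max(mads) else 0.03
  list(sigma_logr = if (length(rl)) max(stats::mad(rl), 1e-3) else 0.15,
       sigma_baf = max(sb, 1e-3))
}

# Median of |N(d, 1)| via a cached root-solved lookup (linear beyond d = 6).
fold_env <- new.env(parent = emptyenv())
folded_median_factor <- function(d) {
  if (is.null(fold_env$tab)) {
    dg <- seq(0, 6, by = 0.05)
    mg <- vapply(dg, function(dd) stats::uniroot(function(m)
      stats::pnorm(m - dd) + stats::pnorm(m + dd) - 1.5,
      c(0, dd + 3))$root, numeric(1))
    fold_env$tab <- list(d = dg, m = mg)
  }
  out <- stats::approx(fold_env$tab$d, fold_env$tab$m,
                       xout = pmin(d, 6), rule = 2)$y
  ifelse(d > 6, d, out)
}

# Expected segment-level median of mirrored BAF for a state with clean
# heterozygous BAF deviation |b - 0.5|: mirroring folds the probe noise, so
# balanced states are observed near 0.5 + 0.675 sigma rather than 0.5.
folded_mbaf <- function(b_clean, sigma) {
  0.5 + sigma * folded_median_factor(abs(b_clean - 0.5) / sigma)
}

#' Fit aberrant-cell fraction, tumor ploidy and allele-specific copy numbers
#'
#' The central estimator of the package. Integrated segments (logR mean plus
#' mBAF median) are matched against the lattice of allele-specific
#' copy-number states `(nA, nB)` with `nA >= nB >= 0` and total at most
#' `max_total`. A grid search over the aberrant-cell fraction `p` and over
#' candidate diploid-logR baselines finds the combination whose nearest
#' lattice points minimize the length-weighted mean squared distance, with
#' the mBAF and logR axes scaled by their probe-level noise SDs. Lattice
#' mBAF levels carry the fold bias that mirroring imposes on segment
#' medians (a balanced state is observed near `0.5 + 0.675 sigma_baf`).
#' The tumor ploidy `psi` is the length-weighted mean of the assigned total
#' copy numbers. Solutions scaled by a whole-genome duplication describe
#' the data almost equally well, so near-tied candidates (within 1.5x of
#' the best score) are grouped by a closed-form ploidy proxy and resolved
#' toward the lowest ploidy class, then best score, then higher purity.
#'
#' A profile with no detectable aberration (every segment balanced at
#' logR ~ 0) cannot constrain `p`; such fits are returned with
#' `degenerate = TRUE`, `purity = NA` and `psi = 2`.
#'
#' @param segments integrated segments from [integrate_segments()] (columns
#'   `chrom`, `start`, `end`, `n_markers`, `mean_logr`, `mean_mbaf`).
#' @param sample optional probe data frame; when given, the noise SDs used
#'   for score scaling are estimated from within-segment residuals.
#' @param purity_grid candidate aberrant-cell fractions.
#' @param max_total cap on total copy number of lattice states.
#' @param sigma_logr,sigma_baf score-scaling SDs; override the estimates.
#' @param min_baf_segments,min_markers minimum informative segments and
#'   total marker support required to attempt a fit.
#' @param min_fit_markers segments with fewer markers (breakpoint slivers)
#'   are excluded from the grid-search score, though they still receive
#'   state assignments; protects the fit from high-leverage artifacts.
#' @return An object of class `"gap_fit"`: list with `purity`, `psi`,
#'   `baseline` (logR of the average-ploidy state), `fit_score`,
#'   `degenerate`, `sigma_logr`, `sigma_baf` and `segments` (the input plus
#'   `nA`, `nB`, `total_cn`, `cn_cont`, `allele_unknown`).
#' @seealso [assign_ascn()], [event_profile()], [gap_ploidy()]
#' @export
gap_fit <- function(segments, sample = NULL,
                    purity_grid = seq(0.10, 1.00, by = 0.01),
                    max_total = 8, sigma_logr = NULL, sigma_baf = NULL,
                    min_baf_segments = 3, min_markers = 100,
                    min_fit_markers = 20) {
  stopifnot(all(c("chrom", "start", "end", "n_markers", "mean_logr",
                  "mean_mbaf") %in% names(segments)))
  has_baf <- !is.na(segments$mean_mbaf)
  if (is.null(sigma_logr) || is.null(sigma_baf)) {
    est <- if (!is.null(sample)) estimate_noise(segments, sample)
           else list(sigma_logr = 0.15, sigma_baf = 0.03)
    if (is.null(sigma_logr)) sigma_logr <- est$sigma_logr
    if (is.null(sigma_baf)) sigma_baf <- est$sigma_baf
  }
  lens <- seg_lengths(segments)
  wts <- lens / sum(lens)

  # degenerate: nothing deviates from a balanced profile at logR 0
  if (all(segments$mean_mbaf[has_baf] < 0.5 + 3 * sigma_baf) &&
      all(abs(segments$mean_logr) < 3 * sigma_logr / sqrt(pmax(segments$n_markers, 1)) + 0.05)) {
    seg <- segments
    seg$nA <- 1L; seg$nB <- 1L; seg$total_cn <- 2L
    seg$cn_cont <- 2; seg$allele_unknown <- !has_baf
    fit <- list(purity = NA_real_, psi = 2, baseline = 0,
                fit_score = 0, degenerate = TRUE,
                sigma_logr = sigma_logr, sigma_baf = sigma_baf,
                segments = seg)
    class(fit) <- "gap_fit"
    return(fit)
  }
  if (sum(has_baf) < min_baf_segments)
    stop("need at least ", min_baf_segments, " segments with mBAF")
  if (sum(segments$n_markers) < min_markers)
    stop("need at least ", min_markers, " markers in total")

  lat <- ascn_lattice(max_total)
  fit_set <- segments$n_markers >= min_fit_markers
  if (sum(fit_set & has_baf) < min_baf_segments) fit_set <- rep(TRUE, nrow(segments))
  sfit <- segments[fit_set, , drop = FALSE]
  obs_l <- sfit$mean_logr
  obs_m <- sfit$mean_mbaf
  has_baf_fit <- !is.na(obs_m)
  nseg <- nrow(sfit)
  lens_fit <- seg_lengths(sfit)
  wfit <- lens_fit / sum(lens_fit)
  totals <- 0:max_total
  # baseline candidates come from the best-supported segments
  top <- order(-sfit$n_markers)[seq_len(min(12, nseg))]
  best <- list(score = Inf)
  cand <- list()
  tie_factor <- 1.5  # solutions within this score ratio count as near-ties
  for (p in purity_grid) {
    d_state <- 2 * (1 - p) + p * (lat$nA + lat$nB)
    b <- ((1 - p) + p * lat$nB) / d_state
    lat_m <- ifelse(d_state <= 0, NA_real_,
                    folded_mbaf(pmax(b, 1 - b), sigma_baf))
    lg <- log2(pmax(2 * (1 - p) + p * totals, 1e-12))
    betas <- unique(round((rep(obs_l[top], each = max_total + 1) -
                             rep(lg, length(top))) * 200) / 200)
    # mBAF distance per lattice state (beta-free part)
    dm <- outer(obs_m, lat_m, function(a, m) ((a - m) / sigma_baf)^2)
    dm[!has_baf_fit, ] <- 0      # logR-only segments
    dm[, is.na(lat_m)] <- Inf    # DNA-free state unusable when BAF present
    if (any(!has_baf_fit)) dm[!has_baf_fit, is.na(lat_m)] <- 0
    lat_l0 <- lg[lat$nA + lat$nB + 1]
    inv_sl2 <- 1 / sigma_logr^2
    nb <- length(betas)
    # rows index (segment, beta) pairs; one arg-min over states for all
    resid <- rep(obs_l, times = nb) - rep(betas, each = nseg)
    M <- dm[rep(seq_len(nseg), times = nb), , drop = FALSE] +
      outer(resid, lat_l0, "-")^2 * inv_sl2
    jmin <- max.col(-M, ties.method = "first")
    mins <- M[cbind(seq_along(jmin), jmin)]
    scores <- colSums(matrix(wfit * mins, nrow = nseg))
    # closed-form ploidy proxy: continuous CN implied by segment logR at
    # each (p, beta), clamped to the lattice range
    psi_prox <- colSums(matrix(wfit * pmin(pmax(
      (2^resid - 2 * (1 - p)) / p, 0), max_total), nrow = nseg))
    for (b in seq_len(nb)) {
      score <- scores[b]
      if (score < best$score) best <- list(score = score, p = p,
                                           beta = betas[b])
      if (score <= best$score * tie_factor + 1e-15)
        cand[[length(cand) + 1]] <- c(score = score, p = p, beta = betas[b],
                                      psi_proxy = psi_prox[b])
    }
  }
  # Near-tied solutions describe the data equally well (the whole-genome
  # duplication ambiguity: scaled states at purity p/(s - (s-1)p) reproduce
  # every segment position). Resolve toward the lowest ploidy class; within
  # a class keep the best-scoring candidate, then the highest purity.
  cm <- do.call(rbind, cand)
  cm <- cm[cm[, "score"] <= best$score * tie_factor + 1e-15, , drop = FALSE]
  psi_class <- round(cm[, "psi_proxy"] + 1e-9)
  ord <- order(psi_class, cm[, "score"], -cm[, "p"])
  pick <- as.list(cm[ord[1], ])
  seg0 <- assign_states(segments, pick$p, pick$beta, lat, max_total,
                        sigma_logr, sigma_baf)
  pick$psi <- sum(wts * seg0$total_cn)
  pick$segments <- seg0
  p <- pick$p; beta <- pick$beta; psi <- pick$psi
  baseline <- log2(2 * (1 - p) + p * psi) + beta
  seg <- pick$segments
  seg$cn_cont <- pmax(((2 * (1 - p) + p * psi) * 2^(seg$mean_logr - baseline) -
                         2 * (1 - p)) / p, 0)
  fit <- list(purity = p, psi = psi, baseline = baseline,
              fit_score = pick$score, degenerate = FALSE,
              sigma_logr = sigma_logr, sigma_baf = sigma_baf,
              segments = seg)
  class(fit) <- "gap_fit"
  fit
}

# nearest-lattice assignment at fixed purity and logR offset beta
assign_states <- function(segments, p, beta, lat, max_total,
                          sigma_logr, sigma_baf) {
  has_baf <- !is.na(segments$mean_mbaf)
  lat_m <- vapply(seq_len(nrow(lat)), function(i) {
    d <- 2 * (1 - p) + p * (lat$nA[i] + lat$nB[i])
    if (d <= 0) return(NA_real_)
    b <- ((1 - p) + p * lat$nB[i]) / d
    folded_mbaf(max(b, 1 - b), sigma_baf)
  }, numeric(1))
  lg <- log2(pmax(2 * (1 - p) + p * (0:max_total), 1e-12))
  lat_l <- lg[lat$nA + lat$nB + 1] + beta
  seg <- segments
  seg$nA <- seg$nB <- NA_integer_
  seg$total_cn <- NA_integer_
  for (i in seq_len(nrow(seg))) {
    dl <- ((seg$mean_logr[i] - lat_l) / sigma_logr)^2
    if (has_baf[i]) {
      dmb <- ((seg$mean_mbaf[i] - lat_m) / sigma_baf)^2
      dmb[is.na(lat_m)] <- Inf
      j <- which.min(dl + dmb)
      seg$nA[i] <- lat$nA[j]; seg$nB[i] <- lat$nB[j]
      seg$total_cn[i] <- lat$nA[j] + lat$nB[j]
    } else {
      # no allelic information: total copy number only
      tot <- unique(lat$nA + lat$nB)
      dl2 <- ((seg$mean_logr[i] - (lg[tot + 1] + beta)) / sigma_logr)^2
      seg$total_cn[i] <- tot[which.min(dl2)]
    }
  }
  seg$allele_unknown <- !has_baf
  seg
}

#' Assign allele-specific copy numbers at fixed purity and ploidy
#'
#' Maps each segment to its nearest lattice state given an already fitted
#' aberrant-cell fraction, ploidy and logR baseline, and computes the
#' continuous total copy number
#' `cn_cont = ((2(1-p) + p psi) 2^(mean_logr - baseline) - 2(1-p)) / p`
#' (floored at 0, reported uncapped). Integer totals are capped at
#' `max_total`; segments without mBAF get a total only, with the allele
#' split flagged unknown.
#'
#' @inheritParams gap_fit
#' @param p aberrant-cell fraction (> 0).
#' @param psi tumor ploidy.
#' @param baseline logR value at which a segment's DNA content equals the
#'   tumor average (0 for a perfectly centralized profile).
#' @return segments with `nA`, `nB`, `total_cn`, `cn_cont`, `allele_unknown`.
#' @export
assign_ascn <- function(segments, p, psi, baseline = 0, max_total = 8,
                        sigma_logr = 0.15, sigma_baf = 0.03) {
  if (p <= 0) stop("p must be > 0")
  beta <- baseline - log2(2 * (1 - p) + p * psi)
  seg <- assign_states(segments, p, beta, ascn_lattice(max_total), max_total,
                       sigma_logr, sigma_baf)
  seg$cn_cont <- pmax(((2 * (1 - p) + p * psi) * 2^(seg$mean_logr - baseline) -
                         2 * (1 - p)) / p, 0)
  seg
}

#' Length-weighted tumor ploidy of an ASCN profile
#'
#' @param ascn_segments data frame with `start`, `end` and `total_cn`.
#' @return length-weighted mean total copy number (copies).
#' @export
gap_ploidy <- function(ascn_segments) {
  stopifnot(nrow(ascn_segments) >= 1)
  lens <- seg_lengths(ascn_segments)
  if (sum(lens) <= 0) stop("segments cover no genome")
  sum(lens * ascn_segments$total_cn) / sum(lens)
}
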