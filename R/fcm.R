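#' DNA flow-cytometry ploidy from histogram peaks
#'
#' The experimental tumor ploidy is the sum over detected histogram peaks
#' of DNA index times the fraction of cells in the peak, scaled by 2 so
#' that a pure diploid population (DNA index 1.0) reads 2N.
#'
#' @param peaks data frame with `dna_index` (> 0) and `fraction`
#'   (non-negative, summing to 1 within 1e-6).
#' @return ploidy in N units.
#' @examples
#' fcm_ploidy(data.frame(dna_index = c(1, 1.5), fraction = c(0.4, 0.6)))  # 2.6
#' @export
fcm_ploidy <- function(peaks) {
  stopifnot(all(c("dna_index", "fraction") %in% names(peaks)),
            all(peaks$dna_index > 0), all(peaks$fraction >= 0))
  if (abs(sum(peaks$fraction) - 1) > 1e-6)
    stop("peak fractions must sum to 1 (got ", sum(peaks$fraction), ")")
  2 * sum(peaks$dna_index * peaks$fraction)
}

#' Epanechnikov kernel density of ploidy estimates
#'
#' Fixed-bandwidth kernel density with K(u) = 0.75 (1 - u^2) on |u| <= 1;
#' `density(x) = 1/(n h) sum K((x - v_i)/h)` where `h` is the kernel
#' half-width on the ploidy (N-unit) axis.
#'
#' @param values numeric ploidy estimates (>= 1 value).
#' @param bandwidth kernel half-width (default 0.08 N).
#' @param grid evaluation grid; defaults to 512 points spanning the data
#'   plus one bandwidth on each side.
#' @return data frame `x`, `density`.
#' @export
epanechnikov_density <- function(values, bandwidth = 0.08, grid = NULL) {
  stopifnot(length(values) >= 1, bandwidth > 0)
  if (is.null(grid))
    grid <- seq(min(values) - bandwidth, max(values) + bandwidth,
                length.out = 512)
  d <- vapply(grid, function(g) {
    u <- (g - values) / bandwidth
    sum(0.75 * pmax(0, 1 - u^2)) / (length(values) * bandwidth)
  }, numeric(1))
  data.frame(x = grid, density = d)
}

#' Count local maxima of a density curve
#'
#' Helper for describing modality of smoothed ploidy distributions: a grid
#' point is a mode when its density exceeds both neighbours and is at
#' least `min_height` times the global maximum.
#'
#' @param dens data frame from [epanechnikov_density()].
#' @param min_height relative height floor for a countable mode.
#' @return integer number of modes.
#' @export
count_modes <- function(dens, min_height = 0.05) {
  d <- dens$density
  n <- length(d)
  if (n < 3) return(as.integer(any(d > 0)))
  is_peak <- d[2:(n - 1)] > d[1:(n - 2)] & d[2:(n - 1)] >= d[3:n] &
    d[2:(n - 1)] >= min_height * max(d)
  sum(is_peak)
}

#' Read a flow-cytometry peak table
#'
#' Tab-separated columns `sample`, `dna_index`, `fraction`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_fcm_peaks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "dna_index", "fraction")
  if (!all(need %in% names(df)))
    stop("peak table must have columns ", paste(need, collapse = ", "))
  df
}
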