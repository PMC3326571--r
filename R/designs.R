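#' Reference tumor designs by ploidy class
#'
#' Fixed allele-specific copy-number layouts on the default 150 Mb genome,
#' one per ploidy class, each carrying at least eight distinct ASCN states.
#' These are the package's validation conditions: diploid-like through
#' tetraploid-like genomes whose true ploidy is the length-weighted mean of
#' the laid-out states.
#'
#' @param class one of `"2.0"`, `"2.6"`, `"3.2"`, `"4.0"` (approximate
#'   target ploidy).
#' @return list with `background` (length-2 ASCN state) and `events`
#'   (data frame `chrom`, `start`, `end`, `nA`, `nB`).
#' @export
tumor_design_layout <- function(class = c("2.0", "2.6", "3.2", "4.0")) {
  class <- match.arg(class)
  ev <- function(...) {
    m <- matrix(c(...), ncol = 4, byrow = TRUE)
    data.frame(chrom = paste0("chr", m[, 1]),
               start = m[, 2] * 1e6 + 1, end = m[, 3] * 1e6,
               nA = m[, 4] %/% 10, nB = m[, 4] %% 10)
  }
  switch(class,
    "2.0" = list(background = c(1L, 1L), events = ev(
      1, 0, 12, 21,   1, 20, 28, 20,   1, 40, 46, 10,
      2, 5, 9, 31,    2, 25, 29, 22,   2, 40, 45, 10,
      3, 5, 10, 30,   3, 20, 20.9, 0, 3, 30, 36, 21)),
    "2.6" = list(background = c(1L, 1L), events = ev(
      1, 0, 25, 21,   1, 40, 48, 20,   1, 50, 50.9, 0,
      2, 0, 25, 21,   2, 30, 36, 31,   2, 42, 46, 10,
      3, 0, 15, 22,   3, 25, 30, 32,   3, 34, 36, 10)),
    "3.2" = list(background = c(2L, 1L), events = ev(
      1, 0, 15, 22,   1, 25, 33, 31,   1, 40, 50, 30,
      2, 0, 6, 42,    2, 20, 26, 11,   2, 35, 40, 32,
      3, 5, 10, 33,   3, 18, 26, 10,   3, 30, 35, 20)),
    "4.0" = list(background = c(2L, 2L), events = ev(
      1, 0, 12, 32,   1, 20, 30, 42,   1, 40, 45, 21,
      2, 0, 10, 40,   2, 20, 27, 33,   2, 35, 40, 20,
      3, 5, 12, 31,   3, 20, 23, 52,   3, 30, 33, 11)))
}

#' Validation cohort of simulated tumors
#'
#' Builds the standard validation cohort: for each ploidy class, one tumor
#' per requested purity, using the fixed layouts of
#' [tumor_design_layout()]. With the defaults this gives 20 tumors with
#' purities spanning 0.3-0.9 and ploidies from near-diploid to
#' near-tetraploid.
#'
#' @param purities aberrant-cell fractions used within each ploidy class.
#' @param classes ploidy classes to include.
#' @param genome the [genome_model()] the layouts are defined on.
#' @return list of designs: each has `id`, `class`, `purity`, `clones`.
#' @export
tumor_designs <- function(purities = c(0.3, 0.45, 0.6, 0.75, 0.9),
                          classes = c("2.0", "2.6", "3.2", "4.0"),
                          genome = default_genome()) {
  out <- list()
  for (cl in classes) {
    lay <- tumor_design_layout(cl)
    for (p in purities) {
      out[[length(out) + 1]] <- list(
        id = sprintf("psi%s_p%02.0f", gsub("\\.", "", cl), 100 * p),
        class = cl, purity = p,
        clones = list(clone_spec(1, lay$events, genome,
                                 background = lay$background)))
    }
  }
  out
}

#' Two-clone design for subclonal copy-number-loss validation
#'
#' A near-triploid tumor (background state (2,1)) on a compact genome with
#' two engineered loss regions: region A, a clonal two-copy-neutral-LOH
#' loss (2,0) present in all aberrant cells, and region B where the main
#' clone carries (2,0) and a subclone of the given prevalence additionally
#' deletes both remaining copies (0,0). Increasing prevalence widens the
#' continuous-CN and logR gaps between the two loss regions, which is
#' exactly the signature the four-rule subclonality detector looks for.
#'
#' The design also carries a clonal high-level gain (5,1): besides being a
#' realistic feature of these tumors, its doubled state would exceed the
#' copy-number cap of the lattice, which anchors the fit on the correct
#' ploidy scale even when the subclonal mixture region falls between
#' integer states.
#'
#' @param prevalence subclone fraction of the aberrant cells, in \[0, 0.5\];
#'   0 gives the purely clonal control design.
#' @param purity aberrant-cell fraction.
#' @param genome genome model; default one 22 Mb chromosome at 10 kb
#'   spacing (loss regions of 300 markers).
#' @return list with `purity`, `clones`, `genome` and the true region
#'   intervals.
#' @export
subclonal_design <- function(prevalence = 0.4, purity = 0.8,
                             genome = genome_model(c(chr1 = 22e6), 1e4)) {
  stopifnot(prevalence >= 0, prevalence <= 0.5)
  regA <- data.frame(chrom = "chr1", start = 2e6 + 1, end = 5e6,
                     nA = 2L, nB = 0L)
  regB <- data.frame(chrom = "chr1", start = 9e6 + 1, end = 12e6,
                     nA = 2L, nB = 0L)
  regC <- data.frame(chrom = "chr1", start = 15e6 + 1, end = 18e6,
                     nA = 5L, nB = 1L)
  main_ev <- rbind(regA, regB, regC)
  if (prevalence == 0) {
    clones <- list(clone_spec(1, main_ev, genome, background = c(2L, 1L)))
  } else {
    sub_ev <- rbind(regA, transform(regB, nA = 0L, nB = 0L), regC)
    clones <- list(
      clone_spec(1 - prevalence, main_ev, genome, background = c(2L, 1L)),
      clone_spec(prevalence, sub_ev, genome, background = c(2L, 1L)))
  }
  list(purity = purity, clones = clones, genome = genome,
       region_a = regA, region_b = regB, region_c = regC)
}
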