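# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. With seed = NULL the global stream is used as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify one tumor clone
#'
#' A clone is a fraction of the aberrant-cell population together with a
#' complete allele-specific copy-number (ASCN) profile. The profile starts
#' from a constant background state (default the heterozygous diploid
#' `(1,1)`) and overlays `events`, so segments always tile the genome.
#'
#' @param fraction proportion of aberrant cells belonging to this clone,
#'   in (0, 1].
#' @param events `NULL` or a data frame `chrom`, `start`, `end`, `nA`, `nB`
#'   of ASCN events; must not overlap each other.
#' @param genome a [genome_model()].
#' @param background length-2 integer vector `(nA, nB)` used outside events.
#' @return list with `fraction` and a tiling `segments` data frame.
#' @export
clone_spec <- function(fraction, events = NULL, genome = default_genome(),
                       background = c(1L, 1L)) {
  stopifnot(fraction > 0, fraction <= 1, length(background) == 2,
            background[1] >= background[2], background[2] >= 0)
  segs <- list()
  for (ch in names(genome$chromosomes)) {
    len <- genome$chromosomes[[ch]]
    ev <- if (is.null(events)) NULL else events[events$chrom == ch, , drop = FALSE]
    if (is.null(ev) || nrow(ev) == 0) {
      segs[[ch]] <- data.frame(chrom = ch, start = 1, end = len,
                               nA = background[1], nB = background[2])
      next
    }
    ev <- ev[order(ev$start), , drop = FALSE]
    if (any(ev$nA < ev$nB) || any(ev$nB < 0))
      stop("clone events must satisfy nA >= nB >= 0")
    if (nrow(ev) > 1 && any(ev$start[-1] <= ev$end[-nrow(ev)]))
      stop("overlapping clone events on ", ch)
    if (ev$start[1] < 1 || ev$end[nrow(ev)] > len)
      stop("clone event outside chromosome ", ch)
    bounds <- c(1, as.vector(rbind(ev$start, ev$end + 1)), len + 1)
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1] - 1
    nA <- rep(background[1], length(starts))
    nB <- rep(background[2], length(starts))
    ev_at <- seq(2, length(starts), by = 2)
    nA[ev_at] <- ev$nA
    nB[ev_at] <- ev$nB
    keep <- starts <= ends
    segs[[ch]] <- data.frame(chrom = ch, start = starts[keep], end = ends[keep],
                             nA = nA[keep], nB = nB[keep])
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  list(fraction = fraction, segments = out)
}

#' Simulate a SNP-array tumor profile with known truth
#'
#' Generates per-probe logR and BAF for a tumor that is a mixture of normal
#' diploid cells (fraction `1 - purity`) and one or more aberrant clones.
#' For a heterozygous probe the noiseless BAF is
#' \deqn{b = \frac{(1-p) + p \sum_c f_c nB_c}{2(1-p) + p \sum_c f_c (nA_c + nB_c)}}
#' and the noiseless logR is
#' \deqn{\log_2 \frac{2(1-p) + p \sum_c f_c (nA_c + nB_c)}{2(1-p) + p\,\psi}}
#' where \eqn{\psi} is the true length-weighted mean total copy number over
#' clones (the in-silico tumor ploidy of the aberrant cells), so the
#' reference level of logR is the sample's own average DNA content.
#' Homozygous probes emit BAF near 0 or 1; heterozygous BAF is randomly
#' phase-flipped about 0.5 (mirroring removes this downstream). Gaussian
#' noise with the configured SDs is added, BAF truncated to \[0, 1\].
#'
#' @param purity aberrant-cell fraction p in (0, 1].
#' @param clones list of [clone_spec()] objects; fractions must sum to 1.
#' @param genome a [genome_model()].
#' @param sigma_logr,sigma_baf Gaussian noise SDs (>= 0).
#' @param het_fraction probability that a probe is a germline heterozygote.
#' @param seed integer seed; identical inputs give bit-identical output.
#' @param phase_flip randomly swap which parental allele is "B" per probe
#'   (default `TRUE`; set `FALSE` to observe the unmirrored closed form).
#' @param sample_id character label attached to the sample.
#' @return list with `sample` (data frame `chrom`, `pos`, `logR`, `BAF`) and
#'   `truth` (class `"sim_truth"`): per-probe total CN, mixture nB, het flag,
#'   the true ploidy `psi` and the input configuration.
#' @examples
#' gm <- genome_model(c(chr1 = 2e6), 1e4)
#' sim <- simulate_tumor(1, list(clone_spec(1, genome = gm)), gm,
#'                       sigma_logr = 0, sigma_baf = 0, seed = 1)
#' all(sim$sample$logR == 0)
#' @export
simulate_tumor <- function(purity, clones, genome = default_genome(),
                           sigma_logr = 0.15, sigma_baf = 0.03,
                           het_fraction = 1/3, seed = NULL,
                           phase_flip = TRUE, sample_id = "sim") {
  stopifnot(purity > 0, purity <= 1, sigma_logr >= 0, sigma_baf >= 0,
            het_fraction >= 0, het_fraction <= 1, length(clones) >= 1)
  fr <- vapply(clones, function(cl) cl$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8)
    stop("clone fractions must sum to 1 (got ", sum(fr), ")")
  np <- nrow(genome$probes)
  t_mix <- numeric(np)
  nb_mix <- numeric(np)
  for (cl in clones) {
    nA <- to_grid(cl$segments, genome, "nA")
    nB <- to_grid(cl$segments, genome, "nB")
    if (anyNA(nA) || anyNA(nB))
      stop("clone segments must tile every chromosome of the genome")
    t_mix <- t_mix + cl$fraction * (nA + nB)
    nb_mix <- nb_mix + cl$fraction * nB
  }
  psi <- mean(t_mix)  # uniform probe spacing => length-weighted
  p <- purity
  dna <- 2 * (1 - p) + p * t_mix
  dref <- 2 * (1 - p) + p * psi
  logr0 <- log2(pmax(dna, 1e-4) / dref)
  with_seed(seed, {
    het <- stats::runif(np) < het_fraction
    baf0 <- numeric(np)
    ok <- dna > 0
    baf0[het & ok] <- ((1 - p) + p * nb_mix[het & ok]) / dna[het & ok]
    if (phase_flip) {
      flip <- het & ok & stats::runif(np) < 0.5
      baf0[flip] <- 1 - baf0[flip]
    }
    baf0[!het] <- as.numeric(stats::runif(sum(!het)) < 0.5)
    baf <- baf0 + stats::rnorm(np, 0, sigma_baf)
    baf <- pmin(pmax(baf, 0), 1)
    baf[het & !ok] <- NA_real_
    logr <- logr0 + stats::rnorm(np, 0, sigma_logr)
    smp <- data.frame(chrom = genome$probes$chrom, pos = genome$probes$pos,
                      logR = logr, BAF = baf, stringsAsFactors = FALSE)
    attr(smp, "sample_id") <- sample_id
    truth <- structure(list(
      probe_truth = data.frame(chrom = smp$chrom, pos = smp$pos,
                               total_cn = t_mix, nB_mix = nb_mix, het = het),
      psi = psi, purity = p, clones = clones, genome = genome,
      sigma_logr = sigma_logr, sigma_baf = sigma_baf,
      het_fraction = het_fraction, seed = seed), class = "sim_truth")
    list(sample = smp, truth = truth)
  })
}

#' True in-silico tumor ploidy of a simulated sample
#'
#' Length-weighted mean, over the genome, of the clone-fraction-weighted
#' total copy number within the aberrant cells.
#'
#' @param truth a `"sim_truth"` object from [simulate_tumor()].
#' @return ploidy in copies.
#' @export
true_gap_ploidy <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  if (nrow(truth$probe_truth) == 0) stop("empty truth")
  mean(truth$probe_truth$total_cn)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("Simulated tumor: purity %.2f, true ploidy %.3f, %d clone(s), %d probes\n",
              x$purity, x$psi, length(x$clones), nrow(x$probe_truth)))
  invisible(x)
}

#' Write / read a probe table
#'
#' Tab-separated text with columns `chrom`, `pos`, `logR`, `BAF`; gzip is
#' used automatically for paths ending in `.gz`.
#'
#' @param sample probe data frame as returned by [simulate_tumor()].
#' @param path file path.
#' @return `read_probe_table` returns the probe data frame.
#' @export
write_probe_table <- function(sample, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(sample, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_table
#' @export
read_probe_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "logR", "BAF")
  if (!all(need %in% names(df)))
    stop("probe table must have columns ", paste(need, collapse = ", "))
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  df
}
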