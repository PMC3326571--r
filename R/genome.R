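#' Define a genome model
#'
#' A genome model is the coordinate system the whole pipeline works in: a set
#' of chromosomes with lengths, and virtual SNP probes at a fixed spacing.
#' Probe positions are the interval centers of a regular tiling, so probe
#' `i` on a chromosome sits at `(i - 1) * spacing + spacing/2` (1-based
#' coordinates, inclusive).
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param probe_spacing distance in bp between consecutive probes.
#' @return An object of class `"genome_model"`: a list with `chromosomes`,
#'   `probe_spacing` and a `probes` data frame (`chrom`, `pos`).
#' @examples
#' gm <- genome_model(c(chr1 = 1e6), probe_spacing = 1e4)
#' head(gm$probes)
#' @export
genome_model <- function(chromosomes, probe_spacing = 10000) {
  stopifnot(is.numeric(chromosomes), length(chromosomes) >= 1,
            all(chromosomes > 0), probe_spacing > 0)
  if (is.null(names(chromosomes)) || anyDuplicated(names(chromosomes)))
    stop("chromosomes must be a uniquely named vector of lengths")
  probes <- do.call(rbind, lapply(names(chromosomes), function(ch) {
    n <- floor(chromosomes[[ch]] / probe_spacing)
    if (n < 1) stop("chromosome ", ch, " shorter than one probe spacing")
    data.frame(chrom = ch,
               pos = as.numeric((seq_len(n) - 1) * probe_spacing + probe_spacing / 2),
               stringsAsFactors = FALSE)
  }))
  structure(list(chromosomes = chromosomes,
                 probe_spacing = probe_spacing,
                 probes = probes),
            class = "genome_model")
}

#' Default synthetic genome
#'
#' Three autosome-like chromosomes of 60, 50 and 40 Mb with probes every
#' 10,000 bp (the common grid spacing used throughout).
#'
#' @return A [genome_model()].
#' @export
default_genome <- function() {
  genome_model(c(chr1 = 60e6, chr2 = 50e6, chr3 = 40e6), probe_spacing = 10000)
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Genome model:", length(x$chromosomes), "chromosomes,",
      format(sum(x$chromosomes), big.mark = ","), "bp,",
      nrow(x$probes), "probes at", x$probe_spacing, "bp spacing\n")
  invisible(x)
}

#' Size of a 1-based inclusive genomic interval
#'
#' @param start,end 1-based inclusive interval bounds (vectors recycle).
#' @return `end - start + 1`, in bp.
#' @examples
#' interval_size(35087594, 35146597)  # 59004
#' @export
interval_size <- function(start, end) {
  if (any(start > end)) stop("start must be <= end")
  end - start + 1
}

#' Map segments onto the common probe grid
#'
#' Each virtual grid probe takes the value of the segment whose interval
#' contains the probe's center coordinate; probes covered by no segment are
#' `NA`. Segments must be non-overlapping within a chromosome.
#'
#' @param segments data frame with `chrom`, `start`, `end` and a value column.
#' @param genome a [genome_model()] defining the grid.
#' @param value name of the value column to transfer (default `"mean_logr"`).
#' @return numeric vector parallel to `genome$probes`.
#' @export
to_grid <- function(segments, genome, value = "mean_logr") {
  stopifnot(inherits(genome, "genome_model"),
            all(c("chrom", "start", "end", value) %in% names(segments)))
  out <- rep(NA_real_, nrow(genome$probes))
  for (ch in unique(segments$chrom)) {
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      stop("overlapping segments on ", ch)
    idx <- which(genome$probes$chrom == ch)
    if (!length(idx)) next
    centers <- genome$probes$pos[idx]
    j <- findInterval(centers, seg$start)
    hit <- j >= 1 & centers <= seg$end[pmax(j, 1)]
    out[idx[hit]] <- seg[[value]][j[hit]]
  }
  out
}

#' Reconstruct segments from grid values
#'
#' Collapses maximal constant runs of per-probe grid values back into
#' segments (the approximate inverse of [to_grid()]). `NA` runs are dropped.
#'
#' @param values numeric vector parallel to `genome$probes`.
#' @param genome a [genome_model()].
#' @return data frame `chrom`, `start`, `end`, `n_markers`, `value`.
#' @export
from_grid <- function(values, genome) {
  stopifnot(length(values) == nrow(genome$probes))
  half <- genome$probe_spacing / 2
  res <- list()
  for (ch in names(genome$chromosomes)) {
    idx <- which(genome$probes$chrom == ch)
    if (!length(idx)) next
    v <- values[idx]
    key <- ifelse(is.na(v), "NA", format(v, digits = 15))
    r <- rle(key)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != "NA"
    if (!any(keep)) next
    pos <- genome$probes$pos[idx]
    res[[ch]] <- data.frame(
      chrom = ch,
      start = pos[starts[keep]] - half + 1,
      end = pos[ends[keep]] + half,
      n_markers = r$lengths[keep],
      value = v[starts[keep]],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# length in bp of segment rows (1-based inclusive)
seg_lengths <- function(segments) interval_size(segments$start, segments$end)
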