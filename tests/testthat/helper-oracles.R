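# Brute-force oracles and random-input generators shared across test files.
# Oracles are written as plain double loops, independent of the package's
# vectorized implementations.

# random non-overlapping segment partition of one chromosome of `n_probes`
# grid probes; returns a data frame with bp intervals aligned to the grid
random_partition <- function(n_probes, max_segs = 6, chrom = "chr1",
                             spacing = 1e4) {
  k <- sample.int(max_segs, 1)
  cuts <- sort(sample.int(n_probes - 1, min(k - 1, n_probes - 1)))
  starts_i <- c(1, cuts + 1)
  ends_i <- c(cuts, n_probes)
  data.frame(chrom = chrom,
             start = (starts_i - 1) * spacing + 1,
             end = ends_i * spacing,
             n_markers = ends_i - starts_i + 1)
}

# per-probe event indicator by direct scan over segments (oracle)
oracle_probe_event <- function(segments, flags, genome) {
  out <- logical(nrow(genome$probes))
  for (i in seq_len(nrow(genome$probes))) {
    ch <- genome$probes$chrom[i]; p <- genome$probes$pos[i]
    for (j in seq_len(nrow(segments))) {
      if (segments$chrom[j] == ch && segments$start[j] <= p &&
          segments$end[j] >= p) {
        out[i] <- isTRUE(flags[j])
        break
      }
    }
  }
  out
}

# oracle cohort frequency: loop over samples and probes
oracle_frequency <- function(profiles, flag_fun, genome) {
  mat <- sapply(profiles, function(pr)
    oracle_probe_event(pr, flag_fun(pr), genome))
  rowMeans(mat)
}

# random event profile on a small genome: partition plus random calls
random_profile <- function(genome, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  segs <- do.call(rbind, lapply(names(genome$chromosomes), function(ch) {
    n <- sum(genome$probes$chrom == ch)
    random_partition(n, max_segs = 5, chrom = ch,
                     spacing = genome$probe_spacing)
  }))
  segs$call <- sample(c("gain", "loss", "neutral"), nrow(segs), replace = TRUE)
  segs$loh <- segs$call != "gain" & stats::runif(nrow(segs)) < 0.3
  segs$cnnai <- segs$call == "neutral" & stats::runif(nrow(segs)) < 0.3
  segs$mean_logr <- stats::rnorm(nrow(segs), 0, 0.4)
  segs
}

# cohort of passenger-only logR segment profiles for recurrence tests
passenger_cohort <- function(n_samples, genome, spike = NULL,
                             spike_fraction = 0, sd_level = 0.25) {
  n <- sum(genome$probes$chrom == names(genome$chromosomes)[1])
  spiked <- seq_len(floor(spike_fraction * n_samples))
  lapply(seq_len(n_samples), function(s) {
    segs <- random_partition(n, max_segs = 8, chrom = names(genome$chromosomes)[1],
                             spacing = genome$probe_spacing)
    segs$mean_logr <- stats::rnorm(nrow(segs), 0, sd_level)
    if (!is.null(spike) && s %in% spiked) {
      segs <- rbind(segs[0, ],
                    clip_partition(segs, spike$start, spike$end, spike$logr))
    }
    segs
  })
}

# overlay a spike interval onto a partition, splitting flanking segments
clip_partition <- function(segs, s0, e0, level) {
  out <- list()
  for (j in seq_len(nrow(segs))) {
    a <- segs$start[j]; b <- segs$end[j]
    if (b < s0 || a > e0) {
      out[[length(out) + 1]] <- segs[j, ]
    } else {
      if (a < s0) { r <- segs[j, ]; r$end <- s0 - 1; out[[length(out) + 1]] <- r }
      if (b > e0) { r <- segs[j, ]; r$start <- e0 + 1; out[[length(out) + 1]] <- r }
    }
  }
  spike_row <- segs[1, ]
  spike_row$start <- s0; spike_row$end <- e0; spike_row$mean_logr <- level
  out[[length(out) + 1]] <- spike_row
  res <- do.call(rbind, out)
  res$n_markers <- pmax(1L, as.integer((res$end - res$start + 1) / 1e4))
  res[order(res$start), ]
}

# run the full per-sample analysis on a simulated design (helper used by
# subclonality and qualitative tests)
analyze_design <- function(design, seed) {
  sim <- simulate_tumor(design$purity, design$clones, design$genome,
                        seed = seed)
  analyze_sample(sim$sample, seed = seed + 1L)
}
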