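test_that("focal amplicons require strict size and amplitude", {
  segs <- data.frame(chrom = "chr1",
                     start = c(1, 100001, 300001),
                     end = c(49000, 180000, 420000),
                     mean_logr = c(1.2, 0.7, 0.9))
  out <- focal_amplicons(segs)
  expect_equal(nrow(out), 1)            # 49 kb too small; 0.7 not > 0.7
  expect_equal(out$start, 300001)
  expect_equal(out$kind, "focal")
})

test_that("a simulated high-level amplicon carries its expected mBAF", {
  gm <- genome_model(c(chr1 = 20e6), 1e4)
  ev <- data.frame(chrom = "chr1", start = 10e6 + 1, end = 10.12e6,
                   nA = 6, nB = 1)
  sim <- simulate_tumor(0.8, list(clone_spec(1, ev, gm)), gm, seed = 15)
  a <- analyze_sample(sim$sample, seed = 16)
  foc <- focal_amplicons(a$segments)
  expect_gte(nrow(foc), 1)
  expect_lt(abs(foc$mean_mbaf[1] - expected_mbaf(6, 1, 0.8)), 0.05)
})

test_that("monoallelic amplification needs one quiet parental allele", {
  expect_true(classify_monoallelic(6, 1, 2))
  expect_false(classify_monoallelic(4, 3, 2))
  expect_true(is.na(classify_monoallelic(NA, NA, 2)))
  expect_true(classify_monoallelic(5, 1, 2.58))
  expect_false(classify_monoallelic(5, 3, 2.58))  # minor allele amplified too
})

test_that("broad events apply the ploidy-relative threshold strictly", {
  mk <- function(total, len_mb, nA = total, nB = 0) {
    ends <- cumsum(len_mb) * 1e6
    data.frame(chrom = "chr1", start = c(1, utils::head(ends, -1) + 1),
               end = ends, n_markers = len_mb * 100,
               mean_logr = 0.5, nA = nA, nB = nB, total_cn = total)
  }
  # psi = 2.58: inclusion needs total CN > 5.58
  segs <- mk(c(2, 6, 2), c(5, 3, 5))
  out <- broad_amplified_events(segs, 2.58)
  expect_equal(nrow(out), 1)
  expect_equal(out$total_cn, 6)
  # boundary: CN 5 at psi 2 is not > 5
  expect_equal(nrow(broad_amplified_events(mk(c(2, 5, 2), c(5, 3, 5)), 2)), 0)
  # merging of adjacent qualifying segments; monoallelic classification
  segs2 <- mk(c(2, 7, 7, 2), c(5, 2, 2, 5), nA = c(1, 6, 6, 1),
              nB = c(1, 1, 1, 1))
  out2 <- broad_amplified_events(segs2, 2)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$end - out2$start + 1, 4e6)
  expect_true(out2$monoallelic)
  # size strictly above 2 Mb
  segs3 <- mk(c(2, 7, 2), c(5, 2, 5))
  expect_equal(nrow(broad_amplified_events(segs3, 2)), 0)
})

test_that("recurrent amplicons report the minimal common overlap", {
  gm <- genome_model(c(chr1 = 40e6), 1e4)
  seg <- function(s, e) data.frame(chrom = "chr1", start = s * 1e6 + 1,
                                   end = e * 1e6, mean_logr = 1.5)
  cohort <- list(a = seg(10, 20), b = seg(15, 30), c = seg(18, 25))
  out <- recurrent_amplicons(cohort, gm, min_fraction = 2 / 3)
  expect_equal(nrow(out), 1)
  expect_equal(out$n_supporting, 3)
  expect_equal(out$start, 18e6 + 1)
  expect_equal(out$end, 20e6)
  # the support threshold is a ceiling of samples
  expect_equal(ceiling(0.03 * 218), 7)
  # single sample: every amplification is its own region
  solo <- recurrent_amplicons(list(a = seg(5, 8)), gm, min_fraction = 0.03)
  expect_equal(nrow(solo), 1)
  expect_equal(c(solo$start, solo$end), c(5e6 + 1, 8e6))
  expect_error(recurrent_amplicons(list(), gm), "empty")
})

test_that("recurrent amplicons agree with a per-probe coverage oracle", {
  gm <- genome_model(c(chr1 = 1e6), 1e4)
  set.seed(30)
  for (r in 1:100) {
    n <- sample(3:8, 1)
    cohort <- lapply(seq_len(n), function(i) {
      s <- random_partition(100, max_segs = 10)
      s$mean_logr <- stats::rnorm(nrow(s), 0.4, 0.6)
      s
    })
    names(cohort) <- paste0("s", seq_len(n))
    k <- ceiling(0.4 * n)
    out <- recurrent_amplicons(cohort, gm, min_logr = 1, min_fraction = 0.4)
    # oracle: per-probe coverage scan
    cov <- integer(100)
    amp_mat <- matrix(FALSE, 100, n)
    for (i in 1:100) {
      p <- gm$probes$pos[i]
      for (s in seq_len(n)) {
        segs <- cohort[[s]]
        for (j in seq_len(nrow(segs))) {
          if (segs$start[j] <= p && segs$end[j] >= p &&
              segs$mean_logr[j] > 1) {
            amp_mat[i, s] <- TRUE
            break
          }
        }
      }
      cov[i] <- sum(amp_mat[i, ])
    }
    # each reported interval: all its probes are at a local max with
    # coverage >= k, and every supporting sample covers the interval
    for (j in seq_len(nrow(out))) {
      probes <- which(gm$probes$pos >= out$start[j] &
                        gm$probes$pos <= out$end[j])
      expect_true(all(cov[probes] >= k))
      ids <- strsplit(out$samples[j], ",")[[1]]
      for (id in ids)
        expect_true(all(amp_mat[probes, match(id, names(cohort))]))
      expect_equal(length(ids), out$n_supporting[j])
    }
    # counts match: number of plateau runs in the oracle equals regions
    runs <- rle(cov >= k & cov > 0)
    n_regions_oracle <- 0
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1
    for (q in which(runs$values)) {
      m <- max(cov[idx_start[q]:idx_end[q]])
      peak <- rle(cov[idx_start[q]:idx_end[q]] == m)
      n_regions_oracle <- n_regions_oracle + sum(peak$values)
    }
    expect_equal(nrow(out), n_regions_oracle)
  }
})
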