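make_profile <- function(vals, spacing = 1e4, chrom = "chr1") {
  data.frame(chrom = chrom,
             pos = (seq_along(vals) - 1) * spacing + spacing / 2,
             logR = vals, BAF = NA_real_)
}

test_that("constant profiles give one segment per chromosome", {
  s <- rbind(make_profile(rep(0.2, 300)),
             make_profile(rep(-0.1, 200), chrom = "chr2"))
  seg <- segment_logr(s, seed = 1)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_markers, c(300, 200))
  expect_equal(seg$mean_logr, c(0.2, -0.1))
})

test_that("a noiseless step is cut at the exact probe", {
  s <- make_profile(c(rep(0, 500), rep(0.585, 500)))
  seg <- segment_logr(s, seed = 2)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$n_markers, c(500, 500))
  expect_equal(seg$mean_logr, c(0, 0.585))
})

test_that("noisy steps are recovered within a few probes", {
  set.seed(33)
  hits <- vapply(1:100, function(r) {
    x <- c(stats::rnorm(200, 0, 0.15), stats::rnorm(200, 0.4, 0.15))
    seg <- segment_logr(make_profile(x))
    k <- which.min(abs(seg$n_markers[1] - 200))
    nrow(seg) >= 2 && abs(seg$n_markers[1] - 200) <= 5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("BAF mirroring reflects about 0.5 and drops homozygotes", {
  s <- data.frame(chrom = "chr1", pos = c(1e4, 2e4, 3e4, 4e4),
                  logR = 0, BAF = c(0.3, 0.5, 0.98, 0.05))
  mb <- mirror_baf(s, hom_exclusion_band = 0.05)
  expect_equal(mb$mbaf, c(0.7, 0.5, 0.95))  # 0.98 excluded, 0.05 kept (band edge)
  expect_true(all(mb$mbaf >= 0.5 & mb$mbaf <= 1))
  allhom <- data.frame(chrom = "chr1", pos = c(1e4, 2e4), logR = 0,
                       BAF = c(0.99, 0.01))
  expect_warning(out <- mirror_baf(allhom), "homozygous")
  expect_equal(nrow(out), 0)
})

test_that("mBAF segmentation finds level changes and uses medians", {
  flat <- data.frame(chrom = "chr1", pos = (1:100) * 1e4, mbaf = 0.5)
  seg <- segment_baf(flat, seed = 3)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$mean_mbaf, 0.5)
  step <- data.frame(chrom = "chr1", pos = (1:200) * 1e4,
                     mbaf = c(rep(0.5, 100), rep(0.75, 100)))
  seg2 <- segment_baf(step, seed = 4)
  expect_equal(seg2$n_het_markers, c(100, 100))
  expect_equal(seg2$mean_mbaf, c(0.5, 0.75))
})

test_that("simulated CNN-LOH levels are estimated accurately", {
  gm <- genome_model(c(chr1 = 20e6), 1e4)
  ev <- data.frame(chrom = "chr1", start = 8e6 + 1, end = 14e6, nA = 2, nB = 0)
  sim <- simulate_tumor(0.5, list(clone_spec(1, ev, gm)), gm,
                        sigma_logr = 0.15, sigma_baf = 0.03, seed = 7)
  mb <- mirror_baf(sim$sample)
  seg <- segment_baf(mb, seed = 8)
  lvl <- seg$mean_mbaf[which.max(seg$mean_mbaf)]
  expect_lt(abs(lvl - 0.75), 0.02)
})

test_that("integration unions breakpoints and recomputes statistics", {
  gm <- genome_model(c(chr1 = 1e6), 1e4)
  sim <- simulate_tumor(1, list(clone_spec(1, genome = gm)), gm, seed = 9)
  mk <- function(cuts_bp) {
    b <- c(1, cuts_bp + 1)
    e <- c(cuts_bp, 1e6)
    data.frame(chrom = "chr1", start = b, end = e)
  }
  lseg <- mk(50e4); lseg$n_markers <- c(50, 50); lseg$mean_logr <- 0
  bseg <- mk(c(30e4, 70e4)); bseg$n_het_markers <- 1; bseg$mean_mbaf <- 0.5
  out <- integrate_segments(lseg, bseg, sim$sample)
  expect_equal(out$start, c(1, 30e4 + 1, 50e4 + 1, 70e4 + 1))
  expect_equal(sum(out$n_markers), 100)
  # identical partitions pass through unchanged
  out2 <- integrate_segments(lseg, transform(lseg, n_het_markers = 1,
                                             mean_mbaf = 0.5), sim$sample)
  expect_equal(out2$start, lseg$start)
  expect_error(integrate_segments(lseg, transform(bseg, chrom = "chrX"),
                                  sim$sample), "different chromosomes")
})

test_that("integration refines both inputs on random partitions", {
  gm <- genome_model(c(chr1 = 1e6), 1e4)
  sim <- simulate_tumor(1, list(clone_spec(1, genome = gm)), gm, seed = 10)
  set.seed(11)
  for (r in 1:100) {
    a <- random_partition(100)
    b <- random_partition(100)
    a$n_markers <- a$n_markers; a$mean_logr <- 0
    b$n_het_markers <- 1; b$mean_mbaf <- 0.5
    out <- integrate_segments(a, b, sim$sample)
    union_starts <- sort(unique(c(a$start, b$start)))
    expect_equal(out$start, union_starts)   # brute-force breakpoint union
    expect_equal(sum(out$n_markers), 100)   # marker conservation
  }
})

test_that("centralization shifts the dominant level to zero", {
  segs <- data.frame(chrom = "chr1", start = c(1, 70e6 + 1),
                     end = c(70e6, 100e6),
                     n_markers = c(7000, 3000), mean_logr = c(0.2, 0.8))
  out <- centralize(segs)
  expect_lt(abs(out$mean_logr[1]), 1e-9)   # 70% of genome maps to 0
  expect_equal(attr(out, "shift"), 0.2)
  # shift invariance on a grid-aligned offset
  segs2 <- transform(segs, mean_logr = mean_logr + 0.3)
  out2 <- centralize(segs2)
  expect_equal(out2$mean_logr, out$mean_logr, tolerance = 1e-9)
  # an already centered profile is unchanged
  segs3 <- data.frame(chrom = "chr1", start = 1, end = 1e6,
                      n_markers = 100, mean_logr = 0)
  expect_lt(abs(centralize(segs3)$mean_logr), 1e-6)
})

test_that("mirrored values stay in range across random simulations", {
  gm <- genome_model(c(chr1 = 5e6), 1e4)
  for (seed in 1:10) {
    ev <- data.frame(chrom = "chr1", start = 1, end = 2e6,
                     nA = sample(0:4, 1), nB = 0)
    sim <- simulate_tumor(stats::runif(1, 0.3, 1),
                          list(clone_spec(1, ev, gm)), gm, seed = seed)
    mb <- mirror_baf(sim$sample)
    expect_true(all(mb$mbaf >= 0.5 & mb$mbaf <= 1))
  }
})
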