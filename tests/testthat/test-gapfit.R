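# analytic integrated-segment table for a given state layout (no noise)
clean_segments <- function(states, lengths_mb, p, psi, n_markers = NULL) {
  if (is.null(n_markers)) n_markers <- lengths_mb * 100
  ends <- cumsum(lengths_mb) * 1e6
  starts <- c(1, utils::head(ends, -1) + 1)
  data.frame(chrom = "chr1", start = starts, end = ends,
             n_markers = n_markers,
             n_het_markers = pmax(1, round(n_markers / 3)),
             mean_logr = vapply(seq_len(nrow(states)), function(i)
               expected_logr(states$nA[i], states$nB[i], p, psi), numeric(1)),
             mean_mbaf = vapply(seq_len(nrow(states)), function(i)
               expected_mbaf(states$nA[i], states$nB[i], p), numeric(1)))
}

test_that("closed-form mBAF and logR match hand calculations", {
  expect_equal(expected_mbaf(1, 1, 0.3), 0.5)
  expect_equal(expected_mbaf(2, 0, 1.0), 1.0)
  expect_equal(expected_mbaf(2, 0, 0.5), 0.75)
  expect_equal(expected_logr(1, 1, 0.7, 2), 0)
  expect_equal(expected_logr(2, 0, 1.0, 2), 0)
  expect_equal(expected_logr(4, 0, 0.5, 2), log2(1.5))
  expect_error(expected_mbaf(0, 0, 1), "no DNA")
  expect_error(expected_logr(1, 1, 0.5, 0), "psi")
})

test_that("state assignment inverts the forward model on the whole lattice", {
  lat <- ascnpipe:::ascn_lattice(8)
  for (p in c(0.3, 0.5, 0.7, 0.9, 1)) {
    use <- lat[!(lat$nA == 0 & lat$nB == 0 & p == 1), ]
    psi <- 2
    segs <- clean_segments(use, rep(1, nrow(use)), p, psi)
    out <- assign_ascn(segs, p, psi, 0, sigma_logr = 1e-3, sigma_baf = 1e-3)
    expect_equal(out$nA, use$nA)
    expect_equal(out$nB, use$nB)
  }
})

test_that("the worked inverse example lands on CNN-LOH", {
  seg <- data.frame(chrom = "chr1", start = 1, end = 1e6, n_markers = 100,
                    mean_logr = 0, mean_mbaf = 0.75)
  out <- assign_ascn(seg, 0.5, 2, 0, sigma_baf = 1e-3)
  expect_equal(c(out$nA, out$nB), c(2, 0))
  expect_equal(out$cn_cont, 2)
  bal <- assign_ascn(transform(seg, mean_mbaf = 0.5), 0.5, 2, 0,
                     sigma_baf = 1e-3)
  expect_equal(c(bal$nA, bal$nB), c(1, 1))
})

test_that("totals are capped at eight while cn_cont is reported uncapped", {
  # logR implying ~11 copies in a pure sample
  seg <- data.frame(chrom = "chr1", start = 1, end = 1e6, n_markers = 100,
                    mean_logr = log2(11 / 2), mean_mbaf = 1)
  out <- assign_ascn(seg, 1, 2, 0)
  expect_equal(out$total_cn, 8)
  expect_gt(out$cn_cont, 10.5)
})

test_that("the fit recovers a noiseless mixed diploid profile exactly", {
  states <- data.frame(nA = c(1, 2, 1, 1), nB = c(1, 0, 0, 1))
  psi <- (40 * 2 + 10 * 2 + 10 * 1 + 40 * 2) / 100
  segs <- clean_segments(states, c(40, 10, 10, 40), 0.6, psi)
  segs <- centralize(segs)
  fit <- gap_fit(segs, sigma_logr = 0.02, sigma_baf = 1e-3)
  expect_equal(fit$purity, 0.6)
  expect_lt(abs(fit$psi - psi), 0.05)
  expect_equal(fit$segments$nA, states$nA)
  expect_equal(fit$segments$nB, states$nB)
})

test_that("a pure normal profile is flagged degenerate", {
  states <- data.frame(nA = c(1, 1), nB = c(1, 1))
  segs <- clean_segments(states, c(50, 50), 0.5, 2)
  fit <- gap_fit(segs)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$purity))
  expect_equal(fit$psi, 2)
})

test_that("genome-doubled ambiguity resolves to the lower ploidy", {
  # all states doubled at p = 0.6: indistinguishable from the halved
  # profile at p = 0.75; the tie-break must take the lower-ploidy reading
  states <- data.frame(nA = c(2, 4, 2, 2), nB = c(2, 0, 0, 2))
  psi <- (40 * 4 + 10 * 4 + 10 * 2 + 40 * 4) / 100
  segs <- clean_segments(states, c(40, 10, 10, 40), 0.6, psi)
  segs <- centralize(segs)
  fit <- gap_fit(segs, sigma_logr = 0.02, sigma_baf = 1e-3)
  expect_lt(fit$psi, 3)
})

test_that("ploidy is the length-weighted mean of assigned totals", {
  states <- data.frame(nA = c(1, 2, 2), nB = c(1, 1, 0))
  segs <- clean_segments(states, c(40, 40, 20), 0.8, 2.4)
  fit <- gap_fit(segs, sigma_logr = 0.02, sigma_baf = 1e-3)
  lens <- segs$end - segs$start + 1
  expect_lt(abs(fit$psi - sum(lens * fit$segments$total_cn) / sum(lens)),
            1e-6)
  expect_equal(gap_ploidy(fit$segments), fit$psi)
  # hand-computed ploidies
  g <- data.frame(chrom = "c", start = c(1, 60e6 + 1), end = c(60e6, 100e6),
                  total_cn = c(2, 3))
  expect_equal(gap_ploidy(g), 2.4)
  g2 <- data.frame(chrom = "c", start = c(1, 50e6 + 1), end = c(50e6, 100e6),
                   total_cn = c(2, 3))
  expect_equal(gap_ploidy(g2), 2.5)
})

test_that("purity and ploidy are recovered end to end per ploidy class", {
  gm <- default_genome()
  for (cl in c("2.0", "2.6", "3.2", "4.0")) {
    d <- tumor_designs(purities = 0.55, classes = cl)[[1]]
    sim <- simulate_tumor(d$purity, d$clones, gm, seed = 300 + match(cl,
      c("2.0", "2.6", "3.2", "4.0")), sample_id = d$id)
    a <- analyze_sample(sim$sample, seed = 400)
    expect_lt(abs(a$fit$purity - d$purity), 0.05)
    expect_lt(abs(a$fit$psi - sim$truth$psi), 0.15)
  }
})

test_that("fit methods expose coherent summaries", {
  states <- data.frame(nA = c(1, 2, 2), nB = c(1, 0, 1))
  psi <- (50 * 2 + 25 * 2 + 25 * 3) / 100
  segs <- clean_segments(states, c(50, 25, 25), 0.7, psi)
  segs <- centralize(segs)
  fit <- gap_fit(segs, sigma_logr = 0.02, sigma_baf = 1e-3)
  expect_equal(unname(coef(fit)), c(0.7, fit$psi))
  pr <- predict(fit)
  expect_equal(nrow(pr), 3)
  res <- residuals(fit)
  expect_true(all(abs(res$logr) < 0.05))
  expect_output(print(fit), "purity 0.70")
  expect_output(print(summary(fit)), "ASCN states")
})
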