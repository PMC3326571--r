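#' Call gain/loss relative to tumor ploidy
#'
#' The neutral baseline is the integer state nearest the tumor ploidy,
#' `B = max(round(psi), 1)`: a segment is a gain when its total copy number
#' exceeds B and a loss when below. Segments with unknown integer total
#' (no allelic information and no integer assignment) are called from
#' `cn_cont` with a +/- 0.5 band around B and flagged.
#'
#' @param ascn segments with `total_cn` (and `cn_cont` for the fallback).
#' @param psi tumor ploidy.
#' @return character vector in `{"gain","loss","neutral"}` with attribute
#'   `"flagged"` marking calls made from `cn_cont`.
#' @export
call_gain_loss <- function(ascn, psi) {
  stopifnot(!is.null(psi), psi > 0)
  B <- max(round(psi), 1)
  tot <- ascn$total_cn
  calls <- rep("neutral", nrow(ascn))
  flagged <- logical(nrow(ascn))
  known <- !is.na(tot)
  calls[known & tot > B] <- "gain"
  calls[known & tot < B] <- "loss"
  if (any(!known)) {
    cc <- ascn$cn_cont[!known]
    calls[!known][cc > B + 0.5] <- "gain"
    calls[!known][cc < B - 0.5] <- "loss"
    flagged[!known] <- TRUE
  }
  attr(calls, "flagged") <- flagged
  calls
}

#' Call loss of heterozygosity
#'
#' LOH requires a lost minor allele (`nB = 0`) with at least one remaining
#' copy, and is never inferred on segments called gain.
#'
#' @param ascn segments with `nA`, `nB`.
#' @param calls gain/loss/neutral calls from [call_gain_loss()].
#' @return logical vector (`NA` where the allele split is unknown).
#' @export
call_loh <- function(ascn, calls) {
  out <- ascn$nB == 0 & ascn$nA >= 1 & calls != "gain"
  out[is.na(ascn$nB)] <- NA
  out
}

#' Call copy-number neutral allelic imbalance
#'
#' CNN-AI: unequal parental-allele copies at a total dosage neutral
#' relative to the tumor ploidy.
#'
#' @inheritParams call_loh
#' @return logical vector (`NA` where the allele split is unknown).
#' @export
call_cnnai <- function(ascn, calls) {
  out <- ascn$nA != ascn$nB & calls == "neutral"
  out[is.na(ascn$nB)] <- NA
  out
}

#' Per-segment event profile of a fitted sample
#'
#' Convenience wrapper running [call_gain_loss()], [call_loh()] and
#' [call_cnnai()] on a [gap_fit()].
#'
#' @param fit a `gap_fit` object.
#' @return the fit's segments with `call`, `loh`, `cnnai` columns.
#' @export
event_profile <- function(fit) {
  stopifnot(inherits(fit, "gap_fit"))
  seg <- fit$segments
  seg$call <- as.character(call_gain_loss(seg, fit$psi))
  seg$loh <- call_loh(seg, seg$call)
  seg$cnnai <- call_cnnai(seg, seg$call)
  seg
}

#' Fraction of genome altered
#'
#' `cn_fga` is the fraction of the genome called gain or loss; `loh_fga`
#' and `cnn_fga` are the fractions flagged LOH and CNN-AI. Segments with
#' unknown allele split contribute to `cn_fga` only.
#'
#' @param profile segments with `call`, `loh`, `cnnai` ([event_profile()]).
#' @param genome_length total genome length in bp (default: sum of segment
#'   lengths).
#' @return named numeric vector `cn_fga`, `loh_fga`, `cnn_fga`.
#' @export
fga <- function(profile, genome_length = sum(seg_lengths(profile))) {
  if (genome_length <= 0) stop("genome length must be > 0")
  lens <- seg_lengths(profile)
  c(cn_fga = sum(lens[profile$call %in% c("gain", "loss")]) / genome_length,
    loh_fga = sum(lens[profile$loh %in% TRUE]) / genome_length,
    cnn_fga = sum(lens[profile$cnnai %in% TRUE]) / genome_length)
}

# map each sample's event indicator onto the grid
event_grid <- function(profiles, genome, event) {
  vapply(profiles, function(pr) {
    ind <- switch(event,
                  gain = as.numeric(pr$call == "gain"),
                  loss = as.numeric(pr$call == "loss"),
                  loh = as.numeric(pr$loh %in% TRUE),
                  cnnai = as.numeric(pr$cnnai %in% TRUE),
                  loss_or_cnnai = as.numeric(pr$call == "loss" | pr$cnnai %in% TRUE),
                  stop("unknown event class ", event))
    pr$.ind <- ind
    to_grid(pr, genome, ".ind")
  }, numeric(nrow(genome$probes)))
}

#' Cohort event-frequency track
#'
#' Per grid probe, the fraction of samples whose covering segment carries
#' the event. Probes not covered in a sample count as event-free for it.
#'
#' @param profiles list of per-sample [event_profile()] data frames, all on
#'   the same genome.
#' @param genome the common [genome_model()].
#' @param event one of `"gain"`, `"loss"`, `"loh"`, `"cnnai"`,
#'   `"loss_or_cnnai"`.
#' @return data frame `chrom`, `pos`, `frequency`.
#' @export
cohort_frequency <- function(profiles, genome, event = "loss") {
  stopifnot(length(profiles) >= 1)
  g <- event_grid(profiles, genome, event)
  g[is.na(g)] <- 0
  data.frame(chrom = genome$probes$chrom, pos = genome$probes$pos,
             frequency = rowMeans(g))
}

#' Combined loss / CNN-AI frequency track
#'
#' Per probe, the fraction of samples locally showing loss of at least one
#' allele: copy-number loss or copy-number-neutral allelic imbalance.
#'
#' @inheritParams cohort_frequency
#' @return data frame `chrom`, `pos`, `frequency`.
#' @export
combined_loss_cnnai_frequency <- function(profiles, genome) {
  cohort_frequency(profiles, genome, "loss_or_cnnai")
}

#' Threshold-based gain/loss frequency tracks
#'
#' Calls gain where a centralized segment mean logR exceeds `gain_thr` and
#' loss where it falls below `loss_thr` (both strict), then counts the
#' fraction of samples per grid probe.
#'
#' @param seg_list list of per-sample centralized segment data frames with
#'   `mean_logr`.
#' @param genome the common [genome_model()].
#' @param gain_thr,loss_thr logR thresholds (defaults +0.12 / -0.12).
#' @return list of two frequency data frames, `gain` and `loss`.
#' @export
logr_threshold_frequency <- function(seg_list, genome,
                                     gain_thr = 0.12, loss_thr = -0.12) {
  gg <- vapply(seg_list, function(s) {
    v <- to_grid(s, genome, "mean_logr")
    as.numeric(!is.na(v) & v > gain_thr)
  }, numeric(nrow(genome$probes)))
  ll <- vapply(seg_list, function(s) {
    v <- to_grid(s, genome, "mean_logr")
    as.numeric(!is.na(v) & v < loss_thr)
  }, numeric(nrow(genome$probes)))
  base <- genome$probes
  list(gain = data.frame(chrom = base$chrom, pos = base$pos,
                         frequency = rowMeans(gg)),
       loss = data.frame(chrom = base$chrom, pos = base$pos,
                         frequency = rowMeans(ll)))
}
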