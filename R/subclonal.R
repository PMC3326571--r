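#' Detect subclonal copy-number loss in one sample
#'
#' A conservative four-rule detector operating on loss regions only:
#' \enumerate{
#'   \item restrict to segments called loss relative to the tumor ploidy;
#'   \item keep losses whose continuous copy number (`cn_cont`) differs by
#'     at least `min_cn_gap` from that of at least one other loss segment;
#'   \item filter to segments with partitioned logR below `logr_thr` and
#'     more than `min_markers` markers;
#'   \item declare subclonal loss when the partitioned logR of the
#'     remaining segments with the highest and lowest `cn_cont` differ by
#'     more than `min_logr_gap` in absolute value.
#' }
#' A mixture of cells with and without a deletion produces intermediate,
#' non-integer copy numbers; two loss regions at clearly different
#' continuous levels that also differ in raw logR are the detector's
#' evidence of such a mixture.
#'
#' @param profile segments with `call`, `cn_cont`, `mean_logr`, `n_markers`
#'   (see [event_profile()]).
#' @param min_cn_gap rule-2 continuous-CN gap (default 0.6).
#' @param logr_thr rule-3 logR ceiling for losses (default -0.12).
#' @param min_markers rule-3 marker support (strictly more; default 100).
#' @param min_logr_gap rule-4 logR gap between the extreme-CN members
#'   (default 0.2).
#' @return list with `is_subclonal` and `evidence` (the qualifying loss
#'   segments, empty when not subclonal).
#' @export
detect_subclonal_loss <- function(profile, min_cn_gap = 0.6,
                                  logr_thr = -0.12, min_markers = 100,
                                  min_logr_gap = 0.2) {
  stopifnot(all(c("call", "cn_cont", "mean_logr", "n_markers") %in%
                  names(profile)))
  loss <- profile[profile$call == "loss", , drop = FALSE]
  none <- list(is_subclonal = FALSE, evidence = loss[0, , drop = FALSE])
  if (nrow(loss) < 2) return(none)
  gap_ok <- vapply(seq_len(nrow(loss)), function(i)
    any(abs(loss$cn_cont[-i] - loss$cn_cont[i]) >= min_cn_gap), logical(1))
  set <- loss[gap_ok, , drop = FALSE]
  set <- set[set$mean_logr < logr_thr & set$n_markers > min_markers, ,
             drop = FALSE]
  if (nrow(set) < 2) return(none)
  hi <- which.max(set$cn_cont)
  lo <- which.min(set$cn_cont)
  is_sub <- abs(set$mean_logr[hi] - set$mean_logr[lo]) > min_logr_gap
  list(is_subclonal = is_sub,
       evidence = if (is_sub) set else set[0, , drop = FALSE])
}

#' Tabulate subclonal-loss calls over a cohort
#'
#' @param profiles named list of per-sample [event_profile()] data frames.
#' @param ... passed to [detect_subclonal_loss()].
#' @return data frame `sample`, `is_subclonal`, `n_evidence_segments`,
#'   `cn_cont_min`, `cn_cont_max`, `logr_min`, `logr_max`.
#' @export
subclonal_table <- function(profiles, ...) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("sample_", seq_along(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    call <- detect_subclonal_loss(profiles[[i]], ...)
    ev <- call$evidence
    data.frame(sample = ids[i], is_subclonal = call$is_subclonal,
               n_evidence_segments = nrow(ev),
               cn_cont_min = if (nrow(ev)) min(ev$cn_cont) else NA_real_,
               cn_cont_max = if (nrow(ev)) max(ev$cn_cont) else NA_real_,
               logr_min = if (nrow(ev)) min(ev$mean_logr) else NA_real_,
               logr_max = if (nrow(ev)) max(ev$mean_logr) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
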