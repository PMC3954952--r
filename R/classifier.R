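#' Fit a single-probe decision stump
#'
#' Chooses the threshold among the midpoints between consecutive sorted
#' unique pooled values (plus `-Inf`/`+Inf`) and the direction
#' (`old-above`: values above the threshold are classified old;
#' `old-below`: the reverse) minimizing the misclassified fraction. Ties
#' are broken deterministically: lowest threshold first, then `old-above`.
#' When all values are identical the stump degenerates to the majority
#' rule, with error equal to the minority group fraction.
#'
#' @param values_young,values_old numeric values (>= 1 each).
#' @return list with `threshold`, `direction`, `training_error`.
#' @export
fit_stump <- function(values_young, values_old) {
  stopifnot(length(values_young) >= 1, length(values_old) >= 1)
  x <- c(values_young, values_old)
  old <- c(rep(FALSE, length(values_young)), rep(TRUE, length(values_old)))
  .stump_fit_cpp(x, old)
}

#' Leave-one-out misclassification of a stump
#'
#' Each sample is held out in turn, the stump is refit on the remainder and
#' the held-out value classified; the returned rate is the fraction
#' misclassified.
#'
#' @param values_young,values_old numeric values (>= 2 each).
#' @return misclassified fraction in `[0, 1]`.
#' @export
loocv_error <- function(values_young, values_old) {
  stopifnot(length(values_young) >= 2, length(values_old) >= 2)
  x <- c(values_young, values_old)
  old <- c(rep(FALSE, length(values_young)), rep(TRUE, length(values_old)))
  .stump_loocv_cpp(x, old)
}

#' Screen every probe as a one-variable age classifier
#'
#' Fits a decision stump to each probe, estimates its misclassification by
#' leave-one-out cross-validation, and flags: universal separators (the two
#' groups' raw value ranges do not overlap at all — every old sample above
#' every young one, or the inverse) and high-probability predictors
#' (cross-validated error at or below `high_prob_bound`). Probes are ranked
#' by cross-validated error, then training error, then decreasing `|t|`.
#'
#' @param betas probes x samples beta matrix (probe ids as rownames).
#' @param samples sample sheet (`sample_id`, `group`) or group vector.
#' @param high_prob_bound cross-validated error bound for the
#'   high-probability flag (default 0.05, about 2 of 48 samples).
#' @param scale classify on `"m"` (logit, default) or `"beta"` values. The
#'   logit is monotone, so training errors and separation flags are
#'   identical on either scale; cross-validated errors can differ slightly
#'   because midpoint thresholds are not equivariant under a nonlinear
#'   transform.
#' @return data frame of class `classifier_report`: `probe_id`,
#'   `threshold`, `direction`, `training_error`, `cv_error`, `t`,
#'   `is_universal`, `is_high_probability`, `rank`; `summary` attribute
#'   with the flag counts.
#' @export
screen_probes <- function(betas, samples, high_prob_bound = 0.05,
                          scale = c("m", "beta")) {
  scale <- match.arg(scale)
  group <- if (is.data.frame(samples)) {
    stopifnot(all(samples$sample_id == colnames(betas)))
    samples$group
  } else as.character(samples)
  stopifnot(length(group) == ncol(betas), all(group %in% c("young", "old")))
  old <- group == "old"
  m <- if (scale == "m") beta_to_m(betas) else betas
  res <- .stump_screen_cpp(m, old)
  t_stat <- row_welch(m, old)$t
  out <- data.frame(probe_id = rownames(betas), res, t = t_stat,
                    stringsAsFactors = FALSE)
  out$is_high_probability <- out$cv_error <= high_prob_bound
  out$rank <- order(order(out$cv_error, out$training_error, -abs(out$t)))
  attr(out, "summary") <- list(
    n_probes = nrow(out),
    n_universal = sum(out$is_universal),
    n_high_probability = sum(out$is_high_probability),
    high_prob_bound = high_prob_bound, scale = scale)
  class(out) <- c("classifier_report", "data.frame")
  out
}

#' @export
print.classifier_report <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "probe classifier screen: %d probes; %d universal separators; %d high-probability (LOOCV error <= %g, %s scale)\n",
    s$n_probes, s$n_universal, s$n_high_probability, s$high_prob_bound,
    s$scale))
  NextMethod()
}
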