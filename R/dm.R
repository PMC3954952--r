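#' Convert beta values to M-values and back
#'
#' `M = log2(beta / (1 - beta))`, the variance-stabilized log-odds scale.
#' Betas are clipped to `[eps, 1 - eps]` before the logit so the transform
#' stays finite; values outside `[0, 1]` are an error.
#'
#' @param beta numeric vector/matrix of proportions in `[0, 1]`.
#' @param eps clipping bound (default `1e-6`).
#' @return M-values with the same shape.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta values must lie in [0, 1]")
  b <- pmin(pmax(beta, eps), 1 - eps)
  out <- log2(b / (1 - b))
  if (is.matrix(beta)) dim(out) <- dim(beta)
  dimnames(out) <- dimnames(beta)
  out
}

#' @rdname beta_to_m
#' @param m M-values.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

# Vectorized Welch two-sample t over matrix rows; t is signed old - young.
# Degenerate rows (zero variance in both groups): equal means -> t = 0,
# p = 1; unequal means -> t = +/-Inf, p = 0, flagged.
row_welch <- function(m, old) {
  stopifnot(is.matrix(m), length(old) == ncol(m), is.logical(old))
  n1 <- sum(!old); n2 <- sum(old)
  stopifnot(n1 >= 2, n2 >= 2)
  x1 <- m[, !old, drop = FALSE]; x2 <- m[, old, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    eq <- degenerate & (m2 == m1)
    t[eq] <- 0; p[eq] <- 1
    ne <- degenerate & (m2 != m1)
    t[ne] <- sign(m2[ne] - m1[ne]) * Inf
    p[ne] <- 0
    degenerate <- ne
  }
  data.frame(t = t, df = df, p = p,
             mean_young = m1, mean_old = m2, degenerate = degenerate)
}

#' Welch t-test of one probe between groups
#'
#' The statistic is signed old minus young, so positive values mean
#' hypermethylation with age; the p-value is two-sided from the Welch
#' reference distribution.
#'
#' @param m_young,m_old M-values (>= 2 each).
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
probe_t_test <- function(m_young, m_old) {
  m <- matrix(c(m_young, m_old), nrow = 1)
  r <- row_welch(m, c(rep(FALSE, length(m_young)), rep(TRUE, length(m_old))))
  list(t = r$t, df = r$df, p = r$p, degenerate = r$degenerate)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate control; a thin wrapper over
#' [stats::p.adjust()] kept as the pipeline's single multiple-testing entry
#' point.
#'
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted p-values (monotone in rank, each `>=` raw, `<=` 1).
#' @export
adjust_fdr <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Call differentially methylated CpGs
#'
#' Betas are logit-transformed to M-values, each probe is tested with a
#' Welch t (old vs young), p-values are BH-adjusted, and probes at or below
#' `q_threshold` are called with a direction from the sign of the
#' group-mean difference. Probes with missing betas are dropped (count
#' reported in the summary).
#'
#' @param betas probes x samples beta matrix with probe ids as rownames.
#' @param samples sample sheet with `sample_id` and `group`
#'   (`young`/`old`), or a group vector aligned with the columns.
#' @param q_threshold BH-adjusted significance cutoff (default 0.05).
#' @param eps beta clipping bound for the logit.
#' @return data frame of class `dm_result`: `probe_id`, `t`, `p`, `p_adj`,
#'   `direction` (`hyper`/`hypo`/`none`), `mean_beta_young`,
#'   `mean_beta_old`, with a `summary` attribute (counts, hyper fraction,
#'   dropped probes).
#' @export
call_dmcpg <- function(betas, samples, q_threshold = 0.05, eps = 1e-6) {
  group <- if (is.data.frame(samples)) {
    stopifnot(all(samples$sample_id == colnames(betas)))
    samples$group
  } else as.character(samples)
  stopifnot(length(group) == ncol(betas), all(group %in% c("young", "old")))
  old <- group == "old"

  complete <- stats::complete.cases(betas)
  n_dropped <- sum(!complete)
  b <- betas[complete, , drop = FALSE]
  mv <- beta_to_m(b, eps)
  r <- row_welch(mv, old)
  p_adj <- adjust_fdr(r$p)
  called <- p_adj <= q_threshold
  direction <- ifelse(called,
                      ifelse(r$mean_old > r$mean_young, "hyper", "hypo"),
                      "none")
  out <- data.frame(probe_id = rownames(b), t = r$t, p = r$p, p_adj = p_adj,
                    direction = direction,
                    mean_beta_young = rowMeans(b[, !old, drop = FALSE]),
                    mean_beta_old = rowMeans(b[, old, drop = FALSE]),
                    row.names = NULL, stringsAsFactors = FALSE)
  n_hyper <- sum(direction == "hyper")
  n_called <- sum(called)
  attr(out, "summary") <- list(
    n_tested = nrow(out), n_dropped = n_dropped, n_called = n_called,
    n_hyper = n_hyper, n_hypo = n_called - n_hyper,
    hyper_fraction = if (n_called > 0) n_hyper / n_called else NA_real_,
    q_threshold = q_threshold)
  class(out) <- c("dm_result", "data.frame")
  out
}

#' @export
print.dm_result <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "dmCpG calls: %d of %d probes at q <= %g (%d hyper / %d hypo%s)\n",
    s$n_called, s$n_tested, s$q_threshold, s$n_hyper, s$n_hypo,
    if (!is.na(s$hyper_fraction))
      sprintf("; hyper fraction %.3f", s$hyper_fraction) else ""))
  if (s$n_dropped > 0)
    cat(sprintf("  (%d probes with missing betas dropped)\n", s$n_dropped))
  NextMethod()
}
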