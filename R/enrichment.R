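#' Observed/expected log2 enrichment ratio
#'
#' `log2((n_dm_region / n_acpg_region) / (n_dm_total / n_acpg_total))`:
#' the fraction of a region's array probes that are differentially
#' methylated, relative to the genome-wide fraction. Algebraically equal to
#' the ratio of dm share to aCpG share of the region. Regions with zero dm
#' probes get a `-Inf` sentinel (kept in tables, excluded from plots).
#'
#' @param n_dm_region,n_acpg_region dm and array probe counts in the region.
#' @param n_dm_total,n_acpg_total genome-wide dm and array probe counts.
#' @return numeric log2 ratio (vectorized).
#' @export
log2_obs_exp <- function(n_dm_region, n_acpg_region, n_dm_total,
                         n_acpg_total) {
  stopifnot(all(n_acpg_region > 0), all(n_dm_total > 0),
            all(n_dm_region >= 0), all(n_dm_region <= n_acpg_region))
  ifelse(n_dm_region == 0, -Inf,
         log2((n_dm_region / n_acpg_region) / (n_dm_total / n_acpg_total)))
}

#' Exact test of dm-probe enrichment in a region
#'
#' Two-sided hypergeometric test: under the null, the `n_dm_total` dm
#' probes are a uniform draw without replacement from the `n_acpg_total`
#' array probes, of which `n_acpg_region` lie in the region. The two-sided
#' p-value sums the probabilities of all outcomes no more likely than the
#' observed one (the exact-test convention). Direction compares the
#' observed count to its expectation.
#'
#' @inheritParams log2_obs_exp
#' @return list with `p_value` and `direction` (`over`/`under`/`none`);
#'   vectorized inputs give vectors.
#' @export
enrichment_test <- function(n_dm_region, n_acpg_region, n_dm_total,
                            n_acpg_total) {
  n <- max(length(n_dm_region), length(n_acpg_region), length(n_dm_total),
           length(n_acpg_total))
  k <- rep_len(n_dm_region, n); K <- rep_len(n_acpg_region, n)
  d <- rep_len(n_dm_total, n); N <- rep_len(n_acpg_total, n)
  if (any(K > N) || any(d > N) || any(k > pmin(K, d)) ||
      any(k < pmax(0, d - (N - K))) || any(k < 0))
    stop("impossible enrichment counts")
  p <- numeric(n); dir <- character(n)
  for (i in seq_len(n)) {
    lo <- max(0, d[i] - (N[i] - K[i]))
    hi <- min(K[i], d[i])
    support <- lo:hi
    dens <- stats::dhyper(support, K[i], N[i] - K[i], d[i])
    d_obs <- dens[support == k[i]]
    p[i] <- min(1, sum(dens[dens <= d_obs * (1 + 1e-7)]))
    expected <- d[i] * K[i] / N[i]
    dir[i] <- if (k[i] > expected) "over" else if (k[i] < expected) "under"
              else "none"
  }
  list(p_value = p, direction = dir)
}

#' Region enrichment table for dmCpG calls
#'
#' One row per category (and, when split, per dm direction class): counts
#' of array and dm probes in the category, the observed/expected log2
#' ratio, the exact two-sided hypergeometric p and the direction.
#' Chromosome categories are always present. The probe universe is every
#' probe assigned by [assign_probe_categories()].
#'
#' @param dm a [call_dmcpg()] result (or a data frame with `probe_id` and
#'   `direction`).
#' @param assignment a [assign_probe_categories()] result.
#' @param split_by_direction also emit rows restricted to hyper-only and
#'   hypo-only dm sets.
#' @param adjust apply BH across rows within each dm class (off by
#'   default: the convention here is per-category `P < 0.05`).
#' @return data frame with columns `category`, `dm_class`,
#'   `n_acpg_in_region`, `n_dm_in_region`, `n_acpg_total`, `n_dm_total`,
#'   `log2_ratio`, `p_value`, `direction`, `significant`.
#' @export
enrichment_table <- function(dm, assignment, split_by_direction = FALSE,
                             adjust = FALSE) {
  stopifnot(inherits(assignment, "probe_categories"))
  mem <- assignment$memberships
  universe <- assignment$probe_ids
  n_acpg_total <- length(universe)
  acpg_in_region <- table(mem$category)

  classes <- if (split_by_direction) c("all", "hyper", "hypo") else "all"
  rows <- lapply(classes, function(cl) {
    dm_ids <- if (cl == "all") dm$probe_id[dm$direction != "none"]
              else dm$probe_id[dm$direction == cl]
    n_dm_total <- length(dm_ids)
    dm_in_region <- table(mem$category[mem$probe_id %in% dm_ids])
    cats <- names(acpg_in_region)
    n_reg <- as.integer(acpg_in_region[cats])
    n_dm_reg <- as.integer(dm_in_region[cats])
    n_dm_reg[is.na(n_dm_reg)] <- 0L
    if (n_dm_total == 0) {
      return(data.frame(category = cats, dm_class = cl,
                        n_acpg_in_region = n_reg, n_dm_in_region = n_dm_reg,
                        n_acpg_total = n_acpg_total, n_dm_total = 0L,
                        log2_ratio = NA_real_, p_value = NA_real_,
                        direction = "none", significant = FALSE,
                        stringsAsFactors = FALSE))
    }
    lr <- log2_obs_exp(n_dm_reg, n_reg, n_dm_total, n_acpg_total)
    tst <- enrichment_test(n_dm_reg, n_reg, n_dm_total, n_acpg_total)
    p <- if (adjust) adjust_fdr(tst$p_value) else tst$p_value
    data.frame(category = cats, dm_class = cl,
               n_acpg_in_region = n_reg, n_dm_in_region = n_dm_reg,
               n_acpg_total = n_acpg_total, n_dm_total = n_dm_total,
               log2_ratio = lr, p_value = p, direction = tst$direction,
               significant = p < 0.05, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
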