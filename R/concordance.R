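#' Per-gene dmCpG summaries by region category
#'
#' Counts hyper- and hypomethylated dmCpGs (and total array probes) per
#' gene within each of the gene-anchored region categories: `intragenic`,
#' the `5prime`/`central`/`3prime` body segments, the promoter window and
#' the CGI-overlapping part of the promoter. The designation is computed
#' per region: a gene can be `hyper-only` intragenically while mixed in
#' another region. Every gene with at least one intragenic array probe
#' appears.
#'
#' @param dm a [call_dmcpg()] result.
#' @param assignment a [assign_probe_categories()] result.
#' @param catalog the [build_region_catalog()] used for the assignment
#'   (provides island intervals for the CGI-promoter region).
#' @return data frame `gene_id`, `region`, `n_acpg`, `n_hyper`, `n_hypo`,
#'   `designation` (`hyper-only`/`hypo-only`/`mixed`/`none`).
#' @export
summarize_genes <- function(dm, assignment, catalog) {
  stopifnot(inherits(assignment, "probe_categories"),
            inherits(catalog, "region_catalog"))
  pg <- assignment$probe_genes
  pp <- assignment$probe_promoters
  dir_of <- stats::setNames(dm$direction, dm$probe_id)

  # probe-(gene, region) pairs
  pairs <- rbind(
    data.frame(probe_id = pg$probe_id, gene_id = pg$gene_id,
               region = "intragenic", stringsAsFactors = FALSE),
    data.frame(probe_id = pg$probe_id, gene_id = pg$gene_id,
               region = pg$segment, stringsAsFactors = FALSE),
    data.frame(probe_id = pp$probe_id, gene_id = pp$gene_id,
               region = "promoter", stringsAsFactors = FALSE))
  if (nrow(pp)) {
    man <- data.frame(probe_id = pp$probe_id, stringsAsFactors = FALSE)
    # CGI-promoter: promoter probes that also sit in an island
    in_cgi <- pp$probe_id %in% assignment$memberships$probe_id[
      assignment$memberships$category == "CGI"]
    if (any(in_cgi)) {
      pairs <- rbind(pairs, data.frame(probe_id = pp$probe_id[in_cgi],
                                       gene_id = pp$gene_id[in_cgi],
                                       region = "CGI-promoter",
                                       stringsAsFactors = FALSE))
    }
  }
  pairs$dir <- dir_of[pairs$probe_id]
  pairs$dir[is.na(pairs$dir)] <- "none"

  genes_in <- unique(pg$gene_id)
  regions <- c("intragenic", "5prime", "central", "3prime", "promoter",
               "CGI-promoter")
  key <- interaction(factor(pairs$gene_id, levels = genes_in),
                     factor(pairs$region, levels = regions), drop = FALSE)
  n_acpg <- tapply(rep(1L, nrow(pairs)), key, sum, default = 0L)
  n_hyper <- tapply(pairs$dir == "hyper", key, sum, default = 0L)
  n_hypo <- tapply(pairs$dir == "hypo", key, sum, default = 0L)
  grid <- expand.grid(gene_id = genes_in, region = regions,
                      stringsAsFactors = FALSE)
  out <- data.frame(grid,
                    n_acpg = as.integer(n_acpg),
                    n_hyper = as.integer(n_hyper),
                    n_hypo = as.integer(n_hypo),
                    stringsAsFactors = FALSE)
  out$designation <- ifelse(out$n_hyper + out$n_hypo == 0, "none",
                       ifelse(out$n_hyper > 0 & out$n_hypo > 0, "mixed",
                         ifelse(out$n_hyper > 0, "hyper-only", "hypo-only")))
  stopifnot(all(out$n_hyper + out$n_hypo <= out$n_acpg))
  out[order(out$gene_id, match(out$region, regions)), ] -> out
  rownames(out) <- NULL
  out
}

#' Minimum-count gene sets
#'
#' For each threshold `k`, the genes designated `hyper-only` (or
#' `hypo-only`) in the region with at least `k` sites of that direction.
#' Sets are nested: a larger `k` gives a subset.
#'
#' @param summaries a [summarize_genes()] result.
#' @param thresholds positive integer minimum dmCpG counts.
#' @param region one region category of the summaries.
#' @param designation `"hyper"` or `"hypo"` (meaning hyper-only /
#'   hypo-only).
#' @return named list (`"1"`, `"2"`, ...) of gene-id character vectors.
#' @export
threshold_gene_sets <- function(summaries, thresholds = c(1, 2, 4, 8, 16),
                                region, designation = c("hyper", "hypo")) {
  designation <- match.arg(designation)
  stopifnot(all(thresholds >= 1), all(thresholds == round(thresholds)))
  s <- summaries[summaries$region == region, , drop = FALSE]
  want <- paste0(designation, "-only")
  count <- if (designation == "hyper") s$n_hyper else s$n_hypo
  sets <- lapply(thresholds, function(k) {
    s$gene_id[s$designation == want & count >= k]
  })
  stats::setNames(sets, as.character(thresholds))
}

#' Cross-tabulate gene sets against expression-change labels
#'
#' @param gene_sets named list of gene-id vectors (e.g. from
#'   [threshold_gene_sets()]).
#' @param labels data frame `gene_id`, `label`; genes absent from it count
#'   as `unchanged` (with a warning).
#' @return data frame `threshold`, `up`, `down`, `unchanged`, `n`.
#' @export
crosstab_expression <- function(gene_sets, labels) {
  lab <- stats::setNames(labels$label, labels$gene_id)
  all_genes <- unique(unlist(gene_sets))
  missing <- setdiff(all_genes, names(lab))
  if (length(missing) > 0)
    warning(length(missing), " gene(s) missing from the label file counted ",
            "as unchanged")
  rows <- lapply(names(gene_sets), function(k) {
    g <- gene_sets[[k]]
    l <- lab[g]
    l[is.na(l)] <- "unchanged"
    data.frame(threshold = as.integer(k),
               up = sum(l == "up"), down = sum(l == "down"),
               unchanged = sum(l == "unchanged"), n = length(g))
  })
  out <- do.call(rbind, rows)
  stopifnot(all(out$up + out$down + out$unchanged == out$n))
  out
}

#' Full concordance table across regions, directions and thresholds
#'
#' @param summaries a [summarize_genes()] result.
#' @param labels expression-change labels (`gene_id`, `label`).
#' @param regions region categories to tabulate.
#' @param thresholds minimum dmCpG counts.
#' @return long data frame `region`, `designation`, `threshold`, `up`,
#'   `down`, `unchanged`, `n`.
#' @export
concordance_table <- function(summaries, labels,
                              regions = c("intragenic", "5prime", "central",
                                          "3prime", "promoter",
                                          "CGI-promoter"),
                              thresholds = c(1, 2, 4, 8, 16)) {
  rows <- list()
  for (region in regions) {
    for (desig in c("hyper", "hypo")) {
      sets <- threshold_gene_sets(summaries, thresholds, region, desig)
      ct <- suppressWarnings(crosstab_expression(sets, labels))
      rows[[length(rows) + 1]] <- data.frame(region = region,
                                             designation = desig, ct,
                                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric overlap test of two gene sets
#'
#' Probability of observing an overlap at least as large as the one seen,
#' when `|B|` genes are drawn without replacement from a universe
#' containing `|A|` marked genes.
#'
#' @param set_a,set_b character vectors of gene ids (within the universe).
#' @param universe_size number of genes in the universe.
#' @return p-value.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe_size) {
  a <- unique(set_a); b <- unique(set_b)
  if (length(a) > universe_size || length(b) > universe_size)
    stop("sets exceed the universe")
  k <- length(intersect(a, b))
  stats::phyper(k - 1, length(a), universe_size - length(a), length(b),
                lower.tail = FALSE)
}

#' Correlation of per-gene dm counts with array-probe counts
#'
#' Pearson correlation between the number of intragenic dmCpGs of a gene
#' and the number of array probes the gene carries, over genes with at
#' least one intragenic dmCpG (set `dm_genes_only = FALSE` for all genes
#' with array probes).
#'
#' @param summaries a [summarize_genes()] result.
#' @param dm_genes_only restrict to genes with >= 1 intragenic dmCpG.
#' @return Pearson r, with attributes `n` (genes used); `NA` with a warning
#'   when either vector is constant or fewer than 3 genes remain.
#' @export
count_correlation <- function(summaries, dm_genes_only = TRUE) {
  s <- summaries[summaries$region == "intragenic", , drop = FALSE]
  dm_count <- s$n_hyper + s$n_hypo
  if (dm_genes_only) {
    keep <- dm_count >= 1
    s <- s[keep, , drop = FALSE]
    dm_count <- dm_count[keep]
  }
  if (nrow(s) < 3 || stats::sd(dm_count) == 0 || stats::sd(s$n_acpg) == 0) {
    warning("correlation undefined: fewer than 3 genes or constant counts")
    return(structure(NA_real_, n = nrow(s)))
  }
  structure(stats::cor(dm_count, s$n_acpg), n = nrow(s))
}
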