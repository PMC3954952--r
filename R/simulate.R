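#' Simulation configuration
#'
#' Defaults emulate the study design the pipeline targets: 24 young vs 24
#' old samples, CpG islands at 60% of gene promoters, and a 92:8
#' hyper:hypo split among differentially methylated probes with a 0.2
#' beta-unit group-mean shift. Per-sample beta values are drawn from a beta
#' distribution around the probe's group mean (`beta_precision` is the
#' concentration); baseline means are bimodal (low in islands, high
#' elsewhere).
#'
#' Differential probes are drawn by weighted sampling without replacement.
#' Besides optional `planted_region_bias` multipliers on named categories,
#' two weight components make dm sites cluster within genes, as they do in
#' real aging muscle data where single genes carry dozens of same-direction
#' sites: a per-gene susceptibility factor (gamma with mean 1, shape
#' `gene_susceptibility_shape`) and a per-gene target segment whose probes
#' get `target_segment_affinity` times the weight. Both components have
#' mean 1 across genes, so category-level expected densities still follow
#' `planted_region_bias`. With `direction_unit = "gene"` (default) all
#' intragenic dm probes of a gene share one direction drawn with
#' probability `hyper_fraction_of_dm`; `"probe"` draws directions i.i.d.
#'
#' @param seed master seed; per-stage child seeds are derived from it.
#' @param n_young,n_old samples per group (>= 2).
#' @param n_chromosomes,chromosome_length toy genome shape.
#' @param n_genes number of genes (placed without overlap).
#' @param gene_length_range,min_gene_gap gene placement controls (bases).
#' @param cgi_promoter_fraction exact fraction of genes whose promoter
#'   (+/-1500 of TSS) overlaps a CpG island.
#' @param cgi_extra_fraction extra intra-/intergenic islands per gene.
#' @param cgi_length_range,skew_length_range feature sizes (bases).
#' @param skew_promoter_fraction fraction of promoters overlapping a
#'   GC-skew region.
#' @param n_probes probes on the toy array.
#' @param cgi_probe_fraction fraction of probes placed inside islands.
#' @param n_separator_probes probes planted with completely separated
#'   group values (young and old ranges disjoint by construction).
#' @param dm_fraction fraction of probes planted as differentially
#'   methylated.
#' @param hyper_fraction_of_dm probability a dm unit is hypermethylated.
#' @param effect_size_beta old-group mean shift in beta units.
#' @param beta_precision beta-distribution concentration of per-sample noise.
#' @param baseline_cgi_mean,baseline_other_mean,baseline_precision baseline
#'   beta-mean model (bimodal).
#' @param mean_clip group means are clipped into this range; clipping is
#'   recorded in the ground truth.
#' @param planted_region_bias named numeric vector of category -> dm
#'   selection-weight multipliers (e.g. `c("gene-3prime" = 4)`).
#' @param gene_susceptibility_shape,target_segment_affinity within-gene dm
#'   clustering controls (see Details).
#' @param direction_unit `"gene"` or `"probe"`.
#' @param conc_base,conc_decay methylation-expression concordance
#'   probability for a gene with `k` dm sites is
#'   `1 - (1 - conc_base) * conc_decay^(k - 1)`; concordance strengthens
#'   with the number of sites.
#' @param background_change probability a gene without dm is labeled
#'   up/down anyway (split evenly).
#' @param discordant_opposite among non-concordant draws, probability of
#'   the opposite label rather than `unchanged`.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_young = 24, n_old = 24,
                       n_chromosomes = 4, chromosome_length = 1.5e6,
                       n_genes = 500,
                       gene_length_range = c(2000, 8000),
                       min_gene_gap = 4000,
                       cgi_promoter_fraction = 0.60,
                       cgi_extra_fraction = 0.30,
                       cgi_length_range = c(300, 1500),
                       skew_promoter_fraction = 0.40,
                       skew_length_range = c(300, 800),
                       n_probes = 20000,
                       cgi_probe_fraction = 0.35,
                       n_separator_probes = 0,
                       dm_fraction = 0.05,
                       hyper_fraction_of_dm = 0.92,
                       effect_size_beta = 0.2,
                       beta_precision = 50,
                       baseline_cgi_mean = 0.15,
                       baseline_other_mean = 0.80,
                       baseline_precision = 30,
                       mean_clip = c(0.02, 0.98),
                       planted_region_bias = NULL,
                       gene_susceptibility_shape = 0.35,
                       target_segment_affinity = 50,
                       direction_unit = c("gene", "probe"),
                       conc_base = 0.6, conc_decay = 0.6,
                       background_change = 0.05,
                       discordant_opposite = 0.25) {
  direction_unit <- match.arg(direction_unit)
  cfg <- as.list(environment())
  fracs <- c(cgi_promoter_fraction, cgi_extra_fraction, skew_promoter_fraction,
             cgi_probe_fraction, dm_fraction, hyper_fraction_of_dm,
             conc_base, conc_decay, background_change, discordant_opposite)
  stopifnot(all(fracs >= 0), all(fracs <= 1),
            n_young >= 2, n_old >= 2,
            effect_size_beta >= 0, effect_size_beta < 1,
            beta_precision > 0, baseline_precision > 0,
            mean_clip[1] > 0, mean_clip[2] < 1, mean_clip[1] < mean_clip[2],
            n_probes >= 0, n_separator_probes <= n_probes)
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-stage child seeds (< 2^31) from the master seed
derive_seeds <- function(seed, n = 4) {
  with_seed(seed, sample.int(2147483646L, n))
}

with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(expr)
}

#' Generate a toy annotated genome and probe manifest
#'
#' Genes are placed without overlap on both strands with at least
#' `min_gene_gap` bases between them; exactly
#' `round(cgi_promoter_fraction * n_genes)` genes get a CpG island
#' overlapping their promoter (and no other gene's promoter), plus extra
#' intra-/intergenic islands kept clear of all promoters. GC-skew intervals
#' are planted the same way. Probes are placed preferentially inside
#' islands (`cgi_probe_fraction`) and uniformly elsewhere, at unique
#' positions. Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `genes`, `cgis`, `skew_regions`, `chrom_lengths`,
#'   `manifest`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed)
  with_seed(seeds[1], generate_genome_impl(config))
}

generate_genome_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom_lengths <- stats::setNames(rep(cfg$chromosome_length,
                                       cfg$n_chromosomes), chroms)
  # --- genes ---------------------------------------------------------------
  per_chrom <- diff(floor(seq(0, cfg$n_genes, length.out = cfg$n_chromosomes + 1)))
  gene_rows <- list()
  gid <- 0
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    len <- chrom_lengths[ci]
    glen <- sample(cfg$gene_length_range[1]:cfg$gene_length_range[2], k,
                   replace = TRUE)
    slack <- len - sum(glen) - (k + 1) * cfg$min_gene_gap
    if (slack < 0)
      stop("infeasible packing: ", k, " genes do not fit on ", chroms[ci])
    extra <- as.vector(stats::rmultinom(1, slack, rep(1, k + 1)))
    gaps <- cfg$min_gene_gap + extra
    starts <- cumsum(gaps[seq_len(k)]) + cumsum(c(0, glen[-k]))
    gene_rows[[ci]] <- data.frame(
      gene_id = sprintf("g%04d", gid + seq_len(k)),
      chrom = chroms[ci], start = starts, end = starts + glen,
      strand = sample(c("+", "-"), k, replace = TRUE),
      stringsAsFactors = FALSE)
    gid <- gid + k
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  prom <- promoter_windows(genes, 1500, chrom_lengths)
  # fast overlap: indices of promoters hit by [s, e) on chrom
  prom_hits <- function(chrom, s, e) {
    which(prom$chrom == chrom & prom$start < e & s < prom$end)
  }

  # --- CpG islands ---------------------------------------------------------
  n_cgi_prom <- round(cfg$cgi_promoter_fraction * cfg$n_genes)
  chosen <- sort(sample.int(cfg$n_genes, n_cgi_prom))
  tss <- gene_tss(genes)
  cgi_rows <- list()
  for (i in chosen) {
    ok <- FALSE
    for (try in 1:25) {
      clen <- round(stats::runif(1, cfg$cgi_length_range[1],
                                 cfg$cgi_length_range[2]))
      center <- tss[i] + round(stats::runif(1, -500, 500))
      cand <- data.frame(chrom = genes$chrom[i],
                         start = max(0, center - floor(clen / 2)),
                         end = min(chrom_lengths[genes$chrom[i]],
                                   center + ceiling(clen / 2)),
                         strand = "*", stringsAsFactors = FALSE)
      hits <- prom_hits(cand$chrom, cand$start, cand$end)
      if (identical(hits, i)) { ok <- TRUE; break }
    }
    if (!ok) {  # tight island straddling the TSS touches only this promoter
      cand <- data.frame(chrom = genes$chrom[i],
                         start = max(0, tss[i] - 150), end = tss[i] + 150,
                         strand = "*", stringsAsFactors = FALSE)
    }
    cgi_rows[[length(cgi_rows) + 1]] <- cand
  }
  n_extra <- round(cfg$cgi_extra_fraction * cfg$n_genes)
  existing <- do.call(rbind, cgi_rows)
  for (j in seq_len(n_extra)) {
    for (try in 1:50) {
      chrom <- sample(chroms, 1)
      clen <- round(stats::runif(1, cfg$cgi_length_range[1],
                                 cfg$cgi_length_range[2]))
      s <- floor(stats::runif(1, 0, chrom_lengths[chrom] - clen))
      cand <- data.frame(chrom = chrom, start = s, end = s + clen,
                         strand = "*", stringsAsFactors = FALSE)
      clash <- length(prom_hits(chrom, s, s + clen)) > 0 ||
        (!is.null(existing) && nrow(existing) > 0 &&
         any(existing$chrom == chrom & existing$start < s + clen &
               s < existing$end))
      if (!clash) {
        cgi_rows[[length(cgi_rows) + 1]] <- cand
        existing <- rbind(existing, cand)
        break
      }
    }
  }
  cgis <- do.call(rbind, cgi_rows)
  rownames(cgis) <- NULL

  # --- GC-skew regions -----------------------------------------------------
  n_skew_prom <- round(cfg$skew_promoter_fraction * cfg$n_genes)
  skew_genes <- sort(sample.int(cfg$n_genes, n_skew_prom))
  skew_rows <- list()
  for (i in skew_genes) {
    slen <- round(stats::runif(1, cfg$skew_length_range[1],
                               cfg$skew_length_range[2]))
    center <- tss[i] + round(stats::runif(1, -400, 400))
    skew_rows[[length(skew_rows) + 1]] <- data.frame(
      chrom = genes$chrom[i],
      start = max(0, center - floor(slen / 2)),
      end = min(chrom_lengths[genes$chrom[i]], center + ceiling(slen / 2)),
      strand = "*", sign = sample(c(1, -1), 1), stringsAsFactors = FALSE)
  }
  n_skew_extra <- round(0.2 * cfg$n_genes)
  for (j in seq_len(n_skew_extra)) {
    for (try in 1:50) {
      chrom <- sample(chroms, 1)
      slen <- round(stats::runif(1, cfg$skew_length_range[1],
                                 cfg$skew_length_range[2]))
      s <- floor(stats::runif(1, 0, chrom_lengths[chrom] - slen))
      cand <- data.frame(chrom = chrom, start = s, end = s + slen,
                         strand = "*", sign = sample(c(1, -1), 1),
                         stringsAsFactors = FALSE)
      if (length(prom_hits(chrom, s, s + slen)) == 0) {
        skew_rows[[length(skew_rows) + 1]] <- cand
        break
      }
    }
  }
  skew <- if (length(skew_rows)) do.call(rbind, skew_rows) else
    cbind(empty_intervals(), sign = numeric())
  rownames(skew) <- NULL

  # exact promoter-CGI count is forced by construction; verify anyway
  got <- sum(classify_promoters(genes, cgis, skew, 1500, chrom_lengths)$has_cgi)
  stopifnot(got == n_cgi_prom)

  # --- probes --------------------------------------------------------------
  manifest <- place_probes(cfg, chroms, chrom_lengths, cgis)
  list(genes = genes, cgis = cgis, skew_regions = skew,
       chrom_lengths = chrom_lengths, manifest = manifest)
}

place_probes <- function(cfg, chroms, chrom_lengths, cgis) {
  if (cfg$n_probes == 0) {
    return(data.frame(probe_id = character(), chrom = character(),
                      pos = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  cgi_m <- gi_merge(cgis)
  cgi_bases <- gi_total_width(cgi_m)
  n_cgi <- min(round(cfg$cgi_probe_fraction * cfg$n_probes), cgi_bases)
  # probes inside islands: sample island bases without replacement
  cgi_probes <- NULL
  if (n_cgi > 0) {
    offs <- sort(sample.int(cgi_bases, n_cgi)) - 1
    cum <- cumsum(cgi_m$end - cgi_m$start)
    idx <- findInterval(offs, c(0, cum), rightmost.closed = FALSE)
    within <- offs - c(0, cum)[idx]
    cgi_probes <- data.frame(chrom = cgi_m$chrom[idx],
                             pos = cgi_m$start[idx] + within,
                             stringsAsFactors = FALSE)
  }
  n_rest <- cfg$n_probes - n_cgi
  rest <- NULL
  if (n_rest > 0) {
    alloc <- as.vector(stats::rmultinom(1, n_rest,
                                        chrom_lengths / sum(chrom_lengths)))
    rest <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      if (alloc[ci] == 0) return(NULL)
      data.frame(chrom = chroms[ci],
                 pos = sample.int(chrom_lengths[ci], alloc[ci]) - 1,
                 stringsAsFactors = FALSE)
    }))
  }
  probes <- rbind(cgi_probes, rest)
  # de-duplicate collisions between pools, topping up uniformly
  probes <- probes[!duplicated(paste(probes$chrom, probes$pos)), ]
  while (nrow(probes) < cfg$n_probes) {
    need <- cfg$n_probes - nrow(probes)
    chrom <- sample(chroms, need, replace = TRUE)
    add <- data.frame(chrom = chrom,
                      pos = floor(stats::runif(need, 0, chrom_lengths[chrom])),
                      stringsAsFactors = FALSE)
    probes <- rbind(probes, add)
    probes <- probes[!duplicated(paste(probes$chrom, probes$pos)), ]
  }
  probes <- probes[order(match(probes$chrom, chroms), probes$pos), ]
  data.frame(probe_id = sprintf("cg%06d", seq_len(nrow(probes))),
             chrom = probes$chrom, pos = probes$pos,
             strand = sample(c("+", "-"), nrow(probes), replace = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Generate a two-group beta-value matrix with planted effects
#'
#' Baseline probe means are bimodal (island probes low, others high);
#' per-sample betas are beta-distributed around the group mean. Planted dm
#' probes shift the old-group mean by `effect_size_beta` in the drawn
#' direction, clipping at `mean_clip` (clipping is recorded). Planted
#' separator probes get completely disjoint young/old value ranges.
#'
#' @param config a [sim_config()].
#' @param manifest,annotation from [generate_genome()] (`annotation` is the
#'   same list minus `manifest`, or the full list).
#' @return list with `betas` (probes x samples matrix), `samples` (sample
#'   sheet), `truth` (per-probe ground truth: `is_dm`, `direction`,
#'   `mu_young`, `mu_old`, `effect_applied`, `clipped`, `is_separator`,
#'   `gene_id`, `segment`).
#' @export
generate_methylation <- function(config, manifest, annotation) {
  stopifnot(inherits(config, "sim_config"), nrow(manifest) > 0)
  seeds <- derive_seeds(config$seed)
  with_seed(seeds[2], generate_methylation_impl(config, manifest, annotation))
}

generate_methylation_impl <- function(cfg, manifest, ann) {
  n <- nrow(manifest)
  catalog <- build_region_catalog(ann$genes, ann$cgis, ann$skew_regions,
                                  ann$chrom_lengths)
  assign <- assign_probe_categories(manifest, catalog)
  in_cgi <- probes_in_intervals(manifest, catalog$cgis)
  pg <- assign$probe_genes
  # one gene per probe in generator genomes (genes never overlap)
  gene_of <- rep(NA_character_, n)
  seg_of <- rep(NA_character_, n)
  m <- match(pg$probe_id, manifest$probe_id)
  gene_of[m] <- pg$gene_id
  seg_of[m] <- pg$segment

  base_mean <- ifelse(in_cgi, cfg$baseline_cgi_mean, cfg$baseline_other_mean)
  mu <- stats::rbeta(n, base_mean * cfg$baseline_precision,
                     (1 - base_mean) * cfg$baseline_precision)
  mu <- pmin(pmax(mu, cfg$mean_clip[1]), cfg$mean_clip[2])

  # --- dm probe selection (weighted, without replacement) ------------------
  w <- rep(1, n)
  if (!is.null(cfg$planted_region_bias)) {
    for (cat in names(cfg$planted_region_bias)) {
      hit <- manifest$probe_id %in%
        assign$memberships$probe_id[assign$memberships$category == cat]
      w[hit] <- w[hit] * cfg$planted_region_bias[[cat]]
    }
  }
  genes <- ann$genes
  susceptibility <- stats::rgamma(nrow(genes), shape = cfg$gene_susceptibility_shape,
                                  rate = cfg$gene_susceptibility_shape)
  target_seg <- sample(c("5prime", "central", "3prime"), nrow(genes),
                       replace = TRUE)
  gidx <- match(gene_of, genes$gene_id)
  intra <- !is.na(gidx)
  aff <- ifelse(seg_of[intra] == target_seg[gidx[intra]],
                cfg$target_segment_affinity, 1)
  # normalize affinity to mean 1 within each gene is unnecessary for the
  # category expectation: targets are uniform over segments, so the
  # across-gene mean multiplier of any segment is the same constant.
  w[intra] <- w[intra] * susceptibility[gidx[intra]] * aff

  n_dm <- round(cfg$dm_fraction * n)
  dm_idx <- if (n_dm > 0) sample.int(n, n_dm, prob = w) else integer()
  is_dm <- rep(FALSE, n); is_dm[dm_idx] <- TRUE

  direction <- rep(NA_character_, n)
  if (n_dm > 0) {
    if (cfg$direction_unit == "gene") {
      dm_genes <- unique(gene_of[dm_idx][!is.na(gene_of[dm_idx])])
      gene_dir <- stats::setNames(
        ifelse(stats::runif(length(dm_genes)) < cfg$hyper_fraction_of_dm,
               "hyper", "hypo"), dm_genes)
      for (i in dm_idx) {
        direction[i] <- if (!is.na(gene_of[i])) gene_dir[[gene_of[i]]] else
          if (stats::runif(1) < cfg$hyper_fraction_of_dm) "hyper" else "hypo"
      }
    } else {
      direction[dm_idx] <- ifelse(
        stats::runif(n_dm) < cfg$hyper_fraction_of_dm, "hyper", "hypo")
    }
  }

  mu_old <- mu
  shift <- ifelse(is_dm, ifelse(direction == "hyper", cfg$effect_size_beta,
                                -cfg$effect_size_beta), 0)
  shift[is.na(shift)] <- 0
  mu_old <- pmin(pmax(mu + shift, cfg$mean_clip[1]), cfg$mean_clip[2])
  effect_applied <- mu_old - mu
  clipped <- is_dm & (abs(effect_applied) < abs(shift) - 1e-12)
  if (any(clipped)) {
    message(sum(clipped), " planted effect(s) clipped at the beta-mean bounds")
  }

  # --- separator probes ----------------------------------------------------
  is_sep <- rep(FALSE, n)
  if (cfg$n_separator_probes > 0) {
    pool <- setdiff(seq_len(n), dm_idx)
    sep_idx <- sample(pool, cfg$n_separator_probes)
    is_sep[sep_idx] <- TRUE
    sep_dir <- ifelse(stats::runif(cfg$n_separator_probes) <
                        cfg$hyper_fraction_of_dm, "hyper", "hypo")
    direction[sep_idx] <- sep_dir
    is_dm[sep_idx] <- TRUE
  }

  # --- sample sheet & matrix ------------------------------------------------
  samples <- data.frame(
    sample_id = c(sprintf("young%02d", seq_len(cfg$n_young)),
                  sprintf("old%02d", seq_len(cfg$n_old))),
    group = rep(c("young", "old"), c(cfg$n_young, cfg$n_old)),
    age = c(round(stats::runif(cfg$n_young, 18, 27)),
            round(stats::runif(cfg$n_old, 68, 89))),
    stringsAsFactors = FALSE)
  n_s <- nrow(samples)
  mu_mat <- cbind(matrix(mu, n, cfg$n_young),
                  matrix(mu_old, n, cfg$n_old))
  betas <- matrix(stats::rbeta(n * n_s, mu_mat * cfg$beta_precision,
                               (1 - mu_mat) * cfg$beta_precision), n, n_s)
  if (any(is_sep)) {
    for (i in which(is_sep)) {
      lo <- stats::runif(n_s, 0.05, 0.42)
      hi <- stats::runif(n_s, 0.58, 0.95)
      young_cols <- seq_len(cfg$n_young)
      if (direction[i] == "hyper") {
        betas[i, young_cols] <- lo[young_cols]
        betas[i, -young_cols] <- hi[-young_cols]
      } else {
        betas[i, young_cols] <- hi[young_cols]
        betas[i, -young_cols] <- lo[-young_cols]
      }
    }
  }
  betas <- pmin(pmax(betas, 1e-6), 1 - 1e-6)
  dimnames(betas) <- list(manifest$probe_id, samples$sample_id)

  truth <- data.frame(probe_id = manifest$probe_id, is_dm = is_dm,
                      direction = ifelse(is_dm, direction, "none"),
                      mu_young = mu, mu_old = mu_old,
                      effect_applied = effect_applied, clipped = clipped,
                      is_separator = is_sep, gene_id = gene_of,
                      segment = seg_of, stringsAsFactors = FALSE)
  list(betas = betas, samples = samples, truth = truth)
}

#' Generate per-gene expression-change labels
#'
#' Mirrors the inverse methylation-expression relationship with the 3'-end
#' exception: genes whose dm sites are hypomethylated are biased toward
#' `up`; hypermethylated genes toward `down`, unless the majority of their
#' hyper sites sit in the 3' gene segment, in which case toward `up`. The
#' concordance probability grows with the number of dm sites in the gene
#' (see [sim_config()]). Genes without dm (or with mixed directions) change
#' with probability `background_change`.
#'
#' @param config a [sim_config()].
#' @param annotation from [generate_genome()].
#' @param truth ground truth from [generate_methylation()].
#' @return data frame `gene_id`, `label` (`up`/`down`/`unchanged`),
#'   `pattern` (the planted pattern used to draw the label).
#' @export
generate_expression_labels <- function(config, annotation, truth) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- derive_seeds(config$seed)
  with_seed(seeds[3], generate_expression_labels_impl(config, annotation, truth))
}

generate_expression_labels_impl <- function(cfg, ann, truth) {
  genes <- ann$genes$gene_id
  dm <- truth[truth$is_dm & !is.na(truth$gene_id), , drop = FALSE]
  n_hyper <- tapply(dm$direction == "hyper", dm$gene_id, sum)
  n_hypo <- tapply(dm$direction == "hypo", dm$gene_id, sum)
  n_hyper3 <- tapply(dm$direction == "hyper" & dm$segment == "3prime",
                     dm$gene_id, sum)
  labels <- character(length(genes))
  patterns <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    hy <- if (g %in% names(n_hyper)) n_hyper[[g]] else 0
    ho <- if (g %in% names(n_hypo)) n_hypo[[g]] else 0
    h3 <- if (g %in% names(n_hyper3)) n_hyper3[[g]] else 0
    k <- hy + ho
    pattern <- if (k == 0) "none"
      else if (ho > 0 && hy > 0) "mixed"
      else if (ho > 0) "hypo"
      else if (h3 > hy / 2) "hyper3"
      else "hyper"
    patterns[i] <- pattern
    if (pattern %in% c("none", "mixed")) {
      u <- stats::runif(1)
      labels[i] <- if (u < cfg$background_change / 2) "up"
        else if (u < cfg$background_change) "down" else "unchanged"
      next
    }
    concordant <- switch(pattern, hypo = "up", hyper3 = "up", hyper = "down")
    opposite <- if (concordant == "up") "down" else "up"
    p <- 1 - (1 - cfg$conc_base) * cfg$conc_decay^(k - 1)
    u <- stats::runif(1)
    labels[i] <- if (u < p) concordant
      else if (u < p + (1 - p) * cfg$discordant_opposite) opposite
      else "unchanged"
  }
  data.frame(gene_id = genes, label = labels, pattern = patterns,
             stringsAsFactors = FALSE)
}

#' Run the full generator
#'
#' Convenience wrapper: genome, methylation matrix and expression labels in
#' one deterministic call.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (annotation + manifest), `methylation`
#'   (betas, samples, truth) and `expression_labels`.
#' @export
simulate_study <- function(config) {
  genome <- generate_genome(config)
  meth <- generate_methylation(config, genome$manifest, genome)
  labels <- generate_expression_labels(config, genome, meth$truth)
  list(genome = genome, methylation = meth, expression_labels = labels)
}

#' Write a simulated study to disk
#'
#' Emits `genes.bed`, `cgi.bed`, `skew.bed`, `chrom_lengths.tsv`,
#' `manifest.tsv`, `betas.tsv`, `samples.tsv`, `expression_labels.tsv`,
#' `truth.tsv` under `outdir`.
#'
#' @param sim a [simulate_study()] result.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  g <- sim$genome
  genes_bed <- data.frame(chrom = g$genes$chrom, start = g$genes$start,
                          end = g$genes$end, strand = g$genes$strand,
                          name = g$genes$gene_id, stringsAsFactors = FALSE)
  write_bed(genes_bed, file.path(outdir, "genes.bed"))
  write_bed(g$cgis, file.path(outdir, "cgi.bed"))
  skew <- g$skew_regions
  if (nrow(skew)) {
    skew$name <- ifelse(skew$sign > 0, "skew_pos", "skew_neg")
  }
  write_bed(skew, file.path(outdir, "skew.bed"))
  write_tsv(data.frame(chrom = names(g$chrom_lengths),
                       length = as.numeric(g$chrom_lengths)),
            file.path(outdir, "chrom_lengths.tsv"))
  write_tsv(g$manifest, file.path(outdir, "manifest.tsv"))
  write_beta_matrix(sim$methylation$betas, file.path(outdir, "betas.tsv"))
  write_tsv(sim$methylation$samples, file.path(outdir, "samples.tsv"))
  write_tsv(sim$expression_labels, file.path(outdir, "expression_labels.tsv"))
  write_tsv(sim$methylation$truth, file.path(outdir, "truth.tsv"))
  invisible(outdir)
}
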