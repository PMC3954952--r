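#' Pipeline configuration
#'
#' Bundles the simulation settings with the analysis-stage parameters. Any
#' field of [sim_config()] can be overridden through `...`.
#'
#' @param seed master seed for the whole run.
#' @param q_threshold BH-adjusted cutoff for dmCpG calls.
#' @param shore_width CpG-island shore flank width (bases).
#' @param promoter_halfwidth promoter half-width around the TSS (bases).
#' @param tss_tes_widths TSS/TES window half-widths.
#' @param gene_fractions 5'/central/3' fractions of the gene body.
#' @param thresholds minimum-dmCpG gene-set thresholds.
#' @param cv_bound LOOCV error bound for the high-probability flag.
#' @param split_direction split the enrichment table by dm direction.
#' @param ... overrides passed to [sim_config()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, q_threshold = 0.05, shore_width = 2000,
                            promoter_halfwidth = 1500,
                            tss_tes_widths = c(200, 1500),
                            gene_fractions = c(1, 1, 1) / 3,
                            thresholds = c(1, 2, 4, 8, 16),
                            cv_bound = 0.05, split_direction = TRUE, ...) {
  stopifnot(q_threshold > 0, q_threshold <= 1, shore_width > 0,
            promoter_halfwidth > 0, all(tss_tes_widths > 0),
            all(thresholds >= 1), cv_bound >= 0, cv_bound <= 1)
  cfg <- list(seed = seed, q_threshold = q_threshold,
              shore_width = shore_width,
              promoter_halfwidth = promoter_halfwidth,
              tss_tes_widths = tss_tes_widths,
              gene_fractions = gene_fractions,
              thresholds = thresholds, cv_bound = cv_bound,
              split_direction = split_direction,
              sim = sim_config(seed = seed, ...))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Flat keys; every [pipeline_config()] and [sim_config()] argument is
#' accepted. Unknown keys are an error.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipe_args <- setdiff(names(formals(pipeline_config)), "...")
  sim_args <- names(formals(sim_config))
  unknown <- setdiff(names(y), union(pipe_args, sim_args))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (!is.null(y$planted_region_bias))
    y$planted_region_bias <- unlist(y$planted_region_bias)
  do.call(pipeline_config, y)
}

#' Run the full pipeline on synthetic data
#'
#' simulate -> call dmCpGs -> annotate -> enrich -> concordance ->
#' classifier screen, with every stage output written under `outdir` and a
#' run report (JSON + text) summarizing the headline quantities. Identical
#' config and seed give byte-identical outputs. A stage failure aborts with
#' the stage name and leaves a `FAILED` marker next to the partial outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created).
#' @return the run report, invisibly (a list; also written as
#'   `report.json` / `report.txt`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                 file.path(outdir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", {
    s <- simulate_study(config$sim)
    write_simulation(s, outdir)
    s
  })
  genome <- sim$genome
  meth <- sim$methylation

  dm <- stage("call-dm", {
    d <- call_dmcpg(meth$betas, meth$samples, config$q_threshold)
    write_tsv(d, file.path(outdir, "dm.tsv"))
    d
  })

  ann <- stage("annotate", {
    catalog <- build_region_catalog(
      genome$genes, genome$cgis, genome$skew_regions, genome$chrom_lengths,
      tss_tes_widths = config$tss_tes_widths,
      promoter_halfwidth = config$promoter_halfwidth,
      shore_width = config$shore_width,
      gene_fractions = config$gene_fractions)
    assignment <- assign_probe_categories(genome$manifest, catalog)
    write_tsv(assignment$memberships, file.path(outdir, "categories.tsv"))
    write_tsv(assignment$probe_genes, file.path(outdir, "probe_genes.tsv"))
    list(catalog = catalog, assignment = assignment)
  })

  enr <- stage("enrich", {
    e <- enrichment_table(dm, ann$assignment,
                          split_by_direction = config$split_direction)
    write_tsv(e, file.path(outdir, "enrichment.tsv"))
    e
  })

  conc <- stage("concord", {
    summaries <- summarize_genes(dm, ann$assignment, ann$catalog)
    ct <- concordance_table(summaries, sim$expression_labels,
                            thresholds = config$thresholds)
    write_tsv(summaries, file.path(outdir, "gene_dm.tsv"))
    write_tsv(ct, file.path(outdir, "concordance.tsv"))
    r <- count_correlation(summaries)
    list(summaries = summaries, table = ct, count_cor = as.numeric(r),
         count_cor_n = attr(r, "n"))
  })

  clf <- stage("classify", {
    rep <- screen_probes(meth$betas, meth$samples, config$cv_bound)
    write_tsv(rep, file.path(outdir, "classifier.tsv"))
    rep
  })

  dms <- attr(dm, "summary")
  cls <- attr(clf, "summary")
  n_intra_dm_genes <- sum(
    conc$summaries$region == "intragenic" &
      conc$summaries$n_hyper + conc$summaries$n_hypo >= 1)
  report <- list(
    package_version = as.character(utils::packageVersion("agemeth")),
    seed = config$seed,
    parameters = list(
      q_threshold = config$q_threshold, shore_width = config$shore_width,
      promoter_halfwidth = config$promoter_halfwidth,
      tss_tes_widths = config$tss_tes_widths,
      thresholds = config$thresholds, cv_bound = config$cv_bound,
      n_young = config$sim$n_young, n_old = config$sim$n_old,
      n_probes = config$sim$n_probes, dm_fraction = config$sim$dm_fraction,
      hyper_fraction_of_dm = config$sim$hyper_fraction_of_dm,
      effect_size_beta = config$sim$effect_size_beta),
    stages = list(
      simulate = list(n_probes = nrow(genome$manifest),
                      n_genes = nrow(genome$genes),
                      n_cgis = nrow(genome$cgis),
                      n_planted_dm = sum(meth$truth$is_dm),
                      n_clipped_effects = sum(meth$truth$clipped)),
      call_dm = list(n_tested = dms$n_tested, n_dropped = dms$n_dropped,
                     n_called = dms$n_called, n_hyper = dms$n_hyper,
                     n_hypo = dms$n_hypo,
                     hyper_fraction = dms$hyper_fraction),
      annotate = list(n_categories =
                        length(unique(ann$assignment$memberships$category))),
      enrich = list(n_rows = nrow(enr),
                    n_dm_total = enr$n_dm_total[enr$dm_class == "all"][1]),
      concord = list(n_genes_summarized =
                       length(unique(conc$summaries$gene_id)),
                     n_genes_intragenic_dm = n_intra_dm_genes,
                     count_correlation = conc$count_cor),
      classify = list(n_universal = cls$n_universal,
                      n_high_probability = cls$n_high_probability)))
  stopifnot(report$stages$enrich$n_dm_total == dms$n_called)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report(report), file.path(outdir, "report.txt"))
  invisible(report)
}

format_report <- function(r) {
  s <- r$stages
  c(sprintf("agemeth %s  (seed %s)", r$package_version, r$seed),
    sprintf("simulate : %d probes, %d genes, %d CGIs, %d planted dm (%d clipped)",
            s$simulate$n_probes, s$simulate$n_genes, s$simulate$n_cgis,
            s$simulate$n_planted_dm, s$simulate$n_clipped_effects),
    sprintf("call-dm  : %d tested, %d called (%d hyper / %d hypo, hyper fraction %.3f)",
            s$call_dm$n_tested, s$call_dm$n_called, s$call_dm$n_hyper,
            s$call_dm$n_hypo, s$call_dm$hyper_fraction),
    sprintf("annotate : %d categories", s$annotate$n_categories),
    sprintf("enrich   : %d rows", s$enrich$n_rows),
    sprintf("concord  : %d genes summarized, %d with intragenic dm, count correlation %.3f",
            s$concord$n_genes_summarized, s$concord$n_genes_intragenic_dm,
            s$concord$count_correlation),
    sprintf("classify : %d universal separators, %d high-probability predictors",
            s$classify$n_universal, s$classify$n_high_probability))
}
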