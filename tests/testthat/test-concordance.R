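# Gene-level dm summaries, threshold sets, expression cross-tabulation and
# the overlap test.

make_summary_fixture <- function() {
  # toy genome: two genes, probes placed across segments
  cl <- c(c = 1e5)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "c",
                      start = c(10000, 50000), end = c(19000, 59000),
                      strand = c("+", "-"))
  catalog <- build_region_catalog(genes, empty_cgi(), empty_cgi(), cl)
  manifest <- data.frame(
    probe_id = sprintf("p%02d", 1:8), chrom = "c",
    # gA(+): 5' [10k,13k) central [13k,16k) 3' [16k,19k)
    # gB(-): 3' [50k,53k) central [53k,56k) 5' [56k,59k)
    pos = c(10500, 11000, 14000, 17000, 50500, 57000, 58000, 80000),
    strand = "+")
  assignment <- assign_probe_categories(manifest, catalog)
  dm <- data.frame(
    probe_id = manifest$probe_id,
    direction = c("hyper", "hyper", "none", "hyper",
                  "hypo", "hyper", "hypo", "hyper"),
    stringsAsFactors = FALSE)
  list(dm = dm, assignment = assignment, catalog = catalog)
}

test_that("per-gene summaries count directions per region with designations", {
  fx <- make_summary_fixture()
  s <- summarize_genes(fx$dm, fx$assignment, fx$catalog)
  a_intra <- s[s$gene_id == "gA" & s$region == "intragenic", ]
  expect_equal(a_intra$n_hyper, 3)
  expect_equal(a_intra$n_hypo, 0)
  expect_equal(a_intra$n_acpg, 4)
  expect_equal(a_intra$designation, "hyper-only")
  a5 <- s[s$gene_id == "gA" & s$region == "5prime", ]
  expect_equal(a5$n_hyper, 2)
  expect_equal(a5$designation, "hyper-only")
  a_c <- s[s$gene_id == "gA" & s$region == "central", ]
  expect_equal(a_c$n_hyper + a_c$n_hypo, 0)
  expect_equal(a_c$designation, "none")
  # gB is mixed intragenically but hypo-only in its 3' region
  b_intra <- s[s$gene_id == "gB" & s$region == "intragenic", ]
  expect_equal(b_intra$designation, "mixed")
  b3 <- s[s$gene_id == "gB" & s$region == "3prime", ]
  expect_equal(b3$designation, "hypo-only")
  # minus strand: probes at 57000/58000 are in gB's 5' region
  b5 <- s[s$gene_id == "gB" & s$region == "5prime", ]
  expect_equal(b5$n_acpg, 2)
  expect_true(all(s$n_hyper + s$n_hypo <= s$n_acpg))
})

test_that("threshold sets are nested and respect designation", {
  fx <- make_summary_fixture()
  s <- summarize_genes(fx$dm, fx$assignment, fx$catalog)
  sets <- threshold_gene_sets(s, c(1, 2, 4), "intragenic", "hyper")
  expect_equal(sets[["1"]], "gA")
  expect_equal(sets[["2"]], "gA")
  expect_equal(sets[["4"]], character(0))  # gA has 3 hyper sites
  # mixed genes excluded from both directional sets
  expect_false("gB" %in% unlist(sets))
  hypo_sets <- threshold_gene_sets(s, c(1, 2), "3prime", "hypo")
  expect_equal(hypo_sets[["1"]], "gB")
  # nestedness on simulated data, all regions/designations
  sim <- suppressMessages(simulate_study(tiny_config(seed = 41)))
  res <- run_small_analysis(sim)
  summ <- summarize_genes(res$dm, res$assignment, res$catalog)
  for (region in c("intragenic", "5prime", "central", "3prime")) {
    for (d in c("hyper", "hypo")) {
      sets <- threshold_gene_sets(summ, c(1, 2, 4, 8, 16), region, d)
      for (i in 2:5) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
    }
  }
})

test_that("gene set sizes match an independent per-gene tally of the truth", {
  sim <- suppressMessages(simulate_study(tiny_config(seed = 42)))
  res <- run_small_analysis(sim)
  summ <- summarize_genes(res$dm, res$assignment, res$catalog)
  # independent tally: join called directions onto the generator's own
  # per-probe gene/segment assignment (recorded in the truth table)
  tr <- sim$methylation$truth
  dirs <- stats::setNames(res$dm$direction, res$dm$probe_id)
  tr$called <- dirs[tr$probe_id]
  intra <- tr[!is.na(tr$gene_id), ]
  tally_h <- tapply(intra$called == "hyper", intra$gene_id, sum)
  tally_o <- tapply(intra$called == "hypo", intra$gene_id, sum)
  genes_hyper_only <- names(tally_h)[tally_h >= 1 & tally_o == 0]
  for (k in c(1, 2, 4)) {
    want <- names(tally_h)[tally_h >= k & tally_o == 0]
    got <- threshold_gene_sets(summ, k, "intragenic", "hyper")[[1]]
    expect_equal(sort(got), sort(want), info = k)
  }
})

test_that("cross-tabulation counts labels with unlabeled genes as unchanged", {
  sets <- list(`1` = c("a", "b", "c", "d"), `2` = c("a", "b"))
  labels <- data.frame(gene_id = c("a", "b", "c"),
                       label = c("up", "down", "up"))
  expect_warning(ct <- crosstab_expression(sets, labels), "missing")
  expect_equal(ct$up, c(2, 1))
  expect_equal(ct$down, c(1, 1))
  expect_equal(ct$unchanged, c(1, 0))
  expect_equal(ct$n, c(4, 2))
  # empty set: all-zero row
  ct0 <- crosstab_expression(list(`1` = character(0)), labels)
  expect_equal(unlist(ct0[c("up", "down", "unchanged", "n")]),
               c(up = 0, down = 0, unchanged = 0, n = 0))
})

test_that("forced concordance pins the crosstab", {
  # concordance probability 1: every hypo-only gene is labeled up
  cfg <- tiny_config(seed = 43, conc_base = 1, background_change = 0)
  sim <- suppressMessages(simulate_study(cfg))
  lab <- sim$expression_labels
  expect_true(all(lab$label[lab$pattern == "hypo"] == "up"))
  expect_true(all(lab$label[lab$pattern == "hyper"] == "down"))
  expect_true(all(lab$label[lab$pattern == "hyper3"] == "up"))
  expect_true(all(lab$label[lab$pattern == "none"] == "unchanged"))
})

test_that("hypergeometric overlap matches enumeration and anchors", {
  u <- letters[1:10]
  expect_equal(hypergeometric_overlap(u[1:5], u[1:5], 10), 1 / 252,
               tolerance = 1e-12)
  # zero overlap: upper tail includes everything
  expect_equal(hypergeometric_overlap(u[1:5], u[6:10], 10), 1)
  # B = universe: overlap forced
  expect_equal(hypergeometric_overlap(u[1:4], u, 10), 1)
  expect_error(hypergeometric_overlap(letters[1:11], u[1:2], 10), "universe")
  # enumeration sweep, universes <= 12
  set.seed(44)
  for (i in 1:40) {
    N <- sample(3:12, 1)
    a <- sample(1:N, 1); b <- sample(1:N, 1)
    set_a <- sample(seq_len(N), a)
    set_b <- sample(seq_len(N), b)
    k <- length(intersect(set_a, set_b))
    got <- hypergeometric_overlap(as.character(set_a), as.character(set_b), N)
    want <- hyper_upper_oracle(k, a, b, N)
    expect_equal(got, unname(want), tolerance = 1e-12, info = i)
  }
})

test_that("count correlation anchors and null behavior", {
  s <- data.frame(gene_id = sprintf("g%d", 1:10), region = "intragenic",
                  n_acpg = 1:10, n_hyper = 1:10, n_hypo = 0,
                  designation = "hyper-only")
  expect_equal(as.numeric(count_correlation(s)), 1)
  # constant dm counts: flagged undefined
  s2 <- s; s2$n_hyper <- 2
  expect_warning(r <- count_correlation(s2), "constant|fewer")
  expect_true(is.na(r))
  # dm counts independent of probe counts: r near 0
  set.seed(45)
  s3 <- data.frame(gene_id = sprintf("g%d", 1:400), region = "intragenic",
                   n_acpg = sample(10:60, 400, replace = TRUE),
                   n_hyper = rpois(400, 2) + 1, n_hypo = 0,
                   designation = "hyper-only")
  r3 <- as.numeric(count_correlation(s3))
  expect_lt(abs(r3), 3 / sqrt(400))
})
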