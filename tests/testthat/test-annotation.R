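# Region catalog construction: gene segmentation, TSS/TES windows, shores,
# GC skew, promoter classes and probe assignment.

test_that("gene segmentation follows transcription direction and floor rounding", {
  plus <- data.frame(gene_id = "g1", chrom = "c", start = 0, end = 9000,
                     strand = "+")
  s <- segment_genes(plus)
  expect_equal(s$start[s$segment == "5prime"], 0)
  expect_equal(s$end[s$segment == "5prime"], 3000)
  expect_equal(s$start[s$segment == "central"], 3000)
  expect_equal(s$end[s$segment == "central"], 6000)
  expect_equal(s$start[s$segment == "3prime"], 6000)
  expect_equal(s$end[s$segment == "3prime"], 9000)

  minus <- plus; minus$strand <- "-"
  s <- segment_genes(minus)
  expect_equal(unname(s$start[s$segment == "5prime"]), 6000)
  expect_equal(unname(s$end[s$segment == "5prime"]), 9000)
  expect_equal(unname(s$start[s$segment == "3prime"]), 0)
  expect_equal(unname(s$end[s$segment == "3prime"]), 3000)

  # floor-of-cumulative-fraction rule
  g <- data.frame(gene_id = "g1", chrom = "c", start = 0, end = 10,
                  strand = "+")
  s <- segment_genes(g, fractions = c(0.3, 0.4, 0.3))
  expect_equal(s$end[s$segment == "5prime"], 3)
  expect_equal(s$end[s$segment == "central"], 7)
})

test_that("segments partition the gene body for all short lengths", {
  # hand enumeration: every base belongs to exactly one segment, boundaries
  # at floor(f1*L) and floor((f1+f2)*L) bases from the 5' end
  for (L in 3:20) {
    for (strand in c("+", "-")) {
      g <- data.frame(gene_id = "g", chrom = "c", start = 5, end = 5 + L,
                      strand = strand)
      s <- segment_genes(g, fractions = c(0.3, 0.4, 0.3))
      covered <- integer(L)
      for (i in seq_len(nrow(s))) {
        covered[(s$start[i] - 5 + 1):(s$end[i] - 5)] <-
          covered[(s$start[i] - 5 + 1):(s$end[i] - 5)] + 1L
      }
      expect_true(all(covered == 1L), info = paste(L, strand))
      b1 <- floor(0.3 * L); b2 <- floor(0.7 * L)
      n5 <- sum(s$end[s$segment == "5prime"] - s$start[s$segment == "5prime"])
      expect_equal(n5, b1, info = paste(L, strand))
      nc <- sum(s$end[s$segment == "central"] - s$start[s$segment == "central"])
      expect_equal(nc, b2 - b1, info = paste(L, strand))
    }
  }
})

test_that("genes shorter than 3 bases are unsegmentable and fully central", {
  g <- data.frame(gene_id = "g", chrom = "c", start = 10, end = 12,
                  strand = "+")
  s <- segment_genes(g)
  expect_true(all(s$unsegmentable))
  expect_equal(s$segment, "central")
  expect_equal(s$start, 10)
  expect_equal(s$end, 12)
})

test_that("TSS/TES windows are centered, clipped and strand-aware", {
  g <- data.frame(gene_id = "g", chrom = "c", start = 5000, end = 9000,
                  strand = "+")
  w <- tss_tes_windows(g, widths = 1500)
  tssw <- w[w$site == "TSS", ]
  expect_equal(tssw$start, 3500)
  expect_equal(tssw$end, 6500)

  # clipping at the chromosome start
  g2 <- data.frame(gene_id = "g", chrom = "c", start = 500, end = 4000,
                   strand = "+")
  w2 <- tss_tes_windows(g2, widths = 1500)
  expect_equal(w2$start[w2$site == "TSS"], 0)
  expect_equal(w2$end[w2$site == "TSS"], 2000)

  # minus strand: TSS is end - 1
  g3 <- data.frame(gene_id = "g", chrom = "c", start = 0, end = 9000,
                   strand = "-")
  w3 <- tss_tes_windows(g3, widths = 200,
                        chrom_lengths = c(c = 100000))
  expect_equal(unname(w3$start[w3$site == "TSS"]), 8799)
  expect_equal(unname(w3$end[w3$site == "TSS"]), 9199)
})

test_that("shores flank islands and never contain island bases", {
  cl <- c(c = 1e5)
  cgi <- data.frame(chrom = "c", start = 5000, end = 6000, strand = "*")
  sh <- compute_shores(cgi, 2000, cl)
  expect_equal(sh$start, c(3000, 6000))
  expect_equal(sh$end, c(5000, 8000))

  # clipped at chromosome start
  cgi2 <- data.frame(chrom = "c", start = 500, end = 1500, strand = "*")
  sh2 <- compute_shores(cgi2, 2000, cl)
  expect_equal(sh2$start[1], 0)
  expect_equal(sh2$end[1], 500)

  # inter-island shore appears once, with no island bases
  cgi3 <- data.frame(chrom = "c", start = c(1000, 3000),
                     end = c(2000, 4000), strand = "*")
  sh3 <- compute_shores(cgi3, 2000, cl)
  mid <- sh3[sh3$start >= 2000 & sh3$end <= 3000, ]
  expect_equal(nrow(mid), 1)
  expect_equal(c(mid$start, mid$end), c(2000, 3000))

  # per-base property on random layouts
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(2:6, 1)
    s <- sort(sample.int(3e4, n))
    cgis <- data.frame(chrom = "c", start = s,
                       end = s + sample(100:2500, n, replace = TRUE),
                       strand = "*")
    shores <- compute_shores(cgis, 2000, c(c = 4e4))
    base_cgi <- mark_bases(cgis, "c", 4e4)
    base_shore <- mark_bases(shores, "c", 4e4)
    expect_false(any(base_cgi & base_shore))
    expect_equal(base_shore, win_from_intervals(cgis, "c", 4e4, 2000) & !base_cgi)
  }
})

test_that("GC skew profile matches direct counting and negates under G<->C swap", {
  expect_equal(gc_skew_profile("GGGGGGGG", 8, 8)$skew, 1)
  expect_equal(gc_skew_profile("GCGCATGC", 8, 8)$skew, 0)
  expect_equal(gc_skew_profile("GGGGGGCC", 8, 8)$skew, 0.5)
  expect_true(is.na(gc_skew_profile("ATATATAT", 8, 8)$skew))
  expect_equal(nrow(gc_skew_profile("", 10, 5)), 0)

  set.seed(3)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
               collapse = "")
  prof <- gc_skew_profile(seq, 200, 50)
  swapped <- chartr("GC", "CG", seq)
  prof2 <- gc_skew_profile(swapped, 200, 50)
  expect_equal(prof2$skew, -prof$skew)
  expect_equal(prof$start, seq(0, 3000 - 200, by = 50))
})

test_that("skew regions are maximal constant-sign runs above threshold", {
  prof <- data.frame(start = seq(0, 450, by = 50),
                     end = seq(0, 450, by = 50) + 100,
                     skew = c(0.2, 0.3, 0.25, 0.05, -0.2, -0.3, -0.15, NA,
                              0.2, 0.2))
  r <- call_skew_regions(prof, threshold = 0.1, min_run = 3, chrom = "c")
  expect_equal(nrow(r), 2)
  expect_equal(r$sign, c(1, -1))
  expect_equal(r$start, c(0, 200))
  expect_equal(r$end, c(200, 400))  # first window start to last window end
  # run of 2 below min_run is dropped
  expect_false(any(r$start == 400))
})

test_that("promoter classification counts 1-base overlaps", {
  cl <- c(c = 1e5)
  genes <- data.frame(gene_id = c("both", "none", "touch"),
                      chrom = "c", start = c(10000, 30000, 50000),
                      end = c(15000, 35000, 55000), strand = "+")
  # promoters: [8500,11500), [28500,31500), [48500,51500)
  cgis <- data.frame(chrom = "c", start = c(9000, 51499),
                     end = c(9500, 53000), strand = "*")
  skew <- data.frame(chrom = "c", start = 10000, end = 10200, strand = "*")
  pc <- classify_promoters(genes, cgis, skew, 1500, cl)
  expect_equal(pc$class[pc$gene_id == "both"], "CGI+skew")
  expect_equal(pc$class[pc$gene_id == "none"], "noCGI-noskew")
  # island starting at the last promoter base (51499) still counts
  expect_equal(pc$class[pc$gene_id == "touch"], "CGI-noskew")
  # island starting exactly at the half-open end does not
  cgis2 <- data.frame(chrom = "c", start = 51500, end = 53000, strand = "*")
  pc2 <- classify_promoters(genes, cgis2, skew, 1500, cl)
  expect_equal(pc2$class[pc2$gene_id == "touch"], "noCGI-noskew")
})

test_that("probe category assignment matches the per-base oracle on random genomes", {
  n_checked <- 0
  for (seed in 1:25) {
    toy <- random_toy_genome(seed)
    catalog <- build_region_catalog(toy$genes, toy$cgis, toy$skew_regions,
                                    toy$chrom_lengths)
    assignment <- assign_probe_categories(toy$manifest, catalog)
    membership <- oracle_base_membership(toy$genes, toy$cgis,
                                         toy$skew_regions, toy$chrom_lengths)
    expected <- oracle_probe_categories(membership, toy$manifest)
    got <- split(assignment$memberships$category,
                 assignment$memberships$probe_id)
    for (pid in toy$manifest$probe_id) {
      expect_equal(sort(got[[pid]]), sort(expected[[pid]]), info = paste(seed, pid))
    }
    n_checked <- n_checked + nrow(toy$manifest)
  }
  expect_gte(n_checked, 1000)
})

test_that("probe assignment respects the half-open convention and exclusivity", {
  cl <- c(c = 1e5)
  genes <- data.frame(gene_id = "g1", chrom = "c", start = 0, end = 9000,
                      strand = "+")
  cgis <- data.frame(chrom = "c", start = 4000, end = 5000, strand = "*")
  catalog <- build_region_catalog(genes, cgis, empty_cgi(), cl)
  manifest <- data.frame(probe_id = c("in_all", "at_end", "outside"),
                         chrom = "c", pos = c(4500, 9000, 50000),
                         strand = "+")
  a <- assign_probe_categories(manifest, catalog)
  cats <- split(a$memberships$category, a$memberships$probe_id)
  expect_true(all(c("intragenic", "gene-central", "CGI", "CGI-intragenic",
                    "chr:c") %in% cats$in_all))
  expect_false("intergenic" %in% cats$in_all)
  # position 9000 is the half-open end of the gene: outside it
  expect_true("intergenic" %in% cats$at_end)
  expect_false("intragenic" %in% cats$at_end)
  expect_equal(sort(intersect(cats$outside, c("intragenic", "intergenic"))),
               "intergenic")
  # every probe: exactly one of intragenic/intergenic, one chromosome
  for (pid in names(cats)) {
    expect_equal(sum(cats[[pid]] %in% c("intragenic", "intergenic")), 1)
    expect_equal(sum(startsWith(cats[[pid]], "chr:")), 1)
  }
})

test_that("probes on unknown chromosomes keep chromosome category with a warning", {
  cl <- c(c = 1e5)
  genes <- data.frame(gene_id = "g1", chrom = "c", start = 0, end = 9000,
                      strand = "+")
  catalog <- build_region_catalog(genes, empty_cgi(), empty_cgi(), cl)
  manifest <- data.frame(probe_id = c("p1", "p2"), chrom = c("c", "weird"),
                         pos = c(100, 100), strand = "+")
  expect_warning(a <- assign_probe_categories(manifest, catalog),
                 "unknown chromosome")
  cats <- split(a$memberships$category, a$memberships$probe_id)
  expect_equal(cats$p2, "chr:weird")
  expect_true("intragenic" %in% cats$p1)
})
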