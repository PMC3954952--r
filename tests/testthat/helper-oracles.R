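# Independent brute-force oracles. These re-derive expected results from
# first principles (per-base membership vectors, exhaustive threshold/fold
# enumeration, exhaustive subset enumeration) without using the package's
# interval, stump or hypergeometric code paths.

# ---- per-base genome membership -------------------------------------------

# Logical membership vector of length chrom_len (index = base + 1) marked
# from a set of [start, end) rows for one chromosome.
mark_bases <- function(df, chrom, chrom_len) {
  v <- logical(chrom_len)
  rows <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    s <- max(0, rows$start[i]); e <- min(chrom_len, rows$end[i])
    if (s < e) v[(s + 1):e] <- TRUE
  }
  v
}

# Membership vectors for every positional category, computed per base.
oracle_base_membership <- function(genes, cgis, skew, chrom_lengths,
                                   fractions = c(1, 1, 1) / 3,
                                   tss_tes_widths = c(200, 1500),
                                   promoter_halfwidth = 1500,
                                   shore_width = 2000) {
  out <- list()
  for (chrom in names(chrom_lengths)) {
    len <- chrom_lengths[[chrom]]
    m <- list()
    m[["intragenic"]] <- mark_bases(genes, chrom, len)
    m[["intergenic"]] <- !m[["intragenic"]]
    # gene segments from transcription-order base offsets
    seg <- list(`gene-5prime` = logical(len), `gene-central` = logical(len),
                `gene-3prime` = logical(len))
    tssv <- tesv <- numeric(0)
    g <- genes[genes$chrom == chrom, , drop = FALSE]
    for (i in seq_len(nrow(g))) {
      L <- g$end[i] - g$start[i]
      b1 <- floor(fractions[1] * L); b2 <- floor((fractions[1] + fractions[2]) * L)
      for (p in g$start[i]:(g$end[i] - 1)) {
        d <- if (g$strand[i] == "-") g$end[i] - 1 - p else p - g$start[i]
        lab <- if (L < 3) "gene-central"
          else if (d < b1) "gene-5prime"
          else if (d < b2) "gene-central" else "gene-3prime"
        seg[[lab]][p + 1] <- TRUE
      }
      tssv <- c(tssv, if (g$strand[i] == "-") g$end[i] - 1 else g$start[i])
      tesv <- c(tesv, if (g$strand[i] == "-") g$start[i] else g$end[i])
    }
    m <- c(m, seg)
    win <- function(centers, w) {
      v <- logical(len)
      for (cc in centers) {
        s <- max(0, cc - w); e <- min(len, cc + w)
        if (s < e) v[(s + 1):e] <- TRUE
      }
      v
    }
    for (w in tss_tes_widths) {
      m[[paste0("TSS", w)]] <- win(tssv, w)
      m[[paste0("TES", w)]] <- win(tesv, w)
    }
    cgi <- mark_bases(cgis, chrom, len)
    near <- win_from_intervals(cgis, chrom, len, shore_width)
    m[["CGI"]] <- cgi
    m[["CGI-shore"]] <- near & !cgi
    prom <- win(tssv, promoter_halfwidth)
    m[["CGI-promoter"]] <- cgi & prom
    m[["CGI-intragenic"]] <- cgi & m[["intragenic"]]
    m[["CGI-intergenic"]] <- cgi & m[["intergenic"]]
    m[["shore-promoter"]] <- m[["CGI-shore"]] & prom
    m[["shore-intragenic"]] <- m[["CGI-shore"]] & m[["intragenic"]]
    m[["shore-intergenic"]] <- m[["CGI-shore"]] & m[["intergenic"]]
    # promoter classes, gene by gene
    skew_m <- mark_bases(skew, chrom, len)
    for (cl in c("CGI+skew", "CGI-noskew", "noCGI+skew", "noCGI-noskew"))
      m[[paste0("promoter-", cl)]] <- logical(len)
    for (i in seq_len(nrow(g))) {
      pw <- win(tssv[i], promoter_halfwidth)
      has_cgi <- any(pw & cgi); has_skew <- any(pw & skew_m)
      cl <- if (has_cgi && has_skew) "CGI+skew"
        else if (has_cgi) "CGI-noskew"
        else if (has_skew) "noCGI+skew" else "noCGI-noskew"
      key <- paste0("promoter-", cl)
      m[[key]] <- m[[key]] | pw
    }
    out[[chrom]] <- m
  }
  out
}

# bases within `w` of any interval base (including the interval itself)
win_from_intervals <- function(df, chrom, len, w) {
  v <- logical(len)
  rows <- df[df$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    s <- max(0, rows$start[i] - w); e <- min(len, rows$end[i] + w)
    if (s < e) v[(s + 1):e] <- TRUE
  }
  v
}

# categories of one probe from the per-base membership vectors
oracle_probe_categories <- function(membership, manifest) {
  res <- lapply(seq_len(nrow(manifest)), function(i) {
    chrom <- manifest$chrom[i]; pos <- manifest$pos[i]
    m <- membership[[chrom]]
    cats <- names(m)[vapply(m, function(v) v[pos + 1], logical(1))]
    c(cats, paste0("chr:", chrom))
  })
  names(res) <- manifest$probe_id
  res
}

# ---- random toy genome for the interval oracle -----------------------------

random_toy_genome <- function(seed) {
  set.seed(seed)
  len <- sample(20000:50000, 1)
  chrom_lengths <- c(chrA = len)
  n_genes <- sample(3:8, 1)
  starts <- sort(sample.int(len - 3000, n_genes))
  ends <- pmin(starts + sample(500:4000, n_genes, replace = TRUE), len)
  keep <- c(TRUE, diff(starts) > 4500)   # keep genes apart
  starts <- starts[keep]; ends <- ends[keep]
  genes <- data.frame(gene_id = sprintf("g%02d", seq_along(starts)),
                      chrom = "chrA", start = starts, end = ends,
                      strand = sample(c("+", "-"), length(starts), replace = TRUE),
                      stringsAsFactors = FALSE)
  n_cgi <- sample(2:6, 1)
  cs <- sort(sample.int(len - 1500, n_cgi))
  cgis <- data.frame(chrom = "chrA", start = cs,
                     end = pmin(cs + sample(200:1200, n_cgi, replace = TRUE), len),
                     strand = "*", stringsAsFactors = FALSE)
  n_skew <- sample(1:4, 1)
  ss <- sort(sample.int(len - 900, n_skew))
  skew <- data.frame(chrom = "chrA", start = ss,
                     end = pmin(ss + sample(200:800, n_skew, replace = TRUE), len),
                     strand = "*", sign = sample(c(1, -1), n_skew, replace = TRUE),
                     stringsAsFactors = FALSE)
  manifest <- data.frame(probe_id = sprintf("cg%04d", 1:150),
                         chrom = "chrA",
                         pos = sample.int(len, 150) - 1,
                         strand = "+", stringsAsFactors = FALSE)
  list(genes = genes, cgis = cgis, skew_regions = skew,
       chrom_lengths = chrom_lengths, manifest = manifest)
}

# ---- exhaustive decision-stump oracle --------------------------------------

# Enumerates every candidate threshold and direction, scoring by explicit
# prediction; ties broken by lowest threshold, then old-above.
stump_fit_oracle <- function(x, old) {
  u <- sort(unique(x))
  thresholds <- c(-Inf, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- NULL
  for (thr in thresholds) {
    for (dir in c("old-above", "old-below")) {
      pred_old <- if (dir == "old-above") x > thr else x < thr
      err <- mean(pred_old != old)
      if (is.null(best) || err < best$training_error) {
        best <- list(threshold = thr, direction = dir, training_error = err)
      }
    }
  }
  best
}

stump_classify_oracle <- function(rule, v) {
  if (rule$direction == "old-above") v > rule$threshold else v < rule$threshold
}

stump_loocv_oracle <- function(x, old) {
  miss <- 0
  for (i in seq_along(x)) {
    rule <- stump_fit_oracle(x[-i], old[-i])
    if (stump_classify_oracle(rule, x[i]) != old[i]) miss <- miss + 1
  }
  miss / length(x)
}

# ---- exhaustive hypergeometric oracles -------------------------------------

# Distribution of |draw of size n  intersect  first K elements| over all
# C(N, n) subsets of 1..N.
hyper_outcome_freq <- function(K, n, N) {
  draws <- utils::combn(N, n)
  counts <- apply(draws, 2, function(d) sum(d <= K))
  table(factor(counts, levels = 0:min(K, n)))
}

hyper_two_sided_oracle <- function(k, K, n, N) {
  freq <- hyper_outcome_freq(K, n, N)
  total <- sum(freq)
  obs <- freq[as.character(k)]
  sum(freq[freq <= obs * (1 + 1e-9)]) / total
}

hyper_upper_oracle <- function(k, K, n, N) {
  freq <- hyper_outcome_freq(K, n, N)
  sum(freq[as.integer(names(freq)) >= k]) / sum(freq)
}
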