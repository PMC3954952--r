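#' Transcription start and end sites of gene models
#'
#' For a `+` strand gene the TSS is `start` and the TES is `end`; for a `-`
#' strand gene the TSS is `end - 1` (the last transcribed base) and the TES
#' is `start`.
#'
#' @param genes gene data frame (`gene_id`, `chrom`, `start`, `end`, `strand`).
#' @return numeric vector of positions, one per gene.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "-", genes$end - 1, genes$start)
}

#' @rdname gene_tss
#' @export
gene_tes <- function(genes) {
  ifelse(genes$strand == "-", genes$start, genes$end)
}

#' Segment gene bodies into 5', central and 3' regions
#'
#' Splits each gene body into three intervals following the direction of
#' transcription: on the `-` strand the 5' segment sits at the
#' high-coordinate end. Boundaries are `floor(cumsum(fractions) * length)`
#' bases from the 5' end. Genes shorter than 3 bases cannot hold three
#' segments and are flagged unsegmentable, with the whole body labeled
#' `central`.
#'
#' @param genes gene data frame.
#' @param fractions three proportions summing to 1 (5', central, 3').
#' @return data frame `gene_id`, `segment` (`5prime`/`central`/`3prime`),
#'   `chrom`, `start`, `end`, `strand`, `unsegmentable`; zero-width segments
#'   are dropped.
#' @export
segment_genes <- function(genes, fractions = c(1, 1, 1) / 3) {
  stopifnot(length(fractions) == 3, all(fractions >= 0))
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (nrow(genes) == 0) {
    return(data.frame(gene_id = character(), segment = character(),
                      chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), unsegmentable = logical()))
  }
  len <- genes$end - genes$start
  b1 <- floor(fractions[1] * len)
  b2 <- floor((fractions[1] + fractions[2]) * len)
  short <- len < 3
  # per gene: offsets of the three segments from the 5' end, as [from, to)
  seg_rows <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (short[i]) {
      cuts <- c(0, len[i], len[i])   # everything central
    } else {
      cuts <- c(b1[i], b2[i], len[i])
    }
    from5 <- c(0, cuts[1], cuts[2])
    to5 <- cuts
    if (g$strand == "-") {
      start <- g$end - to5
      end <- g$end - from5
    } else {
      start <- g$start + from5
      end <- g$start + to5
    }
    data.frame(gene_id = g$gene_id,
               segment = c("5prime", "central", "3prime"),
               chrom = g$chrom, start = start, end = end, strand = g$strand,
               unsegmentable = short[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, seg_rows)
  out <- out[out$start < out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Windows around transcription start/end sites
#'
#' For every width `w`, an interval of `2w` bases centered on the TSS and on
#' the TES of each gene, clipped at chromosome bounds.
#'
#' @param genes gene data frame.
#' @param widths positive integers (defaults follow the TSS200/TSS1500 array
#'   annotation convention).
#' @param chrom_lengths named vector of chromosome lengths (for clipping);
#'   `NULL` clips at 0 only.
#' @return data frame `gene_id`, `site` (`TSS`/`TES`), `width`, `chrom`,
#'   `start`, `end`.
#' @export
tss_tes_windows <- function(genes, widths = c(200, 1500), chrom_lengths = NULL) {
  stopifnot(all(widths > 0))
  tss <- gene_tss(genes)
  tes <- gene_tes(genes)
  rows <- lapply(widths, function(w) {
    data.frame(gene_id = rep(genes$gene_id, 2),
               site = rep(c("TSS", "TES"), each = nrow(genes)),
               width = w,
               chrom = rep(genes$chrom, 2),
               start = c(tss - w, tes - w),
               end = c(tss + w, tes + w),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$start <- pmax(out$start, 0)
  if (!is.null(chrom_lengths)) {
    out$end <- pmin(out$end, as.numeric(chrom_lengths[out$chrom]))
  }
  out <- out[out$start < out$end, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compute CpG-island shores
#'
#' Shores are the flanking `width` bases on each side of every (merged) CpG
#' island, with any base belonging to an island removed and overlapping
#' shore fragments merged.
#'
#' @param cgis interval data frame of CpG islands.
#' @param width flank width in bases (default 2000).
#' @param chrom_lengths named chromosome lengths for clipping (optional).
#' @return merged interval data frame of shores; never intersects the
#'   merged island set.
#' @export
compute_shores <- function(cgis, width = 2000, chrom_lengths = NULL) {
  cgis <- gi_merge(cgis)
  if (nrow(cgis) == 0) return(empty_intervals())
  flanks <- data.frame(
    chrom = rep(cgis$chrom, 2),
    start = c(cgis$start - width, cgis$end),
    end = c(cgis$start, cgis$end + width),
    strand = "*", stringsAsFactors = FALSE)
  flanks$start <- pmax(flanks$start, 0)
  if (!is.null(chrom_lengths)) flanks <- gi_clip(flanks, chrom_lengths)
  flanks <- flanks[flanks$start < flanks$end, , drop = FALSE]
  gi_subtract(flanks, cgis)
}

#' Sliding-window GC skew of a nucleotide sequence
#'
#' Skew per window is `(G - C) / (G + C)` on the given strand; windows with
#' no G or C are undefined (`NA`).
#'
#' @param sequence a character string or [Biostrings::DNAString] over
#'   `A,C,G,T,N`.
#' @param window window size in bases (>= 1).
#' @param step step between window starts.
#' @return data frame `start`, `end` (0-based half-open window coordinates)
#'   and `skew`; empty for sequences shorter than one window.
#' @export
gc_skew_profile <- function(sequence, window = 200, step = 50) {
  stopifnot(window >= 1, step >= 1)
  dna <- if (inherits(sequence, "DNAString")) sequence else
    Biostrings::DNAString(as.character(sequence))
  len <- length(dna)
  if (len < window)
    return(data.frame(start = numeric(), end = numeric(), skew = numeric()))
  starts <- seq(0, len - window, by = step)
  v <- Biostrings::Views(dna, start = starts + 1, width = window)
  counts <- Biostrings::letterFrequency(v, c("G", "C"))
  g <- counts[, "G"]; cc <- counts[, "C"]
  skew <- ifelse(g + cc == 0, NA_real_, (g - cc) / (g + cc))
  data.frame(start = starts, end = starts + window, skew = skew)
}

#' Call GC-skew regions from a skew profile
#'
#' A region is a maximal run of at least `min_run` consecutive windows whose
#' skew has constant sign and magnitude `>= threshold`; undefined windows
#' break runs. The region spans from the first window's start to the last
#' window's end.
#'
#' @param profile output of [gc_skew_profile()] for one chromosome.
#' @param threshold minimum `|skew|` (default 0.1).
#' @param min_run minimum run length in windows (default 3).
#' @param chrom chromosome name stamped on the output.
#' @return interval data frame with a `sign` column (+1/-1).
#' @export
call_skew_regions <- function(profile, threshold = 0.1, min_run = 3,
                              chrom = "chr") {
  if (nrow(profile) == 0)
    return(cbind(empty_intervals(), sign = numeric()))
  s <- profile$skew
  state <- ifelse(is.na(s), 0L, ifelse(s >= threshold, 1L,
                                       ifelse(s <= -threshold, -1L, 0L)))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  begins <- ends - r$lengths + 1
  keep <- r$values != 0L & r$lengths >= min_run
  if (!any(keep)) return(cbind(empty_intervals(), sign = numeric()))
  data.frame(chrom = chrom,
             start = profile$start[begins[keep]],
             end = profile$end[ends[keep]],
             strand = "*",
             sign = r$values[keep],
             stringsAsFactors = FALSE)
}

#' GC-skew regions for a set of chromosome sequences
#'
#' @param sequences named character vector or [Biostrings::DNAStringSet]
#'   (names are chromosome names), or a FASTA path.
#' @inheritParams gc_skew_profile
#' @inheritParams call_skew_regions
#' @return interval data frame with `sign`.
#' @export
find_skew_regions <- function(sequences, window = 200, step = 50,
                              threshold = 0.1, min_run = 3) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  nms <- names(sequences)
  if (is.null(nms)) stop("sequences must be named by chromosome")
  out <- lapply(nms, function(nm) {
    prof <- gc_skew_profile(sequences[[nm]], window, step)
    call_skew_regions(prof, threshold, min_run, chrom = nm)
  })
  do.call(rbind, out)
}

#' Classify gene promoters by CpG island and GC-skew content
#'
#' The promoter is the `+/- promoter_halfwidth` window around the TSS; it
#' "has" an island (or skew region) when the window overlaps one by at
#' least one base.
#'
#' @param genes gene data frame.
#' @param cgis CpG-island intervals.
#' @param skew_regions GC-skew intervals (the `sign` column is ignored:
#'   presence of skew is what is classified).
#' @param promoter_halfwidth half-width of the promoter window (default 1500).
#' @param chrom_lengths optional named lengths for clipping.
#' @return data frame `gene_id`, `has_cgi`, `has_skew`, `class` with class
#'   one of `CGI+skew`, `CGI-noskew`, `noCGI+skew`, `noCGI-noskew`.
#' @export
classify_promoters <- function(genes, cgis, skew_regions,
                               promoter_halfwidth = 1500,
                               chrom_lengths = NULL) {
  prom <- promoter_windows(genes, promoter_halfwidth, chrom_lengths)
  pg <- gi_to_gr(prom)
  has_cgi <- if (nrow(cgis)) IRanges::overlapsAny(pg, gi_to_gr(cgis),
                                                  ignore.strand = TRUE)
             else rep(FALSE, nrow(prom))
  has_skew <- if (nrow(skew_regions)) IRanges::overlapsAny(pg,
                  gi_to_gr(skew_regions), ignore.strand = TRUE)
              else rep(FALSE, nrow(prom))
  cls <- ifelse(has_cgi,
                ifelse(has_skew, "CGI+skew", "CGI-noskew"),
                ifelse(has_skew, "noCGI+skew", "noCGI-noskew"))
  data.frame(gene_id = prom$gene_id, has_cgi = has_cgi, has_skew = has_skew,
             class = cls, stringsAsFactors = FALSE)
}

promoter_windows <- function(genes, halfwidth = 1500, chrom_lengths = NULL) {
  tss <- gene_tss(genes)
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = pmax(tss - halfwidth, 0), end = tss + halfwidth,
                    strand = "*", stringsAsFactors = FALSE)
  if (!is.null(chrom_lengths))
    out$end <- pmin(out$end, as.numeric(chrom_lengths[out$chrom]))
  out[out$start < out$end, , drop = FALSE]
}

#' Build the region catalog
#'
#' Assembles every positional category used by the enrichment stage:
#' intragenic/intergenic, gene 5'/central/3' segments, TSS/TES windows, CpG
#' islands and shores (each crossed with promoter / intragenic / intergenic
#' context), the four promoter CGI-by-skew classes, and (implicitly, at
#' probe-assignment time) one category per chromosome.
#'
#' @param genes gene data frame.
#' @param cgis CpG-island intervals.
#' @param skew_regions GC-skew intervals (may be empty).
#' @param chrom_lengths named vector of chromosome lengths.
#' @param tss_tes_widths TSS/TES window half-widths.
#' @param promoter_halfwidth promoter half-width around the TSS.
#' @param shore_width shore flank width.
#' @param gene_fractions 5'/central/3' fractions of the gene body.
#' @return object of class `region_catalog`: a list with the interval sets
#'   (`categories`), per-gene segment table (`gene_segments`), promoter
#'   windows and classes, and the inputs.
#' @export
build_region_catalog <- function(genes, cgis, skew_regions, chrom_lengths,
                                 tss_tes_widths = c(200, 1500),
                                 promoter_halfwidth = 1500,
                                 shore_width = 2000,
                                 gene_fractions = c(1, 1, 1) / 3) {
  validate_intervals(genes, chrom_lengths)
  if (nrow(cgis)) validate_intervals(cgis, chrom_lengths)
  cgi_m <- gi_merge(cgis)
  shores <- compute_shores(cgi_m, shore_width, chrom_lengths)
  segs <- segment_genes(genes, gene_fractions)
  intragenic <- gi_merge(genes)
  intergenic <- gi_complement(intragenic, chrom_lengths)
  prom <- promoter_windows(genes, promoter_halfwidth, chrom_lengths)
  prom_class <- classify_promoters(genes, cgi_m, skew_regions,
                                   promoter_halfwidth, chrom_lengths)
  prom_merged <- gi_merge(prom)

  cats <- list(
    intragenic = intragenic,
    intergenic = intergenic,
    `gene-5prime` = gi_merge(segs[segs$segment == "5prime", ]),
    `gene-central` = gi_merge(segs[segs$segment == "central", ]),
    `gene-3prime` = gi_merge(segs[segs$segment == "3prime", ]),
    CGI = cgi_m,
    `CGI-shore` = shores,
    `CGI-promoter` = gi_intersect(cgi_m, prom_merged),
    `CGI-intragenic` = gi_intersect(cgi_m, intragenic),
    `CGI-intergenic` = gi_intersect(cgi_m, intergenic),
    `shore-promoter` = gi_intersect(shores, prom_merged),
    `shore-intragenic` = gi_intersect(shores, intragenic),
    `shore-intergenic` = gi_intersect(shores, intergenic)
  )
  tt <- tss_tes_windows(genes, tss_tes_widths, chrom_lengths)
  for (w in tss_tes_widths) {
    for (site in c("TSS", "TES")) {
      cats[[paste0(site, w)]] <-
        gi_merge(tt[tt$site == site & tt$width == w, ])
    }
  }
  for (cl in c("CGI+skew", "CGI-noskew", "noCGI+skew", "noCGI-noskew")) {
    ids <- prom_class$gene_id[prom_class$class == cl]
    cats[[paste0("promoter-", cl)]] <-
      gi_merge(prom[prom$gene_id %in% ids, ])
  }
  structure(list(categories = cats,
                 gene_segments = segs,
                 promoters = prom,
                 promoter_class = prom_class,
                 genes = genes,
                 cgis = cgi_m,
                 skew_regions = skew_regions,
                 chrom_lengths = chrom_lengths,
                 params = list(tss_tes_widths = tss_tes_widths,
                               promoter_halfwidth = promoter_halfwidth,
                               shore_width = shore_width,
                               gene_fractions = gene_fractions)),
            class = "region_catalog")
}

#' Assign probes to region categories
#'
#' Each probe receives every catalog category whose interval set contains
#' its position (half-open: a probe exactly at an interval's `end` is
#' outside), plus one `chr:<name>` category. Intragenic/intergenic and
#' chromosome assignments are exhaustive and mutually exclusive. Probes on
#' chromosomes unknown to the catalog are kept in their chromosome category
#' but excluded, with a warning, from positional categories.
#'
#' @param manifest probe manifest (`probe_id`, `chrom`, `pos`, `strand`).
#' @param catalog a [build_region_catalog()] result.
#' @return object of class `probe_categories`: list with `memberships`
#'   (long data frame `probe_id`, `category`), `probe_genes` (`probe_id`,
#'   `gene_id`, `segment` for probes inside gene bodies) and
#'   `probe_promoters` (`probe_id`, `gene_id` for probes inside promoter
#'   windows).
#' @export
assign_probe_categories <- function(manifest, catalog) {
  stopifnot(inherits(catalog, "region_catalog"))
  if (anyDuplicated(manifest$probe_id)) stop("duplicated probe ids")
  known <- manifest$chrom %in% names(catalog$chrom_lengths)
  if (!all(known)) {
    warning(sum(!known), " probe(s) on unknown chromosomes excluded from ",
            "positional categories")
  }
  pos_manifest <- manifest[known, , drop = FALSE]
  pgr <- probes_to_gr(pos_manifest)

  mem <- lapply(names(catalog$categories), function(nm) {
    df <- catalog$categories[[nm]]
    if (nrow(df) == 0) return(NULL)
    hit <- IRanges::overlapsAny(pgr, gi_to_gr(df), ignore.strand = TRUE)
    if (!any(hit)) return(NULL)
    data.frame(probe_id = pos_manifest$probe_id[hit], category = nm,
               stringsAsFactors = FALSE)
  })
  chrom_mem <- data.frame(probe_id = manifest$probe_id,
                          category = paste0("chr:", manifest$chrom),
                          stringsAsFactors = FALSE)
  memberships <- rbind(do.call(rbind, mem), chrom_mem)
  rownames(memberships) <- NULL

  segs <- catalog$gene_segments
  probe_genes <- overlap_join(pos_manifest, segs,
                              c("gene_id", "segment"))
  probe_promoters <- overlap_join(pos_manifest, catalog$promoters,
                                  "gene_id")
  structure(list(memberships = memberships,
                 probe_genes = probe_genes,
                 probe_promoters = probe_promoters,
                 n_probes = nrow(manifest),
                 probe_ids = manifest$probe_id),
            class = "probe_categories")
}

# probes x intervals overlap join carrying `cols` from the interval table
overlap_join <- function(manifest, df, cols) {
  out0 <- cbind(data.frame(probe_id = character()),
                stats::setNames(rep(list(character()), length(cols)), cols))
  if (nrow(df) == 0 || nrow(manifest) == 0) return(out0)
  hits <- GenomicRanges::findOverlaps(probes_to_gr(manifest), gi_to_gr(df),
                                      ignore.strand = TRUE)
  if (length(hits) == 0) return(out0)
  res <- data.frame(probe_id = manifest$probe_id[S4Vectors::queryHits(hits)],
                    df[S4Vectors::subjectHits(hits), cols, drop = FALSE],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}
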