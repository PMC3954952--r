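#' Read intervals from a BED file
#'
#' BED3/BED6, parsed with [rtracklayer::import()] and returned in the
#' package's 0-based half-open data-frame representation. The BED `name`
#' column, when present, is kept as `name`.
#'
#' @param path path to a BED file.
#' @return interval data frame (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  df <- gr_to_gi(gr)
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) df$name <- as.character(nm)
  df
}

#' Write intervals to a BED file
#'
#' @param df interval data frame; an optional `name` column becomes the BED
#'   name field.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  gr <- gi_to_gr(df)
  if ("name" %in% names(df)) S4Vectors::mcols(gr)$name <- df$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read gene models from BED6 or GFF3
#'
#' BED6 genes use the `name` field as `gene_id`; GFF3 keeps records with
#' feature type `gene` and uses the `ID` attribute. GFF3's 1-based inclusive
#' coordinates are converted to the package's 0-based half-open convention
#' by rtracklayer.
#'
#' @param path path to a `.bed`, `.gff`, `.gff3` file.
#' @param format `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return data frame with `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  if (format == "bed") {
    df <- read_bed(path)
    if (is.null(df$name)) stop("gene BED must carry gene ids in the name field")
    gene_id <- df$name
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
    df <- gr_to_gi(gr)
    gene_id <- as.character(S4Vectors::mcols(gr)$ID)
    if (anyNA(gene_id)) stop("GFF3 gene records must carry an ID attribute")
  }
  out <- data.frame(gene_id = gene_id, chrom = df$chrom, start = df$start,
                    end = df$end, strand = df$strand, stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) stop("duplicated gene ids")
  validate_intervals(out)
  out
}

#' Read a probe manifest
#'
#' Tab-separated file with header `probe_id chrom pos strand`; `pos` is the
#' 0-based base coordinate of the interrogated CpG.
#'
#' @param path TSV path.
#' @return data frame with those four columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("probe_id", "chrom", "pos", "strand")
  if (!all(need %in% names(df))) stop("manifest needs columns: ",
                                      paste(need, collapse = " "))
  if (anyDuplicated(df$probe_id)) stop("duplicated probe ids in manifest")
  df[need]
}

#' Read a beta-value matrix
#'
#' TSV with a `probe_id` column followed by one column per sample.
#'
#' @param path TSV path.
#' @return numeric matrix, probes in rows (rownames = probe ids).
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") stop("first column must be probe_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  storage.mode(m) <- "double"
  m
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `group` (values `young`/`old`) and
#' optionally `age`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_samples <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stop("sample sheet needs sample_id and group columns")
  if (!all(df$group %in% c("young", "old")))
    stop("group labels must be 'young' or 'old'")
  df
}

#' Read expression-change labels
#'
#' TSV with columns `gene_id` and `label` in `up`/`down`/`unchanged`.
#'
#' @param path TSV path.
#' @return data frame.
#' @export
read_expression_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "label") %in% names(df)))
    stop("label file needs gene_id and label columns")
  bad <- setdiff(unique(df$label), c("up", "down", "unchanged"))
  if (length(bad)) stop("unknown expression labels: ", paste(bad, collapse = ", "))
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_beta_matrix <- function(m, path) {
  write_tsv(data.frame(probe_id = rownames(m), m, check.names = FALSE,
                       stringsAsFactors = FALSE), path)
}
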