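# Tab-separated readers and writers for the pipeline's table dialects.
# All tables are written with a fixed column order, tab separation, no
# quoting, and floats at 6 significant digits, so reruns are byte-stable.

write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, what) {
  if (!file.exists(path))
    stop_validation(sprintf("%s: file not found: %s", what, path))
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read and write the pipeline's annotation table
#'
#' External dialect header: `contig_id`, `length`, `source`, `viral_genes`,
#' `host_genes`, `score`, `hallmarks`; mapped to the package's internal
#' column names.
#'
#' @param path TSV path.
#' @return data.frame in internal column names.
#' @export
read_annotations <- function(path) {
  d <- read_tsv(path, "annotations")
  stop_if_not_cols(d, c("contig_id", "length", "source", "viral_genes",
                        "host_genes", "score", "hallmarks"), "annotations")
  data.frame(contig_id = d$contig_id, length_bp = d$length,
             source_fraction = d$source, viral_gene_count = d$viral_genes,
             host_gene_count = d$host_genes, vs_score = d$score,
             hallmark_count = d$hallmarks, stringsAsFactors = FALSE)
}

#' @rdname read_annotations
#' @param annotations internal-format annotations data.frame.
#' @export
write_annotations <- function(annotations, path) {
  write_tsv(data.frame(contig_id = annotations$contig_id,
                       length = annotations$length_bp,
                       source = annotations$source_fraction,
                       viral_genes = annotations$viral_gene_count,
                       host_genes = annotations$host_gene_count,
                       score = annotations$vs_score,
                       hallmarks = annotations$hallmark_count), path)
}

#' Read an ANI table, raw BLAST or pre-aggregated
#'
#' Pre-aggregated tables carry a header with `query_id`, `subject_id`,
#' `ani_pct` (optionally `aligned_fraction`). A headerless 12-column file
#' is treated as BLAST outfmt 6 (`qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore`, 1-based inclusive
#' coordinates) and aggregated per directed pair by identity-weighted
#' alignment length: `ANI = sum(pident * length) / sum(length)`; with
#' `contig_lengths` given, `aligned_fraction = min(1, sum(length) / query
#' length)`.
#'
#' @param path TSV path.
#' @param contig_lengths optional named lengths for aligned-fraction
#'   computation on raw BLAST input.
#' @return data.frame `query_id`, `subject_id`, `ani_pct`,
#'   `aligned_fraction`.
#' @export
read_ani_table <- function(path, contig_lengths = NULL) {
  if (!file.exists(path))
    stop_validation(sprintf("ani table: file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (grepl("query_id", first, fixed = TRUE)) {
    d <- read_tsv(path, "ani table")
    stop_if_not_cols(d, c("query_id", "subject_id", "ani_pct"), "ani table")
    if (is.null(d$aligned_fraction)) d$aligned_fraction <- NA_real_
    return(d[, c("query_id", "subject_id", "ani_pct", "aligned_fraction")])
  }
  d <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) != 12L)
    stop_validation("headerless ANI input must be 12-column BLAST outfmt 6")
  names(d) <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                "gapopen", "qstart", "qend", "sstart", "send", "evalue",
                "bitscore")
  aggregate_blast_ani(d, contig_lengths)
}

#' Aggregate raw BLAST HSPs into directed ANI values
#'
#' @param hsps data.frame in outfmt-6 column names (see
#'   [read_ani_table()]); self-hits are dropped.
#' @param contig_lengths optional named vector for `aligned_fraction`.
#' @return data.frame `query_id`, `subject_id`, `ani_pct`,
#'   `aligned_fraction`.
#' @export
aggregate_blast_ani <- function(hsps, contig_lengths = NULL) {
  hsps <- hsps[hsps$qseqid != hsps$sseqid, , drop = FALSE]
  key <- paste(hsps$qseqid, hsps$sseqid, sep = "\r")
  wsum <- tapply(hsps$pident * hsps$length, key, sum)
  lsum <- tapply(hsps$length, key, sum)
  parts <- do.call(rbind, strsplit(names(wsum), "\r", fixed = TRUE))
  out <- data.frame(query_id = parts[, 1L], subject_id = parts[, 2L],
                    ani_pct = as.numeric(wsum / lsum),
                    aligned_fraction = NA_real_, stringsAsFactors = FALSE)
  if (!is.null(contig_lengths))
    out$aligned_fraction <- pmin(1, as.numeric(lsum) /
                                   contig_lengths[out$query_id])
  out[order(out$query_id, out$subject_id), , drop = FALSE]
}

#' Read an abundance matrix TSV (features x samples)
#'
#' First column `feature_id`, remaining columns one per sample.
#'
#' @param path TSV path.
#' @param kind value kind of the stored matrix.
#' @return an `abundance_table`.
#' @export
read_abundance_matrix <- function(path, kind = "count") {
  d <- read_tsv(path, "abundance matrix")
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  abundance_table(m, kind)
}

#' @rdname read_abundance_matrix
#' @param table an `abundance_table` to write.
#' @export
write_abundance_matrix <- function(table, path) {
  df <- data.frame(feature_id = rownames(table),
                   unclass(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

read_library_sizes <- function(path) {
  d <- read_tsv(path, "library sizes")
  stop_if_not_cols(d, c("sample_id", "library_size"), "library sizes")
  if (any(d$library_size <= 0))
    stop_validation("library sizes must be positive")
  stats::setNames(d$library_size, d$sample_id)
}

read_spacer_hits <- function(path) {
  d <- read_tsv(path, "spacer hits")
  stop_if_not_cols(d, c("spacer_id", "mag_id", "target_contig", "pident",
                        "align_len", "spacer_len"), "spacer hits")
  data.frame(spacer_id = d$spacer_id, mag_id = d$mag_id,
             spacer_len = d$spacer_len, target_contig = d$target_contig,
             n_identical = as.integer(round(d$pident * d$align_len / 100)),
             align_len = d$align_len,
             gapopen = d$gapopen %||% 0L, stringsAsFactors = FALSE)
}

write_spacer_hits <- function(hits, path) {
  write_tsv(data.frame(spacer_id = hits$spacer_id, mag_id = hits$mag_id,
                       target_contig = hits$target_contig,
                       pident = 100 * hits$n_identical / hits$align_len,
                       align_len = hits$align_len,
                       mismatch = hits$align_len - hits$n_identical,
                       gapopen = hits$gapopen,
                       spacer_len = hits$spacer_len), path)
}

read_mag_quality <- function(path) {
  d <- read_tsv(path, "MAG quality")
  stop_if_not_cols(d, c("mag_id", "completeness", "contamination"),
                   "MAG quality")
  data.frame(mag_id = d$mag_id, completeness_pct = d$completeness,
             contamination_pct = d$contamination, stringsAsFactors = FALSE)
}

read_meta <- function(path) {
  d <- read_tsv(path, "metadata")
  stop_if_not_cols(d, c("sample_id", "participant_id", "arm", "day",
                        "donor_id", "fraction"), "metadata")
  d
}

stop_validation <- function(msg) {
  stop(structure(class = c("phagedyn_validation_error", "error",
                           "condition"),
                 list(message = msg, call = NULL)))
}
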