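#' Zero out read counts for contigs with insufficient coverage breadth
#'
#' Contigs are considered present in a sample only when at least
#' `breadth_min` (default 0.75) of their bases are covered by at least one
#' mapped read; read counts of records below that horizontal coverage are
#' set to zero. Idempotent.
#'
#' @param records data.frame with `contig_id`, `sample_id`, `read_count`,
#'   `fraction_covered`.
#' @param breadth_min minimum horizontal coverage in \[0, 1\].
#' @return the records with filtered `read_count`.
#' @export
apply_breadth_filter <- function(records, breadth_min = 0.75) {
  if (breadth_min < 0 || breadth_min > 1)
    stop("breadth_min must be in [0, 1]", call. = FALSE)
  if (nrow(records) == 0L) return(records)
  stop_if_not_cols(records, c("contig_id", "sample_id", "read_count",
                              "fraction_covered"), "records")
  if (any(records$fraction_covered < 0 | records$fraction_covered > 1))
    stop("fraction_covered must be in [0, 1]", call. = FALSE)
  if (any(records$read_count < 0))
    stop("read_count must be non-negative", call. = FALSE)
  records$read_count[records$fraction_covered < breadth_min] <- 0L
  records
}

#' Recompute coverage breadth from a per-base depth table
#'
#' Accepts a presence/absence depth histogram in the bedtools-genomecov
#' dialect capped at depth 1 (columns: contig, depth, n_bases, contig_len,
#' fraction): the breadth of a contig is the fraction of bases at depth
#' >= 1, i.e. `1 - fraction(depth == 0)`.
#'
#' @param depth_hist data.frame with `contig_id`, `sample_id`, `depth`,
#'   `fraction` (of bases at that depth; depths capped at 1).
#' @return data.frame `contig_id`, `sample_id`, `fraction_covered`.
#' @export
breadth_from_depth <- function(depth_hist) {
  stop_if_not_cols(depth_hist, c("contig_id", "sample_id", "depth",
                                 "fraction"), "depth_hist")
  zero <- depth_hist[depth_hist$depth == 0, , drop = FALSE]
  key <- unique(depth_hist[, c("contig_id", "sample_id")])
  zkey <- paste(zero$contig_id, zero$sample_id, sep = "\r")
  f0 <- stats::setNames(zero$fraction, zkey)
  k <- paste(key$contig_id, key$sample_id, sep = "\r")
  key$fraction_covered <- 1 - ifelse(is.na(f0[k]), 0, f0[k])
  rownames(key) <- NULL
  key
}

#' Per-VP RPKM quantification
#'
#' Read counts and contig lengths are summed per viral population, then
#' converted to reads per kilobase per million mapped reads:
#' `RPKM = sum(counts) / ((sum(lengths)/1e3) * (library_size/1e6))`.
#' Contigs without a record in a sample contribute zero counts, but their
#' lengths still enter the VP length sum.
#'
#' @param records coverage records (after [apply_breadth_filter()]).
#' @param vp_membership data.frame `vp_id`, `contig_id` (each contig in
#'   exactly one VP).
#' @param contig_lengths named vector of contig lengths in bp.
#' @param library_sizes named vector of per-sample total mapped reads (> 0).
#' @return an `abundance_table` of kind `"rpkm"` (VPs x samples) carrying
#'   summed VP lengths and the library sizes.
#' @examples
#' rec <- data.frame(contig_id = "c1", sample_id = "s1",
#'                   read_count = 100L, fraction_covered = 1)
#' vm <- data.frame(vp_id = "VP0001", contig_id = "c1")
#' rpkm_per_vp(rec, vm, c(c1 = 10000), c(s1 = 1e6))  # 10
#' @export
rpkm_per_vp <- function(records, vp_membership, contig_lengths,
                        library_sizes) {
  stop_if_not_cols(records, c("contig_id", "sample_id", "read_count"),
                   "records")
  stop_if_not_cols(vp_membership, c("vp_id", "contig_id"), "vp_membership")
  if (anyDuplicated(vp_membership$contig_id))
    stop("a contig belongs to more than one VP", call. = FALSE)
  if (any(library_sizes <= 0))
    stop("library sizes must be positive", call. = FALSE)
  vp_of <- stats::setNames(vp_membership$vp_id, vp_membership$contig_id)
  if (any(is.na(vp_of[records$contig_id])))
    stop("records contain contigs without a VP assignment", call. = FALSE)
  if (any(is.na(contig_lengths[vp_membership$contig_id])))
    stop("contig_lengths missing for some VP members", call. = FALSE)
  vps <- sort(unique(vp_membership$vp_id))
  samples <- names(library_sizes)
  counts <- matrix(0, nrow = length(vps), ncol = length(samples),
                   dimnames = list(vps, samples))
  if (nrow(records) > 0L) {
    if (!all(records$sample_id %in% samples))
      stop("records contain samples without a library size", call. = FALSE)
    agg <- stats::aggregate(
      read_count ~ vp + sample,
      data = data.frame(vp = vp_of[records$contig_id],
                        sample = records$sample_id,
                        read_count = records$read_count),
      FUN = sum)
    counts[cbind(agg$vp, agg$sample)] <- agg$read_count
  }
  vp_len <- vapply(split(contig_lengths[vp_membership$contig_id],
                         vp_membership$vp_id), sum, numeric(1))[vps]
  rpkm <- counts / (vp_len / 1e3) /
    rep(library_sizes[samples] / 1e6, each = length(vps))
  abundance_table(rpkm, "rpkm", feature_length = vp_len,
                  library_size = library_sizes[samples])
}

#' Remove low-abundance, low-prevalence features
#'
#' Keeps features whose total RPKM over all samples is at least `total_min`
#' (default 100) and whose RPKM exceeds `value_min` (default 20) in at least
#' a `prevalence_min` share of samples (default 10%).
#'
#' @param table an `abundance_table` of kind `"rpkm"`.
#' @param total_min minimum total RPKM across samples.
#' @param value_min RPKM that counts as "present" for the prevalence rule
#'   (strictly greater than).
#' @param prevalence_min minimum share of samples exceeding `value_min`.
#' @return the filtered `abundance_table`.
#' @export
filter_low_abundance <- function(table, total_min = 100, value_min = 20,
                                 prevalence_min = 0.10) {
  if (!inherits(table, "abundance_table") || table_kind(table) != "rpkm")
    stop("filter_low_abundance requires an rpkm abundance_table",
         call. = FALSE)
  keep <- rowSums(table) >= total_min &
    rowMeans(unclass(table) > value_min) >= prevalence_min
  retable(table, unclass(table)[keep, , drop = FALSE])
}

#' Richness and Shannon diversity of one sample
#'
#' Richness is the number of features with abundance > 0; the Shannon index
#' is `H = -sum(p_i * log(p_i))` over the positive relative abundances
#' (natural log). An all-zero sample has richness 0 and H = 0.
#'
#' @param table an `abundance_table` with non-negative values.
#' @param sample sample (column) name.
#' @return `richness()`: integer; `shannon()`: numeric.
#' @examples
#' m <- matrix(c(1, 1, 2), 3, 1, dimnames = list(paste0("f", 1:3), "s1"))
#' shannon(abundance_table(m, "rpkm"), "s1")  # 1.0397
#' @export
richness <- function(table, sample) {
  x <- sample_values(table, sample)
  sum(x > 0)
}

#' @rdname richness
#' @export
shannon <- function(table, sample) {
  x <- sample_values(table, sample)
  x <- x[x > 0]
  if (length(x) == 0L) return(0)
  p <- x / sum(x)
  -sum(p * log(p))
}

sample_values <- function(table, sample) {
  if (!sample %in% colnames(table))
    stop(sprintf("unknown sample '%s'", sample), call. = FALSE)
  x <- unclass(table)[, sample]
  if (any(x < 0)) stop("diversity requires non-negative values", call. = FALSE)
  x
}

#' Per-sample diversity table
#'
#' @param table an `abundance_table`.
#' @return data.frame `sample_id`, `richness`, `shannon`.
#' @export
diversity_table <- function(table) {
  data.frame(sample_id = colnames(table),
             richness = vapply(colnames(table), richness,
                               numeric(1), table = table),
             shannon = vapply(colnames(table), shannon,
                              numeric(1), table = table),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Centred log-ratio transform
#'
#' Per sample: `x -> log(x + pseudocount) - mean(log(x + pseudocount))`.
#' The default pseudocount is half the smallest positive value in the table
#' (standard compositional practice when zeros are present).
#'
#' @param table an `abundance_table` of kind count, rpkm or proportion.
#' @param pseudocount positive offset added before taking logs; `NULL` for
#'   the default.
#' @return an `abundance_table` of kind `"clr"` (columns sum to 0).
#' @export
clr_transform <- function(table, pseudocount = NULL) {
  if (!inherits(table, "abundance_table"))
    stop("table must be an abundance_table", call. = FALSE)
  if (table_kind(table) == "clr") return(table)
  v <- unclass(table)
  if (is.null(pseudocount)) {
    pos <- v[v > 0]
    if (length(pos) == 0L) stop("all-zero table has no clr transform",
                                call. = FALSE)
    pseudocount <- min(pos) / 2
  }
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  lg <- log(v + pseudocount)
  clr <- sweep(lg, 2L, colMeans(lg), "-")
  retable(table, clr, "clr")
}

#' Compositional distance between samples
#'
#' Aitchison distance (Euclidean on clr-transformed values, the default) or
#' Bray-Curtis dissimilarity on per-sample proportions.
#'
#' @param table an `abundance_table` of kind count or rpkm.
#' @param method `"aitchison"` or `"bray"`.
#' @param pseudocount passed to [clr_transform()] for Aitchison.
#' @return a `dist` over samples.
#' @export
community_dist <- function(table, method = c("aitchison", "bray"),
                           pseudocount = NULL) {
  method <- match.arg(method)
  if (method == "aitchison") {
    stats::dist(t(unclass(clr_transform(table, pseudocount))))
  } else {
    vegan::vegdist(t(unclass(as_proportions(table))), method = "bray")
  }
}
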