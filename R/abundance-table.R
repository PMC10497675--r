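#' Construct an abundance table
#'
#' The package's central container: a numeric features x samples matrix with
#' a declared value kind and optional per-feature lengths and per-sample
#' library sizes. Rows are features (viral populations, MAGs or species),
#' columns are samples, matching the orientation of count matrices in
#' expression analysis.
#'
#' @param values numeric matrix, features in rows, samples in columns, with
#'   dimnames set. All values must be finite; counts/RPKM must be >= 0.
#' @param kind one of `"count"`, `"rpkm"`, `"proportion"`, `"clr"`.
#' @param feature_length optional named vector of feature lengths in bp.
#' @param library_size optional named vector of per-sample library sizes
#'   (total mapped reads).
#' @return An object of class `abundance_table` (a matrix with attributes
#'   `kind`, `feature_length`, `library_size`).
#' @examples
#' m <- matrix(c(10, 0, 5, 5), 2, 2,
#'             dimnames = list(c("VP1", "VP2"), c("s1", "s2")))
#' abundance_table(m, "count")
#' @export
abundance_table <- function(values, kind = c("count", "rpkm", "proportion", "clr"),
                            feature_length = NULL, library_size = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("values must have feature rownames", call. = FALSE)
  if (ncol(values) > 0L && is.null(colnames(values)))
    stop("values must have sample colnames", call. = FALSE)
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  if (kind %in% c("count", "rpkm", "proportion") && any(values < 0))
    stop(sprintf("%s values must be non-negative", kind), call. = FALSE)
  if (kind == "proportion") {
    cs <- colSums(values)
    if (any(abs(cs[cs > 0] - 1) > 1e-9))
      stop("proportion columns must sum to 1", call. = FALSE)
  }
  if (kind == "clr" && any(abs(colSums(values)) > 1e-9))
    stop("clr columns must sum to 0", call. = FALSE)
  if (!is.null(feature_length)) {
    feature_length <- feature_length[rownames(values)]
    if (any(is.na(feature_length)))
      stop("feature_length missing for some features", call. = FALSE)
  }
  if (!is.null(library_size)) {
    library_size <- library_size[colnames(values)]
    if (any(is.na(library_size)) || any(library_size <= 0))
      stop("library_size must be positive for every sample", call. = FALSE)
  }
  structure(values, class = c("abundance_table", class(values)),
            kind = kind, feature_length = feature_length,
            library_size = library_size)
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("<abundance_table> %d features x %d samples, kind = %s\n",
              nrow(x), ncol(x), attr(x, "kind")))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE], 6L))
  invisible(x)
}

table_kind <- function(x) attr(x, "kind")

# Rebuild an abundance_table with new values but the same metadata.
retable <- function(x, values, kind = table_kind(x)) {
  abundance_table(values, kind,
                  feature_length = attr(x, "feature_length"),
                  library_size = attr(x, "library_size"))
}

#' Convert an abundance table to per-sample proportions
#'
#' Columns with zero total stay all-zero (and are flagged by a zero column
#' sum rather than NaN).
#'
#' @param x an `abundance_table` of kind count or rpkm.
#' @return an `abundance_table` of kind proportion.
#' @export
as_proportions <- function(x) {
  if (!inherits(x, "abundance_table")) stop("x must be an abundance_table")
  if (table_kind(x) == "proportion") return(x)
  if (table_kind(x) == "clr")
    stop("cannot convert clr values back to proportions", call. = FALSE)
  cs <- colSums(x)
  v <- sweep(unclass(x), 2L, ifelse(cs > 0, cs, 1), "/")
  retable(x, v, "proportion")
}
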