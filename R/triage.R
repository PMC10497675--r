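#' Classify contigs as viral by the four-criteria evidence rule
#'
#' A contig is taken to be viral if at least one of the following holds:
#' (1) the gene-content annotator identified at least one viral gene;
#' (2) the viral classifier score is at least `score_min` (default 0.95);
#' (3) at least two viral hallmark genes were identified;
#' (4) no viral and no bacterial genes were identified at all.
#' A missing classifier score fails the score criterion only (an unscored
#' contig cannot pass a score cut) and does not affect the other three.
#'
#' @param annotations data.frame with columns `contig_id`, `viral_gene_count`,
#'   `host_gene_count`, `vs_score` (may be NA), `hallmark_count`.
#' @param score_min minimum classifier score for criterion 2.
#' @return logical vector, one element per row, named by `contig_id`.
#' @examples
#' ann <- data.frame(contig_id = c("a", "b", "c"),
#'                   viral_gene_count = c(1, 0, 0),
#'                   host_gene_count = c(5, 0, 2),
#'                   vs_score = c(0.2, 0.1, 0.949),
#'                   hallmark_count = c(0, 0, 1))
#' classify_viral(ann)  # TRUE TRUE FALSE
#' @export
classify_viral <- function(annotations, score_min = 0.95) {
  stop_if_not_cols(annotations,
                   c("contig_id", "viral_gene_count", "host_gene_count",
                     "vs_score", "hallmark_count"), "annotations")
  v <- annotations$viral_gene_count
  h <- annotations$host_gene_count
  s <- annotations$vs_score
  hm <- annotations$hallmark_count
  if (any(v < 0, na.rm = TRUE) || any(h < 0, na.rm = TRUE) ||
      any(hm < 0, na.rm = TRUE))
    stop("negative gene/hallmark counts: malformed input", call. = FALSE)
  s[is.na(s)] <- 0
  out <- (v >= 1) | (s >= score_min) | (hm >= 2) | (v == 0 & h == 0)
  names(out) <- annotations$contig_id
  out
}

#' Drop contigs below the minimum assembly length
#'
#' Upstream, only contigs longer than `min_length` bp (default 5000) enter
#' viral classification at all.
#'
#' @param annotations data.frame with at least `contig_id` and `length_bp`.
#' @param min_length minimum contig length in bp.
#' @return the filtered data.frame.
#' @export
filter_min_length <- function(annotations, min_length = 5000) {
  stop_if_not_cols(annotations, c("contig_id", "length_bp"), "annotations")
  if (any(annotations$length_bp <= 0))
    stop("length_bp must be positive", call. = FALSE)
  annotations[annotations$length_bp >= min_length, , drop = FALSE]
}

# Directed ANI pairs reconciled to a symmetric lookup keyed "a|b" (a < b),
# taking the maximum of the two orientations.
symmetric_ani <- function(ani_pairs) {
  if (nrow(ani_pairs) == 0L)
    return(numeric(0))
  a <- pmin(ani_pairs$query_id, ani_pairs$subject_id)
  b <- pmax(ani_pairs$query_id, ani_pairs$subject_id)
  key <- paste(a, b, sep = "|")
  tapply(ani_pairs$ani_pct, key, max)
}

#' Remove exact duplicate contigs
#'
#' Contigs connected by an ANI pair at 100% identity with the shorter member
#' fully aligned (`aligned_fraction == 1`) are duplicates; within each
#' connected component of such pairs only the longest contig is kept (ties
#' broken by the lexicographically smallest id). Pairs at 100% identity but
#' partial alignment are not duplicates and both members are kept.
#'
#' @param contigs data.frame with `contig_id`, `length_bp`.
#' @param ani_pairs data.frame with `query_id`, `subject_id`, `ani_pct` and
#'   optionally `aligned_fraction` (fraction of the query aligned; NA fails
#'   the full-alignment requirement).
#' @return character vector of kept contig ids.
#' @export
dedup_exact <- function(contigs, ani_pairs) {
  stop_if_not_cols(contigs, c("contig_id", "length_bp"), "contigs")
  ids <- contigs$contig_id
  len <- stats::setNames(contigs$length_bp, ids)
  if (is.null(ani_pairs) || nrow(ani_pairs) == 0L) return(ids)
  stop_if_not_cols(ani_pairs, c("query_id", "subject_id", "ani_pct"),
                   "ani_pairs")
  af <- ani_pairs$aligned_fraction %||% rep(NA_real_, nrow(ani_pairs))
  # duplicate edge: 100% ANI and the query (the member whose coverage the
  # aligned_fraction describes) is fully aligned and is the shorter member
  dup <- !is.na(ani_pairs$ani_pct) & ani_pairs$ani_pct >= 100 &
    !is.na(af) & af >= 1 &
    len[ani_pairs$query_id] <= len[ani_pairs$subject_id] &
    ani_pairs$query_id != ani_pairs$subject_id
  if (!any(dup)) return(ids)
  # union-find over duplicate edges
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in which(dup)) {
    ra <- find(ani_pairs$query_id[i]); rb <- find(ani_pairs$subject_id[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  root <- vapply(ids, find, character(1))
  keep <- vapply(split(ids, root), function(members) {
    members[order(-len[members], members)][1L]
  }, character(1))
  ids[ids %in% keep]
}

#' Cluster viral contigs into viral populations (VPs)
#'
#' Greedy length-sorted centroid clustering at an average nucleotide
#' identity threshold: contigs are visited longest first (ties by id); each
#' contig joins the first existing VP whose representative it matches at
#' `>= ani_threshold_pct` (directed ANI values are reconciled by maximum),
#' otherwise it founds a new VP with itself as representative.
#' `method = "single"` gives single-linkage components over pairs at or
#' above the threshold instead.
#'
#' @param contigs data.frame with `contig_id`, `length_bp` (deduplicated).
#' @param ani_pairs data.frame with `query_id`, `subject_id`, `ani_pct`.
#' @param ani_threshold_pct clustering threshold in (0, 100]; default 95.
#' @param method `"centroid"` (default) or `"single"`.
#' @return data.frame with columns `vp_id`, `contig_id`, `length_bp`,
#'   `is_representative`; one row per contig; VP ids are assigned in
#'   founding order (`VP0001`, ...).
#' @export
cluster_vps <- function(contigs, ani_pairs, ani_threshold_pct = 95,
                        method = c("centroid", "single")) {
  method <- match.arg(method)
  stop_if_not_cols(contigs, c("contig_id", "length_bp"), "contigs")
  if (ani_threshold_pct <= 0 || ani_threshold_pct > 100)
    stop("ani_threshold_pct must be in (0, 100]", call. = FALSE)
  ids <- contigs$contig_id
  if (anyDuplicated(ids)) stop("duplicate contig ids", call. = FALSE)
  if (nrow(ani_pairs) > 0L) {
    stop_if_not_cols(ani_pairs, c("query_id", "subject_id", "ani_pct"),
                     "ani_pairs")
    unknown <- setdiff(c(ani_pairs$query_id, ani_pairs$subject_id), ids)
    if (length(unknown) > 0L)
      stop(sprintf("ani_pairs reference unknown contigs: %s",
                   paste(utils::head(unknown, 3), collapse = ", ")),
           call. = FALSE)
  }
  len <- stats::setNames(contigs$length_bp, ids)
  ord <- ids[order(-len, ids)]
  ani <- symmetric_ani(ani_pairs)
  ani_of <- function(a, b) {
    v <- ani[paste(min(a, b), max(a, b), sep = "|")]
    if (is.na(v)) -Inf else v
  }
  assignment <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  if (method == "centroid") {
    reps <- character(0)
    for (cid in ord) {
      hit <- 0L
      for (k in seq_along(reps)) {
        if (ani_of(cid, reps[k]) >= ani_threshold_pct) { hit <- k; break }
      }
      if (hit == 0L) { reps <- c(reps, cid); hit <- length(reps) }
      assignment[cid] <- hit
    }
    rep_of <- reps
  } else {
    # single linkage: components of the >= threshold graph
    parent <- stats::setNames(ids, ids)
    find <- function(x) {
      while (parent[[x]] != x) {
        parent[[x]] <<- parent[[parent[[x]]]]
        x <- parent[[x]]
      }
      x
    }
    if (length(ani) > 0L) {
      keys <- names(ani)[ani >= ani_threshold_pct]
      for (k in keys) {
        ab <- strsplit(k, "|", fixed = TRUE)[[1L]]
        ra <- find(ab[1L]); rb <- find(ab[2L])
        if (ra != rb) parent[[ra]] <- rb
      }
    }
    root <- vapply(ids, find, character(1))
    # number components in longest-first order; representative = longest member
    comp_first <- unique(root[ord])
    assignment[] <- match(root, comp_first)
    rep_of <- vapply(comp_first, function(r) {
      members <- ids[root == r]
      members[order(-len[members], members)][1L]
    }, character(1))
  }
  vp_ids <- sprintf("VP%04d", assignment)
  out <- data.frame(vp_id = vp_ids, contig_id = names(assignment),
                    length_bp = as.integer(len[names(assignment)]),
                    is_representative =
                      names(assignment) == rep_of[assignment],
                    stringsAsFactors = FALSE)
  out[order(out$vp_id, -out$length_bp, out$contig_id), , drop = FALSE]
}

#' Summarise viral populations
#'
#' @param vp_membership output of [cluster_vps()].
#' @return data.frame with `vp_id`, `representative_id`, `n_members`,
#'   `total_length_bp`.
#' @export
vp_summary <- function(vp_membership) {
  stop_if_not_cols(vp_membership,
                   c("vp_id", "contig_id", "length_bp", "is_representative"),
                   "vp_membership")
  sp <- split(vp_membership, vp_membership$vp_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(vp_id = d$vp_id[1L],
               representative_id = d$contig_id[d$is_representative][1L],
               n_members = nrow(d),
               total_length_bp = sum(d$length_bp),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
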