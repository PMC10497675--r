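#' Quality-filter metagenome-assembled genomes
#'
#' Keeps MAGs with `completeness - 5 * contamination >= 50` (the standard
#' medium-quality gate).
#'
#' @param mags data.frame with `mag_id`, `completeness_pct`,
#'   `contamination_pct` (both in percent).
#' @param quality_min minimum `completeness - 5 * contamination` score.
#' @return the filtered data.frame.
#' @examples
#' m <- data.frame(mag_id = c("m1", "m2"),
#'                 completeness_pct = c(80, 60),
#'                 contamination_pct = c(5, 3))
#' filter_mags(m)  # keeps m1 (score 55), drops m2 (score 45)
#' @export
filter_mags <- function(mags, quality_min = 50) {
  stop_if_not_cols(mags, c("mag_id", "completeness_pct", "contamination_pct"),
                   "mags")
  if (any(mags$completeness_pct < 0 | mags$completeness_pct > 100) ||
      any(mags$contamination_pct < 0))
    stop("invalid completeness/contamination percentages", call. = FALSE)
  score <- mags$completeness_pct - 5 * mags$contamination_pct
  mags[score >= quality_min, , drop = FALSE]
}

#' Link viral populations to MAGs by prophage containment
#'
#' A viral contig binned into a MAG is a prophage of that MAG; the link is
#' lifted to the contig's VP and deduplicated, so a VP with several member
#' contigs in the same MAG yields one link. Containment is contig-identity
#' membership: in a cross-assembly the binned contig *is* the viral contig.
#'
#' @param vp_membership data.frame `vp_id`, `contig_id`.
#' @param mag_membership data.frame `mag_id`, `contig_id` (quality-filtered
#'   MAGs only).
#' @return data.frame `vp_id`, `mag_id`, `evidence = "prophage"`.
#' @export
link_prophages <- function(vp_membership, mag_membership) {
  stop_if_not_cols(vp_membership, c("vp_id", "contig_id"), "vp_membership")
  stop_if_not_cols(mag_membership, c("mag_id", "contig_id"), "mag_membership")
  m <- merge(vp_membership[, c("vp_id", "contig_id")],
             mag_membership[, c("mag_id", "contig_id")], by = "contig_id")
  out <- unique(data.frame(vp_id = m$vp_id, mag_id = m$mag_id,
                           evidence = rep("prophage", nrow(m)),
                           stringsAsFactors = FALSE))
  out[order(out$vp_id, out$mag_id), , drop = FALSE]
}

#' Filter CRISPR-spacer hits and lift them to VP-MAG links
#'
#' Spacers are retained when their length is between `len_min` and
#' `len_max` bp (defaults 20 and 30) and they match the viral contig with
#' at most `max_mismatch` mismatches (default 2), where mismatches are
#' counted against the full spacer: `spacer_len - n_identical`. Unaligned
#' spacer ends and gap columns therefore count as mismatches — the
#' strictest reading, minimising spurious hits from short local
#' alignments. Kept hits are lifted to `(vp, mag)` links via the target
#' contig's VP; hits whose target contig is in no VP are dropped with a
#' warning.
#'
#' @param hits data.frame with `spacer_id`, `mag_id`, `spacer_len`,
#'   `target_contig`, `n_identical` (and optionally `align_len`,
#'   `gapopen`).
#' @param vp_membership data.frame `vp_id`, `contig_id`.
#' @param len_min,len_max spacer length bounds in bp (inclusive).
#' @param max_mismatch maximum full-length mismatches.
#' @return data.frame `vp_id`, `mag_id`, `evidence = "crispr"`, unique.
#' @export
filter_spacer_hits <- function(hits, vp_membership, len_min = 20,
                               len_max = 30, max_mismatch = 2) {
  stop_if_not_cols(hits, c("spacer_id", "mag_id", "spacer_len",
                           "target_contig", "n_identical"), "hits")
  stop_if_not_cols(vp_membership, c("vp_id", "contig_id"), "vp_membership")
  if (any(hits$n_identical < 0))
    stop("n_identical must be non-negative", call. = FALSE)
  mismatches <- hits$spacer_len - hits$n_identical
  keep <- hits$spacer_len >= len_min & hits$spacer_len <= len_max &
    mismatches <= max_mismatch
  kept <- hits[keep, , drop = FALSE]
  vp_of <- stats::setNames(vp_membership$vp_id, vp_membership$contig_id)
  vp <- vp_of[kept$target_contig]
  if (any(is.na(vp))) {
    orphans <- unique(kept$target_contig[is.na(vp)])
    warning(sprintf("%d spacer hit(s) target contigs in no VP (dropped): %s",
                    sum(is.na(vp)),
                    paste(utils::head(orphans, 3), collapse = ", ")),
            call. = FALSE)
    kept <- kept[!is.na(vp), , drop = FALSE]
    vp <- vp[!is.na(vp)]
  }
  out <- unique(data.frame(vp_id = unname(vp), mag_id = kept$mag_id,
                           evidence = rep("crispr", nrow(kept)),
                           stringsAsFactors = FALSE))
  out[order(out$vp_id, out$mag_id), , drop = FALSE]
}

#' Attach host species to VP-MAG links
#'
#' Species come from the MAG taxonomy table; links to MAGs without an
#' assigned species keep a missing species (they are excluded from
#' species-level analyses downstream but retained here). A VP may link to
#' several MAGs and several species; all links are kept.
#'
#' @param links data.frame `vp_id`, `mag_id`, `evidence`.
#' @param taxonomy data.frame `mag_id`, `species` (NA allowed).
#' @return `links` with a `species` column.
#' @export
resolve_species <- function(links, taxonomy) {
  stop_if_not_cols(links, c("vp_id", "mag_id", "evidence"), "links")
  stop_if_not_cols(taxonomy, c("mag_id", "species"), "taxonomy")
  unknown <- setdiff(links$mag_id, taxonomy$mag_id)
  if (length(unknown) > 0L)
    stop(sprintf("links reference MAGs absent from taxonomy: %s",
                 paste(utils::head(unknown, 3), collapse = ", ")),
         call. = FALSE)
  sp <- stats::setNames(taxonomy$species, taxonomy$mag_id)
  links$species <- unname(sp[links$mag_id])
  links
}

#' Species-level host table of a set of links
#'
#' One row per (vp, species), the union over a VP's links; links with a
#' missing species are dropped.
#'
#' @param links output of [resolve_species()].
#' @return data.frame `vp_id`, `species`, unique.
#' @export
host_table <- function(links) {
  stop_if_not_cols(links, c("vp_id", "species"), "links")
  keep <- !is.na(links$species)
  out <- unique(links[keep, c("vp_id", "species"), drop = FALSE])
  rownames(out) <- NULL
  out[order(out$vp_id, out$species), , drop = FALSE]
}
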