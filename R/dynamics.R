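#' Relative abundance shared with the assigned donor
#'
#' For a recipient sample, the percentage of total VP abundance carried by
#' VPs that are detected (abundance > 0 after breadth filtering) in the
#' assigned donor's profiled sample:
#' `100 * sum(abundance of donor-present VPs) / sum(abundance of all VPs)`.
#' Returns 0 when the recipient sample total is 0.
#'
#' @param vp_table an `abundance_table` (RPKM) of VPs x samples, including
#'   the donor samples.
#' @param meta sample metadata: `sample_id`, `participant_id`, `arm`
#'   (`"FFT"`, `"placebo"`, `"donor"`), `day` (NA for donors), `donor_id`
#'   (assigned donor, FFT arm only).
#' @param participant recipient participant id.
#' @param day study day of the recipient sample.
#' @return percent in \[0, 100\].
#' @export
donor_shared_fraction <- function(vp_table, meta, participant, day) {
  s <- meta_sample(meta, participant, day, colnames(vp_table))
  donor <- unique(meta$donor_id[meta$participant_id == participant &
                                  !is.na(meta$donor_id)])
  donor <- donor[!is.na(donor)]
  if (length(donor) != 1L)
    stop(sprintf("participant '%s' has no unique assigned donor",
                 participant), call. = FALSE)
  ds <- meta$sample_id[meta$participant_id == donor]
  ds <- intersect(ds, colnames(vp_table))
  if (length(ds) != 1L)
    stop(sprintf("donor '%s' has no unique profiled sample", donor),
         call. = FALSE)
  x <- unclass(vp_table)[, s]
  total <- sum(x)
  if (total == 0) return(0)
  shared <- unclass(vp_table)[, ds] > 0
  100 * sum(x[shared]) / total
}

#' Relative abundance of phages absent at baseline
#'
#' The percentage of total VP abundance at the given day carried by VPs
#' with zero abundance in the same participant's day-0 sample.
#'
#' @inheritParams donor_shared_fraction
#' @param day study day (> 0).
#' @return percent in \[0, 100\]; 0 when the sample total is 0.
#' @export
novel_fraction <- function(vp_table, meta, participant, day) {
  if (day == 0) return(0)
  s <- meta_sample(meta, participant, day, colnames(vp_table))
  s0 <- meta_sample(meta, participant, 0, colnames(vp_table))
  x <- unclass(vp_table)[, s]
  total <- sum(x)
  if (total == 0) return(0)
  new <- unclass(vp_table)[, s0] == 0
  100 * sum(x[new]) / total
}

meta_sample <- function(meta, participant, day, within = NULL) {
  stop_if_not_cols(meta, c("sample_id", "participant_id", "day"), "meta")
  s <- meta$sample_id[meta$participant_id == participant &
                        !is.na(meta$day) & meta$day == day]
  if (!is.null(within)) s <- intersect(s, within)
  if (length(s) != 1L)
    stop(sprintf("participant '%s' has %d samples at day %s (need exactly 1)",
                 participant, length(s), day), call. = FALSE)
  s
}

#' Engraftment and novelty trajectories for all recipients
#'
#' @inheritParams donor_shared_fraction
#' @param days days to evaluate (defaults to all non-baseline days in meta).
#' @return long data.frame `participant_id`, `arm`, `day`,
#'   `donor_shared_pct` (NA for placebo participants without a donor),
#'   `novel_pct`.
#' @export
engraftment_table <- function(vp_table, meta, days = NULL) {
  rec <- unique(meta[meta$arm %in% c("FFT", "placebo") &
                       meta$sample_id %in% colnames(vp_table),
                     c("participant_id", "arm")])
  if (is.null(days))
    days <- sort(unique(meta$day[!is.na(meta$day) & meta$day > 0]))
  out <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    p <- rec$participant_id[i]
    has_donor <- any(!is.na(meta$donor_id[meta$participant_id == p]))
    do.call(rbind, lapply(days, function(d) {
      data.frame(participant_id = p, arm = rec$arm[i], day = d,
                 donor_shared_pct = if (has_donor)
                   donor_shared_fraction(vp_table, meta, p, d) else NA_real_,
                 novel_pct = novel_fraction(vp_table, meta, p, d),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Species-level phage-host abundance-change points
#'
#' For each participant with samples at both days and each host species,
#' the mean abundance change of the species' linked VPs and of the species'
#' MAGs between `day_a` and `day_b`. Abundances are per-sample proportions
#' (`scale = "proportion"`, the default) or clr values (`scale = "clr"`).
#' Only VPs with at least one species-resolved link and species with at
#' least one linked MAG participate. A species point is omitted when the
#' species shows no abundance at either day in both the VP and the MAG
#' table (no signal at all).
#'
#' @param vp_table `abundance_table` of VPs x samples (count or rpkm).
#' @param mag_table `abundance_table` of MAGs x samples (count or rpkm).
#' @param links species-resolved links ([resolve_species()] output).
#' @param meta sample metadata; VP and MAG samples are matched to
#'   participants and days independently (the two tables may use different
#'   sample ids, e.g. VLP and WGS fractions).
#' @param day_a,day_b the two study days.
#' @param scale `"proportion"` or `"clr"`.
#' @return data.frame `participant_id`, `species`, `day_a`, `day_b`,
#'   `delta_vp`, `delta_mag`.
#' @export
interaction_points <- function(vp_table, mag_table, links, meta,
                               day_a = 0, day_b = 2,
                               scale = c("proportion", "clr")) {
  scale <- match.arg(scale)
  stop_if_not_cols(links, c("vp_id", "mag_id", "species"), "links")
  links <- links[!is.na(links$species), , drop = FALSE]
  vp_by_sp <- lapply(split(links$vp_id, links$species), unique)
  mag_by_sp <- lapply(split(links$mag_id, links$species), unique)
  tf <- function(tab) {
    if (scale == "proportion") unclass(as_proportions(tab))
    else unclass(clr_transform(tab))
  }
  vp_prop <- tf(vp_table)
  vp_raw <- unclass(as_proportions(vp_table))
  mag_prop <- tf(mag_table)
  mag_raw <- unclass(as_proportions(mag_table))

  participants <- sort(unique(meta$participant_id[
    meta$arm %in% c("FFT", "placebo")]))
  rows <- list()
  for (p in participants) {
    sel <- function(tab, day) {
      s <- meta$sample_id[meta$participant_id == p & !is.na(meta$day) &
                            meta$day == day]
      s <- intersect(s, colnames(tab))
      if (length(s) == 1L) s else NA_character_
    }
    va <- sel(vp_prop, day_a); vb <- sel(vp_prop, day_b)
    ma <- sel(mag_prop, day_a); mb <- sel(mag_prop, day_b)
    if (anyNA(c(va, vb, ma, mb))) next
    for (sp in names(vp_by_sp)) {
      vps <- intersect(vp_by_sp[[sp]], rownames(vp_prop))
      mags <- intersect(mag_by_sp[[sp]], rownames(mag_prop))
      if (length(vps) == 0L || length(mags) == 0L) next
      vp_signal <- sum(vp_raw[vps, c(va, vb)]) > 0
      mag_signal <- sum(mag_raw[mags, c(ma, mb)]) > 0
      if (!vp_signal && !mag_signal) next
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = p, species = sp, day_a = day_a, day_b = day_b,
        delta_vp = mean(vp_prop[vps, vb] - vp_prop[vps, va]),
        delta_mag = mean(mag_prop[mags, mb] - mag_prop[mags, ma]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(participant_id = character(0), species = character(0),
                      day_a = numeric(0), day_b = numeric(0),
                      delta_vp = numeric(0), delta_mag = numeric(0)))
  do.call(rbind, rows)
}

#' Spearman correlation of phage vs host abundance changes, per group
#'
#' Ranks use average ties. Two-sided p-values come from exact enumeration
#' over all rank permutations for n <= 8 and from the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` otherwise. Groups with constant
#' deltas have undefined rho, reported as NA.
#'
#' @param points output of [interaction_points()].
#' @param group_assignment named vector participant_id -> group label, or a
#'   vector of labels aligned with `points` rows.
#' @return data.frame `group`, `rho`, `p`, `n_points`.
#' @export
interaction_correlation <- function(points, group_assignment) {
  stop_if_not_cols(points, c("participant_id", "delta_vp", "delta_mag"),
                   "points")
  g <- if (!is.null(names(group_assignment)))
    unname(group_assignment[points$participant_id]) else group_assignment
  if (length(g) != nrow(points) || anyNA(g))
    stop("every point needs a group assignment", call. = FALSE)
  out <- do.call(rbind, lapply(sort(unique(g)), function(grp) {
    d <- points[g == grp, , drop = FALSE]
    if (nrow(d) < 3L)
      stop(sprintf("group '%s' has fewer than 3 points", grp), call. = FALSE)
    st <- spearman_test(d$delta_vp, d$delta_mag)
    data.frame(group = grp, rho = st$rho, p = st$p, n_points = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Spearman rho (average-rank ties) with a two-sided p-value: exact
# permutation enumeration for n <= exact_max, t-approximation above.
spearman_test <- function(x, y, exact_max = 8L) {
  n <- length(x)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    # rho is affine in the dot product of the permuted ranks, so the
    # two-sided tail can be taken on centred dot products directly
    obs <- sum(rx * ry)
    dots <- as.vector(matrix(rx[perms], nrow(perms), n) %*% ry)
    mu <- mean(dots)
    p <- mean(abs(dots - mu) >= abs(obs - mu) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = min(p, 1))
}

# All permutations of 1..n as a (n!) x n integer matrix; n <= 8.
all_permutations <- function(n) {
  if (n > 8L) stop("refusing to enumerate permutations beyond n = 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Host-species enrichment among differentially abundant VPs
#'
#' One-sided hypergeometric (over-representation) test per host species.
#' The universe is the set of VPs with at least one host link; DA VPs
#' without hosts are excluded from `k`. For a species with `q` DA VPs,
#' `m` linked VPs, `n = (hosted VPs) - m` and `k` hosted DA VPs, the
#' p-value is `P[X >= q]` for `X ~ Hypergeometric(m, n, k)` (computed as
#' `phyper(q - 1, m, n, k, lower.tail = FALSE)`), with Benjamini-Hochberg
#' adjustment across tested species. Species without any DA VP are not
#' tested.
#'
#' @param da_vp_ids ids of differentially abundant VPs.
#' @param host_table data.frame `vp_id`, `species` ([host_table()] output).
#' @param alpha significance cut applied to `p_adj` (reported as a flag).
#' @return data.frame `species`, `q`, `m`, `n`, `k`, `p`, `p_adj`,
#'   `significant`, ordered by p.
#' @export
host_enrichment <- function(da_vp_ids, host_table, alpha = 0.05) {
  stop_if_not_cols(host_table, c("vp_id", "species"), "host_table")
  ht <- unique(host_table[!is.na(host_table$species),
                          c("vp_id", "species"), drop = FALSE])
  universe <- unique(ht$vp_id)
  da_hosted <- intersect(unique(da_vp_ids), universe)
  k <- length(da_hosted)
  species <- sort(unique(ht$species[ht$vp_id %in% da_hosted]))
  if (length(species) == 0L)
    return(data.frame(species = character(0), q = integer(0), m = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  res <- do.call(rbind, lapply(species, function(sp) {
    vps <- ht$vp_id[ht$species == sp]
    m <- length(vps)
    q <- length(intersect(vps, da_hosted))
    n <- length(universe) - m
    if (q > m || k > m + n)
      stop("inconsistent enrichment inputs", call. = FALSE)
    data.frame(species = sp, q = q, m = m, n = n, k = k,
               p = stats::phyper(q - 1, m, n, k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$significant <- res$p_adj < alpha
  res <- res[order(res$p, res$species), , drop = FALSE]
  rownames(res) <- NULL
  res
}
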