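#' Scenario configuration for the synthetic trial
#'
#' Describes the shape of the simulated trial: arm sizes, the faecal
#' sampling grid (defaults to the study grid: baseline and days 2, 4, 7,
#' 14, 28), community sizes and sequencing depth. All randomness downstream
#' flows from the single integer `seed`.
#'
#' @param n_per_arm participants per arm (FFT and placebo).
#' @param days strictly increasing study days including day 0.
#' @param n_vps total number of viral populations in the simulated world,
#'   split into resident, donor-only and novel pools.
#' @param n_mags,n_species numbers of MAGs and bacterial host species
#'   (`n_mags` must be a multiple of `n_species`).
#' @param n_donors number of donors; FFT participants are assigned donors
#'   round-robin.
#' @param n_donor_vps,n_novel_vps sizes of the donor-only and novel VP
#'   pools (the rest are resident).
#' @param library_size_meanlog,library_size_sdlog log-normal parameters of
#'   per-sample library sizes (mapped reads).
#' @param seed master integer seed.
#' @return a validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_per_arm = 12, days = c(0, 2, 4, 7, 14, 28),
                            n_vps = 80, n_mags = 40, n_species = 20,
                            n_donors = 4, n_donor_vps = 16, n_novel_vps = 12,
                            library_size_meanlog = log(3e5),
                            library_size_sdlog = 0.3, seed = 1) {
  if (any(diff(days) <= 0)) stop("days must be strictly increasing",
                                 call. = FALSE)
  if (!0 %in% days) stop("day 0 must be present", call. = FALSE)
  counts <- c(n_per_arm, n_vps, n_mags, n_species, n_donors)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("counts must be positive integers", call. = FALSE)
  if (n_mags %% n_species != 0)
    stop("n_mags must be a multiple of n_species", call. = FALSE)
  n_resident <- n_vps - n_donor_vps - n_novel_vps
  if (n_resident < 2 * n_species)
    stop("n_vps too small: need >= 2 resident VPs per species plus donor and novel pools",
         call. = FALSE)
  structure(list(n_per_arm = n_per_arm, days = days, n_vps = n_vps,
                 n_mags = n_mags, n_species = n_species,
                 n_donors = n_donors, n_donor_vps = n_donor_vps,
                 n_novel_vps = n_novel_vps, n_resident = n_resident,
                 library_size_meanlog = library_size_meanlog,
                 library_size_sdlog = library_size_sdlog,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Planted ground truth of the synthetic world
#'
#' The regime sets the sign of the phage-host abundance-change coupling:
#' for a linked species, the expected log-abundance change of its VPs over
#' a sampling step is `coupling_beta` times the mean log-abundance change
#' of its MAGs, plus Gaussian noise with `noise_sd`. `"antagonistic"`
#' (lytic; beta < 0), `"protagonistic"` (lysogenic; beta > 0) and `"null"`
#' (beta = 0). The default |beta| was calibrated once by Monte-Carlo so the
#' realized Spearman correlation at ~450 points is weak but
#' sign-recoverable (see the methods vignette), since the study reports
#' only a weak correlation with no effect size.
#'
#' @param regime interaction regime.
#' @param coupling_beta signed coupling; `NULL` for the regime default
#'   (-0.3, +0.3, 0; calibrated to a realized Spearman rho of about
#'   -/+0.19 at ~450 proportion-scale points).
#' @param noise_sd log-scale noise of VP changes (> 0).
#' @param mag_step_sd log-scale step size of MAG changes between
#'   consecutive sampling days.
#' @param engraftment_fraction expected share of post-baseline relative
#'   abundance carried by donor VPs in FFT recipients.
#' @param novelty_rate expected share of post-baseline relative abundance
#'   carried by VPs absent at the recipient's baseline (besides donor VPs).
#' @return a validated list of class `synthetic_truth`. Fields
#'   `viral_labels`, `cluster_assignment` and `true_links` are filled in by
#'   the generators.
#' @export
synthetic_truth <- function(regime = c("antagonistic", "protagonistic",
                                       "null"),
                            coupling_beta = NULL, noise_sd = 0.6,
                            mag_step_sd = 0.8,
                            engraftment_fraction = 0.10,
                            novelty_rate = 0.15) {
  regime <- match.arg(regime)
  if (is.null(coupling_beta))
    coupling_beta <- switch(regime, antagonistic = -0.3,
                            protagonistic = 0.3, null = 0)
  ok <- switch(regime, antagonistic = coupling_beta < 0,
               protagonistic = coupling_beta > 0, null = coupling_beta == 0)
  if (!ok) stop("coupling_beta sign must match regime", call. = FALSE)
  if (noise_sd <= 0 || mag_step_sd <= 0)
    stop("noise_sd and mag_step_sd must be positive", call. = FALSE)
  if (engraftment_fraction < 0 || engraftment_fraction > 1 ||
      novelty_rate < 0 || novelty_rate > 1 ||
      engraftment_fraction + novelty_rate >= 1)
    stop("engraftment_fraction and novelty_rate must be proportions with sum < 1",
         call. = FALSE)
  structure(list(regime = regime, coupling_beta = coupling_beta,
                 noise_sd = noise_sd, mag_step_sd = mag_step_sd,
                 engraftment_fraction = engraftment_fraction,
                 novelty_rate = novelty_rate,
                 viral_labels = NULL, cluster_assignment = NULL,
                 true_links = NULL),
            class = "synthetic_truth")
}

#' Synthetic contig annotations exercising the triage rule
#'
#' Cycles through the 16 attempted on/off patterns of the four selection
#' criteria. Criteria 1 (>= 1 viral gene) and 4 (no viral and no bacterial
#' genes) are mutually exclusive, so 12 of the 16 patterns are logically
#' realizable; on conflicting patterns criterion 4's field setting wins.
#' The truth label is the OR of the realized criteria.
#'
#' @param n_contigs number of annotation rows (>= 1).
#' @param seed integer seed.
#' @return list with `annotations` (a data.frame) and `truth`
#'   (`viral_labels`: named logical).
#' @export
generate_triage_fixture <- function(n_contigs, seed = 1) {
  if (n_contigs < 1) stop("n_contigs must be >= 1", call. = FALSE)
  local_seed(child_seed(seed, 1), {
    pat <- (seq_len(n_contigs) - 1L) %% 16L
    c1 <- bitwAnd(pat, 1L) > 0L
    c2 <- bitwAnd(pat, 2L) > 0L
    c3 <- bitwAnd(pat, 4L) > 0L
    c4 <- bitwAnd(pat, 8L) > 0L
    viral <- ifelse(c4, 0L, ifelse(c1, sample(1:5, n_contigs, TRUE), 0L))
    host <- ifelse(c4, 0L, sample(1:6, n_contigs, TRUE))
    score <- ifelse(c2, stats::runif(n_contigs, 0.95, 1),
                    stats::runif(n_contigs, 0, 0.949))
    score[!c2 & pat %% 5L == 0L] <- NA   # some contigs unscored
    hallmarks <- ifelse(c3, sample(2:4, n_contigs, TRUE),
                        sample(0:1, n_contigs, TRUE))
    ann <- data.frame(
      contig_id = sprintf("tri%04d", seq_len(n_contigs)),
      length_bp = sample(5000:60000, n_contigs, TRUE),
      source_fraction = sample(c("WGS", "VLP"), n_contigs, TRUE),
      viral_gene_count = viral, host_gene_count = host,
      vs_score = score, hallmark_count = hallmarks,
      stringsAsFactors = FALSE)
    s0 <- ifelse(is.na(score), 0, score)
    label <- (viral >= 1) | (s0 >= 0.95) | (hallmarks >= 2) |
      (viral == 0 & host == 0)
    list(annotations = ann,
         truth = list(viral_labels = stats::setNames(label, ann$contig_id)))
  })
}

#' Synthetic all-vs-all ANI pairs for a planted clustering
#'
#' Emits both orientations of every contig pair (self-pairs omitted):
#' within-cluster pairs draw their ANI from `within_range` (above the
#' threshold), between-cluster pairs from `between_range` (below it), so
#' the planted partition is recoverable by construction.
#'
#' @param cluster_assignment named character vector contig_id -> cluster id.
#' @param threshold_pct the clustering threshold the fixture targets, in
#'   (0, 100].
#' @param seed integer seed.
#' @param within_range,between_range ANI ranges; defaults separate the
#'   pools by 2 percentage points around the threshold.
#' @return data.frame `query_id`, `subject_id`, `ani_pct`,
#'   `aligned_fraction`.
#' @export
generate_ani_pairs <- function(cluster_assignment, threshold_pct = 95,
                               seed = 1,
                               within_range = c(min(threshold_pct + 2, 100), 100),
                               between_range = c(60, threshold_pct - 2)) {
  if (threshold_pct <= 0 || threshold_pct > 100)
    stop("threshold_pct must be in (0, 100]", call. = FALSE)
  if (length(cluster_assignment) < 1L || is.null(names(cluster_assignment)))
    stop("cluster_assignment must be a named vector with >= 1 contig",
         call. = FALSE)
  ids <- names(cluster_assignment)
  if (length(ids) < 2L)
    return(data.frame(query_id = character(0), subject_id = character(0),
                      ani_pct = numeric(0), aligned_fraction = numeric(0)))
  local_seed(child_seed(seed, 2), {
    pairs <- t(utils::combn(ids, 2L))
    same <- cluster_assignment[pairs[, 1L]] == cluster_assignment[pairs[, 2L]]
    ani <- ifelse(same,
                  stats::runif(nrow(pairs), within_range[1], within_range[2]),
                  stats::runif(nrow(pairs), between_range[1], between_range[2]))
    af <- stats::runif(nrow(pairs), 0.85, 0.999)
    out <- data.frame(
      query_id = c(pairs[, 1L], pairs[, 2L]),
      subject_id = c(pairs[, 2L], pairs[, 1L]),
      ani_pct = c(ani, ani),
      aligned_fraction = c(af, af),
      stringsAsFactors = FALSE)
    out[order(out$query_id, out$subject_id), , drop = FALSE]
  })
}

#' Synthetic CRISPR-spacer hit table with labelled decoys
#'
#' Every true (VP, MAG) link yields one hit that passes the spacer filter
#' (length in \[20, 30\], at most 2 full-length mismatches). Decoys violate
#' exactly one criterion each — length out of range with few mismatches, or
#' in-range length with 3+ mismatches — so the filtered links reproduce the
#' planted links exactly.
#'
#' @param true_links data.frame `vp_id`, `mag_id`.
#' @param decoy_rate share of all hits that are decoys, in \[0, 1).
#' @param seed integer seed.
#' @param vp_contigs optional named map vp_id -> target contig id (defaults
#'   to the vp id itself).
#' @return list with `hits` (data.frame `spacer_id`, `mag_id`,
#'   `spacer_len`, `target_contig`, `n_identical`, `align_len`, `gapopen`)
#'   and `truth` (`is_decoy`: logical per hit row).
#' @export
generate_spacer_hits <- function(true_links, decoy_rate = 0.2, seed = 1,
                                 vp_contigs = NULL) {
  if (decoy_rate < 0 || decoy_rate >= 1)
    stop("decoy_rate must be in [0, 1)", call. = FALSE)
  n_true <- nrow(true_links)
  if (n_true > 0L)
    stop_if_not_cols(true_links, c("vp_id", "mag_id"), "true_links")
  target_of <- function(vp) {
    if (is.null(vp_contigs)) vp else unname(vp_contigs[vp])
  }
  local_seed(child_seed(seed, 3), {
    rows <- list()
    if (n_true > 0L) {
      len <- sample(20:30, n_true, TRUE)
      mm <- sample(0:2, n_true, TRUE)
      rows$true <- data.frame(
        spacer_id = sprintf("spacer%04d", seq_len(n_true)),
        mag_id = true_links$mag_id,
        spacer_len = len,
        target_contig = target_of(true_links$vp_id),
        n_identical = len - mm,
        align_len = len,
        gapopen = 0L,
        stringsAsFactors = FALSE)
    }
    n_decoy <- if (decoy_rate > 0 && n_true > 0L)
      max(1L, round(decoy_rate / (1 - decoy_rate) * n_true)) else 0L
    if (n_decoy > 0L) {
      idx <- sample.int(n_true, n_decoy, replace = TRUE)
      bad_len <- seq_len(n_decoy) %% 2L == 0L
      len <- ifelse(bad_len, sample(c(15:19, 31:35), n_decoy, TRUE),
                    sample(20:30, n_decoy, TRUE))
      mm <- ifelse(bad_len, sample(0:2, n_decoy, TRUE),
                   sample(3:5, n_decoy, TRUE))
      rows$decoy <- data.frame(
        spacer_id = sprintf("decoy%04d", seq_len(n_decoy)),
        mag_id = true_links$mag_id[idx],
        spacer_len = len,
        target_contig = target_of(true_links$vp_id[idx]),
        n_identical = len - mm,
        align_len = pmin(len, len - mm + sample(0:1, n_decoy, TRUE)),
        gapopen = 0L,
        stringsAsFactors = FALSE)
    }
    hits <- do.call(rbind, rows)
    if (is.null(hits))
      hits <- data.frame(spacer_id = character(0), mag_id = character(0),
                         spacer_len = integer(0), target_contig = character(0),
                         n_identical = integer(0), align_len = integer(0),
                         gapopen = integer(0))
    rownames(hits) <- NULL
    list(hits = hits,
         truth = list(is_decoy = grepl("^decoy", hits$spacer_id)))
  })
}

#' Synthetic continuous-glucose-monitor trace
#'
#' First-order autoregressive readings at the device's 15-minute cadence,
#' with stationary mean `mean` and standard deviation `sd` (sd = 0 gives a
#' constant trace).
#'
#' @param seed integer seed.
#' @param minutes trace duration in minutes (> 0); default one week.
#' @param mean,sd stationary mean and sd of glucose in mmol/L (sd >= 0).
#' @param ar1 autocorrelation between consecutive readings.
#' @return data.frame `minute`, `glucose_mmol_l`.
#' @export
generate_cgm_trace <- function(seed = 1, minutes = 7 * 1440, mean = 6.0,
                               sd = 1.0, ar1 = 0.8) {
  if (minutes <= 0) stop("minutes must be positive", call. = FALSE)
  if (sd < 0) stop("sd must be non-negative", call. = FALSE)
  ts <- seq(0, minutes, by = 15)
  local_seed(child_seed(seed, 4), {
    n <- length(ts)
    g <- numeric(n)
    g[1] <- mean + sd * stats::rnorm(1)
    innov <- sd * sqrt(1 - ar1^2) * stats::rnorm(n)
    for (i in seq_len(n)[-1]) g[i] <- mean + ar1 * (g[i - 1] - mean) + innov[i]
    data.frame(minute = ts, glucose_mmol_l = pmax(g, 0.1))
  })
}

#' Synthetic oral glucose tolerance test curve
#'
#' Glucose values on the standard grid (0, 15, 30, 45, 60, 90, 120 min):
#' a rise from baseline to a peak around 45 min with a slow return, plus
#' Gaussian noise.
#'
#' @param seed integer seed.
#' @param baseline fasting glucose in mmol/L.
#' @param peak_delta peak excursion above baseline in mmol/L.
#' @param noise_sd measurement noise in mmol/L (>= 0).
#' @return data.frame `minute`, `glucose_mmol_l`.
#' @export
generate_ogtt_curve <- function(seed = 1, baseline = 5.5, peak_delta = 3.0,
                                noise_sd = 0.2) {
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  profile <- c(0, 0.45, 0.85, 1, 0.9, 0.55, 0.2)
  local_seed(child_seed(seed, 5), {
    g <- baseline + peak_delta * profile +
      noise_sd * stats::rnorm(length(ogtt_grid))
    data.frame(minute = ogtt_grid, glucose_mmol_l = pmax(g, 0.1))
  })
}
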