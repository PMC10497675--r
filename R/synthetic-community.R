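#' Generate the full synthetic trial community with planted truth
#'
#' Builds every input table the pipeline consumes, from one seed: contig
#' annotations (viral plus non-viral decoys), all-vs-all ANI pairs encoding
#' a planted VP partition, per-contig per-sample read counts with coverage
#' breadths, MAG membership/quality/taxonomy (including one low-quality
#' decoy MAG that contains a viral contig and must be removed by the
#' quality gate), CRISPR-spacer hits with labelled decoys, sample metadata
#' and a differentially-abundant VP list.
#'
#' The community model: each recipient has its own resident community of
#' VPs and MAGs whose log abundances follow random walks across the
#' sampling days; for host-linked species the VP step is
#' `coupling_beta x (mean MAG step) + N(0, noise_sd)`. Donors are single
#' pre-intervention samples over donor-specific VP pools disjoint from
#' recipient baselines; in FFT recipients the assigned donor's VPs carry an
#' `engraftment_fraction` share of post-baseline relative abundance, and a
#' pool of novel VPs (absent at day 0 everywhere) carries a `novelty_rate`
#' share in all recipients. Abundances are composed on the proportion
#' scale and sampled to integer counts by a multinomial draw at a
#' log-normal library size.
#'
#' @param config a [scenario_config()].
#' @param truth a [synthetic_truth()].
#' @param low_breadth_rate share of present contig records given a coverage
#'   breadth below 0.75 (their reads are zeroed by the breadth filter and
#'   by the returned planted count table alike).
#' @param tables if `FALSE`, skip the raw pipeline input tables
#'   (annotations, ANI pairs, coverage, spacer hits) and return only the
#'   planted abundance tables, links, metadata and truth — much faster for
#'   Monte-Carlo loops.
#' @return a list; see Details in the package vignette. Key elements:
#'   `vp_counts` and `mag_counts` (`abundance_table`s of planted counts),
#'   `links` (species-resolved true links), `meta`, `truth` (the input
#'   truth with `viral_labels`, `cluster_assignment`, `true_links`,
#'   `donor_assignment` filled), and with `tables = TRUE` also
#'   `annotations`, `ani_pairs`, `coverage`, `vlp_library_sizes`,
#'   `wgs_library_sizes`, `vp_membership`, `mag_membership`, `mag_quality`,
#'   `taxonomy`, `spacer_hits`, `da_vps`.
#' @export
generate_community <- function(config, truth, low_breadth_rate = 0.02,
                               tables = TRUE) {
  if (!inherits(config, "scenario_config"))
    stop("config must be a scenario_config", call. = FALSE)
  if (!inherits(truth, "synthetic_truth"))
    stop("truth must be a synthetic_truth", call. = FALSE)
  cfg <- config
  n_sp <- cfg$n_species
  mags_per_sp <- cfg$n_mags / n_sp

  species <- sprintf("s__Species%02d", seq_len(n_sp))
  mag_ids <- sprintf("MAG%03d", seq_len(cfg$n_mags))
  species_of_mag <- stats::setNames(rep(species, each = mags_per_sp), mag_ids)

  vp_res <- sprintf("VP_R%03d", seq_len(cfg$n_resident))
  vp_don <- sprintf("VP_D%03d", seq_len(cfg$n_donor_vps))
  vp_nov <- sprintf("VP_N%03d", seq_len(cfg$n_novel_vps))
  vps <- c(vp_res, vp_don, vp_nov)

  # first 2 resident VPs per species are host-linked, to every MAG of the
  # species; evidence alternates between crispr and prophage
  linked_vps <- vp_res[seq_len(2L * n_sp)]
  species_of_vp <- stats::setNames(rep(species, each = 2L), linked_vps)
  links <- do.call(rbind, lapply(seq_along(linked_vps), function(i) {
    sp <- species_of_vp[[i]]
    data.frame(vp_id = linked_vps[i],
               mag_id = mag_ids[species_of_mag == sp],
               stringsAsFactors = FALSE)
  }))
  links$evidence <- ifelse(seq_len(nrow(links)) %% 2L == 0L,
                           "prophage", "crispr")
  links$species <- unname(species_of_mag[links$mag_id])

  fft <- sprintf("F%02d", seq_len(cfg$n_per_arm))
  plc <- sprintf("P%02d", seq_len(cfg$n_per_arm))
  donors <- sprintf("D%d", seq_len(cfg$n_donors))
  donor_assignment <- stats::setNames(
    rep(donors, length.out = cfg$n_per_arm), fft)
  recipients <- c(fft, plc)
  days <- cfg$days
  post <- days[days > 0]

  # donor pool split across donors
  donor_chunk <- split(vp_don, rep(seq_len(cfg$n_donors),
                                   length.out = cfg$n_donor_vps))
  names(donor_chunk) <- donors

  e <- truth$engraftment_fraction
  r <- truth$novelty_rate
  beta <- truth$coupling_beta

  # contigs: 1 or 2 per VP, deterministic lengths drawn under child stream
  world <- local_seed(child_seed(cfg$seed, 10), {
    n_members <- ifelse(seq_along(vps) %% 3L == 0L, 2L, 1L)
    contig_of_vp <- lapply(seq_along(vps), function(i)
      sprintf("%s_c%d", vps[i], seq_len(n_members[i])))
    names(contig_of_vp) <- vps
    contigs <- unlist(contig_of_vp, use.names = FALSE)
    contig_len <- stats::setNames(sample(5000:80000, length(contigs), TRUE),
                                  contigs)

    softmax <- function(x) exp(x) / sum(exp(x))
    n_steps <- length(days) - 1L

    # per-recipient trajectories on the log scale
    res_prop <- list(); nov_prop <- list()
    vp_step_store <- list()
    for (p in recipients) {
      mag_log <- stats::rnorm(cfg$n_mags)
      vp_log <- stats::rnorm(cfg$n_resident)
      names(vp_log) <- vp_res
      nov_active <- sort(sample(vp_nov, max(2L, round(0.75 * length(vp_nov)))))
      nov_log <- stats::setNames(stats::rnorm(length(nov_active)), nov_active)
      res_prop[[p]] <- list(); nov_prop[[p]] <- list()
      res_prop[[p]][[as.character(days[1])]] <- softmax(vp_log)
      nov_prop[[p]][[as.character(days[1])]] <-
        stats::setNames(rep(0, length(nov_active)), nov_active)
      mag_prop_p <- list()
      mag_prop_p[[as.character(days[1])]] <-
        stats::setNames(softmax(mag_log), mag_ids)
      for (s in seq_len(n_steps)) {
        mag_step <- stats::rnorm(cfg$n_mags, 0, truth$mag_step_sd)
        names(mag_step) <- mag_ids
        sp_step <- vapply(split(mag_step, species_of_mag[mag_ids]),
                          mean, numeric(1))
        vp_noise <- stats::rnorm(cfg$n_resident, 0, truth$noise_sd)
        vp_step <- vp_noise
        names(vp_step) <- vp_res
        vp_step[linked_vps] <- beta * sp_step[species_of_vp[linked_vps]] +
          vp_noise[seq_along(linked_vps)]
        mag_log <- mag_log + mag_step
        vp_log <- vp_log + vp_step
        nov_log <- nov_log + stats::rnorm(length(nov_log), 0, truth$noise_sd)
        d <- as.character(days[s + 1L])
        res_prop[[p]][[d]] <- softmax(vp_log)
        nov_prop[[p]][[d]] <- softmax(nov_log)
        mag_prop_p[[d]] <- stats::setNames(softmax(mag_log), mag_ids)
      }
      vp_step_store[[p]] <- mag_prop_p
    }

    donor_prop <- lapply(donors, function(d) {
      w <- stats::rnorm(length(donor_chunk[[d]]))
      stats::setNames(softmax(w), donor_chunk[[d]])
    })
    names(donor_prop) <- donors

    list(contig_of_vp = contig_of_vp, contig_len = contig_len,
         res_prop = res_prop, nov_prop = nov_prop,
         mag_prop = vp_step_store, donor_prop = donor_prop)
  })

  # compose per-sample VP proportions
  vp_prop_sample <- function(p, d) {
    out <- stats::setNames(rep(0, length(vps)), vps)
    res <- world$res_prop[[p]][[as.character(d)]]
    if (d == 0) {
      out[vp_res] <- res
      return(out)
    }
    nov <- world$nov_prop[[p]][[as.character(d)]]
    ep <- if (p %in% fft) e else 0
    out[vp_res] <- (1 - ep - r) * res
    out[names(nov)] <- r * nov
    if (ep > 0) {
      dp <- world$donor_prop[[donor_assignment[[p]]]]
      out[names(dp)] <- ep * dp
    }
    out
  }

  samp_vlp <- c(
    unlist(lapply(recipients, function(p) sprintf("%s_d%02d_VLP", p, days))),
    sprintf("%s_VLP", donors))
  samp_wgs <- unlist(lapply(recipients,
                            function(p) sprintf("%s_d%02d_WGS", p, days)))

  contigs <- unlist(world$contig_of_vp, use.names = FALSE)
  vp_of_contig <- stats::setNames(
    rep(names(world$contig_of_vp), lengths(world$contig_of_vp)), contigs)
  len_share <- unlist(lapply(world$contig_of_vp, function(cs) {
    l <- world$contig_len[cs]
    stats::setNames(l / sum(l), cs)
  }), use.names = FALSE)
  names(len_share) <- contigs

  sim <- local_seed(child_seed(cfg$seed, 11), {
    vlp_lib <- stats::setNames(
      round(stats::rlnorm(length(samp_vlp), cfg$library_size_meanlog,
                          cfg$library_size_sdlog)), samp_vlp)
    wgs_lib <- stats::setNames(
      round(stats::rlnorm(length(samp_wgs), cfg$library_size_meanlog,
                          cfg$library_size_sdlog)), samp_wgs)

    contig_counts <- matrix(0L, length(contigs), length(samp_vlp),
                            dimnames = list(contigs, samp_vlp))
    for (p in recipients) for (d in days) {
      s <- sprintf("%s_d%02d_VLP", p, d)
      pv <- vp_prop_sample(p, d)
      pc <- pv[vp_of_contig] * len_share
      contig_counts[, s] <- stats::rmultinom(1, vlp_lib[[s]], pc)
    }
    for (dn in donors) {
      s <- sprintf("%s_VLP", dn)
      pv <- stats::setNames(rep(0, length(vps)), vps)
      dp <- world$donor_prop[[dn]]
      pv[names(dp)] <- dp
      pc <- pv[vp_of_contig] * len_share
      contig_counts[, s] <- stats::rmultinom(1, vlp_lib[[s]], pc)
    }

    breadth <- matrix(stats::runif(length(contig_counts), 0.76, 1),
                      nrow(contig_counts), ncol(contig_counts),
                      dimnames = dimnames(contig_counts))
    if (low_breadth_rate > 0) {
      low <- stats::runif(length(breadth)) < low_breadth_rate
      breadth[low] <- stats::runif(sum(low), 0.30, 0.74)
    }
    breadth[contig_counts == 0] <- 0

    mag_counts <- matrix(0L, cfg$n_mags, length(samp_wgs),
                         dimnames = list(mag_ids, samp_wgs))
    for (p in recipients) for (d in days) {
      s <- sprintf("%s_d%02d_WGS", p, d)
      pm <- world$mag_prop[[p]][[as.character(d)]]
      mag_counts[, s] <- stats::rmultinom(1, wgs_lib[[s]], pm)
    }
    list(vlp_lib = vlp_lib, wgs_lib = wgs_lib,
         contig_counts = contig_counts, breadth = breadth,
         mag_counts = mag_counts)
  })

  # planted VP counts after the breadth rule (records below 75% are zeroed)
  cc_filtered <- sim$contig_counts
  cc_filtered[sim$breadth < 0.75] <- 0L
  vp_counts_m <- rowsum(cc_filtered, vp_of_contig[rownames(cc_filtered)])
  vp_counts_m <- vp_counts_m[vps, , drop = FALSE]
  vp_len <- vapply(world$contig_of_vp,
                   function(cs) sum(world$contig_len[cs]), numeric(1))[vps]
  vp_counts <- abundance_table(vp_counts_m, "count",
                               feature_length = vp_len,
                               library_size = sim$vlp_lib)
  mag_counts <- abundance_table(sim$mag_counts, "count",
                                library_size = sim$wgs_lib)

  meta <- rbind(
    do.call(rbind, lapply(recipients, function(p) data.frame(
      sample_id = sprintf("%s_d%02d_VLP", p, days),
      participant_id = p,
      arm = if (p %in% fft) "FFT" else "placebo",
      day = days,
      donor_id = if (p %in% fft) donor_assignment[[p]] else NA_character_,
      fraction = "VLP", stringsAsFactors = FALSE))),
    data.frame(sample_id = sprintf("%s_VLP", donors), participant_id = donors,
               arm = "donor", day = NA_integer_, donor_id = NA_character_,
               fraction = "VLP", stringsAsFactors = FALSE),
    do.call(rbind, lapply(recipients, function(p) data.frame(
      sample_id = sprintf("%s_d%02d_WGS", p, days),
      participant_id = p,
      arm = if (p %in% fft) "FFT" else "placebo",
      day = days,
      donor_id = if (p %in% fft) donor_assignment[[p]] else NA_character_,
      fraction = "WGS", stringsAsFactors = FALSE))))
  rownames(meta) <- NULL

  truth$viral_labels <- stats::setNames(rep(TRUE, length(contigs)), contigs)
  truth$cluster_assignment <- vp_of_contig
  truth$true_links <- links[, c("vp_id", "mag_id")]
  truth$donor_assignment <- donor_assignment
  truth$species_of_mag <- species_of_mag
  truth$species_of_vp <- species_of_vp

  out <- list(vp_counts = vp_counts, mag_counts = mag_counts,
              links = links[, c("vp_id", "mag_id", "species", "evidence")],
              meta = meta, truth = truth,
              vlp_library_sizes = sim$vlp_lib,
              wgs_library_sizes = sim$wgs_lib)
  if (!tables) return(out)

  out <- c(out, local_seed(child_seed(cfg$seed, 12), {
    # annotations: community contigs pass criterion 1; decoys fail all four
    n_decoy <- 10L
    decoy_ids <- sprintf("decoyctg%02d", seq_len(n_decoy))
    ann <- data.frame(
      contig_id = c(contigs, decoy_ids),
      length_bp = c(as.integer(world$contig_len[contigs]),
                    sample(5000:30000, n_decoy, TRUE)),
      source_fraction = "VLP",
      viral_gene_count = c(sample(1:5, length(contigs), TRUE),
                           rep(0L, n_decoy)),
      host_gene_count = c(sample(0:4, length(contigs), TRUE),
                          sample(2:8, n_decoy, TRUE)),
      vs_score = stats::runif(length(contigs) + n_decoy, 0, 0.9),
      hallmark_count = c(sample(0:1, length(contigs), TRUE),
                         rep(0L, n_decoy)),
      stringsAsFactors = FALSE)
    truth_labels <- c(stats::setNames(rep(TRUE, length(contigs)), contigs),
                      stats::setNames(rep(FALSE, n_decoy), decoy_ids))

    vp_membership <- do.call(rbind, lapply(vps, function(v) {
      cs <- world$contig_of_vp[[v]]
      l <- world$contig_len[cs]
      data.frame(vp_id = v, contig_id = cs, length_bp = as.integer(l),
                 is_representative = cs == cs[order(-l, cs)][1L],
                 stringsAsFactors = FALSE)
    }))

    # MAG contigs: 3 bacterial contigs each, plus the viral contig of each
    # prophage-evidence link; one failing decoy MAG swallows a viral contig
    mag_membership <- do.call(rbind, lapply(mag_ids, function(m) data.frame(
      mag_id = m, contig_id = sprintf("%s_b%d", m, 1:3),
      stringsAsFactors = FALSE)))
    pro <- links[links$evidence == "prophage", , drop = FALSE]
    rep_of <- stats::setNames(
      vp_membership$contig_id[vp_membership$is_representative],
      vp_membership$vp_id[vp_membership$is_representative])
    mag_membership <- rbind(mag_membership, data.frame(
      mag_id = pro$mag_id, contig_id = unname(rep_of[pro$vp_id]),
      stringsAsFactors = FALSE))
    bad_mag <- data.frame(mag_id = "MAGBAD1",
                          contig_id = unname(rep_of[linked_vps[1L]]),
                          stringsAsFactors = FALSE)
    mag_membership <- unique(rbind(mag_membership, bad_mag))

    mag_quality <- data.frame(
      mag_id = c(mag_ids, "MAGBAD1"),
      completeness_pct = c(stats::runif(cfg$n_mags, 70, 99), 55),
      contamination_pct = c(stats::runif(cfg$n_mags, 0, 3), 4),
      stringsAsFactors = FALSE)
    taxonomy <- data.frame(
      mag_id = c(mag_ids, "MAGBAD1"),
      species = c(unname(species_of_mag[mag_ids]), species[1L]),
      stringsAsFactors = FALSE)

    cri <- links[links$evidence == "crispr", c("vp_id", "mag_id"),
                 drop = FALSE]
    sp_hits <- generate_spacer_hits(cri, decoy_rate = 0.2,
                                    seed = child_seed(cfg$seed, 13),
                                    vp_contigs = rep_of)

    ani_pairs <- generate_ani_pairs(vp_of_contig, threshold_pct = 95,
                                    seed = child_seed(cfg$seed, 14))

    cov_idx <- which(sim$contig_counts > 0, arr.ind = TRUE)
    coverage <- data.frame(
      contig_id = rownames(sim$contig_counts)[cov_idx[, 1L]],
      sample_id = colnames(sim$contig_counts)[cov_idx[, 2L]],
      read_count = sim$contig_counts[cov_idx],
      fraction_covered = round(sim$breadth[cov_idx], 4),
      stringsAsFactors = FALSE)
    coverage <- coverage[order(coverage$sample_id, coverage$contig_id), ]
    rownames(coverage) <- NULL

    # DA list: every VP of the first two species plus two unhosted VPs
    da_vps <- c(linked_vps[species_of_vp[linked_vps] %in% species[1:2]],
                vp_res[c(cfg$n_resident - 1L, cfg$n_resident)])

    list(annotations = ann, viral_labels = truth_labels,
         vp_membership = vp_membership, mag_membership = mag_membership,
         mag_quality = mag_quality, taxonomy = taxonomy,
         spacer_hits = sp_hits$hits, spacer_truth = sp_hits$truth,
         ani_pairs = ani_pairs, coverage = coverage, da_vps = da_vps)
  }))
  out$truth$viral_labels <- out$viral_labels
  out$viral_labels <- NULL
  out
}
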