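#' Pipeline configuration
#'
#' All numeric thresholds of the pipeline with their defaults, the master
#' seed, and the input/output paths. `read_identity_min` documents the
#' upstream alignment-identity filter (applied by the mapper before the
#' coverage table is produced); the pipeline consumes post-filter counts.
#'
#' @param indir directory holding the input tables (as written by
#'   [simulate_inputs()] or by upstream tools in the same dialects).
#' @param outdir directory for outputs; created if missing.
#' @param ... overrides for any default listed below.
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(indir = ".", outdir = "out", ...) {
  cfg <- list(
    min_contig_bp = 5000, ani_threshold_pct = 95, breadth_min = 0.75,
    read_identity_min = 0.90, rpkm_total_min = 100, rpkm_value_min = 20,
    prevalence_min = 0.10, mag_quality_min = 50,
    spacer_len_min = 20, spacer_len_max = 30, spacer_max_mismatch = 2,
    tir_lo = 3.9, tir_hi = 10.0, n_perm = 1000, alpha = 0.05, seed = 1,
    permanova_day = 2, distance = "aitchison",
    interaction_scale = "proportion",
    interaction_intervals = list(c(0, 2), c(2, 28), c(0, 28)),
    indir = indir, outdir = outdir)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L)
    stop_validation(sprintf("unknown config key(s): %s",
                            paste(unknown, collapse = ", ")))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop_validation(msg)
  chk(cfg$min_contig_bp > 0, "min_contig_bp must be positive")
  chk(cfg$ani_threshold_pct > 0 && cfg$ani_threshold_pct <= 100,
      "ani_threshold_pct must be in (0, 100]")
  chk(cfg$breadth_min >= 0 && cfg$breadth_min <= 1,
      "breadth_min must be in [0, 1]")
  chk(cfg$prevalence_min >= 0 && cfg$prevalence_min <= 1,
      "prevalence_min must be in [0, 1]")
  chk(cfg$spacer_len_min <= cfg$spacer_len_max, "spacer length bounds inverted")
  chk(cfg$spacer_max_mismatch >= 0, "spacer_max_mismatch must be >= 0")
  chk(cfg$tir_lo < cfg$tir_hi, "time-in-range bounds inverted")
  chk(cfg$n_perm >= 1, "n_perm must be >= 1")
  chk(cfg$alpha > 0 && cfg$alpha < 1, "alpha must be in (0, 1)")
  invisible(cfg)
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file with any subset of the [pipeline_config()] keys.
#' @param ... further overrides (win over the file).
#' @return a `pipeline_config`.
#' @export
read_config <- function(path, ...) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$interaction_intervals))
    vals$interaction_intervals <-
      lapply(seq_len(nrow(vals$interaction_intervals)),
             function(i) vals$interaction_intervals[i, ])
  do.call(pipeline_config, utils::modifyList(vals, list(...)))
}

input_paths <- function(cfg) {
  f <- function(x) file.path(cfg$indir, x)
  list(annotations = f("annotations.tsv"), ani = f("ani_pairs.tsv"),
       coverage = f("coverage.tsv"),
       vlp_library_sizes = f("vlp_library_sizes.tsv"),
       mag_counts = f("mag_counts.tsv"),
       mag_membership = f("mag_membership.tsv"),
       mag_quality = f("mag_quality.tsv"),
       taxonomy = f("taxonomy.tsv"),
       spacer_hits = f("spacer_hits.tsv"),
       meta = f("metadata.tsv"), da_vps = f("da_vps.txt"))
}

#' Write a complete synthetic input set to disk
#'
#' Runs [generate_community()] and serialises every table in the dialect
#' [run_all()] reads, plus `truth.json` with the planted ground truth and a
#' small clinical fixture (adverse-event table, OGTT curves, CGM traces).
#'
#' @param config a [scenario_config()].
#' @param truth a [synthetic_truth()].
#' @param outdir target directory (created if needed).
#' @return invisibly, the [generate_community()] result.
#' @export
simulate_inputs <- function(config, truth, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  com <- generate_community(config, truth, tables = TRUE)
  f <- function(x) file.path(outdir, x)
  write_annotations(com$annotations, f("annotations.tsv"))
  write_tsv(com$ani_pairs, f("ani_pairs.tsv"))
  write_tsv(com$coverage, f("coverage.tsv"))
  write_tsv(data.frame(sample_id = names(com$vlp_library_sizes),
                       library_size = as.integer(com$vlp_library_sizes)),
            f("vlp_library_sizes.tsv"))
  write_abundance_matrix(com$mag_counts, f("mag_counts.tsv"))
  write_tsv(com$mag_membership, f("mag_membership.tsv"))
  write_tsv(data.frame(mag_id = com$mag_quality$mag_id,
                       completeness = com$mag_quality$completeness_pct,
                       contamination = com$mag_quality$contamination_pct),
            f("mag_quality.tsv"))
  write_tsv(com$taxonomy, f("taxonomy.tsv"))
  write_spacer_hits(com$spacer_hits, f("spacer_hits.tsv"))
  write_tsv(com$meta, f("metadata.tsv"))
  writeLines(com$da_vps, f("da_vps.txt"))

  # clinical fixture: related-AE flags planted at the trial's printed
  # subject counts (6 of 12 FFT vs 2 of 12 placebo, scaled to arm size)
  rec <- unique(com$meta[com$meta$arm %in% c("FFT", "placebo"),
                         c("participant_id", "arm")])
  n_fft <- sum(rec$arm == "FFT"); n_plc <- sum(rec$arm == "placebo")
  ae <- ifelse(rec$arm == "FFT",
               seq_len(nrow(rec)) %in% which(rec$arm == "FFT")[
                 seq_len(round(6 / 12 * n_fft))],
               seq_len(nrow(rec)) %in% which(rec$arm == "placebo")[
                 seq_len(round(2 / 12 * n_plc))])
  write_tsv(data.frame(participant_id = rec$participant_id, arm = rec$arm,
                       related_ae = as.integer(ae)), f("adverse_events.tsv"))
  ogtt <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i)
    do.call(rbind, lapply(c(0, 28), function(day) {
      cv <- generate_ogtt_curve(seed = child_seed(config$seed,
                                                  100 + 2 * i + day))
      data.frame(participant_id = rec$participant_id[i], day = day, cv,
                 stringsAsFactors = FALSE)
    }))))
  write_tsv(ogtt, f("ogtt.tsv"))
  cgm <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i)
    do.call(rbind, lapply(c("pre", "post"), function(period) {
      tr <- generate_cgm_trace(seed = child_seed(config$seed,
                                                 500 + 2 * i +
                                                   (period == "post")),
                               minutes = 2 * 1440)
      data.frame(participant_id = rec$participant_id[i], period = period,
                 tr, stringsAsFactors = FALSE)
    }))))
  write_tsv(cgm, f("cgm.tsv"))

  truth_json <- list(
    regime = com$truth$regime, coupling_beta = com$truth$coupling_beta,
    noise_sd = com$truth$noise_sd,
    engraftment_fraction = com$truth$engraftment_fraction,
    novelty_rate = com$truth$novelty_rate,
    viral_labels = as.list(com$truth$viral_labels),
    cluster_assignment = as.list(com$truth$cluster_assignment),
    true_links = com$truth$true_links,
    donor_assignment = as.list(com$truth$donor_assignment))
  jsonlite::write_json(truth_json, f("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(com)
}

log_stage <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Stages: triage -> cluster -> quantify -> link -> dynamics -> enrich
#' (-> clinical when its inputs exist). All inputs are read from
#' `config$indir`, all outputs written under `config$outdir`, and a
#' machine-readable run report (`report.json`) captures versions, the full
#' config echo, per-stage row counts and seeds. Reruns with identical
#' inputs and seed reproduce every output byte for byte.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the report list.
#' @export
run_all <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop_validation("config must be a pipeline_config")
  paths <- input_paths(config)
  required <- unlist(paths[c("annotations", "ani", "coverage",
                             "vlp_library_sizes", "mag_counts",
                             "mag_membership", "mag_quality", "taxonomy",
                             "spacer_hits", "meta", "da_vps")])
  missing <- required[!file.exists(required)]
  if (length(missing) > 0L)
    stop_validation(sprintf("missing input file(s): %s",
                            paste(missing, collapse = ", ")))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  o <- function(x) file.path(config$outdir, x)
  report <- list(package = "phagedyn",
                 version = as.character(utils::packageVersion("phagedyn")),
                 r_version = paste(R.version$major, R.version$minor,
                                   sep = "."),
                 config = unclass(config), stages = list())

  # --- triage ---
  ann <- read_annotations(paths$annotations)
  ann <- filter_min_length(ann, config$min_contig_bp)
  viral <- classify_viral(ann)
  viral_ann <- ann[viral, , drop = FALSE]
  log_stage("triage", "%d/%d contigs classified viral", nrow(viral_ann),
            nrow(ann))
  report$stages$triage <- list(n_input = nrow(ann),
                               n_viral = nrow(viral_ann))

  # --- cluster ---
  ani <- read_ani_table(paths$ani,
                        stats::setNames(ann$length_bp, ann$contig_id))
  ani <- ani[ani$query_id %in% viral_ann$contig_id &
               ani$subject_id %in% viral_ann$contig_id, , drop = FALSE]
  kept <- dedup_exact(viral_ann, ani)
  dedup_ann <- viral_ann[viral_ann$contig_id %in% kept, , drop = FALSE]
  vp_membership <- cluster_vps(dedup_ann, ani, config$ani_threshold_pct)
  write_tsv(vp_membership, o("vp_membership.tsv"))
  log_stage("cluster", "%d contigs -> %d VPs", nrow(vp_membership),
            length(unique(vp_membership$vp_id)))
  report$stages$cluster <- list(n_dedup = nrow(dedup_ann),
                                n_vps = length(unique(vp_membership$vp_id)))

  # --- quantify ---
  cov <- read_tsv(paths$coverage, "coverage")
  cov <- cov[cov$contig_id %in% vp_membership$contig_id, , drop = FALSE]
  cov <- apply_breadth_filter(cov, config$breadth_min)
  libs <- read_library_sizes(paths$vlp_library_sizes)
  rpkm <- rpkm_per_vp(cov, vp_membership,
                      stats::setNames(vp_membership$length_bp,
                                      vp_membership$contig_id), libs)
  write_abundance_matrix(rpkm, o("vp_rpkm.tsv"))
  rpkm_filt <- filter_low_abundance(rpkm, config$rpkm_total_min,
                                    config$rpkm_value_min,
                                    config$prevalence_min)
  write_tsv(diversity_table(rpkm), o("diversity.tsv"))
  meta <- read_meta(paths$meta)
  perm <- NULL
  psam <- meta$sample_id[!is.na(meta$day) & meta$day == config$permanova_day &
                           meta$fraction == "VLP" &
                           meta$arm %in% c("FFT", "placebo")]
  psam <- intersect(psam, colnames(rpkm_filt))
  grp <- meta$arm[match(psam, meta$sample_id)]
  if (length(psam) >= 4L && min(table(grp)) >= 2L && nrow(rpkm_filt) >= 2L) {
    d <- community_dist(retable(rpkm_filt,
                                unclass(rpkm_filt)[, psam, drop = FALSE]),
                        method = config$distance)
    perm <- permanova(d, grp, n_perm = config$n_perm, seed = config$seed)
    jsonlite::write_json(
      list(day = config$permanova_day, distance = config$distance,
           pseudo_F = perm$pseudo_F, p = perm$p, n_perm = perm$n_perm,
           n_samples = length(psam)),
      o("permanova.json"), auto_unbox = TRUE, digits = NA)
  }
  log_stage("quantify", "%d VPs quantified, %d retained after filtering",
            nrow(rpkm), nrow(rpkm_filt))
  report$stages$quantify <- list(n_vps = nrow(rpkm),
                                 n_vps_filtered = nrow(rpkm_filt),
                                 permanova_p = if (!is.null(perm)) perm$p)

  # --- link ---
  magq <- read_mag_quality(paths$mag_quality)
  magq_ok <- filter_mags(magq, config$mag_quality_min)
  mag_membership <- read_tsv(paths$mag_membership, "MAG membership")
  mag_membership <- mag_membership[
    mag_membership$mag_id %in% magq_ok$mag_id, , drop = FALSE]
  pro <- link_prophages(vp_membership, mag_membership)
  hits <- read_spacer_hits(paths$spacer_hits)
  hits <- hits[hits$mag_id %in% magq_ok$mag_id, , drop = FALSE]
  cri <- filter_spacer_hits(hits, vp_membership, config$spacer_len_min,
                            config$spacer_len_max,
                            config$spacer_max_mismatch)
  taxonomy <- read_tsv(paths$taxonomy, "taxonomy")
  links <- resolve_species(rbind(pro, cri), taxonomy)
  write_tsv(links, o("host_links.tsv"))
  log_stage("link", "%d prophage + %d crispr links", nrow(pro), nrow(cri))
  report$stages$link <- list(n_mags_kept = nrow(magq_ok),
                             n_prophage = nrow(pro), n_crispr = nrow(cri))

  # --- dynamics ---
  eng <- engraftment_table(rpkm, meta)
  write_tsv(eng, o("engraftment.tsv"))
  mag_counts <- read_abundance_matrix(paths$mag_counts, "count")
  arm_of <- stats::setNames(meta$arm, meta$participant_id)
  days_avail <- sort(unique(meta$day[!is.na(meta$day)]))
  intervals <- Filter(function(iv) all(iv %in% days_avail),
                      config$interaction_intervals)
  all_points <- list(); correlations <- list()
  for (iv in intervals) {
    pts <- interaction_points(rpkm, mag_counts, links, meta, iv[1], iv[2],
                              scale = config$interaction_scale)
    if (nrow(pts) > 0L) {
      all_points[[length(all_points) + 1L]] <- pts
      grp_n <- table(arm_of[pts$participant_id])
      if (length(grp_n) >= 1L && min(grp_n) >= 3L) {
        cc <- interaction_correlation(pts, arm_of)
        cc$day_a <- iv[1]; cc$day_b <- iv[2]
        correlations[[length(correlations) + 1L]] <- cc
      }
    }
  }
  pts_all <- if (length(all_points)) do.call(rbind, all_points) else
    data.frame()
  if (nrow(pts_all) > 0L) write_tsv(pts_all, o("interaction_points.tsv"))
  corr_all <- if (length(correlations)) do.call(rbind, correlations) else
    data.frame()
  jsonlite::write_json(corr_all, o("interaction_correlations.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  log_stage("dynamics", "%d interaction points over %d interval(s)",
            nrow(pts_all), length(intervals))
  report$stages$dynamics <- list(n_points = nrow(pts_all),
                                 n_intervals = length(intervals))

  # --- enrich ---
  da <- readLines(paths$da_vps)
  da <- da[nzchar(da)]
  # the DA list names planted VPs; map onto clustered VP ids via contigs
  da <- translate_feature_ids(da, vp_membership)
  enr <- host_enrichment(da, host_table(links), config$alpha)
  write_tsv(enr, o("enrichment.tsv"))
  log_stage("enrich", "%d species tested, %d significant", nrow(enr),
            sum(enr$significant))
  report$stages$enrich <- list(n_da = length(da), n_tested = nrow(enr),
                               n_significant = sum(enr$significant))

  # --- clinical (optional) ---
  ae_path <- file.path(config$indir, "adverse_events.tsv")
  if (file.exists(ae_path)) {
    ae <- read_tsv(ae_path, "adverse events")
    tab <- matrix(c(sum(ae$related_ae[ae$arm == "FFT"]),
                    sum(ae$arm == "FFT") - sum(ae$related_ae[ae$arm == "FFT"]),
                    sum(ae$related_ae[ae$arm == "placebo"]),
                    sum(ae$arm == "placebo") -
                      sum(ae$related_ae[ae$arm == "placebo"])),
                  2, 2, byrow = TRUE)
    clin <- list(ae_fisher_p = fisher_exact_two_sided(tab))
    ogtt_path <- file.path(config$indir, "ogtt.tsv")
    if (file.exists(ogtt_path)) {
      og <- read_tsv(ogtt_path, "ogtt")
      auc <- do.call(rbind, lapply(split(og, og[c("participant_id", "day")]),
                                   function(d) data.frame(
        participant_id = d$participant_id[1], day = d$day[1],
        auc = ogtt_auc(d), stringsAsFactors = FALSE)))
      rownames(auc) <- NULL
      auc <- auc[order(auc$participant_id, auc$day), ]
      write_tsv(auc, o("ogtt_auc.tsv"))
      clin$mean_auc_day0 <- mean(auc$auc[auc$day == 0])
    }
    cgm_path <- file.path(config$indir, "cgm.tsv")
    if (file.exists(cgm_path)) {
      cg <- read_tsv(cgm_path, "cgm")
      tir <- do.call(rbind, lapply(
        split(cg, cg[c("participant_id", "period")]), function(d) data.frame(
          participant_id = d$participant_id[1], period = d$period[1],
          tir_pct = time_in_range(d$glucose_mmol_l, config$tir_lo,
                                  config$tir_hi),
          stringsAsFactors = FALSE)))
      rownames(tir) <- NULL
      tir <- tir[order(tir$participant_id, tir$period), ]
      write_tsv(tir, o("time_in_range.tsv"))
    }
    jsonlite::write_json(clin, o("clinical.json"), auto_unbox = TRUE,
                         digits = NA)
    log_stage("clinical", "AE Fisher p = %.4g", clin$ae_fisher_p)
    report$stages$clinical <- clin
  }

  # --- truth comparison, when the input dir carries a planted truth ---
  truth_path <- file.path(config$indir, "truth.json")
  if (file.exists(truth_path)) {
    tr <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
    planted <- split(names(tr$cluster_assignment),
                     unlist(tr$cluster_assignment))
    recovered <- split(vp_membership$contig_id, vp_membership$vp_id)
    report$recovered_partition <- same_partition(planted, recovered)
  }

  jsonlite::write_json(report, o("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(report)
}

# Planted feature ids -> clustered VP ids, via shared contig prefixes: a
# planted id is taken to name the VP containing the contig "<id>_c1".
translate_feature_ids <- function(ids, vp_membership) {
  vp_of <- stats::setNames(vp_membership$vp_id, vp_membership$contig_id)
  direct <- ids %in% vp_membership$vp_id
  mapped <- ifelse(direct, ids, unname(vp_of[paste0(ids, "_c1")]))
  unique(mapped[!is.na(mapped)])
}

same_partition <- function(a, b) {
  norm <- function(p) {
    s <- lapply(p, function(x) sort(unlist(x, use.names = FALSE)))
    s <- s[order(vapply(s, `[`, character(1), 1L))]
    unname(s)
  }
  identical(norm(a), norm(b))
}
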