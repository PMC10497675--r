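test_that("triage fixture covers every realizable criterion combination", {
  fix <- generate_triage_fixture(16, seed = 1)
  ann <- fix$annotations
  s0 <- ifelse(is.na(ann$vs_score), 0, ann$vs_score)
  combo <- paste(ann$viral_gene_count >= 1, s0 >= 0.95,
                 ann$hallmark_count >= 2,
                 ann$viral_gene_count == 0 & ann$host_gene_count == 0)
  # criteria 1 and 4 are mutually exclusive: 12 of 16 patterns exist
  expect_equal(length(unique(combo)), 12L)
  expect_equal(unname(classify_viral(ann)),
               unname(fix$truth$viral_labels))
  # single-criterion spot checks
  expect_true(fix$truth$viral_labels[[which(ann$viral_gene_count >= 1)[1]]])
  fails <- ann$viral_gene_count == 0 & ann$host_gene_count > 0 &
    s0 < 0.95 & ann$hallmark_count < 2
  expect_false(any(fix$truth$viral_labels[fails]))
  expect_error(generate_triage_fixture(0), "n_contigs")
})

test_that("ANI pair fixture: combinatorics, orientation, determinism", {
  assign <- setNames(rep(c("k1", "k2"), each = 3), sprintf("c%d", 1:6))
  pairs <- generate_ani_pairs(assign, 90, seed = 2)
  within <- pairs[assign[pairs$query_id] == assign[pairs$subject_id], ]
  expect_equal(nrow(within), 12L)          # 2 clusters x 3 choose 2 x 2
  expect_true(all(within$ani_pct >= 90))
  between <- pairs[assign[pairs$query_id] != assign[pairs$subject_id], ]
  expect_true(all(between$ani_pct < 90))
  expect_false(any(pairs$query_id == pairs$subject_id))
  # both orientations present with equal ANI
  key <- paste(pairs$query_id, pairs$subject_id)
  rev_key <- paste(pairs$subject_id, pairs$query_id)
  expect_true(all(rev_key %in% key))
  # singleton cluster: no within pairs for that contig
  lone <- generate_ani_pairs(setNames(c("k1", "k1", "k2"),
                                      c("a", "b", "z")), 90, seed = 1)
  wz <- lone[lone$query_id == "z" | lone$subject_id == "z", ]
  expect_true(all(wz$ani_pct < 90))
  # byte-identical rerun
  expect_identical(generate_ani_pairs(assign, 90, seed = 2), pairs)
  expect_error(generate_ani_pairs(assign, 0), "threshold")
})

test_that("spacer-hit fixture decoys each violate exactly one filter", {
  links <- data.frame(vp_id = sprintf("VP%d", 1:8),
                      mag_id = sprintf("m%d", 1:8))
  gen <- generate_spacer_hits(links, decoy_rate = 0.4, seed = 9)
  h <- gen$hits; dec <- gen$truth$is_decoy
  mm <- h$spacer_len - h$n_identical
  len_ok <- h$spacer_len >= 20 & h$spacer_len <= 30
  mm_ok <- mm <= 2
  expect_true(all(len_ok[!dec] & mm_ok[!dec]))
  expect_true(all(xor(len_ok[dec], mm_ok[dec])))
  expect_error(generate_spacer_hits(links, decoy_rate = 1), "decoy_rate")
  # empty link set returns an empty, well-formed table
  none <- generate_spacer_hits(links[0, ], decoy_rate = 0.5, seed = 1)
  expect_equal(nrow(none$hits), 0L)
})

test_that("CGM and OGTT fixtures obey their closed forms", {
  flat <- generate_cgm_trace(seed = 1, minutes = 1440, mean = 5, sd = 0)
  expect_equal(time_in_range(flat), 100)
  expect_equal(diff(flat$minute), rep(15, nrow(flat) - 1))
  expect_identical(generate_cgm_trace(seed = 3), generate_cgm_trace(seed = 3))
  expect_error(generate_cgm_trace(minutes = 0), "minutes")
  expect_error(generate_cgm_trace(sd = -1), "sd")
  const <- generate_ogtt_curve(seed = 1, baseline = 5, peak_delta = 0,
                               noise_sd = 0)
  expect_equal(ogtt_auc(const), 600)
  expect_equal(const$minute, c(0, 15, 30, 45, 60, 90, 120))
})

test_that("config and truth constructors validate their domains", {
  expect_error(scenario_config(days = c(0, 2, 2)), "increasing")
  expect_error(scenario_config(days = c(2, 4)), "day 0")
  expect_error(scenario_config(n_per_arm = 0), "positive")
  expect_error(scenario_config(n_vps = 10), "too small")
  expect_error(synthetic_truth("antagonistic", coupling_beta = 0.5), "sign")
  expect_error(synthetic_truth("null", coupling_beta = 0.1), "sign")
  expect_error(synthetic_truth(noise_sd = 0), "positive")
  expect_error(synthetic_truth(engraftment_fraction = 0.7,
                               novelty_rate = 0.5), "sum")
})

test_that("generate_community: determinism, counts, closure, planted truth", {
  cfg <- scenario_config(n_per_arm = 3, days = c(0, 2), n_vps = 40,
                         n_mags = 10, n_species = 5, seed = 21)
  tr <- synthetic_truth("protagonistic")
  a <- generate_community(cfg, tr, tables = TRUE)
  b <- generate_community(cfg, tr, tables = TRUE)
  expect_identical(a, b)
  # the fast path reproduces the same planted tables
  fast <- generate_community(cfg, tr, tables = FALSE)
  expect_identical(unclass(a$vp_counts), unclass(fast$vp_counts))
  # counts are non-negative integers; proportions close to 1
  expect_true(all(unclass(a$vp_counts) >= 0))
  expect_true(all(unclass(a$vp_counts) == round(unclass(a$vp_counts))))
  p <- as_proportions(a$vp_counts)
  cs <- colSums(p)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-9))
  # every contig has exactly one label and one cluster
  expect_setequal(names(a$truth$cluster_assignment),
                  a$vp_membership$contig_id)
  # novel VPs are absent at every day-0 sample
  nov <- grep("^VP_N", rownames(a$vp_counts), value = TRUE)
  d0 <- grep("_d00_VLP$", colnames(a$vp_counts), value = TRUE)
  expect_true(all(unclass(a$vp_counts)[nov, d0] == 0))
  # donor samples contain only the donor pool
  don <- grep("^D\\d_VLP$", colnames(a$vp_counts), value = TRUE)
  res <- grep("^VP_R", rownames(a$vp_counts), value = TRUE)
  expect_true(all(unclass(a$vp_counts)[res, don] == 0))
  expect_error(generate_community(cfg, list()), "synthetic_truth")
})

test_that("engraftment_fraction = 0 gives zero donor-shared abundance", {
  cfg <- scenario_config(n_per_arm = 3, days = c(0, 2), n_vps = 40,
                         n_mags = 10, n_species = 5, seed = 8)
  tr <- synthetic_truth("null", engraftment_fraction = 0,
                        novelty_rate = 0.1)
  com <- generate_community(cfg, tr, tables = FALSE)
  eng <- engraftment_table(com$vp_counts, com$meta)
  shared <- eng$donor_shared_pct[!is.na(eng$donor_shared_pct)]
  expect_true(all(shared == 0))
})
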