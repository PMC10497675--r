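test_that("donor_shared_fraction: definition and edge cases", {
  meta <- toy_meta("p1", c(0, 2))
  # VPs v1, v2 present in the donor; v3 absent
  tab <- tiny_table(cbind(c(5, 5, 10), c(2, 2, 6), c(8, 1, 0)), "rpkm",
                    features = c("v1", "v2", "v3"),
                    samples = c("p1_d0", "p1_d2", "D1_s"))
  expect_equal(donor_shared_fraction(tab, meta, "p1", 2), 100 * 4 / 10)
  # no shared VPs
  none <- tiny_table(cbind(c(5, 5, 10), c(2, 2, 6), c(0, 0, 0)), "rpkm",
                     features = c("v1", "v2", "v3"),
                     samples = c("p1_d0", "p1_d2", "D1_s"))
  expect_equal(donor_shared_fraction(none, meta, "p1", 2), 0)
  # everything on donor-present VPs
  all_on <- tiny_table(cbind(c(5, 5, 0), c(2, 2, 0), c(8, 1, 0)), "rpkm",
                       features = c("v1", "v2", "v3"),
                       samples = c("p1_d0", "p1_d2", "D1_s"))
  expect_equal(donor_shared_fraction(all_on, meta, "p1", 2), 100)
  # zero-total recipient sample
  zero <- tiny_table(cbind(c(5, 5, 0), c(0, 0, 0), c(8, 1, 0)), "rpkm",
                     features = c("v1", "v2", "v3"),
                     samples = c("p1_d0", "p1_d2", "D1_s"))
  expect_equal(donor_shared_fraction(zero, meta, "p1", 2), 0)
  # missing donor sample is an error
  meta_nodonor <- meta[meta$participant_id != "D1", ]
  expect_error(donor_shared_fraction(tab, meta_nodonor, "p1", 2),
               "donor")
})

test_that("novel_fraction: baseline-referenced novelty", {
  meta <- toy_meta("p1", c(0, 2, 28))
  tab <- tiny_table(cbind(c(5, 5, 0), c(2, 2, 6), c(5, 5, 0)), "rpkm",
                    features = c("v1", "v2", "v3"),
                    samples = c("p1_d0", "p1_d2", "p1_d28"))
  expect_equal(novel_fraction(tab, meta, "p1", 2), 100 * 6 / 10)
  expect_equal(novel_fraction(tab, meta, "p1", 28), 0)  # identical to day 0
  expect_equal(novel_fraction(tab, meta, "p1", 0), 0)
  all_new <- tiny_table(cbind(c(5, 0), c(0, 3)), "rpkm",
                        features = c("v1", "v3"),
                        samples = c("p1_d0", "p1_d2"))
  expect_equal(novel_fraction(all_new, meta, "p1", 2), 100)
  expect_error(novel_fraction(tab, meta[-1, ], "p1", 2), "samples at day")
})

test_that("interaction_points implements the species-mean definition", {
  meta <- toy_meta(c("p1"), c(0, 2))
  vp <- tiny_table(cbind(c(0.10, 0.90), c(0.20, 0.80), c(1, 0)),
                   "proportion", features = c("v1", "v2"),
                   samples = c("p1_d0", "p1_d2", "D1_s"))
  mag <- tiny_table(cbind(c(0.30, 0.70), c(0.10, 0.90)), "proportion",
                    features = c("m1", "m2"),
                    samples = c("p1_d0", "p1_d2"))
  links <- data.frame(vp_id = "v1", mag_id = "m1", evidence = "crispr",
                      species = "spA")
  pts <- interaction_points(vp, mag, links, meta, 0, 2)
  expect_equal(nrow(pts), 1L)
  expect_equal(pts$delta_vp, 0.10)
  expect_equal(pts$delta_mag, -0.20)
  # two VPs of one species average to zero
  links2 <- rbind(links, data.frame(vp_id = "v2", mag_id = "m1",
                                    evidence = "crispr", species = "spA"))
  vp2 <- tiny_table(cbind(c(0.10, 0.90), c(0.20, 0.80), c(1, 0)),
                    "proportion", features = c("v1", "v2"),
                    samples = c("p1_d0", "p1_d2", "D1_s"))
  pts2 <- interaction_points(vp2, mag, links2, meta, 0, 2)
  expect_equal(pts2$delta_vp, 0)
  # links with missing species are excluded
  links3 <- rbind(links, data.frame(vp_id = "v2", mag_id = "m2",
                                    evidence = "crispr",
                                    species = NA_character_))
  expect_equal(nrow(interaction_points(vp, mag, links3, meta, 0, 2)), 1L)
})

test_that("interaction_correlation: rank identities and validation", {
  pts <- data.frame(participant_id = "p1",
                    delta_vp = c(3, 2, 1, 0.5),
                    delta_mag = c(0.1, 0.4, 0.9, 1.3))
  out <- interaction_correlation(pts, c(p1 = "FFT"))
  expect_equal(out$rho, -1)
  expect_equal(out$n_points, 4L)
  # identical inputs for two groups give identical statistics
  pts2 <- rbind(pts, transform(pts, participant_id = "p2"))
  out2 <- interaction_correlation(pts2, c(p1 = "FFT", p2 = "placebo"))
  expect_equal(out2$rho[1], out2$rho[2])
  expect_equal(out2$p[1], out2$p[2])
  # constant deltas: rho undefined
  flat <- data.frame(participant_id = "p1", delta_vp = c(1, 1, 1),
                     delta_mag = c(1, 2, 3))
  expect_true(is.na(interaction_correlation(flat, c(p1 = "g"))$rho))
  expect_error(interaction_correlation(pts[1:2, ], c(p1 = "g")), "fewer")
})

test_that("Spearman p: exact enumeration agrees with cor.test for small n", {
  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(7); y <- rnorm(7)
    got <- phagedyn:::spearman_test(x, y)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                     exact = TRUE))
    expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 0.02)
  }
  # t-approximation path for larger n
  x <- rnorm(40); y <- x + rnorm(40)
  got <- phagedyn:::spearman_test(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman",
                                   exact = FALSE))
  expect_equal(got$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-6)
})

test_that("host_enrichment matches the exhaustive enumeration oracle", {
  # worked example: m = 5, n = 15, k = 4, q = 3
  ht <- data.frame(
    vp_id = sprintf("v%02d", 1:20),
    species = c(rep("spA", 5), rep("spB", 15)))
  da <- c("v01", "v02", "v03", "v06")        # 3 of spA, 1 of spB
  res <- host_enrichment(da, ht)
  ra <- res[res$species == "spA", ]
  expect_equal(c(ra$q, ra$m, ra$n, ra$k), c(3, 5, 15, 4))
  expect_equal(ra$p, 155 / 4845, tolerance = 1e-12)
  expect_equal(ra$p, oracle_hyper_upper(3, 5, 15, 4), tolerance = 1e-12)
  # random universes up to 20 hosted VPs, all tested species vs oracle
  set.seed(13)
  for (i in 1:20) {
    n_vp <- sample(6:20, 1)
    sp <- sample(sprintf("sp%d", 1:3), n_vp, TRUE)
    ht <- data.frame(vp_id = sprintf("v%02d", 1:n_vp), species = sp)
    da <- sample(ht$vp_id, sample(2:n_vp, 1))
    res <- host_enrichment(da, ht)
    for (j in seq_len(nrow(res)))
      expect_equal(res$p[j],
                   oracle_hyper_upper(res$q[j], res$m[j], res$n[j],
                                      res$k[j]),
                   tolerance = 1e-12)
    expect_true(all(res$p_adj >= res$p - 1e-12))
  }
})

test_that("host_enrichment edge cases: single species, untested species,
           unhosted DA VPs excluded from k", {
  one <- data.frame(vp_id = sprintf("v%d", 1:10), species = "spA")
  res <- host_enrichment(c("v1", "v2"), one)
  expect_equal(res$p, 1)
  # species without DA VPs are not tested
  ht <- data.frame(vp_id = sprintf("v%d", 1:6),
                   species = rep(c("spA", "spB"), each = 3))
  res <- host_enrichment(c("v1", "ghost"), ht)
  expect_equal(res$species, "spA")
  expect_equal(res$k, 1L)  # the unhosted "ghost" VP does not count
})

test_that("engraftment/novelty lie in [0, 100] on synthetic data", {
  cfg <- scenario_config(n_per_arm = 4, days = c(0, 2, 7), n_vps = 60,
                         n_mags = 20, n_species = 10, seed = 5)
  com <- generate_community(cfg, synthetic_truth("null"), tables = FALSE)
  eng <- engraftment_table(com$vp_counts, com$meta)
  expect_true(all(eng$novel_pct >= 0 & eng$novel_pct <= 100))
  shared <- eng$donor_shared_pct[!is.na(eng$donor_shared_pct)]
  expect_true(all(shared >= 0 & shared <= 100))
})
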