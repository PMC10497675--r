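test_that("breadth filter zeroes below-threshold records and is idempotent", {
  rec <- data.frame(contig_id = c("c1", "c2", "c3"),
                    sample_id = "s1",
                    read_count = c(500L, 500L, 7L),
                    fraction_covered = c(0.74, 0.75, 1))
  f1 <- apply_breadth_filter(rec)
  expect_equal(f1$read_count, c(0L, 500L, 7L))
  expect_identical(apply_breadth_filter(f1), f1)
  expect_equal(nrow(apply_breadth_filter(rec[0, ])), 0L)
  expect_error(apply_breadth_filter(rec, 1.5), "breadth_min")
})

test_that("breadth_from_depth inverts a depth-1-capped histogram", {
  h <- data.frame(contig_id = c("c1", "c1", "c2"), sample_id = "s1",
                  depth = c(0L, 1L, 1L), fraction = c(0.3, 0.7, 1))
  b <- breadth_from_depth(h)
  expect_equal(b$fraction_covered[b$contig_id == "c1"], 0.7)
  expect_equal(b$fraction_covered[b$contig_id == "c2"], 1)
})

test_that("rpkm_per_vp implements the summed-then-divided rule", {
  vm <- data.frame(vp_id = c("VP1", "VP1"), contig_id = c("c1", "c2"))
  lens <- c(c1 = 4000, c2 = 6000)
  rec <- data.frame(contig_id = "c1", sample_id = "s1", read_count = 40L,
                    fraction_covered = 1)
  tab <- rpkm_per_vp(rec, vm, lens, c(s1 = 1e6))
  expect_equal(unname(unclass(tab)["VP1", "s1"]), 4)  # 40 / (10 kb x 1 M)
  # single-contig arithmetic and library-size scaling identity
  vm1 <- data.frame(vp_id = "VP1", contig_id = "c1")
  r1 <- data.frame(contig_id = "c1", sample_id = "s1", read_count = 100L,
                   fraction_covered = 1)
  expect_equal(unname(unclass(rpkm_per_vp(r1, vm1, c(c1 = 10000),
                                          c(s1 = 1e6)))[1, 1]), 10)
  expect_equal(unname(unclass(rpkm_per_vp(r1, vm1, c(c1 = 10000),
                                          c(s1 = 2e6)))[1, 1]), 5)
  expect_error(rpkm_per_vp(r1, vm1, c(c1 = 10000), c(s1 = 0)), "positive")
  expect_error(rpkm_per_vp(r1, data.frame(vp_id = "VP1", contig_id = "cX"),
                           c(cX = 1000), c(s1 = 1e6)), "without a VP")
})

test_that("RPKM conserves read counts (random fixtures)", {
  for (seed in 1:5) {
    set.seed(seed)
    n_contig <- 30; n_samp <- 8
    vm <- data.frame(vp_id = sprintf("VP%d", sample(1:10, n_contig, TRUE)),
                     contig_id = sprintf("c%02d", 1:n_contig))
    lens <- setNames(sample(2000:50000, n_contig), vm$contig_id)
    libs <- setNames(round(runif(n_samp, 1e5, 1e6)),
                     sprintf("s%d", 1:n_samp))
    rec <- expand.grid(contig_id = vm$contig_id, sample_id = names(libs),
                       stringsAsFactors = FALSE)
    rec$read_count <- rpois(nrow(rec), 50)
    rec$fraction_covered <- runif(nrow(rec))
    rec <- apply_breadth_filter(rec)
    tab <- rpkm_per_vp(rec, vm, lens, libs)
    lenkb <- attr(tab, "feature_length") / 1e3
    back <- colSums(unclass(tab) * lenkb) * libs[colnames(tab)] / 1e6
    retained <- tapply(rec$read_count, rec$sample_id, sum)[colnames(tab)]
    expect_equal(unname(back), as.numeric(retained), tolerance = 1e-10)
  }
})

test_that("filter_low_abundance applies total and prevalence cuts", {
  # 10 samples; f1 fails total (99.9); f2 sits exactly on both boundaries;
  # f3 fails prevalence (never exceeds 20)
  m <- rbind(c(99.9, rep(0, 9)),
             c(21, rep(14.3334, 9)),
             c(rep(15, 10)))
  tab <- tiny_table(m, "rpkm")
  kept <- filter_low_abundance(tab)
  expect_equal(rownames(kept), "f2")
  expect_equal(nrow(filter_low_abundance(tiny_table(matrix(0, 2, 10),
                                                    "rpkm"))), 0L)
  expect_error(filter_low_abundance(tiny_table(m, "count")), "rpkm")
})

test_that("richness and Shannon match closed forms", {
  tab <- tiny_table(cbind(c(1, 1, 1, 1), c(5, 0, 0, 0), c(1, 1, 2, 0),
                          c(0, 0, 0, 0)), "rpkm")
  expect_equal(shannon(tab, "s1"), log(4))
  expect_equal(shannon(tab, "s2"), 0)
  expect_equal(shannon(tab, "s3"),
               -(0.25 * log(0.25) * 2 + 0.5 * log(0.5)))
  expect_equal(shannon(tab, "s4"), 0)
  expect_equal(richness(tab, "s1"), 4L)
  expect_equal(richness(tab, "s3"), 3L)
  expect_equal(richness(tab, "s4"), 0L)
  dt <- diversity_table(tab)
  expect_equal(dt$richness, c(4, 1, 3, 0))
})

test_that("clr transform has zero column sums, kills uniform rows, and is
           scale invariant on positive data", {
  tab <- tiny_table(cbind(c(3, 3, 3), c(1, 10, 100)), "rpkm")
  clr <- clr_transform(tab, pseudocount = 1e-12)
  expect_equal(unname(unclass(clr)[, "s1"]), rep(0, 3), tolerance = 1e-9)
  expect_lt(max(abs(colSums(clr))), 1e-9)
  scaled <- tiny_table(cbind(c(3, 3, 3), c(10, 100, 1000)), "rpkm")
  expect_equal(unclass(clr_transform(scaled, 1e-12))[, "s2"],
               unclass(clr)[, "s2"], tolerance = 1e-6)
  expect_error(clr_transform(tab, pseudocount = 0), "positive")
  # default pseudocount: half the minimum positive value
  withz <- tiny_table(cbind(c(0, 2, 4), c(1, 1, 1)), "rpkm")
  expect_equal(unclass(clr_transform(withz))[, 1],
               unclass(clr_transform(withz, 0.5))[, 1])
})

test_that("as_proportions closes each sample to 1", {
  tab <- tiny_table(cbind(c(2, 2, 4), c(0, 0, 0)), "count")
  p <- as_proportions(tab)
  expect_equal(unname(colSums(p)), c(1, 0))
  expect_equal(unname(unclass(p)[, 1]), c(0.25, 0.25, 0.5))
})
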