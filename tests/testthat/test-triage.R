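test_that("classify_viral matches the four-criteria truth table", {
  # enumerate every realizable field combination and compare against a
  # literal restatement of the rule
  grid <- expand.grid(viral = c(0L, 1L), host = c(0L, 2L),
                      score = c(0.949, 0.95, NA), hallmarks = c(1L, 2L),
                      stringsAsFactors = FALSE)
  ann <- data.frame(contig_id = sprintf("c%02d", seq_len(nrow(grid))),
                    viral_gene_count = grid$viral,
                    host_gene_count = grid$host,
                    vs_score = grid$score,
                    hallmark_count = grid$hallmarks)
  got <- classify_viral(ann)
  want <- with(grid, viral >= 1 |
                 (!is.na(score) & score >= 0.95) |
                 hallmarks >= 2 |
                 (viral == 0 & host == 0))
  expect_equal(unname(got), want)
})

test_that("classify_viral worked examples and input validation", {
  ann <- data.frame(
    contig_id = c("a", "b", "c"),
    viral_gene_count = c(1, 0, 0), host_gene_count = c(5, 0, 2),
    vs_score = c(0.2, 0.1, 0.949), hallmark_count = c(0, 0, 1))
  expect_equal(unname(classify_viral(ann)), c(TRUE, TRUE, FALSE))
  ann$viral_gene_count[1] <- -1
  expect_error(classify_viral(ann), "negative")
})

test_that("filter_min_length applies the 5 kb default", {
  ann <- data.frame(contig_id = c("a", "b", "c"),
                    length_bp = c(4999, 5000, 80000))
  expect_equal(filter_min_length(ann)$contig_id, c("b", "c"))
  expect_error(filter_min_length(data.frame(contig_id = "x", length_bp = 0)),
               "positive")
})

test_that("dedup_exact removes only fully-aligned 100% pairs", {
  contigs <- data.frame(contig_id = c("a", "b", "c"),
                        length_bp = c(8000, 8000, 9000))
  dup <- data.frame(query_id = c("a", "b"), subject_id = c("b", "a"),
                    ani_pct = 100, aligned_fraction = 1)
  expect_equal(dedup_exact(contigs, dup), c("a", "c"))  # ties: smallest id
  part <- dup; part$aligned_fraction <- 0.5
  expect_equal(dedup_exact(contigs, part), c("a", "b", "c"))
  expect_equal(dedup_exact(contigs, dup[0, ]), c("a", "b", "c"))
  # containment: shorter fully aligned into a longer contig is removed
  cont <- data.frame(query_id = "a", subject_id = "c", ani_pct = 100,
                     aligned_fraction = 1)
  expect_equal(dedup_exact(contigs, cont), c("b", "c"))
})

test_that("cluster_vps is greedy centroid, not single linkage", {
  contigs <- data.frame(contig_id = c("A", "B", "C"),
                        length_bp = c(30000, 20000, 10000))
  chain <- data.frame(query_id = c("A", "B"), subject_id = c("B", "C"),
                      ani_pct = c(96, 96))
  vp <- cluster_vps(contigs, chain, 95)
  parts <- split(vp$contig_id, vp$vp_id)
  expect_equal(unname(parts), list(c("A", "B"), "C"))
  expect_equal(vp$contig_id[vp$is_representative], c("A", "C"))
  # single-linkage flag merges the chain
  vs <- cluster_vps(contigs, chain, 95, method = "single")
  expect_equal(length(unique(vs$vp_id)), 1L)
  # mutually similar triple collapses to one VP with the longest as rep
  tri <- data.frame(query_id = c("A", "A", "B"),
                    subject_id = c("B", "C", "C"), ani_pct = 97)
  v1 <- cluster_vps(contigs, tri, 95)
  expect_equal(length(unique(v1$vp_id)), 1L)
  expect_equal(v1$contig_id[v1$is_representative], "A")
  # empty ANI table: all singletons
  v0 <- cluster_vps(contigs, tri[0, ], 95)
  expect_equal(length(unique(v0$vp_id)), 3L)
  expect_error(cluster_vps(contigs, tri, 0), "threshold")
  expect_error(cluster_vps(contigs,
                           data.frame(query_id = "A", subject_id = "Z",
                                      ani_pct = 99), 95), "unknown")
})

test_that("cluster_vps is invariant to input row order", {
  fix <- generate_triage_fixture(20, seed = 4)
  contigs <- fix$annotations[, c("contig_id", "length_bp")]
  assign <- setNames(rep(c("k1", "k2", "k3", "k4"), 5), contigs$contig_id)
  ani <- generate_ani_pairs(assign, 95, seed = 4)
  base <- cluster_vps(contigs, ani, 95)
  local_shuffle <- function(d, seed) d[sample(nrow(d)), , drop = FALSE]
  set.seed(99)
  shuffled <- cluster_vps(contigs[sample(nrow(contigs)), ],
                          ani[sample(nrow(ani)), ], 95)
  expect_equal(split(base$contig_id, base$vp_id),
               split(shuffled$contig_id, shuffled$vp_id))
})

test_that("planted well-separated partitions are recovered exactly", {
  for (seed in 1:5) {
    n <- 24
    ids <- sprintf("ctg%02d", seq_len(n))
    planted <- setNames(rep(sprintf("k%d", 1:6), each = 4), ids)
    set.seed(seed)
    contigs <- data.frame(contig_id = ids,
                          length_bp = sample(5000:50000, n))
    ani <- generate_ani_pairs(planted, 95, seed = seed)
    vp <- cluster_vps(contigs, ani, 95)
    got <- lapply(split(vp$contig_id, vp$vp_id), sort)
    want <- lapply(split(ids, planted), sort)
    expect_true(setequal(unname(got), unname(want)))
    # every member matches its representative at >= threshold
    sym <- tapply(ani$ani_pct,
                  paste(pmin(ani$query_id, ani$subject_id),
                        pmax(ani$query_id, ani$subject_id)), max)
    for (v in unique(vp$vp_id)) {
      mem <- vp$contig_id[vp$vp_id == v]
      rep_id <- vp$contig_id[vp$vp_id == v & vp$is_representative]
      others <- setdiff(mem, rep_id)
      if (length(others) > 0)
        expect_true(all(sym[paste(pmin(others, rep_id),
                                  pmax(others, rep_id))] >= 95))
    }
  }
})

test_that("vp_summary aggregates members and lengths", {
  contigs <- data.frame(contig_id = c("A", "B", "C"),
                        length_bp = c(30000, 20000, 10000))
  ani <- data.frame(query_id = "A", subject_id = "B", ani_pct = 99)
  s <- vp_summary(cluster_vps(contigs, ani, 95))
  expect_equal(s$total_length_bp, c(50000, 10000))
  expect_equal(s$representative_id, c("A", "C"))
})
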