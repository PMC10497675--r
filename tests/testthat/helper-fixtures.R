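# Small fixture builders shared across test files.

# abundance_table from a plain matrix-like spec
tiny_table <- function(values, kind = "rpkm", features = NULL,
                       samples = NULL, ...) {
  m <- as.matrix(values)
  rownames(m) <- features %||% sprintf("f%d", seq_len(nrow(m)))
  colnames(m) <- samples %||% sprintf("s%d", seq_len(ncol(m)))
  abundance_table(m, kind, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent Fisher oracle: explicit choose() enumeration of all tables
# with the observed margins, sum-of-small-probabilities two-sided rule
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  sup <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- vapply(sup, function(x)
    choose(c1, x) * choose(n - c1, r1 - x), numeric(1)) / choose(n, r1)
  sum(pr[pr <= pr[sup == a] * (1 + 1e-7)])
}

# independent hypergeometric upper-tail oracle by closed-form enumeration
oracle_hyper_upper <- function(q, m, n, k) {
  xs <- q:min(m, k)
  sum(vapply(xs, function(x)
    choose(m, x) * choose(n, k - x), numeric(1))) / choose(m + n, k)
}

# pseudo-F by the direct pairwise partition (independent of the package's
# Gower-projection implementation)
oracle_pseudo_f <- function(d, groups) {
  d <- as.matrix(d)^2
  n <- nrow(d); groups <- as.factor(groups); a <- nlevels(groups)
  ss_total <- sum(d[upper.tri(d)]) / n
  ss_within <- sum(vapply(levels(groups), function(g) {
    idx <- which(groups == g)
    sum(d[idx, idx][upper.tri(d[idx, idx])]) / length(idx)
  }, numeric(1)))
  ss_between <- ss_total - ss_within
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# all distinct orderings of a label vector (for exact permutation nulls)
all_label_permutations <- function(labels) {
  n <- length(labels)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  unique(lapply(perms(seq_len(n)), function(p) labels[p]))
}

# metadata + proportion tables for hand-built dynamics cases
toy_meta <- function(participants, days, arm = "FFT", donor = "D1") {
  rbind(
    do.call(rbind, lapply(participants, function(p) data.frame(
      sample_id = sprintf("%s_d%d", p, days), participant_id = p,
      arm = arm, day = days, donor_id = donor, fraction = "VLP",
      stringsAsFactors = FALSE))),
    data.frame(sample_id = "D1_s", participant_id = "D1", arm = "donor",
               day = NA_integer_, donor_id = NA_character_,
               fraction = "VLP", stringsAsFactors = FALSE))
}
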