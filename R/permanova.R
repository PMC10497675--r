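#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Pseudo-F by the squared-distance partition: with N samples in `a` groups,
#' `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` the analogous sum over
#' within-group pairs divided by group size, `SS_between = SS_total -
#' SS_within`, and `F = (SS_between/(a-1)) / (SS_within/(N-a))`. The
#' p-value is `(1 + #{F_perm >= F_obs}) / (1 + n_perm)` over random label
#' permutations, deterministic for a given seed. With `covariates`, a
#' sequential two-term partition is used (covariates first, group last) on
#' the Gower-centred inner-product matrix; this approximates the reference
#' sequential-SS implementation.
#'
#' @param dist a `dist` or a square symmetric matrix with zero diagonal.
#' @param groups group labels, one per sample; at least 2 groups with at
#'   least 2 members each.
#' @param covariates optional data.frame of covariates (one row per sample)
#'   partialled out before the group term.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return list with `pseudo_F`, `p`, `df`, `ss` (between/within/total) and
#'   `n_perm`, of class `phagedyn_permanova`.
#' @export
permanova <- function(dist, groups, covariates = NULL, n_perm = 1000,
                      seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (ncol(d) != n) stop("distance matrix must be square", call. = FALSE)
  if (max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(d)) > 1e-8))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  groups <- as.factor(groups)
  if (length(groups) != n)
    stop("groups length must match the number of samples", call. = FALSE)
  if (nlevels(droplevels(groups)) < 2L || any(table(groups) < 2L))
    stop("need >= 2 groups with >= 2 members each", call. = FALSE)
  groups <- droplevels(groups)
  a <- nlevels(groups)

  # Gower-centred inner products: tr(H G) partitions sums of squares
  d2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * J %*% d2 %*% J
  hat <- function(X) {
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  Xg <- stats::model.matrix(~groups)
  if (is.null(covariates)) {
    H0 <- matrix(1 / n, n, n)           # intercept only
    Hf <- hat(Xg)
    df1 <- a - 1L
    df2 <- n - a
  } else {
    if (nrow(covariates) != n)
      stop("covariates must have one row per sample", call. = FALSE)
    Xc <- stats::model.matrix(~., data = covariates)
    Xf <- cbind(Xc, Xg[, -1L, drop = FALSE])
    H0 <- hat(Xc)
    Hf <- hat(Xf)
    df1 <- a - 1L
    df2 <- n - as.integer(round(sum(diag(Hf))))
    if (df2 < 1L) stop("no residual degrees of freedom", call. = FALSE)
  }
  fstat <- function(Gp) {
    ss_g <- sum(Hf * Gp) - sum(H0 * Gp)
    ss_r <- sum(diag(Gp)) - sum(Hf * Gp)
    (ss_g / df1) / (ss_r / df2)
  }
  f_obs <- fstat(G)
  exceed <- local_seed(seed, {
    sum(vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      fstat(G[p, p])
    }, numeric(1)) >= f_obs - 1e-12)
  })
  ss_total <- sum(diag(G))
  ss_between <- sum(Hf * G) - sum(H0 * G)
  out <- list(pseudo_F = f_obs,
              p = (1 + exceed) / (1 + n_perm),
              df = c(between = df1, within = df2),
              ss = c(between = ss_between,
                     within = ss_total - sum(Hf * G),
                     total = ss_total),
              n_perm = n_perm)
  class(out) <- "phagedyn_permanova"
  out
}

#' @export
print.phagedyn_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g (%d permutations)\n",
              x$pseudo_F, x$df[["between"]], x$df[["within"]], x$p, x$n_perm))
  invisible(x)
}
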