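# Cohort statistics: PERMANOVA with Monte-Carlo permutations, per-axis
# variance partitioning, exact paired Wilcoxon signed-rank, classical MDS
# and 1D kernel densities, and a Shapiro-Wilk gate.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Within-group sum of squares from the squared-distance matrix for a set of
# 0/1 membership columns Z (one column per permutation).
ssw_from_indicators <- function(D2, Z, n_a, n_b) {
  ssa <- colSums((D2 %*% Z) * Z) / (2 * n_a)
  Zb <- 1 - Z
  ssb <- colSums((D2 %*% Zb) * Zb) / (2 * n_b)
  ssa + ssb
}

#' Two-group PERMANOVA on Euclidean coordinates
#'
#' Pseudo-F = (SS_between / (g - 1)) / (SS_within / (n - g)) with g = 2,
#' computed from the Euclidean distance matrix of the pooled rows (raw mm
#' coordinates, no standardization). The permutation p-value shuffles group
#' labels `n_perm` times and includes the observed statistic in numerator
#' and denominator: p = (1 + #\{F_perm >= F_obs\}) / (1 + n_perm). With
#' `exhaustive = TRUE` every distinct label assignment is enumerated instead
#' and p is the exact fraction of assignments with F >= F_obs.
#'
#' @param group_A,group_B coordinate matrices (rows = observations, same
#'   number of columns; each group needs >= 2 rows).
#' @param n_perm number of Monte-Carlo permutations (default 999).
#' @param seed optional integer seed for the permutations (restores the
#'   caller's RNG state).
#' @param exhaustive enumerate all label assignments (only for small n).
#' @return object of class `permanova_result`: `pseudo_F`, `p_value`,
#'   `n_permutations`, `seed`, `ss_between`, `ss_within`.
#' @export
permanova <- function(group_A, group_B, n_perm = 999L, seed = NULL,
                      exhaustive = FALSE) {
  A <- as.matrix(group_A); B <- as.matrix(group_B)
  if (ncol(A) != ncol(B)) stop("groups must share dimensionality")
  if (nrow(A) < 2L || nrow(B) < 2L) {
    stop("each group needs at least 2 rows (within-group SS undefined)")
  }
  X <- rbind(A, B)
  n_a <- nrow(A); n_b <- nrow(B); n <- n_a + n_b
  D2 <- as.matrix(stats::dist(X))^2
  ss_total <- sum(D2[upper.tri(D2)]) / n
  z_obs <- matrix(c(rep(1, n_a), rep(0, n_b)), ncol = 1L)
  ssw_obs <- ssw_from_indicators(D2, z_obs, n_a, n_b)
  ssb_obs <- ss_total - ssw_obs
  f_obs <- ssb_obs / (ssw_obs / (n - 2))

  f_of_ssw <- function(ssw) (ss_total - ssw) / (ssw / (n - 2))
  if (exhaustive) {
    combos <- utils::combn(n, n_a)
    Z <- matrix(0, n, ncol(combos))
    Z[cbind(as.vector(combos),
            rep(seq_len(ncol(combos)), each = n_a))] <- 1
    f_perm <- f_of_ssw(ssw_from_indicators(D2, Z, n_a, n_b))
    p <- mean(f_perm >= f_obs - 1e-12)
    n_used <- ncol(combos)
  } else {
    Z <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        z <- numeric(n); z[sample.int(n, n_a)] <- 1; z
      }, numeric(n))
    })
    f_perm <- f_of_ssw(ssw_from_indicators(D2, Z, n_a, n_b))
    p <- (1 + sum(f_perm >= f_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_F = unname(f_obs), p_value = unname(p),
                 n_permutations = n_used, seed = seed,
                 ss_between = unname(ssb_obs), ss_within = unname(ssw_obs)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat("PERMANOVA: pseudo-F =", format(signif(x$pseudo_F, 4)),
      ", p =", format(signif(x$p_value, 3)),
      "(", x$n_permutations, "permutations )\n")
  invisible(x)
}

#' Per-axis share of the between-group separation
#'
#' Fraction of the squared mean difference carried by each coordinate axis:
#' `(delta_axis)^2 / sum_axes (delta_axis)^2` with
#' `delta = mean_B - mean_A`. For equal group sizes this equals each axis'
#' share of the between-group sum of squares.
#'
#' @param mean_A,mean_B group mean coordinates (length-3, mm).
#' @return named fractions `c(X = , Y = , Z = )` summing to 1.
#' @export
axis_contribution <- function(mean_A, mean_B) {
  d <- drop(as_points(mean_B)) - drop(as_points(mean_A))
  s2 <- d^2
  tot <- sum(s2)
  if (tot < 1e-15) stop("identical group means: axis fractions undefined")
  stats::setNames(s2 / tot, c("X", "Y", "Z"))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired differences. Zeros are dropped
#' before ranking; ties receive midranks. For n <= 25 retained differences
#' the null distribution of W (sum of positive ranks) is exact, built by
#' convolution over the 2^n sign assignments of the observed (mid)ranks;
#' above that a normal approximation with continuity and tie corrections is
#' used.
#'
#' @param paired_diffs numeric vector of within-pair differences.
#' @param exact_max largest n solved exactly (default 25).
#' @return list: `statistic` (W), `p_value` (two-sided), `n` (nonzero
#'   pairs), `method`.
#' @export
wilcoxon_signed_rank <- function(paired_diffs, exact_max = 25L) {
  d <- as.numeric(paired_diffs)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_max) {
    r2 <- as.integer(round(2 * r))   # midranks are halves; double to integers
    counts <- 1
    for (rr in r2) {
      grown <- c(counts, numeric(rr))
      grown[(rr + 1L):(rr + length(counts))] <-
        grown[(rr + 1L):(rr + length(counts))] + counts
      counts <- grown
    }
    total <- 2^n
    w2 <- round(2 * W)
    sums <- seq_along(counts) - 1L
    p_ge <- sum(counts[sums >= w2 - 1e-9]) / total
    p_le <- sum(counts[sums <= w2 + 1e-9]) / total
    p <- min(1, 2 * min(p_ge, p_le))
    method <- "exact (sign-assignment enumeration)"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (continuity + tie corrected)"
  }
  list(statistic = W, p_value = p, n = n, method = method)
}

#' Classical multidimensional scaling
#'
#' Classical (Torgerson) MDS of the Euclidean distances between rows:
#' double-centered squared distances, top eigenvectors scaled by the square
#' root of their eigenvalues. When `dims` reaches the intrinsic dimension
#' the embedded distances reproduce the originals exactly (up to rotation
#' and reflection).
#'
#' @param rows coordinate matrix (>= 3 rows, and more rows than `dims`).
#' @param dims embedding dimension (default 2).
#' @return n x dims matrix of embedded coordinates.
#' @export
mds_embedding <- function(rows, dims = 2L) {
  X <- as.matrix(rows)
  if (nrow(X) < 3L) stop("need at least 3 rows")
  if (nrow(X) < dims + 1L) stop("need more rows than embedding dimensions")
  out <- stats::cmdscale(stats::dist(X), k = dims)
  if (ncol(out) < dims) {   # rank-deficient cloud: pad zero coordinates
    out <- cbind(out, matrix(0, nrow(out), dims - ncol(out)))
  }
  out
}

#' Gaussian kernel density estimate in 1D
#'
#' @param values numeric sample (>= 2 values, nonzero spread).
#' @param bandwidth `"silverman"` (rule of thumb) or a numeric bandwidth in
#'   the data units.
#' @param n grid size.
#' @return list with `x`, `y` (density samples) and `bw`.
#' @export
kde_1d <- function(values, bandwidth = "silverman", n = 512L) {
  v <- as.numeric(values)
  if (length(v) < 2L) stop("need at least 2 values")
  if (identical(bandwidth, "silverman")) {
    if (stats::sd(v) < 1e-12) stop("zero-variance input: bandwidth undefined")
    bw <- stats::bw.nrd0(v)
  } else {
    bw <- as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
  }
  den <- stats::density(v, bw = bw, n = n, kernel = "gaussian")
  list(x = den$x, y = den$y, bw = bw)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper over the standard Shapiro-Wilk routine, used only to gate
#' how results are reported (nonparametric tests are used throughout
#' regardless).
#'
#' @param values numeric sample with 3 <= n <= 5000 and nonzero spread.
#' @return list with `W` and `p_value`.
#' @export
normality_check <- function(values) {
  v <- as.numeric(values)
  if (length(v) < 3L || length(v) > 5000L) {
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  }
  if (stats::sd(v) < 1e-12) stop("degenerate (constant) input")
  res <- stats::shapiro.test(v)
  list(W = unname(res$statistic), p_value = unname(res$p.value))
}
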