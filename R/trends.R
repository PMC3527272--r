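#' Moving-average trend of SLR against a covariate
#'
#' Genes are sorted by the covariate (ties broken by `ids`, lexicographic),
#' and each run of `window` consecutive genes contributes one curve point
#' (mean covariate, mean response). Windows are trailing runs of exactly
#' `window` genes with step 1 and no edge padding, giving
#' `n - window + 1` points. The result is invariant to the input order.
#'
#' @param x covariate per gene (finite).
#' @param y response (typically SLR) per gene.
#' @param window window size in genes (200 in the genome-wide analyses).
#' @param ids optional gene ids used for deterministic tie-breaking.
#' @return object of class `trend_curve`: `x_points`, `y_points`, `window`,
#'   `n_windows`.
#' @export
moving_average_trend <- function(x, y, window = 200L, ids = NULL) {
  stopifnot(length(x) == length(y), all(is.finite(x)))
  n <- length(x)
  if (n < window)
    stop("n (", n, ") < window (", window, "); use a smaller window")
  if (is.null(ids)) ids <- sprintf("g%09d", seq_len(n))
  ord <- order(x, ids)
  xs <- x[ord]; ys <- y[ord]
  w <- as.integer(window)
  cx <- cumsum(xs); cy <- cumsum(ys)
  xp <- (cx[w:n] - c(0, cx)[(w:n) - w + 1L]) / w
  yp <- (cy[w:n] - c(0, cy)[(w:n) - w + 1L]) / w
  structure(list(x_points = xp, y_points = yp, window = w,
                 n_windows = n - w + 1L),
            class = "trend_curve")
}

#' @export
print.trend_curve <- function(x, ...) {
  cat(sprintf("<trend_curve> window %d, %d points, y range [%.3g, %.3g]\n",
              x$window, x$n_windows, min(x$y_points), max(x$y_points)))
  invisible(x)
}

#' Fraction of non-increasing steps along a trend curve
#'
#' Monotonicity is evaluated across abutting windows (stride = `window` by
#' default), i.e. between curve points whose gene sets do not overlap;
#' consecutive step-1 sliding windows share all but one gene, so their
#' differences are dominated by measurement noise and carry no information
#' about the trend.
#'
#' @param curve a [moving_average_trend()] result.
#' @param stride spacing (in genes) between compared curve points.
#' @return fraction of compared adjacent pairs with non-increasing y.
#' @export
trend_monotonicity <- function(curve, stride = curve$window) {
  idx <- seq(1L, curve$n_windows, by = stride)
  yp <- curve$y_points[idx]
  if (length(yp) < 2L) return(NA_real_)
  mean(diff(yp) <= 0)
}

#' Pearson correlation with a permutation p-value
#'
#' Two-sided permutation test of the sample Pearson correlation: `y` is
#' permuted `n_perm` times under the given seed and
#' `p = (1 + #{|r_perm| >= |r|}) / (n_perm + 1)` (add-one estimator).
#' With `exact = TRUE` all `n!` permutations are enumerated instead and
#' `p = #{|r_perm| >= |r|} / n!` (the identity permutation included).
#'
#' @param x,y numeric vectors with non-zero variance, length >= 3.
#' @param n_perm number of random permutations.
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all permutations (only feasible for small n).
#' @return list with `r` and `p`.
#' @export
pearson_with_permutation <- function(x, y, n_perm = 10000L, seed = 1L,
                                     exact = FALSE) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: Pearson correlation undefined")
  r <- stats::cor(x, y)
  if (exact) {
    perms <- all_permutations(length(y))
    rp <- apply(perms, 1L, function(p) stats::cor(x, y[p]))
    return(list(r = r, p = mean(abs(rp) >= abs(r) - 1e-12)))
  }
  with_sim_seed(seed, 0L, {
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (abs(stats::cor(x, sample(y))) >= abs(r) - 1e-12) hits <- hits + 1L
    }
  })
  list(r = r, p = (1 + hits) / (n_perm + 1))
}

# All permutations of 1..n as a (n! x n) matrix; recursive construction.
all_permutations <- function(n) {
  if (n > 8L) stop("exact permutation enumeration limited to n <= 8")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Wilcoxon/Mann-Whitney rank-sum comparison of two groups
#'
#' Two-sided rank-sum test with midrank handling of ties. For combined
#' n <= 12 the permutation distribution of the rank sum over the observed
#' pooled values is enumerated exhaustively (exact even under ties);
#' otherwise the normal approximation with tie correction and a 0.5
#' continuity correction is used.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @param method "auto" switches from exact to the normal approximation
#'   above combined n = 12; "exact"/"normal" force one branch.
#' @return list: `U` (Mann-Whitney U for group A), `p` (two-sided), and
#'   `method` ("exact" or "normal").
#' @export
rank_sum_compare <- function(group_a, group_b,
                             method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(group_a) || !length(group_b)) stop("empty group")
  na <- length(group_a); nb <- length(group_b)
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)                       # midranks
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (method == "exact" || (method == "auto" && na + nb <= 12L)) {
    combos <- utils::combn(na + nb, na)
    rs <- colSums(matrix(rk[combos], nrow = na))
    us <- rs - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    return(list(U = u, p = p, method = "exact"))
  }
  nties <- table(rk)
  n <- na + nb
  sigma2 <- (na * nb / 12) *
    ((n + 1) - sum(nties^3 - nties) / (n * (n - 1)))
  z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = u, p = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       method = "normal")
}

#' Abundance-quartile-stratified moving-average trends
#'
#' Genes are split into quartiles of decreasing `abundance` (quartile 1 =
#' highest abundance; boundary ties go to the lower quartile index), and
#' within each quartile the moving average of `y` against `x` is computed.
#' Used to show that the plasticity association with topoisomerase
#' dependency is not an expression-level artifact.
#'
#' @param abundance stratifying covariate (wild-type mRNA abundance).
#' @param x within-stratum covariate (e.g. SLR).
#' @param y within-stratum response (e.g. plasticity).
#' @param window moving-average window.
#' @param ids optional gene ids for tie-breaking.
#' @return named list of four [moving_average_trend()] curves
#'   (`quartile_1` .. `quartile_4`).
#' @export
quartile_stratified_trend <- function(abundance, x, y, window = 200L,
                                      ids = NULL) {
  n <- length(abundance)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 4L * window)
    stop("need at least 4 * window genes for quartile stratification")
  if (is.null(ids)) ids <- sprintf("g%09d", seq_len(n))
  # rank by decreasing abundance, stable in ids: quartile 1 = highest
  ord <- order(-abundance, ids)
  q <- integer(n)
  bounds <- round(seq_len(4L) * n / 4)
  q[ord] <- rep(1:4, times = diff(c(0L, bounds)))
  out <- lapply(1:4, function(k) {
    sel <- q == k
    if (sum(sel) < window)
      stop("quartile ", k, " smaller than window; use a smaller window")
    moving_average_trend(x[sel], y[sel], window = window, ids = ids[sel])
  })
  names(out) <- paste0("quartile_", 1:4)
  out
}
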