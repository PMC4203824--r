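# Pairwise between-site decomposition, geographic/environmental distance,
# Mantel and partial Mantel permutation tests, distance-binned summaries.

.EARTH_RADIUS_KM <- 6371.0088  # IUGG mean Earth radius

#' Great-circle distance matrix
#'
#' Haversine distance between all site pairs, in kilometres, on a sphere of
#' radius 6371.0088 km.
#'
#' @param coords a [site_coordinates()] table.
#' @return symmetric site x site matrix (km) with attribute
#'   `kind = "geographic_km"`.
#' @export
great_circle_distance <- function(coords) {
  stopifnot(inherits(coords, "site_coordinates"))
  lat <- coords$lat * pi / 180
  lon <- coords$lon * pi / 180
  n <- nrow(coords)
  d <- matrix(0, n, n, dimnames = list(coords$site, coords$site))
  for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
    a <- sin((lat[k] - lat[j]) / 2)^2 +
      cos(lat[j]) * cos(lat[k]) * sin((lon[k] - lon[j]) / 2)^2
    d[j, k] <- d[k, j] <- 2 * .EARTH_RADIUS_KM * asin(min(1, sqrt(a)))
  }
  attr(d, "kind") <- "geographic_km"
  d
}

#' Environmental distance matrix
#'
#' Euclidean distance on scaled environmental variables (log transform of
#' flagged variables, then z-score; see [scale_environment()]).
#'
#' @param env an [environment_table()].
#' @param variables variables to include (default all).
#' @return symmetric site x site matrix with attribute
#'   `kind = "environmental"`.
#' @export
environmental_distance <- function(env, variables = NULL) {
  z <- scale_environment(env, variables)
  d <- as.matrix(stats::dist(z))
  attr(d, "kind") <- "environmental"
  d
}

#' Pairwise sum-of-squares decomposition of CWM dissimilarity
#'
#' For each site pair (j, k): total trait dissimilarity
#' \eqn{d_{total} = (total_j - total_k)^2}, turnover component
#' \eqn{d_{turnover} = (inter_j - inter_k)^2}, ITV component
#' \eqn{d_{intra} = (intra_j - intra_k)^2}, covariation remainder
#' \eqn{d_{cov} = d_{total} - d_{turnover} - d_{intra}
#'  = 2\,\Delta inter\,\Delta intra}, and the relative-importance log-ratio
#' \eqn{\ln(d_{turnover}/d_{intra})} (positive when turnover dominates).
#' Exact zero components give \eqn{\pm\infty} log-ratios; no epsilon is
#' added, and downstream correlation functions drop non-finite pairs.
#'
#' @param triple a [compute_cwms()] result.
#' @param trait which trait (required only when several are present).
#' @return list of class `pairwise_decomposition` with symmetric matrices
#'   `d_total`, `d_turnover`, `d_intra`, `d_cov`, `log_ratio` and the site
#'   ids used.
#' @export
pairwise_decomposition <- function(triple, trait = NULL) {
  tt <- .one_trait(triple, trait)
  if (nrow(tt) < 2L) stop("pairwise decomposition requires at least 2 sites")
  dimn <- list(tt$site, tt$site)
  sq <- function(x) outer(x, x, "-")^2
  d_turnover <- sq(tt$cwm_inter)
  d_intra <- sq(tt$cwm_intra)
  d_total <- sq(tt$cwm_total)
  d_cov <- d_total - d_turnover - d_intra
  log_ratio <- log(d_turnover) - log(d_intra)
  diag(log_ratio) <- NA_real_
  dimnames(d_total) <- dimnames(d_turnover) <- dimnames(d_intra) <-
    dimnames(d_cov) <- dimnames(log_ratio) <- dimn
  n_inf <- sum(!is.finite(log_ratio[lower.tri(log_ratio)]))
  if (n_inf)
    message(n_inf,
            " pair(s) with a zero component; log-ratio set to +/-Inf")
  structure(list(sites = tt$site, trait = tt$trait[1], d_total = d_total,
                 d_turnover = d_turnover, d_intra = d_intra, d_cov = d_cov,
                 log_ratio = log_ratio, n_nonfinite = n_inf),
            class = "pairwise_decomposition")
}

.lower <- function(m) m[lower.tri(m)]

.check_square <- function(A, B) {
  if (!is.matrix(A) || nrow(A) != ncol(A))
    stop("distance matrices must be square")
  if (!all(dim(A) == dim(B)))
    stop("distance matrix dimensions do not match")
}

#' Mantel permutation test
#'
#' Pearson correlation of the lower triangles of two distance matrices; the
#' null distribution is built by simultaneous row/column permutation of `B`.
#' p = (number of permuted statistics at least as extreme as the observed,
#' plus one) / (n_permutations + 1).  Non-finite entries (e.g. infinite
#' log-ratios) are dropped pairwise with a message.
#'
#' @param A,B symmetric matrices with matching site order.
#' @param n_permutations number of permutations (>= 99; default 9999).
#' @param seed optional integer seed for reproducible permutations.
#' @param tail `"two"` (default), `"greater"` (positive r), or `"less"`.
#' @return list of class `mantel_result`: `r`, `p`, `n_permutations`,
#'   `tail`, `partial` flag, `n_pairs` used.
#' @export
mantel_test <- function(A, B, n_permutations = 9999, seed = NULL,
                        tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  .check_square(A, B)
  if (n_permutations < 99) stop("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(A)
  lt <- lower.tri(A)
  a <- A[lt]
  keep_a <- is.finite(a)
  r_obs <- .mantel_r(a, B[lt], keep_a)
  perm <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(n)
    perm[i] <- .mantel_r(a, B[idx, idx][lt], keep_a)
  }
  p <- .perm_p(r_obs, perm, tail)
  structure(list(r = r_obs, p = p, n_permutations = n_permutations,
                 tail = tail, partial = FALSE,
                 n_pairs = sum(keep_a & is.finite(B[lt]))),
            class = "mantel_result")
}

.mantel_r <- function(a, b, keep_a) {
  keep <- keep_a & is.finite(b)
  stats::cor(a[keep], b[keep])
}

.perm_p <- function(obs, perm, tail) {
  switch(tail,
         two = (sum(abs(perm) >= abs(obs)) + 1) / (length(perm) + 1),
         greater = (sum(perm >= obs) + 1) / (length(perm) + 1),
         less = (sum(perm <= obs) + 1) / (length(perm) + 1))
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("%sMantel test (%s-tailed): r = %.4f, p = %.4g (%d permutations, %d pairs)\n",
              if (x$partial) "Partial " else "", x$tail, x$r, x$p,
              x$n_permutations, x$n_pairs))
  invisible(x)
}

#' Partial Mantel permutation test
#'
#' Correlation between `A` and `B` controlling for `C`: both lower
#' triangles are residualized on `C` by OLS, the residuals correlated, and
#' the null built by simultaneous row/column permutation of the matrix of
#' `B ~ C` residuals (residual-permutation method).
#'
#' @inheritParams mantel_test
#' @param C the controlled distance matrix.
#' @return a `mantel_result` with `partial = TRUE`.
#' @export
partial_mantel_test <- function(A, B, C, n_permutations = 9999, seed = NULL,
                                tail = c("two", "greater", "less")) {
  tail <- match.arg(tail)
  .check_square(A, B); .check_square(A, C)
  if (n_permutations < 99) stop("use at least 99 permutations")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(A)
  lt <- lower.tri(A)
  a <- A[lt]; b <- B[lt]; cc <- C[lt]
  keep <- is.finite(a) & is.finite(b) & is.finite(cc)
  res_a <- stats::residuals(stats::lm(a[keep] ~ cc[keep]))
  res_b <- stats::residuals(stats::lm(b[keep] ~ cc[keep]))
  if (stats::sd(res_a) <= 1e-10 * max(stats::sd(a[keep]), 1e-300) ||
      stats::sd(res_b) <= 1e-10 * max(stats::sd(b[keep]), 1e-300))
    stop("zero residual variance after controlling; partial r undefined")
  r_obs <- stats::cor(res_a, res_b)
  # residuals of B~C arranged back into a symmetric matrix, then permuted
  R <- matrix(0, n, n)
  full_res_b <- rep(NA_real_, length(b))
  full_res_b[keep] <- res_b
  R[lt] <- full_res_b
  R <- R + t(R)
  diag(R) <- NA_real_
  perm <- numeric(n_permutations)
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(n)
    rb <- R[idx, idx][lt]
    ok <- keep & is.finite(rb)
    perm[i] <- stats::cor(res_a[ok[keep]], rb[ok])
  }
  p <- .perm_p(r_obs, perm, tail)
  structure(list(r = r_obs, p = p, n_permutations = n_permutations,
                 tail = tail, partial = TRUE, n_pairs = sum(keep)),
            class = "mantel_result")
}

#' Equal-count distance bins with bootstrap confidence intervals
#'
#' Sorts site pairs by distance (index order breaking ties), splits them
#' into `n_bins` equal-count bins -- when the pair count is not divisible,
#' the first (nearest-distance) bins receive the extra pairs, so 231 pairs
#' in 4 bins give sizes 58/58/58/57 -- and returns the per-bin mean of
#' `values` with a percentile bootstrap confidence interval.  Non-finite
#' values are dropped with a message.
#'
#' @param values symmetric matrix (or pair vector matching the lower
#'   triangle of `dist`) of per-pair values, e.g. a component of
#'   [pairwise_decomposition()].
#' @param dist symmetric distance matrix.
#' @param n_bins number of bins (>= 2; default 4).
#' @param n_bootstrap bootstrap replicates for the CI of the mean.
#' @param seed optional integer seed.
#' @param conf confidence level (default 0.95).
#' @return data.frame: `bin`, `n`, `dist_min`, `dist_max`, `mean`, `lower`,
#'   `upper`.
#' @export
distance_bin_summary <- function(values, dist, n_bins = 4,
                                 n_bootstrap = 1000, seed = NULL,
                                 conf = 0.95) {
  if (n_bins < 2) stop("need at least 2 bins")
  d <- if (is.matrix(dist)) .lower(dist) else as.numeric(dist)
  v <- if (is.matrix(values)) .lower(values) else as.numeric(values)
  if (length(v) != length(d)) stop("values and distances differ in length")
  if (length(d) < n_bins) stop("fewer pairs than bins")
  if (!is.null(seed)) set.seed(seed)
  n_bins <- as.integer(n_bins)
  ord <- order(d)  # stable: ties broken by index
  sizes <- rep(length(d) %/% n_bins, n_bins)
  extra <- length(d) %% n_bins
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin <- rep(seq_len(n_bins), sizes)
  out <- data.frame(bin = seq_len(n_bins), n = sizes, dist_min = NA_real_,
                    dist_max = NA_real_, mean = NA_real_, lower = NA_real_,
                    upper = NA_real_)
  alpha <- (1 - conf) / 2
  n_drop <- 0L
  for (bidx in seq_len(n_bins)) {
    sel <- ord[bin == bidx]
    out$dist_min[bidx] <- min(d[sel])
    out$dist_max[bidx] <- max(d[sel])
    vb <- v[sel]
    n_drop <- n_drop + sum(!is.finite(vb))
    vb <- vb[is.finite(vb)]
    out$mean[bidx] <- mean(vb)
    boot <- vapply(seq_len(n_bootstrap), function(i)
      mean(vb[sample.int(length(vb), replace = TRUE)]), numeric(1))
    ci <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE)
    out$lower[bidx] <- ci[1]
    out$upper[bidx] <- ci[2]
  }
  if (n_drop) message(n_drop, " non-finite pair value(s) dropped")
  out
}
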