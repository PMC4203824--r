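# Community-weighted means and the sum-of-squares decomposition of their
# among-site variation into species turnover, intraspecific variation, and
# covariation.

#' Compute total, interspecific, and intraspecific CWMs
#'
#' For each site j and trait, the total ("specific") CWM is
#' \eqn{\sum_i \tilde p_{ij} x_{ij}} over the species with trait
#' measurements in that site, the interspecific ("fixed") CWM is
#' \eqn{\sum_i \tilde p_{ij} x_i}, and the intraspecific CWM is their
#' difference.  \eqn{\tilde p_{ij}} is relative cover renormalized over the
#' trait-sampled species of the site (trait protocols measure the species
#' making up most, not all, of the cover).
#'
#' @param cover a [cover_matrix()].
#' @param ssm a [site_species_means()] table.
#' @param gsm a [global_species_means()] table; computed from `ssm` with the
#'   default site-mean method when `NULL`.
#' @param traits traits to compute (default: all traits in `ssm`).
#' @param gap_fill if `TRUE`, a species with cover but no trait measurement
#'   in a site is assigned its global mean (so it contributes zero ITV)
#'   instead of being dropped.  Off by default: gap-filling deflates the
#'   intraspecific component.
#' @return data.frame of class `cwm_triple` with columns `site`, `trait`,
#'   `cwm_total`, `cwm_inter`, `cwm_intra` (`cwm_intra = cwm_total -
#'   cwm_inter` exactly).
#' @export
compute_cwms <- function(cover, ssm, gsm = NULL, traits = NULL,
                         gap_fill = FALSE) {
  stopifnot(inherits(cover, "cover_matrix"),
            inherits(ssm, "site_species_means"))
  if (is.null(gsm)) gsm <- global_species_means(ssm)
  if (is.null(traits)) traits <- sort(unique(ssm$trait))
  sites <- rownames(cover)
  out <- vector("list", length(traits))
  dropped <- character()
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    s <- ssm[ssm$trait == tr, ]
    g <- gsm[gsm$trait == tr, ]
    gmap <- stats::setNames(g$mean, g$species)
    rows <- data.frame(site = sites, trait = tr, cwm_total = NA_real_,
                       cwm_inter = NA_real_, stringsAsFactors = FALSE)
    for (j in seq_along(sites)) {
      p <- stats::setNames(as.numeric(cover[j, ]), colnames(cover))
      sj <- s[s$site == sites[j], ]
      xij <- stats::setNames(sj$mean, sj$species)
      sampled <- names(p)[p > 0 & names(p) %in% names(xij)]
      if (gap_fill) {
        extra <- names(p)[p > 0 & !(names(p) %in% names(xij)) &
                            names(p) %in% names(gmap)]
        xij <- c(xij, gmap[extra])
        sampled <- c(sampled, extra)
      }
      if (!length(sampled)) next
      pt <- p[sampled] / sum(p[sampled])
      rows$cwm_total[j] <- sum(pt * xij[sampled])
      rows$cwm_inter[j] <- sum(pt * gmap[sampled])
    }
    miss <- is.na(rows$cwm_total)
    if (any(miss)) {
      dropped <- union(dropped, rows$site[miss])
      rows <- rows[!miss, ]
    }
    out[[ti]] <- rows
  }
  if (length(dropped))
    warning("site(s) with no trait-sampled species excluded: ",
            paste(dropped, collapse = ", "))
  res <- do.call(rbind, out)
  res$cwm_intra <- res$cwm_total - res$cwm_inter
  rownames(res) <- NULL
  class(res) <- c("cwm_triple", "data.frame")
  res
}

#' Construct a CWM triple directly
#'
#' Mostly for tests and simulation truth: builds a `cwm_triple` from site
#' ids and total/interspecific series (`cwm_intra` by subtraction).
#'
#' @param site,trait identifiers (recycled as needed).
#' @param total,inter numeric CWM series.
#' @export
cwm_triple <- function(site, total, inter, trait = "trait") {
  df <- data.frame(site = as.character(site), trait = trait,
                   cwm_total = as.numeric(total),
                   cwm_inter = as.numeric(inter),
                   stringsAsFactors = FALSE)
  df$cwm_intra <- df$cwm_total - df$cwm_inter
  class(df) <- c("cwm_triple", "data.frame")
  df
}

.one_trait <- function(triple, trait) {
  stopifnot(inherits(triple, "cwm_triple"))
  trs <- unique(triple$trait)
  if (is.null(trait)) {
    if (length(trs) > 1L)
      stop("multiple traits present; specify `trait`")
    trait <- trs
  }
  tt <- triple[triple$trait == trait, ]
  if (!nrow(tt)) stop("no rows for trait ", trait)
  tt
}

.css <- function(x) sum((x - mean(x))^2)

.decomp_result <- function(ss_turnover, ss_intra, ss_total, kind, n_sites,
                           trait, r_squared = NULL) {
  ss_cov <- ss_total - ss_turnover - ss_intra
  if (ss_total > 0) {
    pct <- 100 * c(ss_turnover, ss_intra, ss_cov) / ss_total
  } else {
    pct <- rep(NA_real_, 3)
  }
  structure(list(trait = trait, kind = kind,
                 ss_turnover = ss_turnover, ss_intra = ss_intra,
                 ss_cov = ss_cov, ss_total = ss_total,
                 pct_turnover = pct[1], pct_intra = pct[2], pct_cov = pct[3],
                 n_sites = n_sites, r_squared = r_squared,
                 degenerate = ss_total <= 0),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("CWM decomposition (%s) -- trait: %s, %d sites\n",
              x$kind, x$trait, x$n_sites))
  cat(sprintf("  SS  turnover %.6g  intraspecific %.6g  covariation %.6g  total %.6g\n",
              x$ss_turnover, x$ss_intra, x$ss_cov, x$ss_total))
  if (!x$degenerate)
    cat(sprintf("  %%   turnover %.1f  intraspecific %.1f  covariation %.1f\n",
                x$pct_turnover, x$pct_intra, x$pct_cov))
  else cat("  total SS is zero; percentages undefined\n")
  if (!is.null(x$r_squared))
    cat(sprintf("  R2  total %.3f  inter %.3f  intra %.3f\n",
                x$r_squared["total"], x$r_squared["inter"],
                x$r_squared["intra"]))
  invisible(x)
}

#' @export
as.data.frame.decomposition_result <- function(x, ...) {
  data.frame(trait = x$trait, kind = x$kind,
             ss_turnover = x$ss_turnover, ss_intra = x$ss_intra,
             ss_cov = x$ss_cov, ss_total = x$ss_total,
             pct_turnover = x$pct_turnover, pct_intra = x$pct_intra,
             pct_cov = x$pct_cov, n_sites = x$n_sites,
             stringsAsFactors = FALSE)
}

#' Decompose among-site CWM variation
#'
#' Centered sums of squares of the interspecific series (turnover
#' component), the intraspecific series (ITV component), and the total
#' series; covariation is the remainder
#' \eqn{SS_{total} - SS_{turnover} - SS_{intra}}, algebraically equal to
#' twice the cross-product of the centered interspecific and intraspecific
#' series.  Reporting covariation as a remainder guarantees additivity by
#' construction.
#'
#' @param triple a [compute_cwms()] result.
#' @param trait which trait (required only when several are present).
#' @return a `decomposition_result` (kind `"total_variation"`).
#' @export
decompose_total_variation <- function(triple, trait = NULL) {
  tt <- .one_trait(triple, trait)
  n <- nrow(tt)
  if (n < 2L) stop("decomposition requires at least 2 sites")
  .decomp_result(.css(tt$cwm_inter), .css(tt$cwm_intra), .css(tt$cwm_total),
                 "total_variation", n, tt$trait[1])
}

.explained_ss <- function(y, mm) {
  fit <- stats::lm.fit(mm, y)
  sum((fit$fitted.values - mean(y))^2)
}

#' Decompose model-explained CWM variation
#'
#' Fits the same ordinary-least-squares predictor set to the total,
#' interspecific, and intraspecific CWM series separately and partitions the
#' explained (regression) sums of squares: turnover and ITV components are
#' the explained SS of the interspecific and intraspecific fits;
#' covariation is the remainder relative to the explained SS of the total
#' fit, and can be negative when the two fits overlap.
#'
#' @param triple a [compute_cwms()] result.
#' @param env an [environment_table()] (raw values are used as predictors).
#' @param predictors character vector of predictor variables.
#' @param trait which trait (required only when several are present).
#' @param allow_saturated permit `length(predictors) >= n_sites - 1`
#'   (normally an error; useful for the saturated-basis identity check).
#' @return a `decomposition_result` (kind `"explained_variation"`) whose
#'   `r_squared` field holds the three fits' R-squared values.
#' @export
decompose_explained_variation <- function(triple, env, predictors,
                                          trait = NULL,
                                          allow_saturated = FALSE) {
  stopifnot(inherits(env, "environment_table"))
  tt <- .one_trait(triple, trait)
  n <- nrow(tt)
  miss <- setdiff(tt$site, rownames(env))
  if (length(miss))
    stop("site(s) missing from environment table: ",
         paste(miss, collapse = ", "))
  if (!allow_saturated && length(predictors) >= n - 1L)
    stop("saturated model: ", length(predictors), " predictors for ", n,
         " sites")
  E <- as.matrix(as.data.frame(env)[tt$site, predictors, drop = FALSE])
  X <- cbind(`(Intercept)` = 1, E)
  ess <- vapply(list(total = tt$cwm_total, inter = tt$cwm_inter,
                     intra = tt$cwm_intra),
                .explained_ss, numeric(1), mm = X)
  tss <- vapply(list(tt$cwm_total, tt$cwm_inter, tt$cwm_intra), .css,
                numeric(1))
  r2 <- ifelse(tss > 0, ess / tss, NA_real_)
  names(r2) <- c("total", "inter", "intra")
  .decomp_result(ess[["inter"]], ess[["intra"]], ess[["total"]],
                 "explained_variation", n, tt$trait[1], r_squared = r2)
}

#' Per-variable variance partitions
#'
#' Runs [decompose_explained_variation()] once per environmental variable
#' as a single predictor.
#'
#' @inheritParams decompose_explained_variation
#' @param variables variables to use (default: all columns of `env`).
#' @return named list of `decomposition_result`, one per variable.
#' @export
single_predictor_partition_table <- function(triple, env, variables = NULL,
                                             trait = NULL) {
  stopifnot(inherits(env, "environment_table"))
  if (is.null(variables)) variables <- names(env)
  stats::setNames(lapply(variables, function(v)
    decompose_explained_variation(triple, env, v, trait = trait)), variables)
}

#' Bray-Curtis dissimilarity between sites
#'
#' \eqn{BC_{jk} = \sum_i |p_{ij} - p_{ik}| / \sum_i (p_{ij} + p_{ik})} on
#' relative cover; `binary = TRUE` converts to presence/absence first
#' (the Sorensen dissimilarity).
#'
#' @param cover a [cover_matrix()].
#' @param binary use presence/absence instead of relative cover.
#' @return symmetric site x site matrix in \[0, 1\].
#' @export
bray_curtis_dissimilarity <- function(cover, binary = FALSE) {
  stopifnot(inherits(cover, "cover_matrix"))
  m <- unclass(cover)
  if (binary) m <- (m > 0) * 1
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (j in seq_len(n - 1L)) for (k in (j + 1L):n) {
    d[j, k] <- d[k, j] <-
      sum(abs(m[j, ] - m[k, ])) / sum(m[j, ] + m[k, ])
  }
  d
}
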