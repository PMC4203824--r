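# OLS fits of CWMs on environmental predictors, AICc stepwise selection,
# and per-species trait-environment regressions.

#' Small-sample corrected AIC of a Gaussian OLS fit
#'
#' `AICc = n log(RSS/n) + 2k + 2k(k+1)/(n - k - 1)` with
#' `k = number of coefficients + 1` (the error variance counts as a
#' parameter).  The additive constant of the Gaussian log-likelihood is
#' dropped; it cancels in every comparison.
#'
#' @param rss residual sum of squares.
#' @param n number of observations.
#' @param n_coef number of regression coefficients including the intercept.
#' @return AICc value (`Inf` when `n - k - 1 <= 0`).
#' @export
aicc <- function(rss, n, n_coef) {
  k <- n_coef + 1
  if (n - k - 1 <= 0) return(Inf)
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Ordinary least squares fit of a site-level response
#'
#' @param y named numeric vector (names = site ids) or unnamed vector in
#'   the row order of `env`.
#' @param env an [environment_table()].
#' @param predictors character vector of predictor variables; empty for the
#'   intercept-only model.
#' @return list of class `linear_model_fit`: `coefficients`, `r_squared`,
#'   `explained_ss`, `residual_ss`, `total_ss`, `aicc`, `n`, `k`
#'   (coefficient count), `predictors`, and the underlying `lm` object.
#' @export
fit_ols <- function(y, env, predictors = character()) {
  stopifnot(inherits(env, "environment_table"))
  E <- as.data.frame(env)
  if (!is.null(names(y))) {
    miss <- setdiff(names(y), rownames(E))
    if (length(miss))
      stop("site(s) missing from environment table: ",
           paste(miss, collapse = ", "))
    E <- E[names(y), , drop = FALSE]
  } else if (length(y) != nrow(E)) {
    stop("length(y) does not match the environment table")
  }
  n <- length(y)
  if (n <= length(predictors) + 1)
    stop("too few observations for ", length(predictors), " predictors")
  dat <- cbind(data.frame(.y = as.numeric(y)), E[predictors])
  form <- if (length(predictors))
    stats::reformulate(predictors, response = ".y") else .y ~ 1
  if (length(predictors) > 1) {
    X <- as.matrix(E[predictors])
    kap <- kappa(cbind(1, scale(X, scale = FALSE)), exact = TRUE)
    if (kap > 1e10) {
      cm <- abs(stats::cor(X))
      diag(cm) <- 0
      worst <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      stop("collinear predictors (condition number ", format(kap),
           "): ", predictors[worst[1]], ", ", predictors[worst[2]])
    }
  }
  fit <- stats::lm(form, data = dat)
  rss <- sum(stats::residuals(fit)^2)
  tss <- .css(as.numeric(y))
  ess <- tss - rss
  structure(list(coefficients = stats::coef(fit),
                 predictors = predictors,
                 r_squared = if (tss > 0) ess / tss else NA_real_,
                 explained_ss = ess, residual_ss = rss, total_ss = tss,
                 aicc = aicc(rss, n, length(stats::coef(fit))),
                 n = n, k = length(stats::coef(fit)), lm = fit),
            class = "linear_model_fit")
}

#' @export
print.linear_model_fit <- function(x, ...) {
  cat(sprintf("OLS fit: %s (n = %d, k = %d)\n",
              if (length(x$predictors))
                paste(x$predictors, collapse = " + ") else "intercept only",
              x$n, x$k))
  cat(sprintf("  R2 = %.4f, AICc = %.3f\n", x$r_squared, x$aicc))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Stepwise model selection by AICc
#'
#' Greedy single-term addition/removal minimizing AICc.  At each step every
#' candidate move is evaluated; the move with the lowest AICc is taken if
#' it strictly improves on the current model, with ties broken toward the
#' smaller model.  The default starts from the full candidate set and
#' searches in both directions.
#'
#' @inheritParams fit_ols
#' @param candidates candidate predictor variables.
#' @param direction `"both"` (default), `"backward"`, or `"forward"`.
#' @param start starting model: `"full"` (default) or `"null"`
#'   (intercept-only; forced for `direction = "forward"`).
#' @param trace print each accepted move.
#' @return the selected `linear_model_fit`.
#' @export
stepwise_aicc <- function(y, env, candidates,
                          direction = c("both", "backward", "forward"),
                          start = NULL, trace = FALSE) {
  direction <- match.arg(direction)
  if (is.null(start)) start <- if (direction == "forward") "null" else "full"
  start <- match.arg(start, c("full", "null"))
  current <- if (start == "full") candidates else character()
  cur_fit <- fit_ols(y, env, current)
  repeat {
    moves <- list()
    if (direction %in% c("both", "backward"))
      for (v in current)
        moves[[paste0("- ", v)]] <- setdiff(current, v)
    if (direction %in% c("both", "forward"))
      for (v in setdiff(candidates, current))
        moves[[paste0("+ ", v)]] <- c(current, v)
    if (!length(moves)) break
    fits <- lapply(moves, function(p) fit_ols(y, env, p))
    aiccs <- vapply(fits, `[[`, numeric(1), "aicc")
    sizes <- lengths(moves)
    ord <- order(aiccs, sizes)  # ties go to the smaller model
    best <- ord[1]
    if (aiccs[best] >= cur_fit$aicc) break
    if (trace)
      cat(sprintf("%s  AICc %.3f -> %.3f\n", names(moves)[best],
                  cur_fit$aicc, aiccs[best]))
    current <- moves[[best]]
    cur_fit <- fits[[best]]
  }
  cur_fit
}

#' Per-species trait response to one environmental variable
#'
#' Simple OLS of a species' site-specific mean trait values on a single
#' predictor -- the species-level view of intraspecific trait change along
#' a gradient.
#'
#' @param ssm a [site_species_means()] table.
#' @param env an [environment_table()].
#' @param species,trait,predictor identifiers of the fit.
#' @param min_sites minimum number of sites with measurements (default 3);
#'   below it the fit is skipped with a warning and `NULL` returned.
#' @return list of class `species_response_fit`: `species`, `trait`,
#'   `predictor`, `slope`, `intercept`, `r_squared`, `n_sites`; or `NULL`.
#' @export
species_trait_response <- function(ssm, env, species, trait, predictor,
                                   min_sites = 3) {
  stopifnot(inherits(ssm, "site_species_means"),
            inherits(env, "environment_table"))
  s <- ssm[ssm$species == species & ssm$trait == trait, ]
  s <- s[s$site %in% rownames(env), ]
  if (nrow(s) < min_sites) {
    warning("species ", species, " measured in ", nrow(s),
            " site(s); need ", min_sites, " -- skipped")
    return(NULL)
  }
  x <- as.data.frame(env)[s$site, predictor]
  fit <- stats::lm(s$mean ~ x)
  tss <- .css(s$mean)
  structure(list(species = species, trait = trait, predictor = predictor,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (tss > 0)
                   1 - sum(stats::residuals(fit)^2) / tss else NA_real_,
                 n_sites = nrow(s)),
            class = "species_response_fit")
}

#' Report strongly correlated predictor pairs
#'
#' Utility mirroring the common screen that retained predictors "not
#' strongly correlated with each other": reports every pair at or above the
#' threshold but drops nothing -- which member of a pair to keep is the
#' analyst's call.
#'
#' @param env an [environment_table()].
#' @param variables variables to screen (default all).
#' @param threshold absolute Pearson correlation flagged (default 0.5).
#' @return data.frame with columns `var1`, `var2`, `r`, ordered by |r|.
#' @export
predictor_correlation_screen <- function(env, variables = NULL,
                                         threshold = 0.5) {
  stopifnot(inherits(env, "environment_table"))
  if (is.null(variables)) variables <- names(env)
  cm <- stats::cor(as.matrix(as.data.frame(env)[variables]))
  idx <- which(upper.tri(cm) & abs(cm) >= threshold, arr.ind = TRUE)
  out <- data.frame(var1 = variables[idx[, 1]], var2 = variables[idx[, 2]],
                    r = cm[idx], stringsAsFactors = FALSE)
  out[order(-abs(out$r)), , drop = FALSE]
}
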