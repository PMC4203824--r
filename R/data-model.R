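#' @keywords internal
"_PACKAGE"

# ---- cover matrix -----------------------------------------------------------

#' Construct a site x species relative-cover matrix
#'
#' A `cover_matrix` is a numeric matrix with sites as rows and species as
#' columns whose rows are renormalized to sum to one on construction
#' (relative cover, the \eqn{p_{ij}} entering every CWM).
#'
#' @param x numeric matrix (or object coercible to one) with site ids as row
#'   names and species ids as column names.  Entries are raw or relative
#'   cover; any non-negative scale is accepted and rows are renormalized.
#' @param normalize renormalize rows to sum to 1 (default `TRUE`).
#' @return a matrix of class `cover_matrix`; rows sum to 1 within `1e-9`.
#' @examples
#' cm <- cover_matrix(rbind(A = c(sp1 = 30, sp2 = 70), B = c(10, 0)))
#' rowSums(cm)
#' @export
cover_matrix <- function(x, normalize = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(rownames(x))) rownames(x) <- paste0("site", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sp", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate site identifiers in cover matrix")
  if (anyDuplicated(colnames(x)))
    stop("duplicate species identifiers in cover matrix")
  if (anyNA(x)) stop("cover matrix contains missing values")
  if (any(x < 0)) stop("cover values must be non-negative")
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("site(s) with zero total cover: ",
         paste(rownames(x)[rs == 0], collapse = ", "))
  # skip the division when rows already sum to 1: normalization is then
  # idempotent and write/read round trips are bit-identical
  if (normalize && any(abs(rs - 1) > 1e-12)) x <- x / rs
  structure(x, class = c("cover_matrix", "matrix", "array"))
}

#' Read / write a cover matrix as delimited text
#'
#' Wide format: first column holds site ids, header row holds species ids.
#'
#' @param path file path.
#' @param delimiter field delimiter (default comma).
#' @return `read_cover_matrix` returns a [cover_matrix()];
#'   `write_cover_matrix` returns `path` invisibly.
#' @export
read_cover_matrix <- function(path, delimiter = ",") {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  cover_matrix(m)
}

#' @rdname read_cover_matrix
#' @param x a `cover_matrix`.
#' @export
write_cover_matrix <- function(x, path, delimiter = ",") {
  body <- apply(unclass(x), 2, .fmt17)
  df <- data.frame(site = rownames(x), body, check.names = FALSE)
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# 17 significant digits: doubles survive a write/read cycle losslessly
.fmt17 <- function(v) sprintf("%.17g", v)

# ---- individual trait records ----------------------------------------------

#' Individual-level trait records
#'
#' Long format table of trait measurements on individuals: one row per
#' (site, species, individual, trait).  Values must be strictly positive in
#' their trait units (height cm, leaf area mm^2, SLA mm^2/mg); LDMC, a mass
#' fraction, must additionally lie in (0, 1].
#'
#' @param df data.frame with columns `site`, `species`, `individual`,
#'   `trait`, `value`.
#' @param ldmc_traits trait names treated as dry-matter-content fractions
#'   and checked against (0, 1].
#' @return `df` with class `trait_records`.
#' @export
trait_records <- function(df, ldmc_traits = "LDMC") {
  need <- c("site", "species", "individual", "trait", "value")
  if (!all(need %in% names(df)))
    stop("trait records need columns: ", paste(need, collapse = ", "))
  df <- as.data.frame(df)[need]
  df$value <- as.numeric(df$value)
  if (anyNA(df$value)) stop("missing trait values")
  if (any(df$value <= 0)) stop("trait values must be strictly positive")
  bad <- df$trait %in% ldmc_traits & df$value > 1
  if (any(bad)) stop("LDMC values must lie in (0, 1]")
  key <- do.call(paste, c(df[c("site", "species", "individual", "trait")],
                          sep = "\r"))
  if (anyDuplicated(key))
    stop("duplicate (site, species, individual, trait) records")
  class(df) <- c("trait_records", "data.frame")
  df
}

#' @rdname trait_records
#' @param path,delimiter file path and field delimiter.
#' @export
read_trait_records <- function(path, delimiter = ",", ldmc_traits = "LDMC") {
  stopifnot(file.exists(path))
  trait_records(utils::read.table(path, header = TRUE, sep = delimiter,
                                  stringsAsFactors = FALSE),
                ldmc_traits = ldmc_traits)
}

#' @rdname trait_records
#' @param x a `trait_records` table.
#' @export
write_trait_records <- function(x, path, delimiter = ",") {
  x <- as.data.frame(x)
  x$value <- .fmt17(x$value)
  utils::write.table(x, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- species mean trait values ---------------------------------------------

#' Site-specific species mean trait values
#'
#' Aggregates individual records to the arithmetic mean per
#' (site, species, trait) cell -- the \eqn{x_{ij}} of the specific CWM.
#' A cell is "sampled" exactly when at least one record exists.
#'
#' @param traits a [trait_records()] table.
#' @return data.frame of class `site_species_means` with columns `site`,
#'   `species`, `trait`, `mean`, `n` (number of individuals averaged).
#' @export
site_species_means <- function(traits) {
  stopifnot(inherits(traits, "trait_records"))
  agg <- stats::aggregate(value ~ site + species + trait, data = traits,
                          FUN = mean)
  cnt <- stats::aggregate(value ~ site + species + trait, data = traits,
                          FUN = length)
  names(agg)[names(agg) == "value"] <- "mean"
  agg$n <- cnt$value
  agg <- agg[order(agg$trait, agg$site, agg$species), ]
  rownames(agg) <- NULL
  class(agg) <- c("site_species_means", "data.frame")
  agg
}

#' Global species mean trait values
#'
#' The \eqn{x_i} of the interspecific ("fixed") CWM: the mean trait value of
#' a species across all sites where it was measured.  The default gives each
#' site one vote (unweighted mean of site-specific means), which makes the
#' fixed CWM insensitive to unequal per-site sampling effort; `"pooled"`
#' weights site means by their individual counts, equivalent to pooling all
#' individuals.
#'
#' @param ssm a [site_species_means()] table.
#' @param method `"site_mean"` (default) or `"pooled"`.
#' @return data.frame of class `global_species_means` with columns
#'   `species`, `trait`, `mean`, `n_sites`.
#' @export
global_species_means <- function(ssm, method = c("site_mean", "pooled")) {
  stopifnot(inherits(ssm, "site_species_means"))
  method <- match.arg(method)
  f <- interaction(ssm$species, ssm$trait, drop = TRUE)
  if (method == "site_mean") {
    # plain mean (long-double accumulation): a species with identical site
    # means gets exactly that value back, keeping the no-ITV limit exact
    m <- tapply(ssm$mean, f, mean)
  } else {
    m <- tapply(ssm$mean * ssm$n, f, sum) / tapply(ssm$n, f, sum)
  }
  ns <- tapply(rep(1, nrow(ssm)), f, sum)
  keys <- do.call(rbind, strsplit(names(m), ".", fixed = TRUE))
  out <- data.frame(species = keys[, 1], trait = keys[, 2],
                    mean = as.numeric(m), n_sites = as.integer(ns),
                    stringsAsFactors = FALSE)
  out <- out[order(out$trait, out$species), ]
  rownames(out) <- NULL
  class(out) <- c("global_species_means", "data.frame")
  out
}

# ---- environment and coordinates -------------------------------------------

#' Site x environmental-variable table
#'
#' @param df data.frame of environmental variables; either row names are
#'   site ids or a `site` column is present.
#' @param log_vars character vector of variables to log-transform when the
#'   table is scaled (variables whose raw distributions are right-skewed,
#'   e.g. available P).  Flagged variables must be strictly positive.
#' @return data.frame of class `environment_table` with sites as row names
#'   and attribute `log_vars`.
#' @export
environment_table <- function(df, log_vars = character()) {
  df <- as.data.frame(df)
  if ("site" %in% names(df)) {
    rownames(df) <- as.character(df$site)
    df$site <- NULL
  }
  if (!all(vapply(df, is.numeric, TRUE)))
    stop("environmental variables must be numeric")
  if (anyNA(df)) stop("environment table contains missing values")
  bad <- intersect(log_vars, names(df))
  bad <- bad[vapply(bad, function(v) any(df[[v]] <= 0), TRUE)]
  if (length(bad))
    stop("log-flagged variable(s) with non-positive values: ",
         paste(bad, collapse = ", "))
  structure(df, log_vars = intersect(log_vars, names(df)),
            class = c("environment_table", "data.frame"))
}

#' @rdname environment_table
#' @param path,delimiter file path and field delimiter.
#' @export
read_environment_table <- function(path, delimiter = ",",
                                   log_vars = character()) {
  stopifnot(file.exists(path))
  environment_table(utils::read.table(path, header = TRUE, sep = delimiter,
                                      stringsAsFactors = FALSE),
                    log_vars = log_vars)
}

#' Scale an environment table
#'
#' Applies the natural log to variables flagged at construction, then
#' z-scores every variable (mean 0, sd 1 across sites) -- the scaling used
#' for environmental distance.
#'
#' @param env an [environment_table()].
#' @param variables variables to retain (default all).
#' @return numeric matrix of scaled variables.
#' @export
scale_environment <- function(env, variables = NULL) {
  stopifnot(inherits(env, "environment_table"))
  if (is.null(variables)) variables <- names(env)
  missing_v <- setdiff(variables, names(env))
  if (length(missing_v))
    stop("unknown environmental variable(s): ",
         paste(missing_v, collapse = ", "))
  m <- as.matrix(as.data.frame(env)[variables])
  lv <- intersect(attr(env, "log_vars"), variables)
  m[, lv] <- log(m[, lv])
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance variable(s): ",
         paste(variables[sds == 0], collapse = ", "))
  scale(m)[, , drop = FALSE]
}

#' Site coordinates in decimal degrees
#'
#' @param df data.frame with columns `site`, `lat`, `lon` (decimal degrees).
#' @return data.frame of class `site_coordinates`.
#' @export
site_coordinates <- function(df) {
  df <- as.data.frame(df)
  if (!all(c("site", "lat", "lon") %in% names(df)))
    stop("coordinates need columns site, lat, lon")
  df <- df[c("site", "lat", "lon")]
  df$site <- as.character(df$site)
  if (anyDuplicated(df$site)) stop("duplicate site identifiers")
  if (any(df$lat < -90 | df$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(df$lon < -180 | df$lon > 180)) stop("longitude outside [-180, 180]")
  class(df) <- c("site_coordinates", "data.frame")
  df
}

#' @rdname site_coordinates
#' @param path,delimiter file path and field delimiter.
#' @export
read_site_coordinates <- function(path, delimiter = ",") {
  stopifnot(file.exists(path))
  site_coordinates(utils::read.table(path, header = TRUE, sep = delimiter,
                                     stringsAsFactors = FALSE))
}
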