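# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

toy_cover <- function() {
  cover_matrix(rbind(A = c(sp1 = 30, sp2 = 50, sp3 = 20),
                     B = c(sp1 = 10, sp2 = 10, sp3 = 80),
                     C = c(sp1 = 60, sp2 = 0,  sp3 = 40)))
}

# five individuals per (site, species, trait) cell with known means
toy_trait_records <- function(means, n_ind = 5, jitter = 0) {
  # means: data.frame site, species, trait, mu
  rows <- lapply(seq_len(nrow(means)), function(i) {
    m <- means[i, ]
    offs <- if (n_ind > 1) seq(-1, 1, length.out = n_ind) * jitter else 0
    data.frame(site = m$site, species = m$species,
               individual = seq_len(n_ind), trait = m$trait,
               value = m$mu + offs, stringsAsFactors = FALSE)
  })
  trait_records(do.call(rbind, rows))
}

random_triple <- function(n = 22, seed = NULL, trait = "t") {
  if (!is.null(seed)) set.seed(seed)
  cwm_triple(sprintf("s%02d", seq_len(n)),
             total = rnorm(n, 50, 10), inter = rnorm(n, 50, 8),
             trait = trait)
}

random_env <- function(n = 22, vars = 6, seed = 1, prefix = "v") {
  set.seed(seed)
  X <- matrix(rnorm(n * vars), n, vars,
              dimnames = list(sprintf("s%02d", seq_len(n)),
                              paste0(prefix, seq_len(vars))))
  environment_table(as.data.frame(X))
}

# symmetric random "distance" matrix (non-negative, zero diagonal)
random_sym <- function(n = 22, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- runif(n * (n - 1) / 2)
  m + t(m)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
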