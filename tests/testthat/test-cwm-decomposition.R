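test_that("compute_cwms matches the defining weighted averages", {
  # one species, p = 1: total = site mean, inter = global mean
  cm <- cover_matrix(rbind(A = c(sp1 = 1), B = c(sp1 = 1)),
                     normalize = FALSE)
  recs <- toy_trait_records(data.frame(site = c("A", "B"), species = "sp1",
                                       trait = "height", mu = c(10, 6)))
  ssm <- site_species_means(recs)
  tri <- compute_cwms(cm, ssm)
  a <- tri[tri$site == "A", ]
  expect_equal(a$cwm_total, 10)
  expect_equal(a$cwm_inter, 8)   # mean of site means 10, 6
  expect_equal(a$cwm_intra, 2)

  # no-ITV limit: x_ij identical across sites -> intra exactly zero
  cm <- toy_cover()
  means <- expand.grid(site = c("A", "B", "C"),
                       species = c("sp1", "sp2", "sp3"),
                       stringsAsFactors = FALSE)
  means$trait <- "height"
  means$mu <- rep(c(10, 25, 40), each = 3)
  tri <- compute_cwms(cm, site_species_means(toy_trait_records(means)))
  expect_true(all(tri$cwm_intra == 0))

  # 3-site, 3-species fixture vs an independent brute-force oracle
  set.seed(11)
  means$mu <- runif(9, 5, 60)
  ssm <- site_species_means(toy_trait_records(means))
  gsm <- global_species_means(ssm)
  tri <- compute_cwms(cm, ssm, gsm)
  for (s in c("A", "B", "C")) {
    p <- cm[s, ]
    xs <- setNames(means$mu[means$site == s], means$species[means$site == s])
    xg <- setNames(gsm$mean, gsm$species)
    sp <- names(p)[p > 0]
    pt <- p[sp] / sum(p[sp])
    expect_equal(tri$cwm_total[tri$site == s],
                 sum(pt * xs[sp]), tolerance = 1e-12)
    expect_equal(tri$cwm_inter[tri$site == s],
                 sum(pt * xg[sp]), tolerance = 1e-12)
  }
})

test_that("cover is renormalized over trait-sampled species only", {
  cm <- toy_cover()  # site C has sp2 cover 0; drop sp3 measurements at C
  means <- data.frame(
    site = c("A", "A", "A", "B", "B", "B", "C"),
    species = c("sp1", "sp2", "sp3", "sp1", "sp2", "sp3", "sp1"),
    trait = "height",
    mu = c(10, 20, 30, 12, 22, 32, 14))
  ssm <- site_species_means(toy_trait_records(means))
  tri <- compute_cwms(cm, ssm)
  # at C only sp1 measured -> weights renormalize to 1 on sp1
  expect_equal(tri$cwm_total[tri$site == "C"], 14)
  # gap-fill mode uses the global mean for unmeasured sp3 at C
  gsm <- global_species_means(ssm)
  tri_gf <- compute_cwms(cm, ssm, gsm, gap_fill = TRUE)
  x3 <- gsm$mean[gsm$species == "sp3"]
  expect_equal(tri_gf$cwm_total[tri_gf$site == "C"],
               0.6 * 14 + 0.4 * x3, tolerance = 1e-12)
})

test_that("a site with no sampled species is excluded with a warning", {
  cm <- toy_cover()
  means <- data.frame(site = c("A", "B"), species = "sp1",
                      trait = "height", mu = c(10, 12))
  ssm <- site_species_means(toy_trait_records(means))
  expect_warning(tri <- compute_cwms(cm, ssm), "excluded")
  expect_setequal(tri$site, c("A", "B"))
})

test_that("total-variation decomposition matches direct arithmetic", {
  tri <- cwm_triple(1:3, total = c(2, 4, 6), inter = c(1, 2, 3))
  d <- decompose_total_variation(tri)
  expect_equal(d$ss_turnover, 2)
  expect_equal(d$ss_intra, 2)
  expect_equal(d$ss_cov, 4)
  expect_equal(d$ss_total, 8)
  expect_equal(c(d$pct_turnover, d$pct_intra, d$pct_cov), c(25, 25, 50))

  # constant intra -> pure turnover
  tri <- cwm_triple(1:4, total = c(3, 5, 7, 9) + 2, inter = c(3, 5, 7, 9))
  d <- decompose_total_variation(tri)
  expect_equal(c(d$pct_turnover, d$pct_intra, d$pct_cov), c(100, 0, 0))

  # identical composition, varying site-specific means -> pure ITV
  cm <- cover_matrix(rbind(A = c(sp1 = 1, sp2 = 1),
                           B = c(sp1 = 1, sp2 = 1),
                           C = c(sp1 = 1, sp2 = 1)))
  means <- expand.grid(site = c("A", "B", "C"), species = c("sp1", "sp2"),
                       stringsAsFactors = FALSE)
  means$trait <- "h"; means$mu <- c(1, 2, 3, 4, 5, 6)
  tri <- compute_cwms(cm, site_species_means(toy_trait_records(means)))
  expect_equal(decompose_total_variation(tri)$pct_turnover, 0)

  expect_error(decompose_total_variation(cwm_triple("A", 1, 1)),
               "at least 2 sites")
  flat <- decompose_total_variation(cwm_triple(1:3, c(1, 1, 1), c(1, 1, 1)))
  expect_true(flat$degenerate)
  expect_true(is.na(flat$pct_turnover))
})

test_that("decomposition additivity, covariation identity, invariances", {
  for (s in 1:50) {
    tri <- random_triple(n = 12, seed = s)
    d <- decompose_total_variation(tri)
    expect_lt(abs(d$ss_total - (d$ss_turnover + d$ss_intra + d$ss_cov)) /
                d$ss_total, 1e-8)
    # independent oracle: covariation = 2 * centered cross-product
    ci <- tri$cwm_inter - mean(tri$cwm_inter)
    cx <- tri$cwm_intra - mean(tri$cwm_intra)
    expect_equal(d$ss_cov, 2 * sum(ci * cx), tolerance = 1e-8)
    expect_equal(d$pct_turnover + d$pct_intra + d$pct_cov, 100,
                 tolerance = 1e-6)
    # scale equivariance and translation invariance
    d2 <- decompose_total_variation(
      cwm_triple(tri$site, 3 * tri$cwm_total + 7, 3 * tri$cwm_inter + 7))
    expect_equal(d2$ss_total, 9 * d$ss_total, tolerance = 1e-10)
    expect_equal(d2$pct_intra, d$pct_intra, tolerance = 1e-8)
  }
})

test_that("explained-variation decomposition behaves at its limits", {
  n <- 20
  env <- random_env(n = n, vars = 3, seed = 5)
  # response built orthogonal to the predictors -> explained SS ~ 0
  set.seed(6)
  y <- rnorm(n)
  X <- cbind(1, as.matrix(as.data.frame(env)))
  y_orth <- y - X %*% solve(crossprod(X), crossprod(X, y))
  tri <- cwm_triple(rownames(env), total = as.numeric(y_orth) + 5,
                    inter = as.numeric(y_orth) / 2 + 5)
  d <- decompose_explained_variation(tri, env, c("v1", "v2", "v3"))
  expect_lt(d$ss_total / .Machine$double.eps^0.5, 1)

  # intra identically zero -> explained_total == explained_inter, cov 0
  set.seed(8)
  tot <- rnorm(n, 10, 3)
  tri <- cwm_triple(rownames(env), tot, tot)
  d <- decompose_explained_variation(tri, env, "v1")
  expect_equal(d$ss_total, d$ss_turnover, tolerance = 1e-12)
  expect_equal(d$ss_intra, 0)
  expect_equal(d$ss_cov, 0, tolerance = 1e-10)

  # single predictor: closed-form r^2 * SS_y oracle
  set.seed(9)
  tri <- random_triple(n = n, seed = 9)
  tri$site <- rownames(env)
  d <- decompose_explained_variation(tri, env, "v2")
  x <- as.data.frame(env)[tri$site, "v2"]
  for (comp in list(c("cwm_total", "ss_total"),
                    c("cwm_inter", "ss_turnover"),
                    c("cwm_intra", "ss_intra"))) {
    yy <- tri[[comp[1]]]
    expect_equal(d[[comp[2]]], cor(x, yy)^2 * sum((yy - mean(yy))^2),
                 tolerance = 1e-10)
  }

  expect_error(decompose_explained_variation(tri, env,
                                             rep(c("v1", "v2", "v3"), 8)),
               "saturated")
})

test_that("saturated site-indicator basis reproduces the total decomposition", {
  tri <- random_triple(n = 10, seed = 3)
  ind <- diag(10)[, -1]
  colnames(ind) <- paste0("s", 2:10)
  env <- environment_table(data.frame(site = tri$site, ind))
  d_sat <- decompose_explained_variation(tri, env, colnames(ind),
                                         allow_saturated = TRUE)
  d_tot <- decompose_total_variation(tri)
  expect_equal(d_sat$ss_turnover, d_tot$ss_turnover, tolerance = 1e-8)
  expect_equal(d_sat$ss_intra, d_tot$ss_intra, tolerance = 1e-8)
  expect_equal(d_sat$ss_total, d_tot$ss_total, tolerance = 1e-8)
})

test_that("single-predictor partition table is internally consistent", {
  env <- random_env(n = 22, vars = 8, seed = 12)
  tri <- random_triple(n = 22, seed = 13)
  tri$site <- rownames(env)
  tab <- single_predictor_partition_table(tri, env)
  expect_length(tab, 8)
  for (d in tab)
    expect_equal(d$ss_total, d$ss_turnover + d$ss_intra + d$ss_cov,
                 tolerance = 1e-8)
  # a predictor equal to cwm_total explains all of the total variation
  env2 <- environment_table(data.frame(site = tri$site,
                                       self = tri$cwm_total, junk = rnorm(22)))
  d <- single_predictor_partition_table(tri, env2, "self")$self
  expect_equal(d$ss_total, decompose_total_variation(tri)$ss_total,
               tolerance = 1e-10)
})

test_that("Bray-Curtis dissimilarity matches hand values and vegan", {
  cm <- cover_matrix(rbind(A = c(0.5, 0.5, 0), B = c(0.5, 0.5, 0),
                           C = c(0, 0.5, 0.5), D = c(1, 0, 0)),
                     normalize = FALSE)
  bc <- bray_curtis_dissimilarity(cm)
  expect_equal(bc["A", "B"], 0)
  expect_equal(bc["A", "C"], 0.5)
  expect_equal(bc["C", "D"], 1)  # disjoint species sets

  skip_if_not_installed("vegan")
  set.seed(21)
  cm <- cover_matrix(matrix(runif(60), 6, 10))
  expect_equal(unname(bray_curtis_dissimilarity(cm)),
               unname(as.matrix(vegan::vegdist(unclass(cm), "bray"))),
               tolerance = 1e-12)
  expect_equal(unname(bray_curtis_dissimilarity(cm, binary = TRUE)),
               unname(as.matrix(vegan::vegdist(unclass(cm), "bray",
                                               binary = TRUE))),
               tolerance = 1e-12)
})
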