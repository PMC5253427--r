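test_that("Gower centring recovers the centred inner product of 1-D points", {
  y <- c(1.5, -2, 0.3, 4, 2.2)
  D <- dist_mat(as.matrix(dist(y)), labels = sprintf("u%d", 1:5))
  G <- gower_center(D)
  yc <- y - mean(y)
  expect_equal(G, outer(yc, yc), ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(rowSums(G), rep(0, 5), tolerance = 1e-9)

  Z <- dist_mat(matrix(0, 4, 4))
  expect_equal(gower_center(Z), matrix(0, 4, 4), ignore_attr = TRUE)

  set.seed(2)
  pts <- matrix(rnorm(30), 10, 3)
  De <- dist_mat(as.matrix(dist(pts)))
  expect_gte(sum(diag(gower_center(De))), 0)
  expect_gte(min(eigen(gower_center(De), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
})

test_that("pseudo-F reduces exactly to the classical regression ANOVA F", {
  set.seed(10)
  n <- 25
  x <- rnorm(n)
  y <- 1 + 0.8 * x + rnorm(n)
  D <- dist_mat(as.matrix(dist(y)), labels = sprintf("u%d", 1:n))
  preds <- tibble::tibble(unit = sprintf("u%d", 1:n), x = x)
  row <- distlm_marginal(D, preds, n_perm = 19, seed = 1)
  classical <- anova(lm(y ~ x))
  expect_equal(unname(row$pseudo_F), classical$`F value`[1], tolerance = 1e-9)
  expect_equal(unname(row$pct_var),
               100 * classical$`Sum Sq`[1] / sum(classical$`Sum Sq`),
               tolerance = 1e-9)

  # multi-level categorical reduces to one-way ANOVA F
  gcat <- factor(rep(letters[1:3], length.out = n))
  y2 <- rnorm(n) + as.numeric(gcat)
  D2 <- dist_mat(as.matrix(dist(y2)), labels = sprintf("u%d", 1:n))
  row2 <- distlm_marginal(D2, tibble::tibble(unit = sprintf("u%d", 1:n),
                                             grp = as.character(gcat)),
                          n_perm = 19, seed = 1)
  expect_equal(unname(row2$pseudo_F), anova(lm(y2 ~ gcat))$`F value`[1],
               tolerance = 1e-9)
})

test_that("pseudo-F agrees with vegan's adonis2 on Euclidean responses", {
  skip_if_not_installed("vegan")
  set.seed(12)
  n <- 30
  pts <- matrix(rnorm(2 * n), n, 2)
  x <- rnorm(n); z <- rnorm(n)
  D <- dist_mat(as.matrix(dist(pts)), labels = sprintf("u%d", 1:n))
  preds <- tibble::tibble(unit = sprintf("u%d", 1:n), x = x, z = z)
  ours <- distlm_marginal(D, preds[, c("unit", "x")], n_perm = 19, seed = 1)
  ref <- vegan::adonis2(dist(pts) ~ x, permutations = 19)
  expect_equal(unname(ours$pseudo_F), ref$F[1], tolerance = 1e-9)
  # conditional: added F of x given z equals sequential adonis2 with x last
  cond <- distlm_conditional(D, preds, covariates = "z", n_perm = 19, seed = 1)
  ref2 <- vegan::adonis2(dist(pts) ~ z + x, permutations = 19, by = "terms")
  expect_equal(unname(cond$pseudo_F[cond$predictor == "x"]), ref2$F[2],
               tolerance = 1e-9)
})

test_that("variance decomposition is conserved and constant predictors fail", {
  set.seed(3)
  n <- 20
  D <- dist_mat(as.matrix(dist(rnorm(n))), labels = sprintf("u%d", 1:n))
  G <- gower_center(D)
  X <- cbind(1, rnorm(n))
  H <- landgenr:::hat_of(X)
  expect_equal(sum(G * H) + sum(diag((diag(n) - H) %*% G %*% (diag(n) - H))),
               sum(diag(G)), tolerance = 1e-9)
  expect_error(distlm_marginal(D, tibble::tibble(unit = sprintf("u%d", 1:n),
                                                 k = rep(1, n)), n_perm = 9),
               "singular")
})

test_that("conditional tests: noise predictors add ~nothing given coordinates", {
  set.seed(21)
  n <- 100
  xy <- matrix(runif(2 * n, 0, 10), n, 2)
  D <- dist_mat(as.matrix(dist(xy)), labels = sprintf("u%d", 1:n))
  preds <- tibble::tibble(unit = sprintf("u%d", 1:n), lon = xy[, 1],
                          lat = xy[, 2], noise = rnorm(n))
  cond <- distlm_conditional(D, preds, covariates = c("lon", "lat"),
                             n_perm = 19, seed = 1)
  expect_lt(abs(cond$pct_var[cond$predictor == "noise"]), 2)
})

test_that("forward selection recovers ordering and decomposes variance", {
  set.seed(31)
  n <- 60
  xy <- matrix(runif(2 * n), n, 2)
  elev <- rnorm(n)
  y <- 3 * xy[, 1] + 3 * xy[, 2] + 1 * elev + rnorm(n, 0, 0.3)
  D <- dist_mat(as.matrix(dist(y)), labels = sprintf("u%d", 1:n))
  preds <- tibble::tibble(unit = sprintf("u%d", 1:n), lon = xy[, 1],
                          lat = xy[, 2], elev = elev, junk = rnorm(n))
  fwd <- distlm_forward(D, preds, groups = list(coordinates = c("lon", "lat")),
                        n_perm = 19, seed = 1)
  expect_equal(fwd$predictor[1], "lon+lat")
  expect_equal(fwd$predictor[2], "elev")
  # sequential added pct sums to the full-model pct
  full_X <- cbind(1, xy, elev, preds$junk)
  H <- landgenr:::hat_of(full_X)
  G <- gower_center(D)
  expect_equal(sum(fwd$pct_var), 100 * sum(G * H) / sum(diag(G)),
               tolerance = 1e-9)

  # duplicated predictor contributes zero added variation and is flagged
  preds2 <- tibble::tibble(unit = sprintf("u%d", 1:n), a = elev, b = elev)
  fwd2 <- distlm_forward(D, preds2, n_perm = 19, seed = 1)
  expect_equal(fwd2$pct_var[2], 0)
  expect_true(is.na(fwd2$pseudo_F[2]))
})

test_that("DISTLM p-values are calibrated under the null", {
  set.seed(777)
  n <- 20
  ps <- vapply(seq_len(200), function(b) {
    D <- dist_mat(as.matrix(dist(rnorm(n))), labels = sprintf("u%d", 1:n))
    preds <- tibble::tibble(unit = sprintf("u%d", 1:n), x = rnorm(n))
    distlm_marginal(D, preds, n_perm = 99)$p.value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("population-level tests delegate and validate", {
  set.seed(41)
  K <- 6
  pops <- sprintf("P%d", 1:K)
  ne <- runif(K, 10, 60)
  fvals <- as.matrix(dist(ne)) / 100
  fst <- dist_mat(fvals, kind = "fst", labels = pops)
  attrs <- population_attributes(tibble::tibble(
    population_id = pops, n_census = as.integer(round(ne * 3)),
    n_effective = ne, centroid_x = runif(K, 0, 100),
    centroid_y = runif(K, 0, 100)))
  res <- distlm_population_level(fst, migration = NULL, attrs, n_perm = 99,
                                 seed = 1)
  expect_true(all(c("marginal", "conditional") %in% res$test_type))
  marg <- distlm_marginal(fst, tibble::tibble(unit = pops, n_effective = ne,
                                              n_census = as.integer(round(ne * 3))),
                          n_perm = 99, seed = 1)
  expect_equal(res$pseudo_F[res$test_type == "marginal"], marg$pseudo_F,
               tolerance = 1e-12)

  few <- dist_mat(fvals[1:3, 1:3], kind = "fst", labels = pops[1:3])
  expect_error(distlm_population_level(few, NULL, attrs, n_perm = 9),
               "at least 4")
  attrs_const <- attrs; attrs_const$n_effective <- 5
  expect_error(distlm_population_level(fst, NULL,
                                       population_attributes(attrs_const),
                                       n_perm = 9), "singular")
})
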