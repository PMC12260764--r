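test_that("log10 transform is exact, monotone and invertible", {
  expect_equal(log10_transform(c(1, 10, 100)), c(0, 1, 2))
  set.seed(2)
  x <- sort(rlnorm(50, 3, 1))
  y <- log10_transform(x)
  expect_true(all(diff(y) > 0))
  expect_equal(10^y, x, tolerance = 1e-12)
  expect_error(log10_transform(c(2, -1, 3)), "indices: 2")
})

test_that("normality screen is calibrated and detects skew", {
  set.seed(101)
  p_null <- vapply(1:200, function(i) shapiro_wilk(rnorm(200))$p_value, 1)
  # null p-values are uniform: the >0.05 fraction sits near 0.95
  # (3 binomial SDs below 0.95 over 200 replicates is ~0.904)
  expect_gt(mean(p_null > 0.05), 0.90)
  sw <- shapiro_wilk(rlnorm(500, 0, 1))
  expect_lt(sw$p_value, 0.01)
  expect_true(sw$statistic > 0 && sw$statistic <= 1)
  expect_error(shapiro_wilk(rep(3, 10)), "constant")
  expect_error(shapiro_wilk(c(1, 2)), "n >= 3")
})

test_that("Kruskal-Wallis matches the textbook rank formula", {
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  kw <- kruskal_wallis(g)
  expect_equal(kw$statistic, kw_oracle(g), tolerance = 1e-12)
  expect_equal(kw$statistic, 7.2, tolerance = 1e-12)  # hand rank computation
  expect_identical(kw$df, 2L)
  # tie-corrected case against the oracle
  set.seed(5)
  gt <- list(a = round(rlnorm(30, 2, 1)), b = round(rlnorm(25, 2.2, 1)),
             c = round(rlnorm(35, 1.8, 1)))
  expect_equal(kruskal_wallis(gt)$statistic, kw_oracle(gt), tolerance = 1e-10)
})

test_that("Kruskal-Wallis degenerate and invariance properties", {
  ident <- list(a = c(2, 2), b = c(2, 2), c = c(2, 2))
  kw <- kruskal_wallis(ident)
  expect_identical(kw$statistic, 0)
  expect_identical(kw$p_value, 1)
  set.seed(6)
  g <- list(a = rnorm(20), b = rnorm(20, 1), c = rnorm(20, 2))
  shifted <- lapply(g, `+`, 100)
  expect_equal(kruskal_wallis(g)$statistic, kruskal_wallis(shifted)$statistic,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(list(a = 1:3)), "2 non-empty groups")
})

test_that("Dunn z statistics agree with the rank-sum oracle", {
  set.seed(9)
  for (rep in 1:20) {
    g <- list(a = round(rlnorm(15 + rep, 2, 1), 1),
              b = round(rlnorm(20, 2.5, 1), 1),
              c = round(rlnorm(18, 2, 1.5), 1))
    got <- dunn_posthoc(g)
    want <- dunn_oracle(g)
    expect_equal(got$z, want$z, tolerance = 1e-9)
  }
})

test_that("Dunn handles degenerate input and adjustment monotonicity", {
  ident <- list(a = rep(1, 5), b = rep(1, 6), c = rep(1, 7))
  d0 <- dunn_posthoc(ident)
  expect_true(all(d0$z == 0) && all(d0$p_value == 1))
  expect_error(dunn_posthoc(list(a = 1:3, b = 1:3)), ">= 3 groups")
  expect_error(dunn_posthoc(list(a = 1:3, b = numeric(0), c = 1:3)), "empty")
  set.seed(10)
  g <- list(a = rnorm(25), b = rnorm(25, 0.5), c = rnorm(25, 1))
  for (adj in c("bonferroni", "holm")) {
    d <- dunn_posthoc(g, adjustment = adj)
    expect_true(all(d$p_unadjusted <= d$p_value + 1e-15))
  }
})

test_that("Dunn separates the natural group when effects mirror the survey", {
  set.seed(12)
  pr <- study_profiles()
  groups <- lapply(pr, function(p) {
    sc <- generate_stand(p, c(200, 80), seed = 12 + p$stem_intensity)
    idx <- sample(nrow(sc$trees), 250)
    aboveground_weight(sc$trees$dbh_cm[idx])
  })
  d <- dunn_posthoc(groups)
  nat <- d$group1 == "natural" | d$group2 == "natural"
  expect_true(all(d$p_value[nat] < 0.05))
  expect_gt(d$p_value[!nat], 0.05)
})

test_that("Spearman matrix is exact under a common monotone driver", {
  set.seed(13)
  D <- runif(60, 6, 39)
  m <- spearman_matrix(trunk_weight(D, 9), aboveground_weight(D),
                       root_weight(D))
  expect_identical(dim(m), c(3L, 3L))
  expect_equal(diag(m), c(trunk = 1, aboveground = 1, root = 1))
  expect_identical(unname(m[upper.tri(m)]), c(1, 1, 1))
  expect_equal(m, t(m))
  # reversing one vector flips its correlations to -1
  m2 <- spearman_matrix(trunk_weight(D, 9), aboveground_weight(D),
                        root_weight(sort(D)[rank(-D)]))
  expect_identical(unname(m2["root", "trunk"]), -1)
  expect_warning(spearman_matrix(rep(1, 10), 1:10, 10:1), "constant")
})

test_that("height noise keeps organ correlations above 0.9", {
  sc <- generate_stand(study_profiles()$natural, c(270, 60), seed = 15)
  sv <- sample_pcqm(sc, transect_design(), transect_origin = c(10, 30))
  w <- tree_weights(sv$records)
  m <- spearman_matrix(w$w_trunk_kg, w$w_ag_kg, w$w_root_kg)
  expect_true(all(m[upper.tri(m)] > 0.9))
})

test_that("the Gaussian GLM is the group-means model", {
  # noiseless saturated case: coefficients are exact mean differences
  flat <- data.frame(
    ecosystem = rep(c("degraded", "natural", "restored"), each = 4),
    site = "s",
    dbh_cm = rep(c(10, 20, 15), each = 4), height_m = rep(c(5, 9, 11), each = 4))
  w <- tree_weights(flat)
  fit <- glm_total_weight(w)
  tot <- w$w_trunk_kg + w$w_ag_kg + w$w_root_kg
  mu <- tapply(tot, w$ecosystem, mean)
  co <- fit$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], unname(mu["degraded"]))
  expect_equal(co$estimate[co$term == "ecosystemnatural"],
               unname(mu["natural"] - mu["degraded"]), tolerance = 1e-10)
  expect_equal(fit$residual_deviance, 0, tolerance = 1e-12)
  expect_identical(fit$residual_df, fit$n - 3L)
  # noisy case: still the one-way means model
  set.seed(17)
  noisy <- data.frame(
    ecosystem = sample(c("degraded", "natural", "restored"), 90, TRUE),
    site = "s", dbh_cm = runif(90, 6, 35), height_m = runif(90, 3, 12))
  wn <- tree_weights(noisy)
  fitn <- glm_total_weight(wn)
  totn <- wn$w_trunk_kg + wn$w_ag_kg + wn$w_root_kg
  mun <- tapply(totn, wn$ecosystem, mean)
  con <- fitn$coefficients
  expect_equal(con$estimate[con$term == "(Intercept)"], unname(mun["degraded"]),
               tolerance = 1e-10)
  expect_equal(con$estimate[con$term == "ecosystemrestored"],
               unname(mun["restored"] - mun["degraded"]), tolerance = 1e-10)
  # permutation invariance
  perm <- wn[sample(nrow(wn)), ]
  expect_equal(glm_total_weight(perm)$coefficients$estimate,
               con$estimate, tolerance = 1e-10)
  # guard rails
  expect_error(glm_total_weight(wn, reference = "mangrove"), "absent")
  tiny <- wn[c(which(wn$ecosystem == "degraded")[1],
               which(wn$ecosystem == "natural")[1:5],
               which(wn$ecosystem == "restored")[1:5]), ]
  expect_error(glm_total_weight(tiny), ">= 2 trees")
})
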