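# Diagnostics: map comparison, convergence curves, factor regression,
# sensitivity/specificity/conjunction machinery, Dice sweep.

test_that("spatial correlation matches hand oracles and handles masks", {
  a <- brain_map(c(1, 2, 3))
  expect_equal(spatial_correlation(a, a), 1)
  expect_equal(spatial_correlation(a, brain_map(-c(1, 2, 3))), -1)
  expect_equal(spatial_correlation(a, brain_map(c(1, 2, 4))), 0.9819805061,
               tolerance = 1e-9)
  # NA entries excluded pairwise
  b <- brain_map(c(1, NA, 3, 5))
  d <- brain_map(c(2, 9, 4, 6))
  expect_equal(spatial_correlation(b, d),
               cor(c(1, 3, 5), c(2, 4, 6)))
  # masks restrict the comparison
  expect_equal(spatial_correlation(brain_map(1:6), brain_map(c(1:3, 9, 8, 7)),
                                   mask = 1:3), 1)
  expect_error(spatial_correlation(brain_map(c(1, 2)), brain_map(c(1, 2))),
               "fewer than 3")
  expect_error(spatial_correlation(brain_map(rep(1, 5)), brain_map(1:5)),
               "constant")
})

test_that("convergence curves rise toward the exhaustive identity case", {
  C <- conn200()
  atl <- atlas200()

  # exhaustive identity input: correlation exactly 1
  expect_equal(cor(coef(lnm(as.list(1:200), C)),
                   map_values(connectome_degree(C))), 1)

  cc <- convergence_to_degree(C, atl, set_sizes = c(1, 5, 25), n_runs = 100,
                              dilation = 0, seed = 2)
  expect_true(all(diff(cc$summary$mean) > 0))

  # size-1 draws take values in {cor(row_i, degree)} exactly
  deg <- map_values(connectome_degree(C))
  row_r <- vapply(1:200, function(i) cor(C$weights[i, ], deg), numeric(1))
  expect_true(all(vapply(cc$r[["1"]], function(v) {
    any(abs(v - row_r) < 1e-12)
  }, logical(1))))
})

test_that("single-region degree trace handles closed-form cases", {
  # rank-one matrix: every row collinear with the degree vector
  set.seed(3)
  g <- abs(rnorm(50)) + 0.5
  W <- tcrossprod(g)
  diag(W) <- 0
  expect_equal(single_region_degree_trace(as_connectome(W)), 1)

  # constant-degree matrix: correlation undefined
  Cc <- as_connectome(matrix(0.5, 10, 10) - diag(0.5, 10))
  expect_error(single_region_degree_trace(Cc), "constant")

  fr <- single_region_degree_trace(conn200())
  expect_gte(fr, 0)
  expect_lte(fr, 1)
})

test_that("factor regression explains in-span maps and rejects collinearity", {
  C <- conn200()
  atl <- atlas200()
  fac <- build_elementary_factors(C, atl)

  fit <- factor_regression(brain_map(2 * fac$design[, 3]), fac)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["module1_mean"]), 2, tolerance = 1e-6)
  others <- setdiff(names(fit$coefficients), c("module1_mean", "(intercept)"))
  expect_true(all(abs(fit$coefficients[others]) < 1e-6))

  # noise orthogonalized against the design has (near) zero R^2
  X <- cbind(1, fac$design)
  noise <- with_seed(4, rnorm(200))
  resid <- noise - X %*% solve(crossprod(X), crossprod(X, noise))
  expect_lt(factor_regression(brain_map(resid), fac)$r_squared, 0.05)

  # R^2 invariant to affine rescaling of the map
  m <- brain_map(coef(lnm(generate_random_lesions(atl, 20, seed = 5), C)))
  expect_equal(factor_regression(m, fac)$r_squared,
               factor_regression(brain_map(3 - 2 * map_values(m)), fac)$r_squared,
               tolerance = 1e-12)

  # nested designs never lose explained variance
  fac6 <- structure(list(design = fac$design[, 1:6],
                         column_names = fac$column_names[1:6]),
                    class = "elementary_factors")
  expect_gte(factor_regression(m, fac)$r_squared,
             factor_regression(m, fac6)$r_squared)

  fac_bad <- structure(list(design = cbind(fac$design,
                                           dup = 2 * fac$design[, 1])),
                       class = "elementary_factors")
  expect_error(factor_regression(m, fac_bad), "rank deficient")
})

test_that("sensitivity, specificity and conjunction behave at the boundaries", {
  s <- lnm_settings()

  # identical maps with one supra-threshold region
  tm <- matrix(rep(c(9, 2, 0), each = 4), 4)
  expect_equal(map_values(sensitivity_test(tm, s)), c(1, 0, 0))

  # a region passing in 74% of lesions is excluded at G = 0.75
  tm2 <- matrix(c(rep(8, 74), rep(0, 26)), ncol = 1)
  expect_equal(map_values(sensitivity_test(tm2, s)), 0)

  # sign-split regions never pass at G > 0.5
  tm3 <- matrix(c(rep(9, 5), rep(-9, 5)), ncol = 1)
  expect_equal(map_values(sensitivity_test(tm3, lnm_settings(consistency_G = 0.51))), 0)

  # identical groups give a zero specificity map
  A <- matrix(rnorm(40), 4)
  expect_true(all(map_values(specificity_test(A, A, s)) == 0))

  # zero within-group variance with a shift gives signed infinity
  B1 <- matrix(1, 3, 2)
  B2 <- matrix(c(0, 1), 3, 2, byrow = TRUE)
  expect_warning(spec_map <- specificity_test(B1, B2, s), "zero pooled")
  expect_identical(map_values(spec_map), c(Inf, 0))

  # swapping the groups negates the map
  set.seed(6)
  T1 <- matrix(rnorm(60, mean = 3), 6)
  T2 <- matrix(rnorm(60), 6)
  s_lo <- lnm_settings(t_threshold_specificity = 0)
  expect_equal(map_values(specificity_test(T1, T2, s_lo)),
               -map_values(specificity_test(T2, T1, s_lo)))

  # conjunction intersects supports and records significance
  sens <- brain_map(c(0, 1, 0.8, 0))
  spec <- brain_map(c(0, 0, 12, -11))
  cj <- conjunction(sens, spec)
  expect_equal(map_values(cj), c(0, 0, 1, 0))
  expect_equal(attr(cj, "n_pass"), 1)
  expect_true(attr(cj, "significant"))
  cj0 <- conjunction(brain_map(c(1, 0)), brain_map(c(0, 1)))
  expect_false(attr(cj0, "significant"))
  expect_equal(map_values(conjunction(cj, cj)), map_values(cj))
})

test_that("Dice averages match set arithmetic", {
  M <- build_lesion_matrix(list(c(1, 2), c(2, 3)), 4)
  expect_equal(dice_average(M), 0.5)
  expect_equal(dice_average(build_lesion_matrix(list(c(1, 2), c(1, 2)), 4)), 1)
  expect_equal(dice_average(build_lesion_matrix(list(1, 2), 4)), 0)
  expect_error(dice_average(build_lesion_matrix(list(1), 4)), "at least 2")
})

test_that("the conjunction sweep separates disjoint from identical lesions", {
  atl <- generate_atlas(60, 4, subcortical_fraction = 0, seed = 7)
  C <- generate_connectome(atl, seed = 7)
  sw <- conjunction_sweep(C, atl, q_grid = c(0, 1e9), n_sets = 8,
                          lesions_per_set = 50, dilation = 2,
                          n_subjects = 20, edge_sd = 0.1, seed = 8)
  expect_true(all(sw$bins$prop_significant >= 0 & sw$bins$prop_significant <= 1))
  top <- sw$sets[sw$sets$q == 1e9, ]
  expect_true(all(top$dice > 0.9))
  expect_equal(mean(top$significant), 1)

  # an unreachable sensitivity threshold kills every set
  sw_inf <- conjunction_sweep(C, atl, q_grid = 1e9, n_sets = 4,
                              lesions_per_set = 25, dilation = 2,
                              n_subjects = 20, edge_sd = 0.1,
                              settings = lnm_settings(t_threshold_sensitivity = Inf),
                              seed = 9)
  expect_true(all(!sw_inf$sets$significant))
})
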