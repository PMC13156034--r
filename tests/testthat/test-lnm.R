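# Core estimator: lesion matrix construction, compressed and full LNM,
# symptom-weighted LNM, thresholding.

test_that("lesion matrix construction normalizes rows and validates input", {
  M <- build_lesion_matrix(list(1), 3)
  expect_equal(M$rows, matrix(c(1, 0, 0), 1))

  M2 <- build_lesion_matrix(list(c(1, 2)), 3)
  expect_equal(M2$rows, matrix(c(0.5, 0.5, 0), 1))

  M3 <- build_lesion_matrix(list(1, 3), 3)
  expect_equal(M3$rows, rbind(c(1, 0, 0), c(0, 0, 1)))

  expect_error(build_lesion_matrix(list(integer(0)), 3), "empty")
  expect_error(build_lesion_matrix(list(4), 3), "outside")
  expect_warning(build_lesion_matrix(list(c(1, 1, 2)), 3), "duplicate")
})

test_that("compressed LNM reproduces hand-computed toy maps", {
  C3 <- toy_c3()

  # identity lesion matrix degenerates to the degree vector, exactly
  fit_I <- lnm(as.list(1:3), C3, scale = "sum")
  expect_identical(coef(fit_I), c(3, 0, 1))
  expect_identical(coef(fit_I), map_values(connectome_degree(C3)))

  # a single-region lesion copies the corresponding connectome row
  expect_identical(coef(lnm(list(1), C3)), c(0, 1, 2))
  expect_identical(coef(lnm(list(3), C3)), C3$weights[3, ])

  # multi-region lesion averages the selected rows (hand oracle)
  expect_equal(coef(lnm(list(c(1, 2)), C3)), c(0.5, 0.5, 0.5))
})

test_that("compressed LNM is linear under row-stacking", {
  C <- conn200()
  atl <- atlas200()
  M1 <- generate_random_lesions(atl, 7, dilation = 2, seed = 1)
  M2 <- generate_random_lesions(atl, 5, dilation = 3, seed = 2)
  stacked <- build_lesion_matrix(c(M1$region_lists, M2$region_lists), 200)
  expect_equal(coef(lnm(stacked, C, scale = "sum")),
               coef(lnm(M1, C, scale = "sum")) + coef(lnm(M2, C, scale = "sum")))
})

test_that("per-lesion t statistics match the closed form", {
  # one edge observed as 2, 4, 6 across three subjects: t = mean/(sd/sqrt(n))
  C2 <- as_connectome(matrix(0, 2, 2))
  mats <- lapply(c(2, 4, 6), function(v) matrix(c(0, v, v, 0), 2))
  H <- structure(list(matrices = mats, n_subjects = 3L, edge_sd = NA,
                      n_regions = 2L, seed = 0L), class = "lnm_subject_set")
  tm <- suppressWarnings(lesion_tmaps(build_lesion_matrix(list(1), 2), H))
  expect_equal(tm[1, 2], 3.464101615, tolerance = 1e-9)
  # the seed region's own value is constant zero: degenerate cell reported
  expect_warning(lesion_tmaps(build_lesion_matrix(list(1), 2), H),
                 "zero variance")
})

test_that("full and compressed routes agree as subject noise vanishes", {
  atl <- generate_atlas(60, 4, seed = 21)
  C <- generate_connectome(atl, seed = 21)
  les <- generate_random_lesions(atl, 20, dilation = 4, seed = 22)
  H <- generate_subject_set(C, 1000, edge_sd = 1e-6, seed = 23)
  full <- lnm(les, subjects = H)
  comp <- lnm(les, C)
  expect_gt(cor(coef(full), coef(comp)), 0.999)
})

test_that("tiny lesion-free toy still flags degenerate seed cells", {
  fit <- suppressWarnings(lnm(build_lesion_matrix(as.list(1:4), 4),
             subjects = generate_subject_set(
               as_connectome(matrix(0.5, 4, 4) - diag(0.5, 4)), 50, 0.05,
               seed = 3),
             settings = lnm_settings(aggregation = "consistency")))
  expect_true(all(map_values(fit) %in% c(0, 0.25, 0.5, 0.75, 1) |
                    map_values(fit) < 0))
})

test_that("t aggregation is rank-identical to mean aggregation under equal variance", {
  C <- conn200()
  les <- build_lesion_matrix(as.list(seq(1, 200, by = 4)), 200)
  H <- equal_variance_subjects(C, n_subjects = 24)
  full_t <- suppressWarnings(lnm(les, subjects = H))
  comp <- lnm(les, C)
  keep <- is.finite(coef(full_t))
  expect_equal(cor(coef(full_t)[keep], coef(comp)[keep], method = "spearman"), 1)
})

test_that("the consistency group rule has a sharp boundary at G", {
  # a region passing the threshold in 3 of 4 lesions survives at G = 0.75
  tm <- rbind(c(8, 0), c(9, 0), c(7.5, 0), c(1, 0))
  pass <- sensitivity_test(tm, lnm_settings(consistency_G = 0.75))
  expect_equal(map_values(pass), c(0.75, 0))
  drop <- sensitivity_test(tm, lnm_settings(consistency_G = 0.76))
  expect_equal(map_values(drop), c(0, 0))
})

test_that("thresholding keeps signed supra-threshold entries", {
  m <- brain_map(c(-8, 5, 7.1), "tmap")
  expect_equal(map_values(threshold_map(m, 7)), c(-8, 0, 7.1))
  expect_equal(map_values(threshold_map(m, 7, keep_sign = FALSE)), c(-1, 0, 1))
  expect_equal(map_values(threshold_map(m, 7, keep_sign = FALSE,
                                        binarize = TRUE)), c(1, 0, 1))
  # zero threshold only removes exact zeros
  expect_equal(map_values(threshold_map(brain_map(c(-2, 0, 3)), 0)), c(-2, 0, 3))
  sub <- threshold_map(m, 10)
  expect_true(attr(sub, "all_zero"))
  expect_equal(attr(sub, "threshold"), 10)
})

test_that("sLNM reproduces hand-computed correlations and is bounded", {
  C3 <- toy_c3()
  M <- build_lesion_matrix(as.list(1:3), 3)
  sv_raw <- c(1, 2, 3)
  fit <- suppressMessages(slnm(M, C3, sv_raw))
  expect_equal(map_values(fit), c(1, -1, -0.6546536707), tolerance = 1e-9)

  # invariant to affine rescaling of the raw scores
  fit2 <- suppressMessages(slnm(M, C3, 10 - 4 * sv_raw))
  expect_equal(map_values(fit2), -map_values(fit), tolerance = 1e-12)

  # bounded in [-1, 1] on structured input
  atl <- atlas200()
  C <- conn200()
  M2 <- generate_random_lesions(atl, 30, dilation = 2, seed = 31)
  r <- map_values(suppressMessages(slnm(M2, C, generate_symptoms(M2, seed = 32))))
  expect_true(all(abs(r[!is.na(r)]) <= 1))

  expect_error(slnm(build_lesion_matrix(list(1, 2), 3), C3, c(1, 2)),
               "at least 3")
})

test_that("sLNM of unrelated symptoms is centered near zero", {
  atl <- atlas200()
  C <- conn200()
  S <- 100
  M <- generate_random_lesions(atl, S, dilation = 0, seed = 41)
  mean_abs_r <- mean(vapply(1:50, function(i) {
    sv <- generate_symptoms(M, mode = "random", seed = 100 + i)
    r <- map_values(suppressMessages(slnm(M, C, sv)))
    mean(abs(r), na.rm = TRUE)
  }, numeric(1)))
  expect_lt(mean_abs_r, 2 / sqrt(S))
})

test_that("sLNM marks zero-variance regions as undefined", {
  W <- matrix(c(0, 1, 0, 0,
                1, 0, 2, 0,
                0, 2, 0, 0,
                0, 0, 0, 0), 4, 4, byrow = TRUE)
  C <- as_connectome(W)
  M <- build_lesion_matrix(list(1, 2, 3), 4)
  expect_message(fit <- slnm(M, C, c(-1, 0, 1)), "zero variance")
  expect_true(is.na(map_values(fit)[4]))
  expect_equal(fit$n_undefined, 1L)
})
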