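# Generators: atlas geometry, structured connectomes, subject sets, lesion
# sets and symptom scores.

test_that("atlas generation honors its contract", {
  atl <- generate_atlas(10, n_modules = 2, subcortical_fraction = 0,
                        k_neighbors = 4, seed = 1)
  expect_s3_class(atl, "lnm_atlas")
  expect_equal(atl$n_regions, 10L)
  expect_equal(nrow(atl$centroids), 10L)
  expect_true(all(abs(sqrt(rowSums(atl$centroids^2)) - 1) < 1e-12))
  expect_setequal(unique(atl$module_labels), 1:2)
  expect_true(all(table(atl$module_labels) > 0))
  expect_true(all(atl$is_cortical))
  # neighbor lists exclude the region itself and have the requested length
  for (r in seq_len(10)) {
    expect_false(r %in% atl$neighbors[[r]])
    expect_length(atl$neighbors[[r]], 4L)
  }

  # n_modules == n_regions forces singleton modules
  atl4 <- generate_atlas(4, n_modules = 4, k_neighbors = 2, seed = 2)
  expect_equal(sort(as.integer(table(atl4$module_labels))), rep(1L, 4))

  # determinism and subcortical clustering
  a1 <- generate_atlas(200, 5, subcortical_fraction = 0.1, seed = 9)
  a2 <- generate_atlas(200, 5, subcortical_fraction = 0.1, seed = 9)
  expect_identical(a1, a2)
  expect_equal(sum(!a1$is_cortical), 20L)

  expect_error(generate_atlas(0), "n_regions")
  expect_error(generate_atlas(10, k_neighbors = 10), "k_neighbors")
  expect_error(generate_atlas(10, n_modules = 11), "n_modules")
})

test_that("connectome generator plants the requested structure", {
  # homogeneous case: one module, no gradients, no noise
  atl1 <- generate_atlas(12, n_modules = 1, seed = 3)
  C1 <- generate_connectome(atl1, n_gradients = 0, within_module_weight = 0.5,
                            noise_sd = 0, target_negative_fraction = NULL,
                            seed = 1)
  off <- C1$weights[upper.tri(C1$weights)]
  expect_true(all(off == 0.5))
  expect_equal(map_values(connectome_degree(C1)), rep(5.5, 12))

  # planted 2-block sign structure at zero noise
  atl2 <- generate_atlas(20, n_modules = 2, seed = 4)
  C2 <- generate_connectome(atl2, n_gradients = 0, within_module_weight = 0.4,
                            between_module_weight = -0.3, noise_sd = 0,
                            target_negative_fraction = NULL, seed = 1)
  lab <- atl2$module_labels
  expect_true(all(C2$weights[lab == 1, lab == 2] < 0))
  W_in <- C2$weights[lab == 1, lab == 1]
  expect_true(all(W_in[upper.tri(W_in)] > 0))

  # symmetry exact, zero diagonal, determinism
  C <- conn200()
  expect_identical(C$weights, t(C$weights))
  expect_true(all(diag(C$weights) == 0))
  C_again <- generate_connectome(atlas200(), seed = 11)
  expect_identical(C$weights, C_again$weights)

  # negative-fraction tuning hits the target band
  expect_true(abs(anticorrelation_fraction(C) - 0.47) <= 0.05)

  # unreachable target errors with the achieved range
  expect_error(
    generate_connectome(atl1, n_gradients = 0, within_module_weight = 0.5,
                        noise_sd = 0, target_negative_fraction = 0.47),
    "cannot reach target"
  )
})

test_that("subject sets have the right mean and homogeneous edge variance", {
  atl <- generate_atlas(60, 4, seed = 5)
  C <- generate_connectome(atl, seed = 5)
  H <- generate_subject_set(C, n_subjects = 1000, edge_sd = 0.1, seed = 6)

  mean_mat <- Reduce(`+`, H$matrices) / H$n_subjects
  ut <- upper.tri(mean_mat)
  expect_gt(cor(mean_mat[ut], C$weights[ut]), 0.99)
  expect_true(all(vapply(H$matrices, function(m) all(diag(m) == 0), logical(1))))

  # per-edge sample sd approximately uniform at the nominal level
  stack <- vapply(H$matrices, function(m) m[ut][1:500], numeric(500))
  sds <- apply(stack, 1, sd)
  expect_lt(max(sds) / min(sds), 1.3)
  expect_true(abs(mean(sds) - 0.1) < 0.01)

  H2 <- generate_subject_set(C, n_subjects = 5, edge_sd = 0.1, seed = 6)
  H3 <- generate_subject_set(C, n_subjects = 5, edge_sd = 0.1, seed = 6)
  expect_identical(H2$matrices, H3$matrices)

  expect_error(generate_subject_set(C, 10, edge_sd = 0), "edge_sd")
  expect_error(generate_subject_set(C, 1, edge_sd = 0.1), "n_subjects")
})

test_that("random lesions are uniform anchors with fixed dilation", {
  atl <- atlas200()
  les <- generate_random_lesions(atl, 25, dilation = 4, seed = 1)
  expect_true(all(lengths(les$region_lists) == 5L))
  expect_true(all(abs(rowSums(les$rows) - 1) < 1e-12))
  expect_true(all(les$rows[les$rows > 0] == 0.2))

  les0 <- generate_random_lesions(atl, 1, dilation = 0, seed = 2)
  expect_equal(sum(les0$rows != 0), 1L)
  expect_equal(max(les0$rows), 1)

  # anchors uniform over regions (chi-square goodness of fit)
  atl50 <- generate_atlas(50, 4, seed = 6)
  anchors <- unlist(generate_random_lesions(atl50, 10000, dilation = 0,
                                            seed = 3)$region_lists)
  p <- chisq.test(tabulate(anchors, 50))$p.value
  expect_gt(p, 0.001)

  expect_error(generate_random_lesions(atl, 5, dilation = 99), "dilation")
})

test_that("overlap parameter q interpolates between uniform and identical", {
  atl <- atlas200()

  # q = 0 reduces to the uniform scheme (two-sample chi-square on anchors)
  a_unif <- unlist(generate_random_lesions(atl, 10000, dilation = 0,
                                           seed = 4)$region_lists)
  a_q0 <- unlist(generate_overlapping_lesions(atl, 10000, q = 0, dilation = 0,
                                              seed = 5)$region_lists)
  tab <- rbind(tabulate(a_unif, 200), tabulate(a_q0, 200))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.001)

  # q -> Inf concentrates every lesion on the first anchor
  les_inf <- generate_overlapping_lesions(atl, 50, q = 1e9, dilation = 0,
                                          seed = 6)
  expect_length(unique(les_inf$region_lists), 1L)
  expect_equal(dice_average(les_inf), 1)

  # average pairwise Dice is monotone non-decreasing in q
  qs <- c(0, 10, 50, 200, 1000)
  mean_dice <- vapply(seq_along(qs), function(i) {
    mean(vapply(seq_len(500), function(s) {
      dice_average(generate_overlapping_lesions(
        atl, 10, q = qs[i], dilation = 0,
        seed = derive_seed(7, "dice", i * 1000L + s)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dice) >= 0))

  expect_error(generate_overlapping_lesions(atl, 5, q = -1), "q")
})

test_that("symptom generation is standardized and recovers planted coupling", {
  atl <- atlas200()
  C <- conn200()
  M <- generate_random_lesions(atl, 100, dilation = 0, seed = 8)

  sv <- generate_symptoms(M, mode = "random", seed = 1)
  expect_lt(abs(mean(sv)), 1e-12)
  expect_equal(sd(sv), 1, tolerance = 1e-12)

  # noiseless map-coupled symptoms let sLNM recover the target direction
  # (target along the connectome's leading gradient, a direction the lesion
  # sampling can actually express)
  target <- principal_components(C, 1)$maps[, 1]
  sv_c <- generate_symptoms(M, C, mode = "map_coupled", target_map = target,
                            effect_size = 1, noise_sd = 0, seed = 2)
  fit <- suppressMessages(slnm(M, C, sv_c))
  r <- map_values(fit)
  expect_gt(abs(cor(r[!is.na(r)], target[!is.na(r)])), 0.9)

  # degenerate constant scores are rejected
  expect_error(
    generate_symptoms(M, C, mode = "map_coupled",
                      target_map = rep(0, 200), noise_sd = 0, seed = 3),
    "constant"
  )
  expect_error(
    generate_symptoms(M, C, mode = "map_coupled", target_map = NULL),
    "target_map"
  )
})
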