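# Shared fixtures, built in code.

# 3-region toy connectome used for hand-verifiable arithmetic.
toy_c3 <- function() {
  as_connectome(matrix(c(0, 1, 2,
                         1, 0, -1,
                         2, -1, 0), 3, 3, byrow = TRUE))
}

# Cached default-structure atlas/connectome at the working scale so expensive
# fixtures are built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

atlas200 <- function() {
  if (is.null(.fixture_cache$atl200)) {
    .fixture_cache$atl200 <- generate_atlas(200, 4, subcortical_fraction = 0.1,
                                            seed = 11)
  }
  .fixture_cache$atl200
}

conn200 <- function() {
  if (is.null(.fixture_cache$c200)) {
    .fixture_cache$c200 <- generate_connectome(atlas200(), seed = 11)
  }
  .fixture_cache$c200
}

# All-cortical atlas/connectome for spin-based analyses.
atlas200c <- function() {
  if (is.null(.fixture_cache$atl200c)) {
    .fixture_cache$atl200c <- generate_atlas(200, 4, subcortical_fraction = 0,
                                             seed = 13)
  }
  .fixture_cache$atl200c
}

conn200c <- function() {
  if (is.null(.fixture_cache$c200c)) {
    .fixture_cache$c200c <- generate_connectome(atlas200c(), seed = 13)
  }
  .fixture_cache$c200c
}

# Subject set with *exactly* equal per-edge sample variance: a centered scalar
# sequence times a fixed +/-1 symmetric pattern, so every off-diagonal edge
# has identical sample sd across subjects and sample mean equal to C exactly.
equal_variance_subjects <- function(C, n_subjects = 24, eps_sd = 0.05,
                                    seed = 7) {
  R <- nrow(C$weights)
  mats <- with_seed(seed, {
    E <- matrix(0, R, R)
    ut <- upper.tri(E)
    E[ut] <- sample(c(-1, 1), sum(ut), replace = TRUE)
    E <- E + t(E)
    eps <- stats::rnorm(n_subjects, sd = eps_sd)
    eps <- eps - mean(eps)
    lapply(eps, function(e) {
      W <- C$weights + e * E
      diag(W) <- 0
      W
    })
  })
  structure(list(matrices = mats, n_subjects = n_subjects, edge_sd = eps_sd,
                 n_regions = R, seed = seed),
            class = "lnm_subject_set")
}

# Hand-built identity spin scheme (fixture for assignment semantics).
identity_spin <- function(n_regions, cortical = seq_len(n_regions)) {
  structure(list(assignment = matrix(seq_len(n_regions), 1, n_regions),
                 rotations = list(diag(3)), cortical = cortical,
                 n_perm = 1L, seed = 0L, n_regions = n_regions),
            class = "spin_perm")
}

skip_if_no_mclust <- function() {
  testthat::skip_if_not_installed("mclust")
}
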