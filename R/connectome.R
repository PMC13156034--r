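# Group connectome container and the structured synthetic generator.
#
# The generator plants the organisational features that shape real group
# functional connectomes: positive modular blocks, anticorrelated opposing
# blocks, a smooth low-rank gradient component tied to the atlas geometry
# (whose leading, globally positive pattern also induces hub structure), and
# symmetric edge noise. Weights are interpreted as signed Fisher-z values.

new_connectome <- function(weights, atlas = NULL, provenance = list()) {
  structure(
    list(weights = weights, atlas = atlas, provenance = provenance),
    class = "lnm_connectome"
  )
}

#' Wrap a symmetric matrix as a group connectome
#'
#' Validates symmetry (tolerance 1e-10), finiteness and a zero diagonal, and
#' attaches optional atlas geometry.
#'
#' @param weights square symmetric numeric matrix of signed Fisher-z weights.
#' @param atlas optional `lnm_atlas` with matching `n_regions`.
#' @param provenance optional list recording how the matrix was obtained.
#' @return An object of class `lnm_connectome`.
#' @export
as_connectome <- function(weights, atlas = NULL, provenance = list()) {
  weights <- as.matrix(weights)
  dimnames(weights) <- NULL
  if (nrow(weights) != ncol(weights)) {
    stop("connectome weights must be a square matrix", call. = FALSE)
  }
  if (any(!is.finite(weights))) {
    stop("connectome weights must all be finite", call. = FALSE)
  }
  if (max(abs(weights - t(weights))) > 1e-10) {
    stop("connectome weights must be symmetric (tolerance 1e-10)", call. = FALSE)
  }
  if (any(diag(weights) != 0)) {
    diag(weights) <- 0
  }
  if (!is.null(atlas) && atlas$n_regions != nrow(weights)) {
    stop("atlas and weight matrix disagree on the number of regions", call. = FALSE)
  }
  new_connectome(weights, atlas, provenance)
}

n_regions <- function(C) nrow(C$weights)

#' Generate a structured synthetic group connectome
#'
#' Builds a symmetric signed weight matrix as the sum of (a) a module block
#' term: `+within_module_weight` inside each planted module and
#' `between_module_weight` between designated opposing module blocks - by
#' default every pair of distinct modules opposes (`opposing = "all"`, the
#' regime where anticorrelation lives between networks), or modules can be
#' paired in label order 1-2, 3-4, ... (`opposing = "paired"`); (b) a
#' low-rank gradient term
#' `sum_k gradient_scales[k] * g_k g_k^T`, where the `g_k` are low-order
#' polynomials of the spherical centroid coordinates (the first carries a
#' positive offset, emulating the globally positive mean connectivity
#' component that ties the leading principal gradient to degree and creates
#' hubs); and (c) seeded symmetric Gaussian edge noise. The diagonal is zero.
#'
#' When `target_negative_fraction` is a number, `between_module_weight` is
#' ignored and retuned by bisection until the off-diagonal fraction of
#' negative weights lies within +/- 0.05 of the target (default 0.47, the
#' anticorrelated-edge fraction reported for empirical group connectomes);
#' generation fails with an informative error if the target is unreachable.
#' Set `target_negative_fraction = NULL` to use `between_module_weight`
#' literally (needed e.g. for fully homogeneous toy matrices).
#'
#' @param atlas an `lnm_atlas` with module labels.
#' @param n_gradients number of planted gradient patterns (1-3).
#' @param within_module_weight positive block weight inside modules.
#' @param between_module_weight block weight between opposing modules
#'   (typically negative); used as given only when
#'   `target_negative_fraction = NULL`.
#' @param gradient_scales numeric vector of length `n_gradients`, the weight
#'   of each rank-one gradient term.
#' @param noise_sd standard deviation of the symmetric Gaussian edge noise.
#' @param opposing which module pairs receive `between_module_weight`:
#'   `"all"` (every between-module pair) or `"paired"` (label order 1-2,
#'   3-4, ...).
#' @param target_negative_fraction desired off-diagonal negative-edge
#'   fraction (+/- 0.05), or `NULL` to disable tuning.
#' @param seed integer seed.
#' @return An `lnm_connectome`; `$provenance` records the planted gradients
#'   (`gradients`), module labels (`blocks`), opposing pairs, the tuned
#'   `between_module_weight` and the realized negative fraction.
#' @examples
#' atl <- generate_atlas(60, n_modules = 4, seed = 1)
#' C <- generate_connectome(atl, seed = 1)
#' C$provenance$negative_fraction
#' @export
generate_connectome <- function(atlas,
                                n_gradients = 3L,
                                within_module_weight = 0.2,
                                between_module_weight = -0.25,
                                gradient_scales = c(0.5, 0.3, 0.15),
                                noise_sd = 0.1,
                                opposing = c("all", "paired"),
                                target_negative_fraction = 0.47,
                                seed = 1L) {
  opposing <- match.arg(opposing)
  stopifnot(inherits(atlas, "lnm_atlas"))
  if (is.null(atlas$module_labels)) {
    stop("atlas must carry module labels", call. = FALSE)
  }
  n_gradients <- check_count(n_gradients, "n_gradients", min = 0L)
  if (length(gradient_scales) < n_gradients) {
    stop("`gradient_scales` must supply one scale per gradient", call. = FALSE)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)

  R <- atlas$n_regions
  labels <- atlas$module_labels
  mods <- sort(unique(labels))

  same <- outer(labels, labels, "==")
  if (opposing == "all") {
    # every distinct-module pair opposes
    pairs <- if (length(mods) >= 2) utils::combn(mods, 2, simplify = FALSE) else list()
    opp <- !same
  } else {
    # label-order pairing (1,2), (3,4), ...; an odd trailing module has no
    # opposing partner
    pairs <- if (length(mods) >= 2) {
      lapply(seq_len(length(mods) %/% 2), function(p) mods[c(2 * p - 1, 2 * p)])
    } else {
      list()
    }
    opp <- matrix(FALSE, R, R)
    for (pr in pairs) {
      a <- labels == pr[1]; b <- labels == pr[2]
      opp[a, b] <- TRUE
      opp[b, a] <- TRUE
    }
  }
  opposing <- opp

  # Gradient patterns: low-order polynomials of the spherical coordinates.
  xyz <- atlas$centroids
  G <- cbind(0.4 + xyz[, 3],            # global + principal axis -> hubs
             xyz[, 1],                  # second axis
             xyz[, 1] * xyz[, 2] * 2)   # smooth second-order pattern
  G <- G[, seq_len(n_gradients), drop = FALSE]

  base <- matrix(0, R, R)
  base[same] <- within_module_weight
  if (n_gradients > 0) {
    for (k in seq_len(n_gradients)) {
      base <- base + gradient_scales[k] * tcrossprod(G[, k])
    }
  }
  noise <- with_seed(seed, {
    N <- matrix(0, R, R)
    ut <- upper.tri(N)
    N[ut] <- stats::rnorm(sum(ut), sd = noise_sd)
    N + t(N)
  })
  base <- base + noise

  ut <- upper.tri(base)
  opp_ut <- opposing & ut
  neg_frac <- function(b) {
    W <- base
    W[opposing] <- W[opposing] + b
    mean(W[ut] < 0)
  }

  if (is.null(target_negative_fraction)) {
    b <- between_module_weight
  } else {
    target <- check_fraction(target_negative_fraction, "target_negative_fraction")
    # Saturating bracket: beyond +/- span every opposing edge has a fixed sign.
    span <- max(abs(base[ut])) + 1
    lo <- -span; hi <- span
    f_lo <- neg_frac(lo); f_hi <- neg_frac(hi)   # f is non-increasing in b
    if (!any(opp_ut) || target > f_lo + 0.05 || target < f_hi - 0.05) {
      stop(sprintf(paste0("cannot reach target negative fraction %.3f; ",
                          "achievable range is [%.3f, %.3f]"),
                   if (is.null(target_negative_fraction)) NA else target,
                   f_hi, f_lo), call. = FALSE)
    }
    b <- 0
    for (step in seq_len(50L)) {
      b <- (lo + hi) / 2
      f <- neg_frac(b)
      if (abs(f - target) <= 0.05) break
      if (f > target) lo <- b else hi <- b
    }
    f <- neg_frac(b)
    if (abs(f - target) > 0.05) {
      stop(sprintf("bisection failed after 50 steps: achieved negative fraction %.3f (target %.3f)",
                   f, target), call. = FALSE)
    }
  }

  W <- base
  W[opposing] <- W[opposing] + b
  diag(W) <- 0

  new_connectome(W, atlas, provenance = list(
    generator = "generate_connectome",
    gradients = G,
    gradient_scales = gradient_scales[seq_len(n_gradients)],
    blocks = labels,
    opposing_pairs = pairs,
    within_module_weight = within_module_weight,
    between_module_weight = b,
    noise_sd = noise_sd,
    negative_fraction = mean(W[ut] < 0),
    seed = seed
  ))
}

#' Generate per-subject connectomes around a group mean
#'
#' Each subject matrix is the group matrix plus symmetric i.i.d. Gaussian
#' noise with a single global standard deviation for every edge, encoding the
#' equal-variance-across-connections assumption under which the per-edge
#' one-sample t test is a monotone function of the group mean. Diagonals stay
#' zero.
#'
#' @param C group `lnm_connectome`.
#' @param n_subjects number of subjects (>= 2).
#' @param edge_sd per-edge noise standard deviation (> 0; a zero-variance set
#'   would break the one-sample t downstream).
#' @param seed integer seed.
#' @return An object of class `lnm_subject_set`: list with `matrices` (list
#'   of R x R matrices), `n_subjects`, `edge_sd`, `seed`.
#' @export
generate_subject_set <- function(C, n_subjects, edge_sd, seed = 1L) {
  stopifnot(inherits(C, "lnm_connectome"))
  n_subjects <- check_count(n_subjects, "n_subjects", min = 2L)
  if (!is.numeric(edge_sd) || length(edge_sd) != 1L || edge_sd <= 0) {
    stop("`edge_sd` must be a positive number", call. = FALSE)
  }
  R <- n_regions(C)
  ut <- upper.tri(matrix(0, R, R))
  mats <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(h) {
      N <- matrix(0, R, R)
      N[ut] <- stats::rnorm(sum(ut), sd = edge_sd)
      W <- C$weights + N + t(N)
      diag(W) <- 0
      W
    })
  })
  structure(
    list(matrices = mats, n_subjects = n_subjects, edge_sd = edge_sd,
         n_regions = R, seed = seed),
    class = "lnm_subject_set"
  )
}

#' @export
print.lnm_connectome <- function(x, ...) {
  R <- n_regions(x)
  ut <- upper.tri(x$weights)
  cat(sprintf("Group connectome: %d x %d signed weights\n", R, R))
  cat(sprintf("  negative edge fraction: %.3f | weight range: [%.3f, %.3f]\n",
              mean(x$weights[ut] < 0), min(x$weights), max(x$weights)))
  if (!is.null(x$provenance$generator)) {
    cat(sprintf("  provenance: %s (seed %s)\n", x$provenance$generator,
                format(x$provenance$seed %||% NA)))
  }
  invisible(x)
}

#' @export
print.lnm_subject_set <- function(x, ...) {
  cat(sprintf("Subject connectome set: %d subjects, %d regions, edge sd %.4g\n",
              x$n_subjects, x$n_regions, x$edge_sd))
  invisible(x)
}
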