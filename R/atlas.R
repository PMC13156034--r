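# Synthetic atlas geometry: quasi-uniform centroids on the unit sphere with
# contiguous module partitions and a spatially clustered subcortical subset.
# The sphere stands in for a cortical surface so that spin permutation is
# well-defined without real meshes.

new_atlas <- function(n_regions, centroids, is_cortical, neighbors,
                      module_labels = NULL, names = NULL) {
  structure(
    list(
      n_regions = as.integer(n_regions),
      centroids = centroids,
      is_cortical = is_cortical,
      neighbors = neighbors,
      module_labels = module_labels,
      region_names = names %||% sprintf("region_%03d", seq_len(n_regions))
    ),
    class = "lnm_atlas"
  )
}

#' Generate a synthetic atlas geometry
#'
#' Places `n_regions` centroids quasi-uniformly on the unit sphere (a
#' Fibonacci lattice perturbed by seeded jitter), partitions them into
#' `n_modules` spatially contiguous modules (Voronoi cells of farthest-point
#' module seeds), marks a spatially clustered subset as subcortical, and
#' records each region's `k_neighbors` nearest centroids. The result plays the
#' role of a parcellation (e.g. a combined cortical + subcortical atlas) in
#' all downstream analyses: lesion dilation uses the neighbor lists, spin
#' permutation uses the centroids, and the module labels are the planted
#' ground truth for community-recovery checks.
#'
#' @param n_regions number of regions R.
#' @param n_modules number of planted modules (<= `n_regions`).
#' @param subcortical_fraction fraction of regions flagged subcortical, in
#'   `[0, 1)`; subcortical regions form one spatial cluster and are excluded
#'   from spin rotation.
#' @param k_neighbors neighbors stored per region (< `n_regions`).
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @return An object of class `lnm_atlas` with fields `n_regions`,
#'   `centroids` (R x 3, unit norm), `is_cortical`, `neighbors` (list of
#'   integer vectors ordered by distance), `module_labels`, `region_names`.
#' @examples
#' atl <- generate_atlas(50, n_modules = 4, seed = 1)
#' table(atl$module_labels)
#' @export
generate_atlas <- function(n_regions, n_modules = 4L, subcortical_fraction = 0,
                           k_neighbors = 8L, seed = 1L) {
  n_regions <- check_count(n_regions, "n_regions")
  n_modules <- check_count(n_modules, "n_modules")
  check_fraction(subcortical_fraction, "subcortical_fraction", closed_upper = FALSE)
  k_neighbors <- check_count(k_neighbors, "k_neighbors")
  if (n_modules > n_regions) {
    stop("`n_modules` must not exceed `n_regions`", call. = FALSE)
  }
  if (k_neighbors >= n_regions) {
    stop("`k_neighbors` must be smaller than `n_regions`", call. = FALSE)
  }

  with_seed(seed, {
    # Fibonacci lattice on the sphere, then tangent jitter, renormalized.
    i <- seq_len(n_regions) - 0.5
    z <- 1 - 2 * i / n_regions
    phi <- (seq_len(n_regions) - 1) * pi * (3 - sqrt(5))
    rad <- sqrt(pmax(0, 1 - z^2))
    P <- cbind(cos(phi) * rad, sin(phi) * rad, z)
    P <- P + matrix(stats::rnorm(3 * n_regions, sd = 0.35 / sqrt(n_regions)),
                    ncol = 3)
    P <- P / sqrt(rowSums(P^2))
    colnames(P) <- c("x", "y", "z")

    # Farthest-point seeds -> Voronoi modules (spatially contiguous, each
    # non-empty because every seed is its own nearest seed).
    seeds <- integer(n_modules)
    seeds[1] <- sample.int(n_regions, 1L)
    if (n_modules > 1L) {
      d_min <- colSums((t(P) - P[seeds[1], ])^2)
      for (m in 2:n_modules) {
        seeds[m] <- which.max(d_min)
        d_min <- pmin(d_min, colSums((t(P) - P[seeds[m], ])^2))
      }
    }
    # Lloyd iterations balance the Voronoi cells while keeping them
    # spatially contiguous (cells of the module mean directions).
    centers <- P[seeds, , drop = FALSE]
    labels <- rep(1L, n_regions)
    for (it in seq_len(20L)) {
      D_seed <- vapply(seq_len(n_modules), function(m) {
        colSums((t(P) - centers[m, ])^2)
      }, numeric(n_regions))
      new_labels <- max.col(-D_seed, ties.method = "first")
      if (identical(new_labels, labels) && it > 1L) break
      labels <- new_labels
      for (m in seq_len(n_modules)) {
        if (any(labels == m)) {
          v <- colMeans(P[labels == m, , drop = FALSE])
          if (sum(v^2) > 0) centers[m, ] <- v / sqrt(sum(v^2))
        }
      }
    }
    # guard: a module emptied by Lloyd falls back to its seed region
    for (m in seq_len(n_modules)) {
      if (!any(labels == m)) labels[seeds[m]] <- m
    }

    # Subcortical: contiguous cluster around a random anchor.
    n_sub <- round(subcortical_fraction * n_regions)
    is_cortical <- rep(TRUE, n_regions)
    if (n_sub > 0) {
      anchor <- sample.int(n_regions, 1L)
      d_anchor <- colSums((t(P) - P[anchor, ])^2)
      is_cortical[order(d_anchor)[seq_len(n_sub)]] <- FALSE
    }

    D <- as.matrix(stats::dist(P))
    neighbors <- lapply(seq_len(n_regions), function(r) {
      order(D[r, ])[2:(k_neighbors + 1L)]
    })

    new_atlas(n_regions, P, is_cortical, neighbors, labels)
  })
}

#' @export
print.lnm_atlas <- function(x, ...) {
  cat(sprintf("Synthetic atlas geometry: %d regions (%d cortical, %d subcortical)\n",
              x$n_regions, sum(x$is_cortical), sum(!x$is_cortical)))
  if (!is.null(x$module_labels)) {
    cat("  modules:", paste(sprintf("%d (n=%d)",
                                    sort(unique(x$module_labels)),
                                    as.integer(table(x$module_labels))),
                            collapse = ", "), "\n")
  }
  cat(sprintf("  %d nearest neighbors stored per region\n",
              length(x$neighbors[[1]])))
  invisible(x)
}
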