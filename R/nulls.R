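# Null models: spin permutation of cortical maps and lesions, degree-
# preserving rewiring, full weight randomization, module-preserving lesion
# shuffles and mixed-pool lesion nulls.

#' Build a spin permutation scheme
#'
#' Draws `n_perm` uniformly random 3D rotations (QR decomposition of Gaussian
#' matrices, determinant +1) and, for each rotation, reassigns every cortical
#' region to the original region whose centroid is nearest to its rotated
#' position (duplicate targets are allowed, the standard nearest-centroid
#' convention). Subcortical regions are held out (identity assignment),
#' matching the practice of spinning cortical data only.
#'
#' @param atlas an `lnm_atlas` with at least 3 non-collinear cortical
#'   centroids.
#' @param n_perm number of rotations.
#' @param seed integer seed.
#' @return Object of class `spin_perm`: list with `assignment` (`n_perm` x R
#'   integer matrix; row p maps region i to source region `assignment[p, i]`),
#'   `rotations` (list of 3 x 3 matrices), `cortical` (indices), `n_perm`,
#'   `seed`.
#' @export
build_spin <- function(atlas, n_perm, seed = 1L) {
  stopifnot(inherits(atlas, "lnm_atlas"))
  n_perm <- check_count(n_perm, "n_perm")
  cort <- which(atlas$is_cortical)
  if (length(cort) < 3L) {
    stop("spin permutation needs at least 3 cortical regions", call. = FALSE)
  }
  P <- atlas$centroids[cort, , drop = FALSE]
  if (qr(scale(P, center = TRUE, scale = FALSE))$rank < 2L) {
    stop("cortical centroids are collinear; spin rotation is degenerate",
         call. = FALSE)
  }
  R <- atlas$n_regions
  rotations <- with_seed(seed, {
    lapply(seq_len(n_perm), function(p) {
      qrd <- qr(matrix(stats::rnorm(9), 3, 3))
      Q <- qr.Q(qrd) %*% diag(sign(diag(qr.R(qrd))))
      if (det(Q) < 0) Q[, 3] <- -Q[, 3]
      Q
    })
  })
  assignment <- matrix(rep(seq_len(R), each = n_perm), n_perm, R)
  for (p in seq_len(n_perm)) {
    rotated <- P %*% t(rotations[[p]])
    # nearest original centroid = max dot product on the unit sphere
    sim <- rotated %*% t(P)
    assignment[p, cort] <- cort[max.col(sim, ties.method = "first")]
  }
  structure(list(assignment = assignment, rotations = rotations,
                 cortical = cort, n_perm = n_perm, seed = seed,
                 n_regions = R),
            class = "spin_perm")
}

#' Apply one spin permutation to a lesion set
#'
#' Maps every lesioned region through the spin assignment of permutation
#' `perm_index`; regions that collide onto the same target have their weights
#' merged, so row sums stay exactly 1.
#'
#' @param M a `lesion_matrix` with all lesioned regions cortical.
#' @param spin a `spin_perm` built on the same atlas.
#' @param perm_index which permutation to apply.
#' @return A `lesion_matrix`.
#' @export
spin_lesions <- function(M, spin, perm_index) {
  stopifnot(inherits(M, "lesion_matrix"), inherits(spin, "spin_perm"))
  perm_index <- check_count(perm_index, "perm_index")
  if (perm_index > spin$n_perm) stop("`perm_index` out of range", call. = FALSE)
  if (M$n_regions != spin$n_regions) {
    stop("lesion matrix and spin scheme disagree on the number of regions",
         call. = FALSE)
  }
  a <- spin$assignment[perm_index, ]
  non_cort <- setdiff(seq_len(M$n_regions), spin$cortical)
  S <- M$n_lesions
  rows <- matrix(0, S, M$n_regions)
  lists <- vector("list", S)
  for (s in seq_len(S)) {
    regs <- M$region_lists[[s]]
    if (any(regs %in% non_cort)) {
      stop(sprintf("lesion %d includes subcortical regions; spinning is defined for cortical lesions only", s),
           call. = FALSE)
    }
    mapped <- a[regs]
    w <- M$rows[s, regs]
    for (j in seq_along(mapped)) {
      rows[s, mapped[j]] <- rows[s, mapped[j]] + w[j]
    }
    lists[[s]] <- sort(unique(mapped))
  }
  new_lesion_matrix(rows, lists)
}

#' Spin-permutation p value for the correlation of two maps
#'
#' Observed statistic: Pearson correlation of the two maps over cortical
#' regions. Null distribution: the first map is spun through each stored
#' rotation and re-correlated with the fixed second map. The two-sided p
#' value uses the +1 convention, `p = (1 + #{|r_null| >= |r_obs|}) /
#' (n_perm + 1)`, so it is never zero.
#'
#' @param map_a,map_b `brain_map`s, `lnm` fits or numeric vectors of length R.
#' @param spin a `spin_perm`.
#' @return Object of class `spin_test`: list with `r_observed`, `p_spin`,
#'   `r_null` (length `n_perm`), `n_perm`.
#' @export
spin_pvalue <- function(map_a, map_b, spin) {
  stopifnot(inherits(spin, "spin_perm"))
  a <- map_values(map_a); b <- map_values(map_b)
  if (length(a) != spin$n_regions || length(b) != spin$n_regions) {
    stop("maps and spin scheme disagree on the number of regions", call. = FALSE)
  }
  cort <- spin$cortical
  av <- a[cort]; bv <- b[cort]
  if (anyNA(av) || anyNA(bv)) {
    keep <- is.finite(av) & is.finite(bv)
    av <- av[keep]; bv <- bv[keep]
  }
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) {
    stop("correlation undefined: constant cortical map", call. = FALSE)
  }
  r_obs <- safe_cor(a[cort], b[cort])
  r_null <- vapply(seq_len(spin$n_perm), function(p) {
    spun <- a[spin$assignment[p, ]]
    stats::cor(spun[cort], b[cort], use = "pairwise.complete.obs")
  }, numeric(1))
  p <- (1 + sum(abs(r_null) >= abs(r_obs), na.rm = TRUE)) / (spin$n_perm + 1)
  structure(list(r_observed = r_obs, p_spin = p, r_null = r_null,
                 n_perm = spin$n_perm),
            class = "spin_test")
}

#' @export
print.spin_test <- function(x, ...) {
  cat(sprintf("Spin test: r = %.4f, p_spin = %.4g (%d permutations)\n",
              x$r_observed, x$p_spin, x$n_perm))
  invisible(x)
}

#' Degree-preserving rewiring of a binarized connectome
#'
#' Binarizes the weight matrix at `weights > r_threshold` and randomizes the
#' resulting graph with Maslov-Sneppen double-edge swaps
#' (`igraph::rewire(keeping_degseq())`, `swaps_per_edge` x edge-count
#' attempts), which preserve every node's binary degree exactly. If no swap
#' is possible the input binarization is returned with a warning.
#'
#' @param C an `lnm_connectome`.
#' @param r_threshold binarization threshold (default 0.2).
#' @param swaps_per_edge swap attempts per edge (default 10).
#' @param seed integer seed.
#' @return An `lnm_connectome` with binary weights.
#' @export
rewire_preserving_degree <- function(C, r_threshold = 0.2, swaps_per_edge = 10L,
                                     seed = 1L) {
  stopifnot(inherits(C, "lnm_connectome"))
  swaps_per_edge <- check_count(swaps_per_edge, "swaps_per_edge")
  A <- (C$weights > r_threshold) * 1
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", diag = FALSE)
  ne <- igraph::ecount(g)
  if (ne < 2L) {
    warning("fewer than 2 edges after binarization; returning the unrewired graph",
            call. = FALSE)
    return(new_connectome(A, C$atlas,
                          provenance = list(generator = "rewire_preserving_degree",
                                            r_threshold = r_threshold, swaps = 0L,
                                            seed = seed)))
  }
  g2 <- with_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(niter = swaps_per_edge * ne)))
  A2 <- as.matrix(igraph::as_adjacency_matrix(g2, sparse = FALSE))
  dimnames(A2) <- NULL
  if (identical(A2, A)) {
    warning("rewiring left the graph unchanged (no legal swap found)",
            call. = FALSE)
  }
  new_connectome(A2, C$atlas,
                 provenance = list(generator = "rewire_preserving_degree",
                                   r_threshold = r_threshold,
                                   swaps_per_edge = swaps_per_edge,
                                   seed = seed))
}

#' Full degree-disrupting randomization of a connectome
#'
#' Permutes the off-diagonal upper-triangle weights uniformly at random and
#' mirrors them, conserving the weight multiset exactly while destroying the
#' degree sequence.
#'
#' @param C an `lnm_connectome`.
#' @param seed integer seed.
#' @return An `lnm_connectome`.
#' @export
randomize_full <- function(C, seed = 1L) {
  stopifnot(inherits(C, "lnm_connectome"))
  W <- C$weights
  ut <- upper.tri(W)
  W[ut] <- with_seed(seed, sample(W[ut]))
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  diag(W) <- 0
  new_connectome(W, C$atlas,
                 provenance = list(generator = "randomize_full", seed = seed))
}

#' Shuffle lesions while preserving modular prevalence
#'
#' Replaces each lesioned region by a uniformly drawn region from the same
#' module (without replacement within a lesion, so lesion sizes and the
#' module histogram of lesioned regions are preserved exactly). A region that
#' is the sole member of its module is kept with a message.
#'
#' @param M a `lesion_matrix`.
#' @param module_labels integer module label per region.
#' @param seed integer seed.
#' @return A `lesion_matrix`.
#' @export
shuffle_lesions_preserving_modules <- function(M, module_labels, seed = 1L) {
  stopifnot(inherits(M, "lesion_matrix"))
  if (length(module_labels) != M$n_regions) {
    stop("`module_labels` must label every region", call. = FALSE)
  }
  pools <- split(seq_len(M$n_regions), module_labels)
  sets <- with_seed(seed, {
    lapply(M$region_lists, function(regs) {
      by_mod <- split(regs, module_labels[regs])
      out <- unlist(lapply(names(by_mod), function(m) {
        pool <- pools[[m]]
        need <- length(by_mod[[m]])
        if (length(pool) == 1L) {
          message(sprintf("module %s has a single region; lesion kept in place", m))
          pool
        } else {
          pool[sample.int(length(pool), need)]
        }
      }), use.names = FALSE)
      sort(out)
    })
  })
  build_lesion_matrix(sets, M$n_regions)
}

#' Draw a mixed-pool lesion null set
#'
#' Samples `n_draw` lesions without replacement from the pooled rows of one
#' or more lesion sets, emulating a null built from lesions with mixed
#' symptomatology.
#'
#' @param lesion_pool a `lesion_matrix` or list of them.
#' @param n_draw number of lesions to draw.
#' @param seed integer seed.
#' @return A `lesion_matrix`.
#' @export
mixed_lesion_null <- function(lesion_pool, n_draw, seed = 1L) {
  if (inherits(lesion_pool, "lesion_matrix")) lesion_pool <- list(lesion_pool)
  stopifnot(all(vapply(lesion_pool, inherits, logical(1), "lesion_matrix")))
  n_draw <- check_count(n_draw, "n_draw")
  R <- unique(vapply(lesion_pool, function(m) m$n_regions, integer(1)))
  if (length(R) != 1L) {
    stop("all pooled lesion sets must share the same atlas", call. = FALSE)
  }
  all_sets <- unlist(lapply(lesion_pool, function(m) m$region_lists),
                     recursive = FALSE)
  if (length(all_sets) < n_draw) {
    stop("lesion pool smaller than `n_draw`", call. = FALSE)
  }
  picked <- with_seed(seed, sample.int(length(all_sets), n_draw))
  build_lesion_matrix(all_sets[picked], R)
}
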