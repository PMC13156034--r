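# Elementary properties of a group connectome: the quantities that LNM
# outputs provably or empirically converge onto.

#' Degree (row-summation) vector of a connectome
#'
#' Signed row sums of the unthresholded weight matrix. This is the elementary
#' property that lesion network maps converge to: with the identity lesion
#' matrix, the compressed LNM map equals this vector exactly.
#'
#' @param C an `lnm_connectome`.
#' @return A `brain_map` of kind `"degree"`.
#' @export
connectome_degree <- function(C) {
  stopifnot(inherits(C, "lnm_connectome"))
  brain_map(rowSums(C$weights), "degree")
}

#' Principal components (functional gradients) of a connectome
#'
#' Column-centered, unscaled PCA of the weight matrix. Components are unit
#' norm with a deterministic sign convention (the entry of largest absolute
#' loading is positive). The leading components play the role of functional
#' connectivity gradients; the first typically overlaps strongly with degree.
#'
#' @param C an `lnm_connectome`.
#' @param k number of components (<= R).
#' @return List with `maps` (R x k matrix of unit-norm components) and
#'   `explained` (fractions of variance, non-increasing).
#' @export
principal_components <- function(C, k = 3L) {
  stopifnot(inherits(C, "lnm_connectome"))
  k <- check_count(k, "k")
  R <- n_regions(C)
  if (k > R) stop("`k` must not exceed the number of regions", call. = FALSE)
  p <- stats::prcomp(C$weights, center = TRUE, scale. = FALSE)
  maps <- p$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(maps[, j]))
    if (maps[i, j] < 0) maps[, j] <- -maps[, j]
  }
  dimnames(maps) <- list(NULL, paste0("pc", seq_len(k)))
  list(maps = maps, explained = (p$sdev^2 / sum(p$sdev^2))[seq_len(k)])
}

# Kernighan-Lin style refinement of a weighted modularity partition: sweep
# nodes, moving each to the community with the largest positive modularity
# gain, until a sweep makes no move. Complements the spectral split, as in
# Newman's original description of the leading-eigenvector method.
refine_modularity <- function(W, labels, max_sweeps = 20L) {
  k <- rowSums(W)
  two_m <- sum(k)
  if (two_m == 0) return(labels)
  for (sweep in seq_len(max_sweeps)) {
    moved <- FALSE
    for (i in seq_len(nrow(W))) {
      comms <- unique(labels)
      # modularity gain of assigning node i to community c (self-terms cancel)
      gain <- vapply(comms, function(c) {
        members <- labels == c
        members[i] <- FALSE
        sum(W[i, members]) - k[i] * sum(k[members]) / two_m
      }, numeric(1))
      best <- comms[which.max(gain)]
      if (best != labels[i] && max(gain) > gain[comms == labels[i]] + 1e-12) {
        labels[i] <- best
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  labels
}

#' Detect functional modules by Newman modularity maximization
#'
#' Runs Newman's leading-eigenvector modularity algorithm on the positive
#' part of the weight matrix (negative weights are zeroed for community
#' detection, the standard convention for signed functional connectivity),
#' followed by the Kernighan-Lin style node-sweep refinement that is part of
#' Newman's spectral method. If more communities than `n_modules_target` are
#' found, the smallest is repeatedly merged into the community it is most
#' strongly connected to (highest mean positive weight) until the target
#' count remains, and the refinement is re-run.
#'
#' @param C an `lnm_connectome`.
#' @param n_modules_target desired number of modules (<= R).
#' @param seed integer seed (the spectral method is deterministic; the seed
#'   guards the fallback greedy path).
#' @return Integer vector of module labels in `1..n_modules`.
#' @export
detect_modules <- function(C, n_modules_target = 4L, seed = 1L) {
  stopifnot(inherits(C, "lnm_connectome"))
  n_modules_target <- check_count(n_modules_target, "n_modules_target")
  R <- n_regions(C)
  if (n_modules_target > R) {
    stop("`n_modules_target` must not exceed the number of regions", call. = FALSE)
  }
  W <- pmax(C$weights, 0)
  diag(W) <- 0
  if (all(W == 0)) {
    stop("no positive structure: all weights are non-positive", call. = FALSE)
  }
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  merge_to_target <- function(labels) {
    while (length(unique(labels)) > n_modules_target) {
      tab <- table(labels)
      small <- as.integer(names(tab)[which.min(tab)])
      others <- setdiff(unique(labels), small)
      mean_conn <- vapply(others, function(o) {
        mean(W[labels == small, labels == o, drop = FALSE])
      }, numeric(1))
      labels[labels == small] <- others[which.max(mean_conn)]
    }
    labels
  }
  modularity_q <- function(labels) {
    igraph::modularity(g, labels, weights = igraph::E(g)$weight)
  }
  # Spectral splitting can stall in a local optimum; evaluate the standard
  # modularity maximizers, each followed by the merge and fine-tuning steps,
  # and keep the partition with the highest Q.
  labels <- with_seed(seed, {
    cands <- list(
      tryCatch(igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight),
               error = function(e) NULL),
      tryCatch(igraph::cluster_fast_greedy(g, weights = igraph::E(g)$weight),
               error = function(e) NULL),
      tryCatch(igraph::cluster_louvain(g, weights = igraph::E(g)$weight),
               error = function(e) NULL)
    )
    cands <- Filter(Negate(is.null), cands)
    if (length(cands) == 0L) stop("community detection failed", call. = FALSE)
    parts <- lapply(cands, function(cl) {
      refine_modularity(W, merge_to_target(
        refine_modularity(W, as.integer(igraph::membership(cl)))))
    })
    parts[[which.max(vapply(parts, modularity_q, numeric(1)))]]
  })
  as.integer(factor(labels))
}

#' Fraction of anticorrelated (negative) edges
#'
#' @param C an `lnm_connectome`.
#' @return Fraction of strictly negative off-diagonal upper-triangle weights.
#' @export
anticorrelation_fraction <- function(C) {
  stopifnot(inherits(C, "lnm_connectome"))
  w <- C$weights[upper.tri(C$weights)]
  mean(w < 0)
}

#' Sum of a row-induced subgraph
#'
#' Element-wise sum over the selected rows of the weight matrix: the limit a
#' lesion network map converges to when all lesions fall into the given
#' regions. Selecting all regions reproduces the degree vector.
#'
#' @param C an `lnm_connectome`.
#' @param regions non-empty vector of region indices.
#' @return A `brain_map` of kind `"other"` (`"degree"`-equivalent when all
#'   rows are selected).
#' @export
row_subgraph_sum <- function(C, regions) {
  stopifnot(inherits(C, "lnm_connectome"))
  regions <- as.integer(regions)
  if (length(regions) == 0L) stop("`regions` must be non-empty", call. = FALSE)
  if (any(regions < 1L | regions > n_regions(C))) {
    stop("region indices out of range", call. = FALSE)
  }
  brain_map(colSums(C$weights[regions, , drop = FALSE]), "other",
            regions = regions)
}

#' Build the nine-factor elementary-property design matrix
#'
#' Columns: mean connectivity of each region to (1) subcortical regions and
#' (2) cortical regions (or the whole brain when `whole_brain = TRUE`, in
#' which case the column equals degree/(R-1) exactly); (3-6) mean
#' connectivity to each of the four modules; (7-9) the first three principal
#' components of the weight matrix. Self-connections are excluded from every
#' mean. These nine regressors summarize the elementary organization of the
#' connectome; regressing any lesion network map on them measures how much
#' of the map is generic connectome structure.
#'
#' @param C an `lnm_connectome`.
#' @param atlas an `lnm_atlas` with cortical/subcortical flags.
#' @param module_labels integer labels with exactly 4 distinct values;
#'   defaults to `detect_modules(C, 4)`.
#' @param whole_brain replace the cortical-mean column by the whole-brain
#'   mean.
#' @return Object of class `elementary_factors`: list with `design` (R x 9
#'   named matrix) and `column_names`.
#' @export
build_elementary_factors <- function(C, atlas, module_labels = NULL,
                                     whole_brain = FALSE) {
  stopifnot(inherits(C, "lnm_connectome"), inherits(atlas, "lnm_atlas"))
  R <- n_regions(C)
  if (atlas$n_regions != R) {
    stop("atlas and connectome disagree on the number of regions", call. = FALSE)
  }
  if (!any(!atlas$is_cortical)) {
    stop("configuration error: atlas has no subcortical regions, so the subcortical-degree factor is undefined",
         call. = FALSE)
  }
  if (is.null(module_labels)) {
    module_labels <- atlas$module_labels
    if (is.null(module_labels)) {
      stop("no module labels available; supply `module_labels` or an atlas with modules",
           call. = FALSE)
    }
  }
  mods <- sort(unique(module_labels))
  if (length(mods) != 4L) {
    stop(sprintf("exactly 4 module labels are required (got %d); merge with detect_modules() first",
                 length(mods)), call. = FALSE)
  }

  W <- C$weights
  mean_to <- function(members) {
    cnt <- sum(members)
    tot <- as.vector(W %*% as.numeric(members))
    # exclude the self term for regions inside the target set (diag is zero,
    # but the denominator must not count the region itself)
    denom <- ifelse(members, cnt - 1L, cnt)
    if (any(denom == 0)) {
      stop("configuration error: a factor target set is too small", call. = FALSE)
    }
    tot / denom
  }

  sub_col <- mean_to(!atlas$is_cortical)
  cort_col <- if (whole_brain) rowSums(W) / (R - 1) else mean_to(atlas$is_cortical)
  mod_cols <- vapply(mods, function(m) mean_to(module_labels == m), numeric(R))
  pcs <- principal_components(C, 3L)$maps

  design <- cbind(sub_col, cort_col, mod_cols, pcs)
  colnames(design) <- c("subcortical_mean",
                        if (whole_brain) "whole_brain_mean" else "cortical_mean",
                        paste0("module", seq_len(4L), "_mean"),
                        paste0("pc", 1:3))
  const <- apply(design, 2, stats::sd) == 0
  if (any(const)) {
    stop(sprintf("constant factor column(s): %s",
                 paste(colnames(design)[const], collapse = ", ")), call. = FALSE)
  }
  structure(list(design = design, column_names = colnames(design)),
            class = "elementary_factors")
}

#' @export
print.elementary_factors <- function(x, ...) {
  cat(sprintf("Elementary-property design matrix: %d regions x %d factors\n",
              nrow(x$design), ncol(x$design)))
  cat("  columns:", paste(x$column_names, collapse = ", "), "\n")
  invisible(x)
}
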