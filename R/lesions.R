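# Lesion containers and generators.
#
# A lesion set is carried as an S x R row-normalized indicator matrix M: row s
# has weight 1/|m_s| on the regions lesioned in patient s and 0 elsewhere, so
# that m_s %*% C is the mean of the selected connectome rows. Region index
# lists are kept alongside for set-based measures such as Dice overlap.

new_lesion_matrix <- function(rows, region_lists) {
  structure(list(rows = rows, region_lists = region_lists,
                 n_lesions = nrow(rows), n_regions = ncol(rows)),
            class = "lesion_matrix")
}

#' Build a row-normalized lesion matrix from region index lists
#'
#' @param region_lists list of integer vectors; element s holds the atlas
#'   region indices (1-based) lesioned in patient s. Duplicates within a set
#'   are collapsed with a warning.
#' @param n_regions total number of atlas regions R.
#' @return A `lesion_matrix`: `rows` is S x R with row sums exactly 1,
#'   `region_lists` the cleaned index sets.
#' @examples
#' M <- build_lesion_matrix(list(1, c(1, 2)), n_regions = 3)
#' M$rows
#' @export
build_lesion_matrix <- function(region_lists, n_regions) {
  n_regions <- check_count(n_regions, "n_regions")
  if (!is.list(region_lists)) region_lists <- list(region_lists)
  cleaned <- lapply(seq_along(region_lists), function(s) {
    idx <- as.integer(region_lists[[s]])
    if (length(idx) == 0L) {
      stop(sprintf("lesion %d is empty", s), call. = FALSE)
    }
    if (any(idx < 1L | idx > n_regions)) {
      stop(sprintf("lesion %d contains region indices outside [1, %d]",
                   s, n_regions), call. = FALSE)
    }
    u <- unique(idx)
    if (length(u) < length(idx)) {
      warning(sprintf("lesion %d: duplicate region indices collapsed", s),
              call. = FALSE)
    }
    u
  })
  S <- length(cleaned)
  rows <- matrix(0, S, n_regions)
  for (s in seq_len(S)) {
    rows[s, cleaned[[s]]] <- 1 / length(cleaned[[s]])
  }
  new_lesion_matrix(rows, cleaned)
}

# Shared anchor-to-lesion expansion: anchor plus its `dilation` nearest
# neighboring parcels.
dilate_anchor <- function(atlas, anchor, dilation) {
  if (dilation == 0L) return(anchor)
  c(anchor, atlas$neighbors[[anchor]][seq_len(dilation)])
}

#' Generate spatially random lesions
#'
#' Each lesion anchors at a region drawn uniformly with probability 1/R
#' (with replacement across lesions) and is dilated by including the anchor's
#' `dilation` closest neighboring parcels, so every lesion covers
#' `dilation + 1` regions. The default dilation of 4 mirrors the convention
#' of simulating parcel-level lesions as an anchor plus its four nearest
#' parcels.
#'
#' @param atlas an `lnm_atlas`.
#' @param n_lesions number of lesions S.
#' @param dilation number of nearest neighbors added to the anchor
#'   (0 <= dilation <= stored neighbors).
#' @param seed integer seed.
#' @return A `lesion_matrix`.
#' @export
generate_random_lesions <- function(atlas, n_lesions, dilation = 4L, seed = 1L) {
  stopifnot(inherits(atlas, "lnm_atlas"))
  n_lesions <- check_count(n_lesions, "n_lesions")
  dilation <- check_count(dilation, "dilation", min = 0L)
  if (dilation > length(atlas$neighbors[[1]])) {
    stop("`dilation` exceeds the number of stored neighbors", call. = FALSE)
  }
  anchors <- with_seed(seed, sample.int(atlas$n_regions, n_lesions, replace = TRUE))
  sets <- lapply(anchors, function(a) dilate_anchor(atlas, a, dilation))
  build_lesion_matrix(sets, atlas$n_regions)
}

#' Generate lesion sets with tunable spatial overlap
#'
#' The first lesion anchors uniformly (probability 1/R) at some region a.
#' Every further lesion anchors at a with probability `(1 + q) / (R + q)` and
#' at each other region with probability `1 / (R + q)`: a proper probability
#' distribution that reduces exactly to the uniform scheme at `q = 0` and
#' concentrates all lesions onto a as `q -> Inf`. Dilation is applied as in
#' [generate_random_lesions()], so `q` controls the expected pairwise Dice
#' overlap of the set.
#'
#' @param atlas an `lnm_atlas`.
#' @param n_lesions lesions per set (conventionally 50).
#' @param q non-negative overlap boost parameter.
#' @param dilation neighbors added to each anchor.
#' @param seed integer seed.
#' @return A `lesion_matrix`.
#' @export
generate_overlapping_lesions <- function(atlas, n_lesions, q, dilation = 4L,
                                         seed = 1L) {
  stopifnot(inherits(atlas, "lnm_atlas"))
  n_lesions <- check_count(n_lesions, "n_lesions")
  dilation <- check_count(dilation, "dilation", min = 0L)
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0) {
    stop("`q` must be a non-negative number", call. = FALSE)
  }
  if (dilation > length(atlas$neighbors[[1]])) {
    stop("`dilation` exceeds the number of stored neighbors", call. = FALSE)
  }
  R <- atlas$n_regions
  anchors <- with_seed(seed, {
    a1 <- sample.int(R, 1L)
    rest <- if (n_lesions > 1L) {
      prob <- rep(1 / (R + q), R)
      prob[a1] <- (1 + q) / (R + q)
      sample.int(R, n_lesions - 1L, replace = TRUE, prob = prob)
    } else {
      integer(0)
    }
    c(a1, rest)
  })
  sets <- lapply(anchors, function(a) dilate_anchor(atlas, a, dilation))
  build_lesion_matrix(sets, atlas$n_regions)
}

#' @export
print.lesion_matrix <- function(x, ...) {
  sizes <- lengths(x$region_lists)
  cat(sprintf("Lesion matrix: %d lesions x %d regions (lesion size %s)\n",
              x$n_lesions, x$n_regions,
              if (length(unique(sizes)) == 1L) unique(sizes)
              else sprintf("%d-%d", min(sizes), max(sizes))))
  invisible(x)
}
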