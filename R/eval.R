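# Diagnostic analyses: map comparison, convergence-to-degree curves, the
# nine-factor variance decomposition, and the sensitivity / specificity /
# conjunction test machinery with the lesion-overlap (Dice) sweep.

#' Pearson correlation between two brain maps
#'
#' Undefined (NA) entries are excluded pairwise; an optional region mask
#' restricts the comparison.
#'
#' @param map_a,map_b `brain_map`s, `lnm` fits or numeric vectors.
#' @param mask optional integer vector of region indices.
#' @return Pearson r.
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  a <- map_values(map_a); b <- map_values(map_b)
  if (length(a) != length(b)) stop("maps differ in length", call. = FALSE)
  if (!is.null(mask)) {
    a <- a[mask]; b <- b[mask]
  }
  safe_cor(a, b)
}

#' Convergence of random-lesion LNM maps to the degree vector
#'
#' For each lesion-set size, draws `n_runs` spatially random lesion sets,
#' computes the compressed LNM map, and correlates it with the degree vector
#' of the connectome. The resulting curve quantifies how quickly LNM output
#' collapses onto this elementary property as sets grow.
#'
#' @param C an `lnm_connectome`.
#' @param atlas the matching `lnm_atlas`.
#' @param set_sizes strictly increasing lesion counts.
#' @param n_runs random sets per size.
#' @param dilation lesion dilation (0 = single-region lesions).
#' @param seed integer seed.
#' @return Object of class `convergence_curve`: `summary` data frame (size,
#'   mean, sd, quartiles), `r` list of per-size correlation vectors.
#' @export
convergence_to_degree <- function(C, atlas, set_sizes = c(1, 5, 10, 25, 50),
                                  n_runs = 500L, dilation = 0L, seed = 1L) {
  stopifnot(inherits(C, "lnm_connectome"), inherits(atlas, "lnm_atlas"))
  set_sizes <- as.integer(set_sizes)
  if (any(set_sizes < 1L) || is.unsorted(set_sizes, strictly = TRUE)) {
    stop("`set_sizes` must be strictly increasing positive integers", call. = FALSE)
  }
  n_runs <- check_count(n_runs, "n_runs")
  deg <- map_values(connectome_degree(C))
  r <- lapply(seq_along(set_sizes), function(i) {
    n <- set_sizes[i]
    vapply(seq_len(n_runs), function(run) {
      les <- generate_random_lesions(atlas, n, dilation = dilation,
                                     seed = derive_seed(seed, "convergence",
                                                        i * 1000000L + run))
      stats::cor(colMeans(les$rows %*% C$weights), deg)
    }, numeric(1))
  })
  names(r) <- set_sizes
  summ <- data.frame(
    size = set_sizes,
    mean = vapply(r, mean, numeric(1)),
    sd = vapply(r, stats::sd, numeric(1)),
    q25 = vapply(r, function(x) unname(stats::quantile(x, 0.25)), numeric(1)),
    median = vapply(r, stats::median, numeric(1)),
    q75 = vapply(r, function(x) unname(stats::quantile(x, 0.75)), numeric(1))
  )
  structure(list(summary = summ, r = r, n_runs = n_runs, dilation = dilation,
                 seed = seed),
            class = "convergence_curve")
}

#' @export
print.convergence_curve <- function(x, ...) {
  cat(sprintf("Convergence to degree (%d runs per size, dilation %d):\n",
              x$n_runs, x$dilation))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.convergence_curve <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$size, s$mean, type = "b", ylim = range(c(s$q25, s$q75, s$mean)),
                 xlab = "lesion set size", ylab = "r(LNM map, degree)",
                 main = "Convergence of LNM maps to the degree vector", ...)
  graphics::arrows(s$size, s$q25, s$size, s$q75, angle = 90, code = 3,
                   length = 0.03, col = "grey40")
  invisible(x)
}

#' Degree trace of single-region lesion maps
#'
#' A single-region lesion copies one row of the connectome. This measures,
#' over all regions i, the fraction whose row correlates with the degree
#' vector beyond `|r| > r_cut` - the probability that even an extreme
#' single-seed analysis still reflects degree structure.
#'
#' @param C an `lnm_connectome` with R >= 3.
#' @param r_cut absolute correlation cutoff (default 0.3).
#' @return Fraction in `[0, 1]`.
#' @export
single_region_degree_trace <- function(C, r_cut = 0.3) {
  stopifnot(inherits(C, "lnm_connectome"))
  R <- n_regions(C)
  if (R < 3L) stop("need at least 3 regions", call. = FALSE)
  deg <- rowSums(C$weights)
  if (stats::sd(deg) == 0) {
    stop("correlation undefined: degree vector is constant", call. = FALSE)
  }
  r_rows <- vapply(seq_len(R), function(i) {
    x <- C$weights[i, ]
    if (stats::sd(x) == 0) return(0)
    stats::cor(x, deg)
  }, numeric(1))
  mean(abs(r_rows) > r_cut)
}

#' Regress a brain map on the nine elementary factors
#'
#' Ordinary least squares of the map on the nine-factor design plus an
#' intercept. The resulting R-squared measures how much of the map is
#' explained by generic connectome organization rather than anything
#' lesion-set specific.
#'
#' @param map `brain_map`, `lnm` fit or numeric vector defined on all R
#'   regions.
#' @param factors an `elementary_factors` object.
#' @return Object of class `factor_fit`: `r_squared`, `coefficients` (named,
#'   including intercept), `fitted`, `residuals`.
#' @export
factor_regression <- function(map, factors) {
  stopifnot(inherits(factors, "elementary_factors"))
  y <- map_values(map)
  X <- cbind(`(intercept)` = 1, factors$design)
  if (length(y) != nrow(X)) {
    stop("map length does not match the factor design", call. = FALSE)
  }
  if (anyNA(y)) stop("map must be defined on all regions", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("factor design is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stop("map is constant; R-squared undefined", call. = FALSE)
  structure(list(r_squared = 1 - rss / tss,
                 coefficients = fit$coefficients,
                 fitted = fit$fitted.values,
                 residuals = fit$residuals),
            class = "factor_fit")
}

#' @export
print.factor_fit <- function(x, ...) {
  cat(sprintf("Elementary-factor regression: R^2 = %.4f\n", x$r_squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Sensitivity (consistency) test over per-lesion t maps
#'
#' A region passes when at least a fraction `consistency_G` of lesions
#' exceed the sensitivity t threshold with a common sign; its value is the
#' signed passing fraction, 0 otherwise. Infinite t values (zero-variance
#' cells) count as passing any threshold.
#'
#' @param per_lesion_tmaps S x R matrix of t statistics (or list of maps).
#' @param settings an [lnm_settings()] bundle.
#' @return A `brain_map` of kind `"lnm"` with the group rule recorded.
#' @export
sensitivity_test <- function(per_lesion_tmaps, settings = lnm_settings()) {
  tm <- if (is.list(per_lesion_tmaps)) {
    do.call(rbind, lapply(per_lesion_tmaps, map_values))
  } else {
    as.matrix(per_lesion_tmaps)
  }
  thr <- settings$t_threshold_sensitivity
  G <- settings$consistency_G
  fpos <- colMeans(tm > thr)
  fneg <- colMeans(tm < -thr)
  val <- ifelse(fpos >= G & fpos >= fneg, fpos,
                ifelse(fneg >= G, -fneg, 0))
  brain_map(val, "lnm", threshold = thr,
            group_rule = sprintf("consistency G = %g", G))
}

#' Specificity test: target versus control per-lesion maps
#'
#' Per-region two-sample t statistic (pooled variance) contrasting the
#' per-lesion values of a target lesion set with those of a control (random)
#' set; entries with `|t|` at or below the specificity threshold are zeroed.
#' Zero pooled variance yields signed infinity with a warning.
#'
#' @param target_tmaps,control_tmaps S x R matrices (or lists of maps) of
#'   per-lesion values, >= 2 rows each.
#' @param settings an [lnm_settings()] bundle.
#' @return A `brain_map` of kind `"tmap"` with the threshold recorded.
#' @export
specificity_test <- function(target_tmaps, control_tmaps,
                             settings = lnm_settings()) {
  as_mat <- function(x) if (is.list(x)) do.call(rbind, lapply(x, map_values)) else as.matrix(x)
  A <- as_mat(target_tmaps); B <- as_mat(control_tmaps)
  if (nrow(A) < 2L || nrow(B) < 2L) {
    stop("both groups need at least 2 per-lesion maps", call. = FALSE)
  }
  if (ncol(A) != ncol(B)) stop("groups differ in the number of regions", call. = FALSE)
  n1 <- nrow(A); n2 <- nrow(B)
  m1 <- colMeans(A); m2 <- colMeans(B)
  v1 <- apply(A, 2, stats::var); v2 <- apply(B, 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  degen <- se == 0
  if (any(degen)) {
    t[degen] <- sign(m1[degen] - m2[degen]) * Inf
    t[degen & m1 == m2] <- 0
    warning(sprintf("%d regions had zero pooled variance; t set to signed infinity",
                    sum(degen)), call. = FALSE)
  }
  t[abs(t) <= settings$t_threshold_specificity] <- 0
  brain_map(t, "tmap", threshold = settings$t_threshold_specificity)
}

#' Conjunction of sensitivity and specificity maps
#'
#' Binary map marking regions where both inputs are nonzero. The attribute
#' `n_pass` records the count of passing regions and `significant` whether
#' it reaches `min_regions` (default 1, the weakest reproducible criterion
#' for a "significant group result").
#'
#' @param sens,spec `brain_map`s on the same atlas.
#' @param min_regions cluster-size criterion for flagging significance.
#' @return A binary `brain_map` of kind `"conjunction"`.
#' @export
conjunction <- function(sens, spec, min_regions = 1L) {
  a <- map_values(sens); b <- map_values(spec)
  if (length(a) != length(b)) stop("maps differ in length", call. = FALSE)
  bin <- as.numeric(a != 0 & b != 0 & !is.na(a) & !is.na(b))
  brain_map(bin, "conjunction", n_pass = sum(bin),
            significant = sum(bin) >= min_regions)
}

#' Average pairwise Dice overlap of a lesion set
#'
#' Mean over all lesion pairs of `2|A intersect B| / (|A| + |B|)` on the
#' region index sets: 0 for fully disjoint sets, 1 when all lesions are
#' identical.
#'
#' @param M a `lesion_matrix` with >= 2 lesions.
#' @return Average pairwise Dice coefficient.
#' @export
dice_average <- function(M) {
  stopifnot(inherits(M, "lesion_matrix"))
  sets <- M$region_lists
  S <- length(sets)
  if (S < 2L) stop("Dice overlap needs at least 2 lesions", call. = FALSE)
  tot <- 0
  for (i in seq_len(S - 1L)) {
    for (j in (i + 1L):S) {
      tot <- tot + 2 * length(intersect(sets[[i]], sets[[j]])) /
        (length(sets[[i]]) + length(sets[[j]]))
    }
  }
  tot / (S * (S - 1) / 2)
}

#' Conjunction-test sweep over lesion overlap
#'
#' Simulates the full conventional test battery as a function of lesion
#' overlap: for every overlap parameter q, `n_sets` lesion sets are drawn
#' ([generate_overlapping_lesions()]), per-lesion one-sample t maps are
#' computed against a normative subject set, the sensitivity (consistency)
#' and specificity (versus a matched random lesion set) maps are derived,
#' and the set is called significant when the conjunction map is non-empty.
#' Sets are then binned by their average pairwise Dice overlap and the
#' proportion of significant sets per bin is reported.
#'
#' @param C group `lnm_connectome` (used to synthesize subjects when
#'   `subjects` is NULL).
#' @param atlas the matching `lnm_atlas`.
#' @param q_grid overlap parameters to sweep.
#' @param n_sets lesion sets per q value.
#' @param lesions_per_set lesions per set (conventionally 50).
#' @param dilation lesion dilation (conventionally 4).
#' @param settings an [lnm_settings()] bundle.
#' @param subjects optional `lnm_subject_set`; otherwise synthesized from
#'   `C` with `n_subjects` and `edge_sd`.
#' @param n_subjects,edge_sd parameters of the synthesized subject set.
#' @param dice_breaks bin edges on average pairwise Dice (default width 0.04).
#' @param seed integer seed.
#' @return Object of class `conjunction_sweep`: `sets` data frame (q, dice,
#'   n_pass, significant), `bins` data frame (dice_lo, dice_hi, n_sets,
#'   prop_significant; empty bins omitted), plus the settings snapshot.
#' @export
conjunction_sweep <- function(C, atlas, q_grid, n_sets = 200L,
                              lesions_per_set = 50L, dilation = 4L,
                              settings = lnm_settings(), subjects = NULL,
                              n_subjects = 60L, edge_sd = 0.1,
                              dice_breaks = seq(0, 1, by = 0.04),
                              seed = 1L) {
  stopifnot(inherits(C, "lnm_connectome"), inherits(atlas, "lnm_atlas"))
  n_sets <- check_count(n_sets, "n_sets")
  if (is.null(subjects)) {
    subjects <- generate_subject_set(C, n_subjects, edge_sd,
                                     seed = derive_seed(seed, "sweep_subjects"))
  }
  rows <- vector("list", length(q_grid) * n_sets)
  k <- 0L
  for (qi in seq_along(q_grid)) {
    q <- q_grid[qi]
    for (set in seq_len(n_sets)) {
      k <- k + 1L
      s_target <- derive_seed(seed, "sweep_target", qi * 1000000L + set)
      s_control <- derive_seed(seed, "sweep_control", qi * 1000000L + set)
      les <- generate_overlapping_lesions(atlas, lesions_per_set, q = q,
                                          dilation = dilation, seed = s_target)
      ctrl <- generate_random_lesions(atlas, lesions_per_set,
                                      dilation = dilation, seed = s_control)
      tm <- lesion_tmaps(les, subjects)
      tmc <- lesion_tmaps(ctrl, subjects)
      sens <- sensitivity_test(tm, settings)
      spec <- specificity_test(tm, tmc, settings)
      conj <- conjunction(sens, spec)
      rows[[k]] <- data.frame(q = q, dice = dice_average(les),
                              n_pass = attr(conj, "n_pass"),
                              significant = attr(conj, "significant"))
    }
  }
  sets <- do.call(rbind, rows)
  bin <- cut(sets$dice, breaks = dice_breaks, include.lowest = TRUE,
             right = FALSE)
  agg <- lapply(split(sets, bin), function(d) {
    if (nrow(d) == 0L) return(NULL)
    data.frame(n_sets = nrow(d), prop_significant = mean(d$significant))
  })
  keep <- !vapply(agg, is.null, logical(1))
  lo <- dice_breaks[-length(dice_breaks)][keep]
  hi <- dice_breaks[-1][keep]
  bins <- cbind(data.frame(dice_lo = lo, dice_hi = hi),
                do.call(rbind, agg[keep]))
  rownames(bins) <- NULL
  structure(list(sets = sets, bins = bins, q_grid = q_grid,
                 settings = settings, n_sets = n_sets,
                 lesions_per_set = lesions_per_set, dilation = dilation,
                 seed = seed),
            class = "conjunction_sweep")
}

#' @export
print.conjunction_sweep <- function(x, ...) {
  cat(sprintf("Conjunction sweep: %d sets x %d q values (%d lesions/set, dilation %d)\n",
              x$n_sets, length(x$q_grid), x$lesions_per_set, x$dilation))
  print(x$bins, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.conjunction_sweep <- function(x, ...) {
  b <- x$bins
  mid <- (b$dice_lo + b$dice_hi) / 2
  graphics::plot(mid, b$prop_significant, type = "b", ylim = c(0, 1),
                 xlab = "average pairwise Dice overlap",
                 ylab = "proportion of significant sets",
                 main = "Conjunction test outcome vs lesion overlap", ...)
  invisible(x)
}
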