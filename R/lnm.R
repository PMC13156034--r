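# Core estimator: lesion network mapping in compressed (linear) and full
# (per-subject t-test) form, plus the symptom-weighted variant.
#
# The compressed form is the exact linear reduction of the conventional
# three-step pipeline in atlas space: precomputing lesion-to-region
# connectivity for every normative subject and replacing the per-edge
# one-sample t test by the group mean (valid under equal per-edge variance)
# turns the whole procedure into the matrix product M x C followed by a
# column aggregation over patients.

# --- brain maps -------------------------------------------------------------

#' Construct a brain map
#'
#' A brain map is a length-R numeric vector with provenance attributes:
#' `kind` (one of lnm, slnm, tmap, degree, factor, conjunction, other),
#' optional `threshold` and `group_rule`.
#'
#' @param values numeric vector of per-region values (NA marks regions where
#'   the quantity is undefined, e.g. zero-variance sLNM entries).
#' @param kind map kind label.
#' @param ... further attributes to record.
#' @return A numeric vector of class `brain_map`.
#' @export
brain_map <- function(values, kind = "other", ...) {
  kinds <- c("lnm", "slnm", "tmap", "degree", "factor", "conjunction", "other")
  kind <- match.arg(kind, kinds)
  x <- as.numeric(values)
  extra <- list(...)
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  attr(x, "kind") <- kind
  class(x) <- "brain_map"
  x
}

#' Extract plain numeric values from a map or map-like object
#' @param x a `brain_map`, an `lnm`/`slnm` fit, or a numeric vector.
#' @return numeric vector.
#' @export
map_values <- function(x) {
  if (inherits(x, "lnm")) x <- x$map
  out <- unclass(x)
  attributes(out) <- NULL
  out
}

#' @export
print.brain_map <- function(x, ...) {
  v <- map_values(x)
  cat(sprintf("Brain map (%s): %d regions", attr(x, "kind"), length(v)))
  if (!is.null(attr(x, "threshold"))) {
    cat(sprintf(", threshold %s", format(attr(x, "threshold"))))
  }
  cat(sprintf("\n  range [%.4g, %.4g], %d NA, %d nonzero\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)),
              sum(is.na(v)), sum(v != 0, na.rm = TRUE)))
  invisible(x)
}

# --- settings ---------------------------------------------------------------

#' Conventional LNM statistical settings
#'
#' Bundles the field's customary constants: the per-lesion one-sample t
#' threshold used for the sensitivity test (|t| > 7), the two-sample t
#' threshold of the specificity test (|t| > 10), and the consistency
#' criterion G (a region is retained when at least a fraction G of lesions
#' pass the threshold with a common sign; conventionally 75%).
#'
#' @param t_threshold_sensitivity one-sample t threshold (>= 0).
#' @param t_threshold_specificity two-sample t threshold (>= 0).
#' @param consistency_G consistency fraction in (0, 1].
#' @param aggregation group rule for the full pipeline: `"mean"` of the
#'   per-lesion maps or the `"consistency"` map.
#' @param keep_sign keep signed values when thresholding (otherwise +/- 1).
#' @param threshold_tmaps threshold per-lesion t maps before mean
#'   aggregation in the full pipeline.
#' @return A list of class `lnm_settings`.
#' @export
lnm_settings <- function(t_threshold_sensitivity = 7,
                         t_threshold_specificity = 10,
                         consistency_G = 0.75,
                         aggregation = c("mean", "consistency"),
                         keep_sign = TRUE,
                         threshold_tmaps = FALSE) {
  if (t_threshold_sensitivity < 0 || t_threshold_specificity < 0) {
    stop("t thresholds must be non-negative", call. = FALSE)
  }
  if (consistency_G <= 0 || consistency_G > 1) {
    stop("`consistency_G` must lie in (0, 1]", call. = FALSE)
  }
  structure(list(
    t_threshold_sensitivity = t_threshold_sensitivity,
    t_threshold_specificity = t_threshold_specificity,
    consistency_G = consistency_G,
    aggregation = match.arg(aggregation),
    keep_sign = isTRUE(keep_sign),
    threshold_tmaps = isTRUE(threshold_tmaps)
  ), class = "lnm_settings")
}

# --- per-lesion t maps ------------------------------------------------------

#' Per-lesion one-sample t maps across a normative subject set
#'
#' For each lesion s and subject h, the seed profile is `m_s %*% C_h`, the
#' lesion-weighted mean of the subject's connectome rows (values are treated
#' as already Fisher-z transformed). A one-sample t statistic against zero is
#' then computed per region across subjects. Regions with zero variance
#' across subjects yield signed infinity (zero mean gives 0) with a warning,
#' so that noise-free fixtures remain usable.
#'
#' @param M a `lesion_matrix`.
#' @param subjects an `lnm_subject_set`.
#' @return S x R matrix of t statistics.
#' @export
lesion_tmaps <- function(M, subjects) {
  stopifnot(inherits(M, "lesion_matrix"), inherits(subjects, "lnm_subject_set"))
  if (M$n_regions != subjects$n_regions) {
    stop("lesion matrix and subject set disagree on the number of regions",
         call. = FALSE)
  }
  H <- subjects$n_subjects
  if (H < 2L) stop("at least 2 subjects are required for a t test", call. = FALSE)
  S1 <- matrix(0, M$n_lesions, M$n_regions)
  S2 <- matrix(0, M$n_lesions, M$n_regions)
  for (h in seq_len(H)) {
    A <- M$rows %*% subjects$matrices[[h]]
    S1 <- S1 + A
    S2 <- S2 + A * A
  }
  m <- S1 / H
  v <- pmax(S2 - H * m * m, 0) / (H - 1)
  se <- sqrt(v / H)
  t <- m / se
  degen <- se == 0
  if (any(degen)) {
    t[degen] <- sign(m[degen]) * Inf
    t[degen & m == 0] <- 0
    warning(sprintf("%d lesion-region cells had zero variance across subjects; t set to signed infinity",
                    sum(degen)), call. = FALSE)
  }
  t
}

# --- the estimator ----------------------------------------------------------

new_lnm <- function(map, per_lesion, method, scale, settings, call,
                    kind = "lnm", extra = list()) {
  structure(c(list(
    map = map,
    per_lesion = per_lesion,
    method = method,
    scale = scale,
    settings = settings,
    n_lesions = nrow(per_lesion),
    n_regions = length(map_values(map)),
    call = call
  ), extra), class = if (kind == "slnm") c("slnm", "lnm") else "lnm")
}

#' Fit a lesion network map
#'
#' With only a group connectome, computes the compressed linear form: the
#' per-lesion maps are the rows of `M %*% C` and the group map is their
#' column-wise mean (or sum). With a subject set, runs the full pipeline:
#' per-lesion one-sample t maps across subjects ([lesion_tmaps()]),
#' optional thresholding at `settings$t_threshold_sensitivity`, and either
#' mean aggregation or the sign-consistency group rule. The two routes agree
#' (up to scale) as subject noise vanishes, which is the degeneracy the
#' package is built to audit.
#'
#' @param lesions a `lesion_matrix` or a list of region index vectors.
#' @param connectome a group `lnm_connectome` (compressed route; also used to
#'   resolve R when `lesions` is a list).
#' @param subjects optional `lnm_subject_set`; when supplied the full
#'   per-subject route is used and `connectome` is not needed.
#' @param settings an [lnm_settings()] bundle (full route only).
#' @param scale `"mean"` (default) or `"sum"` aggregation over patients;
#'   correlation-based diagnostics are invariant to this choice.
#' @return An object of class `lnm` with elements `map` (a `brain_map`),
#'   `per_lesion` (S x R matrix of per-lesion maps or t maps), `method`
#'   (`"compressed"` or `"full"`), `settings`, and the call. Methods:
#'   `print`, `summary`, `coef` (the map values), `plot`.
#' @examples
#' atl <- generate_atlas(40, seed = 1)
#' C <- generate_connectome(atl, seed = 1)
#' fit <- lnm(generate_random_lesions(atl, 10, dilation = 0, seed = 2), C)
#' coef(fit)[1:5]
#' @export
lnm <- function(lesions, connectome = NULL, subjects = NULL,
                settings = lnm_settings(), scale = c("mean", "sum")) {
  scale <- match.arg(scale)
  cl <- match.call()
  R <- if (!is.null(subjects)) subjects$n_regions
       else if (!is.null(connectome)) n_regions(connectome)
       else stop("supply a `connectome` or a `subjects` set", call. = FALSE)
  if (!inherits(lesions, "lesion_matrix")) {
    lesions <- build_lesion_matrix(lesions, R)
  }
  if (lesions$n_regions != R) {
    stop("lesion matrix has the wrong number of regions", call. = FALSE)
  }

  if (is.null(subjects)) {
    per <- lesions$rows %*% connectome$weights
    map <- if (scale == "mean") colMeans(per) else colSums(per)
    return(new_lnm(brain_map(map, "lnm", scale = scale, method = "compressed"),
                   per, "compressed", scale, settings, cl))
  }

  stopifnot(inherits(subjects, "lnm_subject_set"))
  tm <- lesion_tmaps(lesions, subjects)
  if (settings$aggregation == "consistency") {
    map <- sensitivity_test(tm, settings)
    return(new_lnm(map, tm, "full", scale, settings, cl))
  }
  agg_in <- if (settings$threshold_tmaps) {
    tt <- tm
    tt[abs(tt) <= settings$t_threshold_sensitivity] <- 0
    if (!settings$keep_sign) tt <- sign(tt)
    tt
  } else {
    tm
  }
  map <- if (scale == "mean") colMeans(agg_in) else colSums(agg_in)
  new_lnm(brain_map(map, "lnm", scale = scale, method = "full",
                    thresholded = settings$threshold_tmaps),
          tm, "full", scale, settings, cl)
}

#' Fit a symptom-weighted lesion network map
#'
#' Computes, at every region, the Pearson correlation across patients between
#' the per-lesion connectivity values (the columns of `M %*% C`) and the
#' standardized symptom scores. Regions whose per-lesion values have zero
#' variance get `NA` (recorded and excluded from downstream correlations).
#'
#' @param lesions a `lesion_matrix` or list of region index vectors (S >= 3).
#' @param connectome a group `lnm_connectome`.
#' @param symptoms numeric length-S symptom scores; standardized on the fly
#'   (with a notice) if not already.
#' @return An object of class `c("slnm", "lnm")`; `map` holds per-region
#'   correlation coefficients in `[-1, 1]`, `n_undefined` counts NA regions.
#' @export
slnm <- function(lesions, connectome, symptoms) {
  stopifnot(inherits(connectome, "lnm_connectome"))
  cl <- match.call()
  R <- n_regions(connectome)
  if (!inherits(lesions, "lesion_matrix")) {
    lesions <- build_lesion_matrix(lesions, R)
  }
  S <- lesions$n_lesions
  if (S < 3L) {
    stop("symptom-weighted LNM needs at least 3 patients", call. = FALSE)
  }
  sv <- as.numeric(symptoms)
  if (length(sv) != S) {
    stop("symptom vector length must match the number of lesions", call. = FALSE)
  }
  if (abs(mean(sv)) > 1e-12 || abs(stats::sd(sv) - 1) > 1e-12) {
    message("standardizing symptom scores (mean 0, unit sd)")
    sv <- standardize_symptoms(sv)
  }
  A <- lesions$rows %*% connectome$weights
  sds <- apply(A, 2, stats::sd)
  r <- rep(NA_real_, R)
  ok <- sds > 0
  if (any(ok)) r[ok] <- as.vector(stats::cor(A[, ok, drop = FALSE], sv))
  n_undef <- sum(!ok)
  if (n_undef > 0) {
    message(sprintf("%d regions have zero variance across lesions; sLNM undefined there",
                    n_undef))
  }
  new_lnm(brain_map(r, "slnm"), A, "compressed", "mean", lnm_settings(), cl,
          kind = "slnm", extra = list(symptoms = sv, n_undefined = n_undef))
}

#' Threshold a brain map
#'
#' Sets entries with `|value| <= threshold` to zero; surviving entries keep
#' their signed value (`keep_sign = TRUE`), are reduced to their sign, or are
#' binarized to 1 (`binarize = TRUE`, magnitude-only convention).
#'
#' @param map a `brain_map`, `lnm` fit, or numeric vector.
#' @param threshold non-negative threshold.
#' @param keep_sign keep signed values above threshold.
#' @param binarize with `keep_sign = FALSE`, drop the sign entirely.
#' @return A `brain_map` with the threshold recorded; attribute `all_zero`
#'   flags maps with no surviving entry.
#' @export
threshold_map <- function(map, threshold, keep_sign = TRUE, binarize = FALSE) {
  if (threshold < 0) stop("`threshold` must be non-negative", call. = FALSE)
  v <- map_values(map)
  kind <- if (inherits(map, "brain_map")) attr(map, "kind") else "other"
  out <- v
  out[abs(out) <= threshold] <- 0
  if (!keep_sign) out <- if (binarize) as.numeric(out != 0) else sign(out)
  brain_map(out, kind, threshold = threshold,
            all_zero = all(out == 0, na.rm = TRUE))
}

# --- methods ----------------------------------------------------------------

#' @export
print.lnm <- function(x, ...) {
  cat(sprintf("%s fit (%s route): %d lesions, %d regions\n",
              if (inherits(x, "slnm")) "Symptom-weighted LNM" else "LNM",
              x$method, x$n_lesions, x$n_regions))
  v <- map_values(x)
  cat(sprintf("  map range [%.4g, %.4g]\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.lnm <- function(object, ...) map_values(object)

#' @export
summary.lnm <- function(object, top = 5L, ...) {
  v <- map_values(object)
  ord <- order(abs(v), decreasing = TRUE)
  out <- list(
    method = object$method,
    n_lesions = object$n_lesions,
    n_regions = object$n_regions,
    kind = attr(object$map, "kind"),
    map_summary = summary(v),
    top_regions = data.frame(region = ord[seq_len(min(top, length(v)))],
                             value = v[ord[seq_len(min(top, length(v)))]])
  )
  class(out) <- "summary.lnm"
  out
}

#' @export
print.summary.lnm <- function(x, ...) {
  cat(sprintf("%s map over %d regions (%d lesions, %s route)\n",
              x$kind, x$n_regions, x$n_lesions, x$method))
  print(x$map_summary)
  cat("strongest regions:\n")
  print(x$top_regions, row.names = FALSE)
  invisible(x)
}

#' @export
plot.lnm <- function(x, ...) {
  v <- map_values(x)
  graphics::plot(seq_along(v), v, type = "h",
                 xlab = "region", ylab = "map value",
                 main = sprintf("%s map (%s route)",
                                attr(x$map, "kind"), x$method), ...)
  graphics::abline(h = 0, col = "grey60")
  invisible(x)
}
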