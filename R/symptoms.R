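# Symptom score generation and standardization for symptom-weighted LNM.

#' Standardize a symptom score vector
#'
#' Centers to mean 0 and scales to unit sample standard deviation; constant
#' vectors are rejected because the downstream per-region correlation is
#' undefined for them.
#'
#' @param scores numeric vector of raw scores.
#' @return Standardized numeric vector with attribute `standardized = TRUE`.
#' @export
standardize_symptoms <- function(scores) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores))) stop("symptom scores must be finite", call. = FALSE)
  s <- stats::sd(scores)
  if (length(scores) < 2L || s == 0) {
    stop("degenerate symptom vector: scores are constant", call. = FALSE)
  }
  out <- (scores - mean(scores)) / s
  attr(out, "standardized") <- TRUE
  out
}

#' Generate symptom scores for a lesion set
#'
#' In `"random"` mode, scores are seeded standard-normal draws, emulating
#' behavioral scores with no relation to lesion connectivity. In
#' `"map_coupled"` mode, the raw score of patient s is
#' `effect_size * (m_s x C) . target_map` plus Gaussian noise, i.e. linearly
#' coupled to the projection of the patient's lesion connectivity profile
#' onto a chosen target map; this mode exists for parameter-recovery checks
#' of the symptom-weighted variant. Output is always standardized.
#'
#' @param M a `lesion_matrix` (defines the number of patients S).
#' @param C a group `lnm_connectome` (used by `"map_coupled"`).
#' @param mode `"random"` or `"map_coupled"`.
#' @param target_map length-R numeric map (required for `"map_coupled"`).
#' @param effect_size linear coupling strength.
#' @param noise_sd standard deviation of additive score noise.
#' @param seed integer seed.
#' @return Standardized numeric vector of length S.
#' @export
generate_symptoms <- function(M, C = NULL,
                              mode = c("random", "map_coupled"),
                              target_map = NULL, effect_size = 1,
                              noise_sd = 0, seed = 1L) {
  stopifnot(inherits(M, "lesion_matrix"))
  mode <- match.arg(mode)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  S <- M$n_lesions
  raw <- with_seed(seed, {
    if (mode == "random") {
      stats::rnorm(S)
    } else {
      if (is.null(C) || !inherits(C, "lnm_connectome")) {
        stop("`map_coupled` mode requires a connectome", call. = FALSE)
      }
      if (is.null(target_map) || length(target_map) != n_regions(C)) {
        stop("`map_coupled` mode requires a length-R `target_map`", call. = FALSE)
      }
      signal <- as.vector(M$rows %*% C$weights %*% as.numeric(target_map))
      effect_size * signal + stats::rnorm(S, sd = noise_sd)
    }
  })
  standardize_symptoms(raw)
}
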