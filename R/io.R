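# On-disk formats and the end-to-end pipeline.
#
# Matrices and maps travel as TSV (full precision so equivalence checks stay
# meaningful); lesion sets as JSON or long-format TSV; configs and manifests
# as JSON. Region ids are 1-based both in R and on disk.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a group connectome as dense TSV
#'
#' The file is an R x R tab-separated numeric matrix with no header, written
#' at full precision. On reading, the matrix must be square and finite;
#' asymmetry up to 1e-6 is symmetrized (with a message reporting the maximum
#' discrepancy), larger asymmetry is an error; a nonzero diagonal is zeroed
#' with a notice.
#'
#' @param C an `lnm_connectome`.
#' @param path file path.
#' @param atlas optional `lnm_atlas` to attach on reading.
#' @return `read_connectome` returns an `lnm_connectome`;
#'   `write_connectome` returns `path` invisibly.
#' @export
write_connectome <- function(C, path) {
  stopifnot(inherits(C, "lnm_connectome"))
  out <- apply(C$weights, 1, function(row) paste(fmt_num(row), collapse = "\t"))
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(path, atlas = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  W <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE,
                                   colClasses = "numeric"))
  dimnames(W) <- NULL
  if (nrow(W) != ncol(W)) {
    stop(sprintf("connectome file is not square: %d x %d", nrow(W), ncol(W)),
         call. = FALSE)
  }
  if (any(!is.finite(W))) {
    bad <- which(!is.finite(W), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite entry at row %d, column %d", bad[1], bad[2]),
         call. = FALSE)
  }
  asym <- max(abs(W - t(W)))
  if (asym > 1e-6) {
    stop(sprintf("matrix asymmetric beyond tolerance (max |W - t(W)| = %.3g)", asym),
         call. = FALSE)
  }
  if (asym > 0) {
    message(sprintf("symmetrizing matrix (max asymmetry %.3g)", asym))
    W <- (W + t(W)) / 2
  }
  if (any(diag(W) != 0)) {
    message("zeroing nonzero diagonal entries")
    diag(W) <- 0
  }
  as_connectome(W, atlas, provenance = list(source = path))
}

#' Write / read atlas metadata as TSV
#'
#' Columns: `region_id` (1-based), `name`, `x`, `y`, `z`, `is_cortical`
#' (0/1), `module` (integer or NA). Neighbor lists are recomputed from the
#' centroids on reading.
#'
#' @param atlas an `lnm_atlas`.
#' @param path file path.
#' @param k_neighbors neighbors to recompute on reading.
#' @return `read_atlas` returns an `lnm_atlas`; `write_atlas` returns
#'   `path` invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "lnm_atlas"))
  df <- data.frame(region_id = seq_len(atlas$n_regions),
                   name = atlas$region_names,
                   x = fmt_num(atlas$centroids[, 1]),
                   y = fmt_num(atlas$centroids[, 2]),
                   z = fmt_num(atlas$centroids[, 3]),
                   is_cortical = as.integer(atlas$is_cortical),
                   module = atlas$module_labels %||% NA_integer_)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path, k_neighbors = 8L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("region_id", "x", "y", "z", "is_cortical")
  if (!all(need %in% names(df))) {
    stop("atlas file must have columns region_id, name, x, y, z, is_cortical, module",
         call. = FALSE)
  }
  df <- df[order(df$region_id), ]
  R <- nrow(df)
  P <- cbind(x = df$x, y = df$y, z = df$z)
  k <- min(k_neighbors, R - 1L)
  D <- as.matrix(stats::dist(P))
  neighbors <- lapply(seq_len(R), function(r) order(D[r, ])[2:(k + 1L)])
  labels <- if ("module" %in% names(df) && !all(is.na(df$module))) {
    as.integer(df$module)
  } else {
    NULL
  }
  new_atlas(R, P, df$is_cortical == 1, neighbors, labels,
            names = if ("name" %in% names(df)) df$name else NULL)
}

#' Write / read lesion sets
#'
#' JSON layout: an array of `{set_id, lesions: [[region_id, ...], ...]}`.
#' TSV long layout: columns `set_id`, `lesion_id`, `region_id`. The format
#' is chosen by file extension (`.json` vs anything else).
#'
#' @param sets a named list: each element a list of integer vectors (one per
#'   lesion), or a single `lesion_matrix`.
#' @param path file path.
#' @param n_regions atlas size used to rebuild `lesion_matrix` objects.
#' @return `read_lesions` returns a named list of `lesion_matrix` objects;
#'   `write_lesions` returns `path` invisibly.
#' @export
write_lesions <- function(sets, path) {
  if (inherits(sets, "lesion_matrix")) sets <- list(set1 = sets)
  ids <- names(sets) %||% paste0("set", seq_along(sets))
  as_lists <- lapply(sets, function(s) {
    if (inherits(s, "lesion_matrix")) s$region_lists else s
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- lapply(seq_along(as_lists), function(i) {
      list(set_id = ids[i], lesions = lapply(as_lists[[i]], as.integer))
    })
    jsonlite::write_json(payload, path, auto_unbox = TRUE)
  } else {
    rows <- do.call(rbind, lapply(seq_along(as_lists), function(i) {
      do.call(rbind, lapply(seq_along(as_lists[[i]]), function(s) {
        data.frame(set_id = ids[i], lesion_id = s,
                   region_id = as.integer(as_lists[[i]][[s]]))
      }))
    }))
    utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_lesions
#' @export
read_lesions <- function(path, n_regions) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  n_regions <- check_count(n_regions, "n_regions")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    payload <- jsonlite::read_json(path, simplifyVector = FALSE)
    sets <- lapply(payload, function(p) {
      lapply(p$lesions, function(l) as.integer(unlist(l)))
    })
    names(sets) <- vapply(payload, function(p) as.character(p$set_id),
                          character(1))
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    sets <- lapply(split(df, df$set_id), function(d) {
      lapply(split(d$region_id, d$lesion_id), as.integer)
    })
  }
  lapply(sets, build_lesion_matrix, n_regions = n_regions)
}

#' Write / read a brain map as TSV
#'
#' Columns `region_id` (1-based) and `value`, full precision.
#'
#' @param map a `brain_map`, `lnm` fit or numeric vector.
#' @param path file path.
#' @param kind kind label attached on reading.
#' @return `read_map` returns a `brain_map`; `write_map` returns `path`
#'   invisibly.
#' @export
write_map <- function(map, path) {
  v <- map_values(map)
  df <- data.frame(region_id = seq_along(v), value = fmt_num(v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path, kind = "other") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  brain_map(df$value[order(df$region_id)], kind)
}

# --- pipeline ---------------------------------------------------------------

#' Assemble a pipeline configuration
#'
#' Bundles every knob of the end-to-end audit; all stage seeds are derived
#' deterministically from the single master seed via [derive_seed()], so a
#' config fully determines the run. Round-trips losslessly through JSON with
#' [write_config()] / [read_config()].
#'
#' @param seed master seed.
#' @param out_dir output directory.
#' @param n_regions,n_modules,subcortical_fraction atlas parameters.
#' @param n_lesions,dilation lesion-set parameters.
#' @param n_perm spin permutations.
#' @param set_sizes,n_runs convergence-curve parameters.
#' @param q_grid,n_sets,n_subjects,edge_sd conjunction-sweep parameters.
#' @param settings an [lnm_settings()] bundle.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("lnm_audit_"),
                       n_regions = 100L, n_modules = 4L,
                       subcortical_fraction = 0.1,
                       n_lesions = 50L, dilation = 4L, n_perm = 200L,
                       set_sizes = c(1, 5, 10, 25, 50), n_runs = 100L,
                       q_grid = c(0, 25, 200), n_sets = 25L,
                       n_subjects = 40L, edge_sd = 0.1,
                       settings = lnm_settings()) {
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_regions = as.integer(n_regions),
                 n_modules = as.integer(n_modules),
                 subcortical_fraction = subcortical_fraction,
                 n_lesions = as.integer(n_lesions),
                 dilation = as.integer(dilation),
                 n_perm = as.integer(n_perm),
                 set_sizes = as.integer(set_sizes),
                 n_runs = as.integer(n_runs),
                 q_grid = as.numeric(q_grid),
                 n_sets = as.integer(n_sets),
                 n_subjects = as.integer(n_subjects),
                 edge_sd = edge_sd,
                 settings = settings),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  payload <- unclass(config)
  payload$settings <- unclass(payload$settings)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$settings <- do.call(lnm_settings, as.list(raw$settings))
  do.call(run_config, raw)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the end-to-end synthetic audit pipeline
#'
#' Generates an atlas and structured connectome, draws a lesion set, fits
#' the LNM map and compares it with the degree vector (spin test), computes
#' the convergence curve, the nine-factor regression of the LNM map, and a
#' compact conjunction sweep. All maps and tables are written under
#' `config$out_dir` together with a `manifest.json` holding parameter and
#' file digests; the run is fully determined by the master seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  atlas <- run_stage("atlas", generate_atlas(
    config$n_regions, config$n_modules, config$subcortical_fraction,
    seed = derive_seed(seed, "atlas")))
  C <- run_stage("connectome", generate_connectome(
    atlas, seed = derive_seed(seed, "connectome")))
  lesions <- run_stage("lesions", generate_random_lesions(
    atlas, config$n_lesions, dilation = config$dilation,
    seed = derive_seed(seed, "lesions")))
  fit <- run_stage("lnm", lnm(lesions, C))
  deg <- connectome_degree(C)
  spin <- run_stage("spin", build_spin(atlas, config$n_perm,
                                       seed = derive_seed(seed, "spin")))
  degree_test <- run_stage("degree_test", spin_pvalue(fit, deg, spin))
  curve <- run_stage("convergence", convergence_to_degree(
    C, atlas, set_sizes = config$set_sizes, n_runs = config$n_runs,
    dilation = 0L, seed = derive_seed(seed, "convergence")))
  factors <- run_stage("factors", build_elementary_factors(
    C, atlas, detect_modules(C, 4L, seed = derive_seed(seed, "modules"))))
  reg <- run_stage("regression", factor_regression(fit, factors))
  sweep <- run_stage("sweep", conjunction_sweep(
    C, atlas, q_grid = config$q_grid, n_sets = config$n_sets,
    lesions_per_set = config$n_lesions, dilation = config$dilation,
    settings = config$settings, n_subjects = config$n_subjects,
    edge_sd = config$edge_sd, seed = derive_seed(seed, "sweep")))

  out <- function(f) file.path(config$out_dir, f)
  run_stage("write", {
    write_atlas(atlas, out("atlas.tsv"))
    write_connectome(C, out("connectome.tsv"))
    write_lesions(list(main = lesions), out("lesions.json"))
    write_map(fit, out("lnm_map.tsv"))
    write_map(deg, out("degree_map.tsv"))
    utils::write.table(curve$summary, out("convergence.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sweep$bins, out("conjunction_sweep.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_config(config, out("config.json"))
    summary_json <- list(
      degree_correlation = degree_test$r_observed,
      degree_p_spin = degree_test$p_spin,
      factor_r_squared = reg$r_squared,
      convergence_mean_r = stats::setNames(as.list(curve$summary$mean),
                                           paste0("size", curve$summary$size))
    )
    jsonlite::write_json(summary_json, out("summary.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  files <- c("atlas.tsv", "connectome.tsv", "lesions.json", "lnm_map.tsv",
             "degree_map.tsv", "convergence.tsv", "conjunction_sweep.tsv",
             "config.json", "summary.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("lnmaudit")),
    seed = seed,
    digests = as.list(tools::md5sum(file.path(config$out_dir, files)))
  )
  names(manifest$digests) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  invisible(list(atlas = atlas, connectome = C, lesions = lesions, fit = fit,
                 degree_test = degree_test, convergence = curve,
                 regression = reg, sweep = sweep, manifest = manifest,
                 out_dir = config$out_dir))
}
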