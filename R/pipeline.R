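#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end run in one validated document.
#' `manifest = NULL` means a synthetic cohort is generated from the `synth`
#' block instead of reading volumes from disk.
#'
#' @return A named list of configuration values.
#' @export
default_config <- function() {
  list(
    manifest = NULL,
    synth = list(n_ad = 20L, n_cn = 20L, grid_size = 48L,
                 delta_gm = 0.2, omega_ad = 3, omega_cn = 1,
                 sigma = 0.02, jitter = 0.05),
    levels = 256L,
    expanse_mode = "mean_of_sds",
    n_supervoxels = 300L,
    compactness = 10,
    max_iterations = 10L,
    min_region_frac = 0.25,
    n_components = "scree",
    kernel = "linear",
    cost = 1,
    n_splits = 10L,
    test_frac = 0.2,
    seed = 1L,
    compare_kernels = FALSE,
    baseline = TRUE
  )
}

#' Validate a pipeline configuration
#'
#' Unknown keys (top level or in the `synth` block) are rejected before any
#' computation; missing keys fall back to [default_config].
#'
#' @param config a named list, or a path to a YAML file holding one.
#' @return The resolved configuration list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(config$synth)) {
    bad <- setdiff(names(config$synth), names(def$synth))
    if (length(bad))
      stop("unknown synth config keys: ", paste(bad, collapse = ", "),
           call. = FALSE)
    def$synth[names(config$synth)] <- config$synth
    config$synth <- NULL
  }
  def[names(config)] <- config
  if (!def$expanse_mode %in% c("mean_of_sds", "mean_of_means"))
    stop("expanse_mode must be mean_of_sds or mean_of_means", call. = FALSE)
  if (!def$kernel %in% c("linear", "polynomial", "radial"))
    stop("kernel must be linear, polynomial or radial", call. = FALSE)
  def
}

config_slic_params <- function(config) {
  slic_params(n_supervoxels = config$n_supervoxels,
              compactness = config$compactness,
              max_iterations = config$max_iterations,
              min_region_frac = config$min_region_frac,
              seed = config$seed)
}

#' Histon feature matrix for a whole cohort
#'
#' Runs [extract_feature_vector] per subject and stacks the vectors.
#'
#' @param cohort a [generate_cohort] result, or a manifest data.frame from
#'   [read_manifest].
#' @param params a [slic_params] object.
#' @param levels,expanse_mode,histogram_only passed to
#'   [extract_feature_vector].
#' @param verbose print one line per subject.
#' @return A list: `x` (subjects x 3*levels matrix), `manifest`.
#' @export
cohort_features <- function(cohort, params = slic_params(), levels = 256L,
                            expanse_mode = "mean_of_sds",
                            histogram_only = FALSE, verbose = FALSE) {
  man <- if (inherits(cohort, "synthetic_cohort")) cohort$manifest else cohort
  n <- nrow(man)
  x <- matrix(NA_real_, n, 3L * levels,
              dimnames = list(man$subject_id,
                              paste0("f", seq_len(3L * levels) - 1L)))
  for (i in seq_len(n)) {
    subj <- if (inherits(cohort, "synthetic_cohort"))
      cohort_subject_volumes(cohort, i) else man[i, ]
    t0 <- Sys.time()
    fv <- tryCatch(
      extract_feature_vector(subj, params, levels, expanse_mode,
                             histogram_only = histogram_only),
      error = function(e) stop(sprintf("feature extraction failed for %s: %s",
                                       man$subject_id[i], conditionMessage(e)),
                               call. = FALSE))
    x[i, ] <- fv$vector
    if (verbose)
      message(sprintf("features %s (%d/%d) in %.1fs", man$subject_id[i], i, n,
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  list(x = x, manifest = man)
}

# Flattened GM probability vectors for the voxel baseline.
cohort_gm_matrix <- function(cohort) {
  man <- if (inherits(cohort, "synthetic_cohort")) cohort$manifest else cohort
  rows <- lapply(seq_len(nrow(man)), function(i) {
    subj <- if (inherits(cohort, "synthetic_cohort"))
      cohort_subject_volumes(cohort, i)
    else list(gm = read_probability_volume(man$gm_path[i], "GM"))
    as.vector(subj$gm$data)
  })
  do.call(rbind, rows)
}

#' Run the end-to-end pipeline into a run directory
#'
#' Stage order: cohort (synthetic or manifest) -> histon features -> split
#' plan -> PCA + SVM evaluation per split -> optional kernel comparison ->
#' optional voxel baseline with McNemar comparison. The feature matrix is
#' cached as `features.csv` in the run directory and reused on rerun;
#' model outputs live under `models/`, so deleting only that subdirectory
#' and rerunning recomputes them from the cached features. The resolved
#' configuration and package version are stored with the run.
#'
#' @param config a configuration list or YAML path (see [validate_config]).
#' @param out_dir run directory (created if needed).
#' @param verbose print stage progress.
#' @return Invisibly, the report list (also written as
#'   `models/report.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, verbose = FALSE) {
  config <- validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(c(config, list(package_version =
                                    as.character(packageVersion("svhiston")))),
                   file.path(out_dir, "config.yaml"))

  cohort <- if (is.null(config$manifest)) {
    s <- config$synth
    generate_cohort(s$n_ad, s$n_cn,
                    phantom_params(grid_size = s$grid_size,
                                   delta_gm = s$delta_gm,
                                   omega_ad = s$omega_ad,
                                   omega_cn = s$omega_cn,
                                   sigma = s$sigma, jitter = s$jitter),
                    seed = config$seed)
  } else {
    read_manifest(config$manifest)
  }
  man <- if (inherits(cohort, "synthetic_cohort")) cohort$manifest else cohort

  feat_path <- file.path(out_dir, "features.csv")
  if (file.exists(feat_path)) {
    if (verbose) message("features: reusing cached ", feat_path)
    tab <- read.csv(feat_path, check.names = FALSE)
    x <- as.matrix(tab[, -(1:2)])
    rownames(x) <- tab$subject_id
  } else {
    if (verbose) message("features: extracting ", nrow(man), " subjects")
    fm <- cohort_features(cohort, config_slic_params(config),
                          config$levels, config$expanse_mode,
                          verbose = verbose)
    x <- fm$x
    write.csv(data.frame(subject_id = man$subject_id, label = man$label,
                         x, check.names = FALSE),
              feat_path, row.names = FALSE)
  }

  model_dir <- file.path(out_dir, "models")
  dir.create(model_dir, showWarnings = FALSE)
  plan <- make_splits(man, config$n_splits, config$test_frac, config$seed)
  if (verbose) message("evaluate: ", config$n_splits, " splits, ",
                       config$kernel, " kernel")
  ev <- evaluate_splits(x, man$label, plan,
                        n_components = config$n_components,
                        kernel = config$kernel, cost = config$cost)
  s <- summary(ev)
  report <- list(
    n_subjects = nrow(man),
    seed = config$seed,
    kernel = config$kernel,
    per_split = s[-nrow(s), ],
    mean = as.list(s[nrow(s), -1])
  )

  if (isTRUE(config$compare_kernels)) {
    if (verbose) message("kernel comparison")
    report$kernel_comparison <- compare_kernels(x, man$label, plan,
                                                n_components =
                                                  config$n_components,
                                                cost = config$cost)
  }

  if (isTRUE(config$baseline)) {
    if (verbose) message("voxel baseline + McNemar")
    gmx <- cohort_gm_matrix(cohort)
    base_reports <- vector("list", plan$n_splits)
    mcnemar <- vector("list", plan$n_splits)
    pooled <- data.frame(truth = character(), histon = character(),
                         baseline = character())
    for (k in seq_len(plan$n_splits)) {
      sp <- plan$splits[[k]]
      br <- voxel_baseline(gmx[sp$train, , drop = FALSE],
                           man$label[sp$train],
                           gmx[sp$test, , drop = FALSE],
                           man$label[sp$test],
                           man$subject_id[sp$train], man$subject_id[sp$test])
      base_reports[[k]] <- br
      ph <- ev$predictions[[k]]$pred
      pb <- as.character(attr(br, "predictions"))
      truth <- man$label[sp$test]
      mcnemar[[k]] <- mcnemar_compare(ph, pb, truth)
      pooled <- rbind(pooled, data.frame(truth = truth, histon = ph,
                                         baseline = pb))
    }
    report$baseline_mean <- as.list(colMeans(do.call(rbind, lapply(
      base_reports, function(r)
        unlist(r[c("Acc", "Bacc", "NPV", "PPV", "Sen", "Spe", "Fscore")]))),
      na.rm = TRUE))
    report$mcnemar_per_split <- lapply(mcnemar, function(m)
      m[c("statistic", "p_value", "b", "c")])
    report$mcnemar_pooled <- mcnemar_compare(pooled$histon, pooled$baseline,
                                             pooled$truth)
  }

  jsonlite::write_json(report, file.path(model_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(report)
}
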