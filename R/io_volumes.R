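#' @useDynLib svhiston, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats prcomp predict rnorm runif sd qnorm pchisq binom.test
#' @importFrom stats setNames median var
#' @importFrom utils read.csv write.csv packageVersion
NULL

TISSUES <- c("GM", "WM", "CSF")

#' Construct a tissue probability volume
#'
#' Wraps a 3D numeric array as a single tissue's probability map. Unquantized
#' volumes hold probabilities in \[0, 1\]; quantized volumes hold integer
#' intensity levels in \[0, levels - 1\] (256 levels for 8-bit maps).
#'
#' @param data 3D numeric array.
#' @param tissue one of `"GM"`, `"WM"`, `"CSF"`.
#' @param levels integer number of quantization levels, or `NULL` if the
#'   volume still holds raw probabilities.
#' @return An object of class `prob_volume`.
#' @export
prob_volume <- function(data, tissue, levels = NULL) {
  tissue <- match.arg(tissue, TISSUES)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("expected 3D volume", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  if (is.null(levels)) {
    if (min(data) < 0 || max(data) > 1)
      stop("unquantized probability volume must lie in [0, 1]", call. = FALSE)
  } else {
    levels <- as.integer(levels)
    if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
    if (any(data != floor(data)) || min(data) < 0 || max(data) > levels - 1L)
      stop("quantized volume must hold integers in [0, levels - 1]", call. = FALSE)
  }
  structure(list(data = data, tissue = tissue, levels = levels,
                 voxel_count = length(data)),
            class = "prob_volume")
}

#' @export
print.prob_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<prob_volume> tissue %s, %d x %d x %d (%d voxels), %s\n",
              x$tissue, d[1], d[2], d[3], x$voxel_count,
              if (is.null(x$levels)) "probabilities in [0,1]"
              else sprintf("quantized to %d levels", x$levels)))
  invisible(x)
}

is_quantized <- function(volume) !is.null(volume$levels)

#' Read a tissue probability volume from a NIfTI file
#'
#' Float-valued volumes are clipped to \[0, 1\] and kept as probabilities;
#' integer-valued volumes are treated as already-quantized 8-bit intensity
#' maps (values clipped to \[0, 255\], `levels = 256`).
#'
#' @param path path to a 3D NIfTI file (`.nii` or `.nii.gz`).
#' @param tissue tissue tag, one of `"GM"`, `"WM"`, `"CSF"`.
#' @return A [prob_volume].
#' @export
read_probability_volume <- function(path, tissue) {
  tissue <- match.arg(tissue, TISSUES)
  if (!file.exists(path))
    stop(sprintf("volume file not found: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  dat <- as.array(img)
  dat <- drop(dat)
  if (length(dim(dat)) != 3L)
    stop(sprintf("expected 3D volume: %s", path), call. = FALSE)
  if (all(is.na(dat)))
    stop(sprintf("all-NaN volume: %s", path), call. = FALSE)
  if (anyNA(dat)) dat[is.na(dat)] <- 0
  storage.mode(dat) <- "double"
  integer_valued <- all(dat == floor(dat)) && max(dat) > 1
  if (integer_valued) {
    dat <- pmin(pmax(dat, 0), 255)
    prob_volume(dat, tissue, levels = 256L)
  } else {
    dat <- pmin(pmax(dat, 0), 1)
    prob_volume(dat, tissue, levels = NULL)
  }
}

#' Write a probability volume (or any 3D array) to NIfTI
#'
#' @param volume a [prob_volume], or a plain 3D array (e.g. a supervoxel
#'   label field).
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  dat <- if (inherits(volume, "prob_volume")) volume$data else volume
  img <- RNifti::asNifti(dat)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Quantize a probability volume to discrete intensity levels
#'
#' Maps a probability v in \[0, 1\] to `floor(v * (levels - 1) + 0.5)`
#' (round half up), yielding integers in \[0, levels - 1\]. The default 256
#' levels corresponds to the 8-bit intensity maps used throughout the
#' feature pipeline.
#'
#' @param volume an unquantized [prob_volume].
#' @param levels integer >= 2.
#' @return A quantized [prob_volume].
#' @export
quantize <- function(volume, levels = 256L) {
  stopifnot(inherits(volume, "prob_volume"))
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  if (is_quantized(volume))
    stop("volume is already quantized", call. = FALSE)
  q <- floor(volume$data * (levels - 1L) + 0.5)
  prob_volume(q, volume$tissue, levels = levels)
}

#' Build the analysis mask from the three tissue volumes
#'
#' A voxel enters the mask when its total tissue probability
#' (GM + WM + CSF) exceeds `threshold`. All downstream computation — SLIC,
#' expanse, similarity field, histons — is restricted to this mask, so the
#' constant zero background cannot swamp intensity bin 0.
#'
#' @param gm,wm,csf unquantized [prob_volume]s on a common grid.
#' @param threshold inclusion threshold on the summed probability
#'   (default 0: any tissue signal).
#' @return An object of class `brain_mask` with fields `mask` (logical 3D
#'   array) and `included_voxels`.
#' @export
build_brain_mask <- function(gm, wm, csf, threshold = 0) {
  vols <- list(gm, wm, csf)
  dims <- lapply(vols, function(v) dim(v$data))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("tissue volumes have mismatched dimensions", call. = FALSE)
  m <- (gm$data + wm$data + csf$data) > threshold
  structure(list(mask = m, included_voxels = sum(m)), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<brain_mask> %d x %d x %d, %d voxels included (%.1f%%)\n",
              d[1], d[2], d[3], x$included_voxels,
              100 * x$included_voxels / length(x$mask)))
  invisible(x)
}

#' Read a subject manifest
#'
#' The manifest is a CSV with columns `subject_id, label, age, gender,
#' gm_path, wm_path, csf_path`. Labels must be `AD` or `CN`; AD is the
#' positive class throughout.
#'
#' @param path path to the manifest CSV.
#' @param base_dir optional directory against which relative volume paths
#'   are resolved.
#' @return A data.frame of subject records.
#' @export
read_manifest <- function(path, base_dir = NULL) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "label", "age", "gender",
                "gm_path", "wm_path", "csf_path")
  missing <- setdiff(required, names(man))
  if (length(missing))
    stop("manifest missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (!all(man$label %in% c("AD", "CN")))
    stop("labels must be AD or CN", call. = FALSE)
  if (!all(man$gender %in% c("M", "F")))
    stop("gender must be M or F", call. = FALSE)
  if (anyNA(man$age)) stop("age missing for some subjects", call. = FALSE)
  if (!is.null(base_dir))
    for (col in c("gm_path", "wm_path", "csf_path"))
      man[[col]] <- file.path(base_dir, man[[col]])
  man
}
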