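#' Supervoxel-derived similarity thresholds (expanse)
#'
#' The expanse E is the radius of the "similar colour sphere": a voxel
#' counts as similar when, in every tissue channel, its intensity lies
#' within E of its supervoxel's mean intensity. Two derivations are
#' available:
#' \describe{
#'   \item{`mean_of_sds` (default)}{E per tissue is the mean over
#'     supervoxels of the per-supervoxel intensity standard deviation — the
#'     average local deviation of the volume in the supervoxel-defined
#'     space. A deviation is the dimensionally natural radius for a
#'     similarity sphere.}
#'   \item{`mean_of_means`}{E per tissue is the mean over supervoxels of
#'     the supervoxel mean intensity. Kept for fidelity experiments; on
#'     bright channels it makes almost every voxel similar.}
#' }
#'
#' @param labeling a `supervoxel_labeling` with statistics filled.
#' @param mode `"mean_of_sds"` or `"mean_of_means"`.
#' @return An object of class `expanse_thresholds`: named numeric
#'   (GM, WM, CSF) with the mode attached.
#' @export
compute_expanse <- function(labeling, mode = c("mean_of_sds", "mean_of_means")) {
  mode <- match.arg(mode)
  st <- labeling$stats
  if (is.null(st) || nrow(st) == 0L) stop("zero supervoxels", call. = FALSE)
  e <- if (mode == "mean_of_sds") {
    c(GM = mean(st$sd_gm), WM = mean(st$sd_wm), CSF = mean(st$sd_csf))
  } else {
    c(GM = mean(st$mean_gm), WM = mean(st$mean_wm), CSF = mean(st$mean_csf))
  }
  structure(e, mode = mode, class = "expanse_thresholds")
}

#' @export
print.expanse_thresholds <- function(x, ...) {
  cat(sprintf("<expanse_thresholds> mode %s: GM %.3f, WM %.3f, CSF %.3f\n",
              attr(x, "mode"), x["GM"], x["WM"], x["CSF"]))
  invisible(x)
}

#' Binary similarity field over the mask
#'
#' S2(x,y,z) = 1 iff, for every tissue channel, the absolute difference
#' between the voxel's intensity and the mean intensity of its supervoxel
#' is strictly below that tissue's expanse threshold. The conjunction over
#' the three tissues is shared by all three histons.
#'
#' @param labeling a `supervoxel_labeling`.
#' @param gm,wm,csf quantized [prob_volume]s the labeling was computed from.
#' @param expanse an [compute_expanse] result.
#' @return An integer 3D array: 1 similar, 0 dissimilar, 0 outside the mask
#'   (with the logical mask stored in attribute `mask`).
#' @export
compute_similarity_field <- function(labeling, gm, wm, csf, expanse) {
  lab <- as.vector(labeling$labels)
  inside <- lab >= 0
  if (max(lab) + 1L != nrow(labeling$stats))
    stop("expanse/labeling mismatch", call. = FALSE)
  st <- labeling$stats
  li <- lab[inside] + 1L
  sim <- abs(as.double(gm$data)[inside] - st$mean_gm[li]) < expanse[["GM"]] &
    abs(as.double(wm$data)[inside] - st$mean_wm[li]) < expanse[["WM"]] &
    abs(as.double(csf$data)[inside] - st$mean_csf[li]) < expanse[["CSF"]]
  s2 <- integer(length(lab))
  s2[inside] <- as.integer(sim)
  out <- array(s2, dim = dim(labeling$labels))
  attr(out, "mask") <- inside
  out
}

#' Histon of one quantized volume
#'
#' Over the masked voxels, each voxel contributes 1 to the bin of its
#' intensity level, plus 1 more when its similarity indicator is 1:
#' histon(g) = sum over masked voxels of (1 + S2) for voxels at level g.
#' The companion base histogram is the plain count, so
#' histogram(g) <= histon(g) <= 2 histogram(g) bin-wise and the histon's
#' total mass equals masked_voxels + #\{S2 = 1\}.
#'
#' @param volume a [prob_volume] quantized to `levels` levels.
#' @param s2 a similarity field from [compute_similarity_field].
#' @param mask a [build_brain_mask] result.
#' @return A list with `histon` and `histogram` (numeric, length `levels`,
#'   bin g at index g + 1), `masked_voxels` and `similar_voxels`.
#' @export
compute_histon <- function(volume, s2, mask) {
  if (!is_quantized(volume))
    stop("compute_histon requires a quantized volume", call. = FALSE)
  L <- volume$levels
  inside <- as.vector(mask$mask)
  v <- as.integer(volume$data)[inside]
  s <- as.integer(s2)[inside]
  histogram <- tabulate(v + 1L, nbins = L)
  histon <- histogram + tabulate(v[s == 1L] + 1L, nbins = L)
  list(histon = as.numeric(histon), histogram = as.numeric(histogram),
       masked_voxels = sum(inside), similar_voxels = sum(s))
}

#' Extract the 768-component supervoxel-histon feature vector
#'
#' Runs the full per-subject feature chain: brain mask, 8-bit quantization,
#' 3D SLIC over the aggregate GM/WM/CSF volume, connectivity enforcement,
#' expanse thresholds, similarity field, and one 256-bin histon per tissue,
#' concatenated in the fixed order GM, WM, CSF.
#'
#' @param subject either a one-row data.frame from [read_manifest] (volumes
#'   are read from its paths) or a named list with unquantized
#'   [prob_volume]s `gm`, `wm`, `csf`.
#' @param params a [slic_params] object.
#' @param levels quantization levels per tissue (256 gives the
#'   3 x 256 = 768-component vector).
#' @param expanse_mode see [compute_expanse].
#' @param mask_threshold inclusion threshold for [build_brain_mask].
#' @param histogram_only force the similarity field to zero so the feature
#'   degenerates to the plain concatenated histograms (ablation control).
#' @return An object of class `histon_feature`: `vector` (length
#'   3 * levels), per-tissue `histons` and `histograms` matrices, the
#'   `expanse` used, `masked_voxels`, `similar_voxels` and `n_supervoxels`.
#' @export
extract_feature_vector <- function(subject, params = slic_params(),
                                   levels = 256L,
                                   expanse_mode = "mean_of_sds",
                                   mask_threshold = 0,
                                   histogram_only = FALSE) {
  if (is.data.frame(subject)) {
    stopifnot(nrow(subject) == 1L)
    vols <- list(gm = read_probability_volume(subject$gm_path, "GM"),
                 wm = read_probability_volume(subject$wm_path, "WM"),
                 csf = read_probability_volume(subject$csf_path, "CSF"))
  } else {
    stopifnot(all(c("gm", "wm", "csf") %in% names(subject)))
    vols <- subject[c("gm", "wm", "csf")]
  }
  mask <- build_brain_mask(vols$gm, vols$wm, vols$csf, mask_threshold)
  if (mask$included_voxels == 0L)
    stop("empty brain mask; no voxel has tissue signal", call. = FALSE)
  qg <- quantize(vols$gm, levels); qw <- quantize(vols$wm, levels)
  qc <- quantize(vols$csf, levels)
  if (histogram_only) {
    # zero similarity everywhere: the histon degenerates to the plain
    # histogram, so the segmentation stages can be skipped outright
    s2 <- array(0L, dim(qg$data))
    expanse <- NULL
    n_sv <- 0L
  } else {
    labeling <- slic_segment(qg, qw, qc, mask, params)
    expanse <- compute_expanse(labeling, expanse_mode)
    s2 <- compute_similarity_field(labeling, qg, qw, qc, expanse)
    n_sv <- labeling$n_labels
  }
  hg <- compute_histon(qg, s2, mask)
  hw <- compute_histon(qw, s2, mask)
  hc <- compute_histon(qc, s2, mask)
  structure(list(
    vector = c(hg$histon, hw$histon, hc$histon),
    histons = cbind(GM = hg$histon, WM = hw$histon, CSF = hc$histon),
    histograms = cbind(GM = hg$histogram, WM = hw$histogram,
                       CSF = hc$histogram),
    expanse = expanse,
    masked_voxels = mask$included_voxels,
    similar_voxels = hg$similar_voxels,
    n_supervoxels = n_sv,
    levels = as.integer(levels)),
    class = "histon_feature")
}

#' @export
print.histon_feature <- function(x, ...) {
  cat(sprintf("<histon_feature> %d components (%d levels x 3 tissues)\n",
              length(x$vector), x$levels))
  cat(sprintf("  %d masked voxels, %d similar (%.1f%%), %d supervoxels\n",
              x$masked_voxels, x$similar_voxels,
              100 * x$similar_voxels / x$masked_voxels, x$n_supervoxels))
  invisible(x)
}

#' Classic neighbourhood histon (reference mode)
#'
#' The original fixed-neighbourhood histon: for each pixel/voxel, the sum
#' over a centred P x Q (x R) window (clipped at the image border) of
#' squared intensity differences across all channels is compared against a
#' scalar expanse E; the similarity indicator is 1 when that sum is
#' strictly below E. Each channel's histon then adds 1 + S to the bin of
#' the centre value. Intended for cross-checks on small images; plain loops.
#'
#' @param channels a single 2D/3D integer array, or a list of such arrays
#'   (one per channel) on a common grid, values in \[0, levels - 1\].
#' @param window integer window extents, length matching the array
#'   dimensionality; each must be odd.
#' @param expanse scalar similarity threshold E (use `Inf` to force all
#'   pixels similar).
#' @param levels number of intensity levels.
#' @return A list with `histons` (levels x channels matrix), `histograms`
#'   and the similarity indicator array `s`.
#' @export
classic_histon <- function(channels, window, expanse, levels = 256L) {
  if (!is.list(channels)) channels <- list(channels)
  d <- dim(channels[[1]])
  if (is.null(d)) stop("channels must be arrays", call. = FALSE)
  for (ch in channels) stopifnot(identical(dim(ch), d))
  nd <- length(d)
  stopifnot(length(window) == nd, all(window %% 2 == 1))
  if (any(window > d))
    stop("neighbourhood larger than image", call. = FALSE)
  half <- (window - 1L) %/% 2L
  if (nd == 2L) d <- c(d, 1L)  # treat 2D as a single-slice 3D grid
  arrs <- lapply(channels, function(ch) array(ch, dim = d))
  if (nd == 2L) half <- c(half, 0L)

  s <- array(0L, dim = d)
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    xs <- max(1, x - half[1]):min(d[1], x + half[1])
    ys <- max(1, y - half[2]):min(d[2], y + half[2])
    zs <- max(1, z - half[3]):min(d[3], z + half[3])
    dt <- 0
    for (ch in arrs)
      dt <- dt + sum((ch[x, y, z] - ch[xs, ys, zs])^2)
    s[x, y, z] <- as.integer(dt < expanse)
  }
  histograms <- vapply(arrs, function(ch) tabulate(as.integer(ch) + 1L,
                                                   nbins = levels),
                       numeric(levels))
  histons <- vapply(arrs, function(ch) {
    tabulate(as.integer(ch) + 1L, nbins = levels) +
      tabulate(as.integer(ch)[as.vector(s) == 1L] + 1L, nbins = levels)
  }, numeric(levels))
  list(histons = histons, histograms = histograms,
       s = array(as.integer(s), dim = dim(channels[[1]])))
}
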