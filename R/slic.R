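#' SLIC supervoxel parameters
#'
#' @param n_supervoxels target number of supervoxels; the actual count
#'   depends on the mask geometry and connectivity enforcement.
#' @param compactness the SLIC compactness weight m on the 0-255 intensity
#'   scale; larger values emphasise spatial regularity over intensity
#'   adherence.
#' @param max_iterations maximum k-means sweeps; iteration stops early once
#'   the total L1 centroid displacement drops below one voxel.
#' @param min_region_frac connected components smaller than this fraction of
#'   the nominal supervoxel volume (the cube of the seed spacing) are merged
#'   into their largest adjacent supervoxel.
#' @param seed integer recorded with the labeling for provenance; the
#'   segmentation itself is deterministic.
#' @return An object of class `slic_params`.
#' @export
slic_params <- function(n_supervoxels = 1000L, compactness = 10,
                        max_iterations = 10L, min_region_frac = 0.25,
                        seed = 1L) {
  stopifnot(n_supervoxels >= 1, compactness > 0, max_iterations >= 1,
            min_region_frac >= 0)
  structure(list(n_supervoxels = as.integer(n_supervoxels),
                 compactness = compactness,
                 max_iterations = as.integer(max_iterations),
                 min_region_frac = min_region_frac,
                 seed = as.integer(seed)),
            class = "slic_params")
}

# Seed spacing: cube-root of the average voxels per supervoxel.
seed_spacing <- function(masked_voxels, n_supervoxels) {
  max(1L, as.integer(round((masked_voxels / n_supervoxels)^(1 / 3))))
}

#' Place initial supervoxel centroids on a regular grid
#'
#' Seeds are laid on a regular 3D lattice with spacing
#' `round((masked_voxels / n_supervoxels)^(1/3))`; seeds landing outside the
#' mask are moved to the nearest masked voxel, and duplicates are dropped.
#'
#' @param mask a [build_brain_mask] result.
#' @param n_supervoxels target supervoxel count.
#' @return Integer matrix of 0-based seed coordinates (columns x, y, z).
#' @export
init_centroids <- function(mask, n_supervoxels) {
  if (mask$included_voxels == 0L) stop("empty mask", call. = FALSE)
  d <- dim(mask$mask)
  In <- seed_spacing(mask$included_voxels, n_supervoxels)
  axis_seq <- function(n) {
    s <- seq.int(In %/% 2L, n - 1L, by = In)
    if (!length(s)) s <- (n - 1L) %/% 2L
    s
  }
  seeds <- as.matrix(expand.grid(x = axis_seq(d[1]), y = axis_seq(d[2]),
                                 z = axis_seq(d[3])))
  storage.mode(seeds) <- "integer"
  inside <- mask$mask[seeds + 1L]
  if (any(!inside)) {
    mi <- which(mask$mask, arr.ind = TRUE) - 1L
    for (r in which(!inside)) {
      d2 <- (mi[, 1] - seeds[r, 1])^2 + (mi[, 2] - seeds[r, 2])^2 +
        (mi[, 3] - seeds[r, 3])^2
      seeds[r, ] <- mi[which.min(d2), ]
    }
  }
  unique(seeds)
}

#' Segment the aggregate tissue volume into supervoxels (3D SLIC)
#'
#' A spatially constrained k-means over the three quantized tissue channels.
#' Each masked voxel within the cube of half-width one seed spacing around a
#' centroid competes for it under the weighted distance
#' \deqn{D_w = \sqrt{(d_c/m)^2 + (d_s/I_n)^2},}
#' where \eqn{d_c} is the Euclidean intensity distance over the GM/WM/CSF
#' channels, \eqn{d_s} the Euclidean voxel distance, \eqn{m} the compactness
#' and \eqn{I_n} the seed spacing. Centroids (spatial position plus the
#' three channel intensities) are recomputed as cluster means each sweep.
#' Ties go to the lower centroid index; masked voxels outside every search
#' window are assigned to the globally nearest centroid.
#'
#' @param gm,wm,csf quantized [prob_volume]s on a common grid.
#' @param mask a [build_brain_mask] result.
#' @param params a [slic_params] object.
#' @param enforce apply [enforce_connectivity] to the raw labeling
#'   (default TRUE).
#' @return An object of class `supervoxel_labeling`: `labels` (3D integer
#'   array, -1 outside the mask), `n_labels`, `stats` (per-supervoxel size,
#'   centroid and per-tissue mean/sd), `spacing` (the seed spacing I_n) and
#'   `params`.
#' @export
slic_segment <- function(gm, wm, csf, mask, params = slic_params(),
                         enforce = TRUE) {
  for (v in list(gm, wm, csf))
    if (!is_quantized(v))
      stop("slic_segment requires quantized volumes", call. = FALSE)
  d <- dim(gm$data)
  stopifnot(identical(d, dim(wm$data)), identical(d, dim(csf$data)),
            identical(d, dim(mask$mask)))
  if (mask$included_voxels == 0L) stop("empty mask", call. = FALSE)

  In <- seed_spacing(mask$included_voxels, params$n_supervoxels)
  seeds <- init_centroids(mask, params$n_supervoxels)
  gv <- as.double(gm$data); wv <- as.double(wm$data); cv <- as.double(csf$data)
  mk <- as.logical(mask$mask)
  idx <- seeds[, 1] + d[1] * (seeds[, 2] + d[2] * seeds[, 3]) + 1L
  cent <- cbind(seeds[, 1], seeds[, 2], seeds[, 3], gv[idx], wv[idx], cv[idx])
  storage.mode(cent) <- "double"

  labels <- NULL
  win <- 2L * In  # search cube half-width: the classic 2*In SLIC region
  for (iter in seq_len(params$max_iterations)) {
    a <- slic_assign_cpp(cent, gv, wv, cv, mk, d, In, params$compactness, win)
    upd <- slic_update_cpp(a$labels, gv, wv, cv, d, nrow(cent))
    newc <- upd$centroids
    empty <- upd$size == 0L
    newc[empty, ] <- cent[empty, ]
    disp <- sum(abs(newc[, 1:3] - cent[, 1:3]))
    cent <- newc
    if (disp < 1) break
  }
  a <- slic_assign_cpp(cent, gv, wv, cv, mk, d, In, params$compactness, win)
  if (a$n_unreached > 0)
    message(sprintf("slic_segment: %d voxels outside all search windows assigned globally",
                    a$n_unreached))
  labels <- array(a$labels, dim = d)
  labels <- compact_labels(labels)

  out <- structure(list(labels = labels, n_labels = max(labels) + 1L,
                        stats = NULL, spacing = In, params = params),
                   class = "supervoxel_labeling")
  out$stats <- supervoxel_statistics(out, gm, wm, csf)
  if (enforce) out <- enforce_connectivity(out, gm, wm, csf,
                                           params$min_region_frac)
  out
}

# Renumber labels to a dense 0..(K-1) range, ordered by first occurrence in
# scan order; -1 (outside mask) is preserved.
compact_labels <- function(labels) {
  u <- unique(as.vector(labels))
  u <- u[u >= 0]
  map <- integer(max(u) + 1L)
  map[u + 1L] <- seq_along(u) - 1L
  pos <- labels >= 0
  labels[pos] <- map[labels[pos] + 1L]
  labels
}

#' Per-supervoxel intensity statistics
#'
#' For each supervoxel and tissue channel: the mean intensity and the
#' population standard deviation (divisor N, so single-voxel supervoxels get
#' sd 0). The average of these per-supervoxel standard deviations is the
#' local-homogeneity summary from which the default expanse threshold is
#' derived.
#'
#' @param labeling a `supervoxel_labeling`.
#' @param gm,wm,csf quantized [prob_volume]s the labeling was computed from.
#' @return A data.frame with columns `label, size, cx, cy, cz, mean_gm,
#'   mean_wm, mean_csf, sd_gm, sd_wm, sd_csf` (0-based labels and
#'   coordinates).
#' @export
supervoxel_statistics <- function(labeling, gm, wm, csf) {
  lab <- as.vector(labeling$labels)
  inside <- lab >= 0
  lab <- lab[inside]
  if (!length(lab)) stop("labeling has no masked voxels", call. = FALSE)
  K <- max(lab) + 1L
  size <- tabulate(lab + 1L, nbins = K)
  if (any(size == 0L)) stop("label with zero voxels", call. = FALSE)
  d <- dim(labeling$labels)
  co <- arrayInd(which(inside), d) - 1L
  # integer grouping keeps rowsum's row order numeric (0 .. K-1); every
  # label is guaranteed non-empty by the invariant checked above
  msd <- function(x) {
    s1 <- as.vector(rowsum(x, lab))
    s2 <- as.vector(rowsum(x * x, lab))
    mu <- s1 / size
    var <- pmax(s2 / size - mu^2, 0)
    list(mean = mu, sd = sqrt(var))
  }
  g <- msd(as.double(gm$data)[inside])
  w <- msd(as.double(wm$data)[inside])
  cf <- msd(as.double(csf$data)[inside])
  data.frame(label = 0:(K - 1L), size = size,
             cx = as.vector(rowsum(co[, 1], lab)) / size,
             cy = as.vector(rowsum(co[, 2], lab)) / size,
             cz = as.vector(rowsum(co[, 3], lab)) / size,
             mean_gm = g$mean, mean_wm = w$mean, mean_csf = cf$mean,
             sd_gm = g$sd, sd_wm = w$sd, sd_csf = cf$sd)
}

#' Enforce 6-connectivity of the supervoxel labeling
#'
#' Connected components of each label are found under 6-connectivity.
#' Components smaller than `min_region_frac` times the nominal supervoxel
#' volume (seed spacing cubed) are absorbed into their largest 6-adjacent
#' component; every surviving component then receives its own label, so
#' each final label is guaranteed connected. Statistics are recomputed.
#'
#' @param labeling a `supervoxel_labeling`.
#' @param gm,wm,csf the quantized volumes the labeling was computed from.
#' @param min_region_frac minimum component size as a fraction of the
#'   nominal supervoxel volume.
#' @return A `supervoxel_labeling` whose labels are each 6-connected.
#' @export
enforce_connectivity <- function(labeling, gm, wm, csf,
                                 min_region_frac = 0.25) {
  d <- dim(labeling$labels)
  cc <- label_components_cpp(as.vector(labeling$labels), d)
  nc <- length(cc$size)
  min_size <- max(1, floor(min_region_frac * labeling$spacing^3))

  parent <- seq_len(nc)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  csize <- as.numeric(cc$size)

  adj <- component_adjacency_cpp(cc$comp, d)
  nbrs <- vector("list", nc)
  if (nrow(adj)) {
    a1 <- adj[, 1] + 1L; a2 <- adj[, 2] + 1L
    for (r in seq_along(a1)) {
      nbrs[[a1[r]]] <- c(nbrs[[a1[r]]], a2[r])
      nbrs[[a2[r]]] <- c(nbrs[[a2[r]]], a1[r])
    }
  }
  ord <- order(cc$size, seq_len(nc))
  for (i in ord) {
    ri <- find(i)
    if (csize[ri] >= min_size) next
    cand <- unique(vapply(nbrs[[i]], find, integer(1)))
    cand <- cand[cand != ri]
    if (!length(cand)) next
    target <- cand[order(-csize[cand], cand)][1]
    parent[ri] <- target
    csize[target] <- csize[target] + csize[ri]
  }
  roots <- vapply(seq_len(nc), find, integer(1))

  comp <- array(cc$comp, dim = d)
  pos <- comp >= 0
  newlab <- comp
  newlab[pos] <- roots[comp[pos] + 1L] - 1L
  newlab <- compact_labels(newlab)

  out <- labeling
  out$labels <- newlab
  out$n_labels <- max(newlab) + 1L
  out$stats <- supervoxel_statistics(out, gm, wm, csf)
  out
}

#' @export
print.supervoxel_labeling <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<supervoxel_labeling> %d x %d x %d, %d supervoxels, spacing %d\n",
              d[1], d[2], d[3], x$n_labels, x$spacing))
  cat(sprintf("  size: median %d [%d, %d]; mean per-tissue sd: GM %.2f WM %.2f CSF %.2f\n",
              stats::median(x$stats$size), min(x$stats$size), max(x$stats$size),
              mean(x$stats$sd_gm), mean(x$stats$sd_wm), mean(x$stats$sd_csf)))
  invisible(x)
}

#' Write a supervoxel labeling to disk
#'
#' The label field goes to an integer NIfTI volume, the per-supervoxel
#' statistics to a CSV.
#'
#' @param labeling a `supervoxel_labeling`.
#' @param nifti_path,csv_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_labeling <- function(labeling, nifti_path, csv_path) {
  write_volume(labeling$labels, nifti_path)
  write.csv(labeling$stats, csv_path, row.names = FALSE)
  invisible(c(nifti_path, csv_path))
}
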