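# Fixture builders and independent brute-force oracles. The oracles are
# plain nested loops written directly from the feature definitions; they
# share no code with the package internals they check.

# Random quantized volume triplet + mask + hand-made supervoxel partition
# (each of up to `k` labels seeded at a random masked voxel, voxels joined
# to the nearest seed).
random_histon_fixture <- function(seed, max_dim = 8L, max_labels = 4L) {
  set.seed(seed)
  n <- sample(4:max_dim, 1)
  d <- c(n, n, n)
  vol <- function(tissue) prob_volume(array(sample(0:255, prod(d), TRUE), d),
                                      tissue, levels = 256L)
  gm <- vol("GM"); wm <- vol("WM"); csf <- vol("CSF")
  mask_arr <- array(runif(prod(d)) < 0.85, d)
  if (!any(mask_arr)) mask_arr[1, 1, 1] <- TRUE
  mask <- structure(list(mask = mask_arr, included_voxels = sum(mask_arr)),
                    class = "brain_mask")
  k <- min(sample(1:max_labels, 1), mask$included_voxels)
  mi <- which(mask_arr, arr.ind = TRUE)
  seeds <- mi[sample(nrow(mi), k), , drop = FALSE]
  labels <- array(-1L, d)
  for (r in seq_len(nrow(mi))) {
    d2 <- rowSums(sweep(seeds, 2, mi[r, ])^2)
    labels[mi[r, 1], mi[r, 2], mi[r, 3]] <- which.min(d2) - 1L
  }
  labeling <- manual_labeling(labels, gm, wm, csf)
  list(gm = gm, wm = wm, csf = csf, mask = mask, labeling = labeling)
}

# Wrap a hand-made label array as a supervoxel_labeling with stats filled.
manual_labeling <- function(labels, gm, wm, csf, spacing = 2L) {
  labels <- svhiston:::compact_labels(labels)
  out <- structure(list(labels = labels, n_labels = max(labels) + 1L,
                        stats = NULL, spacing = spacing,
                        params = slic_params()),
                   class = "supervoxel_labeling")
  out$stats <- supervoxel_statistics(out, gm, wm, csf)
  out
}

# Expanse oracle: explicit two-pass loop over supervoxels and voxels.
oracle_expanse <- function(labeling, vols, mode = "mean_of_sds") {
  labels <- labeling$labels
  K <- labeling$n_labels
  out <- c(GM = 0, WM = 0, CSF = 0)
  for (t in seq_along(vols)) {
    per_sv <- numeric(K)
    for (k in seq_len(K) - 1L) {
      v <- vols[[t]]$data[labels == k]
      per_sv[k + 1L] <- if (mode == "mean_of_sds") {
        mu <- sum(v) / length(v)
        sqrt(sum((v - mu)^2) / length(v))
      } else sum(v) / length(v)
    }
    out[t] <- sum(per_sv) / K
  }
  out
}

# Similarity-field oracle: per-voxel loop over the three tissue channels.
oracle_similarity <- function(labeling, vols, expanse) {
  d <- dim(labeling$labels)
  K <- labeling$n_labels
  means <- lapply(vols, function(v)
    vapply(seq_len(K) - 1L,
           function(k) mean(v$data[labeling$labels == k]), numeric(1)))
  s2 <- array(0L, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    k <- labeling$labels[x, y, z]
    if (k < 0) next
    ok <- TRUE
    for (t in 1:3) {
      dt <- abs(vols[[t]]$data[x, y, z] - means[[t]][k + 1L])
      if (!(dt < expanse[[t]])) { ok <- FALSE; break }
    }
    s2[x, y, z] <- as.integer(ok)
  }
  s2
}

# Histon oracle: triple loop accumulating (1 + S2) into the centre bin.
oracle_histon <- function(volume, s2, mask, levels = 256L) {
  d <- dim(volume$data)
  h <- numeric(levels)
  base <- numeric(levels)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (!mask$mask[x, y, z]) next
    g <- volume$data[x, y, z] + 1L
    h[g] <- h[g] + 1 + s2[x, y, z]
    base[g] <- base[g] + 1
  }
  list(histon = h, histogram = base)
}

# Brute-force SLIC assignment: every (voxel, centroid) pair, no window.
oracle_assign <- function(cent, gm, wm, csf, mask, In, m) {
  d <- dim(gm)
  lab <- array(-1L, d)
  for (z in 1:d[3]) for (y in 1:d[2]) for (x in 1:d[1]) {
    if (!mask[x, y, z]) next
    best <- Inf; bk <- -1L
    for (k in seq_len(nrow(cent))) {
      dc2 <- (gm[x, y, z] - cent[k, 4])^2 + (wm[x, y, z] - cent[k, 5])^2 +
        (csf[x, y, z] - cent[k, 6])^2
      ds2 <- (x - 1 - cent[k, 1])^2 + (y - 1 - cent[k, 2])^2 +
        (z - 1 - cent[k, 3])^2
      dw <- dc2 / m^2 + ds2 / In^2
      if (dw < best) { best <- dw; bk <- k - 1L }
    }
    lab[x, y, z] <- bk
  }
  lab
}

# Check that every label's voxel set is one 6-connected component.
is_six_connected <- function(labels) {
  d <- dim(labels)
  cc <- svhiston:::label_components_cpp(as.vector(labels), d)
  length(cc$size) == max(labels) + 1L
}

# Small quantized phantom triplet for segmentation tests.
phantom_quantized <- function(seed, grid = 24L, cls = "CN", sigma = 0.02) {
  pp <- phantom_params(grid_size = grid, sigma = sigma)
  vols <- generate_phantom(cls, pp, seed = seed)
  mask <- build_brain_mask(vols$gm, vols$wm, vols$csf)
  list(gm = quantize(vols$gm), wm = quantize(vols$wm),
       csf = quantize(vols$csf), mask = mask)
}
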