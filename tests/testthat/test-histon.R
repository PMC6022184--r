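test_that("the two expanse modes implement their definitions and diverge", {
  n <- 4L
  mk <- function(x, t) prob_volume(array(x, c(n, n, n)), t, levels = 256L)
  gm <- mk(rep(100, n^3), "GM"); wm <- mk(rep(30, n^3), "WM")
  cf <- mk(rep(0, n^3), "CSF")
  labels <- array(0L, c(n, n, n)); labels[, , 3:4] <- 1L
  lb <- manual_labeling(labels, gm, wm, cf)
  e_sd <- compute_expanse(lb, "mean_of_sds")
  e_mu <- compute_expanse(lb, "mean_of_means")
  expect_equal(unclass(e_sd), c(GM = 0, WM = 0, CSF = 0), ignore_attr = TRUE)
  expect_equal(unclass(e_mu), c(GM = 100, WM = 30, CSF = 0),
               ignore_attr = TRUE)
})

test_that("mean-of-sds expanse averages per-supervoxel deviations", {
  # two supervoxels with population sds 2 and 4 -> threshold 3
  labels <- array(-1L, c(8, 1, 1))
  labels[1:8, 1, 1] <- rep(0:1, each = 4)
  mk <- function(x) prob_volume(array(x, c(8, 1, 1)), "GM", levels = 256L)
  gm <- mk(c(10, 10, 14, 14, 20, 20, 28, 28))  # sds 2 and 4
  z <- mk(rep(0, 8))
  lb <- manual_labeling(labels, gm, z, z)
  expect_equal(compute_expanse(lb, "mean_of_sds")[["GM"]], 3)
})

test_that("similarity field honours the strict inequality and the conjunction", {
  n <- 4L
  mk <- function(x, t) prob_volume(array(x, c(n, n, n)), t, levels = 256L)
  const <- mk(rep(50, n^3), "GM")
  z <- mk(rep(0, n^3), "CSF")
  lb <- manual_labeling(array(0L, c(n, n, n)), const, mk(rep(7, n^3), "WM"), z)
  # degenerate constant volume: E = 0 and dt = 0, 0 < 0 is false
  e0 <- compute_expanse(lb, "mean_of_sds")
  s2 <- compute_similarity_field(lb, const, mk(rep(7, n^3), "WM"), z, e0)
  expect_true(all(s2 == 0L))
  # voxel equal to its supervoxel mean in every tissue, all E > 0 -> similar
  e1 <- structure(c(GM = 1, WM = 1, CSF = 1), mode = "mean_of_sds",
                  class = "expanse_thresholds")
  s2 <- compute_similarity_field(lb, const, mk(rep(7, n^3), "WM"), z, e1)
  expect_true(all(s2[lb$labels >= 0] == 1L))
  # conjunction: failing one tissue alone vetoes similarity
  e_veto <- structure(c(GM = 1, WM = 0, CSF = 1), mode = "mean_of_sds",
                      class = "expanse_thresholds")
  s2 <- compute_similarity_field(lb, const, mk(rep(7, n^3), "WM"), z, e_veto)
  expect_true(all(s2 == 0L))
})

test_that("histon collapses to the histogram at S2=0 and doubles at S2=1", {
  set.seed(12)
  n <- 5L
  q <- prob_volume(array(sample(0:255, n^3, TRUE), c(n, n, n)), "GM",
                   levels = 256L)
  mask <- structure(list(mask = array(TRUE, c(n, n, n)),
                         included_voxels = n^3), class = "brain_mask")
  h0 <- compute_histon(q, array(0L, c(n, n, n)), mask)
  expect_identical(h0$histon, h0$histogram)
  h1 <- compute_histon(q, array(1L, c(n, n, n)), mask)
  expect_identical(h1$histon, 2 * h1$histogram)
  expect_equal(sum(h1$histon), 2 * n^3)
})

test_that("expanse, similarity field and histon match brute-force loops", {
  for (s in 101:110) {
    fx <- random_histon_fixture(s)
    vols <- list(fx$gm, fx$wm, fx$csf)
    for (mode in c("mean_of_sds", "mean_of_means")) {
      e <- compute_expanse(fx$labeling, mode)
      expect_equal(unclass(e), oracle_expanse(fx$labeling, vols, mode),
                   ignore_attr = TRUE)
    }
    e <- compute_expanse(fx$labeling, "mean_of_sds")
    s2 <- compute_similarity_field(fx$labeling, fx$gm, fx$wm, fx$csf, e)
    expect_identical(as.integer(s2), as.integer(oracle_similarity(fx$labeling,
                                                                  vols, e)))
    want <- oracle_histon(fx$gm, s2, fx$mask)
    got <- compute_histon(fx$gm, s2, fx$mask)
    expect_identical(got$histon, want$histon)
    expect_identical(got$histogram, want$histogram)
  }
})

test_that("histon invariants: bin sandwich and exact mass", {
  for (s in c(7, 8)) {
    fx <- random_histon_fixture(s, max_dim = 8L)
    e <- compute_expanse(fx$labeling, "mean_of_sds")
    s2 <- compute_similarity_field(fx$labeling, fx$gm, fx$wm, fx$csf, e)
    for (v in list(fx$gm, fx$wm, fx$csf)) {
      h <- compute_histon(v, s2, fx$mask)
      expect_true(all(h$histogram <= h$histon))
      expect_true(all(h$histon <= 2 * h$histogram))
      expect_equal(sum(h$histon), fx$mask$included_voxels + sum(s2))
    }
  }
})

test_that("the histon is sensitive to spatial shuffling, the histogram is not", {
  fx <- phantom_quantized(5, grid = 20L, sigma = 0.05)
  seg <- slic_segment(fx$gm, fx$wm, fx$csf, fx$mask,
                      slic_params(n_supervoxels = 50L))
  e <- compute_expanse(seg)
  s2 <- compute_similarity_field(seg, fx$gm, fx$wm, fx$csf, e)
  h <- compute_histon(fx$gm, s2, fx$mask)

  # permute all three channels with one permutation inside the mask
  set.seed(99)
  idx <- which(fx$mask$mask)
  perm <- sample(idx)
  shuffle <- function(v) {
    d <- v$data; d[idx] <- d[perm]
    prob_volume(d, v$tissue, levels = v$levels)
  }
  sg <- shuffle(fx$gm); sw <- shuffle(fx$wm); sc <- shuffle(fx$csf)
  seg_s <- slic_segment(sg, sw, sc, fx$mask, slic_params(n_supervoxels = 50L))
  e_s <- compute_expanse(seg_s)
  s2_s <- compute_similarity_field(seg_s, sg, sw, sc, e_s)
  h_s <- compute_histon(sg, s2_s, fx$mask)
  expect_identical(h$histogram, h_s$histogram)
  expect_false(identical(h$histon, h_s$histon))
})

test_that("feature vectors have 768 components and are deterministic", {
  pp <- phantom_params(grid_size = 24L)
  vols <- generate_phantom("CN", pp, seed = 31)
  fv <- extract_feature_vector(vols, slic_params(n_supervoxels = 80L))
  expect_length(fv$vector, 768L)
  expect_identical(fv$vector,
                   c(fv$histons[, "GM"], fv$histons[, "WM"],
                     fv$histons[, "CSF"]))
  fv2 <- extract_feature_vector(generate_phantom("CN", pp, seed = 31),
                                slic_params(n_supervoxels = 80L))
  expect_identical(fv$vector, fv2$vector)
  # histogram-only ablation produces the plain histogram concatenation
  fh <- extract_feature_vector(vols, slic_params(n_supervoxels = 80L),
                               histogram_only = TRUE)
  expect_identical(fh$vector,
                   c(fv$histograms[, "GM"], fv$histograms[, "WM"],
                     fv$histograms[, "CSF"]))
  zero <- prob_volume(array(0, c(8, 8, 8)), "GM")
  expect_error(extract_feature_vector(
    list(gm = zero, wm = prob_volume(array(0, c(8, 8, 8)), "WM"),
         csf = prob_volume(array(0, c(8, 8, 8)), "CSF"))), "empty")
})

test_that("classic neighbourhood histon matches its closed-form limits", {
  set.seed(3)
  img <- array(sample(0:15, 25, TRUE), c(5, 5))
  inf_case <- classic_histon(img, c(3, 3), Inf, levels = 16L)
  expect_identical(inf_case$histons[, 1], 2 * inf_case$histograms[, 1])
  zero_case <- classic_histon(img, c(3, 3), 0, levels = 16L)
  expect_identical(zero_case$histons[, 1], zero_case$histograms[, 1])
  expect_error(classic_histon(img, c(7, 7), 1), "larger than image")
})

test_that("classic histon reproduces a hand-computed toy image", {
  # 3x3 zero image with a single 5 in the centre, 3x3 window clipped at the
  # border. Every window contains the centre, so dt = 25 for each zero
  # pixel; the centre sees eight zeros, dt = 8 * 25 = 200. With E = 100 the
  # eight zeros are similar (bin0 = 8 * 2 = 16) and the centre is not
  # (bin5 = 1); with E = 25 the strict inequality excludes everything.
  img <- array(0L, c(3, 3)); img[2, 2] <- 5L
  got <- classic_histon(img, c(3, 3), 100, levels = 8L)
  expect_identical(got$histons[, 1], c(16, 0, 0, 0, 0, 1, 0, 0))
  expect_identical(got$histograms[, 1], c(8, 0, 0, 0, 0, 1, 0, 0))
  strict <- classic_histon(img, c(3, 3), 25, levels = 8L)
  expect_identical(strict$histons[, 1], strict$histograms[, 1])
  # and against an independent full-loop evaluation on a larger image
  set.seed(8)
  img2 <- array(sample(0:7, 36, TRUE), c(6, 6))
  got2 <- classic_histon(img2, c(3, 3), 10, levels = 8L)
  s_want <- array(0L, c(6, 6))
  for (x in 1:6) for (y in 1:6) {
    xs <- max(1, x - 1):min(6, x + 1); ys <- max(1, y - 1):min(6, y + 1)
    dt <- sum((img2[x, y] - img2[xs, ys])^2)
    s_want[x, y] <- as.integer(dt < 10)
  }
  expect_identical(got2$s, s_want)
  h_want <- tabulate(img2 + 1L, 8L) + tabulate(img2[s_want == 1L] + 1L, 8L)
  expect_identical(got2$histons[, 1], as.numeric(h_want))
})
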