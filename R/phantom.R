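#' Parameters of the synthetic brain phantom generator
#'
#' The phantom emulates the output of unified tissue segmentation: three
#' spatially smooth probability volumes (GM, WM, CSF) summing to at most 1
#' inside a head-shaped region and exactly 0 outside. Geometry is a set of
#' concentric smoothed ellipsoids — WM core, GM shell, CSF rim — with a
#' mild fixed anisotropy. Two orthogonal class effects mimic the disease
#' signature:
#' \describe{
#'   \item{atrophy `delta_gm`}{the AD class moves this fraction of GM
#'     probability mass into CSF, shrinking total GM volume;}
#'   \item{ambiguity `omega`}{the width (voxels) of the smooth transition
#'     zone between tissues; a wider zone in AD produces more voxels of
#'     intermediate, ambiguous tissue probability.}
#' }
#' Additive Gaussian segmentation noise of sd `sigma` (probability units)
#' is applied inside the head only, then clipped to \[0, 1\] and
#' renormalized wherever the tissue sum exceeds 1.
#'
#' @param grid_size voxels per axis (cubic grid).
#' @param wm_radius,gm_radius,csf_radius ellipsoid base radii in voxels
#'   (must be increasing); defaults scale with `grid_size`.
#' @param delta_gm AD atrophy fraction in \[0, 0.5\].
#' @param omega_ad,omega_cn per-class transition widths (voxels).
#' @param sigma noise standard deviation (probability units).
#' @param jitter per-subject uniform radius jitter (fraction).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_size = 48L,
                           wm_radius = 10 * grid_size / 48,
                           gm_radius = 16 * grid_size / 48,
                           csf_radius = 19 * grid_size / 48,
                           delta_gm = 0.2, omega_ad = 3, omega_cn = 1,
                           sigma = 0.02, jitter = 0.05) {
  stopifnot(grid_size >= 8, wm_radius < gm_radius, gm_radius < csf_radius,
            delta_gm >= 0, delta_gm <= 0.5, omega_ad >= 0, omega_cn >= 0,
            sigma >= 0, jitter >= 0)
  structure(list(grid_size = as.integer(grid_size), wm_radius = wm_radius,
                 gm_radius = gm_radius, csf_radius = csf_radius,
                 delta_gm = delta_gm, omega_ad = omega_ad,
                 omega_cn = omega_cn, sigma = sigma, jitter = jitter),
            class = "phantom_params")
}

# Anisotropy of the ellipsoids (x, y, z semi-axis factors), fixed.
PHANTOM_ANISOTROPY <- c(1, 0.9, 0.8)

# Inside-probability of a smoothed ellipsoid: 1 well inside radius r, 0
# well outside, cubic smoothstep over a transition band of width omega.
smooth_inside <- function(d, r, omega) {
  if (omega <= 1e-9) return(as.numeric(d < r))
  t <- pmin(pmax((d - (r - omega / 2)) / omega, 0), 1)
  1 - (3 * t^2 - 2 * t^3)
}

#' Generate one synthetic subject (three tissue probability volumes)
#'
#' @param cls `"AD"` or `"CN"`; AD gets the wider transition zone
#'   (`omega_ad`) and the `delta_gm` atrophy mass shift.
#' @param params a [phantom_params] object.
#' @param seed RNG seed; the phantom is bit-reproducible per
#'   (cls, params, seed).
#' @param radius_scale optional length-3 multiplier on (wm, gm, csf) radii,
#'   used for per-subject geometry jitter.
#' @return Named list of unquantized [prob_volume]s `gm`, `wm`, `csf`.
#' @export
generate_phantom <- function(cls = c("CN", "AD"), params = phantom_params(),
                             seed = 1L, radius_scale = c(1, 1, 1)) {
  cls <- match.arg(cls)
  g <- params$grid_size
  omega <- if (cls == "AD") params$omega_ad else params$omega_cn
  radii <- c(params$wm_radius, params$gm_radius, params$csf_radius) *
    radius_scale
  if (any(diff(radii) <= 0))
    stop("jittered radii lost their ordering", call. = FALSE)
  if (max(radii) * max(PHANTOM_ANISOTROPY) + omega / 2 >= g / 2)
    stop("geometry radii exceed the grid", call. = FALSE)

  ctr <- (g - 1) / 2
  ax <- PHANTOM_ANISOTROPY
  x <- ((0:(g - 1)) - ctr) / ax[1]
  y <- ((0:(g - 1)) - ctr) / ax[2]
  z <- ((0:(g - 1)) - ctr) / ax[3]
  d <- sqrt(outer(outer(x^2, y^2, "+"), z^2, "+"))

  f_wm <- smooth_inside(d, radii[1], omega)
  f_gm <- smooth_inside(d, radii[2], omega)
  f_csf <- smooth_inside(d, radii[3], omega)
  wm <- f_wm
  gm <- f_gm - f_wm
  csf <- f_csf - f_gm

  if (cls == "AD" && params$delta_gm > 0) {
    shift <- params$delta_gm * gm
    gm <- gm - shift
    csf <- csf + shift
  }

  if (params$sigma > 0) {
    set.seed(seed)
    head <- (wm + gm + csf) > 0
    nh <- sum(head)
    wm[head] <- wm[head] + rnorm(nh, 0, params$sigma)
    gm[head] <- gm[head] + rnorm(nh, 0, params$sigma)
    csf[head] <- csf[head] + rnorm(nh, 0, params$sigma)
    wm <- pmin(pmax(wm, 0), 1)
    gm <- pmin(pmax(gm, 0), 1)
    csf <- pmin(pmax(csf, 0), 1)
    tot <- wm + gm + csf
    over <- tot > 1
    if (any(over)) {
      wm[over] <- wm[over] / tot[over]
      gm[over] <- gm[over] / tot[over]
      csf[over] <- csf[over] / tot[over]
    }
  }
  dm <- c(g, g, g)
  list(gm = prob_volume(array(gm, dm), "GM"),
       wm = prob_volume(array(wm, dm), "WM"),
       csf = prob_volume(array(csf, dm), "CSF"))
}

#' Generate a synthetic AD/CN cohort
#'
#' Per-subject seeds and +/- `jitter` radius factors are derived from the
#' master seed, so the whole cohort is reproducible from `(params, seed)`.
#' Ages are uniform on 60-90 and genders balanced within each class, giving
#' the split protocol realistic strata.
#'
#' @param n_ad,n_cn subjects per class.
#' @param params a [phantom_params] object.
#' @param seed master seed.
#' @param dir if non-NULL, volumes are written as NIfTI files and a
#'   `manifest.csv` into this directory; otherwise volumes stay in memory.
#' @return An object of class `synthetic_cohort`: `manifest` (data.frame)
#'   and `volumes` (per-subject list of the three [prob_volume]s, NULL when
#'   written to disk).
#' @export
generate_cohort <- function(n_ad = 20L, n_cn = 20L,
                            params = phantom_params(), seed = 1L,
                            dir = NULL) {
  stopifnot(n_ad >= 1, n_cn >= 1)
  n <- n_ad + n_cn
  set.seed(seed)
  subj_seed <- sample.int(.Machine$integer.max - 1L, n)
  scales <- matrix(runif(3 * n, 1 - params$jitter, 1 + params$jitter),
                   nrow = n)
  ages <- round(runif(n, 60, 90))
  label <- c(rep("AD", n_ad), rep("CN", n_cn))
  gender <- c(rep_len(c("M", "F"), n_ad), rep_len(c("M", "F"), n_cn))
  ids <- sprintf("S%03d_%s", seq_len(n), label)

  volumes <- vector("list", n)
  man <- data.frame(subject_id = ids, label = label, age = ages,
                    gender = gender,
                    gm_path = NA_character_, wm_path = NA_character_,
                    csf_path = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    vols <- generate_phantom(label[i], params, seed = subj_seed[i],
                             radius_scale = scales[i, ])
    if (is.null(dir)) {
      volumes[[i]] <- vols
    } else {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      for (t in c("gm", "wm", "csf")) {
        fn <- sprintf("%s_%s.nii.gz", ids[i], t)
        write_volume(vols[[t]], file.path(dir, fn))
        man[[paste0(t, "_path")]][i] <- fn
      }
    }
  }
  if (!is.null(dir)) {
    write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
    volumes <- NULL
  }
  structure(list(manifest = man, volumes = volumes, params = params,
                 seed = seed, dir = dir),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (AD %d / CN %d), grid %d^3%s\n",
              nrow(x$manifest), sum(x$manifest$label == "AD"),
              sum(x$manifest$label == "CN"), x$params$grid_size,
              if (is.null(x$dir)) ", in memory"
              else paste0(", written to ", x$dir)))
  invisible(x)
}

#' Per-subject volume access for a cohort
#'
#' @param cohort a [generate_cohort] result.
#' @param i subject index.
#' @return Named list of the subject's three [prob_volume]s.
#' @export
cohort_subject_volumes <- function(cohort, i) {
  if (!is.null(cohort$volumes)) return(cohort$volumes[[i]])
  row <- cohort$manifest[i, ]
  base <- cohort$dir
  list(gm = read_probability_volume(file.path(base, row$gm_path), "GM"),
       wm = read_probability_volume(file.path(base, row$wm_path), "WM"),
       csf = read_probability_volume(file.path(base, row$csf_path), "CSF"))
}
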