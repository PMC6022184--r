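#' Fit a PCA reduction on training features
#'
#' Columns are centred and (by default) scaled to unit variance using the
#' training rows only; zero-variance columns are dropped with a message.
#' `n_components = "scree"` automates the scree-elbow rule: the component
#' index with the largest drop between consecutive eigenvalues is taken as
#' the elbow (floor 2, ceiling 30, fallback 5 when the spectrum is
#' degenerate).
#'
#' @param x numeric training matrix (rows = subjects).
#' @param n_components integer, or `"scree"` for automatic selection.
#' @param scale logical; standardize columns to unit variance.
#' @return An object of class `pca_model` with orthonormal loadings,
#'   eigenvalues, centering/scaling vectors and the retained column set.
#' @export
fit_pca <- function(x, n_components = "scree", scale = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) stop("fewer than 3 training rows", call. = FALSE)
  v <- apply(x, 2, stats::var)
  keep <- which(v > 0)
  if (length(keep) < ncol(x))
    message(sprintf("fit_pca: dropping %d zero-variance columns",
                    ncol(x) - length(keep)))
  if (length(keep) < 2L) stop("fewer than 2 informative columns", call. = FALSE)
  p <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = scale)
  ev <- p$sdev^2
  k_max <- min(length(ev), nrow(x) - 1L, length(keep))
  if (identical(n_components, "scree")) {
    m <- min(30L, k_max)
    drops <- ev[seq_len(m - 1L)] - ev[seq_len(m - 1L) + 1L]
    k <- if (m < 2L || all(!is.finite(drops)) || max(drops) <= 0) 5L
         else which.max(drops)
    k <- min(max(k, 2L), 30L)
  } else {
    k <- as.integer(n_components)
  }
  k <- min(k, k_max)
  structure(list(loadings = p$rotation[, seq_len(k), drop = FALSE],
                 eigenvalues = ev, n_components = k,
                 center = p$center,
                 scale = if (scale) p$scale else NULL,
                 columns = keep, p = ncol(x)),
            class = "pca_model")
}

#' @export
predict.pca_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)[, object$columns, drop = FALSE]
  newdata <- sweep(newdata, 2, object$center)
  if (!is.null(object$scale)) newdata <- sweep(newdata, 2, object$scale, "/")
  newdata %*% object$loadings
}

#' @export
print.pca_model <- function(x, ...) {
  tot <- sum(x$eigenvalues)
  cat(sprintf("<pca_model> %d components retained of %d, %.1f%% variance\n",
              x$n_components, length(x$eigenvalues),
              100 * sum(x$eigenvalues[seq_len(x$n_components)]) / tot))
  invisible(x)
}

#' Train a soft-margin SVM on reduced features
#'
#' Backed by the standard R SVM implementation with its default
#' parameters: cost 1, gamma 1/dimension, degree 3; no hyperparameter
#' search.
#'
#' @param x numeric feature matrix (rows = subjects).
#' @param y labels, `"AD"` (positive) or `"CN"`.
#' @param kernel `"linear"`, `"polynomial"` or `"radial"`.
#' @param cost soft-margin cost parameter.
#' @param gamma kernel width for polynomial/radial (default 1/ncol).
#' @param degree polynomial degree.
#' @return A fitted `e1071::svm` object.
#' @export
train_svm <- function(x, y, kernel = c("linear", "polynomial", "radial"),
                      cost = 1, gamma = NULL, degree = 3) {
  kernel <- match.arg(kernel)
  y <- factor(y, levels = c("AD", "CN"))
  if (nlevels(droplevels(y)) < 2L)
    stop("single-class training set", call. = FALSE)
  if (is.null(gamma)) gamma <- 1 / ncol(x)
  e1071::svm(as.matrix(x), y, kernel = kernel, cost = cost, gamma = gamma,
             degree = degree, scale = FALSE)
}

#' Fit the histon classifier: PCA reduction followed by an SVM
#'
#' The package's central model. Training features are standardized and
#' reduced by [fit_pca] (training statistics only), then a soft-margin SVM
#' with default parameters is fitted on the component scores. AD is the
#' positive class.
#'
#' @param x numeric feature matrix (rows = subjects, e.g. 768 histon bins).
#' @param y labels `"AD"` / `"CN"`.
#' @param n_components passed to [fit_pca].
#' @param kernel,cost,gamma,degree passed to [train_svm].
#' @param scale standardize columns before PCA.
#' @return An object of class `histon_svm`.
#' @export
histon_svm <- function(x, y, n_components = "scree",
                       kernel = "linear", cost = 1, gamma = NULL,
                       degree = 3, scale = TRUE) {
  x <- as.matrix(x)
  pca <- fit_pca(x, n_components, scale = scale)
  scores <- predict(pca, x)
  model <- train_svm(scores, y, kernel, cost, gamma, degree)
  structure(list(pca = pca, svm = model, kernel = kernel, cost = cost,
                 n_train = nrow(x),
                 class_counts = table(factor(y, levels = c("AD", "CN")))),
            class = "histon_svm")
}

#' @export
predict.histon_svm <- function(object, newdata, decision_values = FALSE, ...) {
  scores <- predict(object$pca, as.matrix(newdata))
  pred <- predict(object$svm, scores, decision.values = decision_values)
  if (decision_values)
    attr(pred, "decision.values") <- attr(pred, "decision.values")
  pred
}

#' @export
print.histon_svm <- function(x, ...) {
  cat(sprintf("<histon_svm> %s kernel, cost %g, %d PCA components, %d training subjects (AD %d / CN %d)\n",
              x$kernel, x$cost, x$pca$n_components, x$n_train,
              x$class_counts[["AD"]], x$class_counts[["CN"]]))
  invisible(x)
}

#' @export
summary.histon_svm <- function(object, ...) {
  print(object)
  ev <- object$pca$eigenvalues
  k <- object$pca$n_components
  cat(sprintf("  variance explained by %d components: %.1f%%\n", k,
              100 * sum(ev[seq_len(k)]) / sum(ev)))
  cat(sprintf("  support vectors: %d\n", nrow(object$svm$SV)))
  invisible(object)
}

#' Back-projected linear weights of the histon classifier
#'
#' For a linear kernel, the SVM weight vector in PCA-score space is mapped
#' back through the loadings (and the standardization) to one weight per
#' original feature bin — the direction in histon space separating AD from
#' CN.
#'
#' @param object a `histon_svm` with linear kernel.
#' @param ... unused.
#' @return Named numeric vector of per-bin weights.
#' @export
coef.histon_svm <- function(object, ...) {
  if (object$kernel != "linear")
    stop("coefficients only defined for the linear kernel", call. = FALSE)
  w_scores <- crossprod(object$svm$coefs, object$svm$SV)[1, ]
  w <- as.vector(object$pca$loadings %*% w_scores)
  if (!is.null(object$pca$scale)) w <- w / object$pca$scale
  out <- rep(0, object$pca$p)
  out[object$pca$columns] <- w
  out
}

#' Scree plot of the fitted PCA spectrum
#'
#' @param x a `histon_svm` or `pca_model`.
#' @param n_show number of leading eigenvalues to draw.
#' @param ... passed to [graphics::plot].
#' @export
plot.histon_svm <- function(x, n_show = 30, ...) {
  ev <- x$pca$eigenvalues
  n <- min(n_show, length(ev))
  graphics::plot(seq_len(n), ev[seq_len(n)], type = "b",
                 xlab = "principal component", ylab = "eigenvalue",
                 main = "Scree plot", ...)
  graphics::abline(v = x$pca$n_components, lty = 2)
  invisible(x)
}

#' Seven confusion-based performance metrics
#'
#' Acc = (TP+TN)/(P+N); NPV = TN/(TN+FN); PPV = TP/(TP+FP);
#' Sen = TP/(TP+FN); Spe = TN/(TN+FP); Fscore = 2 Sen PPV / (Sen + PPV);
#' Bacc = (Spe+Sen)/2. Zero-denominator ratios are reported as `NA` with a
#' warning, never silently zero. AD is the positive class.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return An object of class `metrics_report`.
#' @export
confusion_metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  ratio <- function(num, den, name) {
    if (den == 0) {
      warning(sprintf("%s undefined: zero denominator", name), call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  acc <- ratio(tp + tn, tp + tn + fp + fn, "Acc")
  sen <- ratio(tp, tp + fn, "Sen")
  spe <- ratio(tn, tn + fp, "Spe")
  ppv <- ratio(tp, tp + fp, "PPV")
  npv <- ratio(tn, tn + fn, "NPV")
  fsc <- if (is.na(sen) || is.na(ppv) || (sen + ppv) == 0) {
    if (!is.na(sen) && !is.na(ppv))
      warning("Fscore undefined: Sen + PPV is zero", call. = FALSE)
    NA_real_
  } else 2 * sen * ppv / (sen + ppv)
  bacc <- if (is.na(sen) || is.na(spe)) NA_real_ else (spe + sen) / 2
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 Acc = acc, Bacc = bacc, NPV = npv, PPV = ppv,
                 Sen = sen, Spe = spe, Fscore = fsc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metrics_report> TP %d TN %d FP %d FN %d\n",
              x$TP, x$TN, x$FP, x$FN))
  m <- unlist(x[c("Acc", "Bacc", "NPV", "PPV", "Sen", "Spe", "Fscore")])
  print(round(m, digits))
  invisible(x)
}

metrics_from_predictions <- function(pred, truth) {
  pred <- factor(pred, levels = c("AD", "CN"))
  truth <- factor(truth, levels = c("AD", "CN"))
  stopifnot(length(pred) == length(truth))
  confusion_metrics(tp = sum(pred == "AD" & truth == "AD"),
                    tn = sum(pred == "CN" & truth == "CN"),
                    fp = sum(pred == "AD" & truth == "CN"),
                    fn = sum(pred == "CN" & truth == "AD"))
}

#' Evaluate a fitted histon classifier on held-out subjects
#'
#' @param object a `histon_svm` fitted on training rows only.
#' @param newdata test feature matrix.
#' @param truth test labels (`"AD"` / `"CN"`).
#' @return A [confusion_metrics] report with the predictions attached as
#'   attribute `predictions`.
#' @export
evaluate <- function(object, newdata, truth) {
  if (nrow(as.matrix(newdata)) == 0L) stop("empty test set", call. = FALSE)
  pred <- predict(object, newdata)
  rep <- metrics_from_predictions(pred, truth)
  attr(rep, "predictions") <- pred
  rep
}

# Age decade used as a stratification key (60s, 70s, ...).
age_decade <- function(age) paste0(10 * (floor(age / 10)), "s")

#' Repeated stratified 80/20 split plan
#'
#' Ten (by default) random train/test splits preserving the joint
#' distribution of label, gender and age decade: within each stratum, test
#' slots are allocated proportionally with largest-remainder rounding.
#' Strata containing a single subject trigger a collapse of the
#' stratification (age decade dropped first, then gender) with a warning.
#'
#' @param subjects data.frame with at least `label`, `gender`, `age`.
#' @param n_splits number of random splits.
#' @param test_frac held-out fraction per split.
#' @param seed RNG seed making the plan reproducible.
#' @return An object of class `split_plan`: a list of
#'   `(train, test)` index pairs plus metadata.
#' @export
make_splits <- function(subjects, n_splits = 10L, test_frac = 0.2,
                        seed = 1L) {
  n <- nrow(subjects)
  if (n < 10L) stop("need at least 10 subjects", call. = FALSE)
  if (length(unique(subjects$label)) < 2L)
    stop("both classes must be present", call. = FALSE)

  keysets <- list(c("label", "gender", "decade"), c("label", "gender"),
                  "label")
  subjects$decade <- age_decade(subjects$age)
  strata <- NULL
  for (ks in keysets) {
    strata <- interaction(subjects[ks], drop = TRUE)
    if (min(table(strata)) >= 2L) break
    if (!identical(ks, keysets[[length(keysets)]]))
      warning(sprintf("stratum with a single subject; collapsing to (%s)",
                      paste(setdiff(ks, ks[length(ks)]), collapse = ", ")),
              call. = FALSE)
  }

  n_test_total <- round(test_frac * n)
  sizes <- table(strata)
  quota <- test_frac * as.numeric(sizes)
  base <- floor(quota)
  rem <- n_test_total - sum(base)
  frac <- quota - base
  extra <- integer(length(sizes))
  if (rem > 0) {
    ord <- order(-frac, seq_along(frac))
    extra[ord[seq_len(rem)]] <- 1L
  } else if (rem < 0) {
    ord <- order(frac, seq_along(frac))
    take <- ord[base[ord] > 0][seq_len(-rem)]
    extra[take] <- -1L
  }
  n_test_stratum <- base + extra

  set.seed(seed)
  splits <- lapply(seq_len(n_splits), function(s) {
    test <- integer(0)
    for (i in seq_along(levels(strata))) {
      idx <- which(strata == levels(strata)[i])
      k <- n_test_stratum[i]
      if (k > 0) test <- c(test, sample(idx, k))
    }
    test <- sort(test)
    list(train = setdiff(seq_len(n), test), test = test)
  })
  structure(list(splits = splits, n_splits = n_splits,
                 test_frac = test_frac, seed = seed,
                 strata = as.character(strata)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d splits, test fraction %.2f, %d strata, seed %d\n",
              x$n_splits, x$test_frac, length(unique(x$strata)), x$seed))
  invisible(x)
}

#' Run the repeated-split evaluation protocol
#'
#' For each split: fit [histon_svm] on the training rows, evaluate on the
#' test rows, and collect the seven metrics. Per-split reports, their mean,
#' and the per-split predictions (for paired McNemar comparisons) are
#' returned.
#'
#' @param x feature matrix (all subjects).
#' @param y labels.
#' @param plan a [make_splits] plan.
#' @param ... passed to [histon_svm].
#' @return An object of class `split_eval`.
#' @export
evaluate_splits <- function(x, y, plan, ...) {
  x <- as.matrix(x)
  reports <- vector("list", plan$n_splits)
  preds <- vector("list", plan$n_splits)
  for (s in seq_len(plan$n_splits)) {
    sp <- plan$splits[[s]]
    fit <- histon_svm(x[sp$train, , drop = FALSE], y[sp$train], ...)
    rep <- evaluate(fit, x[sp$test, , drop = FALSE], y[sp$test])
    reports[[s]] <- rep
    preds[[s]] <- data.frame(index = sp$test,
                             truth = as.character(y[sp$test]),
                             pred = as.character(attr(rep, "predictions")),
                             stringsAsFactors = FALSE)
  }
  structure(list(reports = reports, predictions = preds, plan = plan),
            class = "split_eval")
}

#' Per-split and mean metrics of a repeated-split evaluation
#'
#' @param object a `split_eval`.
#' @param ... unused.
#' @return A data.frame: one row per split plus a `mean` row.
#' @export
summary.split_eval <- function(object, ...) {
  cols <- c("Acc", "Bacc", "NPV", "PPV", "Sen", "Spe", "Fscore")
  tab <- t(vapply(object$reports,
                  function(r) unlist(r[cols]), numeric(length(cols))))
  tab <- as.data.frame(tab)
  tab$split <- seq_len(nrow(tab))
  means <- colMeans(tab[cols], na.rm = TRUE)
  out <- rbind(tab[c("split", cols)],
               data.frame(split = NA, as.list(means)))
  rownames(out) <- c(seq_len(nrow(tab)), "mean")
  out
}

#' @export
print.split_eval <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<split_eval> %d splits; mean metrics:\n", x$plan$n_splits))
  print(round(s[nrow(s), -1], 4))
  invisible(x)
}

#' Mean of one metric over the splits
#'
#' @param eval a `split_eval`.
#' @param metric metric name (default `"Bacc"`).
#' @return Numeric mean over splits (NA splits excluded).
#' @export
mean_metric <- function(eval, metric = "Bacc") {
  mean(vapply(eval$reports, function(r) r[[metric]], numeric(1)), na.rm = TRUE)
}

#' McNemar comparison of two paired classifiers
#'
#' b counts subjects classifier A gets right and B wrong; c the converse.
#' The continuity-corrected statistic (|b-c|-1)^2/(b+c) is referred to a
#' chi-square distribution with 1 df. When b + c = 0 the classifiers never
#' disagree and p = 1. An exact binomial variant is available for small
#' discordant counts.
#'
#' @param pred_a,pred_b predictions of the two classifiers on the same
#'   subjects.
#' @param truth true labels.
#' @param exact use the exact binomial test on (b, b + c) instead of the
#'   chi-square approximation.
#' @return A list with `statistic`, `p_value`, `b`, `c`.
#' @export
mcnemar_compare <- function(pred_a, pred_b, truth, exact = FALSE) {
  if (length(pred_a) != length(pred_b) || length(pred_a) != length(truth))
    stop("prediction/truth length mismatch", call. = FALSE)
  ok_a <- as.character(pred_a) == as.character(truth)
  ok_b <- as.character(pred_b) == as.character(truth)
  b <- sum(ok_a & !ok_b)
  cc <- sum(!ok_a & ok_b)
  if (b + cc == 0)
    return(list(statistic = 0, p_value = 1, b = b, c = cc))
  if (exact) {
    p <- binom.test(b, b + cc, 0.5)$p.value
    return(list(statistic = NA_real_, p_value = p, b = b, c = cc))
  }
  stat <- (abs(b - cc) - 1)^2 / (b + cc)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE),
       b = b, c = cc)
}

# Deterministic label-stratified fold assignment (round-robin within class).
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
  }
  folds
}

#' Voxel-feature SVM baseline with cost grid search
#'
#' The comparison baseline: subjects are represented by their flattened
#' grey-matter voxel vectors and classified by a linear-kernel SVM whose
#' cost parameter is chosen by exhaustive grid search over 2^-5 .. 2^5,
#' maximizing balanced accuracy in an inner 5-fold cross-validation on the
#' training subjects (ties to the smallest cost). Train and test must not
#' share subjects.
#'
#' @param x_train,x_test voxel feature matrices (rows = subjects).
#' @param y_train,y_test labels.
#' @param id_train,id_test subject identifiers used for the leakage guard.
#' @param costs cost grid.
#' @param inner_folds inner CV fold count.
#' @return A [confusion_metrics] report with attributes `predictions` and
#'   `cost` (the selected cost).
#' @export
voxel_baseline <- function(x_train, y_train, x_test, y_test,
                           id_train, id_test,
                           costs = 2^(-5:5), inner_folds = 5L) {
  if (length(intersect(id_train, id_test)))
    stop("train/test subject overlap (leakage)", call. = FALSE)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- factor(y_train, levels = c("AD", "CN"))
  if (ncol(x_train) > 4L * nrow(x_train)) {
    # Gram-matrix trick: a linear SVM only sees dot products, which live in
    # the span of the training rows. Rotating onto a training-derived
    # orthonormal basis preserves every training kernel value and every
    # decision value on test rows (their out-of-span component is
    # orthogonal to the weight vector), at a fraction of the cost.
    v <- svd(x_train, nu = 0)$v
    x_test <- x_test %*% v
    x_train <- x_train %*% v
  }
  folds <- stratified_folds(as.character(y_train), inner_folds)
  cv_bacc <- vapply(costs, function(cost) {
    baccs <- vapply(seq_len(inner_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (nlevels(droplevels(y_train[tr])) < 2L || !any(te)) return(NA_real_)
      fit <- e1071::svm(x_train[tr, , drop = FALSE], y_train[tr],
                        kernel = "linear", cost = cost, scale = FALSE)
      pred <- predict(fit, x_train[te, , drop = FALSE])
      r <- suppressWarnings(metrics_from_predictions(pred, y_train[te]))
      r$Bacc
    }, numeric(1))
    mean(baccs, na.rm = TRUE)
  }, numeric(1))
  best <- costs[which.max(cv_bacc)]  # which.max takes the first (smallest) tie
  fit <- e1071::svm(x_train, y_train, kernel = "linear", cost = best,
                    scale = FALSE)
  pred <- predict(fit, x_test)
  rep <- metrics_from_predictions(pred, y_test)
  attr(rep, "predictions") <- pred
  attr(rep, "cost") <- best
  attr(rep, "cv_bacc") <- setNames(cv_bacc, costs)
  rep
}

#' Compare SVM kernels under the repeated-split protocol
#'
#' Runs [evaluate_splits] once per kernel (linear, polynomial degree 3,
#' radial with gamma 1/dimension) on identical splits and tabulates the
#' mean metrics.
#'
#' @param x feature matrix.
#' @param y labels.
#' @param plan a [make_splits] plan.
#' @param kernels kernels to compare.
#' @param ... passed to [histon_svm].
#' @return A data.frame of mean metrics, one row per kernel.
#' @export
compare_kernels <- function(x, y, plan,
                            kernels = c("linear", "polynomial", "radial"),
                            ...) {
  rows <- lapply(kernels, function(k) {
    ev <- evaluate_splits(x, y, plan, kernel = k, ...)
    s <- summary(ev)
    cbind(kernel = k, s[nrow(s), -1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
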