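make_gaussian_cohort <- function(n_per_class, p = 30, shift = 2, seed = 1,
                                 shift_cols = min(3L, p)) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * p), n, p)
  sc <- seq_len(shift_cols)
  x[seq_len(n_per_class), sc] <- x[seq_len(n_per_class), sc] + shift
  y <- rep(c("AD", "CN"), each = n_per_class)
  man <- data.frame(subject_id = sprintf("s%02d", seq_len(n)), label = y,
                    age = round(seq(60, 89, length.out = n)),
                    gender = rep_len(c("M", "F"), n))
  list(x = x, y = y, manifest = man)
}

test_that("PCA recovers exact low-rank structure and conserves variance", {
  set.seed(5)
  basis <- matrix(rnorm(2 * 20), 2, 20)
  scores <- matrix(rnorm(12 * 2), 12, 2)
  x <- scores %*% basis          # exactly rank 2 in 20-space
  p <- fit_pca(x, n_components = 10, scale = FALSE)
  ev <- p$eigenvalues
  expect_gt(sum(ev[1:2]) / sum(ev), 1 - 1e-10)
  # total variance conservation
  expect_equal(sum(ev), sum(apply(x, 2, var)))
  # loadings orthonormal
  ltl <- crossprod(p$loadings)
  expect_equal(ltl, diag(ncol(ltl)), tolerance = 1e-8, ignore_attr = TRUE)
  # eigenvalues non-increasing
  expect_true(all(diff(ev) <= 1e-12))
})

test_that("duplicating a column leaves the spanned variance intact", {
  set.seed(6)
  x <- matrix(rnorm(15 * 6), 15, 6)
  xd <- cbind(x, x[, 3])
  p <- fit_pca(x, 5, scale = FALSE)
  pd <- fit_pca(xd, 5, scale = FALSE)
  expect_equal(sum(pd$eigenvalues), sum(p$eigenvalues) + var(x[, 3]))
  expect_error(fit_pca(x[1:2, ]), "fewer than 3")
})

test_that("zero-variance columns are dropped and projection round-trips", {
  set.seed(7)
  x <- cbind(matrix(rnorm(20 * 5), 20, 5), 3)   # constant sixth column
  expect_message(p <- fit_pca(x, 3), "zero-variance")
  expect_identical(p$columns, 1:5)
  sc <- predict(p, x)
  expect_identical(dim(sc), c(20L, 3L))
  expect_equal(predict(p, x[1:4, , drop = FALSE]), sc[1:4, ])
})

test_that("scree selection clamps to its floor and honours explicit k", {
  set.seed(8)
  x <- matrix(rnorm(20 * 40), 20, 40)
  x[, 1] <- x[, 1] * 8           # one dominant direction -> elbow at 1
  p <- fit_pca(x, "scree", scale = FALSE)
  expect_gte(p$n_components, 2L)
  expect_lte(p$n_components, 30L)
  expect_identical(fit_pca(x, 4)$n_components, 4L)
})

test_that("the SVM separates separable toys deterministically", {
  co <- make_gaussian_cohort(10, p = 2, shift = 6, seed = 3)
  fit <- train_svm(co$x, co$y)
  pred <- predict(fit, co$x)
  expect_identical(as.character(pred), co$y)
  fit2 <- train_svm(co$x, co$y)
  expect_equal(fit$decision.values, fit2$decision.values)
  expect_error(train_svm(co$x, rep("AD", 20)), "single-class")
})

test_that("the histon_svm model object carries its methods", {
  co <- make_gaussian_cohort(15, p = 25, shift = 3, seed = 4)
  fit <- histon_svm(co$x, co$y, n_components = 5)
  expect_s3_class(fit, "histon_svm")
  pred <- predict(fit, co$x)
  expect_true(all(pred %in% c("AD", "CN")))
  expect_gt(mean(pred == co$y), 0.9)
  w <- coef(fit)
  expect_length(w, 25L)
  expect_true(any(w != 0))
  expect_output(print(fit), "histon_svm")
  expect_output(summary(fit), "support vectors")
  rep <- evaluate(fit, co$x, co$y)
  expect_s3_class(rep, "metrics_report")
})

test_that("no training information leaks from test rows", {
  co <- make_gaussian_cohort(12, p = 10, shift = 2, seed = 9)
  tr <- 1:16; te <- 17:24
  fit_a <- histon_svm(co$x[tr, ], co$y[tr], n_components = 3)
  x2 <- co$x
  x2[te, ] <- matrix(rnorm(length(te) * 10, 50), length(te), 10)
  fit_b <- histon_svm(x2[tr, ], co$y[tr], n_components = 3)
  expect_identical(fit_a$pca, fit_b$pca)
  expect_equal(coef(fit_a), coef(fit_b))
  expect_identical(as.character(predict(fit_a, co$x[te, ])),
                   as.character(predict(fit_b, co$x[te, ])))
})

test_that("confusion metrics reproduce hand-computed values", {
  m <- confusion_metrics(10, 10, 0, 0)
  for (f in c("Acc", "Bacc", "NPV", "PPV", "Sen", "Spe", "Fscore"))
    expect_equal(m[[f]], 1)
  m <- confusion_metrics(8, 7, 3, 2)
  expect_equal(m$Sen, 0.8); expect_equal(m$Spe, 0.7)
  expect_equal(m$Bacc, 0.75); expect_equal(m$Acc, 0.75)
  expect_equal(m$PPV, 8 / 11); expect_equal(m$NPV, 7 / 9)
  expect_equal(m$Fscore, 2 * (0.8 * 8 / 11) / (0.8 + 8 / 11))
  expect_warning(m <- confusion_metrics(0, 5, 0, 5), "PPV undefined")
  expect_true(is.na(m$PPV))
  expect_equal(m$Spe, 1)
})

test_that("metric consistency holds on random confusion tables", {
  set.seed(11)
  for (i in 1:20) {
    cts <- as.list(sample(1:30, 4, replace = TRUE))
    m <- do.call(confusion_metrics, cts)
    expect_equal(m$Bacc, (m$Sen + m$Spe) / 2)
    expect_gte(m$Acc, min(m$Sen, m$Spe))
    expect_lte(m$Acc, max(m$Sen, m$Spe))
    expect_identical(m$TP + m$FN, cts[[1]] + cts[[4]])
  }
})

test_that("McNemar matches its closed form and the stats oracle", {
  # b = c = 5: (|0| - 1)^2 / 10
  r <- mcnemar_compare(c("AD", "AD"), c("AD", "AD"), c("AD", "AD"))
  expect_equal(r$p_value, 1); expect_equal(r$b + r$c, 0)
  set.seed(13)
  n <- 60
  truth <- sample(c("AD", "CN"), n, TRUE)
  pa <- ifelse(runif(n) < 0.7, truth, sample(c("AD", "CN"), n, TRUE))
  pb <- ifelse(runif(n) < 0.6, truth, sample(c("AD", "CN"), n, TRUE))
  got <- mcnemar_compare(pa, pb, truth)
  tab <- table(factor(pa == truth, c(TRUE, FALSE)),
               factor(pb == truth, c(TRUE, FALSE)))
  want <- mcnemar.test(tab, correct = TRUE)
  expect_equal(got$statistic, unname(want$statistic))
  expect_equal(got$p_value, unname(want$p.value))
  expect_error(mcnemar_compare(pa[1:5], pb, truth), "length mismatch")
})

test_that("split plans stratify, are deterministic and hit the test fraction", {
  co <- make_gaussian_cohort(50, p = 2, seed = 21)    # 100 subjects, 50/50
  plan <- make_splits(co$manifest, 10, 0.2, seed = 5)
  for (sp in plan$splits) {
    expect_length(sp$test, 20L)
    expect_length(intersect(sp$train, sp$test), 0L)
    n_ad <- sum(co$manifest$label[sp$test] == "AD")
    expect_lte(abs(n_ad - 10), 1)
  }
  plan2 <- make_splits(co$manifest, 10, 0.2, seed = 5)
  expect_identical(plan$splits, plan2$splits)
  expect_error(make_splits(co$manifest[1:5, ], seed = 1), "at least 10")
})

test_that("gender proportions are preserved within one subject across seeds", {
  set.seed(31)
  n <- 139
  man <- data.frame(subject_id = sprintf("s%03d", 1:n),
                    label = sample(c("AD", "CN"), n, TRUE, c(0.45, 0.55)),
                    age = round(runif(n, 60, 92)),
                    gender = sample(c("M", "F"), n, TRUE, c(0.4, 0.6)))
  g_frac <- mean(man$gender == "M")
  for (seed in 1:20) {
    plan <- suppressWarnings(make_splits(man, 3, 0.2, seed = seed))
    for (sp in plan$splits) {
      m_test <- sum(man$gender[sp$test] == "M")
      expect_lte(abs(m_test - g_frac * length(sp$test)), 1 + 1e-9)
      expect_lte(abs(length(sp$test) - 0.2 * n), 1 + 1e-9)
    }
  }
})

test_that("the repeated-split protocol recovers a growing effect monotonically", {
  baccs <- vapply(c(0.5, 1.5, 4), function(shift) {
    co <- make_gaussian_cohort(20, p = 40, shift = shift, seed = 41)
    plan <- make_splits(co$manifest, 10, 0.2, seed = 42)
    ev <- evaluate_splits(co$x, co$y, plan, n_components = 5)
    mean_metric(ev)
  }, numeric(1))
  expect_true(all(diff(baccs) >= 0))
  expect_gt(baccs[3], baccs[1])
  expect_gte(baccs[3], 0.85)
})

test_that("kernel comparison reports one row of metrics per kernel", {
  co <- make_gaussian_cohort(15, p = 20, shift = 3, seed = 51)
  plan <- make_splits(co$manifest, 3, 0.2, seed = 52)
  tab <- suppressWarnings(compare_kernels(co$x, co$y, plan, n_components = 4))
  expect_identical(tab$kernel, c("linear", "polynomial", "radial"))
  expect_true(all(c("Acc", "Bacc", "Fscore") %in% names(tab)))
  expect_true(all(tab$Bacc >= 0 & tab$Bacc <= 1))
})

test_that("voxel baseline guards leakage, searches cost and beats chance", {
  co <- make_gaussian_cohort(20, p = 500, shift = 1.5, seed = 61,
                             shift_cols = 10L)
  tr <- c(1:15, 21:35); te <- c(16:20, 36:40)
  ids <- co$manifest$subject_id
  expect_error(voxel_baseline(co$x[tr, ], co$y[tr], co$x[tr[1:5], ],
                              co$y[tr[1:5]], ids[tr], ids[tr[1:5]]),
               "leakage")
  rep <- voxel_baseline(co$x[tr, ], co$y[tr], co$x[te, ], co$y[te],
                        ids[tr], ids[te])
  expect_gt(rep$Bacc, 0.6)
  expect_true(attr(rep, "cost") %in% 2^(-5:5))
  # clearly separable data: every cost reaches the same inner-CV optimum,
  # so the tie rule must return the smallest cost on the grid
  co2 <- make_gaussian_cohort(20, p = 50, shift = 8, seed = 62)
  rep2 <- voxel_baseline(co2$x[tr, ], co2$y[tr], co2$x[te, ], co2$y[te],
                         ids[tr], ids[te])
  cv <- attr(rep2, "cv_bacc")
  expect_identical(attr(rep2, "cost"),
                   min(as.numeric(names(cv)[cv == max(cv)])))
})
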