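# wrap a bare matrix as a feature_matrix for direct SVM-level tests
as_fm <- function(x) {
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  structure(list(x = x, feature_ids = colnames(x),
                 scaling = list(center = setNames(rep(0, ncol(x)),
                                                  colnames(x)),
                                scale = rep(1, ncol(x)),
                                impute = numeric(0), enabled = FALSE,
                                constant = rep(FALSE, ncol(x)))),
            class = "feature_matrix")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# primal and dual objectives of the soft-margin problem at the fitted model
svm_objectives <- function(model, x, y01) {
  ys <- ifelse(y01 == 1, 1, -1)
  w <- model$weights; b <- model$bias
  sc <- drop(x %*% w + b)
  primal <- 0.5 * sum(w^2) + model$C * sum(pmax(0, 1 - ys * sc))
  fit <- model$fit
  a <- numeric(length(ys)); a[fit$index] <- abs(fit$coefs)
  dual <- sum(a) - 0.5 * sum(w^2)  # w = X'(a*y) at the solver's solution
  list(primal = primal, dual = dual, alpha = a, margins = ys * sc)
}

test_that("symmetric separable 1-D data yields the zero boundary", {
  x <- matrix(c(rep(1, 10), rep(-1, 10)), ncol = 1)
  y <- c(rep(1, 10), rep(0, 10))
  model <- train_linear_svm(as_fm(x), y)
  s <- predict_scores(model, as_fm(x))
  expect_equal(unname(model$bias), 0, tolerance = 1e-6)
  expect_true(all(s[y == 1] > 0))
  expect_true(all(s[y == 0] < 0))
  expect_equal(unname(attr(s, "labels")), y)
  # single-class input is rejected
  expect_error(train_linear_svm(as_fm(x), rep(1, 20)), "single class")
})

test_that("SVM solution matches a quadratic-programming oracle", {
  skip_if_not_installed("kernlab")
  set.seed(12)
  for (i in 1:10) {
    n <- sample(10:20, 1); p <- sample(2:4, 1)
    x <- matrix(rnorm(n * p), n)
    y <- rbinom(n, 1, 0.5)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
    C <- sample(c(0.5, 1, 2), 1)
    model <- train_linear_svm(as_fm(x), y, C = C, tolerance = 1e-8)
    # dual QP: min 1/2 a'Qa - 1'a, 0 <= a <= C, y'a = 0
    ys <- ifelse(y == 1, 1, -1)
    Q <- (ys %o% ys) * tcrossprod(x)
    # tiny ridge keeps the interior-point solver away from the singular
    # boundary (retrying larger if its Newton system is ill-conditioned);
    # the effect on the optimum is far below the 1e-4 tolerance
    a <- NULL
    for (ridge in c(1e-9, 1e-7, 1e-6)) {
      qp <- tryCatch(
        kernlab::ipop(c = matrix(-1, n), H = Q + diag(ridge, n),
                      A = t(ys), b = 0,
                      l = matrix(0, n), u = matrix(C, n), r = 0,
                      sigf = 8),
        error = function(e) NULL)
      if (!is.null(qp)) { a <- kernlab::primal(qp); break }
    }
    expect_false(is.null(a))
    w_or <- drop(t(x) %*% (a * ys))
    expect_equal(unname(model$weights), w_or, tolerance = 1e-4)
    free <- which(a > 1e-5 * C & a < C * (1 - 1e-5))
    if (length(free)) {
      # with free support vectors the bias is pinned by margin = 1
      b_or <- mean(ys[free] - x[free, , drop = FALSE] %*% w_or)
      expect_equal(model$bias, b_or, tolerance = 1e-4)
    }
  }
})

test_that("trained models satisfy KKT conditions and have a tiny duality gap", {
  set.seed(13)
  for (i in 1:5) {
    n <- 40
    x <- matrix(rnorm(n * 3), n)
    y <- rbinom(n, 1, 0.5)
    while (length(unique(y)) < 2) y <- rbinom(n, 1, 0.5)
    model <- train_linear_svm(as_fm(x), y, C = 1, tolerance = 1e-8)
    ob <- svm_objectives(model, x, y)
    # duality gap
    expect_lt(ob$primal - ob$dual, 1e-6)
    # KKT: alpha = 0 -> margin >= 1; 0 < alpha < C -> margin = 1;
    # alpha = C -> margin <= 1 (all within 1e-4)
    at0 <- ob$alpha < 1e-8
    atC <- ob$alpha > 1 - 1e-8
    free <- !at0 & !atC
    expect_true(all(ob$margins[at0] >= 1 - 1e-4))
    expect_true(all(abs(ob$margins[free] - 1) <= 1e-4))
    expect_true(all(ob$margins[atC] <= 1 + 1e-4))
  }
})

test_that("duplicating every training point halves the equivalent penalty", {
  # objective identity: data duplicated with C/2 has the same optimum as
  # the original data with C
  set.seed(14)
  n <- 30
  x <- matrix(rnorm(n * 2), n)
  y <- rbinom(n, 1, 0.5)
  m1 <- train_linear_svm(as_fm(x), y, C = 1)
  m2 <- train_linear_svm(as_fm(rbind(x, x)), c(y, y), C = 0.5)
  expect_equal(unname(m1$weights), unname(m2$weights), tolerance = 1e-4)
  expect_equal(m1$bias, m2$bias, tolerance = 1e-4)
})

test_that("large C drives training error to zero on separable data", {
  set.seed(15)
  n <- 30
  x <- rbind(matrix(rnorm(n * 2, 2), n), matrix(rnorm(n * 2, -2), n))
  y <- rep(c(1, 0), each = n)
  model <- train_linear_svm(as_fm(x), y, C = 1000)
  s <- predict_scores(model, as_fm(x))
  expect_equal(unname(attr(s, "labels")), y)
})

test_that("decision scores are the affine map w'x + b", {
  set.seed(16)
  x <- matrix(rnorm(30), 10, 3)
  y <- c(1, 0, 1, 0, 1, 0, 1, 0, 1, 0)
  model <- train_linear_svm(as_fm(x), y)
  # hand-computed dot products
  s <- predict_scores(model, as_fm(x))
  expect_equal(as.vector(s), unname(drop(x %*% model$weights + model$bias)))
  # zero feature vector scores exactly the bias
  s0 <- predict_scores(model, as_fm(matrix(0, 1, 3)))
  expect_equal(as.vector(s0), model$bias)
  # feature mismatch is named
  xm <- x; colnames(xm) <- c("f1", "f2", "zzz")
  expect_error(predict_scores(model, as_fm(xm)), "zzz")
})

test_that("feature matrix assembles canonical columns with training scaling", {
  sim <- small_signal_cohort()
  ch <- sim$cohort
  sel <- select_features(ch, ch$phenotypes[, 1], thresholds = 0.05)
  fm <- build_feature_matrix(ch, sel)
  expect_identical(fm$feature_ids,
                   c(sel$common$snp_id, paste0("burden_", sel$rare$gene),
                     "age", "sex", "smoking"))
  # scaled training columns have mean 0, sd 1
  keep <- !fm$scaling$constant
  expect_true(all(abs(colMeans(fm$x[, keep])) < 1e-10))
  expect_true(all(abs(apply(fm$x[, keep], 2, sd) - 1) < 1e-10))
  # rare columns equal the collapse of their frozen member list
  if (nrow(sel$rare)) {
    g1 <- sel$rare$gene[1]
    members <- strsplit(sel$rare$snp_ids[1], ",")[[1]]
    raw <- collapse_gene(ch$genotypes, members)
    col <- fm$x[, paste0("burden_", g1)]
    unscaled <- col * fm$scaling$scale[paste0("burden_", g1)] +
      fm$scaling$center[paste0("burden_", g1)]
    expect_equal(unname(round(unscaled)), raw, tolerance = 1e-8)
  }
  # validation matrices reuse training scaling verbatim
  fm_va <- build_feature_matrix(ch, sel, subset = rownames(ch$genotypes)[1:50],
                                scaling = fm$scaling)
  expect_identical(fm_va$scaling, fm$scaling)
})

test_that("empty selection degrades to a covariate-only model", {
  sim <- small_null_cohort()
  ch <- sim$cohort
  sel <- select_features(ch, ch$phenotypes[, 1], thresholds = 1e-9)
  expect_equal(nrow(sel$common) + nrow(sel$rare), 0)
  fm <- build_feature_matrix(ch, sel)
  expect_identical(fm$feature_ids, c("age", "sex", "smoking"))
  model <- train_linear_svm(fm, ch$phenotypes[, 1])
  expect_length(model$weights, 3)
})

test_that("missing dosages are imputed from the training subset", {
  sim <- small_signal_cohort()
  ch <- sim$cohort
  sel <- select_features(ch, ch$phenotypes[, 1], thresholds = 0.05)
  stopifnot(nrow(sel$common) >= 1)  # deterministic fixture has common hits
  s1 <- sel$common$snp_id[1]
  g <- ch$genotypes
  g[1:4, s1] <- NA_integer_
  ch2 <- ch; ch2$genotypes <- g
  fm <- build_feature_matrix(ch2, sel, scale_features = FALSE)
  fill <- round(mean(g[, s1], na.rm = TRUE))
  expect_equal(unname(fm$x[1:4, s1]), rep(fill, 4))
})

test_that("radial-kernel mode scores via the fitted machine", {
  set.seed(18)
  x <- rbind(matrix(rnorm(40, 1.5), 20), matrix(rnorm(40, -1.5), 20))
  y <- rep(c(1, 0), each = 20)
  model <- train_linear_svm(as_fm(x), y, kernel = "radial")
  s <- predict_scores(model, as_fm(x))
  expect_gt(compute_auc(s, y), 0.9)
  expect_gt(mean(s[y == 1]), mean(s[y == 0]))  # positive = case convention
})

test_that("risk model serializes to JSON", {
  set.seed(19)
  x <- matrix(rnorm(40), 20, 2)
  y <- rbinom(20, 1, 0.5); y[1:2] <- c(0, 1)
  model <- train_linear_svm(as_fm(x), y)
  path <- withr::local_tempfile(fileext = ".json")
  write_risk_model(model, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(back$weights), setNames(as.numeric(model$weights),
                                              model$feature_ids))
  expect_equal(back$bias, model$bias)
})
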