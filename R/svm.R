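#' Assemble the SVM feature matrix
#'
#' Columns in canonical order: selected common SNPs as minor-allele dosages
#' (0/1/2), selected rare gene burdens as carrier indicators (0/1, collapsed
#' over the member SNP list frozen at selection time), then age, sex,
#' smoking. Missing dosages are imputed to the training subset's rounded
#' mean dosage (collapsing already treats missing as non-carrier). When
#' scaling is on, each column is standardized by the training-set mean and
#' standard deviation; zero-variance columns are left unscaled and flagged.
#' Validation matrices must be built with the training matrix's
#' \code{scaling} so coding and centering never leak across the split.
#'
#' @param chrt a \code{\link{cohort}}.
#' @param selected a \code{selected_features} object.
#' @param subset individual ids to include (default: all).
#' @param scaling NULL to fit scaling on this subset (training use), or the
#'   \code{scaling} element of a training matrix (validation use).
#' @param scale_features standardize columns (default TRUE); ignored when a
#'   \code{scaling} object is supplied.
#' @return List of class \code{feature_matrix}: \code{x} (numeric matrix),
#'   \code{feature_ids}, \code{scaling} (list with \code{center},
#'   \code{scale}, \code{impute}, \code{enabled}, \code{constant}).
#' @export
build_feature_matrix <- function(chrt, selected, subset = NULL,
                                 scaling = NULL, scale_features = TRUE) {
  stopifnot(inherits(chrt, "cohort"), inherits(selected, "selected_features"))
  if (is.null(subset)) subset <- rownames(chrt$genotypes)
  g <- chrt$genotypes[subset, , drop = FALSE]
  cov <- chrt$covariates[match(subset, chrt$covariates$id), , drop = FALSE]

  cols <- list()
  common <- selected$common$snp_id
  missing_feat <- setdiff(common, colnames(g))
  if (length(missing_feat))
    stop("unknown common feature(s): ", paste(missing_feat, collapse = ","))
  impute <- if (is.null(scaling)) NULL else scaling$impute
  for (s in common) {
    d <- as.numeric(g[, s])
    if (anyNA(d)) {
      fill <- if (!is.null(impute) && s %in% names(impute)) impute[[s]]
      else round(mean(d, na.rm = TRUE))
      if (is.nan(fill)) fill <- 0
      d[is.na(d)] <- fill
    }
    cols[[s]] <- d
  }
  if (nrow(selected$rare)) {
    for (i in seq_len(nrow(selected$rare))) {
      members <- strsplit(selected$rare$snp_ids[i], ",", fixed = TRUE)[[1]]
      missing_feat <- setdiff(members, colnames(g))
      if (length(missing_feat))
        stop("unknown rare-feature member SNP(s): ",
             paste(missing_feat, collapse = ","))
      cols[[paste0("burden_", selected$rare$gene[i])]] <-
        as.numeric(collapse_gene(g, members))
    }
  }
  cols[["age"]] <- cov$age
  cols[["sex"]] <- as.numeric(cov$sex)
  cols[["smoking"]] <- as.numeric(cov$smoking)
  x <- do.call(cbind, cols)
  rownames(x) <- subset

  if (is.null(scaling)) {
    ctr <- colMeans(x)
    sdv <- apply(x, 2, stats::sd)
    constant <- sdv == 0 | is.na(sdv)
    imp <- vapply(common, function(s) {
      d <- g[, s]
      v <- round(mean(d, na.rm = TRUE))
      if (is.nan(v)) 0 else as.numeric(v)
    }, 0)
    scaling <- list(center = ctr, scale = sdv, impute = imp,
                    enabled = isTRUE(scale_features), constant = constant)
  } else {
    if (!identical(names(scaling$center), colnames(x)))
      stop("scaling features do not match: expected ",
           paste(names(scaling$center), collapse = ","))
  }
  if (scaling$enabled) {
    sc <- ifelse(scaling$constant, 1, scaling$scale)
    ct <- ifelse(scaling$constant, 0, scaling$center)
    x <- sweep(sweep(x, 2, ct, "-"), 2, sc, "/")
  }
  structure(list(x = x, feature_ids = colnames(x), scaling = scaling),
            class = "feature_matrix")
}

#' Train a soft-margin linear SVM risk model
#'
#' Solves the soft-margin problem
#' \deqn{\min_{w,b,\xi} \tfrac12\|w\|^2 + C\sum_i \xi_i \quad
#'   s.t.\; y_i(w'x_i + b) \ge 1 - \xi_i,\; \xi_i \ge 0}
#' with labels mapped to \{-1, +1\} (case = +1), via the LIBSVM solver in
#' e1071. The default stopping tolerance (1e-5) keeps the Karush-Kuhn-Tucker
#' residuals of the returned solution around 1e-5 (comfortably inside the
#' 1e-4 contract) at negligible cost; tighten \code{tolerance} (e.g. 1e-8)
#' when a near-zero duality gap is required.
#' The explicit weight vector and bias are extracted, with the sign
#' convention fixed so positive decision values predict case status. An
#' optional radial kernel (\code{exp(-gamma ||x-y||^2)}) is available for
#' sensitivity analysis; the linear kernel is the default analysis.
#'
#' @param fm a \code{feature_matrix} (training subset).
#' @param y 0/1 labels (both classes required).
#' @param C penalty parameter (> 0; default 1).
#' @param kernel \code{"linear"} (default) or \code{"radial"}.
#' @param gamma radial-kernel width; default 1/#features.
#' @param tolerance solver stopping tolerance.
#' @return Object of class \code{linear_risk_model}: weights, bias, C,
#'   kernel, feature_ids, scaling, and the underlying fit (for the radial
#'   mode and for dual-based diagnostics).
#' @export
train_linear_svm <- function(fm, y, C = 1, kernel = c("linear", "radial"),
                             gamma = NULL, tolerance = 1e-5) {
  kernel <- match.arg(kernel)
  stopifnot(inherits(fm, "feature_matrix"), C > 0)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("training labels contain a single class")
  if (is.null(gamma)) gamma <- 1 / ncol(fm$x)
  yf <- factor(y, levels = c(0, 1))
  fit <- e1071::svm(fm$x, yf, type = "C-classification", kernel = kernel,
                    cost = C, gamma = gamma, scale = FALSE,
                    tolerance = tolerance)
  # decision values are positive for the class LIBSVM saw first; flip so
  # positive = case
  flip <- fit$levels[fit$labels[1]] != "1"
  if (kernel == "linear") {
    w <- drop(crossprod(fit$coefs, fit$SV))
    b <- -fit$rho
    if (flip) { w <- -w; b <- -b }
    names(w) <- fm$feature_ids
  } else {
    w <- NULL
    b <- NULL
  }
  structure(list(weights = w, bias = b, C = C, kernel = kernel,
                 gamma = gamma, feature_ids = fm$feature_ids,
                 scaling = fm$scaling, flip = flip, fit = fit),
            class = "linear_risk_model")
}

#' @export
print.linear_risk_model <- function(x, ...) {
  cat(sprintf("soft-margin %s SVM risk model: %d feature(s), C = %g\n",
              x$kernel, length(x$feature_ids), x$C))
  invisible(x)
}

#' Decision scores of a risk model
#'
#' score_i = w'x_i + b on the (already scaled) feature matrix; higher score
#' means higher predicted disease risk. Hard labels (score > 0) are attached
#' as the \code{"labels"} attribute.
#'
#' @param model a \code{linear_risk_model}.
#' @param fm a \code{feature_matrix} built with the model's scaling.
#' @return Named numeric vector of decision values, attribute
#'   \code{"labels"} holding the 0/1 hard calls.
#' @export
predict_scores <- function(model, fm) {
  stopifnot(inherits(model, "linear_risk_model"),
            inherits(fm, "feature_matrix"))
  if (!identical(model$feature_ids, fm$feature_ids)) {
    extra <- setdiff(fm$feature_ids, model$feature_ids)
    missing <- setdiff(model$feature_ids, fm$feature_ids)
    stop("feature mismatch; missing: ", paste(missing, collapse = ","),
         "; extra: ", paste(extra, collapse = ","))
  }
  if (model$kernel == "linear") {
    s <- drop(fm$x %*% model$weights + model$bias)
  } else {
    dv <- attr(stats::predict(model$fit, fm$x, decision.values = TRUE),
               "decision.values")
    s <- drop(dv)
    if (model$flip) s <- -s
  }
  names(s) <- rownames(fm$x)
  attr(s, "labels") <- as.integer(s > 0)
  s
}

#' Serialize a linear risk model to JSON
#'
#' @param model a \code{linear_risk_model} (linear kernel only).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_risk_model <- function(model, path) {
  stopifnot(model$kernel == "linear")
  jsonlite::write_json(list(
    feature_ids = model$feature_ids,
    weights = as.list(stats::setNames(as.numeric(model$weights),
                                      model$feature_ids)),
    bias = model$bias, C = model$C,
    scaling = list(center = as.list(model$scaling$center),
                   scale = as.list(model$scaling$scale),
                   impute = as.list(model$scaling$impute),
                   enabled = model$scaling$enabled,
                   constant = as.list(model$scaling$constant))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
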