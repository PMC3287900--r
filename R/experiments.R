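#' Configuration for the two risk-prediction experiments
#'
#' @param thresholds ordered p-value cut points for variant selection
#'   (default the seven-point sweep 1e-5 ... 0.01).
#' @param training_sizes training-set sizes for the split design (default
#'   300, 400, 500, 600); must be smaller than the cohort size.
#' @param maf_threshold rare/common MAF boundary (default 0.05).
#' @param C SVM penalty parameter (default 1).
#' @param kernel \code{"linear"} (default) or \code{"radial"}.
#' @param scale_features standardize SVM inputs on the training subset
#'   (default TRUE).
#' @param seed master seed for all random splits.
#' @param train_replicate the trait replicate used for selection and
#'   training in the replicate-train design (default 1).
#' @param stratified_split preserve the case:control ratio in the random
#'   training split (default FALSE: simple random split).
#' @return Object of class \code{experiment_config}.
#' @export
experiment_config <- function(thresholds = c(0.01, 0.005, 0.001, 5e-4,
                                             1e-4, 5e-5, 1e-5),
                              training_sizes = c(300L, 400L, 500L, 600L),
                              maf_threshold = 0.05, C = 1,
                              kernel = c("linear", "radial"),
                              scale_features = TRUE, seed = 1L,
                              train_replicate = 1L,
                              stratified_split = FALSE) {
  kernel <- match.arg(kernel)
  stopifnot(all(thresholds > 0), all(thresholds < 1), C > 0,
            all(training_sizes >= 2))
  structure(list(thresholds = thresholds,
                 training_sizes = as.integer(training_sizes),
                 maf_threshold = maf_threshold, C = C, kernel = kernel,
                 scale_features = scale_features, seed = as.integer(seed),
                 train_replicate = as.integer(train_replicate),
                 stratified_split = stratified_split),
            class = "experiment_config")
}

# fit the with-rare and without-rare models on one training subset and
# return validation scores for both
.fit_pair <- function(chrt, sel, train_ids, y_train, valid_ids, config) {
  sel_common_only <- sel
  sel_common_only$rare <- sel$rare[0, , drop = FALSE]
  score_one <- function(s) {
    fm_tr <- build_feature_matrix(chrt, s, subset = train_ids,
                                  scale_features = config$scale_features)
    model <- train_linear_svm(fm_tr, y_train, C = config$C,
                              kernel = config$kernel)
    fm_va <- build_feature_matrix(chrt, s, subset = valid_ids,
                                  scaling = fm_tr$scaling)
    list(model = model, scores = predict_scores(model, fm_va))
  }
  list(with_rare = score_one(sel),
       without_rare = score_one(sel_common_only))
}

#' Replicate-train design: select and train on one trait replicate
#'
#' Feature selection and model fitting use all individuals under the labels
#' of one trait replicate (default the first); prediction is then assessed
#' on every remaining replicate — same individuals, independently
#' re-simulated labels — giving one validation AUC per replicate per model.
#' The with-rare and without-rare models are compared by paired t-test
#' across those replicates, per p-value threshold.
#'
#' @param chrt a \code{\link{cohort}} with >= 2 trait replicates.
#' @param config an \code{\link{experiment_config}}.
#' @return Object of class \code{experiment_result} (design
#'   \code{"replicate_train"}): \code{cells} summary data.frame and
#'   \code{comparisons} (per-threshold \code{replicate_comparison}).
#' @export
run_experiment1 <- function(chrt, config = experiment_config()) {
  stopifnot(inherits(chrt, "cohort"), ncol(chrt$phenotypes) >= 2)
  r0 <- config$train_replicate
  stopifnot(r0 >= 1, r0 <= ncol(chrt$phenotypes))
  y_train <- chrt$phenotypes[, r0]
  valid_reps <- setdiff(seq_len(ncol(chrt$phenotypes)), r0)
  all_ids <- rownames(chrt$genotypes)

  sels <- select_features(chrt, y_train, thresholds = config$thresholds,
                          maf_threshold = config$maf_threshold)
  if (length(config$thresholds) == 1)
    sels <- stats::setNames(list(sels), as.character(config$thresholds))

  cells <- list(); comparisons <- list()
  for (t in names(sels)) {
    sel <- sels[[t]]
    pair <- .fit_pair(chrt, sel, all_ids, y_train, all_ids, config)
    # scores are fixed; each validation replicate contributes its labels
    auc_with <- vapply(valid_reps, function(r)
      compute_auc(pair$with_rare$scores, chrt$phenotypes[, r]), 0)
    auc_without <- vapply(valid_reps, function(r)
      compute_auc(pair$without_rare$scores, chrt$phenotypes[, r]), 0)
    cmp <- compare_paired_auc(auc_with, auc_without)
    comparisons[[t]] <- cmp
    cells[[t]] <- data.frame(
      threshold = sel$threshold, n_common = nrow(sel$common),
      n_rare = nrow(sel$rare), auc_without = cmp$mean_without,
      auc_with = cmp$mean_with, diff = cmp$mean_diff,
      ci_lo = cmp$ci[1], ci_hi = cmp$ci[2], t_stat = cmp$t_stat,
      p_paired_t = cmp$p_paired_t, n_replicates = cmp$n_replicates)
  }
  structure(list(design = "replicate_train",
                 cells = do.call(rbind, c(cells, make.row.names = FALSE)),
                 comparisons = comparisons, config = config),
            class = "experiment_result")
}

# deterministic training split for (seed, replicate, size)
.draw_split <- function(ids, status, size, seed, stratified, max_attempts = 100L) {
  n <- length(ids)
  stopifnot(size < n)
  for (attempt in 0:max_attempts) {
    tr <- with_seed(derive_seed(seed, 200L, attempt), {
      if (stratified) {
        k1 <- round(size * mean(status))
        k1 <- max(1L, min(size - 1L, k1))
        c(sample(ids[status == 1], k1),
          sample(ids[status == 0], size - k1))
      } else sample(ids, size)
    })
    y_tr <- status[match(tr, ids)]
    y_va <- status[match(setdiff(ids, tr), ids)]
    if (length(unique(y_tr)) == 2 && length(unique(y_va)) == 2)
      return(tr)
    message("resampling a split without both classes on each side")
  }
  stop("could not draw a split with both classes in training and validation")
}

#' Split design: per-replicate random training/validation division
#'
#' For every trait replicate and every training size, a seeded random
#' training subset is drawn; the MAF partition, both selection stages,
#' feature scaling and both SVM fits are recomputed on that subset alone,
#' and the validation AUC of each model is recorded on the held-out
#' individuals under the same replicate's labels. Each (threshold, size)
#' cell aggregates the paired per-replicate AUCs into a
#' \code{replicate_comparison}.
#'
#' @param chrt a \code{\link{cohort}}.
#' @param config an \code{\link{experiment_config}}.
#' @param replicates which trait replicates to use (default: all).
#' @return Object of class \code{experiment_result} (design
#'   \code{"random_split"}): \code{cells} data.frame (one row per
#'   threshold x size) and \code{comparisons} keyed
#'   \code{"<threshold>|<size>"}.
#' @export
run_experiment2 <- function(chrt, config = experiment_config(),
                            replicates = NULL) {
  stopifnot(inherits(chrt, "cohort"))
  if (is.null(replicates)) replicates <- seq_len(ncol(chrt$phenotypes))
  ids <- rownames(chrt$genotypes)
  stopifnot(all(config$training_sizes < length(ids)))

  aucs <- list()  # key: threshold|size -> list(with = c(), without = c())
  for (size in config$training_sizes) {
    for (r in replicates) {
      status <- chrt$phenotypes[, r]
      split_seed <- derive_seed(config$seed, r, size)
      train_ids <- .draw_split(ids, status, size, split_seed,
                               config$stratified_split)
      valid_ids <- setdiff(ids, train_ids)
      y_train <- status[match(train_ids, ids)]
      y_valid <- status[match(valid_ids, ids)]
      sels <- select_features(chrt, y_train, train_ids = train_ids,
                              thresholds = config$thresholds,
                              maf_threshold = config$maf_threshold)
      if (length(config$thresholds) == 1)
        sels <- stats::setNames(list(sels),
                                as.character(config$thresholds))
      for (t in names(sels)) {
        pair <- .fit_pair(chrt, sels[[t]], train_ids, y_train, valid_ids,
                          config)
        key <- paste(t, size, sep = "|")
        if (is.null(aucs[[key]]))
          aucs[[key]] <- list(with = numeric(0), without = numeric(0),
                              n_common = 0, n_rare = 0)
        aucs[[key]]$with <- c(aucs[[key]]$with,
                              compute_auc(pair$with_rare$scores, y_valid))
        aucs[[key]]$without <- c(aucs[[key]]$without,
                                 compute_auc(pair$without_rare$scores,
                                             y_valid))
        aucs[[key]]$n_common <- aucs[[key]]$n_common +
          nrow(sels[[t]]$common)
        aucs[[key]]$n_rare <- aucs[[key]]$n_rare + nrow(sels[[t]]$rare)
      }
    }
  }
  cells <- list(); comparisons <- list()
  for (size in config$training_sizes) {
    for (t in as.character(config$thresholds)) {
      key <- paste(t, size, sep = "|")
      a <- aucs[[key]]
      cmp <- compare_paired_auc(a$with, a$without)
      comparisons[[key]] <- cmp
      cells[[key]] <- data.frame(
        threshold = as.numeric(t), training_size = size,
        mean_n_common = a$n_common / length(replicates),
        mean_n_rare = a$n_rare / length(replicates),
        auc_without = cmp$mean_without, auc_with = cmp$mean_with,
        diff = cmp$mean_diff, ci_lo = cmp$ci[1], ci_hi = cmp$ci[2],
        t_stat = cmp$t_stat, p_paired_t = cmp$p_paired_t,
        n_replicates = cmp$n_replicates)
    }
  }
  structure(list(design = "random_split",
                 cells = do.call(rbind, c(cells, make.row.names = FALSE)),
                 comparisons = comparisons, config = config),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("experiment result (%s design): %d cell(s)\n",
              x$design, nrow(x$cells)))
  print(x$cells, digits = 4)
  invisible(x)
}

#' Summarize an experiment result as a flat table
#'
#' One row per (threshold [, training size]) cell, in the layout of the
#' published comparison tables: AUC of the common-only model, AUC of the
#' common+rare model, the paired difference with its 95\% CI, and the
#' paired-t p-value.
#'
#' @param result an \code{experiment_result}.
#' @return data.frame (a copy of \code{result$cells}).
#' @export
summarize_experiment <- function(result) {
  stopifnot(inherits(result, "experiment_result"))
  result$cells
}

#' Write an experiment summary as TSV
#'
#' @param result an \code{experiment_result}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_experiment_tsv <- function(result, path) {
  utils::write.table(summarize_experiment(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an experiment summary TSV
#'
#' @param path TSV written by \code{\link{write_experiment_tsv}}.
#' @return data.frame matching \code{summarize_experiment} output.
#' @export
read_experiment_tsv <- function(path) {
  utils::read.delim(path)
}
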