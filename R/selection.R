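#' Partition SNPs into rare, common and monomorphic
#'
#' Applies the MAF-5\% convention: a SNP is rare when 0 < MAF < threshold,
#' common when MAF >= threshold (the boundary value counts as common), and
#' monomorphic when MAF = 0. Monomorphic SNPs are untestable and excluded
#' from both screening stages. MAFs must be computed on the training subset
#' of the experiment at hand (never on validation individuals).
#'
#' @param maf named numeric vector of per-SNP MAFs (see
#'   \code{\link{compute_sample_maf}}); NAs are treated as monomorphic
#'   (excluded).
#' @param maf_threshold rare/common boundary (default 0.05).
#' @return An object of class \code{variant_partition}: list with
#'   \code{common}, \code{rare}, \code{monomorphic} SNP-id vectors and
#'   \code{maf_threshold}.
#' @export
partition_variants <- function(maf, maf_threshold = 0.05) {
  stopifnot(!is.null(names(maf)), maf_threshold > 0, maf_threshold < 0.5)
  usable <- !is.na(maf)
  structure(list(
    common = names(maf)[usable & maf >= maf_threshold],
    rare = names(maf)[usable & maf > 0 & maf < maf_threshold],
    monomorphic = names(maf)[!usable | maf == 0],
    maf_threshold = maf_threshold), class = "variant_partition")
}

#' Fisher's exact allele-count test for one SNP
#'
#' Builds the 2x2 table of minor vs. major allele counts in cases vs.
#' controls (each individual contributes two alleles; individuals with a
#' missing genotype are excluded) and computes the two-sided exact p-value:
#' the sum of hypergeometric probabilities of all tables with the same
#' margins whose point probability does not exceed that of the observed
#' table (ties within relative tolerance 1e-7). A degenerate margin (SNP
#' monomorphic in the subset, or a single class) yields p = 1 with
#' \code{degenerate = TRUE}.
#'
#' @param dosages per-individual minor-allele dosage (0/1/2/NA).
#' @param status per-individual 0/1 disease status.
#' @return List: \code{table} (2x2, rows minor/major, cols case/control),
#'   \code{p_value}, \code{degenerate}.
#' @export
fisher_allele_test <- function(dosages, status) {
  stopifnot(length(dosages) == length(status))
  keep <- !is.na(dosages) & !is.na(status)
  dosages <- dosages[keep]; status <- status[keep]
  if (!any(status == 1) || !any(status == 0))
    stop("need at least one case and one control")
  minor_case <- sum(dosages[status == 1])
  minor_ctrl <- sum(dosages[status == 0])
  tab <- matrix(c(minor_case, 2 * sum(status == 1) - minor_case,
                  minor_ctrl, 2 * sum(status == 0) - minor_ctrl),
                nrow = 2,
                dimnames = list(allele = c("minor", "major"),
                                status = c("case", "control")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    return(list(table = tab, p_value = 1, degenerate = TRUE))
  p <- .fisher_two_sided(tab[1, 1], sum(tab[1, ]), sum(tab), sum(tab[, 1]))
  list(table = tab, p_value = min(p, 1), degenerate = FALSE)
}

# IRLS logistic fit with the gene-scan control settings; separation is
# detected and flagged by callers, so glm.fit's saturation warning is muffled
.quiet_logit <- function(x, y) {
  ctl <- stats::glm.control(epsilon = 1e-10, maxit = 50)
  withCallingHandlers(
    stats::glm.fit(x, y, family = stats::binomial(), control = ctl),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# two-sided exact p for a 2x2 table with margins (K minor alleles, N total
# alleles, n case alleles) and observed case-minor count a: sum of
# hypergeometric point probabilities <= the observed one (relative tie
# tolerance 1e-7). Vectorized over the support, so it stays fast at
# allele-count margins in the hundreds where generic implementations crawl.
.fisher_two_sided <- function(a, K, N, n) {
  support <- max(0, n - (N - K)):min(n, K)
  probs <- stats::dhyper(support, K, N - K, n)
  p_obs <- probs[a - support[1] + 1]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Collapse a gene's rare SNPs into a carrier indicator
#'
#' Presence/absence burden coding: individual i is a carrier (1) when any of
#' the listed SNPs has dosage > 0, else 0. Missing dosages count as
#' non-carrier. Idempotent and order-independent in \code{snp_ids}.
#'
#' @param genotypes individuals x SNPs dosage matrix.
#' @param snp_ids non-empty vector of member SNP ids.
#' @return Integer 0/1 vector, one entry per individual.
#' @export
collapse_gene <- function(genotypes, snp_ids) {
  if (!length(snp_ids)) stop("snp_ids must be non-empty")
  missing <- setdiff(snp_ids, colnames(genotypes))
  if (length(missing))
    stop("unknown SNP id(s): ", paste(utils::head(missing, 5), collapse = ","))
  g <- genotypes[, snp_ids, drop = FALSE]
  g[is.na(g)] <- 0L
  as.integer(rowSums(g > 0) > 0)
}

#' Covariate-adjusted logistic fit for a burden indicator
#'
#' Fits status ~ intercept + indicator + age + sex + smoking by maximum
#' likelihood (IRLS, convergence tolerance 1e-10 on the relative deviance
#' change, at most 50 iterations) and tests the indicator by a 1-df
#' likelihood-ratio test against the covariate-only model. AIC = 2k - 2 lnL
#' with k the number of fitted coefficients. Quasi-complete separation is
#' flagged (\code{converged = FALSE}) when any coefficient exceeds 50 on the
#' log-odds scale; the LRT p at the last iterate is still returned.
#'
#' @param response 0/1 vector with both classes present.
#' @param indicator numeric/integer predictor of interest (the burden
#'   indicator; must be non-constant).
#' @param covariates data.frame with age, sex, smoking for the same
#'   individuals (NULL for an unadjusted fit).
#' @return List: \code{coefficients}, \code{lnL}, \code{aic}, \code{p_value}
#'   (indicator LRT), \code{converged}.
#' @export
fit_logistic <- function(response, indicator, covariates = NULL) {
  stopifnot(length(unique(response)) == 2)
  n <- length(response)
  xc <- if (is.null(covariates)) NULL else
    cbind(age = covariates$age, sex = covariates$sex,
          smoking = covariates$smoking)
  x0 <- cbind(`(Intercept)` = rep(1, n), xc)
  x1 <- cbind(x0[, 1, drop = FALSE], indicator = indicator,
              x0[, -1, drop = FALSE])
  # drop rank-deficient columns (never the intercept or indicator)
  qrx <- qr(x1)
  if (qrx$rank < ncol(x1)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- colnames(x1)[-keep]
    if (any(c("(Intercept)", "indicator") %in% dropped))
      stop("indicator is constant or collinear with the intercept")
    warning("dropping rank-deficient column(s): ",
            paste(dropped, collapse = ","))
    x1 <- x1[, sort(keep), drop = FALSE]
    x0 <- x0[, intersect(colnames(x0), colnames(x1)), drop = FALSE]
  }
  f1 <- .quiet_logit(x1, response)
  f0 <- .quiet_logit(x0, response)
  k <- ncol(x1)
  lnL <- -f1$deviance / 2
  converged <- isTRUE(f1$converged) && max(abs(f1$coefficients)) <= 50
  p <- stats::pchisq(max(f0$deviance - f1$deviance, 0), df = 1,
                     lower.tail = FALSE)
  list(coefficients = f1$coefficients, lnL = lnL, aic = 2 * k - 2 * lnL,
       p_value = p, converged = converged)
}

#' Fisher screen over a set of common SNPs
#'
#' Runs \code{\link{fisher_allele_test}} for every listed SNP on the
#' training individuals. Threshold-free: the returned p-values are filtered
#' by \code{\link{select_common_features}}, so a sweep over thresholds needs
#' one scan.
#'
#' @param genotypes individuals x SNPs dosage matrix (training subset rows).
#' @param snp_ids common SNPs to test.
#' @param status 0/1 training labels.
#' @return data.frame: snp_id, p_value, degenerate.
#' @export
fisher_screen <- function(genotypes, snp_ids, status) {
  res <- lapply(snp_ids, function(s)
    fisher_allele_test(genotypes[, s], status))
  data.frame(snp_id = as.character(snp_ids),
             p_value = vapply(res, `[[`, 0, "p_value"),
             degenerate = vapply(res, `[[`, TRUE, "degenerate"),
             stringsAsFactors = FALSE)
}

#' Gene-level collapsing scan over rare variants
#'
#' For every gene with at least one rare SNP, collapses the two candidate
#' sets — all rare SNPs, and nonsynonymous rare SNPs — into carrier
#' indicators and fits the covariate-adjusted logistic model for each
#' non-empty, non-constant set. Returns one row per fitted (gene, set);
#' filtering and the AIC choice between sets happen in
#' \code{\link{select_rare_features}}.
#'
#' @param genotypes training-subset dosage matrix.
#' @param annotation cohort annotation (gene, nonsynonymous per SNP).
#' @param rare_snps SNP ids in the rare stratum (training-subset MAF).
#' @param status 0/1 training labels.
#' @param covariates training-subset covariates (age, sex, smoking).
#' @return data.frame: gene, set_type, p_value, aic, converged, n_carriers,
#'   snp_ids (comma-joined member list, frozen for validation-time reuse).
#' @export
rare_gene_scan <- function(genotypes, annotation, rare_snps, status,
                           covariates) {
  ann <- annotation[annotation$snp_id %in% rare_snps, , drop = FALSE]
  n <- length(status)
  x0 <- cbind(`(Intercept)` = rep(1, n), age = covariates$age,
              sex = covariates$sex, smoking = covariates$smoking)
  # the covariate-only null is shared by every gene: fit it once
  f0 <- .quiet_logit(x0, status)
  rows <- list()
  for (g in unique(ann$gene)) {
    members_all <- ann$snp_id[ann$gene == g]
    members_ns <- ann$snp_id[ann$gene == g & ann$nonsynonymous]
    for (set_type in c("all_rare", "nonsyn_rare")) {
      members <- if (set_type == "all_rare") members_all else members_ns
      if (!length(members)) next
      ind <- collapse_gene(genotypes, members)
      if (length(unique(ind)) < 2) next  # constant indicator: untestable
      x1 <- cbind(x0[, 1, drop = FALSE], indicator = ind,
                  x0[, -1, drop = FALSE])
      f1 <- .quiet_logit(x1, status)
      k <- ncol(x1)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, set_type = set_type,
        p_value = stats::pchisq(max(f0$deviance - f1$deviance, 0), df = 1,
                                lower.tail = FALSE),
        aic = 2 * k + f1$deviance,
        converged = isTRUE(f1$converged) &&
          max(abs(f1$coefficients)) <= 50,
        n_carriers = sum(ind),
        snp_ids = paste(members, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(gene = character(), set_type = character(),
                      p_value = numeric(), aic = numeric(),
                      converged = logical(), n_carriers = integer(),
                      snp_ids = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Select common-SNP features at a p-value threshold
#'
#' Keeps SNPs with a strictly smaller Fisher p than the threshold
#' (degenerate tests are never selected).
#'
#' @param screen output of \code{\link{fisher_screen}}.
#' @param threshold p-value cutoff in (0, 1].
#' @return data.frame subset of \code{screen}, ordered by p.
#' @export
select_common_features <- function(screen, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  keep <- screen[!screen$degenerate & screen$p_value < threshold, ,
                 drop = FALSE]
  keep[order(keep$p_value, keep$snp_id), , drop = FALSE]
}

#' Select rare-gene burden features at a p-value threshold
#'
#' Keeps genes where at least one candidate set reaches p < threshold. When
#' both sets pass, the one with the smaller AIC is retained; on an exact AIC
#' tie the nonsynonymous set wins (the more restrictive annotation). At most
#' one feature per gene.
#'
#' @param scan output of \code{\link{rare_gene_scan}}.
#' @param threshold p-value cutoff in (0, 1].
#' @return data.frame: gene, set_type, p_value, aic, n_carriers, snp_ids;
#'   one row per selected gene, ordered by p.
#' @export
select_rare_features <- function(scan, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  pass <- scan[scan$p_value < threshold, , drop = FALSE]
  if (!nrow(pass)) return(pass[, names(pass) != "converged"])
  picked <- lapply(split(pass, pass$gene), function(d) {
    if (nrow(d) == 1) return(d)
    # both sets pass: smaller AIC; tie -> nonsynonymous set
    ns <- d[d$set_type == "nonsyn_rare", , drop = FALSE]
    al <- d[d$set_type == "all_rare", , drop = FALSE]
    if (al$aic < ns$aic) al else ns
  })
  out <- do.call(rbind, picked)
  out <- out[order(out$p_value, out$gene), names(out) != "converged",
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full two-stage feature selection on a training subset
#'
#' Computes training-subset MAFs, partitions SNPs at the MAF threshold, runs
#' the Fisher screen on common SNPs and the collapsing scan on rare SNPs,
#' and applies the p-value threshold(s). All quantities — MAF partition,
#' screens, indicator membership — are computed on the training individuals
#' only.
#'
#' @param chrt a \code{\link{cohort}}.
#' @param status 0/1 labels for the training individuals.
#' @param train_ids training individual ids (default: all).
#' @param thresholds one or more p-value cutoffs.
#' @param maf_threshold rare/common MAF boundary (default 0.05).
#' @return For a single threshold, an object of class
#'   \code{selected_features}: list with \code{threshold}, \code{common}
#'   (data.frame), \code{rare} (data.frame), \code{partition}, and
#'   \code{train_ids}. For several thresholds, a named list of such objects
#'   (one scan, filtered per threshold — nestedness is structural).
#' @export
select_features <- function(chrt, status, train_ids = NULL,
                            thresholds = 0.01, maf_threshold = 0.05) {
  stopifnot(inherits(chrt, "cohort"))
  if (is.null(train_ids)) train_ids <- rownames(chrt$genotypes)
  g <- chrt$genotypes[train_ids, , drop = FALSE]
  cov <- chrt$covariates[match(train_ids, chrt$covariates$id), , drop = FALSE]
  stopifnot(length(status) == length(train_ids))
  maf <- compute_sample_maf(g)
  part <- partition_variants(maf, maf_threshold)
  screen <- fisher_screen(g, part$common, status)
  scan <- rare_gene_scan(g, chrt$annotation, part$rare, status, cov)
  one <- function(t) {
    structure(list(threshold = t,
                   common = select_common_features(screen, t),
                   rare = select_rare_features(scan, t),
                   partition = part, train_ids = train_ids),
              class = "selected_features")
  }
  if (length(thresholds) == 1) one(thresholds)
  else stats::setNames(lapply(thresholds, one), as.character(thresholds))
}

#' @export
print.selected_features <- function(x, ...) {
  cat(sprintf("selected features at p < %g: %d common SNP(s), %d rare gene burden(s)\n",
              x$threshold, nrow(x$common), nrow(x$rare)))
  invisible(x)
}

#' Write selected features as TSV
#'
#' One row per feature: feature_id, kind (common|rare), set_type, p_value,
#' aic, snp_ids.
#'
#' @param sel a \code{selected_features} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_selected_features <- function(sel, path) {
  common <- if (nrow(sel$common)) data.frame(
    feature_id = sel$common$snp_id, kind = "common", set_type = NA,
    p_value = sel$common$p_value, aic = NA, snp_ids = sel$common$snp_id,
    stringsAsFactors = FALSE) else NULL
  rare <- if (nrow(sel$rare)) data.frame(
    feature_id = sel$rare$gene, kind = "rare", set_type = sel$rare$set_type,
    p_value = sel$rare$p_value, aic = sel$rare$aic,
    snp_ids = sel$rare$snp_ids, stringsAsFactors = FALSE) else NULL
  out <- rbind(common, rare)
  if (is.null(out))
    out <- data.frame(feature_id = character(), kind = character(),
                      set_type = character(), p_value = numeric(),
                      aic = numeric(), snp_ids = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
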