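#' Configuration for the mini-exome cohort simulator
#'
#' Describes a mini-exome style cohort of unrelated individuals: a fixed genotype
#' matrix with gene-grouped SNPs whose allele-frequency spectrum spans rare
#' (MAF < 5\%) and common variants, per-SNP nonsynonymous flags, three
#' environmental covariates, and many binary trait replicates re-simulated on
#' the same genotypes. Defaults mirror the structure of that data at desk
#' scale: 697 individuals, 200 genes (set \code{n_genes = 3205} to mirror the
#' full mini-exome), a mean of 7.6 SNPs per gene, 75\% rare SNPs, 200 trait
#' replicates, 30\% cases per replicate.
#'
#' @param n_individuals number of unrelated individuals (>= 2).
#' @param n_genes number of genes (>= 1).
#' @param mean_snps_per_gene mean of the per-gene SNP count, drawn as
#'   \code{1 + Poisson(mean - 1)} so every gene has at least one SNP
#'   (mean >= 5).
#' @param prop_rare fraction of SNPs in the rare stratum.
#' @param rare_maf_range population-MAF bounds (low, high) of the rare
#'   stratum; high must not exceed \code{common_maf_range[1]}. Frequencies
#'   are drawn log-uniformly (density proportional to 1/x) within the
#'   bounds, mimicking the excess of very rare alleles in sequence data;
#'   low must be positive unless low = high.
#' @param common_maf_range population-MAF bounds of the common stratum.
#' @param prop_nonsynonymous fraction of SNPs flagged nonsynonymous.
#' @param n_replicates number of trait replicates (>= 1).
#' @param target_prevalence mean case probability per replicate, in (0, 1).
#' @param seed RNG seed for the genotype/covariate draw.
#' @return An object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 697L, n_genes = 200L,
                       mean_snps_per_gene = 7.6, prop_rare = 0.75,
                       rare_maf_range = c(5e-4, 0.05),
                       common_maf_range = c(0.05, 0.5),
                       prop_nonsynonymous = 0.6, n_replicates = 200L,
                       target_prevalence = 0.3, seed = 1L) {
  stopifnot(n_individuals >= 2, n_genes >= 1, mean_snps_per_gene >= 1,
            prop_rare >= 0, prop_rare <= 1,
            prop_nonsynonymous >= 0, prop_nonsynonymous <= 1,
            length(rare_maf_range) == 2, length(common_maf_range) == 2,
            rare_maf_range[1] <= rare_maf_range[2],
            rare_maf_range[1] > 0 || rare_maf_range[1] == rare_maf_range[2],
            common_maf_range[1] <= common_maf_range[2],
            rare_maf_range[2] <= common_maf_range[1],
            common_maf_range[2] <= 0.5,
            n_replicates >= 1,
            target_prevalence > 0, target_prevalence < 1)
  structure(list(n_individuals = as.integer(n_individuals),
                 n_genes = as.integer(n_genes),
                 mean_snps_per_gene = mean_snps_per_gene,
                 prop_rare = prop_rare,
                 rare_maf_range = rare_maf_range,
                 common_maf_range = common_maf_range,
                 prop_nonsynonymous = prop_nonsynonymous,
                 n_replicates = as.integer(n_replicates),
                 target_prevalence = target_prevalence,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a fixed genotype matrix with gene structure
#'
#' Each gene receives \code{1 + Poisson(mean - 1)} SNPs. Each SNP is assigned
#' to the rare or common stratum (probability \code{prop_rare}), its
#' population allele frequency drawn uniformly within the stratum's range,
#' and its genotypes drawn as two independent allele draws per individual
#' (Hardy-Weinberg, linkage equilibrium). Nonsynonymous flags are Bernoulli
#' per SNP. The realized (sample) MAF is recorded alongside the true
#' population frequency.
#'
#' @param config a \code{\link{sim_config}}.
#' @return List with \code{genotypes} (individuals x SNPs integer matrix) and
#'   \code{annotation} (snp_id, chrom, pos, gene, nonsynonymous, true_maf,
#'   maf).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_individuals
    sz <- 1L + stats::rpois(config$n_genes,
                            max(config$mean_snps_per_gene - 1, 0))
    gene_ids <- sprintf("GENE%04d", seq_len(config$n_genes))
    gene_of <- rep(gene_ids, sz)
    m <- length(gene_of)
    snp_ids <- sprintf("SNP%06d", seq_len(m))
    is_rare <- stats::runif(m) < config$prop_rare
    # rare stratum: 1/x-shaped spectrum (log-uniform) mimicking the excess
    # of very rare alleles in sequence data; common stratum: uniform
    lo <- config$rare_maf_range[1]; hi <- config$rare_maf_range[2]
    rare_freq <- if (lo == hi) rep(lo, m) else
      exp(stats::runif(m, log(lo), log(hi)))
    freq <- ifelse(is_rare, rare_freq,
                   stats::runif(m, config$common_maf_range[1],
                                config$common_maf_range[2]))
    nonsyn <- stats::runif(m) < config$prop_nonsynonymous
    g <- matrix(stats::rbinom(n * m, 2L, rep(freq, each = n)),
                nrow = n, ncol = m,
                dimnames = list(sprintf("IND%04d", seq_len(n)), snp_ids))
    storage.mode(g) <- "integer"
    ann <- data.frame(snp_id = snp_ids, chrom = 1L, pos = seq_len(m) * 100L,
                      gene = gene_of, nonsynonymous = nonsyn,
                      true_maf = freq,
                      maf = unname(compute_sample_maf(g)),
                      stringsAsFactors = FALSE)
    list(genotypes = g, annotation = ann)
  })
}

#' Simulate environmental covariates
#'
#' Age ~ Normal(50, 10^2) truncated to [20, 90]; sex ~ Bernoulli(0.5);
#' smoking ~ Bernoulli(0.3).
#'
#' @param config a \code{\link{sim_config}}.
#' @return data.frame with columns id, age, sex, smoking.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 2L), {
    n <- config$n_individuals
    age <- stats::rnorm(n, 50, 10)
    while (any(bad <- age < 20 | age > 90))
      age[bad] <- stats::rnorm(sum(bad), 50, 10)
    data.frame(id = sprintf("IND%04d", seq_len(n)),
               age = round(age, 1),
               sex = stats::rbinom(n, 1, 0.5),
               smoking = stats::rbinom(n, 1, 0.3),
               stringsAsFactors = FALSE)
  })
}

#' Specify the generative disease model
#'
#' A population logistic model for binary disease status:
#' \deqn{\eta_i = \beta_0 + \beta_a age_i + \beta_s sex_i + \beta_k smoking_i
#'   + \sum_j \beta_j g_{ij} + \sum_g \gamma_g c_{ig}}
#' where \eqn{g_{ij}} is the minor-allele dosage at causal common SNP j and
#' \eqn{c_{ig}} the carrier indicator (any minor allele at a rare SNP) of
#' causal gene g, with the rare set per gene being either all rare SNPs or
#' only the nonsynonymous rare ones. Status is Bernoulli(expit(eta)).
#'
#' @param intercept baseline log-odds.
#' @param covariate_effects named numeric: log-odds per unit for
#'   \code{age}, \code{sex}, \code{smoking} (defaults 0).
#' @param common_effects named numeric: SNP id -> log-odds per allele copy.
#' @param rare_gene_effects named numeric: gene id -> carrier log-odds.
#' @param causal_rare_set named character: gene id -> \code{"all_rare"} or
#'   \code{"nonsyn_rare"}; genes absent default to \code{"all_rare"}.
#' @return An object of class \code{true_model}.
#' @export
true_model <- function(intercept = 0,
                       covariate_effects = c(age = 0, sex = 0, smoking = 0),
                       common_effects = numeric(0),
                       rare_gene_effects = numeric(0),
                       causal_rare_set = character(0)) {
  ce <- c(age = 0, sex = 0, smoking = 0)
  ce[names(covariate_effects)] <- covariate_effects
  if (length(common_effects) && is.null(names(common_effects)))
    stop("common_effects must be named by SNP id")
  if (length(rare_gene_effects) && is.null(names(rare_gene_effects)))
    stop("rare_gene_effects must be named by gene id")
  set <- rep("all_rare", length(rare_gene_effects))
  names(set) <- names(rare_gene_effects)
  set[names(causal_rare_set)] <- causal_rare_set
  stopifnot(all(set %in% c("all_rare", "nonsyn_rare")))
  structure(list(intercept = intercept, covariate_effects = ce,
                 common_effects = common_effects,
                 rare_gene_effects = rare_gene_effects,
                 causal_rare_set = set),
            class = "true_model")
}

# linear predictor WITHOUT the intercept; rare membership uses the true
# (population) MAF so the generative model is independent of sampling noise
.linear_predictor <- function(model, genotypes, annotation, covariates,
                              maf_threshold = 0.05) {
  unknown <- setdiff(names(model$common_effects), annotation$snp_id)
  if (length(unknown))
    stop("model references unknown SNP(s): ",
         paste(utils::head(unknown, 5), collapse = ","))
  unknown <- setdiff(names(model$rare_gene_effects), annotation$gene)
  if (length(unknown))
    stop("model references unknown gene(s): ",
         paste(utils::head(unknown, 5), collapse = ","))
  ce <- model$covariate_effects
  eta <- ce["age"] * covariates$age + ce["sex"] * covariates$sex +
    ce["smoking"] * covariates$smoking
  for (s in names(model$common_effects)) {
    d <- genotypes[, s]
    d[is.na(d)] <- 0L
    eta <- eta + model$common_effects[[s]] * d
  }
  pop_maf <- if (!is.null(annotation$true_maf)) annotation$true_maf else
    annotation$maf
  for (g in names(model$rare_gene_effects)) {
    members <- annotation$snp_id[annotation$gene == g &
                                   pop_maf < maf_threshold & pop_maf > 0]
    if (model$causal_rare_set[[g]] == "nonsyn_rare")
      members <- intersect(members,
                           annotation$snp_id[annotation$nonsynonymous])
    if (!length(members)) next
    carrier <- collapse_gene(genotypes, members)
    eta <- eta + model$rare_gene_effects[[g]] * carrier
  }
  unname(eta)
}

#' Calibrate the model intercept to a target prevalence
#'
#' Finds the intercept \eqn{\beta_0} such that the population mean of
#' \eqn{expit(\beta_0 + \eta_i)} over the cohort equals
#' \code{target_prevalence}. The mean is strictly increasing in the
#' intercept, so monotone root-finding always succeeds; the result satisfies
#' the target within 1e-6.
#'
#' @param model a \code{\link{true_model}} (its current intercept is ignored).
#' @param genotypes,annotation,covariates cohort components.
#' @param target_prevalence desired mean case probability, in (0, 1).
#' @return The calibrated intercept (log-odds scale).
#' @export
calibrate_intercept <- function(model, genotypes, annotation, covariates,
                                target_prevalence) {
  stopifnot(target_prevalence > 0, target_prevalence < 1)
  eta0 <- .linear_predictor(model, genotypes, annotation, covariates)
  f <- function(b) mean(expit(b + eta0)) - target_prevalence
  r <- stats::uniroot(f, interval = c(-20, 20), extendInt = "upX",
                      tol = 1e-12)
  b <- r$root
  stopifnot(abs(f(b)) < 1e-6)
  b
}

#' Simulate binary trait replicates on fixed genotypes
#'
#' Draws \code{n_replicates} independent re-simulations of disease status on
#' the same genotypes and covariates: replicate r uses a deterministic
#' sub-seed derived from \code{(seed, r)}, and status is
#' Bernoulli(expit(eta)) per individual under the supplied generative model.
#' Replicates in which one class is absent (possible only in tiny cohorts)
#' are redrawn with a further derived seed, deterministically.
#'
#' @param genotypes,annotation,covariates cohort components.
#' @param model a \code{\link{true_model}}.
#' @param n_replicates number of replicates.
#' @param seed master seed for the trait draws.
#' @param mode \code{"bernoulli"} (population model, random case count; the
#'   default) or \code{"fixed_count"} (exactly
#'   \code{round(n * mean(p))} cases per replicate, sampled without
#'   replacement with probability proportional to individual risk —
#'   an approximate case-control resampling mode).
#' @return Integer matrix individuals x replicates (columns
#'   \code{rep_1..rep_R}) of 0/1 status.
#' @export
simulate_phenotype_replicates <- function(genotypes, annotation, covariates,
                                          model, n_replicates, seed,
                                          mode = c("bernoulli",
                                                   "fixed_count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "true_model"), n_replicates >= 1)
  eta <- model$intercept +
    .linear_predictor(model, genotypes, annotation, covariates)
  p <- expit(eta)
  n <- nrow(genotypes)
  out <- matrix(0L, n, n_replicates,
                dimnames = list(rownames(genotypes),
                                sprintf("rep_%d", seq_len(n_replicates))))
  for (r in seq_len(n_replicates)) {
    attempt <- 0L
    repeat {
      y <- with_seed(derive_seed(seed, 100L + r, attempt), {
        if (mode == "bernoulli") stats::rbinom(n, 1L, p)
        else {
          k <- max(1L, min(n - 1L, round(n * mean(p))))
          y <- integer(n)
          y[sample.int(n, k, prob = p)] <- 1L
          y
        }
      })
      if (any(y == 1L) && any(y == 0L)) break
      attempt <- attempt + 1L
      if (attempt > 100L) stop("cannot draw a replicate with both classes")
    }
    out[, r] <- y
  }
  out
}

#' Simulate a complete cohort
#'
#' Convenience wrapper: genotypes + covariates from \code{config}, then trait
#' replicates under \code{model} (a null model with intercept calibrated to
#' \code{config$target_prevalence} if \code{model} is NULL; if a model is
#' supplied with \code{calibrate = TRUE}, its intercept is recalibrated to
#' the target prevalence first).
#'
#' @param config a \code{\link{sim_config}}.
#' @param model optional \code{\link{true_model}}.
#' @param calibrate recalibrate the supplied model's intercept (default TRUE).
#' @return A list: \code{cohort} (a \code{\link{cohort}}) and \code{model}
#'   (the generative model actually used, calibrated intercept included).
#' @export
simulate_cohort <- function(config, model = NULL, calibrate = TRUE) {
  gen <- simulate_genotypes(config)
  cov <- simulate_covariates(config)
  if (is.null(model)) model <- true_model()
  if (calibrate)
    model$intercept <- calibrate_intercept(model, gen$genotypes,
                                           gen$annotation, cov,
                                           config$target_prevalence)
  ph <- simulate_phenotype_replicates(gen$genotypes, gen$annotation, cov,
                                      model, config$n_replicates,
                                      derive_seed(config$seed, 3L))
  list(cohort = cohort(gen$genotypes, gen$annotation, cov, ph),
       model = model)
}

#' Build a causal disease model with common and rare-burden effects
#'
#' Selects causal features from a simulated cohort's annotation: common
#' causal SNPs drawn from a mid-frequency band (so their effect is
#' detectable), and rare-burden causal genes whose carrier frequency (any
#' minor allele across the gene's rare SNPs) falls in a target band. Defaults
#' encode a strong rare-variant architecture: 20 causal genes at carrier
#' frequency 2-5\% with carrier log-odds 1.5, 10 common causal SNPs with
#' per-allele log-odds 0.4, and modest covariate effects.
#'
#' @param genotypes,annotation cohort components.
#' @param n_common number of common causal SNPs.
#' @param n_rare_genes number of rare-burden causal genes.
#' @param common_effect per-allele log-odds of each common causal SNP.
#' @param rare_effect carrier log-odds of each causal gene.
#' @param common_maf_band MAF band from which common causal SNPs are drawn.
#' @param carrier_freq_band admissible carrier-frequency band of causal genes.
#' @param covariate_effects named log-odds for age/sex/smoking.
#' @param maf_threshold rare/common MAF boundary (default 0.05).
#' @param seed seed for the causal-feature draw.
#' @return A \code{\link{true_model}} (intercept 0; calibrate before use).
#' @export
causal_model <- function(genotypes, annotation, n_common = 10,
                         n_rare_genes = 20, common_effect = 0.4,
                         rare_effect = 1.5,
                         common_maf_band = c(0.1, 0.4),
                         carrier_freq_band = c(0.02, 0.05),
                         covariate_effects = c(age = 0.02, sex = 0.25,
                                               smoking = 0.4),
                         maf_threshold = 0.05, seed = 1L) {
  pop_maf <- if (!is.null(annotation$true_maf)) annotation$true_maf else
    annotation$maf
  eligible_snps <- annotation$snp_id[pop_maf >= common_maf_band[1] &
                                       pop_maf <= common_maf_band[2]]
  rare_snps <- annotation$snp_id[pop_maf < maf_threshold & pop_maf > 0]
  gm <- gene_map(annotation)
  carrier_freq <- vapply(gm, function(members) {
    members <- intersect(members, rare_snps)
    if (!length(members)) return(0)
    mean(collapse_gene(genotypes, members))
  }, 0)
  eligible_genes <- names(carrier_freq)[carrier_freq >= carrier_freq_band[1] &
                                          carrier_freq <= carrier_freq_band[2]]
  if (length(eligible_snps) < n_common)
    stop("not enough common SNPs in the requested MAF band")
  if (length(eligible_genes) < n_rare_genes)
    stop("not enough genes in the requested carrier-frequency band")
  with_seed(derive_seed(seed, 4L), {
    cs <- sample(eligible_snps, n_common)
    cg <- sample(eligible_genes, n_rare_genes)
    true_model(intercept = 0, covariate_effects = covariate_effects,
               common_effects = stats::setNames(rep(common_effect,
                                                    n_common), cs),
               rare_gene_effects = stats::setNames(rep(rare_effect,
                                                       n_rare_genes), cg))
  })
}

#' Write the generative model to JSON
#'
#' @param model a \code{\link{true_model}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_true_model <- function(model, path) {
  # named vectors must become lists so jsonlite keeps the names
  x <- lapply(unclass(model), as.list)
  x$intercept <- model$intercept
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a generative model from JSON
#'
#' @param path JSON file written by \code{\link{write_true_model}}.
#' @return A \code{\link{true_model}}.
#' @export
read_true_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  true_model(intercept = x$intercept,
             covariate_effects = unlist(x$covariate_effects),
             common_effects = unlist(x$common_effects),
             rare_gene_effects = unlist(x$rare_gene_effects),
             causal_rare_set = unlist(x$causal_rare_set))
}
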