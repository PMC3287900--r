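# Shared fixtures, built in code and memoized for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# small null cohort: no genetic or covariate effects
small_null_cohort <- function() {
  memo("small_null", function() {
    cfg <- sim_config(n_individuals = 250, n_genes = 30, n_replicates = 6,
                      seed = 11)
    simulate_cohort(cfg)
  })
}

# small cohort with common + rare-burden causal effects
small_signal_cohort <- function() {
  memo("small_signal", function() {
    cfg <- sim_config(n_individuals = 300, n_genes = 40, n_replicates = 8,
                      seed = 5)
    gen <- simulate_genotypes(cfg)
    cov <- simulate_covariates(cfg)
    mdl <- causal_model(gen$genotypes, gen$annotation, n_common = 4,
                        n_rare_genes = 5,
                        carrier_freq_band = c(0.02, 0.12), seed = 5)
    mdl$intercept <- calibrate_intercept(mdl, gen$genotypes, gen$annotation,
                                         cov, 0.3)
    ph <- simulate_phenotype_replicates(gen$genotypes, gen$annotation, cov,
                                        mdl, cfg$n_replicates, seed = 99)
    list(cohort = cohort(gen$genotypes, gen$annotation, cov, ph),
         model = mdl)
  })
}

# hand-sized cohort where every piece can be checked by eye
tiny_cohort <- function() {
  g <- matrix(c(0L, 1L, 0L, 2L,
                0L, 0L, 1L, 1L,
                2L, 1L, 0L, 0L,
                0L, 0L, 0L, 1L,
                1L, 2L, 1L, 0L,
                0L, 1L, 0L, 0L),
              nrow = 6, byrow = TRUE,
              dimnames = list(paste0("I", 1:6), paste0("S", 1:4)))
  ann <- data.frame(snp_id = paste0("S", 1:4), chrom = 1L, pos = 1:4 * 10L,
                    gene = c("GA", "GA", "GB", "GB"),
                    nonsynonymous = c(TRUE, FALSE, TRUE, TRUE),
                    stringsAsFactors = FALSE)
  cov <- data.frame(id = paste0("I", 1:6), age = c(40, 55, 61, 47, 52, 38),
                    sex = c(0L, 1L, 0L, 1L, 1L, 0L),
                    smoking = c(0L, 0L, 1L, 0L, 1L, 1L))
  ph <- matrix(c(1L, 0L, 1L, 0L, 1L, 0L,
                 0L, 1L, 1L, 0L, 0L, 1L),
               ncol = 2, dimnames = list(paste0("I", 1:6),
                                         c("rep_1", "rep_2")))
  cohort(g, ann, cov, ph)
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins and sum the hypergeometric probabilities not exceeding the
# observed one (relative tie tolerance 1e-7)
fisher_enum_p <- function(tab) {
  K <- sum(tab[1, ])        # total minor alleles
  N <- sum(tab)
  n <- sum(tab[, 1])        # case alleles
  a_obs <- tab[1, 1]
  support <- max(0, n - (N - K)):min(n, K)
  # direct combinatorics, independent of the implementation's code path
  lp <- lchoose(K, support) + lchoose(N - K, n - support) - lchoose(N, n)
  probs <- exp(lp)
  p_obs <- exp(lchoose(K, a_obs) + lchoose(N - K, n - a_obs) -
                 lchoose(N, n))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force Mann-Whitney AUC with tie half-credit
auc_pairs <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# independent logistic ML fit: BFGS on the log-likelihood with analytic
# gradient (different code path from the IRLS implementation)
logistic_bfgs <- function(x, y) {
  nll <- function(beta) {
    eta <- drop(x %*% beta)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  }
  grad <- function(beta) {
    p <- 1 / (1 + exp(-drop(x %*% beta)))
    drop(t(x) %*% (p - y))
  }
  fit <- stats::optim(rep(0, ncol(x)), nll, grad, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-16))
  list(coefficients = fit$par, lnL = -fit$value,
       aic = 2 * ncol(x) + 2 * fit$value)
}
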