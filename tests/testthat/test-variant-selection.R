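test_that("MAF partition applies the 5% convention with a common boundary", {
  maf <- c(a = 0.049, b = 0.050, c = 0.20, d = 0.001, e = 0, f = NA)
  part <- partition_variants(maf)
  expect_setequal(part$common, c("b", "c"))   # boundary 0.05 is common
  expect_setequal(part$rare, c("a", "d"))
  expect_setequal(part$monomorphic, c("e", "f"))
  # three buckets partition all SNPs
  expect_setequal(c(part$common, part$rare, part$monomorphic), names(maf))
})

test_that("Fisher allele-count test matches hand-computed examples", {
  # identical allele proportions: 10/10 vs 10/10 -> p = 1
  dos <- c(rep(1, 10), rep(1, 10))
  status <- c(rep(1, 10), rep(0, 10))
  r <- fisher_allele_test(dos, status)
  expect_equal(r$p_value, 1)
  expect_equal(unname(r$table[, "case"]), c(10, 10))
  # extreme table with all margins 5: cases (5 minor, 0 major), controls
  # (0, 5): two-sided p = 2 / choose(10, 5) = 2/252
  tab5 <- matrix(c(5, 0, 0, 5), 2,
                 dimnames = list(allele = c("minor", "major"),
                                 status = c("case", "control")))
  expect_equal(stats::fisher.test(tab5)$p.value, 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_enum_p(tab5), 2 / 252, tolerance = 1e-12)
  # dosage-level build: 5 of 6 case alleles minor vs 1 of 4 control alleles
  r <- fisher_allele_test(c(2, 2, 1, 1, 0), c(1, 1, 1, 0, 0))
  expect_equal(unname(r$table[, "case"]), c(5, 1))
  expect_equal(unname(r$table[, "control"]), c(1, 3))
  expect_equal(r$p_value, fisher_enum_p(r$table), tolerance = 1e-12)
  # degenerate (monomorphic in subset)
  r <- fisher_allele_test(c(0, 0, 0, 0), c(1, 1, 0, 0))
  expect_true(r$degenerate)
  expect_equal(r$p_value, 1)
  expect_error(fisher_allele_test(c(0, 1), c(1, 1)), "control")
})

test_that("Fisher p equals the enumeration oracle on random tables", {
  set.seed(20)
  for (i in 1:200) {
    tab <- matrix(sample(0:15, 4, TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p_impl <- rarepred:::.fisher_two_sided(tab[1, 1], sum(tab[1, ]),
                                           sum(tab), sum(tab[, 1]))
    expect_equal(p_impl, fisher_enum_p(tab), tolerance = 1e-12)
    # stats::fisher.test uses the same two-sided rule: third, fully
    # independent route
    expect_equal(p_impl, stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("gene collapsing is the presence/absence indicator", {
  g <- rbind(c(0L, 0L), c(1L, 0L), c(0L, 2L), c(1L, 1L))
  dimnames(g) <- list(paste0("I", 1:4), c("S1", "S2"))
  expect_equal(collapse_gene(g, c("S1", "S2")), c(0L, 1L, 1L, 1L))
  # all-zero gene
  g0 <- g; g0[] <- 0L
  expect_equal(collapse_gene(g0, c("S1", "S2")), rep(0L, 4))
  # single heterozygote carries
  expect_equal(collapse_gene(g, "S1"), c(0L, 1L, 0L, 1L))
  # missing treated as non-carrier
  gna <- g; gna[2, 1] <- NA_integer_
  expect_equal(collapse_gene(gna, c("S1", "S2")), c(0L, 0L, 1L, 1L))
  # idempotent and order-independent
  expect_equal(collapse_gene(g, c("S2", "S1")),
               collapse_gene(g, c("S1", "S2")))
  expect_error(collapse_gene(g, character(0)), "non-empty")
  expect_error(collapse_gene(g, "NOPE"), "NOPE")
})

test_that("logistic fit matches closed forms and an independent optimizer", {
  # intercept-only MLE on 2 cases / 2 controls: lnL = 4 ln(1/2)
  fit <- fit_logistic(c(1, 1, 0, 0), indicator = c(1, 0, 1, 0))
  # the indicator here is balanced within classes; check against the
  # 2-parameter direct optimum instead
  x <- cbind(1, c(1, 0, 1, 0))
  oracle <- logistic_bfgs(x, c(1, 1, 0, 0))
  expect_equal(fit$lnL, oracle$lnL, tolerance = 1e-6)
  expect_equal(fit$aic, oracle$aic, tolerance = 1e-6)
  # intercept-only AIC via an unadjusted fit where indicator carries no
  # information: lnL of the null component is 4 ln(0.5)
  expect_equal(4 * log(0.5), -2.772589, tolerance = 1e-6)

  # 20 random datasets: coefficients, lnL and AIC match BFGS within 1e-6
  set.seed(31)
  for (i in 1:20) {
    n <- 200
    ind <- rbinom(n, 1, 0.15)
    cov <- data.frame(age = rnorm(n, 50, 10), sex = rbinom(n, 1, 0.5),
                      smoking = rbinom(n, 1, 0.3))
    eta <- -1 + 0.8 * ind + 0.01 * (cov$age - 50) + 0.3 * cov$sex
    y <- rbinom(n, 1, expit(eta))
    if (length(unique(y)) < 2 || length(unique(ind)) < 2) next
    fit <- fit_logistic(y, ind, cov)
    x <- cbind(1, ind, cov$age, cov$sex, cov$smoking)
    oracle <- logistic_bfgs(x, y)
    expect_equal(unname(fit$coefficients), oracle$coefficients,
                 tolerance = 1e-6)
    expect_equal(fit$lnL, oracle$lnL, tolerance = 1e-6)
    expect_equal(fit$aic, oracle$aic, tolerance = 1e-6)
  }
})

test_that("logistic LRT p-values are null-uniform and separation is flagged", {
  # null indicator: LRT p approximately Uniform(0,1)
  set.seed(17)
  n <- 400
  ps <- replicate(300, {
    y <- rbinom(n, 1, 0.3)
    ind <- rbinom(n, 1, 0.2)
    if (length(unique(y)) < 2 || length(unique(ind)) < 2) return(NA)
    fit_logistic(y, ind)$p_value
  })
  ps <- ps[!is.na(ps)]
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
  # quasi-complete separation: indicator perfectly predicts case
  y <- c(rep(1, 5), rep(0, 20))
  ind <- c(rep(1, 5), rep(0, 20))
  fit <- fit_logistic(y, ind)
  expect_false(fit$converged)
  expect_lt(fit$p_value, 0.01)  # LRT at the last iterate still informative
})

test_that("rare-feature selection keeps the smaller-AIC set, tie to nonsyn", {
  scan <- data.frame(
    gene = c("G1", "G1", "G2", "G3", "G3"),
    set_type = c("all_rare", "nonsyn_rare", "all_rare", "all_rare",
                 "nonsyn_rare"),
    p_value = c(0.001, 0.002, 0.5, 0.004, 0.004),
    aic = c(510.2, 508.9, 600, 500, 500),
    converged = TRUE, n_carriers = 10,
    snp_ids = "s", stringsAsFactors = FALSE)
  sel <- select_rare_features(scan, 0.01)
  # G1: both pass, nonsyn has smaller AIC
  expect_equal(sel$set_type[sel$gene == "G1"], "nonsyn_rare")
  # G2 fails the threshold
  expect_false("G2" %in% sel$gene)
  # G3: exact AIC tie -> nonsynonymous set
  expect_equal(sel$set_type[sel$gene == "G3"], "nonsyn_rare")
  # at most one feature per gene
  expect_equal(anyDuplicated(sel$gene), 0L)
})

test_that("AIC tie-break is exercised end-to-end when the two sets coincide", {
  # gene whose rare SNPs are all nonsynonymous: identical indicators, equal
  # AIC, nonsynonymous set must win
  set.seed(5)
  n <- 150
  g <- cbind(S1 = rbinom(n, 1, 0.04), S2 = rbinom(n, 1, 0.03),
             S3 = rbinom(n, 2, 0.3))
  rownames(g) <- sprintf("I%03d", 1:n)
  storage.mode(g) <- "integer"
  ann <- data.frame(snp_id = c("S1", "S2", "S3"), gene = c("G", "G", "G"),
                    nonsynonymous = c(TRUE, TRUE, TRUE))
  carrier <- collapse_gene(g, c("S1", "S2"))
  y <- rbinom(n, 1, expit(-1 + 2.5 * carrier))
  cov <- data.frame(id = rownames(g), age = rnorm(n, 50, 10),
                    sex = rbinom(n, 1, 0.5), smoking = rbinom(n, 1, 0.3))
  scan <- rare_gene_scan(g, ann, c("S1", "S2"), y, cov)
  expect_equal(nrow(scan), 2)
  expect_equal(scan$aic[1], scan$aic[2], tolerance = 1e-9)
  sel <- select_rare_features(scan, 0.05)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$set_type, "nonsyn_rare")
})

test_that("common-SNP selection is strict and nested across thresholds", {
  sim <- small_signal_cohort()
  ch <- sim$cohort
  status <- ch$phenotypes[, 1]
  maf <- compute_sample_maf(ch$genotypes)
  part <- partition_variants(maf)
  screen <- fisher_screen(ch$genotypes, part$common, status)
  s_loose <- select_common_features(screen, 0.05)
  s_tight <- select_common_features(screen, 0.001)
  expect_true(all(s_tight$snp_id %in% s_loose$snp_id))
  expect_true(all(s_loose$p_value < 0.05))
  # threshold 1.0 keeps every non-degenerate testable SNP with p < 1
  s_all <- select_common_features(screen, 1)
  expect_equal(nrow(s_all), sum(!screen$degenerate & screen$p_value < 1))
})

test_that("selection at a threshold is nested within any looser threshold", {
  sim <- small_signal_cohort()
  ch <- sim$cohort
  sels <- select_features(ch, ch$phenotypes[, 1],
                          thresholds = c(0.05, 0.005, 5e-4))
  for (i in 2:3) {
    expect_true(all(sels[[i]]$common$snp_id %in% sels[[1]]$common$snp_id))
    expect_true(all(sels[[i]]$rare$gene %in% sels[[1]]$rare$gene))
  }
})

test_that("null selection rate does not exceed the threshold", {
  # global null: fraction of selected features is at most the threshold
  # plus Monte-Carlo error (Fisher is conservative; LRT is calibrated)
  sim <- small_null_cohort()
  ch <- sim$cohort
  t <- 0.05
  n_tested <- 0; n_sel <- 0
  for (r in 1:6) {
    sel <- select_features(ch, ch$phenotypes[, r], thresholds = t)
    maf <- compute_sample_maf(ch$genotypes)
    part <- partition_variants(maf)
    n_tested <- n_tested + length(part$common) +
      length(unique(ch$annotation$gene[ch$annotation$snp_id %in% part$rare]))
    n_sel <- n_sel + nrow(sel$common) + nrow(sel$rare)
  }
  rate <- n_sel / n_tested
  mc <- 3 * sqrt(t * (1 - t) / n_tested)
  expect_lte(rate, t + mc)
})

test_that("selected features serialize to TSV", {
  sim <- small_signal_cohort()
  sel <- select_features(sim$cohort, sim$cohort$phenotypes[, 1],
                         thresholds = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_selected_features(sel, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(sel$common) + nrow(sel$rare))
  expect_setequal(back$feature_id[back$kind == "rare"], sel$rare$gene)
})
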