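# small deterministic data set with a genotype factor and modest HYS structure
model_fixture <- function(seed = 1, n_sires = 6, range = c(4, 4),
                          sigma_a2 = 4, sigma_e2 = 8) {
  cfg <- small_config(seed = seed, n_sires = n_sires, range = range,
                      a = 3, d = 1, sigma_a2 = sigma_a2, sigma_e2 = sigma_e2)
  cfg$n_farms <- 2; cfg$n_years <- 1; cfg$n_seasons <- 2
  co <- simulate_cohort(cfg)
  dat <- filter(co$phenotypes, lactation == 1)
  dat$genotype <- lactsnp:::snp_factor(co$genotypes, "TEST", "A", "C")[
    match(dat$animal, co$genotypes$animal)]
  list(cfg = cfg, co = co, dat = dat,
       ainv = build_A_inverse(co$pedigree[, 1:3]),
       A = build_A(co$pedigree[, 1:3]))
}

test_that("the MME solution equals dense GLS on a small instance", {
  fx <- model_fixture(seed = 5)          # 24 daughters + parents
  fit <- fit_animal_model(fx$dat, "yield", fx$ainv, factor_name = "genotype")
  # oracle: explicit V = ZAZ' sa2 + I se2 at the fitted variance components
  df <- fx$dat
  X <- model.matrix(~ hys + calving_age + genotype,
                    transform(df, hys = factor(hys)))
  Z <- matrix(0, nrow(df), nrow(fx$A))
  Z[cbind(seq_len(nrow(df)), match(df$animal, rownames(fx$A)))] <- 1
  or <- gls_fixed_effects(df$yield, X, Z, fx$A, fit$sigma_a2, fit$sigma_e2)
  expect_equal(unname(fit$beta), or$beta, tolerance = 1e-6)
  expect_equal(unname(fit$cov_beta), unname(or$cov), tolerance = 1e-6)
})

test_that("the REML optimum matches a 10^4-point dense grid search", {
  # 12-animal fixture: 4 sires x 3 daughters
  fx <- model_fixture(seed = 8, n_sires = 4, range = c(3, 3))
  fit <- fit_animal_model(fx$dat, "yield", fx$ainv, factor_name = "genotype")
  df <- fx$dat
  X <- model.matrix(~ hys + calving_age + genotype,
                    transform(df, hys = factor(hys)))
  Z <- matrix(0, nrow(df), nrow(fx$A))
  Z[cbind(seq_len(nrow(df)), match(df$animal, rownames(fx$A)))] <- 1
  grid <- exp(seq(log(1e-3), log(1e3), length.out = 1e4))
  m2ll <- vapply(grid, function(l) dense_reml_m2ll(l, df$yield, X, Z, fx$A), 0)
  # the fitted lambda attains the grid's best -2*logLik (the profile is very
  # flat at 4 residual df, so compare attained values, not locations)
  at_fit <- dense_reml_m2ll(fit$lambda, df$yield, X, Z, fx$A)
  expect_lte(at_fit, min(m2ll) + 1e-6 * abs(min(m2ll)))
  # profile is unimodal: on a coarser grid (steps large enough to clear float
  # noise) the slope changes sign at most once, decreasing before increasing
  coarse <- m2ll[seq(1, length(m2ll), by = 50)]
  sgn <- sign(diff(coarse))
  sgn <- sgn[sgn != 0]
  expect_lte(sum(diff(sgn) != 0), 1)
  if (any(diff(sgn) != 0)) expect_equal(sgn[1], -1)
})

test_that("null heritability is recovered when sigma_a2 = 0", {
  cfg <- small_config(seed = 3, n_sires = 40, range = c(20, 25),
                      sigma_a2 = 0, sigma_e2 = 3e4)
  co <- simulate_cohort(cfg)
  dat <- filter(co$phenotypes, lactation == 1)
  ainv <- build_A_inverse(co$pedigree[, 1:3])
  fit <- suppressWarnings(fit_animal_model(dat, "yield", ainv))
  expect_lt(fit$heritability, 0.02)
})

test_that("LS-means reduce to raw group means in the balanced fixed-effect limit", {
  set.seed(44)
  n <- 60
  g <- factor(rep(c("AA", "AB", "BB"), each = n / 3))
  dat <- tibble(animal = sprintf("u%03d", 1:n),
                yield = rnorm(n, 100 + c(5, 0, -5)[as.integer(g)], 1),
                genotype = g)
  ped <- tibble(animal = dat$animal, sire = NA_character_, dam = NA_character_)
  ainv <- build_A_inverse(ped)
  # no HYS, no covariate; unrelated animals with sigma_a2 ~ 0
  fit <- suppressWarnings(
    fit_animal_model(dat, "yield", ainv, factor_name = "genotype",
                     class_vars = character(0), covariates = character(0)))
  lsm <- ls_means(fit)
  raw <- tapply(dat$yield, dat$genotype, mean)
  expect_equal(lsm$estimate, as.vector(raw[lsm$level]), tolerance = 1e-3)
})

test_that("adding a constant shifts every LS-mean by exactly that constant", {
  fx <- model_fixture(seed = 2)
  f1 <- fit_animal_model(fx$dat, "yield", fx$ainv, factor_name = "genotype")
  dat2 <- mutate(fx$dat, yield = yield + 1234)
  f2 <- fit_animal_model(dat2, "yield", fx$ainv, factor_name = "genotype")
  expect_equal(ls_means(f2)$estimate, ls_means(f1)$estimate + 1234,
               tolerance = 1e-6)
})

test_that("results are invariant to record order and genotype relabelling", {
  fx <- model_fixture(seed = 6)
  f1 <- suppressWarnings(
    fit_animal_model(fx$dat, "yield", fx$ainv, factor_name = "genotype"))
  perm <- sample(nrow(fx$dat))
  f2 <- suppressWarnings(
    fit_animal_model(fx$dat[perm, ], "yield", fx$ainv, factor_name = "genotype"))
  # numerically identical up to the sparse-factorisation ordering
  expect_equal(f1$sigma_a2, f2$sigma_a2, tolerance = 1e-4)
  expect_equal(ls_means(f1)$estimate, ls_means(f2)$estimate, tolerance = 1e-5)
  # relabel genotype levels: estimates follow the labels
  dat3 <- mutate(fx$dat, genotype = factor(genotype,
                                           levels = rev(levels(genotype))))
  f3 <- suppressWarnings(
    fit_animal_model(dat3, "yield", fx$ainv, factor_name = "genotype"))
  l1 <- ls_means(f1); l3 <- ls_means(f3)
  expect_equal(l3$estimate[match(l1$level, l3$level)], l1$estimate,
               tolerance = 1e-6)
  expect_equal(test_factor(f1)$chisq, test_factor(f3)$chisq, tolerance = 1e-6)
})

test_that("confounded designs raise a singularity error naming the term", {
  fx <- model_fixture(seed = 4)
  dat <- mutate(fx$dat, genotype2 = genotype)
  expect_error(fit_animal_model(dat, "yield", fx$ainv, factor_name = "genotype2",
                                class_vars = c("hys", "genotype")),
               "singular|confounded")
})

test_that("a single-level factor tests as df 0, p 1", {
  fx <- model_fixture(seed = 7)
  dat <- mutate(fx$dat, mono = factor("only"))
  fit <- suppressWarnings(fit_animal_model(dat, "yield", fx$ainv, factor_name = "mono"))
  wt <- test_factor(fit)
  expect_equal(wt$df, 0L)
  expect_equal(wt$p_value, 1)
})

test_that("tidy and glance expose coefficients and variance components", {
  fx <- model_fixture(seed = 9)
  fit <- fit_animal_model(fx$dat, "yield", fx$ainv, factor_name = "genotype")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(fx$dat))
  expect_gt(gl$sigma_e2, 0)
})
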