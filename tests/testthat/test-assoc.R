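test_that("allele relabelling negates beta and preserves p exactly", {
  co <- simulate_cohort(genetic_architecture(800, 30, h2 = 0.2, seed = 4))
  a <- gwas(co, "trait")
  flipped_cohort <- co
  flipped_cohort$dosages[, 3] <- 2 - co$dosages[, 3]
  flipped_cohort$variants$eaf <- colMeans(flipped_cohort$dosages) / 2
  b <- gwas(flipped_cohort, "trait")
  expect_equal(b$beta[3], -a$beta[3], tolerance = 1e-12)
  expect_equal(b$se[3], a$se[3], tolerance = 1e-12)
  expect_equal(b$p[3], a$p[3], tolerance = 1e-12)
  expect_equal(b$eaf[3], 1 - a$eaf[3], tolerance = 1e-12)
  # same symmetry through the summary-row helper
  f <- flip_alleles(a, a$snv_id[3])
  expect_equal(f$beta[3], -a$beta[3])
  expect_equal(f$eaf[3], 1 - a$eaf[3])
  expect_identical(f$p, a$p)
})

test_that("gwas matches lm() per variant with covariates", {
  co <- simulate_cohort(genetic_architecture(400, 5, h2 = 0.3, seed = 6))
  a <- gwas(co, "trait", covariates = c("sex", "age"))
  for (j in c(1, 4)) {
    fit <- lm(co$traits$trait ~ co$dosages[, j] + co$traits$sex + co$traits$age)
    sm <- summary(fit)$coefficients[2, ]
    expect_equal(a$beta[j], unname(sm[1]), tolerance = 1e-10)
    expect_equal(a$se[j], unname(sm[2]), tolerance = 1e-10)
    expect_equal(a$p[j], unname(sm[4]), tolerance = 1e-10)
  }
})

test_that("a planted variant with 1% variance share reaches genome-wide p", {
  arch <- genetic_architecture(6000, 40, h2 = 0.01,
                               causal_effects = c(1, rep(0, 39)), seed = 7)
  co <- simulate_cohort(arch)
  a <- gwas(co, "trait")
  expect_lt(a$p[1], 5e-8)  # non-centrality n * share = 60
  expect_gt(min(a$p[-1]), 5e-8)
})

test_that("monomorphic and rare variants are skipped, collinearity errors", {
  co <- simulate_cohort(genetic_architecture(300, 10, h2 = 0.1, seed = 8))
  co$dosages[, 2] <- 0
  expect_message(a <- gwas(co, "trait"), "skipped")
  expect_false("snv00002" %in% a$snv_id)
  X <- cbind(co$traits$sex, co$traits$sex * 2)
  expect_error(gwas(co, "trait", covariates = X), "collinear")
})

test_that("conditional p equals marginal p for orthogonal variants", {
  g1 <- rep(c(0L, 2L), 200)
  g2 <- rep(c(0L, 2L, 2L, 0L), 100)
  set.seed(11)
  y <- 0.2 * g1 + 0.1 * g2 + rnorm(400)
  co <- manual_cohort(cbind(g1, g2), trait = y)
  marg <- gwas(co, "trait")
  cond <- conditional_regression(co, "trait", NULL,
                                 lead_snv = colnames(co$dosages)[1],
                                 candidate_snv = colnames(co$dosages)[2])
  fit <- lm(y ~ co$dosages[, 2])
  expect_equal(cond$beta, unname(coef(fit)[2]), tolerance = 1e-8)
  expect_false(cond$dropped)
})

test_that("a candidate in perfect LD with the lead is dropped and flagged", {
  co <- simulate_cohort(genetic_architecture(500, 5, h2 = 0.1, seed = 12))
  co$dosages[, 2] <- co$dosages[, 1]
  cond <- conditional_regression(co, "trait", NULL,
                                 lead_snv = "snv00001", candidate_snv = "snv00002")
  expect_true(cond$dropped)
  expect_true(is.na(cond$p_conditional))
  expect_error(conditional_regression(co, "trait", NULL, "snv00001", "snv00001"),
               "differ")
})

test_that("two independent causal variants both survive conditioning", {
  arch <- genetic_architecture(4000, 20, h2 = 0.02,
                               causal_effects = c(1, 1, rep(0, 18)), seed = 14)
  co <- simulate_cohort(arch)
  cond <- conditional_regression(co, "trait", NULL,
                                 lead_snv = "snv00001", candidate_snv = "snv00002")
  expect_lt(cond$p_conditional, 1e-4)
})

test_that("Haseman-Elston recovers a null heritability", {
  co <- simulate_cohort(genetic_architecture(1500, 400, h2 = 0, seed = 15))
  he <- heritability_he(co, "trait")
  expect_lt(abs(he$h2), 2 * he$se)
})

test_that("Haseman-Elston is invariant to affine trait transformation", {
  co <- simulate_cohort(genetic_architecture(800, 200, h2 = 0.4, seed = 16))
  grm <- he_grm(co)
  a <- heritability_he(co, co$traits$trait, grm = grm)
  b <- heritability_he(co, 5 - 3 * co$traits$trait, grm = grm)
  expect_equal(a$h2, b$h2, tolerance = 1e-12)
  expect_equal(a$se, b$se, tolerance = 1e-12)
})

test_that("genetic correlation of a trait with itself is exactly 1", {
  co <- simulate_cohort(genetic_architecture(600, 150, h2 = 0.4, seed = 17))
  rg <- genetic_correlation_he(co, co$traits$trait, co$traits$trait)
  expect_equal(rg$rg, 1, tolerance = 1e-12)
})

test_that("genetic correlation recovers a null rg", {
  co <- simulate_cohort(genetic_architecture(2000, 800, h2 = 0.4, h2_b = 0.4,
                                             rg = 0, seed = 18))
  rg <- genetic_correlation_he(co, "trait", "trait2")
  expect_true(rg$defined)
  expect_lt(abs(rg$rg), 2 * rg$se)
})

test_that("association results are independent of variant and sample order", {
  co <- simulate_cohort(genetic_architecture(500, 20, h2 = 0.2, seed = 19))
  a <- gwas(co, "trait")
  perm_v <- sample(ncol(co$dosages))
  perm_i <- sample(nrow(co$dosages))
  co2 <- co
  co2$dosages <- co$dosages[perm_i, perm_v]
  co2$variants <- co$variants[perm_v, ]
  co2$traits <- co$traits[perm_i, ]
  b <- gwas(co2, "trait")
  b <- b[match(a$snv_id, b$snv_id), ]
  expect_equal(b$beta, a$beta, tolerance = 1e-10)
  expect_equal(b$p, a$p, tolerance = 1e-10)
})
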