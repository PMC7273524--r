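test_that("nearby candidates form one locus led by the smallest p", {
  rows <- assoc_rows(c("a", "b"), chrom = c(1, 1), pos = c(1e6, 1.1e6),
                     p = c(1e-8, 1e-9))
  loci <- define_loci(rows)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$lead$snv_id, "b")
  expect_setequal(loci[[1]]$members$snv_id, c("a", "b"))
})

test_that("locus absorption respects the 500 kb boundary", {
  # members at exactly 500,000 bp from the lead are absorbed; one base
  # further founds a new locus
  rows <- assoc_rows(c("lead", "edge", "beyond"), chrom = c(1, 1, 1),
                     pos = c(1e6, 1.5e6, 1.500001e6),
                     p = c(1e-12, 1e-8, 1e-9))
  loci <- define_loci(rows)
  expect_length(loci, 2)
  expect_setequal(loci[[1]]$members$snv_id, c("lead", "edge"))
  expect_equal(loci[[2]]$lead$snv_id, "beyond")
})

test_that("greedy locus definition handles chained spacing", {
  # 0 / 600 kb / 1.1 Mb with p = 1e-12, 1e-9, 1e-10: the first lead
  # cannot absorb the 600 kb variant (>500 kb away); the 1.1 Mb variant
  # leads next and absorbs it at exactly 500 kb
  rows <- assoc_rows(c("s1", "s2", "s3"), chrom = c(2, 2, 2),
                     pos = c(0, 6e5, 1.1e6) + 1,
                     p = c(1e-12, 1e-9, 1e-10))
  loci <- define_loci(rows)
  expect_length(loci, 2)
  expect_equal(vapply(loci, function(l) l$lead$snv_id, ""), c("s1", "s3"))
})

test_that("locus definition partitions the candidate set", {
  set.seed(21)
  rows <- assoc_rows(sprintf("v%03d", 1:60),
                     chrom = sample(1:3, 60, replace = TRUE),
                     pos = sample.int(5e6, 60),
                     p = 10^runif(60, -12, -2))
  loci <- define_loci(rows, p_select = 1e-6)
  members <- unlist(lapply(loci, function(l) l$members$snv_id))
  cands <- rows$snv_id[rows$p < 1e-6]
  expect_setequal(members, cands)
  expect_equal(anyDuplicated(members), 0)
  for (l in loci) expect_equal(l$lead$p, min(l$members$p))
  expect_length(define_loci(rows, p_select = 1e-30), 0)
})

test_that("replication requires the Bonferroni p and direction concordance", {
  disc <- assoc_rows(c("a", "b", "c"), 1, c(1e6, 3e6, 5e6),
                     p = c(1.2e-15, 1.7e-8, 1e-8),
                     beta = c(-0.066, -0.050, -0.04))
  repl <- assoc_rows(c("a", "b", "c"), 1, c(1e6, 3e6, 5e6),
                     p = c(2.5e-14, 7.5e-3, 1e-4),
                     beta = c(-0.054, -0.020, +0.03))
  d <- replication_decide(disc, repl, m_candidates = 21)
  expect_equal(d$replicated, c(TRUE, FALSE, FALSE))
  expect_equal(d$reason, c("replicated", "replication_p_above_threshold",
                           "discordant_direction"))
  # candidate missing from the replication table
  d2 <- replication_decide(disc, repl[1:2, ], m_candidates = 21)
  expect_true(is.na(d2$replicated[3]))
  expect_equal(d2$reason[3], "not_testable")
})

test_that("threshold monotonicity: shrinking p_select never adds candidates", {
  set.seed(22)
  disc <- assoc_rows(sprintf("v%02d", 1:40), 1, (1:40) * 2e6,
                     p = 10^runif(40, -10, -3))
  repl <- disc; repl$p <- 10^runif(40, -6, -1)
  loose <- replication_decide(disc, repl, p_select = 1e-6)
  tight <- replication_decide(disc, repl, p_select = 1e-8)
  expect_true(all(loose$candidate[tight$candidate]))
  new_repl <- which(tight$replicated & !loose$candidate)
  expect_length(new_repl, 0)
})

test_that("full-dataset significance excludes replicated variants", {
  comb <- assoc_rows(c("kcnd3", "edge", "rnf207"), 1, c(1e6, 3e6, 5e6),
                     p = c(9.1e-10, 6e-8, 5.8e-28))
  d <- fulldata_decide(comb, already_replicated = "rnf207")
  expect_equal(d$fulldata_significant, c(TRUE, FALSE, FALSE))
  expect_equal(d$reason, c("genome_wide_significant",
                           "not_genome_wide_significant",
                           "already_replicated"))
})

test_that("secondary-signal rule reproduces its printed truth table", {
  expect_true(secondary_signal_rule(1e-10, 1e-8, 1e-7))   # 1.25 and 1.14
  expect_false(secondary_signal_rule(1e-10, 1e-5, 1e-5))  # condition 1 fails
  expect_false(secondary_signal_rule(1e-30, 1e-8, 1e-8))  # 30/8 >= 1.5
  expect_false(secondary_signal_rule(1e-10, 1e-8, 0.5))   # conditional too weak
  expect_error(secondary_signal_rule(0, 1e-8, 1e-8), "0")
  expect_false(secondary_signal_rule(1e-10, 1e-8, 1))     # p >= 1 fails
})

test_that("secondary-signal rule is monotone in the conditional p", {
  p_cond <- 10^seq(-2, -12, by = -0.5)
  dec <- secondary_signal_rule(rep(1e-10, length(p_cond)),
                               rep(1e-8, length(p_cond)), p_cond)
  # once true, decreasing p_cond further never flips the decision back
  expect_true(all(diff(as.integer(dec)) >= 0))
})

test_that("percent variance explained recovers a planted variant share", {
  arch <- genetic_architecture(4000, 200, h2 = 0.032,
                               causal_effects = c(1, rep(0, 199)), seed = 23)
  co <- simulate_cohort(arch)
  pve <- percent_variance_explained(co, "trait", NULL, "snv00001")
  expect_equal(pve, 3.2, tolerance = 0.25)
  # empty set explains nothing
  expect_equal(percent_variance_explained(co, "trait", NULL, character(0)), 0)
  # a duplicated variant adds no variance (collinear column dropped)
  expect_message(
    pve_dup <- percent_variance_explained(co, "trait", NULL,
                                          c("snv00001", "snv00001", "snv00002")),
    "collinear")
  pve_two <- percent_variance_explained(co, "trait", NULL,
                                        c("snv00001", "snv00002"))
  expect_equal(pve_dup, pve_two, tolerance = 1e-10)
  expect_error(percent_variance_explained(co, "trait", NULL, "snv00001",
                                          n_pcs = 4000), "n_pcs")
})

test_that("a male-only effect is flagged male-specific", {
  set.seed(24)
  n <- 3000
  g <- rbinom(n, 2, 0.4)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.17 * as.vector(scale(g)) * sex + rnorm(n)
  G <- cbind(g, matrix(rbinom(n * 4, 2, 0.3), n, 4))
  colnames(G) <- c("snp", sprintf("null%d", 1:4))
  co <- manual_cohort(G, trait = y, traits_extra = data.frame(sex = sex))
  res <- sex_stratified(co, "trait", covariates = "sex")
  expect_true(res$flags$male_specific[res$flags$snv_id == "snp"])
  expect_false(res$flags$female_specific[res$flags$snv_id == "snp"])
})

test_that("equal effects in both sexes are not flagged sex-specific", {
  set.seed(25)
  n <- 3000
  g <- rbinom(n, 2, 0.4)
  sex <- rbinom(n, 1, 0.5)
  y <- 0.3 * as.vector(scale(g)) + rnorm(n)
  co <- manual_cohort(cbind(snp = g), trait = y,
                      traits_extra = data.frame(sex = sex))
  res <- sex_stratified(co, "trait", covariates = "sex")
  expect_false(any(res$flags$male_specific | res$flags$female_specific))
  # tiny stratum is an error
  co$traits$sex <- c(rep(1, 50), rep(0, n - 50))
  expect_error(sex_stratified(co, "trait", covariates = "sex"), "100")
})

test_that("tally combines stage counts and the heritability fraction", {
  t1 <- tally(sprintf("r%02d", 1:15), sprintf("a%02d", 1:13),
              sprintf("s%02d", 1:4), pve = 3.20, h2 = 15.6)
  expect_equal(t1$n_lead, 28)
  expect_equal(t1$n_total, 32)
  expect_equal(t1$heritability_fraction_pct, 21)
  t0 <- tally(character(0), character(0))
  expect_equal(t0$n_total, 0)
  expect_error(tally(c("x", "y"), c("y")), "overlapping")
})
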