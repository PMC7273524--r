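#' Additive genetic architecture for cohort simulation
#'
#' @param n_individuals,n_variants cohort dimensions.
#' @param maf_range minor-allele-frequency range; per-variant MAF is
#'   drawn uniformly from it (must lie in (0, 0.5]).
#' @param h2 narrow-sense heritability of the first trait in [0, 1].
#' @param h2_b heritability of the second trait (defaults to `h2`);
#'   ignored when `rg` is `NULL`.
#' @param rg genetic correlation in [-1, 1] between the two traits, or
#'   `NULL` for a single trait.
#' @param causal_effects optional per-variant effect sizes (trait SD per
#'   standardized dosage); when `NULL` all variants are causal with
#'   Gaussian effects (the polygenic case).
#' @param seed RNG seed.
#' @return an object of class `genetic_architecture`.
#' @export
genetic_architecture <- function(n_individuals, n_variants,
                                 maf_range = c(0.05, 0.5),
                                 h2 = 0.156, h2_b = h2, rg = NULL,
                                 causal_effects = NULL, seed = 1L) {
  check_positive(n_individuals, "n_individuals")
  check_positive(n_variants, "n_variants")
  if (!is.numeric(h2) || h2 < 0 || h2 > 1) stop_invalid("h2 must lie in [0, 1]")
  if (!is.numeric(h2_b) || h2_b < 0 || h2_b > 1) stop_invalid("h2_b must lie in [0, 1]")
  if (!is.null(rg) && (abs(rg) > 1 || !is.finite(rg)))
    stop_invalid("rg must lie in [-1, 1]")
  if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop_invalid("maf_range must lie within (0, 0.5]")
  if (!is.null(causal_effects) && length(causal_effects) != n_variants)
    stop_invalid("causal_effects must have one entry per variant")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range, h2 = h2, h2_b = h2_b, rg = rg,
                 causal_effects = causal_effects, seed = seed),
            class = "genetic_architecture")
}

# scale a vector to an exact sample variance (0 variance -> zeros)
scale_to_var <- function(x, v) {
  if (v <= 0) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (s == 0) stop_invalid("cannot scale a constant vector to positive variance")
  (x - mean(x)) / s * sqrt(v)
}

#' Simulate an unrelated diploid cohort with additive trait architecture
#'
#' Genotypes are hard calls drawn under Hardy-Weinberg equilibrium,
#' `g ~ Binomial(2, MAF)`, independent across variants (linkage
#' equilibrium).  The quantitative trait is built from standardized
#' dosages: `y = Z b + e`, with the genetic component rescaled to an
#' exact sample variance of `h2` and the noise to `1 - h2`, so the
#' realized heritability of the generated cohort equals the target.
#' When `rg` is given, a second trait is generated whose effect vector
#' has exact correlation `rg` with the first.
#'
#' Covariates (sex, age, BMI, smoking, diabetes, genotyping-array
#' indicator) are drawn independently of genotype and trait; association
#' models adjust for them, mirroring the covariate sets used downstream.
#'
#' @param arch a [genetic_architecture()].
#' @return an object of class `genotype_cohort`: list with `dosages`
#'   (n x m matrix), `variants` (snv_id, chrom, pos, ref, alt, eaf),
#'   `traits` (id, trait, trait2 when `rg` given, covariates), and
#'   `truth` (effect vectors and genetic values).
#' @export
simulate_cohort <- function(arch) {
  stopifnot(inherits(arch, "genetic_architecture"))
  n <- arch$n_individuals; m <- arch$n_variants
  with_seed(arch$seed, {
    maf <- stats::runif(m, arch$maf_range[1], arch$maf_range[2])
    G <- matrix(stats::rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
    ids <- sprintf("id%06d", seq_len(n))
    snv <- sprintf("snv%05d", seq_len(m))
    dimnames(G) <- list(ids, snv)

    eaf <- colMeans(G) / 2
    Z <- scale(G)  # centre + unit variance per variant
    # monomorphic columns (possible at tiny n) carry no information
    Z[, attr(Z, "scaled:scale") == 0] <- 0

    b <- arch$causal_effects
    if (is.null(b)) b <- stats::rnorm(m)
    g1 <- scale_to_var(as.vector(Z %*% b), arch$h2)
    y1 <- g1 + scale_to_var(stats::rnorm(n), 1 - arch$h2)

    y2 <- g2 <- b2 <- NULL
    if (!is.null(arch$rg)) {
      u1 <- b / sqrt(sum(b^2))
      e <- stats::rnorm(m)
      e <- e - sum(e * u1) * u1
      u2 <- e / sqrt(sum(e^2))
      b2 <- arch$rg * u1 + sqrt(max(0, 1 - arch$rg^2)) * u2
      g2 <- scale_to_var(as.vector(Z %*% b2), arch$h2_b)
      y2 <- g2 + scale_to_var(stats::rnorm(n), 1 - arch$h2_b)
    }

    chrom <- ((seq_len(m) - 1L) %% 22L) + 1L
    pos <- (((seq_len(m) - 1L) %/% 22L) + 1L) * 1000000L
    traits <- data.frame(
      id = ids, trait = y1,
      sex = stats::rbinom(n, 1, 0.5),
      age = round(stats::runif(n, 40, 69)),
      bmi = stats::rnorm(n, 27, 4),
      smoking = stats::rbinom(n, 1, 0.3),
      diabetes = stats::rbinom(n, 1, 0.05),
      array = stats::rbinom(n, 1, 0.1),
      stringsAsFactors = FALSE)
    if (!is.null(y2)) traits$trait2 <- y2

    structure(list(
      dosages = G,
      variants = data.frame(snv_id = snv, chrom = chrom, pos = pos,
                            ref = "A", alt = "G", eaf = eaf,
                            stringsAsFactors = FALSE),
      traits = traits,
      truth = list(effects = b, effects2 = b2, genetic = g1, genetic2 = g2,
                   maf = maf, h2 = arch$h2, h2_b = arch$h2_b, rg = arch$rg),
      arch = arch),
      class = "genotype_cohort")
  })
}

#' @export
print.genotype_cohort <- function(x, ...) {
  cat(sprintf("<genotype_cohort> %d individuals x %d variants\n",
              nrow(x$dosages), ncol(x$dosages)))
  invisible(x)
}

#' Simulate a rare binary outcome from a genetic risk score truth
#'
#' Logistic generation: the linear predictor is the weighted dosage sum
#' (centred), with an intercept solved numerically so the expected
#' prevalence equals the target.  With zero weights this reduces to
#' i.i.d. Bernoulli(prevalence) draws.
#'
#' @param cohort a `genotype_cohort`.
#' @param weights per-variant log-odds weights (length = n_variants).
#' @param prevalence target event fraction, strictly inside (0, 1).
#' @param seed RNG seed.
#' @return integer 0/1 vector named by individual id.
#' @export
simulate_binary_outcome <- function(cohort, weights, prevalence, seed = 1L) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop_invalid("prevalence must lie strictly inside (0, 1)")
  if (length(weights) != ncol(cohort$dosages))
    stop_invalid("weights must have one entry per variant")
  eta <- as.vector(cohort$dosages %*% weights)
  eta <- eta - mean(eta)
  alpha <- stats::uniroot(function(a) mean(stats::plogis(a + eta)) - prevalence,
                          interval = c(-50, 50))$root
  y <- with_seed(seed, stats::rbinom(length(eta), 1L, stats::plogis(alpha + eta)))
  names(y) <- rownames(cohort$dosages)
  y
}
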