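# Resolve a trait argument (numeric vector or column name of
# cohort$traits) to a numeric vector.
resolve_trait <- function(cohort, trait) {
  if (is.character(trait) && length(trait) == 1L) {
    if (!trait %in% names(cohort$traits))
      stop_invalid("trait column '", trait, "' not found")
    return(cohort$traits[[trait]])
  }
  if (!is.numeric(trait) || length(trait) != nrow(cohort$dosages))
    stop_invalid("trait must be a column name or a numeric vector of length n")
  trait
}

# Covariate design matrix (with intercept) from column names or a
# numeric matrix; errors on collinearity.
covariate_matrix <- function(cohort, covariates) {
  n <- nrow(cohort$dosages)
  if (is.null(covariates)) X <- matrix(1, n, 1)
  else if (is.character(covariates)) {
    miss <- setdiff(covariates, names(cohort$traits))
    if (length(miss)) stop_invalid("missing covariates: ", paste(miss, collapse = ", "))
    X <- cbind(1, as.matrix(cohort$traits[covariates]))
  } else X <- cbind(1, as.matrix(covariates))
  storage.mode(X) <- "double"
  if (anyNA(X)) stop_invalid("missing values in covariates")
  if (qr(X)$rank < ncol(X)) stop_invalid("collinear covariates")
  X
}

#' Per-variant additive association scan
#'
#' Ordinary least squares of the trait on each variant's allele dosage
#' plus the trait-specific covariates, one variant at a time, with a
#' two-sided Wald p from the t distribution with residual degrees of
#' freedom.  Equivalent to fitting `lm(trait ~ dosage + covariates)`
#' per variant, but computed by residualizing trait and dosages on the
#' covariates once.  Variants below the MAF floor or monomorphic in the
#' analyzed sample are skipped (with a message).
#'
#' @param cohort a `genotype_cohort`.
#' @param trait numeric vector or name of a column in `cohort$traits`.
#' @param covariates character vector of covariate column names, a
#'   numeric matrix, or `NULL`.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @return data.frame of association rows: `snv_id`, `chrom`, `pos`,
#'   `ea` (effect allele = ALT), `aa` (other allele), `eaf`, `beta`,
#'   `se`, `p`, `n`.
#' @export
gwas <- function(cohort, trait, covariates = NULL, maf_min = 0.01) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  y <- resolve_trait(cohort, trait)
  X <- covariate_matrix(cohort, covariates)
  G <- cohort$dosages
  n <- nrow(G)

  eaf <- colMeans(G) / 2
  maf <- pmin(eaf, 1 - eaf)
  keep <- maf >= maf_min & maf > 0
  if (any(!keep))
    message(sum(!keep), " variant(s) skipped (monomorphic or MAF < ", maf_min, ")")
  G <- G[, keep, drop = FALSE]
  vi <- cohort$variants[keep, , drop = FALSE]
  if (ncol(G) == 0L) stop_invalid("no variants pass the MAF filter")

  Q <- qr.Q(qr(X))
  yr <- y - Q %*% crossprod(Q, y)
  Gr <- G - Q %*% crossprod(Q, G)
  den <- colSums(Gr^2)
  beta <- as.vector(crossprod(Gr, yr)) / den
  df <- n - ncol(X) - 1L
  rss <- sum(yr^2) - beta^2 * den
  se <- sqrt(pmax(rss / df, 0) / den)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)

  data.frame(snv_id = vi$snv_id, chrom = vi$chrom, pos = vi$pos,
             ea = vi$alt, aa = vi$ref, eaf = eaf[keep],
             beta = beta, se = se, p = p, n = n,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Flip the effect allele of association rows
#'
#' Relabelling the effect allele maps `(beta, eaf)` to
#' `(-beta, 1 - eaf)` and swaps the allele columns; `se` and `p` are
#' unchanged.
#'
#' @param rows association data.frame from [gwas()].
#' @param snv_ids which rows to flip (default: all).
#' @return the data.frame with the selected rows flipped.
#' @export
flip_alleles <- function(rows, snv_ids = rows$snv_id) {
  i <- rows$snv_id %in% snv_ids
  tmp <- rows$ea[i]; rows$ea[i] <- rows$aa[i]; rows$aa[i] <- tmp
  rows$beta[i] <- -rows$beta[i]
  rows$eaf[i] <- 1 - rows$eaf[i]
  rows
}

#' Conditional association of a candidate variant on a locus lead
#'
#' Joint regression of the trait on the candidate dosage with the lead
#' variant's dosage added to the covariates; returns the candidate's
#' Wald p from the joint model.  A candidate in (near-)perfect LD with
#' the lead is unidentifiable: its coefficient is dropped and the
#' result flagged instead of reporting a spurious p.
#'
#' @param cohort a `genotype_cohort`.
#' @param trait trait vector or column name.
#' @param covariates covariate specification as in [gwas()].
#' @param lead_snv,candidate_snv variant ids (must differ).
#' @return list with `p_conditional`, `beta`, `se`, `dropped` (logical
#'   collinearity flag).
#' @export
conditional_regression <- function(cohort, trait, covariates = NULL,
                                   lead_snv, candidate_snv) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  if (identical(lead_snv, candidate_snv))
    stop_invalid("lead and candidate variant must differ")
  snvs <- colnames(cohort$dosages)
  if (!all(c(lead_snv, candidate_snv) %in% snvs))
    stop_invalid("both variants must be present in the cohort")
  y <- resolve_trait(cohort, trait)
  X <- covariate_matrix(cohort, covariates)
  g_lead <- cohort$dosages[, lead_snv]
  g_cand <- cohort$dosages[, candidate_snv]

  Xl <- cbind(X, g_lead)
  Q <- qr.Q(qr(Xl))
  gr <- g_cand - Q %*% crossprod(Q, g_cand)
  if (sum(gr^2) < 1e-8 * sum(g_cand^2))
    return(list(p_conditional = NA_real_, beta = NA_real_, se = NA_real_,
                dropped = TRUE))
  yr <- y - Q %*% crossprod(Q, y)
  den <- sum(gr^2)
  beta <- sum(gr * yr) / den
  df <- length(y) - ncol(Xl) - 1L
  sigma2 <- max(sum(yr^2) - beta^2 * den, 0) / df
  se <- sqrt(sigma2 / den)
  list(p_conditional = 2 * stats::pt(-abs(beta / se), df),
       beta = beta, se = se, dropped = FALSE)
}

#' Genetic relationship matrix from standardized dosages
#'
#' `A = Z Z' / m` with `Z` the column-standardized dosage matrix
#' (monomorphic variants contribute zero).  Shared by the
#' Haseman-Elston estimators.
#'
#' @param cohort a `genotype_cohort`.
#' @return list with the GRM `A` and the variant count `m`.
#' @export
he_grm <- function(cohort) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  Z <- scale(cohort$dosages)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  m <- ncol(Z)
  list(A = tcrossprod(Z) / m, m = m)
}

# Off-diagonal sums used by the HE estimators, plus their leave-one-
# individual-out updates.
he_sums <- function(A, u, v) {
  Au <- A %*% u
  dA <- diag(A)
  num <- sum(u * (A %*% v)) - sum(dA * u * v)
  row_uv <- as.vector(A %*% v) * u + as.vector(Au) * v - 2 * dA * u * v
  list(num = num, row = row_uv)
}

#' Haseman-Elston estimate of narrow-sense heritability
#'
#' Regresses pairwise trait cross-products on the off-diagonal GRM
#' entries, which for standardized traits has the closed form
#' `h2 = sum_{i != j} A_ij y_i y_j / sum_{i != j} A_ij^2`.  The
#' standard error is a leave-one-individual-out jackknife.  The trait
#' is standardized internally, making the estimate invariant to affine
#' transformation.
#'
#' @param cohort a `genotype_cohort`.
#' @param trait trait vector or column name.
#' @param grm optional precomputed [he_grm()] result.
#' @return object of class `he_estimate`: list with `h2`, `se`, `n`,
#'   `m`.
#' @export
heritability_he <- function(cohort, trait, grm = NULL) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  n <- nrow(cohort$dosages)
  if (n < 500) stop_invalid("Haseman-Elston needs at least 500 individuals")
  y <- as.vector(scale(resolve_trait(cohort, trait)))
  if (is.null(grm)) grm <- he_grm(cohort)
  A <- grm$A
  dA <- diag(A)
  den <- sum(A^2) - sum(dA^2)
  if (den <= 0) stop_invalid("degenerate GRM: no off-diagonal variation")
  s <- he_sums(A, y, y)
  h2 <- s$num / den
  den_row <- 2 * (rowSums(A^2) - dA^2)
  h2_k <- (s$num - s$row) / (den - den_row)
  se <- sqrt((n - 1) / n * sum((h2_k - mean(h2_k))^2))
  structure(list(h2 = h2, se = se, n = n, m = grm$m), class = "he_estimate")
}

#' @export
print.he_estimate <- function(x, ...) {
  cat(sprintf("HE heritability: h2 = %.4f (se %.4f), n = %d, m = %d\n",
              x$h2, x$se, x$n, x$m))
  invisible(x)
}

#' Bivariate Haseman-Elston genetic correlation
#'
#' Estimates the genetic covariance between two traits by regressing
#' cross-trait products on off-diagonal GRM entries, and reports
#' `rg = cov_g / sqrt(va * vb)` with a leave-one-individual-out
#' jackknife standard error.  If either trait's heritability estimate
#' is non-positive the correlation is undefined and flagged.
#'
#' @param cohort a `genotype_cohort`.
#' @param trait_a,trait_b trait vectors or column names (same
#'   individuals).
#' @param grm optional precomputed [he_grm()] result.
#' @return object of class `rg_estimate`: list with `rg`, `se`, `h2_a`,
#'   `h2_b`, `defined`.
#' @export
genetic_correlation_he <- function(cohort, trait_a, trait_b, grm = NULL) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  n <- nrow(cohort$dosages)
  ya <- as.vector(scale(resolve_trait(cohort, trait_a)))
  yb <- as.vector(scale(resolve_trait(cohort, trait_b)))
  if (is.null(grm)) grm <- he_grm(cohort)
  A <- grm$A
  dA <- diag(A)
  den <- sum(A^2) - sum(dA^2)
  if (den <= 0) stop_invalid("degenerate GRM: no off-diagonal variation")

  sa <- he_sums(A, ya, ya)
  sb <- he_sums(A, yb, yb)
  sc <- he_sums(A, ya, yb)
  h2a <- sa$num / den; h2b <- sb$num / den
  if (h2a <= 0 || h2b <= 0)
    return(structure(list(rg = NA_real_, se = NA_real_, h2_a = h2a,
                          h2_b = h2b, defined = FALSE),
                     class = "rg_estimate"))
  rg <- (sc$num / den) / sqrt(h2a * h2b)

  den_row <- 2 * (rowSums(A^2) - dA^2)
  dk <- den - den_row
  h2a_k <- (sa$num - sa$row) / dk
  h2b_k <- (sb$num - sb$row) / dk
  cg_k <- (sc$num - sc$row) / dk
  ok <- h2a_k > 0 & h2b_k > 0
  rg_k <- ifelse(ok, cg_k / sqrt(h2a_k * h2b_k), rg)
  se <- sqrt((n - 1) / n * sum((rg_k - mean(rg_k))^2))
  structure(list(rg = rg, se = se, h2_a = h2a, h2_b = h2b, defined = TRUE),
            class = "rg_estimate")
}

#' @export
print.rg_estimate <- function(x, ...) {
  if (x$defined)
    cat(sprintf("HE genetic correlation: rg = %.4f (se %.4f)\n", x$rg, x$se))
  else cat("HE genetic correlation undefined (non-positive heritability)\n")
  invisible(x)
}

#' Write / read association rows as TSV (summary-statistics schema)
#'
#' Column order follows the conventional summary-statistics layout:
#' SNV, CHR, BP, EA, AA, EAF, BETA, SE, P, N.
#'
#' @param rows association data.frame; @param path file path.
#' @return `read_assoc_tsv` returns a data.frame in [gwas()] column
#'   naming.
#' @export
write_assoc_tsv <- function(rows, path) {
  out <- data.frame(SNV = rows$snv_id, CHR = rows$chrom, BP = rows$pos,
                    EA = rows$ea, AA = rows$aa, EAF = rows$eaf,
                    BETA = rows$beta, SE = rows$se, P = rows$p, N = rows$n)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_assoc_tsv
#' @export
read_assoc_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(snv_id = d$SNV, chrom = d$CHR, pos = d$BP, ea = d$EA, aa = d$AA,
             eaf = d$EAF, beta = d$BETA, se = d$SE, p = d$P, n = d$N,
             stringsAsFactors = FALSE)
}
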