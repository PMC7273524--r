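#' Bonferroni replication threshold
#'
#' `alpha / m_candidates`, rounded to two significant figures for
#' reporting (e.g. 21 resting-Tpe candidates give 0.05/21 = 2.4e-3 and
#' 7 recovery candidates give 7.1e-3).  Decisions use the unrounded
#' value.
#'
#' @param m_candidates number of variants taken into replication.
#' @param alpha family-wise level (default 0.05).
#' @param sigfigs significant figures for the reported threshold.
#' @return list with `threshold` (exact) and `reported` (rounded).
#' @export
bonferroni_threshold <- function(m_candidates, alpha = 0.05, sigfigs = 2) {
  check_positive(m_candidates, "m_candidates")
  thr <- alpha / m_candidates
  list(threshold = thr, reported = signif(thr, sigfigs))
}

#' Map candidate variants to loci by genomic distance
#'
#' Greedy locus assignment: repeatedly take the smallest-p unassigned
#' variant below `p_select` as a locus lead and absorb every unassigned
#' candidate on the same chromosome within `distance_kb` of it.  A
#' variant strictly more than `distance_kb` from every lead founds its
#' own locus (a member at exactly the distance limit is absorbed).  The
#' output is a partition of the candidate set; every lead has the
#' smallest p within its locus.
#'
#' @param rows association data.frame ([gwas()] schema).
#' @param p_select candidate threshold (default 1e-6, strict `<`).
#' @param distance_kb absorption radius in kb (default 500).
#' @return list of loci; each locus is a list with `lead` (one-row
#'   data.frame), `members` (data.frame), and `span`
#'   (chrom, start, end).
#' @export
define_loci <- function(rows, p_select = 1e-6, distance_kb = 500) {
  cand <- rows[!is.na(rows$p) & rows$p < p_select, , drop = FALSE]
  if (nrow(cand) == 0L) return(list())
  cand <- cand[order(cand$p), , drop = FALSE]
  assigned <- rep(FALSE, nrow(cand))
  loci <- list()
  dist_bp <- distance_kb * 1000
  while (!all(assigned)) {
    i <- which(!assigned)[1L]  # smallest remaining p (rows are p-sorted)
    lead <- cand[i, , drop = FALSE]
    member_idx <- which(!assigned & cand$chrom == lead$chrom &
                          abs(cand$pos - lead$pos) <= dist_bp)
    members <- cand[member_idx, , drop = FALSE]
    assigned[member_idx] <- TRUE
    loci[[length(loci) + 1L]] <- list(
      lead = lead, members = members,
      span = list(chrom = lead$chrom, start = min(members$pos),
                  end = max(members$pos)))
  }
  loci
}

#' Two-stage replication decisions
#'
#' A candidate (discovery `p < p_select`) is replicated iff its
#' replication p-value is at most `alpha / m` (Bonferroni over the `m`
#' candidates taken forward) *and* the replication effect has the same
#' direction as in discovery.  Candidates absent from the replication
#' table are marked not testable.
#'
#' @param discovery,replication association data.frames sharing
#'   `snv_id`, `beta`, `p`.
#' @param m_candidates number of candidates taken forward (defaults to
#'   the number of discovery rows below `p_select`).
#' @param p_select candidate threshold (default 1e-6).
#' @param alpha family-wise replication level (default 0.05).
#' @return data.frame: `snv_id`, `candidate`, `replicated`, `reason`.
#' @export
replication_decide <- function(discovery, replication, m_candidates = NULL,
                               p_select = 1e-6, alpha = 0.05) {
  cand <- !is.na(discovery$p) & discovery$p < p_select
  if (is.null(m_candidates)) m_candidates <- sum(cand)
  thr <- if (m_candidates > 0) alpha / m_candidates else NA_real_
  idx <- match(discovery$snv_id, replication$snv_id)
  out <- data.frame(snv_id = discovery$snv_id, candidate = cand,
                    replicated = FALSE, reason = "not_a_candidate",
                    stringsAsFactors = FALSE)
  for (i in which(cand)) {
    j <- idx[i]
    if (is.na(j)) {
      out$replicated[i] <- NA
      out$reason[i] <- "not_testable"
      next
    }
    p_ok <- replication$p[j] <= thr
    dir_ok <- sign(replication$beta[j]) == sign(discovery$beta[i])
    out$replicated[i] <- p_ok && dir_ok
    out$reason[i] <- if (p_ok && dir_ok) "replicated"
      else if (!p_ok) "replication_p_above_threshold"
      else "discordant_direction"
  }
  out
}

#' Full-dataset significance decisions
#'
#' An additional locus is declared when the combined-analysis p-value
#' reaches genome-wide significance (`p <= p_gw`) for a variant that
#' did not already replicate in the two-stage design.
#'
#' @param combined association data.frame (`snv_id`, `p`).
#' @param already_replicated character vector of replicated variant
#'   ids.
#' @param p_gw genome-wide threshold (default 5e-8).
#' @return data.frame: `snv_id`, `fulldata_significant`, `reason`.
#' @export
fulldata_decide <- function(combined, already_replicated = character(),
                            p_gw = 5e-8) {
  sig <- !is.na(combined$p) & combined$p <= p_gw
  repl <- combined$snv_id %in% already_replicated
  data.frame(
    snv_id = combined$snv_id,
    fulldata_significant = sig & !repl,
    reason = ifelse(repl, "already_replicated",
                    ifelse(sig, "genome_wide_significant",
                           "not_genome_wide_significant")),
    stringsAsFactors = FALSE)
}

#' Secondary-signal declaration rule
#'
#' A conditional signal at a locus is declared secondary when all three
#' hold: (1) its unconditioned p-value is below 1e-6; (2) the lead and
#' secondary p-values differ by less than 1.5-fold on the -log10 scale,
#' `-log10(p_lead) / -log10(p_sec) < 1.5`; and (3) the secondary and
#' conditional p-values differ by less than 1.5-fold on the -log10
#' scale, `-log10(p_sec) / -log10(p_cond) < 1.5`.  Vectorized; any
#' p-value of exactly 0 is an error (its log is undefined), and any
#' p >= 1 fails the rule.
#'
#' @param p_lead,p_secondary,p_conditional p-values in (0, 1).
#' @param p_select unconditioned-significance threshold (default 1e-6).
#' @param fold ratio limit on the -log10 scale (default 1.5).
#' @return logical vector.
#' @export
secondary_signal_rule <- function(p_lead, p_secondary, p_conditional,
                                  p_select = 1e-6, fold = 1.5) {
  ps <- cbind(p_lead, p_secondary, p_conditional)
  if (any(ps == 0)) stop_invalid("p-value of 0: -log10 undefined")
  if (any(ps < 0) || any(is.na(ps))) stop_invalid("p-values must lie in (0, 1)")
  valid <- p_lead < 1 & p_secondary < 1 & p_conditional < 1
  l_lead <- -log10(p_lead); l_sec <- -log10(p_secondary)
  l_cond <- -log10(p_conditional)
  valid & (p_secondary < p_select) & (l_lead / l_sec < fold) &
    (l_sec / l_cond < fold)
}

#' Sex-stratified association scan
#'
#' Runs the association scan separately in men and women with sex
#' removed from the covariates, plus a combined scan with sex retained.
#' A variant is flagged sex-specific when it reaches genome-wide
#' significance in one sex but not in the combined analysis.
#'
#' @param cohort a `genotype_cohort` whose trait table has a 0/1 `sex`
#'   column.
#' @param trait trait vector or column name.
#' @param covariates covariate column names including `"sex"`.
#' @param p_gw genome-wide threshold (default 5e-8).
#' @param maf_min MAF floor passed to [gwas()].
#' @return list with `male`, `female`, `combined` association tables
#'   and `flags` (`snv_id`, `male_specific`, `female_specific`).
#' @export
sex_stratified <- function(cohort, trait, covariates, p_gw = 5e-8,
                           maf_min = 0.01) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  if (!"sex" %in% names(cohort$traits)) stop_invalid("no sex covariate")
  sex <- cohort$traits$sex
  if (min(table(sex)) < 100) stop_invalid("a sex stratum has fewer than 100 individuals")
  y <- resolve_trait(cohort, trait)
  cov_nosex <- setdiff(covariates, "sex")
  if (length(cov_nosex) == 0L) cov_nosex <- NULL

  subset_cohort <- function(keep) {
    sub <- cohort
    sub$dosages <- cohort$dosages[keep, , drop = FALSE]
    sub$traits <- cohort$traits[keep, , drop = FALSE]
    sub$variants$eaf <- colMeans(sub$dosages) / 2
    sub
  }
  run <- function(keep, covs, yy) gwas(subset_cohort(keep), yy[keep],
                                       covariates = covs, maf_min = maf_min)
  male <- run(sex == 1, cov_nosex, y)
  female <- run(sex == 0, cov_nosex, y)
  combined <- gwas(cohort, y, covariates = covariates, maf_min = maf_min)

  j_m <- match(combined$snv_id, male$snv_id)
  j_f <- match(combined$snv_id, female$snv_id)
  comb_ns <- combined$p > p_gw
  flags <- data.frame(
    snv_id = combined$snv_id,
    male_specific = !is.na(j_m) & male$p[j_m] <= p_gw & comb_ns,
    female_specific = !is.na(j_f) & female$p[j_f] <= p_gw & comb_ns,
    stringsAsFactors = FALSE)
  list(male = male, female = female, combined = combined, flags = flags)
}

#' Percent trait variance explained by identified variants
#'
#' Residualizes the trait on its covariates, then compares the adjusted
#' R-squared of two models for those residuals: identified variants
#' plus the top genotype principal components, versus the principal
#' components alone.  The difference, in percent, is the variance
#' explained attributable to the identified variants.  Duplicated or
#' collinear variant columns are dropped (with a message) rather than
#' inflating the model.
#'
#' @param cohort a `genotype_cohort`.
#' @param trait trait vector or column name.
#' @param covariates covariate specification as in [gwas()].
#' @param identified_snvs character vector of variant ids (may be
#'   empty).
#' @param n_pcs number of genotype principal components (default 10;
#'   must be < n).
#' @return percent variance explained (numeric scalar).
#' @export
percent_variance_explained <- function(cohort, trait, covariates = NULL,
                                       identified_snvs, n_pcs = 10) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  n <- nrow(cohort$dosages)
  if (n_pcs >= n) stop_invalid("n_pcs must be smaller than the sample size")
  y <- resolve_trait(cohort, trait)
  X <- covariate_matrix(cohort, covariates)
  res <- stats::lm.fit(X, y)$residuals

  Z <- scale(cohort$dosages)
  Z[, attr(Z, "scaled:scale") == 0] <- 0
  pcs <- svd(Z, nu = n_pcs, nv = 0)$u

  adj_r2 <- function(M) {
    f <- stats::lm(res ~ M)
    summary(f)$adj.r.squared
  }
  r2_null <- adj_r2(pcs)
  if (length(identified_snvs) == 0L) return(0)
  miss <- setdiff(identified_snvs, colnames(cohort$dosages))
  if (length(miss)) stop_invalid("variants not in cohort: ",
                                 paste(miss, collapse = ", "))
  V <- cohort$dosages[, identified_snvs, drop = FALSE]
  qrv <- qr(cbind(1, V))
  if (qrv$rank < ncol(V) + 1L) {
    keep <- qrv$pivot[seq_len(qrv$rank)] - 1L
    keep <- keep[keep >= 1L]
    message("dropped ", ncol(V) - length(keep),
            " collinear/duplicated variant column(s)")
    V <- V[, keep, drop = FALSE]
  }
  100 * (adj_r2(cbind(V, pcs)) - r2_null)
}

#' Tally the inference stages
#'
#' Combines the stage decisions into headline counts: replicated and
#' additional lead variants, secondary signals, sex-specific loci, the
#' total variant count, and (when percent variance explained and
#' heritability are supplied, both in percent) the share of
#' heritability accounted for, `round(100 * pve / h2)`.
#'
#' Replicated / additional / secondary id sets must be disjoint.
#'
#' @param replicated_ids,additional_ids,secondary_ids,sex_specific_ids
#'   character vectors of variant ids per category.
#' @param pve percent variance explained by the identified variants.
#' @param h2 heritability, percent.
#' @return list of counts (`n_replicated`, `n_additional`, `n_lead`,
#'   `n_secondary`, `n_total`, `n_sex_specific`) plus
#'   `heritability_fraction_pct` when `pve` and `h2` are given.
#' @export
tally <- function(replicated_ids, additional_ids, secondary_ids = character(),
                  sex_specific_ids = character(), pve = NULL, h2 = NULL) {
  sets <- list(replicated_ids, additional_ids, secondary_ids)
  for (i in 1:2) for (j in (i + 1):3) {
    ov <- intersect(sets[[i]], sets[[j]])
    if (length(ov)) stop_invalid("overlapping categories: ",
                                 paste(ov, collapse = ", "))
  }
  out <- list(n_replicated = length(replicated_ids),
              n_additional = length(additional_ids),
              n_lead = length(replicated_ids) + length(additional_ids),
              n_secondary = length(secondary_ids),
              n_total = length(replicated_ids) + length(additional_ids) +
                length(secondary_ids),
              n_sex_specific = length(sex_specific_ids))
  if (!is.null(pve) && !is.null(h2)) {
    check_positive(h2, "h2")
    out$heritability_fraction_pct <- round(100 * pve / h2)
  }
  out
}

#' Published lead-variant summary statistics for resting Tpe
#'
#' Two-stage GWAS summary statistics (discovery, replication, combined
#' stages: effect-allele frequency, beta, SE, p, n) for the 28 lead
#' SNVs reported for the resting Tpeak-to-Tend interval, as printed.
#' Shipped as a plain-text table and used to exercise the stage-decision
#' rules against a known classification (15 replicated, 13 additional).
#'
#' @return data.frame with one row per lead variant.
#' @export
lead_snv_table <- function() {
  path <- system.file("extdata", "resting_tpe_lead_snvs.tsv",
                      package = "tpegwas", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Stage tables from the published lead-variant summary statistics
#'
#' Splits [lead_snv_table()] into discovery / replication / combined
#' association tables in the [gwas()] row schema.
#'
#' @return list of three data.frames: `discovery`, `replication`,
#'   `combined`.
#' @export
lead_snv_stages <- function() {
  d <- lead_snv_table()
  stage <- function(sfx) data.frame(
    snv_id = d$snv, chrom = d$chr, pos = d$bp, ea = d$ea, aa = d$aa,
    eaf = d[[paste0("eaf_", sfx)]], beta = d[[paste0("beta_", sfx)]],
    se = d[[paste0("se_", sfx)]], p = d[[paste0("p_", sfx)]],
    n = d[[paste0("n_", sfx)]], stringsAsFactors = FALSE)
  list(discovery = stage("disc"), replication = stage("repl"),
       combined = stage("comb"))
}
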