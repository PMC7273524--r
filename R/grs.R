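#' Genetic risk score model
#'
#' A set of variants selected by a p-value cutoff from trait summary
#' statistics, with their GWAS effect sizes taken verbatim as weights.
#'
#' @param summary_stats association data.frame ([gwas()] schema).
#' @param p_cutoff inclusion threshold: variants with `p <= p_cutoff`.
#' @return object of class `grs_model`: `included_snvs`, `weights`
#'   (named by variant), `p_cutoff`, and `training_assoc_p` (filled by
#'   [grs_scan_cutoffs()]).
#' @export
grs_model <- function(summary_stats, p_cutoff) {
  keep <- !is.na(summary_stats$p) & summary_stats$p <= p_cutoff
  structure(list(
    included_snvs = summary_stats$snv_id[keep],
    weights = stats::setNames(summary_stats$beta[keep],
                              summary_stats$snv_id[keep]),
    p_cutoff = p_cutoff, training_assoc_p = NA_real_),
    class = "grs_model")
}

#' @export
print.grs_model <- function(x, ...) {
  cat(sprintf("<grs_model> %d variants at p <= %g (training p = %g)\n",
              length(x$included_snvs), x$p_cutoff, x$training_assoc_p))
  invisible(x)
}

#' Score individuals with a GRS model
#'
#' Weighted allele-dosage sum, `score_i = sum_j w_j dosage_ij`, over the
#' model variants present in the cohort; missing genotype values are
#' mean-imputed per variant.  Linear in dosages and invariant to
#' variant ordering.
#'
#' @param cohort a `genotype_cohort`.
#' @param model a `grs_model`.
#' @return numeric score vector named by individual id.
#' @export
grs_score <- function(cohort, model) {
  stopifnot(inherits(cohort, "genotype_cohort"), inherits(model, "grs_model"))
  snvs <- intersect(model$included_snvs, colnames(cohort$dosages))
  if (length(model$included_snvs) > 0L && length(snvs) == 0L)
    stop_invalid("no model variants present in the cohort")
  if (length(snvs) == 0L)
    return(stats::setNames(numeric(nrow(cohort$dosages)),
                           rownames(cohort$dosages)))
  G <- cohort$dosages[, snvs, drop = FALSE]
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    for (j in seq_len(ncol(G))) G[is.na(G[, j]), j] <- mu[j]
  }
  drop(G %*% model$weights[snvs])
}

#' Stratified training/validation split
#'
#' Random partition of individuals into training and validation
#' subsets, stratified on the binary outcome so event prevalence is
#' equal across subsets by construction.
#'
#' @param outcome named 0/1 vector.
#' @param train_frac training fraction (default 0.8).
#' @param seed RNG seed.
#' @return list with `train` and `validation` id vectors (a partition).
#' @export
grs_split <- function(outcome, train_frac = 0.8, seed = 1L) {
  if (is.null(names(outcome))) stop_invalid("outcome must be named by id")
  with_seed(seed, {
    ids <- names(outcome)
    pick <- function(v) sample(v, round(train_frac * length(v)))
    train <- c(pick(ids[outcome == 1]), pick(ids[outcome == 0]))
    list(train = train, validation = setdiff(ids, train))
  })
}

subset_by_ids <- function(cohort, ids) {
  keep <- rownames(cohort$dosages) %in% ids
  cohort$dosages <- cohort$dosages[keep, , drop = FALSE]
  cohort$traits <- cohort$traits[keep, , drop = FALSE]
  cohort
}

#' P-value-threshold scan for the GRS
#'
#' For each cutoff in the grid, builds the GRS from all summary-
#' statistics variants with `p <= cutoff`, scores the training cohort,
#' and fits `glm(outcome ~ standardized score, binomial)`.  The model
#' with the strongest (smallest-p) training association is returned.
#'
#' @param cohort training `genotype_cohort`.
#' @param outcome named 0/1 vector aligned with the cohort.
#' @param summary_stats trait association table supplying weights.
#' @param cutoffs p-value cutoff grid (default log-spaced from 5e-8 to
#'   1).
#' @return the selected `grs_model` with `training_assoc_p` filled and
#'   the full `scan` table attached as an attribute.
#' @export
grs_scan_cutoffs <- function(cohort, outcome, summary_stats,
                             cutoffs = 10^seq(log10(5e-8), 0, length.out = 15)) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  y <- outcome[rownames(cohort$dosages)]
  if (anyNA(y)) stop_invalid("outcome missing for some cohort individuals")
  if (sum(y) == 0L) stop_invalid("no cases in the training split")
  scan <- data.frame(cutoff = cutoffs, n_snvs = NA_integer_, p = NA_real_)
  models <- vector("list", length(cutoffs))
  for (k in seq_along(cutoffs)) {
    mod <- grs_model(summary_stats, cutoffs[k])
    models[[k]] <- mod
    scan$n_snvs[k] <- length(mod$included_snvs)
    if (length(mod$included_snvs) == 0L) next
    s <- grs_score(cohort, mod)
    if (stats::sd(s) == 0) next
    fit <- stats::glm(y ~ scale(s), family = stats::binomial())
    scan$p[k] <- summary(fit)$coefficients[2, 4]
  }
  if (all(is.na(scan$p))) stop_invalid("no cutoff produced a scorable model")
  best <- which.min(scan$p)
  out <- models[[best]]
  out$training_assoc_p <- scan$p[best]
  attr(out, "scan") <- scan
  out
}

#' Validate a GRS in a held-out cohort
#'
#' Logistic regression of the outcome on the standardized score (plus
#' optional covariates) in a validation cohort disjoint from training;
#' reports the odds ratio per score SD with a two-sided Wald p.
#'
#' @param cohort validation `genotype_cohort`.
#' @param outcome named 0/1 vector.
#' @param model a `grs_model` (typically from [grs_scan_cutoffs()]).
#' @param covariates optional covariate column names in
#'   `cohort$traits`.
#' @param training_ids ids used in training; overlap with the
#'   validation cohort is an error.
#' @return list with `or_per_sd`, `beta`, `se`, `p`, `n`, `n_cases`.
#' @export
grs_validate <- function(cohort, outcome, model, covariates = NULL,
                         training_ids = character()) {
  stopifnot(inherits(cohort, "genotype_cohort"), inherits(model, "grs_model"))
  ids <- rownames(cohort$dosages)
  ov <- intersect(ids, training_ids)
  if (length(ov)) stop_invalid("training/validation overlap: ",
                               paste(utils::head(ov, 5), collapse = ", "))
  y <- outcome[ids]
  if (anyNA(y)) stop_invalid("outcome missing for some cohort individuals")
  s <- grs_score(cohort, model)
  if (stats::sd(s) == 0) stop_invalid("zero-variance score in validation cohort")
  dat <- data.frame(y = y, score = as.vector(scale(s)))
  if (!is.null(covariates)) dat <- cbind(dat, cohort$traits[covariates])
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = dat)
  co <- summary(fit)$coefficients["score", ]
  list(or_per_sd = exp(co[1]), beta = unname(co[1]), se = unname(co[2]),
       p = unname(co[4]), n = length(y), n_cases = sum(y))
}

#' Serialize / load a GRS model as TSV
#'
#' Variant, weight rows preceded by a `#` header carrying the cutoff
#' and training association p.
#'
#' @param model a `grs_model`; @param path file path.
#' @return `read_grs_model` returns a `grs_model`.
#' @export
write_grs_model <- function(model, path) {
  hdr <- c(sprintf("# p_cutoff=%.10g", model$p_cutoff),
           sprintf("# training_assoc_p=%.10g", model$training_assoc_p))
  body <- c("snv\tweight",
            sprintf("%s\t%.10g", model$included_snvs,
                    model$weights[model$included_snvs]))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_grs_model
#' @export
read_grs_model <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- do.call(rbind, strsplit(sub("^# ", "", hdr), "="))
  d <- utils::read.delim(text = lines[!grepl("^#", lines)])
  structure(list(included_snvs = as.character(d$snv),
                 weights = stats::setNames(d$weight, d$snv),
                 p_cutoff = as.numeric(kv[kv[, 1] == "p_cutoff", 2]),
                 training_assoc_p = as.numeric(kv[kv[, 1] == "training_assoc_p", 2])),
            class = "grs_model")
}
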