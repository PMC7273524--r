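#' Write / read a genotype cohort as a dosage TSV
#'
#' Variants are rows (`snv_id`, `chrom`, `pos`, `ref`, `alt`, then one
#' dosage column per individual).
#'
#' @param cohort a `genotype_cohort`; @param path file path.
#' @return `read_dosage_tsv` returns a `genotype_cohort` (without
#'   generator truth or trait table).
#' @export
write_dosage_tsv <- function(cohort, path) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  out <- cbind(cohort$variants[c("snv_id", "chrom", "pos", "ref", "alt")],
               as.data.frame(t(cohort$dosages)))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("snv_id", "chrom", "pos", "ref", "alt")
  stopifnot(all(meta_cols %in% names(d)))
  G <- t(as.matrix(d[setdiff(names(d), meta_cols)]))
  colnames(G) <- d$snv_id
  structure(list(dosages = G,
                 variants = data.frame(d[meta_cols],
                                       eaf = colMeans(G) / 2,
                                       stringsAsFactors = FALSE),
                 traits = NULL, truth = NULL, arch = NULL),
            class = "genotype_cohort")
}

#' Write a genotype cohort as a minimal VCF
#'
#' Hard-call genotypes only (`GT` field; dosage 0/1/2 mapped to
#' `0/0`, `0/1`, `1/1`).  The effect allele is ALT.
#'
#' @param cohort a `genotype_cohort`; @param path file path (plain
#'   text, uncompressed).
#' @return invisibly, the path.
#' @export
write_vcf <- function(cohort, path) {
  stopifnot(inherits(cohort, "genotype_cohort"))
  v <- cohort$variants
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_codes[cohort$dosages + 1L], nrow = nrow(cohort$dosages))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", rownames(cohort$dosages)),
                    collapse = "\t"))
  body <- vapply(seq_len(nrow(v)), function(j)
    paste(c(v$chrom[j], v$pos[j], v$snv_id[j], v$ref[j], v$alt[j], ".",
            "PASS", ".", "GT", gt[, j]), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a genotype cohort
#'
#' Parses with `vcfR` and converts hard-call `GT` fields to allele
#' dosages (count of ALT alleles).
#'
#' @param path VCF path.
#' @return a `genotype_cohort` (dosages + variant metadata).
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    a <- strsplit(x, "[/|]")
    vapply(a, function(al) sum(al == "1"), numeric(1))
  }
  G <- t(apply(gt, 1, count_alt))
  G <- t(G)  # individuals x variants
  colnames(G) <- vcfR::getID(v)
  fix <- vcfR::getFIX(v)
  structure(list(
    dosages = G,
    variants = data.frame(snv_id = fix[, "ID"],
                          chrom = as.integer(fix[, "CHROM"]),
                          pos = as.integer(fix[, "POS"]),
                          ref = fix[, "REF"], alt = fix[, "ALT"],
                          eaf = colMeans(G) / 2,
                          stringsAsFactors = FALSE),
    traits = NULL, truth = NULL, arch = NULL),
    class = "genotype_cohort")
}
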