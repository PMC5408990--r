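# Readers and writers for the pipeline's plain-text interchange formats.
# All tables are TSV with a header row; ages are real-valued years and
# genomic coordinates are 1-based.

WEIGHT_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                 "other_allele", "effect_allele_freq", "weight",
                 "phenotype_tag")
PHENOTYPE_TAGS <- c("overall_bc", "er_pos_bc", "er_neg_bc", "oc", "custom")
COHORT_COLS <- c("individual_id", "family_id", "study", "gene", "affected",
                 "age_end")

#' Read a SNP weight table
#'
#' A weight table lists the variants of one polygenic risk score: identifier,
#' position, effect and other allele, effect-allele frequency and the
#' per-allele log risk ratio (natural-log scale) attached to the effect
#' allele, plus a phenotype tag (\code{overall_bc}, \code{er_pos_bc},
#' \code{er_neg_bc}, \code{oc} or \code{custom}).
#'
#' @param path path to a TSV file with the columns \code{variant_id},
#'   \code{chrom}, \code{pos}, \code{effect_allele}, \code{other_allele},
#'   \code{effect_allele_freq}, \code{weight}, \code{phenotype_tag}.
#' @return A validated data frame of class \code{snp_weight_table}, row
#'   order preserved.
#' @export
read_weight_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(WEIGHT_COLS, names(x))
  if (length(miss))
    stop("weight table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  validate_weight_table(x[WEIGHT_COLS])
}

#' Construct a SNP weight table
#'
#' Builds and validates a \code{snp_weight_table} from vectors (the in-code
#' equivalent of \code{\link{read_weight_table}}).
#'
#' @param variant_id unique variant identifiers.
#' @param effect_allele,other_allele single-base alleles; the weight refers
#'   to the effect allele.
#' @param effect_allele_freq effect-allele frequencies in (0,1).
#' @param weight per-allele log risk ratios (natural-log scale).
#' @param chrom,pos chromosome and 1-based position (defaults provided for
#'   synthetic tables).
#' @param phenotype_tag one of \code{overall_bc}, \code{er_pos_bc},
#'   \code{er_neg_bc}, \code{oc}, \code{custom}.
#' @return A validated \code{snp_weight_table}.
#' @export
snp_weight_table <- function(variant_id, effect_allele, other_allele,
                             effect_allele_freq, weight,
                             chrom = "1", pos = seq_along(variant_id),
                             phenotype_tag = "custom") {
  validate_weight_table(data.frame(
    variant_id = as.character(variant_id), chrom = as.character(chrom),
    pos = as.integer(pos), effect_allele = effect_allele,
    other_allele = other_allele,
    effect_allele_freq = effect_allele_freq, weight = weight,
    phenotype_tag = phenotype_tag, stringsAsFactors = FALSE))
}

validate_weight_table <- function(x) {
  bad_row <- function(cond, what) {
    if (any(cond)) stop("weight table: ", what, " at row ",
                        which(cond)[1], call. = FALSE)
  }
  dup <- duplicated(x$variant_id)
  bad_row(dup, "duplicate variant_id")
  bad_row(!is.finite(x$weight), "non-finite weight")
  bad_row(!is.finite(x$effect_allele_freq) |
          x$effect_allele_freq <= 0 | x$effect_allele_freq >= 1,
          "effect_allele_freq outside (0,1)")
  bad_row(x$effect_allele == x$other_allele,
          "effect_allele equals other_allele")
  bad_row(!(x$phenotype_tag %in% PHENOTYPE_TAGS), "unknown phenotype_tag")
  bad_row(!is.finite(x$pos) | x$pos < 1, "non-positive position")
  class(x) <- c("snp_weight_table", "data.frame")
  x
}

#' Read a genotype dosage matrix
#'
#' Genotypes are effect-allele-count dosages in [0, 2]; missing entries are
#' kept as \code{NA} (they are imputed later, at PRS computation, never
#' silently zeroed). Two formats are supported: a dosage TSV with
#' individuals as rows (first column \code{individual_id}) and variant ids
#' as columns, or a VCF in which the \code{DS} FORMAT field is preferred
#' and \code{GT} (phased or unphased alike) falls back to the ALT allele
#' count. For VCF input the counted allele (ALT) and the other allele (REF)
#' are recorded in the \code{"alleles"} attribute so that
#' \code{\link{harmonize_genotypes}} can flip strands of reference; dosage
#' TSVs carry no allele labels and are matched by variant id only.
#'
#' @param path path to the file.
#' @param format \code{"dosage_tsv"} or \code{"vcf"}.
#' @return A numeric matrix (individuals x variants) with dimnames, dosages
#'   in [0,2] or \code{NA}, and for VCF input an \code{"alleles"} attribute
#'   (data frame: \code{variant_id}, \code{counted}, \code{other}).
#' @export
read_genotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "dosage_tsv") {
    x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (names(x)[1] != "individual_id")
      stop("dosage TSV must have 'individual_id' as its first column")
    g <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(g) <- "double"
    rownames(g) <- as.character(x$individual_id)
    check_dosages(g)
    return(g)
  }
  read_genotypes_vcf(path)
}

check_dosages <- function(g) {
  bad <- !is.na(g) & (g < -1e-6 | g > 2 + 1e-6)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("dosage outside [0,2] for individual '", rownames(g)[w[1]],
         "', variant '", colnames(g)[w[2]], "'")
  }
  invisible(g)
}

read_genotypes_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  ids <- fix[, "ID"]
  fmt <- vcf@gt[, 1]
  has_ds <- all(grepl("(^|:)DS(:|$)", fmt))
  if (has_ds) {
    d <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(vcf, element = "GT")
    # ALT allele count; phased and unphased separators treated identically
    d <- apply(gt, c(1, 2), function(s) {
      if (is.na(s) || s %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(s, "[/|]")[[1]]) > 0)
    })
  }
  g <- t(d)
  colnames(g) <- ids
  attr(g, "alleles") <- data.frame(variant_id = ids,
                                   counted = fix[, "ALT"],
                                   other = fix[, "REF"],
                                   stringsAsFactors = FALSE)
  check_dosages(g)
  g
}

#' Read a carrier cohort phenotype table
#'
#' One row per mutation carrier: identifier, family, study stratum, gene
#' (\code{BRCA1} or \code{BRCA2}), affection status, and \code{age_end} (age
#' at diagnosis if affected, else age at censoring). \code{age_entry}
#' (delayed entry into the risk set) is optional and defaults to 18.
#'
#' @param path path to a TSV file.
#' @return A validated data frame of class \code{cohort_table}.
#' @export
read_cohort <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(COHORT_COLS, names(x))
  if (length(miss))
    stop("cohort table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  if (is.null(x$age_entry)) x$age_entry <- 18
  validate_cohort(x[c(COHORT_COLS, "age_entry")])
}

validate_cohort <- function(x) {
  bad_row <- function(cond, what) {
    if (any(cond)) stop("cohort table: ", what, " at row ",
                        which(cond)[1], call. = FALSE)
  }
  x$affected <- as.integer(x$affected)
  bad_row(duplicated(x$individual_id), "duplicate individual_id")
  bad_row(!(x$gene %in% c("BRCA1", "BRCA2")), "gene must be BRCA1 or BRCA2")
  bad_row(!(x$affected %in% c(0L, 1L)), "affected must be 0/1")
  bad_row(!is.finite(x$age_end) | x$age_end <= 18 | x$age_end > 100,
          "age_end outside (18, 100]")
  bad_row(!is.finite(x$age_entry) | x$age_entry < 18,
          "age_entry below 18")
  bad_row(x$age_entry >= x$age_end, "age_entry >= age_end")
  class(x) <- c("cohort_table", "data.frame")
  x
}

#' Read an average carrier incidence curve
#'
#' @param path path to a TSV file with columns \code{age} and \code{hazard}
#'   (per year; piecewise constant between grid ages).
#' @return An \code{\link{incidence_curve}}.
#' @export
read_incidence <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("age", "hazard") %in% names(x)))
    stop("incidence file ", path, " must have columns 'age' and 'hazard'")
  if (any(x$hazard < 0))
    stop("incidence file: negative hazard at row ", which(x$hazard < 0)[1])
  incidence_curve(x$age, x$hazard)
}

#' Write an incidence curve to TSV
#' @param ic an \code{incidence_curve}.
#' @param path output path.
#' @export
write_incidence <- function(ic, path) {
  stopifnot(inherits(ic, "incidence_curve"))
  write_tsv6(as.data.frame(ic), path)
}

#' Write a cohort table to TSV
#' @param cohort a \code{cohort_table}.
#' @param path output path.
#' @export
write_cohort <- function(cohort, path) {
  write_tsv6(as.data.frame(cohort)[, c(COHORT_COLS, "age_entry")], path)
}

#' Write a genotype dosage matrix to TSV
#' @param g genotype matrix (individuals x variants).
#' @param path output path.
#' @export
write_dosages <- function(g, path) {
  df <- data.frame(individual_id = rownames(g), as.data.frame(g),
                   check.names = FALSE)
  write_tsv6(df, path)
}

#' Write model results in tidy one-row-per-estimate form
#'
#' Writes the standard results layout used throughout the pipeline:
#' \code{term}, \code{estimate} (log hazard-ratio scale), \code{se},
#' \code{robust_se}, \code{hr}, \code{ci_low}, \code{ci_high},
#' \code{p_one_sided}, \code{p_two_sided}, in that order, at 6 significant
#' digits.
#'
#' @param records a data frame with (a superset of) the standard columns, or
#'   a fitted \code{coxwc} model (its \code{\link{results_table}} is used).
#' @param path output path.
#' @export
write_results <- function(records, path) {
  if (inherits(records, "coxwc")) records <- results_table(records)
  cols <- c("term", "estimate", "se", "robust_se", "hr", "ci_low",
            "ci_high", "p_one_sided", "p_two_sided")
  miss <- setdiff(cols, names(records))
  if (length(miss))
    stop("results are missing column(s): ", paste(miss, collapse = ", "))
  write_tsv6(records[cols], path)
}

write_tsv6 <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
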