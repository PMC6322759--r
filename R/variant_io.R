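## I/O for per-case annotated variant observations and reference-population
## allele frequencies. The native table dialect is tab-separated text with a
## fixed header; a minimal VCF reader is provided for single-sample VCFs
## carrying the same annotations in INFO fields.

OBS_COLUMNS <- c(
  "case_id", "sex", "ga", "gene", "chrom", "pos", "ref", "alt",
  "hgvs_c", "hgvs_p", "consequence", "zygosity", "dbsnp", "cadd_scaled",
  "maf_exac_nfe", "maf_swegen", "reported_in_affected", "functional_evidence",
  "conservation_low", "splice_prediction_affected", "acmg_class_published"
)

CONSEQUENCES <- c("missense", "nonsense", "frameshift", "splice_site",
                  "synonymous", "intronic", "other")
ZYGOSITIES <- c("heterozygous", "homozygous")

#' Read per-case annotated variant observations
#'
#' One row per case-variant observation. Missing cells are `"-"` (or empty)
#' and become `NA`; evidence flags are 0/1; `acmg_class_published` carries a
#' previously assigned simplified ACMG class (3 or 4) used as a per-row
#' override during triage, or `NA`.
#'
#' @param source Path to a tab-separated observation table with the fixed
#'   21-column header (see the packaged example cohort for the format).
#' @return A `variant_observations` data.frame with an added `key` column
#'   ([variant_key()]); row order preserved.
#' @export
read_observations <- function(source) {
  if (!file.exists(source)) stop("observation file not found: ", source)
  df <- utils::read.delim(source, colClasses = "character")
  if (!identical(names(df), OBS_COLUMNS))
    stop("observation table header must be exactly: ",
         paste(OBS_COLUMNS, collapse = " "))
  as_observations(df)
}

#' Validate and type a raw observation data.frame
#'
#' @param df data.frame with the observation columns as character.
#' @return A typed `variant_observations` data.frame.
#' @export
as_observations <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(OBS_COLUMNS, names(df))
  if (length(missing)) stop("missing observation columns: ",
                            paste(missing, collapse = ", "))
  df <- df[, OBS_COLUMNS]
  n <- nrow(df)
  if (n == 0) {
    df$pos <- integer(0); df$cadd_scaled <- numeric(0)
    df$maf_exac_nfe <- numeric(0); df$maf_swegen <- numeric(0)
    for (fl in c("reported_in_affected", "functional_evidence",
                 "conservation_low", "splice_prediction_affected"))
      df[[fl]] <- logical(0)
    df$acmg_class_published <- integer(0)
    df$key <- character(0)
    return(structure(df, class = c("variant_observations", "data.frame")))
  }
  line <- function(i) paste0(" (line ", i + 1L, ")")
  df$gene <- toupper(df$gene)
  bad <- which(!df$consequence %in% CONSEQUENCES)
  if (length(bad)) stop("unknown consequence token '", df$consequence[bad[1]],
                        "'", line(bad[1]))
  bad <- which(!df$zygosity %in% ZYGOSITIES)
  if (length(bad)) stop("unknown zygosity token '", df$zygosity[bad[1]],
                        "'", line(bad[1]))
  bad <- which(!df$sex %in% c("XX", "XY", "unknown", "-"))
  if (length(bad)) stop("unknown sex token '", df$sex[bad[1]], "'", line(bad[1]))
  df$sex[df$sex == "-"] <- "unknown"
  df$pos <- as.integer(df$pos)
  df$cadd_scaled <- .na_dash_num(df$cadd_scaled)
  if (any(df$cadd_scaled < 0, na.rm = TRUE)) stop("negative scaled CADD score")
  for (m in c("maf_exac_nfe", "maf_swegen")) {
    df[[m]] <- .na_dash_num(df[[m]])
    bad <- which(df[[m]] < 0 | df[[m]] > 1)
    if (length(bad)) stop(m, " outside [0,1]", line(bad[1]))
  }
  for (fl in c("reported_in_affected", "functional_evidence",
               "conservation_low", "splice_prediction_affected")) {
    v <- df[[fl]]
    bad <- which(!v %in% c("0", "1", "TRUE", "FALSE"))
    if (length(bad)) stop(fl, " must be 0/1", line(bad[1]))
    df[[fl]] <- v %in% c("1", "TRUE")
  }
  ac <- df$acmg_class_published
  ac[ac %in% c("-", "")] <- NA_character_
  if (!all(is.na(ac) | ac %in% c("3", "4")))
    stop("acmg_class_published must be 3, 4 or '-'")
  df$acmg_class_published <- as.integer(ac)
  ga_weeks(df$ga)  # validates the GA tokens
  df$key <- variant_key(df$chrom, df$pos, df$ref, df$alt)
  structure(df, class = c("variant_observations", "data.frame"))
}

#' Write observations in the native table dialect
#'
#' Round-trips through [read_observations()] with all fields preserved.
#'
#' @param obs A `variant_observations` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  df <- as.data.frame(obs)[, OBS_COLUMNS]
  for (fl in c("reported_in_affected", "functional_evidence",
               "conservation_low", "splice_prediction_affected"))
    df[[fl]] <- as.integer(df[[fl]])
  for (m in c("cadd_scaled", "maf_exac_nfe", "maf_swegen",
              "acmg_class_published")) {
    v <- as.character(df[[m]])
    v[is.na(v)] <- "-"
    df[[m]] <- v
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read observations from a minimal single-sample VCF
#'
#' Expects VCF v4.2 with bi-allelic records and INFO keys `GENE`, `CSQ`
#' (consequence token), `CADD`, `MAF_EXAC_NFE`, `MAF_SWEGEN`, `EV_AFF`,
#' `EV_FUNC`, `CONS_LOW`, `SPLICE_HIT`, plus a genotype column whose first
#' FORMAT field is GT. `1/1` maps to homozygous; `0/1` and `1/0` to
#' heterozygous.
#'
#' @param source Path to the VCF file.
#' @param case_id Case identifier to attach to every record.
#' @return A `variant_observations` data.frame.
#' @export
read_vcf_observations <- function(source, case_id) {
  if (!file.exists(source)) stop("VCF file not found: ", source)
  lines <- readLines(source)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) return(as_observations(empty_observations_df()))
  fields <- strsplit(body, "\t", fixed = TRUE)
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < 10) stop("VCF record ", i, " lacks a genotype column")
    if (grepl(",", f[5], fixed = TRUE))
      stop("multi-allelic VCF record at line ", i, "; split records first")
    info <- strsplit(strsplit(f[8], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    kv <- stats::setNames(
      vapply(info, function(p) if (length(p) > 1) p[2] else "", ""),
      vapply(info, `[`, "", 1L))
    need <- c("GENE", "CSQ", "CADD", "MAF_EXAC_NFE", "MAF_SWEGEN",
              "EV_AFF", "EV_FUNC", "CONS_LOW", "SPLICE_HIT")
    absent <- setdiff(need, names(kv))
    if (length(absent)) stop("VCF record ", i, " missing INFO key(s): ",
                             paste(absent, collapse = ", "))
    gt <- strsplit(strsplit(f[10], ":", fixed = TRUE)[[1]][1], "[/|]")[[1]]
    zyg <- if (identical(gt, c("1", "1"))) "homozygous"
           else if (setequal(gt, c("0", "1"))) "heterozygous"
           else stop("unsupported genotype '", f[10], "' in record ", i)
    chrom <- if (startsWith(f[1], "chr")) f[1] else paste0("chr", f[1])
    data.frame(
      case_id = case_id, sex = "unknown", ga = "-", gene = kv[["GENE"]],
      chrom = chrom, pos = f[2], ref = f[4], alt = f[5],
      hgvs_c = "-", hgvs_p = "-", consequence = kv[["CSQ"]], zygosity = zyg,
      dbsnp = if (f[3] == ".") "-" else f[3],
      cadd_scaled = kv[["CADD"]], maf_exac_nfe = kv[["MAF_EXAC_NFE"]],
      maf_swegen = kv[["MAF_SWEGEN"]],
      reported_in_affected = kv[["EV_AFF"]], functional_evidence = kv[["EV_FUNC"]],
      conservation_low = kv[["CONS_LOW"]],
      splice_prediction_affected = kv[["SPLICE_HIT"]],
      acmg_class_published = "-", stringsAsFactors = FALSE)
  })
  as_observations(do.call(rbind, rows))
}

empty_observations_df <- function() {
  df <- as.data.frame(stats::setNames(
    replicate(length(OBS_COLUMNS), character(0), simplify = FALSE),
    OBS_COLUMNS), stringsAsFactors = FALSE)
  df
}

#' Construct a reference population
#'
#' A reference population is a named cohort of `n_individuals` genotyped (or
#' frequency-catalogued) individuals with per-variant minor allele
#' frequencies. The allele number is exactly `2 * n_individuals`. Variants
#' absent from `maf` are treated as unobserved (frequency 0) by consumers.
#'
#' @param name Population name, e.g. `"ExAC_NFE"`.
#' @param n_individuals Number of individuals.
#' @param maf Named numeric vector of MAFs keyed by [variant_key()] strings.
#' @return A `reference_population` object.
#' @export
reference_population <- function(name, n_individuals, maf = numeric(0)) {
  n_individuals <- .assert_scalar_count(n_individuals, "n_individuals")
  if (n_individuals < 1) stop("n_individuals must be positive")
  maf <- unlist(maf)
  if (length(maf) && (is.null(names(maf)) || any(names(maf) == "")))
    stop("maf must be named by variant key")
  if (any(maf < 0 | maf > 1)) stop("MAF outside [0,1]")
  structure(list(name = name, n_individuals = n_individuals,
                 allele_number = 2L * n_individuals, maf = maf),
            class = "reference_population")
}

#' Load a reference population frequency table
#'
#' @param source Tab-separated file with header `chrom pos ref alt maf`.
#' @param name Population name.
#' @param n_individuals Number of individuals in the population.
#' @return A `reference_population`.
#' @export
load_reference <- function(source, name, n_individuals) {
  if (!file.exists(source)) stop("reference file not found: ", source)
  df <- utils::read.delim(source, colClasses = "character")
  need <- c("chrom", "pos", "ref", "alt", "maf")
  if (!all(need %in% names(df)))
    stop("reference table must have columns: ", paste(need, collapse = ", "))
  maf <- .na_dash_num(df$maf)
  if (anyNA(maf) && nrow(df)) stop("missing MAF in reference table")
  keys <- if (nrow(df)) variant_key(df$chrom, as.integer(df$pos), df$ref, df$alt)
          else character(0)
  reference_population(name, n_individuals, stats::setNames(maf, keys))
}

#' Look up reference MAFs for variant keys
#'
#' @param ref A `reference_population`.
#' @param keys Variant key strings.
#' @param missing Value for keys absent from the population (default `NA`;
#'   burden aggregation uses 0).
#' @return Numeric vector of MAFs.
#' @export
ref_maf <- function(ref, keys, missing = NA_real_) {
  stopifnot(inherits(ref, "reference_population"))
  out <- unname(ref$maf[keys])
  out[is.na(out)] <- missing
  out
}

#' @export
print.reference_population <- function(x, ...) {
  cat("Reference population", x$name, ":", x$n_individuals, "individuals (",
      x$allele_number, "alleles ),", length(x$maf), "catalogued variants\n")
  invisible(x)
}
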