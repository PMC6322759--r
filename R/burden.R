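## Carrier aggregation and burden comparisons.
##
## Case-level carrier counts are distinct-case counts of putative
## pathogenic calls. Reference populations provide only allele frequencies,
## so the expected number of reference carriers is computed under the
## one-carrier assumption: no reference individual carries more than one of
## the cohort's variants, hence expected carriers = sum over distinct
## variants of MAF x allele number, rounded to the nearest individual.

.pathogenic_rows <- function(results) {
  stopifnot(inherits(results, "triage_result") || is.data.frame(results))
  results[results$fate == "retained" &
          results$label == "putative_pathogenic", , drop = FALSE]
}

#' Summarize case-level carriers of putative pathogenic variants
#'
#' A carrier is a case with at least one retained putative-pathogenic
#' observation. Category counts are distinct-case counts per disease
#' category; a case with one channelopathy and one cardiomyopathy variant
#' is counted in both categories but once in the total.
#'
#' @param results A `triage_result` from [triage()].
#' @param panel A `gene_panel` covering every gene in `results`.
#' @param cohort_size Declared number of cases in the cohort.
#' @return A `carrier_summary` list: `cohort_size`, `carriers_total`,
#'   `carriers_one`, `carriers_two_plus`, `carriers_by_category`,
#'   `dual_category_cases`.
#' @export
summarize_carriers <- function(results, panel, cohort_size) {
  cohort_size <- .assert_scalar_count(cohort_size, "cohort_size")
  path <- .pathogenic_rows(results)
  n_distinct_all <- length(unique(results$case_id))
  if (cohort_size < n_distinct_all)
    stop("cohort_size (", cohort_size, ") smaller than number of distinct cases (",
         n_distinct_all, ")")
  if (nrow(path) == 0) {
    return(structure(list(
      cohort_size = cohort_size, carriers_total = 0L, carriers_one = 0L,
      carriers_two_plus = 0L,
      carriers_by_category = c(channelopathy = 0L, cardiomyopathy = 0L),
      dual_category_cases = 0L), class = "carrier_summary"))
  }
  per_case <- table(path$case_id)
  cat_by_row <- category_of(panel, path$gene)
  by_cat <- vapply(PANEL_CATEGORIES, function(cc)
    length(unique(path$case_id[cat_by_row == cc])), 0L)
  n_cats_per_case <- tapply(cat_by_row, path$case_id,
                            function(x) length(unique(x)))
  structure(list(
    cohort_size = cohort_size,
    carriers_total = length(per_case),
    carriers_one = sum(per_case == 1),
    carriers_two_plus = sum(per_case >= 2),
    carriers_by_category = by_cat,
    dual_category_cases = sum(n_cats_per_case == 2)
  ), class = "carrier_summary")
}

#' @export
print.carrier_summary <- function(x, ...) {
  pct <- function(k) sprintf("%.2f%%", round(100 * k / x$cohort_size, 2))
  cat("Carriers:", x$carriers_total, "of", x$cohort_size,
      paste0("(", pct(x$carriers_total), ")"), "-",
      x$carriers_one, "with one variant,", x$carriers_two_plus,
      "with two or more\n")
  for (cc in names(x$carriers_by_category))
    cat(sprintf("  %s: %d (%s)\n", cc, x$carriers_by_category[[cc]],
                pct(x$carriers_by_category[[cc]])))
  invisible(x)
}

#' Expected reference-population carriers under the one-carrier assumption
#'
#' Each distinct variant contributes its reference MAF (0 if absent from
#' the population) times the population allele number; the sum, rounded to
#' the nearest integer and capped at the number of individuals, is the
#' expected carrier count if no individual carries more than one variant.
#'
#' @param keys Distinct variant-key strings (duplicates are collapsed).
#' @param ref A `reference_population`.
#' @return List with `count` (integer) and `proportion` (count / individuals).
#' @export
expected_reference_carriers <- function(keys, ref) {
  stopifnot(inherits(ref, "reference_population"))
  keys <- unique(keys)
  mafs <- ref_maf(ref, keys, missing = 0)
  count <- min(round(sum(mafs) * ref$allele_number), ref$n_individuals)
  list(count = as.integer(count), proportion = count / ref$n_individuals)
}

#' Cohort minor allele frequency for one variant
#'
#' Heterozygous observations contribute one alternate allele, homozygous
#' two; the denominator is `2 * cohort_size` chromosomes.
#'
#' @param observations Observation rows all sharing one variant key.
#' @param cohort_size Number of cases in the cohort.
#' @return The cohort MAF.
#' @export
cohort_maf <- function(observations, cohort_size) {
  cohort_size <- .assert_scalar_count(cohort_size, "cohort_size")
  if (nrow(observations) == 0) return(0)
  if (length(unique(observations$key)) != 1)
    stop("observations must all share a single variant key")
  alleles <- sum(ifelse(observations$zygosity == "homozygous", 2L, 1L))
  if (alleles > 2 * cohort_size)
    stop("allele count exceeds 2 * cohort_size")
  alleles / (2 * cohort_size)
}

#' Carrier-burden exact test for a category
#'
#' Builds the individuals-unit 2x2 table (cohort carriers vs reference
#' carriers) for the chosen category and runs the two-sided exact test.
#'
#' @param summary A `carrier_summary`.
#' @param category `"all"`, `"channelopathy"` or `"cardiomyopathy"`.
#' @param ref_carriers Reference-population carrier count (e.g. from
#'   [expected_reference_carriers()], or supplied directly when genotype
#'   counts are known).
#' @param ref_n Reference-population size in individuals.
#' @return An `exact_test`.
#' @export
carrier_burden_test <- function(summary, category = c("all", "channelopathy",
                                                      "cardiomyopathy"),
                                ref_carriers, ref_n) {
  stopifnot(inherits(summary, "carrier_summary"))
  category <- match.arg(category)
  ref_carriers <- .assert_scalar_count(ref_carriers, "ref_carriers")
  ref_n <- .assert_scalar_count(ref_n, "ref_n")
  if (ref_carriers > ref_n) stop("ref_carriers exceeds ref_n")
  carriers <- if (category == "all") summary$carriers_total
              else summary$carriers_by_category[[category]]
  fisher_exact_two_sided(burden_table(
    carriers, summary$cohort_size - carriers,
    ref_carriers, ref_n - ref_carriers, unit = "individuals"))
}

#' Gene-wide allele-burden exact test
#'
#' Compares the cohort's putative-pathogenic alternate-allele count in one
#' gene against a reference alternate-allele count, on the allele scale
#' (denominators `2 * cohort_size` and the reference allele number).
#'
#' @param gene Gene symbol.
#' @param results A `triage_result`.
#' @param cohort_size Number of cases.
#' @param ref_alt_alleles Reference alternate-allele count for the gene
#'   (e.g. pathogenic/likely-pathogenic alleles catalogued for the
#'   population).
#' @param ref A `reference_population` (supplies the allele number).
#' @return An `exact_test`.
#' @export
gene_allele_burden <- function(gene, results, cohort_size, ref_alt_alleles, ref) {
  stopifnot(inherits(ref, "reference_population"))
  cohort_size <- .assert_scalar_count(cohort_size, "cohort_size")
  ref_alt_alleles <- .assert_scalar_count(ref_alt_alleles, "ref_alt_alleles")
  path <- .pathogenic_rows(results)
  path <- path[path$gene == toupper(gene), , drop = FALSE]
  alt <- if (nrow(path)) sum(ifelse(path$zygosity == "homozygous", 2L, 1L)) else 0L
  if (alt == 0 && ref_alt_alleles == 0)
    stop("degenerate comparison: no pathogenic alleles in cohort or reference")
  fisher_exact_two_sided(burden_table(
    alt, 2L * cohort_size - alt,
    ref_alt_alleles, ref$allele_number - ref_alt_alleles, unit = "alleles"))
}

#' Variant-level cohort-vs-reference MAF exact test
#'
#' @param key Variant-key string; must be present in `ref`.
#' @param observations Observation rows for that key (cohort occurrences).
#' @param cohort_size Number of cases.
#' @param ref A `reference_population`.
#' @return An `exact_test` on the allele scale, with the reference
#'   alternate-allele count `round(MAF x allele number)`.
#' @export
variant_maf_test <- function(key, observations, cohort_size, ref) {
  stopifnot(inherits(ref, "reference_population"))
  cohort_size <- .assert_scalar_count(cohort_size, "cohort_size")
  maf <- ref_maf(ref, key)
  if (is.na(maf)) stop("variant ", key, " absent from reference ", ref$name)
  observations <- observations[observations$key == key, , drop = FALSE]
  alt <- if (nrow(observations))
    sum(ifelse(observations$zygosity == "homozygous", 2L, 1L)) else 0L
  ref_alt <- round(maf * ref$allele_number)
  fisher_exact_two_sided(burden_table(
    alt, 2L * cohort_size - alt,
    ref_alt, ref$allele_number - ref_alt, unit = "alleles"))
}

#' One row per case from an observation table
#'
#' Collapses an observation table to per-case demographics, keeping the
#' first occurrence of each case (cases recorded with discrepant
#' gestational ages across rows resolve to their first row).
#'
#' @param obs A `variant_observations` data.frame.
#' @return data.frame with columns `case_id`, `sex`, `ga`.
#' @export
case_table <- function(obs) {
  first <- !duplicated(obs$case_id)
  as.data.frame(obs)[first, c("case_id", "sex", "ga")]
}

#' Demographic comparison of carrier cases against the complete cohort
#'
#' For gestational age (`test = "chi2"`), case counts are binned by
#' `ga_breaks` and the carrier distribution is compared to the distribution
#' expected from the complete cohort: `E_i = n_carriers * all_i / all_total`,
#' statistic `sum((O - E)^2 / E)` on `bins - 1` degrees of freedom. For sex
#' (`test = "fisher"`), the XX/XY counts form a 2x2 table tested exactly.
#'
#' @param carrier_cases data.frame of carrier cases with columns `ga`, `sex`
#'   (one row per case).
#' @param all_cases data.frame for the complete cohort, same columns.
#' @param ga_breaks Bin breakpoints in weeks (right-open bins; default
#'   four intervals spanning weeks 22-43).
#' @param test `"chi2"` (gestational age) or `"fisher"` (sex).
#' @return For `"chi2"`: list `statistic`, `df`, `p_value`, `observed`,
#'   `expected`. For `"fisher"`: an `exact_test`.
#' @export
compare_demographics <- function(carrier_cases, all_cases,
                                 ga_breaks = c(22, 28, 33, 37, 43),
                                 test = c("chi2", "fisher")) {
  test <- match.arg(test)
  if (test == "fisher") {
    cc <- table(factor(carrier_cases$sex, levels = c("XX", "XY")))
    ac <- table(factor(all_cases$sex, levels = c("XX", "XY")))
    return(fisher_exact_two_sided(burden_table(
      cc[["XX"]], cc[["XY"]], ac[["XX"]], ac[["XY"]],
      unit = "individuals")))
  }
  bin <- function(df) {
    w <- ga_weeks(df$ga)
    w <- w[!is.na(w)]
    table(cut(w, breaks = ga_breaks, right = FALSE))
  }
  obs <- as.numeric(bin(carrier_cases))
  all <- as.numeric(bin(all_cases))
  expected <- sum(obs) * all / sum(all)
  if (any(expected == 0))
    stop("expected count of 0 in a gestational-age bin; merge bins")
  stat <- sum((obs - expected)^2 / expected)
  df <- length(obs) - 1
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       observed = obs, expected = expected)
}
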