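## Monte Carlo permutation comparison of pathogenic-variant proportions
## between two variant cohorts: repeatedly draw equal-size variant subsets
## from each cohort and average the pathogenic fraction across iterations.

#' Construct a variant cohort for permutation sampling
#'
#' @param name Cohort name.
#' @param keys Distinct variant-key strings.
#' @param is_pathogenic Logical flag per variant.
#' @return A `variant_cohort` list.
#' @export
variant_cohort <- function(name, keys, is_pathogenic) {
  if (length(keys) != length(is_pathogenic))
    stop("keys and is_pathogenic must have equal length")
  if (anyDuplicated(keys)) stop("variant keys must be distinct")
  if (anyNA(is_pathogenic)) stop("is_pathogenic must not contain NA")
  structure(list(name = name, keys = keys,
                 is_pathogenic = as.logical(is_pathogenic)),
            class = "variant_cohort")
}

#' Extract a permutation cohort from triage results
#'
#' Keeps retained missense and loss-of-function variants whose reference
#' MAFs are all below the exclusion threshold, collapsed to distinct
#' variant keys; a variant is flagged pathogenic iff its triage label is
#' `putative_pathogenic`.
#'
#' @param results A `triage_result`.
#' @param cfg A [triage_config()] (supplies the MAF threshold and the
#'   loss-of-function consequence set).
#' @param name Cohort name.
#' @return A `variant_cohort`.
#' @export
build_cohort_from_triage <- function(results, cfg = triage_config(),
                                     name = "triage_cohort") {
  keep <- results$fate == "retained" &
    results$consequence %in% c("missense", cfg$lof_consequences)
  mafs <- .obs_mafs(results)
  below <- !apply(mafs >= cfg$maf_exclusion_threshold, 1, any, na.rm = TRUE)
  sel <- results[keep & below, , drop = FALSE]
  first <- !duplicated(sel$key)
  variant_cohort(name, sel$key[first],
                 sel$label[first] == "putative_pathogenic")
}

#' Monte Carlo permutation comparison of pathogenic proportions
#'
#' Per iteration, `sample_size` variants are drawn without replacement
#' (optionally with replacement) independently from each cohort and the
#' pathogenic variants among them counted; the result reports the mean
#' sampled pathogenic proportion per cohort over all iterations. As an
#' extension beyond the mean proportions, the fraction of iterations in
#' which cohort A's count exceeds cohort B's (and the tie fraction) is also
#' reported.
#'
#' @param a,b `variant_cohort` objects.
#' @param iterations Number of Monte Carlo iterations (default 10000).
#' @param sample_size Variants drawn per cohort per iteration (default 50).
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @param replace Draw with replacement (default `FALSE`).
#' @param keep_counts Retain the per-iteration pathogenic counts.
#' @return A `permutation_result` list: `mean_proportion_a`,
#'   `mean_proportion_b`, `prop_a_greater`, `prop_tied`, `iterations`,
#'   `sample_size`, `seed`, and optionally `counts_a`/`counts_b`.
#' @export
permute_proportions <- function(a, b, iterations = 10000, sample_size = 50,
                                seed, replace = FALSE, keep_counts = FALSE) {
  stopifnot(inherits(a, "variant_cohort"), inherits(b, "variant_cohort"))
  iterations <- .assert_scalar_count(iterations, "iterations")
  sample_size <- .assert_scalar_count(sample_size, "sample_size")
  if (iterations < 1) stop("iterations must be >= 1")
  if (missing(seed)) stop("seed is required for reproducibility")
  if (!replace && (sample_size > length(a$keys) || sample_size > length(b$keys)))
    stop("sample_size exceeds a cohort's variant count")
  if (length(a$keys) == 0 || length(b$keys) == 0)
    stop("cohorts must be non-empty")
  ## Sampling indexes the cohort's flag vector after a canonical sort by
  ## key, so the result depends on the variant set, not input order.
  flags <- function(ch) ch$is_pathogenic[order(ch$keys)]
  fa <- flags(a); fb <- flags(b)
  counts_a <- integer(iterations); counts_b <- integer(iterations)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(iterations)) {
    counts_a[i] <- sum(fa[sample.int(length(fa), sample_size, replace = replace)])
    counts_b[i] <- sum(fb[sample.int(length(fb), sample_size, replace = replace)])
  }
  out <- list(
    mean_proportion_a = mean(counts_a) / sample_size,
    mean_proportion_b = mean(counts_b) / sample_size,
    prop_a_greater = mean(counts_a > counts_b),
    prop_tied = mean(counts_a == counts_b),
    iterations = iterations, sample_size = sample_size, seed = seed,
    replace = replace,
    cohort_a = a$name, cohort_b = b$name)
  if (keep_counts) {
    out$counts_a <- counts_a
    out$counts_b <- counts_b
  }
  structure(out, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation comparison (%d iterations x %d variants, seed %d):\n",
    x$iterations, x$sample_size, x$seed))
  cat(sprintf("  mean pathogenic proportion: %s %.4f vs %s %.4f\n",
              x$cohort_a, x$mean_proportion_a, x$cohort_b, x$mean_proportion_b))
  cat(sprintf("  iterations with %s count > %s count: %.4f (ties %.4f)\n",
              x$cohort_a, x$cohort_b, x$prop_a_greater, x$prop_tied))
  invisible(x)
}
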