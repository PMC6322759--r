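## Synthetic cohort generator. Produces a stillbirth-style case series with
## known ground truth: a configurable fraction of cases carry one or two
## putative-pathogenic variants that are guaranteed to survive triage, plus
## decoy variants (VUS, likely-benign, synonymous, common) that exercise
## the filters. Reference populations are generated alongside with
## log-uniform rare-variant MAFs.

#' Simulation configuration
#'
#' Defaults describe a 290-case cohort in which 12% of cases carry at least
#' one putative-pathogenic variant, about 11% of carriers harbour a second
#' variant, and 23/35 of carrier variants fall in channelopathy genes —
#' the carrier structure observed in the packaged example cohort.
#'
#' @param n_cases Cohort size (default 290).
#' @param carrier_prevalence Fraction of cases drawn as carriers
#'   (default 0.12).
#' @param dual_variant_fraction Fraction of carriers given a second
#'   pathogenic variant (default 4/35).
#' @param category_split Probability a pathogenic variant lands in a
#'   channelopathy gene (default 23/35).
#' @param vus_per_case_rate Mean number of VUS decoys per case (Poisson;
#'   default 0.5).
#' @param benign_decoy_rate Per-case probability of a likely-benign decoy
#'   (low conservation, low CADD; default 0.1).
#' @param synonymous_decoy_rate Per-case probability of a synonymous decoy
#'   (default 0.2).
#' @param common_decoy_rate Per-case probability of a common-variant decoy
#'   with reference MAF 5% (default 0.2).
#' @param maf_log10_range log10-MAF interval for generated rare variants
#'   (default `c(-5, -2.3)`, i.e. 0.001%-0.5%, safely below the 1%
#'   exclusion threshold).
#' @param ref_populations Named integer vector of reference-population
#'   sizes (default ExAC_NFE = 33370, SweGen = 1000).
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cases = 290, carrier_prevalence = 0.12,
                              dual_variant_fraction = 4 / 35,
                              category_split = 23 / 35,
                              vus_per_case_rate = 0.5,
                              benign_decoy_rate = 0.1,
                              synonymous_decoy_rate = 0.2,
                              common_decoy_rate = 0.2,
                              maf_log10_range = c(-5, -2.3),
                              ref_populations = c(ExAC_NFE = 33370L,
                                                  SweGen = 1000L),
                              seed = 1L) {
  n_cases <- .assert_scalar_count(n_cases, "n_cases")
  fr <- c(carrier_prevalence, dual_variant_fraction, category_split,
          benign_decoy_rate, synonymous_decoy_rate, common_decoy_rate)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0,1]")
  if (vus_per_case_rate < 0) stop("vus_per_case_rate must be >= 0")
  if (length(maf_log10_range) != 2 || diff(maf_log10_range) < 0)
    stop("maf_log10_range must be an increasing interval")
  if (maf_log10_range[2] >= log10(0.01))
    stop("maf_log10_range upper bound must stay below log10(0.01) so that ",
         "generated pathogenic variants survive the frequency filter")
  if (n_cases == 0 && carrier_prevalence > 0)
    stop("cannot place carriers in an empty cohort")
  structure(list(n_cases = n_cases, carrier_prevalence = carrier_prevalence,
                 dual_variant_fraction = dual_variant_fraction,
                 category_split = category_split,
                 vus_per_case_rate = vus_per_case_rate,
                 benign_decoy_rate = benign_decoy_rate,
                 synonymous_decoy_rate = synonymous_decoy_rate,
                 common_decoy_rate = common_decoy_rate,
                 maf_log10_range = maf_log10_range,
                 ref_populations = ref_populations, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a synthetic cohort with known truth
#'
#' Carrier cases are drawn by independent Bernoulli trials at
#' `carrier_prevalence`; each carrier receives one pathogenic variant (a
#' reported/functional-evidence missense with probability 0.7, otherwise a
#' loss-of-function variant) and a second with probability
#' `dual_variant_fraction`. Genes are drawn from the default panel with the
#' configured category split. Decoy variants (VUS, likely-benign,
#' synonymous, common) are sprinkled over all cases. Every generated
#' variant key is distinct; all pathogenic and decoy rare variants carry
#' log-uniform reference MAFs inside `maf_log10_range`, while common decoys
#' carry MAF 0.05 and must be removed by the frequency filter.
#'
#' @param cfg A [simulation_config()].
#' @return A `synthetic_cohort` list: `observations`
#'   (`variant_observations`), `truth` (list with per-`case` and
#'   per-`variant` data.frames), `references` (named list of
#'   `reference_population`), `panel`, `cohort_size`, `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  panel <- load_panel()
  n <- cfg$n_cases
  case_ids <- sprintf("S%04d", seq_len(n))
  sex <- sample(c("XX", "XY"), n, replace = TRUE)
  ga <- paste0(sample(22:41, n, replace = TRUE), "+",
               sample(0:6, n, replace = TRUE))

  is_carrier <- stats::runif(n) < cfg$carrier_prevalence
  n_var <- integer(n)
  n_var[is_carrier] <- 1L +
    (stats::runif(sum(is_carrier)) < cfg$dual_variant_fraction)
  vus_count <- stats::rpois(n, cfg$vus_per_case_rate)
  benign <- stats::runif(n) < cfg$benign_decoy_rate
  synon <- stats::runif(n) < cfg$synonymous_decoy_rate
  common <- stats::runif(n) < cfg$common_decoy_rate

  ## one flat vector of (case, kind) slots, then fully vectorized draws
  case_idx <- c(rep(seq_len(n), n_var), rep(seq_len(n), vus_count),
                which(benign), which(synon), which(common))
  kind <- c(rep("pathogenic", sum(n_var)), rep("vus", sum(vus_count)),
            rep("benign", sum(benign)), rep("synonymous", sum(synon)),
            rep("common", sum(common)))
  total_var <- length(case_idx)

  if (total_var > 0) {
    pos <- sample.int(2e8L, total_var)        # distinct keys by construction
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, total_var, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L +
                    sample.int(3L, total_var, replace = TRUE)) %% 4L + 1L]
    chan <- stats::runif(total_var) < cfg$category_split
    chan_pool <- panel$symbol[panel$category == "channelopathy"]
    card_pool <- panel$symbol[panel$category == "cardiomyopathy"]
    gene <- ifelse(chan,
                   chan_pool[sample.int(length(chan_pool), total_var, TRUE)],
                   card_pool[sample.int(length(card_pool), total_var, TRUE)])
    cons <- rep("missense", total_var)
    rep_aff <- func <- cons_low <- rep(FALSE, total_var)
    cadd <- stats::runif(total_var, 10, 30)
    draw_maf <- function(k) 10^stats::runif(k, cfg$maf_log10_range[1],
                                            cfg$maf_log10_range[2])
    maf_e <- draw_maf(total_var)
    maf_s <- draw_maf(total_var)
    label <- rep("vus", total_var)

    ip <- kind == "pathogenic"
    ev <- ip & stats::runif(total_var) < 0.7
    lof <- ip & !ev
    rep_aff[ev] <- TRUE
    func[ev] <- stats::runif(sum(ev)) < 0.5
    cadd[ev] <- stats::runif(sum(ev), 20, 40)
    cons[lof] <- sample(c("nonsense", "frameshift", "splice_site"),
                        sum(lof), replace = TRUE)
    cadd[lof] <- stats::runif(sum(lof), 20, 45)
    label[ip] <- "putative_pathogenic"

    ib <- kind == "benign"
    cons_low[ib] <- TRUE
    cadd[ib] <- stats::runif(sum(ib), 0, 9)
    label[ib] <- "likely_benign"

    is_syn <- kind == "synonymous"
    cons[is_syn] <- "synonymous"
    cadd[is_syn] <- stats::runif(sum(is_syn), 0, 10)
    label[is_syn] <- "excluded"

    ic <- kind == "common"
    maf_e[ic] <- 0.05
    maf_s[ic] <- 0.05
    label[ic] <- "excluded"

    maf_s[!ic & stats::runif(total_var) < 0.5] <- NA_real_

    fmt_maf <- function(x) ifelse(is.na(x), "-",
                                  format(x, scientific = FALSE, trim = TRUE))
    obs <- as_observations(data.frame(
      case_id = case_ids[case_idx], sex = sex[case_idx], ga = ga[case_idx],
      gene = gene, chrom = "chr1", pos = as.character(pos),
      ref = ref, alt = alt, hgvs_c = "-", hgvs_p = "-",
      consequence = cons, zygosity = "heterozygous", dbsnp = "-",
      cadd_scaled = as.character(round(cadd, 2)),
      maf_exac_nfe = fmt_maf(maf_e), maf_swegen = fmt_maf(maf_s),
      reported_in_affected = as.character(as.integer(rep_aff)),
      functional_evidence = as.character(as.integer(func)),
      conservation_low = as.character(as.integer(cons_low)),
      splice_prediction_affected = "0",
      acmg_class_published = "-", stringsAsFactors = FALSE))
    vt <- data.frame(key = obs$key, truth_label = label,
                     maf_exac_nfe = maf_e,
                     maf_swegen = ifelse(is.na(maf_s), 0, maf_s),
                     stringsAsFactors = FALSE)
  } else {
    obs <- as_observations(empty_observations_df())
    vt <- data.frame(key = character(0), truth_label = character(0),
                     maf_exac_nfe = numeric(0), maf_swegen = numeric(0))
  }

  refs <- lapply(names(cfg$ref_populations), function(nm) {
    col <- if (nm == "SweGen") vt$maf_swegen else vt$maf_exac_nfe
    keep <- col > 0
    reference_population(nm, cfg$ref_populations[[nm]],
                         stats::setNames(col[keep], vt$key[keep]))
  })
  names(refs) <- names(cfg$ref_populations)

  structure(list(
    observations = obs,
    truth = list(
      case = data.frame(case_id = case_ids, sex = sex, ga = ga,
                        is_carrier = is_carrier, n_pathogenic = n_var,
                        stringsAsFactors = FALSE),
      variant = vt),
    references = refs, panel = panel, cohort_size = n, config = cfg),
    class = "synthetic_cohort")
}

#' End-to-end recovery and calibration report
#'
#' Runs simulate -> triage -> carrier summary -> burden test over
#' `replicates` independent cohorts. The reference carrier count shares the
#' generator's one-carrier null: `round(carrier_prevalence * ref_n)`
#' reference carriers out of `ref_n`, so with `enrichment = 1` the burden
#' test is under its null and its rejection rate estimates the empirical
#' type-I error; `enrichment > 1` multiplies the cohort prevalence only and
#' yields a power estimate.
#'
#' @param cfg A [simulation_config()]; its seed spawns per-replicate seeds.
#' @param replicates Number of simulated cohorts (>= 1).
#' @param enrichment Multiplier on cohort prevalence relative to the
#'   reference (default 1 = null).
#' @param ref_n Reference-population size (default 33370).
#' @param alpha Significance level for the rejection rate (default 0.05).
#' @return List: `replicates` (per-replicate data.frame with estimated
#'   prevalence and p-value), `bias`, `mean_estimate`, `coverage`
#'   (fraction of exact binomial 95% CIs containing the true prevalence),
#'   `rejection_rate`, `alpha`, `enrichment`.
#' @export
end_to_end_recovery <- function(cfg = simulation_config(), replicates = 50,
                                enrichment = 1, ref_n = 33370, alpha = 0.05) {
  replicates <- .assert_scalar_count(replicates, "replicates")
  if (replicates < 1) stop("replicates must be >= 1")
  p_cohort <- min(1, cfg$carrier_prevalence * enrichment)
  ref_carriers <- round(cfg$carrier_prevalence * ref_n)
  res <- lapply(seq_len(replicates), function(r) {
    cfg_r <- cfg
    cfg_r$carrier_prevalence <- p_cohort
    cfg_r$seed <- cfg$seed + r
    sim <- simulate_cohort(cfg_r)
    tri <- triage(sim$observations)
    summ <- summarize_carriers(tri, sim$panel, sim$cohort_size)
    test <- carrier_burden_test(summ, "all", ref_carriers, ref_n)
    ci <- stats::binom.test(summ$carriers_total, sim$cohort_size)$conf.int
    data.frame(replicate = r, carriers = summ$carriers_total,
               estimate = summ$carriers_total / sim$cohort_size,
               ci_lo = ci[1], ci_hi = ci[2], p_value = test$p_two_sided)
  })
  res <- do.call(rbind, res)
  list(replicates = res,
       mean_estimate = mean(res$estimate),
       bias = mean(res$estimate) - p_cohort,
       coverage = mean(res$ci_lo <= p_cohort & p_cohort <= res$ci_hi),
       rejection_rate = mean(res$p_value < alpha),
       alpha = alpha, enrichment = enrichment)
}
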