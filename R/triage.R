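## Variant triage: frequency and consequence filters followed by a
## pathogenicity decision tree, with a per-variant decision trace.
##
## Rules, in order:
##   1. frequency filter — any reference-population MAF above the exclusion
##      threshold (default 1%) removes the variant; missing frequencies never
##      exclude.
##   2. consequence filter — synonymous variants are removed, as are intronic
##      variants without a splice prediction hit; intronic variants predicted
##      to affect splicing are reclassified as splice-site.
##   3. classification — loss-of-function variants (nonsense, frameshift,
##      splice site) are putative pathogenic, as are variants with prior
##      reports in affected individuals or functional evidence; missense
##      variants with no supporting evidence, low conservation AND a low
##      scaled CADD score are likely benign; everything else is a VUS.
##
## The simplified ACMG class covers the two tiers seen in clinical triage of
## this kind: 3 (uncertain significance) and 4 (likely pathogenic). The
## default rule assigns class 4 to loss-of-function variants with no prior
## disease report, class 3 otherwise; a per-row published class, when
## present, overrides the rule (curated classes incorporate criteria that
## cannot be recomputed from the annotation columns alone).

#' Triage configuration
#'
#' @param maf_exclusion_threshold Exclude variants with any reference MAF
#'   strictly above this fraction. Default 0.01 (the conventional 1% rarity
#'   cutoff for dominant cardiac disease variants).
#' @param cadd_low_threshold Scaled CADD below which a score counts as "low"
#'   for the likely-benign rule. Default 10: scaled CADD is phred-like, so
#'   10 marks the top 10% of possible variants, a conservative floor for
#'   calling a variant benign.
#' @param lof_consequences Consequence tokens treated as loss-of-function.
#' @param any_population_excludes If `TRUE` (default) one population above
#'   the threshold suffices to exclude; if `FALSE` all non-missing
#'   populations must exceed it.
#' @param use_published_override Honour the `acmg_class_published` column
#'   when assigning the simplified ACMG class (default `TRUE`).
#' @return A `triage_config` list.
#' @export
triage_config <- function(maf_exclusion_threshold = 0.01,
                          cadd_low_threshold = 10,
                          lof_consequences = c("nonsense", "frameshift",
                                               "splice_site"),
                          any_population_excludes = TRUE,
                          use_published_override = TRUE) {
  if (maf_exclusion_threshold <= 0 || maf_exclusion_threshold > 1)
    stop("maf_exclusion_threshold must be in (0,1]")
  if (cadd_low_threshold < 0) stop("cadd_low_threshold must be >= 0")
  structure(list(maf_exclusion_threshold = maf_exclusion_threshold,
                 cadd_low_threshold = cadd_low_threshold,
                 lof_consequences = lof_consequences,
                 any_population_excludes = any_population_excludes,
                 use_published_override = use_published_override),
            class = "triage_config")
}

.obs_mafs <- function(obs) {
  cbind(obs$maf_exac_nfe, obs$maf_swegen)
}

#' Frequency filter
#'
#' @param obs A `variant_observations` data.frame.
#' @param cfg A [triage_config()].
#' @return Logical vector: `TRUE` where the observation passes (is rare or
#'   unobserved in every reference population).
#' @export
frequency_filter <- function(obs, cfg = triage_config()) {
  mafs <- .obs_mafs(obs)
  if (any(mafs > 0.5, na.rm = TRUE))
    stop("reference MAF above 0.5: not a minor allele frequency")
  above <- mafs > cfg$maf_exclusion_threshold
  if (cfg$any_population_excludes) {
    !apply(above, 1, any, na.rm = TRUE)
  } else {
    all_above <- apply(above, 1, function(r) {
      r <- r[!is.na(r)]
      length(r) > 0 && all(r)
    })
    !all_above
  }
}

#' Consequence filter
#'
#' Synonymous variants fail; intronic variants fail unless predicted to
#' affect splicing, in which case they pass and are reclassified as
#' splice-site for the downstream loss-of-function rule.
#'
#' @inheritParams frequency_filter
#' @return List with `pass` (logical) and `consequence` (character, with
#'   splice-rescued intronic variants relabelled `"splice_site"`).
#' @export
consequence_filter <- function(obs, cfg = triage_config()) {
  cons <- obs$consequence
  pass <- !(cons == "synonymous" |
            (cons == "intronic" & !obs$splice_prediction_affected))
  cons[cons == "intronic" & obs$splice_prediction_affected] <- "splice_site"
  list(pass = pass, consequence = cons)
}

#' Triage annotated variant observations
#'
#' Applies the frequency filter, the consequence filter, and the
#' pathogenicity decision tree to every observation, recording for each one
#' its fate, label, simplified ACMG class, and an ordered trace of the rules
#' that fired.
#'
#' @inheritParams frequency_filter
#' @return A `triage_result` data.frame: the input columns plus `fate`
#'   (`excluded_frequency`, `excluded_consequence`, `retained`), `label`
#'   (`putative_pathogenic`, `vus`, `likely_benign`, `none`), `acmg_class`
#'   (`"3"`, `"4"`, `"unassigned"`) and `trace` (semicolon-joined rule
#'   names).
#' @export
triage <- function(obs, cfg = triage_config()) {
  stopifnot(inherits(cfg, "triage_config"))
  obs <- as_observations(as.data.frame(obs))
  n <- nrow(obs)
  fate <- rep("retained", n)
  label <- rep("none", n)
  acmg <- rep("unassigned", n)
  trace <- vector("list", n)

  freq_ok <- frequency_filter(obs, cfg)
  cf <- consequence_filter(obs, cfg)
  cons <- cf$consequence

  for (i in seq_len(n)) {
    tr <- character(0)
    if (!freq_ok[i]) {
      fate[i] <- "excluded_frequency"
      trace[[i]] <- "frequency_above_threshold"
      next
    }
    tr <- c(tr, "frequency_pass")
    if (!cf$pass[i]) {
      fate[i] <- "excluded_consequence"
      trace[[i]] <- c(tr, if (obs$consequence[i] == "synonymous")
        "synonymous_excluded" else "intronic_no_splice_effect")
      next
    }
    if (cons[i] != obs$consequence[i]) tr <- c(tr, "intronic_rescued_as_splice_site")
    is_lof <- cons[i] %in% cfg$lof_consequences
    has_evidence <- isTRUE(obs$reported_in_affected[i]) ||
      isTRUE(obs$functional_evidence[i])
    if (is_lof || has_evidence) {
      label[i] <- "putative_pathogenic"
      tr <- c(tr, if (is_lof) "lof_pathogenic" else NULL,
              if (has_evidence) "evidence_pathogenic" else NULL)
      default_class <- if (is_lof && !isTRUE(obs$reported_in_affected[i])) "4" else "3"
      pub <- obs$acmg_class_published[i]
      if (cfg$use_published_override && !is.na(pub)) {
        acmg[i] <- as.character(pub)
        if (acmg[i] != default_class) tr <- c(tr, "acmg_published_override")
        else tr <- c(tr, "acmg_default_rule")
      } else {
        acmg[i] <- default_class
        tr <- c(tr, "acmg_default_rule")
      }
    } else if (cons[i] == "missense" &&
               isTRUE(obs$conservation_low[i]) &&
               !is.na(obs$cadd_scaled[i]) &&
               obs$cadd_scaled[i] < cfg$cadd_low_threshold) {
      label[i] <- "likely_benign"
      tr <- c(tr, "benign_low_conservation_low_cadd")
    } else {
      label[i] <- "vus"
      tr <- c(tr, "vus_fallback")
    }
    trace[[i]] <- tr
  }

  out <- as.data.frame(obs)
  out$consequence <- cons
  out$fate <- fate
  out$label <- label
  out$acmg_class <- acmg
  out$trace <- vapply(trace, paste, "", collapse = ";")
  structure(out, class = c("triage_result", "data.frame"))
}

#' Genome-rank fraction implied by a scaled CADD score
#'
#' Scaled CADD is phred-like: a score C places a variant among the top
#' `10^(-C/10)` fraction of all possible genomic variants by predicted
#' deleteriousness (20 = top 1%, 30 = top 0.1%).
#'
#' @param score Non-negative scaled CADD score(s).
#' @return Fraction(s) in (0, 1].
#' @export
cadd_rank_fraction <- function(score) {
  if (any(score < 0, na.rm = TRUE)) stop("scaled CADD score must be >= 0")
  10^(-score / 10)
}
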