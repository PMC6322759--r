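## End-to-end pipeline: triage -> carrier summary -> burden tests, with
## machine-readable tables plus a human-readable summary. Logs go to
## standard error; results only ever go to files.

#' Pipeline configuration
#'
#' @param variants Path to an observation table ([read_observations()]).
#' @param panel Path to a panel file (default packaged 70-gene panel).
#' @param cohort_size Declared cohort size.
#' @param references Named list of `list(path =, n =)` reference frequency
#'   tables, or ready-made `reference_population` objects.
#' @param ref_carriers Optional named integer vector overriding the
#'   MAF-derived expected carrier count per reference population (used when
#'   genotype-level carrier counts are known for a population).
#' @param triage_cfg A [triage_config()].
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed recorded in outputs (the deterministic stages
#'   do not consume randomness).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(variants, panel = default_panel_file(),
                            cohort_size, references = list(),
                            ref_carriers = NULL,
                            triage_cfg = triage_config(),
                            out_dir = ".", seed = 1L) {
  if (!file.exists(variants)) stop("variant file not found: ", variants)
  if (!file.exists(panel)) stop("panel file not found: ", panel)
  structure(list(variants = variants, panel = panel,
                 cohort_size = cohort_size, references = references,
                 ref_carriers = ref_carriers, triage_cfg = triage_cfg,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.log <- function(...) {
  message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [cardioburden] ", ...)
}

.fmt_pct <- function(k, n) sprintf("%.2f%%", round(100 * k / n, 2))

#' Run the full analysis pipeline
#'
#' Stages: read inputs, triage every observation, summarize carriers,
#' run carrier-burden tests against every configured reference population
#' (per category and overall), gene-level allele counts, and per-variant
#' cohort MAFs. Writes `triage.tsv`, `carrier_summary.tsv`, `burden.tsv`,
#' `variant_maf.tsv` and `summary.txt` to the output directory and returns
#' the results invisibly.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `triage`, `summary`, `burden`
#'   (data.frame), `variant_maf` (data.frame), `paths`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  .log("reading panel: ", cfg$panel)
  panel <- load_panel(cfg$panel)
  .log("reading observations: ", cfg$variants)
  obs <- read_observations(cfg$variants)
  refs <- lapply(cfg$references, function(r) {
    if (inherits(r, "reference_population")) r
    else load_reference(r$path, r$name, r$n)
  })

  .log("triaging ", nrow(obs), " observations")
  tri <- triage(obs, cfg$triage_cfg)
  triage_path <- file.path(cfg$out_dir, "triage.tsv")
  utils::write.table(as.data.frame(tri), triage_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)

  summ <- summarize_carriers(tri, panel, cfg$cohort_size)
  summ_df <- data.frame(
    metric = c("cohort_size", "carriers_total", "carriers_one",
               "carriers_two_plus", "carriers_channelopathy",
               "carriers_cardiomyopathy", "dual_category_cases"),
    value = c(summ$cohort_size, summ$carriers_total, summ$carriers_one,
              summ$carriers_two_plus,
              summ$carriers_by_category[["channelopathy"]],
              summ$carriers_by_category[["cardiomyopathy"]],
              summ$dual_category_cases))
  summary_path <- file.path(cfg$out_dir, "carrier_summary.tsv")
  utils::write.table(summ_df, summary_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  path_rows <- .pathogenic_rows(tri)
  burden <- list()
  for (nm in names(refs)) {
    ref <- refs[[nm]]
    for (cat in c("all", "channelopathy", "cardiomyopathy")) {
      keys <- if (cat == "all") path_rows$key
              else path_rows$key[category_of(panel, path_rows$gene) == cat]
      keys <- unique(keys)
      carriers <- if (cat == "all") summ$carriers_total
                  else summ$carriers_by_category[[cat]]
      if (summ$carriers_total == 0) {
        burden[[length(burden) + 1L]] <- data.frame(
          reference = nm, category = cat, cohort_carriers = 0L,
          cohort_n = summ$cohort_size, ref_carriers = NA_integer_,
          ref_n = ref$n_individuals, cohort_pct = "0.00%", ref_pct = NA,
          p_two_sided = NA_real_, odds_ratio = NA_real_, note = "not applicable")
        next
      }
      rc <- if (!is.null(cfg$ref_carriers) && nm %in% names(cfg$ref_carriers) &&
                cat == "all") {
        cfg$ref_carriers[[nm]]
      } else {
        expected_reference_carriers(keys, ref)$count
      }
      test <- carrier_burden_test(summ, cat, rc, ref$n_individuals)
      burden[[length(burden) + 1L]] <- data.frame(
        reference = nm, category = cat, cohort_carriers = carriers,
        cohort_n = summ$cohort_size, ref_carriers = rc,
        ref_n = ref$n_individuals,
        cohort_pct = .fmt_pct(carriers, summ$cohort_size),
        ref_pct = .fmt_pct(rc, ref$n_individuals),
        p_two_sided = test$p_two_sided, odds_ratio = test$odds_ratio,
        note = "")
    }
  }
  burden <- if (length(burden)) do.call(rbind, burden) else data.frame()
  burden_path <- file.path(cfg$out_dir, "burden.tsv")
  utils::write.table(burden, burden_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## per-variant cohort MAFs (putative pathogenic only)
  vkeys <- unique(path_rows$key)
  vm <- lapply(vkeys, function(k) {
    rows <- path_rows[path_rows$key == k, , drop = FALSE]
    data.frame(key = k, gene = rows$gene[1], n_obs = nrow(rows),
               cohort_maf = cohort_maf(rows, cfg$cohort_size))
  })
  vm <- if (length(vm)) do.call(rbind, vm) else
    data.frame(key = character(0), gene = character(0),
               n_obs = integer(0), cohort_maf = numeric(0))
  vm_path <- file.path(cfg$out_dir, "variant_maf.tsv")
  utils::write.table(vm, vm_path, sep = "\t", quote = FALSE, row.names = FALSE)

  txt_path <- file.path(cfg$out_dir, "summary.txt")
  lines <- c(
    sprintf("cohort: %d cases, %d observations, seed %d",
            summ$cohort_size, nrow(obs), cfg$seed),
    sprintf("carriers: %d (%s); one variant %d, two or more %d",
            summ$carriers_total, .fmt_pct(summ$carriers_total, summ$cohort_size),
            summ$carriers_one, summ$carriers_two_plus),
    sprintf("  channelopathy %d (%s), cardiomyopathy %d (%s), dual %d",
            summ$carriers_by_category[["channelopathy"]],
            .fmt_pct(summ$carriers_by_category[["channelopathy"]], summ$cohort_size),
            summ$carriers_by_category[["cardiomyopathy"]],
            .fmt_pct(summ$carriers_by_category[["cardiomyopathy"]], summ$cohort_size),
            summ$dual_category_cases),
    if (nrow(burden) && any(burden$note == "")) apply(
      burden[burden$note == "", , drop = FALSE], 1, function(r)
        sprintf("burden %s / %s: %s vs %s carriers, p = %s",
                r[["reference"]], r[["category"]], r[["cohort_pct"]],
                r[["ref_pct"]],
                format(as.numeric(r[["p_two_sided"]]), digits = 3)))
    else "burden: not applicable (no carriers)")
  writeLines(lines, txt_path)
  .log("wrote results to ", cfg$out_dir)

  invisible(list(triage = tri, summary = summ, burden = burden,
                 variant_maf = vm,
                 paths = c(triage = triage_path, summary = summary_path,
                           burden = burden_path, variant_maf = vm_path,
                           text = txt_path)))
}
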