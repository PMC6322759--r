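## Packaged example cohort: annotated putative-pathogenic variant
## observations from a screen of 290 stillbirth cases on the 70-gene
## cardiac panel, with reference-population frequency objects rebuilt from
## the table's ExAC-NFE and SweGen MAF columns.
##
## One caveat: the 8-base deleted sequence of the TRPM4 frameshift
## (c.1195_1202del) is not part of the source annotation, so its ref/alt
## strings in the table are a synthetic placeholder; the key is unique and
## all counts are unaffected.

#' Packaged stillbirth cohort fixture
#'
#' Returns the packaged example cohort: 39 case-variant observations over
#' 35 distinct cases and 33 distinct variants from a 290-case stillbirth
#' cohort, reference populations rebuilt from the table's MAF columns
#' (ExAC non-Finnish Europeans, n = 33,370 individuals; SweGen, n = 1,000),
#' and the default 70-gene panel.
#'
#' @return List with elements `observations` (`variant_observations`),
#'   `references` (named list of `reference_population`: `ExAC_NFE`,
#'   `SweGen`), `panel` (`gene_panel`) and `cohort_size` (290).
#' @export
stillbirth_fixture <- function() {
  obs <- read_observations(
    system.file("extdata", "stillbirth_cohort_variants.tsv",
                package = "cardioburden", mustWork = TRUE))
  first <- !duplicated(obs$key)
  mk_ref <- function(col, name, n) {
    maf <- obs[[col]][first]
    keys <- obs$key[first]
    keep <- !is.na(maf)
    reference_population(name, n, stats::setNames(maf[keep], keys[keep]))
  }
  list(observations = obs,
       references = list(
         ExAC_NFE = mk_ref("maf_exac_nfe", "ExAC_NFE", 33370L),
         SweGen = mk_ref("maf_swegen", "SweGen", 1000L)),
       panel = load_panel(),
       cohort_size = 290L)
}
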