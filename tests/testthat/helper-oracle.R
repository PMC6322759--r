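# Independent exact-test oracle: exhaustive enumeration over all 2x2 tables
# with the observed margins, probabilities computed from plain binomial
# coefficients (choose), two-sided mass by the point-probability rule.
# Kept free of dhyper/fisher.test so it is a genuinely separate route.
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(m, k)
  prob <- vapply(support, function(x)
    choose(m, x) * choose(n, k - x) / choose(m + n, k), 0)
  p_obs <- prob[support == a]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# random valid 2x2 table with total at most `max_total` and positive rows
random_table <- function(max_total = 60) {
  repeat {
    cells <- as.vector(stats::rmultinom(1, sample(4:max_total, 1), rep(1, 4)))
    if (cells[1] + cells[2] > 0 && cells[3] + cells[4] > 0) return(cells)
  }
}

# minimal observation row(s) for triage unit tests
make_obs <- function(n = 1, consequence = "missense", maf_exac = "-",
                     maf_swe = "-", reported = "0", functional = "0",
                     cons_low = "0", cadd = "25", splice_hit = "0",
                     zygosity = "heterozygous", gene = "KCNQ1",
                     case_id = NULL, acmg = "-") {
  if (n == 0) {
    one <- make_obs(1)
    return(as_observations(utils::head(as.data.frame(one), 0)))
  }
  if (is.null(case_id)) case_id <- sprintf("C%03d", seq_len(n))
  as_observations(data.frame(
    case_id = case_id, sex = "XX", ga = "30+0", gene = gene,
    chrom = "chr1", pos = as.character(seq_len(n) + 1000L),
    ref = "A", alt = "G", hgvs_c = "-", hgvs_p = "-",
    consequence = consequence, zygosity = zygosity, dbsnp = "-",
    cadd_scaled = cadd, maf_exac_nfe = maf_exac, maf_swegen = maf_swe,
    reported_in_affected = reported, functional_evidence = functional,
    conservation_low = cons_low, splice_prediction_affected = splice_hit,
    acmg_class_published = acmg, stringsAsFactors = FALSE))
}
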