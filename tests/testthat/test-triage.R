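test_that("frequency filter excludes on any population above threshold", {
  cfg <- triage_config()
  expect_true(frequency_filter(make_obs(maf_exac = "0.002397"), cfg))
  expect_false(frequency_filter(make_obs(maf_exac = "0.02"), cfg))
  expect_false(frequency_filter(make_obs(maf_exac = "0.0005", maf_swe = "0.02"), cfg))
  expect_true(frequency_filter(make_obs(), cfg))  # all missing: not common
  # exactly 1% is not "> 1%"
  expect_true(frequency_filter(make_obs(maf_exac = "0.01"), cfg))
  # all-must-exceed mode
  cfg2 <- triage_config(any_population_excludes = FALSE)
  expect_true(frequency_filter(make_obs(maf_exac = "0.02", maf_swe = "0.001"), cfg2))
  expect_false(frequency_filter(make_obs(maf_exac = "0.02", maf_swe = "0.03"), cfg2))
  # MAF above 0.5 is not a minor allele frequency
  expect_error(frequency_filter(make_obs(maf_exac = "0.9"), cfg), "0.5")
})

test_that("raising the MAF threshold never excludes a retained variant", {
  set.seed(42)
  mafs <- sprintf("%.6f", runif(50, 0, 0.05))
  obs <- make_obs(50, maf_exac = mafs)
  thresholds <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  prev <- rep(FALSE, 50)
  for (th in thresholds) {
    cur <- frequency_filter(obs, triage_config(maf_exclusion_threshold = th))
    expect_true(all(cur[prev]))  # monotone: once retained, stays retained
    prev <- cur
  }
})

test_that("consequence filter drops synonymous and rescues splice-hit intronic", {
  cf <- consequence_filter(make_obs(consequence = "synonymous"))
  expect_false(cf$pass)
  cf <- consequence_filter(make_obs(consequence = "intronic", splice_hit = "0"))
  expect_false(cf$pass)
  cf <- consequence_filter(make_obs(consequence = "intronic", splice_hit = "1"))
  expect_true(cf$pass)
  expect_equal(cf$consequence, "splice_site")
  expect_true(consequence_filter(make_obs(consequence = "missense"))$pass)
})

test_that("classification follows the LoF/evidence > benign > VUS precedence", {
  # novel nonsense: putative pathogenic, class 4 by the default rule
  tri <- triage(make_obs(consequence = "nonsense"))
  expect_equal(tri$fate, "retained")
  expect_equal(tri$label, "putative_pathogenic")
  expect_equal(tri$acmg_class, "4")
  expect_match(tri$trace, "lof_pathogenic")

  # reported missense with functional evidence: pathogenic, class 3
  tri <- triage(make_obs(reported = "1", functional = "1", maf_exac = "0.000270"))
  expect_equal(tri$label, "putative_pathogenic")
  expect_equal(tri$acmg_class, "3")

  # unsupported missense, low conservation, low CADD: likely benign
  tri <- triage(make_obs(cons_low = "1", cadd = "3.0"))
  expect_equal(tri$label, "likely_benign")

  # benign rule needs BOTH low conservation and low CADD
  tri <- triage(make_obs(cons_low = "0", cadd = "3.0"))
  expect_equal(tri$label, "vus")
  tri <- triage(make_obs(cons_low = "1", cadd = "25"))
  expect_equal(tri$label, "vus")

  # published class overrides the default rule and is traced
  tri <- triage(make_obs(consequence = "nonsense", acmg = "3"))
  expect_equal(tri$acmg_class, "3")
  expect_match(tri$trace, "acmg_published_override")
  tri <- triage(make_obs(consequence = "nonsense", acmg = "3"),
                triage_config(use_published_override = FALSE))
  expect_equal(tri$acmg_class, "4")
})

test_that("every observation gets exactly one fate and consistent label", {
  set.seed(7)
  n <- 200
  obs <- make_obs(
    n,
    consequence = sample(c("missense", "nonsense", "frameshift", "splice_site",
                           "synonymous", "intronic", "other"), n, TRUE),
    maf_exac = sample(c("-", "0.0001", "0.005", "0.02"), n, TRUE),
    maf_swe = sample(c("-", "0.0005", "0.03"), n, TRUE),
    reported = sample(c("0", "1"), n, TRUE),
    functional = sample(c("0", "1"), n, TRUE),
    cons_low = sample(c("0", "1"), n, TRUE),
    cadd = sample(c("2", "15", "30"), n, TRUE),
    splice_hit = sample(c("0", "1"), n, TRUE))
  tri <- triage(obs)
  expect_true(all(tri$fate %in% c("excluded_frequency", "excluded_consequence",
                                  "retained")))
  # excluded => no label, no class
  excl <- tri$fate != "retained"
  expect_true(all(tri$label[excl] == "none"))
  expect_true(all(tri$acmg_class[excl] == "unassigned"))
  # retained => exactly one informative label
  expect_true(all(tri$label[!excl] %in%
                    c("putative_pathogenic", "vus", "likely_benign")))
  # pathogenic => class 3 or 4
  path <- tri$label == "putative_pathogenic"
  expect_true(all(tri$acmg_class[path] %in% c("3", "4")))
  # frequency fate wins over consequence fate (precedence)
  both <- obs$maf_exac_nfe > 0.01 & !is.na(obs$maf_exac_nfe) &
    obs$consequence == "synonymous"
  expect_true(all(tri$fate[both] == "excluded_frequency"))
})

test_that("fixture regression: all rows pathogenic, printed class-4 set", {
  fx <- stillbirth_fixture()
  tri <- triage(fx$observations)
  expect_true(all(tri$fate == "retained"))
  expect_true(all(tri$label == "putative_pathogenic"))
  four <- tri[tri$acmg_class == "4", ]
  expect_setequal(
    paste(four$gene, four$hgvs_c),
    c("DSG2 c.3340C>T", "SCN5A c.1663G>T", "TRPM4 c.1195_1202del",
      "TTN c.25639+1G>T"))
})

test_that("scaled CADD maps to its genome-rank fraction", {
  expect_equal(cadd_rank_fraction(20), 0.01)
  expect_equal(cadd_rank_fraction(30), 0.001)
  expect_equal(cadd_rank_fraction(0), 1)
  expect_equal(cadd_rank_fraction(c(10, 40)), c(0.1, 1e-4))
  expect_error(cadd_rank_fraction(-1), ">= 0")
})
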