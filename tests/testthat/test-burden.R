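test_that("exact test matches the exhaustive enumeration oracle", {
  set.seed(123)
  for (i in 1:200) {
    cl <- random_table(60)
    t <- burden_table(cl[1], cl[2], cl[3], cl[4])
    res <- fisher_exact_two_sided(t)
    expect_equal(res$p_two_sided, oracle_fisher_p(cl[1], cl[2], cl[3], cl[4]),
                 tolerance = 1e-12)
  }
})

test_that("exact test reproduces known tables and edge behaviour", {
  # equal proportions: p = 1 by symmetry
  res <- fisher_exact_two_sided(burden_table(5, 15, 5, 15))
  expect_equal(res$p_two_sided, 1)
  expect_equal(res$odds_ratio, 1)
  # large sparse table
  res <- fisher_exact_two_sided(burden_table(5, 575, 219, 66521, "alleles"))
  expect_equal(res$p_two_sided, 0.0455, tolerance = 1e-3)
  # odds ratio conventions
  expect_equal(fisher_exact_two_sided(burden_table(3, 0, 1, 5))$odds_ratio, Inf)
  expect_true(is.nan(fisher_exact_two_sided(burden_table(0, 3, 0, 5))$odds_ratio))
  # degenerate margins rejected at construction
  expect_error(burden_table(0, 0, 1, 1), "degenerate")
  expect_error(burden_table(1, -1, 1, 1), "non-negative")
})

test_that("upper-tail mass is monotone in the enriched cell", {
  # with the other cells fixed, pushing a above its null expectation only
  # shrinks the probability of seeing something as or more extreme above
  b <- 40; c <- 10; d <- 40
  upper_tail <- function(a) {
    m <- a + b; n <- c + d; k <- a + c
    sum(stats::dhyper(a:min(m, k), m, n, k))
  }
  vals <- vapply(10:20, upper_tail, 0)
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("carrier summary counts distinct cases and categories", {
  fx <- stillbirth_fixture()
  tri <- triage(fx$observations)
  s <- summarize_carriers(tri, fx$panel, 290)
  expect_equal(s$carriers_total, 35)
  expect_equal(s$carriers_one, 31)
  expect_equal(s$carriers_two_plus, 4)
  expect_equal(unname(s$carriers_by_category[["channelopathy"]]), 23)
  expect_equal(unname(s$carriers_by_category[["cardiomyopathy"]]), 15)
  expect_equal(s$dual_category_cases, 3)
  # dual-category consistency
  expect_equal(sum(s$carriers_by_category) - s$dual_category_cases,
               s$carriers_total)
  # conservation: carriers + non-carriers = cohort size
  expect_equal(s$carriers_total + (290 - s$carriers_total), s$cohort_size)
})

test_that("carrier summary edge cases", {
  fx <- stillbirth_fixture()
  empty <- triage(make_obs(0))
  s <- summarize_carriers(empty, fx$panel, 290)
  expect_equal(s$carriers_total, 0)
  expect_equal(sum(s$carriers_by_category), 0)

  # two pathogenic variants in one case, same gene: one carrier, two-plus
  two <- triage(make_obs(2, consequence = "nonsense", case_id = c("A", "A")))
  s <- summarize_carriers(two, fx$panel, 10)
  expect_equal(s$carriers_total, 1)
  expect_equal(s$carriers_two_plus, 1)

  expect_error(summarize_carriers(two, fx$panel, 0), "cohort_size")
})

test_that("expected reference carriers follow the one-carrier assumption", {
  fx <- stillbirth_fixture()
  keys <- unique(fx$observations$key)
  erc <- expected_reference_carriers(keys, fx$references$ExAC_NFE)
  expect_equal(erc$count, 1776)
  expect_equal(erc$proportion, 1776 / 33370, tolerance = 1e-12)
  # each distinct variant counted once however many cases carry it
  erc2 <- expected_reference_carriers(fx$observations$key,
                                      fx$references$ExAC_NFE)
  expect_equal(erc2$count, erc$count)
  # hand arithmetic: MAFs 0.001 + 0.002 over 2000 alleles -> 6 carriers
  ref <- reference_population("toy", 1000,
                              c("chr1:1:A:C" = 0.001, "chr1:2:A:C" = 0.002))
  expect_equal(expected_reference_carriers(names(ref$maf), ref)$count, 6)
  # empty set, and capping at the population size
  expect_equal(expected_reference_carriers(character(0), ref)$count, 0)
  ref2 <- reference_population("sat", 5, c("chr1:1:A:C" = 0.5, "chr1:2:A:C" = 0.5))
  expect_equal(expected_reference_carriers(names(ref2$maf), ref2)$count, 5)
})

test_that("cohort MAF applies the zygosity allele rule", {
  fx <- stillbirth_fixture()
  obs <- fx$observations
  gp <- obs[obs$gene == "GPD1L", ]
  expect_equal(cohort_maf(gp, 290), 4 / 580)
  hom <- obs[obs$zygosity == "homozygous", ]
  expect_equal(cohort_maf(hom, 290), 2 / 580)
  expect_equal(cohort_maf(obs[0, ], 290), 0)
  expect_error(cohort_maf(obs, 290), "single variant key")
  expect_error(cohort_maf(hom, 0), "exceeds")
})

test_that("category burden tests reproduce the published comparisons", {
  fx <- stillbirth_fixture()
  tri <- triage(fx$observations)
  s <- summarize_carriers(tri, fx$panel, 290)
  # all genes vs the MAF-derived expected carrier count
  erc <- expected_reference_carriers(unique(tri$key), fx$references$ExAC_NFE)
  t_all <- carrier_burden_test(s, "all", erc$count, 33370)
  expect_lt(t_all$p_two_sided, 0.001)
  # channelopathy genes vs the published SweGen carrier count
  t_chan <- carrier_burden_test(s, "channelopathy", 23, 1000)
  expect_lt(t_chan$p_two_sided, 0.001)
  # cardiomyopathy genes vs SweGen: not significant
  t_card <- carrier_burden_test(s, "cardiomyopathy", 28, 1000)
  expect_equal(t_card$p_two_sided, 0.061, tolerance = 1e-2)
  # equal-rate synthetic table
  s0 <- s; s0$carriers_total <- 29L; s0$cohort_size <- 290L
  expect_equal(carrier_burden_test(s0, "all", 100, 1000)$p_two_sided, 1)
  expect_error(carrier_burden_test(s, "all", 11, 10), "exceeds")
})

test_that("gene-wide allele burden reproduces the KCNQ1 comparison", {
  fx <- stillbirth_fixture()
  tri <- triage(fx$observations)
  res <- gene_allele_burden("KCNQ1", tri, 290, 219, fx$references$ExAC_NFE)
  expect_equal(res$table$a, 5)               # 5/580 = 0.86% cohort alleles
  expect_equal(res$table$a + res$table$b, 580)
  expect_equal(res$table$c, 219)             # 219/66740 = 0.33% reference
  expect_equal(res$p_two_sided, 0.0455, tolerance = 1e-3)
  # gene with no cohort alleles and no reference alleles: nothing to compare
  expect_error(gene_allele_burden("AKAP9", tri, 290, 0, fx$references$ExAC_NFE),
               "degenerate")
})

test_that("variant-level MAF test reproduces the GPD1L comparison", {
  fx <- stillbirth_fixture()
  obs <- fx$observations
  gp <- obs[obs$gene == "GPD1L", ]
  res <- variant_maf_test(gp$key[1], gp, 290, fx$references$ExAC_NFE)
  expect_equal(res$table$c, 160)  # round(0.002397 * 66740)
  expect_equal(res$p_two_sided, 0.0542, tolerance = 1e-3)
  expect_error(variant_maf_test("chr9:9:A:C", gp, 290, fx$references$ExAC_NFE),
               "absent")
  # equal cohort and reference MAF on a small synthetic table -> p = 1
  ref <- reference_population("toy", 100, c("chr1:1001:A:G" = 0.01))
  one <- make_obs(1, case_id = "C1")
  expect_equal(variant_maf_test(one$key, one, 50, ref)$p_two_sided, 1)
  # small tables agree with the enumeration oracle
  set.seed(5)
  for (i in 1:20) {
    n_cases <- sample(5:15, 1)
    carriers <- sample(0:3, 1)
    ref_n <- sample(10:20, 1)
    maf <- sample(1:5, 1) / (2 * ref_n)
    ref <- reference_population("t", ref_n, c("chr1:1001:A:G" = maf))
    o <- if (carriers > 0) make_obs(carriers, case_id = paste0("C", 1:carriers))
         else make_obs(0)
    o$key <- rep(variant_key("chr1", 1001, "A", "G"), nrow(o))
    res <- variant_maf_test("chr1:1001:A:G", o, n_cases, ref)
    tt <- res$table
    expect_equal(res$p_two_sided, oracle_fisher_p(tt$a, tt$b, tt$c, tt$d),
                 tolerance = 1e-12)
  }
})

test_that("case_table keeps the first occurrence of each case", {
  fx <- stillbirth_fixture()
  ct <- case_table(fx$observations)
  expect_equal(nrow(ct), 35)
  # a case recorded twice with discrepant gestational ages resolves to its
  # first row
  expect_equal(ct$ga[ct$case_id == "286"], "41+1")
  # carrier demographics feed the exact sex comparison
  res <- compare_demographics(ct, ct, test = "fisher")
  expect_equal(res$p_two_sided, 1)
})

test_that("demographic comparisons: chi-square binning and exact sex test", {
  all_cases <- data.frame(
    ga = c(rep("23+0", 100), rep("30+0", 200), rep("38+0", 100)),
    sex = rep(c("XX", "XY"), 200))
  # identical distribution: statistic 0, p = 1
  res <- compare_demographics(all_cases, all_cases,
                              ga_breaks = c(22, 28, 33, 43), test = "chi2")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # hand-computed 3-bin case: O = (15,15,10) vs E = (10,20,10) -> 3.75, df 2
  carriers <- data.frame(
    ga = c(rep("23+0", 15), rep("30+0", 15), rep("38+0", 10)),
    sex = rep("XX", 40))
  res <- compare_demographics(carriers, all_cases,
                              ga_breaks = c(22, 28, 33, 43), test = "chi2")
  expect_equal(res$statistic, 3.75)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 0.1534, tolerance = 1e-3)  # textbook chi2(2) tail
  # empty expected bin advises merging
  expect_error(compare_demographics(carriers, all_cases,
                                    ga_breaks = c(22, 28, 33, 41, 43),
                                    test = "chi2"),
               "merge")
  # sex with equal proportions: p = 1
  res <- compare_demographics(all_cases[1:40, ], all_cases, test = "fisher")
  expect_equal(res$p_two_sided, 1)
})
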