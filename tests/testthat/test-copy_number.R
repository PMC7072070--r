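test_that("depth expectations scale with repeat-unit multiplicity", {
  geom <- depth_geometry(scale = 0.1)
  set.seed(10)
  ratios <- vapply(c("A/A", "AG/AG", "AGG/AGG"), function(k) {
    # average the estimate over profiles to beat the sampling noise
    mean(vapply(1:30, function(i) {
      prof <- simulate_depth(parse_genotype(k), geom, mean_coverage = 25)
      call_cnv_from_depth(prof)$estimate
    }, numeric(1)))
  }, numeric(1))
  expect_equal(unname(ratios[, drop = TRUE]), c(1, 2, 3), tolerance = 0.05)
  # monotone in unit count
  expect_true(all(diff(ratios) > 0))
})

test_that("the depth caller is exact on constant profiles and validates inputs", {
  geom <- depth_geometry(scale = 0.1)
  set.seed(11)
  prof <- simulate_depth(parse_genotype("A/A"), geom)
  prof$count <- 50L
  res <- call_cnv_from_depth(prof)
  expect_equal(res$estimate, 1)
  expect_equal(res$call, 1)
  prof$count <- 0L
  expect_error(call_cnv_from_depth(prof), "reference coverage absent")
  few <- prof[1:8, ]
  expect_error(call_cnv_from_depth(few, attr(prof, "cnv_interval")),
               "at least 5")
  expect_error(call_cnv_from_depth(prof, cnv_interval = NULL),
               "must be supplied")
})

test_that("boundary-straddling windows are excluded from the ratio", {
  geom <- depth_geometry(flank5 = 1025, cnv_length = 3000, flank3 = 1000,
                         window = 50)
  set.seed(12)
  prof <- simulate_depth(parse_genotype("AG/AG"), geom, mean_coverage = 30)
  res <- call_cnv_from_depth(prof)
  n_windows <- nrow(prof)
  expect_lt(res$n_windows_cnv + res$n_windows_flank, n_windows)
})

test_that("qPCR Ct simulation encodes template dosage and no-amplification", {
  # deterministic limit: Ct differences equal log2 template ratios
  set.seed(13)
  ct <- simulate_qpcr(genotype("AG", "A"), noise_sd = 0)
  ct_of <- function(a) unique(ct$ct[ct$amplicon == a])
  expect_equal(ct_of("BCAT1_8") - ct_of("CsACS1"), log2(3 / 2))
  expect_equal(ct_of("BCAT1_8") - ct_of("CsMYB"), log2(3 / 2))
  # junction amplicon counts G units only: 1 per diploid here
  expect_equal(ct_of("BCAT1_8") - ct_of("F_junction"), log2(1 / 2))
  # triple-repeat homozygote: junction template 4 per diploid -> Ct base - 1
  ct3 <- simulate_qpcr(am297(), noise_sd = 0, base_ct = 25)
  expect_equal(unique(ct3$ct[ct3$amplicon == "F_junction"]), 24)
  # monecious: no junction amplification
  ct0 <- simulate_qpcr(line9930(), noise_sd = 0)
  expect_true(all(is.na(ct0$ct[ct0$amplicon == "F_junction"])))
})

test_that("qPCR copy estimation recovers template ratios exactly at sigma = 0", {
  set.seed(14)
  for (k in c("A/A", "AG/A", "AG/AG", "AGG/AGG")) {
    g <- parse_genotype(k)
    est <- estimate_copy_qpcr(simulate_qpcr(g, noise_sd = 0))
    expected <- c(CsACS1 = (n_units(g$hap1) + n_units(g$hap2)) / 2,
                  F_junction = g_dosage(g) / 2)
    expect_equal(est$copies[est$amplicon == "CsACS1"],
                 unname(expected["CsACS1"]))
    expect_equal(est$copies[est$amplicon == "F_junction"],
                 unname(expected["F_junction"]))
  }
})

test_that("junction copy calls map 0 / 1 / 2 across the three line classes", {
  set.seed(15)
  calls <- vapply(c("A/A", "AG/AG", "AGG/AGG"), function(k) {
    est <- estimate_copy_qpcr(simulate_qpcr(parse_genotype(k)))
    est$call[est$amplicon == "F_junction"]
  }, numeric(1))
  expect_equal(unname(calls), c(0, 1, 2))
})

test_that("qPCR estimation validates the reference amplicon", {
  set.seed(16)
  ct <- simulate_qpcr(gy14(), amplicons = c("CsACS1", "CsMYB"))
  expect_error(estimate_copy_qpcr(ct), "reference amplicon")
  ct2 <- simulate_qpcr(gy14(), k = 2)
  expect_error(estimate_copy_qpcr(ct2), "at least 3 replicates")
})

test_that("delta-delta-Ct recovers fold changes and the calibrator is 1", {
  fold <- matrix(c(1, 0.25, 1, 1), 2, 2,
                 dimnames = list(c("wt", "mut"), c("gene_dn", "gene_same")))
  set.seed(17)
  ct <- simulate_expression_ct(fold, bio_sd = 0.05, tech_sd = 0.02)
  re <- relative_expression(ct, calibrator_sample = "wt")
  mut_dn <- re$fold[re$sample_id == "mut" & re$amplicon == "gene_dn"]
  mut_same <- re$fold[re$sample_id == "mut" & re$amplicon == "gene_same"]
  expect_equal(mean(mut_dn), 0.25, tolerance = 0.15)
  expect_equal(mean(mut_same), 1, tolerance = 0.15)
  wt <- re$fold[re$sample_id == "wt" & re$amplicon == "gene_dn"]
  expect_equal(mean(wt), 1, tolerance = 0.15)
  # noise-free folds are exact and the calibrator mean is exactly 1
  ct0 <- simulate_expression_ct(fold, bio_sd = 0, tech_sd = 0)
  re0 <- relative_expression(ct0, calibrator_sample = "wt")
  expect_equal(unique(re0$fold[re0$sample_id == "mut" &
                               re0$amplicon == "gene_dn"]), 0.25)
  expect_error(relative_expression(ct, calibrator_sample = "nope"),
               "calibrator")
})
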