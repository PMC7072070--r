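test_that("scenario bundles are byte-identical per seed", {
  cfg <- scenario_config("fig3_qpcr_panel", seed = 101)
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_scenario(cfg, d1)
  generate_scenario(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
  expect_error(scenario_config("fig3_qpcr_panel"), "seed")
  expect_error(scenario_config("unknown_scenario", seed = 1))
})

test_that("depth scenario truths are recovered by the CNV caller", {
  cfg <- scenario_config("fig1_depth", seed = 7)
  dir <- file.path(tempdir(), "fig1")
  unlink(dir, recursive = TRUE)
  b <- generate_scenario(cfg, dir)
  truth <- truth_report(b)
  expect_equal(sort(truth$samples$expected_ratio), c(1, 1, 1, 2, 2, 2))
  for (r in seq_len(nrow(truth$samples))) {
    prof <- b$profiles[[truth$samples$sample_id[r]]]
    call <- call_cnv_from_depth(prof)
    expect_equal(call$call, truth$samples$expected_ratio[r],
                 label = truth$samples$sample_id[r])
  }
  # reading the truth back from disk matches the in-memory object
  disk <- truth_report(dir)
  expect_equal(disk$samples$expected_ratio, truth$samples$expected_ratio)
  # locus artifacts for the three structural classes are in the bundle
  expect_true(all(c("monecious_locus.fasta", "gynoecious_locus.gff3",
                    "triple_units.bed") %in% basename(b$files)))
  unlink(dir, recursive = TRUE)
})

test_that("the 30-line qPCR panel recovers 1 / 1.5 / 2 / 3 copy classes", {
  cfg <- scenario_config("fig3_qpcr_panel", seed = 3)
  dir <- file.path(tempdir(), "fig3")
  unlink(dir, recursive = TRUE)
  b <- generate_scenario(cfg, dir)
  est <- estimate_copy_qpcr(b$ct)
  acs1 <- est[est$amplicon == "CsACS1", ]
  merged <- merge(acs1, b$panel, by = "sample_id")
  expect_equal(nrow(merged), 30L)
  expect_true(mean(merged$call == merged$expected_copies) >= 0.9)
  # the single triple-repeat line reads 3 copies
  expect_equal(merged$call[merged$sample_id == "G14_AM297"], 3)
  unlink(dir, recursive = TRUE)
})

test_that("expression scenario: CsACS1/CsACS2 down, CsMYB unchanged", {
  cfg <- scenario_config("fig5_expression", seed = 5)
  dir <- file.path(tempdir(), "fig5")
  unlink(dir, recursive = TRUE)
  b <- generate_scenario(cfg, dir)
  truth <- truth_report(b)
  expect_setequal(truth$down_regulated, c("CsACS1", "CsACS2"))
  re <- relative_expression(b$ct, calibrator_sample = truth$calibrator)
  wt_fold <- function(gene) re$fold[re$sample_id == "Gy14" &
                                    re$amplicon == gene]
  mut_fold <- function(gene) re$fold[re$sample_id != "Gy14" &
                                     re$amplicon == gene]
  tt_dn <- welch_t(wt_fold("CsACS1"), mut_fold("CsACS1"))
  expect_true(tt_dn$significant_at[["0.01"]])
  tt_same <- welch_t(wt_fold("CsMYB"), mut_fold("CsMYB"))
  expect_false(tt_same$significant_at[["0.01"]])
  expect_lt(mean(mut_fold("CsACS2")), 0.5)
  unlink(dir, recursive = TRUE)
})

test_that("screen scenario tags transient plants and confirms true mutants", {
  cfg <- scenario_config("gy14_screen", seed = 9)
  dir <- file.path(tempdir(), "screen")
  unlink(dir, recursive = TRUE)
  b <- generate_scenario(cfg, dir)
  truth <- truth_report(b)
  expect_equal(truth$n_plants, 2236)
  # tagged plants far outnumber confirmed mutants (66 vs 3 in the screen)
  expect_gt(truth$n_tagged, truth$n_confirmed)
  expect_gt(truth$n_tagged, 30)
  # every confirmable plant is a true non-G plant
  conf <- b$confirmed
  expect_true(all(conf$true_phenotype[conf$confirmed] != "G"))
  # the population file round-trips
  pop <- utils::read.delim(file.path(dir, "population.tsv"))
  expect_equal(nrow(pop), 2236)
  expect_equal(sum(pop$observed_tagged), truth$n_tagged)
  unlink(dir, recursive = TRUE)
})

test_that("table of crosses reproduces the expected phenotype distributions", {
  cfg <- scenario_config("table1_crosses", seed = 13)
  dir <- file.path(tempdir(), "tab1")
  unlink(dir, recursive = TRUE)
  b <- generate_scenario(cfg, dir)
  sim <- b$simulated
  # uniform rows are simulated as uniform
  gy_f1 <- sim[sim$population == "(Gy14 x 9930) F1", ]
  expect_equal(gy_f1$p_SubG, 1)
  expect_equal(gy_f1$sim_SubG, 16)
  am_f2 <- sim[sim$population == "(AM297 x 9930) F2", ]
  expect_equal(am_f2$p_SubG, 0)
  expect_equal(am_f2$p_G, 0.75)
  expect_equal(am_f2$sim_SubG, 0)
  unlink(dir, recursive = TRUE)
})

test_that("the printed segregation table is internally consistent", {
  tab <- table1_observed()
  expect_equal(nrow(tab), 15L)
  counted <- tab[!is.na(tab$n_M) & tab$population != "Gy14" &
                 tab$population != "G06", ]
  expect_true(all(counted$n_G + counted$n_SubG + counted$n_M == counted$n))
  # the screens' printed G counts exclude the tagged plants
  gy <- tab[tab$population == "Gy14", ]
  expect_equal(gy$n - (gy$n_G + gy$n_SubG + gy$n_M), 63L)
})
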