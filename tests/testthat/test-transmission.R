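test_that("dosage maps genotypes to the published sex classes", {
  expect_equal(dosage_phenotype(line9930()), "M")
  expect_equal(dosage_phenotype(genotype("AG", "A")), "SubG")
  expect_equal(dosage_phenotype(gy14()), "G")
  expect_equal(dosage_phenotype(genotype("AGG", "A")), "G")
  expect_equal(dosage_phenotype(am297()), "G")
})

test_that("UCO on the two-unit homozygote yields the reciprocal deletion and duplication", {
  # force UCO by setting the rate to 1
  p <- uco_params(uco_rate = 1)
  set.seed(1)
  gam <- replicate(400, simulate_meiosis(gy14(), p), simplify = FALSE)
  keys <- vapply(gam, function(g) paste(g$haplotype$units, collapse = ""),
                 character(1))
  origins <- vapply(gam, `[[`, character(1), "origin")
  expect_setequal(unique(keys), c("A", "AGG"))
  expect_equal(unname(origins[keys == "A"][1]), "uco_deletion")
  expect_equal(unname(origins[keys == "AGG"][1]), "uco_duplication")
  # reciprocal frequencies are symmetric
  expect_gt(mean(keys == "A"), 0.4)
  expect_lt(mean(keys == "A"), 0.6)
})

test_that("single-unit homozygotes have no misaligned register", {
  p <- uco_params(uco_rate = 1)  # even at rate 1, no UCO is possible
  set.seed(2)
  keys <- replicate(50, paste(simulate_meiosis(line9930(), p)$haplotype$units,
                              collapse = ""))
  expect_true(all(keys == "A"))
  d <- enumerate_gametes(line9930(), p)
  expect_equal(d$haplotype, "A")
  expect_equal(d$prob, 1)
})

test_that("gamete enumeration matches the published examples and the brute-force oracle", {
  # Mendelian segregation of the heterozygote at mu = 0
  d <- enumerate_gametes(genotype("AG", "A"), uco_params(0))
  expect_equal(gamete_prob(d, "AG"), 0.5)
  expect_equal(gamete_prob(d, "A"), 0.5)
  d <- enumerate_gametes(gy14(), uco_params(0))
  expect_equal(d$haplotype, "AG")
  # small UCO rate splits mass between the reciprocal products
  d <- enumerate_gametes(gy14(), uco_params(0.001))
  expect_equal(gamete_prob(d, "AG"), 0.999)
  expect_equal(gamete_prob(d, "A"), 0.0005)
  expect_equal(gamete_prob(d, "AGG"), 0.0005)

  # brute-force register enumeration agrees on assorted genotypes
  cases <- list(genotype("AG", "AG"), genotype("AGG", "A"),
                genotype("AGG", "AGG"), genotype("AGG", "AG"),
                genotype("AGGG", "AG"))
  for (g in cases) {
    got <- enumerate_gametes(g, uco_params(0.01))
    want <- brute_gametes(g, 0.01)
    expect_equal(sum(got$prob), 1)
    for (k in want$haplotype) {
      expect_equal(gamete_prob(got, k), gamete_prob(want, k),
                   info = paste("haplotype", k))
    }
  }
})

test_that("forced UCO on the triple-repeat homozygote gives 2- and 4-unit reciprocals", {
  d <- enumerate_gametes(am297(), uco_params(1))
  lens <- nchar(d$haplotype[d$prob > 0])
  expect_setequal(sort(unique(lens)), c(2L, 4L))
})

test_that("reciprocal gametes conserve total unit count (all genotypes to 4 units)", {
  units <- list("A", "G", "AG", "GG", "AGG", "AGGG")
  for (a in units) for (b in units) {
    g <- genotype(a, b)
    n_tot <- n_units(g$hap1) + n_units(g$hap2)
    # reciprocal conservation implies the exact gamete distribution has mean
    # unit count n_tot / 2, at any UCO rate
    for (mu in c(0.2, 1)) {
      d <- enumerate_gametes(g, uco_params(mu))
      expect_equal(sum(nchar(d$haplotype) * d$prob), n_tot / 2,
                   info = paste(a, b, mu))
    }
  }
})

test_that("simulated meioses match the exact distribution within 4-sigma", {
  g <- genotype("AGG", "AG")
  p <- uco_params(uco_rate = 0.05)
  n <- 20000
  set.seed(4)
  keys <- vapply(seq_len(n), function(i) {
    paste(simulate_meiosis(g, p)$haplotype$units, collapse = "")
  }, character(1))
  d <- enumerate_gametes(g, p)
  for (r in seq_len(nrow(d))) {
    obs <- mean(keys == d$haplotype[r])
    se <- sqrt(d$prob[r] * (1 - d$prob[r]) / n)
    expect_lt(abs(obs - d$prob[r]), 4 * se + 1e-12,
              label = paste("freq of", d$haplotype[r]))
  }
})

test_that("crosses reproduce the dosage-model segregation ratios", {
  p0 <- uco_params(0)
  # selfed heterozygote: 1 G : 2 SubG : 1 M
  cr <- cross(genotype("AG", "A"), genotype("AG", "A"), p0)
  expect_equal(unname(cr$phenotypes[c("G", "SubG", "M")]),
               c(0.25, 0.5, 0.25))
  # selfed [A,G,G]/[A]: 3 G : 1 M with zero SubG
  cr <- cross(genotype("AGG", "A"), genotype("AGG", "A"), p0)
  expect_equal(unname(cr$phenotypes[c("G", "SubG", "M")]),
               c(0.75, 0, 0.25))
  # Gy14-like x monecious F1 is uniformly SubG
  cr <- cross(gy14(), line9930(), p0)
  expect_equal(unname(cr$phenotypes["SubG"]), 1)
  # swap invariance is exact
  a <- cross(gy14(), line9930(), p0)
  b <- cross(line9930(), gy14(), p0)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("selfed homozygote populations are pure at mu = 0", {
  set.seed(5)
  pop <- self_population(gy14(), 300, generations = 2, p = uco_params(0))
  expect_true(all(pop$true_phenotype == "G"))
  pop <- self_population(line9930(), 300, generations = 2,
                         p = uco_params(0.05))
  expect_true(all(pop$true_phenotype == "M"))
})

test_that("progeny testing confirms true heterozygotes and rejects tagged G plants", {
  p0 <- uco_params(0)
  pop <- data.frame(plant_id = 1:2,
                    genotype = c("AG/A", "AG/AG"),
                    true_phenotype = c("SubG", "G"),
                    observed_tagged = c(TRUE, TRUE),
                    generation = 1L)
  set.seed(6)
  conf <- confirm_mutants(pop, progeny_size = 40, p = p0)
  expect_true(conf$confirmed[conf$genotype == "AG/A"])
  expect_false(conf$confirmed[conf$genotype == "AG/AG"])
  expect_equal(conf$stable_m_line[conf$genotype == "AG/A"], "A/A")
  expect_warning(confirm_mutants(pop, progeny_size = 5, p = p0),
                 "low power")
  # a stable monecious derived line stays monecious over many selfings
  line <- parse_genotype("A/A")
  for (gen in 1:6) {
    cr <- cross(line, line, uco_params(1.25e-3))
    expect_equal(unname(cr$phenotypes["M"]), 1)
    line <- parse_genotype(cr$genotypes$genotype[1])
  }
})
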