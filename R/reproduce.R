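#' Reproduce the study's printed quantities from synthetic inputs
#'
#' Runs every stage end to end on generated inputs and reports each quantity
#' against its stored expectation: the gynoecy-loss mutation rates, the
#' segregation chi-square p-values of the printed F2 counts, the expected sex
#' expression of every line and cross (including the all-gynoecious F1 and
#' SubG-free F2 of the triple-repeat x monecious cross), the recombinant
#' promoter arithmetic, the junction in-silico PCR products, and the recovery
#' of copy-number truths by the qPCR and read-depth estimators.
#'
#' @param out_dir directory for `report.tsv` and `report.json` (`NULL` to
#'   skip writing).
#' @param seed integer seed for the stochastic stages.
#' @param qpcr_trials seeded trials per genotype for the qPCR recovery
#'   summary.
#' @param depth_seeds replicate profiles for the depth-ratio summary.
#' @param scale locus scale factor for sequence-level checks.
#' @return data.frame with columns `check`, `value`, `expected`, `tol`,
#'   `pass`.
#' @export
reproduce_paper <- function(out_dir = NULL, seed = 1L, qpcr_trials = 100L,
                            depth_seeds = 20L, scale = 0.1) {
  rows <- list()
  add <- function(check, value, expected, tol = 0) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, value = value, expected = expected, tol = tol,
      pass = is.finite(value) && abs(value - expected) <= tol,
      stringsAsFactors = FALSE)
  }

  # mutation rates from the printed screen counts
  add("gy14_rate_percent", mutation_rate(3, 2236)$percent, 0.13)
  add("g06_rate_percent", mutation_rate(3, 2573)$percent, 0.11)
  add("pooled_rate_percent", mutation_rate(6, 4809)$percent, 0.12)

  # chi-square tests on the printed F2 counts
  add("gy14_f2_chisq_p", chisq_gof(c(47, 98, 55), c(1, 2, 1))$p_value,
      0.6976, tol = 2e-4)
  add("am297_f2_chisq_p", chisq_gof(c(735, 265), c(3, 1))$p_value,
      0.2733, tol = 5e-5)

  # promoter arithmetic
  prom <- build_recombinant_promoter()
  add("recombinant_promoter_bp", prom$total_length, 1504)
  add("intron8_missing_tail_bp", prom$missing_tail, 56)

  # expected sex expression of every table row at mu = 0
  p0 <- uco_params(0)
  tab <- table1_observed()
  exp_map <- c(M = "M", SubG = "SubG", G = "G")
  n_ok <- 0L
  for (r in seq_len(nrow(tab))) {
    parents <- strsplit(tab$parents[r], "|", fixed = TRUE)[[1]]
    cr <- cross(parse_genotype(parents[1]), parse_genotype(parents[2]), p0)
    if (tab$f1_selfed[r]) {
      f1 <- parse_genotype(cr$genotypes$genotype[which.max(cr$genotypes$prob)])
      cr <- cross(f1, f1, p0)
    }
    exp_sex <- tab$expected_sex[r]
    ok <- if (exp_sex %in% names(exp_map)) {
      cr$phenotypes[exp_sex] == 1
    } else if (grepl("1G:2SubG:1M", exp_sex)) {
      isTRUE(all.equal(unname(cr$phenotypes[c("G", "SubG", "M")]),
                       c(0.25, 0.5, 0.25)))
    } else {
      isTRUE(all.equal(unname(cr$phenotypes[c("G", "SubG", "M")]),
                       c(0.75, 0, 0.25)))
    }
    n_ok <- n_ok + ok
  }
  add("table1_expected_sex_rows_ok", n_ok, nrow(tab))
  am297_f1 <- cross(build_line_structure("triple_AM297_like"),
                    build_line_structure("monecious_9930_like"), p0)
  add("AM297xM_F1_G_fraction", unname(am297_f1$phenotypes["G"]), 1)
  f1 <- parse_genotype(am297_f1$genotypes$genotype[1])
  add("AM297xM_F2_SubG_expected",
      unname(cross(f1, f1, p0)$phenotypes["SubG"]), 0)

  # junction in-silico PCR on the three structural classes
  params <- locus_params(scale = scale, seed = seed)
  primers <- junction_primer_pair(params)
  pcr_products <- function(units) {
    loc <- assemble_locus_sequence(haplotype(units), params)
    suppressMessages(insilico_pcr(loc, primers))
  }
  add("junction_products_monecious", nrow(pcr_products("A")), 0)
  gy <- pcr_products("AG")
  add("junction_products_gynoecious", nrow(gy), 1)
  add("junction_amplicon_bp",
      if (nrow(gy)) gy$product_length[1] else NA_real_, 111)
  add("junction_products_triple", nrow(pcr_products("AGG")), 2)

  # copy-number recovery: modal qPCR rounded call per copy class, and the
  # depth ratio
  with_seed(seed, {
    genos <- c(`1` = "A/A", `1.5` = "AG/A", `2` = "AG/AG", `3` = "AGG/AGG")
    for (i in seq_along(genos)) {
      g <- parse_genotype(genos[i])
      target <- as.numeric(names(genos)[i])
      calls <- vapply(seq_len(qpcr_trials), function(t) {
        est <- estimate_copy_qpcr(
          simulate_qpcr(g, amplicons = c("CsACS1", "BCAT1_8")))
        est$call[est$amplicon == "CsACS1"]
      }, numeric(1))
      modal <- as.numeric(names(which.max(table(calls))))
      add(sprintf("qpcr_modal_call_%s_copies", names(genos)[i]),
          modal, target)
    }
    gy14 <- parse_genotype("AG/AG")
    ratios <- vapply(seq_len(depth_seeds), function(t) {
      call_cnv_from_depth(simulate_depth(gy14, mean_coverage = 20))$estimate
    }, numeric(1))
    add("depth_ratio_gynoecious", mean(ratios), 2, tol = 0.1)
  })

  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(report, file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}
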