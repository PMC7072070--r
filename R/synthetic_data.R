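#' Printed segregation table of the reference lines and crosses
#'
#' Observed sex-expression counts for the gynoecy-loss screens, reference
#' lines, and the F1/F2 generations of crosses among the two-unit gynoecious
#' line (Gy14), the triple-repeat line (AM297), the monecious testers (9930,
#' XTMC, S52) and the stable monecious mutant Gy14M-17. These printed counts
#' are inputs to the segregation statistics. The screens' G counts exclude
#' the transiently tagged plants; the Gy14M-17 x 9930 F1 row is recorded
#' qualitatively (its printed counts are internally inconsistent) with the
#' all-monecious expectation.
#'
#' @return data.frame with one row per population: `population`, `parents`
#'   (`"key1|key2"` genotype keys, `NA` for inbred lines scored as-is),
#'   `f1_selfed` (`TRUE` for F2 populations), `csacs1g_copies`,
#'   `expected_sex`, `n`, `n_G`, `n_SubG`, `n_M`, `ratio`, `p_printed`.
#' @export
table1_observed <- function() {
  row <- function(population, parents, f2, copies, expected, n, G, SubG, M,
                  ratio = NA_character_, p = NA_real_) {
    data.frame(population = population, parents = parents, f1_selfed = f2,
               csacs1g_copies = copies, expected_sex = expected,
               n = n, n_G = G, n_SubG = SubG, n_M = M,
               ratio = ratio, p_printed = p, stringsAsFactors = FALSE)
  }
  rbind(
    row("Gy14", "AG/AG|AG/AG", FALSE, "2", "G", 2236L, 2170L, 0L, 3L),
    row("G06", "AG/AG|AG/AG", FALSE, "2", "G", 2573L, 2537L, 0L, 3L),
    row("9930", "A/A|A/A", FALSE, "0", "M", 20L, 0L, 0L, 20L),
    row("S52", "A/A|A/A", FALSE, "0", "M", 20L, 0L, 0L, 20L),
    row("XTMC", "A/A|A/A", FALSE, "0", "M", 20L, 0L, 0L, 20L),
    row("AM297", "AGG/AGG|AGG/AGG", FALSE, "4", "G", 20L, 20L, 0L, 0L),
    row("(Gy14 x 9930) F1", "AG/AG|A/A", FALSE, "1", "SubG",
        16L, 1L, 15L, 0L),
    row("(Gy14 x XTMC) F1", "AG/AG|A/A", FALSE, "1", "SubG",
        16L, 2L, 14L, 0L),
    row("(Gy14 x S52) F1", "AG/AG|A/A", FALSE, "1", "SubG",
        16L, 0L, 16L, 0L),
    row("(Gy14 x 9930) F2", "AG/AG|A/A", TRUE, "0,1,2",
        "Segregating 1G:2SubG:1M", 200L, 47L, 98L, 55L, "1:2:1", 0.6976),
    row("(AM297 x 9930) F1", "AGG/AGG|A/A", FALSE, "2", "G",
        16L, 16L, 0L, 0L),
    row("(AM297 x XTMC) F1", "AGG/AGG|A/A", FALSE, "2", "G",
        16L, 16L, 0L, 0L),
    row("(AM297 x S52) F1", "AGG/AGG|A/A", FALSE, "2", "G",
        16L, 16L, 0L, 0L),
    row("(AM297 x 9930) F2", "AGG/AGG|A/A", TRUE, "0,2,4",
        "Segregating 3G:1M", 1000L, 735L, 0L, 265L, "3:1", 0.2733),
    row("(Gy14M-17 x 9930) F1", "A/A|A/A", FALSE, "0", "M",
        14L, 0L, 0L, NA_integer_)
  )
}

#' Scenario configuration for the synthetic-data generator
#'
#' Named scenarios emulate the study's data sets: the two gynoecy-loss
#' screens (`gy14_screen`: 2236 plants, two prior selfing generations, 66
#' tagged of which 3 confirm; `g06_screen`: 2573 plants), the segregation
#' table of crosses (`table1_crosses`), the six resequencing depth profiles
#' (`fig1_depth`: three gynoecious at CNV/flank ratio 2, three monecious at
#' 1), the 30-line genomic qPCR panel (`fig3_qpcr_panel`: 5 hermaphroditic +
#' 13 gynoecious at 2 copies, 1 triple-repeat line at 3, 8 monecious at 1, 3
#' subgynoecious F1 at 1.5), and the expression comparison of the mutant
#' lines (`fig5_expression`: CsACS1 and CsACS2 knocked down, CsMYB
#' unchanged).
#'
#' @param scenario scenario name.
#' @param seed mandatory integer seed.
#' @param scale locus scale factor (copy-number and segregation truths are
#'   scale-invariant).
#' @param uco_rate per-meiosis UCO rate for screen scenarios.
#' @param p_transient spurious tagging rate on true-G plants (default
#'   63/2236, the screens' tagged-minus-confirmed fraction; a noise
#'   parameter, never an acceptance quantity).
#' @param ct_sd Ct noise (cycles).
#' @param coverage_range fold-coverage range for depth profiles.
#' @param knockdown_fold true expression fold of down-regulated genes in
#'   `fig5_expression`.
#' @param progeny_size confirmation progeny per tagged plant.
#' @return a list of class `flocus_scenario_config`.
#' @export
scenario_config <- function(scenario = c("gy14_screen", "g06_screen",
                                         "table1_crosses", "fig1_depth",
                                         "fig3_qpcr_panel",
                                         "fig5_expression"),
                            seed,
                            scale = 0.1,
                            uco_rate = 1.25e-3,
                            p_transient = 63 / 2236,
                            ct_sd = 0.15,
                            coverage_range = c(15, 30),
                            knockdown_fold = 0.25,
                            progeny_size = 20L) {
  scenario <- match.arg(scenario)
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory")
  stopifnot(p_transient >= 0, p_transient <= 1, ct_sd >= 0,
            uco_rate >= 0, uco_rate <= 1)
  structure(list(scenario = scenario, seed = as.integer(seed), scale = scale,
                 uco_rate = uco_rate, p_transient = p_transient,
                 ct_sd = ct_sd, coverage_range = coverage_range,
                 knockdown_fold = knockdown_fold,
                 progeny_size = as.integer(progeny_size)),
            class = "flocus_scenario_config")
}

#' Simulate an expression qPCR Ct table
#'
#' Biological replicates shift the per-gene Ct by normal noise `bio_sd`;
#' technical replicates add `tech_sd` on top. True expression enters as
#' `Ct = base_ct - log_E(fold)`, with the reference gene at fold 1 in every
#' sample.
#'
#' @param fold matrix of true fold changes, samples x genes (calibrator row
#'   = 1).
#' @param reference reference gene name added at fold 1.
#' @param n_bio,n_tech biological and technical replicates.
#' @param bio_sd,tech_sd Ct noise components (cycles).
#' @param efficiency amplification efficiency.
#' @param base_ct baseline Ct.
#' @return a Ct data.frame with columns `sample_id`, `amplicon`, `bio`,
#'   `replicate`, `ct`.
#' @export
simulate_expression_ct <- function(fold, reference = "actin2",
                                   n_bio = 3L, n_tech = 3L,
                                   bio_sd = 0.15, tech_sd = 0.05,
                                   efficiency = 2, base_ct = 22) {
  stopifnot(is.matrix(fold), !is.null(rownames(fold)), !is.null(colnames(fold)))
  fold <- cbind(fold, matrix(1, nrow(fold), 1,
                             dimnames = list(NULL, reference)))
  rows <- list()
  for (s in rownames(fold)) {
    for (g in colnames(fold)) {
      true_ct <- base_ct - log(fold[s, g]) / log(efficiency)
      for (b in seq_len(n_bio)) {
        bio_ct <- true_ct + stats::rnorm(1, 0, bio_sd)
        for (t in seq_len(n_tech)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = s, amplicon = g, bio = b,
            replicate = (b - 1L) * n_tech + t,
            ct = bio_ct + stats::rnorm(1, 0, tech_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "efficiency") <- efficiency
  class(out) <- c("flocus_ct", "data.frame")
  out
}

panel_genotypes <- function() {
  labels <- c(sprintf("H%02d", 1:5), sprintf("G%02d", 1:13), "G14_AM297",
              sprintf("M%02d", 1:8), sprintf("S%02d", 1:3))
  keys <- c(rep("AG/AG", 5), rep("AG/AG", 13), "AGG/AGG",
            rep("A/A", 8), rep("AG/A", 3))
  morph <- c(rep("H", 5), rep("G", 14), rep("M", 8), rep("SubG", 3))
  data.frame(sample_id = labels, genotype = keys, sex_morph = morph,
             expected_copies = vapply(keys, function(k) {
               g <- parse_genotype(k)
               (n_units(g$hap1) + n_units(g$hap2)) / 2
             }, numeric(1)),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic scenario bundle
#'
#' Writes every input the corresponding pipeline stage consumes, plus a
#' `truth.json` recording the latent quantities (genotypes, template copies,
#' UCO rate, fold changes) for recovery tests, and a `manifest.json` listing
#' the files. Byte-identical across runs with the same configuration.
#'
#' @param cfg a [scenario_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `files`, `truth` and the scenario objects.
#' @export
generate_scenario <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "flocus_scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- with_seed(cfg$seed, switch(
    cfg$scenario,
    gy14_screen = scenario_screen(cfg, out_dir, n = 2236L),
    g06_screen = scenario_screen(cfg, out_dir, n = 2573L),
    table1_crosses = scenario_table1(cfg, out_dir),
    fig1_depth = scenario_depth(cfg, out_dir),
    fig3_qpcr_panel = scenario_qpcr_panel(cfg, out_dir),
    fig5_expression = scenario_expression(cfg, out_dir)
  ))
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(out$truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(scenario = cfg$scenario, seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("flocus")),
                   config = unclass(cfg),
                   files = c(basename(out$files), "truth.json"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$files <- c(out$files, truth_path, file.path(out_dir, "manifest.json"))
  out$config <- cfg
  invisible(out)
}

scenario_screen <- function(cfg, out_dir, n) {
  founder <- build_line_structure("gynoecious_Gy14_like")
  p <- uco_params(cfg$uco_rate)
  pop <- self_population(founder, n, generations = 2L, p = p,
                         p_transient = cfg$p_transient)
  conf <- confirm_mutants(pop, progeny_size = cfg$progeny_size, p = p)
  pop_path <- file.path(out_dir, "population.tsv")
  write_population_tsv(pop, pop_path)
  conf_path <- file.path(out_dir, "confirmed.tsv")
  utils::write.table(conf, conf_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(
    scenario = cfg$scenario,
    founder = genotype_key(founder),
    uco_rate = cfg$uco_rate,
    p_transient = cfg$p_transient,
    n_plants = n,
    n_tagged = sum(pop$observed_tagged),
    true_mutant_ids = pop$plant_id[pop$true_phenotype != "G"],
    n_true_mutants = sum(pop$true_phenotype != "G"),
    n_confirmed = sum(conf$confirmed))
  list(files = c(pop_path, conf_path), truth = truth,
       population = pop, confirmed = conf)
}

scenario_table1 <- function(cfg, out_dir) {
  tab <- table1_observed()
  p0 <- uco_params(0)
  rows <- lapply(seq_len(nrow(tab)), function(r) {
    parents <- strsplit(tab$parents[r], "|", fixed = TRUE)[[1]]
    cr <- cross(parse_genotype(parents[1]), parse_genotype(parents[2]), p0)
    if (tab$f1_selfed[r]) {
      # F2: self the (unique, at mu = 0) F1 genotype
      f1 <- parse_genotype(cr$genotypes$genotype[which.max(cr$genotypes$prob)])
      cr <- cross(f1, f1, p0)
    }
    counts <- stats::rmultinom(1, tab$n[r], cr$phenotypes)[, 1]
    data.frame(population = tab$population[r],
               expected_sex = tab$expected_sex[r],
               p_M = unname(cr$phenotypes["M"]),
               p_SubG = unname(cr$phenotypes["SubG"]),
               p_G = unname(cr$phenotypes["G"]),
               sim_M = counts["M"], sim_SubG = counts["SubG"],
               sim_G = counts["G"], n = tab$n[r],
               stringsAsFactors = FALSE)
  })
  sim <- do.call(rbind, rows)
  path <- file.path(out_dir, "crosses.tsv")
  utils::write.table(sim, path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(scenario = cfg$scenario, uco_rate = 0,
                populations = sim[, c("population", "expected_sex",
                                      "p_M", "p_SubG", "p_G")])
  list(files = path, truth = truth, simulated = sim, observed = tab)
}

scenario_depth <- function(cfg, out_dir) {
  geom <- depth_geometry(scale = cfg$scale)
  samples <- data.frame(
    sample_id = c("G1", "G2", "G3", "M1", "M2", "M3"),
    genotype = c(rep("AG/AG", 3), rep("A/A", 3)),
    stringsAsFactors = FALSE)
  samples$expected_ratio <- vapply(samples$genotype, function(k) {
    g <- parse_genotype(k)
    (n_units(g$hap1) + n_units(g$hap2)) / 2
  }, numeric(1))
  samples$coverage <- round(stats::runif(nrow(samples),
                                         cfg$coverage_range[1],
                                         cfg$coverage_range[2]), 1)
  files <- character(0)
  profiles <- list()
  for (r in seq_len(nrow(samples))) {
    prof <- simulate_depth(parse_genotype(samples$genotype[r]), geom,
                           mean_coverage = samples$coverage[r])
    path <- file.path(out_dir, paste0(samples$sample_id[r], "_depth.tsv"))
    write_depth_tsv(prof, path)
    files <- c(files, path)
    profiles[[samples$sample_id[r]]] <- prof
  }
  # annotated reference loci of the three structural classes
  params <- locus_params(scale = cfg$scale, seed = cfg$seed)
  loci <- list(monecious = haplotype("A"), gynoecious = haplotype("AG"),
               triple = haplotype("AGG"))
  for (nm in names(loci)) {
    loc <- assemble_locus_sequence(loci[[nm]], params)
    fa <- file.path(out_dir, paste0(nm, "_locus.fasta"))
    gff <- file.path(out_dir, paste0(nm, "_locus.gff3"))
    bed <- file.path(out_dir, paste0(nm, "_units.bed"))
    write_locus_fasta(loc, fa, seqname = nm)
    write_locus_gff3(loc, gff, seqname = nm)
    write_units_bed(loc, bed, seqname = nm)
    files <- c(files, fa, gff, bed)
  }
  truth <- list(scenario = cfg$scenario,
                cnv_interval = attr(profiles[[1]], "cnv_interval"),
                samples = samples)
  list(files = files, truth = truth, profiles = profiles, samples = samples)
}

scenario_qpcr_panel <- function(cfg, out_dir) {
  panel <- panel_genotypes()
  tabs <- lapply(seq_len(nrow(panel)), function(r) {
    simulate_qpcr(parse_genotype(panel$genotype[r]),
                  k = 7L, noise_sd = cfg$ct_sd,
                  sample_id = panel$sample_id[r])
  })
  ct <- do.call(rbind, tabs)
  attr(ct, "efficiency") <- 2
  class(ct) <- c("flocus_ct", "data.frame")
  path <- file.path(out_dir, "qpcr_panel.tsv")
  write_ct_tsv(ct, path)
  truth <- list(scenario = cfg$scenario, ct_sd = cfg$ct_sd,
                samples = panel)
  list(files = path, truth = truth, ct = ct, panel = panel)
}

scenario_expression <- function(cfg, out_dir) {
  samples <- c("Gy14", "Gy14M_17", "Gy14M_42", "Gy14M_63")
  genes <- c("CsACS1", "CsACS2", "CsMYB")
  fold <- matrix(1, length(samples), length(genes),
                 dimnames = list(samples, genes))
  fold[-1, "CsACS1"] <- cfg$knockdown_fold
  fold[-1, "CsACS2"] <- cfg$knockdown_fold
  ct <- simulate_expression_ct(fold, bio_sd = cfg$ct_sd,
                               tech_sd = cfg$ct_sd / 3)
  path <- file.path(out_dir, "expression_ct.tsv")
  write_ct_tsv(ct, path)
  truth <- list(scenario = cfg$scenario, calibrator = "Gy14",
                knockdown_fold = cfg$knockdown_fold,
                down_regulated = c("CsACS1", "CsACS2"),
                unchanged = "CsMYB",
                true_fold = as.data.frame(fold))
  list(files = path, truth = truth, ct = ct, fold = fold)
}

#' Ground truth of a generated bundle
#'
#' @param bundle a [generate_scenario()] result, or the bundle directory.
#' @return the truth list.
#' @export
truth_report <- function(bundle) {
  if (is.character(bundle)) {
    return(jsonlite::read_json(file.path(bundle, "truth.json"),
                               simplifyVector = TRUE))
  }
  bundle$truth
}
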