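#' Unequal crossing over parameters
#'
#' Meiosis is modelled with at most one crossover opportunity per bivalent in
#' the F-locus interval. With probability `1 - uco_rate` (or whenever no
#' misaligned register exists) the crossover is equal or absent and the gamete
#' is one parental haplotype chosen uniformly. With probability `uco_rate` the
#' repeat arrays misalign by an offset drawn from `offset_weights` and a
#' crossover between registers i (hap1) and j (hap2), i != j, produces the
#' reciprocal recombinants `hap1[1..i] + hap2[j+1..]` and
#' `hap2[1..j] + hap1[i+1..]`. Unit identity travels with its 5' promoter.
#'
#' The default rate of 1.25e-3 per meiosis is the value recovered by
#' [calibrate_uco_rate()] from the pooled gynoecy-loss screens (6 confirmed
#' mutants among 4809 plants); it can be recalibrated for any screen design.
#'
#' @param uco_rate per-meiosis UCO probability in `[0, 1]`.
#' @param max_offset largest allowed misalignment register (>= 1).
#' @param offset_weights probability weights over offsets `1..max_offset`
#'   (default uniform); renormalised over the offsets feasible for a genotype.
#' @return a list of class `flocus_uco_params`.
#' @export
uco_params <- function(uco_rate = 1.25e-3, max_offset = 1L,
                       offset_weights = NULL) {
  if (!is.numeric(uco_rate) || length(uco_rate) != 1L ||
      is.na(uco_rate) || uco_rate < 0 || uco_rate > 1) {
    stop("'uco_rate' must be a probability in [0, 1]")
  }
  max_offset <- as.integer(max_offset)
  if (max_offset < 1L) stop("'max_offset' must be >= 1")
  w <- offset_weights %||% rep(1, max_offset)
  if (length(w) != max_offset || any(w < 0) || sum(w) <= 0) {
    stop("'offset_weights' must be non-negative weights over 1..max_offset")
  }
  structure(list(uco_rate = uco_rate, max_offset = max_offset,
                 offset_weights = w / sum(w)),
            class = "flocus_uco_params")
}

# all misaligned crossover registers (i in hap1, j in hap2, i != j,
# |i - j| <= max_offset)
misaligned_pairs <- function(n1, n2, max_offset) {
  grid <- expand.grid(i = seq_len(n1), j = seq_len(n2))
  grid$offset <- abs(grid$i - grid$j)
  grid[grid$offset >= 1L & grid$offset <= max_offset, , drop = FALSE]
}

recombine <- function(u1, u2, i, j) {
  c(u1[seq_len(i)], if (j < length(u2)) u2[(j + 1L):length(u2)])
}

#' Map genotype to sex phenotype by CsACS1G dosage
#'
#' Total G-unit dosage d across both haplotypes determines sex expression
#' deterministically: d = 0 monecious (`"M"`), d = 1 subgynoecious (`"SubG"`),
#' d >= 2 gynoecious (`"G"`).
#'
#' @param g a [genotype()].
#' @return `"M"`, `"SubG"` or `"G"`.
#' @export
dosage_phenotype <- function(g) {
  dosage_class(g_dosage(g))
}

dosage_class <- function(d) {
  ifelse(d == 0L, "M", ifelse(d == 1L, "SubG", "G"))
}

phenotype_levels <- c("M", "SubG", "G")

#' Exact gamete distribution under the UCO model
#'
#' Enumerates every gamete haplotype a genotype can produce and its exact
#' probability: the closed-form counterpart of [simulate_meiosis()].
#'
#' @param g a [genotype()].
#' @param p [uco_params()].
#' @return data.frame with columns `haplotype` (unit-string key) and `prob`;
#'   probabilities sum to 1.
#' @export
enumerate_gametes <- function(g, p = uco_params()) {
  u1 <- g$hap1$units; u2 <- g$hap2$units
  n1 <- length(u1); n2 <- length(u2)
  acc <- new.env(parent = emptyenv())
  add <- function(units, pr) {
    key <- paste(units, collapse = "")
    assign(key, pr + (if (exists(key, acc)) get(key, acc) else 0), acc)
  }
  pairs <- misaligned_pairs(n1, n2, p$max_offset)
  if (nrow(pairs) == 0L || p$uco_rate == 0) {
    add(u1, 0.5); add(u2, 0.5)
  } else {
    mu <- p$uco_rate
    add(u1, (1 - mu) / 2); add(u2, (1 - mu) / 2)
    feas <- sort(unique(pairs$offset))
    w <- p$offset_weights[feas]
    w <- w / sum(w)
    names(w) <- feas
    for (r in seq_len(nrow(pairs))) {
      d <- pairs$offset[r]
      pr_pair <- mu * w[[as.character(d)]] / sum(pairs$offset == d)
      add(recombine(u1, u2, pairs$i[r], pairs$j[r]), pr_pair / 2)
      add(recombine(u2, u1, pairs$j[r], pairs$i[r]), pr_pair / 2)
    }
  }
  keys <- ls(acc)
  out <- data.frame(haplotype = keys,
                    prob = vapply(keys, get, numeric(1), envir = acc),
                    stringsAsFactors = FALSE)
  out <- out[out$prob > 0, , drop = FALSE]
  out <- out[order(-out$prob, out$haplotype), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate one meiosis
#'
#' Stochastic single-draw counterpart of [enumerate_gametes()]; uses the
#' global RNG. Draw order: (1) uniform deviate for the UCO event, then if UCO
#' occurs (2) the misalignment offset, (3) the register pair, (4) a fair coin
#' for which reciprocal product is recovered; otherwise (2') a fair pick of
#' the parental haplotype.
#'
#' @param g a [genotype()].
#' @param p [uco_params()].
#' @return a list of class `flocus_gamete` with `haplotype` and `origin`
#'   (`"equal"`, `"uco_deletion"` or `"uco_duplication"`).
#' @export
simulate_meiosis <- function(g, p = uco_params()) {
  u1 <- g$hap1$units; u2 <- g$hap2$units
  pairs <- misaligned_pairs(length(u1), length(u2), p$max_offset)
  if (nrow(pairs) > 0L && stats::runif(1) < p$uco_rate) {
    feas <- sort(unique(pairs$offset))
    w <- p$offset_weights[feas]
    d <- if (length(feas) == 1L) feas else sample(feas, 1L, prob = w)
    cand <- which(pairs$offset == d)
    r <- if (length(cand) == 1L) cand else sample(cand, 1L)
    rec1 <- recombine(u1, u2, pairs$i[r], pairs$j[r])
    rec2 <- recombine(u2, u1, pairs$j[r], pairs$i[r])
    units <- if (stats::runif(1) < 0.5) rec1 else rec2
    mean_n <- (length(u1) + length(u2)) / 2
    origin <- if (length(units) < mean_n) "uco_deletion"
              else if (length(units) > mean_n) "uco_duplication"
              else "equal"
  } else {
    units <- if (stats::runif(1) < 0.5) u1 else u2
    origin <- "equal"
  }
  structure(list(haplotype = haplotype(units), origin = origin),
            class = "flocus_gamete")
}

#' Exact offspring distribution of a cross
#'
#' The offspring genotype distribution is the product of the two parental
#' gamete distributions ([enumerate_gametes()]), aggregated over unordered
#' haplotype pairs; the phenotype distribution is its push-forward through
#' [dosage_phenotype()]. Selfing is `cross(g, g, p)`. Exactly symmetric in
#' the parents.
#'
#' @param parent1,parent2 [genotype()] objects.
#' @param p [uco_params()].
#' @return an object of class `flocus_cross` with `genotypes` (data.frame:
#'   `genotype`, `dosage`, `phenotype`, `prob`) and `phenotypes` (named
#'   probability vector over `M`, `SubG`, `G`).
#' @export
cross <- function(parent1, parent2, p = uco_params()) {
  d1 <- enumerate_gametes(parent1, p)
  d2 <- enumerate_gametes(parent2, p)
  acc <- new.env(parent = emptyenv())
  for (a in seq_len(nrow(d1))) {
    for (b in seq_len(nrow(d2))) {
      k <- sort(c(d1$haplotype[a], d2$haplotype[b]),
                method = "radix", decreasing = TRUE)
      key <- paste(k, collapse = "/")
      pr <- d1$prob[a] * d2$prob[b]
      assign(key, pr + (if (exists(key, acc)) get(key, acc) else 0), acc)
    }
  }
  keys <- ls(acc)
  prob <- vapply(keys, get, numeric(1), envir = acc)
  dosage <- vapply(strsplit(keys, ""), function(ch) sum(ch == "G"),
                   integer(1))
  geno <- data.frame(genotype = keys, dosage = dosage,
                     phenotype = dosage_class(dosage), prob = unname(prob),
                     stringsAsFactors = FALSE)
  geno <- geno[order(-geno$prob, geno$genotype), , drop = FALSE]
  rownames(geno) <- NULL
  ph <- vapply(phenotype_levels,
               function(l) sum(geno$prob[geno$phenotype == l]), numeric(1))
  structure(list(genotypes = geno, phenotypes = ph,
                 parents = c(genotype_key(parent1), genotype_key(parent2)),
                 params = p),
            class = "flocus_cross")
}

#' @export
print.flocus_cross <- function(x, ...) {
  cat("<cross> ", x$parents[1], " x ", x$parents[2], "\n", sep = "")
  ph <- x$phenotypes
  cat("  phenotypes: ",
      paste(sprintf("%s %.4g", names(ph), ph), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Sample offspring from a cross
#'
#' Multinomial draw over the exact genotype distribution (uses the global
#' RNG).
#'
#' @param cr a [cross()] result.
#' @param n number of offspring.
#' @return data.frame with `genotype`, `dosage`, `phenotype`, one row per
#'   offspring.
#' @export
sample_offspring <- function(cr, n) {
  counts <- stats::rmultinom(1, n, cr$genotypes$prob)[, 1]
  idx <- rep(seq_along(counts), counts)
  out <- cr$genotypes[idx, c("genotype", "dosage", "phenotype")]
  rownames(out) <- NULL
  out
}

#' Simulate a selfed population
#'
#' Reproduces the screen design of the gynoecy-loss experiments: a single
#' founder plant is carried through `generations - 1` single-plant selfing
#' generations (one random offspring becomes the next parent), and the final
#' selfing generation produces `n_plants` phenotyped plants. Plants showing
#' male flowers are tagged: every true SubG/M plant, plus true-G plants
#' spuriously tagged at rate `p_transient` (transient male flowers are
#' observation noise, not phenotype state).
#'
#' @param founder founder [genotype()].
#' @param n_plants final population size.
#' @param generations number of selfing generations (>= 1).
#' @param p [uco_params()].
#' @param p_transient spurious tagging rate for true-G plants.
#' @return data.frame of class `flocus_population` with columns `plant_id`,
#'   `genotype`, `true_phenotype`, `observed_tagged`, `generation`; summary
#'   counts in `attr(, "summary")`.
#' @export
self_population <- function(founder, n_plants, generations = 1L,
                            p = uco_params(), p_transient = 0) {
  stopifnot(n_plants >= 1L, generations >= 1L)
  parent <- founder
  if (generations > 1L) {
    for (t in seq_len(generations - 1L)) {
      cr <- cross(parent, parent, p)
      pick <- sample(nrow(cr$genotypes), 1L, prob = cr$genotypes$prob)
      parent <- parse_genotype(cr$genotypes$genotype[pick])
    }
  }
  cr <- cross(parent, parent, p)
  off <- sample_offspring(cr, n_plants)
  tagged <- off$phenotype != "G"
  if (p_transient > 0) {
    is_g <- off$phenotype == "G"
    tagged[is_g] <- stats::runif(sum(is_g)) < p_transient
  }
  pop <- data.frame(plant_id = seq_len(n_plants),
                    genotype = off$genotype,
                    true_phenotype = off$phenotype,
                    observed_tagged = tagged,
                    generation = generations,
                    stringsAsFactors = FALSE)
  attr(pop, "summary") <- c(
    n = n_plants,
    n_G = sum(off$phenotype == "G"),
    n_SubG = sum(off$phenotype == "SubG"),
    n_M = sum(off$phenotype == "M"))
  attr(pop, "founder") <- genotype_key(founder)
  attr(pop, "final_parent") <- genotype_key(parent)
  class(pop) <- c("flocus_population", "data.frame")
  pop
}

#' Progeny-test tagged plants
#'
#' Each tagged plant is selfed and `progeny_size` offspring are phenotyped;
#' the plant is a confirmed gynoecy-loss mutant when monecious offspring
#' segregate (tagged true-G plants are rejected because their selfed progeny
#' stay gynoecious at realistic UCO rates). For confirmed plants the derived
#' stable monecious line (a zero-dosage progeny genotype) is reported.
#'
#' @param pop a [self_population()] table.
#' @param progeny_size selfed progeny per tagged plant; values below 8 give
#'   low power to observe segregation (warning).
#' @param p [uco_params()].
#' @return data.frame with one row per tagged plant: `plant_id`, `genotype`,
#'   `true_phenotype`, `n_progeny_m`, `confirmed`, `stable_m_line`.
#' @export
confirm_mutants <- function(pop, progeny_size = 20L, p = uco_params()) {
  if (progeny_size < 8L) {
    warning("progeny_size < 8: low power to observe monecious segregation")
  }
  tagged <- pop[pop$observed_tagged, , drop = FALSE]
  rows <- lapply(seq_len(nrow(tagged)), function(r) {
    g <- parse_genotype(tagged$genotype[r])
    cr <- cross(g, g, p)
    counts <- stats::rmultinom(1, progeny_size, cr$genotypes$prob)[, 1]
    m_idx <- which(cr$genotypes$dosage == 0L & counts > 0L)
    n_m <- sum(counts[cr$genotypes$dosage == 0L])
    data.frame(plant_id = tagged$plant_id[r],
               genotype = tagged$genotype[r],
               true_phenotype = tagged$true_phenotype[r],
               n_progeny_m = n_m,
               confirmed = n_m > 0L,
               stable_m_line = if (n_m > 0L) cr$genotypes$genotype[m_idx[1]]
                               else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plant_id = integer(0), genotype = character(0),
               true_phenotype = character(0), n_progeny_m = integer(0),
               confirmed = logical(0), stable_m_line = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a population table as TSV
#'
#' @param pop a [self_population()] table.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_population_tsv <- function(pop, path) {
  utils::write.table(as.data.frame(pop), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
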