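#' Chi-square goodness of fit to a segregation ratio
#'
#' Pearson statistic against expected counts scaled from a positive ratio
#' (e.g. `c(1, 2, 1)`), with upper-tail p-values in closed form for the
#' degrees of freedom that occur in two- and three-class segregation tables:
#' `p = erfc(sqrt(x / 2))` for df = 1 and `p = exp(-x / 2)` for df = 2
#' (general df falls back to the chi-square survival function). No continuity
#' correction is applied. The p-value is invariant to rescaling the ratio.
#'
#' @param observed non-negative observed counts.
#' @param expected_ratio positive weights, same length.
#' @return a list of class `flocus_gof` with `observed`, `expected`, `chi2`,
#'   `df`, `p_value`.
#' @examples
#' chisq_gof(c(47, 98, 55), c(1, 2, 1))   # chi2 0.72, p 0.6977
#' chisq_gof(c(735, 265), c(3, 1))        # chi2 1.2,  p 0.2733
#' @export
chisq_gof <- function(observed, expected_ratio) {
  if (length(observed) != length(expected_ratio)) {
    stop("'observed' and 'expected_ratio' must have the same length")
  }
  if (sum(observed) <= 0) stop("total observed count must be positive")
  if (any(expected_ratio <= 0)) stop("expected ratio weights must be > 0")
  expected <- expected_ratio / sum(expected_ratio) * sum(observed)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- chisq_p_closed(chi2, df)
  structure(list(observed = observed, expected = expected, chi2 = chi2,
                 df = df, p_value = p),
            class = "flocus_gof")
}

# complementary error function
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

# upper-tail chi-square p: closed forms for df 1 and 2, survival function
# otherwise
chisq_p_closed <- function(x, df) {
  if (df == 1L) {
    erfc(sqrt(x / 2))
  } else if (df == 2L) {
    exp(-x / 2)
  } else {
    stats::pchisq(x, df, lower.tail = FALSE)
  }
}

#' @export
print.flocus_gof <- function(x, ...) {
  cat("chi-square goodness of fit: X2 = ", format(x$chi2),
      ", df = ", x$df, ", p = ", format(round_half_up(x$p_value, 4), nsmall = 4),
      "\n", sep = "")
  invisible(x)
}

#' Mutation-rate estimate with exact binomial CI
#'
#' Point rate with Clopper-Pearson interval (appropriate for the very small
#' success counts of gynoecy-loss screens). The reported percentage is
#' printed to two decimals by truncation, the convention of the screen
#' reports (3/2236 = 0.13417% prints as 0.13%, 3/2573 = 0.11660% as 0.11%).
#'
#' @param successes number of mutants.
#' @param trials number of plants screened.
#' @param conf confidence level.
#' @return a list of class `flocus_rate` with `successes`, `trials`, `rate`,
#'   `percent` (rounded), `ci` (proportions).
#' @examples
#' mutation_rate(3, 2236)$percent  # 0.13
#' @export
mutation_rate <- function(successes, trials, conf = 0.95) {
  successes <- as.integer(successes); trials <- as.integer(trials)
  if (trials < 1L || successes < 0L || successes > trials) {
    stop("need 0 <= successes <= trials, trials >= 1")
  }
  rate <- successes / trials
  a <- 1 - conf
  lo <- if (successes == 0L) 0 else
    stats::qbeta(a / 2, successes, trials - successes + 1)
  hi <- if (successes == trials) 1 else
    stats::qbeta(1 - a / 2, successes + 1, trials - successes)
  structure(list(successes = successes, trials = trials, rate = rate,
                 percent = trunc(100 * rate * 100 + 1e-9) / 100,
                 ci = c(lo, hi), conf = conf),
            class = "flocus_rate")
}

#' @export
print.flocus_rate <- function(x, ...) {
  cat(sprintf("%d/%d = %.2f%% (exact %d%% CI %.4f%% - %.4f%%)\n",
              x$successes, x$trials, x$percent, round(100 * x$conf),
              100 * x$ci[1], 100 * x$ci[2]))
  invisible(x)
}

#' Welch two-sample t test
#'
#' Unequal-variance two-sided comparison, the default for small replicate
#' groups (k = 3 biological replicates in expression assays). Two groups with
#' zero variance and equal means give p = 1 by convention (and p = 0 when the
#' means differ).
#'
#' @param group_a,group_b numeric replicate values (>= 2 each).
#' @return a list of class `flocus_welch` with `t`, `df`, `p_value` and
#'   `significant_at` (named logical for 0.05 and 0.01).
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need at least 2 values per group")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    equal <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    res <- list(t = if (equal) 0 else Inf,
                df = length(group_a) + length(group_b) - 2,
                p_value = if (equal) 1 else 0)
  } else {
    ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value)
  }
  res$significant_at <- c(`0.05` = res$p_value < 0.05,
                          `0.01` = res$p_value < 0.01)
  class(res) <- "flocus_welch"
  res
}

#' @export
print.flocus_welch <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.3g, p = %.4g%s\n", x$t, x$df,
              x$p_value,
              if (x$significant_at["0.01"]) " (**)"
              else if (x$significant_at["0.05"]) " (*)" else ""))
  invisible(x)
}

#' Screen design for UCO-rate calibration
#'
#' Describes how a gynoecy-loss screen maps the per-meiosis UCO rate to an
#' observable mutant frequency: founder genotype, number of single-plant
#' selfing generations before the observed one (the screens grew the observed
#' population from a single plant after two prior selfings; whether the
#' mutants arose in those generations is not observable, so both assumptions
#' are available), and the progeny-test size used for confirmation.
#'
#' @param founder founder [genotype()].
#' @param prior_selfing_generations selfing generations before the observed
#'   population (0 = mutants arise in the observed generation only).
#' @param progeny_size selfed progeny per tagged plant in confirmation.
#' @param max_units haplotype-size cap for the generation chain (tail mass at
#'   realistic rates is negligible).
#' @param max_offset misalignment register cap.
#' @return a list of class `flocus_screen_design`.
#' @export
screen_design <- function(founder = build_line_structure("gynoecious_Gy14_like"),
                          prior_selfing_generations = 0L,
                          progeny_size = 20L,
                          max_units = 5L,
                          max_offset = 1L) {
  structure(list(founder = founder,
                 prior_selfing_generations = as.integer(prior_selfing_generations),
                 progeny_size = as.integer(progeny_size),
                 max_units = as.integer(max_units),
                 max_offset = as.integer(max_offset)),
            class = "flocus_screen_design")
}

# exact expected frequency of confirmed gynoecy-loss mutants in the observed
# generation of a screen, as a function of the UCO rate
expected_mutant_frequency <- function(mu, design) {
  p <- uco_params(uco_rate = mu, max_offset = design$max_offset)
  dist <- data.frame(genotype = genotype_key(design$founder), prob = 1,
                     stringsAsFactors = FALSE)
  evolve <- function(dist) {
    acc <- new.env(parent = emptyenv())
    for (r in seq_len(nrow(dist))) {
      cr <- cross_by_key(dist$genotype[r], p)
      for (s in seq_len(nrow(cr$genotypes))) {
        key <- cr$genotypes$genotype[s]
        n_max <- max(nchar(strsplit(key, "/", fixed = TRUE)[[1]]))
        if (n_max > design$max_units) next  # truncate vanishing tail
        pr <- dist$prob[r] * cr$genotypes$prob[s]
        assign(key, pr + (if (exists(key, acc)) get(key, acc) else 0), acc)
      }
    }
    keys <- ls(acc)
    out <- data.frame(genotype = keys,
                      prob = vapply(keys, get, numeric(1), envir = acc),
                      stringsAsFactors = FALSE)
    out$prob <- out$prob / sum(out$prob)
    out
  }
  for (t in seq_len(design$prior_selfing_generations)) dist <- evolve(dist)
  # observed generation: offspring that are dosage < 2 and then confirmed by
  # a progeny test segregating monecious plants
  freq <- 0
  for (r in seq_len(nrow(dist))) {
    cr <- cross_by_key(dist$genotype[r], p)
    gg <- cr$genotypes
    for (s in seq_len(nrow(gg))) {
      if (gg$dosage[s] >= 2L) next
      p_conf <- if (gg$dosage[s] == 0L) 1 else {
        p_m <- cross_by_key(gg$genotype[s], p)$phenotypes["M"]
        1 - (1 - p_m)^design$progeny_size
      }
      freq <- freq + dist$prob[r] * gg$prob[s] * p_conf
    }
  }
  unname(freq)
}

cross_by_key <- function(key, p) {
  g <- parse_genotype(key)
  cross(g, g, p)
}

#' Calibrate the per-meiosis UCO rate from an observed mutant frequency
#'
#' Solves `E[confirmed mutant frequency | mu, design] = observed rate` by
#' monotone bisection, with the expectation computed exactly from the gamete
#' enumeration composed over the screen's generations. The CI is the
#' Clopper-Pearson interval of the observation propagated through the same
#' inversion.
#'
#' @param observed a [mutation_rate()] result, or `c(successes, trials)`.
#' @param design a [screen_design()].
#' @param upper upper bracket for the rate search.
#' @param tol bisection tolerance on mu.
#' @return a list of class `flocus_uco_calibration` with `mu`, `ci`,
#'   `observed`, `design`.
#' @export
calibrate_uco_rate <- function(observed, design = screen_design(),
                               upper = 0.2, tol = 1e-10) {
  if (!inherits(observed, "flocus_rate")) {
    observed <- mutation_rate(observed[1], observed[2])
  }
  solve_mu <- function(rate) {
    if (rate == 0) return(0)
    f_hi <- expected_mutant_frequency(upper, design)
    if (rate > f_hi) {
      stop("observed rate ", format(rate),
           " exceeds the achievable frequency ", format(f_hi),
           " at mu = ", upper)
    }
    lo <- 0; hi <- upper
    repeat {
      mid <- (lo + hi) / 2
      if (hi - lo < tol) return(mid)
      if (expected_mutant_frequency(mid, design) < rate) lo <- mid
      else hi <- mid
    }
  }
  mu <- solve_mu(observed$rate)
  ci <- c(solve_mu(observed$ci[1]), solve_mu(observed$ci[2]))
  structure(list(mu = mu, ci = ci, observed = observed, design = design),
            class = "flocus_uco_calibration")
}

#' @export
print.flocus_uco_calibration <- function(x, ...) {
  cat(sprintf("UCO rate: %.4g per meiosis (95%% CI %.4g - %.4g) from %d/%d\n",
              x$mu, x$ci[1], x$ci[2], x$observed$successes,
              x$observed$trials))
  invisible(x)
}
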