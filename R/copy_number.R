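#' Reference geometry for read-depth simulation
#'
#' The depth caller operates on a single-unit reference: the 30-kb CNV
#' interval with 10-kb flanks on either side (50 kb total at full scale),
#' tiled by fixed-width windows. Window width scales with the locus so that
#' window counts per region are preserved in down-scaled test runs.
#'
#' @param scale multiplicative scale factor.
#' @param flank5,flank3,cnv_length region lengths (bp).
#' @param window window width (bp).
#' @param read_length nominal read length used to convert fold coverage to
#'   expected reads per window.
#' @return a list of class `flocus_depth_geometry`.
#' @export
depth_geometry <- function(scale = 1,
                           flank5 = round(10000 * scale),
                           cnv_length = round(30000 * scale),
                           flank3 = round(10000 * scale),
                           window = round(500 * scale),
                           read_length = 150L) {
  stopifnot(window >= 1L, flank5 > 0L, flank3 > 0L, cnv_length > 0L)
  structure(list(flank5 = as.integer(flank5),
                 cnv_length = as.integer(cnv_length),
                 flank3 = as.integer(flank3),
                 window = as.integer(window),
                 read_length = as.integer(read_length)),
            class = "flocus_depth_geometry")
}

#' Simulate a windowed read-depth profile
#'
#' Per-window read counts are drawn independently with expectation
#' `mean_coverage * window / read_length * copies / 2`, where the diploid
#' segment copy number is 2 in the flanks and the genotype's total repeat-unit
#' count inside the CNV interval (all units of a tandem array map onto the
#' single-unit reference). Windows straddling a CNV boundary get the
#' length-weighted mixture expectation. Counts are Poisson, or negative
#' binomial when `dispersion > 0`.
#'
#' @param g a [genotype()].
#' @param geom [depth_geometry()].
#' @param mean_coverage fold coverage of the diploid genome.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @return data.frame of class `flocus_depth` (bedGraph-style: `chrom`,
#'   `start`, `end`, `count`), with the CNV interval in
#'   `attr(, "cnv_interval")`.
#' @export
simulate_depth <- function(g, geom = depth_geometry(), mean_coverage = 20,
                           dispersion = 0) {
  stopifnot(mean_coverage > 0)
  total <- geom$flank5 + geom$cnv_length + geom$flank3
  starts <- seq.int(0L, total - geom$window, by = geom$window)
  ends <- starts + geom$window
  ci <- c(geom$flank5, geom$flank5 + geom$cnv_length)
  cnv_copies <- n_units(g$hap1) + n_units(g$hap2)
  # bp of each window inside the CNV interval
  in_cnv <- pmax(0L, pmin(ends, ci[2]) - pmax(starts, ci[1]))
  copies <- (in_cnv * cnv_copies + (geom$window - in_cnv) * 2) / geom$window
  lambda <- mean_coverage * geom$window / geom$read_length * copies / 2
  counts <- if (dispersion > 0) {
    stats::rnbinom(length(lambda), mu = lambda, size = 1 / dispersion)
  } else {
    stats::rpois(length(lambda), lambda)
  }
  prof <- data.frame(chrom = "F_ref", start = starts, end = ends,
                     count = counts)
  attr(prof, "cnv_interval") <- ci
  attr(prof, "geometry") <- geom
  attr(prof, "genotype") <- genotype_key(g)
  attr(prof, "mean_coverage") <- mean_coverage
  class(prof) <- c("flocus_depth", "data.frame")
  prof
}

#' Call CNV copy number from a depth profile
#'
#' The copy estimate (per haploid equivalent, flank = 1) is the ratio of
#' 10%-trimmed mean window depth inside the CNV interval to that in the
#' flanks; windows overlapping a CNV boundary are excluded. The rounded call
#' snaps to the half-integer grid (exact ties to the nearest even half). The
#' interval is a normal-approximation CI propagated from the window spread.
#'
#' @param profile a [simulate_depth()] profile (or any bedGraph-like
#'   data.frame with `start`, `end`, `count`).
#' @param cnv_interval numeric `c(start, end)`, 0-based half-open; defaults to
#'   the profile's recorded interval.
#' @param trim trimming fraction for the window means.
#' @return data.frame of class `flocus_copy_call` with `region`, `estimate`,
#'   `ci_lo`, `ci_hi`, `call`, `n_windows_cnv`, `n_windows_flank`.
#' @export
call_cnv_from_depth <- function(profile,
                                cnv_interval = attr(profile, "cnv_interval"),
                                trim = 0.1) {
  if (is.null(cnv_interval)) stop("'cnv_interval' must be supplied")
  ci <- cnv_interval
  in_cnv <- profile$start >= ci[1] & profile$end <= ci[2]
  in_flank <- profile$end <= ci[1] | profile$start >= ci[2]
  x_cnv <- profile$count[in_cnv]
  x_fl <- profile$count[in_flank]
  if (sum(in_cnv) < 5L || sum(in_flank) < 5L) {
    stop("need at least 5 whole windows in both the CNV interval and flanks")
  }
  m_cnv <- mean(x_cnv, trim = trim)
  m_fl <- mean(x_fl, trim = trim)
  if (m_fl <= 0) stop("reference coverage absent")
  r <- m_cnv / m_fl
  se <- r * sqrt(stats::var(x_cnv) / length(x_cnv) / m_cnv^2 +
                 stats::var(x_fl) / length(x_fl) / m_fl^2)
  out <- data.frame(region = "cnv", estimate = r,
                    ci_lo = r - 1.96 * se, ci_hi = r + 1.96 * se,
                    call = round_to_half(r),
                    n_windows_cnv = sum(in_cnv),
                    n_windows_flank = sum(in_flank))
  class(out) <- c("flocus_copy_call", "data.frame")
  out
}

#' Write a depth profile as bedGraph-style TSV
#' @param profile a [simulate_depth()] profile.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_depth_tsv <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# per-diploid template copies of an amplicon given the genotype
amplicon_template_copies <- function(g, amplicon) {
  per_hap <- function(hap) {
    nu <- n_units(hap)
    ng <- g_dosage(hap)
    switch(amplicon,
           CsACS1 = nu,       # primers hit CsACS1 and CsACS1G gene bodies
           CsMYB = nu,
           BCAT9_10 = ng + 1L, # in each recombinant promoter + trailing BCAT
           BCAT1_8 = 1L,       # outside the CNV: single-copy reference
           F_junction = ng,    # junction exists only in G units
           actin2 = 1L,
           CsACS2 = 1L,
           stop("unknown amplicon '", amplicon, "'"))
  }
  per_hap(g$hap1) + per_hap(g$hap2)
}

#' Simulate a genomic qPCR Ct table
#'
#' Quantification cycles follow `Ct = base_ct - log_E(copies / 2) + noise`
#' with amplification efficiency `E` (2 = perfect doubling) and per-diploid
#' template copies derived from the genotype. Amplicons with zero template
#' (e.g. the junction amplicon in a monecious line, where the primers point
#' away from each other) are recorded as `NA` — the "no amplification"
#' sentinel.
#'
#' @param g a [genotype()].
#' @param amplicons amplicon names (see [estimate_copy_qpcr()] for the
#'   conventional panel).
#' @param k replicates per amplicon (7 for genomic qPCR).
#' @param noise_sd Ct noise standard deviation (cycles).
#' @param efficiency amplification efficiency `E`.
#' @param base_ct Ct of a single diploid-equivalent template.
#' @param sample_id sample label.
#' @return data.frame of class `flocus_ct` with `sample_id`, `amplicon`,
#'   `replicate`, `ct`.
#' @export
simulate_qpcr <- function(g,
                          amplicons = c("CsACS1", "CsMYB", "BCAT9_10",
                                        "BCAT1_8", "F_junction"),
                          k = 7L, noise_sd = 0.15, efficiency = 2,
                          base_ct = 25, sample_id = genotype_key(g)) {
  stopifnot(noise_sd >= 0, k >= 1L, efficiency > 1)
  rows <- lapply(amplicons, function(a) {
    copies <- amplicon_template_copies(g, a)
    ct <- if (copies == 0L) {
      rep(NA_real_, k)
    } else {
      base_ct - log(copies / 2) / log(efficiency) +
        stats::rnorm(k, 0, noise_sd)
    }
    data.frame(sample_id = sample_id, amplicon = a, replicate = seq_len(k),
               ct = ct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "efficiency") <- efficiency
  class(out) <- c("flocus_ct", "data.frame")
  out
}

#' Estimate copy number from genomic qPCR
#'
#' Within-sample delta-Ct quantification: for each replicate pairing, copies
#' per haploid equivalent are `E^(Ct_ref - Ct_target)` with the single-copy
#' reference (BCAT exons 1-8) defined as 1, so monecious lines read 1 and
#' two-unit gynoecious lines read 2. "No amplification" (`NA` Ct) propagates
#' as 0 copies. The report is the replicate mean, a t-based CI, and the
#' half-integer rounded call.
#'
#' @param ct a [simulate_qpcr()] table (any `flocus_ct`-shaped data.frame).
#' @param reference_amplicon the normaliser (default `"BCAT1_8"`).
#' @param efficiency amplification efficiency `E`.
#' @param conf confidence level.
#' @return data.frame of class `flocus_copy_call`: one row per sample x
#'   amplicon with `copies`, `ci_lo`, `ci_hi`, `call`, `n_replicates`.
#' @export
estimate_copy_qpcr <- function(ct, reference_amplicon = "BCAT1_8",
                               efficiency = attr(ct, "efficiency") %||% 2,
                               conf = 0.95) {
  out <- list()
  for (s in unique(ct$sample_id)) {
    tab <- ct[ct$sample_id == s, , drop = FALSE]
    ref <- tab[tab$amplicon == reference_amplicon, , drop = FALSE]
    if (nrow(ref) == 0L) {
      stop("reference amplicon '", reference_amplicon,
           "' missing for sample '", s, "'")
    }
    if (sum(!is.na(ref$ct)) < 3L) {
      stop("reference amplicon needs at least 3 replicates (sample '",
           s, "')")
    }
    for (a in setdiff(unique(tab$amplicon), reference_amplicon)) {
      tgt <- tab[tab$amplicon == a, , drop = FALSE]
      reps <- intersect(ref$replicate, tgt$replicate)
      vals <- vapply(reps, function(r) {
        ct_t <- tgt$ct[tgt$replicate == r]
        ct_r <- ref$ct[ref$replicate == r]
        if (is.na(ct_t)) 0 else efficiency^(ct_r - ct_t)
      }, numeric(1))
      m <- mean(vals)
      se <- stats::sd(vals) / sqrt(length(vals))
      hw <- if (length(vals) > 1L && is.finite(se) && se > 0) {
        stats::qt(1 - (1 - conf) / 2, length(vals) - 1L) * se
      } else 0
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, amplicon = a, copies = m,
        ci_lo = m - hw, ci_hi = m + hw, call = round_to_half(m),
        n_replicates = length(vals), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("flocus_copy_call", "data.frame")
  res
}

#' Relative expression by delta-delta-Ct
#'
#' Fold change versus a calibrator sample: `E^-(dCt_sample - dCt_calibrator)`
#' with `dCt = Ct_gene - Ct_reference` (reference defaults to actin2). When
#' the Ct table carries a `bio` column, technical replicates are averaged
#' within each biological replicate and folds are reported per biological
#' replicate (the unit of downstream t tests); otherwise each replicate index
#' is its own group.
#'
#' @param ct a Ct table (`sample_id`, `amplicon`, `replicate`, `ct`, optional
#'   `bio`).
#' @param reference_amplicon normaliser gene.
#' @param calibrator_sample sample whose mean dCt defines fold 1.
#' @param efficiency amplification efficiency `E`.
#' @return data.frame with `sample_id`, `amplicon`, `group`, `fold`; the
#'   per-sample mean folds are in `attr(, "summary")`.
#' @export
relative_expression <- function(ct, reference_amplicon = "actin2",
                                calibrator_sample,
                                efficiency = attr(ct, "efficiency") %||% 2) {
  if (!calibrator_sample %in% ct$sample_id) {
    stop("calibrator sample '", calibrator_sample, "' not in the Ct table")
  }
  grp <- if ("bio" %in% names(ct)) ct$bio else ct$replicate
  agg <- stats::aggregate(ct$ct,
                          by = list(sample_id = ct$sample_id,
                                    amplicon = ct$amplicon, group = grp),
                          FUN = mean, na.rm = TRUE)
  names(agg)[4] <- "ct"
  genes <- setdiff(unique(agg$amplicon), reference_amplicon)
  dct <- do.call(rbind, lapply(genes, function(g) {
    t_g <- agg[agg$amplicon == g, ]
    t_r <- agg[agg$amplicon == reference_amplicon, ]
    m <- merge(t_g, t_r, by = c("sample_id", "group"),
               suffixes = c("_gene", "_ref"))
    data.frame(sample_id = m$sample_id, amplicon = g, group = m$group,
               dct = m$ct_gene - m$ct_ref, stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(genes, function(g) {
    d <- dct[dct$amplicon == g, ]
    cal <- mean(d$dct[d$sample_id == calibrator_sample])
    data.frame(sample_id = d$sample_id, amplicon = g, group = d$group,
               fold = efficiency^(-(d$dct - cal)), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "summary") <- stats::aggregate(
    out$fold, by = list(sample_id = out$sample_id, amplicon = out$amplicon),
    FUN = mean)
  out
}

#' Write a Ct table as TSV
#' @param ct a Ct table.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_ct_tsv <- function(ct, path) {
  utils::write.table(as.data.frame(ct), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
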