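#' Parameters for synthetic F-locus assembly
#'
#' Geometry and generator settings for building annotated synthetic locus
#' sequences. The full-scale G unit is 30,200 bp (the duplicated tandem-repeat
#' unit); the A unit is exactly 1504 bp shorter, lacking the recombinant
#' distal promoter. Length-derived constants that the locus model pins down
#' (the 1504-bp promoter block, the 410-bp proximal promoter, the 111-bp
#' junction amplicon) are held fixed regardless of `scale`, so a down-scaled
#' locus (e.g. `scale = 0.1`) preserves every structural target while keeping
#' sequences small.
#'
#' @param scale multiplicative factor on unit, gene and flank lengths.
#' @param seed integer seed for the background sequence.
#' @param gc background GC content (cucumber-like 0.35).
#' @param g_unit_length length of a G repeat unit (bp).
#' @param flank5,flank3 flank lengths (bp).
#' @param acs1_length,myb_length gene-body lengths within a unit (bp).
#' @param inject_snps if `TRUE`, two SNPs are placed in the shared core of G
#'   units (the observed divergence between CsACS1 and CsACS1G cores).
#' @param snp_positions optional 0-based core offsets for the injected SNPs.
#' @param bcat CsBCAT [gene_model()].
#' @param truncate_intron8_to bp of BCAT intron 8 kept in the promoter block.
#' @param junction_left_offset,junction_right_offset distances (bp) from the
#'   promoter/core junction to the outer ends of the junction amplicon; their
#'   sum is the amplicon length (default 60 + 51 = 111).
#' @param primer_length junction primer length (nt).
#' @param max_product default in-silico PCR product-size cap (bp).
#' @return a list of class `flocus_params`.
#' @export
locus_params <- function(scale = 1,
                         seed = 1L,
                         gc = 0.35,
                         g_unit_length = round(30200 * scale),
                         flank5 = round(10000 * scale),
                         flank3 = round(10000 * scale),
                         acs1_length = round(4600 * scale),
                         myb_length = round(3000 * scale),
                         inject_snps = FALSE,
                         snp_positions = NULL,
                         bcat = bcat_gene_model(),
                         truncate_intron8_to = 928L,
                         junction_left_offset = 60L,
                         junction_right_offset = 51L,
                         primer_length = 20L,
                         max_product = 1000L) {
  distal <- build_recombinant_promoter(bcat, truncate_intron8_to)$total_length
  proximal <- 410L
  a_unit <- g_unit_length - distal
  spacer <- a_unit - proximal - acs1_length - myb_length
  if (spacer < 2L) {
    stop("unit too small: proximal promoter + genes exceed the A-unit length")
  }
  p <- list(scale = scale, seed = as.integer(seed), gc = gc,
            g_unit_length = as.integer(g_unit_length),
            a_unit_length = as.integer(a_unit),
            distal_length = as.integer(distal),
            proximal_length = proximal,
            flank5 = as.integer(flank5), flank3 = as.integer(flank3),
            acs1_length = as.integer(acs1_length),
            myb_length = as.integer(myb_length),
            spacer1 = as.integer(spacer %/% 2L),
            spacer2 = as.integer(spacer - spacer %/% 2L),
            inject_snps = isTRUE(inject_snps),
            snp_positions = snp_positions,
            bcat = bcat,
            truncate_intron8_to = as.integer(truncate_intron8_to),
            junction_left_offset = as.integer(junction_left_offset),
            junction_right_offset = as.integer(junction_right_offset),
            primer_length = as.integer(primer_length),
            max_product = as.integer(max_product))
  class(p) <- "flocus_params"
  p
}

# Layout of the shared unit core (identical bytes in A and G units),
# 0-based offsets within the core:
#   [0, 410)                proximal promoter
#   [410, 410+acs1)         ACS1-family gene body (TSS at offset 410)
#   spacer1
#   [.., ..)                CsMYB gene body
#   spacer2
core_layout <- function(p) {
  acs1_start <- p$proximal_length
  acs1_end <- acs1_start + p$acs1_length
  myb_start <- acs1_end + p$spacer1
  myb_end <- myb_start + p$myb_length
  list(acs1 = c(acs1_start, acs1_end), myb = c(myb_start, myb_end),
       core_len = p$a_unit_length)
}

# Seeded draws, in documented order: 5' flank, shared unit core, CsBCAT gene,
# 3' flank, then SNP positions/bases when injection is on. The draws do not
# depend on the haplotype, so all loci built from the same params share their
# background sequence.
locus_raw_sequences <- function(p) {
  with_seed(p$seed, {
    flank5 <- rand_dna(p$flank5, p$gc)
    core <- rand_dna(p$a_unit_length, p$gc)
    bcat_seq <- rand_dna(gene_length(p$bcat), p$gc)
    flank3 <- rand_dna(p$flank3, p$gc)
    snps <- NULL
    if (p$inject_snps) {
      lay <- core_layout(p)
      pos <- p$snp_positions %||%
        sort(sample(seq(0L, lay$acs1[2] - 1L), 2L))
      snps <- lapply(pos, function(at) {
        ref <- substr(core, at + 1L, at + 1L)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        list(pos = at, ref = ref, alt = alt)
      })
    }
    list(flank5 = flank5, core = core, bcat = bcat_seq, flank3 = flank3,
         snps = snps)
  })
}

apply_snps <- function(core, snps) {
  for (s in snps) substr(core, s$pos + 1L, s$pos + 1L) <- s$alt
  core
}

#' Assemble an annotated synthetic F-locus haplotype sequence
#'
#' Builds the 5'->3' sequence `flank5 | unit_1 | ... | unit_k | CsBCAT |
#' flank3` for one haplotype. A-unit sequence is the shared core (proximal
#' promoter + ACS1 gene + CsMYB); a G unit prepends the 1504-bp recombinant
#' distal promoter. Cores are byte-identical across units (optionally
#' diverged by two injected SNPs in G units), mirroring the near-identity of
#' CsACS1 and CsACS1G from -410 through the 3' UTR. Deterministic per seed.
#'
#' @param hap a [haplotype()].
#' @param params [locus_params()].
#' @return an object of class `flocus_locus` with elements `seq`
#'   (a [Biostrings::DNAString]), `annotation` (0-based half-open feature
#'   table), `params` and `haplotype`.
#' @export
assemble_locus_sequence <- function(hap, params = locus_params()) {
  if (!inherits(hap, "flocus_haplotype")) hap <- haplotype(hap)
  p <- params
  raw <- locus_raw_sequences(p)
  block <- build_recombinant_promoter(p$bcat, p$truncate_intron8_to,
                                      bcat_seq = raw$bcat)
  g_core <- if (p$inject_snps) apply_snps(raw$core, raw$snps) else raw$core
  lay <- core_layout(p)

  feats <- list()
  add <- function(id, type, name, start, end, strand = "+", unit = NA_integer_) {
    feats[[length(feats) + 1L]] <<- data.frame(
      feature_id = id, type = type, name = name,
      start = start, end = end, strand = strand, unit = unit,
      stringsAsFactors = FALSE)
  }

  pieces <- character(0)
  pos <- 0L
  if (p$flank5 > 0L) {
    add("flank5", "flank", "flank5", 0L, p$flank5)
    pieces <- c(pieces, raw$flank5)
    pos <- p$flank5
  }
  for (k in seq_along(hap$units)) {
    v <- hap$units[k]
    u_start <- pos
    if (v == "G") {
      add(sprintf("distal_promoter_u%d", k), "promoter_distal",
          "CsACS1G_distal_promoter", pos, pos + p$distal_length, unit = k)
      pieces <- c(pieces, block$seq)
      pos <- pos + p$distal_length
      add(sprintf("junction_u%d", k), "junction", "F_junction",
          pos - 1L, pos + 1L, unit = k)
    }
    core_start <- pos
    add(sprintf("proximal_promoter_u%d", k), "promoter_proximal",
        "proximal_promoter", core_start, core_start + p$proximal_length,
        unit = k)
    gname <- if (v == "G") "CsACS1G" else "CsACS1"
    add(sprintf("%s_u%d", gname, k), "gene", gname,
        core_start + lay$acs1[1], core_start + lay$acs1[2], unit = k)
    add(sprintf("CsMYB_u%d", k), "gene", "CsMYB",
        core_start + lay$myb[1], core_start + lay$myb[2], unit = k)
    pieces <- c(pieces, if (v == "G") g_core else raw$core)
    pos <- core_start + p$a_unit_length
    add(sprintf("unit%d", k), "repeat_unit", sprintf("unit_%s", v),
        u_start, pos, unit = k)
  }
  add("CsBCAT", "gene", "CsBCAT", pos, pos + nchar(raw$bcat))
  pieces <- c(pieces, raw$bcat)
  pos <- pos + nchar(raw$bcat)
  if (p$flank3 > 0L) {
    add("flank3", "flank", "flank3", pos, pos + p$flank3)
    pieces <- c(pieces, raw$flank3)
    pos <- pos + p$flank3
  }

  ann <- do.call(rbind, feats)
  stopifnot(all(ann$end > ann$start))
  structure(list(seq = Biostrings::DNAString(paste0(pieces, collapse = "")),
                 annotation = ann, params = p, haplotype = hap),
            class = "flocus_locus")
}

#' @export
print.flocus_locus <- function(x, ...) {
  cat("<synthetic F locus> [", paste(x$haplotype$units, collapse = ","),
      "] haplotype, ", length(x$seq), " bp, ",
      nrow(x$annotation), " features\n", sep = "")
  invisible(x)
}

#' Promoter offsets relative to transcription start
#'
#' Reports, per unit, the 1-based negative positions (relative to the ACS1
#' TSS at +1) of the proximal-promoter start and, for G units, the 5' extent
#' of the recombinant distal promoter. With default geometry these are -410
#' and -1914.
#'
#' @param locus a `flocus_locus`.
#' @return data.frame with columns `unit`, `variant`, `proximal_from`,
#'   `distal_from` (`NA` for A units).
#' @export
promoter_offsets <- function(locus) {
  ann <- locus$annotation
  units <- sort(unique(ann$unit[!is.na(ann$unit)]))
  out <- lapply(units, function(k) {
    rows <- ann[!is.na(ann$unit) & ann$unit == k, ]
    tss <- rows$start[rows$type == "gene" & rows$name %in% c("CsACS1", "CsACS1G")]
    prox <- rows$start[rows$type == "promoter_proximal"]
    dist <- rows$start[rows$type == "promoter_distal"]
    data.frame(unit = k,
               variant = locus$haplotype$units[k],
               proximal_from = -(tss - prox),
               distal_from = if (length(dist)) -(tss - dist) else NA_integer_)
  })
  do.call(rbind, out)
}

#' Reverse-complement a locus with its annotation
#'
#' Flips the sequence and maps every feature onto the opposite strand; all
#' feature lengths are preserved.
#'
#' @param locus a `flocus_locus`.
#' @return a `flocus_locus` on the opposite strand.
#' @export
revcomp_locus <- function(locus) {
  len <- length(locus$seq)
  ann <- locus$annotation
  new_start <- len - ann$end
  new_end <- len - ann$start
  ann$start <- new_start
  ann$end <- new_end
  ann$strand <- ifelse(ann$strand == "+", "-", "+")
  ann <- ann[order(ann$start, ann$end), ]
  rownames(ann) <- NULL
  out <- locus
  out$seq <- Biostrings::reverseComplement(locus$seq)
  out$annotation <- ann
  out
}

locus_granges <- function(locus, seqname = "F_locus") {
  ann <- locus$annotation
  gr <- GenomicRanges::GRanges(
    seqnames = seqname,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end),
    strand = ann$strand)
  S4Vectors::mcols(gr)$type <- ifelse(ann$type == "gene", "gene", "region")
  S4Vectors::mcols(gr)$ID <- ann$feature_id
  S4Vectors::mcols(gr)$Name <- ann$name
  S4Vectors::mcols(gr)$feature_class <- ann$type
  gr
}

#' Write locus artifacts
#'
#' FASTA (60-column wrap), GFF3 (1-based inclusive, via rtracklayer) and BED
#' intervals of the repeat units.
#'
#' @param locus a `flocus_locus`.
#' @param path output file.
#' @param seqname sequence name used in the files.
#' @return the path, invisibly.
#' @export
write_locus_fasta <- function(locus, path, seqname = "F_locus") {
  set <- Biostrings::DNAStringSet(list(locus$seq))
  names(set) <- seqname
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' @rdname write_locus_fasta
#' @export
write_locus_gff3 <- function(locus, path, seqname = "F_locus") {
  rtracklayer::export(locus_granges(locus, seqname), path, format = "gff3")
  invisible(path)
}

#' @rdname write_locus_fasta
#' @export
write_units_bed <- function(locus, path, seqname = "F_locus") {
  gr <- locus_granges(locus, seqname)
  gr <- gr[S4Vectors::mcols(gr)$feature_class == "repeat_unit"]
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    name = S4Vectors::mcols(gr)$Name)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
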