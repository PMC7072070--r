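#' Primer pair for in-silico PCR
#'
#' @param name label.
#' @param left_seq,right_seq primer sequences, 5'->3' as synthesised (the
#'   right primer anneals to the minus strand). At least 15 nt each.
#' @param max_product maximum product length (bp).
#' @return an object of class `flocus_primer_pair`.
#' @export
primer_pair <- function(name, left_seq, right_seq, max_product = 1000L) {
  left_seq <- toupper(as.character(left_seq))
  right_seq <- toupper(as.character(right_seq))
  if (nchar(left_seq) < 15L || nchar(right_seq) < 15L) {
    stop("sequence-based primers must be at least 15 nt")
  }
  structure(list(name = name, left_seq = left_seq, right_seq = right_seq,
                 max_product = as.integer(max_product)),
            class = "flocus_primer_pair")
}

#' Junction-spanning qPCR primer pair
#'
#' Derives, from the generator configuration, the primer pair that straddles
#' the recombinant-promoter/CsACS1 junction of a G unit: the left primer sits
#' near the BCAT exon-10 end of the 1504-bp promoter block, the right primer
#' just inside the proximal promoter (the start of CsACS1 sequence identity),
#' facing each other across the junction. With default offsets the product is
#' 111 bp. On a locus with no G unit the left primer has no plus-strand site
#' (its sequence occurs only reverse-complemented, inside the trailing
#' CsBCAT), so the primers point away from each other and no product forms.
#'
#' @param params [locus_params()]; must match the loci the pair will be used
#'   on (same seed and geometry).
#' @return a [primer_pair()].
#' @export
junction_primer_pair <- function(params = locus_params()) {
  p <- params
  loc <- assemble_locus_sequence(haplotype("G"), p)
  ann <- loc$annotation
  b <- ann$end[ann$type == "promoter_distal"][1]  # junction: core start
  seq <- as.character(loc$seq)
  lo <- p$junction_left_offset
  ro <- p$junction_right_offset
  len <- p$primer_length
  if (lo < len || ro < len) stop("primer length exceeds junction offsets")
  left <- substr(seq, b - lo + 1L, b - lo + len)
  right_site <- substr(seq, b + ro - len + 1L, b + ro)
  right <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(right_site)))
  primer_pair("F_junction", left, right, max_product = p$max_product)
}

#' In-silico PCR by exact primer matching
#'
#' Locates exact matches of both primers on both strands of the target and
#' reports every product in which a plus-strand primer site lies upstream of
#' a minus-strand primer site within `max_product` bp (facing orientation).
#' A primer absent from both strands raises a warning (distinct from the
#' orientation failure logged when sites exist but none face each other).
#'
#' @param x a `flocus_locus`, [Biostrings::DNAString] or character sequence.
#' @param primers a [primer_pair()].
#' @return data.frame with columns `product_length`, `start`, `end` (0-based
#'   half-open on the target), `fwd_primer`, `rev_primer`; zero rows when no
#'   product forms.
#' @export
insilico_pcr <- function(x, primers) {
  seq <- if (inherits(x, "flocus_locus")) x$seq
         else if (methods::is(x, "DNAString")) x
         else Biostrings::DNAString(as.character(x))
  prm <- list(left = primers$left_seq, right = primers$right_seq)

  empty <- data.frame(product_length = integer(0), start = integer(0),
                      end = integer(0), fwd_primer = character(0),
                      rev_primer = character(0), stringsAsFactors = FALSE)

  fwd <- list(); rev <- list()
  for (nm in names(prm)) {
    pat <- Biostrings::DNAString(prm[[nm]])
    plus <- Biostrings::start(Biostrings::matchPattern(pat, seq))
    minus <- Biostrings::start(
      Biostrings::matchPattern(Biostrings::reverseComplement(pat), seq))
    if (length(plus) == 0L && length(minus) == 0L) {
      warning("primer '", nm, "' of pair '", primers$name,
              "' not found on either strand")
      return(empty)
    }
    n <- nchar(prm[[nm]])
    if (length(plus)) {
      fwd[[nm]] <- data.frame(primer = nm, start0 = plus - 1L, len = n)
    }
    if (length(minus)) {
      rev[[nm]] <- data.frame(primer = nm, start0 = minus - 1L, len = n)
    }
  }
  fwd <- do.call(rbind, fwd)
  rev <- do.call(rbind, rev)
  if (is.null(fwd) || is.null(rev)) {
    message("primer pair '", primers$name,
            "': sites found but orientations oppose; no facing pair")
    return(empty)
  }

  out <- list()
  for (i in seq_len(nrow(fwd))) {
    for (j in seq_len(nrow(rev))) {
      p_start <- fwd$start0[i]
      p_end <- rev$start0[j] + rev$len[j]          # half-open end
      size <- p_end - p_start
      if (rev$start0[j] >= p_start + fwd$len[i] - 1L &&
          size >= max(fwd$len[i], rev$len[j]) &&
          size <= primers$max_product) {
        out[[length(out) + 1L]] <- data.frame(
          product_length = size, start = p_start, end = p_end,
          fwd_primer = fwd$primer[i], rev_primer = rev$primer[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    message("primer pair '", primers$name,
            "': no facing pair within max_product")
    return(empty)
  }
  res <- do.call(rbind, out)
  res[order(res$start), , drop = FALSE]
}

#' Junction products predicted from annotation alone
#'
#' Independent of the sequence search: one product per junction feature, with
#' length given by the configured primer offsets. Used to cross-check
#' [insilico_pcr()].
#'
#' @param locus a `flocus_locus`.
#' @return data.frame with `product_length`, `start`, `end` per junction.
#' @export
junction_products_from_annotation <- function(locus) {
  p <- locus$params
  ann <- locus$annotation
  b <- ann$end[ann$type == "promoter_distal"]  # core start of each G unit
  n <- length(b)
  data.frame(
    product_length = rep(p$junction_left_offset + p$junction_right_offset, n),
    start = b - p$junction_left_offset,
    end = b + p$junction_right_offset)
}
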