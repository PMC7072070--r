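#' Exon/intron gene model
#'
#' Minimal length-based gene model used to lay out the synthetic locus and to
#' assemble the recombinant CsACS1G distal promoter from CsBCAT parts.
#'
#' @param name gene name.
#' @param exon_lengths integer exon lengths (bp), 5'->3'.
#' @param intron_lengths integer intron lengths (bp); one fewer than exons.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `flocus_gene_model`.
#' @export
gene_model <- function(name, exon_lengths, intron_lengths, strand = "+") {
  exon_lengths <- as.integer(exon_lengths)
  intron_lengths <- as.integer(intron_lengths)
  if (length(intron_lengths) != length(exon_lengths) - 1L) {
    stop("need exactly length(exons) - 1 introns")
  }
  if (any(c(exon_lengths, intron_lengths) <= 0L)) {
    stop("all exon and intron lengths must be positive")
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(name = name, exon_lengths = exon_lengths,
                 intron_lengths = intron_lengths, strand = strand),
            class = "flocus_gene_model")
}

gene_length <- function(gm) sum(gm$exon_lengths) + sum(gm$intron_lengths)

# 0-based half-open coordinates of each exon/intron within the gene
gene_part_coords <- function(gm) {
  n <- length(gm$exon_lengths)
  parts <- character(0); lens <- integer(0)
  for (i in seq_len(n)) {
    parts <- c(parts, paste0("exon", i))
    lens <- c(lens, gm$exon_lengths[i])
    if (i < n) {
      parts <- c(parts, paste0("intron", i))
      lens <- c(lens, gm$intron_lengths[i])
    }
  }
  end <- cumsum(lens)
  data.frame(part = parts, start = end - lens, end = end, length = lens,
             stringsAsFactors = FALSE)
}

#' Default CsBCAT gene model
#'
#' Ten exons. Intron 8 (984 bp), exon 9 (113 bp), intron 9 (350 bp) and exon
#' 10 (113 bp) carry the lengths that define the recombinant CsACS1G distal
#' promoter; the remaining exon/intron lengths are nominal synthetic values.
#'
#' @return a [gene_model()].
#' @export
bcat_gene_model <- function() {
  gene_model("CsBCAT",
             exon_lengths   = c(rep(150L, 8), 113L, 113L),
             intron_lengths = c(rep(200L, 7), 984L, 350L))
}

#' Assemble the recombinant CsACS1G distal promoter
#'
#' The distal promoter of CsACS1G is the reverse-complemented run of CsBCAT
#' parts intron 8 (truncated), exon 9, intron 9 and exon 10, read 5'->3'
#' toward the gene, with exon 10 abutting the -410 proximal-promoter boundary.
#' With the default truncation (928 of 984 bp kept) the block totals 1504 bp
#' and the last 56 bp of intron 8 are missing.
#'
#' @param bcat a CsBCAT [gene_model()] with at least 10 exons.
#' @param truncate_intron8_to bp of intron 8 retained (from its 5' end).
#' @param bcat_seq optional full CsBCAT gene sequence (character); when given,
#'   the block sequence is assembled by reverse-complementing each component.
#' @return a list with `components` (per-part table with block coordinates,
#'   0-based half-open), `total_length`, `missing_tail` (bp of intron 8 lost),
#'   and `seq` (character, or `NULL` when no sequence was supplied).
#' @examples
#' build_recombinant_promoter()$total_length  # 1504
#' @export
build_recombinant_promoter <- function(bcat = bcat_gene_model(),
                                       truncate_intron8_to = 928L,
                                       bcat_seq = NULL) {
  if (length(bcat$exon_lengths) < 10L) {
    stop("the CsBCAT model must have at least 10 exons")
  }
  coords <- gene_part_coords(bcat)
  full_i8 <- coords$length[coords$part == "intron8"]
  truncate_intron8_to <- as.integer(truncate_intron8_to)
  if (truncate_intron8_to > full_i8) {
    stop("cannot keep ", truncate_intron8_to, " bp of a ", full_i8,
         "-bp intron 8")
  }
  if (truncate_intron8_to < 0L) stop("'truncate_intron8_to' must be >= 0")

  parts <- c("intron8", "exon9", "intron9", "exon10")
  lens <- c(truncate_intron8_to,
            coords$length[match(parts[-1], coords$part)])
  keep <- lens > 0L
  end <- cumsum(lens[keep])
  components <- data.frame(
    component = parts[keep],
    length = lens[keep],
    start = end - lens[keep],
    end = end,
    stringsAsFactors = FALSE
  )

  seq <- NULL
  if (!is.null(bcat_seq)) {
    bcat_seq <- as.character(bcat_seq)
    rc <- function(s) {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    }
    pick <- function(part, len) {
      i <- match(part, coords$part)
      substr(bcat_seq, coords$start[i] + 1L, coords$start[i] + len)
    }
    seq <- paste0(vapply(which(keep), function(k) {
      rc(pick(parts[k], lens[k]))
    }, character(1)), collapse = "")
  }

  list(components = components,
       total_length = sum(lens),
       missing_tail = full_i8 - truncate_intron8_to,
       seq = seq)
}
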