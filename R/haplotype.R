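#' Repeat-unit haplotypes and genotypes at the F locus
#'
#' The cucumber F locus is a tandem array of ~30.2-kb repeat units. Each unit
#' carries an ACS1-family gene plus CsMYB; a unit is of variant `"A"`
#' (CsACS1 with its native upstream context) or `"G"` (CsACS1G, the same core
#' preceded by a 1504-bp recombinant distal promoter derived from the CsBCAT
#' gene). A haplotype is the ordered 5'->3' list of units on one chromosome,
#' always followed by a complete CsBCAT gene downstream of the array.
#'
#' @param units character vector of unit variants (`"A"`/`"G"`), or a single
#'   string such as `"AG"`.
#' @param trailing_bcat logical; a complete CsBCAT gene lies downstream of the
#'   array (always `TRUE`: BCAT exons 1-8 are outside the CNV).
#' @return an object of class `flocus_haplotype`.
#' @examples
#' haplotype("AG")            # the gynoecious Gy14-like haplotype
#' haplotype(c("A", "G", "G")) # the triple-repeat AM297-like haplotype
#' @export
haplotype <- function(units, trailing_bcat = TRUE) {
  if (is.character(units) && length(units) == 1L && nchar(units) > 1L) {
    units <- strsplit(units, "")[[1]]
  }
  units <- as.character(units)
  if (length(units) < 1L || !all(units %in% c("A", "G"))) {
    stop("'units' must be a non-empty vector of \"A\"/\"G\" variants")
  }
  if (!isTRUE(trailing_bcat)) {
    stop("'trailing_bcat' must be TRUE: BCAT exons 1-8 lie outside the CNV")
  }
  structure(list(units = units, trailing_bcat = TRUE),
            class = "flocus_haplotype")
}

#' @export
print.flocus_haplotype <- function(x, ...) {
  cat("<F-locus haplotype> [", paste(x$units, collapse = ","),
      "] + CsBCAT\n", sep = "")
  invisible(x)
}

hap_key <- function(hap) paste(hap$units, collapse = "")

#' Number of repeat units in a haplotype
#' @param hap a [haplotype()].
#' @return integer count.
#' @export
n_units <- function(hap) length(hap$units)

#' CsACS1G (G-unit) dosage
#'
#' Functional dosage of the femaleness determinant: the count of G units.
#'
#' @param x a [haplotype()] or [genotype()].
#' @return integer G-unit count.
#' @export
g_dosage <- function(x) UseMethod("g_dosage")

#' @export
g_dosage.flocus_haplotype <- function(x) sum(x$units == "G")

#' @export
g_dosage.flocus_genotype <- function(x) {
  g_dosage(x$hap1) + g_dosage(x$hap2)
}

#' Diploid genotype at the F locus
#'
#' An unordered pair of haplotypes; the stored order is canonical so that
#' `genotype(a, b)` and `genotype(b, a)` are identical objects.
#'
#' @param hap1,hap2 [haplotype()] objects (or unit strings).
#' @return an object of class `flocus_genotype`.
#' @examples
#' genotype("AG", "A")  # subgynoecious heterozygote
#' @export
genotype <- function(hap1, hap2) {
  if (!inherits(hap1, "flocus_haplotype")) hap1 <- haplotype(hap1)
  if (!inherits(hap2, "flocus_haplotype")) hap2 <- haplotype(hap2)
  keys <- c(hap_key(hap1), hap_key(hap2))
  # canonical order: decreasing radix sort of the unit-string keys (must
  # match the aggregation key used in cross())
  ord <- order(keys, decreasing = TRUE, method = "radix")
  haps <- list(hap1, hap2)[ord]
  structure(list(hap1 = haps[[1]], hap2 = haps[[2]]),
            class = "flocus_genotype")
}

genotype_key <- function(g) paste(hap_key(g$hap1), hap_key(g$hap2), sep = "/")

#' @export
print.flocus_genotype <- function(x, ...) {
  cat("<F-locus genotype> ", genotype_key(x),
      "  (CsACS1G dosage ", g_dosage(x), ")\n", sep = "")
  invisible(x)
}

#' Parse haplotype / genotype string keys
#'
#' Keys are the compact strings used in population tables, e.g. `"AG"` for a
#' haplotype and `"AG/A"` for a genotype.
#'
#' @param key character key.
#' @return a [haplotype()] or [genotype()].
#' @export
parse_haplotype <- function(key) haplotype(strsplit(key, "")[[1]])

#' @rdname parse_haplotype
#' @export
parse_genotype <- function(key) {
  parts <- strsplit(key, "/", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop("genotype key must look like \"AG/A\"")
  genotype(parse_haplotype(parts[1]), parse_haplotype(parts[2]))
}

#' F-locus structure of reference cucumber lines
#'
#' Returns the homozygous genotype of one of the three structural classes:
#' the monecious single-unit line (9930-like, `[A]/[A]`), the gynoecious
#' two-unit line (Gy14-like, `[A,G]/[A,G]`), and the gynoecious triple-repeat
#' line (AM297-like, `[A,G,G]/[A,G,G]`). An explicit pair of unit vectors may
#' be given instead of a line name.
#'
#' @param line_name one of `"monecious_9930_like"`, `"gynoecious_Gy14_like"`,
#'   `"triple_AM297_like"`, or a list of two unit vectors/strings.
#' @return a [genotype()].
#' @examples
#' build_line_structure("gynoecious_Gy14_like")
#' build_line_structure(list("AGG", "A"))
#' @export
build_line_structure <- function(line_name) {
  if (is.list(line_name)) {
    if (length(line_name) != 2L) {
      stop("an explicit structure must be a list of two haplotype unit sets")
    }
    return(genotype(haplotype(line_name[[1]]), haplotype(line_name[[2]])))
  }
  lines <- list(
    monecious_9930_like  = "A",
    gynoecious_Gy14_like = "AG",
    triple_AM297_like    = "AGG"
  )
  if (!line_name %in% names(lines)) {
    stop("unknown line name '", line_name, "'; valid options: ",
         paste(names(lines), collapse = ", "))
  }
  h <- haplotype(lines[[line_name]])
  genotype(h, h)
}
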