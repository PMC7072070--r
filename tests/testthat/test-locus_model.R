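test_that("reference line structures carry the published G-unit dosages", {
  expect_equal(g_dosage(line9930()), 0L)
  expect_equal(g_dosage(gy14()), 2L)
  expect_equal(g_dosage(am297()), 4L)
  expect_equal(n_units(gy14()$hap1), 2L)
  expect_error(build_line_structure("no_such_line"), "valid options")
  g <- build_line_structure(list("AGG", "A"))
  expect_equal(g_dosage(g), 2L)
})

test_that("genotypes are swap-invariant unordered pairs", {
  a <- genotype("AG", "A")
  b <- genotype("A", "AG")
  expect_identical(a, b)
  expect_identical(parse_genotype("A/AG"), a)
})

test_that("recombinant promoter arithmetic matches the BCAT-derived block", {
  prom <- build_recombinant_promoter()
  expect_equal(prom$total_length, 1504)
  expect_equal(prom$missing_tail, 56)
  expect_equal(prom$components$length, c(928, 113, 350, 113))
  # fully dropping intron 8 leaves exon9 + intron9 + exon10
  expect_equal(build_recombinant_promoter(truncate_intron8_to = 0)$total_length,
               113 + 350 + 113)
  expect_error(build_recombinant_promoter(truncate_intron8_to = 1000),
               "cannot keep")
  expect_error(build_recombinant_promoter(gene_model("x", c(10, 10), 5)),
               "at least 10 exons")
})

test_that("recombinant promoter sequence reverse-complements each component", {
  gm <- bcat_gene_model()
  raw_len <- sum(gm$exon_lengths) + sum(gm$intron_lengths)
  bcat_seq <- substr(paste(rep("ACGT", ceiling(raw_len / 4)), collapse = ""),
                     1, raw_len)
  prom <- build_recombinant_promoter(bcat_seq = bcat_seq)
  expect_equal(nchar(prom$seq), 1504)
  # the block must end with the reverse complement of exon 10, which
  # occupies the last 113 bases of the gene
  exon10 <- substr(bcat_seq, raw_len - 113 + 1, raw_len)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exon10)))
  expect_equal(substr(prom$seq, 1504 - 113 + 1, 1504), rc)
})

test_that("assembled loci have the expected structure and annotation", {
  p <- small_params()
  locA <- assemble_locus_sequence(haplotype("A"), p)
  locG <- assemble_locus_sequence(haplotype("AG"), p)
  locT <- assemble_locus_sequence(haplotype("AGG"), p)

  # total length = flanks + units + trailing BCAT
  bcat_len <- sum(p$bcat$exon_lengths) + sum(p$bcat$intron_lengths)
  expect_equal(length(locA$seq),
               p$flank5 + p$a_unit_length + bcat_len + p$flank3)
  # a G unit exceeds an A unit by exactly the 1504-bp promoter block
  unit_len <- function(loc, k) {
    r <- loc$annotation[loc$annotation$type == "repeat_unit" &
                        loc$annotation$unit == k, ]
    r$end - r$start
  }
  expect_equal(unit_len(locG, 2) - unit_len(locG, 1), 1504)
  # adding one G unit adds exactly one G-unit length to the locus
  expect_equal(length(locT$seq) - length(locG$seq), p$g_unit_length)
  expect_equal(length(locG$seq) - length(locA$seq), p$g_unit_length)

  # gene order along each haplotype
  genes <- function(loc) {
    ann <- loc$annotation
    ann$name[ann$type == "gene"][order(ann$start[ann$type == "gene"])]
  }
  expect_equal(genes(locA), c("CsACS1", "CsMYB", "CsBCAT"))
  expect_equal(genes(locG), c("CsACS1", "CsMYB", "CsACS1G", "CsMYB", "CsBCAT"))

  # junction features: one per G unit
  n_junctions <- function(loc) sum(loc$annotation$type == "junction")
  expect_equal(n_junctions(locA), 0L)
  expect_equal(n_junctions(locG), 1L)
  expect_equal(n_junctions(locT), 2L)

  # promoter offsets relative to the TSS: -410 proximal, -1914 distal
  off <- promoter_offsets(locT)
  expect_true(all(off$proximal_from == -410))
  expect_equal(off$distal_from[off$variant == "G"], c(-1914, -1914))
  expect_true(is.na(off$distal_from[off$variant == "A"]))
})

test_that("assembly is deterministic per seed and seed-sensitive", {
  p <- small_params(seed = 7)
  l1 <- assemble_locus_sequence(haplotype("AG"), p)
  l2 <- assemble_locus_sequence(haplotype("AG"), p)
  expect_identical(as.character(l1$seq), as.character(l2$seq))
  expect_identical(l1$annotation, l2$annotation)
  l3 <- assemble_locus_sequence(haplotype("AG"), small_params(seed = 8))
  expect_false(identical(as.character(l1$seq), as.character(l3$seq)))
})

test_that("A and G unit cores are byte-identical unless SNPs are injected", {
  p <- small_params()
  loc <- assemble_locus_sequence(haplotype("AG"), p)
  ann <- loc$annotation
  s <- as.character(loc$seq)
  unit <- function(k) {
    r <- ann[ann$type == "repeat_unit" & ann$unit == k, ]
    substr(s, r$start + 1, r$end)
  }
  coreA <- unit(1)
  coreG <- substr(unit(2), 1505, nchar(unit(2)))
  expect_identical(coreA, coreG)

  p2 <- small_params(inject_snps = TRUE)
  loc2 <- assemble_locus_sequence(haplotype("AG"), p2)
  s2 <- as.character(loc2$seq)
  ann2 <- loc2$annotation
  u <- function(k) {
    r <- ann2[ann2$type == "repeat_unit" & ann2$unit == k, ]
    substr(s2, r$start + 1, r$end)
  }
  diff <- mapply(function(a, b) a != b,
                 strsplit(u(1), "")[[1]],
                 strsplit(substr(u(2), 1505, nchar(u(2))), "")[[1]])
  expect_equal(sum(diff), 2L)
})

test_that("reverse-complement round trip preserves feature lengths", {
  p <- small_params()
  loc <- assemble_locus_sequence(haplotype("AGG"), p)
  rc <- revcomp_locus(loc)
  expect_equal(sort(rc$annotation$end - rc$annotation$start),
               sort(loc$annotation$end - loc$annotation$start))
  expect_true(all(rc$annotation$strand == "-"))
  # double flip restores the original coordinates
  back <- revcomp_locus(rc)
  a <- loc$annotation[order(loc$annotation$feature_id), ]
  b <- back$annotation[order(back$annotation$feature_id), ]
  expect_equal(a$start, b$start)
  expect_equal(a$end, b$end)
  expect_identical(as.character(back$seq), as.character(loc$seq))
})

test_that("junction in-silico PCR yields one 111-bp product per G unit", {
  p <- small_params()
  primers <- junction_primer_pair(p)
  for (case in list(list("A", 0L), list("AG", 1L), list("AGG", 2L))) {
    loc <- assemble_locus_sequence(haplotype(case[[1]]), p)
    prod <- suppressMessages(insilico_pcr(loc, primers))
    expect_equal(nrow(prod), case[[2]])
    if (case[[2]] > 0) {
      expect_true(all(prod$product_length == 111))
    }
    # annotation route agrees with the sequence search
    ann_prod <- junction_products_from_annotation(loc)
    expect_equal(nrow(ann_prod), nrow(prod))
    expect_equal(ann_prod$product_length, prod$product_length)
    expect_equal(ann_prod$start, prod$start)
  }
})

test_that("in-silico PCR distinguishes missing primers from bad orientation", {
  p <- small_params()
  loc <- assemble_locus_sequence(haplotype("A"), p)
  primers <- junction_primer_pair(p)
  # both primer sites exist on the monecious locus, but they face away
  expect_message(res <- insilico_pcr(loc, primers), "orientations oppose")
  expect_equal(nrow(res), 0L)
  absent <- primer_pair("absent", strrep("ACGTT", 4), strrep("TTGCA", 4))
  expect_warning(res2 <- insilico_pcr(loc, absent), "not found")
  expect_equal(nrow(res2), 0L)
})

test_that("FASTA/GFF3/BED round-trip through rtracklayer/Biostrings", {
  p <- small_params()
  loc <- assemble_locus_sequence(haplotype("AG"), p)
  fa <- tempfile(fileext = ".fasta")
  gff <- tempfile(fileext = ".gff3")
  bed <- tempfile(fileext = ".bed")
  write_locus_fasta(loc, fa)
  write_locus_gff3(loc, gff)
  write_units_bed(loc, bed)

  seq_in <- Biostrings::readDNAStringSet(fa)
  expect_equal(as.character(seq_in[[1]]), as.character(loc$seq))

  gff_in <- rtracklayer::import(gff)
  expect_equal(length(gff_in), nrow(loc$annotation))
  # GFF3 is 1-based inclusive: starts shift by one
  expect_setequal(BiocGenerics::start(gff_in), loc$annotation$start + 1L)

  bed_in <- rtracklayer::import(bed)
  expect_equal(length(bed_in), 2L)  # two repeat units
  expect_equal(sum(BiocGenerics::width(bed_in)),
               p$a_unit_length + p$g_unit_length)
})
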