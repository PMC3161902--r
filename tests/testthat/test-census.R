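test_that("trinucleotide categories partition all inputs", {
  expect_identical(categorize_trinucleotide(c("CCA", "CCG", "CCC", "CAT",
                                              "CTA", "GCA", "ACA", "CC", "")),
                   c("CCA", "CCN", "CCN", "CNN", "CNN", "OTHER", "OTHER",
                     "TRUNCATED", "TRUNCATED"))
  # every trinucleotide falls in exactly one category
  b <- c("A", "C", "G", "T")
  tri <- as.vector(outer(outer(b, b, paste0), b, paste0))
  cats <- categorize_trinucleotide(tri)
  expect_true(all(cats %in% c("CCA", "CCN", "CNN", "OTHER")))
  expect_equal(sum(cats == "CCA"), 1L)
  expect_equal(sum(cats == "CCN"), 3L)
  expect_equal(sum(cats == "CNN"), 12L)
  expect_equal(sum(cats == "OTHER"), 48L)
  # RNA input is normalized
  expect_identical(categorize_trinucleotide("CCU"), "CCN")
})

test_that("extract_trinucleotide reads the coding-strand downstream bases", {
  genome <- c(chr = "AAAATTTTCCAGGAAA")
  plus <- data.frame(gene_id = "g1", seq_id = "chr", start = 2L, end = 8L,
                     strand = "+", stringsAsFactors = FALSE)
  rec <- extract_trinucleotide(genome, plus)
  expect_identical(rec$trinucleotide, "CCA")
  expect_identical(rec$category, "CCA")

  # minus-strand gene whose upstream-on-genome bases are TGG -> CCA
  genome2 <- c(chr = "AAATGGCCCCTTTTAA")
  minus <- data.frame(gene_id = "g2", seq_id = "chr", start = 6L, end = 12L,
                      strand = "-", stringsAsFactors = FALSE)
  rec2 <- extract_trinucleotide(genome2, minus)
  expect_identical(rec2$trinucleotide, "CCA")

  # clipping at the contig edge truncates
  short <- data.frame(gene_id = "g3", seq_id = "chr", start = 2L, end = 14L,
                      strand = "+", stringsAsFactors = FALSE)
  expect_identical(extract_trinucleotide(genome, short)$category, "TRUNCATED")

  expect_error(extract_trinucleotide(genome, transform(plus, seq_id = "nope")),
               "unknown seq_id")
  expect_error(extract_trinucleotide(genome, transform(plus, strand = ".")),
               "strand")
})

test_that("strand handling matches the whole-genome reverse-complement oracle", {
  for (seed in 1:5) {
    g <- synth_genome(mixture = c(cca = 4, ccn = 3, cnn = 6, other = 7),
                      seed = seed)
    fwd <- extract_trinucleotide(g$genome, g$genes)
    fl <- flip_genome(g$genome, g$genes)
    rev <- extract_trinucleotide(fl$genome, fl$genes)
    expect_identical(fwd$trinucleotide, rev$trinucleotide)
    expect_identical(fwd$category, g$truth$category)
  }
})

test_that("tabulate_census reproduces published-style rows with round-half-up", {
  row <- tabulate_census(counts = c(cca = 0, ccn = 1, cnn = 11, total = 37),
                         label = "Arabidopsis thaliana")
  expect_equal(row$percent, 32)           # 12/37 = 32.43 -> 32
  expect_equal(tabulate_census(counts = c(cca = 2, ccn = 3, cnn = 5, total = 29))$percent,
               34)                         # 10/29 = 34.48 -> 34
  expect_equal(tabulate_census(counts = c(cca = 0, ccn = 0, cnn = 0, total = 10))$percent,
               0)
  expect_equal(tabulate_census(counts = c(cca = 1, ccn = 0, cnn = 0, total = 8))$percent,
               13)                         # 12.5 rounds half up
  expect_error(tabulate_census(data.frame()), "no census records")
  expect_error(tabulate_census(counts = c(cca = 0, ccn = 0, cnn = 0, total = 0)),
               "zero")
})

test_that("census_pipeline recovers the planted category mixture", {
  g <- synth_genome(mixture = c(cca = 3, ccn = 2, cnn = 5, other = 10), seed = 42)
  cs <- census_pipeline(g$genome, g$genes, label = "synthetic")
  expect_equal(cs$row$n_cca, 3L)
  expect_equal(cs$row$n_ccn, 2L)
  expect_equal(cs$row$n_cnn, 5L)
  expect_equal(cs$row$n_total, 20L)
  expect_equal(cs$row$percent, 50)
  expect_identical(cs$per_gene$gene_id, g$genes$gene_id)
  expect_identical(cs$per_gene$category, g$truth$category)
})

test_that("the census is invariant under genome reverse complement", {
  for (seed in c(7, 8, 9)) {
    g <- synth_genome(n_genes = 30,
                      mixture = c(cca = 5, ccn = 5, cnn = 10, other = 10),
                      frac_minus = 0.4, seed = seed)
    row_fwd <- census_pipeline(g$genome, g$genes, label = "x")$row
    fl <- flip_genome(g$genome, g$genes)
    row_rev <- census_pipeline(fl$genome, fl$genes, label = "x")$row
    expect_identical(row_fwd, row_rev)
  }
})

test_that("BED and GFF3 annotations give identical census rows", {
  g <- synth_genome(mixture = c(cca = 2, ccn = 2, cnn = 2, other = 4), seed = 5)
  bed <- tempfile(fileext = ".bed")
  gff <- tempfile(fileext = ".gff3")
  write_annotations(g$genes, bed, format = "bed")
  write_annotations(g$genes, gff, format = "gff3")
  row_bed <- census_pipeline(g$genome, read_annotations(bed), label = "x")$row
  row_gff <- census_pipeline(g$genome, read_annotations(gff), label = "x")$row
  expect_identical(row_bed, row_gff)
  expect_equal(row_bed$n_total, 10L)
})

test_that("shifting gene ends by one changes categories as the genome predicts", {
  g <- synth_genome(mixture = c(cca = 5, ccn = 5, cnn = 5, other = 5), seed = 77)
  shifted <- g$genes
  shifted$end <- shifted$end + ifelse(shifted$strand == "+", 1L, 0L)
  shifted$start <- shifted$start - ifelse(shifted$strand == "-", 1L, 0L)
  rec <- extract_trinucleotide(g$genome, shifted)
  contig <- g$genome[["synth_contig"]]
  for (i in seq_len(nrow(shifted))) {
    gn <- shifted[i, ]
    pred <- if (gn$strand == "+") substr(contig, gn$end + 1L, gn$end + 3L)
    else as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(substr(contig, gn$start - 2L, gn$start))))
    expect_identical(rec$trinucleotide[i], pred)
  }
  # equivalently: the discriminator-excluded convention reproduces the
  # unshifted genes' windows one base further downstream
  rec2 <- extract_trinucleotide(g$genome, g$genes, discriminator_included = FALSE)
  expect_identical(rec2$trinucleotide, rec$trinucleotide)
})
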