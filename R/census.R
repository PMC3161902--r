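#' Categorize a post-discriminator trinucleotide
#'
#' tRNase Z cleaves immediately after the discriminator (N73), and the CCA
#' needed at tRNA positions 74-76 may be partly encoded in the gene. The
#' trinucleotide read 5'-to-3' on the coding strand immediately downstream
#' of the discriminator is binned as: `CCA` (full CCA encoded), `CCN`
#' (first two bases, third not A), `CNN` (first C only, second not C),
#' `OTHER` (first base not C), or `TRUNCATED` (fewer than three bases
#' available). The categories partition all inputs.
#'
#' @param trinucleotide Character vector of trinucleotides over
#'   `A`/`C`/`G`/`T`/`N` (RNA `U` is normalized to `T`); strings shorter
#'   than 3 are `TRUNCATED`.
#' @return Character vector of categories.
#' @examples
#' categorize_trinucleotide(c("CCA", "CCG", "CTT", "GCA", "CC"))
#' @export
categorize_trinucleotide <- function(trinucleotide) {
  tri <- chartr("Uu", "Tt", toupper(trinucleotide))
  vapply(tri, function(t) {
    if (is.na(t) || nchar(t) < 3L) return("TRUNCATED")
    b <- strsplit(t, "", fixed = TRUE)[[1L]][1:3]
    if (b[1L] != "C") "OTHER"
    else if (b[2L] != "C") "CNN"
    else if (b[3L] != "A") "CCN"
    else "CCA"
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the post-discriminator trinucleotide of a tRNA gene
#'
#' Gene spans are 0-based half-open on the genome and are assumed to end at
#' the discriminator (its last base is N73), so positions 74-76 are the
#' first three bases downstream of the span on the coding strand. For a
#' plus-strand gene that is genomic `[end, end + 3)`; for a minus-strand
#' gene it is the reverse complement of genomic `[start - 3, start)`.
#' Windows clipped by a contig edge yield category `TRUNCATED`.
#'
#' @param genome Named character vector of contig sequences (DNA, uppercase
#'   enforced), or a `Biostrings::DNAStringSet`.
#' @param genes Data frame of tRNA genes with columns `gene_id`, `seq_id`,
#'   `start`, `end` (0-based half-open), `strand` (`+`/`-`), e.g. from
#'   [read_annotations()].
#' @param discriminator_included If `FALSE`, gene spans are taken to stop
#'   one base before the discriminator and the window shifts right by one.
#' @return Data frame with `gene_id`, `trinucleotide`, `category`.
#' @export
extract_trinucleotide <- function(genome, genes, discriminator_included = TRUE) {
  genome <- as_genome_store(genome)
  shift <- if (discriminator_included) 0L else 1L
  need <- c("gene_id", "seq_id", "start", "end", "strand")
  if (!all(need %in% names(genes))) stop("'genes' lacks columns: ",
                                         paste(setdiff(need, names(genes)), collapse = ", "))
  tri <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (!g$seq_id %in% names(genome)) stop("unknown seq_id: ", g$seq_id)
    if (!g$strand %in% c("+", "-")) stop("malformed strand for gene ", g$gene_id)
    contig <- genome[[g$seq_id]]
    clen <- nchar(contig)
    if (g$strand == "+") {
      from <- g$end + shift           # 0-based
      if (from + 3L > clen) return(NA_character_)
      substr(contig, from + 1L, from + 3L)
    } else {
      to <- g$start - shift           # 0-based exclusive
      if (to - 3L < 0L) return(NA_character_)
      revcomp(substr(contig, to - 2L, to))
    }
  }, character(1))
  data.frame(gene_id = genes$gene_id,
             trinucleotide = tri,
             category = categorize_trinucleotide(tri),
             stringsAsFactors = FALSE)
}

# accept a DNAStringSet or a named character vector; normalize to the latter
as_genome_store <- function(genome) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  if (!is.character(genome) || is.null(names(genome)))
    stop("'genome' must be a named character vector or DNAStringSet")
  setNames(chartr("Uu", "Tt", toupper(genome)), names(genome))
}

revcomp <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Tabulate census records into a per-genome summary row
#'
#' Counts the CCA/CCN/CNN categories and reports the integer percentage of
#' examined genes that encode the whole or a leading part of the CCA
#' (round-half-up, which reproduces the published per-genome percentages
#' exactly from their printed counts). `OTHER` genes count toward the total
#' examined; `TRUNCATED` records are reported separately and excluded from
#' both numerator and total by default.
#'
#' @param records Data frame from [extract_trinucleotide()] (needs a
#'   `category` column), or `NULL` when passing `counts` directly.
#' @param label Genome/species label for the row.
#' @param counts Optional named numeric vector with elements `cca`, `ccn`,
#'   `cnn`, `total` to tabulate pre-counted data (e.g. a published table
#'   row) without records.
#' @param include_truncated_in_total Count `TRUNCATED` records in the total
#'   examined (default `FALSE`).
#' @return A one-row data frame of class `trz_census_row`: `label`, `n_cca`,
#'   `n_ccn`, `n_cnn`, `n_other`, `n_truncated`, `n_total`, `percent`.
#' @examples
#' tabulate_census(counts = c(cca = 0, ccn = 1, cnn = 11, total = 37),
#'                 label = "Arabidopsis thaliana")  # percent 32
#' @export
tabulate_census <- function(records = NULL, label = "genome", counts = NULL,
                            include_truncated_in_total = FALSE) {
  if (is.null(counts)) {
    if (is.null(records) || nrow(records) == 0L)
      stop("no census records to tabulate")
    tab <- table(factor(records$category,
                        levels = c("CCA", "CCN", "CNN", "OTHER", "TRUNCATED")))
    n_cca <- tab[["CCA"]]; n_ccn <- tab[["CCN"]]; n_cnn <- tab[["CNN"]]
    n_other <- tab[["OTHER"]]; n_trunc <- tab[["TRUNCATED"]]
    n_total <- n_cca + n_ccn + n_cnn + n_other +
      if (include_truncated_in_total) n_trunc else 0L
  } else {
    n_cca <- counts[["cca"]]; n_ccn <- counts[["ccn"]]; n_cnn <- counts[["cnn"]]
    n_total <- counts[["total"]]
    n_other <- n_total - n_cca - n_ccn - n_cnn
    n_trunc <- 0L
  }
  if (n_total < 1L) stop("no usable census records (total examined is zero)")
  percent <- round_half_up(100 * (n_cca + n_ccn + n_cnn) / n_total)
  out <- data.frame(label = label, n_cca = n_cca, n_ccn = n_ccn, n_cnn = n_cnn,
                    n_other = n_other, n_truncated = n_trunc,
                    n_total = n_total, percent = percent,
                    stringsAsFactors = FALSE)
  class(out) <- c("trz_census_row", "data.frame")
  out
}

# round-half-up to integer (R's round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

#' @export
print.trz_census_row <- function(x, ...) {
  cat(sprintf("<trz_census_row> %s: CCA=%d CCN=%d CNN=%d other=%d (trunc=%d) / %d genes, %d%%\n",
              x$label, x$n_cca, x$n_ccn, x$n_cnn, x$n_other, x$n_truncated,
              x$n_total, x$percent))
  invisible(x)
}

#' Run the chloroplast tRNA CCA census on a genome
#'
#' Composition of [extract_trinucleotide()] and [tabulate_census()] over
#' standard files or in-memory objects: classify every annotated tRNA gene's
#' post-discriminator trinucleotide and summarize the genome.
#'
#' @param genome Path to a genome FASTA, a named character vector, or a
#'   `DNAStringSet`.
#' @param annotations Path to a GFF3/BED/TSV annotation file, or a data
#'   frame of genes (see [read_annotations()]).
#' @param label Row label.
#' @param feature GFF3 feature type to keep (default `"tRNA"`).
#' @param discriminator_included See [extract_trinucleotide()].
#' @param per_gene_out,row_out Optional TSV output paths.
#' @return A list of class `trz_census`: `row` (`trz_census_row`) and
#'   `per_gene` (record data frame in annotation order).
#' @export
census_pipeline <- function(genome, annotations, label = "genome",
                            feature = "tRNA", discriminator_included = TRUE,
                            per_gene_out = NULL, row_out = NULL) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- read_fasta(genome, type = "DNA")
  genes <- if (is.data.frame(annotations)) annotations
  else read_annotations(annotations, feature = feature)
  if (nrow(genes) == 0L)
    stop("no tRNA features found in annotations")
  per_gene <- extract_trinucleotide(genome, genes,
                                    discriminator_included = discriminator_included)
  row <- tabulate_census(per_gene, label = label)
  if (!is.null(per_gene_out))
    utils::write.table(per_gene, per_gene_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(row_out))
    utils::write.table(as.data.frame(row), row_out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  structure(list(row = row, per_gene = per_gene), class = "trz_census")
}

#' @export
print.trz_census <- function(x, ...) {
  print(x$row)
  invisible(x)
}

#' Generate a synthetic mini chloroplast genome with planted tRNA genes
#'
#' Plants `n_genes` non-overlapping tRNA-sized genes (70-90 bp) on both
#' strands of a single random contig, and writes each gene's
#' post-discriminator trinucleotide so that the per-gene census categories
#' follow the requested mixture exactly. Minus-strand genes are realized by
#' reverse complement. Deterministic for a fixed seed.
#'
#' @param n_genes Number of genes; must equal `sum(mixture)`.
#' @param mixture Named integer vector `c(cca=, ccn=, cnn=, other=)`.
#' @param frac_minus Fraction of genes on the minus strand.
#' @param intergenic_mean Mean intergenic spacer length (minimum 10 bp is
#'   always kept so neighbouring trinucleotide windows cannot collide).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return A list with `genome` (named character vector, one contig),
#'   `genes` (annotation data frame, 0-based half-open), and `truth` (data
#'   frame `gene_id`, `category`, `trinucleotide`).
#' @examples
#' g <- synth_genome(mixture = c(cca = 3, ccn = 2, cnn = 5, other = 10), seed = 42)
#' census_pipeline(g$genome, g$genes, label = "synthetic")$row$percent  # 50
#' @export
synth_genome <- function(n_genes = sum(mixture),
                         mixture = c(cca = 3L, ccn = 2L, cnn = 5L, other = 10L),
                         frac_minus = 0.5, intergenic_mean = 40, seed = NULL) {
  stopifnot(all(c("cca", "ccn", "cnn", "other") %in% names(mixture)))
  if (sum(mixture) != n_genes) stop("mixture counts must sum to n_genes")
  if (frac_minus < 0 || frac_minus > 1) stop("frac_minus must be in [0, 1]")
  with_seed(seed, {
    cats <- sample(rep(c("CCA", "CCN", "CNN", "OTHER"), times = mixture[c("cca", "ccn", "cnn", "other")]))
    n_minus <- round(frac_minus * n_genes)
    strands <- sample(c(rep("-", n_minus), rep("+", n_genes - n_minus)))
    tri <- vapply(cats, sample_trinucleotide, character(1))
    bases <- c("A", "C", "G", "T")
    spacer <- function() {
      n <- max(10L, stats::rpois(1L, intergenic_mean))
      paste(sample(bases, n, replace = TRUE), collapse = "")
    }
    pieces <- character(); pos <- 0L
    starts <- integer(); ends <- integer()
    contig_chunks <- list()
    for (i in seq_len(n_genes)) {
      sp <- spacer()
      glen <- sample(70:90, 1L)
      body <- paste(sample(bases, glen, replace = TRUE), collapse = "")
      if (strands[i] == "+") {
        # trinucleotide occupies the first 3 bases of the downstream spacer
        chunk <- paste0(sp, body)
        starts <- c(starts, pos + nchar(sp))
        pos <- pos + nchar(chunk)
        ends <- c(ends, pos)
        contig_chunks[[length(contig_chunks) + 1L]] <- chunk
        contig_chunks[[length(contig_chunks) + 1L]] <- tri[i]
        pos <- pos + 3L
      } else {
        # coding-strand trinucleotide maps to revcomp just upstream on genome
        chunk <- paste0(sp, revcomp(tri[i]), body)
        starts <- c(starts, pos + nchar(sp) + 3L)
        pos <- pos + nchar(chunk)
        ends <- c(ends, pos)
        contig_chunks[[length(contig_chunks) + 1L]] <- chunk
      }
    }
    contig_chunks[[length(contig_chunks) + 1L]] <- spacer()
    contig <- paste(unlist(contig_chunks), collapse = "")
    ids <- sprintf("trna_%03d", seq_len(n_genes))
    list(genome = c(synth_contig = contig),
         genes = data.frame(gene_id = ids, seq_id = "synth_contig",
                            start = starts, end = ends, strand = strands,
                            stringsAsFactors = FALSE),
         truth = data.frame(gene_id = ids, category = unname(cats),
                            trinucleotide = unname(tri),
                            stringsAsFactors = FALSE))
  })
}

# draw a concrete trinucleotide from a category's string set
sample_trinucleotide <- function(category) {
  non_a <- c("C", "G", "T"); non_c <- c("A", "G", "T"); any4 <- c("A", "C", "G", "T")
  switch(category,
         CCA = "CCA",
         CCN = paste0("CC", sample(non_a, 1L)),
         CNN = paste0("C", sample(non_c, 1L), sample(any4, 1L)),
         OTHER = paste0(sample(non_c, 1L), sample(any4, 1L), sample(any4, 1L)),
         stop("unknown category: ", category))
}
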