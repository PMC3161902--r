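#' Read a FASTA file
#'
#' Order-preserving FASTA reader (via Biostrings) returning uppercase
#' sequences; duplicate record identifiers and empty records are rejected.
#' Identifiers are the first whitespace-delimited token of each header.
#'
#' @param path FASTA path.
#' @param type `"AA"` for protein, `"DNA"` for nucleotide (RNA `U` is
#'   normalized to `T`).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
  else Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (type == "DNA") seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) stop("empty FASTA record(s): ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(sequences)) {
    writeLines(paste0(">", id), con)
    s <- sequences[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read tRNA gene annotations
#'
#' Reads GFF3 (1-based closed), BED (0-based half-open) or a simple
#' 5-column TSV (`gene_id`, `seq_id`, `start`, `end`, `strand`, already
#' 0-based half-open) and normalizes everything to the internal 0-based
#' half-open convention. GFF3/BED parsing goes through rtracklayer.
#'
#' @param path Annotation file path.
#' @param format `"auto"` (by extension), `"gff3"`, `"bed"` or `"tsv"`.
#' @param feature GFF3 feature type to keep (default `"tRNA"`; ignored for
#'   BED/TSV).
#' @return Data frame `gene_id`, `seq_id`, `start`, `end`, `strand`.
#' @export
read_annotations <- function(path, format = c("auto", "gff3", "bed", "tsv"),
                             feature = "tRNA") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gff = , gff3 = "gff3", bed = "bed", tsv = , txt = "tsv",
                     stop("cannot infer annotation format from extension '", ext, "'"))
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "seq_id", "start", "end", "strand")
    if (!all(need %in% names(df)))
      stop("TSV annotations lack columns: ",
           paste(setdiff(need, names(df)), collapse = ", "))
    out <- df[, need]
  } else if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    if (!is.null(gr$type) && feature %in% as.character(gr$type))
      gr <- gr[as.character(gr$type) == feature]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else paste0("feat", seq_along(gr))
    out <- data.frame(gene_id = ids,
                      seq_id = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,  # to 0-based
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  } else {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if (!is.null(gr$name)) as.character(gr$name) else paste0("feat", seq_along(gr))
    out <- data.frame(gene_id = ids,
                      seq_id = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE)
  }
  bad <- which(out$start >= out$end)
  if (length(bad)) stop("inverted coordinates (start >= end) in record(s): ",
                        paste(out$gene_id[bad], collapse = ", "))
  bad <- which(!out$strand %in% c("+", "-"))
  if (length(bad)) stop("unknown strand for record(s): ",
                        paste(out$gene_id[bad], collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Write tRNA gene annotations
#'
#' Writes internal 0-based half-open gene records as GFF3, BED6 or TSV
#' (GFF3/BED through rtracklayer, with the coordinate conversions those
#' formats require).
#'
#' @param genes Data frame with `gene_id`, `seq_id`, `start`, `end`,
#'   `strand`.
#' @param path Output path.
#' @param format `"gff3"`, `"bed"` or `"tsv"`.
#' @param feature GFF3 feature type to write.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genes, path, format = c("gff3", "bed", "tsv"),
                              feature = "tRNA") {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(genes[, c("gene_id", "seq_id", "start", "end", "strand")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genes$seq_id,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  if (format == "gff3") {
    gr$ID <- genes$gene_id
    gr$type <- feature
    gr$source <- "trzsurvey"
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    gr$name <- genes$gene_id
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Classify every protein in a FASTA and summarize the survey
#'
#' The per-protein survey pipeline: read (or accept) the candidate protein
#' sequences, classify each with [classify_type()], and tally the calls by
#' type. Deterministic: identical inputs give identical outputs.
#'
#' @param proteins Path to a protein FASTA or a named character vector.
#' @param catalog Motif catalog.
#' @param out Optional TSV path for the typing table.
#' @param evidence_out Optional JSON path for the per-protein evidence dump
#'   (motif presence and arm descriptors).
#' @return A list of class `trz_survey`: `typing` (a `trz_typing` data
#'   frame) and `summary` (named counts by type).
#' @export
run_survey <- function(proteins, catalog = trz_catalog(), out = NULL,
                       evidence_out = NULL) {
  seqs <- if (is.character(proteins) && length(proteins) == 1L &&
              file.exists(proteins)) read_fasta(proteins, "AA") else proteins
  if (!length(seqs)) stop("no protein sequences supplied")
  typing <- trz_classify(seqs, catalog)
  counts <- table(typing$type)
  if (!is.null(out))
    utils::write.table(as.data.frame(typing), out, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(evidence_out)) {
    ev <- lapply(attr(typing, "results"), function(r)
      list(protein_id = r$protein_id, length = r$length, form = r$form,
           type = r$ztype, missing_required = r$missing_required,
           arm = r$arm[c("start", "end", "length", "arm_type",
                         "has_gp", "has_kl")]))
    names(ev) <- typing$protein_id
    jsonlite::write_json(ev, evidence_out, auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(typing = typing,
                 summary = setNames(as.integer(counts), names(counts))),
            class = "trz_survey")
}

#' @export
print.trz_survey <- function(x, ...) {
  cat(sprintf("<trz_survey> %d proteins\n", nrow(x$typing)))
  for (ty in names(x$summary)) cat(sprintf("  %-14s %d\n", ty, x$summary[[ty]]))
  invisible(x)
}

#' Write a synthetic truth object to JSON
#'
#' Coordinates are emitted 0-based half-open, with the generator seed for
#' provenance.
#'
#' @param truth A `trz_truth`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "trz_truth"))
  jsonlite::write_json(
    list(ztype = truth$ztype, length = truth$length,
         seed = truth$seed, junction = truth$junction, arm = truth$arm,
         coordinates = "0-based half-open",
         motifs = truth$motifs, knockouts = truth$knockouts),
    path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
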