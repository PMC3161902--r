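#' Strong conservation groups used for percent similarity
#'
#' The widely used "strong" amino-acid conservation groups; two aligned
#' residues are counted similar when identical or members of the same group.
#' @return List of character vectors.
#' @export
strong_groups <- function() {
  lapply(c("STA", "NEQK", "NHQK", "NDEQ", "QHRK", "MILV", "MILF", "HY", "FYW"),
         function(g) strsplit(g, "")[[1L]])
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch dynamic programming with a linear gap penalty
#' (defaults: match +1, mismatch 0, gap -1). Traceback ties are broken
#' deterministically: diagonal, then up (gap in `b`), then left (gap in
#' `a`).
#'
#' @param a,b Protein sequence strings (non-empty).
#' @param match,mismatch,gap Scoring parameters.
#' @param ids Identifiers for the two sequences.
#' @return A list of class `trz_alignment`: `ids`, `aligned` (two strings
#'   with `-` gaps), `score`, `n_identical`, `n_similar`,
#'   `n_aligned_columns` (columns where neither sequence is gapped),
#'   `n_columns` (full alignment length).
#' @examples
#' aln <- global_align("ACDE", "ACD")
#' aln$aligned
#' @export
global_align <- function(a, b, match = 1, mismatch = 0, gap = -1,
                         ids = c("a", "b")) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1L, m + 1L)
  S[, 1L] <- gap * (0:n)
  S[1L, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(A[i] == B, match, mismatch)
    for (j in seq_len(m))
      S[i + 1L, j + 1L] <- max(S[i, j] + sub[j], S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
  }
  # traceback, diagonal > up > left
  i <- n; j <- m; ra <- character(); rb <- character()
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] == S[i, j] + (if (A[i] == B[j]) match else mismatch)) {
      ra <- c(A[i], ra); rb <- c(B[j], rb); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
      ra <- c(A[i], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(B[j], rb); j <- j - 1L
    }
  }
  gapless <- ra != "-" & rb != "-"
  ident <- gapless & ra == rb
  groups <- strong_groups()
  similar <- ident
  for (g in groups) similar <- similar | (gapless & ra %in% g & rb %in% g)
  structure(list(ids = ids,
                 aligned = c(paste(ra, collapse = ""), paste(rb, collapse = "")),
                 score = S[n + 1L, m + 1L],
                 n_identical = sum(ident),
                 n_similar = sum(similar),
                 n_aligned_columns = sum(gapless),
                 n_columns = length(ra)),
            class = "trz_alignment")
}

#' @export
print.trz_alignment <- function(x, ...) {
  cat(sprintf("<trz_alignment> %s vs %s  score=%g  identical=%d/%d columns\n",
              x$ids[1L], x$ids[2L], x$score, x$n_identical, x$n_aligned_columns))
  cat(" ", x$aligned[1L], "\n ", x$aligned[2L], "\n")
  invisible(x)
}

#' Percent identity and similarity of an alignment
#'
#' Identity is the percentage of identical residue pairs, similarity the
#' percentage of identical-or-same-group pairs (see [strong_groups()]), both
#' over the columns where neither sequence is gapped (alternative
#' denominators selectable). Rounded to one decimal.
#'
#' @param alignment A `trz_alignment` from [global_align()].
#' @param denominator `"gapless"` (default), `"shorter"` (length of the
#'   shorter input) or `"alignment"` (full alignment length).
#' @return Named numeric vector `c(identity =, similarity =)` in percent.
#' @examples
#' percent_identity_similarity(global_align("ST", "TS"))  # 0, 100
#' @export
percent_identity_similarity <- function(alignment,
                                        denominator = c("gapless", "shorter", "alignment")) {
  stopifnot(inherits(alignment, "trz_alignment"))
  denominator <- match.arg(denominator)
  den <- switch(denominator,
                gapless = alignment$n_aligned_columns,
                shorter = min(nchar(gsub("-", "", alignment$aligned, fixed = TRUE))),
                alignment = alignment$n_columns)
  if (den == 0L) stop("alignment has zero aligned columns")
  c(identity = round(100 * alignment$n_identical / den, 1L),
    similarity = round(100 * alignment$n_similar / den, 1L))
}

#' Per-column frequency and information-content matrix of motif instances
#'
#' Computes, for a set of equal-length motif instances, the per-column
#' residue frequencies over the 20-letter alphabet and the per-column
#' information content in bits, `IC = log2(20) - H` with `H` the Shannon
#' entropy of the column's frequencies (no small-sample correction). This is
#' the numeric matrix underlying a sequence logo, where letter height
#' reflects per-position conservation.
#'
#' @param instances Character vector of equal-length sequences (standard
#'   alphabet).
#' @return A list of class `trz_logo`: `freq` (20 x L matrix, columns sum to
#'   1) and `ic` (length-L vector in bits, within `[0, log2(20)]`).
#' @examples
#' logo_matrix(c("KLK", "KMK"))$ic
#' @export
logo_matrix <- function(instances) {
  if (length(instances) < 1L) stop("need at least one instance")
  lens <- nchar(instances)
  if (length(unique(lens)) != 1L) stop("instances must have equal lengths (ragged input)")
  chars <- do.call(rbind, strsplit(instances, "", fixed = TRUE))
  bad <- setdiff(unique(as.vector(chars)), AA20)
  if (length(bad)) stop("non-standard residues: ", paste(bad, collapse = ", "))
  L <- lens[1L]
  freq <- vapply(seq_len(L), function(j) {
    tab <- table(factor(chars[, j], levels = AA20))
    as.numeric(tab) / length(instances)
  }, numeric(20L))
  rownames(freq) <- AA20
  entropy <- apply(freq, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  structure(list(freq = freq, ic = log2(20) - entropy), class = "trz_logo")
}

#' @export
print.trz_logo <- function(x, ...) {
  cat(sprintf("<trz_logo> %d columns, IC range [%.3f, %.3f] bits\n",
              ncol(x$freq), min(x$ic), max(x$ic)))
  invisible(x)
}

#' @export
plot.trz_logo <- function(x, ...) {
  graphics::barplot(x$ic, names.arg = seq_along(x$ic),
                    xlab = "column", ylab = "information content (bits)",
                    ylim = c(0, log2(20)), ...)
  invisible(x)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via [ape::nj()]) over a
#' validated symmetric zero-diagonal distance matrix; taxa are ordered
#' lexicographically first so that equal inputs give identical output
#' regardless of row order.
#'
#' @param d Symmetric numeric distance matrix with zero diagonal,
#'   at least 3 taxa; row/col names are the taxon labels (or supply
#'   `labels`).
#' @param labels Optional taxon labels overriding dimnames.
#' @return An [ape::phylo] unrooted tree with branch lengths.
#' @seealso [nj_newick()] for the Newick string.
#' @export
nj_tree <- function(d, labels = NULL) {
  d <- as.matrix(d)
  if (!is.null(labels)) dimnames(d) <- list(labels, labels)
  if (is.null(rownames(d))) dimnames(d) <- list(paste0("t", seq_len(nrow(d))),
                                                paste0("t", seq_len(nrow(d))))
  if (nrow(d) < 3L) stop("need at least 3 taxa")
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix must be symmetric")
  if (any(diag(d) != 0)) stop("distance matrix must have a zero diagonal")
  if (any(d < 0)) stop("distances must be non-negative")
  o <- order(rownames(d))
  ape::nj(d[o, o])
}

#' Newick serialization of a tree
#'
#' @param tree An `ape::phylo` tree.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
nj_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

#' Pairwise p-distance matrix over motif regions
#'
#' For a set of proteins, concatenates each protein's planted/observed motif
#' instances (from a truth object or by chaining against an architecture)
#' and computes pairwise p-distances, `1 - fraction identical over gapless
#' columns` of the global alignment — the tree input used for clade-recovery
#' checks.
#'
#' @param sequences Named character vector of motif-region sequences (e.g.
#'   from [motif_region()]).
#' @return Symmetric distance matrix.
#' @export
p_distance_matrix <- function(sequences) {
  n <- length(sequences)
  labs <- names(sequences)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  if (n < 2L) return(d)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    aln <- global_align(sequences[[i]], sequences[[j]])
    d[i, j] <- d[j, i] <- 1 - aln$n_identical / aln$n_aligned_columns
  }
  d
}

#' Concatenated motif region of a synthetic protein
#'
#' @param sequence Protein sequence.
#' @param truth Its `trz_truth` (planted coordinates).
#' @return The concatenation of the planted motif instances plus the arm
#'   segment, N-to-C.
#' @export
motif_region <- function(sequence, truth) {
  stopifnot(inherits(truth, "trz_truth"))
  m <- truth$motifs[order(truth$motifs$start), ]
  paste(substring(sequence, m$start + 1L, m$end), collapse = "")
}

#' Validate a targeting-signal record
#'
#' Subcellular targeting signals (N-terminal chloroplast or mitochondrial
#' presequences) are bookkept as sequence plus a declared length; this
#' checks that the declared length matches the residue count.
#'
#' @param sequence Amino-acid string (non-empty, standard alphabet).
#' @param declared_length Declared length in aa, or `NA` when none.
#' @return List with `length` (computed) and `consistent` (`TRUE` iff equal
#'   to the declared length; `NA` declared counts as consistent).
#' @examples
#' validate_signal("MQISIPL", 7)
#' @export
validate_signal <- function(sequence, declared_length = NA) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a non-empty string")
  bad <- setdiff(strsplit(sequence, "")[[1L]], AA20)
  if (length(bad)) stop("non-standard residues: ", paste(bad, collapse = ", "))
  n <- nchar(sequence)
  list(length = n,
       consistent = if (is.na(declared_length)) TRUE else n == declared_length)
}

#' Read a targeting-signal table
#'
#' Reads a TSV with columns `protein_id`, `compartment` (`C`hloroplast,
#' `M`itochondrial, `N`uclear), `sequence`, `declared_length`, such as the
#' curated table shipped in `inst/extdata/targeting_signals.tsv`, and
#' validates every row with [validate_signal()].
#'
#' @param path TSV path.
#' @return The table with added `computed_length` and `consistent` columns.
#' @export
read_signal_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "compartment", "sequence", "declared_length")
  if (!all(need %in% names(df)))
    stop("signal table lacks columns: ", paste(setdiff(need, names(df)), collapse = ", "))
  v <- lapply(seq_len(nrow(df)), function(i)
    validate_signal(df$sequence[i], df$declared_length[i]))
  df$computed_length <- vapply(v, `[[`, numeric(1), "length")
  df$consistent <- vapply(v, `[[`, logical(1), "consistent")
  df
}
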