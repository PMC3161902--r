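# Independent oracles and random-case generators used across the suite.

# Brute-force motif scanner, independent of scan_motif: tokenizes the
# pattern with a regex and checks every window with an explicit double loop.
brute_scan <- function(sequence, pattern, max_mm, require_mm = integer()) {
  toks <- regmatches(pattern, gregexpr("\\[[A-Z]+\\]|[A-Z]|x", pattern))[[1L]]
  s <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  L <- length(toks)
  out <- data.frame(start = integer(), mismatches = integer())
  if (length(s) < L) return(out)
  for (w in seq_len(length(s) - L + 1L)) {
    mm <- 0L
    ok_req <- TRUE
    for (k in seq_len(L)) {
      tk <- toks[k]
      hit <- if (tk == "x") TRUE else {
        set <- strsplit(gsub("[][]", "", tk), "", fixed = TRUE)[[1L]]
        s[w + k - 1L] %in% set
      }
      if (!hit) mm <- mm + 1L
      if (k %in% require_mm && hit) ok_req <- FALSE
    }
    if (mm <= max_mm && ok_req)
      out <- rbind(out, data.frame(start = w - 1L, mismatches = mm))
  }
  out
}

# Exhaustive global-alignment score by plain recursion over all alignments
# (no memoization): the independent optimality oracle for short sequences.
brute_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- strsplit(a, "", fixed = TRUE)[[1L]]
  B <- strsplit(b, "", fixed = TRUE)[[1L]]
  rec <- function(i, j) {
    if (i == 0L && j == 0L) return(0)
    best <- -Inf
    if (i > 0L && j > 0L)
      best <- max(best, rec(i - 1L, j - 1L) +
                    (if (A[i] == B[j]) match else mismatch))
    if (i > 0L) best <- max(best, rec(i - 1L, j) + gap)
    if (j > 0L) best <- max(best, rec(i, j - 1L) + gap)
    best
  }
  rec(length(A), length(B))
}

# random degenerate pattern of given length: mixes exacts, wildcards, sets
random_pattern <- function(len) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(vapply(seq_len(len), function(i) {
    kind <- sample(c("exact", "wild", "set"), 1L, prob = c(0.5, 0.35, 0.15))
    switch(kind,
           exact = sample(aa, 1L),
           wild = "x",
           set = paste0("[", paste(sample(aa, sample(2:3, 1L)), collapse = ""), "]"))
  }, character(1)), collapse = "")
}

random_protein <- function(len, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                             "I", "K", "L", "M", "N", "P", "Q",
                                             "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# chain structural soundness: pairwise non-overlap + strictly increasing rank
expect_sound_chain <- function(chain) {
  h <- chain$hits
  if (nrow(h) >= 2L) {
    expect_true(all(diff(h$start) > 0))
    expect_true(all(h$start[-1L] >= h$end[-nrow(h)]))
    expect_true(all(diff(h$rank) > 0))
  }
  expect_true(all(h$end - h$start > 0))
  invisible(chain)
}

# reverse-complement a whole genome and flip gene coordinates accordingly,
# for strand-invariance checks
flip_genome <- function(genome, genes) {
  rc <- vapply(genome, function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))),
    character(1))
  lens <- nchar(genome)[genes$seq_id]
  flipped <- data.frame(gene_id = genes$gene_id, seq_id = genes$seq_id,
                        start = lens - genes$end, end = lens - genes$start,
                        strand = ifelse(genes$strand == "+", "-", "+"),
                        stringsAsFactors = FALSE)
  list(genome = rc, genes = flipped)
}
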