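# The 20 standard amino acids, one-letter code.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Compile a degenerate consensus motif pattern
#'
#' Parses a consensus string in the notation used throughout the package:
#' an uppercase letter is an exact residue, a lowercase `x` is a wildcard
#' matching any residue, and a bracketed group such as `[KL]` matches any
#' residue listed inside the brackets. The compiled model records, for each
#' position, the set of residues allowed there, and carries the mismatch
#' tolerance used when scanning.
#'
#' @param pattern Consensus string, e.g. `"HxHxDH"` or `"Px[KL]xRN"`.
#' @param max_mismatches Non-negative integer; the number of non-matching
#'   (non-wildcard) positions tolerated in a reported hit. If `NULL`, a
#'   catalog default is applied: 0 for patterns of length 6 or less, 1 for
#'   longer patterns.
#' @param name Short identifier for the motif (e.g. `"MOTIF_II"`).
#' @param rank Integer rank giving the motif's place in the canonical
#'   N-to-C motif order of an architecture (`NA` if unranked).
#' @param require_mismatch Integer vector of 1-based pattern positions that
#'   are required to MISMATCH the consensus for a window to be reported.
#'   Used to model pseudo-motifs, which differ from their parent motifs at
#'   catalytically critical residues.
#'
#' @return An object of class `trz_motif`: a list with elements `name`,
#'   `pattern`, `positions` (list of allowed-residue character vectors,
#'   `NULL` for wildcard), `max_mismatches`, `rank`, `require_mismatch`.
#' @examples
#' m <- compile_motif("HxHxDH")
#' format_motif(m)
#' @export
compile_motif <- function(pattern, max_mismatches = NULL, name = NA_character_,
                          rank = NA_integer_, require_mismatch = integer()) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop("'pattern' must be a non-empty string")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  positions <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      positions[length(positions) + 1L] <- list(NULL)  # wildcard slot
      i <- i + 1L
    } else if (ch %in% AA20) {
      positions[[length(positions) + 1L]] <- ch
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      set <- character()
      while (j <= length(chars) && chars[j] != "]") {
        if (!chars[j] %in% AA20)
          stop(sprintf("illegal character '%s' inside bracket at index %d of pattern '%s'",
                       chars[j], j, pattern))
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > length(chars))
        stop(sprintf("unbalanced bracket opened at index %d of pattern '%s'", i, pattern))
      if (length(set) == 0L)
        stop(sprintf("empty bracket set at index %d of pattern '%s'", i, pattern))
      positions[[length(positions) + 1L]] <- unique(set)
      i <- j + 1L
    } else {
      stop(sprintf("illegal character '%s' at index %d of pattern '%s'", ch, i, pattern))
    }
  }
  if (is.null(max_mismatches))
    max_mismatches <- if (length(positions) <= 6L) 0L else 1L
  max_mismatches <- as.integer(max_mismatches)
  if (max_mismatches < 0L || max_mismatches >= length(positions))
    stop("'max_mismatches' must be in [0, pattern length)")
  require_mismatch <- as.integer(require_mismatch)
  if (any(require_mismatch < 1L | require_mismatch > length(positions)))
    stop("'require_mismatch' positions out of range")
  structure(list(name = name, pattern = pattern, positions = positions,
                 max_mismatches = max_mismatches, rank = as.integer(rank),
                 require_mismatch = require_mismatch),
            class = "trz_motif")
}

#' @export
length.trz_motif <- function(x) length(x$positions)

#' Format a compiled motif back to its consensus string
#'
#' Inverse of [compile_motif()]: the returned string round-trips through the
#' parser.
#'
#' @param model A `trz_motif` object.
#' @return The consensus pattern string.
#' @export
format_motif <- function(model) {
  stopifnot(inherits(model, "trz_motif"))
  paste(vapply(model$positions, function(p) {
    if (is.null(p)) "x"
    else if (length(p) == 1L) p
    else paste0("[", paste(p, collapse = ""), "]")
  }, character(1)), collapse = "")
}

#' @export
print.trz_motif <- function(x, ...) {
  cat(sprintf("<trz_motif> %s  pattern=%s  len=%d  max_mm=%d  rank=%s%s\n",
              ifelse(is.na(x$name), "(unnamed)", x$name), x$pattern,
              length(x$positions), x$max_mismatches,
              ifelse(is.na(x$rank), "NA", x$rank),
              if (length(x$require_mismatch))
                paste0("  require_mismatch=", paste(x$require_mismatch, collapse = ","))
              else ""))
  invisible(x)
}

#' Scan a protein sequence for mismatch-tolerant motif hits
#'
#' Slides the compiled pattern over every window of the sequence and reports
#' each window whose mismatch count (over non-wildcard positions) does not
#' exceed the model's tolerance. Equivalent to brute force over all windows.
#' The unknown residue `X` matches only wildcard positions. For pseudo-motif
#' models, windows are additionally required to mismatch the consensus at
#' every `require_mismatch` position.
#'
#' @param sequence A single protein sequence string (standard alphabet,
#'   `X` allowed).
#' @param model A `trz_motif` object.
#' @return A data frame with one row per hit, sorted by `start`:
#'   `motif`, `start` (0-based inclusive), `end` (0-based exclusive),
#'   `matched` (the sequence slice), `mismatches`.
#' @examples
#' scan_motif("AAHSHLDHAA", compile_motif("HxHxDH", 0, name = "MOTIF_II"))
#' @export
scan_motif <- function(sequence, model) {
  stopifnot(inherits(model, "trz_motif"))
  empty <- data.frame(motif = character(), start = integer(), end = integer(),
                      matched = character(), mismatches = integer(),
                      stringsAsFactors = FALSE)
  if (!is.character(sequence) || length(sequence) != 1L) stop("'sequence' must be one string")
  s <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  plen <- length(model$positions)
  n <- length(s) - plen + 1L
  if (n < 1L) return(empty)
  # mm[w, ] accumulated per window; vectorized across windows per position
  mm <- integer(n)
  req_ok <- rep(TRUE, n)
  for (j in seq_len(plen)) {
    allowed <- model$positions[[j]]
    if (is.null(allowed)) next
    bad <- !(s[j:(j + n - 1L)] %in% allowed)
    mm <- mm + bad
    if (j %in% model$require_mismatch) req_ok <- req_ok & bad
  }
  keep <- which(mm <= model$max_mismatches & req_ok)
  if (length(keep) == 0L) return(empty)
  data.frame(motif = model$name,
             start = keep - 1L,
             end = keep - 1L + plen,
             matched = substring(sequence, keep, keep + plen - 1L),
             mismatches = as.integer(mm[keep]),
             stringsAsFactors = FALSE)
}

#' Assemble an order-consistent motif chain
#'
#' Scans the sequence with every motif of the named architecture and selects,
#' by dynamic programming, the maximum-coverage (total matched residues) set
#' of non-overlapping hits whose motif ranks strictly increase along the
#' sequence — the family's motifs occur in the same relative order in every
#' member in which they are present. Ties are broken by fewer total
#' mismatches, then by leftmost starts.
#'
#' @param sequence Protein sequence string.
#' @param catalog A `trz_catalog` object (see [trz_catalog()]).
#' @param architecture Architecture name present in the catalog, e.g.
#'   `"TM_S"`, `"BACTERIAL_S"`, `"EUKARYOTIC_L_C"`, `"EUKARYOTIC_L_N"`.
#' @return An object of class `trz_chain`: list with `protein_id`, `hits`
#'   (data frame as from [scan_motif()] plus a `rank` column, sorted by
#'   start), `complete` (all required motifs placed), `missing_required`,
#'   `architecture`, `total_mismatches`, `coverage`.
#' @export
find_motif_chain <- function(sequence, catalog = trz_catalog(), architecture) {
  stopifnot(inherits(catalog, "trz_catalog"))
  arch <- catalog$architectures[[architecture]]
  if (is.null(arch)) stop(sprintf("unknown architecture '%s'", architecture))
  motif_names <- c(arch$required, arch$optional)
  hits <- do.call(rbind, lapply(motif_names, function(nm) {
    model <- catalog$entries[[nm]]
    h <- scan_motif(sequence, model)
    nspec <- sum(lengths(model$positions) > 0L)  # non-wildcard positions
    if (nrow(h)) { h$rank <- model$rank; h$nspec <- nspec }
    else { h$rank <- integer(); h$nspec <- integer() }
    h
  }))
  chain <- chain_dp(hits)
  placed <- unique(chain$motif)
  missing <- setdiff(arch$required, placed)
  structure(list(protein_id = NA_character_,
                 hits = chain,
                 complete = length(missing) == 0L,
                 missing_required = missing,
                 architecture = architecture,
                 total_mismatches = sum(chain$mismatches),
                 coverage = sum(chain$end - chain$start)),
            class = "trz_chain")
}

# DP over candidate hits: maximize coverage (total matched residues); break
# ties by total pattern specificity (non-wildcard positions, so the fully
# specified motifs outrank the minimal Asp/His anchors), then by fewer total
# mismatches, then by leftmost starts. Hits must be non-overlapping with
# strictly increasing rank along the sequence.
chain_dp <- function(hits) {
  empty <- data.frame(motif = character(), start = integer(), end = integer(),
                      matched = character(), mismatches = integer(),
                      rank = integer(), stringsAsFactors = FALSE)
  if (is.null(hits) || nrow(hits) == 0L) return(empty)
  if (is.null(hits$nspec)) hits$nspec <- hits$end - hits$start
  o <- order(hits$start, hits$rank, hits$mismatches)
  hits <- hits[o, , drop = FALSE]
  n <- nrow(hits)
  len <- hits$end - hits$start
  cov <- numeric(n)      # best coverage of a chain ending at i
  spc <- numeric(n)      # its total specificity
  mmt <- numeric(n)      # its total mismatches
  prev <- integer(n)     # back-pointer (0 = chain start)
  for (i in seq_len(n)) {
    cov[i] <- len[i]; spc[i] <- hits$nspec[i]; mmt[i] <- hits$mismatches[i]
    prev[i] <- 0L
    js <- which(hits$end <= hits$start[i] & hits$rank < hits$rank[i])
    for (j in js) {
      c2 <- cov[j] + len[i]; s2 <- spc[j] + hits$nspec[i]
      m2 <- mmt[j] + hits$mismatches[i]
      if (c2 > cov[i] ||
          (c2 == cov[i] && (s2 > spc[i] ||
                            (s2 == spc[i] && m2 < mmt[i])))) {
        cov[i] <- c2; spc[i] <- s2; mmt[i] <- m2; prev[i] <- j
      }
    }
  }
  # pick best chain end; ties: specificity, fewer mismatches, leftmost
  best <- which(cov == max(cov))
  best <- best[spc[best] == max(spc[best])]
  best <- best[mmt[best] == min(mmt[best])]
  best <- best[1L]
  idx <- integer()
  i <- best
  while (i != 0L) { idx <- c(i, idx); i <- prev[i] }
  out <- hits[idx, , drop = FALSE]
  out$nspec <- NULL
  rownames(out) <- NULL
  out
}

#' @export
print.trz_chain <- function(x, ...) {
  cat(sprintf("<trz_chain> architecture=%s  hits=%d  complete=%s\n",
              x$architecture, nrow(x$hits), x$complete))
  if (length(x$missing_required))
    cat("  missing required:", paste(x$missing_required, collapse = ", "), "\n")
  if (nrow(x$hits)) print(x$hits, row.names = FALSE)
  invisible(x)
}
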