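#' Classify protein form from length
#'
#' tRNase Z occurs in a short form (roughly 300-400 aa) and a long form
#' (roughly 700-800 aa, a tandem duplication of the short form). Because
#' surveyed candidates fall somewhat outside the nominal ranges, the form
#' call uses generous cutoffs with an explicit ambiguous band between them;
#' evidence-based override (a complete long-form architecture) can resolve
#' the band later in [classify_type()].
#'
#' @param length Protein length in amino acids (positive).
#' @param s_max Largest length called `S` (default 450).
#' @param l_min Smallest length called `L` (default 600).
#' @return One of `"S"`, `"L"`, `"AMBIGUOUS"`.
#' @examples
#' classify_form(280)  # "S"
#' classify_form(942)  # "L"
#' classify_form(500)  # "AMBIGUOUS"
#' @export
classify_form <- function(length, s_max = 450L, l_min = 600L) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) || length < 1)
    stop("'length' must be a positive number")
  if (length <= s_max) "S" else if (length >= l_min) "L" else "AMBIGUOUS"
}

#' Delineate the flexible arm of a tRNase Z candidate
#'
#' The flexible arm (exosite) is the tRNase Z-specific substrate-binding
#' insertion that sits between the His motif (Motif II) and Motif III. This
#' function takes a motif chain, extracts the inter-motif segment between
#' the configured anchors, scans it for the arm-defining KL and GP motifs,
#' and types the arm from motif content and length: a KL-bearing arm of at
#' most `tm_max` residues is TM-type (~30 aa nominal), a GP-bearing arm of
#' at most `bact_max` residues is bacterial-type (~55 aa), and a longer
#' GP-bearing arm is eukaryotic-type (~62 aa).
#'
#' @param chain A `trz_chain` from [find_motif_chain()].
#' @param sequence The protein sequence the chain was computed on.
#' @param catalog Motif catalog supplying the KL and GP models.
#' @param left_anchor,right_anchor Motif names bounding the arm
#'   (defaults `MOTIF_II` / `MOTIF_III`).
#' @param region_end Optional 0-based exclusive end of the arm region, used
#'   in place of `right_anchor` when the chain has no right anchor (the
#'   N-terminal half of a long form, which lacks Motif III).
#' @param tm_max,bact_max Arm-length cutoffs (defaults 45 and 58, midway
#'   between the nominal ~30/~55/~62 lengths).
#' @return A list of class `trz_arm`: `start`, `end` (0-based half-open),
#'   `length`, `arm_type` (`"TM"`, `"BACTERIAL"`, `"EUKARYOTIC"` or
#'   `"NONE"`), `has_gp`, `has_kl`, `flagged` (TRUE when anchors were
#'   missing and no region could be delineated).
#' @export
delineate_arm <- function(chain, sequence, catalog = trz_catalog(),
                          left_anchor = "MOTIF_II", right_anchor = "MOTIF_III",
                          region_end = NULL, tm_max = 45L, bact_max = 58L) {
  stopifnot(inherits(chain, "trz_chain"))
  none <- structure(list(start = 0L, end = 0L, length = 0L, arm_type = "NONE",
                         has_gp = FALSE, has_kl = FALSE, flagged = TRUE),
                    class = "trz_arm")
  h <- chain$hits
  li <- which(h$motif == left_anchor)
  if (!length(li)) return(none)
  start <- h$end[li[1L]]
  ri <- which(h$motif == right_anchor)
  end <- if (length(ri)) h$start[ri[1L]] else if (!is.null(region_end)) region_end else return(none)
  if (end < start) return(none)
  segment <- substr(sequence, start + 1L, end)
  has_kl <- nrow(scan_motif(segment, catalog$entries[["KL"]])) > 0L
  has_gp <- nrow(scan_motif(segment, catalog$entries[["GP"]])) > 0L
  len <- end - start
  arm_type <- if (has_kl && !has_gp && len <= tm_max) "TM"
  else if (has_gp && len <= bact_max) "BACTERIAL"
  else if (has_gp && len > bact_max) "EUKARYOTIC"
  else "NONE"
  structure(list(start = start, end = end, length = len, arm_type = arm_type,
                 has_gp = has_gp, has_kl = has_kl, flagged = FALSE),
            class = "trz_arm")
}

#' @export
print.trz_arm <- function(x, ...) {
  cat(sprintf("<trz_arm> [%d, %d) len=%d type=%s gp=%s kl=%s%s\n",
              x$start, x$end, x$length, x$arm_type, x$has_gp, x$has_kl,
              if (x$flagged) " (flagged: anchors missing)" else ""))
  invisible(x)
}

#' Split a long-form candidate into N- and C-terminal halves
#'
#' The long form arose by tandem duplication: its C-terminal half carries the
#' complete catalytic architecture (PxKxRN, Motifs I-V, HEAT, HST) while the
#' N-terminal half retains only degenerate pseudo-motifs plus the eukaryotic
#' flexible arm. The split point is taken as the start of the first motif of
#' the best C-half (full-architecture) chain over the whole sequence; when no
#' such chain exists (or it would start at position 0) the midpoint is used.
#'
#' @param sequence Protein sequence string.
#' @param catalog Motif catalog.
#' @return A list of class `trz_halfsplit`: `split_index` (0-based),
#'   `n_half_chain` (chain for `EUKARYOTIC_L_N`, coordinates within the
#'   N-half, i.e. the full-protein frame), `c_half_chain` (chain for
#'   `EUKARYOTIC_L_C`, hit coordinates shifted into the full-protein frame).
#' @export
split_halves <- function(sequence, catalog = trz_catalog()) {
  len <- nchar(sequence)
  whole <- find_motif_chain(sequence, catalog, "EUKARYOTIC_L_C")
  split <- if (nrow(whole$hits) && whole$hits$start[1L] > 0L)
    whole$hits$start[1L] else as.integer(len %/% 2L)
  n_half <- find_motif_chain(substr(sequence, 1L, split), catalog, "EUKARYOTIC_L_N")
  c_half <- find_motif_chain(substr(sequence, split + 1L, len), catalog, "EUKARYOTIC_L_C")
  if (nrow(c_half$hits)) {
    c_half$hits$start <- c_half$hits$start + split
    c_half$hits$end <- c_half$hits$end + split
  }
  structure(list(split_index = split, n_half_chain = n_half,
                 c_half_chain = c_half),
            class = "trz_halfsplit")
}

#' Classify a protein into tRNase Z form and type
#'
#' Implements the survey's decision scheme. Short-form candidates are tested
#' against the TM-type architecture (EGxSxxG, Motifs I-V, KL-arm, xExT, HxH)
#' and the bacterial-type architecture (PxKxRN, Motifs I-V, GP-arm, HEAT,
#' HST); a complete chain gives the type, and if both are complete the one
#' with fewer total mismatches wins (tie going to TM-type when a KL arm is
#' present, the KL motif being TM-diagnostic). Short candidates with an
#' incomplete architecture are tRNase Z-like (`TLP_S`), with the missing
#' required motifs recorded; candidates lacking even the signature His motif
#' list `MOTIF_II` among them. Long-form candidates are split into halves;
#' a complete C-half architecture together with a eukaryotic GP-arm in the
#' N-half gives `EUKARYOTIC_L`, anything else `TLP_L`. Length-ambiguous
#' candidates are resolved to `L` when they carry the complete long-form
#' evidence, and are `UNKNOWN` otherwise.
#'
#' @param sequence Protein sequence string (non-empty).
#' @param catalog Motif catalog.
#' @param protein_id Optional identifier carried into the result.
#' @param s_max,l_min Form cutoffs, see [classify_form()].
#' @return A list of class `trz_typing_result`: `protein_id`, `length`,
#'   `form` (`S`/`L`/`AMBIGUOUS`), `ztype` (`TM_S`, `BACTERIAL_S`,
#'   `EUKARYOTIC_L`, `TLP_S`, `TLP_L`, `UNKNOWN`), `missing_required`,
#'   `arm` (a `trz_arm`), `evidence` (named logical presence map over the
#'   tested architecture's motifs plus chains).
#' @examples
#' p <- synth_protein(protein_spec("TM_S", seed = 1))
#' classify_type(p$sequence)$ztype  # "TM_S"
#' @export
classify_type <- function(sequence, catalog = trz_catalog(),
                          protein_id = NA_character_,
                          s_max = 450L, l_min = 600L) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("'sequence' must be a non-empty string")
  len <- nchar(sequence)
  form <- classify_form(len, s_max = s_max, l_min = l_min)

  res <- function(form, ztype, missing, arm, evidence)
    validate_typing(structure(list(protein_id = protein_id, length = len,
                                   form = form, ztype = ztype,
                                   missing_required = missing, arm = arm,
                                   evidence = evidence),
                              class = "trz_typing_result"))

  classify_s <- function() {
    tm <- find_motif_chain(sequence, catalog, "TM_S")
    bact <- find_motif_chain(sequence, catalog, "BACTERIAL_S")
    arm_tm <- delineate_arm(tm, sequence, catalog)
    arm_bact <- delineate_arm(bact, sequence, catalog)
    ev <- list(TM_S = tm, BACTERIAL_S = bact)
    if (tm$complete && bact$complete) {
      pick_tm <- tm$total_mismatches < bact$total_mismatches ||
        (tm$total_mismatches == bact$total_mismatches && arm_tm$has_kl)
      if (pick_tm) res("S", "TM_S", character(), arm_tm, ev)
      else res("S", "BACTERIAL_S", character(), arm_bact, ev)
    } else if (tm$complete) {
      res("S", "TM_S", character(), arm_tm, ev)
    } else if (bact$complete) {
      res("S", "BACTERIAL_S", character(), arm_bact, ev)
    } else {
      # TLP: report the closer architecture's deficit
      pick_tm <- length(tm$missing_required) < length(bact$missing_required) ||
        (length(tm$missing_required) == length(bact$missing_required) &&
           tm$total_mismatches <= bact$total_mismatches)
      best <- if (pick_tm) tm else bact
      arm <- if (pick_tm) arm_tm else arm_bact
      missing <- best$missing_required
      if (nrow(scan_motif(sequence, catalog$entries[["MOTIF_II"]])) == 0L)
        missing <- union(missing, "MOTIF_II")
      res("S", "TLP_S", missing, arm, ev)
    }
  }

  classify_l <- function(form_out = "L") {
    hs <- split_halves(sequence, catalog)
    arm <- delineate_arm(hs$n_half_chain, sequence, catalog,
                         left_anchor = "PSEUDO_II", right_anchor = "MOTIF_III",
                         region_end = hs$split_index)
    ev <- list(split = hs, arm = arm)
    if (hs$c_half_chain$complete && arm$arm_type == "EUKARYOTIC") {
      # complete long-form evidence resolves an ambiguous length to L
      res("L", "EUKARYOTIC_L", character(), arm, ev)
    } else if (form_out == "L") {
      missing <- hs$c_half_chain$missing_required
      if (arm$arm_type != "EUKARYOTIC") missing <- union(missing, "GP_ARM")
      res("L", "TLP_L", missing, arm, ev)
    } else NULL
  }

  if (form == "S") classify_s()
  else if (form == "L") classify_l()
  else {
    out <- classify_l(form_out = "AMBIGUOUS")
    if (!is.null(out)) out else {
      res("AMBIGUOUS", "UNKNOWN", character(),
          structure(list(start = 0L, end = 0L, length = 0L, arm_type = "NONE",
                         has_gp = FALSE, has_kl = FALSE, flagged = TRUE),
                    class = "trz_arm"),
          list())
    }
  }
}

# structural invariants every typing result must satisfy
validate_typing <- function(x) {
  stopifnot(inherits(x, "trz_typing_result"))
  if (x$ztype %in% c("TM_S", "BACTERIAL_S") && x$form != "S")
    stop("internal error: short type with non-S form")
  if (x$ztype == "EUKARYOTIC_L" && x$form != "L")
    stop("internal error: long type with non-L form")
  if (x$ztype %in% c("TLP_S", "TLP_L") && length(x$missing_required) == 0L)
    stop("internal error: TLP call with empty missing set")
  x
}

#' @export
print.trz_typing_result <- function(x, ...) {
  cat(sprintf("<trz_typing_result> %s  length=%d  form=%s  type=%s  arm=%s(%d aa)\n",
              ifelse(is.na(x$protein_id), "(unnamed)", x$protein_id),
              x$length, x$form, x$ztype, x$arm$arm_type, x$arm$length))
  if (length(x$missing_required))
    cat("  missing required:", paste(x$missing_required, collapse = ", "), "\n")
  invisible(x)
}

#' Classify a set of proteins
#'
#' Vectorized driver over [classify_type()] returning a tabular summary, the
#' natural entry point for a FASTA's worth of candidates.
#'
#' @param sequences Named character vector of protein sequences (names are
#'   protein ids), e.g. from [read_fasta()].
#' @param catalog Motif catalog.
#' @param ... Passed on to [classify_type()].
#' @return An object of class `trz_typing`: a data frame with columns
#'   `protein_id`, `length`, `form`, `type`, `arm_type`, `arm_len`,
#'   `n_missing`, `missing_required` (comma-separated), with the full
#'   per-protein results in `attr(, "results")`.
#' @export
trz_classify <- function(sequences, catalog = trz_catalog(), ...) {
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  results <- lapply(names(sequences), function(id)
    classify_type(sequences[[id]], catalog, protein_id = id, ...))
  df <- data.frame(
    protein_id = names(sequences),
    length = vapply(results, `[[`, numeric(1), "length"),
    form = vapply(results, `[[`, character(1), "form"),
    type = vapply(results, `[[`, character(1), "ztype"),
    arm_type = vapply(results, function(r) r$arm$arm_type, character(1)),
    arm_len = vapply(results, function(r) r$arm$length, numeric(1)),
    n_missing = vapply(results, function(r) length(r$missing_required), numeric(1)),
    missing_required = vapply(results, function(r)
      paste(r$missing_required, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, results = results, class = c("trz_typing", "data.frame"))
}

#' @export
summary.trz_typing <- function(object, ...) {
  tab <- table(factor(object$type, levels = c("TM_S", "BACTERIAL_S",
                                              "EUKARYOTIC_L", "TLP_S",
                                              "TLP_L", "UNKNOWN")))
  structure(list(n = nrow(object), counts = tab), class = "summary.trz_typing")
}

#' @export
print.summary.trz_typing <- function(x, ...) {
  cat(sprintf("tRNase Z typing of %d proteins:\n", x$n))
  print(x$counts)
  invisible(x)
}

#' @export
print.trz_typing <- function(x, ...) {
  cat(sprintf("<trz_typing> %d proteins\n", nrow(x)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
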