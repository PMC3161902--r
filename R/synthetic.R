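# Run code under a temporary RNG state seeded with `seed`; the caller's
# stream is restored afterwards. seed = NULL uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Linker-safe residue alphabet for a catalog
#'
#' Residues appearing as exact (single-residue) requirements anywhere in the
#' catalog are excluded from linker sampling, so that random linkers can
#' never complete a catalog pattern by chance and planted-recovery tests are
#' exact rather than probabilistic. With the default catalog the safe
#' alphabet is C, F, M, Q, V, W.
#'
#' @param catalog A `trz_catalog`.
#' @return Character vector of safe residues.
#' @export
safe_alphabet <- function(catalog = trz_catalog()) {
  exact <- unique(unlist(lapply(catalog$entries, function(m)
    unlist(m$positions[lengths(m$positions) == 1L]))))
  setdiff(AA20, exact)
}

# Sample one concrete instance of a motif pattern. Wildcards are drawn from
# the safe alphabet (keeps exact residues unique to planted loci); bracket
# sets are drawn uniformly from their members; require_mismatch positions
# are set to Gln (never an exact requirement in the catalog).
sample_instance <- function(model, safe) {
  res <- vapply(seq_along(model$positions), function(j) {
    p <- model$positions[[j]]
    if (j %in% model$require_mismatch) "Q"
    else if (is.null(p)) sample(safe, 1L)
    else if (length(p) == 1L) p
    else sample(p, 1L)
  }, character(1))
  paste(res, collapse = "")
}

#' Specification for one synthetic tRNase Z protein
#'
#' @param ztype Type to plant: `"TM_S"`, `"BACTERIAL_S"` or `"EUKARYOTIC_L"`.
#' @param length Total protein length in aa. Defaults: 300 (TM_S),
#'   340 (BACTERIAL_S), 880 (EUKARYOTIC_L).
#' @param arm_len Flexible-arm length in aa. Defaults: 30 (TM), 55
#'   (bacterial), 62 (eukaryotic) — the family's nominal arm lengths.
#' @param knockouts Character vector of motif names to destroy (producing a
#'   TLP); must belong to the planted architecture.
#' @param knockout_mode `"corrupt"` (mutate invariant residues to Gln,
#'   keeping length) or `"delete"` (overwrite the instance with linker
#'   residues, keeping length).
#' @param seed Integer seed; `NULL` draws from the current RNG stream.
#' @return A list of class `trz_protein_spec`.
#' @export
protein_spec <- function(ztype = c("TM_S", "BACTERIAL_S", "EUKARYOTIC_L"),
                         length = NULL, arm_len = NULL,
                         knockouts = character(),
                         knockout_mode = c("corrupt", "delete"),
                         seed = NULL) {
  ztype <- match.arg(ztype)
  defaults <- list(TM_S = c(300L, 30L), BACTERIAL_S = c(340L, 55L),
                   EUKARYOTIC_L = c(880L, 62L))[[ztype]]
  structure(list(ztype = ztype,
                 length = as.integer(if (is.null(length)) defaults[1L] else length),
                 arm_len = as.integer(if (is.null(arm_len)) defaults[2L] else arm_len),
                 knockouts = knockouts,
                 knockout_mode = match.arg(knockout_mode),
                 seed = seed),
            class = "trz_protein_spec")
}

#' Generate a synthetic tRNase Z protein with planted ground truth
#'
#' Emits a protein assembled from concrete instances of the catalog's motif
#' consensus patterns joined by random linkers drawn from the linker-safe
#' alphabet, with the motifs in canonical N-to-C order and the flexible arm
#' (of the requested length, carrying its KL or GP motif) between Motif II
#' and Motif III. For `EUKARYOTIC_L` the N-terminal half carries the
#' pseudo-motifs and the eukaryotic GP-arm and the C-terminal half the full
#' catalytic architecture; the junction position is recorded in the truth.
#' Knockouts are applied through [mutate_to_tlp()]. Deterministic for a
#' fixed spec and seed.
#'
#' @param spec A `trz_protein_spec` from [protein_spec()].
#' @param catalog Motif catalog.
#' @return A list with `sequence` (string) and `truth`: list of class
#'   `trz_truth` with `ztype`, `length`, `seed`, `junction` (0-based start
#'   of the C-half chain, `NA` for short forms), `arm` (0-based half-open
#'   arm span), `motifs` (data frame `name`, `start`, `end`, `instance`,
#'   `knocked`), `knockouts`.
#' @examples
#' p <- synth_protein(protein_spec("TM_S", seed = 1))
#' substr(p$sequence, p$truth$motifs$start[1] + 1, p$truth$motifs$end[1])
#' @export
synth_protein <- function(spec, catalog = trz_catalog()) {
  stopifnot(inherits(spec, "trz_protein_spec"))
  with_seed(spec$seed, {
    safe <- safe_alphabet(catalog)
    if (spec$ztype %in% c("TM_S", "BACTERIAL_S")) {
      arch <- catalog$architectures[[spec$ztype]]$required
      arm_motif <- arch[4L]   # rank-4 slot: KL or GP
      segments <- build_segments(arch, arm_motif, arm_after = arch[3L],
                                 spec$length, spec$arm_len, catalog, safe)
      junction <- NA_integer_
    } else {
      n_arch <- catalog$architectures[["EUKARYOTIC_L_N"]]$required
      c_arch <- catalog$architectures[["EUKARYOTIC_L_C"]]$required
      # budget the halves: N-half gets its motifs + arm + ~40% of linker
      n_core <- sum(vapply(catalog$entries[n_arch], length, integer(1))) +
        (spec$arm_len - length(catalog$entries[["GP"]]))
      c_core <- sum(vapply(catalog$entries[c_arch], length, integer(1)))
      linker_total <- spec$length - n_core - c_core
      if (linker_total < 2L * 14L)
        stop("infeasible length budget for EUKARYOTIC_L spec")
      n_len <- n_core + floor(0.4 * linker_total)
      segments_n <- build_segments(n_arch, "GP", arm_after = "PSEUDO_II",
                                   n_len, spec$arm_len, catalog, safe)
      segments_c <- build_segments(c_arch, arm_motif = NULL, arm_after = NULL,
                                   spec$length - n_len, 0L, catalog, safe)
      segments_c$motifs$start <- segments_c$motifs$start + n_len
      segments_c$motifs$end <- segments_c$motifs$end + n_len
      junction <- segments_c$motifs$start[1L]  # first C-half motif
      segments <- list(sequence = paste0(segments_n$sequence, segments_c$sequence),
                       motifs = rbind(segments_n$motifs, segments_c$motifs),
                       arm = segments_n$arm)
    }
    truth <- structure(list(ztype = spec$ztype, length = spec$length,
                            seed = spec$seed, junction = junction,
                            arm = segments$arm,
                            motifs = transform(segments$motifs, knocked = FALSE),
                            knockouts = character()),
                       class = "trz_truth")
    out <- list(sequence = segments$sequence, truth = truth)
    if (length(spec$knockouts))
      out <- mutate_to_tlp(out$sequence, out$truth, spec$knockouts,
                           mode = spec$knockout_mode, catalog = catalog)
    out
  })
}

# Assemble one half (or whole short form): motifs in order with random-size
# linkers; the arm (of total length arm_len, containing arm_motif) replaces
# the gap after `arm_after`. Returns sequence, motif truth table, arm span.
build_segments <- function(arch, arm_motif, arm_after, total_len, arm_len,
                           catalog, safe, min_gap = 2L) {
  plain <- if (is.null(arm_motif)) arch else setdiff(arch, arm_motif)
  inst <- lapply(catalog$entries[arch], sample_instance, safe = safe)
  lens <- vapply(catalog$entries[arch], length, integer(1))
  arm_extra <- if (is.null(arm_motif)) 0L else arm_len - lens[[arm_motif]]
  if (!is.null(arm_motif) && arm_extra < 0L)
    stop("arm_len shorter than its arm motif")
  # gap slots: leading, one between each adjacent pair of plain-layout
  # elements, trailing. The arm consumes the slot after `arm_after` AND the
  # slot before the following motif (so the inter-anchor segment length is
  # exactly arm_len).
  motif_follows_arm <- !is.null(arm_motif) && match(arm_motif, arch) < length(arch)
  n_gaps <- length(plain) + 1L - as.integer(motif_follows_arm)
  linker_total <- total_len - sum(lens) - arm_extra
  if (linker_total < min_gap * n_gaps)
    stop(sprintf("infeasible length budget: need >= %d linker residues, have %d",
                 min_gap * n_gaps, linker_total))
  extra <- as.integer(stats::rmultinom(1L, linker_total - min_gap * n_gaps,
                                       rep(1, n_gaps)))
  gaps <- min_gap + extra
  arm_split <- if (arm_extra > 0L) sample(0:arm_extra, 1L) else 0L

  rand_linker <- function(n) if (n > 0L) paste(sample(safe, n, replace = TRUE),
                                               collapse = "") else ""
  pieces <- character()
  starts <- integer(); ends <- integer(); nm <- character(); seqs <- character()
  pos <- 0L
  arm_span <- c(NA_integer_, NA_integer_)
  gi <- 1L
  just_left_arm <- FALSE
  for (m in arch) {
    if (!is.null(arm_motif) && m == arm_motif) {
      # arm = left pad + arm motif + right pad, directly after `arm_after`
      arm_start <- pos
      pieces <- c(pieces, rand_linker(arm_split))
      pos <- pos + arm_split
      starts <- c(starts, pos); nm <- c(nm, m); seqs <- c(seqs, inst[[m]])
      pieces <- c(pieces, inst[[m]])
      pos <- pos + lens[[m]]
      ends <- c(ends, pos)
      pieces <- c(pieces, rand_linker(arm_extra - arm_split))
      pos <- pos + (arm_extra - arm_split)
      arm_span <- c(arm_start, pos)
      just_left_arm <- TRUE
    } else {
      if (just_left_arm) {
        just_left_arm <- FALSE   # no gap: the next anchor abuts the arm
      } else {
        pieces <- c(pieces, rand_linker(gaps[gi]))
        pos <- pos + gaps[gi]
        gi <- gi + 1L
      }
      starts <- c(starts, pos); nm <- c(nm, m); seqs <- c(seqs, inst[[m]])
      pieces <- c(pieces, inst[[m]])
      pos <- pos + lens[[m]]
      ends <- c(ends, pos)
    }
  }
  pieces <- c(pieces, rand_linker(gaps[gi]))
  pos <- pos + gaps[gi]
  stopifnot(pos == total_len)
  list(sequence = paste(pieces, collapse = ""),
       motifs = data.frame(name = nm, start = starts, end = ends,
                           instance = seqs, stringsAsFactors = FALSE),
       arm = arm_span)
}

#' Destroy planted motifs, producing a tRNase Z-like protein
#'
#' Knocks out the listed planted motif instances while preserving the
#' coordinates of everything else (length never changes). In `"corrupt"`
#' mode the first `max_mismatches + 1` invariant (exact) residues of the
#' instance are mutated to Gln, guaranteeing the hit no longer passes the
#' model's mismatch tolerance — for the His motif this reduces to the single
#' His-to-Gln substitution observed in natural TLPs. In `"delete"` mode the
#' whole instance is overwritten with linker-safe residues.
#'
#' @param sequence Protein sequence string.
#' @param truth A `trz_truth` with the planted coordinates.
#' @param motifs Character vector of planted motif names to destroy.
#' @param mode `"corrupt"` or `"delete"`.
#' @param catalog Motif catalog.
#' @param seed Optional seed for the delete-mode linker draw.
#' @return A list with updated `sequence` and `truth` (`knocked` flags set,
#'   `knockouts` extended).
#' @export
mutate_to_tlp <- function(sequence, truth, motifs,
                          mode = c("corrupt", "delete"),
                          catalog = trz_catalog(), seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(truth, "trz_truth"))
  if (!length(motifs)) return(list(sequence = sequence, truth = truth))
  unknown <- setdiff(motifs, truth$motifs$name)
  if (length(unknown))
    stop("motifs not planted in truth: ", paste(unknown, collapse = ", "))
  with_seed(seed, {
    safe <- safe_alphabet(catalog)
    chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    for (m in motifs) {
      row <- which(truth$motifs$name == m)[1L]
      start <- truth$motifs$start[row]
      model <- catalog$entries[[m]]
      if (mode == "delete") {
        span <- (start + 1L):truth$motifs$end[row]
        chars[span] <- sample(safe, length(span), replace = TRUE)
      } else {
        exact_pos <- which(lengths(model$positions) == 1L)
        exact_pos <- setdiff(exact_pos, model$require_mismatch)
        hit <- exact_pos[seq_len(min(model$max_mismatches + 1L, length(exact_pos)))]
        chars[start + hit] <- "Q"
      }
      truth$motifs$knocked[row] <- TRUE
    }
    truth$knockouts <- union(truth$knockouts, motifs)
    list(sequence = paste(chars, collapse = ""), truth = truth)
  })
}

#' Generate a balanced set of synthetic proteins
#'
#' Convenience batch generator for benchmarking the classifier: `n_per_type`
#' proteins of each requested type, with `TLP_S` realized as a TM-type or
#' bacterial-type protein with one random required motif knocked out, and
#' `TLP_L` as a eukaryotic long form with one C-half required motif knocked
#' out. Deterministic for a fixed seed.
#'
#' @param n_per_type Proteins per type.
#' @param types Types to generate (default all five).
#' @param seed Integer seed.
#' @param catalog Motif catalog.
#' @return A list with `sequences` (named character vector), `truths` (list
#'   of `trz_truth`), and `expected` (character vector of expected
#'   classification labels).
#' @export
synth_protein_set <- function(n_per_type = 5L,
                              types = c("TM_S", "BACTERIAL_S", "EUKARYOTIC_L",
                                        "TLP_S", "TLP_L"),
                              seed = 1L, catalog = trz_catalog()) {
  with_seed(seed, {
    sequences <- character(); truths <- list(); expected <- character()
    k <- 0L
    for (ty in types) for (i in seq_len(n_per_type)) {
      k <- k + 1L
      if (ty == "TLP_S") {
        base <- sample(c("TM_S", "BACTERIAL_S"), 1L)
        ko <- sample(catalog$architectures[[base]]$required, 1L)
        sp <- protein_spec(base, knockouts = ko)
      } else if (ty == "TLP_L") {
        ko <- sample(catalog$architectures[["EUKARYOTIC_L_C"]]$required, 1L)
        sp <- protein_spec("EUKARYOTIC_L", knockouts = ko)
      } else sp <- protein_spec(ty)
      p <- synth_protein(sp, catalog)
      id <- sprintf("%s_%03d", ty, i)
      sequences[[id]] <- p$sequence
      truths[[id]] <- p$truth
      expected[[id]] <- ty
    }
    list(sequences = sequences, truths = truths, expected = expected)
  })
}
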