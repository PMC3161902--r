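#' Default tRNase Z motif catalog
#'
#' Builds the catalog of degenerate consensus motifs that define the tRNase Z
#' domain grammar, together with the motif architectures of the three types
#' found in green plants:
#'
#' * `TM_S` — TM-type short form: Gly-rich `EGxSxxG` (in place of PxKxRN),
#'   Motifs I-V of the metallo-beta-lactamase domain, the short (~30 aa)
#'   flexible arm carrying the Lys/Leu-rich KL motif
#'   (`KLKxxYxxLxGxxIxxLK`), and the variant catalytic `xExT` and `HxH`
#'   motifs in place of HEAT and HST.
#' * `BACTERIAL_S` — bacterial-type short form: `Px[KL]xRN` (the plant
#'   bacterial-type candidates carry the Lys-to-Leu variant), Motifs I-V,
#'   the ~55 aa GP-arm (`GxPxGP`), and the `HEAT` and `HST` motifs.
#' * `EUKARYOTIC_L_C` — the C-terminal half of the eukaryotic long form:
#'   `PxKxRN`, Motifs I-V, `HEAT`, `HST`.
#' * `EUKARYOTIC_L_N` — the N-terminal half of the long form: pseudo-PxKxRN
#'   and pseudo-Motifs I/II (degenerate remnants required to differ from the
#'   parent consensus at a catalytically critical residue) plus the
#'   eukaryotic (~62 aa) GP-arm.
#'
#' Motifs I, III, IV and V have no full consensus beyond their invariant
#' Asp/His anchors; the catalog ships minimal anchored patterns for them
#' (`xxDx`, `xHxx`, `xDxx`, `xHxx`). They are weighted lightly: chain
#' assembly resolves their placement through the order constraint, and
#' classification leans on the fully specified motifs. All defaults are
#' overridable via a catalog file ([read_catalog()]).
#'
#' Canonical N-to-C ranks: 1 = PxKxRN/EGxSxxG slot, 2 = Motif I, 3 = Motif
#' II (His motif), 4 = flexible-arm motif (KL or GP), 5-7 = Motifs III-V,
#' 8 = HEAT/xExT, 9 = HST/HxH.
#'
#' @return An object of class `trz_catalog`: list with `entries` (named list
#'   of `trz_motif`) and `architectures` (named list with `required` /
#'   `optional` motif-name vectors in canonical order).
#' @examples
#' cat <- trz_catalog()
#' names(cat$entries)
#' @export
trz_catalog <- function() {
  spec <- list(
    #        name            pattern                mm  rank  req_mm
    list("PXKXRN",        "Px[KL]xRN",           0L, 1L, integer()),
    list("EGXSXXG",       "EGxSxxG",             1L, 1L, integer()),
    list("PSEUDO_PXKXRN", "Px[KL]xRN",           2L, 1L, 3L),
    list("MOTIF_I",       "xxDx",                0L, 2L, integer()),
    list("PSEUDO_I",      "xxDx",                2L, 2L, 3L),
    list("MOTIF_II",      "HxHxDH",              0L, 3L, integer()),
    list("PSEUDO_II",     "HxHxDH",              2L, 3L, 3L),
    list("KL",            "KLKxxYxxLxGxxIxxLK",  1L, 4L, integer()),
    list("GP",            "GxPxGP",              0L, 4L, integer()),
    list("MOTIF_III",     "xHxx",                0L, 5L, integer()),
    list("MOTIF_IV",      "xDxx",                0L, 6L, integer()),
    list("MOTIF_V",       "xHxx",                0L, 7L, integer()),
    list("HEAT",          "HEAT",                1L, 8L, integer()),
    list("XEXT",          "[TMVL]E[SAMTCA]T",    0L, 8L, integer()),
    list("HST",           "HST",                 0L, 9L, integer()),
    list("HXH",           "H[TS]H",              0L, 9L, integer())
  )
  entries <- lapply(spec, function(e)
    compile_motif(e[[2]], e[[3]], name = e[[1]], rank = e[[4]],
                  require_mismatch = e[[5]]))
  names(entries) <- vapply(spec, `[[`, character(1), 1L)
  architectures <- list(
    TM_S = list(
      required = c("EGXSXXG", "MOTIF_I", "MOTIF_II", "KL", "MOTIF_III",
                   "MOTIF_IV", "MOTIF_V", "XEXT", "HXH"),
      optional = character()),
    BACTERIAL_S = list(
      required = c("PXKXRN", "MOTIF_I", "MOTIF_II", "GP", "MOTIF_III",
                   "MOTIF_IV", "MOTIF_V", "HEAT", "HST"),
      optional = character()),
    EUKARYOTIC_L_C = list(
      required = c("PXKXRN", "MOTIF_I", "MOTIF_II", "MOTIF_III",
                   "MOTIF_IV", "MOTIF_V", "HEAT", "HST"),
      optional = character()),
    EUKARYOTIC_L_N = list(
      required = c("PSEUDO_PXKXRN", "PSEUDO_I", "PSEUDO_II", "GP"),
      optional = character())
  )
  validate_catalog(structure(list(entries = entries, architectures = architectures),
                             class = "trz_catalog"))
}

validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "trz_catalog"))
  for (an in names(catalog$architectures)) {
    arch <- catalog$architectures[[an]]
    nm <- c(arch$required, arch$optional)
    missing <- setdiff(nm, names(catalog$entries))
    if (length(missing))
      stop(sprintf("architecture '%s' references unknown motifs: %s",
                   an, paste(missing, collapse = ", ")))
    ranks <- vapply(catalog$entries[nm], `[[`, integer(1), "rank")
    if (anyDuplicated(ranks))
      stop(sprintf("architecture '%s' has duplicated motif ranks", an))
    if (is.unsorted(ranks, strictly = TRUE))
      stop(sprintf("architecture '%s' motifs are not in canonical rank order", an))
  }
  catalog
}

#' @export
print.trz_catalog <- function(x, ...) {
  cat(sprintf("<trz_catalog> %d motifs, %d architectures\n",
              length(x$entries), length(x$architectures)))
  for (m in x$entries)
    cat(sprintf("  %-14s %-20s mm=%d rank=%d%s\n", m$name, m$pattern,
                m$max_mismatches, m$rank,
                if (length(m$require_mismatch))
                  paste0(" require_mismatch=", paste(m$require_mismatch, collapse = ","))
                else ""))
  for (an in names(x$architectures))
    cat(sprintf("  [%s] %s\n", an,
                paste(x$architectures[[an]]$required, collapse = " > ")))
  invisible(x)
}

#' Read a motif catalog from a plain-text configuration file
#'
#' The format has one `motif` line per entry and one `architecture` line per
#' type:
#' ```
#' motif  NAME  PATTERN  MAX_MISMATCHES  RANK  [REQUIRE_MISMATCH(csv)]
#' architecture  NAME  required=M1,M2,...  [optional=M3,...]
#' ```
#' Blank lines and lines starting with `#` are ignored. Fields are
#' whitespace-separated.
#'
#' @param path Path to the catalog file.
#' @return A `trz_catalog` object.
#' @seealso [write_catalog()], [trz_catalog()]
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- list()
  architectures <- list()
  for (ln in lines) {
    f <- strsplit(ln, "[ \t]+")[[1L]]
    if (f[1L] == "motif") {
      if (length(f) < 5L) stop("malformed motif line: ", ln)
      rq <- if (length(f) >= 6L) as.integer(strsplit(f[6L], ",")[[1L]]) else integer()
      entries[[f[2L]]] <- compile_motif(f[3L], as.integer(f[4L]), name = f[2L],
                                        rank = as.integer(f[5L]),
                                        require_mismatch = rq)
    } else if (f[1L] == "architecture") {
      if (length(f) < 3L) stop("malformed architecture line: ", ln)
      kv <- f[-(1:2)]
      get <- function(key) {
        hit <- kv[startsWith(kv, paste0(key, "="))]
        if (!length(hit)) return(character())
        strsplit(sub(paste0("^", key, "="), "", hit[1L]), ",")[[1L]]
      }
      architectures[[f[2L]]] <- list(required = get("required"),
                                     optional = get("optional"))
    } else stop("unrecognized catalog line: ", ln)
  }
  validate_catalog(structure(list(entries = entries, architectures = architectures),
                             class = "trz_catalog"))
}

#' Write a motif catalog to a plain-text configuration file
#'
#' @param catalog A `trz_catalog` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_catalog()]
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "trz_catalog"))
  out <- c("# trzsurvey motif catalog",
           vapply(catalog$entries, function(m) {
             base <- sprintf("motif\t%s\t%s\t%d\t%d", m$name, m$pattern,
                             m$max_mismatches, m$rank)
             if (length(m$require_mismatch))
               base <- paste0(base, "\t", paste(m$require_mismatch, collapse = ","))
             base
           }, character(1)),
           vapply(names(catalog$architectures), function(an) {
             a <- catalog$architectures[[an]]
             ln <- sprintf("architecture\t%s\trequired=%s", an,
                           paste(a$required, collapse = ","))
             if (length(a$optional))
               ln <- paste0(ln, "\toptional=", paste(a$optional, collapse = ","))
             ln
           }, character(1)))
  writeLines(out, path)
  invisible(path)
}
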