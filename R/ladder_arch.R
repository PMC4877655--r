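#' Can a residue hold the asparagine ladder?
#'
#' The ladder hydrogen bond is donated by Asn or, in substituted modules, by
#' other hydrogen-bond donors: Thr, Ser, or Cys.
#'
#' @param residue One-letter residue code(s).
#' @return Logical vector: `TRUE` where the residue is ladder-competent.
#' @export
ladder_competence <- function(residue) {
  toupper(residue) %in% c("N", "T", "S", "C")
}

#' Split a module stack into N-terminal, central and C-terminal segments
#'
#' Terciles by module ordinal, remainder modules assigned to the central
#' segment; all segments are contiguous and non-empty.
#'
#' @param n_modules Number of LRR modules (at least 6).
#' @return List of `c(first, last)` module indices: `nterm`, `central`, `cterm`.
#' @export
segment_modules <- function(n_modules) {
  n_modules <- as.integer(n_modules)
  if (n_modules < 6L) stop("too few modules to segment (need >= 6)")
  k <- n_modules %/% 3L
  list(nterm = c(1L, k),
       central = c(k + 1L, n_modules - k),
       cterm = c(n_modules - k + 1L, n_modules))
}

segment_stats <- function(flags, range, run_threshold, frac_threshold) {
  seg <- flags[range[1]:range[2]]
  runs <- rle(!seg)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  frac <- mean(!seg)
  list(frac_incompetent = frac, longest_run = longest,
       broken = longest >= run_threshold || frac >= frac_threshold)
}

#' Classify an ectodomain architecture from its ladder competence flags
#'
#' A segment is BROKEN iff its longest run of ladder-incompetent modules is at
#' least `run_threshold`, or its incompetent fraction is at least
#' `frac_threshold`. Verdicts: `SD` when no segment is broken; `TD` when only
#' the central segment is broken; `TTD` when both terminal segments are broken
#' and the central one is intact; `AMBIGUOUS` otherwise.
#'
#' @param flags Logical vector of per-module ladder competence (length >= 6).
#' @param segmentation Optional segmentation from [segment_modules()].
#' @param run_threshold Minimum incompetent run length that breaks a segment.
#' @param frac_threshold Minimum incompetent fraction that breaks a segment.
#' @return An object of class `arch_call` with `verdict`, per-segment `broken`
#'   flags, and a diagnostics table.
#' @export
classify_architecture <- function(flags,
                                  segmentation = segment_modules(length(flags)),
                                  run_threshold = 2L, frac_threshold = 0.4) {
  stopifnot(is.logical(flags), !anyNA(flags))
  if (length(flags) < 6L) stop("need >= 6 competence flags")
  st <- lapply(segmentation, segment_stats, flags = flags,
               run_threshold = run_threshold, frac_threshold = frac_threshold)
  broken <- vapply(st, `[[`, logical(1), "broken")
  verdict <- if (!any(broken)) "SD"
  else if (broken[["central"]] && !broken[["nterm"]] && !broken[["cterm"]]) "TD"
  else if (!broken[["central"]] && broken[["nterm"]] && broken[["cterm"]]) "TTD"
  else "AMBIGUOUS"
  diagnostics <- data.frame(
    segment = names(st),
    first = vapply(segmentation, `[`, integer(1), 1L),
    last = vapply(segmentation, `[`, integer(1), 2L),
    frac_incompetent = vapply(st, `[[`, numeric(1), "frac_incompetent"),
    longest_run = vapply(st, `[[`, numeric(1), "longest_run"),
    broken = broken,
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(verdict = verdict, broken = broken,
                 diagnostics = diagnostics),
            class = "arch_call")
}

#' @exportS3Method base::print
print.arch_call <- function(x, ...) {
  cat("architecture:", x$verdict, "| broken segments:",
      if (any(x$broken)) paste(names(x$broken)[x$broken], collapse = ",")
      else "none", "\n")
  invisible(x)
}

#' Grade the evolutionary conservation of an alignment column
#'
#' An ordinal nine-grade scale from most variable (1) to most conserved (9):
#' the score is one minus the normalized Shannon entropy of the column's
#' residue frequencies (log base 20), and the grade is `1 + floor(8 * score)`
#' capped at 9. Gaps are excluded; fewer than two non-gap residues give `NA`.
#'
#' @param column Character vector of residues (one alignment column).
#' @return Integer grade in 1..9, or `NA_integer_`.
#' @export
conservation_grade <- function(column) {
  res <- column[column != "-" & !is.na(column)]
  if (length(res) < 2L) return(NA_integer_)
  p <- table(res) / length(res)
  H <- -sum(p * log(p)) / log(20)
  score <- 1 - H
  min(1L + as.integer(floor(8 * score)), 9L)
}

# map ungapped positions of a reference row to alignment columns
ref_columns <- function(aln, ref_id) {
  i <- match(ref_id, aln$ids)
  if (is.na(i)) stop("reference '", ref_id, "' not present in the alignment")
  ch <- strsplit(aln$seqs[i], "")[[1]]
  which(ch != "-")
}

#' Consensus ladder profile of an ortholog family
#'
#' For each LRR module of the reference annotation, finds the alignment column
#' holding the reference ladder position and reports the modal non-gap residue
#' across the family, its frequency, the competence of the modal residue, and
#' the column's conservation grade. When all non-reference rows are gapped in a
#' column, the reference residue is reported with frequency over 1 and the
#' grade is missing.
#'
#' @param alignment A [multiple_alignment()] containing the reference row.
#' @param annotation `ecto_annotation` of the reference sequence (unaligned).
#' @param ref_id Reference row id (defaults to the annotation's record id).
#' @return An object of class `ladder_profile`: a per-module table plus the
#'   module segmentation as attribute `segments`.
#' @export
consensus_ladder_profile <- function(alignment, annotation,
                                     ref_id = annotation$record_id) {
  stopifnot(inherits(alignment, "multiple_alignment"),
            inherits(annotation, "ecto_annotation"))
  mods <- annotation$modules
  if (nrow(mods) < 1L) stop("annotation has no modules")
  cols <- ref_columns(alignment, ref_id)
  if (max(mods$ladder_pos) > length(cols)) {
    stop("reference ladder positions extend past its ungapped length")
  }
  m <- aln_matrix(alignment)
  out <- lapply(seq_len(nrow(mods)), function(k) {
    col_idx <- cols[mods$ladder_pos[k]]
    col <- m[, col_idx]
    nong <- col[col != "-"]
    if (length(nong) == 0L || all(names(nong) %in% ref_id) ||
        length(nong) == 1L) {
      modal <- m[ref_id, col_idx]
      if (modal == "-") modal <- mods$ladder_res[k]
      freq <- 1.0
      n_used <- 1L
    } else {
      tab <- table(nong)
      top <- max(tab)
      modal <- sort(names(tab)[tab == top])[1]  # alphabetical tie-break
      freq <- top / length(nong)
      n_used <- length(nong)
    }
    data.frame(module = mods$index[k], column = col_idx,
               modal_residue = modal, modal_freq = freq,
               competent = ladder_competence(modal),
               grade = conservation_grade(col),
               n_residues = n_used, stringsAsFactors = FALSE)
  })
  profile <- do.call(rbind, out)
  structure(profile,
            segments = segment_modules(nrow(mods)),
            class = c("ladder_profile", "data.frame"))
}

#' Classify an ectodomain from its annotation (and optionally its family)
#'
#' With an alignment the per-module competence flags come from the modal ladder
#' residues of the family (the consensus display); alone, from the reference's
#' own ladder residues.
#'
#' @param annotation `ecto_annotation` of the sequence.
#' @param alignment Optional [multiple_alignment()] of the ortholog family.
#' @param ... Passed to [classify_architecture()].
#' @return An `arch_call`.
#' @export
classify_ectodomain <- function(annotation, alignment = NULL, ...) {
  flags <- if (is.null(alignment)) {
    ladder_competence(annotation$modules$ladder_res)
  } else {
    consensus_ladder_profile(alignment, annotation)$competent
  }
  classify_architecture(flags, ...)
}

#' Phenylalanine-spine presence per module (experimental)
#'
#' Flags, per module, whether the modal residue at the designated convex-face
#' spine offset is aromatic (F/Y/W). The spine position is
#' `motif_start + spine_offset` (default offset 11, i.e. the residue after the
#' 11-position concave motif). Marked experimental: the spine offset is a
#' configuration choice, not a measured quantity.
#'
#' @param annotation `ecto_annotation` of the reference sequence.
#' @param alignment [multiple_alignment()] containing the reference row.
#' @param ref_id Reference row id.
#' @param spine_offset Offset from the motif start to the spine position.
#' @return Data frame with per-module `spine` flags (attribute
#'   `experimental = TRUE`).
#' @export
phenylalanine_spine_profile <- function(annotation, alignment,
                                        ref_id = annotation$record_id,
                                        spine_offset = 11L) {
  mods <- annotation$modules
  cols <- ref_columns(alignment, ref_id)
  m <- aln_matrix(alignment)
  pos <- mods$motif_start + spine_offset
  pos <- pmin(pos, length(cols))
  flag <- vapply(pos, function(p) {
    col <- m[, cols[p]]
    nong <- col[col != "-"]
    if (length(nong) == 0L) return(FALSE)
    tab <- table(nong)
    modal <- sort(names(tab)[tab == max(tab)])[1]
    modal %in% c("F", "Y", "W")
  }, logical(1))
  structure(data.frame(module = mods$index, spine_pos = pos, spine = flag,
                       stringsAsFactors = FALSE),
            experimental = TRUE)
}
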