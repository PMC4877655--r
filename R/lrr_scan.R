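# Residue sets used throughout: the concave-face consensus of an LRR module
# is L..L.L..N.L over 11 positions (constrained at 1, 4, 6, 9, 11), with the
# ladder position (9) occupied by Asn or another hydrogen-bond donor.
MOTIF_CONSTRAINED <- c(1L, 4L, 6L, 9L, 11L)

#' Parameters of the concave-surface motif scan
#'
#' The scanner scores 11-residue windows against the conserved concave-face
#' pattern of LRR modules: hydrophobic residues at positions 1, 4, 6 and 11
#' and a hydrogen-bond donor (the ladder residue) at position 9. Asn and Cys
#' earn the full position-9 weight; Thr and Ser, which can also donate the
#' ladder hydrogen bond, earn half.
#'
#' @param hydrophobic Residues accepted at the hydrophobic positions.
#' @param weights Nonnegative weights for the 11 window positions
#'   (unconstrained positions are ignored).
#' @param min_len,max_len Allowed module length range (canonical length 24).
#' @param canonical_len Canonical module length used to close the last module.
#' @param min_score Minimum window score for a candidate module anchor.
#' @param half_credit Score multiplier for Thr/Ser at position 9.
#' @return An object of class `motif_params`.
#' @export
motif_params <- function(hydrophobic = c("L", "I", "V", "F", "M"),
                         weights = rep(1, 11),
                         min_len = 20L, max_len = 30L, canonical_len = 24L,
                         min_score = 3.0, half_credit = 0.5) {
  stopifnot(length(weights) == 11L, all(weights >= 0), sum(weights) > 0)
  if (!(min_len <= canonical_len && canonical_len <= max_len)) {
    stop("module length window must contain the canonical length")
  }
  structure(list(hydrophobic = hydrophobic, weights = as.numeric(weights),
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 canonical_len = as.integer(canonical_len),
                 min_score = min_score, half_credit = half_credit),
            class = "motif_params")
}

#' Score an 11-residue window against the concave-surface motif
#'
#' @param window A string of exactly 11 residues.
#' @param params A [motif_params()] object.
#' @return The window score (0 up to the maximum attainable under `weights`).
#' @export
score_motif_window <- function(window, params = motif_params()) {
  if (nchar(window) != 11L) stop("motif window must be exactly 11 residues")
  ch <- strsplit(window, "")[[1]]
  w <- params$weights
  hyd <- ch %in% params$hydrophobic
  s <- sum(w[c(1, 4, 6, 11)] * hyd[c(1, 4, 6, 11)])
  s9 <- if (ch[9] %in% c("N", "C")) w[9] else
    if (ch[9] %in% c("T", "S")) params$half_credit * w[9] else 0
  s + s9
}

# vectorized window scores for all start positions 1..(L-10)
motif_window_scores <- function(chars, params) {
  L <- length(chars)
  if (L < 11L) return(numeric(0))
  p <- seq_len(L - 10L)
  hyd <- chars %in% params$hydrophobic
  w <- params$weights
  s9 <- ifelse(chars %in% c("N", "C"), w[9],
               ifelse(chars %in% c("T", "S"), params$half_credit * w[9], 0))
  w[1] * hyd[p] + w[4] * hyd[p + 3L] + w[6] * hyd[p + 5L] +
    w[11] * hyd[p + 10L] + s9[p + 8L]
}

# Maximum-total-score chain over candidate anchors with successive anchors at
# least min_len apart. Ties broken toward more modules, then leftmost starts.
# Returns indices into `pos` for the chosen chain.
chain_candidates <- function(pos, score, min_len) {
  k <- length(pos)
  if (k == 0L) return(integer(0))
  # chains[[i]]: best chain ending at candidate i (score, member indices)
  chain_score <- numeric(k)
  chain_prev <- integer(k)
  chain_len <- integer(k)
  members <- function(i) {
    out <- integer(0)
    while (i > 0L) { out <- c(i, out); i <- chain_prev[i] }
    out
  }
  better <- function(s1, m1, s2, m2) {
    # is chain 1 (score s1, member idx m1) better than chain 2?
    if (s1 > s2 + 1e-9) return(TRUE)
    if (s1 < s2 - 1e-9) return(FALSE)
    if (length(m1) != length(m2)) return(length(m1) > length(m2))
    p1 <- pos[m1]; p2 <- pos[m2]
    d <- which(p1 != p2)
    if (length(d) == 0L) return(FALSE)
    p1[d[1]] < p2[d[1]]
  }
  for (i in seq_len(k)) {
    chain_score[i] <- score[i]
    chain_prev[i] <- 0L
    chain_len[i] <- 1L
    for (j in seq_len(i - 1L)) {
      if (pos[i] - pos[j] < min_len) next
      cand_s <- chain_score[j] + score[i]
      if (better(cand_s, c(members(j), i), chain_score[i], members(i))) {
        chain_score[i] <- cand_s
        chain_prev[i] <- j
        chain_len[i] <- chain_len[j] + 1L
      }
    }
  }
  best <- 1L
  for (i in seq_len(k)) {
    if (better(chain_score[i], members(i), chain_score[best], members(best))) {
      best <- i
    }
  }
  members(best)
}

#' Detect LRR modules in an ectodomain sequence
#'
#' Scores every 11-residue window against the concave-surface motif, keeps
#' windows at or above `min_score` as candidate module anchors, and selects
#' the maximum-total-score chain of anchors spaced at least `min_len` apart
#' by dynamic programming. Each module runs from its anchor to one residue
#' before the next module's anchor, truncated at `max_len`; residues beyond
#' `max_len` before the next anchor are reported as unassigned inserts. The
#' last module is closed at the canonical length (24), truncated at the
#' sequence end. The ladder position is motif position 9; its residue is
#' recorded without requiring Asn, so broken ladders remain detectable.
#'
#' @param seq Amino-acid string (ectodomain).
#' @param params A [motif_params()] object.
#' @param id Record id carried into the annotation.
#' @return An object of class `ecto_annotation` with the module table
#'   (`modules`), optional cap spans (`lrrnt`, `lrrct`), unassigned insert
#'   spans, and the total chain score.
#' @export
detect_lrr_modules <- function(seq, params = motif_params(), id = "query") {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < params$min_len) stop("sequence shorter than the minimum module length")
  chars <- strsplit(seq, "")[[1]]
  sc <- motif_window_scores(chars, params)
  cand <- which(sc >= params$min_score - 1e-9)
  if (length(cand) == 0L) {
    ann <- structure(list(record_id = id,
                          modules = empty_module_table(),
                          lrrnt = NULL, lrrct = NULL, inserts = NULL,
                          total_score = 0, no_modules = TRUE, seq_length = L),
                     class = "ecto_annotation")
    warning("no candidate module above the score threshold for '", id, "'")
    return(ann)
  }
  sel <- chain_candidates(cand, sc[cand], params$min_len)
  anchors <- cand[sel]
  n <- length(anchors)
  ends <- integer(n)
  inserts <- NULL
  for (i in seq_len(n)) {
    if (i < n) {
      full_end <- anchors[i + 1L] - 1L
      ends[i] <- min(full_end, anchors[i] + params$max_len - 1L)
      if (full_end > ends[i]) {
        inserts <- rbind(inserts, c(ends[i] + 1L, full_end))
      }
    } else {
      ends[i] <- min(anchors[i] + params$canonical_len - 1L, L)
    }
  }
  modules <- data.frame(
    index = seq_len(n),
    start = anchors,
    end = ends,
    motif_start = anchors,
    ladder_pos = anchors + 8L,
    ladder_res = chars[anchors + 8L],
    score = sc[anchors],
    stringsAsFactors = FALSE)
  caps <- delimit_caps(seq, modules)
  structure(list(record_id = id, modules = modules,
                 lrrnt = caps$lrrnt, lrrct = caps$lrrct,
                 inserts = inserts,
                 total_score = sum(modules$score),
                 no_modules = FALSE, seq_length = L),
            class = "ecto_annotation")
}

empty_module_table <- function() {
  data.frame(index = integer(0), start = integer(0), end = integer(0),
             motif_start = integer(0), ladder_pos = integer(0),
             ladder_res = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Delimit the cysteine-capped flanks of an LRR stack
#'
#' The N-terminal cap (LRRNT) is any flank of at least 10 residues containing
#' at least two cysteines before the first module; the C-terminal cap (LRRCT)
#' likewise after the last module.
#'
#' @param seq Ectodomain sequence.
#' @param modules Module table from [detect_lrr_modules()] (at least one row).
#' @return List with `lrrnt` and `lrrct`, each `c(start, end)` or `NULL`.
#' @export
delimit_caps <- function(seq, modules) {
  stopifnot(nrow(modules) >= 1L)
  L <- nchar(seq)
  cap <- function(start, end) {
    if (end - start + 1L < 10L) return(NULL)
    flank <- substr(seq, start, end)
    if (lengths(regmatches(flank, gregexpr("C", flank))) >= 2L) {
      c(start, end)
    } else NULL
  }
  nt <- if (modules$start[1] > 1L) cap(1L, modules$start[1] - 1L) else NULL
  ct <- if (modules$end[nrow(modules)] < L) {
    cap(modules$end[nrow(modules)] + 1L, L)
  } else NULL
  list(lrrnt = nt, lrrct = ct)
}

#' @exportS3Method base::print
print.ecto_annotation <- function(x, ...) {
  cat("ecto_annotation '", x$record_id, "': ", nrow(x$modules), " LRR modules",
      if (!is.null(x$lrrnt)) " +LRRNT", if (!is.null(x$lrrct)) " +LRRCT",
      "\n", sep = "")
  invisible(x)
}
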