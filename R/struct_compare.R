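#' TM-score distance scale
#'
#' `d0(L) = 1.24 * (L - 15)^(1/3) - 1.8` Angstroms, floored at 0.5. For
#' normalization lengths of 15 or fewer the floor is used (with a warning
#' where that happens in [tm_score()]).
#'
#' @param L Normalization length.
#' @return `d0` in Angstroms.
#' @export
tm_d0 <- function(L) {
  if (L > 15) max(1.24 * (L - 15)^(1 / 3) - 1.8, 0.5) else 0.5
}

#' Kabsch least-squares superposition
#'
#' Finds the rigid transform (rotation with determinant +1 and translation)
#' minimizing the RMSD between paired coordinate sets; reflections are
#' excluded.
#'
#' @param P,Q `n x 3` coordinate matrices of paired points (`n >= 3`).
#' @return List: `rotation` (3x3, column-vector convention `q = R p + t`),
#'   `translation` (length-3), `rmsd`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  n <- nrow(P)
  if (n < 3L || nrow(Q) != n) stop("need >= 3 paired points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_p <- svd(Pc)$d
  if (sv_p[2] < 1e-8 * max(sv_p[1], 1e-12)) {
    stop("degenerate (collinear) coordinates")
  }
  H <- crossprod(Pc, Qc)            # minimizes |Pc %*% Rr - Qc|
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  Rr <- sv$u %*% D %*% t(sv$v)      # row-vector rotation
  fitted <- Pc %*% Rr
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  rotation <- t(Rr)                 # column-vector convention
  translation <- as.numeric(cq - rotation %*% cp)
  list(rotation = rotation, translation = translation, rmsd = rmsd)
}

apply_rigid <- function(P, fit) {
  sweep(as.matrix(P) %*% t(fit$rotation), 2, fit$translation, `+`)
}

# TM optimization over a fixed correspondence: iteratively superpose on the
# close-pair subset and rescore; returns the best state found.
tm_optimize <- function(P, Q, corr, Lnorm, d0, max_iter = 20L) {
  Pa <- P[corr[, 1L], , drop = FALSE]
  Qb <- Q[corr[, 2L], , drop = FALSE]
  nali <- nrow(corr)
  sub <- seq_len(nali)
  best <- list(tm = -Inf, fit = NULL, d = NULL)
  prev_sub <- integer(0)
  for (it in seq_len(max_iter)) {
    if (length(sub) < 3L) {
      ord <- order(best$d)
      sub <- ord[seq_len(min(3L, nali))]
    }
    fit <- tryCatch(kabsch(Pa[sub, , drop = FALSE], Qb[sub, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) break
    d <- sqrt(rowSums((apply_rigid(Pa, fit) - Qb)^2))
    tm <- sum(1 / (1 + (d / d0)^2)) / Lnorm
    if (tm > best$tm) best <- list(tm = tm, fit = fit, d = d)
    sub_new <- which(d < d0)
    if (length(sub_new) < 3L) {
      sub_new <- order(d)[seq_len(min(3L, nali))]
    }
    if (identical(sub_new, prev_sub)) break
    prev_sub <- sub
    sub <- sub_new
  }
  best
}

#' TM-score of corresponded coordinate pairs
#'
#' After the superposition that maximizes the score over the corresponded
#' pairs (iterative close-pair refitting), computes
#' `TM = (1/Lnorm) * sum 1 / (1 + (d_i / d0(Lnorm))^2)`.
#'
#' @param P,Q Coordinate matrices (`n x 3`).
#' @param corr Two-column integer matrix of corresponded row indices
#'   (strictly increasing in both columns).
#' @param Lnorm Normalization length; values of 15 or below fall back to the
#'   `d0` floor of 0.5 Angstroms with a warning.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(P, Q, corr, Lnorm) {
  corr <- as.matrix(corr)
  if (nrow(corr) == 0L) stop("empty correspondence")
  if (any(diff(corr[, 1L]) <= 0) || any(diff(corr[, 2L]) <= 0)) {
    stop("correspondence must be strictly increasing in both columns")
  }
  if (Lnorm <= 15) {
    warning("normalization length <= 15: using the d0 floor of 0.5 A")
  }
  tm_optimize(P, Q, corr, Lnorm, tm_d0(Lnorm))$tm
}

#' Align two CA traces and score their structural similarity
#'
#' A simplified TM-align-style procedure: the initial correspondence comes
#' from a global alignment of the traces' residue letters (match +1,
#' mismatch 0, gap -1); then superposition and correspondence are refined
#' alternately — superpose on the current correspondence (TM-optimal), then
#' rebuild the correspondence by dynamic programming on the proximity score
#' `S(i,j) = 1 / (1 + (d_ij / d0)^2)` with gap penalty `gap` — until the
#' TM-score changes by less than `tol` or `max_iter` rounds. The best-scoring
#' state across iterations is returned, so the reported score never decreases
#' with more iterations.
#'
#' @param A,B [ca_trace()] objects (at least 20 residues each).
#' @param gap Gap penalty of the refinement alignment.
#' @param tol Convergence tolerance on the TM-score.
#' @param max_iter Maximum refinement rounds.
#' @return List with `correspondence` (two-column matrix) and `comparison`, an
#'   object of class `struct_comparison` holding `rotation`, `translation`,
#'   `rmsd`, `tm_a` (normalized by length of A), `tm_b`, and `tm_avg`.
#' @export
align_structures <- function(A, B, gap = -0.6, tol = 1e-4, max_iter = 20L) {
  stopifnot(inherits(A, "ca_trace"), inherits(B, "ca_trace"))
  LA <- nrow(A$xyz); LB <- nrow(B$xyz)
  if (LA < 20L || LB < 20L) stop("traces must have at least 20 residues")
  match_mat <- outer(A$aa, B$aa, `==`) * 1.0
  corr <- nw_align_cpp(match_mat, -1.0)
  if (nrow(corr) < 5L) stop("no sequence-seeded correspondence of length >= 5")
  Lmin <- min(LA, LB)
  d0 <- tm_d0(Lmin)
  best <- list(tm = -Inf, corr = corr, opt = NULL)
  prev_tm <- -Inf
  for (it in seq_len(max_iter)) {
    opt <- tm_optimize(A$xyz, B$xyz, corr, Lmin, d0)
    if (opt$tm > best$tm) best <- list(tm = opt$tm, corr = corr, opt = opt)
    if (abs(opt$tm - prev_tm) < tol) break
    prev_tm <- opt$tm
    PA <- apply_rigid(A$xyz, opt$fit)
    D2 <- outer(rowSums(PA^2), rowSums(B$xyz^2), `+`) - 2 * PA %*% t(B$xyz)
    S <- 1 / (1 + pmax(D2, 0) / d0^2)
    corr_new <- nw_align_cpp(S, gap)
    if (nrow(corr_new) < 3L || identical(corr_new, corr)) break
    corr <- corr_new
  }
  corr <- best$corr
  fit <- best$opt$fit
  Pa <- A$xyz[corr[, 1L], , drop = FALSE]
  Qb <- B$xyz[corr[, 2L], , drop = FALSE]
  d <- sqrt(rowSums((apply_rigid(Pa, fit) - Qb)^2))
  tm_a <- tm_optimize(A$xyz, B$xyz, corr, LA, tm_d0(LA))$tm
  tm_b <- tm_optimize(A$xyz, B$xyz, corr, LB, tm_d0(LB))$tm
  comparison <- structure(
    list(id_a = A$id, id_b = B$id,
         rotation = fit$rotation, translation = fit$translation,
         rmsd = sqrt(mean(d^2)), n_aligned = nrow(corr),
         tm_a = tm_a, tm_b = tm_b, tm_avg = (tm_a + tm_b) / 2),
    class = "struct_comparison")
  list(correspondence = corr, comparison = comparison)
}

#' @exportS3Method base::print
print.struct_comparison <- function(x, ...) {
  cat(sprintf("%s vs %s: tm_avg=%.3f (tm_a=%.3f tm_b=%.3f) rmsd=%.2f A over %d pairs\n",
              x$id_a, x$id_b, x$tm_avg, x$tm_a, x$tm_b, x$rmsd, x$n_aligned))
  invisible(x)
}

#' Per-class-pair summary of structural comparisons
#'
#' Groups `tm_avg` values by the unordered pair of architecture classes and
#' reports mean and standard error of the mean (SEM reported as 0 with an
#' `n = 1` flag for singleton groups).
#'
#' @param comparisons Data frame with columns `class_a`, `class_b`, `tm_avg`.
#' @return Data frame: `group`, `n`, `mean_tm`, `sem`.
#' @export
class_summary <- function(comparisons) {
  stopifnot(all(c("class_a", "class_b", "tm_avg") %in% names(comparisons)))
  key <- mapply(function(a, b) paste(sort(c(a, b)), collapse = "x"),
                comparisons$class_a, comparisons$class_b)
  groups <- split(comparisons$tm_avg, key)
  out <- data.frame(
    group = names(groups),
    n = lengths(groups),
    mean_tm = vapply(groups, mean, numeric(1)),
    sem = vapply(groups, function(v) {
      if (length(v) < 2L) 0 else stats::sd(v) / sqrt(length(v))
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$group), , drop = FALSE]
}
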