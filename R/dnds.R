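# Nei-Gojobori (1986) counting with Jukes-Cantor correction.
# Site and pathway tables over the 61 sense codons of the standard code are
# computed once per session and cached.

.ng_cache <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")

# standard-code sense codons, their amino acids, and lookups
ng_code <- function() {
  if (!is.null(.ng_cache$code)) return(.ng_cache$code)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  code <- list(codons = sense, aa = unname(gc[sense]),
               index = stats::setNames(seq_along(sense), sense),
               is_stop = stats::setNames(gc == "*", names(gc)))
  .ng_cache$code <- code
  code
}

#' Synonymous and nonsynonymous site counts of a codon
#'
#' For each codon position, the synonymous fraction is the number of the three
#' possible single-nucleotide changes that are synonymous and do not create a
#' stop codon, divided by the number that do not create a stop codon. The
#' codon's synonymous site count `s` is the sum of the three fractions and
#' `n = 3 - s`, so `n + s = 3` for every sense codon.
#'
#' @param codon A 3-letter sense codon (ACGT alphabet).
#' @return Named numeric vector `c(n = , s = )`; `NA`s for a stop or
#'   ambiguous codon (skip signal, not an error).
#' @export
codon_site_counts <- function(codon) {
  codon <- toupper(codon)
  code <- ng_code()
  if (!codon %in% code$codons) return(c(n = NA_real_, s = NA_real_))
  aa <- code$aa[code$index[[codon]]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0L; valid <- 0L
    for (nt in setdiff(NUCS, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- nt
      if (code$is_stop[[alt]]) next
      valid <- valid + 1L
      if (code$aa[code$index[[alt]]] == aa) syn <- syn + 1L
    }
    if (valid > 0L) s <- s + syn / valid
  }
  c(n = 3 - s, s = s)
}

# per-codon site counts for all 61 sense codons (cached)
ng_site_table <- function() {
  if (!is.null(.ng_cache$sites)) return(.ng_cache$sites)
  code <- ng_code()
  tab <- t(vapply(code$codons, codon_site_counts, c(n = 0, s = 0)))
  .ng_cache$sites <- tab
  tab
}

# Average (nd, sd) over minimal mutational pathways between two sense codons,
# excluding pathways through stop codons (equal weights on the remainder; if
# every pathway is blocked, all pathways are used). Cached as 61x61 matrices.
ng_pair_table <- function() {
  if (!is.null(.ng_cache$pairs)) return(.ng_cache$pairs)
  code <- ng_code()
  k <- length(code$codons)
  ND <- matrix(0, k, k, dimnames = list(code$codons, code$codons))
  SD <- ND
  perms2 <- list(c(1L, 2L), c(2L, 1L))
  perms3 <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                 c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      a <- code$codons[i]; b <- code$codons[j]
      diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      d <- length(diffpos)
      orders <- switch(d, list(1L), perms2, perms3)
      nd_paths <- numeric(0); sd_paths <- numeric(0); blocked <- logical(0)
      for (ord in orders) {
        cur <- a; nd <- 0; sdx <- 0; bad <- FALSE
        for (step in ord) {
          pos <- diffpos[step]
          nxt <- cur
          substr(nxt, pos, pos) <- substr(b, pos, pos)
          if (code$is_stop[[nxt]]) { bad <- TRUE; break }
          if (code$aa[code$index[[nxt]]] == code$aa[code$index[[cur]]]) {
            sdx <- sdx + 1
          } else nd <- nd + 1
          cur <- nxt
        }
        nd_paths <- c(nd_paths, nd); sd_paths <- c(sd_paths, sdx)
        blocked <- c(blocked, bad)
      }
      use <- if (all(blocked)) {
        # re-walk all pathways ignoring the stop exclusion
        res <- vapply(orders, function(ord) {
          cur <- a; nd <- 0; sdx <- 0
          for (step in ord) {
            pos <- diffpos[step]
            nxt <- cur
            substr(nxt, pos, pos) <- substr(b, pos, pos)
            aa_n <- Biostrings::GENETIC_CODE[[nxt]]
            aa_c <- Biostrings::GENETIC_CODE[[cur]]
            if (aa_n == aa_c) sdx <- sdx + 1 else nd <- nd + 1
            cur <- nxt
          }
          c(nd, sdx)
        }, numeric(2))
        list(nd = res[1, ], sd = res[2, ])
      } else {
        list(nd = nd_paths[!blocked], sd = sd_paths[!blocked])
      }
      ND[i, j] <- mean(use$nd)
      SD[i, j] <- mean(use$sd)
    }
  }
  .ng_cache$pairs <- list(ND = ND, SD = SD)
  .ng_cache$pairs
}

# codon string -> indices into the 61 sense codons (NA for gap/N/stop/other)
codon_indices <- function(sequence) {
  sequence <- toupper(sequence)
  if (nchar(sequence) %% 3L != 0L) {
    stop("coding sequence length not divisible by 3")
  }
  n <- nchar(sequence) %/% 3L
  codons <- substring(sequence, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  unname(ng_code()$index[codons])
}

jc_correct <- function(p) {
  ifelse(is.na(p) | p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' Pairwise dN/dS by Nei-Gojobori counting
#'
#' Synonymous/nonsynonymous sites are averaged over the two sequences; per
#' differing codon pair, substitutions are averaged over all minimal
#' mutational pathways that avoid stop codons. Proportions are Jukes-Cantor
#' corrected; `omega = dN/dS` is `NA` when `dS` is zero or a proportion
#' reaches the correction's domain boundary (3/4). Codon columns containing
#' gaps, `N`s, or stops in either sequence are skipped.
#'
#' @param a,b Coding sequences (strings or lists with a `sequence` field),
#'   aligned in frame and of equal length.
#' @return An object of class `dnds_estimate` with fields `N`, `S`, `Nd`,
#'   `Sd`, `pN`, `pS`, `dN`, `dS`, `omega`, and `n_codons` (compared codons).
#' @export
pairwise_dnds <- function(a, b) {
  sa <- if (is.list(a)) a$sequence else a
  sb <- if (is.list(b)) b$sequence else b
  if (nchar(sa) != nchar(sb)) stop("sequences must be aligned (equal length)")
  ia <- codon_indices(sa)
  ib <- codon_indices(sb)
  ok <- !is.na(ia) & !is.na(ib)
  sites <- ng_site_table()
  pt <- ng_pair_table()
  N <- sum((sites[ia[ok], "n"] + sites[ib[ok], "n"]) / 2)
  S <- sum((sites[ia[ok], "s"] + sites[ib[ok], "s"]) / 2)
  Nd <- sum(pt$ND[cbind(ia[ok], ib[ok])])
  Sd <- sum(pt$SD[cbind(ia[ok], ib[ok])])
  pN <- if (N > 0) Nd / N else NA_real_
  pS <- if (S > 0) Sd / S else NA_real_
  dN <- jc_correct(pN)
  dS <- jc_correct(pS)
  omega <- if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else NA_real_
  structure(list(N = N, S = S, Nd = Nd, Sd = Sd, pN = pN, pS = pS,
                 dN = dN, dS = dS, omega = omega, n_codons = sum(ok)),
            class = "dnds_estimate")
}

#' @exportS3Method base::print
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("dN/dS: dN=%.4f dS=%.4f omega=%s (N=%.1f S=%.1f, %d codons)\n",
              x$dN, x$dS,
              if (is.na(x$omega)) "undefined" else sprintf("%.4f", x$omega),
              x$N, x$S, x$n_codons))
  invisible(x)
}

# per-pair, per-codon-column contribution arrays for a set of sequences
dnds_column_arrays <- function(idx_mat) {
  n_seq <- nrow(idx_mat)
  pairs <- utils::combn(n_seq, 2L)
  sites <- ng_site_table()
  pt <- ng_pair_table()
  np <- ncol(pairs)
  nc <- ncol(idx_mat)
  Nm <- matrix(0, np, nc); Sm <- Nm; NDm <- Nm; SDm <- Nm
  for (p in seq_len(np)) {
    ia <- idx_mat[pairs[1L, p], ]
    ib <- idx_mat[pairs[2L, p], ]
    ok <- !is.na(ia) & !is.na(ib)
    Nm[p, ok] <- (sites[ia[ok], "n"] + sites[ib[ok], "n"]) / 2
    Sm[p, ok] <- (sites[ia[ok], "s"] + sites[ib[ok], "s"]) / 2
    NDm[p, ok] <- pt$ND[cbind(ia[ok], ib[ok])]
    SDm[p, ok] <- pt$SD[cbind(ia[ok], ib[ok])]
  }
  list(N = Nm, S = Sm, Nd = NDm, Sd = SDm, pairs = pairs)
}

# mean omega over pairs from per-pair totals; NA pairs dropped
mean_omega_from_totals <- function(N, S, Nd, Sd) {
  dN <- jc_correct(ifelse(N > 0, Nd / N, NA_real_))
  dS <- jc_correct(ifelse(S > 0, Sd / S, NA_real_))
  om <- ifelse(!is.na(dN) & !is.na(dS) & dS > 0, dN / dS, NA_real_)
  if (all(is.na(om))) return(NA_real_)
  mean(om, na.rm = TRUE)
}

#' Mean dN/dS of a locus with a codon-column bootstrap CI
#'
#' Computes omega for every sequence pair, averages the defined values, and
#' builds a percentile 95% confidence interval by resampling codon columns
#' (all pair statistics recomputed per replicate). Deterministic under a
#' fixed seed. A warning is issued below 5 sequences (few-sequence loci give
#' unstable means); an error if no pair has a defined omega.
#'
#' @param records List or data.frame of aligned coding sequences (each with a
#'   `sequence` field, or a character vector).
#' @param n_boot Number of bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @param label Locus label carried into the summary.
#' @return An object of class `locus_summary`: `label`, `mean_omega`,
#'   `ci_low`, `ci_high`, `n_seq`, `n_pairs`, `n_boot`.
#' @export
locus_mean_dnds <- function(records, n_boot = 1000L, seed = 1L, label = "locus") {
  seqs <- if (is.data.frame(records)) records$sequence
  else if (is.list(records)) vapply(records, function(r)
    if (is.list(r)) r$sequence else r, character(1))
  else as.character(records)
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (length(seqs) < 5L) {
    warning("fewer than 5 sequences at '", label,
            "': mean omega may be unstable")
  }
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must be aligned")
  idx <- do.call(rbind, lapply(seqs, codon_indices))
  arr <- dnds_column_arrays(idx)
  np <- nrow(arr$N)
  point <- mean_omega_from_totals(rowSums(arr$N), rowSums(arr$S),
                                  rowSums(arr$Nd), rowSums(arr$Sd))
  if (is.na(point)) stop("no sequence pair with a defined omega at '", label, "'")
  nc <- ncol(arr$N)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      tab <- tabulate(sample.int(nc, nc, replace = TRUE), nbins = nc)
      mean_omega_from_totals(arr$N %*% tab, arr$S %*% tab,
                             arr$Nd %*% tab, arr$Sd %*% tab)
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  ci <- c(min(ci[1], point), max(ci[2], point))
  structure(list(label = label, mean_omega = point,
                 ci_low = ci[1], ci_high = ci[2],
                 n_seq = length(seqs), n_pairs = np,
                 n_boot = as.integer(n_boot)),
            class = "locus_summary")
}

#' @exportS3Method base::print
print.locus_summary <- function(x, ...) {
  cat(sprintf("%s: mean omega = %.3f [%.3f, %.3f] (%d seqs, %d pairs)\n",
              x$label, x$mean_omega, x$ci_low, x$ci_high, x$n_seq, x$n_pairs))
  invisible(x)
}
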