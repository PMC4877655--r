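# Independent oracles and fixture builders used across the suite.
# These deliberately do NOT share code paths with the package internals.

# -- exhaustive chain enumeration ------------------------------------------
# Enumerates every feasible anchor chain (successive anchors >= min_len
# apart) and returns the maximum total score. Independent of the package's
# dynamic program.
brute_force_chain_score <- function(pos, score, min_len) {
  k <- length(pos)
  best <- 0
  extend <- function(last, acc) {
    if (acc > best) best <<- acc
    from <- if (last == 0L) 1L else last + 1L
    if (from > k) return(invisible())
    for (i in from:k) {
      if (last == 0L || pos[i] - pos[last] >= min_len) {
        extend(i, acc + score[i])
      }
    }
  }
  extend(0L, 0)
  best
}

# uniform random protein sequence: candidate windows appear at a density of
# roughly one per twelve positions, right for the chaining oracle
random_scannable_seq <- function(len, seed) {
  aas <- c("L", "I", "V", "F", "M", "A", "C", "D", "E", "G", "H", "K", "N",
           "P", "Q", "R", "S", "T", "W", "Y")
  with_seed_helper(seed, paste(sample(aas, len, TRUE), collapse = ""))
}

with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# -- brute-force NG86 counting ---------------------------------------------
oracle_site_counts <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  s <- 0
  for (pos in 1:3) {
    frac_num <- 0L
    frac_den <- 0L
    for (nt in nts) {
      if (nt == substr(codon, pos, pos)) next
      mut <- paste0(substr(codon, 1, pos - 1), nt, substr(codon, pos + 1, 3))
      if (gc[[mut]] == "*") next
      frac_den <- frac_den + 1L
      if (gc[[mut]] == gc[[codon]]) frac_num <- frac_num + 1L
    }
    if (frac_den > 0L) s <- s + frac_num / frac_den
  }
  c(n = 3 - s, s = s)
}

# average substitution counts over minimal mutational pathways, enumerated
# recursively with stop-codon pruning (all pathways used if all are blocked)
oracle_pair_counts <- function(a, b, allow_stops = FALSE) {
  gc <- Biostrings::GENETIC_CODE
  diffpos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  paths <- list()
  walk <- function(cur, remaining, nd, sd) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- c(nd, sd)
      return(invisible())
    }
    for (p in remaining) {
      nxt <- paste0(substr(cur, 1, p - 1), substr(b, p, p),
                    substr(cur, p + 1, 3))
      if (!allow_stops && gc[[nxt]] == "*") next
      walk(nxt, setdiff(remaining, p),
           nd + as.integer(gc[[nxt]] != gc[[cur]]),
           sd + as.integer(gc[[nxt]] == gc[[cur]]))
    }
  }
  walk(a, diffpos, 0L, 0L)
  if (length(paths) == 0L) return(oracle_pair_counts(a, b, allow_stops = TRUE))
  m <- do.call(rbind, paths)
  c(nd = mean(m[, 1]), sd = mean(m[, 2]))
}

# mean omega of an alignment without bootstrap (plain mean over pair wise
# estimates), used where only the point estimate matters
mean_pairwise_omega <- function(records) {
  seqs <- records$sequence
  oms <- c()
  for (i in seq_along(seqs)[-length(seqs)]) {
    for (j in (i + 1):length(seqs)) {
      oms <- c(oms, pairwise_dnds(seqs[i], seqs[j])$omega)
    }
  }
  mean(oms, na.rm = TRUE)
}

# -- geometry helpers -------------------------------------------------------
random_rotation <- function(seed) {
  with_seed_helper(seed, {
    M <- matrix(stats::rnorm(9), 3, 3)
    qr_d <- qr(M)
    R <- qr.Q(qr_d)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    R
  })
}

rigid_move <- function(trace, R, t) {
  ca_trace(trace$id, trace$resno, trace$aa,
           sweep(trace$xyz %*% t(R), 2, t, `+`))
}

# -- PDB fixture text -------------------------------------------------------
pdb_fixture_lines <- function(resno, aa3, chain, xyz, altloc = NULL) {
  if (is.null(altloc)) altloc <- rep(" ", length(resno))
  c(sprintf("ATOM  %5d  CA %s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            seq_along(resno), altloc, aa3, chain, resno,
            xyz[, 1], xyz[, 2], xyz[, 3]),
    "END")
}
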