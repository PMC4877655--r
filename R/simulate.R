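# Synthetic-data generators. Every generator is seed-deterministic and
# returns (or attaches) a truth record sufficient to regenerate and to score
# downstream recovery.
#
# The sequence background deliberately excludes the hydrophobic motif set
# {L,I,V,F,M}: in these fixtures the concave-face anchors are the only
# hydrophobic positions, so module boundaries are identifiable and the
# generator truth is well defined. Real sequences are noisier; see the
# methods vignette for what this does and does not validate.

BG_RESIDUES <- c("A", "C", "D", "E", "G", "H", "K", "N", "P", "Q", "R", "S",
                 "T", "W", "Y")

# sample() treats a length-1 vector as 1:x; guard ranges against that
sample_range <- function(lo, hi, n) {
  if (lo == hi) rep(as.integer(lo), n)
  else sample(seq(as.integer(lo), as.integer(hi)), n, replace = TRUE)
}
HYDROPHOBIC_SET <- c("L", "I", "V", "F", "M")
LADDER_VARIANTS <- c("T", "S", "C")
INCOMPETENT_SET <- c("A", "G", "D", "E", "K", "R", "Q", "H")

#' Simulate an LRR ectodomain with a known ladder architecture
#'
#' Builds an N-terminal cap (with two planted cysteines), `n_modules` LRR
#' modules from the concave-face template (hydrophobics at motif positions
#' 1/4/6/11, the ladder residue at position 9, a Phe spine at position 12
#' except in planted-break modules, background elsewhere), and a C-terminal
#' cap. Ladder residues follow the requested architecture: `SD` plants
#' competent residues everywhere (Asn, occasionally Thr/Ser/Cys); `TD` makes
#' the central tercile ladder-incompetent; `TTD` the two terminal terciles.
#' Outside planted breaks, `noise` flips each module's ladder competence
#' independently.
#'
#' @param architecture `"SD"`, `"TD"`, or `"TTD"`.
#' @param n_modules Number of LRR modules (6 to 30; the observed range in
#'   vertebrate ectodomains is 12-25).
#' @param seed RNG seed.
#' @param noise Per-module competence flip probability outside planted breaks.
#' @param module_len_range Module length range (sampled uniformly).
#' @param cap_len_range Cap length range.
#' @param p_ladder_variant Probability that a competent ladder residue is a
#'   Thr/Ser/Cys variant instead of Asn.
#' @return List with `record` (`id`, `sequence`) and `truth` (class
#'   `synthetic_truth`): architecture, anchors, module boundaries, ladder
#'   positions and residues, planted break modules, segmentation, seed.
#' @export
simulate_ectodomain <- function(architecture = c("SD", "TD", "TTD"),
                                n_modules = 21L, seed = 1L, noise = 0.05,
                                module_len_range = c(22L, 26L),
                                cap_len_range = c(12L, 16L),
                                p_ladder_variant = 0.05) {
  architecture <- match.arg(architecture)
  n_modules <- as.integer(n_modules)
  if (n_modules < 6L) stop("need at least 6 modules")
  with_seed(seed, {
    segs <- segment_modules(n_modules)
    break_modules <- switch(architecture,
      SD = integer(0),
      TD = seq(segs$central[1], segs$central[2]),
      TTD = c(seq(segs$nterm[1], segs$nterm[2]),
              seq(segs$cterm[1], segs$cterm[2])))
    competent <- !(seq_len(n_modules) %in% break_modules)
    flip <- competent & stats::runif(n_modules) < noise
    competent[flip] <- FALSE
    ladder <- ifelse(competent,
                     ifelse(stats::runif(n_modules) < p_ladder_variant,
                            sample(LADDER_VARIANTS, n_modules, replace = TRUE),
                            "N"),
                     sample(INCOMPETENT_SET, n_modules, replace = TRUE))
    lens <- sample_range(module_len_range[1], module_len_range[2], n_modules)
    make_cap <- function() {
      len <- sample_range(cap_len_range[1], cap_len_range[2], 1L)
      cap <- sample(BG_RESIDUES, len, replace = TRUE)
      cap[sample(len, 2L)] <- "C"
      cap
    }
    cap_n <- make_cap()
    modules <- lapply(seq_len(n_modules), function(i) {
      l <- lens[i]
      mod <- sample(BG_RESIDUES, l, replace = TRUE)
      mod[c(1L, 4L, 6L, 11L)] <- sample(HYDROPHOBIC_SET, 4L, replace = TRUE)
      mod[9L] <- ladder[i]
      if (l >= 12L) {
        mod[12L] <- if (i %in% break_modules) {
          sample(setdiff(BG_RESIDUES, c("W", "Y")), 1L)
        } else "F"
      }
      mod
    })
    cap_c <- make_cap()
    seq_chars <- c(cap_n, unlist(modules), cap_c)
    anchors <- length(cap_n) + 1L + c(0L, cumsum(lens)[-n_modules])
    id <- sprintf("%s_m%02d_s%d", architecture, n_modules, seed)
    truth <- structure(list(
      architecture = architecture, n_modules = n_modules,
      module_lengths = lens, anchors = anchors,
      module_start = anchors, module_end = anchors + lens - 1L,
      ladder_pos = anchors + 8L, ladder_res = ladder,
      competent = competent, break_modules = break_modules,
      segments = segs,
      lrrnt = c(1L, length(cap_n)),
      lrrct = c(length(seq_chars) - length(cap_c) + 1L, length(seq_chars)),
      noise = noise, seed = seed), class = "synthetic_truth")
    list(record = list(id = id, sequence = paste(seq_chars, collapse = "")),
         truth = truth)
  })
}

#' Simulate an ortholog family by star-tree evolution
#'
#' Evolves `n - 1` descendants from a root sequence on a star tree: per
#' column, each descendant substitutes with probability
#' `1 - exp(-rate * branch_length)`, drawing the replacement uniformly from
#' the 20 canonical residues. The root is returned as the first alignment row
#' so it can serve as the reference in consensus profiling. Gap-free.
#'
#' @param root Root record (list with `id`, `sequence`, or a string).
#' @param n Total number of rows (root + descendants), at least 2.
#' @param site_rates Per-column nonnegative rates (length = root length).
#' @param branch_length Star branch length.
#' @param seed RNG seed.
#' @return A [multiple_alignment()] with attribute `truth` (rates, branch
#'   length, seed).
#' @export
simulate_ortholog_family <- function(root, n, site_rates, branch_length,
                                     seed = 1L) {
  root_id <- if (is.list(root)) root$id else "root"
  root_seq <- if (is.list(root)) root$sequence else root
  L <- nchar(root_seq)
  stopifnot(n >= 2L, length(site_rates) == L, all(site_rates >= 0),
            branch_length >= 0)
  p_sub <- 1 - exp(-site_rates * branch_length)
  root_chars <- strsplit(root_seq, "")[[1]]
  aas <- c(BG_RESIDUES, HYDROPHOBIC_SET)
  rows <- with_seed(seed, {
    vapply(seq_len(n - 1L), function(k) {
      ch <- root_chars
      hit <- stats::runif(L) < p_sub
      if (any(hit)) ch[hit] <- sample(aas, sum(hit), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
  })
  aln <- multiple_alignment(
    c(root_id, sprintf("%s_ortho%02d", root_id, seq_len(n - 1L))),
    c(root_seq, rows))
  attr(aln, "truth") <- list(site_rates = site_rates,
                             branch_length = branch_length, seed = seed)
  aln
}

# 61x61 codon rate matrix (MG94-flavored): single-nucleotide exchanges at
# rate 1, times kappa for transitions, times omega for nonsynonymous changes;
# scaled to one expected substitution per codon per unit time at the uniform
# stationary distribution. Cached per (omega, kappa).
codon_rate_matrix <- function(omega, kappa = 1) {
  key <- sprintf("Q_%g_%g", omega, kappa)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  code <- ng_code()
  k <- length(code$codons)
  Q <- matrix(0, k, k, dimnames = list(code$codons, code$codons))
  is_transition <- function(x, y) {
    (x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))
  }
  split_codons <- strsplit(code$codons, "")
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      diffpos <- which(split_codons[[i]] != split_codons[[j]])
      if (length(diffpos) != 1L) next
      rate <- 1
      if (is_transition(split_codons[[i]][diffpos], split_codons[[j]][diffpos])) {
        rate <- rate * kappa
      }
      if (code$aa[i] != code$aa[j]) rate <- rate * omega
      Q[i, j] <- rate
    }
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / mean(-diag(Q))
  .ng_cache[[key]] <- Q
  Q
}

codon_transition_probs <- function(omega, kappa, t) {
  key <- sprintf("P_%g_%g_%g", omega, kappa, t)
  if (!is.null(.ng_cache[[key]])) return(.ng_cache[[key]])
  Q <- codon_rate_matrix(omega, kappa)
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  .ng_cache[[key]] <- P
  P
}

evolve_codons <- function(anc_idx, P) {
  out <- integer(length(anc_idx))
  for (v in unique(anc_idx)) {
    sel <- anc_idx == v
    out[sel] <- sample.int(ncol(P), sum(sel), replace = TRUE, prob = P[v, ])
  }
  out
}

#' Simulate a codon alignment under a known omega
#'
#' Star-tree continuous-time codon substitution: a random sense-codon
#' ancestor evolves into `n_seq` lineages of branch length `t / 2`, so any
#' two sequences are separated by divergence `t` (expected substitutions per
#' codon). Transitions are scaled by `kappa` and nonsynonymous changes by
#' `omega`; stop codons are excluded throughout.
#'
#' @param n_seq Number of sequences.
#' @param n_codons Alignment length in codons.
#' @param omega True dN/dS (> 0, or 0 for strictly synonymous evolution).
#' @param t Pairwise divergence in expected substitutions per codon.
#' @param kappa Transition/transversion rate ratio.
#' @param seed RNG seed.
#' @return List: `records` (data.frame `id`, `sequence`) and `truth`
#'   (omega, t, kappa, ancestor, seed).
#' @export
simulate_codon_alignment <- function(n_seq, n_codons, omega, t, kappa = 1,
                                     seed = 1L) {
  stopifnot(n_seq >= 2L, n_codons >= 1L, omega >= 0, t >= 0)
  code <- ng_code()
  with_seed(seed, {
    anc <- sample.int(length(code$codons), n_codons, replace = TRUE)
    P <- codon_transition_probs(omega, kappa, t / 2)
    seqs <- vapply(seq_len(n_seq), function(k) {
      paste(code$codons[evolve_codons(anc, P)], collapse = "")
    }, character(1))
    list(records = data.frame(id = sprintf("seq%02d", seq_len(n_seq)),
                              sequence = seqs, stringsAsFactors = FALSE),
         truth = list(omega = omega, t = t, kappa = kappa,
                      ancestor = paste(code$codons[anc], collapse = ""),
                      seed = seed))
  })
}

#' Simulate one codon sequence pair under a known omega
#'
#' Two lineages of length `t / 2` from a random sense-codon ancestor; see
#' [simulate_codon_alignment()].
#'
#' @param n_codons Ancestor length in codons.
#' @inheritParams simulate_codon_alignment
#' @return List: `a`, `b` (each `id` + `sequence`) and `truth`.
#' @export
simulate_codon_pair <- function(n_codons, omega, t, kappa = 1, seed = 1L) {
  sim <- simulate_codon_alignment(2L, n_codons, omega, t, kappa, seed)
  list(a = list(id = sim$records$id[1], sequence = sim$records$sequence[1]),
       b = list(id = sim$records$id[2], sequence = sim$records$sequence[2]),
       truth = sim$truth)
}

#' Simulate a horseshoe-shaped ectodomain CA trace
#'
#' Places one CA per residue of a simulated ectodomain along a solenoid: the
#' module stack follows a planar circular arc (the horseshoe) while residues
#' wind around the stack axis with the canonical 24-residue period. With
#' `central_distortion` the central-tercile modules are pulled to a smaller
#' radius and bent out of plane, mimicking the shape change of three-domain
#' ectodomains. Isotropic Gaussian noise of `noise_sd` Angstroms is added per
#' coordinate.
#'
#' @param n_modules Number of LRR modules.
#' @param central_distortion Distort the central tercile (three-domain-like)?
#' @param noise_sd Coordinate noise standard deviation in Angstroms.
#' @param seed RNG seed.
#' @param arc_radius Horseshoe radius of the module stack path (Angstroms).
#' @param coil_radius Winding radius of the residue path around the stack.
#' @return A [ca_trace()] with attribute `truth` (the ectodomain truth plus
#'   the distortion flag and noise level).
#' @export
simulate_horseshoe <- function(n_modules = 21L, central_distortion = FALSE,
                               noise_sd = 0, seed = 1L,
                               arc_radius = 30, coil_radius = 10) {
  sim <- simulate_ectodomain(if (central_distortion) "TD" else "SD",
                             n_modules = n_modules, seed = seed, noise = 0,
                             module_len_range = c(24L, 24L))
  truth <- sim$truth
  chars <- strsplit(sim$record$sequence, "")[[1]]
  L <- length(chars)
  idx <- seq_len(L)
  theta <- 1.5 * pi * (idx - 1) / (L - 1)
  phi <- 2 * pi * ((idx - 1) %% 24L) / 24
  central_mods <- seq(truth$segments$central[1], truth$segments$central[2])
  central_res <- idx >= truth$module_start[central_mods[1]] &
    idx <= truth$module_end[central_mods[length(central_mods)]]
  R0 <- rep(arc_radius, L)
  zoff <- numeric(L)
  if (central_distortion && any(central_res)) {
    u <- seq(0, 1, length.out = sum(central_res))
    R0[central_res] <- 0.72 * arc_radius
    zoff[central_res] <- 9 * sin(pi * u)
  }
  r_eff <- R0 + coil_radius * cos(phi)
  xyz <- cbind(r_eff * cos(theta),
               r_eff * sin(theta),
               coil_radius * sin(phi) + zoff)
  if (noise_sd > 0) {
    xyz <- xyz + with_seed(seed + 1L,
                           matrix(stats::rnorm(3 * L, 0, noise_sd), L, 3))
  }
  tr <- ca_trace(id = sprintf("%s_trace", sim$record$id),
                 resno = idx, aa = chars, xyz = xyz)
  attr(tr, "truth") <- c(truth, list(central_distortion = central_distortion,
                                     noise_sd = noise_sd))
  tr
}
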