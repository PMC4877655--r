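test_that("ladder competence is the hydrogen-donor set N/T/S/C", {
  expect_true(all(ladder_competence(c("N", "T", "S", "C"))))
  expect_false(any(ladder_competence(c("L", "D", "A", "Q", "G", "K"))))
})

test_that("module segmentation is terciles with remainder to the center", {
  expect_equal(segment_modules(21),
               list(nterm = c(1L, 7L), central = c(8L, 14L), cterm = c(15L, 21L)))
  expect_equal(segment_modules(19),
               list(nterm = c(1L, 6L), central = c(7L, 13L), cterm = c(14L, 19L)))
  expect_equal(segment_modules(12),
               list(nterm = c(1L, 4L), central = c(5L, 8L), cterm = c(9L, 12L)))
  expect_error(segment_modules(5), "too few")
})

test_that("the three architecture patterns classify as SD, TD and TTD", {
  all_ok <- rep(TRUE, 21)
  expect_equal(classify_architecture(all_ok)$verdict, "SD")

  td <- all_ok; td[8:12] <- FALSE
  call <- classify_architecture(td)
  expect_equal(call$verdict, "TD")
  expect_true(call$broken[["central"]])

  ttd <- all_ok; ttd[c(1:3, 19:21)] <- FALSE
  expect_equal(classify_architecture(ttd)$verdict, "TTD")

  odd <- all_ok; odd[1:3] <- FALSE  # only the N-terminal segment broken
  expect_equal(classify_architecture(odd)$verdict, "AMBIGUOUS")
})

test_that("degenerate ladders never misclassify (exhaustive 6-30)", {
  for (n in 6:30) {
    expect_false(classify_architecture(rep(FALSE, n))$verdict == "SD")
    expect_equal(classify_architecture(rep(TRUE, n))$verdict, "SD")
  }
})

test_that("an isolated flip does not break a long segment", {
  flags <- rep(TRUE, 21); flags[10] <- FALSE  # 1/7 = 0.14 < 0.4, run 1 < 2
  expect_equal(classify_architecture(flags)$verdict, "SD")
})

test_that("conservation grading maps entropy onto the nine-grade scale", {
  expect_equal(conservation_grade(rep("N", 10)), 9L)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  expect_equal(conservation_grade(aas), 1L)
  # 8 x N + 2 x S: H = 0.167, score 0.833 -> grade 7 (hand computation)
  expect_equal(conservation_grade(c(rep("N", 8), rep("S", 2))), 7L)
  expect_true(is.na(conservation_grade(c("N", "-", "-"))))
})

test_that("adding copies of the modal residue never lowers the grade", {
  for (seed in 1:10) {
    col <- with_seed_helper(seed, sample(c("N", "S", "T", "A", "L"), 12, TRUE))
    modal <- names(sort(table(col), decreasing = TRUE))[1]
    g <- conservation_grade(col)
    for (extra in 1:5) {
      g2 <- conservation_grade(c(col, rep(modal, extra)))
      expect_gte(g2, g)
      g <- g2
    }
  }
})

make_family <- function(arch, n_modules, seed, n = 8, rates = NULL, bl = 0.4) {
  sim <- simulate_ectodomain(arch, n_modules, seed = seed, noise = 0)
  L <- nchar(sim$record$sequence)
  if (is.null(rates)) rates <- rep(1, L)
  aln <- simulate_ortholog_family(sim$record, n, rates, bl, seed = seed + 100)
  ann <- detect_lrr_modules(sim$record$sequence, id = sim$record$id)
  list(sim = sim, aln = aln, ann = ann)
}

test_that("consensus profile of identical rows echoes the reference ladder", {
  fam <- make_family("SD", 12, seed = 2, rates = NULL, bl = 0)
  prof <- consensus_ladder_profile(fam$aln, fam$ann)
  expect_equal(prof$modal_freq, rep(1, 12))
  expect_equal(prof$modal_residue, fam$sim$truth$ladder_res)
  expect_equal(prof$grade, rep(9L, 12))
})

test_that("modal residue and frequency are counted over non-gap rows", {
  fam <- make_family("SD", 12, seed = 5, rates = NULL, bl = 0, n = 5)
  # overwrite one ladder column to N,N,N,T,S across the 5 rows
  pos <- fam$sim$truth$ladder_pos[4]
  seqs <- fam$aln$seqs
  substr(seqs[4], pos, pos) <- "T"
  substr(seqs[5], pos, pos) <- "S"
  aln <- multiple_alignment(fam$aln$ids, seqs)
  prof <- consensus_ladder_profile(aln, fam$ann)
  expect_equal(prof$modal_residue[4], "N")
  expect_equal(prof$modal_freq[4], 0.6)
})

test_that("planted central substitutions surface as incompetent modal residues", {
  fam <- make_family("TD", 18, seed = 9, bl = 0.2)
  prof <- consensus_ladder_profile(fam$aln, fam$ann)
  segs <- attr(prof, "segments")
  central <- segs$central[1]:segs$central[2]
  expect_true(all(!prof$competent[central]))
  expect_true(all(prof$competent[-central] |
                  !fam$sim$truth$competent[-central]))
  call <- classify_ectodomain(fam$ann, fam$aln)
  expect_equal(call$verdict, "TD")
})

test_that("a fast-evolving ladder column gets the lowest grade", {
  sim <- simulate_ectodomain("SD", 12, seed = 13, noise = 0)
  L <- nchar(sim$record$sequence)
  rates <- rep(0.02, L)
  hot <- sim$truth$ladder_pos[6]
  rates[hot] <- 8
  aln <- simulate_ortholog_family(sim$record, 20, rates, 1.0, seed = 77)
  ann <- detect_lrr_modules(sim$record$sequence, id = sim$record$id)
  prof <- consensus_ladder_profile(aln, ann)
  expect_equal(which.min(prof$grade), 6L)
})

test_that("spine flags are present in intact modules, absent in planted breaks", {
  fam <- make_family("TD", 15, seed = 21, bl = 0.1)
  spine <- phenylalanine_spine_profile(fam$ann, fam$aln)
  segs <- fam$sim$truth$segments
  central <- segs$central[1]:segs$central[2]
  expect_true(all(!spine$spine[central]))
  expect_true(all(spine$spine[-central]))
  expect_true(isTRUE(attr(spine, "experimental")))

  # direct column checks
  famF <- make_family("SD", 12, seed = 30, rates = NULL, bl = 0)
  spineF <- phenylalanine_spine_profile(famF$ann, famF$aln)
  expect_true(all(spineF$spine))
})

test_that("consensus profiling requires the reference in the alignment", {
  fam <- make_family("SD", 12, seed = 2, bl = 0)
  expect_error(consensus_ladder_profile(fam$aln, fam$ann, ref_id = "nope"),
               "not present")
})
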