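perfect_module <- function() paste0("LAALALAANAL", strrep("A", 13))  # 24-mer

test_that("motif window scoring follows the concave-face template", {
  expect_equal(score_motif_window("LAALALAANAL"), 5.0)
  expect_equal(score_motif_window("AAAAAAAAAAA"), 0.0)
  # I,V,M,F at the hydrophobic positions; Cys holds the ladder
  expect_equal(score_motif_window("IAAVAMAACAF"), 5.0)
  # Thr/Ser at position 9 earn half credit
  expect_equal(score_motif_window("LAALALAATAL"), 4.5)
  expect_equal(score_motif_window("LAALALAADAL"), 4.0)
  expect_error(score_motif_window("LAAL"), "11 residues")
})

test_that("two abutting perfect modules are chained at starts 1 and 25", {
  seq <- strrep(perfect_module(), 2)
  ann <- detect_lrr_modules(seq)
  expect_equal(nrow(ann$modules), 2L)
  expect_equal(ann$modules$start, c(1L, 25L))
  expect_equal(ann$modules$ladder_pos, c(9L, 33L))
  expect_equal(ann$modules$ladder_res, c("N", "N"))
})

test_that("noise-free synthetic ectodomains are recovered exactly", {
  for (seed in 1:20) {
    arch <- c("SD", "TD", "TTD")[1L + seed %% 3L]
    n_mod <- 12L + seed %% 14L
    sim <- simulate_ectodomain(arch, n_mod, seed = seed, noise = 0)
    ann <- detect_lrr_modules(sim$record$sequence, id = sim$record$id)
    expect_equal(nrow(ann$modules), n_mod)
    expect_equal(ann$modules$ladder_pos, sim$truth$ladder_pos)
    expect_equal(ann$modules$ladder_res, sim$truth$ladder_res)
  }
})

test_that("a shuffled sequence yields far fewer modules than structured input", {
  sim <- simulate_ectodomain("SD", 20, seed = 11, noise = 0)
  chars <- strsplit(sim$record$sequence, "")[[1]]
  shuf <- with_seed_helper(42, paste(sample(chars), collapse = ""))
  ann_shuf <- suppressWarnings(detect_lrr_modules(shuf))
  ann_real <- detect_lrr_modules(sim$record$sequence)
  expect_equal(nrow(ann_real$modules), 20L)
  # shuffling the same composition destroys most of the chainable signal
  expect_lt(nrow(ann_shuf$modules), nrow(ann_real$modules) / 1.5)
})

test_that("raising the score threshold never increases the module count", {
  sim <- simulate_ectodomain("TD", 18, seed = 7, noise = 0.05)
  counts <- vapply(c(1, 2, 3, 4, 4.5, 5), function(th) {
    ann <- suppressWarnings(
      detect_lrr_modules(sim$record$sequence, motif_params(min_score = th)))
    nrow(ann$modules)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("DP chaining matches exhaustive enumeration on small inputs", {
  params <- motif_params()
  tested <- 0L
  for (seed in 1:15) {
    seq <- random_scannable_seq(160, seed)
    chars <- strsplit(seq, "")[[1]]
    sc <- ladderlens:::motif_window_scores(chars, params)
    cand <- which(sc >= params$min_score - 1e-9)
    if (length(cand) < 1L || length(cand) > 18L) next
    tested <- tested + 1L
    dp_sel <- ladderlens:::chain_candidates(cand, sc[cand], params$min_len)
    dp_score <- sum(sc[cand][dp_sel])
    bf_score <- brute_force_chain_score(cand, sc[cand], params$min_len)
    expect_equal(dp_score, bf_score, tolerance = 1e-9)
  }
  expect_gte(tested, 5L)
})

test_that("chain ties break toward more modules, then leftmost starts", {
  # chains {1,21} and {5} both score 6: the two-module chain must win
  sel <- ladderlens:::chain_candidates(c(1L, 5L, 21L), c(3, 6, 3), 20L)
  expect_equal(c(1L, 5L, 21L)[sel], c(1L, 21L))
  # chains {1} and {3} tie at one module each: leftmost start wins
  sel2 <- ladderlens:::chain_candidates(c(1L, 3L), c(4, 4), 20L)
  expect_equal(sel2, 1L)
})

test_that("caps are recognized by length and cysteine content", {
  mods <- data.frame(index = 1L, start = 12L, end = 35L, motif_start = 12L,
                     ladder_pos = 20L, ladder_res = "N", score = 5,
                     stringsAsFactors = FALSE)
  seq <- paste0("CPSCSLTHFPG", perfect_module(), "A")
  caps <- delimit_caps(seq, mods)
  expect_equal(caps$lrrnt, c(1L, 11L))
  expect_null(caps$lrrct)

  mods2 <- mods; mods2$start <- 1L; mods2$end <- 24L
  expect_null(delimit_caps(paste0(perfect_module(), "A"), mods2)$lrrnt)

  sim <- simulate_ectodomain("SD", 15, seed = 3, noise = 0,
                             module_len_range = c(24L, 24L))
  ann <- detect_lrr_modules(sim$record$sequence)
  expect_equal(ann$lrrnt, sim$truth$lrrnt)
  expect_equal(ann$lrrct, sim$truth$lrrct)
})

test_that("a sequence with no candidates yields an empty flagged annotation", {
  expect_warning(ann <- detect_lrr_modules(strrep("A", 60)), "no candidate")
  expect_equal(nrow(ann$modules), 0L)
  expect_true(ann$no_modules)
})
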