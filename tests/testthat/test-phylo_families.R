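test_that("protein distances match the closed forms", {
  aln <- multiple_alignment(c("r1", "r2"), c("AAAA", "AAAT"))
  expect_equal(protein_distance(aln, "p", min_overlap = 1)["r1", "r2"], 0.25)
  expect_equal(protein_distance(aln, "poisson", min_overlap = 1)["r1", "r2"],
               -log(0.75))
  aln_id <- multiple_alignment(c("r1", "r2"), c("MKVL", "MKVL"))
  expect_equal(protein_distance(aln_id, "p", min_overlap = 1)["r1", "r2"], 0)
})

test_that("X residues count as mismatches and low overlap errors name the pair", {
  aln <- multiple_alignment(c("r1", "r2"), c("XXXX", "XXXX"))
  expect_equal(protein_distance(aln, "p", min_overlap = 1)["r1", "r2"], 1)
  gappy <- multiple_alignment(c("ga", "gb"), c("AAAA----", "----TTTT"))
  expect_error(protein_distance(gappy, "p", min_overlap = 1), "ga.*gb")
})

test_that("three taxa resolve by the closed three-point formulas", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  expect_equal(sort(tr$edge.length), c(1, 2, 3))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), rownames(d)], d)
})

test_that("NJ recovers additive 4-taxon trees exactly", {
  gen <- read_newick("((a:1,b:2):1,(c:3,d:4):0);")
  D <- ape::cophenetic.phylo(gen)
  tr <- nj_tree(D[letters[1:4], letters[1:4]])
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]],
               D[letters[1:4], letters[1:4]], tolerance = 1e-12)
  # topology: the a|b cherry must exist
  expect_equal(ape::dist.topo(ape::unroot(gen), tr)[1], 0, ignore_attr = TRUE)
})

test_that("NJ is exact on random additive matrices (8 taxa)", {
  for (seed in 1:8) {
    gen <- with_seed_helper(seed, ape::rtree(8))
    labs <- gen$tip.label
    D <- ape::cophenetic.phylo(gen)[labs, labs]
    tr <- nj_tree(D)
    expect_equal(ape::cophenetic.phylo(tr)[labs, labs], D, tolerance = 1e-8)
    expect_equal(ape::dist.topo(ape::unroot(gen), tr)[1], 0, ignore_attr = TRUE)
  }
})

test_that("negative NJ branches are clamped without breaking leaf paths", {
  # a slightly non-additive matrix that produces a negative internal branch
  d <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d["a", "b"] <- d["b", "a"] <- 2
  d["a", "c"] <- d["c", "a"] <- 2
  d["a", "d"] <- d["d", "a"] <- 2.1
  d["b", "c"] <- d["c", "b"] <- 2
  d["b", "d"] <- d["d", "b"] <- 2
  d["c", "d"] <- d["d", "c"] <- 0.1
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("nj_tree validates its input", {
  d <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), NULL))
  expect_error(nj_tree(d), "symmetric")
})

test_that("family labels propagate through clean reference clades", {
  tr <- read_newick("(((A1:1,q1:1):1,A2:1):3,((B1:1,B2:1):1,q2:1):3);")
  refs <- c(A1 = "F1", A2 = "F1", B1 = "F7", B2 = "F7")
  fams <- assign_families(tr, refs)
  expect_equal(fams[["q1"]], "F1")
  expect_equal(fams[["q2"]], "F7")
  expect_equal(fams[["A1"]], "F1")
})

test_that("queries whose smallest reference clade mixes families are unassigned", {
  tr <- read_newick("((q:1,(A1:1,B1:1):1):2,(A2:1,B2:1):2);")
  refs <- c(A1 = "F1", A2 = "F1", B1 = "F7", B2 = "F7")
  fams <- assign_families(tr, refs)
  expect_equal(fams[["q"]], "UNASSIGNED")
})

test_that("assign_families errors when a reference leaf is missing", {
  tr <- read_newick("((a:1,b:1):1,(c:1,d:1):1);")
  expect_error(assign_families(tr, c(a = "F1", z = "F7")), "z")
})

test_that("synthetic families are clustered and labeled accurately", {
  n_fam <- 8L
  n_per <- 6L
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  roots <- with_seed_helper(500, lapply(seq_len(n_fam), function(i) {
    list(id = sprintf("fam%d_ref", i),
         sequence = paste(sample(aas, 120, TRUE), collapse = ""))
  }))
  alns <- lapply(seq_len(n_fam), function(i) {
    simulate_ortholog_family(roots[[i]], n_per, rep(1, 120), 0.15,
                             seed = 600 + i)
  })
  ids <- unlist(lapply(alns, `[[`, "ids"))
  seqs <- unlist(lapply(alns, `[[`, "seqs"))
  aln <- multiple_alignment(ids, seqs)
  d <- protein_distance(aln, "poisson")
  tr <- nj_tree(d)
  refs <- stats::setNames(sprintf("F%d", seq_len(n_fam)),
                          sprintf("fam%d_ref", seq_len(n_fam)))
  fams <- assign_families(tr, refs)
  truth <- rep(sprintf("F%d", seq_len(n_fam)), each = n_per)
  names(truth) <- ids
  queries <- setdiff(ids, names(refs))
  acc <- mean(fams[queries] == truth[queries])
  expect_gte(acc, 0.95)

  # invariance to leaf input order: permute the distance matrix
  perm <- with_seed_helper(7, sample(ids))
  tr2 <- nj_tree(d[perm, perm])
  fams2 <- assign_families(tr2, refs)
  expect_equal(fams2[ids], fams[ids])
})
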