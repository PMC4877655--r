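#!/usr/bin/env Rscript
# Distance-based family clustering: simulates eight TLR-like ortholog
# families from distinct root sequences, builds a neighbor-joining tree on
# Poisson-corrected protein distances, and labels every leaf by its
# reference-anchored clade. Reports assignment accuracy against the
# simulated family memberships.

library(ladderlens)

dir.create("results", showWarnings = FALSE)
n_fam <- 8L
n_per <- 10L
aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

set.seed(900)
roots <- lapply(seq_len(n_fam), function(i) {
  list(id = sprintf("fam%d_ref", i),
       sequence = paste(sample(aas, 150, TRUE), collapse = ""))
})
alns <- lapply(seq_len(n_fam), function(i) {
  simulate_ortholog_family(roots[[i]], n_per, rep(1, 150), 0.2,
                           seed = 910L + i)
})
aln <- multiple_alignment(unlist(lapply(alns, `[[`, "ids")),
                          unlist(lapply(alns, `[[`, "seqs")))

d <- protein_distance(aln, "poisson")
tree <- nj_tree(d)
writeLines(write_newick(tree), "results/family_tree.nwk")

refs <- setNames(sprintf("F%d", seq_len(n_fam)),
                 sprintf("fam%d_ref", seq_len(n_fam)))
fams <- assign_families(tree, refs)
truth <- setNames(rep(sprintf("F%d", seq_len(n_fam)), each = n_per), aln$ids)
out <- data.frame(id = names(fams), assigned = unname(fams),
                  truth = unname(truth[names(fams)]))
write.table(out, "results/family_assignments.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

queries <- setdiff(aln$ids, names(refs))
acc <- mean(fams[queries] == truth[queries])
cat(sprintf("family assignment: %.1f%% of %d query leaves correct; %d unassigned\n",
            100 * acc, length(queries), sum(fams == "UNASSIGNED")))
cat("tree written to results/family_tree.nwk\n")
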