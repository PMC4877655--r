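#!/usr/bin/env Rscript
# Builds the synthetic study inputs used by the downstream analysis scripts:
# an ectodomain cohort spanning the three ladder architectures, an ortholog
# family for consensus profiling, codon loci evolved under three selection
# regimes, and horseshoe CA traces with and without central distortion.
# Everything is seed-deterministic; ground truth is saved alongside.

library(ladderlens)

data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

## ectodomain cohort: 30 per architecture, realistic module counts, 5% noise
set <- expand.grid(arch = c("SD", "TD", "TTD"), rep = 1:30,
                   stringsAsFactors = FALSE)
sims <- lapply(seq_len(nrow(set)), function(i) {
  simulate_ectodomain(set$arch[i], 12L + (i * 5L) %% 14L, seed = 100L + i)
})
recs <- data.frame(id = vapply(sims, function(s) s$record$id, character(1)),
                   sequence = vapply(sims, function(s) s$record$sequence,
                                     character(1)))
write_fasta(recs, file.path(data_dir, "ecto_cohort.fasta"))
truth <- data.frame(
  id = recs$id,
  architecture = vapply(sims, function(s) s$truth$architecture, character(1)),
  n_modules = vapply(sims, function(s) s$truth$n_modules, integer(1)))
write.table(truth, file.path(data_dir, "ecto_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

## ortholog family of one TD ectodomain (for the ladder profile table)
ref <- simulate_ectodomain("TD", 19, seed = 400L, noise = 0)
fam <- simulate_ortholog_family(ref$record, 25,
                                rep(0.25, nchar(ref$record$sequence)),
                                0.4, seed = 401L)
write_fasta(data.frame(id = fam$ids, sequence = fam$seqs),
            file.path(data_dir, "td_family.fasta"))
write_fasta(data.frame(id = ref$record$id, sequence = ref$record$sequence),
            file.path(data_dir, "td_reference.fasta"))

## codon loci: three selection regimes, ten sequences each
for (w in c(0.2, 0.5, 1.0)) {
  cds <- simulate_codon_alignment(10, 300, w, 0.3, seed = 500L + round(10 * w))
  write_fasta(cds$records,
              file.path(data_dir, sprintf("locus_omega%02d.fasta", round(10 * w))))
}

## CA traces: five intact and five centrally distorted horseshoes
for (s in 1:5) {
  write_ca_trace(simulate_horseshoe(21, FALSE, noise_sd = 0.5, seed = 600L + s),
                 file.path(data_dir, sprintf("sd_%d.pdb", s)))
  write_ca_trace(simulate_horseshoe(21, TRUE, noise_sd = 0.5, seed = 700L + s),
                 file.path(data_dir, sprintf("td_%d.pdb", s)))
}

cat("wrote synthetic cohort to", data_dir, "\n")
cat("ectodomains:", nrow(recs), "| family rows:", length(fam$ids),
    "| codon loci: 3 | traces: 10\n")
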