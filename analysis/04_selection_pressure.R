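#!/usr/bin/env Rscript
# Per-locus selective pressure: estimates mean dN/dS with codon-bootstrap
# 95% confidence intervals for the three simulated loci (true omega 0.2,
# 0.5 and 1.0), mirroring a purifying-to-neutral gradient across loci.
# Run analysis/01_simulate_cohort.R first.

library(ladderlens)

data_dir <- "results/data"
loci <- data.frame(label = c("locus_w0.2", "locus_w0.5", "locus_w1.0"),
                   file = sprintf("locus_omega%02d.fasta", c(2, 5, 10)),
                   truth = c(0.2, 0.5, 1.0))

rows <- lapply(seq_len(nrow(loci)), function(i) {
  recs <- read_fasta(file.path(data_dir, loci$file[i]), "nucleotide")
  s <- locus_mean_dnds(recs, n_boot = 1000, seed = 70L + i,
                       label = loci$label[i])
  print(s)
  data.frame(locus = s$label, true_omega = loci$truth[i],
             mean_omega = s$mean_omega, ci_low = s$ci_low,
             ci_high = s$ci_high, n_seq = s$n_seq, n_pairs = s$n_pairs)
})
out <- do.call(rbind, rows)
write.table(out, "results/dnds_by_locus.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("\nestimates order with the truth: %s\n",
            ifelse(all(diff(out$mean_omega) > 0), "yes", "no")))
cat("omega < 1 throughout the purifying loci:",
    all(out$ci_high[out$true_omega < 1] < 1), "\n")
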