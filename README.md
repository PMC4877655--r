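# ladderlens

Classification of vertebrate Toll-like receptor (TLR) ectodomain
architectures from the asparagine ladder of their leucine-rich repeat (LRR)
modules, with the supporting quantitative analyses: conservation grading of
ladder positions, distance-based family clustering, per-locus dN/dS under
purifying selection, and TM-score structural comparison of ectodomain
shapes.

## The science

TLR ectodomains are horseshoe-shaped solenoids of 12–25 LRR modules. The
concave face of a canonical 24-residue module carries the consensus
`LxxLxLxxN/CxL`; the asparagines at motif position 9 of consecutive modules
hydrogen-bond into a continuous "asparagine ladder" that stabilizes the
horseshoe. Where the ladder residue is substituted, only hydrogen-bond
donors (Thr, Ser, Cys) can stand in for Asn. The pattern of competent and
incompetent ladder positions along the module stack separates ectodomains
into three architectures:

- **SD** (single-domain): ladder intact throughout;
- **TD** (three-domain): ladder broken in the central subdomain;
- **TTD** (trans-three-domain): ladder broken in both terminal subdomains,
  intact centrally.

`ladderlens` detects LRR modules by scoring 11-residue windows against the
concave-face pattern (hydrophobic positions 1/4/6/11, hydrogen-donor
position 9) and chaining non-overlapping candidate anchors by dynamic
programming; splits the stack into terciles; and calls a segment *broken*
when it holds an incompetent run of length ≥ 2 or an incompetent fraction
≥ 0.4. Around this core it provides:

- **Conservation grading** — per alignment column, grade
  `1 + floor(8 * (1 − H))` where `H` is Shannon entropy in log base 20;
  grade 1 = most variable, 9 = most conserved.
- **Family clustering** — Poisson-corrected protein distances
  (`−ln(1 − p)`), Saitou–Nei neighbor joining, and reference-anchored clade
  labeling under midpoint rooting.
- **Selection** — Nei–Gojobori (1986) pathway counting with Jukes–Cantor
  correction, `ω = dN/dS`, and percentile 95% CIs from a codon-column
  bootstrap.
- **Structure** — Kabsch superposition and dual-normalized TM-scores
  (`d0(L) = 1.24 (L−15)^{1/3} − 1.8` Å, floored at 0.5 Å) from a
  sequence-seeded, iteratively refined correspondence.
- **Synthetic data** — seed-deterministic generators for ladder-architected
  ectodomains, star-tree ortholog families, codon alignments with known ω,
  and horseshoe CA traces, each carrying its ground truth.

## Worked example

```r
library(ladderlens)

sim <- simulate_ectodomain("TD", n_modules = 21, seed = 3, noise = 0)
ann <- detect_lrr_modules(sim$record$sequence, id = sim$record$id)
ann
#> ecto_annotation 'TD_m21_s3': 21 LRR modules +LRRNT +LRRCT
classify_ectodomain(ann)
#> architecture: TD | broken segments: central

p <- simulate_codon_pair(300, omega = 0.2, t = 0.3, seed = 5)
pairwise_dnds(p$a, p$b)
#> dN/dS: dN=0.0569 dS=0.2831 omega=0.2010 (N=675.2 S=224.8, 300 codons)

A <- simulate_horseshoe(21, central_distortion = FALSE, noise_sd = 0.5, seed = 1)
B <- simulate_horseshoe(21, central_distortion = TRUE,  noise_sd = 0.5, seed = 3)
align_structures(A, B)$comparison$tm_avg
#> [1] 0.7916997   # below the ~0.97 of two intact horseshoes
```

The detected modules sit exactly on the generator's planted anchors; the TD
verdict comes from the central tercile's incompetent ladder residues; the
dN/dS estimate recovers the simulated ω = 0.2; and the central distortion
lowers the TM-score relative to intact-vs-intact comparisons while staying
above the 0.5 same-fold threshold.

## The analysis workflow

Numbered drivers under `analysis/` regenerate the study end to end
(`01_simulate_cohort.R` → `05_structure_similarity.R`), writing tables
under `results/`: architecture calls and recovery rates, the per-module
ladder-profile table (modal residue, frequency, competence, grade), the
family tree and assignments, per-locus mean ω with 95% CIs, and the
per-class-pair TM-score summary.

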