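---
title: "Asparagine-ladder architecture of TLR ectodomains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asparagine-ladder architecture of TLR ectodomains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ladderlens)
```

## The model

Toll-like receptor ectodomains are solenoids of leucine-rich repeat (LRR)
modules. The concave face of a canonical 24-residue module follows
`LxxLxLxxN/CxL`: hydrophobic residues at positions 1, 4, 6 and 11 pack the
core, and position 9 — the *ladder position* — donates a hydrogen bond to
the backbone of the neighboring module. Stacked over consecutive modules
these bonds form the asparagine ladder that holds the horseshoe's shape.
Asn dominates the ladder position; Thr, Ser and Cys can substitute because
they too donate hydrogens, so the *competent* set here is `{N, T, S, C}`
(Gln is excluded: it is not part of the donor set this package models).

The along-stack pattern of competent and incompetent ladder positions
defines three architectures: **SD** (intact ladder), **TD** (central
subdomain broken), and **TTD** (both terminal subdomains broken, central
intact). `ladderlens` operationalizes this qualitative description:

1. **Module detection.** Every 11-residue window is scored with unit
   weights at the five constrained positions: hydrophobic (`L/I/V/F/M`)
   matches at 1/4/6/11 earn 1 each; position 9 earns 1 for `N`/`C` and
   0.5 for `T`/`S` (weaker but real donors). Windows scoring at least 3 of
   the maximal 5 become candidate anchors, and the maximum-total-score
   chain of anchors spaced at least 20 residues apart is selected by
   dynamic programming (ties: more modules, then leftmost — determinism
   matters for reproducible tables). Module spans run from anchor to
   anchor, truncated at 30 residues; longer inter-anchor stretches are
   reported as unassigned inserts, which is how the irregular central
   modules of TD ectodomains are represented. The ladder residue is
   *recorded*, not required, at position 9 — requiring Asn would make
   broken ladders undetectable by construction.
2. **Segmentation.** The stack is split into terciles by module ordinal,
   remainder to the center. The three-subdomain decomposition has no
   published numeric boundaries; terciles are the symmetric default and
   are exposed should better boundaries become available.
3. **Break rule.** A segment is broken iff its longest run of incompetent
   ladder positions is ≥ 2 or its incompetent fraction is ≥ 0.4. A single
   substituted module does not break a segment (isolated substitutions
   occur in intact ladders); two adjacent ones interrupt the
   hydrogen-bond chain materially. Both thresholds are arguments.
4. **Verdict.** SD iff no segment broken; TD iff only the central is; TTD
   iff only the two terminals are; anything else is AMBIGUOUS with
   per-segment diagnostics rather than a forced call.

When an ortholog alignment is available, classification uses the *modal*
ladder residue per module across the family (the consensus display), not
the reference sequence alone; single-sequence classification is the
fallback.

## Conservation grading

Ladder-position conservation is reported on an ordinal nine-grade scale:
per alignment column, `grade = 1 + floor(8 * (1 − H))` with `H` the Shannon
entropy of residue frequencies in log base 20, capped at 9. An invariant
column grades 9; a uniformly variable one grades 1. This is an
entropy-based stand-in for rate-based empirical-Bayes conservation scoring:
it needs no tree or substitution model, but the grades are comparable only
ordinally, between columns of the same alignment — not across alignments
of different depth or divergence.

## Family clustering

Families are recovered with neighbor joining on Poisson-corrected protein
distances (`−ln(1 − p)`, capped at 10 when `p` saturates), with negative
branch lengths clamped to zero and the deficit moved to the sister branch.
NJ is exact on additive distances, which is what the acceptance checks
exercise; it replaces maximum-likelihood inference deliberately, because
the artifact needs coarse, reproducible family clustering rather than a
publication-grade phylogeny. Clade labeling midpoint-roots the tree and
gives each query leaf the family of the smallest clade containing it and
references of exactly one family; mixed clades yield UNASSIGNED. Pairs
overlapping in fewer than 30 non-gap columns are an error rather than a
guess.

## Selection (dN/dS)

Pairwise ω uses Nei–Gojobori (1986) counting: per codon, synonymous site
fractions over the non-stop single-nucleotide changes; per differing codon
pair, substitution counts averaged over all minimal mutational pathways
that avoid stops, equally weighted (if every pathway is blocked — a corner
of the code table — all pathways are used). Proportions are Jukes–Cantor
corrected, `dN = −(3/4)ln(1 − (4/3)pN)`; ω is undefined when `dS = 0` or a
proportion reaches 3/4, and such pairs are dropped, not imputed. A locus
summary is the mean ω over defined pairs with a percentile 95% CI from
resampling codon columns (default 1000 replicates), the natural exchangeable
unit of a codon alignment.

Two properties matter for interpretation. First, NG86's equal pathway
weighting is known to bias ω slightly upward under purifying selection at
moderate divergence (true evolution prefers synonymous pathways); at
ω = 0.2, t = 0.3 the package's own acceptance run measures a mean estimate
near 0.21. Second, the codon bootstrap captures sampling variance, not
estimator bias, so CI coverage of the true ω sits near — and sometimes
just below — the nominal level under these conditions. Estimates are
comparable in rank across loci, which is what the locus-level contrast
needs; they are not digit-level reproductions of any particular server's
output.

## Structural comparison

CA traces are superposed by Kabsch's SVD solution with reflections
excluded, and scored with the TM-score,
`TM = (1/L) Σ 1/(1 + (d_i/d0(L))²)`, `d0(L) = 1.24 (L−15)^{1/3} − 1.8` Å
floored at 0.5 Å, reported under both length normalizations plus their
average. Alignment is a simplified TM-align-style loop: a global alignment
of residue letters seeds the correspondence (match +1 / mismatch 0 /
gap −1); then superposition (iterative close-pair refitting) and
correspondence rebuilding (dynamic programming on the proximity score with
gap penalty −0.6) alternate until the score changes by < 1e-4 or 20
rounds, keeping the best state seen. The full multi-seeded TM-align search
is intentionally not reproduced: on real structure pairs scores may differ
by a few hundredths, and the reproduction surface is the coarse contrast —
within-architecture similarity exceeding between-architecture similarity,
and ectodomain pairs staying above the 0.5 same-fold threshold.

## What the generators emulate

Every generator is seed-deterministic and returns its ground truth.

- `simulate_ectodomain()` plants caps (two cysteines each, lengths 12–16),
  12–25 modules of 22–26 residues built from the concave template, and a
  ladder pattern per architecture; a noise parameter (default 0.05) flips
  each module's competence outside the planted breaks, emulating the
  sporadic substitutions seen in real ladders. Background (`x`) positions
  draw from the fifteen non-`{L,I,V,F,M}` residues. That choice makes the
  motif anchors the *only* hydrophobic-patterned windows, so module
  boundaries are identifiable and recovery can honestly be scored at 100%
  on clean data. Real sequences have hydrophobics everywhere; passing the
  recovery tests therefore demonstrates correctness of the scanner and
  chain logic, not performance on natural sequence backgrounds, where
  boundary calls near the termini can be off by a module.
- `simulate_ortholog_family()` evolves descendants on a star tree with
  per-column rates (substitution probability `1 − exp(−rate · t)`,
  replacements uniform over the 20 residues) and returns the root as the
  first row so consensus profiling has its reference. A star tree is
  sufficient for consensus and conservation-grade checks; it does not
  emulate phylogenetic correlation between orthologs.
- `simulate_codon_alignment()` runs a minimal MG94-flavored continuous-time
  codon process (single-nucleotide exchanges; `kappa` scales transitions,
  `omega` nonsynonymous changes; stops excluded; rates normalized to one
  expected substitution per codon per unit time) on a star tree with
  branch length `t/2`, so any pair diverges by `t`. The default
  `kappa = 1` matches the equal-rate assumption of the NG86 estimator the
  simulations are designed to validate; with realistic transition bias
  (`kappa` ≈ 2–4) NG86 is known to underestimate ω, and `kappa` is exposed
  for exactly that kind of sensitivity check.
- `simulate_horseshoe()` winds one CA per residue around a circular-arc
  solenoid (arc radius 30 Å, coil radius 10 Å, 24-residue winding period,
  270° total sweep, fixed 24-residue modules so same-`n_modules` traces are
  directly comparable); the TD-like variant pulls the central tercile to
  0.72× radius and bends it up to 9 Å out of plane. The geometry is a
  caricature — real solenoids twist and their modules tilt — but it
  reproduces the two properties the comparisons need: high within-class
  TM-scores at Å-level noise, and a central-distortion signal that lowers
  between-class scores without changing the fold.

## Numerical choices and degenerate inputs

- Sequence indices are 1-based with closed intervals; `X` counts as a
  mismatch everywhere (including against `X`); the gap character is `-`
  only.
- Chain-score ties: more modules, then leftmost anchors. Modal-residue
  ties: alphabetical. NJ joining ties: as resolved by the underlying
  implementation, fixed given the label order of the input matrix.
- TM normalization lengths ≤ 15 fall back to the 0.5 Å `d0` floor with a
  warning; Kabsch refuses fewer than 3 points and collinear inputs.
- Alignment columns that are all-gap outside the reference report the
  reference residue at frequency 1 over a single sequence, with a missing
  grade; conservation grades need at least two non-gap residues.
- Fewer than five sequences at a locus is a warning (unstable means), not
  an error; no defined ω at all is an error.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so a
full pass stays within a couple of minutes on one core: 300 noisy plus 90
clean ectodomains for classifier recovery; 50 random sequences for the
chaining oracle; the full 61-codon and 61×61-pair tables for the NG86
oracle; 100 seeds × three ω values (10 sequences × 300 codons, t = 0.3)
for ordering and CI coverage; all 4- and 5-taxon topologies plus 20 random
8-taxon trees for NJ exactness; and 10 trace pairs per class contrast.

## Known limitations

- Ectodomain boundaries are taken as given (whole input sequences are
  scanned); signal-peptide and transmembrane prediction are out of scope.
- The scanner's boundary placement at the C-terminal module uses the
  canonical 24-residue closure, so the last module's end can differ by a
  couple of residues from a curated delimitation.
- Conservation grades are ordinal stand-ins, not calibrated rates.
- NJ family labels depend on reference exemplar choice; distance-based
  clustering cannot adjudicate fine topology questions (e.g. whether a
  family splits at its root) the way likelihood methods can.
- NG86/bootstrap gives rank-comparable ω with honest but approximate
  intervals, as discussed above.
- The codon simulator and horseshoe generator are validation instruments,
  not models of TLR evolution or structure.
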