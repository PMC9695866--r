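---
title: "In silico COI screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico COI screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cixscreen)
```

## The problem

*Pentastiridius leporinus* is the main planthopper vector of the syndrome
"basses richesses" (SBR) in sugar beet. Field monitoring is complicated by
two morphologically similar cixiids, *Reptalus quinquecostatus* and
*Hyalesthes obsoletus*, and species-level keys exist only for male adults.
A species-specific PCR on the mitochondrial COI barcode solves this: a
primer pair that matches the target's COI perfectly but carries 3'-terminal
mismatches against every confounder amplifies a diagnostic 341 bp fragment
from the target only. `cixscreen` implements the *in silico* half of that
assay — degenerate-primer mismatch profiling, amplification prediction,
discriminative primer search — together with the distance/neighbor-joining
phylogeny used to show that the short fragment separates the genera, and a
seeded simulator so every stage can be exercised without database access.

## Primer matching and the extension rule

Matching is purely combinatorial. Primers and templates are IUPAC strings;
a primer position matches a template position when their base sets
intersect (`bases_compatible()`), so `R` pairs with `A` or `G` and `N`
pairs with everything. `find_best_binding_site()` scans every window of the
requested strand and returns the one minimizing the mismatch count, with
ties broken towards the smallest plus-strand start; mismatch positions are
reported as 0-based offsets from the primer's 3' terminus because extension
blocking is a 3'-end phenomenon. Degenerate *template* codes count as a
match when compatible (optimistic); `pessimistic = TRUE` instead requires
the template set to be contained in the primer set, which is the right
reading when an `N` in a database record should not be trusted to pair.

Whether a site supports amplification is decided by `extension_rule()`:

* `clamp_length = 2` — the two 3'-terminal positions must be mismatch-free;
* `max_total_mismatches = 4` — the mismatch budget over the whole footprint.

These defaults are calibrated on the assay's observed behaviour, which the
matching module must reproduce simultaneously: the universal primers Ron
and Calvin bind all three cixiids with at most one (non-terminal) mismatch
and amplify them all; UEA8 has three mismatches against the target
including one at the next-to-last 3' base and never amplifies it; the
species-specific pair meets 1–4 forward and 3–9 reverse mismatches on the
confounders, always including the 3' end, and never amplifies them. A
clamp of 2 with a budget of 4 is the simplest rule consistent with all
three observations — note the forward-primer totals (1–4) force the clamp,
not the budget, to carry the specificity. There is deliberately no
thermodynamic model (no Tm or ΔG): the assay's published argument is
mismatch-position-based, and a combinatorial rule keeps the prediction
deterministic and auditable. Both parameters are configurable everywhere.

`simulate_pcr()` combines forward sites (plus strand) and reverse sites
(minus strand) in productive orientation — forward footprint strictly
upstream — and reports products up to `max_product` (default 3000 bp, a
generous bound for COI work). Product length is counted outer edge to
outer edge, inclusive of both primer footprints; under this convention the
specific pair yields its published 341 bp product. A template cell in a
`specificity_matrix()` is "amplified" when *any* productive combination
passes the rule.

## Discriminative primer search

`enumerate_discriminative_primers()` reproduces the design criterion behind
the specific pair: candidate primers are windows of the target-alignment
consensus (strict per-column majority, `N` on ties) that match every target
row exactly; reverse candidates are reverse complements of such windows.
Against every non-target — evaluated by best-site search over both strands
of the full sequence, because distant non-targets need not be alignable —
the *pair* must show at least `min_nontarget_mismatches` in total and
`min_clamp_mismatches` inside the 3' clamp. The pair-level reading (rather
than per primer) is deliberate: a single diagnostic column covered by one
primer's clamp is already assay-discriminating, and it makes the search's
behaviour on minimal test cases exact. Pairs are ranked by the worst case
over non-targets of combined clamp mismatches, then combined totals, then
coordinates for determinism. Defaults (primer length 18–32 nt, product
150–1200 bp, non-degenerate candidates, no GC/Tm filter) span the published
pair — a 20 nt forward, a 31 nt reverse, 341 bp product — and reflect that
the original design reported no composition filters; optional GC bounds are
available behind `gc_range`.

## Distances, trees, supports

Distances are computed on pre-aligned input (alignment construction is out
of scope; any aligner's FASTA output is accepted) with **pairwise
deletion**: for each pair, only columns where both rows carry an
unambiguous A/C/G/T are retained.

The headline method, `mcl_distance_matrix()`, is a maximum composite
likelihood distance in the Tamura–Nei form: base frequencies are pooled
over the whole alignment; the purine and pyrimidine
transition/transversion rate ratios are estimated **once** for the
alignment by maximizing the sum of pairwise multinomial log-likelihoods
(each pair profiled over its own divergence); each pair's distance is then
the 1-D composite-ML divergence estimate under those shared rates. The
p-distance and Jukes–Cantor fallbacks (`distance_matrix(method =)`) are
provided as the equal-rate reference; on equal-rate simulations MCL and JC
agree within Monte-Carlo error, and MCL never falls below the p-distance.
Numerical edge cases are handled loudly: compositions with a missing base
get a unit pseudocount; pairs whose divergence estimate runs into the
optimizer bound (saturation, where the moment inversion would take the log
of a non-positive number) are flagged in the `saturated` matrix and set to
the largest finite distance so neighbor joining stays runnable; an
all-saturated matrix is an error, not a guess.

`neighbor_joining()` is the standard Saitou–Nei agglomeration, exact on
additive matrices. Negative branch estimates are clamped to zero with the
deficit moved to the sibling branch created at the same join, preserving
path lengths — common practice where the source analysis is silent.
`bootstrap_supports()` resamples alignment columns with replacement
(default 1000 replicates, the conventional choice), rebuilds distances and
the NJ tree per replicate, and annotates each internal edge of the
full-data tree with the percentage of replicates containing its
bipartition — supports are against the full-data tree, not a majority-rule
consensus. The whole-alignment rate ratios are reused across replicates:
they are global properties of the data, re-estimating them per replicate
changes supports negligibly and costs roughly thirtyfold more. Replicates
in which some pair retains no columns are dropped, warned about, and
excluded from the denominator. A single integer seed drives one sampling
stream, so supports are byte-reproducible. `root_with_outgroup()` places
the root on the edge separating a monophyletic outgroup; a
non-monophyletic outgroup is an error naming the smallest containing
clade.

Printed barcoding distances for short fragments are conventionally on a
per-100-sites scale (an intraspecific "0.6" means 0.006 substitutions per
site). Because the two scales are easily confused, the pipeline writes the
distance matrix **both** raw and ×100 rather than guessing a reader's
intent.

## What the simulator states, and what a green test establishes

`simulate_family()` evolves a random root along a species tree and then
radiates specimens within species, under Jukes–Cantor (default) or Kimura
two-parameter substitution with closed-form per-branch transition
probabilities; no indels, no rate heterogeneity across sites, no codon
structure. Defaults state the world the assay assumes: 3 species × 4
specimens, 341 nt (the specific amplicon scale; use ~1000 for the
universal-primer scale), intraspecific divergence 0.006 and interspecific
0.051 substitutions per site — the published 0.6 vs 5.1 per 100 sites.
Species branches are scaled net of the within-species radiation so a
heterospecific pair diverges by exactly `inter` in expectation. The
"symmetric" species tree is a star (every interspecific pair at the same
expected divergence, which is what a single stated interspecific value
means); a caterpillar shape is available for NJ stress tests.

`implant_primer_sites()` builds templates whose binding sites carry an
exactly specified mismatch geometry, choosing planted mismatch bases
incompatible with the primer code at that position, and *verifies its own
construction* by re-running the search — a returned fixture is recovered
by definition or the constructor errors.

`synthetic_cixiid_panel()` and `synthetic_barcode_set()` are deterministic
stand-ins for the field/database material: the panel realizes the assay's
published mismatch geometry on three COI-like templates, and the barcode
set realizes the published distance structure (0, 2 and 17 substitutions
on 341 sites ≈ 0.0, 0.6 and 5.1 per 100, plus confounder-genus clades and
a distant outgroup pair). Substitution counts on 341 sites are discrete —
one substitution is ~0.3 per 100 sites — so the stand-ins use the counts
nearest the published values and tests assert agreement to one
substitution step. A green test therefore establishes that the *machinery*
reproduces the published reasoning on sequences that satisfy its premises;
it does not establish anything about real field specimens, primer
thermodynamics, or template quality — the considerations the wet-lab half
of the assay covers.

## Pipeline and reproducibility

`run_specificity()` and `run_phylogeny()` orchestrate the two analyses
from a single `run_config()`: mismatch table (TSV), specificity matrix
(CSV), amplicon FASTA, distance CSVs (raw and ×100), Newick tree with
integer supports, a barcoding-gap summary (species inferred from tip-label
prefixes up to the first underscore, overridable by relabelling), and a
JSON manifest recording the seed, rule, primer sequences and input
checksums — enough to reproduce a run byte-for-byte. `run_specificity()`
returns status 2 when the specific pair is predicted to amplify any
non-target, so the screen can gate a CI-style workflow; a thin command
line wrapper with `specificity`, `phylogeny`, `design` and `simulate`
subcommands ships in `inst/cli/cixscreen.R`.

## Known limitations

* Ungapped binding sites only; indel-containing sites are out of scope.
* No primer-dimer/hairpin screening and no annealing thermodynamics.
* The extension rule is a hard threshold; real polymerases are graded.
* The simulator's JC/K2P world has uniform stationary frequencies and
  site-homogeneous rates; empirical COI composition bias is emulated only
  through the frequency pooling on real input, not in simulation.
* Alignment construction is delegated to external tools.
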