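---
title: "Graph-degree molecular complexity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-degree molecular complexity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molcomplex)
```

## The model

Both scores in this package are functions of the *molecular graph*: the
heavy-atom skeleton with every bond treated as single and every atom as
carbon. Under this reduction the only information a molecule retains is the
heavy-neighbour count (degree) of each atom, and the central quantity is
the partition of atoms into *divalent* nodes (exactly two heavy
neighbours — CH₂, ether O, chain NH) and *non-divalent* nodes (chain ends,
branch points, ring-fusion atoms).

**MC1** is the fraction of non-divalent nodes, `1 − FDV`. It is
size-independent: a branching point signals synthetic work (an extra bond
to form, possible protecting groups, possible stereocentres, steric
hindrance near the branch), whereas a divalent node merely extends a chain
or a ring, which rarely adds such work. Because degree ignores element and
bond order, MC1 is invariant under the hydrocarbon reduction by
construction; `hydrocarbon_reduction()` exists so tests can assert this
rather than assume it.

**MC2** is the *count* of non-divalent nodes, with one chemistry-aware
correction: the carbonyl carbon and its double-bonded oxygen are not
counted when the carbon also carries a single-bonded nitrogen or oxygen —
i.e. in acids, esters, amides, carbonates, carbamates and ureas, the
carboxyl derivatives whose formation is routine. The matching rule is
deliberately minimal and is published as a SMARTS-equivalent string
(`mc2_exclusion_pattern()`): a real carbon with at least one double bond to
oxygen and at least one single-bonded N or O neighbour; the carbon and its
(lowest-index) double-bonded oxygen are excluded, each matched carbon only
once, however many X neighbours it has. Sulfur and phosphorus analogues
never match, so thioesters, thiones, sulfonamides, amidines and guanidines
are counted in full.

Two readings of the exclusion were possible; this package excludes *only*
the C=O pair and lets the X atom stand on its own degree. The ester oxygen
and amide nitrogen are divalent and would never be counted anyway; the one
observable consequence is that a carboxylic acid's hydroxyl oxygen
(monovalent) still counts toward MC2. The carboxylate anion is treated
exactly like the acid, since the graph view is charge-insensitive.

## Polymer repeat units

A repeat unit is written with two dummy-atom attachment points, e.g.
`[*]CC(C)[*]` for polypropylene. An attachment contributes +1 to the degree
of its neighbour but is excluded from the heavy-atom count and from the
divalent/non-divalent partition. This convention is not a guess: for every
repeat unit shipped in the tests, the degree multiset of a *central* unit
inside a 3-mer built by `oligomerize()` equals the attachment-mode degree
multiset of the lone unit (`unit_degree_multiset()` makes this a one-line
assertion). Hydrogen-capping the unit instead would get chain-end degrees
wrong — the oligomer ends are intentionally hydrogen-capped so that end
units differ from interior units, which is exactly the distinction the
convention has to capture.

MC1 of a repeat unit describes the unit, not the material: cross-linkers
are not considered, and both MC1 and MC2 are explicitly uninformative for
polymers as molecules. The anhydroglucose unit of cellulose illustrates
why worked examples need an exact structure convention: the in-chain and
hydrogen-capped representations give the same rounded MC1 here (0.73), and
neither matches some published per-polymer values whose repeat-unit
drawing is not available; such cases are scored but not used as reference
values.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `fragment_policy` | `"largest"` | Salt/mixture handling: keep the component with the most heavy atoms (ties: lexicographically first canonical SMILES); `"whole"` and `"error_on_multi"` are available. The measures themselves are silent on salts; largest-fragment is the common batch default. |
| `fail` / `fail_policy` | `"skip"` | A molecule that cannot be parsed becomes a `status = "skip"` row with the reason; `"abort"` stops the run. |
| `decimals` | 2 | Display rounding of FDV/MC1 at write time only; internal values stay full-precision, and `mc1 = 1 - fdv` holds exactly before rounding. |
| `min_hac_warn` | 0 (off) | Annotates records below a heavy-atom threshold, since MC1 is uninformative for very small molecules (methane scores MC1 = 1, MC2 = 1, as-is). |
| `min_pairs` | 3 | Minimum pairwise-complete observations per correlation cell; below it the cell is an explicit `NA`. |

## Numerical and degenerate-input choices

- Degrees are neighbour counts, never bond-order sums: a carbonyl oxygen is
  monovalent, an allene centre divalent.
- Hydrogens (including explicit `[H]` and isotopes) are removed at
  ingestion; a structure with no heavy atoms left is an error, not a
  silent zero.
- SMILES input is kekulized once at parse time, so the exclusion rule sees
  explicit C=O bonds (lactams written aromatically still match) and never
  depends on how the input was kekulized; aromatic ring oxygens never
  match. SDF (V2000) input is read verbatim; aromatic bond order 4 is not
  a double bond.
- Constant score columns yield an undefined correlation marker (`NA`), not
  0 or 1, including on the matrix diagonal.
- Quantiles in `distribution_summary()` are type-7 (R's default), so
  summaries are deterministic and comparable across runs.
- Fixture generators save and restore the caller's RNG state; the same
  `(kind, n, seed)` always returns the identical structure.

## What the synthetic fixtures do and do not show

The generator produces chains, cycles, stars, uniform random recursive
trees, heteroatom/double-bond "decorated" trees (valence-safe so they can
round-trip through SMILES), and oligomers. Chains, cycles and stars carry
closed-form expected scores (chain of n: MC1 = 2/n, MC2 = 2; cycle: 0 and
0; star of n ≥ 4: MC1 = 1, MC2 = n — a 3-star is a 3-chain and is reported
as such). These fixtures exercise the counting machinery exhaustively, but
they do not emulate drug-like chemistry: no realistic ring-system,
functional-group or size distributions. Passing fixture tests therefore
validates the *graph arithmetic* and the exclusion rule, not any claim
about how the measures distribute over real compound collections; the
desk-scale comparison harness makes no attempt to reproduce
database-scale correlation values, which require the source databases.

Problem sizes used by the test suite — structures up to 50 nodes for the
closed forms, a few hundred random graphs of at most 12 nodes for oracle
equivalence, 3-mers for the polymer convention — were chosen because the
properties under test are size-independent, so small instances already
carry the full evidential weight.

## Implementation notes

Structure ingestion is delegated to OpenBabel through
ChemmineOB/ChemmineR; everything downstream of the SDF atom/bond blocks —
degree profiling, the exclusion matcher, the polymer convention, the
fixture generators and the comparison harness — is implemented in this
package and cross-checked in the tests against an independent brute-force
adjacency-matrix oracle that shares no code with the pipeline. Pearson
correlations call `stats::cor` with pairwise-complete observations; the
test oracle recomputes them from the covariance formula.

## Known limitations

- Stereochemistry, tautomers and charge normalization are out of scope;
  input structures are scored as drawn (after kekulization).
- The exclusion list is fixed to X–C=O with X = N or O; it is published as
  a pattern string for audit but not user-extensible rule-by-rule.
- Scores do not consider starting-material availability; two molecules of
  equal graph complexity can differ greatly in practical accessibility.
- OpenBabel's parse diagnostics go to the process stderr; the package's
  error conditions carry the offending input text rather than a character
  position.
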