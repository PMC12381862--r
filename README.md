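# molcomplex

Graph-degree molecular complexity scores for chemists and cheminformaticians
who need a fast, transparent, size-aware estimate of how hard a molecule is
to make — without any machine-learned model, reaction database, or
starting-material lookup.

## The measures

Both scores are computed on the **molecular graph**: the heavy-atom skeleton
of a molecule with every bond treated as single and every atom as carbon, so
that only connectivity (the heavy-neighbour count of each atom) matters.

- **MC1 = 1 − FDV**, where FDV is the fraction of divalent nodes (atoms
  with exactly two heavy neighbours: CH₂, ether O, chain NH, ...). MC1 is
  size-independent and rises with every branching point, because a new
  tri- or tetravalent node typically means an extra synthesis step, possible
  protecting groups, steric hindrance, or a new stereocentre. Adding
  divalent nodes merely extends a chain or ring and leaves MC1 lower.
- **MC2 = NDV**, the *number* of non-divalent nodes, not counting the C=O
  carbon and its double-bonded oxygen in X–C=O groups with X = N or O
  (acids, esters, amides, carbonates, carbamates, ureas) — the carboxyl
  derivatives whose formation is synthetically routine. Sulfur and
  phosphorus analogues (thioesters, thiones, sulfonamides, amidines,
  guanidines, ...) are counted normally. MC2 grows with size, but only if
  branching grows: fatty acids stay simple, polycyclic alkaloids do not.

Polymer repeat units are scored with dummy-atom attachment points
(`[*]CC(C)[*]` for polypropylene): an attachment adds one neighbour to the
atom it is bonded to but is itself excluded from the heavy-atom count, which
reproduces the degrees an interior unit has inside the chain.

Caveats built into the measures: MC1 is uninformative for very small
molecules (trifluoroacetic acid and *tert*-butanol both score the maximum
MC1 = 1) and for polymers; MC2 is uninformative for polymers.

## Worked example

```r
library(molcomplex)

tibble::tibble(
  name   = c("paracetamol", "hexane", "polypropylene unit"),
  smiles = c("CC(=O)Nc1ccc(O)cc1", "CCCCCC", "[*]CC(C)[*]")
) |>
  mc_score(id_col = "name")
```

```
# A tibble: 3 × 10
  id                 smiles               hac   fdv   mc1   mc2 n_excluded n_attachments status message
  <chr>              <chr>              <int> <dbl> <dbl> <int>      <int>         <int> <chr>  <chr>
1 paracetamol        CC(=O)Nc1ccc(O)cc1    11 0.455 0.545     4          2             0 ok     ""
2 hexane             CCCCCC                 6 0.667 0.333     2          0             0 ok     ""
3 polypropylene unit [*]CC(C)[*]            3 0.333 0.667     2          0             2 ok     ""
```

Reading the paracetamol row: 11 heavy atoms, 5 of them divalent (four
aromatic CH and the amide N), so MC1 ≈ 0.55; of the 6 non-divalent atoms,
the amide C=O pair is excluded (`n_excluded = 2`), leaving MC2 = 4 — the
acetyl CH₃, the two substituted ring carbons and the phenol O, all judged
by degree, not chemistry. Hexane is a plain chain: only its two terminal
carbons are non-divalent, so MC2 = 2 regardless of chain length.

Single molecules, fragments and diagnostics:

```r
score_molecule("OC(=O)C(F)(F)F")        # TFA: mc1 = 1
parse_structure("[*]OCC[*]") |> degree_profile()
detect_excluded_carbonyls(parse_structure("CC(N)=O"))
```

The comparison harness takes any molecules × measures table (external
measures such as SAscore join as precomputed columns) and mirrors a
correlation-matrix / violin-plot analysis at desk scale:

```r
t  <- fixture_score_table(n_each = 25, seed = 1)
r2 <- pairwise_r2(t)      # squared Pearson correlations, pairwise-complete
tidy(r2); glance(r2)      # long table / one-row summary
autoplot(r2)              # heatmap
plot_score_distributions(t)
```

A batch CLI wraps the same functions:

```sh
Rscript inst/cli/molcomplex score --input mols.smi --output scores.tsv
Rscript inst/cli/molcomplex compare --scores scores.tsv --out-prefix cmp
```

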