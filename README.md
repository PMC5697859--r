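# protblocks

Knowledge-based prediction of protein local backbone structure in the
Protein Blocks alphabet, for structural bioinformaticians who need
per-residue conformational hypotheses from sequence alone — model building,
fragment selection, or quality estimation of predicted backbones.

## What it does

**Protein Blocks (PBs)** are 16 canonical five-residue backbone
conformations, letters `a`–`p` (PB `m` ≈ α-helix core, PB `d` ≈ β-strand
core), each defined by eight standard dihedral angles
(ψ<sub>i−2</sub>, φ<sub>i−1</sub>, ψ<sub>i−1</sub>, φ<sub>i</sub>,
ψ<sub>i</sub>, φ<sub>i+1</sub>, ψ<sub>i+1</sub>, φ<sub>i+2</sub>).
A residue gets the PB minimizing the angular RMSD

RMSDA(v, w) = √(⅛ Σ<sub>k</sub> Δ(v<sub>k</sub>, w<sub>k</sub>)²)

over the wrapped angle differences Δ. The package:

1. **Encodes** structures (PDB → φ/ψ → PB strings; internal torsion
   geometry, `bio3d` parsing).
2. **Builds a pentapeptide knowledge base**: every overlapping amino-acid
   5-mer of every chain with its central-residue PB and the source chain's
   sequence-identity cluster memberships at 30–100% thresholds.
3. **Predicts** a PB sequence for a query sequence. Each 5-residue window
   queries the base (exact 5-mer, then 4-mer-prefix wildcard) for its
   candidate PBs with raw counts (S1). The *majority rule* takes the top
   count; the *hybrid method* takes the top S1·S2 product, where S2 sums
   tri-PB motif odds over the flanking windows' candidates. Querying is
   either *classic* (one identity cut-off) or *noise filtering* (per
   window, closest homologues first, widening only on miss).
4. **Scores** any PB sequence for plausibility:
   A = Σ log₁₀ N<sub>i</sub> / l over its penta-PB windows (−5 per
   never-observed motif) — a self-estimate of prediction accuracy needing
   no structure.
5. **Evaluates** against structure-derived truth: Q16, confusion matrix,
   per-PB sensitivity/specificity/MCC, relaxed `{c,d}`-equivalence
   accuracy, candidate-list coverage.
6. **Generates synthetic worlds** (PB strings → reconstructed backbones →
   homologue families at scheduled identities with matching tier tables),
   so everything above is testable offline.

## Worked example

```r
library(protblocks)

fx <- make_fixture(seed = 42)          # 3 families x 4 homologues, 40 aa
db <- fixture_pentadb(fx)              # pentapeptide knowledge base
db
#> Pentapeptide knowledge base
#>   records:             432
#>   unique 5-mers:       286
#>   source chains:       12

tripb <- pb_frequency_table(fx$chains$pb, order = 3, mode = "odds")
penta <- pb_frequency_table(fx$chains$pb, order = 5, mode = "odds")

q <- fx$chains[1, ]                    # query one chain, excluding itself
pred <- predict_pb(q$aa, db, method = "hybrid", scheme = "noise-filter",
                   start = "100", query_chain = q$chain, tripb = tripb)
pred
#> PB prediction (hybrid, noise-filter)
#>   ZZehiacddehiacddehiacehiacdfklnopZZaZfZZ
#>   windows: 36 (exact 30, wildcard 3, none 3, ties 0)

evaluate_prediction(q$pb, pred)
#> PB prediction evaluation
#>   Q16: 97.0%  (strict denominator: 88.9%)  relaxed: 97.0%
#>   positions scored: 33

accuracy_score(pred$pb, penta)$score
#> [1] 2.67
```

The prediction string aligns with the query residue-by-residue: `Z` marks
the two termini on each side and the three windows for which no
pentapeptide (or 4-mer prefix) from an accessible chain was ever seen. Q16
is the percentage of jointly defined positions predicted exactly (97.0%
here, because a 95%-identical homologue was accessible); the strict
denominator also counts the no-hit positions as errors. The accuracy score
(+2.67) is in the range typical of native-like PB sequences — large
positive values mean the predicted motifs are ones that recur in the
corpus, and the score tracks actual accuracy, so it serves as a quality
estimate when no structure is available.

Per-window detail (candidate profiles, S1/S2 scores, tie flags, tier used)
is a tibble away: `tidy(pred)`; `glance(pred)` summarises match kinds;
`autoplot(evaluate_prediction(q$pb, pred)$confusion)` draws the confusion
heatmap.

A command-line front end wraps the same functions
(`inst/exec/protblocks`): `build-db`, `db-stats`, `build-tables`,
`predict`, `score`, `evaluate`, `make-fixture`.

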