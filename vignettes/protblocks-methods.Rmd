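---
title: "Knowledge-based local structure prediction with Protein Blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based local structure prediction with Protein Blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protblocks)
```

## The structural alphabet

Protein Blocks (PBs) are a 16-letter structural alphabet (`a`–`p`) in which
each letter is a canonical backbone conformation of five consecutive
residues, defined by eight standard dihedral angles
$(\psi_{i-2}, \phi_{i-1}, \psi_{i-1}, \phi_i, \psi_i, \phi_{i+1},
\psi_{i+1}, \phi_{i+2})$. PB `m` is the core of the $\alpha$-helix and PB
`d` the core of the $\beta$-strand; the other letters describe caps, turns
and transition geometries. A residue is assigned the PB whose prototype
minimizes the RMSDA — the root mean square deviation over the eight wrapped
angular differences:

$$\mathrm{RMSDA}(v, w) = \sqrt{\tfrac{1}{8}\sum_{k=1}^{8}
  \Delta(v_k, w_k)^2},$$

with $\Delta$ the signed circular difference in $(-180^\circ, 180^\circ]$.
The prototype table shipped in `inst/extdata/pb_prototypes.tsv` is the
canonical one published by de Brevern, Etchebest & Hazout (2000, *Proteins*
41:271–288); `pb_alphabet()` accepts any table with the same shape, so the
alphabet is configuration, not code. We deliberately do not re-derive the
prototypes (originally obtained by unsupervised learning on a non-redundant
structure set); the alphabet is taken as given.

Two conventions are ours rather than part of the published alphabet:

* **Tie-breaking.** Exact RMSDA ties between prototypes are broken towards
  the alphabetically smaller letter. Ties are measure-zero for real
  dihedrals; the rule only pins down determinism.
* **Undefined positions.** The first two and last two residues of a chain,
  and any residue whose eight-angle window touches a missing atom or a
  chain break, carry the letter `Z`. `Z` positions are excluded from every
  accuracy denominator; where a rate with the stricter denominator (counting
  unpredicted residues as errors) is informative, `evaluate_prediction()`
  reports both.

## Geometry

$\phi_i$ is the torsion C$(i{-}1)$–N$(i)$–CA$(i)$–C$(i)$ and $\psi_i$ the
torsion N$(i)$–CA$(i)$–C$(i)$–N$(i{+}1)$, computed internally with the
standard atan2 formulation (IUPAC sign convention; validated against
`bio3d::torsion.xyz`). Consecutive residues whose peptide C–N distance
exceeds 2.5 Å are treated as a chain break and the spanning angles are
undefined; 2.5 Å is a generous upper bound for a real peptide bond
(~1.33 Å) while safely below typical gap distances. PDB files are parsed
with `bio3d::read.pdb`; we keep the first model of multi-model files (a
single conformation is being encoded) and, where alternate locations exist,
the highest-occupancy altloc with ties resolved towards `A`.

`build_backbone()` inverts the encoding for fixture construction: each
residue receives the central $(\phi, \psi)$ pair of its letter's prototype,
optionally perturbed by Gaussian noise, and atoms are placed sequentially by
natural-extension internal coordinates (N–CA 1.458 Å, CA–C 1.525 Å, C–N
1.329 Å, standard bond angles, trans peptide). The central-angle choice is
the standard way to realize a PB string as a backbone when, as here, no
reconstruction recipe is prescribed: prototypes of adjacent windows overlap
in six of eight angles, so a residue's own central pair is the only
assignment that is consistent across all windows containing it.

## The pentapeptide knowledge base

Every overlapping 5-mer of every chain whose central residue has a defined
PB becomes one record: the amino-acid 5-mer, the central PB, the source
chain and the position. The store is an in-memory table keyed on the 5-mer
and its 4-mer prefix, persisted as plain TSV; at the scales this package
addresses (up to a few thousand chains) this met the same query contract as
a relational server — exact and prefix lookup, persistence, per-query
filtering — without any deployment.

Querying a 5-mer returns the **candidate profile**: the observed central
PBs with their raw counts (S1 scores), the "list of all possible PBs" for
that window. If the exact 5-mer is absent, a fallback matches the first
four residues with a wildcard fifth (the wildcard position is fixed at
position 5; moving it has been reported not to change outcomes). 5-mers
containing `X` (nonstandard residues) are stored and can be hit exactly,
but `X` never matches as a wildcard stand-in for a concrete residue.

**Identity tiers.** Each source chain carries its cluster membership at the
thresholds 30, 40, 50, 70, 90, 95 and 100% sequence identity. Access
control is expressed through these memberships:

* classic scheme at cut-off $t$: records from chains *not* co-clustered
  with the query at $t$ (identity below $t$), query always excluded;
* noise filtering: an ordered ladder of chain sets from closest homologues
  outward. Each query window independently takes its profile from the first
  rung with a non-empty exact hit; the wildcard is consulted only after the
  entire ladder misses on exact 5-mers, again closest-first. A ladder
  starting at "<t" first discards all chains with identity $\ge t$ — the
  same universe as the classic scheme at $<t$ — which is why the deepest
  start (<30%) collapses to a single rung identical to the classic 30%
  cut-off, a property the test suite asserts.

Whether wildcard lookups should also be tiered is not prescribed anywhere we
could find; exhausting exact matches across all rungs before any wildcard is
our reading (an exact match in a distant homologue seems more trustworthy
than a prefix match in a close one), implemented symmetrically so the
alternative would be a local change.

## Prediction

Per window, the **majority rule** picks the candidate with the highest raw
count. The **hybrid method** multiplies each candidate's count (S1) by a
contextual score S2: the sum of normalized tri-PB frequencies ("odds") of
every three-letter motif formed with the candidate PBs of the two flanking
windows that has the candidate in the centre. Design points:

* A flanking window that is missing (terminus) or empty (no hits)
  contributes the full 16-letter alphabet to the motif enumeration, so S2
  degrades gracefully toward an unconditioned context rather than vanishing.
* If every candidate's product is zero (no tri-PB through the candidates
  was ever observed), the window falls back to the majority rule: an
  observed pentapeptide should not become unpredicted because its context is
  rare.
* Count ties are flagged, all tied letters recorded, and the alphabetically
  smallest emitted, since downstream a single PB string is needed;
  evaluation against the full tied set is possible from the per-window
  table.

## Motif statistics and the accuracy score

`pb_frequency_table()` counts tri-PB or penta-PB motifs in a PB corpus
(windows containing `Z` are skipped). Two normalizations are available:
plain frequency (entries sum to 1) and **marginal odds** — motif frequency
divided by the product of the single-letter marginal frequencies. Odds is
the default for both S2 and the accuracy score, for a substantive reason:
the self-estimated accuracy score

$$A = \frac{\sum_{i=1}^{l-4} \log_{10} N_i}{l}$$

(with $N_i$ the normalized frequency of the window's penta-PB motif, $l$
the scored sequence length, and a flat $-5$ contribution for a window whose
motif was never observed) is reported to take values up to about $+3$ for
native-like sequences. Plain frequencies are bounded by 1, making positive
scores impossible; over-representation odds, which exceed 1 for motifs
enriched relative to an independence model, reproduce the reported score
range. Both the normalization and the logarithm base are arguments, not
constants, because the original normalization is described only in
supplementary material we could not consult; the defaults are our choice
and are flagged as such. The $-5$ penalty and the denominator $l$ (sequence
length, not window count) follow the published definition exactly;
`accuracy_score()`'s worked examples in the tests pin the arithmetic
(a single window with $N = 0.01$ over $l = 5$ gives $-0.4$; a single
unobserved window gives $-1$, i.e. $-5/l$).

## Evaluation

`q16_accuracy()` is the percentage of jointly defined positions whose
predicted letter matches the structure-derived one. The confusion matrix
feeds one-vs-rest per-PB statistics; the Matthews correlation coefficient
uses the standard four-term form with a zero denominator mapped to 0, and
is cross-checked in the tests against an independent formulation (MCC as
the Pearson correlation of indicator vectors). Specificity is computed
one-vs-rest and is high nearly by construction against 15 negative classes;
sensitivity is the discriminating number. `relaxed_accuracy()` treats
user-chosen letter sets as interchangeable; only `{c, d}` — the one
well-documented confusion between the two extended-region PBs — is a
default, since no complete equivalence enumeration is part of the method;
fuller sets derived from PB substitution matrices can be supplied.

## Synthetic worlds: what they do and do not show

`make_fixture()` builds families of chains sharing one backbone. Its
defaults are the package's study conditions and were fixed once:

* **3 families × 4 chains × 40 residues**, identity schedule
  (100, 95, 70, 40)% — small enough that the whole suite runs in seconds,
  large enough that every tier band between the thresholds is populated.
* **PB strings** are sampled from a first-order Markov chain whose allowed
  transitions are those with overlap RMSDA below 40° between the trailing
  six prototype angles of one letter and the leading six of the next,
  restricted to the strongly connected core (13 of 16 letters) and weighted
  by $e^{-d/20^\circ}$. This is the point where fixture design meets the
  encoder: within this transition set, every admissible five-letter context
  re-assigns its central letter exactly (verified exhaustively; the
  smallest margin to a runner-up prototype is ~23°), so
  `encode_chain(build_backbone(s))` recovers `s` at all interior positions
  for noise up to $\sigma = 5°$ per angle. Letters `b`, `g`, `j` are
  transition blocks whose own window overlaps are internally inconsistent
  under central-angle reconstruction; they appear in real encoded
  structures but not in generated strings.
* **Dihedral noise** $\sigma = 2°$ by default: visible thermal-scale jitter
  that leaves assignments comfortably inside their basins.
* **Sequences** are drawn from a reduced 4-letter amino-acid alphabet. With
  20 letters, a desk-scale store would contain essentially no cross-family
  5-mer collisions and every query without accessible homologues would
  return nothing; a real structure database, six orders of magnitude
  larger, observes most pentapeptides even among unrelated proteins. The
  reduced alphabet restores that saturation regime (a few thousand possible
  5-mers against a few hundred observed windows).
* **Tier tables** come from the generative schedule itself (a member chain
  co-clusters with its family at thresholds up to its identity to the
  master), which keeps threshold boundaries exact. The separate
  `toy_identity_clusterer()` measures identities by global alignment and is
  used for externally supplied sequence sets.

Because family members share coordinates exactly, a 100%-identity homologue
in the store carries the query's true PBs — the fixtures isolate the lookup
and scoring machinery from structural divergence. Real identical sequences
can adopt locally different conformations, so passing these tests
demonstrates the machinery, not attainable accuracy on real proteins; the
published full-scale behaviour (bimodal accuracy, twilight-zone collapse)
is reproduced qualitatively, not numerically, at this scale.

## Numerical choices

* Angles are normalized to $(-180°, 180°]$ at ingestion; all angular
  arithmetic wraps.
* Degenerate torsion geometry (coincident or collinear points) yields an
  undefined angle, which propagates to `Z` rather than erroring.
* All stochastic components (string sampling, mutation, noise) take
  explicit seeds and restore the caller's RNG state.
* Problem sizes in the tests and the acceptance script — 30–40-residue
  chains, 3–4 families, 50-string round-trip batches, 1000 random
  confusion matrices — were chosen so the full suite completes in about two
  minutes while leaving every assertion statistically comfortable.

## Known limitations

* No mmCIF input, side chains, occupancy-weighted ensembles or structure
  validation; first-model-only NMR handling.
* The store is loaded in memory; it targets fixture-to-thousands of chains,
  not a full structure archive.
* The odds normalization and log base of the accuracy score are declared
  defaults (see above), not published constants.
* Generated fixtures do not couple amino-acid identity to local structure;
  prediction accuracy on them measures retrieval fidelity, not
  sequence-structure learning.
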