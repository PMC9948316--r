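---
title: "Reconstructing molecules from structural fingerprints: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing molecules from structural fingerprints: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Structural fingerprints — MACCS keys, path and atom-pair fingerprints,
topological torsions, circular (Morgan/ECFP) environments — encode a
molecule as a *set* of substructure-derived features. The encoding is
lossy by design: connectivity between features is discarded, and hashed
variants additionally fold feature identifiers into a fixed-width bit
vector. `fp2mol` treats the inverse problem as machine translation: the
ordered sequence of fingerprint feature tokens is the source sentence,
and the SMILES or SELFIES string of the molecule is the target sentence.
A transformer encoder–decoder is a natural fit because attention is
permutation-invariant, matching the unordered set character of a
fingerprint, while positional encodings can still exploit the
conventional index order of the features.

## The model

The translator is the standard pre-layer-norm transformer: encoder and
decoder stacks of identical layers (default 6), each sublayer preceded
by layer normalization and followed by a residual connection and
dropout (rate 0.1), with an additional normalization after the final
encoder and decoder layers. Multi-head attention uses 8 heads over a
512-dimensional model width with a 2048-dimensional ReLU feed-forward
inner layer. Token embeddings are scaled by the square root of the
model width and augmented with sinusoidal positional encodings on both
sides; source and target embeddings are untied because the two
vocabularies are of entirely different kinds (integer feature IDs
versus chemical string tokens). Training minimizes the mean per-token
negative log-likelihood under teacher forcing, with padding positions
excluded from both the loss and the attention keys.

These defaults (`model_config()`) describe the full-scale
configuration. The package's own experiments use a reduced instance
(2 layers, 4 heads, width 128, feed-forward 256) because the intent at
desk scale is to verify the machinery — batching, masking, gradients,
decoding — rather than to reach corpus-scale accuracy.

The whole network, including backpropagation, is implemented in R
matrix algebra with one Rcpp/Armadillo kernel for the batched
multi-head attention inner loops. The analytic gradients are verified
against central finite differences in the test suite, which is the
strongest correctness check the package has: every layer's backward
pass agrees with the numerical derivative to ~1e-7 relative error.

## The learning-rate schedule

Training uses a cyclic decayed schedule parameterized directly by its
endpoints: within each cycle of 25,000 steps the rate ramps linearly
from the floor (3.9e-12) to the peak (0.001) over 5,000 warmup steps,
then decays geometrically so that it reaches the floor exactly at the
cycle end, and jumps back into the ramp. Geometric (log-linear) decay
is the only monotone shape that meets both printed endpoints exactly,
which is why it was chosen over a Noam-style inverse-square-root form;
the associated constant factor (5) is retained in `sched_config()` for
provenance but does not drive the computation. The per-cycle maximum is
constant across cycles: the rate "increases to its maximum again" at
each cycle, rather than decaying across cycles. `lr_at()` is exactly
periodic, attains the peak exactly at the warmup end, and is continuous
at the ramp/decay junction — all property-tested.

For the desk-scale memorization runs the same schedule family is used
with a shorter warmup (500) and a cycle of 11,000 steps, chosen so that
a 3,000-step run ends with the rate annealed to roughly 1e-5: enough
late-stage annealing to stabilize exact-string decoding without
freezing the optimizer halfway through the run.

## Token-count batching

Batches are sized by a token budget (default 8,000) rather than a pair
count: pairs are bucketed by source length, packed greedily so that
(max source length + max target length) × pairs stays within the
budget, and batch order is shuffled per epoch. This mirrors how
variable-length fingerprint sentences are batched in practice — short
MACCS sentences pack densely, long atom-pair sentences sparsely — and
makes the memory footprint predictable.

## The fingerprint featurizers

The registry holds exactly thirteen featurizers in five families, all
computed from a kekulized molecular graph:

* **MACCS** — a 166-position substructure key set (ring sizes, element
  presence, common functional groups, size/charge features). The
  positions are fixed; keys whose predicates never fire in a corpus
  simply never enter the vocabulary, which is why observed MACCS
  vocabularies are slightly smaller than 166.
* **Avalon-style** — paths and feature classes (atom types, bond
  types, short paths, ring sizes, degree features) folded to 512 bits.
  The exact feature-class composition of the original Avalon generator
  is not re-derived; this is a same-shape stand-in documented as such.
* **Path-based** — hashed branched (RDK4) or linear-only (RDK4-L)
  connected subgraphs of 2–4 bonds, and the hashed atom-pair
  fingerprint (HashAP) over typed atom pairs at topological distances
  1–6, all folded to 2048 bits.
* **4-atom paths** — topological torsions over paths of four bonded
  atoms with Carhart-style atom types, sparse (TT) and hashed (HashTT).
* **Circular** — Morgan environments: sparse radius-1 atom
  environments (AEs), hashed radius 0/1/2 (ECFP0/2/4), and
  pharmacophoric feature-class variants (FCFP2/4) whose initial atom
  invariants are donor/acceptor/aromatic/halogen/basic/acidic flags.

Feature identifiers come from a package-local 31-bit FNV-1a hash, so
featurization is deterministic across platforms and sessions. Bit-level
agreement with any particular external toolkit is deliberately not a
goal — the package's claims are at the level of the featurizer
*contracts* (families, dimensions, parameters, set semantics), which is
what the tests pin down. Everything is presence-only: sparse sets and
hashed bit vectors alike are compared with the set Tanimoto
coefficient, with the convention that two empty sets have similarity 1.
For similarity there are fifteen metrics: the thirteen featurizers plus
the explicit-bit (unhashed) variants ECFP2* and ECFP4*.

An isolated atom is a degenerate case worth noting: its radius-1
environment is identical to its radius-0 environment, so a one-heavy-
atom molecule contributes exactly one AEs feature rather than two.

## Chemistry kernel and string codecs

Chemical perception — canonical ordering, aromaticity, stereo sanity —
is delegated to OpenBabel through the ChemmineR/ChemmineOB stack;
canonical isomeric SMILES is the package's molecular identity (equal
strings = same molecule). SMILES *syntax* (parsing into atoms, bonds,
ring closures, stereo annotations; atom-wise tokenization; writing) is
implemented in the package, with kekulized bond orders aligned from the
kernel's connection table. Stereo stripping happens at the annotation
level followed by re-canonicalization, so `canonicalize(x, keep_stereo
= FALSE)` maps both members of an enantiomer or cis/trans pair to one
string.

The SELFIES-style codec is a self-contained robust molecular string
language: atom tokens (organic-subset elements, charged N+/O-,
tetrahedral-tagged carbon, with optional =, #, / or \\ bond prefixes),
branch tokens that read an index token for their length, and ring
tokens that read an index token for their back-offset. Decoding is a
valence state machine — bond orders are capped by the remaining valence
of both partners, unrealizable branches and rings are skipped, leftover
valence becomes implicit hydrogens — so *every* token sequence decodes
to a chemically valid molecule; the fuzz test asserts a 0% invalidity
rate on 1,000 random sequences. Encoding walks the kekulized parse tree
depth-first and is exactly inverted by the decoder; round trips are
verified by canonical equivalence. One known limitation: tetrahedral
parity at atoms that open a ring closure is defined relative to the
codec's own neighbor-order convention, so SELFIES ground truths are
always compared after decoding, which keeps the comparison internally
consistent.

## The synthetic corpus

No public compound collection ships with the package. The corpus
generator is a first-class module that emulates the regime of interest:
small to medium drug-like organic molecules of at most 50 heavy atoms
(inclusive bound), roughly 30% of them carrying stereochemistry.
Generation samples random token sequences from the robust codec
alphabet (carbon-rich weights with occasional heteroatoms, branches,
rings, charges and stereo tags, 6–42 tokens) and decodes them, which
guarantees validity without any external database; molecules below 5
heavy atoms are rejected as not drug-like, duplicates are resolved by
canonical SMILES with first occurrence winning. When the running stereo
fraction is below target, unassigned stereocenters are fixed randomly
— candidate tetrahedral carbons get a random parity tag, double bonds
get directional marks — and the kernel's canonicalizer acts as the
arbiter: an assignment only counts if the annotation survives
canonicalization. A 2,000-molecule run lands within a percentage point
of the 30% stereo target with heavy atoms spanning ~5–30.

What this corpus does *not* emulate: the scaffold diversity, functional
group distribution, ring-system complexity and molecular weight profile
of real screening collections. Passing tests on it demonstrates that
the pipeline is correct and trainable, not that the reported
corpus-scale accuracies transfer; those require millions of real
molecules and were explicitly left out of scope.

For corpus extension there is a greedy atom-type diversity selector:
candidates are ranked by how many radius-0 circular features (atom
types) they add to the covered set, ties break by input order, and
selection stops at the budget or when nothing new is covered. The
greedy-until-budget stopping rule is this package's choice; the
selection is verified against an exhaustive greedy oracle in the tests.

## Evaluation

The primary metric is **Tanimoto exactness**: the percentage of
predictions whose similarity to the ground truth equals 1 under a
chosen metric fingerprint, with invalid predictions counting in the
denominator only. Because a fingerprint shared with the source
representation biases the comparison, the **bias matrix** recomputes
exactness under all fifteen metrics, one row per model.

The **breakdown** classifies each prediction by the first matching
rule: invalid → not-exact (primary Tc < 1 under sparse radius-1
circular) → string-exact → non-canonical (stereo-preserving canonical
forms equal) → stereo (stereo-stripped canonical forms equal) →
others. The priority order resolves overlaps the categories would
otherwise have: a prediction that is both non-canonically written and
stereo-flipped lands in "stereo", consistent with diagnosing stereo
errors by stripping stereo and re-comparing. "Others" is operationally
the residual class; chain homologs are its classic members, since a
sparse radius-1 fingerprint cannot distinguish hexane from octane. The
mean Tanimoto score assigns 0 to invalid predictions to keep the
denominator consistent. The partition identity (string-exact + stereo +
non-canonical + others = Tc-exact; Tc-exact + not-exact + invalid =
100%) is enforced by construction and property-tested.

**Significance thresholds** calibrate raw similarity values: for a
fingerprint, sample random unordered molecule pairs (no self-pairs)
from a corpus and report the empirical (1−p) quantile of their
similarities — the value exceeded by only a fraction p of random
pairs. The package uses the empirical quantile (sorted-sample
indexing, verified against a brute-force oracle) rather than a
parametric fit of the similarity distribution: at desk-scale sample
sizes a parametric CDF fit is less stable than the order statistic,
and the empirical quantile is assumption-free. For stereo errors,
records in the stereo category are further profiled as reversed
(annotations flipped), missing, spurious, or mixed.

## Attribution

Integrated gradients explain a prediction token-by-token: for target
position t, the attribution of source token i is the path integral of
the gradient of the teacher-forced log-probability of the target token
with respect to the source embedding, from a baseline x′ to the input
x, approximated with a m-step Riemann sum (default 64). The baseline is
the padding-token embedding — for a fingerprint, "this feature is
absent" is precisely what padding encodes, which makes it the natural
reference point. The completeness identity (row sums equal the
log-probability difference between input and baseline) is tested to
within 2% at 64 steps. Cross-attention maps are the supplementary
view: by default the final decoder layer averaged over heads, rows
exactly normalized. Which layer/head combination is most informative is
an open question in general; both aggregations are parameters.

## Numerical choices and degenerate inputs

* Feature hashing: FNV-1a into [0, 2^31), folded by modulus for hashed
  specs; token sequences are strictly ascending with duplicates
  removed.
* Tanimoto of two empty sets is 1.0 (string-identical molecules must
  score 1 under every metric, including featurizers that can emit
  empty sets, such as torsions on propane).
* Beam search: width 5 by default, length normalization off (at desk
  scale hypotheses are short; the flag exists). Beam width 1 is exactly
  greedy argmax, asserted against an independent token-by-token oracle.
  A hypothesis that never emits the end token within the length cap is
  returned truncated and flagged, and counts as invalid downstream.
* Training aborts on non-finite loss; zero-step runs return the
  initial state unchanged; two runs with one seed produce identical
  loss traces.
* An empty molecule request returns an empty record set; an empty
  record set is an error for evaluation functions (no silent NaNs).

## Desk-scale problem sizes

The test suite and the acceptance script use: a 2,000-molecule
synthetic corpus (200 held out), 1,000-sequence fuzz and round-trip
checks, a 200-pair memorization run of the reduced transformer for
3,000 steps at a token budget of 400, beam-5 decoding of the held-out
set, 1,000 sampled pairs per significance threshold, and 64-step
integrated gradients. These sizes were chosen as the smallest at which
each property is meaningfully exercised — memorization capacity,
generalization above a shuffled-pairing baseline, quantile stability —
while keeping a full run in the tens of minutes on one CPU.

## Known limitations

* The chemistry kernel is permissive about unusual valences (it
  sanitizes rather than rejects hypervalent atoms); validity therefore
  means "parseable and canonicalizable", which is the kernel's notion,
  not a physical plausibility check.
* MACCS and Avalon featurizers implement the family contract (fixed
  positions/width, path and feature classes) rather than reproducing
  any external toolkit bit-for-bit.
* The stereo-error profile compares canonical strings positionally;
  molecules whose canonical atom order changes between stereoisomers
  are classified "mixed" rather than per-center.
* Desk-scale training demonstrates capacity and correctness, not
  chemical generalization; held-out exactness above a shuffled
  baseline is the honest desk-scale analogue of corpus-scale accuracy.
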