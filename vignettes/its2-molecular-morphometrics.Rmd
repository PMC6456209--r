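---
title: "ITS2 molecular morphometrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ITS2 molecular morphometrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(its2morph)
```

This vignette explains the science implemented by `its2morph`: what each
stage models, which parameters matter and why their defaults were chosen,
what the synthetic-data generator does and does not emulate, and where
design decisions were genuinely open.

## The delimitation model

The ITS2 spacer of the nuclear ribosomal operon folds into a conserved
secondary structure: a central loop from which three to four helices
radiate (numbered I–IV in 5'→3' order), helix III the longest and carrying
a UGGC tetranucleotide at its base (CGGC in some lineages).  A
*compensatory base change* (CBC) between two records is a conserved base
pair whose two nucleotides both differ while the pairing remains valid
(e.g. G–C ↔ A–U); a *hemi-CBC* changes one side only (G–C ↔ G–U).  The
delimitation premise is that one or more CBCs between two ITS2 structures
mark distinct species, while the absence of CBCs is not evidence of
conspecificity.  Consequently:

- the *minimal species count* of a record set is the smallest number of
  blocks such that no within-block pair shows a CBC — the chromatic
  number of the graph whose edges are CBC-separated pairs.  We solve
  this exactly (branch and bound) up to 16 records and flag the greedy
  fallback beyond that, because the greedy bound is only an upper bound;
- a query is *named* after a reference species only on absolute identity
  with that reference's structure, and CBC-free consistency; all other
  queries stay at genus level as "type-NN" blocks.  Hemi-CBCs are
  reported but never used for delimitation.

"Absolute structural identity" has no unique operational definition; the
default (`strict`) requires identical sequence and identical dot-bracket,
because species names should not be transferred across even
unpaired-region substitutions.  A `structure-only` mode (identical
dot-bracket, any sequence) is provided for sensitivity analysis.

## Folding model

Folding is a Zuker-style dynamic programme over an unambiguous grammar
(exterior / paired / multiloop-region states) with:

- a simplified nearest-neighbour **stacking table** (one energy per
  stacked pair-type combination, rounded literature-like values in
  kcal/mol, G–U wobble allowed),
- logarithmic hairpin / bulge / interior-loop penalties with the
  interior/bulge size capped at 30 unpaired nt,
- an affine multiloop cost a + b·branches + c·unpaired
  (3.4, 0.4, 0.1 kcal/mol),
- minimum hairpin loop 3 nt, no pseudoknots, dangling ends and coaxial
  stacking ignored.

This model reproduces the *topology-level* behaviour the pipeline needs —
which helices form, their lengths, which suboptimal structure to prefer —
but makes no claim of reproducing Mfold/Turner absolute energies; that is
why externally predicted Vienna-format structures can be injected at the
folding stage and flow through the rest of the pipeline unchanged.  A
`pair-count` model (−1 per pair, no loop terms) is kept for oracle
testing, since both models share the recursion but not the evaluator.

Suboptimal structures are enumerated completely (Wuchty-style traceback
over the same grammar) within a 5% energy band of the MFE, truncated to
50 after sorting — the conventional bounded-suboptimality setting for
ITS2 work.  The *selection rule* then returns the lowest-energy candidate
whose annotated topology shows 3–4 principal helices; if none qualifies
the MFE structure is returned flagged `"non-canonical topology"` rather
than silently accepted, so unusual records stay visible downstream.

Two folding-related questions were open and resolved as follows.  The
20-nt 5.8S/28S pads are used to *locate* and contextualize the ITS2 but
the bare spacer is folded by default: pads pair with each other in the
real molecule (the 5.8S/28S proximal stem), and folding them with a
nearest-neighbour model would graft a spurious enclosing helix onto the
spacer topology.  Padding-inclusive folding remains available by folding
the `padded` field directly.  Second, traceback ties are broken toward
the 5'-most pairing and then toward stacking, making folding fully
deterministic.

## Structure annotation

The central loop is the exterior loop of the nested structure.  A
top-level stem of **at most 3 pairs** enclosing a second-level multiloop
is treated as an "extended subdomain" of the central bulge, and the
helices it bears are distinguished from those radiating directly — the
distinction behind topology types 2, 3 and 5.  The 3-pair threshold is a
design choice (the field's descriptions say only that the subdomain stem
is short); it is a parameter of `build_helix_tree`.  Small helices (≤3
pairs) lying between two larger ones are labelled IIa-style and excluded
from the principal helix count, so a type-3 structure still counts three
principal helices.  Helix III is identified positionally (third principal
helix 5'→3'); when it is not also the longest, the positional labelling
wins and a log line records the conflict.  Unclassified topologies map to
type 0 and propagate as flags, never as errors.

Consensus structures follow per-column majority rules: majority residue
among non-gap entries, conservation = its frequency, conserved flag at
\>0.51, and a consensus pairing state held by more than half of all
records.  Majority brackets are re-matched; unmatched brackets revert to
unpaired — which is exactly how a helix paired in under half the records
(helix IV, typically) drops out of a consensus.

## Alignment and distances

Sequence and structure are aligned jointly in a 12-letter alphabet,
{A,C,G,U} × {unpaired, open, close}.  The default scoring matrix is +3
for residue-and-state match, +1 state-only, −1 residue-only, −2 neither,
with affine gaps (−5 open, −1 extend): structure similarity dominates
sequence similarity, the ordering the method assumes.  Published
ITS2-specific matrices with the same dimnames can be dropped in.
Pairwise alignment is exact affine-gap DP (a C++ kernel over a
precomputed column-score matrix); multiple alignment is progressive along
a UPGMA guide tree with profile-profile scores `f_a' S f_b` through the
same kernel.

CBC counting is defined on *maintained* pairings: a column pair counts
only when it is paired in both records, gap-free in both, and both pairs
are canonical or wobble.  Columns where the two records disagree on
pairedness are structural, not substitutional, differences and contribute
to neither CBC nor hemi-CBC.  Whether hemi-CBCs should admit G–U on both
sides in every case is not settled in the literature; here any
canonical/wobble-to-canonical/wobble single-sided change counts, and the
rule is fixed and documented.

Distances for the phylogeny are computed on the encoded alphabet:
p-distance over co-ungapped columns, or the Poisson-type correction for a
12-state alphabet, d = −(11/12) ln(1 − (12/11) p), capped (and flagged)
near saturation.  A GTR-on-structure model fitted by external tools is
not re-derivable from published descriptions; the Poisson-corrected
12-state distance preserves the method's character — structure-aware
distances — with a defensible closed form, and is labelled as such.
Neighbor joining is canonical (Saitou–Nei Q-criterion) with deterministic
tie-breaks and negative branch lengths clamped to zero, the deficit moved
to the sister branch.  Bootstrap pseudo-replicates resample alignment
columns with replacement; supports are mapped onto the full-data tree
(the standard presentation), with the majority-rule consensus available
as an alternate output.

## Diversity battery

The index battery mirrors what endophyte surveys report.  Formulas and
conventions:

- CF = isolates / segments × 100; EIR = infected segments / segments ×
  100; RPO = group density / total density × 100 (all to one decimal);
- Shannon H′ in natural log (the reported values in such surveys are
  consistent with nats);
- inverse Simpson uses the *unbiased* finite-sample D = Σ nᵢ(nᵢ−1) /
  (N(N−1)) by default, the plug-in form by flag;
- Fisher's alpha solves S = α ln(1 + N/α) by bracketed root-finding at
  1e-8 tolerance; it diverges as S → N, which is an error, not a value;
- Chao1 uses the bias-corrected form S_obs + F₁(F₁−1)/(2(F₂+1)) by
  default (the EstimateS default), the classic form by flag;
- ACE uses the standard rare-class (≤10) coverage estimator and falls
  back to Chao1 when the coverage is zero (all-singleton samples);
- Chao–Jaccard follows the abundance-based coverage-corrected U/V
  estimator with the published convention of replacing a zero doubleton
  count by one; the Chao-type shared-species estimate uses
  bias-corrected (+1) denominators, a deliberate conservative variant;
- accumulation curves are sample-order randomizations (mean ± SD over
  seeded resamples), endpoint exactly S_obs.

ACE and Chao1 are computed independently even though published tables
sometimes print them identical; agreement or disagreement is then a
property of the data, not of the code.

## The synthetic generator: what it does and does not emulate

`generate_species_set` instantiates a structure template (default: three
helices of 13/17/25 bp with 5/6/8-nt apical loops, ~152-nt ITS2, within
the 145–181-nt range typical of fungal ITS2; helix III carries the
TGGC/UGGC basal motif) and plants mutation events with known truth:

- `cbc_between` CBCs per species at *disjoint* stem slots at least two
  pairs from helix ends (and clear of the helix-III motif), so every
  between-species pair carries exactly 2×`cbc_between` CBCs and
  conspecific pairs carry none — the delimitation premise by
  construction;
- hemi-CBCs, unpaired substitutions and INDELs (unpaired regions only)
  distinguish conspecific individuals without ever creating a CBC;
- loops and spacers are drawn from an A/C-only alphabet, among which no
  canonical or wobble pair exists, so the planted stems are the only
  favourable pairings and the template is provably the MFE under the
  package's model — planted truth and re-predicted structures coincide.

`generate_community` assigns isolates to species by a sequential urn
scheme whose expected richness obeys the log-series relation
E[S] = α ln(1 + N/α) (Fisher's alpha is the natural parameter of the
abundance model such surveys fit), splits segments evenly over sampling
events and the midrib/lamina regions, and yields one isolate per
infected segment.

What passing these tests shows — and does not.  The generator emulates
the *statistical shape* of a culture-based survey (planted CBC structure,
segment-level infection, log-series abundances), not its biology: no
PCR/sequencing error, no intragenomic ITS variation, no refolding
ambiguity of real Mfold-era structures, no taxonomic reference database.
End-to-end recovery of planted partitions therefore validates the
pipeline's logic, not the biological error rate on real cultures.

## Numerical choices and degenerate inputs

Energies are integer hundredths of kcal/mol internally, so all folding
comparisons are exact; equal-energy structures are ordered by energy then
dot-bracket for reproducibility.  Alignment and NJ tie-breaks are
deterministic (documented in the function pages).  Degenerate inputs
have defined behaviour rather than crashes: structures with no pairs
yield empty helix trees; singleton communities are rejected by indices
that are undefined for them; saturated distances are capped and flagged;
unclassifiable topologies are type 0; padding beyond the source sequence
is truncated and logged, never invented.

Problem sizes used in the shipped test-suite were chosen to keep the full
suite in the low minutes on one core: exhaustive folding oracles at
length ≤14 (1,000 cases), brute-force CBC scans on ≤6 records × ≤40
columns, 200 additive 6-taxon NJ recoveries, 100 seeded end-to-end runs,
1,000 random communities for estimator bounds — each one an instance of
the corresponding property at the size where its oracle is exact.

## Known limitations

- The folding energies are model energies; only topology-level
  conclusions should be drawn from them, and real-data workflows should
  prefer injecting structures from a dedicated folding engine.
- Progressive alignment has no iterative refinement; pathological indel
  patterns can misalign, which CBC counting then conservatively ignores
  (disagreeing pairedness contributes nothing).
- The greedy colouring beyond 16 records is an upper bound on the
  minimal species count and is flagged as inexact.
- Genus labels are an input: the package delimits within genera but does
  not place records taxonomically.
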