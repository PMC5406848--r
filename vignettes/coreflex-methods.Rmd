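---
title: "coreflex: methods, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coreflex: methods, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coreflex)
```

`coreflex` compares the genetic targets of adaptation in a laboratory
evolution experiment with sequence variation in nature. This vignette is the
package's own account of the models it implements, the conventions it
adopts where the underlying definitions are ambiguous, and the numerical
policies behind the statistics. Nothing here reports an empirical result;
all quantitative claims about the code are exercised by the test suite.

## 1. Core genome identification

A *panortholog* (core gene) is a single-copy gene with exactly one ortholog
in every genome of a collection. The pipeline identifies them in four
steps:

1. **All-vs-all similarity.** Every protein of genome A is aligned against
   every protein of genome B with end-to-end (Needleman–Wunsch) alignment
   under BLOSUM62 (gap opening 10, extension 0.5). Identity is matches
   divided by alignment columns. Hits below the identity and coverage
   thresholds (both 0.5 by default) are discarded. Because identity can
   never exceed min(len)/max(len) under global alignment, pairs failing
   that bound are skipped without aligning — a pure optimization with no
   effect on results. The scorer is pluggable: an external search program
   producing `query, subject, score, identity, coverage` rows can be
   substituted.
2. **Reciprocal best hits.** (a, b) is kept iff b is a's *unique*
   top-scoring hit and vice versa. A tie for the top score disqualifies the
   query: ties are exactly what recent duplications produce, and a
   conservative guard is preferable to an arbitrary tie-break.
3. **Groups.** Candidate families are connected components of the pooled
   RBH graph that contain exactly one gene per genome *and* form a clique —
   every cross-genome pair inside the component must itself be an RBH pair.
   The clique requirement (rather than mere connectivity) was a genuinely
   open choice; we chose it because connectivity alone lets one spurious
   edge chain two families together, and with a clique the later stages can
   treat every within-family pair as a validated ortholog pair.
4. **Best-local-hit guard.** No member may have a higher-scoring hit
   anywhere (including a within-genome paralog) than its group partner.
   This is the second duplication/transfer guard and mirrors step 2 at the
   group level.

The reference genome's genes inside any group form the core compartment;
all its other protein-coding genes are flexible. `L_core + L_flex` always
equals the reference coding length, and the partition is invariant to the
order in which genomes are supplied.

## 2. Amino-acid diversity, site partitions, divergence

Diversity adapts the classical nucleotide-diversity statistic to protein
alignments. For rows *i*, *j* of an alignment, let *c(i, j)* be the number
of columns where at least one of the two rows has a residue, and *d(i, j)*
the number of those columns where the symbols differ. A residue opposite a
gap **counts as a difference**, each gap column separately — an indel
spanning 10 residues contributes 10 differences even though it was probably
one event. Then

π_aa = mean over all n(n−1)/2 pairs of d(i, j) / c(i, j).

Three conventions required decisions:

* **Gap–gap columns** are skipped per pair. Whether the original analyses
  excluded them is not documented; exclusion is the only choice that keeps
  the per-pair denominator meaningful when both sequences lack a region.
* **Per-pair normalization.** We average per-pair per-site values rather
  than pooling differences and sites across pairs. Both are implemented
  (`normalization = "pooled"`); they coincide for gap-free alignments, and
  the per-pair mean is the default because it weights each sequence pair
  equally rather than weighting pairs by their aligned length.
* **A pair with zero compared columns** (possible only when two rows are
  gap-everywhere together) is an error naming the pair, not a silent NaN.

Site-partitioned diversity applies the same machinery to a target column
set (typically the alignment columns of residues mutated in the
experiment) and its complement. Interspecies divergence *d* is the same
statistic on a two-row alignment of orthologs from two species.

The built-in aligner is deterministic center-star progressive alignment:
every sequence is aligned pairwise to the longest sequence (ties broken by
name) and gap patterns are merged. This is adequate for the moderately
diverged single-copy families this pipeline analyses and keeps the package
dependency-free; pre-computed alignments (e.g. from a dedicated MSA tool)
can be loaded with `load_alignment()` and always take precedence, with an
exact ungapping check against the input sequences.

## 3. Mutation classification and site counting

Codon changes are classed by the bacterial genetic code (table 11;
ATG/GTG/TTG initiators translate as Met). A change creating a stop codon
is reported as `nonsense` but **counts as nonsynonymous in every tally**,
matching the convention of gene-level parallelism scores.

Sites at risk are counted by the equal-weight (Nei–Gojobori style)
convention: each of the nine single-nucleotide changes of a codon
contributes 1/3 of a site, synonymous iff it preserves the amino acid,
with stop-creating changes counted as nonsynonymous and no
transition/transversion weighting. `syn_sites + nonsyn_sites = 3 ×
n_codons` holds per gene (trailing stop excluded). The genome-wide ratio
ρ = Σnonsyn/Σsyn normalizes count-based dN/dS; because published analyses
often quote a fixed ρ, it is also accepted as a configuration constant
(default 3.22) so printed results can be reproduced exactly.

**Potential knockouts.** Small indels with length not divisible by 3,
IS-element insertions, and large deletions overlapping a gene are flagged
as potential knockouts; point mutations never are. Two boundaries are not
standardized anywhere and are package choices: "small" vs "large" indels
split at 50 bp (configurable), and a deletion overlapping several genes
flags each of them. Events within 5 codons of the stop are additionally
marked `near_terminal`, because a frameshift in, say, the penultimate
codon may leave a functional product.

**Independent events.** Repeated observations of one mutational event
(same `independent_event_id`) collapse to a single record before any
parallelism or enrichment counting; identical amino-acid changes arising
independently in different populations keep distinct ids and count
separately. Mutator context is an input column — deriving it requires
lineage reconstructions that are upstream of this package.

## 4. Selection statistics

* **Enrichment.** The headline statistic is the raw count ratio
  core/flexible — this is what the published tables print — with the
  length-normalized rate ratio `(core_n/L_core)/(flex_n/L_flex)` computed
  alongside. The p-value is the exact two-tailed binomial test of the core
  count against p₀ = L_core/(L_core+L_flex), using the minimum-likelihood
  two-sided rule (sum the probabilities of all outcomes no more likely than
  the observation).
* **G scores.** G = 2·O·ln(O/E), E = T·L/ΣL; G = 0 when O = 0 (the x·ln x
  limit). ΣE = T exactly.
* **Rank tests.** Spearman correlation uses average ranks for ties and an
  exact full-permutation p for n ≤ 8 (t approximation beyond). The
  Mann–Whitney U is computed by pair counting (ties score 1/2). Its exact
  two-tailed p is used within n_a·n_b ≤ 400: by direct enumeration of
  group assignments when there are at most ~2×10⁵ of them (this branch
  handles ties exactly), or from the exact tie-free U distribution
  otherwise; beyond the cap, a normal approximation with tie correction.
  The Wilcoxon signed-rank test drops zero differences, uses average ranks
  on tied magnitudes, and enumerates all 2ⁿ sign assignments for n ≤ 15.
  These caps were fixed in advance so that brute-force oracles remain
  feasible in the test suite.
* **Welch's t and Fisher's exact test** delegate to the standard R
  implementations (`t.test`, `fisher.test`), which match the required
  definitions exactly; a Fisher table with a zero margin is degenerate and
  reported as p = 1 with a flag.
* **Bootstrap median CIs** use the percentile method with a mandatory seed
  (default 10,000 resamples) and restore the caller's RNG state.

No multiple-testing correction is applied anywhere, deliberately mirroring
the analysis style this package reproduces.

## 5. Structure contacts

PDB ATOM/HETATM records are parsed (via bio3d, after a line-validation
pass that reports malformed coordinates with their line numbers); waters
are dropped, the first alternate location is kept, and chains are typed
protein / nucleic / ligand from residue names, with non-water hetero atoms
always treated as ligand atoms. A mutated residue is mapped through a
two-row alignment onto the structure chain — author residue numbering is
honored, and a residue opposite a gap yields an explicit unmapped result.
The contact statistic is the minimum Euclidean distance from any atom of
the target residue to any atom outside its chain (plus ligand atoms within
it); the interface criterion is inclusive, distance ≤ 8 Å. All atoms
present are used — crystal structures rarely include hydrogens, and no
side-chain-only filter is applied since none is documented for the
original analysis.

## 6. The synthetic-data generator

The generator exists so that every stage has inputs with known truth:

* **Pangenome** — by default 5 genomes, 20 core and 10 flexible families,
  ancestor lengths 40–80 codons, per-codon substitution probability 0.02
  (within-family amino-acid identity ≳ 0.9, safely above the 0.5 identity
  threshold, while between-family identity of random sequences stays far
  below it), in-frame indels with probability 0.05. Flexible families are
  present per genome with probability 0.6 and guaranteed absent somewhere.
  Sequence evolution is a star tree — independent divergence of each member
  from the family ancestor — because no downstream statistic uses tree
  shape.
* **Mutation table** — six nonmutator and six mutator populations; default
  event totals (194 and 6,473, with synonymous fractions 20/194 and
  1698/6473) mirror the scale of a 50,000-generation clone collection, and
  the default planted core enrichment r = 2.5 matches the rate ratio
  implied by the published compartment counts. Nonsynonymous events land on
  genes with per-bp probability proportional to r in the core; synonymous
  events are strictly length-proportional. Codon changes are drawn by
  rejection against the classifier, so generated `codon_from → codon_to`
  pairs always re-classify to their labels.
* **Essentiality table** — integer scores on the +3…−4 scale from
  compartment-specific distributions whose defaults put more mass on
  positive (essential) scores for core genes.
* **Toy structures** — parallel chains displaced perpendicular to their
  axis, so each planted minimum inter-chain distance is realized exactly.

All draws flow from one master seed through labelled sub-seeds per
artifact, making runs byte-identical for a fixed configuration and stable
under partial regeneration.

What passing on synthetic data does **not** show: the generator makes no
attempt to mimic real codon usage, GC content, operon structure, gene
families with genuine paralogy gradients, or population-genetic linkage.
Perfect core/flexible recovery on simulated families therefore validates
the orthology logic, not its robustness to the hard cases of real
pangenomes (recent paralogs at the identity threshold, partial genes,
contamination).

## 7. Pipeline, scale and reproducibility

`run_pipeline()` chains simulation → orthology → partition → family
alignment and diversity → mutation annotation → enrichment / dN/dS /
G scores → diversity and divergence comparisons → site-partitioned
diversity at mutated residues → essentiality and knockout cross-tabulation
→ structure contacts, writing one TSV per analysis plus a log of every
parameter that affects results (seed, thresholds, ρ, genetic code). Output
files are listed with md5 checksums, and identical configurations produce
identical checksums. The orchestration is exposed as R functions
(`validate_config()` accepts YAML or lists and reports all violations at
once) rather than a shell executable, since the package's users drive it
from R.

Default problem sizes — a 5-genome collection with ~30 families, hundreds
to a few thousand simulated mutation events, 200-replicate recovery
simulations in the test suite — were chosen as the smallest scales at which
every statistical property under test is comfortably resolvable.

## 8. Known limitations

* The built-in aligner is center-star, not iterative refinement; deep
  families with long indels deserve an external MSA tool via
  `load_alignment()`.
* Orthology is protein-level only: no synteny, no nucleotide-level calls,
  no explicit paralog trees.
* dN/dS is count-based with a single genome-wide ρ, not a per-gene
  codon-model estimate.
* mmCIF structures are not parsed; convert to PDB first.
* The Mann–Whitney "exact with ties" branch is limited by enumeration
  feasibility, as described above.
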