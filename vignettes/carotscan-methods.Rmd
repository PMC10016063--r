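---
title: "Detecting horizontally transferred carotenogenesis cassettes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontally transferred carotenogenesis cassettes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(carotscan)
```

## The problem

Carotenoid biosynthesis from geranylgeranyl pyrophosphate needs three
enzymatic steps — phytoene synthase (CrtB), phytoene desaturase (CrtI) and
a lycopene cyclase (here the heterodimeric CrtYc/d) — and β-carotene can
be cleaved to retinal by a 15-15′ oxygenase (Blh or Rpe65). In several
unrelated heterotrophic protists these domains occur fused into one
multidomain protein and, in phylogenies of each domain, the eukaryotic
sequences group *together*, nested inside clades of Actinobacteria,
Bacteroidetes and Archaea rather than beside their own photosynthetic
relatives. That combination — an all-eukaryote clade spanning several
supergroups, embedded in prokaryotic context — is the operational
signature of repeated horizontal gene transfer (HGT), and `carotscan`
implements the full desk-scale workflow for producing and reading it:
family curation, distance/NJ/bootstrap tree inference, midpoint rooting,
tree-guided taxonomic dereplication, fusion-architecture calling, a
disjunct-clade scan, and Beer–Lambert pigment quantification for the
accompanying wet-lab readout.

## Curation

**Length filter.** Within a homolog family with lengths $L$, a record of
length $\ell$ is removed iff $|\ell - \mathrm{median}(L)| > k \cdot
\mathrm{sd}(L)$. We use the *sample* standard deviation ($n-1$
denominator), the standard choice for the small families this filter sees,
and default $k = 1$ (one standard deviation from the median). The boundary
is inclusive-keep: removal requires being strictly *further* than the
bound, so the family `[50, 100, 150]` (sd exactly 50) keeps all three
records. The rule is deliberately *not* idempotent — re-running it
recomputes the sd on the reduced family and may remove more — so the
report carries the frozen `lower`/`upper` bounds for reproducible reruns.

**Fragment merging.** Domain searches can select two halves of one split
gene model as separate records. Groups of two or more hits sharing a
(`parent_id`, domain) pair are replaced by a single record holding the
*full* parent sequence, scored with the group's maximum bit score. How
split pairs are recognised upstream is a data-preparation question; the
explicit `parent_id` column is this package's convention for carrying that
information, and the simulator emits it for every fragment it plants.

**Gap trimming.** A column is kept iff its gap fraction is strictly less
than the threshold (defaults 0.90 and 0.99): at threshold 0.90 a column
with 9 gaps among 10 sequences is removed ($0.9 < 0.9$ is false), at 0.99
it is kept. The strict inequality mirrors the usual "retain positions
where less than X% of sequences contain gaps" phrasing. Comparisons use
the gap *fraction*, never `count < t*n`, to avoid floating-point boundary
artefacts.

## Tree inference

Likelihood tree inference is out of scope by design: the tree stage is a
distance pipeline whose every component has an exact independent oracle.

**Distances.** Pairwise deletion: for each pair, only columns gap-free in
both are compared; $p$ is the mismatch fraction, and the Poisson
correction is $d = -\ln(1-p)$. A pair with *no* comparable columns is an
error naming the pair (a replicate hitting this during bootstrap is
dropped and counted instead). Saturated pairs ($p = 1$) are capped at
$p = 0.999$ so matrices stay finite.

**Neighbor joining.** The Saitou–Nei algorithm with the standard
$Q$-criterion. Two determinism choices: input labels are canonicalised to
sorted order before the loop (otherwise floating-point summation order
would make the result depend on input row order), and $Q$-ties are broken
by the lexicographically smallest pair of cluster representatives (a
cluster is represented by its smallest tip label). Negative estimated
branch lengths — possible on non-additive inputs — are clamped to zero
with the total deficit recorded as an attribute; on additive matrices NJ
is provably exact and the test suite verifies recovery of topology and
branch lengths to $10^{-9}$ on 1,000 random trees.

**Midpoint rooting.** The root is placed at the midpoint of the longest
tip-to-tip path; ties between equally long paths are broken by the
lexicographically smallest tip pair, and a midpoint falling on an existing
node (tolerance $10^{-12}$, relative) roots there. Internally the tree is
handled as an undirected graph whose *edges* carry the support values, so
supports stay attached to their bipartition across re-rooting; when the
root splits an edge, both root-adjacent edges inherit that edge's support
(they represent the same split). A brute-force oracle — minimise the
maximum root-to-tip depth over every position on every edge — is checked
on 200 random 8-tip trees, and `phangorn::midpoint` serves as an
additional independent cross-check in the tests.

**Bootstrap.** Felsenstein column resampling: each replicate resamples
`n_cols` columns with replacement, rebuilds distances + NJ, and each
internal edge of the original tree is supported by the fraction of
replicates containing the same unordered bipartition. This is *not*
numerically comparable to SH-aLRT or ultrafast bootstrap percentages from
likelihood software; it is the classical nonparametric support on the
same $[0,1]$ scale the package uses for all supports (percent-scale
Newick labels are divided by 100 on ingest). The default of 1,000
replicates matches common practice; the end-to-end experiments use 100 to
keep 50-seed runs fast.

## Tree-guided dereplication

Redundant same-taxon sequences are removed *on the tree*: "sisters" are
interpreted strictly as cherries (two tips that are children of the same
node), and while any cherry shares a non-missing label at the chosen
rank, the first cherry in sorted order is resolved by dropping the
lower-scoring tip (ties drop the lexicographically larger id). The
resulting degree-2 node is suppressed by summing its two incident branch
lengths, which preserves tip-to-tip distances among survivors. Iterating
to a fixpoint (rather than a single pass) is a deliberate choice: it
makes a same-taxon caterpillar collapse to its single best-scoring tip,
which is the behaviour one wants from "one representative per taxon".
Same-taxon tips that are *not* cherries are retained — a documented
limitation of the sister-pair rule. The `derep_pipeline()` wrapper
rebuilds the tree between rounds (default 2; use 1 for small families),
since removing tips changes which pairs are cherries.

## Architecture calling

Per protein, hits are resolved greedily by descending bit score (ties:
N-terminal first); a hit is kept iff it overlaps every kept hit by at
most 20% of the shorter envelope — a conventional domain-calling
tolerance that permits the small envelope overlaps real profile matches
produce while rejecting duplicate calls. Envelope coordinates are 1-based
inclusive throughout. The architecture string joins domain names N→C with
`+`, and classification is an exact ordered-tuple lookup in a registry
whose defaults name the biologically attested patterns: trifunctional
`CrtI+CrtB+CrtYc/d`, quadrifunctional `CrtI+CrtB+CrtYc/d+Blh`, the two
bifunctional patterns `CrtB+CrtYc/d` and `CrtI+CrtYc/d`, and
`single_domain_<name>`. CrtYc and CrtYd are treated as the single token
`CrtYc/d`, as is usual when the heterodimer is modelled by one profile.

## The disjunct-clade scan

`scan_disjunct_clades()` formalises "unrelated eukaryotes grouping
together inside a prokaryotic lineage" as: a clade of a rooted tree, all
of whose tips are eukaryotic, spanning at least `min_groups` distinct
labels at the grouping rank, with support at least `min_support`. Only
*maximal* such clades are reported. Nesting is reported rather than
thresholded: each report carries the fraction of prokaryotic or viral
tips among its parent clade's other descendants
(`parent_context_foreign_fraction`), because "nested within" is a
description of context, not a crisp predicate — and giant viruses are
counted as foreign context since they are documented carriers of
carotenogenesis cassettes. For the same reason the end-to-end experiments
run the scan with `min_support = 0`: the question they ask is whether the
topology isolates the recipients, with support reported alongside.
Singleton clades count as monophyletic with support 1 by convention; the
root likewise.

## What the simulator emulates — and what it does not

`build_dataset()` generates the study condition the recovery experiments
use. Its defaults are fixed, not tuning knobs:

* **Species tree.** 40 species in 6 monophyletic groups — three
  prokaryotic (Actinobacteria, Bacteroidetes, Halobacteria: the classic
  donor-side assemblage) and three eukaryotic (Stramenopila, Alveolata,
  Obazoa), sizes 7/7/6/7/7/6. Topologies are Yule (uniform tip
  splitting), the simplest exchangeable bifurcating model; branch lengths
  are i.i.d. exponential with mean 0.3, giving moderate per-branch
  divergence ($1-e^{-0.2\cdot0.3}\approx6\%$ of sites) at the default
  substitution rate 0.2.
* **Families.** CrtI (500 aa), CrtB (300 aa), CrtYc/d (120 aa) form the
  transferred cassette, carried vertically by prokaryotes only; Rpe65
  (530 aa) is carried by everyone, supplying the vertical background.
  Sites evolve independently with per-branch mutation probability
  $1-e^{-rt}$ and uniform replacement among the other 19 residues — no
  indels, so the site-wise identity *is* the true alignment and the
  curation/tree stages can be tested without implementing an aligner.
* **The transfer.** One event: the cassette goes from one Actinobacteria
  tip into one recipient per eukaryote group (`post_transfer_scale`
  0.1). Each recipient's copy passes through one *shared* mutation round
  at the effective rate `subst_rate * post_transfer_scale` and then one
  independent round at the same rate. The shared round models the common,
  unsampled proximate donor lineage behind repeated transfers — the
  "ghost" donor — and is what gives the recipients a positive internal
  edge. Without it the sampled donor tip sits at the exact centre of a
  star between the recipients, and no method could consistently resolve
  them as a clade; with it, recovery is a fair test of the pipeline
  rather than of a tie-break. At scale 0 recipients are exact copies of
  the donor sequence.
* **Fusions and scores.** Recipients fuse their cassette N→C with a
  2-residue `GS` linker; ground-truth hits carry exact envelope
  coordinates, and the synthetic bit score is
  $\mathrm{length}\times(1-\mathrm{divergence\ from\ the\ domain\ root})$
  — monotone in completeness and conservation, which is all the
  dereplication tie-break needs from a score.
* **Curation workload.** 10% of single-domain records become length
  outliers (truncated to 40% or extended to 160%, safely outside the
  median ± 1 sd interval at these fractions) and 5% are split into two
  fragments sharing a `parent_id`.

Not emulated: indels and alignment uncertainty, rate heterogeneity across
sites or lineages, gene duplication and loss, codon structure, and
realistic profile-search score distributions. Passing the end-to-end
tests therefore shows the pipeline's logic is sound under its own model
assumptions; it does not certify performance on real alignments, where
alignment error and heterotachy add noise this simulator does not
produce.

## Numerical and degenerate-input choices

* Poisson distance cap at $p = 0.999$; NJ negative-branch clamping to 0
  (deficit logged); midpoint node-hit tolerance $10^{-12}$ relative.
* A 2-tip tree midpoint-roots to equal halves of the total path; an
  all-zero-length tree is an error (midpoint undefined).
* Dereplication down to a single tip constructs a minimal one-tip tree
  rather than failing, so the fixpoint is always reached.
* Spectra are looked up at the nearest sampled wavelength within 0.25 nm
  (half of the 0.5 nm sampling grid); negative zeroed absorbance clamps
  to 0 with a warning; `zero_spectrum()` is idempotent.
* All tables are tab-separated UTF-8 with headers; FASTA ids are the
  first header token with the remainder kept as description.

## Problem sizes

The shipped experiments use: 1,000 random 4–12-tip trees for NJ
recovery, 200 8-tip trees for the midpoint oracle, 1,000 random
tree/taxonomy/score instances plus 200 caterpillars for dereplication,
500 random alignments for trimming, and 50 seeds of the 40-species
default condition (100 bootstrap replicates each) for end-to-end
recovery. These sizes give exact checks where the property is exact and
tight Monte-Carlo bounds elsewhere, while a full run stays in the
low minutes on one core.

## Known limitations

* NJ and Felsenstein bootstrap stand in for likelihood inference; on
  real, saturated alignments the distance pipeline will be less accurate
  than the ML tools it replaces at desk scale.
* Dereplication only sees cherry redundancy; paraphyletic same-taxon
  groups larger than repeated cherries can retain more than one
  representative.
* The scan requires exact monophyly of the eukaryote clade; a single
  intruding prokaryote tip splits a report in two (the context fraction
  is the diagnostic to watch in that case).
* The simulator's bit scores and fragment conventions are synthetic; real
  profile-search output needs only the documented columns, but its score
  scale is unrelated.
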