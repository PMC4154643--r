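---
title: "Modeling heteroduplex DNA tracts in meiotic recombination products"
author: "hdnaTracts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling heteroduplex DNA tracts in meiotic recombination products}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdnaTracts)
```

# The scientific problem

Meiotic recombination starts with a programmed double-strand break (DSB) on
one chromatid that is repaired using the homologous chromosome as template,
yielding a crossover (CO) or noncrossover (NCO).  Repair intermediates
contain heteroduplex DNA (hDNA): duplex regions whose two strands derive
from different parents, so that every polymorphism inside the region is a
base–base mismatch or a small insertion/deletion loop.  Different repair
mechanisms leave different hDNA architectures in the final products:

* **SDSA** (synthesis-dependent strand annealing): one 3' end invades the
  homolog, is extended, and re-anneals to the other break end.  NCO only;
  a single hDNA tract confined to one side of the break (*cis*), with a
  nick at the unligated junction.
* **dHJ resolution**: a ligated double Holliday junction is cleaved.
  Cutting different strands at the two junctions gives a CO; one of the two
  cleavage orientations leaves a single hDNA tract, the other leaves a
  full gene-conversion tract (both strands donor) adjacent to the hDNA.
  Nicks are left at the cleavage points.
* **dHJ dissolution**: helicase plus topoisomerase unwind the joint
  molecule without cutting.  NCO with *trans* hDNA — donor sequence on
  opposite strands on the two sides of the break — and, distinctively,
  **no nicks**.
* **Two-end engagement**: both resected ends engage the same homologous
  chromatid and are extended by synthesis, leaving unligated (nicked)
  junctions.  Helicase disassembly yields an NCO with trans hDNA and
  nicks; nuclease cleavage across from the existing nicks yields a CO with
  a single hDNA tract spanning the break and **no** full-conversion tract.
  Two-ended SDSA produces the same observable NCO pattern and is provided
  as an alias model; the two mechanisms cannot be distinguished from
  recovered products.
* **Gap repair**: the break is widened to a gap before repair; synthesis
  across the gap copies the donor on both strands, giving full conversion
  with no hDNA.

hDNA is normally erased by mismatch repair (MMR) before it can be observed.
The package models the two relevant repair layers: canonical long-patch MMR
(nick-directed, co-directional across a whole hDNA region) and a
short-patch pathway with the excision geometry of nucleotide excision
repair (NER).  Knocking out canonical MMR (*Msh6*) exposes patchy
short-patch repair; additionally knocking out NER-dependent short-patch
repair (*Xpc*; *Msh6*) leaves hDNA intact, which is the observational
regime in which tract architecture can be read directly.

The package provides: a strand-level simulator of all of the above; the
repair overlays; a purine-selection observation model; an analysis layer
that reconstructs tracts from per-strand marker calls, classifies CO/NCO
and cis/trans, scores conversion/restoration/unrepaired outcomes, and
tabulates co-repair of adjacent marker pairs; and a truncated-exponential
tract-length estimator.

# Data representation

A locus is a half-open integer interval with a `MarkerMap` of polymorphic
sites (coordinates relative to an anchor; they may be negative).  The two
selection sites — the mutations used to select wild-type recombinants —
are themselves polymorphisms and appear both as marker rows and in a
dedicated slot recording which parent is mutant at each site.

A `RecombinantDuplex` stores each strand as a mosaic of parental-origin
segments tiling the locus, plus per-strand nick positions and ground-truth
metadata (model, DSB, CO/NCO label).  hDNA is simply the set of positions
where the two strands' origins differ; all simulator and repair operations
are interval rewrites.  Only the recovered chromatid is simulated: the
assay recovers one chromatid per meiosis, so no four-strand tetrad
bookkeeping is attempted.

An `ObservedRecombinant` is the sequencing-level view: per-strand parental
calls at each unmasked marker.  Sequencing is modeled error-free (bulk plus
clone sequencing is treated as exact); coverage gaps enter only through an
explicit mask.

# The packaged marker map

The published supplementary marker list is not redistributed; the fixture
map (`rosyMarkerMap()`, also shipped as
`inst/extdata/rosy_markers_synthetic.tsv` and labeled synthetic) matches
the described spacing statistics of the assayed locus instead: selection
sites at -468 and +3312 (left site mutant on parent P2, right on P1, so the
recipient P1 chromatid carries the downstream mutation), about thirty
markers over roughly 5 kb with several adjacent pairs closer than 21 bp,
two small indels, sparse markers around the downstream selection site, and
denser SNPs around the upstream one.

The real assay reads the crossover status of a recombinant from recessive
markers far outside the locus.  The fixture map emulates this with two
distal flank markers placed 5 kb beyond the gene-region markers: DSB
positions default to the gene region (breaks occur throughout the gene,
with no hotspot), and the probability that an hDNA tail reaches a flank
marker is of order $0.99717^{5000} \approx 10^{-6}$, so the flanking phase
effectively always resolves.

# Simulator parameters

* **Resection and synthesis tract lengths** are geometric with a 1 bp
  minimum and per-bp continuation probability 0.99717 on each side
  (independently), i.e. a mean scale of $1/(1-p) \approx 353$ bp.  No
  resection-length distribution is published; the geometric choice matches
  the memoryless extension model underlying the tract-length estimator, so
  simulated tract scales and estimator prior agree by construction.
  Left/right parameters are independent to allow asymmetric resection or
  capture; defaults are symmetric.
* **DSB positions** are uniform over the configured region (default: the
  gene region).  Uniformity is a default, not a claim.
* **`resolutionBias`** (default 0.5) is the probability that dHJ
  resolution uses the orientation yielding a single hDNA tract; the
  classical model takes the two orientations as equally likely.
* **`engagementCOProb`** (default 0.5) is the probability that a two-end
  engagement intermediate is nicked into a CO rather than disassembled
  into an NCO.

# Mismatch repair overlays

**Canonical MMR** repairs each contiguous hDNA region that carries at
least one nick within the region or at its boundary: the nicked strand is
excised and rewritten from the other strand across the whole region, so
all mismatches in the region are repaired co-directionally.  When both
strands carry qualifying nicks, the choice is random.  Conversion versus
restoration is an emergent outcome of which strand is excised, not a
separate parameter.  Nick-free regions — dissolution products — pass
through untouched.

**Short-patch MMR** visits mismatched markers in random order.  Each
still-unrepaired mismatch triggers an excision event with probability
`repairProb` (default 0.82, the overall repair frequency observed in
canonical-MMR mutants); the excised strand is drawn with `strandBias`
(default 0.5, so isolated mismatches convert or restore with equal
probability), and window arms are drawn uniformly from 22–24 nt on the 5'
side and 5–6 nt on the 3' side of the lesion.

A deliberate design choice concerns window *placement*.  A rigidly
anchored asymmetric window, with the excised strand chosen at random,
would cover a neighbour 6–21 bp away in only half of the events, giving a
co-repair probability of 3/4 for close pairs even at `repairProb = 1`.
We instead model placement as processive: an excision event co-excises
every still-unrepaired mismatch within `w5 + w3` (27–30) bp of the
triggering lesion, reflecting the positioning flexibility of the excision
machinery over a patch of fixed length.  This makes two clean properties
hold exactly: pairs closer than 27 bp with `repairProb = 1` are always
co-repaired (one patch covers both), and pairs farther apart than 30 bp
are repaired in strictly independent events.  For distant pairs with
unbiased strand choice the counted-pair co-repair fraction has the closed
form
$$\Pr(\text{co} \mid \text{counted}) =
  \frac{r^2/2}{1-(1-r)^2} = \frac{r}{2(2-r)} \approx 0.347
  \quad (r = 0.82),$$
the dotted independence line of the published co-repair figure, and close
to the observed 36% for distant pairs.

Genotypes compose the layers: `wild_type` runs canonical then short-patch
repair; `Msh6` short-patch only; `Xpc_Msh6` nothing (an optional residual
repair probability, default 0, accommodates e.g. maternally deposited
protein).  Per-mismatch-type repair efficiencies are deliberately uniform:
the observed spectrum shows all mismatch types repaired with similar
efficiency.  Whether short-patch repair is biased toward conversion or
restoration is not known; the default is unbiased.

# Selection and observation

Purine selection kills larvae without gene function.  After replication
each strand founds its own cell lineage and the gene product acts
non-cell-autonomously, so a duplex survives if **at least one single
strand** carries the wild-type allele at both selection sites — mosaics
whose hDNA spans a mutant site survive.  Selection is monotone in
wild-type content and enriches for longer NCO tracts, because an NCO on
the recipient chromatid is recoverable only if its tract spans the
selection site and plants the donor (wild-type) allele there; COs between
the two mutant sites are recoverable regardless of tract length.

# Tract reconstruction conventions

* Marker states derive from the two strand calls: heteroduplex when they
  differ.  CO/NCO is read from the outermost markers, which must both be
  homoduplex.
* A tract is a maximal run of non-background markers (heteroduplex or
  converted) bounded by background homoduplex markers.  For NCOs, runs
  separated by at most one interior background marker are merged, so a
  restoration flanked by tract markers stays inside the tract (the
  observed patchy-tract pattern); restorations at tract edges are
  invisible, exactly as in the real assay.  Counting rules therefore run
  over observable sites only.
* Each tract carries a minimum span (outermost included markers; the
  marker footprint for single-marker tracts) and a maximum span (nearest
  excluded flanking markers, or the locus bound at the map edge).
  Display bounds use the halfway-point convention: a tract end is drawn
  midway between the last included and first excluded marker.
* cis/trans uses strand-phase runs of the heteroduplex markers only, never
  an assumed DSB position; tracts with fewer than two heteroduplex markers
  are undetermined and excluded from trans/cis tallies.
* Adjacent-pair co-repair: co-repaired when both converted or both
  restored; not co-repaired when one converted and one restored, or one
  repaired and one not; both-unrepaired pairs are not counted.
* For crossover tracts the two flanks disagree; each marker is scored
  against the flank of its nearer tract edge.

# Tract-length estimation

Tract lengths are modeled as exponential with per-base extension
probability $p$ ($\lambda = -\ln p$; default $p = 0.99717$, a value
derived previously for gene-conversion tracts at this locus).  A tract
with inclusion bound $a$ and exclusion bound $b$ is estimated by the
conditional expectation of the exponential truncated to $[a, b]$:
$$\hat L = \frac{1}{\lambda} +
  \frac{a e^{-\lambda a} - b e^{-\lambda b}}
       {e^{-\lambda a} - e^{-\lambda b}}.$$

We use the truncated-distribution *expectation*, not the mode: the mode of
a truncated exponential is always the lower bound $a$, which is not a
useful "most likely length".  Whether the original tract-length software
returns the expectation, the mode, or a posterior summary is not
documented; the expectation interpretation is recorded here as this
package's choice.  The continuous exponential is used instead of the
discrete geometric because for $p$ this close to 1 the two differ by under
1 bp while the continuous closed form is exact and fast; a discrete-sum
reference is kept in the test suite as an oracle.  Single-marker tracts
use the same formula with $a$ equal to the marker footprint.  Numerically,
the estimate is computed via `expm1` in the shifted form
$1/\lambda + (a - b e^{-\lambda d})/(1 - e^{-\lambda d})$, $d = b - a$,
with the midpoint returned when $\lambda d < 10^{-9}$ and $a$ when
$a = b$ — the correct uniform and degenerate limits.

Trans tracts are split into their two phase runs, each treated as an
independent tract (each half has the same predicted origin as a single cis
tract); the inner boundary sits at the halfway point between the facing
heteroduplex markers of the two runs.  Conclusions from simulated
length comparisons are stable as $p$ varies over $[0.990, 0.999]$, the
documented sensitivity range.

```{r estimator}
estimateTractLength(a = 100, b = 1000)            # default p = 0.99717
estimateTractLength(a = 100, b = 300, p = 0.9999) # near the uniform limit
```

# Statistics

The two-sided Fisher exact test is computed by direct hypergeometric
enumeration with a relative tie tolerance of $10^{-7}$ (tie handling
changes the two-sided p on degenerate tables, so the tolerance is fixed).
`runPaperTables()` applies it to the three published 2x2 comparisons.
`binomialZeroProbability()` exposes the closed form $(1-q)^n$ for the
probability of detecting zero of $n$ expected events.  Tract-length
comparisons default to a Welch t test (unpaired groups) or a paired t test
(the short and long halves of trans tracts come from the same event), with
a seeded permutation alternative for both; the published length
comparisons do not name their test, so these defaults are an
interpretation, not a reproduction.

# What the generator does and does not emulate

The generator reproduces the *structural* signatures of each mechanism —
strand-level hDNA architecture, nick placement, conversion adjacency,
selection mosaicism — under idealized conditions: error-free sequencing,
no PCR recombination artifacts, exactly one DSB per chromatid, no
multi-chromatid intermediates, sister-template switching, heteroduplex
rejection, or crossover interference, and no per-position DSB landscape
beyond a uniform default.  Passing tests therefore demonstrate internal
consistency of the mechanistic reasoning (e.g. that frequent trans hDNA
excludes pure one-ended SDSA), not agreement with any particular fly
dataset.  Published per-event tract maps and the 710/773 bp mean tract
lengths depend on per-clone marker-inclusion data available only
graphically, and are out of scope.

# Problem sizes and determinism

All simulations are seeded and deterministic; an experiment's TSV outputs
are byte-identical across runs with the same configuration.  The shipped
checks use problem sizes chosen to make binomial sampling error small
relative to the effects tested — typically 400–2,000 products per model
signature, 10,000 marker pairs for co-repair fractions, and 5,000 meioses
for the selection-enrichment comparison.

# Known limitations

* Second-end capture versus second-end invasion (two-end engagement
  versus two-ended SDSA) are observationally identical here, as in the
  assay; the alias model exists so mixtures can be labeled honestly.
* The CO/NCO classifier requires resolved flanking markers; with the
  packaged map the unresolved fraction is negligible but not exactly zero.
* Tract merging across interior background markers uses a one-marker
  gap by default; data with heavy restoration patchiness may warrant a
  larger gap, at the cost of occasionally fusing independent tracts.
* The binomial zero-detection probability is exposed as a closed form;
  reported values for it in the literature depend on an unstated
  per-event detection probability and are not reproduced.
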