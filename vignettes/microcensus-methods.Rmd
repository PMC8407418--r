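---
title: "Methods: quantifying rare ultrasmall microbes in size-fractionated metagenomes"
author: "microcensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying rare ultrasmall microbes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcensus)
```

# The measurement problem

Candidate Phyla Radiation (CPR) bacteria and DPANN archaea have cell
diameters small enough to pass a 0.2 µm filter and genomes of roughly 1 Mb.
In soil they appear to be members of the rare biosphere: on the order of
10⁻⁵ % of community cells, which at a typical soil density of 10⁹ microbial
cells per gram is 1–100 cells per gram. At that abundance a bulk shotgun
metagenome at tens of Gbp leaves their genomes below 1× expected coverage,
so they are effectively invisible to assembly. Sequencing the 0.2 µm
filtrate concentrates them 100–1,000-fold in relative abundance, enough to
assemble draft genomes and ask quantitative questions: how enriched is each
genome, how abundant was it in the original soil, is the genome complete,
what can it metabolize, would amplicon surveys have seen it, and is its
terminal-oxidase operon collinear with the canonical reference?

`microcensus` implements that chain of analyses as composable functions plus
a simulator that generates paired bulk/concentrate datasets with known
ground truth, so every stage is testable without any external sequencing
data.

# Coverage and abundance model

Per-scaffold profiles are computed from samtools-depth-style tables (scaffold,
1-based position, depth; zero rows optional — both dialects are read and give
identical profiles). Mean depth averages over *all* positions of the
scaffold, so scaffold lengths must come from a lengths table or FASTA, never
inferred from the depth file (the zero tail is ambiguous there). Breadth is
the fraction of positions with depth ≥ `breadth_min_depth`; the default of 1
(any coverage counts) is a choice, exposed as a parameter, since mapping
stringency conventions vary.

Two relative-abundance flavors are kept deliberately distinct:

- **base fraction** — depth × length over its sample total: the share of
  sequenced bases. Used for per-scaffold enrichment, where the measured
  quantity is sequence representation.
- **cell fraction** (bins) — bin mean depth over the total of bin mean
  depths. Depth is proportional to genome copy number, so this is the
  organism-level abundance, and it is what the census consumes.

Bins aggregate scaffolds by length weighting: bin mean depth is
Σ(depthᵢ·Lᵢ)/ΣLᵢ and bin breadth is covered bases over total bases.

# Enrichment with an honest detection limit

The enrichment factor of a unit is its concentrate relative abundance over
its bulk relative abundance. For these organisms zero bulk abundance is the
*expected* case, and a pseudocount would silently convert "not detected"
into an arbitrary number. Instead the bulk abundance is replaced by an
explicit detection floor — by default the base fraction contributed by a
single read, read_length / total mapped bases — and the resulting ratio is
flagged as a lower bound. Per-bin summaries use medians and quartiles over
the finite values only (robust to fragmented-scaffold noise, and matching
the boxplot presentation these experiments use); lower bounds are counted,
never averaged in.

# The census model

The default census is deliberately minimal: cells/g = cell fraction ×
N_total, with N_total = 10⁹ cells per gram. It reproduces the arithmetic
chain exactly: a lineage at 10⁻⁷ of the community is 100 cells per gram and
10⁻⁵ % of cells. An alternative DNA-mass model converts a base fraction into
genome copies per gram via the extraction yield and the mass of a base pair
(650 g·mol⁻¹ / Avogadro ≈ 1.079 × 10⁻²¹ g), under a one-genome-per-cell
assumption; it is provided because absolute-abundance arguments are
sometimes anchored to DNA yield rather than cell density. Estimates below
one cell per gram are reported as-is with a `sub_unity` flag — rounding them
would hide exactly the regime of interest. Estimating N_total or yield from
data is out of scope.

# Genome QC definitions

Completeness is the percentage of a single-copy-gene set present at least
once; contamination is the percentage present in two or more copies. The
duplication-based contamination notion (CheckM-like, restricted to the set)
is a definition choice, made explicit and configurable (`contamination_mode
= "excess_copies"` counts copies minus one instead). Matching is exact after
case-folding, and two identical hit rows count as two copies — deduplication
is the annotator's responsibility. The retention filter is strict on both
sides (completeness > 70, contamination < 10), so boundary bins are
rejected. The packaged default marker set is a 43-identifier
ribosomal-protein-centric reconstruction appropriate for reduced CPR-like
genomes; it ships as an editable text file and any set can be substituted.

# Metabolic profiles

Marker presence and pathway completeness are identifier-based: upstream
annotation emits gene symbols or EC numbers and the panel maps them through
alias lists (e.g. EC 3.6.1.1 → inorganic pyrophosphatase). Pathways are flat
gene sets scored as percent of members present; boolean KEGG-module logic is
a non-goal because the target presentation is a simple percent-completeness
heat map. The shipped pathway memberships (F-type ATPase, TCA, AA, Lip, Pur,
Pyr) are reconstructions of standard definitions and are clearly marked as
such in the panel file.

# In-silico PCR

A primer site matches a window if the Hamming mismatch count is ≤ k, where a
primer IUPAC code matches any base in its expansion. Two degenerate-subject
rules are resolved conservatively for detectability claims: subject N never
satisfies a primer position (it counts as a mismatch), and other subject
ambiguity codes match iff the expansions intersect. A sequence is detectable
iff a forward site and a reverse-complement-correct reverse site occur in
amplifiable orientation with a product length (inclusive of both primer
footprints) inside the pair's range; both template orientations are checked,
making detectability invariant under reverse complement. Default k = 0 with
a documented 0–3 range, and no 3′-anchor rule by default — both are
conventions, not facts about any particular assay, so they are parameters.
Hit positions are reported 1-based, consistent with the GFF3 convention used
elsewhere in the package.

# Operon synteny

Gene-order conservation against the E. coli K-12 *cyoABCDE* reference is
scored as LCS(cluster labels, reference)/|reference| — a gene-order
comparison, not a sequence alignment. Clusters chain same-scaffold genes
with intergenic gaps ≤ 500 bp (configurable; no published chaining rule
exists, and assembly fragmentation motivates the explicit `fragmented`
class, assigned at genome level when the reference labels split across
clusters). Minus-strand clusters are read in transcriptional order.
Classification ties are resolved by a stated rule: `rearranged` requires at
least two shared labels whose relative order disagrees with the reference;
otherwise an incomplete cluster is `partial`.

# The simulator and what it does (not) emulate

`community_spec()`/`build_community()` draw log-normal cell abundances,
flag an ultrasmall subset, down-weight that subset in the bulk sample by a
rarity factor (default 10⁻⁴) so sub-1× bulk coverage is reachable at
realistic sequencing effort, and plant per-genome fold-enrichments drawn
from the 100–1,000 range. Ultrasmall genome lengths are scaled by 0.3
relative to the common length draw, mirroring ~1 Mb CPR genomes against
typical 3–4 Mb bacteria. Coverage is independent per-base Poisson — the
Lander–Waterman regime, giving expected breadth 1 − e^(−c) at depth c —
because the analysis consumes only depth and breadth statistics, never read
identity. Sequences, when emitted, have uniform base composition.

Concentrate composition follows the filtration physics: ultrasmall mass is
bulk fraction × planted enrichment; other genomes contribute bulk fraction ×
`concentrate_capture_of_large`; masses are renormalized. The default capture
of 0 models perfect size exclusion, under which the concentrate contains
*only* ultrasmall genomes and their realized relative-abundance enrichment
is far larger than the planted factor (the truth table records both). Real
concentrates are not like that: they retain abundant non-target DNA
(fragments of lysed large cells, viruses, mobile elements), which is
precisely why observed enrichment lands in the 100–1,000× range while
target genomes stay a minority of the concentrate. The recovery experiments
in the tests and the acceptance script therefore use capture = 0.99 — a
background-dominated concentrate — under which realized enrichment equals
the planted fold-change to within a fraction of a percent.

Problem sizes for the packaged experiments were chosen to make Monte Carlo
error negligible relative to the tolerances while keeping simulations cheap:
genomes of 50–150 kb (ultrasmall 15–45 kb), 50 genomes, and sequencing
effort solved via `seq_bases_for_depth()` so the shallowest planted genome
reaches exactly 2× (bulk) and 20× (concentrate) expected depth. At those
depths the relative standard error of a genome's mean depth is below 1 %,
so recovered enrichment sits within ~1 % of truth against a 10 % acceptance
band.

What passing these tests shows — and what it does not: the pipeline's
estimators are unbiased and correctly normalized under Poisson coverage with
known composition. Real data add mapping bias, conserved-region cross-mapping,
GC-dependent coverage, strain variation and extraction bias, none of which
the simulator emulates; results on real metagenomes inherit those caveats.

# Numerical and degenerate-input choices

- Abundance normalizations are exact ratios; per-sample sums are asserted to
  1 within 1e-9 in the tests.
- An all-zero sample yields abundances flagged `undefined` (NA), never 0/0.
- Enrichment with both abundances zero is an error, not NA — the caller must
  decide what such a unit means.
- Expected depths conserve sequenced bases exactly: Σ depth·L = seq_bases.
- All randomness flows from integer seeds through per-component derived
  sub-seeds, so outputs are byte-identical under a fixed seed and invariant
  to evaluation order.

# Interfaces

Every stage reads and writes plain text: depth TSV (both zero-row dialects),
lengths TSV or FASTA, bin TSV, gene-hit TSV, GFF3 (1-based inclusive,
labels from `gene=`/`product=` attributes via a synonym table), primer TSV,
and JSON for truth/manifest/summaries. `run_pipeline()` executes the stages
in dependency order with a single seed and writes a manifest (seed, package
version, MD5 checksums) sufficient to re-run byte-identically; the thin
CLI wrapper in `inst/scripts/microcensus.R` exposes the same operations as
shell subcommands.

```{r pipeline-example, eval = FALSE}
run_pipeline(list(community = list(n_genomes = 8, n_ultrasmall = 2,
                                   genome_length_bp = c(2e3, 5e3),
                                   seq_bases_bulk = 4e5,
                                   seq_bases_concentrate = 4e5,
                                   concentrate_capture_of_large = 0.9,
                                   ultrasmall_rarity = 1e-2)),
             outdir = tempfile("microcensus_run"), seed = 11)
```

# Known limitations

- Read placement, sequencing error, chimeras and mapping ambiguity are not
  simulated; the Poisson model is the stated scope.
- The census assumes one genome copy per cell and takes N_total as given.
- Primer screening is purely combinatorial; thermodynamics and PCR bias are
  out of scope, so "detectable" means "sites present under the mismatch
  rule", an upper bound on real amplification.
- Synteny classification depends on upstream annotation quality; it never
  searches for homologs itself.
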