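---
title: "Assessing COI barcode diversity: models, thresholds and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing COI barcode diversity: models, thresholds and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coidiv)
```

## The problem

DNA barcoding identifies specimens from a short standard marker — for
animals, a ~650 bp fragment of the mitochondrial cytochrome *c* oxidase
subunit 1 gene (COI). The approach works when divergence between species
clearly exceeds divergence within species (the "barcoding gap"). Assessing
that gap across a taxonomically structured data set — hundreds of species
spanning many genera and families — requires a chain of steps, each with
its own pitfalls: sequence quality control (length, stop codons, indels,
nuclear pseudogene copies), distance estimation, partitioning of pairwise
divergences by taxonomic rank, tree-based monophyly checks, threshold
clustering into molecular operational taxonomic units (MOTUs), correction
for unequal sampling of taxa, and compositional analysis. `coidiv`
implements this chain as tested, reusable functions, together with a
synthetic data generator that provides ground truth for every screening
step.

## The distance model

Divergence is measured with the Kimura 2-parameter (K2P) distance, the de
facto standard in barcoding. With $P$ the proportion of transitional
differences (A↔G, C↔T) and $Q$ the proportion of transversional
differences among compared sites,

$$ d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q). $$

Sites at which either sequence carries a gap or an IUPAC ambiguity letter
are excluded pair by pair (*pairwise deletion*), never column-wide, and no
rate-heterogeneity correction is applied (uniform rates among sites).
Distances are held internally as fractions; report layers print percent.
When a log argument is non-positive (a saturated pair) the distance is
undefined and propagated as `NA`, excluded and counted in summaries rather
than raised as an error — an exception is raised only where an operation
cannot proceed at all (a pair with zero comparable sites, or an `NA` entry
reaching the strict neighbor-joining builder).

```{r k2p}
k2p_distance(count_site_differences("AAGGCCTT", "AAGACCTA"))
```

## Trees, monophyly and clusters

`build_nj()` implements Saitou–Nei neighbor joining with two deterministic
conventions: ties in the Q-criterion are broken by the first minimal pair
in current node order, and negative branch lengths (possible on
non-additive input) are clamped to zero so patristic distances stay
metric-like. On additive matrices the reconstruction is exact; the test
suite verifies `patristic_matrix(build_nj(D)) == D` to $10^{-9}$ on random
additive matrices, and cross-checks topologies against an independent NJ
implementation.

Monophyly of a species is defined as clade exclusivity on the rooted tree:
the smallest clade containing all of the species' records contains no
others. Because rooting affects clades and barcode trees have no natural
outgroup, trees are midpoint-rooted before monophyly calls (the choice is
exposed, not hardwired into the monophyly test itself).

MOTUs are single-linkage connected components: records joined when a chain
of pairwise distances, each *strictly* below the threshold, connects them.
The default threshold is 2% K2P, the conventional barcode limit for
intraspecific divergence; strictness means a pair at exactly the threshold
is split, and a zero threshold yields all-singleton clusters.

## Quality control and numt screening

COI is protein-coding, so genuine mitochondrial copies translate without
internal stop codons under the invertebrate mitochondrial code (NCBI
table 5: AGA/AGG = Ser, ATA = Met, TGA = Trp; stops TAA/TAG only). Records
are removed when shorter than 500 ungapped bases, when their best reading
frame (fewest stops over the three offsets, ties to the smallest offset)
still contains a stop, or when they carry interior alignment gaps. A
record failing several filters is tallied once, under the first reason in
a fixed order, so QC reports are deterministic and conserve counts.

Three numt/misidentification heuristics flag surviving records:
conspecific K2P above 10%; GC content deviating from the family mean by
more than 3 family standard deviations (families with fewer than 5 records
fall back to the data-set-wide mean/SD); and a terminal NJ branch longer
than 5 times the median terminal branch. The 10% ceiling is a stated
convention of barcode curation; the 3-SD and 5×-median rules are this
package's own quantifications of "aberrant composition" and "unusually
long branches" — deliberately scale-free, deterministic, and exposed as
configuration (`gc_sd`, `branch_factor`) rather than claimed as
reconstructions of any particular study's visual judgement.

## Sampling-bias validation

Unequal representation of taxa biases a raw intraspecific-distance
distribution: a heavily sampled, diverse species contributes quadratically
many pairs. The validation layer therefore compares four distributions:
the full data set (A) versus the data set with flagged species removed
(B), crossed with raw pairwise values (R) versus one mean per multi-record
species (M). Mann–Whitney U tests (exact by enumeration for combined
samples of at most 12 without ties; otherwise the normal approximation
with tie and continuity corrections) compare A_R vs B_R, A_M vs B_M,
A_R vs A_M and B_R vs B_M, alongside the fraction of intraspecific values
strictly below 3%. The report returns statistics and p values with the
nominal alpha; it deliberately hardcodes no verdict and applies no
multiplicity correction across the four tests, leaving interpretation to
the caller. Species flagged as problematic are those spanning two or more
threshold clusters (putative cryptic diversity), failing monophyly, or
involved in a congeneric pair below the threshold.

Before any of this, taxon representation is equalized by capping records
at 10 per species, drawn uniformly without replacement in species-label
order from a private seeded RNG stream — reproducible, and without
disturbing the caller's RNG.

## Composition analysis

GC content is computed over unambiguous bases only, on sequences trimmed
to their 5'-most 500 ungapped bases so heterogeneous-length records are
compared over a homologous window. Codon-position GC is pooled within each
sequence and then averaged across sequences, so the reported ±SE reflects
between-sequence dispersion; whether to pool or average was genuinely
open, and averaging was chosen to match per-sequence summary conventions.
Composition tables are sorted by ascending mean GC. The
transition/transversion ratio R sums per-site discordant pairs — a site
with base counts $(n_A, n_C, n_G, n_T)$ contributes
$n_A n_G + n_C n_T$ transition pairs and $(n_A+n_G)(n_C+n_T)$
transversion pairs — which equals the sum over all record pairs at a
fraction of the cost.

## The synthetic generator

The generator emulates the structure the analysis assumes, so every
screening rule can be tested against known truth.

**Tree.** A nested, ultrametric-style taxonomy: individuals of a species
coalesce at depth $d_S/2$, species of a genus at $d_G/2$, genera of a
family at $d_F/2$, families at $d_O/2$; each node height carries
multiplicative log-normal jitter ($\sigma = 0.2$) and is clamped above its
children. Expected pairwise path lengths therefore equal the rank targets.
Defaults ($d_S = 0.5\%$, $d_G = 15.5\%$, $d_F = 22.3\%$, $d_O = 26.1\%$)
follow the order-level K2P means typical of decapod COI surveys; sequence
length defaults to 657, the classic Folmer-region length.

**Sequences.** Evolution is K80-style transition-biased with
position-class stationary frequencies (an HKY-type model): positions 1
and 2 use fixed COI-like compositions (GC ≈ 51% and 43%), position 3 uses
a family-specific composition hitting that family's GC3 target (defaults
evenly spaced over 8–32%, echoing the spread observed across decapod
families). A pure K80 process was considered and rejected: its stationary
composition is uniform, so family GC targets would decay with depth and
composition-recovery tests would be meaningless. With uniform frequencies
the model reduces exactly to K80, which is how the transition/transversion
calibration is tested. The `kappa` parameter is the *expected
transition/transversion count ratio* (the quantity the `tstv_ratio`
estimator reports); the internal rate ratio is derived from it and the
stationary frequencies. Rates are normalized to one expected substitution
per site per unit branch length, uniformly across position classes, so
tree path lengths are directly comparable to K2P estimates. Substitutions
that would create an in-frame stop are redrawn from the transition row
restricted to {C, T} at the third base — this always breaks the stop and
preserves the GC target in expectation (a naive 50/50 C/T redraw
measurably inflates GC3). Family GC targets are imposed by redrawing third
positions at each family founder; this adds between-family divergence
beyond $d_O$, so parameter-recovery checks target the S/G/F ranks, whose
construction is unaffected.

**Anomalies, with deduced truth labels.**

* *Cryptic split*: a second lineage with $0.8\,d_G$ of extra divergence
  hangs off the species' own crown, carrying half its records. Hanging it
  off the crown (rather than re-evolving from the genus node) keeps the
  species monophyletic by construction, so the expected flag set is
  exactly {CRYPTIC} — re-evolving from the genus split would make
  monophyly a coin flip and the truth labels unusable.
* *Merge (haplotype sharing)*: one record of a congeneric species pair is
  replaced by a near-copy (0.2% divergence) of the other species'
  sequence. Both species are expected NON_MONOPHYLETIC and
  LOW_CONGENERIC; the recipient also genuinely spans two clusters and is
  expected CRYPTIC.
* *Numt*: a record is duplicated with third-position GC lowered by 8
  points and one frameshifting deletion, positioned in the interior third
  of the fragment so both flanks read out of frame in any single
  candidate frame (a cut near an end leaves one frame nearly clean and
  the pseudogene undetectable by translation); one random base is
  appended to preserve the alignment length.
* *Imbalance*: one species' record count is multiplied by the `imbalance`
  factor with the extra records drawn from a deeper coalescence
  ($3 d_S/2$), making it simultaneously heavily sampled and
  high-diversity — the configuration that inflates a raw intraspecific
  distribution relative to the taxon-weighted one.

Default anomaly rates (2.7% of species cryptic, 10% of genera carrying a
merged pair, 1% of records duplicated as numts) echo the proportions
reported in large decapod barcode compilations.

**What the generator does not emulate.** Coalescent genealogies within
species, population structure, migration, indel evolution, sequencing
error and chimeras are all absent. Passing recovery tests therefore shows
the screening rules are correct for cleanly structured data with known
effect sizes — not that they would achieve the same sensitivity on real
GenBank material, where effect sizes vary and the anomaly classes blur
into each other.

## Numerical and design choices

* Deterministic tie-breaking everywhere (NJ pair choice, frame ties,
  subsampling order) makes whole-pipeline runs byte-reproducible given a
  seed.
* Strict inequalities at thresholds (<2%, <3%) so boundary values fall
  outside clusters and frequency bins.
* The SE reported with divergence summaries is the sample SD of pairwise
  values over $\sqrt{n}$; pairs sharing a record are not independent, so
  it is descriptive only.
* "Intraorder" is defined as all pairs from different families, which
  makes the rank partition provably exhaustive
  ($|S|+|G|+|F|+|O| = \binom{n}{2}$); published tables that exclude a
  handful of comparisons cannot be force-matched by construction.
* Kruskal–Wallis on S/G/F distributions uses the chi-square approximation
  with tie correction; the degenerate all-tied case returns $H = 0$,
  $p = 1$ by convention.
* Identification success is reported in both raw (max intraspecific ≤
  threshold) and mean (mean intraspecific ≤ threshold) modes, since both
  conventions are in circulation; mean mode is never stricter than raw
  mode.

## Problem sizes used in validation

The shipped checks run the generator at 24–450 records per data set:
closed-form and additivity oracles at 5–12 leaves (100 replicates),
rank-mean recovery at 450 records × 20 replicates, anomaly-flag recovery
at 150 records × 50 replicates, and bias-test behaviour at 90–175 records
× 100 replicates per condition. Composition recovery is assessed as a
mean over 15 replicate founders because all records of one data set
inherit a single root draw whose realized GC3 alone has a sampling SD of
about 2.3 points at 166 third-position sites.

## Worked example

```{r example}
spec <- sim_spec(n_families = 3, genera_per_family = 2,
                 species_per_genus = 3, records_per_species = 6,
                 p_cryptic = 0.15, p_merge = 0.3, p_numt = 0.02)
sim <- simulate_dataset(spec, seed = 2024)
bundle <- run_pipeline(run_config(seed = 11), dataset = sim$dataset)
bundle$rank_summary
bundle$species_flags
bundle$bias$comparisons
```

## Known limitations

* K2P mildly underestimates path lengths under strong compositional skew
  (the estimator assumes uniform frequencies); recovered rank means sit a
  few percent below deep targets, well inside the ±20% recovery bound but
  visible.
* The NJ builder is quadratic per join (cubic overall) in pure R;
  practical to a few thousand records, not tens of thousands.
* Monophyly verdicts depend on midpoint rooting; a pathological outgroup
  structure could flip clades. Outgroup rooting can be supplied by
  rooting the tree before `flag_problem_species()`.
* The relative long-branch flag (terminal branch > 5× the median terminal
  branch) over-fires on tightly clustered data: when most species are
  near-identical the median terminal branch approaches zero and ordinary
  coalescent spread exceeds the multiple. It is therefore reported as a
  screening aid but not relied upon as a pseudogene call; recovery
  statistics score the diagnostic screens (stop codons after frame
  disruption, aberrant composition).
* The numt screens are heuristics: a numt with an intact frame, ordinary
  composition and a short branch is undetectable by design — definitive
  numt identification requires cloning or nuclear assemblies.
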