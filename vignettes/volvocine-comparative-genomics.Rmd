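---
title: "Methods: comparative genomics of the volvocine transition to multicellularity"
author: "volvocomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics of the volvocine transition to multicellularity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(volvocomp)
```

## Scope and scientific setting

The volvocine green algae span the transition from unicellular
(*Chlamydomonas reinhardtii*) through undifferentiated colonial
(*Gonium pectorale*) to germ–soma differentiated (*Volvox carteri*)
organisms, which makes them a tractable system for asking how much genomic
innovation the origin of multicellularity actually required. volvocomp
implements the comparative analyses used to answer that question as a
tested, reusable pipeline:

* **Genome summary statistics** — GC content, gene density, intron
  statistics from FASTA + GFF3.
* **Phylostratigraphy** — assigning each gene an age class from the
  taxonomy of its homology hits.
* **TAP classification** — rule-based assignment of proteins to
  transcription-associated-protein families from domain hits.
* **Domain enrichment** — G-tests of protein-domain abundance between
  unicellular and colonial/multicellular species groups.
* **Gene-family gain–loss reconstruction** — Wagner (integer copy numbers)
  and Dollo (presence/absence) parsimony on a rooted species tree.
* **RB motif scanning** — putative CDK phosphorylation sites in
  retinoblastoma-family proteins, compared across aligned orthologs and
  annotated protein regions.

The package consumes standard formats (FASTA, GFF3, Newick, TSV hit tables
and copy-number matrices). The upstream searches and clusterings that
produce those inputs — BLAST against nr, hmmscan against Pfam, OrthoMCL
clustering, tree inference — are external tools and are out of scope: their
*outputs* are this package's inputs. A synthetic-data generator with
planted ground truth stands in for the real proteomes so that every stage
is testable without databases.

## Phylostratigraphy

A phylostratum ladder is the ordered list of taxa on the focal species'
own lineage, index 1 the most inclusive (oldest) taxon and index `k` the
species itself; the canonical volvocine ladder has nine strata. Each
homology hit maps to the deepest ladder index whose taxon appears in the
hit's subject lineage (the divergence point of subject from focal
lineage); the gene's stratum is the **minimum** over its hits. This is
Dollo reasoning: a homolog detected in a distant clade implies presence in
the common ancestor, so one origin is placed at the oldest node with
evidence. Genes with no surviving hit are species-specific (stratum `k`).

Parameters that matter:

* `evalue_max` (default 0.001, inclusive) — the hit-inclusion threshold.
* `focal_proteins` — subject ids belonging to the focal proteome, excluded
  as self-hits by default, since otherwise every gene is trivially
  assigned stratum `k` by its own database record.

Lineage matching is by exact taxon-name string comparison against the
ladder. No taxid resolution is attempted (parsing taxonomy dumps is out of
scope), which is the module's main practical limitation: names must be
spelled as in the hit table. A hit sharing no taxon with the ladder (not
even the root) is conservatively assigned stratum 1 with a warning. Among
equal-stratum hits the supporting hit is the one with the lowest E-value,
then the lexicographically smallest subject id.

## TAP classification

A family rule holds 1–3 mandatory domains, up to 6 forbidden domains, and
a gathering threshold (GA) per mandatory domain — the minimum bit score
that counts, calibrated as the lowest score among known true positives
(`calibrate_ga()`). A protein is eligible for a family iff every mandatory
domain has a hit at or above its GA and no hit matches a forbidden domain
*at any score* (the conservative reading; a thresholded veto can be
expressed in the rule file by simply omitting weak forbidden hits
upstream). Among eligible families the call is the one with the highest
family score.

Two points were genuinely open and decided here:

* **Family score** = the maximum bit score over mandatory-domain hits
  (rather than a sum across mandatory domains). Non-rule domains never
  contribute; forbidden hits never contribute.
* **Ties** between equal-scoring families break to the lexicographically
  smallest family name, deterministically.

Each protein is assigned to at most one family, so TAP abundance matrices
partition proteomes and column sums are bounded by proteome sizes. Raising
any GA can only shrink abundance entries (monotonicity), which the test
suite checks by property.

## Domain enrichment

Hit counts are pooled within each species group (the alternative —
treating species as replicates — is not what a contingency-table test of
independence does, and pooling matches the analysis the abundance matrix
supports). For each domain the 2×2 table is (this domain, all other
domains) × (group A, group B), tested with the G-test of independence:

$$G = 2 \sum_{cells,\,O>0} O \ln(O/E), \qquad G \sim \chi^2_1 \text{ under } H_0,$$

with zero cells contributing zero (the $x \ln x \to 0$ limit). No Williams
or Yates correction is applied by default; both are available behind the
`correction` flag. Significance is raw $\alpha = 0.05$ by default, with a
Benjamini–Hochberg option (`adjust = "BH"`) that is recommended for
genome-scale scans. Sign is +1 for significant over-representation in
group A, −1 for under-representation, 0 otherwise; swapping the groups
flips every sign.

Abundance (pooled hit counts) is the default tested quantity. A diversity
mode tests per-species presence/absence counts with Fisher's exact test,
since species counts are small integers where the G-test's asymptotics are
not trustworthy.

## Gene-family gain–loss reconstruction

`prepare_matrix()` first gives every unclustered gene (singleton) its own
single-gene family, so per-species totals are not biased by cluster
membership.

**Wagner parsimony.** Branch cost is linear,
$c(s \to t) = g\max(t-s,0) + \ell\max(s-t,0)$ for gain and loss penalties
$g, \ell$; symmetric mode has $g = \ell = 1$ and asymmetric mode $g = 2,
\ell = 1$ (a gain penalised twice as much as a loss). Minimum-cost integer
ancestral states are found exactly by Sankoff-style dynamic programming
over states $0..S$ — bottom-up cost tables, top-down traceback.
Numerical/structural choices:

* **State bound** $S$ = the family's maximum leaf count + 2. Under linear
  costs an ancestral state above the leaf maximum is never profitable; the
  margin is kept for multifurcations and is confirmed harmless by the
  exhaustive-enumeration oracle tests.
* **Ties** in the traceback resolve to the smallest state (fewest retained
  copies), deterministically.
* **Multifurcations** are handled natively (the DP sums over children); no
  arbitrary binarisation. The tree is consumed rooted; no root inference.

**Dollo parsimony.** Presence/absence characters originate exactly once:
at the most recent common ancestor of the leaves carrying the family,
present on the minimal spanning subtree, lost on branches leaving it. A
family whose spanning ancestor is the root is reported as gained on a root
pseudo-branch (branch id = the root's label), so "exactly one gain branch
per present family" holds uniformly — the invariant the tests assert.
Per-branch summaries report families gained (parent 0 → child > 0), lost,
expanded (child > parent > 0) and contracted, with net = gained − lost;
"net families gained" is a presence-level quantity, copy-number expansions
are reported separately.

The Wagner implementation is verified against an independent brute-force
oracle (exhaustive enumeration of all ancestral assignments) on 500 random
instances with up to 6 leaves and copy numbers up to 4, under both cost
models; trees this small keep the enumeration exact and the whole check
under a minute while still exercising multifurcation-free and pectinate
shapes alike.

## Synthetic data and what it does (not) show

The generator produces every pipeline input with planted truth:

* `simulate_family_evolution()` — families evolve along a rooted tree:
  the root carries `root_families` families at copy 1; per branch,
  Poisson(`gain_rate`) new families appear, Poisson(`loss_rate`)
  present families drop to 0 (uniformly chosen), and each copy duplicates
  with probability `dup_rate`. Rates are **per branch**, not per unit
  length, because branch lengths are optional in the consumed trees. The
  demo configuration uses gain 3, loss 1, duplication 0.05 per branch on a
  four-species tree with 40 root families — enough turnover that every
  event type occurs, sparse enough that parsimony is near-exact.
* `simulate_tap_proteome()` — planted members receive all mandatory
  domains above threshold; background proteins receive decoy domains and
  occasionally a *sub-threshold* mandatory domain; with probability
  `noise` a member also receives a forbidden domain and must be rejected
  from its planted family.
* `simulate_homology_hits()` — each gene gets an anchor hit diverging at
  exactly its planted stratum plus younger hits, and decoys above the
  E-value threshold; species-specific genes get only decoys (or nothing).
* `simulate_toy_genome()` — gene structures first, then a chromosome
  *constructed* with an exact G+C count, so GC content is known exactly
  rather than in expectation.

All randomness flows from one integer seed through `withr::with_seed`; no
global RNG state leaks, and fixed seeds make every generator and the whole
pipeline byte-reproducible.

What passing these tests shows: the algorithms invert their own forward
models exactly under the stated conditions. What they do not show:
behaviour on real proteomes, where homology detection decays with
distance (phylostrata are biased young for fast-evolving genes), Pfam and
nr versions move, bit-score distributions are long-tailed, and OrthoMCL
clusters are noisy. The published organism-level counts (net families
gained at the origin of multicellularity, over/under-represented domain
totals, per-stratum gene numbers, single-copy orthologue counts) depend on
those databases and are therefore not targets here; the pipeline computes
quantities of the same kind from synthetic inputs.

## Pipeline

`validate_config()` fills defaults (α = 0.05, E-value 0.001, asymmetric
gain:loss 2:1), rejects unknown keys, and cross-checks groups against the
species tree. `run_pipeline()` runs synth → stats → phylostrat → tap →
enrich → parsimony, writing TSVs and a JSON manifest of every parameter
used plus MD5 checksums of every output; outputs carry no timestamps, so a
rerun under the same seed is byte-identical. The demo problem sizes (tens
of genes, tens of families, four species) keep a full run under a few
seconds while touching every code path; all sizes scale through the
configuration.

```{r demo, eval = FALSE}
out <- tempfile()
manifest <- run_pipeline(list(seed = 1), out)
str(manifest$stages$parsimony)
```

## Known limitations

* Taxon matching in phylostratigraphy is by exact name, not taxid.
* The TAP rule file is an input; the published 96-family rule set is not
  redistributed here, and merging rule databases is out of scope.
* The G-test is asymptotic; for small pooled counts prefer the diversity
  (Fisher) mode.
* Region coordinates for RB-family proteins (N, RB-A, L1, RB-B, C) are
  supplied by the user; shipped examples use synthetic coordinates.
* No likelihood (birth–death) reconstruction; parsimony only.
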