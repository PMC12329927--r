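---
title: "Benchmarking ITS metabarcoding classification with simulated mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking ITS metabarcoding classification with simulated mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmcbench)
```

## What the package models

Defined mock communities (DMCs) — samples of known species composition —
are the standard instrument for measuring how well an amplicon
metabarcoding workflow recovers a fungal community. `dmcbench` builds the
whole experiment in silico so that every stage is observable and every
claim testable: a synthetic species pool with ITS1/ITS2 marker sequences,
reference databases of controlled completeness, five-species communities
mixed at equal theoretical abundance, paired short reads with configurable
noise, an OTU pipeline, three classifier back-ends, and an adjudication
layer that scores every OTU call against the known members.

The study design emulated by the defaults: 51 species over 35 genera; 37
communities of five distinct species each at 20% abundance; four
communities contain two congeners (four distinct genera instead of five);
the final two communities are an identical-composition technical
replicate pair. All of these are configurable
(`benchmark_config()`), but the defaults *are* the study conditions and
the tests assert against them.

## The synthetic-data generator

**Taxonomy and markers.** Species are synthetic binomials
(`Genus07 fictum2`); the genus is always the first whitespace token, so
rank logic is independent of real nomenclature. Each genus draws an
independent random marker ancestor per subregion, with lengths sampled
around 280 bp (clipped to 180–420), matching the empirical ITS subregion
length scale; species then mutate their genus ancestor at a 5%
substitution rate. Random ancestors make inter-genus distances
concentrate near the ~75% identity of unrelated sequences, far above the
intra-genus scale — a deliberately clean separation that real ITS data,
with its conserved cores, does not always offer (see *Limitations*).

**Confusable groups.** A confusable group models congeners whose ITS
subregions barely diverge. Members share a group ancestor and each
receives at most `floor(d_conf · length / 2)` substitutions, which bounds
every within-group pairwise distance by `d_conf` (default 0.03, the OTU
cutoff). With `d_conf = 0` the group is fully indistinguishable:
identical markers, hence identical reference entries, hence exactly tied
top hits. The end-to-end confusable scenario in the tests and the
acceptance script uses `d_conf = 0` by design: tied hits are what make
strict adjudication fail in a predictable, countable way (the affected
OTUs and only those), whereas small nonzero divergence leaves an exact
query's own reference uniquely best and demonstrates nothing. This
mirrors the observed phenomenon of several congeners collapsing into a
single OTU with multiple equivalent hits.

**Subgeneric ranks.** Genera with at least two species carry section
assignments (three consecutive species per section). This is the
table-driven stand-in for expert curation of sections, series and species
complexes: the evaluation only consumes a `species → (kind, name)` map,
so a user can substitute a real curated table.

**Reads.** 250-bp paired reads are cut from `5' anchor + marker +
3' anchor` amplicons (the fixed 25-base anchors stand in for conserved
rRNA/primer context and make flank trimming exact and testable).
Per-species depths are multinomial on the theoretical abundances,
optionally skewed by per-species copy-number weights drawn log-uniformly
in [0.5, 2] — a modest default for marker copy-number variation, whose
real magnitude is unknown. Substitution errors are i.i.d. per base at a
configured mean rate, modulated along the read by a linear Q38→Q18
quality profile (errors concentrate toward read ends). Chimeras join a
prefix of one member's amplicon to a suffix of another's at a uniform
interior breakpoint. Every read carries its true species and chimera
status in a truth table keyed by read id. The per-community depth
(default 1000 pairs) is a package choice — the emulated study does not
state per-sample yields — set so that per-species depth (~200×) dwarfs
the 0.05% rare-OTU threshold.

Every generator draws from its own RNG stream seeded by `(global seed,
operation, entity)`, so regenerating one community is independent of
generation order and all outputs are byte-reproducible.

## Pipeline choices that needed a decision

- **Trimming order** is LEADING → TRAILING → SLIDINGWINDOW, the documented
  order of the tool whose settings (10/10/4:20/10) the pipeline adopts.
- **Merging** is ungapped (the simulator has no indel error model) and
  accepts the best overlap by matches-minus-mismatches only when the
  score is positive and overlap identity is at least 0.9; conflicting
  bases resolve by higher quality, ties become `N`.
- **Marker extraction** accepts a 5'-eroded anchor down to 15 of 25
  bases, reproducing extraction software occasionally missing the first
  conserved bases; the threshold is configurable.
- **Distances** come from a plain global alignment (match +1, mismatch
  −1, gap open −2, gap extend −1) whose *identity count* excludes
  terminal gap columns and compresses each internal gap run to one
  difference — the dialect of the usual OTU distance tools. The end gaps
  are penalised in the DP but excluded from the count: making them free
  in the optimisation itself rewards degenerate "staggered" alignments in
  which two unrelated sequences overlap by a few perfect bases and
  everything else is terminal gap, collapsing their distance toward zero.
- **Clustering** re-implements the MCC-optimising strategy from its
  published description: starting from singletons, single sequences move
  (in decreasing-weight order, ties by id) to whichever cluster maximises
  the Matthews correlation between "clustered together" and "within
  0.03", until no move improves it (cap: 100 sweeps). A perfect partition
  (no false pairs either way) is scored 1 even where the classic formula
  is 0/0. An abundance-sorted complete-linkage baseline exists purely as
  a comparison oracle, and the tests require OptiClust ≥ baseline in MCC.
- **Chimera detection** is a simplified de novo two-parent scan: parents
  must be ≥ 2× the query's abundance, the best crossover must explain the
  query with ≥ 4 fewer mismatches than the best single parent, and each
  side must be ≥ 80% identical to its parent segment. All three
  thresholds are configurable; the 80% side-identity floor is what keeps
  false flags at zero on clean data (random-parent crossovers easily gain
  4 mismatches, but never reach 80% per side).
- **Rare-OTU filtering** removes singletons and OTUs at or below 0.05% of
  reads. The inclusive "≤" resolves an ambiguity between "less than" and
  "≤" formulations of the same rule; inclusive matches the sweep
  semantics, where the threshold-0 grid point must still remove nothing
  but singletons.
- **Top-hit equivalence** uses exact ties on (identity, alignment score)
  under the fixed scoring (+2/−3/−5/−2, free end gaps, coverage ≥ 0.8,
  identity ≥ 0.95). No E-value is computed: in a fixed scoring scheme
  with a fixed database, equal E-value and identity reduce to equal score
  and identity.
- **Naive-Bayes (Wang-style)** uses per-species 8-mer presence models
  with add-half smoothing against the database-wide prior, 100 bootstrap
  iterations each rescoring a 1/8 subsample of the query's k-mers, and an
  80% per-rank confidence cutoff. Tied top models in a bootstrap
  iteration are broken uniformly at random — with identical references
  the votes must split, otherwise confidence would be spuriously perfect
  for whichever species sorts first. Confidence is enforced monotone
  toward higher ranks (agreement at species implies agreement at genus).
- **knn** uses the same alignment distance as the OTU stage (internal
  consistency; the emulated tool's internal metric is not documented),
  breaking ties by identity then accession order, and never abstains on a
  fully annotated database.

## Adjudication semantics

The counting unit is the OTU (the taxon for consensus). A false negative
is an *unclassified* OTU; a wrong name is a false positive — the
three-way definition underlying all metrics. Two further points needed a
decision:

- A truth member with no surviving OTU contributes no FN under the
  OTU-unit definition. Such members are visible in reports as undetected
  (their absence from TP taxa), and the consensus path does count them as
  FN at the taxon level; per-OTU recall is therefore a property of the
  classified OTUs, not a detection rate. This reading keeps TP+FP+FN
  equal to the number of adjudicated OTUs, which the confusion-count
  invariant asserts.
- L1 abundance distances renormalise observed fractions over classified
  reads after excluding unclassified OTUs. Renormalisation keeps the
  observed vector a probability distribution and preserves the printed
  [0, 2] range; without it the metric would conflate classification loss
  with abundance error.
- At genus level an equivalence group is projected to genus names and
  deduplicated first — a within-genus tie is genus-unique and can be a
  strict genus TP while remaining a strict species FN. Synonyms are
  canonicalised (with chain-following) on both sides before any
  comparison, and genus extraction happens after canonicalisation.
- The loose setting's false-positive representative is drawn with a seed
  derived from (OTU, database, method, level), so reports are
  reproducible run to run.
- Consensus requires the same correct taxon at the same level in both
  markers; a taxon called in at least one marker that is neither
  consensus-correct nor a member counts as a consensus FP. Cross-level
  agreement (species in one marker, genus in the other) is not accepted.

## Problem sizes

The packaged tests and the acceptance script run the full 37-community
design with 1000 read pairs per community for the single-marker scenarios
(error-free, complete database — the conditions under which recovery must
be perfect), and the full two-marker, two-database, three-back-end grid
for the headline benchmark. On one CPU the complete benchmark takes about
two minutes and the full acceptance script about three; unit tests use
communities of 3–5 and read depths of 150–400.

## What passing tests do and do not show

The generator's clean separations (independent genus ancestors, exact
anchors, substitution-only errors) make correctness claims sharp: with a
complete annotated database and error-free reads, anything short of
perfect recovery is a pipeline defect, and every deliberate degradation
(incomplete databases, unannotated entries, indistinguishable congeners,
chimeras, abundance skew) produces its expected, quantified signature.
They do not show performance on real ITS data: real markers share
conserved cores across genera (inter-genus distances far below random),
real length variation exceeds the simulated range, indel and
PCR-stutter errors exist (the simulator is substitution-only), primer
bias is not modelled, and real reference databases carry
mis-annotations rather than merely missing or truncated entries. Real
classifier rankings — especially bootstrap-confidence behaviour as
database size grows — can therefore differ from the synthetic ones.

## Known limitations

No indel error model and therefore no gapped merging; no HMM-based
marker-boundary detection (fixed anchors instead); no ASV/denoising
path; no heuristic search indexing (databases here are desk-scale); no
E-value statistics; the subgeneric map must be supplied, not inferred.
The OTU pipeline runs per community by default (whether pooling across
communities changes results is a question the configuration can explore
but the defaults do not).
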