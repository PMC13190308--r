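---
title: "Reconstructing metastatic seeding histories from clone trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing metastatic seeding histories from clone trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cloneseed)
```

## The problem

Multi-region sequencing of a primary tumour together with its metastases
(pre-mortem biopsies and research-autopsy samples) yields, per patient, a
set of mutation clusters — groups of somatic mutations that arose in the
same subclone — with a cancer cell fraction (CCF) for every cluster in
every sequenced region, plus allele-specific fractional copy-number
segments. From these summaries, `cloneseed` reconstructs how the
metastatic disease was seeded: which subclones migrated, from which tumour
to which, with what confidence, and what the orthogonal copy-number and
radiological evidence says about those routes.

The package deliberately starts downstream of variant calling and mutation
clustering. Cluster assignments and CCFs are inputs; so are
allele-specific copy-number segments and (optionally) per-cluster
subclone copy-number profiles, driver annotations and whole-genome
doubling (WGD) calls.

## Clone trees: scoring and enumeration

A clone tree is a rooted tree over the mutation clusters whose root is the
trunk (the most recent common ancestor of all sequenced cancer cells). Two
constraints link a topology to the observed CCFs:

* **Pigeonhole (sum) condition** — in every region, the CCFs of a node's
  children cannot sum to more than the node's own CCF.
* **Crossing rule** — a cluster cannot descend from another whose CCF it
  exceeds in any region (tolerance `tau = 0.05` CCF to absorb estimation
  noise; configurable).

The sum condition error (SCE) of a topology totals its violations,
$\mathrm{SCE} = \sum_{v,r} \max\!\big(0,\; \sum_{c\in\mathrm{ch}(v)}
\mathrm{CCF}(c,r) - \mathrm{CCF}(v,r)\big)$. `enumerate_trees()` generates
every topology admissible under the crossing rule (guarded at 10 clusters;
larger instances should supply an externally reconstructed tree), scores
each by SCE, and returns them sorted with a deterministic
lexicographic-edge-list tie-break. The rank-1 tree is used for point
estimates; the ranked ensemble feeds migration probabilities.

## Subclone proportions and clonality

`infer_subclone_proportions()` converts CCFs into terminal subclone
proportions: a leaf's proportion is its CCF; an internal node's is its CCF
minus the summed CCFs of its children, iterated leaf to trunk. Negative
values (constraint violations from noisy CCFs) are clipped to zero and the
clipped mass is reported per region. Subclones at or below 5% in every
region are flagged extinct; the comparison uses a `1e-9` epsilon so that
an exact 5% boundary case is classified as the rule states.

Clonality classes come from mutation *detection* (more than one mutant
read; CCF > 0 as a fallback with a warning), aggregated to tumour kind:
truncal, primary-unique, metastasis-unique, shared subclonal. Somatic
events (drivers, LOH, WGD) inherit the class of their cluster.

Detection and cell presence are deliberately distinct notions. A
metastasis carries the mutations of every ancestor of its founding clone,
but none of those ancestral populations migrated. Migration inference
therefore uses `migration_presence()`: a subclone takes part in a
tumour's labeling only where its inferred terminal proportion exceeds the
extinction threshold in at least one region of that tumour (a flag admits
any positive proportion).

## Migration histories by weighted parsimony

The clone tree is refined by attaching one fixed observation leaf per
(cluster, tumour) pair where the cluster has cells; the root is fixed to
the primary. Internal nodes are then labeled with tumours. A migration is
a tree edge whose endpoints carry different labels; the migrating clone is
the child endpoint's cluster. No migration may enter the primary, which
was resected before detectable metastatic relapse.

Three seeding models of increasing complexity are evaluated:
`primary_only` (every migration starts at the primary), `single_source`
(each metastasis receives migrations from exactly one source tumour) and
`multi_source` (unconstrained). `select_seeding_model()` keeps the
smallest migration count, breaking ties toward the simpler model.

The labeling objective is lexicographic:

1. number of migrations $\mu$;
2. number of comigrations $\gamma$, counted as distinct ordered
   (source, target) pairs — coarser than the comigration number of the
   integer-programming formulation this module replaces, and documented as
   such;
3. number of free nodes labeled with a tumour in which their cluster was
   never detected (observation consistency);
4. number of distinct source tumours;
5. maximally many primary-labeled internal nodes, then label order.

The observation-consistency term deserves a note: among equal-$(\mu,
\gamma)$ solutions, a chain such as trunk(P) → A (detected only in M1) →
B (detected only in M2) admits both the all-primary labeling (P→M1, P→M2)
and the observed route (P→M1, M1→M2). Preferring labelings that place
clones only where they were observed resolves such ties toward the route
with evidence, without touching $(\mu, \gamma)$ optimality.

The search is an exact branch-and-bound over internal labels with a
Sankoff dynamic-programming lower bound, exact for the tumour counts seen
in practice (a 20,000-solution enumeration cap guards pathological tie
plateaus and is reported when hit). Its $(\mu, \gamma)$ optimum is
property-tested against a naive exhaustive labeler on hundreds of random
small instances.

Multifurcations are refined (`resolve_polytomies()`) by inserting free
intermediate nodes carrying the polytomy node's cluster whenever the
refinement strictly reduces $\mu$ (then $\gamma$): exhaustively over
binary join trees for degree ≤ 6, by grouping children with a shared
dominant tumour beyond. A local Sankoff screen skips candidates that
cannot lower the subtree cost array; the grouped candidate is always
evaluated in full so $\gamma$-level gains survive the screen. Gains that
would come only from exotic binary refinements at equal $\mu$ and
$\gamma$ are not pursued.

Phylogenetic uncertainty is handled by rerunning the labeling on the
lowest-SCE tree ensemble; `migration_probabilities()` reports, per
(source, target) pair and per cluster-level migration, the fraction of
solutions containing it, and `threshold_sweep()` recomputes the
seeded-by-metastasis proportions across probability cutoffs.

## Orthogonal validation

**Conserved LOH.** LOH is irreversible, so every LOH event clonal in the
seeding tumour must be present in the seeded one. Clonal LOH is called per
region from purity-adjusted fractional copy number,
$\mathrm{CN}_\mathrm{adj} = (\mathrm{CN}_\mathrm{obs} - (1-\rho))/\rho <
0.1$, assuming one normal copy per allele from admixed normal cells (the
adjustment inverts the generator's admixture exactly, which is tested at
machine precision), intersected across a tumour's regions. Conservation
requires allele identity — loss of opposite parental alleles (mirrored
allelic imbalance) does not count. The conserved fraction is normalised by
the source's clonal LOH set; the count of source-clonal events absent
from the target flags routes incompatible with irreversibility.

**Detection times.** A tumour's first detection is the earliest scan
listing it; tumours sampled only at autopsy get the midpoint of the last
scan and death. Scan days are normalised between the relapse scan and
death (≤ 50% first half, > 50% second half). `validate_history()`
compares detection-day distributions of primary- versus metastasis-seeded
tumours (Mann–Whitney) and conserved-LOH fractions of inferred sources
versus alternatives.

## Seeding analysis

Migrating clusters are primary-to-metastasis or metastasis-to-metastasis
seeders by their migration's source kind; truncal clusters are excluded
from seeder versus non-seeder comparisons. Seeding capacity is tested with
a Monte Carlo multinomial likelihood-ratio test: $G = 2\sum_i o_i
\ln(o_i/e_i)$ with $e_i = n/k$ under an equal-probability null, $p = (1 +
\#\{G_\mathrm{sim} \ge G_\mathrm{obs}\})/(\mathrm{reps}+1)$. The +1
correction keeps $p$ off zero; a maximally even count vector attains the
minimal statistic, so its $p$ is exactly 1 for any seed. Type-I error at
$\alpha = 0.05$ is calibrated within [0.03, 0.07] in the test suite.

Duration in situ is proxied by the mutations and copy-number breakpoints
private to a metastasis that descend from its seeding subclone(s). The
patient-level "sufficient duration" threshold is the 90th percentile
(linear interpolation) of the mutation counts accumulated from trunk to
each metastasis-to-metastasis seeding subclone; a published description of
this threshold mixes a per-patient percentile with a cohort mean, which is
internally inconsistent — the per-patient percentile is implemented. A
metastasis' total detected mutation count (private-only behind a flag)
decides sufficiency.

Cavity analysis cross-tabulates met-to-met migrations by intrathoracic /
extrathoracic source and target; chest wall and diaphragm sites require a
pleural-boundary qualifier and error without one. SCNA burden per subclone
is the breakpoint count of its copy-number profile, with seeder versus
non-seeder strata compared by paired Wilcoxon signed-rank tests on
per-patient medians — a deliberate nonparametric substitute for
linear mixed models, which are out of scope.

## Signature dynamics

Per-cluster trinucleotide spectra are refit onto a fixed signature matrix
by non-negative least squares; activities are fractions of mutations with
an unexplained remainder. Clusters with fewer than 50 mutations are
stabilised by resampling (1,000 iterations by default): each iteration
draws the cluster's own number of mutations from a 60/20/20 mixture of
the index cluster, a tree neighbour (uniform among parent and children; a
flag restricts to the parent) and a clonality-matched cluster, refits, and
the mean is reported with per-signature standard deviations; clusters with
sd > 0.1 on two or more signatures are excluded. Missing sources reweight
the remainder proportionally.

Aetiology groups (clock-like SBS1+SBS5, smoking SBS4, APOBEC SBS2+SBS13,
other SBS17b, platinum SBS31+SBS35 — the latter only for platinum-treated
patients) are detected at activity ≥ 0.06 and called majority above 0.5.
Episodic APOBEC requires inactive-to-active transitions along a
trunk-to-leaf lineage: trunk-active plus a later emergence, or two or more
emergences. Cosine distances compare metastasis-unique clusters with their
ancestral primary clusters.

The shipped signature matrix is synthetic — deterministic sparse random
96-context profiles, not a catalogue of real signatures — because all
downstream statistics consume activity fractions, and tests construct
their own mixtures from it.

## The synthetic cohort generator

Every downstream stage is tested against `simulate_patient()`, which
emulates the data structure of the target cohort with full ground truth:

* a clone tree grown by uniform attachment (linear and branched shapes);
* a primary with 2–8 regions and 2–12 anatomically labelled metastases by
  default (1–3 regions each); the cohort-scale extremes (up to 37
  metastases, up to 60 clusters) are reachable through the configuration,
  and the test suite runs at 6–15 clusters to keep the suite fast — a
  problem-size choice of the package, stated here once;
* seeding under primary-only / single-source / multi-source regimes with
  60% of eligible seedings metastasis-sourced by default; ~25% of
  seedings are polyclonal;
* per-region CCFs implied by terminal proportions (stick-breaking along
  the tree: each present clone keeps 20–50% of the mass entering its
  subtree, so clones retain non-negligible populations) plus
  truncated-normal noise clipped to [0, 1.5];
* irreversible clonal LOH and occasional gains accumulated along
  branches, mixed by proportions and admixed by purity into fractional
  segments;
* per-cluster signature activities with episodic APOBEC bursts and
  platinum exposure confined to metastatic clusters of treated patients;
* radiological first-detection times = seeding day plus exponential
  latency (mean 60 days), never before the source's detection.

Three generative choices matter for identifiability and mirror the
biology of a resected primary: (i) metastasis founders seeded from the
primary are occult in the primary specimen with probability 0.5 (the
minor subclone that seeded before resection is often below detection);
(ii) new metastatic subclones preferentially (3:1) arise from met-private
populations; (iii) onward seeding re-uses an existing cluster only when
that cluster is unique to the source tumour — a clone shared between
tumours leaves no record of which one it physically departed from, so no
parsimony method could recover such a route, and multi-step seeding
capacity instead arises through descendants of seeders.

What the generator does **not** emulate: read-level noise and coverage
variation, mutation-cluster mis-assignment, subclonal copy-number noise,
sampling bias of autopsy programmes, and clock-calibrated timing.
Recovery results on it therefore demonstrate the correctness of the
inference machinery under its stated assumptions, not performance on real
cohorts.

## Numerical choices

* crossing-rule tolerance `tau = 0.05` CCF; CCF ceiling 1.5 with warning;
* extinction threshold 5% with a `1e-9` comparison epsilon;
* SCNA diversity normalises each allele by sample ploidy and rescales by
  the diploid reference, so a clean whole-genome doubling scores 0
  against its undoubled parent; major and minor alleles contribute
  separately (flag to sum);
* SNV diversity weights cluster terms by mutation count (equivalent to
  per-mutation CCF vectors; flag to unweight); truncal terms only when
  the MRCA is a seeding subclone;
* DNV calling uses a two-sided two-proportion z-test with pooled variance
  at α = 0.05 per sample, any sample sufficing (flags: require all
  samples; TOST equivalence at margin 0.1 instead of failure-to-reject);
* the biallelic-inactivation call applies Holm–Šidák correction across
  the supplied family and, as printed in its source description, calls an
  event when the corrected p falls below 0.05 in any sample — note this
  rejects the all-copies-mutated null; `invert_call` flips the reading;
* Monte Carlo capacity tests default to 1e5 replicates with a mandatory
  seed; statistic comparisons use a `1e-9` epsilon so tied statistics
  count as "at least as extreme".

## Known limitations

The parsimony labeler optimises a coarser comigration count than the
integer-programming formulation it replaces; probabilities from tree
ensembles inherit whatever bias the SCE ranking carries; polytomy
refinement beyond degree 6 is greedy; clusters shared between tumours
make some true metastasis-to-metastasis routes fundamentally
unidentifiable (ties resolve toward the primary); and the LME-based
covariate adjustments of cohort-scale analyses are replaced by stratified
nonparametric tests throughout.
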