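---
title: "Detecting recombination and species borders in multilocus haploid data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination and species borders in multilocus haploid data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombscan)
```

## The problem

Many fungi — the *Trichoderma/Hypocrea* species complexes are a canonical
example — reproduce clonally most of the time, while retaining (or
occasionally losing) the capacity for sexual recombination. Whether a
named "species" is a clonal lineage, a panmictic recombining population,
or a mixture of both cannot be observed directly: crosses fail in vitro
and teleomorphs are found erratically. What can be observed is the
statistical footprint that recombination leaves in multilocus sequence
data: incongruence between gene genealogies, homoplasy between nearby
sites, and the decay of multilocus linkage. `recombscan` implements the
standard battery of such tests for haploid multilocus datasets, a
genealogical-concordance species-recognition step, and an iterative
Phi-test scan that maps the *borders* of a recombining population around
a clonal core, together with a coalescent simulator that provides
datasets with known truth for calibration and power analysis.

## Data model

A dataset is a set of per-locus alignments (three unlinked loci of a few
hundred nt each is the motivating design) over one shared strain set,
plus a strain manifest (ids, origins, subclade labels, teleomorph and
ex-type flags, GenBank accessions). Coordinates are 0-based and
half-open throughout; concatenation records each locus's column range so
any partition-aware test can recover it exactly. A packaged manifest of
93 strains of the *H. lixii / T. harzianum* species complex is included
as a realistic fixture (`system.file("extdata", "strain_manifest.tsv",
package = "recombscan")`).

Clone correction collapses strains whose concatenated sequences are
*literally* identical (gaps and ambiguity codes compared as characters)
to the first representative in manifest order. Exact string equality is
deliberate: any looser rule (e.g. treating `N` as a wildcard) makes the
collapse order-dependent and non-transitive.

## The three recombination tests

### Pairwise homoplasy index (Phi)

For two aligned sites the *refined incompatibility* score is the minimum
number of extra state changes needed to fit both sites on any single
tree:

$$\ell(a,b) = (V-1) + (C-1) - (k_a-1) - (k_b-1)$$

with $V$ the number of distinct observed joint states, $C$ the number of
connected components of the bipartite graph joining states observed
together, and $k_a, k_b$ the per-site state counts. $\ell = 0$ iff the
sites are compatible; for two biallelic sites $\ell = 1$ is the
four-gamete condition. The closed form is validated in the test suite
against exhaustive enumeration of all topologies with Fitch scoring; the
enumeration is the authority and the closed form an optimisation.

Phi is the mean of $\ell$ over all pairs of parsimony-informative sites
at most `window_w` nucleotides apart (default 100 nt, the conventional
default for this test; the window is measured in alignment positions, so
on a concatenated multilocus alignment inter-locus pairs are mostly out
of window). Under clonality the genealogy is shared along the sequence,
site positions are exchangeable, and permuting them leaves the statistic's
distribution unchanged — this is what makes the permutation test exact.
Under recombination nearby sites share genealogies while distant sites do
not, so the observed nearby-pair Phi falls *below* its permutation null;
significance is therefore the lower tail,
$p = (1 + \#\{\Phi_{perm} \le \Phi_{obs}\})/(n+1)$. A normal
approximation from the permutation moments is available as a secondary
p-value. With fewer than two informative sites the test signals a typed
`phi_not_computable` condition rather than an error, so iterative callers
can record and skip such steps.

Note one degenerate regime: data simulated without recurrent mutation
(infinite sites) and without recombination are perfectly compatible, so
$\Phi = 0$ for observed *and* permuted data and $p = 1$ identically. A
null calibration of the test's size therefore requires a finite-sites
mutation model; the package's size simulations use the JC model for
exactly this reason, while infinite-sites clonal data are used to verify
the $\Phi \equiv 0$ invariant. Even under recurrent mutation the test is
*conservative* at moderate diversity: most clonal datasets at
$\theta = 10$ per ~500 nt locus contain no incompatible site pair at
all, the statistic is then heavily discrete, and the tie-inclusive
$(1+b)/(n+1)$ estimator cannot produce small p-values — the measured
size at $\alpha = 0.05$ is below 0.01 rather than nominal. This is a
property of the test itself, not a defect: it never rejects clonality
too often, and its power against genuine recombination at the same
diversity remains essentially 1.

### Index of association (IA)

On clone-corrected haplotypes, with $d(j,k)$ the number of loci at which
two haplotypes differ, $IA = V_{obs}/V_{exp} - 1$, where $V_{obs}$ is
the variance of $d$ over pairs and $V_{exp}$ is its linkage-equilibrium
expectation (the sum of per-locus mismatch-indicator variances). IA is 0
under panmixia. The ratio is invariant to the variance-divisor
convention. The null is generated by permuting allele assignments among
individuals independently at each locus;
$p = (1 + \#\{IA_{perm} \ge IA_{obs}\})/(n+1)$. Loci whose mismatch
indicator has no variance — monomorphic loci, but also loci at which
*every* haplotype is unique — contribute nothing to $V_{exp}$ and are
dropped with a warning. Alongside the permutation p-value the result
carries the field-traditional heuristic reading (values below 1 read as
consistent with panmixia, above 1 as rejecting recombination); the two
can disagree and both are reported.

### Partition-homogeneity test (PHT / ILD)

The observed statistic is the sum over loci of maximum-parsimony tree
lengths; replicates reassign the concatenated columns randomly to
partitions of the same sizes. Under clonality the loci share a genealogy
and re-partitioned sums resemble the observed one; under between-locus
recombination the true partition is *shorter* than random ones, so
$p = (1 + \#\{T_{rep} \le T_{obs}\})/(n+1)$. The internal parsimony
search is random-order stepwise addition followed by
nearest-neighbour-interchange hill climbing (first improving move in a
deterministic edge ordering; the random addition order is the only
stochastic element and is seed-controlled), with an exhaustive
enumeration mode for at most 11 taxa that serves as the oracle in tests.
Site patterns are compressed once over the concatenated alignment, so
each replicate costs only a weight re-tabulation plus the search itself.
The replicate default is 1000; larger counts are a flag away but change
little at the sample sizes this package targets.

The ILD null is itself degenerate under clonality: when all loci share
one genealogy, every column attains its parsimony minimum on the shared
tree, so the summed length is *additive* — invariant under column
re-partitioning — and $T_{obs}$ equals the replicate sums up to search
noise, giving $p \approx 1$ for almost every clonal dataset. The test is
therefore extremely conservative as a null procedure (measured null
rejection 0 at $\alpha = 0.05$) while retaining essentially full power
against loci with conflicting genealogies. Users should read a
non-significant PHT as "no evidence", never as calibrated support for
clonality.

## Genealogical concordance (GCPSR)

A candidate clade is *supported* in a locus iff, restricted to that
locus's taxa, it equals one side of a bipartition whose support meets
the threshold; it is *contradicted* iff any supported bipartition there
is incompatible with it (four-intersection rule after restriction to the
shared taxa; restrictions below two taxa, or below four shared taxa, are
neutral). A clade is recognized as a phylogenetic species when it is
supported in at least one locus and contradicted in none. Support equals
*identity* with a supported split, not mere compatibility — the strict
reading of concordance; compatibility alone would recognise clades that
no gene tree actually shows. Candidates default to the supported clades
of a combined-data tree (both sides of each bipartition are evaluated,
since trees are unrooted); the combined tree itself is *not* counted as
an independent locus by default, because its support is not independent
evidence — a flag-free design choice the user can override by passing it
as an extra clade table.

Gene trees may be supplied (newick with support labels) or built
internally as neighbor-joining trees with nonparametric bootstrap
supports — a deliberate desk-scale surrogate for Bayesian posterior
probabilities. The 0.95 threshold is kept from the posterior-probability
convention; whether 95% bootstrap is an equally calibrated cutoff is a
user-level question, and the threshold is an argument everywhere.

## The border scan

The scan formalises a trial-and-error procedure for locating the borders
of a recombining population: start from a baseline that is known clean —
the focal clade's members plus a handful of phylogenetically distant
control strains — verify that the baseline itself passes the Phi test,
then test candidates in order of increasing mean patristic distance to
the focal clade (on a supplied combined tree; ties break
lexicographically). In the default *fixed-baseline* mode each candidate
is tested as baseline + that one candidate, so a triggering strain never
contaminates later steps and step verdicts are mutually independent; a
*cumulative* mode (non-triggering candidates accumulate) is provided for
sensitivity analysis. The scan deliberately continues past the first
trigger: the first triggering strain is the inner border, the last the
outer border, and the recombining population is the focal clade plus all
triggering strains. Steps where Phi is not computable are recorded as
such and skipped — this is precisely the small-clade situation the
baseline-plus-candidate construction exists to avoid. No multiple-testing
correction is applied by default, matching how such scans are run in
practice as exploratory cartography; a Benjamini–Hochberg summary of the
step p-values is available separately (`scan_bh_summary`).

## Population statistics

Watterson's $\theta_W = S/a_1$, mean pairwise differences $\pi$, and
Tajima's D with the textbook variance constants; S and D use
complete-deletion columns, $\pi$ is additionally reported under pairwise
deletion. $\theta_W$ here is a deliberate desk-scale surrogate for
coalescent-MCMC estimates of $\theta$; no growth-rate estimation is
attempted. FST between two populations is the Hudson form
$1 - H_w/H_b$ (within- over between-population mean pairwise
differences, the within term weighted by pair counts); negative
estimates are reported as computed, since truncation at zero hides
exactly the near-zero differentiation the statistic is meant to flag.
The Hudson–Kaplan $R_m$ lower bound on recombination events is the size
of a maximal set of disjoint four-gamete-incompatible intervals over
biallelic sites, verified in tests against brute-force interval
enumeration.

## The simulator

All simulation time is in coalescent units and mutations arise at rate
$\theta/2$ per lineage per unit time per locus, so the analytic
checkpoints are exact: $E[T_{MRCA}] = 2(1 - 1/n)$ and, under infinite
sites, $E[S] = \theta\,a_1(n)$. The generator covers five regimes:

* **clonal** — one genealogy shared by all loci (no recombination of any
  kind);
* **free_recomb** — an independent genealogy per locus (free inter-locus
  recombination);
* **intralocus** — independent genealogies for contiguous blocks within
  each locus (4 blocks per locus by default);
* **structured** — two demes that coalesce only within themselves until
  a divergence time $\tau$;
* **border_scenario** — a clonal core plus hidden donor lineages in one
  deme, distant controls in the other ($\tau_{control} = 5$), one shared
  genealogy for all loci; each halo strain is a block mosaic that copies
  its home donor or, with probability `halo_intensity`, a random clade
  lineage (a core strain or another donor). At intensity 0 every halo
  strain is a clean copy of one lineage and the scan finds nothing; at
  the default intensity 1 the halo is fully recombinant.

Mosaic-by-copying is a deliberate simplification relative to an
ancestral recombination graph: it produces exactly the homoplasy and
incongruence signals the tests consume, with truth labels that are
unambiguous. It does not model recombination events at random
genealogical depths, gene conversion, or mutation after recombination —
so passing power figures here speak to detectability of *recent, clean*
recombinants, not to every biological regime. Similarly, infinite-sites
data contain no recurrent mutation and JC is the only finite-sites model
offered (rate heterogeneity and base-composition bias are absent), which
is adequate for test calibration but not a substitute for model-based
inference on real data.

## Study conditions and numerical choices

The calibration and power studies run by the test suite and by
`scripts/acceptance.R` use these sizes, chosen to mirror the motivating
study design (haploid strains, three ~500 nt loci) while staying
desk-scale:

* Phi size: 500 clonal JC simulations, $n = 20$, $\theta = 10$/locus,
  1000 permutations — rejection at $\alpha = 0.05$ expected in
  [0.03, 0.07]; power: 500 intra-locus simulations (4 blocks/locus),
  expected $\ge 0.8$.
* IA: 1000 free-recombination simulations, mean within $\pm 0.05$ of 0.
* PHT: 100 + 100 two-locus simulations at 200 replicates; null rejection
  in [0.02, 0.10], power $\ge 0.8$.
* GCPSR: 100 structured simulations, $\tau = 3$, $\theta = 8$/locus,
  10+10 strains, 100 bootstrap replicates: both deme clades recognized
  in $\ge 90\%$.
* Border scenario: 8 core + 10 halo + 5 controls, $\theta = 30$/locus.
  $\theta$ is higher here than in the other regimes because the
  informative signal lives inside one subclade of a tree whose branch
  length is dominated by the distant controls; at $\theta = 30$ the
  *within-clade* number of segregating sites per locus lands in the
  tens, matching what the three motivating loci show within subclades.
  50 simulations, pooled per-strain classification accuracy $\ge 80\%$.
* Coalescent analytics: 10 000 genealogies for $E[T_{MRCA}]$, 5 000 for
  $E[S]$, agreement within 3 Monte-Carlo standard errors.

Other fixed choices: permutation p-values always use the
$(1+b)/(n+1)$ estimator (never exactly zero); NJ branch lengths are
clamped at zero with the clamped deficit logged; K3ST distances raise a
saturation error naming the offending pair rather than returning NaN;
Fitch treats IUPAC ambiguity as state sets and gaps as the full set;
polytomies are scored as an arbitrary binary resolution; all stochastic
steps consume seeds derived from a single master seed.

## A worked run

```{r example}
cfg <- sim_config(mode = "border_scenario", theta_per_locus = 30, seed = 211)
sim <- simulate_multilocus(cfg)
ids <- sim$dataset$manifest$strain_id
core <- ids[sim$truth_labels == "clonal_core"]
ctrl <- ids[sim$truth_labels == "control"]
tree <- gene_tree(concatenate(sim$dataset)$alignment, bootstrap = 0)
scan <- scan_borders(sim$dataset, tree, core[1:4], ctrl, seed = 211)
scan
head(scan$steps)
```

## Known limitations

* The Phi permutation null assumes exchangeable site positions; strong
  rate heterogeneity along the sequence can mimic the recombination
  signature.
* Bootstrap supports on NJ trees are a surrogate for posterior
  probabilities; the 0.95 threshold is a convention, not a calibration.
* The scan's candidate ordering depends on the supplied tree; a poor
  combined tree degrades the inner/outer border labels (though not the
  per-candidate verdicts in fixed-baseline mode).
* $R_m$ is a lower bound and scales poorly in information content for
  high diversity; FST is the two-population Hudson form only.
```
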