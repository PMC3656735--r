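---
title: "Harmonizing multi-study microsatellite panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-study microsatellite panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatmerge)
```

# The problem

Microsatellite (STR) genotypes are recorded as PCR product lengths in
nucleotides. When the same locus is genotyped in different studies — with
different primer pairs, calling software, or calling conventions — the same
underlying allele can be reported with a systematic integer size difference.
Merging panels from several studies therefore requires, locus by locus,
deciding whether the two studies' calls agree exactly, differ by a constant
offset that can be corrected, or disagree in a way no constant can fix (for
example allele-specific adjustments), in which case the locus must be
dropped. After alignment, the combined panel has to be cleaned of duplicate
samples, excessive missing data, and cryptic close relatives before standard
population-genetic analyses (distances, ordination, trees, diversity
gradients) are meaningful.

`msatmerge` implements this pipeline end to end, together with a synthetic
panel generator that injects every artifact the pipeline is supposed to
detect — so each step can be validated against known truth.

# Offset inference from duplicate samples

Individuals genotyped in both data sets anchor the alignment. For a pair of
individuals the package computes the proportions of loci sharing 0, 1, or 2
alleles identical by state (`p0`, `p1`, `p2`), using only loci at which
neither member is missing; allele sharing at a locus is the multiset
intersection of the two unordered genotypes. Duplicate samples have `p2`
near 1 (reduced only by genotyping error and, before correction, by offset
loci), while even first-degree relatives rarely exceed `p2` of about 0.5 at
panels of several hundred polymorphic loci. `find_duplicates()` reports all
pairs above a threshold (default 0.83) plus the largest sub-threshold `p2`,
so the bimodal gap separating duplicates from relatives can be inspected
rather than assumed.

At a locus, `infer_offset()` translates the incoming data set's alleles by
every integer $c$ in $[a-B,\,A-b]$, where $a,A$ are the smallest/largest
reference alleles and $b,B$ the smallest/largest incoming alleles — outside
this range no translated allele can coincide with any reference allele, so
restricting the argmax loses nothing. It maximizes $g_{c,2}$, the proportion
of usable duplicate pairs sharing two alleles IBS after translation.
Classification of the maximizing constant $c^*$: *exact* if $c^*=0$ and
$g_{2}\ge$ a threshold (default 0.75, chosen inside the empirical gap that
separates well-aligned loci from irreconcilable ones), *offset* if
$c^*\neq 0$ at the same condition, *mismatch* otherwise. The secondary
statistic $g_{c^*,1\vee2}$ (sharing at least one allele) is reported as a
plausibility check: a true constant offset plus rare genotyping error leaves
$g_{1\vee2}$ near 1 even when $g_2$ is not exactly 1.

Two conventions are the package's own and are stated in the output rather
than hidden: the sign of $c^*$ is the correction *added to the incoming*
data set, and ties among maximizing constants resolve to the smallest
magnitude, then the negative value (favoring "no change"; the `tie` flag
marks affected loci).

`merge_datasets()` applies the classification in the order mismatch-drop,
offset-translate, duplicate-drop (keeping the reference copy, whose
population labels are trusted), then concatenates individuals over the
intersection of surviving loci. Loci removed at one step are not considered
at later steps.

# Missing-data filters

`filter_loci_by_missingness()` and `filter_individuals_by_missingness()`
implement the two-stage filter with strict thresholds (defaults 0.146 for
the per-locus fraction $l_m$, then 0.277 for the per-individual fraction
$i_m$, computed over the surviving loci). Order matters and is enforced by
convention: loci first, then individuals. The individual filter also
verifies a condition the threshold is meant to guarantee — that every
remaining pair of individuals shares non-missing genotypes at more than half
the loci — and reports it as a diagnostic rather than filtering on it, since
two individuals missing 40% each on disjoint loci can pass the marginal
filter yet share only 20% of the panel. Loci with zero data in some
population are flagged (`flag_population_missing_loci()`) but retained.

# Relationship classification

Pairs are classified among MZ, PO, FS, a collapsed second-degree class, CO,
and unrelated by composite likelihood over unlinked loci. Conditional on the
number $m$ of alleles shared identical by descent, the joint probability of
an unordered genotype pair under Hardy-Weinberg proportions has the standard
closed form; a relationship with IBD-sharing coefficients $(k_0,k_1,k_2)$
gives per locus

$$P(G_1,G_2\mid R)=k_0P_0+k_1P_1+k_2P_2,$$

and log-likelihoods sum over loci at which both genotypes are observed and
every carried allele has positive count-estimated frequency. Linkage is
deliberately ignored: a map-aware hidden-Markov model adds power to separate
half-sib from grandparent-grandchild from avuncular pairs, but without it
the three second-degree pedigrees share $(\tfrac12,\tfrac12,0)$ and are
exactly likelihood-equivalent, so the package exposes them as one
`SECOND_DEGREE` class instead of pretending to distinguish them.

Genotyping error enters the likelihood exactly rather than approximately.
Under the model in which each allele call is independently replaced, with
probability $\varepsilon$, by a random draw from the locus frequency vector,
the marginal genotype distribution stays at HWE and each cross-individual
IBD link survives with probability $s=(1-\varepsilon)^2$; the error
therefore folds into the mixing weights:
$k_2'=k_2s^2,\; k_1'=k_1s+2k_2s(1-s),\; k_0'=1-k_1'-k_2'$. The default
$\varepsilon$ is 0.008. A pair is *accepted* when the best non-unrelated
class beats the unrelated class by a likelihood ratio of at least the
critical value (default 100) and the best class is not CO — first-cousin
calls are unreliable at these panel sizes and are reported only as
diagnostics. How a likelihood-ratio critical value in a composite-likelihood
setting maps onto thresholds used by map-aware software is not asserted;
the semantics here are exactly as stated and configurable.

Screening runs separately within each population (frequencies from that
population) and, for inter-population pairs, within each geographic region
(pooled regional frequencies, testing only pairs from distinct populations).
Population-specific frequencies applied to structured pools are a known
source of spurious relatedness; this is why inter-population second-degree
calls are never used for exclusions (below). Populations where relative
inference is known to be unreliable can be opted out via
`relatedness_config(exclude_populations=)`. `find_trios()` reports
individuals with accepted PO calls to two partners that carry no accepted
call between them; a three-generation chain is rejected because its flanking
pair is called second-degree.

# Standardized subsets

`build_subsets()` produces three nested sets: (1) no MZ pairs and no
inter-population first-degree relatives, (2) additionally no
intra-population first-degree relatives, (3) additionally no
intra-population second-degree relatives. Both members of inter-population
MZ and first-degree pairs are removed — when two supposedly distinct
populations contain the same person or a parent-offspring pair, the correct
population affiliation of either member is unknowable. Intra-population
pairs lose one member. Inter-population second-degree pairs are never
excluded.

For the one-member removals, the governing objective is to remove as few
individuals as possible. Pure highest-degree greedy covering — remove the
individual in the most remaining pairs first — achieves this on almost all
family graphs but not all; during development a random 12-node instance was
found where greedy removes one individual more than necessary. Since
relative graphs decompose into small family components, the package instead
computes an exact minimum vertex cover per component (branch and bound,
components up to 25 nodes; larger components, which do not arise in
realistic relative graphs, fall back to greedy) and uses the greedy
preference order only to choose *among* minimum covers: individuals covering
more remaining pairs first, then individuals in more relative pairs overall,
then the member with more missing data, then a fixed lexicographic rule so
results are deterministic.

# Distances, MDS, and Procrustes against geography

The individual allele-sharing distance is
$d=1-\text{(shared alleles)}/(2\cdot\text{loci used})$, equal to
$1-(p_1/2+p_2)$; the population-level distance averages, per locus, the
proportion of shared alleles over all cross-population pairs with data and
takes one minus the mean over usable loci. Classical metric MDS
double-centers the squared-distance matrix and eigendecomposes it (backed by
`stats::cmdscale`); negative eigenvalues — allele-sharing distances are not
guaranteed Euclidean — are excluded from coordinates but reported.

Agreement between the MDS configuration and geography uses Procrustes
analysis: after optimal translation, isotropic scaling, and rotation, the
similarity is $t_0=\sqrt{1-\text{minimized normalized residual}}$, computed
from the closed-form SVD solution, together with the rotation angle
$\theta$. Reflections are allowed by default — the common Procrustes
convention — with `allow_reflection = FALSE` available since the choice is a
genuine convention, not a mathematical necessity. Geographic coordinates are
first mapped through the Gall-Peters equal-area projection
($x=R\lambda,\ y=2R\sin\varphi$), so that planar distances are not distorted
by latitude-dependent area inflation.

Significance is assessed by permuting which geographic location is assigned
to which *population*, individuals moving as blocks; this preserves the
within-population structure of the genetic configuration under the null. The
p-value uses the add-one estimator $p=(1+\#\{t_\text{perm}\ge
t_0\})/(1+n_\text{perm})$ and is never exactly zero; with $10{,}000$
permutations the smallest reportable value is just under $10^{-4}$. The
permutation loop exploits the block structure (per-population sums of the
genetic configuration), so each permutation costs $O(P)$ rather than $O(n)$.
`region_balanced_subsample()` supports ordinations with equal regional
sample sizes; it samples individuals ignoring population membership, so not
every population need be represented.

# Trees

`neighbor_joining()` is the standard Saitou-Nei agglomeration with two
pinned conventions: $Q$-matrix ties break to the lowest label-index pair,
and negative branch lengths are clamped to zero with the deficit moved to
the sister branch so path lengths are preserved (disable with
`clamp_negative = FALSE`). On additive matrices the generating tree is
recovered to machine precision; tests verify this against a path-length
oracle and against the independent `ape::nj` implementation.
`bootstrap_distance_trees()` resamples loci with replacement, rebuilding the
population distance matrix from a precomputed per-locus sharing table so a
thousand replicates are cheap; replicates in which some population pair
loses all usable loci are dropped and counted. `greedy_consensus()` ranks
bipartitions by frequency and accepts each in order when compatible with
those already accepted; ties at equal frequency resolve by the canonical
lexicographic order of the split (flagged, since consensus programs differ
silently here), and supports are written as internal node labels in Newick
output.

# Heterozygosity and the founder gradient

Per-locus expected heterozygosity uses the finite-sample estimator
$\frac{2n}{2n-1}(1-\sum_a \hat p_a^2)$ over the $2n$ non-missing gene
copies. With known close relatives in the sample, $\sum\hat p_a^2$ is
inflated beyond binomial expectation; deriving
$E[\sum_a\hat p_a^2]$ under pairwise kinship gives the unbiased estimator

$$\hat H=\frac{4n^2}{4n^2-2n-S}\Bigl(1-\sum_a\hat p_a^2\Bigr),
\qquad S=8\sum_{\text{pairs}}\theta_{ij},$$

with kinship $\theta$ implied by the accepted call (MZ $\tfrac12$, PO and FS
$\tfrac14$, second degree $\tfrac18$), summed per locus over pairs whose
members are both non-missing there. With no relatives, $S=0$ recovers the
uncorrected form exactly; unbiasedness under simulated pedigrees is the
tested contract (naive bias about $-0.018$ under six full-sib pairs in a
twelve-individual sample, corrected bias within Monte-Carlo error of zero).
Loci at which every individual is missing are omitted and listed.

Geographic distances from an origin follow waypoint routes: haversine
great-circle legs (radius 6371 km) summed through designated cities that
approximate overland migration corridors. The default rule table routes
Sub-Saharan African populations (and the named North-East African
exceptions) directly, European populations through Cairo and Istanbul,
Oceanian through Cairo and Phnom Penh, Native American through Cairo,
Anadyr, and Prince Rupert, and everything else through Cairo. Waypoint city
coordinates are standard atlas values shipped as an editable configuration;
whether intermediate cities beyond Cairo intervene on the Americas route is
ambiguous in common usage, and the default (Cairo then Anadyr then Prince
Rupert) can be overridden per region or per population.
`heterozygosity_distance_regression()` fits ordinary least squares of mean
heterozygosity on route distance over populations with at least five
individuals (configurable) and reports slope and $R^2$.

# The synthetic generator

`simulate_panel()` emulates exactly the structural features the pipeline
consumes. Per-locus ancestral frequencies are Dirichlet(1) vectors over a
random window of about 10 adjacent states on a dinucleotide ladder (80-140
nt). A founder chain applies, at each step, a founding bottleneck (default
50 diploids, 10% of the drift size) followed by 30 generations of
multinomial drift at size 500 with symmetric single-step mutation at
$5\times10^{-4}$ per copy per generation — enough to produce a clean,
monotone serial-founder heterozygosity gradient without a coalescent
simulator. Individuals are drawn under HWE; relatives by explicit Mendelian
transmission from simulated ancestors (MZ, PO, FS, HS, GG, AV, and
parent/parent/offspring trios); duplicates are the same underlying genotypes
re-observed in a second data set with independent error and missingness.
Data-set artifacts are applied last: per-locus integer offsets, one-repeat
slips ($\pm2$ nt) at rate 0.008 per allele call, and per-genotype
missingness at 0.03, matching the scale of missingness the filters are
designed around. The truth record carries every injected offset, duplicate,
relationship, the generating frequencies and their exact heterozygosities,
population coordinates along a great-circle route, and the artifact-free
merged table a correct pipeline must reproduce.

What the generator does *not* emulate — real allele-frequency spectra,
linkage between loci, inbreeding, admixture, allele-specific calling
artifacts beyond the mismatch test case — bounds what passing tests show:
they demonstrate that the procedures are implemented correctly under their
own assumptions, not that those assumptions hold in any particular real data
set.

Note the deliberate asymmetry between the generator's error model (physical
one-repeat slips) and the classifier's (frequency-replacement): classifier
accuracies are measured under model misspecification, as they would be in
practice.

# Validation sizes and numerical choices

The shipped validation (testthat suite plus `scripts/acceptance.R`) uses:
offset recovery on 600 loci with 97 offsets and 28 duplicate pairs;
duplicate screening on the same design without offsets; classifier accuracy
on 500 pairs per class (tests) or 200 (script) at 600 loci; 200 null
replicates of the permutation test at 999 permutations; 1000/500 replicates
for estimator bias; 20 founder-chain
seeds; and an eight-data-set end-to-end merge at 300 loci. These sizes give
comfortable Monte-Carlo resolution for the stated checks while keeping a
full run in the low minutes on one core.

Other numerical conventions: genotypes are canonicalized as (min, max) pairs
on ingest; both alleles of a genotype are present or both missing; the
missing sentinel in files is $-9$ (configurable); degenerate inputs
(zero-variance Procrustes configurations, pairs with no shared loci,
populations missing all data) are errors, not silent NAs; loci carrying an
allele absent from the frequency group are skipped per pair in likelihoods
rather than contributing $-\infty$; and every stochastic routine is
deterministic under a supplied seed.

# Known limitations

* The composite likelihood ignores linkage; with dense mapped panels a
  map-aware HMM separates second-degree pedigrees and gains power.
* Count-estimated frequencies include the tested pair; at very small
  population samples this biases likelihood ratios conservatively.
* Offset inference requires duplicate pairs; with none, loci cannot be
  aligned and are reported as such rather than guessed.
* The relative-corrected heterozygosity assumes non-inbred individuals and
  accurate relationship calls; kinship from misclassified pairs propagates
  into the correction.
* Bootstrap consensus supports inherit the usual caveats of greedy
  consensus: order of incompatible mid-frequency splits can depend on the
  documented tie rule.
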