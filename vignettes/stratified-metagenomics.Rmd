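---
title: "Depth-resolved metagenomic profiling with stratiprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved metagenomic profiling with stratiprof}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

In temperate seas the photic water column alternates between a
stratified regime (roughly May to November), in which temperature,
light and nutrients form strong vertical gradients, and a mixed winter
regime in which those gradients vanish. `stratiprof` implements the
quantitative machinery for asking how prokaryotic communities respond:
which genomes occupy narrow depth bands (*stenobathic*), which span the
whole photic zone (*eurybathic*), and which appear only under
stratification or only during winter mixing. The intended design is a
depth series sampled every 15 m through the photic zone (15–90 m) during
stratification plus a winter pair (20 and 80 m), and that design is what
the bundled synthetic generator emulates.

# The recruitment model

The central statistic is read recruitment at high nucleotide identity.
A read recruits to the genome holding its maximal-scoring local
alignment (both strands searched) and is counted iff

* percent identity ≥ 99 (identity = matches / alignment columns, gaps
  counting as columns), and
* alignment length ≥ 50 columns.

Each read counts at most once, for its best-hit genome; score ties
break lexicographically by genome id so that reruns are bit-identical.
Counts are normalised to **RPKG** — reads per kilobase of genome per
gigabase of metagenome:

$$\mathrm{RPKG} = \frac{c}{(L_g/10^3)\,(B/10^9)}$$

with $c$ the recruited read count, $L_g$ the genome length in bp and
$B$ the total sequenced bases of the sample (not its read count). A
genome is *present* in a sample when RPKG ≥ 3 there; a genome is
retained at all when it is present in at least one sample. All three
thresholds are inclusive.

Presence across the stratified series is then classified:
**stenobathic** = one depth, or two adjacent depths, occupied;
**eurybathic** = all sampled depths occupied; **intermediate** =
anything else; **absent** = none. Two occupied depths separated by a
sub-threshold dip are *not* stenobathic — strict adjacency is used.
Seasonal occupancy compares the stratified and mixed groups: present in
both = `always`, in exactly one = `stratified_only` / `winter_only`.

## Aligner implementation and its assumptions

The aligner (in C++) is seed-and-extend: exact 16-mer seeds at stride 4
along the read locate candidate diagonals, and the maximal-scoring
*ungapped* segment (match +1, mismatch −2) on each diagonal is taken as
the local alignment. Restricting to gap-free alignments is deliberate:
the package's simulator uses a substitution-only error model (no
indels), under which ungapped and gapped local alignment coincide, and
it keeps identity arithmetic exact. On real indel-bearing data the
aligner under-recruits reads with indels; that is a documented
limitation, not a silent approximation. rRNA regions are not masked
before recruitment, which can inflate counts for genomes sharing
near-identical rRNA operons; this bias is inherited from the method
being modelled.

# The synthetic community generator

The generator is first-class, tested code; its defaults *are* the study
conditions for every end-to-end guarantee the package makes.

**Genomes.** Order-3 Markov sequences. Every transition row emits G+C
with exactly the target probability, so realised GC concentrates
tightly on the target (±2% at 100 kb is comfortably met), while the
within-GC and within-AT splits are drawn per context with jitter 0.6,
giving each genome a distinct tetranucleotide signature — the feature
that makes composition binning work and that real genomes exhibit as
their "genome signature".

**Niches.** Depth profiles are Gaussian,
$a(d) = p\,\exp(-(d-\mu)^2/2\sigma^2)$, with a flat flag for eurybathic
taxa and a separate winter weight. Width 0 collapses to an indicator at
the nearest sampled depth. The default 12-genome community holds 8
stenobathic niches (4 centred on sampled depths with σ = 2.5 m, 4
centred midway between two depths with σ = 4 m), 2 flat eurybathic
genomes present year-round, and 2 winter-only genomes. The widths come
from the threshold arithmetic: at 50,000 reads × 150 bp per sample the
3-RPKG presence threshold on a 60 kb genome corresponds to ≈1.4 reads,
so niches are shaped to put occupied depths orders of magnitude above
that and unoccupied depths orders of magnitude below. Expected counts
at a depth 15 m from a σ = 2.5 niche centre are suppressed by
$e^{-18}$; for the σ = 4 straddling niches the two flanking depths
carry $0.17\,p$ each while the next depth out is suppressed by
$e^{-16}$ relative to peak.

**Markers.** Each genome carries one 16S copy (a distinct taxon from
the bundled reference, diverged 1.5% from its centroid), one recA and
one radA (diverged ~8% from their family template per genome), and 0–1
rhodopsins with a declared tuning class (third-codon-position
divergence that preserves the tuning codon and never introduces
stops). The per-genome divergence matters: identical marker copies
across genomes would multi-map at the 99% filter and destroy
recruitment specificity; ~8% divergence puts cross-genome marker
identity far below the filter, as paralogue families in real genomes
typically are.

**Reads.** Length-weighted sampling (probability ∝ abundance × genome
length) so that RPKG recovers relative cell abundance up to a constant;
uniform positions; equiprobable strands; i.i.d. substitution errors at
rate 0.002 (a realistic post-filter Illumina rate), read length 150 bp.
Per-read source genome, position and strand are recorded as truth.

**Ground truth labels.** Depth-range and occupancy truth is defined by
converting the *expected* count profile (the configured niches, length-
weighted and normalised) to expected RPKG and applying exactly the same
threshold and classification rules. This makes the truth deterministic
and independent of any particular read realisation while remaining
faithful to what the classifier can in principle recover.

**What the generator does not emulate.** No indels, no quality scores,
no paired-end structure, no chimeras, no strain-level microdiversity
clouds (one sequence per genome), no rRNA operon sharing between taxa,
and genomes of 60 kb stand in for megabase genomes. Passing tests
therefore demonstrate correctness of the statistical machinery under
the stated model, not robustness to assembler- or platform-specific
artefacts.

# The 16S fragment cascade

The reference is built by greedy identity clustering in input order
(radius 0.90): a sequence joins the first centroid at ≥ 90% global
identity, otherwise founds a new centroid. The bundled synthetic
reference holds 14 taxa (10 bacterial, 4 archaeal) derived from two
domain cores; because its divergence is substitution-only the set is
equal-length and doubles as a gap-free alignment.

The cascade is screen → verify → classify:

1. **Screen** (recall-oriented): best local alignment to any centroid
   at ≥ 70% identity over ≥ 40 bp. This replaces a database E-value
   screen, which would depend on database size.
2. **Verify**: best ungapped placement along per-domain positional
   log-odds profiles ($\log_2$ frequency over uniform background,
   pseudocount 0.5). The cutoff is calibrated from mononucleotide
   shuffles of the candidates themselves — the 99.5th percentile of the
   null best-score distribution — so composition alone cannot pass.
3. **Classify**: best-identity centroid, kept iff identity ≥ 80% and
   alignment length ≥ 90 bp (inclusive); the fragment takes the
   centroid's full lineage and tables are cut at the requested rank,
   with Proteobacteria conventionally reported at class level.

Relative abundances are percentages of classified fragments; the
display table keeps taxa reaching 1% in some sample and folds the rest
into `other`. Diversity is the Gini–Simpson index $D = 1-\sum p_i^2$,
the probability that two random fragments come from different taxa.

# Whole-metagenome similarity

Reciprocal read matching: the fraction of (seeded, subsampled) reads of
one sample with an end-to-end match at ≥ 95% identity to some read of
the other, computed in both directions and averaged. End gaps count as
columns, so a shift of $s$ between two overlapping 150 bp reads caps
identity at $(150-s)/(150+s)$ — only near-coincident reads match, which
is what makes the statistic sensitive to shared community content at
high coverage. Samples are clustered by complete-linkage `hclust` on
euclidean distances between similarity-matrix rows (linkage exposed as
a flag; the tree is exported as newick with branch lengths).

# Binning and marker-based quality

Contigs ≥ 10 kb take a taxon when strictly more than half their genes
agree; everything else is `unclassified`. Features per contig (≥ 1 kb):
canonical tetranucleotide frequencies (4-mers pooled with reverse
complements into 136 keys, N-containing windows skipped, normalised),
GC, and per-sample coverages. TNF is centred, scaled and projected onto
the top principal components (signs fixed so the largest-magnitude
loading is positive); GC and $\log_{10}(\text{coverage}+0.1)$ join as
extra standardised axes — the log tames coverage's dynamic range and
the pseudo-count keeps absent samples finite.

The original procedure this codifies was interactive inspection of PCA
plots; reproducibility requires an algorithm, so binning is
taxonomy-stratified density clustering (DBSCAN, `min_pts` 4, `eps`
defaulting to twice the median distance to the `min_pts`-th neighbour
per group). Noise points stay unbinned. Two genomes with identical
composition and coverage can merge — the known failure mode of all
composition binning — and the duplicated-marker contamination estimate
is what flags it.

Completeness = % of a universal single-copy catalogue (35 or 111
markers) present; contamination = extra copies beyond the first as a %
of the catalogue. These are the simple estimators; lineage-specific
marker sets are out of scope.

# Rhodopsins

Genes are detected on contigs ≥ 5 kb by six-frame translation and local
protein alignment (BLOSUM62) to bundled exemplars, at ≥ 40% identity
over ≥ 70% exemplar coverage; per frame the best hit is masked and the
frame rescanned so multiple copies are found. Spectral tuning reads a
single residue: the query is aligned globally to the tuning reference
and the residue in the column of reference position 105 decides —
leucine (L) green, glutamine (Q) blue, anything else (or an unalignable
query) unknown. The convention is pinned by the shipped reference, and
the call is invariant to synonymous nucleotide changes by construction.

Community rhodopsin abundance normalises length-corrected rhodopsin
read counts by length-corrected recA+radA counts:

$$\widehat{R} \;=\; \frac{n_{rho}/\bar L_{rho}}
  {(n_{recA}+n_{radA})/(\bar L_{recA}+\bar L_{radA})}$$

Because recA and radA are universal single-copy genes, the denominator
counts genome equivalents and $\widehat{R}$ estimates rhodopsin copies
per genome. The length normalisation is per gene copy (mean family
gene length); normalising by *summed* reference length would cancel the
rhodopsin-bearing fraction and is the one implementation of the verbal
formula that cannot work. Zero recA+radA reads is an error (the sample
is too shallow to normalise), and an optional exclusion reference list
removes reads whose best hit is viral/eukaryotic. Per-gene depth
profiles use the same recruitment contract with gene length in the
RPKG denominator; genes never reaching 1 RPKG are dropped (inclusive).

# Functional profiles

GH rates: EQ = GH genes per 1000 genes of a taxon;
NORM = EQ × (taxon's 16S percentage / 100). The source description
("normalized by the percentage of 16S rRNA reads") does not name the
operator; multiplication is used because NORM is presented as a
community-level contribution, and dividing would inflate rare taxa. A
`mode = "divide"` flag exposes the per-capita reading. Family counts
cross-tabulate GH-annotated genes on classified contigs ≥ 5 kb by
taxon × depth group (UP = 15/30 m, DCM = 45/60 m, LP = 75/90 m,
MIX = winter). Category matrices are z-scored per row with the n−1
standard deviation; zero-variance rows become NA and are flagged.

# Environmental metrics

N:P = total N / total P, reported at two decimals with half-away-from-
zero rounding. Flow-cytometry concentration
$N = 1000\,n/(q\,t)$ with $q$ in µL/min and $t$ in minutes (a seconds
argument converts, since runs are usually quoted in seconds). The
bundled nine-sample nutrient table reproduces its printed N:P row
exactly in the seven autumn/deep columns; the two winter columns
disagree by ≤ 0.8, consistent with the printed inputs having been
rounded from rawer measurements — tests pin the exact columns and bound
the winter discrepancy instead of asserting equality.

# Numerical and testing choices

* Coordinates are 0-based half-open throughout; N is allowed in
  sequences and excluded from GC and k-mer statistics.
* Seed k-mer lengths: 16 (stride 4) for the 99%-identity recruitment
  and read-vs-read matching; 10 (stride 1) against the divergent 16S
  centroids. Exact-seed alignment cannot find matches with no exact
  k-mer run, which is immaterial at the identity levels the thresholds
  target but explains why adversarially even mismatch spacings evade
  detection.
* The read-vs-read matcher prunes candidates whose alignment span
  already caps identity below the threshold and stops at the first
  qualifying match; both shortcuts are exact with respect to the
  ≥-threshold decision.
* Problem sizes: the default study is 12 genomes × 60 kb and 8 samples
  × 50,000 reads × 150 bp; end-to-end guarantees run it across 5 seeds.
  The rhodopsin regimes use 12–20 genomes × 12 kb at 60,000 reads over
  10 seeds; binning uses 3 × 200 kb genomes in 20 kb windows. These
  sizes put every stochastic check several standard errors away from
  its threshold while keeping a full run on a single CPU inexpensive.
* All randomness flows through R's RNG (the C++ kernels draw via
  `unif_rand`), so a single `set.seed` reproduces everything.

# Known limitations

Assembly, gene prediction and database annotation are out of scope —
genes, taxonomy labels and GH families are inputs. The aligner is
gap-free (see above). Sequence-identity clustering and protein
alignment use O(nm) dynamic programming and are meant for
reference-scale, not read-scale, inputs. The synthetic 16S/rhodopsin
references are labelled synthetic and pin conventions (tuning position,
domain profiles) rather than reproducing natural sequence families.
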