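---
title: "Benchmarking virome assembly and diversity estimation with simulated mock communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking virome assembly and diversity estimation with simulated mock communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viromock)
```

## Why simulated mock communities

Assemblies of viral metagenomes cannot be validated against reference
databases the way bacterial metagenomes often can: most environmental
viruses have no close reference. The practical alternative is an *in
silico* mock community — a set of genomes with known sequences, known
relative abundances and known relatedness structure — from which reads are
simulated, assembled and scored against the ground truth. `viromock`
implements that entire loop except the assembly itself, which is an
external tool's job: it simulates the communities and reads, scores contigs
returned by any assembler, and estimates community diversity from contig
spectra.

Two community designs are built in. The *evolved mock community* is a
single 300-genome community (6 families × 50 genomes) whose genomes are
related at controlled levels: per family, 10 genomes are left unmodified
and 40 are generated from 8 source genomes as sibling groups — two pairs
and two octets at each of two per-site transition rates (0.01 and 0.0025),
i.e. duplicates of all four rate × group-size combinations. Within each
family's power-law rank-abundance list, one unmodified genome is
intercalated after every four evolved genomes, so reconstruction can be
read off at every abundance level with and without sibling interference.
The *benchmark set* is a factorial collection of communities crossing
richness with evenness (rank-1 abundance), 25 replicates per cell by
default, used to probe diversity estimators.

## Sibling evolution and the transition-rate calibration

Siblings are evolved from a source genome along a random bifurcating tree:
a pure-birth topology (a uniformly chosen active lineage splits until the
requested number of tips exists) with i.i.d. exponential branch lengths,
rescaled so the mean root-to-tip depth equals `tree_scale`. Along a branch
of length $t$ each site substitutes independently with probability
$\min(1, \alpha t)$; substitutions are transitions (A↔G, C↔T) by default.
No indels are introduced, so genomes stay length-aligned and the average
nucleotide identity (ANI) between two siblings is simply the fraction of
identical positions.

The single free scale of this process, `tree_scale`, is fixed by
calibration rather than by convention: `calibrate_tree_scale()` simulates a
fixed bank of trees (common random numbers) and root-finds the scale at
which the *expected* mean pairwise ANI at $\alpha = 0.01$ equals 0.85. The
expectation is computed exactly given each tree — a site differs between
two tips iff an odd number of flips occurred on the path, so
$P(\text{differ}) = \tfrac12\bigl(1 - \prod_e (1 - 2\,\alpha t_e)\bigr)$
over the path's branches — which makes the objective smooth and the
root-finding deterministic. The calibrated default is `tree_scale = 12.149`.
A deliberate cross-check is that the *other* rate is not calibrated: with
the scale fixed at the $\alpha = 0.01$ target, substitution accumulation is
still nearly linear at $\alpha = 0.0025$, so the mean pairwise ANI among 10
siblings should land around 0.95–0.96 without any further adjustment. The
acceptance suite verifies exactly this.

## Read simulation

`simulate_reads()` draws source genomes multinomially from the community's
relative abundances, start positions uniformly (genomes are linear; reads
never wrap an origin — one reason short genomes are later excluded from
reconstruction scoring), strands with probability 1/2, and injects errors
from a parametric platform profile: a per-base substitution probability
ramping linearly along the read, plus a uniform per-base indel probability
whose insertions duplicate the current base (homopolymer-style). The
bundled profiles are deliberately simple stand-ins for empirically trained
error models: 454-FLX+ (700 bp single-end) and 454-Ti (450 bp) with flat
0.001 substitutions and 5e-4 indels; GAIIx/HiSeq/MiSeq paired-end profiles
with a 0.001→0.01 substitution ramp and no indels. Paired profiles use a
500 ± 50 bp insert. Every read keeps its provenance (source genome, start,
strand), which downstream metrics treat as ground truth. What this
generator does **not** emulate: sequence-context-specific error hotspots,
quality-score structure (a constant Q30 placeholder is written to FASTQ),
or coverage bias along genomes (e.g. %GC effects). Passing tests therefore
show correctness of the scoring machinery under idealized uniform
sampling, not robustness to platform-specific coverage artifacts.

## Assembly scoring

Contigs shorter than 500 bp are removed, mirroring standard practice.
Contig-to-genome alignments (nucmer-style coords; 1-based inclusive on
disk, 0-based half-open internally, converted exactly) are filtered at
≥95% identity and ≥100 bp, both inclusive; per contig, only alignments to
its best-scoring genome are retained. That "best-scoring alignments"
plural is read as: all (split) alignments of the contig to its top genome
survive for *coverage* purposes, while *accuracy* uses the single
top-scoring alignment — coverage needs the union of split alignments,
accuracy is defined on one local alignment. Ties for the best genome break
lexicographically; ties for "longest contig" break by greater aligned
length, then id.

Per genome (genomes under 1700 nt excluded, because short circular genomes
interact with the alignment thresholds): *overall contig coverage* is the
percentage covered by the union of all retained alignments; *maximum
contig coverage* the percentage covered by the single longest aligning
contig. Per contig: *accuracy* = identity × (aligned fraction of the
contig) × 100, and *chimericity* = Shannon entropy (natural log) of the
distribution of source genomes among the contig's mapped reads — 0 for a
single-origin contig, ln 2 for a perfect 50/50 chimera. Natural log is the
right base here because the reported few-genome mixtures take values
around ~1.3, consistent with ln for 3–5-way splits. *Coverage by others*
(CbO) counts reads mapping to a genome minus reads truly originating from
it, per bp of genome; its ratio to the genome's own per-bp read coverage
(CbO/C, equivalently foreign/own reads) gauges how much material other
genomes could steal or contribute during assembly. Paired comparisons
between platform/assembler/depth combinations use two-sided Wilcoxon
signed-rank tests; all-zero difference vectors are reported as p = 1
rather than an error. Sibling-similarity structure is summarized by
classical metric scaling (PCoA) of d = 1 − ANI, with the centroid-nearest
member identified (classical scaling centres the configuration, so that is
the member with the smallest coordinate norm).

The repeat scan answers one narrow question — could long exact repeats
explain poor maximum contig coverage? `longest_repeat()` finds the exact
length of the longest substring occurring at two or more positions by
binary search on the span length with a hashed duplicate-substring check;
the predicate is monotone (a repeat of length L contains one of length
L − 1), so the result is exact at any length, including repeats shorter
than a fixed anchor size would see.

## Contig spectra

A contig spectrum is the vector $c_q$ counting contigs assembled from
exactly $q$ reads. `build_spectrum()` forms it by single-linkage
clustering of reads under an overlap criterion (98% identity over ≥35 bp,
both strands, both thresholds inclusive). The base criterion is ungapped —
every end-to-end offset is scanned — which is fast and exact for
substitution-only differences. Because the 454 profiles simulate indels,
and an indel shifts the frame of an ungapped comparison, the spectrum
builders default to a *gapped* fallback: a pair failing every ungapped
offset is re-tested with an ends-free overlap alignment in which gap
columns count as identity errors (a shared 11-mer prescreen rejects
unrelated pairs cheaply). This mirrors how overlap assemblers treat
indel-type errors. The effect is not cosmetic: strictly ungapped
clustering of indel-bearing 454 reads systematically splits true overlaps
whose frames are shifted, deflating the multi-read entries of the
spectrum, and the downstream richness fit can then lose its interior
minimum in S; gapped clustering restores the spectrum the island model
expects.

Production clustering indexes shared 14-mers (integer-coded) to propose
(pair, orientation, offset) candidates and verifies each against the same
criterion; a quadratic all-pairs mode is retained and the two are checked
for exact agreement in the tests. 14 rather than a longer anchor keeps
candidate recall high when overlaps carry errors: a clean 20-base run
inside a minimal 35 bp overlap is frequently destroyed at ~2% combined
mismatch density, and a missed candidate (unlike a false one) cannot be
repaired by verification.

`subsampled_spectrum()` limits coverage before clustering: each of 10
repetitions (a chosen default; the upstream tool's repetition count is not
documented) samples `ceiling(fold_coverage × mean genome length / mean
read length)` reads without replacement at 3× fold coverage, and spectra
are averaged element-wise — so averaged counts may be fractional, while
read conservation $\sum_q q\,c_q = n$ holds exactly per repetition and in
the mean.

## Diversity estimation

The estimation model treats each species' reads as a Lander–Waterman
coverage process. With $n_i = n a_i$ reads of length $L$ on a genome of
length $G$ and minimum detectable overlap $T$, species coverage is
$c_i = n_i L / G$ and the effective overlap fraction $\sigma = 1 - T/L$;
the expected number of $q$-read contigs is

$$E[c_q] = \sum_i n_i\, e^{-2 c_i \sigma} \left(1 - e^{-c_i
\sigma}\right)^{q-1},$$

whose geometric series sums to exact read conservation. Abundances $a_i$
come from a parametric rank-abundance model: power ($a_r \propto r^{-b}$),
log-series ($\propto e^{-br}/r$), exponential ($\propto e^{-br}$), a
discretized lognormal ($\propto e^{b\,\Phi^{-1}((S-r+0.5)/S)}$), or
uniform. `fit_spectrum()` minimizes $\sum_q (obs_q - exp_q)^2 /
\max(exp_q, 10^{-6})$ — a relative-error (Pearson-style) objective chosen
because spectrum entries span orders of magnitude; the reference tool's
exact objective is not published — over form, richness $S$ and the form
parameter. Bins whose expected count falls below 1 are pooled with the
analytic high-$q$ tail into a single bucket before the comparison
(Cochran-style pooling): a 10-repetition-averaged spectrum carries
fractional counts like 0.1–0.5 in its far tail, and comparing those
bin-by-bin against near-zero expectations lets sampling noise in
statistically empty bins dominate the objective and drag the fitted
richness toward the grid edge. The
exhaustive search scans all five forms on a 50-point log grid of $S$ from
1 to $10^6$, refines $S$ locally per form between the neighbouring grid
points, and optimizes the single form parameter by golden-section search
on a log scale; everything is deterministic. Two numerical details
matter. First, species whose island-extension probability $1 -
e^{-c_i\sigma}$ is below $10^{-6}$ contribute only singletons (their
multi-read terms are bounded by $n \times 10^{-6}$), which keeps
million-species evaluations affordable without changing the optimum.
Second, candidates displace the incumbent only on a genuine error
improvement; at numerically equal error the smaller $S$ wins. Without this
parsimony tie-break, forms that can park surplus species at vanishing
abundance would report arbitrarily inflated $S$ at identical fit.

Richness is the fitted $S$; Shannon diversity is the entropy of the fitted
abundances; evenness is Shannon over $\ln S$ (defined as 1 for $S = 1$).
The fit flags degenerate spectra (all mass in $c_1$) as wide-confidence.

Two comparison estimators embody the failure modes the benchmark is
designed to expose. `frequency_count_richness()` treats the spectrum as
capture frequency counts — observed clusters plus $c_1^2/(2c_2)$ (the
bias-corrected $c_1(c_1-1)/(2(c_2+1))$ when $c_2 = 0$) — a deliberate
proxy for the frequency-count estimator class whose defining assumption is
that each contig represents a distinct genome; with genomes sequenced at
multi-read depth that assumption inflates richness by orders of magnitude,
which is the property under test, so the full parametric-mixture machinery
of such tools is out of scope. `clustering_richness()` greedily clusters
whole metagenomes at 98/90/75% identity (first-fit centroids, both
strands, identity = best ungapped matches over the shorter length). Both
can be rescaled by `genome_length_correction()`, dividing by (mean genome
length − mean read length); since that quotient carries units of per-bp,
the read-length-scaled variant (× mean read length) is also emitted, and
both columns are reported rather than silently choosing one.

## The scaled benchmark and its feasibility corner

The full factorial benchmark (S ∈ {100, 1000} × top abundance {2%, 25%} ×
25 replicates, 200,000 reads each) is scaled for routine runs to 12
communities — 3 replicates × (S ∈ {30, 100}) × (top ∈ {2%, 25%}) with
20,000 reads of ~450 bp on synthetic 5–50 kb genomes — sizes chosen so the
whole set fits in minutes while each community still yields ~200-read
spectra at 3× subsampling, the same spectrum scale the full design
produces. One corner of that scaled grid is mathematically infeasible: a
power law with top abundance 2% requires S ≥ 50, so at S = 30 the
high-evenness corner is clamped to the most even feasible community
(uniform, top = 1/30 ≈ 3.3%); at S = 100 the true 2% is used. The
acceptance suite checks that the spectrum fit is the closest of the
estimators to the true richness, that fitted richness and evenness order
the community structures correctly, and that the frequency-count proxy
exceeds the fit by at least an order of magnitude.

A caveat the tests make visible rather than hide: with ~200-read
subsampled spectra, richness is only weakly identified. Most replicates
fit within tens of percent of the truth, but the fit-error surface in $S$
is nearly flat above the true value, and occasional replicates escape to
$S$ in the thousands; the *mean* relative error across a small replicate
set is therefore heavy-tailed and can be dominated by one or two escapes
even when the typical (median) error is modest and the fitted evenness
orders every community structure correctly. At the full design size (100
communities,
25 replicates per structure) such escapes average out far less
destructively than in a 12-community scaled run.

## Determinism and degenerate inputs

Every stochastic entry point takes a seed and is reproducible to the byte
in its file outputs (fixed field formatting, no timestamps in logs,
input paths reduced to basenames). Degenerate cases are explicit rather
than silent: zero-read contigs have undefined chimericity (`NA`, excluded
from summaries); a genome with zero own reads has an undefined CbO/C
ratio (flagged); an empty contig set yields a zero-count stats record;
spectra with all mass in $c_1$ are flagged wide-confidence; infeasible
power-law requests error out with the feasibility bound.

## Known limitations

The error model is parametric, not empirically trained; absolute error
rates and their read-position structure differ from real instruments. The
evolution model is substitution-only, so ANI is positional and alignment-
free — real sibling genomes also differ by indels and rearrangements.
Overlap detection tolerates indels only through the gapped fallback's
single best alignment; heavily indel-laden overlaps may still be missed.
The clustering-richness implementation is a greedy first-fit heuristic
with a k-mer prescreen, adequate for reads differing by sequencing error
but not a general sequence clusterer at 75% identity. Scaled-down runs
replicate the *logic* of the full-size evaluation, not its numbers that
depend on external assemblers.
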