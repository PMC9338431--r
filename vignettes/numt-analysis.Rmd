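---
title: "Detecting numts and testing selection on mitonuclear genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting numts and testing selection on mitonuclear genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(numtforge)
```

## The problem

Nuclear copies of mitochondrial DNA (numts) arise when fragments of the
mitochondrial genome integrate into nuclear chromosomes. Most numts decay
into pseudogenes: the vertebrate mitochondrial and nuclear genetic codes
differ at four codons (ATA, TGA, AGA, AGG), so a freshly inserted
mitochondrial gene typically reads with premature stops under the nuclear
code, and once in the nucleus it accumulates mutations without functional
constraint, degrading its *mitochondrial* reading frame too.

Numts that deviate from this expectation are informative. An old insertion
whose mitochondrial reading frame is still intact despite many synonymous
substitutions suggests selective constraint after insertion. A young
insertion that nevertheless differs substantially from the resident
mitogenome points to a divergent donor lineage: a heteroplasmic mtDNA
variant, or mtDNA introgressed through hybridisation. numtforge implements
the complete analysis that separates these scenarios: genome scanning and
fragment clustering, genetic-code-aware reading-frame classification,
pairwise dN/dS, distance phylogenetics, and a maximum-likelihood codon-model
suite with likelihood-ratio tests, together with a synthetic-data generator
that provides ground truth for all of it.

## Discovery: scan, filter, cluster

`scan_numts()` searches the mitogenome against the nuclear scaffolds. The
search is a seed-and-extend local alignment with exact seeds of
`word_size = 20` and an E-value cutoff of 0.01, executed by the `blastn`
program behind the package's hit-table contract (the executable is the
canonical implementation of this search; the contract also makes it
replaceable). A circular mitogenome is extended by `word_size - 1` bases so
seeds can cross the origin; hits running past the end are split at position
1 and reported as two mitochondrial intervals, matching how D-loop-spanning
numts are conventionally tabulated.

Two thresholds define a numt. Hits must be *longer than* 200 bp
(`filter_hits()`, strict inequality, read literally from the defining
convention), and hits whose nuclear intervals lie within 10 kb of one
another on a scaffold are clustered into a single numt
(`cluster_fragments()`, single linkage on the gap between nearest fragment
ends, irrespective of strand or mitochondrial origin). The boundary is
exact: a 9,900 bp spacer merges, a 10,100 bp spacer splits. Numts are
numbered in genome order; fragment order within a numt follows nuclear
position. `profile_conservation()` repeats the search against other
genomes (blastn defaults) and summarises each as query cover plus top-hit
identity, the two numbers used to date insertions against a species tree.

The E-value cutoff for the discovery scan itself is not fixed by
convention; the package uses 0.01, the same value as the cross-genome
profiling step, for uniformity.

## Reading-frame intactness

`classify_reading_frame()` aligns a numt fragment to a complete
mitochondrial CDS (match +1, mismatch −1, gap open −5, extend −2; both
strands tried). By default only the overlapping segment is examined
(`mode = "overlap"`); `mode = "full"` additionally requires the whole gene
to align. The fragment's aligned codons are translated in the gene's frame
under both codes. A gene copy is *intact* when the alignment is gap-free
and contains no internal stop under the mitochondrial code; the gene's own
terminal stop is excluded (a stop there is not premature), and incomplete
stops completed by polyadenylation are not treated as stops — only the
3-nt stop set counts. Codons disrupted by indels are skipped rather than
misread, so a single indel does not cascade into frameshift stop counts.

## Pairwise dN/dS

`pairwise_dnds()` implements Nei–Gojobori (1986) counting. Each codon
position contributes the fraction of its single-nucleotide changes that
are synonymous (changes to stop codons are excluded from the denominator);
site counts are averaged over the two sequences. Codon pairs differing at
2–3 positions are averaged over all stop-free orderings of single steps.
Rates are corrected with the Jukes–Cantor formula
$d = -\tfrac{3}{4}\log(1 - \tfrac{4p}{3})$; a proportion reaching 3/4 is
reported as a saturation flag, never as infinity or NaN. Significance is a
Fisher exact test on the 2×2 table of substitutions versus remaining
sites; because the NG86 counts are fractional, the table is rounded to the
nearest integers for the test. Alongside the fractional counts the package
reports integer counts from the stop-free minimal path that maximises
synonymous steps — the form in which substitution counts are conventionally
printed — with that tie-break fixed for determinism. Genes with zero
observed substitutions get dN = dS = 0, an undefined ratio and p = 1,
mirroring the dash convention of published tables.

## Distance trees

`tajima_nei()` implements the Tajima–Nei (1984) distance
$d = -b\log(1 - p/b)$ with $b = \tfrac{1}{2}(1 - \sum_i g_i^2 + p^2/h)$
and $h = \sum_{i<j} x_{ij}^2/(2 g_i g_j)$, which reduces to Jukes–Cantor
for equal base frequencies and balanced mismatch types. Sites with gaps or
N are deleted pairwise (the common default of distance-matrix programs;
complete deletion would discard most data in ragged numt alignments).
Saturated pairs are an error naming the pair, not an infinite entry.
`neighbor_joining()` is Saitou–Nei NJ with two determinism policies: ties
in the rate-corrected criterion break to the lowest index pair, and
negative branch-length estimates are clamped to zero with the deficit
moved to the sister branch. On additive matrices it recovers the
generating tree exactly. `label_numt_clade()` partitions branches into the
numt clade (including its stem) versus the rest — the branch classes used
by the selection models — and insists the numt taxa actually form a clade
in the unrooted sense, because the branch-model formulation presupposes
one.

## Codon models and likelihood-ratio tests

The selection machinery is a GY94-family 60/61-state codon chain:
$q_{ij} \propto \pi_j \kappa^{\mathrm{ts}} \omega^{\mathrm{nonsyn}}$ for
single-nucleotide changes, zero otherwise. Every rate matrix is scaled to
one expected substitution per codon per unit branch length at
stationarity, so branch lengths are expected substitutions per codon
within a site class; the simulator uses the identical convention, making
simulation and inference mutually consistent (programs that jointly scale
across site classes express branch lengths slightly differently; omega
orderings and LRTs are unaffected). Codon frequencies come from the
alignment via F3x4 by default (position-specific nucleotide frequencies,
with a pseudocount so no sense codon has zero frequency), with F1x4 and
equal-frequency options; they are held fixed during optimisation.

`fit_codon_model()` supports one-ratio, two-ratio and two-ratio-fixed
branch models, M1a and M2a site models, and clade model C (three site
classes: shared purifying, shared neutral, and a class whose omega differs
between the numt and background partitions) plus its fixed variant with
the numt omega of class 3 pinned to 1. The likelihood is Felsenstein
pruning over site patterns (duplicate columns collapsed), with per-pattern
rescaling against underflow and transition matrices from the
eigendecomposition of the reversible generator. Optimisation is L-BFGS-B
on log-transformed parameters with bounds omega ∈ [10⁻⁶, 50], kappa ∈
[0.05, 100], branch lengths ∈ [10⁻⁸, 20]; class proportions use a softmax
reparameterisation; seeded multi-start (3 by default) guards against local
optima. Branch lengths are free per branch, which absorbs the rate
difference between mitochondrial and nuclear lineages without a clock
constraint. Columns containing an untranslatable codon in some taxon are
treated as missing data for that taxon rather than dropped.

`lrt_codon()` computes $2\Delta\log L$ against a chi-square with df
defaulting to the difference in free non-branch parameters (one-ratio vs
two-ratio: 1; two-ratio vs fixed: 1; clade C vs two-ratio: 3; clade C vs
M1a: 3; clade C vs fixed: 1), always overridable since reports rarely
print df. An omega fixed at 1 is interior to the parameter space, so the
standard chi-square applies; proportions estimated at 0 are boundary
cases and are the user's cue for caution. Small negative statistics from
optimisation noise are clamped to zero; larger violations are an error
because they contradict nesting. The function accepts bare log-likelihood
values, so published model tables can be re-examined directly.

The three-class site model often labelled "M22" in reports is interpreted
here as M2a (purifying / neutral / unrestricted), which matches its
printed three-class structure. Similarly, a clade-C class-1 omega printed
as exactly 0 is treated as a boundary estimate: the package estimates it
freely (bounded below 1) and reports it, rather than fixing it to zero.

## The synthetic-data generator

`simulate_mitogenome()` builds a 16.5 kb circular genome with a leading
2.6 kb rRNA/tRNA block, 13 protein-coding genes with vertebrate-like
lengths separated by 60 bp spacers, and a trailing D-loop; every gene is a
stop-free ORF under the mitochondrial code by construction. All genes are
placed on the forward strand (real mitogenomes carry ND6 on the reverse
strand; strandedness of insertions is exercised separately by planting
reverse-complemented copies).

`simulate_numt_landscape()` plants insertions with controlled source,
age, strand and fragmentation. Functional donors (heteroplasmic/hybrid)
are evolved to the requested divergence with stop-creating changes in
genes rejected and nonsynonymous changes accepted with probability 0.2,
emulating purifying selection on an expressed mitochondrial lineage; the
target number of substitutions is placed at distinct sites, separately for
gene and non-gene regions, so realized divergence tracks the target
uniformly along the molecule. Post-insertion evolution is uniform per-site
substitution at the nuclear rate with no coding constraint, plus optional
indels (geometric lengths, mean 2, at 5% of the substitution rate; off by
default so frame analyses stay exact). Divergences are expressed as the
expected proportion of changed sites, appropriate for the ≤ 0.3 range the
generator targets; multiple hits per site are not modelled. The default
nuclear:mitochondrial rate ratio for aging scenarios is 1:10,
configurable.

`default_numt_landscape()` fixes the reference study conditions: 12
events on four 250 kb scaffolds, total lengths 250–14,000 bp, ages 0–0.12,
one to four fragments per event with spacers below the clustering gap,
both strands, and all three donor types. These values were chosen once to
span the regimes the thresholds must separate (a 250 bp exact copy just
above the length filter; a 12%-diverged copy near the practical identity
limit of a 20-mer-seeded scan; fragmented events bracketing the 10 kb
rule) and are not tuned thereafter.

What the generator does not emulate: repeat landscapes and
retrotransposon context, assembly artefacts, sequencing error, rate
variation among nuclear sites, and multiple hits at high divergence.
Passing the round-trip tests therefore demonstrates the pipeline's logic
and calibration, not robustness to repetitive real genomes.

`simulate_codon_alignment()` evolves codon sites along a labelled tree
under exactly the fitted model family. The package's reference simulation
design, `numt_demo_tree()`, is a six-taxon tree (three numt, three
background taxa; numt subtree length 0.9), sized so that a clade omega
near 1 is estimated with standard error about 0.1 from 500 codons —
reflecting the multi-species design of real numt selection studies rather
than a minimal quartet, where the same estimator is unbiased but far
noisier.

## Problem sizes and numerical choices

The validation suite runs at deliberately modest sizes chosen for tight
oracle checks: brute-force likelihood summation on 4-leaf trees with ≤ 25
codons (exhaustive over internal-state pairs), exhaustive single-mutant
enumeration over all sense codons of both codes, 50 random additive
matrices of up to 8 taxa for NJ, 500-codon alignments and 20 replicates
for parameter-recovery studies, and 10 seeds for the clustering boundary.
Convergence uses L-BFGS-B's default gradient tolerance with `factr = 1e7`;
fits report the number of converged restarts. Degenerate inputs fail
loudly: stop codons passed to site counting, non-symmetric distance
matrices, saturated distances, non-monophyletic clade labels and nesting
violations are all errors, not silent NAs.

## The pipeline

`run_pipeline()` chains the stages — scan → filter → cluster → frame
classification → dN/dS on intact genes → NJ trees for genes with more
than five nucleotide substitutions (a strict-inequality config constant)
→ optional codon-model fits → age classification — writing TSV reports
shaped like the standard numt summary, per-gene dN/dS and model/LRT
tables, Newick trees, and a JSON manifest with per-stage counts and
output checksums (reruns with identical inputs and seed reproduce
identical checksums). `classify_numt_age()` codifies the qualitative
dating narrative as explicit rules with dS taking precedence over
conservation profiles: dS > 1 or presence in all comparison genomes →
ancient; dS < 0.1 or absence from all → recent; otherwise intermediate;
no evidence → unclassified. The rule precedence is this package's
codification of an informally argued inference, and the thresholds are
ordinary config values.
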