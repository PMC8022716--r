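---
title: "Detecting Chi-like recombination motifs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Chi-like recombination motifs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiscan)
```

## The biological problem

Chi sites are short DNA motifs — `GCTGGTGG` in *Escherichia coli* — whose
recognition by the RecBCD helicase–nuclease switches the complex from DNA
degradation to recombination initiation. A genome that relies on a Chi motif
leaves two statistical fingerprints:

1. **Overrepresentation in the core genome.** Selection for efficient repair
   of essential regions enriches the motif far beyond what the genome's
   oligonucleotide composition predicts, and the enrichment is concentrated
   in the conserved (core) gene repertoire.
2. **Leading-strand polarization.** RecBCD recognizes Chi in a fixed
   orientation relative to replication, so occurrences cluster on the leading
   strand and the strand of occurrence flips at the replication origin and
   terminus.

`chiscan` turns each fingerprint into a test statistic and combines them into
per-species candidate calls, together with the supporting machinery: pseudo
core-genome construction, candidate motif-set generation, false-positive
estimation on an outgroup, parsimony mapping of presence/absence onto a
phylogeny, and a synthetic-genome generator that makes the whole pipeline
verifiable without any external data.

## The overrepresentation statistic

For a word $w$ of length $h$ (octamers throughout the Chi analysis) counted
on the core gene sequences, the null model is a stationary Markov chain of
order $m \in \{0, \dots, 5\}$ — order 0 captures mononucleotide composition,
order 5 hexanucleotide composition. All counts are overlapping windows that
never span sequence boundaries; windows containing `N` are skipped
everywhere.

The expected count is the classical maximal-overlap plug-in estimator built
from the $(m{+}1)$-mer and $m$-mer counts of the *same* sequences being
scored:

$$\hat E_m(w) = \frac{\prod_{j=1}^{h-m} N(w_j \dots w_{j+m})}
                     {\prod_{j=2}^{h-m} N(w_j \dots w_{j+m-1})},$$

with $N(\varepsilon)$ the total 1-mer window count, so that for $h = m+1$
the estimator degenerates to the observed count itself. If any denominator
factor is zero the statistic is marked non-evaluable, and a non-evaluable
order counts as *not passed* in detection — the conservative choice.

The z-score is $z = (N_{\text{obs}}(w) - \hat E_m(w)) / \hat\sigma_m(w)$.
For the variance we deliberately chose a **parametric bootstrap** as the
normative method rather than an asymptotic formula: the order-$m$ model is
fitted to the core, $B = 200$ replicate sequence sets with the same per-gene
lengths are simulated from it, and $\hat\sigma_m(w)$ is the sample standard
deviation of the word count over replicates. The bootstrap is fully specified
by the model and a seed, is correct for any word (self-overlapping or not,
near sequence ends, at any length), and one batched run yields the null mean
and sd of *all* $4^h$ words simultaneously, so scoring 25 motifs or 65,536
costs the same. An analytic overlap-corrected variance would be faster per
call but is not implemented; the bootstrap is the only variance path.

The simulation chain draws its first $m$ symbols from the empirical $m$-mer
distribution and falls back to the mononucleotide distribution at contexts
unseen in training. The inner loop runs in C++ with a small internal PCG32
generator seeded from R's RNG stream, so `set.seed()` (or any `seed`
argument) fully determines the output while sustaining the throughput the
calibration studies need.

**Calibration.** On cores simulated from the fitted model itself, the
resulting z-scores for a word without self-overlap are close to standard
normal; the test suite verifies $|\bar z| < 0.15$ and
$\mathrm{sd}(z) \in (0.85, 1.15)$ over 300 simulated cores of 500 kb (100
per order for $m \in \{0,1,2\}$, $B = 200$). Strongly self-overlapping words
(e.g. homopolymers) have heavier-tailed counts and the Gaussian reading of
$z$ is approximate for them; the bootstrap sd itself remains valid.

## The polarity test

Occurrences of the motif are located on both strands of each replicon
(`find_occurrences`), with `-` entries recorded at the forward-strand start
of the reverse-complement match. Circular replicons are additionally scanned
across the origin junction, without double counting. Because replication
origin and terminus cannot be confidently located in every assembly, the test
uses no ori/ter knowledge: under polarization, forward- and reverse-strand
occurrences occupy different arcs of the chromosome, which appears as a
location shift between the two samples of start positions. We test it with a
two-sided two-sample Wilcoxon rank-sum test: exact when both strands have at
most 25 occurrences and positions are untied, otherwise the normal
approximation with tie and continuity corrections. A motif is *polarized*
when $P < 0.001$ (the conventional threshold for this analysis). With fewer
than `min_per_strand = 3` occurrences on either strand the test is
*indeterminate* and the motif fails the polarity criterion — complete absence
from one strand therefore never auto-passes.

A complementary `same_strand_run_test` (fraction of position-adjacent
occurrence pairs on the same strand, permutation null) is provided for
diagnostics; the rank-sum test is the one used in detection. Positions are
used as assembled — no rotation of circular coordinates is attempted — so a
genome assembled with its origin near the middle of an arc loses no power,
while one split exactly at ori loses a little.

## The candidate rule and its thresholds

A motif is a candidate in a species when

* $z \ge z_m$ under at least `min_models` $= 3$ of the six Markov orders, and
* (polarized mode) its genomic occurrences are polarized at $P < 0.001$.

The per-order thresholds default to $z_m = 4$ for every order, roughly a
one-sided Gaussian tail of $3.2 \times 10^{-5}$ — strict enough that six
simultaneous looks at one motif stay conservative. Where a reference species
with a known functional motif is available, `calibrate_thresholds()` replaces
the defaults with the z-scores of that motif in that species' core (the
*E. coli*-anchored procedure), making "as overrepresented as the known Chi
site" the operative definition. Unpolarized mode drops the second clause
(candidates form a superset); polarity is still computed and reported.

Overrepresentation is always evaluated on the core genes' coding strands
(Chi function is strand-specific; no reverse-complement pooling), polarity on
whole replicons — a motif must be enriched where repair matters and oriented
where replication runs.

## Pseudo core genomes

Most bacterial species have too few sequenced strains for a true core
genome, so the pipeline approximates it: the core of a species is the set of
its genes with a best-reciprocal-hit ortholog in *both* of its two
phylogenetically closest relatives. Distances come from a concatenated marker
alignment after a per-column gap filter (columns with gap fraction > 0.5
dropped — a deterministic stand-in for heuristic trimmers; only the distance
*ranking* feeds the pipeline), using the p-distance over gap-free comparable
columns. BRH uses global Needleman–Wunsch alignment (match +1, mismatch −1,
gap open −5, gap extend −1) with identity defined as matches over the full
alignment length *including* gap columns — the stricter, deterministic
variant, since popular aligners disagree on the denominator — with thresholds
of 70% identity and 80% length conservation, and lexicographic tie-breaks
for best hits. Both conventions (distance metric, identity denominator) are
package decisions where the field's tools vary; they are stated here and
fixed by tests.

## The synthetic-data generator

The generator exists so that every claim the pipeline makes can be checked
against a known truth:

* `simulate_genome()` — order-0 background at a target GC (default 0.5), or
  an order-$m$ chain fitted to a template.
* `plant_polarized_motifs()` — a Poisson number of non-overlapping sites at a
  target density (default in the studies: 0.2/kb, i.e. one per 5 kb, the
  density reported for Chi in *E. coli*), each written on the leading strand
  of its replichore with probability `polarization_level` (0.9 in the
  studies, emulating "almost exclusively on the leading strand"; 0.5 is the
  unpolarized null). Planting overwrites the background in place, preserving
  length and ori/ter geometry; chance background occurrences are recorded
  separately in the truth table so sensitivity is measured against planted
  sites only.
* `simulate_species_trio()` — ancestor coding sequences diverged to target
  *nucleotide* identities by point mutation, silent-agnostic, internal stops
  redrawn. Realized protein identities are recorded per gene; since random
  nucleotide mutation degrades protein identity faster than nucleotide
  identity, BRH recovery claims are asserted against the realized *protein*
  identity — the quantity the 70% threshold actually sees.
* `simulate_species()` / `make_toy_dataset()` — genomes with tiled CDS
  features (900 nt genes every 3 kb, random strand), their extracted cores,
  a species tree, and truth tables, written as FASTA/GFF3/TSV/Newick.

What the generator does *not* emulate: real gene-content evolution, codon
usage and amino-acid composition biases, repeats and mobile elements,
GC skew, and replication-associated gene orientation bias. Passing the
end-to-end tests therefore demonstrates that the statistics behave as
designed under their own assumptions — not that real genomes satisfy those
assumptions. On real data the Markov orders 3–5 absorb genuine compositional
structure (codon bias in particular), which is exactly why the detection rule
demands agreement across at least three orders; the GC-contrast diagnostic
(`gc_group_comparison`) flags the residual compositional false positives
that remain, which in practice concentrate in GC-rich genomes.

## Problem sizes and numerical choices

The validation studies use sizes at which the statistics are informative yet
a full run stays comfortable on a single core: 500 kb cores for z-score
calibration (300 simulated cores, $B = 200$), 1 Mb genomes with ~300 kb of
core genes for the 40-species end-to-end recovery study, 60–120 kb genomes
for the 1,300-replicate polarity size/power study, and 12-gene trios for BRH
recovery. The acceptance script scales the same designs to 10+10+8 species.
Parsimony reconstruction uses a two-pass inside/outside dynamic program over
the two states (unit gain/loss costs, polytomies handled exactly); ambiguous
ancestors are reported as state *sets* — the "present in the ancestor, lost
later" and "gained later" readings of a patchy clade are deliberately left
as the set of equally parsimonious reconstructions rather than resolved.

Other fixed choices: ties in best-hit identity and in closest-relative
distance break lexicographically; empty cores and empty BRH intersections
warn and return empty results rather than erroring; `detection_config`
seeds derive per-order bootstrap seeds as `seed + order`, so any single
statistic can be reproduced in isolation.

## A worked miniature

```{r example, eval = FALSE}
set.seed(1)
sp <- simulate_species("demo", length = 2e5, motif = "GCTGGTGG",
                       density = 0.2, polarization_level = 0.9, seed = 7)
calls <- detect_candidates(sp$core, list(sp$genome),
                           hamming_neighborhood("GCTGGTGG")$members,
                           detection_config(seed = 7))
subset(calls, candidate)
```

The `analysis/` directory runs the full workflow — dataset simulation, core
construction, motif scan, detection, false-positive estimation, extended and
de novo searches, and phylogenetic mapping — as numbered scripts writing
their tables under `results/`.

## Known limitations

* The Gaussian reading of $z$ weakens for strongly self-overlapping words
  and for words with expected counts near zero (non-evaluable statistics are
  excluded, but small-expectation words are skew).
* The plug-in expectation uses the scored sequences themselves; for very
  short cores the fitted model absorbs part of the signal, biasing $z$
  downward — another reason the multi-order rule is conservative.
* p-distance ranking of relatives ignores rate variation; with a
  user-supplied distance matrix any metric can be substituted.
* The polarity test assumes a single ori/ter pair (two replichores); linear
  replicons and multi-origin chromosomes weaken its interpretation.
* BRH orthology is one-to-one; recent paralogs compete for the best-hit slot
  and can drop true orthologs from the core.
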