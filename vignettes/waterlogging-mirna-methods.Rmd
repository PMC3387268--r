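---
title: "Methods: small-RNA profiling and regulatory-network inference under waterlogging"
author: "hypoxamir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small-RNA profiling and regulatory-network inference under waterlogging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`hypoxamir` analyses a two-library (waterlogging treatment vs. control)
small RNA-seq experiment together with qPCR expression assays in three
maize inbred lines of graded tolerance, and assembles the implied
TF → miRNA → target regulatory network. This vignette records the
statistical models, the tunable parameters with their defaults and
rationale, what the synthetic-data generator does and does not emulate,
and the design choices made where the methodology was genuinely open.

# Small-RNA processing and differential expression

**Adapter trimming.** Reads are classified by the first exact occurrence
of the adapter's `min_overlap`-base prefix (default 6 nt): everything
from that occurrence onward is removed. An occurrence at position 1
marks an adapter-only read; no occurrence leaves the read untrimmed, so
full-length untrimmed reads fall into the `too_long` bin of the size
filter rather than silently disappearing. Exact prefix search with
first-occurrence-wins is the simplest defensible policy; mismatch-
tolerant adapter alignment is deliberately out of scope. The adapter
sequence itself is a required user input.

**Size filter and collapsing.** Inserts of 18–26 nt without N are
deduplicated by exact sequence (U normalized to T internally; the
original alphabet is preserved on output elsewhere). Library statistics
partition every read into exactly one of adapter-only / N-containing /
too-short / too-long / filtered, so totals reconcile by construction.

**RPM.** Reads-per-million uses the library's *filtered* read total
(post adapter/size/N filtering) as the denominator, not the raw total.
Per-usable-reads normalization is the convention that makes the two
libraries comparable after differing adapter contamination, and it makes
the conservation property Σ RPM = 10⁶ exact.

**The χ² test.** For a signature with counts $(a, b)$ and library
totals $(N_a, N_b)$, the statistic is the Pearson χ² (df = 1, no Yates
correction; a flag enables it) of the table
$\{a, N_a-a; b, N_b-b\}$, computed in closed form and referred to the
upper tail of $\chi^2_1$. Any expected cell below 1 sets a
`low_expectation` flag rather than suppressing the result. The
acceptance suite verifies the nominal type-I error empirically: 10,000
null signature pairs drawn as Poisson(100) counts against totals of 10⁶
reject at α = 0.01 within the exact binomial 99% interval
[0.0075, 0.0127]. The Poisson rate of 100 reads is a typical moderate
miRNA abundance at these depths.

**The DE filter.** A signature passes iff *p* < 0.01, the RPM fold
change is ≥ 1.5 or ≤ 1/1.5, and max(RPM_treatment, RPM_control) > 50.
Applying the abundance floor to the larger of the two libraries is the
permissive reading (a strongly induced miRNA absent from the control
still qualifies); it is configurable. Fold changes are computed after
adding 0.5 reads to both numerator and denominator counts — this
pseudocount protects against division by zero for treatment-specific
signatures and touches only the fold, never the counts or the test.

# Novel miRNA discovery

The candidate cascade retains tags with ≥ 100 combined reads, maps them
to the genome by exact match on both strands (a tag with zero hits or
more than 20 hits is dropped; 20 is the repetitiveness cutoff), removes
tags overlapping the repeat annotation, and removes tags within Hamming
distance 2 of any known miRNA or other ncRNA, compared at equal length
against every window of the longer sequence. Reads (not RPM) are the
primary abundance unit. Every removed tag is attributed to the first
stage that rejects it, so the cascade counts are non-increasing and sum
correctly.

**Folding.** The built-in folding backend is a Nussinov-style dynamic
program that maximizes a stacking-aware stability score (G:C 3, A:U 2,
G:U 1, +1 per stacked pair, minimum hairpin loop 3 nt) and reports the
negated total as a pseudo free energy. It is deterministic,
dependency-free and written in C++ for speed. The fold contract
(`function(seq) -> list(structure, mfe)`) is pluggable: `fold_rnafold()`
wraps the external ViennaRNA `RNAfold` binary when present, and the test
suite uses it as an independent oracle on designed perfect hairpins.
Because the built-in energies are a pairing score rather than a
thermodynamic model, the −18 energy ceiling is permissive for it; the
discriminating criteria in practice are the structural ones, and the
dinucleotide-shuffle control (≤ 5% false passes over 200 shuffles)
demonstrates their joint specificity.

**Hairpin criteria.** A folded window passes iff (a) the mature span
lies in one arm — no bracket-direction change and monotone partner
positions; (b) ≤ 4 mature bases are unpaired in the mature:star duplex;
(c) no asymmetric bulge > 2 nt inside the duplex; (d) energy ≤ −18; (e)
the mature span avoids every terminal (hairpin) loop. These thresholds
follow the conventional hairpin-vetting practice for plant miRNAs; the
primary literature does not pin exact values, so all five are config
keys. Precursor windows use flank pairs (20, 160) and (160, 20) —
plant precursors are long and asymmetric, and two windows cover a
mature tag on either arm.

# Target prediction

Candidate sites are every transcript window within Hamming distance 6
of the reverse-complemented miRNA (plain sliding-window search; the C++
kernel is an optimization with a mandatory brute-force oracle test).
Sites are then scored positionally from the miRNA 5′ end: Watson–Crick
match 0, everything else 1. **G:U wobbles score 1 by default** — the
text-literal reading of "all other mismatches" — with
`wobble_score = 0.5` available for the softer convention in which rule
thresholds compare against the summed score; validated duplexes do
contain wobbles, so this switch materially matters and is surfaced
rather than hidden. The four acceptance rules (≤ 1 in positions 2–12,
none at 10/11, no ≥ 3-run wholly after 12, ≤ 4 total) are evaluated
independently so a site's failure is attributable per rule. Duplexes
are ungapped throughout (the candidate search is ungapped Hamming, and
bulged duplex alignment is out of scope).

Cleavage-clone classification centers a 100-nt window on the site
midpoint; the canonical slicing position is the transcript coordinate
pairing miRNA position 10, i.e. immediately 3′ of the 10/11 boundary on
the target.

# Promoter cis-element analysis

Promoters are −1000..+500 nt around the pri-miRNA TSS,
strand-oriented, clipped (and flagged) at contig edges. PWMs are
normalized with a pseudocount of 0.1 per cell; scanning uses log2
odds against the genome's base composition on both strands, with a hit
threshold at 80% of each PWM's maximum attainable score —
a width-invariant policy. Over-representation per motif is an
upper-tail binomial test of the total foreground hit count over the
foreground's scanned positions at the per-position background rate,
Bonferroni-corrected by the number of motifs tested; selection
additionally requires ≥ 3 occurrences in at least one promoter
(`min_promoters_ge3` widens this to several/all promoters if desired).

The background rate is estimated from length-matched windows sampled
uniformly from the genome, **excluding the foreground promoter
intervals**. Without the exclusion the planted/true occurrences leak
into the background estimate and depress significance — a real effect
at desk scale where promoters are a noticeable fraction of the genome —
and with it the background is an honest null. A zero-hit background is
floored at 0.5 hits (flagged) rather than producing a zero rate.

# Expression assays

WTC (waterlogging tolerance coefficient) is the treated-to-control
ratio of trait means; total dry weight TW = LW + RW is the headline
trait. Stem-loop RT primers are the invariant 44-nt body plus the DNA
reverse complement of the mature 3′ hexamer; miRNAs sharing that
hexamer collide to identical primers and a warning says so. Relative
expression uses the comparative 2^−ΔΔCt method against an 18S-like
reference with replicate Cts averaged before differencing —
amplification-efficiency-corrected variants are out of scope.
Clustering of log2(treatment/control) matrices is agglomerative with
Euclidean distance and average linkage, cut at k = 4 by default to
match the four observed expression archetypes; k is configurable.
Negative correlation between a miRNA and a candidate target is Pearson
r < 0 over the time points **in all three lines**, computed on log2
ratios; with n = 3 per line no significance test is defensible, so the
call is the strict literal criterion, and a zero-variance profile makes
the correlation undefined and the call FALSE (flagged).

# Network assembly

Nodes are miRNA genes and TF families (targets roll up to family level;
per-gene tables remain available upstream). TF-family → miRNA edges
come from selected motifs with ≥ 3 occurrences in that miRNA's
promoter; miRNA → TF-family edges from negative-correlation target
calls. Edges deduplicate; node roles (upstream_only / target_only /
both) derive from incident edges, and edge-kind bipartiteness is
asserted on every build. Feedback loops are directed 2-cycles at family
level. miRNA families derive from the maximal `miR<number>` (or
`miRn<number>`) name prefix after stripping a species prefix. The
builder always reports the counts its inputs imply: the published
summary of this network states 47 nodes alongside 30 miRNAs + 16 TF
families (= 46), and the package surfaces its own arithmetic rather
than reconciling to a printed total.

# The synthetic-data generator

`simulate_genome()` draws i.i.d.-uniform contigs and plants, without
overlap: designed hairpins (a 31-bp perfectly complementary stem —
5-nt extensions around the 21-nt mature — and an 8-nt loop, so the
mature sits inside a clean helix away from the terminal loop), known
mature miRNA loci (some signatures at two loci), 10-mer × 30 tandem
repeat blocks, and promoters for the differentially expressed miRNA
genes carrying ≥ 3 planted consensus occurrences of each assigned PWM.
PWMs are width-8 count matrices with an 85/5/5/5 column profile, at
which only the exact consensus clears the 80% score threshold — making
planted-hit arithmetic predictable. Default desk scale: 2 × 500 kb
contigs, 20 known signatures (10 DE at fold 3.0 / 0.33), 5 hairpins,
100 transcripts, 10 PWMs (5 planted), 2 × 2·10⁵ reads.

`simulate_libraries()` keeps the two libraries' usable totals equal by
letting a random-background read class absorb the mass difference
created by the fold map, so the observed RPM ratio of every miRNA
equals its true fold in expectation. `sampling = "expected"` replaces
the multinomial draw with largest-remainder rounded counts — the
zero-noise regime in which recovery must be exact; `"multinomial"` adds
realistic sampling noise. Adapter-only (3%) and too-short (2%) reads
exercise the trimming statistics.

`simulate_transcript_targets()` embeds, for every DE miRNA, an all-pass
site in a regulated (anti-correlated) transcript and in a non-regulated
decoy, plus one site of each rule-violation class and a
Hamming-distance-7 decoy for the first two; every planted class is
verified against `score_duplex()` at generation time. Expression truth
ramps a DE miRNA's relative expression over time with line-specific
exponents (tolerant 1, mid 0.6, sensitive −0.8 — the sensitive line
responds oppositely), regulated targets follow the reciprocal profile
(log2 correlation exactly −1), non-regulated targets are flat (their
zero variance deterministically blocks a negative-correlation call at
zero noise). Ct values are reference + offset − log2(rel) + N(0, σ);
trait replicates are control mean × line multiplier × lognormal noise.
An assay catalog records each assayed entity with the mature sequence
its primer was designed from, which is how the pipeline links
discovered novel tags to their qPCR profiles — exactly the information
a real assay design sheet carries.

What the generator does **not** emulate: sequencing error and quality
profiles, realistic maize base composition (background is uniform, with
known hit statistics as the benefit), multi-site targets, isomiR
variation, or amplification-efficiency differences in qPCR. Passing
tests on these data therefore demonstrate algorithmic correctness and
calibration, not robustness to those real-data phenomena.

# Numerical choices and problem sizes

Ties in the folding traceback resolve by a fixed preference order, so
structures are deterministic; hclust tie-breaking follows row order;
the generator derives each stage's seed from the master seed by fixed
offsets, keeping every derived seed well below 2³¹. The test suite runs
the generator at a reduced scale (2 × 30 kb contigs, 6 signatures, 2
hairpins, 6 PWMs, 2 × 2·10⁴ reads) for most properties and at desk
scale for the end-to-end closure; the enrichment null study uses 100
seeded runs with 60 background windows each; the χ² calibration uses
10⁴ null signatures. These sizes are the package's chosen trade-off
between statistical resolution and a suite that runs in about a minute.

# Known limitations

The built-in fold energy is a score, not kcal/mol; swap in a
thermodynamic folder for energy-faithful work. Reproduction of the
published supplementary-table counts (22 DE signatures; the
47-node/133-edge network) requires the user to supply those tables —
they ship with the article, not with this package — and the node-count
check may legitimately disagree by one (46 vs 47, above). Genome-scale
runs against a real maize genome are out of scope at desk scale,
though nothing in the implementation is desk-specific except time.
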