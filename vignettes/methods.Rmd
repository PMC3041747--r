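---
title: "Methods: GC content, junction-window folding, and splice-site usage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GC content, junction-window folding, and splice-site usage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The analysis in one paragraph

spliceGC tests whether the guanine–cytosine (GC) content of the sequence
surrounding exon–intron junctions tracks how those junctions are used in
splicing, with the stability of local pre-mRNA secondary structure as the
mediating quantity. Splice sites are categorized from transcript models
(alternative, constitutive, skipped/cassette, and first-exon donors), a
fixed sense-strand window is cut around each junction, the window's
minimum free energy (MFE) of secondary-structure formation is predicted,
and a battery of rank tests, regressions, matched-bin comparisons, and
permutation controls asks: do alternative sites carry more GC and more
stable structure, does GC alone explain the stability differences, are
real junctions GC-enriched relative to decoy junctions, and is the GC
effect stronger than the nucleotide-order effect?

# Splice-site categorization

Transcript models are flat exon tables (0-based half-open coordinates
internally; 1-based inclusive in all exported tables). The junction
coordinate convention is fixed once: a donor's `junction_pos` is the first
intronic base and an acceptor's the last intronic base, which pins the
GT/AG consensus dinucleotide deterministically relative to every record.

* **Constitutive** — an internal exon appearing with identical boundaries
  as an internal exon in every isoform of the gene having at least three
  exons, overlapping no other distinct exon of the gene, in genes with at
  least four isoforms. Both of its junctions are reported.
* **Alternative** — internal exons sharing one boundary while differing at
  the other define competing sites; all variants are reported, subject to
  minimum separations of 5 bp between donors and 8 bp between acceptors of
  the same exon. With more than two variants, the group is kept only when
  every pairwise separation passes the filter — the rule is stated for
  pairs, and requiring all pairs is the conservative extension (the
  synthetic generator only plants two-variant groups, so the choice does
  not affect round-trip tests).
* **Skipped** — a cassette exon: present (identical coordinates) in one
  isoform and absent in another isoform that retains both flanking exons
  and has no exon overlapping the cassette region. Requiring the retained
  flanks prevents transcript-truncation artifacts from being read as
  skipping.
* **First-exon donors** — considered only for genes whose isoforms (at
  least three, each with at least three exons) share one transcription
  start site; the shared-TSS first-exon donor is `first_constitutive` when
  identical in all isoforms and `first_alternative` otherwise.

The category lists are built independently and a site may appear in more
than one list; overlaps are reported, never resolved, since downstream
comparisons are per-category.

# Junction windows and GC metrics

Each junction yields the sense-strand sequence of length `2*flank + 1`
(default flank 70, i.e. 141 nt; flank 30 reproduces the 61-nt variant)
centered on the junction base, cut from raw genomic sequence regardless of
neighboring feature boundaries. In sense orientation the exonic half lies
left of center for donors and right of center for acceptors. The center
base is intronic under both junction conventions and is counted with the
intronic half, so `gc_number` decomposes exactly into exonic + intronic
counts. `N` counts as non-GC and never pairs during folding. Positional
GC profiles average the per-position GC indicator across windows aligned
on the junction, with negative offsets on the exonic side. The
junction-proximal enrichment statistic divides the GC fraction of the
50-bp exonic region adjacent to the junction by that of the 100-bp exonic
region, removing whole-exon GC elevation.

# The folding model

MFE prediction uses a simplified Zuker-style nearest-neighbor model:
Watson–Crick and GU wobble pairs; stacking free energies; size-dependent
hairpin, bulge, and interior-loop penalties (interior loops capped at 30
unpaired bases, the standard restriction); and an affine multibranch-loop
term. External-loop bases are free, so the open chain scores zero and the
MFE is never positive. Dangling ends, terminal-pair penalties, coaxial
stacking, and exact RNAfold/Turner parameter parity are deliberately out
of scope: the analyses depend on relative stability across GC
composition, not on absolute energies, and the acceptance suite checks
that relative behavior directly (the GC–MFE Pearson correlation on random
141-mers is about −0.9, mirroring the magnitudes reported on real sites).

Temperature enters through an enthalpy/entropy split: stack free energy
at temperature $T$ (Kelvin) is $\Delta H - T\,\Delta S$, with $\Delta H$
tied to the 37 °C table so every stack stabilizes on cooling, and loop
penalties — entropic — scale with $T/310.15$. Presets: 37 °C
(human/mouse), 25 °C (nematode), 24 °C (fruit fly). All derived
parameters are rounded to 0.01 kcal/mol at model construction so
structure energies are sums of exact hundredths; "exact" oracle
comparisons are then made at 10⁻⁹ tolerance, insulated from float
summation order.

Correctness rests on a dual route: the production folder is an O(n³)
dynamic program (C++), while `enumerate_structures()` exhaustively lists
every pseudoknot-free structure of a short sequence and scores each with
an independent loop-decomposition evaluator (`structure_energy()`); the
two must agree exactly on every tested sequence up to 18 nt, and the
evaluator must reproduce the DP's energy from its dot-bracket output at
full window length. `nussinov_max_pairs()` bounds the pair count as a
third sanity check. Traceback ties are broken deterministically (earliest
opening index), so outputs are reproducible; among co-optimal structures
the choice is otherwise arbitrary and only the energy is contract.

# Decoy splice sites

The splice-site strength scorer is a position log-odds (weight matrix)
model over the conventional windows — donor 9-mer (3 exonic + 6 intronic),
acceptor 23-mer (20 intronic + 3 exonic) — trained with a pseudocount on
the supplied real sites, with the overall training-set base frequencies as
background. This replaces a maximum-entropy scorer: only a
consensus-similarity *ranking* is needed to pick decoys, and the scorer is
pluggable. Decoy candidates are GT (donor) or AG (acceptor) dinucleotides
in sense orientation in the intron flanking the real site, with junctions
150–300 nt away; candidates scoring at least 0 bits (configurable — the
original cutoff is unstated) qualify, and the nearest qualifier becomes
the decoy. Paired real-versus-decoy comparisons use the Wilcoxon
signed-rank test on GC fraction, on MFE, and on normalized junction GC.

# Shuffle nulls and the nucleotide-order effect

Mononucleotide shuffles are uniform character permutations. Dinucleotide
shuffles use the Altschul–Erickson random Eulerian-path construction,
preserving the full 16-dinucleotide count vector and both endpoints
exactly; both preservation properties are asserted programmatically on
every emitted shuffle in the tests.

A subtlety drives the order-effect design. For windows whose letters are
exchangeable (iid), the native sequence and any of its shuffles have
identical marginal MFE distributions, so both |native − mono-shuffled|
and |native − dinuc-shuffled| mean differences are exactly zero in
expectation and their comparison is a coin flip — the "order effect" is
only well-posed for sequences that *have* order structure, as real
pre-mRNA does. The synthetic module therefore provides
`markov_windows()`: windows drawn from a stationary first-order Markov
chain (`P(b | prev) = persistence·I(b = prev) + (1 − persistence)·π(b)`,
default persistence 0.4). This is precisely the model class for which
dinucleotide-preserving shuffles are the correct null — conditional on
its dinucleotide counts, a first-order realization is uniform over all
arrangements with those counts — so native-versus-dinuc-shuffle p-values
are exactly calibrated while mononucleotide shuffles destroy the planted
order structure and differ systematically (natives fold a few kcal/mol
more stably, the direction observed on real sequences). Per-window
shuffle substreams are derived from (seed, window index), so results do
not depend on iteration order.

# Statistics

Rank-sum and signed-rank tests switch to exact enumeration when the
pooled (or non-zero) sample size is at most 12 — all group assignments or
sign vectors are enumerated on mid-ranks — and otherwise use the
tie-corrected normal approximation without continuity correction.
Degenerate inputs (identical samples; all-zero differences) return p = 1.
No multiple-testing correction is applied anywhere; raw p-values are
reported with sample sizes. GC-matched comparisons bin windows by GC
number (width 5 by default) and rank-test the two categories within each
sufficiently populated bin; underpopulated bins are reported as skipped.
Distance-controlled pairing matches each alternative site to its nearest
same-side reference site within 3000 nt, breaking exact ties toward the
upstream (smaller-coordinate) site.

The tissue rule: an event is tissue-specific when **any** tissue shows an
isoform-proportion change of at least 0.10 with p < 0.3, and
non-tissue-specific when **every** tissue shows a change below 0.05 or
p > 0.3. As stated, the rule leaves a gap (changes in [0.05, 0.10) with
small p); rather than forcing membership, a third `unclassified` class is
returned. The closed boundary (≥ 0.10) is frozen in tests; synthetic
tissue tables are drawn clear of all thresholds (specific tissues:
delta in (0.12, 0.4), p in (0, 0.25); all other entries: delta in
(0, 0.04)), so truth recovery is exact regardless of boundary choice.

# The synthetic world

`generate_genome_annotation()` emits one sequence per gene following a
fixed six-exon template with four isoforms that realize every category at
once: a constitutive exon identical in all isoforms, a cassette exon
skipped by an isoform retaining both flanks, donor variants 6 bp apart
and acceptor variants 9 bp apart (clear of the 5/8 bp filters), and a
shared-TSS first exon. Introns are ≥ 400 nt so the 150–300 nt decoy zone
always fits. Per-category GC targets are drawn around the planted means
(alternative 0.52, constitutive 0.48, skipped 0.47, first-exon 0.62/0.64,
tissue-specific 0.56 vs 0.52, sd 0.05) and the 141-nt junction windows
are composition-sampled to hit them exactly (GC count = round(target ×
length)); the remaining sequence sits at a 0.45 background. Noisy
consensus motifs (GT/AG fixed) mark every real junction; exact-consensus
decoy motifs are planted 155–195 nt into the flanking introns of the
constitutive donor and the cassette acceptor, positioned so no planted
elements overlap. Because decoy selection returns the *nearest*
qualifying candidate, planting also scrubs competing GT/AG dinucleotides
from the stretch of the search zone nearer than the planted decoy —
otherwise a random candidate scoring marginally above background could
preempt it and the planted truth ("this site's decoy is at X") would not
be self-consistent. Half the genes sit on the minus strand and half carry
a long (250 bp > 200) constitutive exon.

What the generator does *not* emulate: realistic splice-site logos beyond
the consensus dinucleotide, branch points and polypyrimidine-tract
variation beyond a fixed motif, isochore-scale GC gradients, repeats, and
any evolutionary correlation structure. A green round-trip therefore
establishes that the classifiers implement the stated rules and that the
statistical battery recovers planted composition effects at realistic
effect sizes — not that the pipeline would reproduce any particular
published number on a real genome.

# Numerical and design choices

* Coordinates 0-based half-open internally, 1-based in reports.
* The junction base belongs to the intronic half of the window (both
  sides), documented rather than configurable.
* Energy parameters rounded to 0.01 kcal/mol; oracle equality asserted at
  10⁻⁹.
* Decoy threshold defaults to 0 bits (more consensus-like than
  background); score ties cannot arise at equal distance within one side,
  and the nearest qualifier always wins.
* Windows running past sequence ends are dropped with a warning in batch
  mode and are an error for single-site extraction.
* All generators take a single integer seed; fixed seed implies
  byte-identical output, and derived sub-seeds stay below 2³¹.

# Known limitations

The folding model is intentionally not RNAfold: absolute MFE values are
not comparable to published kcal/mol figures, only orderings and
GC-relationships are. The scorer is a first-order weight matrix, blind to
position dependencies a maximum-entropy model captures. Exact rank-test
enumeration is limited to pooled sizes ≤ 12 (beyond that the normal
approximation is used, as in standard practice). The pipeline's
distance-controlled and first-exon stages run on the genome route and at
small synthetic scale have modest power; the cohort route carries the
statistical weight.
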