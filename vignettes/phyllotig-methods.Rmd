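---
title: "Methods: contig-level analysis of long-read phyllosphere metagenomes"
author: "phyllotig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contig-level analysis of long-read phyllosphere metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllotig)
```

## Scope

Long-read metagenome assemblies of plant-associated microbial communities
yield contigs that range from short fragments to complete circular
replicons: closed chromosomes, megaplasmids, repABC-family plasmids,
smaller plasmid-like elements and bacteriophages. `phyllotig` implements
the contig-level analysis that follows such an assembly:

1. assembly summary statistics and quality filtering,
2. detection of circular contigs by terminal sequence overlap,
3. full-length 16S rRNA taxonomy with tiered novelty ranks and
   depth-weighted community profiling, and
4. rule-based replicon classification with VirB/VirD4 type-IV secretion
   system (T4SS) scoring.

Everything upstream (read mapping, assembly, gene calling, functional
annotation, phage scoring) is consumed as input: depths arrive as a
per-contig table, gene annotations as a labelled feature table, and
external phage/completeness scores as an optional per-contig table.

## Quality filtering and assembly statistics

A contig is *high quality* when its mean read depth is strictly greater
than 5 (`min_depth`, configurable). A separate, inclusive depth cutoff
(>= 5) governs which contigs are eligible to contribute 16S genes; the
two thresholds are deliberately distinct parameters because the two
filters serve different purposes (assembly reliability versus abundance
estimation) and are applied at different stages.

Artificial contigs are removed by a mononucleotide test: a contig is
flagged when it contains a single-base run of at least 1000 bases
(`min_run`) or when any one base exceeds half the sequence
(`max_mono_run_frac = 0.5`). No run length is canonical for this kind of
assembler artifact; both knobs are exposed.

N50 follows the standard largest-first cumulative definition: sort
lengths descending, accumulate, and report the length of the first contig
at which the running sum reaches half the total. When the sum hits
exactly half, that contig's length is the N50.

## Circularity by terminal overlap

A circular replicon emitted linearly carries its first bases duplicated
at its end. The detector scans candidate overlap lengths from
`min(max_overlap, floor(len/2))` down to `min_overlap` (defaults 50 kbp
and 1 kbp) and accepts the first candidate L whose prefix/suffix Hamming
mismatch count is at most `floor(max_mismatch_frac * L)` (default 2%).
Longest overlap wins and the scan is deterministic.

The comparison is substitution-only. Assembler-produced terminal repeats
from highly accurate long reads rarely contain indels, and the Hamming
scan is linear per candidate with early abort, so whole-assembly scans
are cheap. An indel-bearing overlap shifts the frame and will be missed
— this is a documented limitation, and the mismatch tolerance is the
knob to loosen first if such contigs are suspected.

Trimming (`circularize()`) removes the trailing copy of the overlap and
leaves the rotation start untouched. Both raw and trimmed lengths are
reported, since conventions differ on which length to quote for circular
elements.

## Pairwise identity and coverage

All 16S comparisons use one ends-free (semi-global) alignment with
linear gap costs (match +1, mismatch -1, gap -2). Unaligned terminal
stretches of either sequence are free; this matters because a reference
record may be a fragment that covers only part of a full-length gene,
and that deficit must surface as *coverage*, not as spurious mismatch.

- **identity** = matches / aligned core columns (matches + mismatches +
  interior gaps) x 100;
- **query coverage** = query bases inside the aligned core / query
  length x 100.

Among equal-score alignments the result is pinned by a lexicographic
objective — maximise score, then matches, then the query core, then
prefer fewer columns — computed cell-wise in the dynamic program, so the
reported numbers are unique and independent of traceback order. The test
suite checks the implementation against an independently coded quadratic
DP oracle, exactly, on hundreds of random and mutated pairs.

This identity denominator (aligned columns, end gaps excluded) is not
the same as BLAST-style local identity; values can differ slightly for
divergent pairs. The package applies one definition everywhere, so tier
thresholds are internally consistent.

## Reference curation and tiered taxonomy

Reference 16S records of 1400 bases or shorter are removed; the
remainder are clustered greedily at 97% identity: records are taken
longest-first (ties by id), each either joining the first representative
it matches at or above the threshold or seeding a new cluster. This is
the standard longest-first greedy scheme used by common sequence
clusterers; representatives are the output.

Metagenome-derived 16S genes (>= 1400 bases, on contigs with depth
>= 5) are aligned to the curated set. Hits covering less than 95% of the
query are discarded; the best remaining identity wins, with ties broken
by higher coverage and then lexicographic reference id.

Identity tiers map the top-hit identity to the deepest reliable rank,
lower-inclusive:

| identity (%)   | resolved rank | novelty flag   |
|----------------|---------------|----------------|
| >= 97          | species       | known_species  |
| [94.5, 97)     | genus         | novel_species  |
| [86.5, 94.5)   | family        | novel_genus    |
| [82, 86.5)     | order         | novel_family   |
| [78, 82)       | class         | novel_order    |
| < 78           | unresolved    | novel_class    |

Lower-inclusive boundaries follow the usage of ">= 97%" for species
calls together with "< 78%" for the deepest novelty tier; the tiers are
exhaustive and mutually exclusive over (0, 100], which the suite checks
by property test.

## Community profiling

Relative abundance is estimated from the depths of the contigs carrying
species-level (>= 97%) 16S genes. The default `per_contig` weighting
counts a contig's depth once per taxon no matter how many gene copies it
carries; rRNA operons are frequently multi-copy (up to nine copies on
one contig is plausible), and copy number would otherwise double-count
abundance. `per_gene` weighting is available as a switch for comparison
with copy-number-weighted protocols. Abundances are normalised to sum
to 100 and are invariant to rescaling all depths, and with planted
per-species depths the estimate recovers the planted proportions to
within numerical precision — both are tested properties.

`compare_profiles()` implements the standard cross-method check: take
the taxa above an abundance threshold (default 1%) in one profile, count
how many are present in the other, and report the combined abundance of
that taxon set in each profile separately.

## Replicon classification

Per-contig feature vectors are existence summaries over annotation
labels (DnaA, RepA, RepAB, repC, TraY, partitioning proteins, phage
structural genes, VirB1–VirB11, VirD4), plus pass-through external
scores. Classification is an ordered decision list, first match wins:

1. circular, >= 1 Mbp, dnaA present (or genome completeness >= 50%) and
   no plasmid-type replication gene → **chromosome**;
2. circular, >= 1 Mbp, plasmid-type replication (repA, repC or repAB) →
   **megaplasmid**;
3. phage score > 0.8 → **bacteriophage**;
4. repC present → **repABC plasmid**;
5. repAB, repA or TraY present, or partitioning/VirB genes without phage
   structural genes → **putative plasmid**;
6. otherwise **unclassified**.

The size-and-replication logic of rules 1–2 operationalises the
widely used chromosome/megaplasmid criteria (essential replication
machinery and completeness versus plasmid-type replication at
chromosome scale); the 1 Mbp and 50% thresholds are parameters of
`replicon_params()`. Precedence (chromosome/megaplasmid over phage over
repABC over putative plasmid) encodes relative evidence strength and is
fixed in code rather than configuration so that calls are reproducible;
the suite asserts the precedence explicitly (a megaplasmid-qualifying
contig with a high phage score stays a megaplasmid). A dnaA gene on a
small circular contig is recorded as evidence but does not force a
chromosome call — small dnaA-bearing plasmids are documented in several
genera — so such contigs fall through to the later rules.

Contig-level taxonomy is a consensus rule: a genus is assigned only when
the genes hitting it (at >= 80% identity and >= 80% coverage) strictly
exceed one fourth of *all* annotated genes on the contig and every
qualifying hit comes from a single phylum. "Strictly exceed" is taken
literally (26 of 100 genes qualifies, 25 does not), and the denominator
counts all annotated genes, the stricter reading. Ambiguity — two phyla
among qualifying hits, or two genera tied — leaves the contig
unassigned.

## T4SS scoring

The reference VirB/VirD4 system comprises the eleven VirB components
plus VirD4. Completeness is the count of distinct components present:
12 = complete, 10–11 = nearly complete, 1–9 = partial, 0 = absent. The
10–11 band for "nearly complete" is this package's convention; no
numeric definition is standard. Arrangement comparison reports
duplicated and missing components and whether the de-duplicated observed
order is a subsequence of the reference operon order under any circular
rotation, on either strand — operons on circular plasmids have a free
rotation and orientation, so both must be checked before calling an
arrangement rearranged.

## The synthetic community generator

Every stage is tested against communities with known ground truth,
generated by `generate_community()` from a synthetic reference database.

What it emulates:

- a replicon mix dominated by small plasmids and phages with a few
  closed chromosomes and a rare megaplasmid, matching the observed
  composition of circular contigs in long-read phyllosphere assemblies;
- circular contigs emitted with a duplicated 2 kbp terminal overlap;
- log-normal contig depths (default mu = 2, sigma = 1, floored at 0.1);
  no canonical depth distribution exists for such assemblies, so the
  parameters are configuration knobs;
- multi-copy 16S genes (1–4 copies per bearing contig) mutated to
  controlled target identities. The default identity levels are sampled
  with weights that put roughly 69% of copies at species level and
  spread the rest down to the class tier, mirroring the tier proportions
  reported for full-length 16S genes in this setting;
- marker annotations per class, with realistic redundancy: repABC
  plasmids carry one or two repC genes (assemblies of such plasmids
  often annotate more than one) and putative plasmids one to three
  plasmid-associated genes — single-copy markers would make any dropout
  robustness test structurally impossible for single-evidence classes;
- per-gene best-hit taxonomy on a fraction of ordinary genes, so the
  one-fourth consensus rule can be exercised.

What it does not model: 16S secondary structure (templates are random
cores between fixed conserved terminal blocks, sufficient for identity
arithmetic and alignment anchoring, nothing more), indel divergence
(substitution-only, so target identity is exactly controllable; indel
robustness is tested separately in the alignment tests), read-level
errors, chimeras, strain mixtures and repeat-driven misassembly.
Passing tests on these communities therefore demonstrate correctness of
the *rules and arithmetic*, not robustness to assembly pathology.

Sizes: chromosomes are drawn at 1–5 Mbp, megaplasmids 1–2 Mbp (the
classification rules place the chromosome/megaplasmid boundary at
1 Mbp, so planted megaplasmids must sit above it to be recoverable),
repABC and putative plasmids 8–300 kbp, phages 10–80 kbp. One global
seed drives the whole generation; identical configuration gives
byte-identical output, and the caller's RNG state is never disturbed.

## Numerical and degenerate-input choices

- All thresholds are parameters with the defaults above; the pipeline
  log records every value actually used.
- The depth filter is strict (`> 5`) and the 16S depth eligibility
  inclusive (`>= 5`); both appear in the configuration.
- Reference curation drops records with length `<= 1400` (exclusive
  keep).
- Empty annotation tables degrade gracefully: all contigs unclassified,
  empty profile with a warning.
- A contig shorter than twice `min_overlap` cannot be scanned for
  circularity and is reported linear by the set-level wrapper (the
  scalar function treats it as a contract violation).
- Tie-breaks are deterministic everywhere: alignment (lexicographic
  objective), top-hit search (identity, then coverage, then reference
  id), clustering order (length, then id), contig taxonomy (ties are
  refused rather than broken arbitrarily).

## Problem sizes used by the test suite

The suite runs on one CPU in a few minutes; sizes were chosen as the
smallest that still exercise each property convincingly: 200
random/mutated pairs of 50–300 bases for the alignment oracle, a
20-record set for the clustering oracle, 200 random length sets for
N50, 100 contigs (50 planted circular, 50 linear) for circularity
recovery, a 36-contig community for noise-free truth recovery, a
150-contig community for 10% annotation dropout, and a 33-contig demo
(two replicons above 1 Mbp) for the end-to-end golden-file test.

## Known limitations

- The Hamming circularity scan misses indel-bearing terminal overlaps.
- Identity is alignment-defined, not BLAST-local; tier boundaries near
  a threshold can differ from BLAST-based workflows by a fraction of a
  percentage point.
- Contig taxonomy trusts the supplied best-hit labels; it does not
  re-align anything.
- The generator's truth classes are noise-free constructions; accuracy
  numbers on synthetic data are upper bounds for real assemblies.
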