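---
title: "Marker-gene fingerprints and copy-number-aware community quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-gene fingerprints and copy-number-aware community quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fingerquant)
```

## The problem

Conventional amplicon profiling of a synthetic community (SynCom) — a defined
set of cultured bacterial isolates — assigns reads to one reference sequence
per isolate, usually the most common 16S rRNA variant. Two facts of bacterial
genomics undermine this. First, the 16S rRNA gene is multi-copy (one to
~15 copies per genome), so read counts conflate cell abundance with copy
number. Second, the copies within one genome are not identical: they carry
SNPs and small indels, so two near-isogenic strains can share their "main"
16S sequence while differing in a minor intragenomic haplotype.

`fingerquant` addresses both. For each isolate it builds a *fingerprint* —
the complete set of intragenomic marker-gene haplotypes together with their
copy numbers — and then uses the fingerprints as a pseudoalignment reference:
reads are assigned by shared k-mers over equivalence classes, multi-compatible
reads are resolved by EM, and counts are divided by copy number before being
expressed as relative abundances.

## Stage 1: fingerprints from an assembly and its reads

1. **Locus finding.** A full-length seed gene (1,544 bp by default, the
   canonical 16S length) is anchored on every contig by exact 15-mers and
   aligned locally (banded, match +1 / mismatch −1 / gap −2). Hits are kept
   when their length is within ±300 bp of the seed (natural 16S length
   variation) and identity — matches over alignment columns, gaps counted as
   mismatches — is at least 0.75. Overlapping hits are resolved greedily by
   identity (an accepted hit suppresses hits it overlaps by more than half
   their length). The best-identity locus becomes the mapping reference.
2. **Read recruitment and alignment.** Reads sharing at least two canonical
   21-mers with the locus (either orientation) are recruited, along with
   their mates. Each read is anchored by exact k-mers, clipped to the locus,
   and compared ungapped; reads with indel evidence fall back to a banded
   glocal alignment (band half-width 8). Reads below 80% identity are
   dropped and counted in the log.
3. **Mapping quality.** Loci at or above 97% identity to the selected locus
   are copies of the same marker — intragenomic 16S copies are expected to
   exceed 95% identity — and never compete for reads. Lower-identity loci
   (diverged paralogs, contaminant fragments) act as competitors:
   `mq = min(60, 4 * (S1 − S2))` from the best and best-competitor alignment
   scores, and 60 with no competitor. If every copy competed with every
   other, all reads would be multi-mapping and variant calling would starve;
   mapping against the single selected locus mirrors how the fingerprint is
   meant to be constructed.
4. **Variant calling.** The pileup uses only alignments with `mq >= 30`
   (Phred 30, a 0.1% error rate) and base calls with quality at least 20. A
   site is called when the alternate allele (substitution, deletion, or
   insertion) reaches fraction 0.1, count 4, at depth 10. The fraction floor
   sits well below the smallest true allele fraction a 15-copy genome can
   produce (1/15 ≈ 6.7%) and well above the sequencing error rate; strand
   bias (Fisher exact), supporting-read mapping/base quality, and in-read
   position bias (Wilcoxon) are annotated but do not hard-filter.
5. **Phasing.** Variants are phased under a diploid model — at most two
   haplotypes, complementary at every called site. The bipartition minimizing
   the weighted minimum-error-correction (MEC) cost is found by exact
   enumeration up to 12 sites and by a seeded local search with 10 restarts
   beyond. Reads collapse to weighted allele patterns first, so the cost of
   enumeration is independent of depth. The two-haplotype ceiling is a known,
   deliberate limitation: genomes with three or more distinct haplotypes are
   under-called.
6. **Copy number.** The total copy number is the mean locus depth (50 bp
   flanks trimmed, where coverage necessarily decays) over the mapping-free
   genome-wide depth (total read bases / assembly length), rounded half-up
   with a floor of one. Copies are apportioned among haplotypes by
   largest-remainder on the phased read-support fractions, each haplotype
   receiving at least one copy. No G+C correction is applied; an elevated
   marker:genome G+C ratio (> 0.85), like externally supplied contamination
   (> 5 / > 10%) and heterogeneity (> 25%) values, only raises a QC flag.

## Stage 2: amplicon trimming

Degenerate primers (IUPAC codes; V3-V4 `CCTACGGGNGGCWGCAG` /
`GACTACHVGGGTATCTAATCC` and V5-V7 `AACMGGATTAGATACCCKG` /
`ACGTCATCCCCACCTTCC` are bundled) are matched with up to 2 mismatches and no
indels; among valid site pairs the fewest total mismatches, then the longest
amplicon (minimum 50 bp), wins. The emitted amplicon *excludes* the primer
sites, mirroring primer-trimmed amplicon reads; `keep_primers = TRUE`
restores the inclusive convention. Haplotypes whose amplicons coincide are
merged with copies summed, so total copies are conserved across trimming.
Because primers are excised, re-trimming an amplicon fingerprint fails
unless the primers genuinely re-match — this is asserted by a test, not
silently tolerated.

## Stage 3: quantification

Fingerprint haplotypes are joined with a spacer of 31 N's — the index k —
so no k-mer spans a junction, and canonical 31-mers map to equivalence
classes of member sets. Read assignment is the strict intersection of the
classes of the read's k-mers (k-mers absent from the index are skipped;
sequencing errors produce novel k-mers, which this skip absorbs); an empty
intersection falls back to members hit by at least 80% of matched k-mers.
Paired candidates are the intersection of the mates' sets when both map.
Surviving candidates are validated by banded alignment at a minimum mapping
read identity of 0.95: at 95% identity nearly every 31-mer is destroyed, so
a k-mer-count proxy could not implement this floor faithfully.

Shared reads are resolved by EM over a categorical mixture; reads are
grouped by candidate set, making iterations O(classes). Uniform
initialization keeps exactly symmetric evidence at the symmetric fixed
point. Raw counts are member posteriors summed over reads; the reported
confidence for a member is the mean of its posterior over reads compatible
with it (a definition this package fixes, since "pseudoalignment
confidence" is not otherwise pinned down). Copy-number normalization divides
counts by copies and renormalizes; for relative output the order of the two
operations is immaterial, which is why dividing-then-renormalizing is safe.

A genuine identifiability limit is worth stating: when one member's
fingerprint is locally nested in another's (for instance a twin pair whose
discriminating SNP lies on one haplotype while a second, shared haplotype
carries the reference allele at that site), the nested member has no unique
k-mers, and the EM maximum-likelihood solution pushes its abundance to
zero. No pseudoalignment method resolves that pair; the simulator therefore
states the identifiable scenario (single-haplotype twins) when it builds
near-isogenic pairs. Similarly, a reference whose identity to another lies
strictly between 0.95 and 1 is reachable by alignment at the 0.95 floor but
not by k-mer intersection — the substitutions that keep it below 1.0 are
exactly the ones that destroy the shared k-mers.

## Stage 4: evaluation

Fingerprints are clustered at 100% identity — exact equality of the
serialized haplotype + copy-number set — or greedily below that threshold
(members in decreasing length order join the first centroid at or above the
threshold by global alignment identity). For comparison against a reference
(metagenome-derived) composition, member abundances are summed within
clusters in both tables, taxa absent in either table are removed from both
(per sample by default; a pooled `global` scope is available), and samples
are renormalized. The deviation score is

NRMSE = (1/K) Σᵢ √((aᵢ − mᵢ)²) / ((aᵢ + mᵢ)/2),

the per-taxon absolute deviation over the pairwise mean abundance, averaged
over the K compared taxa: dimensionless, symmetric, zero iff the
compositions agree, and bounded by 2 per taxon. It is computed per sample,
reported with its across-sample mean, since pooling taxa across samples
would weight samples by their taxon counts. Presence/absence performance
uses a 0.5% relative-abundance threshold in both tables, with the reference
as truth: accuracy, precision, recall, specificity from the per-sample 2×2
table, zero-denominator ratios reported as `NA`, never as 0.

## The simulator: what the stated world is, and is not

`simulate_isolate()` builds a uniform-composition background genome
(default 25 kb) with 1-7 embedded marker copies carrying 1-3 haplotypes,
then draws uniform shotgun reads (default 50x, 150 bp, 0.1% substitution
error, constant Phred quality consistent with that rate). The 25 kb
background is a desk-scale surrogate for a Mb-scale genome: the copy-number
estimate depends only on the locus/genome depth *ratio*, which is invariant
to genome length, so the small background changes runtime, not the
statistics being tested. Haplotype-distinguishing SNPs are placed inside a
100 bp window in the gene interior — real intragenomic 16S variation
clusters in hypervariable loops, and sites farther apart than a read (or
fragment) span are unphaseable by any read-based method, a limitation the
generator does not try to hide. The bundled 1,544 bp seed is synthetic, with
V3-V4 and V5-V7 primer sites embedded at positions approximating the
standard gene numbering; primer-binding regions and the terminal 20 bp are
held conserved by the mutator, as they are in nature (that is why universal
primers exist). The simulator injects substitution errors only: no indel
errors, no platform-specific quality profiles, no chimeras or PCR bias. A
green end-to-end test therefore establishes correctness of the pipeline's
statistics under a clean error model — not robustness to real library
artefacts.

## Numerical and interface choices

* Phred encoding is fixed to +33; input whose quality distribution looks
  +64-shifted is rejected rather than misread. FASTQ parsing is a strict
  4-line-record parser so that sequence/quality length mismatches are
  reported as errors instead of being padded silently.
* Coordinates are 0-based half-open internally and in BED output; 1-based
  inclusive in user-facing variant tables.
* Rounding of the copy ratio is half-up (`floor(x + 0.5)`), not banker's.
* Largest-remainder apportionment breaks ties by haplotype order; the
  one-copy floor takes from the largest allocation when needed.
* The amplicon site pair is chosen by fewest mismatches then longest
  amplicon with a 50 bp floor; an upper length cap tied to an "expected"
  amplicon length was dropped because the expectation is not knowable from
  the inputs.
* EM convergence is `max |Δθ| < 1e-8` with a 1,000-iteration cap; the
  observed-data log-likelihood trace is returned so monotonicity is
  testable.
* Phasing restarts are seeded (default 42) and exposed, as is every
  simulator seed; identical seeds give byte-identical output.

## Limitations

Beyond the two-haplotype phasing ceiling, the nested-reference
identifiability limit, and the clean error model above: the mapping-free
genome depth is biased when many reads come from unassembled or contaminant
sequence; contamination and heterogeneity are accepted as external QC
values, not computed; taxonomy collapse expects a user-supplied map; and
the greedy sub-100% clustering is order-dependent by construction (the
order — decreasing length, then id — is fixed for determinism rather than
globally optimal).
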