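---
title: "Screening a transgenic genome for unintended vector insertions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a transgenic genome for unintended vector insertions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdnascreen)
```

## The problem

A transgenic plant produced by *Agrobacterium*-mediated transformation is
supposed to carry one copy of the T-DNA — the transfer segment of the
binary vector, delimited by ~25 bp border repeats — at one known genomic
location. In practice, transformation can also leave behind small
unintended fragments ("splinters") of the T-DNA or even of the vector
backbone (the replication origin and bacterial selection marker that
should never integrate). Demonstrating the *absence* of such fragments
matters wherever a transgenic intermediate is used in breeding and the
final product is a null segregant: regulatory conventions treat ≥20 bp of
inserted foreign sequence as a new combination of genetic material (the
"20 bp rule"), so the screen must find any ≥20 bp stretch of vector
sequence anywhere in the genome.

`tdnascreen` implements a comparative whole-genome-resequencing screen for
this question. It takes short paired-end reads of the transgenic line and
of its non-transgenic progenitor ("wild type"), the vector sequence, and a
host reference genome, and decides for every vector-matching sequence in
the read pool whether it is the known insertion, pre-existing host
sequence, contamination, a library artifact — or a candidate unintended
insertion that needs wet-lab confirmation.

## The procedure

1. **Trim.** 3′ quality trimming with the BWA-style running-sum rule
   (cutoff Q30) and a 50 bp length filter; a read that fails leaves its
   mate as an orphan that still participates in coverage mapping but not
   in pairing.
2. **Screen.** Every continuous 20-mer of the (circular) vector is
   indexed, both strands. A read matches when one of its 20 bp windows is
   identical to a vector 20-mer *and* every base in that window has Phred
   ≥ 20; a pair is retained when at least one mate matches. The
   per-position count of matched 20-mer starts is the frequency profile
   that separates T-DNA coverage from backbone coverage at a glance.
3. **Assemble.** Matching reads of the transgenic sample (all experiments
   pooled) are clustered by shared vector 20-mer positions (union-find)
   and laid out by their vector-coordinate anchors. Overlaps ≥ 30 bp
   extend a contig; the consensus is the column majority; reads whose
   anchored alignment exceeds a 2% mismatch cap are taken out and
   re-assembled among themselves. No read is discarded — a read that fits
   nowhere becomes a singleton contig. This keep-all-reads property is the
   reason for a purpose-built assembler: off-the-shelf assemblers drop
   low-coverage reads, and a dropped read here is a missed insertion.
   Mates of placed reads that did not place in the same contig are
   attached at the contig ends as *context* sequence.
4. **Coverage.** All trimmed reads of both genotypes are mapped back to
   the contigs (exact 20-mer seed, ungapped extension, ≤ 5% mismatches,
   equally-best placements shared fractionally). Depths are normalized by
   each sample's mean genome depth, and a region counts as "present" in a
   sample when ≥ 80% of its bases reach normalized depth ≥ 3. A contig
   whose vector-identity segment is absent in the wild type is a
   target-only contig; otherwise it is shared (type 1 when the whole
   contig is present in both genotypes, type 2 when only parts are).
5. **Triage.** Five steps, applied in order, first hit decides:
   the known insertion (host flanks on both contig ends, ≤ 100 bp apart in
   the reference, T-DNA interior); shared presence in both genotypes;
   vector-identity segments present in the host reference (≥ 95% over the
   full segment); underrepresentation (≤ 2 supporting reads; single-
   experiment support is reported as evidence but does not decide by
   default); and an origin assessment of the remainder by local homology
   search of contig plus context against host, vector and a contaminant
   panel. The sixth step of the laboratory procedure — PCR confirmation
   of chimeric candidates — is outside the software; such contigs are
   flagged `CANDIDATE_INSERTION` together with their junction sequence.
6. **Characterize.** The known-insertion contig is turned into an
   insertion call: both host flanks are located by local search (≥ 98%
   identity, reaching the junction-adjacent base), the right junction is
   the last host base before the insert, the left junction the first host
   base after it, and the deletion is the strict gap between them — an
   integration printed as `a–b` therefore implies a deletion of
   `b − a − 1` bp. Coordinates are 1-based inclusive throughout.

## What the synthetic study emulates

Because the real datasets behind such screens run to hundreds of millions
of read pairs, the package ships a study generator that reproduces the
design at desk scale with exact ground truth. The defaults are fixed once
and define the validation conditions used by the test suite:

* a 500 kb diploid host chromosome, GC 0.38, heterozygous SNP rate 0.005
  (the progenitor of a typical transformation line is highly
  heterozygous); haplotype A is identical to the reference, which mirrors
  how real insertion flanks were reconstructed in the wild type;
* a 10,699 bp circular vector whose T-DNA spans positions 8..5,726
  between a 25 bp right-border and a 24 bp left-border motif, of which
  29..5,484 integrate — the coordinates of the study design the package
  is validated against;
* one integration on haplotype A at position 250,000 with an 11 bp host
  deletion. The generator forces the host bases flanking the insert to
  differ from the vector bases adjacent to the integrated interval:
  junction microhomology would otherwise make the true junction
  coordinates ill-defined (with probability ~¼ per end) and exact truth
  recovery meaningless;
* two sequencing experiments: 100 bp pairs at 30× and 150 bp pairs at
  60× of the diploid mix (≈ 60× and 120× of the haploid reference, ≈ 180×
  pooled), fragment sizes 350 ± 35 and 500 ± 50 bp, substitution error
  rates 0.002 and 0.001, and a position-dependent Phred model (mean
  declining from ~38 to ~33–34, sd ≈ 3, floor 3, ceiling 40) so the Q20
  screen filter and the Q30 trimmer both have work to do;
* two contaminant genomes — random 30 kb "endophyte" backbones carrying
  the vector's bla-like and ColE1-like backbone segments verbatim — at 2%
  of experiment-1 pairs. By default they contaminate the transgenic
  sample only: contamination present in both genotypes is excluded at
  step 2 exactly like any shared sequence (that case is exercised
  separately in the tests), whereas the step-5 contamination verdicts the
  procedure exists for arise from material seen in the transgenic data
  only. Both-genotype contamination remains available via
  `contaminated_samples`;
* five decoy loci: exact vector 20-mers copied into the host reference
  and all haplotypes (planted non-extendable, so the true match length is
  exactly 20 bp), emulating host sequence that incidentally satisfies the
  20 bp rule;
* about six chimeric artifact reads drawn from a single vector‖host
  template in experiment 1, emulating a ligation artifact that produces a
  persuasive-looking junction until coverage and PCR argue otherwise;
* optionally, a duplicated copy of the insertion-flank region elsewhere
  in the genome (`flank_paralog`), which reproduces the diagnostic 4:1
  flank-to-insert depth ratio of a single-homolog insertion whose flanks
  are collinear with a second locus.

What the generator deliberately does **not** model: indel sequencing
errors (the mapper and assembler are ungapped), PCR/optical duplicates,
adapter read-through, reference gaps ("N" stretches), and real host
sequence content with its repeat families. Passing the synthetic suite
therefore shows that the machinery is correct under the stated error
model, not that every complication of a real orchard genome is handled.

## Numerical and design choices

* **Determinism.** Every stage derives its RNG stream from the master
  seed; re-running a configuration reproduces byte-identical FASTQ, TSV
  and JSON output. Assembly canonicalizes read order by read id, greedy
  ties are broken by (longer overlap, fewer mismatches, smaller read id),
  and consensus ties fall to the earliest-placed read.
* **Contigs are numbered by descending vector-identity length**, so
  `contig_0` is the T-DNA-sized insertion contig when one exists.
* **Step-2 presence rule.** "Similar coverage in both genotypes" is
  operationalized through the presence thresholds above rather than a
  ratio test; a contig whose vector segment the wild type does not reach
  at normalized depth 3 over 80% of its bases proceeds to step 3 even if
  the transgenic coverage is itself thin — the contig exists because the
  transgenic read pool produced it, so wild-type absence is what matters.
* **Step-5 comparison.** "The contaminant panel explains the contig
  better than the vector does" is measured as strictly more aggregate
  matched bases across contig plus context, not percent identity: a
  backbone-only contig hits both the vector and a contaminant carrying
  the same segment at 100%, and only the alignment extent (contaminant
  backbone beyond the shared segment, contaminant-matching context) can
  separate them. A tie is reported as `VECTOR_ONLY` — vector identity
  without host identity, hence no evidence of an insertion, the verdict
  the equivalent unresolved cases receive in practice.
* **Local search** is seed-and-extend (12-mer seeds), ungapped, +1/−2
  scoring, reporting maximal positive-scoring diagonal segments ≥ 20 bp
  and ≥ 80% identity. It stands in for a remote nucleotide BLAST so the
  package runs self-contained; it will miss homology with no shared
  12-mer, which at the ≥ 95–98% identity thresholds the triage uses is
  immaterial.
* **Insertion calls with duplicated flanks.** When the flanks hit several
  host loci (collinear duplication), the caller picks the flank-hit pair
  on one subject and strand with the smallest non-negative gap, which is
  the parsimonious integration interpretation.
* **Problem sizes in the test suite.** Module tests run on 20–40 kb
  hosts; the truth-recovery acceptance test runs the full default
  conditions (500 kb host, both experiments, contamination, decoys,
  chimera) over six seeds, a sample the suite's runtime budget
  accommodates while still exercising every triage outcome; junction
  coverage, as a cheaper property, is asserted over twenty seeds.

## A worked run

```r
library(tdnascreen)
cfg <- simulation_config(seed = 7, host_length = 60000,
                         insertion_pos = 30000, decoy_kmer_count = 3,
                         chimeric_artifact_rate = 2e-4)
study <- simulate_study(cfg)
run <- run_pipeline(study)
print(run)
run$triage$table
```

`print(run)` reports the Table-style accounting (raw, trimmed and
vector-matching read counts per sample and experiment with merged
totals), the per-category contig counts, and the insertion call — for
the default design: exactly one `KNOWN_INSERTION` whose junctions
reproduce the planted site, an 11 bp deletion, and the integrated
interval 29..5,484.

## Known limitations

Ungapped alignment throughout means an insertion whose junction-proximal
reads carry indels would be characterized imprecisely (the contig would
still be found and flagged). Contigs are compared against a *provided*
contaminant panel; an unexpected contaminant with no panel representative
and no host identity surfaces as `VECTOR_ONLY`/`UNDERREPRESENTED` rather
than `CONTAMINANT`, which is the conservative direction. The screen's
sensitivity floor is the 20 bp exact-match rule itself: an integrated
fragment shorter than 20 bp, or one diverged by even a single
substitution in every window, is invisible by construction — a property
of the screen design, not of this implementation.
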