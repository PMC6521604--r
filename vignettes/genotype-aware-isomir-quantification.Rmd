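---
title: "Genotype-aware alignment and isomiR quantification with polymiR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-aware alignment and isomiR quantification with polymiR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polymiR)
```

## The problem

Mature miRNAs are ~22 nt RNAs whose sequenced reads rarely match the
reference exactly. Two mechanisms produce the variability. First,
post-transcriptional editing trims or extends the read extremities
(isomiRs): imprecise DROSHA/DICER cleavage and terminal nucleotidyl
transferases act mostly on the 3' end, much more rarely on the 5' end.
Second, germline SNPs inside the mature sequence (we call such miRNAs
polymiRs) make reads from the alternative allele mismatch the reference
internally. An aligner that forbids mismatches silently drops
alternative-allele reads; an aligner that tolerates them cannot tell a
genuine allele from a sequencing artifact. When the sequenced samples also
have genome-wide genotypes — an increasingly common situation — both
problems can be addressed at once, and that is what this package implements.

## The workflow

1. **Library augmentation.** Single-nucleotide variants from a VCF are
   intersected with the genomic loci of the mature miRNAs. For every
   polymiR, one alignment target per haplotype (the Cartesian product over
   each variant's alleles) is added to the library; the canonical entry
   keeps the bare mature name. Minus-strand loci mirror the offset
   (`end - position`) and complement the alleles onto the mature strand,
   and a variant inside two overlapping opposite-strand matures joins both
   polymiRs.
2. **Preprocessing.** 3' bases below the Phred floor are trimmed, the 3'
   adapter (the earliest position where an adapter prefix matches the read
   suffix with at most 10% mismatches over an overlap of at least 3) is
   removed, reads outside 15–27 nt are dropped, identical reads are
   collapsed with summed counts.
3. **Alignment.** A seed-and-extend exact-core local aligner: every shared
   17-mer between read and library entry is extended while bases match. A
   candidate needs a mismatch-free core of at least 17 nt and at most 10
   soft-clipped bases per end; only the forward strand is searched, because
   strand-specific adapter ligation fixes the sequencing direction. Per
   entry one candidate is kept (longest core, then smallest reference
   start, then smallest read start).
4. **Editing annotation and scoring.** Missing reference bases at either
   core end are trimming; clipped read bases are tailing. A 3' tail is
   *templated* when the 3' end is untrimmed and the tail matches, base by
   base from the junction, the parent hairpin immediately downstream of the
   mature (mirrored at 5'). Templated bases validate the read's parentage
   and are free; every trimmed or non-templated tailed base is one editing
   event. The alignment score is `N5 * W5 + N3`, per-base event counts with
   the 5' weight `W5 = 4` by default.
5. **Disambiguation.** Per read, only minimum-score alignments survive. A
   read retaining `n > 1` alignments on distinct matures gets weight `1/n`
   on each and is logged as ambiguous. Alignments scoring above the
   threshold (9 by default, inclusive) are discarded as unreliable.
6. **Genotype consistency.** A read whose matched core covers a variant
   supports the allele its entry carries there. If that allele is absent
   from the sample's genotype the alignment is discarded; the discarded
   group is *plausible* — reported for manual follow-up, since it may
   indicate a genotyping error or an unannotated homologous locus — when it
   is supported by more than 1% of the allele-informative reads (or at
   least 5 reads when fewer than 500 are informative).
7. **Outputs.** Merged per-mature, per-polymiR-entry and per-isomiR
   abundance tables, a mirGFF3 file, annotation side files and an
   `inconsistents.sam` of discarded alignments.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `W5` | 4 | weight of 5' editing events in the score |
| `score_threshold` | 9 | maximum score kept (inclusive) |
| `seed_len` | 17 | minimum exact-match core (nt) |
| `max_clip` | 10 | maximum soft-clipped bases per read end |
| `min_len`/`max_len` | 15/27 | insert window kept after trimming (nt) |
| `min_quality` | 28 | Phred floor for 3' quality trimming |
| `rate_threshold` | 0.01 | plausibility rate for unexpected alleles |
| `min_reads` | 5 | absolute plausibility floor at low depth |
| `low_count_total` | 500 | informative-read depth where the floor applies |

All are exposed through `pipeline_config()` and the CLI. The 5' weight
reflects the biology: ~94% of reads are unedited at the 5' end, so a 5'
modification is a stronger hint that a cross-mapping read belongs
elsewhere. The inclusive score threshold separates plausible isomiRs from
alignments whose implied number of editing events is unrealistic.

## Design choices where the design was open

* **Exact-core semantics.** The matched core must be contiguous and
  mismatch-free; trimming is inferred from the core's position on the
  reference, tailing from the clipped bases. This is the only reading under
  which "no internal mismatches, variation at the extremities" and local
  alignment coexist. A bowtie2-local SAM can be imported instead
  (`import_sam_alignments()`); records violating the exact-core policy are
  dropped at import.
* **Per-base event counting.** Each trimmed or non-templated tailed base is
  one event (rather than one event per end). Only per-base counting yields
  the wide score range and the "score difference of two = two extra 3'
  modifications" granularity that the scoring is designed around.
* **Tails after trimming are never templated.** Because cores are extended
  maximally, the first clipped base after a trimmed end necessarily
  mismatches the reference, so a templated continuation is impossible by
  construction; partial tails split into a templated prefix and a
  non-templated remainder.
* **Variant-blind ties collapse to the canonical entry.** When tied
  minimum-score alignments are haplotype entries of the same polymiR and
  the read's core does not cover any variant, the entries are identical
  over the read span; the read is assigned to the canonical entry with
  weight 1. The alternative — splitting the weight — would fabricate
  alternative-allele counts out of reads that carry no allele information.
* **Weighted tallies.** Consistency supporting/total counts use collapsed
  multiplicity times disambiguation weight, restricted to
  allele-informative reads (cores covering the variant site). This matches
  the natural reading of the 980/20 worked example: 20/1000 = 2%,
  plausible, reported.
* **Paralog protection.** When a mature is produced by several loci and at
  least one locus lacks the variant, reference-allele reads may always come
  from the variant-free copy, so they are never called inconsistent — even
  in a homozygous-alternative carrier.
* **Hairpin attribution.** Templated tail bases are matched against each
  parent hairpin's flanks; the set of parents explaining all templated
  bases is recorded in `expressed_hairpins.annot` (a proper subset is
  `deduced`/`ambiguous`; no discriminating bases means `undetermined`, and
  the count is then shown once per parent). Attribution never affects the
  alignment itself.
* **5' label signs.** The labels follow the taxonomy in which
  `iso_5p:+N` denotes 5' trimming and `iso_5p:-N` templated 5' tailing;
  `scoring_config(iso5p_sign = "mirgff3")` flips the 5' signs for
  consumers expecting the mirGFF3 community convention. 3' labels are
  identical under both conventions.

## Numerical and degenerate-input behavior

Sequences are normalized internally to uppercase DNA (U to T); output FASTA
keeps the input alphabet convention at the record level. Coordinates are
GFF3-style 1-based inclusive; mature offsets are 0-based from the 5' end.
Weighted counts are sums of `1/n` fractions rendered with four decimals, so
reruns are byte-identical. Matures flush against a hairpin edge get empty
flanks (all tails non-templated, with a warning); indels are rejected with
a clear message; variants outside every mature locus are excluded with a
warning; a VCF without genotype columns runs the full pipeline minus the
consistency step; an empty sample yields zero-filled columns and headered
but empty annotation files.

## What the synthetic fixtures emulate — and what they do not

`make_fixture_bundle()` generates, from one seed, a toy reference
(RNA-alphabet FASTA, GFF3, VCF) and per-sample FASTQs with a truth table.
It plants every structural case the workflow distinguishes: plus- and
minus-strand single-SNP polymiRs, a two-SNP polymiR, one genomic SNP shared
by two overlapping opposite-strand matures, and a paralogous mature where
only one of two loci is polymorphic. Three samples cover the hom-ref /
het / hom-alt genotypes at every variant. Per-read editing classes default
to a field-typical profile (40% canonical; 3' trimming dominant; templated
and non-templated tailing; rare 5' events), with one forced exemplar per
label class; inserts are screened so that adapter removal reconstructs them
exactly, which is what makes the planted truth exact. Default problem
sizes — 30 reads per mature per sample, nine matures, three samples — keep
a full run around a thousand reads.

The fixtures deliberately do not model Illumina error profiles, PCR
duplication, other small-RNA species contaminating the library, or
A-to-I editing. Passing the recovery suite therefore shows that the
algorithmic chain is faithful to its definition on clean data, not that
real-data accuracy reaches any particular level.

## Limitations

Gapped alignment and internal-mismatch isomiRs (including A-to-I editing)
are out of scope; indel variants are rejected; genotype calling from reads
is intentionally not attempted — inconsistencies are reported, not
corrected. The score threshold is study-specific: deeply sequenced or
noisy libraries may warrant a different cut.
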