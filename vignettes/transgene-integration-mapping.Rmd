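---
title: "Mapping a multi-copy transgene integration site from shallow WGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a multi-copy transgene integration site from shallow WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgmap)
```

## The problem

Classic transgenic mouse lines — such as the pmel-1 T-cell-receptor line —
were made by pronuclear injection, which inserts the construct at a random
genomic position, usually as a tandem array of many copies, and usually with
a small deletion of host sequence at the integration site. For most of these
lines the integration site was never determined, so zygosity cannot be read
from a simple PCR: breeders must be genotyped by progeny testing or by
expensive phenotypic assays. Shallow (~8X) paired-end whole-genome sequencing
of a homozygous animal is enough to locate the site exactly, because the
junctions between host chromosome and transgene leave two unmistakable
footprints in the alignments:

* **discordant read pairs** whose mates map to different chromosomes — one
  mate in the host flank, the other in the genomic region the construct was
  derived from (for a TCR transgene, the endogenous TCR alpha/beta loci); and
* **soft-clipped (split) reads** that align partly to the host flank and
  partly to the construct, with the clip at the junction base.

Because the construct is present in many tandem copies while the reference
genome carries its source region once, the construct region also shows up as
a strong **read-depth duplication**, and the ratio of its mean depth to the
genome-wide depth estimates the inserted copy number.

`tgmap` implements this whole inference chain as a fitting function,
`locate_insertion()`, that returns a classed object with `print()`,
`summary()`, `coef()` and `plot()` methods, plus a synthetic-locus simulator
so the chain can be exercised and tested end to end with no external data.

## The procedure

Given paired-end alignment records (SAM via `read_sam()`, or the simulator's
oracle alignments):

1. **Insert-size model.** Concordance bounds are `median ± k · 1.4826 · MAD`
   (default `k = 3`) over same-contig inward-facing pairs, with a 1-bp floor
   on the scaled MAD. Robust statistics mean a handful of chimeric pairs
   cannot widen the window.
2. **Pair classification** (`classify_pairs()`): different contigs →
   `discordant_interchrom`; same contig but outward/same-facing →
   `discordant_orientation`; insert outside the model bounds →
   `discordant_size`; otherwise concordant. Pairs with either mate below
   `min_mapq = 20` are flagged non-unique and excluded from SV evidence —
   the operational meaning of "uniquely mapped" here, since aligner-reported
   MAPQ is the standard proxy.
3. **Clip extraction** (`extract_clips()`): one event per soft clip of at
   least `min_clip = 10` bp. `boundary_pos` is the last aligned base next to
   the clip; for left-side clips that is `pos - 1`, and right-boundary
   resolution adds the one back. 10 bp excludes adapter/error clips at
   101-bp reads while keeping real junction reads informative.
4. **Clustering** (`cluster_discordant_pairs()`): single linkage over unique
   discordant pairs; two pairs join a cluster iff both their A-side and
   B-side footprints are within `window = 2 ×` insert median. That window
   captures every pair whose fragment spans one junction without merging the
   two junctions of a small deletion (their partner sides differ).
5. **Depth duplications** (`scan_depth_duplications()`): bins (200 bp) at
   `≥ 1.5 ×` baseline are merged into calls scored by the normalised read
   count `rc`. The baseline is the **median of covered bins**, which is
   robust to the duplications themselves and to unsampled reference
   stretches (see below). 1.5× reliably detects ≥2-fold gains at 8X.
6. **Filtering** (`apply_filters()`), codifying the manual candidate review:
   support outside `[5, 16]` pairs; clusters on excluded (mitochondrial /
   centromeric) contigs; intra-chromosomal clusters; "multiple adjacent
   rearrangements" (≥3 other clusters of support ≥2 within 10 kb); and
   clusters with **both** sides inside depth duplications. The last rule is
   this package's codification of removing candidates "associated with
   repeats": links between two duplicated regions are artifacts of the
   tandem array itself (e.g. the beta-block/alpha-block junction inside the
   array) and cannot be the host junction. Crowding deliberately ignores
   single stray pairs and uses a fixed support floor of 2 so that filtering
   stays monotone in the support window.
7. **Ranking** (`rank_candidates()`): split-read support, then whether a
   side is bridged to a depth duplication, then pair support, then
   coordinates — a deterministic total order.
8. **Boundary resolution** (`resolve_boundary()`): the top candidate defines
   a window (± 2 × insert upper bound); within it, right-side clips resolve
   the left boundary and left-side clips the right boundary, each as the
   mode of clip positions (ties toward the smaller coordinate). Junction
   reads that the aligner assigned to the *cassette* side are re-anchored
   into the window by matching their clipped tails against the flank
   reference (`rescue_junction_clips`) — these are precisely the reads that
   "map partially to the cassette and partially to the chromosome", and at
   8X one junction frequently has no flank-aligned clip without them. The
   clipped sequences are collapsed by per-column majority (≥50%, truncated
   at the first dissent — robust in the 1–5-read regime) and matched against
   the cassette ends; the best placement shift measures the duplicated span
   and assigns the partner cassette (mismatch rate must stay below 10%).
9. **The call** (`assemble_insertion_call()`): deletion length is the
   coordinate difference `right − left` (the convention in which such sites are reported;
   the inclusive deleted base count is one less — a deliberate convention,
   flagged here). Microhomology per side is the longest exact
   flank-suffix/cassette-prefix overlap (mirror image on the right), from
   `compute_microhomology()`.
10. **Copy folds** (`estimate_copy_fold()`): mean depth over the
    edge-trimmed cassette interval divided by the genome-wide mean — the
    "X" arithmetic (e.g. 16X alpha, 4X beta over an 8X genome). Edge trim
    (200 bp) avoids the soft-clip depth dip at the array ends; a percentile
    bootstrap over bins gives a CI. The estimate is reported as a coverage
    *ratio*: converting to a per-haploid biological copy count needs the
    zygosity and the endogenous-copy status, which coverage alone cannot
    disambiguate, so that interpretation is left to the user.

## The synthetic world

`simulate_locus_spec()` + `build_alleles()` + `simulate_read_pairs()` +
`emit_oracle_alignments()` generate a three-contig genome (host chromosome
surrogate plus one donor contig per cassette), a transgenic allele and
wild-type allele, uniform-coverage 101-bp paired reads, and the alignments a
local-mode aligner would emit. Defaults state the world once:

| parameter | default | why |
|---|---|---|
| boundaries | 68,208,872 / 68,209,029 | the mouse chr2 frame of the mapped site; 157-bp coordinate-difference deletion |
| duplicated motifs | CCAGCAG (left), TGGAT (right) | the pmel-1 junction microhomologies |
| array | 4 beta units then 16 alpha units | left junction partners beta, right partners alpha, and the folds are 4X/16X over an 8X genome |
| unit lengths | beta 4 kb, alpha 2 kb | desk-scale; beta (which carries the genotyping junction) is kept above the 3-kb amplifiable window so tandem-ladder PCR products are out of range, as with real vector-scale cassettes |
| read length / depth | 101 bp / 8X | the sequencing regime being emulated |
| insert | Normal(400, 40), truncated at the read length | a typical 2012-era paired-end WGS library |
| error rate | 0.002 substitutions/base | Illumina-like; indel errors are out of scope |
| flanks / donor pads | 12 kb / 2 kb | > 2 × insert mean, with room for primer design |
| seed | 8 | one generator drives all randomness |

The duplicated boundary motifs are stored **once** physically (carried by
the flank; the array is trimmed of its duplicated prefix/suffix), so that
alignments are ambiguous over the duplicated span exactly as at a real
microhomology junction — this is what the resolver's shift search measures.

Oracle alignments assign each read by its true origin; junction-spanning
reads go to the side with the longer match and are clipped at the true
boundary. Reads wholly inside a tandem unit map **uniquely** in reference
space (all copies collapse onto the one donor locus) and keep mapq 60 —
giving them mapq 0 would discard the junction-bridging pairs the method
depends on. Reads spanning a same-cassette unit–unit junction admit two
equally good local placements on the donor and get mapq 0.

What a green test does **not** establish: the simulator has no GC bias, no
PCR duplicates, no indel errors, constant base quality, uniform (not
fragment-biased) sampling, and an aligner oracle instead of a real aligner;
real data additionally face repeats and an incompletely known vector
sequence. The spec of the array itself (orientations, interleaving) is
configuration, not inference: the read evidence does not determine it,
and the package only ever reports per-cassette copy folds, not array
structure.

Because the sampled genome omits donor contigs when endogenous copies are
off, donor pads have zero coverage; a naive genome-wide mean would be
deflated. Hence the duplication baseline uses the covered-bin median, and
`estimate_copy_fold()`'s background defaults (in the fit) to contigs
carrying no cassette interval — on real whole-genome data the background is
simply the rest of the genome.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive everywhere; BED/bedGraph conversion to
  0-based half-open happens only in the writers.
* Modal clip position ties break toward the smaller coordinate; candidate
  ranking ends in a coordinate tie-break, so outputs are deterministic.
* A constant insert distribution floors the MAD at 1 bp rather than
  producing a zero-width window.
* With no clip evidence a boundary falls back to the discordant-cluster
  midpoint and the call is flagged `approximate`; it is never silently
  promoted.
* Zero cassette copies with a unit deletion reproduce the wild type
  exactly; inconsistent duplicated motifs fail construction naming the
  violated side.
* `estimate_copy_fold()` refuses intervals shorter than twice the edge trim.
* In-silico PCR product length is the 5'-to-5' inclusive span (gel-size
  convention); primer Tm uses the Wallace `2(A+T) + 4(G+C)` rule, adequate
  for 14–30-nt primers and requiring no thermodynamic tables; with
  mismatches allowed, the 3'-terminal 3 bases must still match exactly
  (extension chemistry).
* `design_primers()` places the forward primer in the shared left flank,
  one reverse primer inside the deleted host segment (wild-type-only band)
  and one inside the junction-proximal cassette (transgenic-only band). A
  primer inside a tandem unit necessarily recurs in every copy, so its
  uniqueness is required only within the 3-kb amplifiable window; deeper
  ladder products must fall outside it.

## A worked run

```{r, eval = FALSE}
library(tgmap)
run <- run_pipeline(pipeline_config(seed = 8))
print(run)
coef(run$fit)
#  left_boundary right_boundary deletion_length
#       68208872       68209029             157
plot(run$fit)
```

The fit reports the evidence funnel (total pairs → discordant → unique →
clusters → filtered → ranked → resolved), the boundary calls with their
discordant-pair and soft-clip support, the junction microhomologies, the
per-cassette copy folds with bootstrap CIs, and — in synthetic runs — a
designed three-primer set whose predicted band patterns are 308 bp
(homozygote), 203 bp (wild type) or both (heterozygote).

## Known limitations

* The method nominates a *single* integration site; multi-site lines would
  need the candidate list (`summary(fit)`) inspected past rank 1.
* Copy folds are coverage ratios; they conflate transgene copies with any
  endogenous copies of the same sequence, as any read-depth method must.
* The internal structure of the array ("except for a few gaps") is not
  resolved; local assembly of the array is a non-goal.
* Which reverse primer of the classic assay binds the deleted host segment
  versus the vector junction is not determined by the band sizes alone;
  the assay here fixes the geometry by
  construction and treats primer naming as configuration.
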