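---
title: "Calling miRNA-guided cleavage from degradome (PARE) libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling miRNA-guided cleavage from degradome (PARE) libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degracall)
```

## The biological problem

In plants, most miRNA-guided regulation works by slicing: the RISC complex,
programmed with a mature miRNA, cleaves a near-complementary mRNA between
the nucleotides paired to miRNA positions 10 and 11 (counted from the miRNA
5' end). The 3' cleavage fragment keeps a 5' monophosphate, which degradome
(PARE) library protocols capture selectively. A sequenced degradome tag
therefore marks, by its 5' end, an uncapped mRNA 5' terminus — and a pile of
tag 5' ends exactly opposite miRNA nucleotide 10 of a predicted target site
is direct physical evidence that the site is sliced in vivo.

`degracall` implements this logic end to end: raw degradome reads are
trimmed, filtered and collapsed into unique tags; tags are mapped exactly to
a transcript set to build per-transcript 5'-end signature profiles;
candidate miRNA complementary sites are found with a plant-style penalty
score; and sites with signature support near the canonical slicing
coordinate are emitted as cleavage calls with a CleaveLand-style confidence
category (0–4). The same machinery, pointed at pre-miRNA hairpins instead of
mRNAs, detects processing products, miRNA/miRNA*-directed self-cleavage of
precursors, feedback loops, and duplexes whose star strand is itself a
functional guide.

## The scoring model

Target recognition is scored as an ungapped, antiparallel pairing of the
miRNA against a transcript window of the same length: miRNA nucleotide $i$
faces transcript position $s + L - i$ for a window starting at $s$ (so the
window's first position pairs with the miRNA 3' end). Each pair contributes
a penalty:

| pair state | penalty | doubled over miRNA positions 2–13 |
|---|---|---|
| Watson–Crick match | 0 | — |
| G:U wobble | 0.5 | 1.0 |
| mismatch | 1.0 | 2.0 |

The total is the site score; smaller is better, and every half-unit value
is attainable. The position-2–13 doubling encodes the biological weight of
the 5' core whose pairing RISC requires for slicing. The canonical cleavage
coordinate of an alignment is the transcript position paired to miRNA
nucleotide 10, i.e. $s + L - 10$.

The default discovery cutoff is 4.5 penalty units, the upper end of the
operating range seen in published *Populus* degradome calls; it can be
relaxed to the conventional looser 7.0. Gapped (bulged) alignments are
deliberately out of scope: the ungapped restriction keeps the scorer exact,
fast and easy to reason about, at the cost of missing the minority of
genuine sites with target bulges.

Ambiguous transcript bases inside a window are scored as mismatches —
conservative in the only direction that matters for calling.

## Category 0–4 classification

A candidate site becomes a call when the transcript's signature profile has
at least one occupied position within the register window (default ±1 nt,
`window = 3` for an extended register) of the canonical cleavage
coordinate. Each such position is classified independently against the
transcript-wide profile statistics (maximum count, number of positions
attaining it, and the median count over occupied positions):

* **category 4** — exactly one raw read at the position (lowest
  confidence). This test runs first: a lone read that also happens to be
  the transcript maximum is still category 4, because the top class
  requires more than one read.
* **category 0** — the unique transcript maximum, with more than one read
  (highest confidence).
* **category 1** — a maximum attained at more than one position.
* **category 2** — below the maximum but above the median.
* **category 3** — at or below the median (ties at the median fall here,
  since the class is defined as "equal to or less than" the median).

Two numerical choices deserve a note. The median is taken over *occupied*
positions only: including the sea of zero positions would make the median 0
on almost every transcript and collapse categories 2 and 3 into one. And
the register window default of ±1 nt reflects that observed cleavage
registers can shift by a nucleotide or two between family members; every
call records its `offset` from the canonical coordinate so downstream
analysis can restrict to offset 0 if desired.

## Preprocessing rules

Degradome tags are 5'-defined, so trimming never touches the read 5' end.
The 3' adapter is removed at its leftmost full occurrence, or at a terminal
adapter prefix of at least `min_overlap` (default 5) nt; reads with neither
are discarded as adapterless. Tags shorter than 18 nt or containing an
ambiguous base are discarded; tags longer than 24 nt are discarded by
default (the retained 18–24 band matches observed filtered degradome
libraries) or truncated with a flag. ncRNA contamination (rRNA, tRNA,
snRNA, snoRNA) is removed by exact substring membership in a supplied
contaminant set — a deterministic stand-in for database annotation. An
optional homopolymer filter (≥80% one base) is available but off by
default, as it has no counterpart in standard degradome filtering rules.

Mapping is exact, sense-strand only. Multi-mapping tags contribute their
full count at every locus (the standard degradome convention, since each
transcript is categorised independently); `fractional = TRUE` divides
counts by locus multiplicity for sensitivity analysis.

## Precursor analysis

Hairpin precursors are analysed three ways. `locate_products()` reports
every exact occurrence of degradome tags and catalog miRNAs inside the
hairpins, with 1-based inclusive spans (`span_end = span_start + length -
1`). `precursor_self_targets()` reruns the whole calling pipeline with the
hairpins as the transcript set, so mature strands that slice their own (or
a relative's) precursor mid-hairpin are detected with the same category
rules. `detect_feedback_loops()` keeps the precursor calls whose guide
belongs to the precursor's own family — the negative-feedback configuration
in which excess precursor is destroyed by its own product — and
cross-references the two arms when both cleave the same hairpin. Finally
`functional_star_pairs()` tallies calls per duplex arm over transcripts and
precursors jointly and reports duplexes with at least one call on each arm:
the cases where the miRNA* passenger strand is a working guide rather than
a degradation byproduct.

## The synthetic degradome generator

Because real degradome libraries are large and external, the package ships
a generator that emulates the relevant structure of one at desk scale, with
complete ground truth:

* **Transcripts** — random composition, lengths uniform on a configurable
  range (default 500–2000 nt, 50 transcripts).
* **Hairpins** — per family: 5' flank (5–30 nt) + arm + loop (8–20 nt) +
  arm + 3' flank, one arm the mature miRNA (default 21 nt), the other the
  star strand: the reverse complement of the miR arm with 1–3 planted
  mismatch/G:U positions. Edits are constrained so the guide-versus-own-
  precursor score stays at or below 4.5 in *both* guided directions (an
  edit at miR position $p$ lands at position $L-p+1$ when the star is the
  guide, so a one-sided cap would let tail edits double into the star's
  core); mid-hairpin self-targets are therefore discoverable by
  construction. Flank and loop lengths are free choices — realistic
  precursor geometry without modelling folding.
* **Target sites** — for each guide strand, reverse-complement windows with
  0–2 random edits written into transcripts, by default at most one site
  per transcript while unused transcripts remain (two strong sites on one
  transcript would force the weaker into category 2 purely by
  construction). Planted scores are obtained by re-scoring the edited
  window, so generator and scorer agree exactly.
* **Reads** — per site, a Poisson(`signal_mean`, default 20) bundle of
  reads whose 5' ends sit exactly at the canonical cleavage coordinate
  (negative-binomial and fixed-count options exist for robustness and
  single-read studies); uniform background 5' ends at `background_rate`
  (default 0.005) per position, matching the null that ordinary decay lacks
  positional structure; optional guided self-cleavage reads on a
  configurable subset of hairpins; ncRNA contaminant windows at a
  configurable library fraction; tag lengths 18–24 nt with weights strongly
  favouring 20- and 21-mers, as in real filtered degradome libraries. Every
  read receives a 3' adapter (default the Illumina TruSeq small-RNA
  adapter, `TGGAATTCTCGGGTGCCAAGG` — a free choice, as is the pre-trim read
  structure) and a configurable fraction is deliberately corrupted
  (truncated, N-injected, or adapterless) to exercise the filters.

Every stage seeds the RNG from `seed` plus a fixed stage offset, so each
stage is reproducible in isolation and the composed simulation is
byte-deterministic.

What the generator does *not* emulate: sequencing errors inside tags, PCR
duplication, expression-level heterogeneity between transcripts, secondary
structure, and genomic (intron-aware) mapping. Passing tests on synthetic
data therefore demonstrate the correctness of the pipeline's logic and
arithmetic under the stated generative model — not calling performance on a
real library, where signal-to-background is messier and exact mapping and
ungapped scoring are genuine simplifications.

## Worked example

```{r example}
cfg <- sim_config(seed = 7, n_transcripts = 20, n_mirna_families = 4,
                  sites_per_mirna = 2, signal_mean = 15,
                  background_rate = 0.003, self_cleavage_mean = 4)
sim <- simulate_degradome(cfg)
pre <- preprocess_reads(sim$reads, cfg$adapter, ncrna_set = sim$ncrna)
profiles <- build_profiles(map_tags(pre$tags, sim$transcripts)$hits)
alignments <- scan_catalog(setNames(sim$mature$sequence, sim$mature$id),
                           sim$transcripts, max_score = 4.5)
calls <- call_cleavages(alignments, profiles, window = 1)
table(calls$category)
category_census(calls)[, c("stratum", "n_sites", "n_cat0", "n_cat4",
                           "pct_high_conf")]
```

Precursor side:

```{r precursor}
pc <- precursor_self_targets(sim$mature, sim$hairpins, pre$tags)
detect_feedback_loops(pc, sim$mature)[, 1:4]
functional_star_pairs(rbind(calls, pc), sim$mature)
```

Or all of it in one call, with every table written to disk:

```{r pipeline, eval = FALSE}
res <- run_pipeline(pipeline_config(seed = 7), "degradome_run")
```

## Reporting conventions

Census percentages are integers rounded half-up from `100 * count /
n_sites` and always recomputed from the stored counts, never cached. The
high-confidence share pools categories 0–2 (all at or above the
above-median threshold). Distinct-target tallies key on target identifier,
so several call sites on one transcript count it once.

## Problem sizes and numerical notes

The bundled study conditions are deliberately desk-scale: the reference
recovery simulation uses 50 transcripts of 0.5–2 kb, 10 miRNA families and
3 planted sites per guide; scanner-versus-enumeration checks run 20 random
5-kb transcripts; the classifier is cross-checked against a literal
evaluation of its five defining rules on 10,000 random profiles. Score
comparisons use an epsilon of 1e-9 to keep 0.5-step arithmetic exact under
floating point; profile medians with an even number of occupied positions
take the mean of the central pair.

## Known limitations

Ungapped scoring misses bulged target sites; exact mapping misses tags with
sequencing errors; the category system, following standard degradome
practice, is a relative-abundance heuristic with no significance model —
the package deliberately reports no p-values. miRNA class labels
(conserved / non-conserved / novel) are input annotation, never computed.
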