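---
title: "Resolving plastome structure and transcript features from long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving plastome structure and transcript features from long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Chloroplast genomes of land plants are circular molecules of roughly
110–220 kb with a conserved quadripartite architecture: a large and a small
single-copy region (LSC, SSC) separated by two *exact* inverted-repeat
copies (IRa/IRb) of tens of kilobases. Their transcriptomes are
prokaryote-like — polycistronic operons, self-splicing group-II introns, and
post-transcriptional C-to-U RNA editing at specific cytidines, each edited
in only a fraction of transcript molecules (the site's *editing
efficiency*). Long genomic reads resolve the repeat structure that defeats
short-read assembly; full-length cDNAs (Iso-Seq style) expose introns,
editing and operon structure on single molecules.

`chloroplastr` implements that analysis chain — quadripartite resolution,
k-mer fishing of chloroplast reads from a mixed pool, spliced mapping of
full-length cDNAs, intron/editing/operon calling, and p-distance scoring of
barcode markers — together with a ground-truthed simulator, so every stage
can be validated by planted-truth recovery rather than by eye.

## The synthetic data generator

`plastome_spec()` + `generate_genome()` emit a circular genome as
LSC + IRa + SSC + IRb, with IRb the exact reverse complement of IRa. The
defaults are the study conditions the package is validated under:

* Region lengths 91,210 / 14,058 / 31,844 bp scaled by `scale`
  (default 1/10). Per-region GC targets IR 40.06%, LSC 33.47%, SSC 30.17%;
  region filler is composition-exact (the G+C count is fixed, only the
  order is random), so region GC lands within a few hundredths of a point
  of target and the length-weighted overall GC is reproducible.
* A gene plan (`duckweed_gene_plan()`) of nine polycistronic units — sizes
  4, 2, 3, 5, 2, 4, 3, 4 and 8 genes, named with real plastid gene
  families (atp, psb, psa, ndh, rpo, rpl/rps) — plus intron-bearing
  monocistronic genes. Nine group-II introns are planted in seven genes
  (ycf3 and clpP carry two each), every intron flanked by the group-II
  boundary motif, 5' `GTGYG` … `AY` 3' in transcript sense. With
  `full = TRUE` the plan pads to the 107-gene complement (78 CDS, 25 tRNA,
  4 rRNA) and adds a 6,930 bp ycf2-like CDS carrying planted 45 bp and
  48 bp tandem duplications.
* 37 editing sites — 30 in CDS, 1 in an intron, 6 intergenic — whose
  reference base is forced to C on the annotated strand. Efficiencies come
  from a fixed vector spanning 0.21–1.0 with median 0.93
  (`default_editing_efficiencies()`), i.e. the empirical range and central
  tendency of plastid editing.
* Transcription units get a fixed 30 bp UTR extension at both ends; the
  six intergenic editing sites are planted inside those UTR windows, which
  is how intergenic sites become observable in transcripts at all.

`simulate_genomic_reads()` draws read lengths from a log-normal truncated
to [300 bp, 3× mean] and applies an indel-dominated error model
(substitution : insertion : deletion = 1 : 2 : 2), the regime that actually
stresses a k-mer classifier and a spliced mapper. `simulate_isoseq()`
transcribes each unit `depth` times; each intron is spliced out per
transcript except with probability `retain_prob` (default 0.5) — intron
retention is common in plastid full-length cDNA pools, and it is what gives
the intronic editing site coverage. Editing is applied to the pre-mRNA with
per-site Bernoulli draws at the planted efficiency.

What the generator deliberately does **not** model: chimeric or 5'-degraded
reads, polyA tails, realistic quality strings, condition-dependent
expression (transcripts are uniform across units), and genes inside the
IRs — duplicated genes would make synthetic transcripts multi-map and
muddy planted-truth scoring, so the IRs are gene-free here. Passing tests
therefore demonstrate algorithmic correctness under clean assumptions, not
robustness to every artefact of real PacBio libraries.

## Quadripartite resolution

`find_inverted_repeats()` is exact seed-and-extend: 21-mers of the circular
sequence are matched against its reverse complement, seed pairs cluster on
anti-diagonals, and one representative per cluster is extended base-wise to
maximality (vectorised in chunks). Palindromic self-overlaps are trimmed
symmetrically so an interval is never paired with itself.
`partition_quadripartite()` takes the longest pair ≥ `min_ir` (default
1,000 bp), names the longer inter-IR arc the LSC, and normalises rotation
so position 0 is the LSC start adjacent to the IRb end. Ties between
equal-length arcs go to the lexicographically smaller sequence — arbitrary,
but deterministic and rotation/strand invariant. Genomes without a large IR
raise a structured `no_ir_error` rather than a partition.

The independent check in the test suite is
`Biostrings::findPalindromes()`, which finds the same arm on every genome
small enough to compare exhaustively.

## Read fishing

`build_kmer_index()` stores the strand-collapsed (canonical) 15-mers of the
doubled circular reference; `classify_read()` accepts a read when it has at
least `min_hits = 25` index k-mers and a hit fraction of at least
`min_frac = 0.02`. At ~12% long-read error the expected intact 15-mer
fraction is about 0.88^15 ≈ 0.15, comfortably above the threshold, while an
unrelated genome shares almost no 15-mers; the margin makes the
classification essentially error-free in both directions. The thresholds
are this package's own — alignment-based selection tools do not publish
equivalent cutoffs.

## Spliced mapping and junction placement

`spliced_map()` seeds with exact 13-mers (both strands; the circular target
is doubled, with hits restricted to the canonical image), groups seeds into
co-linear segments in query order, and chains segments with a small dynamic
program. A chained gap with target span ≥ `min_intron` (50 bp) and
near-zero query gap is an intron candidate.

Junction placement is the numerically delicate step. For each candidate
junction the mapper runs a "glue" DP between an exact seed anchor on either
side: prefix alignment scores of the query window against the donor-side
target and (reversed) against the acceptor-side target, with match +1,
mismatch −1, gap −2. All (split, donor, acceptor) combinations scoring
within 3 of the optimum are enumerated — a sequencing indel adjacent to the
junction can make the true placement score exactly one gap worse than a
shifted one, so the optimum alone is not trustworthy. Among the
candidates, any with both group-II boundary motifs wins; remaining ties
slide to the leftmost donor. On error-free transcripts this recovers every
planted junction base-exactly, and at 2% indel-dominated error the
per-observation exactness stays above 95% (the property the test suite
locks in).

Blocks are then materialised by stitching the exact anchors with tiny
Needleman–Wunsch patches over inter-anchor gaps, which keeps per-read cost
near-linear. Alignments round-trip through SAM 1.6 (introns as `N`
operations, substitutions via `MD`, the chain score as `AS`);
origin-wrapping records split into a primary plus supplementary pair at the
origin.

## Feature calling

**Introns** (`call_introns()`): junction observations (reads extending
≥ 10 bp into both flanking exons) are clustered; observations within 10 bp
of a cluster's modal junction are absorbed and the mode is the call. The
defaults `min_support = 3`, lengths 50–5,000 bp cover plastid intron sizes
with margin.

**Editing** (`call_editing()`): per-strand pileups over alignment blocks; a
candidate is any reference C (on the transcript strand) with coverage
≥ `min_cov = 10`. A site is called when the edited fraction is
≥ `min_eff = 0.10` and a one-sided binomial test against the error rate
`err = 0.02` rejects after Benjamini–Hochberg correction across all
candidates (`alpha = 0.05`). `min_eff` sits below the lowest efficiency the
generator plants (0.21) so sensitivity is limited by the statistics, not
the cutoff, while the binomial/BH combination keeps editing-free
simulations at zero false calls. Efficiency is the raw edited/covering
fraction; at the validation depth of 500 transcripts per unit its binomial
standard error is at most ~0.022 (worst case near efficiency 0.5), which
puts the suite's ±0.07 recovery band at roughly three standard errors.
CDS-site consequences are translated under genetic code table 11 (plastid/
bacterial).

**Operons** (`call_operons()`): a transcript covers a gene when its blocks
overlap ≥ 50% of the gene's exonic span on the same strand; transcripts
with the identical ordered gene list form one evidence group, and groups
with ≥ 2 genes and ≥ 3 transcripts become calls. Identity of the ordered
list — not maximal-overlap merging — is deliberate: processed sub-operons
remain separate calls with a `subset_of` cross-reference instead of being
absorbed. Calls are named by the *majority* gene family among their
members (title-cased, `_1`/`_2` ordinals in genome order), with the first
gene breaking ties; majority naming is what reproduces conventional operon
names when a unit carries a minority of genes from other families (an
NADH-dehydrogenase unit led by a ribosomal-protein gene is still "Ndh").

## Divergence scoring

`p_distance()` is the proportion of differing sites among compared
positions, with pairwise deletion by default (positions gapped or N in
either sequence are dropped) — the default of the standard distance
software in this field; complete deletion is available when the full
alignment is supplied. `variable_sites()` counts gap-free columns with two
or more distinct bases, N treated as missing. `rank_markers()` sorts by
mean distance with variable-site and name tie-breaks. The package does not
align markers: divergence values depend on the alignment that produced the
input, so reproducing published tables exactly requires the original
alignments, and only ranking-level agreement is claimed.

## Problem sizes and validation design

The validation suite runs the transcriptomic chain at 1/10 of the
full-scale region lengths — the smallest scale at which the complete gene
plan (38 named genes, 9 operons, 9 introns, 37 editing sites) physically
fits into the single-copy regions — and uses full scale only for the
genome-level statistics. Editing-efficiency recovery uses depth 500 per
unit (the power analysis above); intron-junction and operon recovery use
depths 10–20, where support thresholds are already saturated. The
false-positive check runs twenty editing-free simulations at 2% error on a
compact three-gene plan.

## Known limitations

* Transcripts spanning the circular origin are not chained across the seam
  (the simulator never places genes there; real data occasionally would).
* The spliced mapper assumes high-identity alignments (plastome
  transcripts on their own genome); it is not a general-purpose aligner
  for diverged or nuclear targets.
* Editing calling treats sites independently; linked editing on single
  molecules is visible in the alignments but not modelled.
* The GenBank writer/parser covers the subset of the format the pipeline
  emits (LOCUS, gene/CDS/tRNA/rRNA features with `join`/`complement`
  locations, ORIGIN); it is not a general GenBank implementation.
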