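---
title: "Identifying paralog pairs and quantifying their divergence: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying paralog pairs and quantifying their divergence: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paralogr)
```

# The problem

Salmonid fishes descend from an ancestor whose genome was duplicated
whole (a WGD event, roughly 50--100 Ma), and their genomes have continued
to accumulate local, typically tandem, gene duplications (LGD) since.
Given a transcriptome assembly, a draft genome and a linkage map,
`paralogr` identifies paralog gene pairs, decides whether each pair
descends from the WGD or from an LGD event, estimates synonymous and
nonsynonymous divergence (Ks, Ka) per pair, scales relative divergence
times from Ks ratios, and quantifies functional divergence within pairs
against two control sets. A synthetic-data generator with a truth table
makes every stage testable without any external download.

# The identification workflow

The decision procedure runs in four stages, each a plain function over
tibbles:

1. **Variant collapse** (`collapse_isogroups()`). Assemblies cluster
   transcript variants (alleles, splice forms; "isotigs") into gene-level
   groups ("isogroups"). Only the longest isotig per isogroup is kept, so
   within-gene variants cannot masquerade as duplicate genes. Ties go to
   the lexicographically smaller id; unmapped sequences count as
   singleton isogroups (permissive ingestion).
2. **Reciprocal best hits** (`all_vs_all_self_search()`,
   `reciprocal_best_pairs()`). An all-vs-all nucleotide search within the
   collapsed set; two sequences form a candidate pair only if each is the
   other's top-scoring hit. Candidates must align over at least 300 bp
   (inclusive) at more than 80% identity (strict) -- both thresholds are
   config keys, and `sensitivity_grid()` rescans the
   70/75/80/85% x 300/600 bp grid.
3. **Allelic filtering by genome anchoring** (`anchor_transcripts()`,
   `classify_pair()`). Each pair member is aligned to the genome contigs.
   Pairs with overlapping anchors on one contig are allelic variants of a
   single locus and are discarded. Pairs on one contig separated by more
   than 5 kb (measured between the nearest interval ends, strict) are
   LGD; when a best-annotation table is supplied, the two members must
   additionally have distinct best hits (one annotated / one not counts
   as distinct), otherwise distance alone decides. Same-contig,
   non-overlapping pairs within 5 kb are labelled `AMBIGUOUS` and
   excluded from origin statistics -- their fate is genuinely
   undeterminable at contig scale.
4. **Chromosome assignment** (`assign_chromosome()`). Contigs map to
   chromosomes through the linkage map. Pairs on different chromosomes
   are WGD; different contigs on one chromosome are LGD (chromosome-level
   identity, not contig-level, defines "same chromosome"); unmapped
   contigs leave a pair `UNASSIGNED`. With no linkage map the workflow
   still runs and such pairs simply stay unassigned.

Genome anchors keep the best-scoring locus plus any locus scoring within
10% of it: a transcript whose two loci score that closely cannot be
safely assigned to either, and the extra anchor lets the allelic rule
fire. Multi-anchor chromosome conflicts resolve to the top-scoring
anchor and are recorded in the pair's evidence string, never silently
dropped.

# The internal aligner

The search engine is a seed-and-extend local aligner
(`seed_and_extend_align()`): a query/subject/strand combination is
considered only if it shares an exact k-mer (default k = 11), and gated
combinations are scored by full affine-gap dynamic programming (Gotoh,
in C++), so every reported hit carries the *optimal* local alignment
score for that pair -- the tests verify this against an independent
full-DP implementation. Scoring defaults are +2/-3 with gap costs
5 + 2L; E-values use the Karlin-Altschul form `E = K m n exp(-lambda S)`
with fixed documented constants (lambda = 0.625, K = 0.41), because only
hit ranking and the E <= 1e-20 retention threshold matter to the
workflow, not absolute E-value accuracy. For the all-vs-all search,
candidate pairs must share at least five distinct seeds: at realistic
pool sizes two random ~1 kb sequences share a canonical 11-mer by chance
about once in three pairs, while any pair that can pass the workflow
thresholds shares hundreds. Genome anchoring likewise extends only seed
clusters supported by at least three seeds and skips loci with less than
30% of the best locus's seed support, which cannot reach the 10%
retention window. External 12-column tabular hit files can replace the
internal search at every call site.

Tie-breaking is deterministic everywhere: substitution beats gap in the
DP; higher score, then longer alignment, then smaller subject id decide
"top hit".

# Ka/Ks estimation

For each retained pair: the best of the 36 translated frame
combinations is found by local protein alignment of the six-frame
translations (stops translate to a terminator symbol scored -10 against
everything); the longest stop-free codon run overlapping that aligned
region is taken as each member's ORF (stop-to-stop, no ATG requirement,
minimum 30 codons); the two peptides are aligned globally (BLOSUM62,
affine gaps -10/-1) and the alignment is back-translated to codons,
reconstructing each ORF byte-exactly.

`nei_gojobori()` then counts synonymous (S) and nonsynonymous (N) sites
per codon from the universal code -- single-nucleotide changes that
would create a stop codon count as nonsynonymous -- and averages
synonymous/nonsynonymous differences over all mutational pathways
between differing codons, excluding pathways through stop codons
(weighting all equally if every pathway is blocked). Proportions are
corrected with Jukes-Cantor, `d = -(3/4) ln(1 - (4/3) p)`. Saturation
(p >= 3/4) and Ks = 0 are flags, not errors, and Ka/Ks with Ks = 0 is
undefined rather than infinite. These conventions differ between
published NG implementations; the test suite pins this package's
convention by exhaustive enumeration over all 61 x 61 sense-codon pairs.

The original toolchain filtered alignments "by quality score (minimum
score = 100)", a tool-specific quantity that cannot be reconstructed;
the implemented proxy is a minimum of 100 gap-free codon columns
(`min_codons`), recorded as a `TOO_SHORT` flag on every failing result.
A single best frame pair is used (rather than combining translated
hits), and pairwise global alignment stands in for a multiple-alignment
tool since only two sequences are ever aligned.

Relative divergence times use the Ks-ratio scaling
`t = t_ref * ks_focal / ks_ref` (`divergence_time()`); with the
published group summaries (LGD mean Ks 0.23 / median 0.21 against WGD
mean 0.40 / median 0.27) and WGD calibrations of 100 and 50 Ma this
gives 57.5, 77.8, 28.8 and 38.9 Ma. Group comparisons follow the
prescribed recipe: percent identity is arcsine-square-root transformed
(standard for percentages), checked with Shapiro-Wilk, and compared by a
two-sided rank-sum test; Ks is compared on the natural-log scale with a
Welch t-test, excluding zero/undefined Ks with the exclusion count
reported.

# Functional divergence

Two control sets frame the paralog pairs: C1 pairs two isotigs from one
isogroup (same gene; no isogroup reused), C2 pairs isotigs from
different isogroups (different genes; no sequence reused, rejection
sampling capped at 1000 attempts per slot). Within-pair comparisons are:

- **Best-hit concordance**: `SAME_HIT` / `DIFFERENT_HIT` (including
  one-member-annotated) / `NO_HIT`, compared across the three groups by
  a Pearson chi-squared test on the full 3 x 3 table (df = 4); displays
  conventionally hide `NO_HIT` but the test never does.
- **GO-term overlap**: per-pair Jaccard index, compared by
  Kruskal-Wallis plus pairwise rank-sum tests with Bonferroni
  correction. GO terms are flat sets; no ontology-graph propagation.
- **Coding potential**: per-sequence scores in [0, 1] with 0.5 as the
  coding/noncoding boundary; the absolute within-pair difference is
  compared between groups by a permutation test on the median *and* the
  IQR (default 100,000 label permutations), the IQR arm being the reason
  to permute at all -- rank tests only see location.

The permutation p-value counts permuted differences **at least as
large** as the observed one (`>=`). Ties at the observed value are
common with medians of bounded scores, and the non-strict count is the
conservative choice; the strict "greater than" variant is available via
`strict = TRUE`. A zero count is reported at the test's resolution
(`< 1/n_rounds`). Label permutation (not bootstrap resampling) is the
implemented scheme. Fisher's exact tests for GO enrichment are
two-sided with Benjamini-Hochberg adjustment at q <= 0.05; sidedness
and the FDR procedure are deliberate choices where convention is split.

## The built-in coding-potential scorer

The built-in model is a two-feature ridge-penalised logistic classifier:
the fraction of the sequence covered by its longest stop-free reading
frame (any of six frames) and a hexamer log-odds score, fitted once on a
deterministic synthetic corpus (coding: codon sequences with
untranslated flanks at 50-100% ORF coverage; noncoding: uniform random
nucleotides). The ridge penalty keeps the fit away from quasi-separation
so scores spread smoothly over (0, 1) instead of saturating at the
extremes. It is explicitly *not* a reimplementation of any published
coding-potential program -- only the [0, 1] range and the 0.5 threshold
are fixed semantics -- and an external per-sequence score table
(`read_score_table()`) is the fidelity path for real data.

# The synthetic-data generator

`simulate_dataset()` plants, under one master seed: ancestral genes
(stop-free random codon sequences of 250--350 codons with 5--50%
untranslated flanks, spaced >= 10 kb on contigs), a whole-genome
duplication (every chromosome gains a homeolog; every copy diverged to
an expected Ks of 0.40 at Ka/Ks 0.21), tandem copies for 30% of genes
(expected Ks 0.23, gaps 6--50 kb downstream on the same contig), allelic
variants (0.5% divergence, slightly 3'-trimmed so the locus transcript
stays the longest isotig) and in-frame exon-skipping isoforms clustered
into isogroups, and coding-to-noncoding drift for 15% of duplicate
copies (one-nucleotide deletion plus codon shuffle outside a preserved
40% anchor). The divergence targets sit where the screening thresholds
comfortably contain them (about 87% nucleotide identity at Ks 0.40), the
planted tandem gaps all exceed the 5 kb rule by at least 1 kb, and the
Ks/Ka targets are the published group means, so the generator's defaults
*are* the study conditions rather than knobs.

Divergence is applied as sequential synonymous/nonsynonymous
substitutions drawn from Poisson processes with expectations
`ks * S` and `ka * N`; realized counts are Poisson-dispersed around the
targets and are recorded in the truth table, so exact-value tests
compare against realized, not nominal, divergence. Substitutions that
would create stop codons are rejected and redrawn. Transcripts are
unspliced genomic substrings, so genome anchoring is exact by
construction; intron/UTR structure beyond plain flanks, transposon
dynamics and expression levels are out of scope.

Three generator choices deserve justification because nothing in the
data model forces them:

- **A fraction of allelic variants (30%) is emitted unclustered** (in
  its own isogroup), emulating assembly failure to cluster alleles.
  Clustered variants are removed at the collapse stage; only the
  unclustered ones reach the genome-anchoring filter, which is the stage
  the allelic rules exist for.
- **Duplicate copies redraw their untranslated extents** (lognormal
  jitter, sd 0.4) and **annotations are sparse and redundant** (60% of
  gene families have a database hit; a duplicate's best hit switches to
  a different database entry with probability 0.5). Real transcript
  boundaries and protein databases behave this way, and together these
  give the observed control-set structure: same-gene pairs dominated by
  identical hits and near-zero coding-potential differences, paralog
  pairs intermediate, different-gene pairs with no shared hits and the
  widest differences. At desk scale the expected number of
  same-accession C2 pairs is well below one, but it is not structurally
  zero: an unlucky seed can pair a gene with its own paralog.
- **GO terms are inherited with 10% per-term turnover** in duplicate
  copies, which separates the C1/paralog/C2 Jaccard distributions by
  construction without asserting any real-data statistic.

A planted pair can only be recovered if the reciprocal-best-hit stage
pairs its two members; a gene whose nearest relative is a younger tandem
copy pairs with that copy, and its WGD partner goes unpaired. This is a
property of the method being modelled, not a defect of the generator, so
recovery statistics report label accuracy over recovered pairs together
with the recovered/planted counts.

# Problem sizes and numerical choices

The packaged tests and the acceptance script run the full pipeline on
the generator's default dimensions -- 120 ancestral genes on 6
chromosomes (12 after duplication, 24 contigs, about 3.5 Mb of genome
and ~500 transcripts) -- which a single core handles in about two
minutes; estimator-recovery checks use 50 replicates of 500 codons per
Ks level, and the permutation-test calibration uses 1000 replicates of
2000 rounds. Monte-Carlo tolerances follow from these sizes (e.g. the
type-I error of the permutation test is asserted at 0.05 +/- 0.02).
Alignment problems are capped at 60 million DP cells per traceback,
far above anything the workflow produces; anchoring windows pad the
seed span by up to one query length. What passing these tests shows is
that the implementation is internally correct and calibrated under the
generator's assumptions; real 454 assemblies add chimeras, sequencing
error, incomplete isogroup clustering and database noise that the
generator deliberately does not model, so real-data thresholds may need
the sensitivity grid rather than the defaults.

# Known limitations

- Ka/Ks uses approximate (Nei-Gojobori) counting only; no
  maximum-likelihood dN/dS, rate variation among sites, or codon-usage
  corrected site counting.
- ORFs extending into untranslated flanks slightly inflate per-pair Ks
  when the flanks are included in the longest stop-free run, exactly as
  in the original protocol; the truth-regression test tolerates this as
  an additive offset.
- Paralog pairs in which one copy is unexpressed in the sampled tissues
  are invisible to a transcriptome-based screen.
- The Karlin-Altschul constants are fixed, not estimated from the
  scoring matrix; E-values rank hits but are not calibrated
  probabilities.
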