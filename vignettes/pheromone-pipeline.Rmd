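---
title: "Methods: grammar-based pheromone discovery in a courtship-gland transcriptome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grammar-based pheromone discovery in a courtship-gland transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salamandr)
```

# The problem

Male salamanders secrete proteinaceous courtship pheromones from cloacal
glands. The known families — sodefrin precursor-like factor (SPF, in alpha
and beta forms), preprosodefrin (PPS), plethodontid modulating factor
(PMF), and a PMF-like axolotl antifreeze protein (AFP) — share a modular
architecture built around the three-finger domain (TFD), a fold of three
loops pinned by a conserved pattern of disulfide-bonded cysteines.
Because loop sequence evolves quickly while the cysteine scaffold is
conserved, homology search alone under-detects these genes; what is
diagnostic is the *grammar* of the precursor: a secretory signal peptide,
one complete TFD closed by a terminal cysteine motif, optionally a partial
TFD lacking that motif, and a characteristic carboxy-terminal tail.

`salamandr` implements that grammar as an explicit, testable classifier,
embedded in a compact de novo transcriptome pipeline: read QC, digital
normalization, ORF extraction, homology filtering, classification, and
TPM quantification. Every stage is computed by the package itself (no
external aligners or predictors), and a simulator generates
grammar-conformant precursors and reads with known ground truth so the
whole chain is verified against planted answers.

# The domain grammar

Motifs are read over a three-letter alphabet: `C` (literal cysteine), `N`
(literal asparagine), `X` (any residue). The two terminal motifs are

* `CC_terminal` = `CCXXXXCN`, closing 10-cysteine complete TFDs
  (beta SPF, PPS, PMF, AFP);
* `XC_terminal` = `XCXXXXCN`, closing 8-cysteine complete TFDs
  (alpha SPF).

A site matching `CC` also matches `XC`; `CC` is tried first, and if its
10-cysteine count-back fails the site is still considered as an `XC`
match — the beta/alpha distinction therefore hinges jointly on the
double-cysteine and on the count, which is what the class definitions
require.

A **complete TFD** is a region that ends at a terminal-motif match and
contains, counting upstream from the motif's final cysteine, the
motif-implied number of cysteines with at most `max_gap = 30` residues
between consecutive cysteines, spanning 55–115 residues overall. The
paper trail for these families gives cysteine counts and motifs but no
spacing bounds; the gap bound and span window are package parameters
(config-exposed) chosen to comfortably accept the aligned domains the
families exhibit. Domains reported in the literature with 10–12 cysteines
motivate a tolerance: up to two additional chained cysteines immediately
upstream of the canonical count are accepted and flagged
(`extra_cysteines`) rather than rejected. A **partial TFD** is a
downstream cysteine cluster with the family-expected count (6 after an
XC domain, 8 after a CC domain) and *no* terminal motif; one missing
cysteine is tolerated with a `reduced_cysteine_count` flag, matching
reported variants with five of six cysteines.

**Signal peptides** are detected by a deterministic hydropathy heuristic,
not a trained model: within the first 35 residues there must be an
8-residue window of mean Kyte–Doolittle hydropathy above 1.5, and the
cleavage site is the first position 15–30 with small residues (A/G/S) at
its −3 and −1 positions. This is sufficient for generator templates and
keeps the package self-contained and deterministic; for real data an
external predictor can be substituted via the annotation interface.

**Low-complexity tails** (the sodefrin-bearing PPS tail) are suffixes
that are cysteine-free, at least 40 residues long, and have mean windowed
Shannon entropy at most 2.9 bits (window 12). A uniform-random 20-letter
suffix has windowed entropy near the window ceiling (about 3.2–3.4 bits
at window 12) and is rejected; a 4-letter low-complexity alphabet sits
near 1.9 bits and is accepted with a wide margin.

**Classification order**: (1) CC-terminal complete TFD plus a qualifying
low-complexity tail → PPS; (2) complete plus partial TFD → beta SPF
(CC) or alpha SPF (XC); (3) a single CC-terminal complete TFD with at
most 30 residues of tail → PMF or AFP, with tails longer than 8
residues flagged `extended_tail` (PMF-like contigs extended ~25 residues
past the motif are reported); (4) otherwise no call. PMF and AFP share
one grammar and are separable only by sequence homology, so the default
mode breaks the tie by best Smith–Waterman score against the bundled
PMF/AFP templates; grammar-only mode labels both `PMF_like`.
Interleukin-6-family pheromones (PRF) lack the TFD cysteine pattern by
definition and fall through to "none". A call is `complete` when a
signal peptide is present together with the class's full domain set,
else `partial` — matching how 5'-truncated contigs are reported.

# The synthetic data generator

Templates encode the published class layouts: alpha SPF (18-aa signal,
8-Cys XC-terminal TFD, 6-Cys partial TFD, short tail), beta SPF (18-aa
signal, 10-Cys CC-terminal TFD, 8-Cys partial TFD, short tail), PPS
(18-aa signal, CC-family TFD, cysteine-free 63-aa low-complexity tail),
PMF and AFP (20-aa signal, CC-terminal TFD, little or no tail). Design
choices the sources leave open, decided once here:

* **Filler residues** between cysteines are uniform over the standard
  amino acids minus Cys, Met *and Asn*. Excluding Asn (beyond the
  spurious-motif/internal-start exclusions of Cys and Met) means no
  terminal motif can arise anywhere a template did not place one, making
  classifier recovery on noiseless templates structural rather than
  probabilistic.
* **PMF/AFP TFD size**: no cysteine count is published for PMF's TFD;
  the grammar ties the CC motif to a 10-cysteine count-back, so the
  templates use 10, keeping generator and classifier consistent.
* **PPS signal length**: not separately published; PPS is beta-derived,
  so the SPF value (18 aa) is used.
* **Loop widths**: PMF/AFP and alpha templates use wider inter-cysteine
  loops than the canonical minimal domains so every precursor protein
  exceeds the pipeline's 125-aa ORF threshold — consistent with the
  observation that the PMF-like contigs in this gland are longer than
  canonical PMF, with more residues between cysteines. PMF and AFP get
  *different* fixed spacing patterns, so each synthetic family has its
  own loop geometry and the homology tie-break is meaningful.
* **Low-complexity tails** use a 4-letter alphabet (A/G/S/P), guaranteeing
  detection by the entropy rule.
* **Quality model**: per-base phred `clamp(Normal(34, 4), 2, 41)`, which
  puts roughly 85–90% of bases at Q30 or above, echoing the reported
  regime of the real libraries; substitution errors occur at the
  phred-implied rate. A fixed 33-nt adapter is appended when the insert
  is shorter than the 50-bp read.
* **Reverse translation** picks synonymous codons uniformly and forces an
  in-frame TAA immediately 5' of the CDS, so the planted ORF is the
  maximal stop-free stretch of its frame.
* **Default abundances** echo the study's ranks: housekeeping decoys
  (collagen-like etc.) on top, beta SPF (weight 1477) and PMF (1336) as
  the leading pheromones, alpha SPF moderate, AFP and PPS low.

What the simulator does **not** emulate: indels, paired ends, coverage
and sequence bias, chimeric contigs, or empirically learned quality
profiles. Tests passing on this generator therefore certify the
*computational rules* — not performance on real libraries, where signal
peptides, domain spacing and assembly artifacts are messier.

# Pipeline stages and their numerical rules

* **Read QC** applies, in order: 3' adapter removal (first position whose
  read/adapter overlap of ≥8 bases has ≤12.5% mismatches; N counts as a
  mismatch), end-trimming of terminal bases below Q20, then discarding
  reads shorter than 35 bp or — the read-level Q20 rule is interpreted as
  the **mean** per-read phred after trimming, matching average-quality
  filter semantics; the statistic is a config switch. QC is idempotent up
  to pathological chance re-matches of trimmed adapters under heavy error
  (the suite pins the exact behavior under fixed seeds).
* **Digital normalization** is the single-pass median-k-mer rule at
  k = 20, cutoff = 20, with exact hash counting (the probabilistic
  counting of the original tooling is an implementation detail, not part
  of the rule). The median of an even count is the lower middle element,
  keeping "median < cutoff" integer-exact; 100 identical reads leave
  exactly 20. Reads shorter than k are dropped with a distinct reason.
* **ORF extraction** takes every maximal stop-free stretch in all six
  frames (not ATG-anchored, so 5'-partial precursors survive), emitting
  stretches of ≥125 residues (stop excluded), with 0-based half-open
  coordinates on the forward strand.
* **Homology filtering** replaces the external-database search with a
  bundled panel (the canonical class templates plus housekeeping decoys;
  any protein FASTA can be substituted). Alignment is exact
  Smith–Waterman with affine gaps (BLOSUM62, gap open 11, extend 1, a
  length-k gap costing 11 + k; `X` scores 0 against everything),
  compiled in C++ as the field's aligners are. Significance uses the
  Karlin–Altschul form `E = K·m·n·exp(−λS)` with the published gapped
  BLOSUM62/11/1 parameters (λ = 0.267, K = 0.041), `m` the query length
  and `n` the total panel residue count, no edge correction. Retention
  at `E ≤ 1e-5`; the stated threshold "at least 1e-5" is read as "at
  most", its only sensible direction.
* **Quantification** maps reads by exact 20-mer seeds extended to
  full-length ungapped alignments with ≤2 substitutions on either strand
  (reads are 50 bp and simulator errors are substitutions; gaps are out
  of scope). Multi-mapping is resolved by EM with responsibilities
  proportional to `θ_i/ℓ_i` and effective length
  `ℓ = L − read_len + 1` (floor 1; single-end fixed-length reads need no
  fragment-length model), converging at `max |Δθ| < 1e-8` or 1000
  iterations. TPM is `(c/ℓ)` normalized to 1e6. Confidence intervals are
  a percentile bootstrap over reads (default 100 replicates) — the
  original tool's CI method is not described, so this is a stated
  substitute, not a claim of equivalence. Ranks break ties by contig id;
  flags mark TPM ≥ 2 (biologically active) and > 100 (highly
  expressed). The quantification input is the QC-filtered read set, not
  the normalized subset: normalization exists to speed assembly, and
  abundance estimation maps the filtered reads back to the contigs.
* **Assembly statistics**: N50 as the first length whose descending
  cumulative sum reaches half the total; GC over A/C/G/T only; length
  histogram in width-100 bins from 200 bp; TPM histogram in width-1 bins
  to 100 and width-100 bins above.

De novo assembly itself is out of scope: the pipeline accepts contigs
from file, or uses the simulator's true transcripts, so everything
downstream of assembly is exercised faithfully.

# A worked run

```{r pipeline, eval = FALSE}
res <- run_pipeline(seed = 1, config = pipeline_config(n_reads = 4000))
res
res$calls[res$calls$class_label != "none",
          c("orf_id", "class_label", "completeness")]
head(tidy(res$quant))
autoplot(res$quant)
```

On the default synthetic pool this recovers all five planted precursor
classes as complete calls, rejects the housekeeping decoys (three retained
by homology and classified "none"; two discarded by the panel filter),
and ranks beta SPF and PMF as the most abundant pheromones, mirroring the
planted weights.

# Problem sizes and verification

The test suite verifies each bespoke rule against an independent oracle:
ORF extraction against direct six-frame translation on 500 random contigs
up to 2 kb; Smith–Waterman against a non-affine explicit-gap DP on 200
random pairs up to 50 residues (and against an independent aligner);
digital normalization against a recount-from-scratch oracle; EM against a
dense grid search of the two-transcript likelihood; the classifier at
100% on all noiseless templates and truncations and ≥95% over 200
precursors carrying 2% random non-cysteine substitutions; TPM parameter
recovery at Pearson r ≥ 0.99 (every relative error ≤ 10%) on a
five-transcript pool at 100× coverage with zero error. End-to-end runs
use 1,500–4,000 simulated reads and 10 transcripts with 10–25 bootstrap
replicates — sizes chosen so the full suite runs in a few minutes on a
laptop while keeping every statistical check well-powered.

# Known limitations

* The signal-peptide heuristic is tuned to the generator's templates; it
  is not a general predictor and will miss unusual real signal peptides.
* The homology panel is synthetic; on real data a curated protein panel
  (or the original large databases) should be supplied.
* Karlin–Altschul parameters are fixed, not estimated from the scoring
  system; E-values are comparative, not calibrated for other matrices.
* No indel handling anywhere downstream of QC; reads with indels simply
  fail to map.
* Whether partial TFDs form disulfide bridges is unknown; the package
  annotates sequence patterns and makes no structural claim.
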