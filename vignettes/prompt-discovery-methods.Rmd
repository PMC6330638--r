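---
title: "Methods: PROMPT discovery and characterization with promptscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PROMPT discovery and characterization with promptscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

promptscape implements a complete analysis around promoter upstream
transcripts (PROMPTs): long noncoding RNAs transcribed within a short window
upstream of a protein-coding gene's transcription start site (TSS), in either
orientation. This vignette is the package's account of the models and
procedures, the parameters that matter, the synthetic-data generators used in
testing, and the design choices made where the methodology was genuinely
open.

## The identification cascade

Transcriptional units (TUs) pass three filters to be called lncRNA
candidates, all strict inequalities:

* length > 200 nt;
* longest open reading frame (ORF) < 300 nt, scanned over all six frames of
  both strands, where an ORF is `ATG ... stop` with the stop codon included
  in the length and required (no open-ended ORFs — the upstream tools'
  convention here is not published, so the stricter reading was fixed and is
  tested against a brute-force six-frame scanner);
* coding-potential score < 0.

The built-in coding-potential heuristic implements the decision contract of
the CPC/CNCI class of tools (negative score = noncoding) rather than either
tool's internals: the score is
`2 * (ORF coverage - 0.5) + mean hexamer log-odds`, where the hexamer table
is trained on the fly against synthetic codon-structured versus
composition-matched random backgrounds under a fixed internal seed (so scores
are deterministic). ORF coverage dominates for transcript-length sequences;
the hexamer term separates codon-biased sequence from background at equal
coverage. Scores from an external tool can be imported as a TSV and passed
through unchanged (`read_coding_scores()` + `filter_lncrna(scores = ...)`).

A surviving lncRNA is classified as a PROMPT iff its whole span lies strictly
upstream of some gene's TSS with no overlap of that gene's body, and its
distance to the TSS (`TSS - TU end` on `+` genes, `TU start - TSS` on `-`
genes) is at most the promoter window. The window defaults to 2,500 bp: the
mammalian literature places PROMPTs 0.5-2.5 kb upstream while poplar PROMPTs
concentrate at 0.4-0.8 kb, so the inclusive default favors recall and the
recorded distance supports downstream filtering. Whether "located in promoter
regions" allows a TU to straddle the window edge is not defined anywhere we
could anchor to; whole-TU-in-window was chosen. Ties between equidistant
genes go to the lexicographically smaller gene id for determinism.
Orientation is sense/antisense by strand agreement; the pair class marks
divergent shared-promoter situations (`sense/antisense`) when a second
qualifying gene sits on the opposite strand.

## Differential expression

The engine is a per-TU negative-binomial Wald test: counts are total-count
normalized (library scaled to the mean library size), the NB dispersion
(`var = mu + alpha mu^2`) is estimated by method of moments and pooled across
the two groups, and the test statistic is the difference of log group means
over its delta-method standard error. Two published threshold presets are
exposed because the source material is internally inconsistent: the
`results` preset (default) calls `up` at fold change > 2 with p < 0.005 and
BH FDR < 0.05; the `methods` preset uses p < 0.01 with the same fold-change
rule. All inequalities strict.

Total-count normalization is the simplest scheme consistent with the FPKM
formula the pipeline also implements, and is a deliberate deviation from
DESeq's median-of-ratios. Its known failure mode is composition bias: when a
large fraction of the transcriptome shifts in one direction, library scaling
transfers part of that shift onto unchanged TUs. The calibration tests place
planted changes in 10% of TUs, where sensitivity is unaffected; interpret
genome-wide shifts with this caveat.

Zero handling: an all-zero TU is reported `ns` with p = 1; a continuity shift
of 0.5 normalized counts stabilizes the log fold change when one group mean
is zero. Correlations are computed on `log2(FPKM + 1)`; the pseudocount is
recorded here as the package-wide convention.

The PROMPT-downstream-gene relationship is summarized two ways, because "the
correlation" is ambiguous: a per-pair Pearson correlation across samples, and
the pooled correlation across pairs of pair-mean `log2(FPKM + 1)` — the
scatter-plot statistic. The pooled value is the headline number; both are
returned.

## Co-expression network and modules

All-pairs Pearson correlations on `log2(x + 1)` are standardized against the
empirical distribution of the off-diagonal upper triangle
(`Z = (r - mean) / sd`), and edges kept at `Z > 5`. "Normalized
co-expression" has no published formula here; standardizing the observed
correlation distribution is the most direct reading, with a Fisher-z variant
behind the `method` flag for comparison. Degenerate inputs (all profiles
identical) have zero spread and yield an explicit empty network.

Modules are extracted greedily: PROMPTs ranked by gene-neighbor count
(degree), each in turn claiming its unassigned gene neighbors, keeping
modules with at least 51 genes. Membership is disjoint within one network
run. GO enrichment is the upper-tail hypergeometric test on a plain
`gene -> term` map with BH adjustment across terms; no ontology propagation
is performed, since the map's semantics are the caller's responsibility.
The much stricter pairing rule used for trans-target candidates
(r > 0.9999, p < 1e-4) is a separate filter (`strict_coexpressed_genes()`),
not part of network construction.

A note on the Z > 5 rule worth knowing before applying it: with a planted
module of 81 members among ~580 nodes, the module's own high-correlation
block inflates the spread of the empirical r distribution, so a Z of 5
corresponds to r of roughly 0.84 and is only reachable when the
between-sample noise term `1/(n-1)` is small relative to the block term.
The module-recovery test conditions (100 samples, within-module correlation
0.95) were chosen from this arithmetic — with 40 samples no edge can clear
Z = 5 in that configuration, regardless of implementation.

## Secondary structure

Folding is delegated to the ViennaRNA programs (`RNAfold`, `RNAeval`) under
their defaults: Turner 2004 nearest-neighbor parameters at 37 °C, dangles
model 2, lonely pairs allowed, minimum hairpin loop 3, no pseudoknots. DNA
input is transcribed to RNA internally; all reported coordinates stay on the
input sequence. The folding contract is verified two ways: spot energies of
designed hairpins, and an exhaustive-enumeration oracle that generates every
pseudoknot-free structure over canonical pairs for sequences up to 14 nt,
scores each with `RNAeval`, and checks the minimum equals `RNAfold`'s answer.

Element annotation is the standard structure parse: paired positions are
`stem`; each unpaired position is classified by its enclosing loop (hairpin,
internal, bulge, multiloop, or exterior). Two granularities of "loop" are
used deliberately: hairpin loops carry the 5'→3' loop numbering used in
deletion/mutation experiments, while the loop-versus-stem dichotomy for motif
enrichment counts all enclosed unpaired classes (hairpin, internal, bulge,
multiloop) as loop; the exterior strand is excluded from "loop" by default
because it is not part of any folded element, and the class list is a
parameter.

Motif scanning is IUPAC-consensus matching with overlaps, on both strands,
with minus-strand hits mapped to plus coordinates. An `N` in the scanned
sequence matches nothing — the conservative choice, since an ambiguous base
is not evidence for a site. The shipped motif table (ERF, GATA, Dof, WRKY,
MYB1AT, AT-Hook, RAV1AAT, ATHB5ATCORE) is PLACE-style configuration, editable
by design: consensus definitions belong to the user's motif library of
record, not to this package.

Variant effects fold both alleles and report `delta_mfe = mfe_alt - mfe_ref`
exactly, plus a structure-changed flag; SNP sets can be applied jointly as a
haplotype. Loop deletions remove exactly the unpaired hairpin interval
(closing pair retained — whether published deletion constructs removed the
closing pairs is unstated, and this is the smaller perturbation), refold, and
report the energy increase. The loop-to-stem search enumerates substitution
sets of bounded size confined to the loop and maximizes the paired fraction
of the former loop interval in the refold, with deterministic tie-breaking
(fewer changes, then lower energy); it is exhaustive up to a candidate cap
and returns the original with a flag when nothing improves pairing.

## Population statistics

* Haplotype frequencies count distinct allele strings over phased haplotype
  rows complete at the chosen sites. Unphased diploid input is rejected
  rather than EM-phased: haplotype inference is a different algorithmic
  problem and silently imputing phase would contaminate LD downstream.
* LD is haplotypic: `D = p_AB - p_A p_B`, `r² = D²/(p_A q_A p_B q_B)`, with
  significance from `chi² = n r²` on 1 df — the convention matching an
  "r² with p" presentation. Whether published values were haplotypic or
  genotypic r² is unknowable from the text; haplotypic was implemented and
  is stated here.
* Tissue specificity is the standard tau index,
  `tau = sum(1 - x_i/x_max)/(N-1)`, on max-normalized non-negative values —
  the only widely accepted formula behind the name "tau score".
* Divergence uses the Jukes-Cantor distance `d = -(3/4) ln(1 - 4p/3)` on
  gap- and N-free columns, the simplest model consistent with treating
  ancestral repeats (ARs) as a neutral rate proxy; it is cross-checked
  against `ape::dist.dna(model = "JC69")` in the tests. The selection
  statistic is the per-pair ratio `d_PROMPT/d_AR` with its median and a
  one-sided Wilcoxon signed-rank test against 1; saturated pairs
  (p ≥ 0.75) and pairs with `d_AR = 0` are dropped with a warning.

## Synthetic data: what it emulates, and what it does not

The generators produce every input with known truth, at the study's stated
conditions wherever a condition is stated:

* **Genome and loci**: 10 chromosomes × 100 kb with 200 genes in margin-
  guarded slots; 60 planted PROMPTs at 400-800 bp upstream, orientation mix
  95.5% antisense / 4.5% sense; 40 intergenic decoys verified to fail the
  PROMPT geometry; 20 coding decoys placed like PROMPTs but carrying a long
  ORF. Planted TU segments are rejection-sampled to pass (or fail) the
  sequence filters in both orientations and patched into the genome, so the
  truth holds by construction and classifier precision/recall are
  well-defined.
* **Counts**: NB with dispersion 0.1 and 3 replicates per group; baseline
  log2 abundances Gaussian (mean 6, sd 1.5 — a realistic ~2-decade dynamic
  range); planted log2 fold changes of ±3; PROMPT/gene pairs share a
  Gaussian latent factor on the log scale whose loading targets a 0.65
  across-pairs baseline correlation, plus a fully shared per-sample factor
  (sd 0.5 log2) for within-pair co-variation. The across-pairs statistic is
  the calibrated one; the per-pair correlation is qualitative.
* **Population**: 505 diploid individuals drawn multinomially from three
  haplotypes at (0.595, 0.394, 0.011) over eight sites.
* **Divergence**: matched alignment pairs mutated under Jukes-Cantor, ARs at
  distance 0.10 and PROMPTs at 0.93 × that (7% suppression), length 1,000.
* **Structured sequences**: multi-hairpin scaffolds with GC-rich stems,
  AT-rich loops, and concrete IUPAC motif instances planted at recorded loop
  offsets.

What passing these tests does *not* show about real data: the generators
have no splicing complexity, no read-level noise or mapping ambiguity, no
overdispersion heterogeneity across TUs, no LD decay within haplotypes
(haplotypes are drawn whole), no indels in alignments, and decoy classes are
clean by construction. Results on the synthetic suite validate the
*machinery*, not the biology of any particular dataset; the motif-enrichment
null in particular (uniform background within a designed scaffold) is this
package's construction, since no background model is published for that
analysis.

### The PROMPT_1281 surrogate

The published PROMPT_1281 haplotype sequences are not redistributable with
this package, so structure-level checks run on a synthetic surrogate built to
the *described* architecture: five hairpins, a MYB1AT instance (WAACCA) in
loop 4, and three transcript SNPs — one softening a stem Watson-Crick pair
into a G-U wobble (verified to cost energy) and two in-loop substitutions
verified energy-neutral. On the current construction the surrogate's
haplotype gap is ~1.9 kcal/mol and per-SNP effects span 0 to ~1.9 kcal/mol;
these are properties of the surrogate, computed at run time, and are labelled
as such everywhere. Published absolute energies of the real molecule cannot
be reproduced without its sequence.

## Numerical and reproducibility choices

* All randomness flows through per-operation seeds; the pipeline derives
  per-stage substreams from one master seed by a fixed integer hash, so
  stages stay reproducible independently. Reruns of `run_pipeline()` under
  one config are byte-identical (manifest MD5s are compared in the tests).
* Problem sizes in the test suite (e.g. 2,000 TUs for DE calibration, 500
  alignment pairs, 200 oracle sequences up to 14 nt, 10 seeds for module
  recovery) were chosen as the smallest sizes at which the Monte-Carlo error
  of each recovered quantity is comfortably inside its acceptance band.
* Coordinates are GFF3 1-based closed everywhere internally; BED-style
  half-open intervals are converted at the I/O boundary. Density bins are
  half-open from position 1, so a start on a boundary belongs to the
  right-hand bin.
* The genotype TSV dialect (one haplotype row per chromosome copy) is
  defined by this package and documented in `?read_genotypes`; VCF is the
  interchange format, and phased input is required.

## Known limitations

Beyond the synthetic-data caveats above: the DE engine is not a DESeq
reimplementation and will differ numerically from it; module extraction is
greedy, not optimal, and a gene claimed by a higher-ranked module is
unavailable to later ones even if more correlated there; the loop-to-stem
search cost grows combinatorially with loop length and `n_changes`; and the
coding-potential heuristic, while calibrated to its decision contract, is
not a substitute for a trained classifier when real annotation quality
matters — use the TSV import path in that case.
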