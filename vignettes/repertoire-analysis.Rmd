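---
title: "Models and methods behind repsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind repsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repsim)
```

`repsim` simulates and analyses iNKT-cell TCR repertoires. This vignette
is the package's own account of its models: what is assumed, which
parameters matter, what the synthetic generator does and does not emulate,
and where genuinely open design choices were resolved.

## The clone-size model

Clonal expansion is summarised by the distribution of clonotype counts.
We model clone sizes with the logarithmic-series distribution

$$p_k = \frac{\theta^k}{k\,(-\ln(1-\theta))}, \qquad k = 1, 2, \dots$$

chosen because it is the simplest one-parameter heavy-tailed count
distribution whose singleton fraction is a closed form of its parameter,
$p_1 = \theta/(-\ln(1-\theta))$. That closed form is what allows the
tissue presets to be calibrated *exactly* to target singleton fractions
rather than fitted:

```{r}
theta <- c(thymus = 0.60, spleen = 0.60, mLN = 0.80, iLN = 0.90)
round(sapply(theta, logseries_singleton_fraction), 4)
```

spleen/thymus ≈ 65% singletons, mLN ≈ 50%, iLN ≈ 39% — the ordering of
progressively stronger clonal expansion in lymph nodes that the presets
encode. Sampling is by inverse-CDF lookup against a tabulated cumulative
distribution (tail mass below 1e-12 is clamped to the last tabulated
class); the sampler is validated in the tests against the closed forms
and against an independent rejection sampler.

The model is i.i.d. across clonotypes: it ignores competition between
clones and any covariance between clone size and V gene or CDR3 — a
deliberate simplification, which is also why the planted-signal test for
`rare_vs_abundant_usage()` has to introduce a V–size association
explicitly.

## The junction model and the germline toy reference

A CDR3 junction is, inclusively, the conserved V cysteine codon through
the conserved J phenylalanine/tryptophan codon of the [FW]GXG motif.
Junctions are generated as

V-templated prefix (Cys codon → V end) + untemplated N region +
J-templated suffix (J start → Phe codon),

with the N region drawn codon-wise from the 61 non-stop codons for
productive junctions. Nonproductive junctions (default 10% of β
clonotypes; this rate exists purely to exercise the productivity filter)
are frameshifted by ±1 nt or carry a random in-frame stop, with the
choice made by the generator's RNG.

The shipped germline reference is synthetic: 60-nt segments with valid
anchors, named after the genes whose usage the presets control (TRBV1,
TRBV13-1/2/3, TRBV19, TRBV29, a `TRBVother` catch-all; three TRBJ; TRAV11
and TRAV10; TRAJ18 and TRAJ9). It is a stand-in, not IMGT data — segment
bodies are random, so nothing downstream may rely on real V-gene sequence
content. Real references are accepted in the same annotated-FASTA form.
Two design points deserve note:

* **Why a second TRAV/TRAJ.** With a single α V and J, *every* α
  clonotype would trivially be TRAV11–TRAJ18 and the canonical-fraction
  statistic would be vacuous. The non-canonical share (default 3%) uses
  TRAV10 — a V gene for which an α-GalCer-reactive non-canonical NKT
  population is actually described — paired with TRAJ18 or TRAJ9.
* **Canonical α.** The default canonical CDR3α is the widely reported
  15-aa mouse iNKT junction `CVVGDRGSALGRLHF`; its nucleotide encoding is
  fixed (templated ends plus a deterministic reverse translation), so the
  canonical α is a single clonotype after assembly. The canonical
  fraction is therefore measured count-weighted — the fraction of α
  *sequences* carrying TRAV11–TRAJ18 — which is also what ">96%
  canonical" means in the bulk-sequencing setting the generator emulates.

Preset TRBV vectors reproduce only the qualitative tissue ordering
(TRBV13-2 depressed, `TRBVother` elevated in lymph nodes); they are
configuration, not ground truth. TRBJ usage is uniform because no
quantitative per-tissue constraint was available. The CDR3β length
spectrum over 11–18 aa has its mode at 14 aa
(`{11: .03, 12: .09, 13: .18, 14: .30, 15: .20, 16: .12, 17: .06, 18: .02}`);
the tail shape is invented. Clonotypes are spread over 4 samples per
tissue by default, matching the four-replicate design typical of such
studies.

**What passing tests show — and what they do not.** The generator
contains no sequencing error, no read-level simulation, no D-segment
beyond the N region, no allelic variation, and reads start and end
exactly at segment boundaries. Tests passing on this material validate
the *logic* of extraction, filtering and statistics; they say nothing
about robustness to real alignment ambiguity, which is the domain of
full-scale tools and explicitly out of scope.

## Extraction and clonotype assembly

Gene assignment is anchored Hamming matching: the read prefix against
each V prefix (through the Cys codon), the read suffix against each J
anchor-containing suffix, fewest mismatches wins, ties broken by gene
name, tolerance `max_mismatch = 2` by default. This is a toy-scale
contract — correct on clean and lightly mutated reads — not a
re-implementation of production aligner heuristics. Reads failing
assignment or the [FW]GXG motif check are written to a rejects table with
a reason code, never silently dropped.

Productivity is the conjunction of two predicates: junction length
divisible by 3, and a stop-free translation. Clonotypes are keyed on
(V gene, CDR3 nucleotide) — J is reported but not part of the key,
matching common clonotype conventions; the key is a parameter
(`key = c("v_call", "j_call", "junction")` or `"junction_aa"` for
amino-acid clonotypes). Assembly is per-sample by default with a pooled
mode merging a tissue's samples first, mirroring how pooled-per-tissue
repertoire figures are built. `duplicate_count` is treated as a read
count; whether upstream counts are reads or collapsed molecules is
outside the package's knowledge, and all statistics are agnostic to that
interpretation.

## Repertoire statistics: weightings and tie-breaks

Two denominators coexist deliberately. Gene-usage *of sequences* is
count-weighted; clone-size class fractions are over *distinct
clonotypes*. `v_usage()` exposes both weightings because published
figure legends are rarely explicit about which is meant. The V–J pairing
matrix is count-weighted and sums to 100%, and its row margin equals
100 × count-weighted V usage — an identity asserted in the tests.

Prevalence ranking for the top-N clonality curve breaks ties
deterministically (count desc, CDR3 aa asc, CDR3 nt asc) so top-25 values
are bit-reproducible. The rare-vs-abundant contrast compares V usage of
singletons against clonotypes with count ≥ 2 by default ("two copies or
more"; the threshold is a parameter since ">2 copies" also appears in
this literature).

## CDR3 physicochemistry

* **Hydrophobicity** is the mean Kyte–Doolittle value per residue; the
  mean (not the sum) is the default because it is scale-free across
  lengths, with the sum available via `method = "sum"`.
* **Isoelectric point** solves the Henderson–Hasselbalch charge balance
  with the nine-group EMBOSS default pK set (termini 8.6/3.6; K 10.8,
  R 12.5, H 6.5, D 3.9, E 4.1, C 8.5, Y 10.1), free cysteines assumed.
  The net charge is strictly decreasing in pH, so the root is unique;
  bisection runs to interval convergence (1e-8 pH) rather than stopping
  at the first |Q| < 1e-4, because near-flat charge curves make the
  small-|Q| region far wider than the root's neighbourhood (for
  tri-glycine the |Q| < 1e-4 band is ~0.014 pH wide). A 1e-4-resolution
  grid search serves as the test oracle, with agreement required within
  2e-4 pH.
* **Residue classes** follow the printed definition — polar
  {D,E,H,K,N,Q,R,S,T}, aliphatic {A,I,L,V}, aromatic {F,H,W,Y} — taken
  literally, including histidine's membership in *both* polar and
  aromatic classes, so class fractions may sum above 1.
* **Ambiguity.** `X` residues contribute zero hydropathy (staying in the
  mean's denominator, preserving concatenation linearity), carry no
  charge, and are excluded from class-frequency denominators; each use
  warns.
* **Logo matrices.** `position_frequency_matrix()` filters to a fixed
  length (defaults used in practice: 15 aa for CDR3α, 14 aa for CDR3β),
  reports how many sequences were kept, and returns raw per-column
  information content `log2(20) − H` in bits. The small-sample logo
  correction is intentionally omitted — the kept count is reported so it
  is recomputable — because logo output here is a matrix for inspection,
  not a quantitative estimator.

## Comparison statistics

`mann_whitney()` defines `U = Σ 1(a > b) + ½·1(a = b)` and, for
`n_a + n_b ≤ 14`, computes the two-sided p exactly by enumerating all
`choose(n_a + n_b, n_a)` group assignments of the pooled values — valid
under ties, where the classical exact null distribution is not. The
cutoff 14 (3432 assignments) balances fidelity and runtime. Above it, a
tie-corrected normal approximation with continuity correction is used.
The two-sided exact p is `min(1, 2·min(P(U* ≤ U), P(U* ≥ U)))`.

`t_test()` wraps `stats::t.test` with Welch as the unpaired default
(pooled variance by flag); degenerate inputs error, except
paired-identical samples, which return t = 0, p = 1. `one_way_anova()`
computes the between/within decomposition directly (zero within-group
variance errors as degenerate) with Tukey–Kramer HSD p-values from
`stats::ptukey` — numerical integration of the studentized-range
distribution, the method being recorded in the output — and is
cross-checked in the tests against `aov`/`TukeyHSD`. `pearson_cor()`
wraps `stats::cor.test`. No multiple-testing correction beyond Tukey is
applied anywhere: testing is per-analysis, matching the per-figure
conventions of the field.

## Determinism and problem sizes

All randomness in a simulation flows from one `seed`; re-running with an
identical config is byte-identical, and `run_pipeline()` writes a
manifest (config, seed, package version, constant tables, output
checksums) so every number is traceable. The package's own validation
uses 20,000-clonotype repertoires for distributional recovery (singleton
fractions within ±2 percentage points of their targets; usage vectors
within 3 binomial SE), 100,000 draws for sampler-vs-closed-form checks,
1,000 random peptides for the pI oracle, and 10,000 replicates for
type-I-error calibration — sizes chosen so sampling noise is well below
the tolerances being asserted while the whole suite runs in well under a
minute.

## Known limitations

* The toy extraction assumes reads spanning V start to J end; no
  quality scores, no read rescue, no D-gene calling, no allele calls.
* The log-series model cannot represent a clone-size distribution whose
  singleton fraction and mean are inconsistent with one θ.
* Diversity indices (Shannon, Gini–Simpson, Chao1, rarefaction) are
  deliberately absent: the analyses this package reproduces do not use
  them, and adding them would be trivial but untested surface.
* The human repertoire setting (Vα24–Vβ11) is not modelled; the
  comparison statistics apply unchanged, but no human presets exist.
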