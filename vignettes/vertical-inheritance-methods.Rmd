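---
title: "Methods: testing vertical inheritance of a bacterial gene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing vertical inheritance of a bacterial gene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertitrace)
```

# The question

When a gene family is confined to one clade of bacteria, two histories can
explain it: the gene arose once in the clade's ancestor and was inherited
vertically, or it arrived by lateral gene transfer (LGT), possibly more than
once. The two histories leave different marks. A recently transferred gene
tends to carry the nucleotide composition of its donor (deviant GC, a
compositional island around the locus), sits in a neighbourhood whose gene
content varies erratically across strains, and produces a gene tree that
disagrees with the species tree. A vertically inherited gene matches its
host composition, keeps a syntenic neighbourhood, evolves under the same
selective regime as housekeeping genes, and maps onto the species tree as a
single gain with occasional losses.

`vertitrace` implements this converging-evidence chain as independent,
individually testable stages, together with generators that produce
synthetic data with known ground truth for every stage. The package never
collapses the criteria into one score: the final report keeps each line of
evidence separate, because the argument for vertical inheritance is their
convergence, not any single statistic.

# Composition screens

**Gene vs genome GC.** `gc_content()` counts `(G + C) / (A + C + G + T)`;
`N` bases (assembly gaps) are excluded from the denominator everywhere.
Genome GC pools base counts over all contigs rather than averaging
per-contig fractions, so short contigs are weighted by length.
`gene_vs_genome_gc()` reports, per strain, the gene GC, genome GC and their
difference; `gc_deviation_z()` places one gene against a background of gene
GC values using the sample (n−1) standard deviation. Fractions are used
internally; percentages appear only in reports.

**Z-curve segmentation.** `compute_zcurve()` builds the three cumulative
disparity series (purine−pyrimidine, amino−keto, weak−strong).
`segment_sequence()` performs recursive binary segmentation: every split
position leaving both children at least `min_len` bp is scored with the
quadratic divergence

$$\Delta = n\left[\tfrac{n_L}{n}S(p^L) + \tfrac{n_R}{n}S(p^R) - S(p)\right]
        = n\,\tfrac{n_L}{n}\tfrac{n_R}{n}\,\lVert p^L - p^R\rVert_2^2,$$

where $S(p)=\sum_b p_b^2$ is the genome order index and $p$ the pooled
composition. The best split (ties broken by the smallest position, for
determinism) is accepted iff $\Delta \ge t_0$, and the procedure recurses.
Defaults are $t_0 = 100$ and `min_len = 1000` bp, the parameters used for
corynephage-style island detection. `scan_locus()` then reports the
distance from the focal gene to the nearest breakpoint.

Two properties of this statistic matter for interpretation. First, under a
homogeneous composition the maximal $\Delta$ over a 50 kb sequence is
around 5–10, far below $t_0 = 100$, so false segmentation is essentially
absent (the regression suite pins the null breakpoint fraction at 0 of 100
runs). Second, $\Delta$ grows linearly in segment size at fixed contrast,
which yields a hard detectability floor: a 5 kb island inside a 50 kb
sequence is detectable at $t_0=100$ only when the L1 composition contrast
exceeds roughly 0.2 (edge placement) to 0.3 (interior placement). Weak
islands below this floor are invisible by construction — a conservative
behaviour appropriate to a screen whose positive control is a strongly
deviant integrated phage. The recursive implementation is verified against
an exhaustive brute-force segmenter that re-scans counts at every candidate
split.

# Selection analysis

**Codon alignments.** `backtranslate()` maps a trusted protein alignment
onto its coding sequences (the PAL2NAL construction): each amino-acid
column becomes its source codon, protein gaps become `---`, a terminal stop
is tolerated and stripped, and any translation mismatch is an error naming
the sequence and position.

**NG86 dN/dS.** `ng86_pair()` implements the Nei–Gojobori (1986) counting
method. Per sense codon, each of the nine single-base changes is classified
synonymous or nonsynonymous; changes to stop codons are excluded and that
position's denominator reduced, giving site counts $s$ and $n = 3 - s$.
Site totals $S, N$ are averaged over the two sequences. For codons
differing at $k$ positions, difference counts are averaged over all $k!$
mutational pathways with equal weight; pathways through stop codons are
excluded and the weights renormalised (a column whose every pathway crosses
a stop is skipped). Columns with gaps or ambiguity codes in either sequence
are skipped pairwise. Proportions $p_S = S_d/S$, $p_N = N_d/N$ receive the
Jukes–Cantor correction $d = -\tfrac34\log(1-\tfrac43 p)$.

Each pair carries a status implementing the reporting filters, checked in
this order: `undefined_pS0` when $p_S = 0$; `saturated` when
$\tfrac43 p \ge 1$ for either proportion (the correction diverges);
`filtered_dN0_or_dS0` when $d_N = 0$ or $d_S = 0$; else `ok`. Only `ok`
pairs contribute $\omega = d_N/d_S$ to the retained set. Note that an
identical pair is reported `undefined_pS0` (the $p_S$ check runs first),
not as a zero-distance filter hit; either way it is excluded.

Equal pathway weighting (no transition/transversion weighting) is used —
pure NG86. The estimator is deliberately simpler than the simulator that
tests it: `sim_codon_pair()` evolves codons with a free
transition/transversion ratio `kappa`, so recovery tests probe estimator
robustness rather than a shared-model tautology. At `kappa = 1` and true
$\omega = 1$ the mean estimate over 200 pairs of 500 codons is within 0.05
of 1; the estimate is monotone in the true $\omega$ across 0.1/0.5/1.0.

**Bootstrap equality of means.** `boot_mean_eq_test()` compares the focal
gene's retained $\omega$ set against the core-gene background with a
two-sided shift bootstrap: both groups are translated to the pooled mean
(imposing the null), resampled with replacement at their own sizes `B`
times (default 1000), and the p-value is the add-one estimator
$(1 + \#\{|T^\ast| \ge |T_{obs}|\})/(B+1)$, so the smallest attainable p is
$1/(B+1)$ and $p = 0$ never occurs. Replicates are drawn in a canonical
group order so the p-value is exactly invariant to swapping the groups. A
shift bootstrap (not a permutation test, and not studentized) was chosen as
the plainest reading of "bootstrap test for equality of means"; the variant
is recorded in every report. Type-I error at $\alpha = 0.05$ is verified to
sit inside the binomial 99% band over 1000 null simulations.
`box_summary()` provides the box-plot statistics (type-7 linear
interpolation quartiles, whiskers at the most extreme points within 1.5
IQR).

# Trait evolution on the species tree

**Mk ancestral-state reconstruction.** `mk_asr()` fits a two-state Markov
model of presence/absence with gain rate $q_{01}$ and loss rate $q_{10}$
(`ER` ties them — the default, matching the common one-rate Mk
reconstruction; `ARD` frees them) by maximising the Felsenstein pruning
likelihood over log-rates in $[10^{-8}, 10^3]$, with an equal root prior by
default. Marginal node probabilities come from the standard
re-rooting (up–down) construction; the pruning likelihood is verified
against exhaustive enumeration of internal state assignments on all trees
up to 10 tips (tolerance $10^{-10}$) and against the two-tip closed form.

**Gains, losses, origin.** `count_transitions()` labels each node with its
max-marginal state — ties inherit the parent's label, and a root tie takes
absence, biasing toward fewer inferred gains — and counts $0\to1$ and
$1\to0$ edges. `origin_node()` returns the deepest node with marginal
presence probability at or above the threshold (default 0.5, reported
alongside the marginal so stricter cutoffs can be applied) from which all
present tips descend, falling back to the MRCA of present tips with a
warning. In recovery simulations (64-tip trees, a single gain, up to three
losses), a call is scored as *confident* when the inferred origin's
marginal is at least 0.9 and its parent's at most 0.1 — i.e. the origin
edge itself is decisively reconstructed; among confident calls the true
gain node is recovered in ≥ 90% of replicates, and the loss count is within
±1 of truth in ≥ 80% of all replicates. Unconfident calls are typically
gains high on long edges, where no method can place the event on a single
node.

**Dating.** `date_nodes()` is an explicitly simplified relative-rate
stand-in for full relative-time dating: node depth is the mean path length
to descendant tips (substitutions/site); one rate is fitted through the
origin by least squares against the calibration ages,
$r = \sum h_c a_c / \sum a_c^2$; ages are $h(v)/r$ with CIs from refitting
$r$ at the calibration CI bounds. On clock-like trees calibrations are
recovered exactly. On non-clock trees the raw mean path depth is *not*
monotone from root to tips (a parent averaging a deep and a shallow subtree
can sit below its deep child), so parent depths are floored at their
children's depths in postorder — a no-op on clock-like trees that
guarantees child age ≤ parent age. Reports label the method as a
simplified stand-in; its age estimates are qualitative.

**Transfer flagging.** `lgt_flags()` compares, per tip, the tip's sister
set (the tips of its sibling subtree) between the gene tree and the species
tree pruned to the shared tips. `incongruent` records every raw sister-set
difference. Because a single regrafted tip also perturbs the sister sets of
its new neighbour (the donor) and its former neighbours, the `flagged`
call is refined to the minimal explanation: among incongruent tips, those
whose single removal restores full topological congruence. When no single
tip explains the conflict — including transfers into a tip's own sister
group, which are symmetric and intrinsically unattributable — all
incongruent tips stay flagged. The proposed donor lineage of a flagged tip
is its gene-tree sister set. This is tip-level incongruence detection, not
duplication-transfer-loss reconciliation; it matches the single
tip-level allele transfer the evidence chain is designed to catch.

# Subtypes and synteny

`trim_alignment()` removes a poorly aligned N-terminal block (default 30
columns) and an explicit column range (default 475–549, 1-based inclusive)
— the trims are always explicit parameters because they only make sense
for alignments of comparable width. `identity_matrix()` computes percent
identity over mutually ungapped columns (so fragments are not penalised
for missing termini; the denominator convention is recorded).
`cluster_subtypes()` groups variants by single-linkage at a threshold
(default 85%), chosen between reported within-variant identities (91–99%)
and between-subtype identities; single linkage matches the "variant cloud"
semantics of subtypes. Labels are `subtype.variant` (e.g. `1.1`), subtypes
numbered by decreasing size and variants by input order. Automatic
clustering approximates a partly manual, tree-guided subgrouping, and the
report says so. `neighborhood_synteny()` scores two windowed gene
neighbourhoods as the mean of the Jaccard index of their family sets and
the fraction of adjacent ordered family pairs of the first profile
preserved in the second; family labels are caller-provided.

# Synthetic data: what it emulates and what it does not

Every generator is a pure function of its arguments including an explicit
seed, and emits machine-readable truth beside the data.

* `sim_genome_with_islands()`: i.i.d. background with sharp-boundary
  i.i.d. islands — the integrated-phage positive control. Real islands
  have compositional gradients and repeats; sharp boundaries make the
  recovery tests optimistic about boundary precision.
* `sim_codon_pair()`: event-by-event continuous-time simulation on sense
  codons (single-base steps, stops disallowed), with `kappa` and `omega`
  weights; divergence is scaled so `t` is the expected substitutions per
  codon at neutrality. No indels, no codon-usage bias.
* `sim_yule_tree()`: pure-birth trees (ultrametric); expected root depth
  $\sum_{k=2}^{n} 1/(k\lambda)$ is verified.
* `sim_trait_on_tree()`: exponential-waiting-time flips along each edge.
* `apply_transfer()`: prunes the recipient and regrafts it at the midpoint
  of the donor's pendant edge — a clean allele transfer with no gene-tree
  estimation error, so transfer-detection results bound what noisy real
  gene trees can achieve.
* `sim_variant_proteins()`: subtype ancestors and variants built by
  mutating disjoint position sets, so within-subtype identities are exact
  and between-subtype identities land within a few points of target
  (ancestor divergence is set to `between/within` so the compounded
  variant-level identity hits `between`).

Passing tests on these generators show the algorithms are correct under
their stated models; they do not show robustness to alignment error,
annotation error, assembly artefacts or model misspecification beyond the
deliberate `kappa` mismatch in the codon simulator.

# The pipeline and its problem sizes

`run_pipeline()` executes composition → segmentation → dN/dS → bootstrap →
ASR → dating → transfer flagging → subtypes → synteny from one config, with
one master seed from which per-stage seeds are derived and recorded; stages
with missing inputs are skipped and stage failures are recorded without
aborting independent stages. The verdict table marks, per criterion,
whether the result is evidence *for* transfer (deviant GC beyond 2 GC
points, a breakpoint within the locus window, mean synteny below 0.7,
bootstrap p below 0.05, more than one inferred gain, any flagged tip).

The packaged validation runs at desk scale, chosen to exercise every code
path while keeping the whole suite within a few minutes on one core:
segmentation oracles on 100 sequences of 0.3–2.5 kb plus 200 runs at the
full 50 kb study geometry; 1000 oracle-checked codon pairs up to 50 codons
and 600 simulated 500-codon pairs for estimator calibration; 1000 null
bootstrap datasets; 100 64-tip trait datasets; 50 transfer and 50 subtype
scenarios. The demonstration scenario in the acceptance script simulates
congeneric core genes at ~0.15 substitutions per codon — low divergence is
what makes per-pair $\omega$ estimates noisy in real within-genus data,
and the equality-of-means test correspondingly conservative.

# Known limitations

* The halting statistic's scale fixes a detectability floor (above) —
  GC-subtle islands require a lower $t_0$, which should be recalibrated on
  a positive control rather than changed silently.
* NG86 is a counting estimator: at high divergence it saturates (flagged,
  not silently corrected), and with strong transition bias it inherits
  NG86's known biases.
* Dating assumes one global rate; it is a sanity check on timescales, not
  a substitute for relaxed-clock dating.
* Transfer flagging is tip-level; transfers of whole clades or transfers
  between adjacent lineages are outside its resolution.
* Subtype clustering reproduces a manual, tree-guided subgrouping only up
  to its threshold; the threshold is exposed and recorded.
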