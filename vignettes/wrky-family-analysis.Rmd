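---
title: "Genome-wide WRKY family analysis: models, parameters and design"
author: "wrkyfamkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide WRKY family analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

wrkyfamkit reimplements, as plain R with a small C++ likelihood core, the
chain of analyses used to characterize a WRKY transcription-factor family in
a newly sequenced plant genome: motif-based identification and
classification of family members, intron mapping, a neighbor-joining (NJ)
domain phylogeny with bootstrap, tandem and microsynteny-based segmental
duplication detection, pairwise Ka/Ks and a branch-site codon-model test of
episodic positive selection, and drought-expression classification from
RPKM matrices and qRT-PCR Ct tables. A seeded genome/alignment/expression
simulator plants all of these structures with known truth so that every
stage can be validated end to end without external downloads.

# Family identification and classification

WRKY proteins carry one or two ~60-residue DNA-binding domains, each an
invariant heptapeptide (`WRKYGQK`) followed by a zinc finger. The scanner
(`find_wrky_domains`) searches for exact heptapeptide occurrences
(configurable variants, e.g. `WRKYGKK`, may be added) and, downstream of
each, for a C2H2 finger (`C-X4/5-C-X22/23-H-X-H`) or a C2HC finger
(`C-X7-C-X23-H-X-C`). Two choices bound the search: the first cysteine must
begin within 30 residues of the heptapeptide (the domain is only ~60
residues long) and the whole domain may span at most 120 residues. When both
finger types could start at the same cysteine the more tightly constrained
C2H2 spacing wins, a fixed tie-break that makes the scanner deterministic.
This pattern scanner plays the role that a profile-HMM search plus manual
motif inspection play in practice; the manual inspection step is exactly
what the patterns encode. Classification then follows the standard scheme:
two or more complete domains define Group 1, a single C2H2 domain Group 2, a
single C2HC domain Group 3.

Subgroups 2a–2e are not defined by the motif but by tree position.
`assign_subgroup` labels a member by its nearest labeled reference in the
domain tree (patristic distance; ties broken by the smaller enclosing
clade). The same mechanism implements the re-annotation rule for
single-domain proteins whose domain clusters with the C-terminal domains of
Group 1: if the nearest reference is a Group-1 CTWD, the member is
re-labeled Group 1. Labeled references are an explicit input; in practice
they come from a reference organism, in the synthetic pipeline from the
generator's truth table. Reference members keep their own labels.

Intron mapping (`map_domain_gene_structure`) converts protein offsets to CDS
nucleotide offsets (residue i occupies nucleotides `3i..3i+2`), walks the
CDS segments in transcription order (reversed for minus-strand genes), and
reports introns that fall strictly inside the domain interval, with phase
defined as the number of upstream coding nucleotides modulo 3.

# Phylogeny

Group-1 members contribute their N- and C-terminal domains as separate rows
(suffixes `-NTWD`, `-CTWD`), so the tree is a tree of domains, which is what
makes the CTWD-ancestry signal visible. The progressive aligner builds a
guide tree from 3-mer distances (average linkage) and merges profiles by
global Needleman–Wunsch with BLOSUM62 expected-score columns and a linear
gap penalty of −8. It is intentionally minimal: domain sequences are short
and highly conserved, and for two sequences it reduces exactly to pairwise
Needleman–Wunsch (a property the tests exploit). It is not a general
replacement for a production aligner, and inputs are sorted by identifier
internally so the result is invariant to input order.

Distances use pairwise deletion: for each pair, columns gapped in either row
are dropped, and the mismatch proportion `p` is either reported as is
(p-distance) or Poisson-corrected, `d = −ln(1 − p)`. The Poisson correction
is the default stand-in for the JTT+Γ model used by ML programs; the
published analysis carried its downstream conclusions on the NJ tree, which
is the tree reimplemented here. NJ follows Saitou–Nei with the Q criterion,
deterministic lowest-index tie-breaks, and negative branch lengths clamped
to zero; on additive matrices it reproduces both topology and path lengths
exactly. Bootstrap support resamples columns with replacement, rebuilds the
NJ tree per replicate, and reports the percentage of replicates containing
each internal bipartition; one master seed derives independent per-replicate
seeds, so runs are reproducible. The published setting of 1000 replicates is
the default.

# Duplication

Tandem detection follows the published "within 10 genes" rule literally:
gene rank is position among *all* annotated genes on the chromosome
(strand-ignored), and family members whose ranks differ by at most
`max_gene_distance = 10` are single-linkage clustered; clusters of two or
more are reported.

Microsynteny detection mirrors the MicroSyn-style parameters: windows of 50
genes centered on each family gene of a pair, at least 3 homologous anchor
pairs, block E-value at most 0.01, tandem gap 2. The published source does
not state the E-value formula, so the package uses a standard collinearity
significance: the hypergeometric tail probability of observing at least the
chained number of homologous pairs between two windows, given the
genome-wide homolog density, Bonferroni-scaled by the number of family
pairs tested. The exact E-values of the published synteny table are
therefore not a comparison surface (they also depend on the original
genome); the packaged transcription of that table carries the published
values for fixture-level checks. Anchors are the longest rank-monotone
chain, in either orientation, so inversions are tolerated; homologous
neighbors within the tandem gap that match the same region are collapsed to
a single anchor, which is the role of the tandem-gap parameter. Duplication
classes follow the MCScanX scheme with precedence
segmental > tandem > proximal > dispersed, and singleton for family genes
with no family homolog. Block-level synonymous divergence is summarized as
the mean and sample SD of NG86 Ks over anchor pairs, excluding saturated
pairs (`ps >= 3/4` or `Ks > 5`); a single usable pair reports SD 0 with a
flag, none reports NA with an `undefined` flag.

# Ka/Ks and the branch-site test

The published analysis reports Ka/Ks without naming the estimator; the
package uses Nei–Gojobori (1986) — the de facto default behind Ks tables of
this kind — with equal pathway weighting and Jukes–Cantor correction.
Synonymous-site fractions count mutations to stop codons as nonsynonymous
so that `S + N = 3 × codons`; multi-position codon differences average
synonymous/nonsynonymous steps over all substitution orders, skipping
orders that pass through a stop codon (if every order does, all are used).
`p >= 3/4` flags saturation and the corrected distance is undefined.

The codon likelihood machinery uses the Goldman–Yang-style rate matrix
`q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]` over the 61
sense codons, with frequencies either equal or F3x4 (position-specific
nucleotide frequencies, floored at 1e-3 and renormalized so no codon has
zero frequency). One numerical convention matters: the generator is
normalized by the *neutral* (omega = 1) mean rate for the given kappa and
pi, so a branch length of 1 is one expected substitution per codon under
neutrality, and — unlike the mixture-weighted normalization used by some
programs — the scale does not depend on the site-class weights. That choice
lets the class weights be profiled out of the likelihood cheaply (the
per-class site likelihoods do not change when only the weights move), and
the simulator and the fitter share the same convention and the same matrix
code, so parameter-recovery tests isolate optimizer correctness from model
mismatch. Likelihoods are computed by Felsenstein pruning in C++ with
per-site rescaling; because the model is reversible, the tree is re-rooted
at the parent of the foreground branch, and the two background passes
(omega0 and 1) are shared across the four site classes, with only the
foreground-edge contribution swapped per class.

Branch-site model A has four site classes — conserved (0 < omega0 < 1),
neutral (omega1 = 1), and 2a/2b which switch to omega2 >= 1 on the
foreground branch — with weights constrained by `p2a/p2b = p0/p1`. (The
published description of class 1 as "neutral with omega1 < 1" is read as a
typo for omega1 = 1, the standard model.) The null fixes omega2 = 1. The
fit is staged: branch lengths and kappa are first estimated by maximum
likelihood under a one-ratio (M0) model (L-BFGS-B on log scale, branch
lengths included); the site-class stage then holds background branch
lengths fixed and optimizes kappa, omega0, omega2 (capped at 999, the
conventional ceiling) and the foreground branch length by multi-start
Nelder–Mead on transformed parameters, starting omega2 at 1.5 (the printed
control-file initialization) and two larger values, with class weights
profiled out at every step. Re-optimizing the foreground branch length is
essential: holding it at its M0 estimate absorbs part of the selection
signal into the branch length and costs real power. `branch_site_test`
fits the null first and seeds the alternative with the null solution, so
the nesting inequality `lnL_alt >= lnL_null` holds by construction and the
LRT statistic `2ΔlnL` is non-negative. The p-value uses chi-square with one
degree of freedom, as in the published test; the statistically conservative
50:50 mixture of a point mass at zero and chi-square-1 is available via
`null_dist = "mixture"`.

# Expression

RPKM is `1e9 * counts / (library_size * length_bp)`. Log ratios are base-2
(the figure-legend convention wins over the ambiguous "log(x/y)" in the
text), with a pseudocount of 1 RPKM by default to bound ratios at zero
counts; analyses of strictly positive matrices (such as the simulator's
zero-noise output) set the pseudocount to 0 so planted ratios are exact. A
gene is `up` if any treatment condition reaches +1 on the log2 scale
(two-fold), `down` at −1; a gene crossing both is classed `up` with a flag,
matching the mutually exclusive published partition while preserving the
information. Heatmap ordering uses stats::hclust on euclidean or
correlation distances; the euclidean metric is the pipeline default because
genes that are flat across conditions (common at low noise) have undefined
correlation. qRT-PCR relative expression is `2^-ddCt` with replicate-paired
dCt, the control sample as calibrator, and the SE of the per-replicate
relative values.

# The synthetic genome and what passing means

`family_plant_spec()` defaults encode the published family census: 103
members (17 Group 1 — one of them a single-domain CTWD-only protein
mimicking a truncated annotation — 6/10/24/15/16 in 2a–2e, 15 in Group 3;
the subgroup sizes are back-computed from the published percentages of
drought-responsive genes per subgroup), the 15 printed tandem clusters with
their sizes, groups and chromosomes, and six segmental blocks whose anchor
counts (33…8) span the printed range. Background genes (200 per chromosome,
60 per scaffold) are random proteins screened to contain no WRKY
heptapeptide. Chromosome counts follow the printed per-chromosome layout
qualitatively; the published text says 87 mapped genes while its
per-chromosome counts sum to 86 — the generator does not try to resolve
that discrepancy and simply distributes non-clustered members where space
allows.

Placement uses gene ranks. Clusters sample their member gaps uniformly in
1..max_gap; blocks reserve a focal gene with 25 background genes on each
side and plant the anchor pairs (duplicated background genes) at identical
rank offsets on the two chromosomes; all other members are placed at random
ranks at least 12 ranks from any other member (so no unplanted tandem pair
arises under the 10-gene rule) and outside every block's window-plus-anchor
span (so no pair of windows can borrow a planted anchor chain and form an
unplanted significant block). Members of a subgroup share a signature
protein, so at zero flank noise subgroup recovery through the tree is
exact; CDSs are reverse-translated with random synonymous codons, which
gives anchor pairs realistic nonzero Ks. Each family gene carries one
intron inside its (C-terminal) WRKY domain — phase 2 except subgroups
2a/2b, where it is phase 0 — echoing the published gene-structure pattern.

The generator's homology truth is the union of same-template family pairs
and the planted anchor pairs. The end-to-end test feeds the generator's
outputs through the full pipeline and requires exact equality with the
truth tables: member set, groups, subgroups (including the Group-1
override), tandem clusters, blocks with exact anchor counts, duplication
classes, and expression calls (44 up, 19 down — the published counts — at
zero noise). What this shows is that the pipeline's logic is faithful and
self-consistent at its operating parameters. What it does not show: the
generator's background genes are random sequences, not a real intergenic
landscape; flanks within a subgroup are identical rather than merely
similar; anchors are exact duplicates; expression noise is log-normal and
independent across genes. Real data will degrade each stage gracefully
(the noise parameters exist to study that), but the exact-recovery
guarantee applies to the idealized conditions only.

# Problem sizes and seeds

Simulation-based checks run at desk scale, chosen for adequate power rather
than speed alone: NJ recovery on 50 random 8-taxon additive matrices;
branch-site recovery on 20 seeded 8-taxon, 300-codon alignments with
omega2 = 5, omega0 = 0.2, kappa = 2, 20% of sites in the selected classes
and a foreground terminal branch of length 0.4 (these conditions give the
LRT high power at n = 300, which is what a correctness check needs); null
calibration on 100 seeded datasets with omega2 = 1, where the chi-square-1
test is expected to be conservative relative to its boundary-mixture null.
Every stochastic step takes an explicit seed, and one master seed derives
per-replicate seeds, so all reported numbers are reproducible bit for bit.

# Known limitations

* The progressive aligner has no iterative refinement and a linear gap
  penalty; for real proteomes a production aligner's output can be supplied
  directly via the `alignment` inputs.
* Block E-values are a hypergeometric approximation, not the original
  MicroSyn statistic; anchor counts and significance calls are comparable,
  absolute E-values are not.
* The branch-site fit holds background branch lengths at their M0 estimates
  (foreground re-optimized). This is a standard approximation; it slightly
  biases the LRT toward conservatism in our null simulations.
* ML (JTT+I+G) and parsimony trees, de novo motif discovery, read mapping,
  GO/KEGG enrichment and the branch-site REL variant of the selection test
  are out of scope.
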