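---
title: "Methods: retro-biosynthesis-guided BGC inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retro-biosynthesis-guided BGC inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrobgc)
```

# The inference model

`retrobgc` identifies the biosynthetic gene cluster behind a known
polyketide by chaining five inferences, each with an explicit, auditable
rule. The package was built around rasfonin, an α-pyrone metabolite of
*Chalara gorgonifer* assembled from an ester-linked hexaketide and
tetraketide, but every stage is parameterized and reusable.

## Retro-biosynthesis

A polyketide chain is encoded as ordered ketide units counted from the
starter, each carrying an α-methyl flag and a β-carbon state. The state
fixes which reductive domains of the iterative synthase must have acted in
that extension cycle:

| β-state  | domains       |
|----------|---------------|
| ketone   | —             |
| hydroxyl | KR            |
| enoyl    | KR, DH        |
| reduced  | KR, DH, ER    |

with MT added for an α-methyl and the condensation core {KS, AT, ACP}
always present. A chain of *u* units implies *u − 1* malonyl-CoA extensions.
Compound-level demands follow from three rules: an inter-chain ester link
demands an O-acyltransferase; release by hydrolysis or pyrone cyclization
without an intrinsic release domain demands a standalone thioesterase; each
post-assembly hydroxylation demands cytochrome P450 activity (demands are
merged per enzyme class, because a single P450 may act at several
positions — gene-level assignment is deliberately not attempted).

Construction of a compound enforces the carbon bookkeeping identity
Σ(2·units + methyls) = formula carbon count; for rasfonin,
2·(6 + 4) + 5 = 25 = C of C₂₅H₃₈O₆. The shipped rasfonin specification
fixes the unit and methyl counts from the structure (methyls at C6, C8, C10
map to hexaketide units 2–4 counted from the starter; C4′, C6′ to
tetraketide units 2–3). The β-state sequence is constrained by the
structure only up to the set of states present; the shipped choice (two
reduced, one enoyl, one hydroxyl, one ketone unit on the hexaketide;
reduced/enoyl/reduced on the tetraketide) is one consistent assignment, and
only the unit counts, methyl counts and the domain-set union — which is
invariant across consistent assignments — are treated as results. The
C8′/C10′ hydroxyls are modelled as post-assembly P450 tailoring rather than
as β-hydroxyl chain states, matching the proposed route in which they are
installed after transacylation.

Masses use a fixed table of NIST lightest-isotope masses. Ion masses
subtract `charge` electron masses (mₑ = 5.4858 × 10⁻⁴ Da); with that
correction the protonated ion C₂₅H₃₉O₆⁺ computes to m/z 435.2741. Whether a
given published "calcd" value used the electron correction is rarely
stated; this package always applies it and documents so.

## Architecture matching and co-localization

Matching is set containment over domain codes: required ⊆ architecture.
Domain *order* is not enforced — the inference argues from the presence of
enzymatic functions, and annotated domain orders of iterative fungal PKSs
vary between annotation tools. Strand is likewise ignored throughout;
cluster logic treats the locus as a linear gene string in coordinate order.

Clusters come either from an upstream assignment column (pass-through) or
from distance grouping: maximal runs with intergenic gaps ≤ 10 kb. The
10 kb default makes the usual "close proximity" notion explicit and
tunable. A candidate needs ≥ 2 genes matching the full required
architecture and, by default, a transferase gene (domain code OAT or cAT) —
the enzyme the retro-analysis demands for an ester-linked two-chain
compound. Ties in ranking break by scaffold and start coordinate for
determinism.

## Expression machinery

RPKM is count × 10⁹ / (length × library size). The expressed/silent call
thresholds log₂RPKM at 1 (RPKM ≥ 2), *boundary inclusive* (the natural
reading of "threshold of 1" on a log₂ scale; the choice at the exact
boundary affects no shipped result). Reported expression below threshold is
floored to 0. Condition means are taken over replicates *before*
thresholding, giving one call per time point, and the Cat1/Cat2/Cat3
categories (silent at both / expressed at exactly one / expressed at both)
partition any gene set by construction.

TMM normalization is implemented from its definition: reference sample by
closest 75th percentile of library-scaled counts, trimming of 30% on
log-ratios (M) and 5% on abundances (A) per side, precision-weighted mean
of the surviving M values, factors rescaled to geometric mean 1. It agrees
with the edgeR reference implementation to ~1% on test matrices (edgeR is
used only as that cross-check, never as the implementation).

The differential test is a Welch two-sample t-test on TMM-normalized
log₂-CPM with a 0.5-read pseudo-count, applying the published decision
rule: significant iff raw p < 0.05, strong iff |log₂FC| ≥ 1 (no
multiple-testing correction — deliberately, to mirror the rule it
implements). This is a documented substitute for moderated linear-model
machinery (limma-voom), whose exact per-gene outputs are a non-goal;
instead the test's statistical behaviour is validated on synthetic data:
null type-I error within [0.03, 0.07] at n = 3 vs 3 over 2000 NB genes
(measured ≈ 0.033–0.039, slightly conservative, as expected for a Welch
test at n = 3), and power ≥ 0.9 for a fourfold change at low dispersion.
With fewer than two replicates per condition the p-value is undefined (NA)
and significance is never claimed; exactly constant groups give p = 1 when
equal, 0 otherwise.

## Border calling

"Coregulation" is operationalized categorically: the producing pattern is
*silent at 24 h and expressed at 48 h*. Border walking starts from the
anchor-to-anchor interval (the matching synthase pair), requires both
anchors and all interior genes to match (a violating interior gene is a
hard "cluster interrupted" error, not a silent shrink), then extends
outward gene by gene with zero gap tolerance — a single non-matching gene
ends the span. A correlation-based pattern was considered and rejected: the
signature of interest is a binary on/off switch between growth phases, and
a categorical rule is auditable gene by gene. Requiring statistical
significance on top of the pattern is available as a flag
(`require_significant`) but off by default, since the categorical pattern
alone reproduces the reference locus. If every scaffold gene matches, the
whole scaffold is returned with a warning rather than failing.

# The synthetic-data generator

The generator emulates the features the inference relies on, not sequence
realism. `generate_genome()` lays out ~120 genes over 3 scaffolds (gene
lengths log-normal, median 1.5 kb; within-cluster gaps 0.5–5 kb;
between-gene gaps elsewhere 15–30 kb so distance grouping at 10 kb isolates
clusters), plants the 9-gene cluster in the rsf role order (HR-PKS, P450,
O-acyltransferase, MFS, thioesterase, P450, unknown, P450, HR-PKS) and adds
decoys: a *silent* two-HR-PKS cluster with transferase (the critical
negative control — right architecture, wrong expression), single-PKS
clusters and an NRPS cluster. `generate_counts()` draws negative binomial
counts with gene-shared dispersion 0.1 (an RNA-seq-typical value; Poisson
in the zero-dispersion limit) at expected count = RPKM × length × depth /
10⁹, with planted genes at mean RPKM 0.5 (24 h) and 16 (48 h) and
everything else condition-invariant. Background composition: 25%
constitutively silent (RPKM 0.4), the rest log-normal around 20 RPKM —
placed away from the RPKM = 2 threshold so that border walking is not
dominated by threshold flicker, which mirrors the clear on/off contrast of
the reference locus.

Because the simulated gene set is a small window of a transcriptome, its
column sums are *not* the library size; `generate_counts()` therefore
returns the configured read depth (default 5 × 10⁶) as the RPKM
denominator, and all pipeline calls pass it through.

What passing tests show — and do not. Recovery of the planted cluster in
20/20 seeds with exact spans shows the chain is correct and robust *under
this noise model*: NB counts, shared dispersion, clean on/off planted
signal, background kept off the threshold. Real data add ambiguous
annotations, genes hovering at the expression threshold, partial
coregulation and cluster-prediction artifacts; the fixture encodes one real
genome's facts, but passing here does not certify performance on arbitrary
genomes. Genes silent at both time points have fold-change estimates
dominated by the pseudo-count (background median |log₂FC| ≈ 0.31 including
them, ≈ 0.27 over genes with measurable expression), which is why the
no-condition-effect property is asserted on the measurable subset.

# The reference dataset

`reference_fixture()` encodes, deterministically and entirely in code, the
facts the chain must reproduce: 24 clusters holding 308 genes; 14 PKS-class
genes (ten PKSs, three PKS-NRPS hybrids, one type III PKS — the three
partial PKSs each lack at least one required domain) of which seven carry
the full architecture; two clusters with a co-localized matching pair plus
transferase (the rsf locus, and the silent CgPKS10/CgPKS11 cluster with
DNG_07106); per-gene condition means making the rsf pair 48 h-only and the
decoy pair silent; rsf-locus flanks that break the producing pattern on
both sides; and backbone expression categories totalling 14 Cat1, 3 Cat2
and 12 Cat3. One bookkeeping choice: the published backbone inventory sums
to 28 while the category counts sum to 29; the fixture carries 29 backbone
genes (six rather than five NRPSs) so that the category arithmetic — the
tested quantity — is exact. Coordinates, filler genes and the decoy
cluster's non-synthase content are synthetic.

# Numerical and interface choices

* Coordinates are 1-based inclusive (GFF3 convention). In GFF3 input the
  `domains` attribute is comma-separated (`;` being the attribute
  separator) and is normalized to the TSV dialect's `;` on read.
* Unknown domain strings map to `UNK` with a warning, never an error:
  ingestion must tolerate heterogeneous annotators.
* GC content excludes ambiguity codes from the denominator; N50 follows the
  sorted-descending cumulative convention and is tested against a
  brute-force oracle on all integer partitions up to 15.
* All randomness flows from a single integer seed per generator call;
  repeated calls with one seed are byte-identical.
* Problem sizes in the shipped tests and scripts — 120-gene genomes, 20
  seeds, 2000-gene null matrices — were chosen as the smallest sizes at
  which the measured properties (recovery rates, type-I error) are stable.

# Known limitations

Chains are annotated specifications, not parsed structures: no
SMILES/InChI, no stereochemistry. Domain annotation is consumed as input
(profile-HMM scanning is pluggable upstream work). Cluster similarity
search, probabilistic border models and moderated differential statistics
are out of scope. P450 demands are counted, not assigned to genes. The
backbone classification rule table approximates dedicated cluster-
annotation tools and is validated only on the shipped reference dataset.
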