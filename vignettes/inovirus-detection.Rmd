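---
title: "Detecting and classifying inovirus prophages with inoviscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying inovirus prophages with inoviscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inoviscope)
```

## The problem

Inoviruses are filamentous phages with circular ssDNA genomes of roughly
5–20 kb and a chronic, non-lytic infection cycle. They are close to
invisible for generic prophage detectors: their genomes carry a handful of
short genes, most without recognizable homologs, and the only gene conserved
across the whole group encodes the morphogenesis ATPase (the pI-like
protein, related to the Zot domain). What *is* characteristic of an inovirus
region is the combination of (1) short structural proteins of 30–90 amino
acids with one (sometimes two) transmembrane domains, (2) genes that are
functionally uncharacterized or inovirus-specific, and (3) genes markedly
shorter than the host background.

inoviscope operationalizes this as a two-step detector. A position-specific
search finds pI-like marker genes; a random-forest classifier then decides,
from genome-context features of windows around each marker hit, whether the
neighbourhood looks like an inovirus. Boundaries are recovered as flanking
direct-repeat attachment (att) sites, detections are dereplicated into
species by average nucleotide identity (ANI), proteins are organized into
clusters and families, genomes are classified by shared gene content on a
bipartite network, and host genomes are screened for CRISPR targeting,
Caudovirales co-infection and toxin–antitoxin systems.

## Marker search

The production path consumes parsed `hmmsearch --tblout` output
(`parse_hmmsearch_tblout()`); hit filtering applies the published cutoffs —
bit score ≥ 30 and E ≤ 0.001 for profile searches, bit score ≥ 50 for the
singleton marker (`filter_marker_hits()`).

The built-in engine (`score_profile()`) is an ungapped position-specific
scoring matrix (PSSM) scan: the bit score of a protein is the maximum over
all ungapped placements of the summed per-column log2-odds. It is *not* a
profile HMM — no insert/delete states — which keeps the engine dependency-
free, deterministic and exactly testable against an exhaustive-placement
oracle. The E-value calibration is `E = N_targets × 2^(−bit)`, the minimal
calibration consistent with a bit-score interpretation; it is overridable,
and the thresholds were designed for hmmer scores, so real analyses should
prefer the tabular path. Marker models are rebuilt iteratively from
validated hits (`refine_marker_models()`): greedy clustering at 90% identity
(global alignment, identity over the shorter sequence, longest-first
centroids — mirroring cd-hit behaviour), one representative per cluster, and
a profile rebuilt from a star alignment onto the longest representative.

The seed models shipped with the package (`inovirus_seed_model()`,
`terminase_seed_models()`) are **synthetic** consensus motifs; the original
profiles are built from reference sets that cannot be redistributed. They
exist so that the whole pipeline can run and be benchmarked offline, and the
synthetic generator plants exactly these motifs.

## Protein features

TMDs are predicted by the classic hydropathy rule: 19-residue windows of
mean Kyte–Doolittle hydropathy ≥ 1.6, merged over overlaps
(`predict_tmds()`). Signal peptides use a tripartite heuristic: a basic
residue (n-region), a hydrophobic stretch of ≥ 7 residues ending before
position 35 (h-region; A/G/S are excluded from this set so the cleavage-site
residues cannot be absorbed into it), cleavage after the first A/G/S
following the stretch (`strip_signal_peptide()`). A structural candidate is
a protein whose mature form is 30–90 aa with 1–2 TMDs
(`is_candidate_structural()`); the stricter single-TMD variant is a
parameter. TMDs are counted after signal-peptide removal. These heuristics
replace license-restricted external predictors; parsers for real predictor
output can be slotted in wherever span counts are consumed, because the
pipeline contract only needs counts and spans.

## Window classification

`extract_features()` summarizes a candidate gene window with 10 features:
gene density (genes/kb), median gene length (nt), fraction of genes < 300
nt, fraction of unannotated genes, number of structural candidates, fraction
of genes hitting known inovirus protein clusters (caller-supplied flags),
mean intergenic gap (bp, floored at 0), strand coherence (modal-strand
fraction), presence of a replication-initiation annotation, and window size
in genes / 30. The known-PC feature depends on a reference PC database; in
the self-contained synthetic benchmark no such database exists, so the flags
default to all-`FALSE` and the classifier works on the remaining nine
features.

The classifier is a random forest with 2000 trees and otherwise default
parameters (`train_classifier()`); the window score is the fraction of trees
voting "inovirus". A logistic-regression baseline sits behind the same
interface. `cross_validate()` implements tenfold cross-validation with
pooled out-of-fold scores and reports the operating point used for model
selection — the best true-positive rate at a false-positive rate below 1%.

`scan_windows()` enumerates every gene interval containing the pI gene with
at most 30 genes in total (a per-side variant is a parameter), scores all of
them in one batch, and keeps the argmax if it exceeds 0.9. Ties go to the
smallest interval, then the leftmost — explicit rules, because the argmax is
compared verbatim against an exhaustive enumeration oracle in the tests.

## Boundaries: att sites

`find_att_sites()` reports all maximal exact direct repeats ≥ 10 bp with one
copy in each flank (default search distance 20 kb, truncated at contig
ends), annotated by context: `tRNA` when a copy overlaps a tRNA gene (the
canonical integration signature), `non_integrase` when the enclosed region
contains an integrase that neither copy sits inside, else `plain`. Results
are ordered by repeat length, then proximity to the span.

The scored window can over-reach the provirus by a gene or two; an att copy
swallowed into the span is invisible to a flank search, and a random ≥ 10 bp
repeat would then fake the boundary. `detect_inoviruses()` therefore refines
boundaries over *nested* windows — the scored window shrunk by up to two
genes per side, never past the pI gene — and keeps the best repeat across
all of them (longest, then closest). Integration duplicates the repeat at
the true boundary, so when the true att is visible in any nested window it
wins on length. Completeness classes follow from topology and context:
`circular` (whole circular contig), `canonical_att`, `noncanonical_att`,
`fuzzy` (no identifiable ends); a window with ≥ 2 pI genes is flagged tandem
(multiple adjacent integrations). Circularity is taken from topology
metadata, or inferred from an exact terminal repeat ≥ 20 bp when absent.

## Species, protein families, taxonomy

`compute_ani()` estimates ANI from exact shared 15-mers grouped by alignment
diagonal; each diagonal contributes an ungapped block from its first to its
last anchor, block ends are extended through mismatches with an X-drop rule
(match +1 / mismatch −1, stop 5 below the running maximum), and identity is
counted base-by-base over the union of blocks. The alignment fraction (AF)
is the covered fraction of the shorter sequence. The X-drop extension
matters at the margins: without it, a 5%-divergent pair loses a few
unanchored terminal bases and fails a strict AF ≈ 1 test on a technicality.

`cluster_species()` applies the species rule — 95% ANI on 100% AF (0.999
tolerance for edge artifacts) — with tiered greedy seeding: circular/
canonical-att isolate detections seed first, then noncanonical, then other
isolate detections, then metagenome-derived sequences; within a tier, seeds
are taken longest-first with ties broken by identifier. Tandem predictions
are pooled and clustered separately so multi-provirus regions cannot bridge
species. Host genomes dereplicate at 95% identity / 95% AF
(`dereplicate_hosts()`) before prevalence is computed. Accumulation curves
average first-occurrence counts over 100 random orderings.

Protein clusters (PCs) come from Infomap communities of the all-vs-all
similarity graph, with edges kept at E ≤ 0.001 and bit ≥ 50, or bit ≥ 30
when both proteins are ≤ 70 aa (`build_similarity_graph()`,
`cluster_pcs()`). The built-in aligner is a BLOSUM62 Smith–Waterman with a
Karlin–Altschul bit conversion (λ = 0.267, K = 0.041); external tabular
output is the production path. PCs merge into iPFs when profile–profile
hits reach ≥ 90% probability with ≥ 50% coverage, or ≥ 99% probability with
≥ 20% coverage and hit length ≥ 100; iPFs are connected components, so the
result is order-invariant. Profile–profile comparison itself is consumed,
not reimplemented. Partial sequences are dropped below half the 10%-trimmed
mean length. Toxin–antitoxin screening reports genes within one intervening
gene of a toxin-annotated gene; unannotated iPFs seen next to the same toxin
iPF in ≥ 2 genomes become putative antitoxins.

The gene-content taxonomy links genomes to PCs (≥ 2 members; tandem genomes
excluded) in a bipartite network and applies two-level Infomap: groups
(proposed families) and nested subgroups (proposed subfamilies). The summary
network connects a subgroup to a PC present in > 50% of its genomes, or
> 25% for the largest subgroup, which is computed, not hard-coded. The
backend contract is planted-block recovery, not algorithm identity.

## Host interactions

Spacer matching is an exhaustive Hamming scan over both strands keeping
placements with ≤ 1 mismatch — for ≤ 60-nt queries this is strictly more
sensitive than the seeded heuristic it replaces, and indels are deliberately
not allowed because the filter is defined on mismatch counts. Host-derived
spacers additionally require a cas-labelled gene within ±10 kb of the spacer
locus (configurable label prefixes: cas, csn, csy, cmr, cst);
metagenome-derived spacers without coordinates pass flagged. Self-targeting
means the spacer's host genome carries the matched provirus. Caudovirales
co-infection is flagged by terminase marker hits at bit ≥ 30, with distinct
prophages counted as hits ≥ 5 kb apart.

## The synthetic benchmark

`generate_fixture()` defines the study conditions: 50 host genomes of ~40
lognormal genes (median 900 nt), 25 carrying a planted inovirus cassette
(6–12 genes, median ~300 nt, ≥ 2 structural candidates, one pI gene with the
seed motif carrying 0–3 substitutions, 70% with an RCR-labelled replication
gene, 30% with an atypical N-terminal pI TMD), and 25 carrying hard-negative
cassettes — plasmid-like and Caudovirales-like elements that share the
"many short genes" property and, in 70% of cases, a diverged ATPase decoy
that still clears the marker filter, so precision is tested against the
classifier, not just the marker gate. Integrated proviruses are flanked by
14-bp att repeats (half with a tRNA overlapping the left copy); 20% of
plantings are circular contigs. Substitutions are applied at an *exact*
count (`round(rate × length)` positions, each forced to a different base) so
nominal divergence is realized exactly and accuracy bands are not blurred by
binomial noise. The generator asserts that every planted att is the
top-ranked recoverable repeat pair in its flanks and that every planted
structural protein passes `is_candidate_structural()`; infeasible geometry
is an error, not a silent degradation.

`training_features()` builds a labelled set from truth (planted windows
positive; confounder windows and random host windows negative), and
`score_against_truth()` computes prediction-level recall and precision at
≥ 50% reciprocal overlap, with att-coordinate offsets as boundary-error
statistics (an empty prediction set reports precision 1 with a zero-call
flag). The end-to-end benchmark in the test suite trains on a 30-genome
fixture and evaluates on the 50-genome fixture, asserting recall ≥ 0.90 and
precision ≥ 0.95; `scripts/acceptance.R` recomputes the same quantities from
scratch.

What the generator does *not* emulate: real nucleotide composition and codon
structure, gene calling errors, assembly fragmentation, real protein
homology (proteins are composition-biased random strings), and hmmer score
statistics. Passing the benchmark therefore demonstrates that the machinery
— marker gating, window maximization, boundary delineation, clustering —
is correct under controlled conditions; it does not certify recall on real
genomes, which depends on marker profiles and annotation quality.

## Numerical choices and limitations

* Coordinates are 0-based half-open internally, 1-based inclusive in all
  files; the conversion is an exact bijection.
* All stochastic stages take explicit seeds and are bit-reproducible;
  Infomap and the random forest draw from R's RNG.
* `detect_fixture()` searches att sites within 2.5 kb of the window rather
  than the 20-kb default: the synthetic genomes are compact (~40 kb), att
  copies are planted immediately at cassette boundaries, and between 20-kb
  flanks a coincidental ≥ 14 bp repeat pair is expected more than once per
  genome, which would make boundary assignment dominated by chance rather
  than by the method under test. Real analyses on sparse large genomes keep
  the 20-kb default.
* Test and benchmark problem sizes (50-genome benchmark, 100 window
  landscapes, 200 2-kb flank pairs, 1000 spacer cases, 3000–5000-bp ANI
  pairs) were chosen as the smallest sizes at which the properties under
  test are statistically meaningful.
* Greedy ANI clustering depends on seed order; the tier/length/identifier
  ordering makes it deterministic, but it is not a globally optimal
  clustering — the same trade-off the incremental protocol it mirrors makes.
* The ungapped PSSM engine undercalls diverged markers relative to a profile
  HMM with indel states; sensitivity-critical work should use the hmmsearch
  tabular path.
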