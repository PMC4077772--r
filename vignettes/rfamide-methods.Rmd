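---
title: "Methods: RFamide precursor mining, mass verification, phylogeny and synteny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RFamide precursor mining, mass verification, phylogeny and synteny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rfamide)
```

This vignette is the package's own account of the science it implements:
the models and heuristics, the parameters that matter, the synthetic-data
generators that stand in for wet-lab inputs, and the places where the design
was genuinely open.

## The biological problem

RFamide neuropeptides (C-terminal Arg-Phe-NH~2~) are released from larger
prepropeptides by the secretory pathway: an N-terminal signal peptide is
removed at the endoplasmic reticulum, prohormone convertases cut at
basic-residue motifs, carboxypeptidases trim the exposed basic residues, and
peptidylglycine alpha-amidating monooxygenase converts a C-terminal glycine
into the amide group that these peptides require for receptor binding. Two
vertebrate subfamilies share this architecture: LPXRFamide peptides
(gonadotropin-inhibitory hormone and its orthologs; suffix
Leu-Pro-Xaa-Arg-Phe-NH~2~, Xaa = Leu or Gln) and PQRFamide peptides
(neuropeptide FF group; suffix Pro-Gln-Arg-Phe-NH~2~). Deciding whether a
cDNA encodes such peptides, and verifying the prediction against mass
spectra, phylogeny and gene neighborhoods, is the pipeline implemented
here.

## Precursor annotation

**ORF scan.** Input is oriented cDNA, so only the three forward frames are
scanned. An ORF runs from an ATG to the first in-frame stop; ORFs reaching
the sequence end without a stop are returned flagged `incomplete` rather
than dropped, since truncated cDNAs are common. Codons containing the
ambiguity base N are untranslatable; a candidate ORF containing one is
excluded — a conservative, loud failure preferred over guessing. Nested
ORFs (internal ATGs sharing a stop) are all reported, longest first;
`annotate_precursor()` uses the longest. Coordinates are 0-based half-open
internally; printed reports are 1-based inclusive.

**Signal peptide.** No machine-learned predictor is used (deliberately: the
heuristic is transparent and has two interpretable knobs). The predictor
searches the first 40 residues for the most hydrophobic window of 7
residues (arithmetic mean of Kyte–Doolittle indices; ties resolved
N-terminally). If that core reaches a mean hydropathy of 1.6, candidate cut
positions from the core end to 8 residues past it are tested against the
(−3,−1) rule — small residues {A,G,S,C,T,Q} at −1 and small/aliphatic
{A,V,S,C,T,G,I,L} at −3 relative to the cut — and the qualifying cut
closest to the core is returned. Window 7 and threshold 1.6 are standard
hydropathy-plot practice for transmembrane-like stretches and both are
arguments, as are the 40-residue search limit and the 8-residue offset.
Proteins shorter than 15 residues cannot carry a plausible signal and
return `NA`.

**Convertase cleavage.** Three motif classes are scanned, all reported with
the 0-based index of the first residue after the cut:

* dibasic pairs KR, RR, KK, RK — cut after the pair;
* tetrabasic [K/R]-X-X-R — cut after the final R, **except** when the first
  X is proline or a bulky aromatic (F/W/Y). This exception matters: the
  PQRF suffix itself contains R-P-Q-R, which a literal [K/R]XXR scan would
  cut, destroying the very peptides the motif defines. Proline and bulky
  aromatics adjacent to the scissile bond are poor convertase substrates,
  so the restricted rule keeps genuine flanks such as KVSR and RSGR while
  leaving ...RPQRF and ...RFGR-type contexts intact;
* a single K or R immediately preceded by glycine — cut after the basic
  residue. The glycine is the amide donor, so these sites are
  amidation-competent.

Overlapping matches are all recorded (deduplicated by position and kind);
peptide extraction uses the union of cut points, i.e. the most parsimonious
maximal fragmentation. This sidesteps having to decide whether a motif like
RSGR is the C-flank of one peptide or the N-flank of the next.

**Excision and amidation.** Candidate peptides are the intervals between
consecutive cut points (the signal boundary and the protein end close the
outer intervals). Leading and trailing basic residues — the carboxypeptidase
substrates — are stripped; if the segment then ends in a glycine whose
successor in the precursor is basic, the glycine is trimmed and the peptide
marked amidated. Segments outside 3–50 residues are discarded: the bounds
are not mechanistic but span known mature RFamide peptides while
suppressing spacer fragments. A protein with no cut site at all yields no
peptides — an uncut protein is not a processed peptide. Family labels are a
pure function of the amide flag and the C-terminal residues, tested in
priority order LPXRFa > PQRFa > RFa.

## Mass-spectrometric verification

Monoisotopic residue masses are used (the printed masses practitioners
compare against are monoisotopic); average masses are available behind the
`monoisotopic` flag. The constants are water 18.010565 Da, proton 1.007276
Da, and the amidation delta −0.984016 Da (OH → NH~2~). Fragment ladders
contain only singly charged b and y ions, which is what post-source decay
on a MALDI instrument produces; a/x/c/z series, multiple charges and
residue modifications other than the C-terminal amide are out of scope.
The ladder satisfies the complementarity identity
b~i~ + y~n−i~ = [M+H]⁺ + proton, which the tests assert for random
peptides.

Peak assignment is nearest-neighbor within an absolute tolerance, default
**0.5 Da**: MALDI-TOF calibration errors on peptides of this size are
typically a few tenths of a dalton, so 0.5 Da accepts them with margin
while rejecting wrong monoisotopic assignments >1 Da away. The tolerance is
symmetric and flat — no recalibration model is fitted. A single observed
peak may explain several theoretical ions only when those ions are
themselves closer than the tolerance (then flagged ambiguous). Candidate
ranking is deterministic: precursor hit, then fragment coverage, then
absolute precursor error, then the sequence string.

## Phylogenetics

Distances are p (proportion of differing residues) or Poisson-corrected
−ln(1−p); gap handling is pairwise deletion by default (per pair, drop
columns where either row is gapped) or complete deletion. p = 1 under the
Poisson model is an explicit error naming the offending pair rather than an
infinity. The default model is Poisson with pairwise deletion — the common
choice for protein distance trees when no substitution matrix is invoked —
and both are arguments.

Neighbor joining follows the Saitou–Nei Q-criterion with the standard
branch-length and distance-update formulas. Two numerical choices are made
explicit: Q-ties are broken by the lexicographically smallest pair of
cluster keys (a cluster's key is its smallest leaf label), making the tree
independent of input row order; and negative branch-length estimates — a
known NJ artifact — are clamped to zero with a warning, never silently.
The test suite checks the implementation against an independent NJ
implementation (ape) and against a brute-force least-squares topology
search over all topologies for up to six taxa.

Bootstrap supports resample alignment columns with replacement and count,
per internal edge of the full-data tree, the percentage of replicate trees
containing the same leaf bipartition. Supports attach to bipartitions, not
node order, so relabeling cannot corrupt them, and rooting (placed at the
midpoint of the outgroup's pendant edge) leaves them unchanged. Replicates
whose distance matrix is undefined (a resample can push p to 1) are
redrawn; redraws are counted and capped at 10 times the replicate count,
beyond which the error advises switching to the p model or longer
alignments. Each replicate draws from its own derived substream of the
user's seed, so runs are reproducible and replicate r is independent of how
many redraws earlier replicates needed.

## Synteny

Neighborhoods are windows of up to k genes (default 10) on each side of a
focal gene, in gene order on the same scaffold — gene order, not base-pair
distance, because assemblies of very different contiguity are being
compared. Shared content is counted with set semantics (a gene with several
orthologs counts once, avoiding inflation by tandem duplicates), summarized
as a Jaccard index, and order conservation as the longest common
subsequence of ortholog-projected gene orders, maximized over the second
neighborhood read forward and reversed (inversions are conservation too).
Strand is ignored for membership and enters only through that reversal.

Because "the neighborhood looks conserved" is otherwise unfalsifiable, an
empirical null is provided: the B-side neighborhood is replaced by random
gene sets of the same size drawn from table B, and the add-one empirical
p-value (1 + #{null ≥ observed})/(1 + n~perm~) is reported.

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of seed and parameters, and each obeys a
zero-noise round-trip contract against its consuming module — those
contracts are what the test suite enforces.

* `generate_precursor_cdna()` builds a 14-residue leader (M + 12 L + A)
  that the signal predictor provably cuts after position 14, then peptides
  with a chosen family suffix, each preceded by a dibasic site and followed
  by the amide-donor glycine plus a flank of the requested kind, with short
  non-basic spacers; the protein is reverse-translated with uniformly
  random synonymous codons (no codon-usage bias — none of the consumers is
  sensitive to it) and wrapped in pyrimidine-only UTRs so no spurious
  upstream ATG can outrank the designed ORF. Peptide bodies avoid K, R, G
  and L so that no unintended cleavage or family motif can arise; real
  precursors are under no such constraint, which is exactly why the
  accession-tier behavior on natural sequences is a separate question from
  these round trips.
* `simulate_maldi()` perturbs the precursor and full b/y ladder by Gaussian
  m/z error (default sd 0.1 Da, a realistic MALDI-TOF spread), adds uniform
  noise peaks and log-normal intensities. No isotope envelopes, detector
  saturation or retention-time structure.
* `evolve_alignment()` draws a uniform root sequence and, along each branch
  of length t, substitutes each site with probability 1 − exp(−t), the
  replacement uniform over the other 19 residues — the generative dual of
  the Poisson-corrected distance, chosen so that parameter recovery is a
  clean statistical test. No indels, no rate heterogeneity, no empirical
  substitution matrix; real protein alignments violate all three.
* `generate_synteny_tables()` plants round(f·2k) ortholog pairs of the
  focal neighborhoods in conserved order; the remaining genes carry no
  orthology. Real ortholog maps are noisier and many-to-many.

Passing round trips therefore demonstrate internal consistency of each
module with its generator's assumptions — not performance on natural data,
where signal peptides are heterogeneous, convertase usage is
context-dependent, and alignments are gapped and rate-variable.

## Problem sizes and defaults used by the test suite

The suite runs the statistical checks at sizes chosen to make the expected
outcome near-certain under the stated models while keeping a default run
fast: 8-taxon trees with 400–500 columns for topology recovery (100
seeds), 200–300 bootstrap replicates for support calibration, 1,000 random
peptides for the mass-oracle comparison, and 99–199 permutations for the
synteny null. The workflow defaults (`n_reps` 100, `n_perm` 999, tolerance
0.5 Da, k = 10, `min_codons` 50) are production-oriented; a bootstrap meant
for publication should use 1,000 replicates.

## Known limitations

* The signal predictor is a two-parameter heuristic; sequences with
  atypical leaders (very short cores, charged cleavage regions) will be
  missed, and no eukaryote-wide benchmark is claimed.
* The KXXR exception list ({P,F,W,Y} at the first X) is a pragmatic
  blocker, not a convertase specificity model; a glycine-preceded basic
  residue close to a peptide's own N-terminus can still be called as a
  cut, so unusual natural peptides starting G-R/G-K may be truncated.
* Masses assume the 20 standard residues and a single modification (the
  C-terminal amide); oxidation, pyroglutamate and isotope fine structure
  are out of scope.
* NJ is a distance method; very unequal rates can defeat it regardless of
  implementation quality, and only the Poisson/p distances are offered.
* The synteny permutation null randomizes gene identity, not genomic
  position structure; clustered gene families make it anticonservative.
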