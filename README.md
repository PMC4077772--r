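# rfamide

Discovery and verification of RFamide neuropeptide precursors, in R.

Secreted neuropeptides of the RFamide family — which in chordates includes
gonadotropin-inhibitory hormone (GnIH/LPXRFamide) and neuropeptide FF
(NPFF/PQRFamide) — are not encoded as such: they are excised from a larger
prepropeptide. Identifying them from a cDNA therefore takes a chain of
predictions, each of which this package implements and tests:

1. **Precursor annotation** — forward-strand ORF scan; signal peptide
   prediction from a Kyte–Doolittle hydropathy core plus the von Heijne
   (−3,−1) rule; prohormone convertase cleavage sites (dibasic pairs
   KR/RR/KK/RK, tetrabasic \[K/R\]-X-X-R motifs, and single basic residues
   carrying an amide-donor glycine); excision and C-terminal amidation of
   mature peptides; family classification by C-terminal motif
   (Pro-Gln-Arg-Phe-NH₂ = PQRFa; Leu-Pro-Xaa-Arg-Phe-NH₂, Xaa = L/Q =
   LPXRFa).
2. **Mass-spectrometric verification** — monoisotopic peptide masses with
   the amidation delta (−0.984016 Da), singly charged [M+H]⁺ = M + 1.007276,
   complete b/y fragment-ion ladders (bᵢ = Σ residues 1..i + proton,
   yᵢ = Σ last i residues + H₂O + amide Δ + proton), and tolerance-based
   assignment against MALDI-TOF / post-source-decay peak lists.
3. **Phylogenetics** — p or Poisson-corrected (−ln(1−p)) amino-acid
   distances with pairwise or complete gap deletion, a deterministic
   Saitou–Nei neighbor-joining implementation, column-resampling bootstrap
   with bipartition supports, and outgroup rooting.
4. **Synteny** — gene-order neighborhoods around focal loci, shared-ortholog
   counts, Jaccard similarity, inversion-tolerant collinear runs, and an
   empirical permutation null.
5. **Synthetic data** — ground-truthed generators for precursor cDNAs,
   MALDI-like spectra, alignments evolved along a tree, and gene tables with
   planted shared synteny, so the whole pipeline is testable with no
   downloads.
6. **Workflow** — `run_discovery()` chains the stages from one flat YAML
   config into per-stage files plus a reproducible JSON report.

## Worked example

Generate a ground-truthed precursor, annotate it, and verify one peptide
against its simulated spectrum:

```r
library(rfamide)

tr  <- generate_precursor_cdna(seed = 3, n_peptides = 3)
ann <- annotate_precursor(tr$cdna, min_codons = 20)
ann
#> Precursor annotation: precursor
#>   ORF: nt 9-194 (frame 2), 62 aa
#>   signal peptide: 14 aa (cut after residue 14)
#>   10 cleavage site(s), 3 mature peptide(s)
#>     YSHYTPTPQRF  aa 17-27  PQRFa (amidated)
#>     DNTNWWTPQRF  aa 33-43  PQRFa (amidated)
#>     TQEPQRF  aa 50-56  PQRFa (amidated)
```

The three predicted peptides are amidated PQRFa-family peptides with their
1-based spans in the precursor. Their theoretical singly protonated masses:

```r
round(singly_protonated_mz(
  peptide_monoisotopic_mass(ann$peptides$sequence, amidated = TRUE)), 2)
#> [1] 1395.68 1463.68  904.46
```

Simulate a MALDI spectrum of the second peptide (0.1 Da Gaussian error, 25
noise peaks) and ask which candidate explains it:

```r
sim  <- simulate_maldi(ann$peptides[2, c("sequence", "amidated")],
                       sd = 0.1, n_noise = 25, seed = 4)
identify_peptides(sim$peaks, ann$peptides[, c("sequence", "amidated")])
#>      sequence amidated precursor_mz precursor_matched precursor_error  coverage
#> 1 DNTNWWTPQRF     TRUE    1463.6815              TRUE      0.02167549 1.0000000
#> 2     TQEPQRF     TRUE     904.4635             FALSE              NA 0.4166667
#> 3 YSHYTPTPQRF     TRUE    1395.6804             FALSE              NA 0.2500000
```

The true source peptide ranks first: its precursor ion is found within the
0.5 Da tolerance and every theoretical b/y ion is assigned (coverage 1.0).
A command-line front end over the same functions is in
`inst/scripts/rfamide-cli.R` (subcommands `mine`, `ms-match`, `phylo`,
`synteny`, `simulate`, `run`).

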