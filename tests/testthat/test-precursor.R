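test_that("find_orfs locates start-to-stop reading frames in all frames", {
  orfs <- find_orfs("ATGAAATAG", min_codons = 2)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$protein, "MK")
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 6L)
  expect_false(orfs$incomplete)

  orfs <- find_orfs("CCATGGCTTGA", min_codons = 2)
  expect_equal(orfs$protein, "MA")
  expect_equal(orfs$start, 2L)
  expect_equal(orfs$end, 8L)
  expect_equal(orfs$frame, 2L)

  # no stop codon: reported, flagged incomplete
  orfs <- find_orfs("ATGAAAAAA", min_codons = 2)
  expect_equal(orfs$protein, "MKK")
  expect_true(orfs$incomplete)

  # nested ATGs share a stop; sorted longest-first
  orfs <- find_orfs("ATGCCCATGAAATAG", min_codons = 2)
  expect_equal(orfs$protein, c("MPMK", "MK"))
  expect_true(all(diff(nchar(orfs$protein)) <= 0))
})

test_that("find_orfs excludes codons containing N and rejects bad input", {
  expect_equal(nrow(find_orfs("ATGAANAAATAG", min_codons = 2)), 0L)
  # N after the stop does not affect the ORF
  expect_equal(find_orfs("ATGAAATAGNNN", min_codons = 2)$protein, "MK")
  expect_error(find_orfs("", min_codons = 2), "non-empty")
  expect_error(find_orfs("ATGXXX", min_codons = 1), "unknown residue")
})

test_that("hydropathy profile averages Kyte-Doolittle indices over windows", {
  expect_equal(hydropathy_profile("IIIIIIIII", 9)$hydropathy, 4.5)
  expect_equal(hydropathy_profile("RRRRRRRRR", 9)$hydropathy, -4.5)
  expect_equal(hydropathy_profile("AIAIAIAIA", 9)$hydropathy,
               (1.8 * 5 + 4.5 * 4) / 9)
  prof <- hydropathy_profile("AAAAGGGG", 3)
  expect_equal(nrow(prof), 6L)
  expect_equal(prof$center, 2:7)
  expect_error(hydropathy_profile("AAZAA", 3), "position 3")
  expect_error(hydropathy_profile("AAA", 5), "window")
})

test_that("signal peptide predictor agrees with an exhaustive scan oracle", {
  cases <- c(
    "MKWLLLLLLLLLLLLLASAADEFQRSTW",
    paste0("M", strrep("L", 12), "AKVSRWDEAWRPQRFGRSGR"),
    paste0("M", strrep("I", 15), "GSADEFGHKNPQ"),
    "MDDDDDDDDDDDDDDDDDDD",           # no hydrophobic core
    "MKWLLLL"                          # too short
  )
  for (p in cases) {
    expect_identical(predict_signal_peptide(p), oracle_signal_scan(p),
                     info = p)
  }
  # predicted cuts satisfy the (-3,-1) rule and sit past a hydrophobic core
  for (p in cases) {
    cut <- predict_signal_peptide(p)
    if (is.na(cut)) next
    ch <- strsplit(p, "")[[1]]
    expect_true(ch[cut] %in% c("A", "G", "S", "C", "T", "Q"))
    expect_true(ch[cut - 2] %in% c("A", "V", "S", "C", "T", "G", "I", "L"))
  }
  expect_identical(predict_signal_peptide("MDDDDDDDDDDDDDDDDDDD"),
                   NA_integer_)
})

test_that("cleavage site scan reports dibasic, KXXR and glycine-basic cuts", {
  s <- find_cleavage_sites("AAKVSRAA")
  expect_equal(nrow(s), 1L)
  expect_equal(s$motif, "KVSR")
  expect_equal(s$kind, "KXXR")
  expect_equal(s$position, 6L)

  expect_equal(nrow(find_cleavage_sites("AAAAAA")), 0L)

  # RFGR decomposes as amide-donor G + monobasic R, not as a KXXR cut
  s <- find_cleavage_sites("PQRFGRSS")
  expect_equal(nrow(s), 1L)
  expect_equal(s$kind, "glycine_basic")
  expect_equal(s$motif, "GR")
  expect_equal(s$position, 6L)

  # RSGR stays a KXXR site
  s <- find_cleavage_sites("AARSGRAA")
  expect_true(any(s$kind == "KXXR" & s$motif == "RSGR" & s$position == 6L))

  # proline at P3 blocks the KXXR cut inside a PQRF-motif peptide
  s <- find_cleavage_sites("AWRPQRFA")
  expect_false(any(s$kind == "KXXR"))

  # overlapping dibasic pairs are all reported
  s <- find_cleavage_sites("AKRRA")
  expect_equal(s$position[s$kind == "dibasic"], c(3L, 4L))
})

test_that("mature peptides are excised, trimmed and amidated", {
  p <- paste0("M", strrep("L", 12), "A", "KVSR", "WDEAWRPQRF", "GRSGR")
  sites <- find_cleavage_sites(p)
  peps <- extract_mature_peptides(p, predict_signal_peptide(p), sites)
  expect_equal(nrow(peps), 1L)
  expect_equal(peps$sequence, "WDEAWRPQRF")
  expect_true(peps$amidated)
  expect_equal(peps$family, "PQRFa")
  # the donor glycine sits right after the excised span
  expect_equal(substr(p, peps$end + 1L, peps$end + 1L), "G")

  # an uncut protein yields no peptides
  p2 <- paste0("M", strrep("L", 12), "AWDEAWAAA")
  expect_equal(nrow(extract_mature_peptides(p2, 14L,
                                            find_cleavage_sites(p2))), 0L)

  expect_error(extract_mature_peptides("MAAA", 10L,
                                       find_cleavage_sites("MAAA")),
               "signal_end")
})

test_that("family classification is a suffix + amidation rule", {
  expect_equal(classify_rfamide_family("WDEAWRPQRF", TRUE), "PQRFa")
  expect_equal(classify_rfamide_family("SGTGLSATLPQRF", TRUE), "LPXRFa")
  expect_equal(classify_rfamide_family("SGTGLSATLPLRF", TRUE), "LPXRFa")
  expect_equal(classify_rfamide_family("WDEAWRPQRF", FALSE), "other")
  expect_equal(classify_rfamide_family("AAAMRF", TRUE), "RFa")
  expect_equal(classify_rfamide_family("AAAMRA", TRUE), "other")

  # property: depends only on the C-terminal 5 residues and the flag
  set.seed(42)
  for (i in 1:50) {
    pep <- random_peptide(sample(5:20, 1))
    tail5 <- substr(pep, nchar(pep) - 4, nchar(pep))
    prefix <- random_peptide(sample(0:10, 1))
    expect_equal(classify_rfamide_family(pep, TRUE),
                 classify_rfamide_family(paste0(prefix, tail5), TRUE))
  }
})

test_that("annotate_precursor composes the chain deterministically", {
  ann <- annotate_precursor("ATGAAATAG", min_codons = 2)
  expect_equal(ann$orf$protein, "MK")
  expect_true(is.na(ann$signal_end))
  expect_equal(nrow(ann$peptides), 0L)

  ann <- annotate_precursor("CCCCCC", min_codons = 2)
  expect_null(ann$orf)
  expect_s3_class(ann, "precursor_annotation")

  tr <- generate_precursor_cdna(11, n_peptides = 2)
  a1 <- annotate_precursor(tr$cdna, min_codons = 20)
  a2 <- annotate_precursor(tr$cdna, min_codons = 20)
  expect_identical(a1$peptides, a2$peptides)
})

test_that("excised peptides never contain an internal dibasic pair", {
  for (seed in 1:20) {
    tr <- generate_precursor_cdna(seed, n_peptides = sample(1:4, 1))
    ann <- annotate_precursor(tr$cdna, min_codons = 20)
    for (sq in ann$peptides$sequence) {
      expect_false(grepl("[KR][KR]", sq), info = sq)
    }
  }
})

test_that("peptide tables print 1-based inclusive coordinates", {
  tr <- generate_precursor_cdna(3, n_peptides = 2)
  ann <- annotate_precursor(tr$cdna, min_codons = 20)
  tab <- peptide_table(ann)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$start_1based, ann$peptides$start + 1L)
  expect_equal(tab$end_1based, ann$peptides$end)
  # the 1-based span re-extracts the peptide
  expect_equal(substr(ann$orf$protein, tab$start_1based[1], tab$end_1based[1]),
               tab$peptide_seq[1])
})

test_that("the conserved C-terminal hexapeptide of the three mature peptides is WRPQRF", {
  peps <- c("WDEAWRPQRF", "GDHTKDGWRPQRF", "GRDQGWRPQRF")
  suf <- longest_common_csuffix(peps)
  expect_equal(suf, "WRPQRF")
  expect_equal(nchar(suf), 6L)
  expect_equal(longest_common_csuffix(c("AB", "CD")), "")
  expect_equal(longest_common_csuffix("ABC"), "ABC")
})
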