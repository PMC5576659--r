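test_that("pad_sequence adds (L-1)/2 dummy residues per side", {
  expect_equal(pad_sequence("ACDE", 7), "XXXACDEXXX")
  expect_equal(pad_sequence("M", 5), "XXMXX")
  expect_equal(pad_sequence("ACDE", 1), "ACDE")
  expect_error(pad_sequence("ACDE", 6), "odd")
  expect_error(pad_sequence("ACDE", -3), "odd")
  expect_error(pad_sequence("", 5), "non-empty")
})

test_that("protein_chain validates its invariants", {
  expect_error(protein_chain("c", "ACDE", binding_positions = 5), "outside")
  expect_error(protein_chain("c", "ACDE", binding_positions = 0), "outside")
  expect_error(protein_chain("c", "ACDE", ss = "HEC"), "length mismatch")
  expect_error(protein_chain("c", "ACDE", ss = "HEQC"), "letters")
  expect_error(protein_chain("c", "ACDE", rsa = c(0.1, 0.2, -0.3, 0.4)), ">= 0")
  # non-standard residues normalize to X
  expect_equal(protein_chain("c", "acBZuo")$sequence, "ACXXXX")
})

test_that("extract_segments yields one labeled segment per residue", {
  ch <- protein_chain("c", "ACDEF", binding_positions = 2)
  segs <- extract_segments(ch, 7)
  expect_equal(nrow(segs), 5)
  expect_equal(sum(segs$label == "positive"), 1)
  expect_equal(segs$label[2], "positive")
  segs5 <- extract_segments(ch, 5)
  expect_equal(segs5$residues[1], "XXACD")
  expect_equal(segs5$residues[5], "DEFXX")
  expect_equal(nchar(segs5$residues), rep(5, 5))
})

test_that("segment counts match direct enumeration on a generated set", {
  ds <- generate_dataset(simulation_spec(n_chains = 8, seed = 4))
  for (L in c(5, 9)) {
    segs <- extract_segments_all(ds$chains, L)
    expect_equal(nrow(segs), sum(vapply(ds$chains, function(c) nchar(c$sequence), 0)))
    expect_equal(
      sum(segs$label == "positive"),
      sum(vapply(ds$chains, function(c) length(c$binding_positions), 0L))
    )
    # labels sit exactly at the binding positions
    for (ch in ds$chains[1:2]) {
      lab <- segs$label[segs$chain_id == ch$id]
      expect_equal(which(lab == "positive"), ch$binding_positions)
    }
  }
})

test_that("channel strings are parallel and padded", {
  segs <- extract_segments(tiny_chain(), 7)
  expect_true(all(c("hydro6", "charge3", "ss3", "sa4") %in% names(segs)))
  expect_true(all(nchar(segs$ss3) == 7))
  # first segment: 3 pad positions on every channel
  expect_equal(substr(segs$hydro6[1], 1, 3), "XXX")
  expect_equal(substr(segs$ss3[1], 1, 3), "XXX")
  expect_equal(substr(segs$sa4[1], 1, 3), "XXX")
})

test_that("hydropathy recoding follows the six-class grouping", {
  expect_equal(recode_hydro("R"), "1")
  expect_equal(recode_hydro("C"), "6")
  expect_equal(recode_hydro("X"), "X")
  expect_equal(recode_hydro("RDENQKH"), "1111111")
  expect_equal(recode_hydro("LIVAMF"), "222222")
  expect_equal(recode_hydro("STYW"), "3333")
  expect_equal(recode_hydro("PG"), "45")
  expect_error(recode_hydro("RB"), "invalid residue")
})

test_that("charge recoding follows the three-class grouping", {
  expect_equal(recode_charge("K"), "p")
  expect_equal(recode_charge("D"), "n")
  expect_equal(recode_charge("KRP"), "ppp")
  expect_equal(recode_charge("DE"), "nn")
  expect_equal(recode_charge("NQHLIVAMFSTYWCG"), strrep("u", 15))
  expect_error(recode_charge("U"), "invalid residue")
})

test_that("solvent accessibility binning matches the four regions", {
  expect_equal(recode_sa(0.3), "J")
  expect_equal(recode_sa(0.5), "M")
  expect_equal(recode_sa(c(0, 0.95)), "IN") # clamp decisions at both ends
  expect_equal(recode_sa(c(0.2, 0.45, 0.6, 0.85)), "IJMN") # closed right ends
  expect_equal(recode_sa(c(0.21, 0.46, 0.61)), "JMN")
  expect_equal(recode_sa(NA), "X")
  expect_error(recode_sa(-0.1), "negative")
})

test_that("segments round-trip through the segment TSV", {
  segs <- extract_segments(tiny_chain(), 7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segments(segs, path)
  back <- read_segments(path)
  expect_equal(back$residues, segs$residues)
  expect_equal(back$label, segs$label)
  expect_equal(back$center, segs$center)
  expect_equal(back$sa4, segs$sa4)
  expect_equal(attr(back, "L"), 7)
})

test_that("chains round-trip through FASTA + sites + annotations", {
  dir <- withr::local_tempdir()
  chains <- list(ch1 = tiny_chain("ch1"), ch2 = tiny_chain("ch2"))
  write_chains(chains,
    fasta = file.path(dir, "c.fasta"), sites = file.path(dir, "s.tsv"),
    annotations = file.path(dir, "a.tsv"), ion = "ZN"
  )
  back <- read_chains(file.path(dir, "c.fasta"),
    sites = file.path(dir, "s.tsv"),
    annotations = file.path(dir, "a.tsv")
  )
  expect_equal(names(back), c("ch1", "ch2"))
  expect_equal(back$ch1$sequence, chains$ch1$sequence)
  expect_equal(back$ch1$binding_positions, chains$ch1$binding_positions)
  expect_equal(back$ch1$ss, chains$ch1$ss)
  expect_equal(back$ch1$rsa, chains$ch1$rsa, tolerance = 1e-4)
  # ion filter
  none <- read_chains(file.path(dir, "c.fasta"),
    sites = file.path(dir, "s.tsv"), ion = "CA"
  )
  expect_equal(none$ch1$binding_positions, integer())
})

test_that("per-ion default windows are as screened", {
  expect_equal(ion_window("zn"), 7)
  expect_equal(ion_window("CU"), 13)
  expect_equal(ion_window("ca"), 9)
  expect_equal(ion_window("k"), 11)
  expect_error(ion_window("pb"), "unknown ion")
})
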