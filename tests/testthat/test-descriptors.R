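test_that("aac matches hand counts and sums to 1", {
  v <- aac("AAAA")
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  v <- aac(paste(aa_alphabet(), collapse = ""))
  expect_true(all(v == 0.05))
  v <- aac("ACCG")
  expect_equal(unname(v[c("A", "C", "G")]), c(0.25, 0.5, 0.25))
  expect_error(aac(""), "non-empty")
})

test_that("dpc counts overlapping pairs and errors below length 2", {
  expect_equal(unname(dpc("AA")["AA"]), 1)
  v <- dpc("ACAC")
  expect_equal(unname(v["AC"]), 2 / 3)
  expect_equal(unname(v["CA"]), 1 / 3)
  expect_equal(sum(v), 1)
  expect_error(dpc("A"), "length >= 2")
})

test_that("composition sums hold for random sequences", {
  for (seed in 1:5) {
    s <- random_protein(60, seed)
    expect_equal(sum(aac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(dpc(s)), 1, tolerance = 1e-9)
  }
})

test_that("ctd composition, transition and distribution behave as specified", {
  v <- ctd("AAAAAAAA")
  # homopolymer: no class changes
  expect_true(all(v[grep("\\.Tr", names(v))] == 0))
  # sequence entirely in hydrophobicity class 1 (polar: R K E D Q N)
  v <- ctd("RKEDQNRK")
  expect_equal(unname(v["hydrophobicity.Group1"]), 1)
  expect_equal(unname(v["hydrophobicity.Group2"]), 0)
  expect_equal(unname(v["hydrophobicity.Group3"]), 0)
  # 8-mer whose first hydrophobicity-class-2 residue sits at position 5
  v <- ctd("RKEDGRKE")
  expect_equal(unname(v["prop1.G2.residue0"]), 5 / 8 * 100)
})

test_that("ctd distribution values are ordered percentages within [0, 100]", {
  for (seed in 1:10) {
    s <- random_protein(sample(10:80, 1), seed)
    v <- ctd(s)
    d <- v[grep("residue", names(v))]
    expect_true(all(d >= 0 & d <= 100))
    for (p in 1:7) for (g in 1:3) {
      q <- v[paste0("prop", p, ".G", g,
                    ".residue", c(0, 25, 50, 75, 100))]
      if (any(q > 0)) expect_true(all(diff(q) >= 0))
    }
  }
})

test_that("conjoint triad matches exhaustive window enumeration", {
  v <- conjoint_triad("ACD")
  expect_equal(sum(v == 1), 1)  # single triad -> single unit value
  expect_equal(conjoint_triad("AVAVA"), oracle_ctriad("AVAVA"))
  for (seed in 1:5)
    expect_equal(conjoint_triad(random_protein(30, seed)),
                 oracle_ctriad(random_protein(30, seed)))
  expect_error(conjoint_triad("AC"), "length >= 3")
})

test_that("autocorrelation dimensions, constant-profile values and guards", {
  s <- random_protein(50, 1)
  for (m in c("moreau-broto", "moran", "geary"))
    expect_length(autocorrelation(s, m), 240)
  # homopolymer: standardized property is constant c along the sequence,
  # so Moreau-Broto equals c^2 at every lag and Geary is 0 by the guard
  tab <- aaindex_default_table()
  cval <- (tab[["CIDH920105"]] - mean(tab[["CIDH920105"]])) /
    sqrt(mean((tab[["CIDH920105"]] - mean(tab[["CIDH920105"]]))^2))
  mb <- autocorrelation(strrep("W", 40), "moreau-broto",
                        indices = "CIDH920105", nlag = 5)
  expect_equal(unname(mb), rep(unname(cval["W"])^2, 5), tolerance = 1e-12)
  ge <- autocorrelation(strrep("W", 40), "geary", indices = "CIDH920105",
                        nlag = 5)
  expect_true(all(ge == 0))
  expect_error(autocorrelation(random_protein(20, 1), "moran", nlag = 30),
               "exceed nlag")
})

test_that("qso/socn couple sequence order through distance matrices", {
  s <- random_protein(50, 2)
  v <- qso_socn(s)
  expect_length(v, 160)
  # coupling numbers match a direct double-loop summation
  G <- grantham_matrix()
  for (d in c(1, 3, 7))
    expect_equal(unname(v[paste0("Grantham.lag", d)]), oracle_socn(s, d, G))
  S <- scdist_matrix()
  expect_equal(unname(v["scdist.lag2"]), oracle_socn(s, 2, S))
  # w = 0 reduces the first 20 QSO values to the composition
  v0 <- qso_socn(s, w = 0)
  expect_equal(unname(v0[paste0("scdist.Xr.", aa_alphabet())]),
               unname(aac(s)))
  expect_error(qso_socn(random_protein(25, 1), nlag = 30), "exceed nlag")
})

test_that("paac/apaac dimensions and limiting cases", {
  s <- random_protein(60, 3)
  expect_length(paac(s), 50)
  expect_length(apaac(s), 80)
  expect_length(paac_apaac(s), 130)
  # lambda = 0: pure composition
  expect_equal(unname(paac(s, lambda = 0)), unname(aac(s)))
  # homopolymer: all property differences vanish, so PAAC order terms are 0
  v <- paac(strrep("K", 40), lambda = 5)
  expect_true(all(v[grep("Xc2", names(v))] == 0))
  expect_error(paac(random_protein(20, 1), lambda = 30), "exceed lambda")
})

test_that("aaindex profile is the per-sequence mean of each index", {
  toy <- list(TOY1 = stats::setNames(c(1, 2, 6, rep(0, 17)),
                                     c("A", "C", "D", setdiff(aa_alphabet(),
                                                              c("A","C","D")))))
  expect_equal(unname(aaindex_profile("ACD", toy)), 3)
  expect_equal(unname(aaindex_profile("D", toy)), 6)
  const <- list(K1 = stats::setNames(rep(4.2, 20), aa_alphabet()))
  expect_equal(unname(aaindex_profile(random_protein(30, 1), const)), 4.2)
})

test_that("read_aaindex parses the flat-file format and drops incomplete indices", {
  tab <- read_aaindex(test_path("fixtures", "toy_aaindex_synthetic.txt"))
  expect_named(tab, c("SYNX000001", "SYNX000002"))
  # value block order is A R N D C Q E G H I / L K M F P S T W Y V
  expect_equal(unname(tab$SYNX000001[c("A", "R", "V")]), c(1, 2, 20))
  expect_true(all(tab$SYNX000002 == 2.5))
  expect_error(read_aaindex(withr::local_tempfile(fileext = ".txt")),
               "file not found")
})

test_that("amino-acid group counts partition the sequence", {
  v <- aa_groups_length("DDEE")
  expect_equal(unname(v["negatively.charged"]), 4)
  expect_equal(unname(v["length"]), 4)
  expect_equal(sum(v[setdiff(names(v), c("negatively.charged", "length"))]), 0)
  v <- aa_groups_length("GPGP")
  expect_equal(unname(v["conformational"]), 4)
  for (seed in 1:5) {
    s <- random_protein(50, seed)
    v <- aa_groups_length(s)
    expect_equal(sum(v[names(v) != "length"]), unname(v["length"]))
  }
})

test_that("featurize assembles families with unique stable names and propagates ids on error", {
  ds <- make_dataset(c(random_protein(45, 1), random_protein(45, 1)),
                     ids = c("a", "b"))
  fm <- featurize(ds)
  expect_equal(ncol(fm), 1947)  # 1920 + PSSM 20 + groups/length 7
  expect_false(anyDuplicated(colnames(fm)) > 0)
  expect_equal(unname(fm["a", ]), unname(fm["b", ]))  # identical sequences
  # per-family error carries the sequence id
  short <- make_dataset(c(random_protein(45, 2), random_protein(20, 3)),
                        ids = c("ok", "tooshort"))
  expect_error(featurize(short), "tooshort")
  # feature matrix TSV round-trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(colnames(back), colnames(fm))
  attr(fm, "config") <- NULL
  expect_equal(unname(back), unname(fm), tolerance = 1e-9)
})
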