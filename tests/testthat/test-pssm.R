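test_that("parse_pssm extracts the 20-column score block from the ASCII layout", {
  p <- parse_pssm(test_path("fixtures", "toy.pssm"), id = "toy")
  expect_s3_class(p, "pssm_matrix")
  expect_equal(dim(p$scores), c(5L, 20L))
  # frozen fixture values: row i holds ((i-1) + j - 1) mod 13 - 6 for column j
  expected <- t(vapply(1:5, function(i) ((i - 1) + 0:19) %% 13 - 6,
                       numeric(20)))
  expect_equal(unname(p$scores), expected)
  expect_equal(rownames(p$scores), c("M", "K", "C", "W", "A"))
  # header/footer lines are ignored: row count equals residue count
  expect_equal(nrow(p$scores), 5L)
  expect_error(parse_pssm(""), "empty PSSM")
  expect_error(parse_pssm("no scores here at all"), "empty|no PSSM")
})

test_that("format/parse round-trip preserves all scores", {
  p <- parse_pssm(test_path("fixtures", "toy.pssm"))
  back <- parse_pssm(format_pssm(p))
  expect_equal(back$scores, p$scores)
})

test_that("gap_pool is the column mean with alphabetical PSSM names", {
  one <- matrix(1:20, nrow = 1, dimnames = list(NULL, PSIBLAST_ORD))
  p1 <- toxscreen:::new_pssm("x", one)
  expect_equal(unname(gap_pool(p1)[paste0("PSSM_", PSIBLAST_ORD)]),
               as.numeric(1:20))
  const <- matrix(3.5, nrow = 4, ncol = 20,
                  dimnames = list(NULL, PSIBLAST_ORD))
  expect_true(all(gap_pool(toxscreen:::new_pssm("x", const)) == 3.5))
  two <- rbind(rep(1, 20), rep(3, 20))
  colnames(two) <- PSIBLAST_ORD
  expect_true(all(gap_pool(toxscreen:::new_pssm("x", two)) == 2))
})

test_that("gap_pool is linear and bounded by column extremes", {
  set.seed(5)
  m <- matrix(rnorm(8 * 20), 8, dimnames = list(NULL, PSIBLAST_ORD))
  p <- toxscreen:::new_pssm("x", m)
  p3 <- toxscreen:::new_pssm("x", 3 * m)
  expect_equal(gap_pool(p3), 3 * gap_pool(p), tolerance = 1e-12)
  g <- gap_pool(p)[paste0("PSSM_", PSIBLAST_ORD)]
  expect_true(all(g >= apply(m, 2, min) - 1e-12))
  expect_true(all(g <= apply(m, 2, max) + 1e-12))
  expect_equal(unname(gap_pool(p)), unname(oracle_gap(m)[aa_alphabet()]))
})

test_that("fallback provider builds deterministic substitution-matrix profiles", {
  prov <- pssm_provider_fallback()
  p <- prov("id1", "MKVW")
  expect_equal(nrow(p$scores), 4L)
  expect_equal(p$provenance, "fallback-blosum62")
  expect_identical(p$scores, prov("id1", "MKVW")$scores)
  # directory provider errors for unknown ids
  dprov <- pssm_provider_dir(withr::local_tempdir())
  expect_error(dprov("nope", "MKVW"), "no precomputed PSSM")
})

test_that("run_psiblast reports a missing executable without partial output", {
  expect_error(run_psiblast("MKVLAC", "db", exe = "psiblast-does-not-exist"),
               "not found")
})

test_that("run_psiblast produces an L x 20 matrix on a toy database", {
  db_seqs <- make_dataset(c(
    "MKVLACDEFGHIKLMNPQRSTVWYACDEFGHIKLMNPQRST",
    "MKVLACDEFGHLKLMNPQRSTVWYACDEFGH",
    "GGGGACDEFGHIKAMNPQRSTVWY"), ids = c("db1", "db2", "db3"))
  dir <- withr::local_tempdir()
  write_fasta(db_seqs, file.path(dir, "db.fasta"))
  status <- system2("makeblastdb",
                    c("-in", file.path(dir, "db.fasta"), "-dbtype", "prot",
                      "-out", file.path(dir, "toydb")),
                    stdout = FALSE, stderr = FALSE)
  expect_equal(status, 0L)
  q <- db_seqs$sequence[1]
  p <- run_psiblast(q, file.path(dir, "toydb"), id = "q1")
  expect_equal(nrow(p$scores), nchar(q))
  expect_equal(ncol(p$scores), 20L)
  # parsing the same invocation twice is identical
  p2 <- run_psiblast(q, file.path(dir, "toydb"), id = "q1")
  expect_identical(p$scores, p2$scores)
})
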