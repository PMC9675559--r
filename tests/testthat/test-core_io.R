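writeTempTsv <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

test_that("expression TSV reader validates shape, ids and cells", {
  f <- writeTempTsv(c("gene\ts1\ts2", "GAPDH\t1.5\t2.0", "ACTB\t0.1\t-0.3",
                      "TP53\t3\t4"))
  m <- readExpressionTsv(f)
  expect_s4_class(m, "ExpressionMatrix")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(geneIds(m), c("GAPDH", "ACTB", "TP53"))
  expect_equal(exprValues(m)["ACTB", "s2"], -0.3)

  dup <- writeTempTsv(c("gene\ts1", "GAPDH\t1", "GAPDH\t2"))
  expect_error(readExpressionTsv(dup), "duplicate gene id: GAPDH")
  dupS <- writeTempTsv(c("gene\ts1\ts1", "GAPDH\t1\t2"))
  expect_error(readExpressionTsv(dupS), "duplicate sample id: s1")
  hole <- writeTempTsv(c("gene\ts1\ts2", "GAPDH\t1\t", "ACTB\t2\t3"))
  expect_error(readExpressionTsv(hole), "row 1 .*GAPDH.* column s2")
  txt <- writeTempTsv(c("gene\ts1", "GAPDH\tlow"))
  expect_error(readExpressionTsv(txt), "non-numeric")
})

test_that("expression matrices round-trip through TSV", {
  m <- toyExpr(7, 4, seed = 42)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionTsv(m, f)
  back <- readExpressionTsv(f)
  expect_equal(geneIds(back), geneIds(m))
  expect_equal(sampleIds(back), sampleIds(m))
  expect_equal(exprValues(back), exprValues(m), tolerance = 1e-12)
})

test_that("GMT reader parses sets, dedups genes, rejects malformed lines", {
  f <- writeTempTsv(c("SETA\tdesc\tG1\tG2", "SETB\tdesc\tG3"))
  col <- readGmt(f)
  expect_equal(signatureNames(col), c("SETA", "SETB"))
  expect_equal(geneMembers(col[["SETA"]]), c("G1", "G2"))

  dup <- writeTempTsv("SETB\tdesc\tG1\tG1")
  expect_warning(colDup <- readGmt(dup), "duplicate genes")
  expect_equal(geneMembers(colDup[["SETB"]]), "G1")

  expect_error(readGmt(writeTempTsv("SETC\tdesc")), "zero genes")
  expect_error(readGmt(writeTempTsv(c("SETA\td\tG1", "SETA\td\tG2"))),
               "duplicate gene-set name")
})

test_that("gene-set collections round-trip through GMT", {
  col <- SignatureCollection(list(GeneSet("A", c("X", "Y", "Z")),
                                  GeneSet("B", c("P", "Q"))))
  f <- withr::local_tempfile(fileext = ".gmt")
  writeGmt(col, f)
  back <- readGmt(f)
  expect_equal(signatureNames(back), signatureNames(col))
  expect_equal(lapply(geneSets(back), geneMembers),
               lapply(geneSets(col), geneMembers))
})

test_that("clinical table reader enforces the survival invariants", {
  ok <- writeTempTsv(c("sample_id\tegfr_status\tos_time\tos_event",
                       sprintf("P%d\t%s\t%d\t%d", 1:5,
                               c("WT", "Mutant", "wild-type", "wt", "MUT"),
                               10 * (1:5), c(1, 0, 1, 0, 1))))
  tbl <- readClinicalTable(ok)
  expect_equal(nrow(tbl), 5L)
  expect_equal(tbl$egfr_status,
               c("wild-type", "mutant", "wild-type", "wild-type", "mutant"))

  bad <- function(row) writeTempTsv(
    c("sample_id\tegfr_status\tos_time\tos_event", row))
  expect_error(readClinicalTable(bad("P1\tWT\t10\t2")), "os_event")
  expect_error(readClinicalTable(bad("P1\tWT\t-1\t1")), "os_time")
  noCol <- writeTempTsv(c("sample_id\tos_time\tos_event", "P1\t1\t1"))
  expect_error(readClinicalTable(noCol), "egfr_status")
})

test_that("HR/CI conversion matches the closed form and round-trips", {
  conv <- hrCiToLogHR(2.0, 1.0, 4.0)
  expect_equal(conv$log_hr, log(2), tolerance = 1e-12)
  expect_equal(conv$se, log(4) / (2 * 1.959964), tolerance = 1e-9)
  expect_equal(conv$se, 0.35364, tolerance = 1e-4)

  expect_error(hrCiToLogHR(1.0, 1.0, 1.0), "se must be > 0")
  expect_error(hrCiToLogHR(-0.5, 0.2, 0.9), "positive")
  expect_error(hrCiToLogHR(1.0, 2.0, 0.5), "ci_lower exceeds")
  expect_warning(hrCiToLogHR(5.0, 1.0, 2.0), "outside")

  set.seed(9)
  for (i in 1:20) {
    lo <- runif(1, 0.1, 1); hi <- lo * runif(1, 1.1, 5)
    hr <- sqrt(lo * hi)
    cv <- hrCiToLogHR(hr, lo, hi)
    back <- logHRToHrCi(cv$log_hr, cv$se)
    expect_equal(back$ci_lower, lo, tolerance = 1e-6)
    expect_equal(back$ci_upper, hi, tolerance = 1e-6)
  }
})

test_that("meta table reader accepts both column conventions", {
  f <- writeTempTsv(c("study_id,hr,ci_lower,ci_upper,n",
                      "A,2.0,1.0,4.0,100", "B,0.8,0.5,1.28,200"))
  tbl <- readMetaTable(f)
  expect_equal(tbl$log_hr[1], log(2), tolerance = 1e-12)
  expect_equal(tbl$n, c(100L, 200L))

  g <- writeTempTsv(c("study_id,log_hr,se,subgroup", "A,0.2,0.1,ici"))
  tbl2 <- readMetaTable(g)
  expect_equal(tbl2$se, 0.1)
  expect_equal(tbl2$subgroup, "ici")
  expect_error(readMetaTable(writeTempTsv(c("study_id,log_hr,se", "A,0.2,0"))),
               "se must be > 0")
})
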