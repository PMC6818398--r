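writeTempTable <- function(df, names = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  if (!is.null(names)) colnames(df) <- names
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

nativeRows <- function() {
  data.frame(
    cdr3_nt = c("TGTGCCAGC", "TGTTTTCAT", "TGTAAAGAA"),
    cdr3_aa = c("CAS", "CFH", "CKE"),
    v_segment = c("TRBV20-1", "TRBV11-2", "TRBV6-5"),
    j_segment = c("TRBJ2-1", "TRBJ1-1", "TRBJ2-7"),
    count = c(5L, 3L, 2L), stringsAsFactors = FALSE)
}

test_that("a valid native table is read with correct totals", {
  rep <- readClonotypeTable(writeTempTable(nativeRows()))
  expect_s4_class(rep, "Repertoire")
  expect_equal(totalReads(rep), 10)
  expect_equal(nUnique(rep), 3)
  expect_equal(keyLevel(rep), "nt+VJ")
  expect_equal(repMetadata(rep)$rejectedRows, 0)
})

test_that("vdjtools and airr dialects map onto the same repertoire", {
  df <- nativeRows()
  native <- readClonotypeTable(writeTempTable(df))
  vdj <- readClonotypeTable(
    writeTempTable(cbind(df, freq = df$count / 10)[
      , c("count", "freq", "cdr3_nt", "cdr3_aa", "v_segment", "j_segment")],
      names = c("count", "freq", "cdr3nt", "cdr3aa", "v", "j")),
    dialect = "vdjtools")
  airr <- readClonotypeTable(
    writeTempTable(df[, c("count", "cdr3_nt", "cdr3_aa", "v_segment",
                          "j_segment")],
      names = c("duplicate_count", "junction", "junction_aa", "v_call",
                "j_call")),
    dialect = "airr")
  expect_setequal(clonotypeKeys(vdj), clonotypeKeys(native))
  expect_setequal(clonotypeKeys(airr), clonotypeKeys(native))
  expect_equal(totalReads(vdj), 10)
  expect_equal(totalReads(airr), 10)
})

test_that("non-productive and malformed rows are dropped with a tally", {
  df <- rbind(nativeRows(),
              data.frame(cdr3_nt = "TGTGCCAGCTAAGAAGAAGAAGAAGCC",
                         cdr3_aa = "CAS*EEEEA", v_segment = "TRBV2",
                         j_segment = "TRBJ1-2", count = 7L),
              data.frame(cdr3_nt = "TGTGC", cdr3_aa = "CA",
                         v_segment = "TRBV2", j_segment = "TRBJ1-2",
                         count = 4L),
              data.frame(cdr3_nt = "TGTGCA", cdr3_aa = "CA",
                         v_segment = "TRBV2", j_segment = "TRBJ1-2",
                         count = 0L))
  rep <- readClonotypeTable(writeTempTable(df))
  expect_equal(nUnique(rep), 3)
  expect_equal(repMetadata(rep)$rejectedRows, 3)
  expect_equal(repMetadata(rep)$rejectedRows +
                 nUnique(rep), repMetadata(rep)$inputRows)
})

test_that("duplicate keys are merged by summing counts", {
  df <- nativeRows()[c(1, 1, 2), ]
  df$count <- c(2L, 3L, 4L)
  rep <- readClonotypeTable(writeTempTable(df))
  expect_equal(nUnique(rep), 2)
  expect_equal(clonotypes(rep)$count[clonotypes(rep)$cdr3_nt ==
                                       "TGTGCCAGC"], 5)
})

test_that("allele suffixes are stripped from segment names", {
  df <- nativeRows()
  df$v_segment <- paste0(df$v_segment, "*01")
  rep <- readClonotypeTable(writeTempTable(df))
  expect_true(all(!grepl("\\*", clonotypes(rep)$v_segment)))
})

test_that("format and degenerate-input errors are informative", {
  df <- nativeRows()
  expect_error(readClonotypeTable(writeTempTable(df[, -5])), "count")
  allBad <- df
  allBad$cdr3_aa <- "C*S"
  expect_error(readClonotypeTable(writeTempTable(allBad)),
               "empty repertoire")
})

test_that("write then read round-trips keys, counts and totals", {
  set.seed(11)
  for (n in c(1, 7, 200)) {
    rep <- randomRep(n, sampleId = "rt")
    path <- withr::local_tempfile(fileext = ".tsv")
    writeClonotypeTable(rep, path)
    back <- readClonotypeTable(path, sampleId = "rt")
    ordA <- order(clonotypeKeys(rep))
    ordB <- order(clonotypeKeys(back))
    expect_equal(clonotypeKeys(back)[ordB], clonotypeKeys(rep)[ordA])
    expect_equal(clonotypes(back)$count[ordB], clonotypes(rep)$count[ordA])
    expect_equal(totalReads(back), totalReads(rep))
  }
})

test_that("aggregation merges nt clones into aa clones and preserves reads", {
  df <- data.frame(
    cdr3_nt = c("TGTGCCAGC", "TGCGCCAGC"),  # synonymous first codon
    cdr3_aa = c("CAS", "CAS"),
    v_segment = c("TRBV2", "TRBV2"), j_segment = c("TRBJ1-1", "TRBJ1-1"),
    count = c(4, 6))
  rep <- Repertoire(df, keyLevel = "nt+VJ")
  expect_equal(nUnique(rep), 2)
  aa <- aggregateRepertoire(rep, "aa")
  expect_equal(nUnique(aa), 1)
  expect_equal(clonotypes(aa)$count, 10)
  expect_equal(totalReads(aa), 10)
})

test_that("aggregation to the same level is the identity", {
  rep <- makeRep(c(5, 3, 2))
  expect_identical(aggregateRepertoire(rep, "nt+VJ"), rep)
  aa <- aggregateRepertoire(rep, "aa")
  expect_equal(clonotypes(aggregateRepertoire(aa, "aa")), clonotypes(aa))
})

test_that("refinement requests fail and singletons survive all levels", {
  rep <- makeRep(10)
  aa <- aggregateRepertoire(rep, "aa")
  expect_error(aggregateRepertoire(aa, "nt"), "invalid aggregation")
  for (lvl in c("nt+VJ", "nt", "aa"))
    expect_equal(nUnique(aggregateRepertoire(rep, lvl)), 1)
})

test_that("aggregation is idempotent and total-preserving on random input", {
  set.seed(42)
  for (i in 1:20) {
    rep <- randomRep(sample(2:80, 1))
    for (lvl in c("nt", "aa")) {
      agg <- aggregateRepertoire(rep, lvl)
      expect_equal(totalReads(agg), totalReads(rep))
      expect_lte(nUnique(agg), nUnique(rep))
      expect_equal(clonotypes(aggregateRepertoire(agg, lvl)),
                   clonotypes(agg))
      expect_equal(sum(cloneFrequencies(agg)), 1, tolerance = 1e-9)
    }
  }
})

test_that("the 15-patient clinical table reads and validates", {
  md <- readMetadata(system.file("extdata", "lung15_clinical.tsv",
                                 package = "TCRcompare"))
  expect_equal(nrow(md), 15)
  expect_equal(sum(md$age <= 60), 6)
  expect_equal(md$differentiation[md$patient_id == "P6"], "unknown")
  expect_true(all(md$tnm_stage %in% c("I", "II", "III")))
})

test_that("metadata validation rejects bad input with row context", {
  md <- read.delim(system.file("extdata", "lung15_clinical.tsv",
                               package = "TCRcompare"))
  bad <- md; bad$age[3] <- "old"
  expect_error(readMetadata(writeTempTable(bad)), "age in row 3")
  bad <- md; bad$tnm_stage[2] <- "IV"
  expect_error(readMetadata(writeTempTable(bad)), "TNM stage 'IV' in row 2")
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("patient_id\tage\tsex\tpath_type\tdifferentiation\ttnm_stage",
             empty)
  expect_error(readMetadata(empty), "empty")
})
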