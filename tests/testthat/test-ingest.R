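test_that("deposit tables read, flag missing metrics, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "pdb_id,deposition_date,resolution,molecule_class,structural_genomics,journal_raw,issn,clashscore,rama_outliers,rota_outliers,rsrz_outliers,r_free,r_work",
    "1ABC,1999-03-04,1.8,protein,false,J Test,1234-5678,5.1,0.4,2.2,3.3,21.5,18.2",
    "2DEF,2005,2.4,protein,true,,,7.0,1.1,3.0,,24.0,20.0",
    "3GHI,2010-11-30,3.1,nucleic_acid,false,Other J,,9.9,,,6.5,27.0,23.0"),
    path)

  d <- read_deposit_table(path)
  expect_equal(nrow(d), 3)
  expect_equal(sum(is.na(d$rsrz_outliers)), 1)
  expect_identical(d$pdb_id[is.na(d$rsrz_outliers)], "2DEF")
  # year-only date canonicalized to Jan 1
  expect_equal(d$deposition_date[2], as.Date("2005-01-01"))
  expect_equal(d$deposition_year, c(1999L, 2005L, 2010L))
  expect_equal(nrow(attr(d, "rejected")), 0)

  out <- withr::local_tempfile(fileext = ".csv")
  write_deposit_table(d, out)
  d2 <- read_deposit_table(out)
  for (col in setdiff(names(d), "journal")) {
    expect_identical(d2[[col]], d[[col]], label = col)
  }
})

test_that("header-only file yields an empty collection without error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("pdb_id,deposition_date,resolution,molecule_class", path)
  d <- read_deposit_table(path)
  expect_equal(nrow(d), 0)
})

test_that("mandatory columns are enforced and bad rows rejected with reasons", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pdb_id,resolution,molecule_class", "1ABC,2.0,protein"), path)
  expect_error(read_deposit_table(path), "mandatory")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "pdb_id,deposition_date,resolution,molecule_class,r_free",
    "1ABC,2001-01-01,2.0,protein,22",
    "2BAD,2002-01-01,-1.0,protein,22",     # non-positive resolution
    "3BAD,2003-01-01,2.0,protein,150",     # r_free out of range
    "1ABC,2004-01-01,2.0,protein,22",      # duplicate accession
    "4OKK,2005-01-01,2.5,nucleic_acid,25"),
    path2)
  d <- read_deposit_table(path2)
  expect_equal(nrow(d), 2)
  rej <- attr(d, "rejected")
  expect_equal(nrow(rej), 3)
  expect_true(any(grepl("resolution", rej$reason)))
  expect_true(any(grepl("r_free", rej$reason)))
  expect_true(any(grepl("duplicate", rej$reason)))
  # nucleic-acid rama/rota forced inapplicable
  expect_true(is.na(d$rama_outliers[d$molecule_class == "nucleic_acid"]))
})

test_that("schema mapping renames file columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,dep_date,res,type", "1ABC,2001-05-06,2.0,protein"), path)
  d <- read_deposit_table(path, schema = list(pdb_id = "id",
                                              deposition_date = "dep_date",
                                              resolution = "res",
                                              molecule_class = "type"))
  expect_equal(d$pdb_id, "1ABC")
  expect_equal(d$resolution, 2.0)
})

test_that("journal cleaning collapses spelling variants and is idempotent", {
  d <- make_deposits(4, journal_raw = c("FEBS J.", "Febs J", "FEBS J", NA))
  c1 <- clean_journal_names(d)
  expect_equal(unique(c1$journal[1:3]), "FEBS J")
  expect_equal(c1$journal[4], TO_BE_PUBLISHED)
  c2 <- clean_journal_names(c1)
  expect_identical(c2$journal, c1$journal)
})

test_that("alias map resolves raw variants to canonical names", {
  d <- make_deposits(5, journal_raw = c("Nature Str. Biol.", "Nat Struct Biol",
                                        "NSMB", "J. Mol. Biol.", "JMB"))
  map_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("raw,canonical,issn",
               "Nature Str Biol,Nat Struct Mol Biol,1545-9993",
               "NSMB,Nat Struct Mol Biol,1545-9993",
               "Nat Struct Biol,Nat Struct Mol Biol,1545-9993",
               "J Mol Biol,J Mol Biol,0022-2836",
               "JMB,J Mol Biol,0022-2836"), map_path)
  map <- read_alias_map(map_path)
  cleaned <- clean_journal_names(d, map)
  expect_equal(sort(unique(cleaned$journal)), c("J Mol Biol", "Nat Struct Mol Biol"))
  expect_equal(cleaned$issn[1], "1545-9993")
  # idempotent through the alias map as well
  expect_identical(clean_journal_names(cleaned, map)$journal, cleaned$journal)
})

test_that("molecule classification is total on non-empty compositions", {
  expect_equal(classify_molecule("protein"), "protein")
  expect_equal(classify_molecule(c("protein", "DNA")), "complex")
  expect_equal(classify_molecule("RNA"), "nucleic_acid")
  expect_error(classify_molecule(character(0)), "no polymer")
  # complexes are scored with proteins
  expect_equal(pdbqual:::molecule_group("complex"), "protein")
})

test_that("bibliometrics reader validates rows and uniqueness", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("issn,year,ipp,snip",
               "1234-5678,1999,2.5,1.1",
               "1234-5678,2000,2.7,1.2",
               "9999-0000,1999,4.0,1.5",
               "9999-0000,2000,4.2,1.6"), path)
  b <- read_bibliometrics(path)
  expect_equal(nrow(b), 4)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("issn,year,ipp,snip",
               "1234-5678,1999,2.5,1.1", "1234-5678,1999,2.6,1.1"), dup)
  expect_error(read_bibliometrics(dup), "duplicate")

  neg <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("issn,year,ipp,snip",
               "1234-5678,1999,-2.5,1.1", "9999-0000,1999,4.0,1.5"), neg)
  b2 <- read_bibliometrics(neg)
  expect_equal(nrow(b2), 1)
  expect_equal(nrow(attr(b2, "rejected")), 1)
})
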