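write_tsv <- function(df) {
  path <- tempfile(fileext = ".tsv")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("activity tables load, drop bad rows, and validate their schema", {
  df <- simple_actives(5)
  expect_equal(nrow(load_activity_table(write_tsv(df))), 5)

  bad <- df; bad$value[2] <- "NA"; bad$smiles[3] <- ""
  expect_message(rec <- load_activity_table(write_tsv(bad)), "dropped 2")
  expect_equal(nrow(rec), 3)

  nocol <- df[setdiff(names(df), "target_id")]
  expect_error(load_activity_table(write_tsv(nocol)), "target_id",
               class = "ppb_schema_error")

  ## dialect remapping of ChEMBL-style headers
  chembl <- df
  names(chembl)[names(chembl) == "smiles"] <- "canonical_smiles"
  names(chembl)[names(chembl) == "activity_type"] <- "standard_type"
  rec <- load_activity_table(write_tsv(chembl),
                             dialect = c(smiles = "canonical_smiles",
                                         activity_type = "standard_type"))
  expect_equal(nrow(rec), 5)
  expect_error(load_activity_table(write_tsv(df), dialect = c(smiles = "nope")),
               class = "ppb_schema_error")
})

test_that("the retention filter applies the potency and inhibition rules", {
  rec <- data.frame(
    compound_id = sprintf("c%d", 1:7), smiles = "CCO", target_id = "T",
    target_name = "T", target_type = "", organism = "",
    activity_type = c("IC50", "IC50", "Ki", "PercentInhibition",
                      "PercentInhibition", "EC50", "IC50"),
    value = c(5, 20, 10000, 50, 50.1, 9.9, 1),
    unit = c("uM", "uM", "nM", "%", "%", "uM", "furlongs"),
    stringsAsFactors = FALSE)
  kept <- suppressWarnings(filter_activities(rec))
  expect_setequal(kept$compound_id, c("c1", "c3", "c5", "c6"))
  ## 10 uM boundary is inclusive, 50% is strict, unknown units drop
  expect_true("c3" %in% kept$compound_id)    # 10000 nM = 10 uM
  expect_false("c4" %in% kept$compound_id)   # exactly 50%
  expect_warning(filter_activities(rec), "furlongs")
  ## idempotence
  expect_identical(suppressWarnings(filter_activities(kept)), kept)
  ## micro sign and molar conversions
  mu <- rec[1, ]; mu$unit <- "µM"; mu$value <- 10
  expect_equal(nrow(filter_activities(mu)), 1)
  mM <- rec[1, ]; mM$unit <- "mM"; mM$value <- 0.01
  expect_equal(nrow(filter_activities(mM)), 1)
})

test_that("group building deduplicates per target and enforces the size floor", {
  ## 12 records, 3 of them alternative spellings of structures already present
  df <- simple_actives(9)
  dup <- df[1:3, ]
  dup$compound_id <- paste0("dup", 1:3)
  dup$smiles <- c("OCCCC", "COCCCC", "CCOCCCC")   # reversed spellings of rows 1-3
  db <- suppressWarnings(build_target_groups(rbind(df, dup), min_size = 10,
                                             ionize = FALSE))
  expect_equal(nrow(db$targets), 0)               # 12 - 3 duplicates = 9 < 10

  db10 <- build_target_groups(simple_actives(10), min_size = 10, ionize = FALSE)
  expect_equal(nrow(db10$targets), 1)
  expect_equal(db10$targets$n_members, 10L)
  expect_equal(nrow(db10$compounds), 10)
  expect_false(any(grepl("@", db10$compounds$canonical_smiles, fixed = TRUE)))
})

test_that("a compound active on two targets joins both groups with one profile", {
  two <- rbind(simple_actives(10, "T1", "A"), simple_actives(10, "T2", "B"))
  db <- build_target_groups(two, min_size = 10, ionize = FALSE)
  expect_equal(nrow(db$targets), 2)
  expect_equal(nrow(db$compounds), 10)            # same 10 structures
  shared <- db$compounds$canonical_smiles[1]
  expect_setequal(db$comp2targets[[shared]], c("T1", "T2"))
})

test_that("group membership is invariant to record order", {
  df <- rbind(simple_actives(11, "T1", "A"), simple_actives(10, "T2", "B"))
  db1 <- build_target_groups(df, ionize = FALSE)
  db2 <- build_target_groups(df[rev(seq_len(nrow(df))), ], ionize = FALSE)
  for (tid in db1$targets$target_id)
    expect_setequal(db1$members[[tid]]$canonical_smiles,
                    db2$members[[tid]]$canonical_smiles)
})

test_that("databases round-trip losslessly and detect corruption", {
  db <- fit1()$db
  dir <- tempfile("db")
  save_database(db, dir)
  db2 <- load_database(dir)
  expect_equal(db2$targets, db$targets)
  expect_equal(db2$members, db$members)
  expect_equal(db2$compounds, db$compounds)
  for (s in ppb_base_schemes())
    expect_equal(unname(db2$profiles[[s]]), unname(db$profiles[[s]]))
  expect_equal(db2$provenance$min_size, db$provenance$min_size)
  expect_equal(db2$provenance$built, db$provenance$built)

  ## truncation is caught by the checksum
  pt <- file.path(dir, "profiles.tsv")
  writeLines(utils::head(readLines(pt), 5), pt)
  expect_error(load_database(dir), class = "ppb_integrity_error")

  ## version mismatch is named
  dir2 <- tempfile("db")
  save_database(db, dir2)
  ck <- file.path(dir2, "checksums.json")
  x <- jsonlite::read_json(ck)
  x$format_version <- "99"
  jsonlite::write_json(x, ck, auto_unbox = TRUE)
  expect_error(load_database(dir2), "99", class = "ppb_version_error")
})

test_that("drug annotation matches by canonical structure with a promiscuity cap", {
  w <- world1(); db <- fit1()$db
  member <- db$members[[db$targets$target_id[1]]]$canonical_smiles[1]
  ann <- known_target_annotations(c(member, "CCCCCCCCCC"), ids = c("d1", "d2"),
                                  db = db, ionize = FALSE)
  expect_equal(ann$drug_id, "d1")                  # unknown structure excluded
  expect_true(db$targets$target_id[1] %in% ann$known_targets[[1]])
  ## cap: max_targets = 0 excludes everything
  expect_equal(nrow(known_target_annotations(member, ids = "d1", db = db,
                                             max_targets = 0,
                                             ionize = FALSE)), 0)
})
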