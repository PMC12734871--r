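test_that("feature tables round-trip through write/read unchanged", {
  tbl <- make_feature_table(
    make_feature_row("Emodin", "C15H10O5", "positive", ppm = 1.2),
    make_feature_row("Rhein", "C15H8O6", "negative", rt = 12.5,
                     db_hits = "mzVault"),
    make_feature_row("Aloin A", "C21H22O9", "positive", db_hits = "",
                     has_ms2 = FALSE, msi_level = 4L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), 3)
  for (f in c("compound_name", "formula", "ion_mode", "db_hits", "has_ms2",
              "msi_level", "species", "replicate_id"))
    expect_equal(back[[f]], tbl[[f]], info = f)
  for (f in c("precursor_mz", "calc_mw", "rt", "peak_area"))
    expect_equal(signif(back[[f]], 6), signif(tbl[[f]], 6), info = f)
})

test_that("an empty table writes a header-only file that reads back empty", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(feature_table(), path)
  expect_equal(length(readLines(path)), 1)
  expect_equal(nrow(read_feature_table(path)), 0)
})

test_that("ion-mode strings are normalized through the dialect map", {
  tbl <- make_feature_table(make_feature_row(ion_mode = "positive"),
                            make_feature_row(ion_mode = "negative"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path)
  # the default dialect writes the raw "ESI+"/"ESI-" vendor strings
  raw <- read.csv(path, check.names = FALSE)
  expect_setequal(unique(raw[["Ion Mode"]]), c("ESI+", "ESI-"))
  expect_equal(read_feature_table(path)$ion_mode, c("positive", "negative"))
})

test_that("a 200-row synthetic export reads back matching the generator", {
  gen <- generate_cd_table(generator_spec(seed = 3), n_rows = 200)
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(gen$table, path)
  back <- read_feature_table(path)
  expect_equal(nrow(back), nrow(gen$ledger))
  expect_equal(sum(back$peak_area), sum(gen$table$peak_area),
               tolerance = 1e-6)
  expect_equal(sum(back$precursor_mz), sum(gen$table$precursor_mz),
               tolerance = 1e-9)
  expect_equal(back$db_hits, gen$table$db_hits)
})

test_that("list-style db_hits dialects are accepted", {
  d <- cd_dialect(db_style = "list",
                  columns = c(cd_dialect()$columns, db_hits = "DB Hits"))
  tbl <- make_feature_table(make_feature_row(db_hits = "mzCloud;MassList"),
                            make_feature_row(db_hits = ""))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path, d)
  back <- read_feature_table(path, d)
  expect_equal(back$db_hits, tbl$db_hits)
})

test_that("missing mandatory columns and bad numerics are reported precisely", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Name,RT [min]", "x,1"), path)
  expect_error(read_feature_table(path), "Ion Mode",
               class = "hadmet_config_error")

  tbl <- make_feature_table(make_feature_row(), make_feature_row("Rhein"))
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tbl, path2)
  raw <- readLines(path2)
  raw[3] <- sub("\"([0-9.]+)\"", "\"not-a-number\"", raw[3])
  writeLines(raw, path2)
  expect_error(read_feature_table(path2), "row 2",
               class = "hadmet_parse_error")
})

test_that("feature-table invariants are enforced", {
  expect_error(feature_table(make_feature_row(msi_level = 7L)),
               class = "hadmet_validation_error")
  expect_error(feature_table(make_feature_row(db_hits = "NotADatabase")),
               class = "hadmet_validation_error")
  row <- make_feature_row(); row$ion_mode <- "both"
  expect_error(feature_table(row), class = "hadmet_validation_error")
})

test_that("the default ontology is the 19-superclass hierarchy", {
  onto <- default_ontology()
  expect_length(onto$superclass_parent, 19)
  path <- withr::local_tempfile(fileext = ".csv")
  write_ontology(onto, path)
  back <- read_ontology(path)
  expect_equal(back$superclass_parent, onto$superclass_parent)
  expect_equal(back$class_parent, onto$class_parent)
})

test_that("an empty ontology file yields an empty ontology", {
  path <- withr::local_tempfile(fileext = ".csv")
  file.create(path)
  onto <- read_ontology(path)
  expect_length(onto$pathways, 0)
  expect_length(onto$class_parent, 0)
})

test_that("multi-parent classes are rejected; random triples load faithfully", {
  bad <- data.frame(pathway = c("P1", "P1"), superclass = c("S1", "S2"),
                    class = c("C1", "C1"))
  expect_error(ontology_from_triples(bad), "C1",
               class = "hadmet_validation_error")

  set.seed(42)
  for (rep in 1:5) {
    n_sc <- sample(3:8, 1)
    triples <- data.frame(
      superclass = paste0("S", seq_len(n_sc)),
      pathway = paste0("P", sample(2, n_sc, replace = TRUE)))
    triples <- triples[sample(nrow(triples), 20, replace = TRUE), ]
    triples$class <- paste0("C", seq_len(nrow(triples)))
    path <- withr::local_tempfile(fileext = ".csv")
    write.csv(triples[, c("pathway", "superclass", "class")], path,
              row.names = FALSE)
    onto <- read_ontology(path)
    # brute-force scan of the file for each lookup
    for (cl in sample(triples$class, 5)) {
      expect_equal(unname(onto$class_parent[cl]),
                   triples$superclass[triples$class == cl][1])
      expect_equal(unname(onto$superclass_parent[onto$class_parent[cl]]),
                   triples$pathway[triples$class == cl][1])
    }
  }
})
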