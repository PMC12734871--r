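## feature_io: Compound-Discoverer-style feature tables and the
## pathway/superclass/class ontology.

FEATURE_FIELDS <- c("compound_name", "formula", "ion_mode", "precursor_mz",
                    "calc_mw", "rt", "peak_area", "db_hits", "has_ms2",
                    "msi_level", "species", "replicate_id")
MANDATORY_FIELDS <- c("ion_mode", "precursor_mz", "calc_mw", "rt", "peak_area")

#' Construct a feature table
#'
#' A feature table holds one row per detected LC-MS feature with its
#' annotation metadata: compound name, Hill formula, ionization mode,
#' precursor m/z (Da), calculated neutral monoisotopic mass (Da), retention
#' time (min), maximum peak area (instrument counts), database hits,
#' MS2 availability, MSI confidence level, species and replicate id.
#'
#' `db_hits` is stored as a single `";"`-delimited string per row drawn from
#' the five reference sources (mzCloud, mzVault, Metabolika, ChemSpider,
#' MassList); an empty string means no database match.
#'
#' @param df data.frame with (a subset of) the feature fields; missing
#'   optional columns are filled with `NA`.
#' @return a `feature_table` (data.frame subclass), validated.
#' @export
feature_table <- function(df = data.frame()) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (f in FEATURE_FIELDS) {
    if (!f %in% names(df)) {
      df[[f]] <- switch(f,
        precursor_mz = , calc_mw = , rt = , peak_area = numeric(nrow(df)) * NA,
        has_ms2 = rep(NA, nrow(df)),
        msi_level = rep(NA_integer_, nrow(df)),
        db_hits = rep("", nrow(df)),
        rep(NA_character_, nrow(df)))
    }
  }
  df <- df[, FEATURE_FIELDS, drop = FALSE]
  df$db_hits[is.na(df$db_hits)] <- ""
  ## canonical source order, so round trips are byte-stable
  df$db_hits <- vapply(strsplit(df$db_hits, ";", fixed = TRUE), function(h)
    paste(c(DB_SOURCES[DB_SOURCES %in% h], setdiff(h, DB_SOURCES)),
          collapse = ";"), character(1))
  class(df) <- c("feature_table", "data.frame")
  validate_feature_table(df)
  df
}

#' Validate feature-table invariants
#'
#' Checks ionization modes, positivity of m/z, nonnegative retention times
#' and areas, MSI levels in 1..4, and db_hits within the five reference
#' sources. Invalid rows raise an error naming the first offending row.
#'
#' @param tbl a `feature_table`.
#' @return the table, invisibly.
#' @export
validate_feature_table <- function(tbl) {
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      had_stop(sprintf("invalid feature table: %s (first at row %d)",
                       what, i[1]), "hadmet_validation_error")
  }
  ok_mode <- is.na(tbl$ion_mode) | tbl$ion_mode %in% c("positive", "negative")
  bad(!ok_mode, "ion_mode must be 'positive' or 'negative'")
  bad(!is.na(tbl$precursor_mz) & tbl$precursor_mz <= 0, "precursor_mz must be > 0")
  bad(!is.na(tbl$rt) & tbl$rt < 0, "rt must be >= 0")
  bad(!is.na(tbl$peak_area) & tbl$peak_area < 0, "peak_area must be >= 0")
  bad(!is.na(tbl$msi_level) & !tbl$msi_level %in% 1:4, "msi_level must be in 1..4")
  hits <- strsplit(tbl$db_hits, ";", fixed = TRUE)
  okdb <- vapply(hits, function(h) all(h %in% DB_SOURCES), logical(1))
  bad(!okdb, paste("db_hits must be a subset of", paste(DB_SOURCES, collapse = ", ")))
  invisible(tbl)
}

#' Default Compound-Discoverer column dialect
#'
#' CD exports vary between versions; a dialect maps internal field names to
#' the column headers of a particular export, declares how ion-mode strings
#' and database hits are encoded, and names the delimiter. The default
#' dialect reconstructs the supplementary-table header set: one column per
#' field plus one yes/no flag column per reference database.
#'
#' @param columns named character vector, internal field -> column header.
#' @param ion_mode_map named character vector mapping raw mode strings to
#'   `"positive"`/`"negative"`.
#' @param db_style `"flags"` (one logical column per source) or `"list"`
#'   (a single delimited column named by `columns["db_hits"]`).
#' @param db_flag_columns named character vector, source -> column header
#'   (used when `db_style = "flags"`).
#' @param db_sep separator for `"list"`-style db hits.
#' @param sep field delimiter of the file (`","` or `"\t"`).
#' @return a `cd_dialect` list.
#' @export
cd_dialect <- function(columns = c(compound_name = "Name",
                                   formula = "Molecular Formula",
                                   ion_mode = "Ion Mode",
                                   precursor_mz = "Precursor m/z",
                                   calc_mw = "Calc. MW",
                                   rt = "RT [min]",
                                   peak_area = "Area (Max.)",
                                   has_ms2 = "MS2",
                                   msi_level = "MSI Level",
                                   species = "Species",
                                   replicate_id = "Replicate"),
                       ion_mode_map = c("ESI+" = "positive", "ESI-" = "negative",
                                        "positive" = "positive",
                                        "negative" = "negative"),
                       db_style = c("flags", "list"),
                       db_flag_columns = c(mzCloud = "mzCloud", mzVault = "mzVault",
                                           Metabolika = "Metabolika",
                                           ChemSpider = "ChemSpider",
                                           MassList = "MassList"),
                       db_sep = ";", sep = ",") {
  db_style <- match.arg(db_style)
  structure(list(columns = columns, ion_mode_map = ion_mode_map,
                 db_style = db_style, db_flag_columns = db_flag_columns,
                 db_sep = db_sep, sep = sep),
            class = "cd_dialect")
}

parse_truthy <- function(x) {
  if (is.logical(x)) return(x)
  tolower(trimws(as.character(x))) %in% c("true", "t", "yes", "y", "1", "x")
}

#' Read a Compound-Discoverer-style feature table
#'
#' Reads a delimited text export and normalizes it into the internal
#' [feature_table()] model through a column dialect. Unmapped optional
#' fields are set absent (`NA`); database hits are assembled either from
#' per-source flag columns or from a single delimited column, depending on
#' the dialect.
#'
#' @param path path to a CSV/TSV file with a header row (UTF-8).
#' @param dialect a [cd_dialect()].
#' @return a `feature_table`.
#' @export
read_feature_table <- function(path, dialect = cd_dialect()) {
  if (!file.exists(path))
    had_stop(paste("file not found:", path), "hadmet_io_error")
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           quote = "\"", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  cols <- dialect$columns
  for (f in MANDATORY_FIELDS) {
    if (!f %in% names(cols) || !cols[[f]] %in% names(raw))
      had_stop(sprintf("mandatory column '%s' (field %s) missing from %s",
                       if (f %in% names(cols)) cols[[f]] else f, f, path),
               "hadmet_config_error")
  }
  n <- nrow(raw)
  get <- function(f) if (f %in% names(cols) && cols[[f]] %in% names(raw))
    raw[[cols[[f]]]] else rep(NA_character_, n)
  num <- function(f) {
    x <- get(f)
    out <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & nzchar(trimws(x)) & is.na(out))
    if (length(bad))
      had_stop(sprintf("unparseable numeric cell in column '%s', row %d: '%s'",
                       cols[[f]], bad[1], x[bad[1]]), "hadmet_parse_error")
    out
  }
  mode_raw <- trimws(get("ion_mode"))
  mm <- dialect$ion_mode_map
  unknown <- which(!is.na(mode_raw) & !mode_raw %in% names(mm))
  if (length(unknown))
    had_stop(sprintf("unknown ion-mode string '%s' at row %d (add it to the dialect map)",
                     mode_raw[unknown[1]], unknown[1]), "hadmet_parse_error")
  ion_mode <- unname(mm[mode_raw])

  if (dialect$db_style == "flags") {
    hits <- vapply(seq_len(n), function(i) {
      present <- vapply(DB_SOURCES, function(s) {
        col <- dialect$db_flag_columns[[s]]
        !is.null(col) && col %in% names(raw) && parse_truthy(raw[[col]][i])
      }, logical(1))
      paste(DB_SOURCES[present], collapse = ";")
    }, character(1))
  } else {
    x <- get("db_hits")
    x[is.na(x)] <- ""
    hits <- vapply(strsplit(x, dialect$db_sep, fixed = TRUE), function(h) {
      h <- trimws(h)
      paste(h[nzchar(h)], collapse = ";")
    }, character(1))
  }

  msi <- suppressWarnings(as.integer(get("msi_level")))
  feature_table(data.frame(
    compound_name = as.character(get("compound_name")),
    formula = as.character(get("formula")),
    ion_mode = ion_mode,
    precursor_mz = num("precursor_mz"),
    calc_mw = num("calc_mw"),
    rt = num("rt"),
    peak_area = num("peak_area"),
    db_hits = hits,
    has_ms2 = ifelse(is.na(get("has_ms2")), NA, parse_truthy(get("has_ms2"))),
    msi_level = msi,
    species = as.character(get("species")),
    replicate_id = as.character(get("replicate_id")),
    stringsAsFactors = FALSE))
}

#' Write a feature table
#'
#' Writes a `feature_table` as delimited text readable by
#' [read_feature_table()] with the same dialect; the round trip is the
#' identity on valid tables (numeric fields to full precision).
#'
#' @param tbl a `feature_table`.
#' @param path output path.
#' @param dialect a [cd_dialect()].
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(tbl, path, dialect = cd_dialect()) {
  validate_feature_table(tbl)
  cols <- dialect$columns
  out <- data.frame(row.names = seq_len(nrow(tbl)))
  mode_inv <- names(dialect$ion_mode_map)[match(tbl$ion_mode, dialect$ion_mode_map)]
  for (f in names(cols)) {
    val <- switch(f,
      ion_mode = mode_inv,
      has_ms2 = ifelse(is.na(tbl$has_ms2), "", ifelse(tbl$has_ms2, "TRUE", "FALSE")),
      precursor_mz = , calc_mw = , rt = , peak_area =
        formatC(tbl[[f]], digits = 10, format = "g"),
      tbl[[f]])
    out[[cols[[f]]]] <- val
  }
  if (dialect$db_style == "flags") {
    hits <- strsplit(tbl$db_hits, ";", fixed = TRUE)
    for (s in DB_SOURCES) {
      out[[dialect$db_flag_columns[[s]]]] <-
        ifelse(vapply(hits, function(h) s %in% h, logical(1)), "TRUE", "FALSE")
    }
  } else {
    out[[cols[["db_hits"]] %||% "DB Hits"]] <-
      gsub(";", dialect$db_sep, tbl$db_hits, fixed = TRUE)
  }
  ok <- tryCatch({
    utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                       quote = TRUE, fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    had_stop(paste("cannot write feature table:", conditionMessage(ok)),
             "hadmet_io_error")
  invisible(path)
}

## ---------------------------------------------------------------------------
## Ontology: the three-level natural-product hierarchy.

#' Construct an ontology from (pathway, superclass, class) triples
#'
#' The hierarchy is a tree: each class has exactly one superclass parent and
#' each superclass exactly one pathway parent. Conflicting parentage raises
#' a validation error listing the conflicts.
#'
#' @param triples data.frame with columns `pathway`, `superclass`, `class`.
#' @return an `ontology`: list with `pathways` (character),
#'   `superclass_parent` (named character, superclass -> pathway) and
#'   `class_parent` (named character, class -> superclass).
#' @export
ontology_from_triples <- function(triples) {
  stopifnot(all(c("pathway", "superclass", "class") %in% names(triples)))
  triples <- unique(as.data.frame(triples, stringsAsFactors = FALSE))
  conflict <- function(child, parent, what) {
    tab <- unique(data.frame(child = child, parent = parent))
    dup <- tab$child[duplicated(tab$child)]
    if (length(dup))
      had_stop(sprintf("%s with multiple parents: %s", what,
                       paste(unique(dup), collapse = ", ")),
               "hadmet_validation_error")
    stats::setNames(tab$parent, tab$child)
  }
  sc <- conflict(triples$superclass, triples$pathway, "superclass")
  cl <- conflict(triples$class, triples$superclass, "class")
  structure(list(pathways = sort(unique(triples$pathway)),
                 superclass_parent = sc, class_parent = cl),
            class = "ontology")
}

#' Read an ontology file
#'
#' Three-column CSV (`pathway`, `superclass`, `class`); validated as a tree.
#' An empty file (header only or zero bytes) yields an empty ontology.
#'
#' @param path CSV path.
#' @return an `ontology`.
#' @export
read_ontology <- function(path) {
  if (!file.exists(path))
    had_stop(paste("file not found:", path), "hadmet_io_error")
  if (file.size(path) == 0)
    return(ontology_from_triples(data.frame(pathway = character(),
                                            superclass = character(),
                                            class = character())))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  ontology_from_triples(df)
}

#' Write an ontology file
#' @param ontology an `ontology`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ontology <- function(ontology, path) {
  cl <- ontology$class_parent
  df <- data.frame(pathway = unname(ontology$superclass_parent[unname(cl)]),
                   superclass = unname(cl), class = names(cl),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Default natural-product ontology
#'
#' The 19 superclasses observed across the four botanical drugs, each with
#' its biosynthetic pathway parent and representative classes. Used by the
#' synthetic generator and as the default hierarchy for consistency checks.
#'
#' @return an `ontology` with 19 superclasses.
#' @export
default_ontology <- function() {
  t <- rbind(
    c("Shikimates and Phenylpropanoids", "Flavonoids", "Flavones"),
    c("Shikimates and Phenylpropanoids", "Flavonoids", "Flavonols"),
    c("Shikimates and Phenylpropanoids", "Flavonoids", "Flavanones"),
    c("Shikimates and Phenylpropanoids", "Flavonoids", "Flavan-3-ols"),
    c("Shikimates and Phenylpropanoids", "Flavonoids", "Proanthocyanins"),
    c("Shikimates and Phenylpropanoids", "Phenylpropanoids (C6-C3)", "Cinnamic acids and derivatives"),
    c("Polyketides", "Polycyclic aromatic polyketides", "Anthraquinones and anthrones"),
    c("Shikimates and Phenylpropanoids", "Isoflavonoids", "Isoflavones"),
    c("Shikimates and Phenylpropanoids", "Coumarins", "Simple coumarins"),
    c("Terpenoids", "Diterpenoids", "Abietane diterpenoids"),
    c("Shikimates and Phenylpropanoids", "Lignans", "Dibenzylbutane lignans"),
    c("Shikimates and Phenylpropanoids", "Benzenoids", "Phenols"),
    c("Terpenoids", "Monoterpenoids", "Iridoid monoterpenoids"),
    c("Polyketides", "Phloroglucinols", "Benzophenones"),
    c("Polyketides", "Aromatic polyketides", "Alkylphenols"),
    c("Alkaloids", "Pseudoalkaloids", "Terpenoid alkaloids"),
    c("Shikimates and Phenylpropanoids", "Stilbenoids", "Stilbenes"),
    c("Alkaloids", "Tyrosine alkaloids", "Isoquinoline alkaloids"),
    c("Fatty acids", "Fatty acids and conjugates", "Unsaturated fatty acids"),
    c("Polyketides", "Naphthalenes", "Naphthols"),
    c("Shikimates and Phenylpropanoids", "Phenolic acids (C6-C1)", "Gallic acid derivatives"),
    c("Polyketides", "Chromanes", "Chromones"),
    c("Unclassified", "Unclassified", "Unclassified"))
  colnames(t) <- c("pathway", "superclass", "class")
  ontology_from_triples(as.data.frame(t, stringsAsFactors = FALSE))
}

#' Look up the pathway/superclass parents of a class label
#' @param ontology an `ontology`.
#' @param class character vector of class labels.
#' @return data.frame with `class`, `superclass`, `pathway` (NA if unknown).
#' @export
ontology_parents <- function(ontology, class) {
  sc <- unname(ontology$class_parent[class])
  pw <- unname(ontology$superclass_parent[sc])
  data.frame(class = class, superclass = sc, pathway = pw,
             stringsAsFactors = FALSE)
}
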