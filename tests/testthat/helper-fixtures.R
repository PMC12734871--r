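# Shared fixtures, built in code at test time.

# One well-formed feature row with overridable fields.
make_feature_row <- function(name = "Emodin", formula = "C15H10O5",
                             ion_mode = "positive", ppm = 0, rt = 20,
                             peak_area = 5e6, db_hits = "mzCloud;ChemSpider",
                             has_ms2 = TRUE, msi_level = 2L,
                             species = "Cascara", replicate_id = "R1") {
  mw <- formula_mass(formula)
  mz <- theoretical_mz(mw, ion_mode) * (1 + ppm * 1e-6)
  data.frame(compound_name = name, formula = formula, ion_mode = ion_mode,
             precursor_mz = mz, calc_mw = mw, rt = rt, peak_area = peak_area,
             db_hits = db_hits, has_ms2 = has_ms2, msi_level = msi_level,
             species = species, replicate_id = replicate_id,
             stringsAsFactors = FALSE)
}

make_feature_table <- function(...) {
  feature_table(do.call(rbind, list(...)))
}

# SMILES parsing is the slowest step; parse each fixture set once per run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small labelled molecule set (2 families x 15) with graphs and batch.
small_molecule_fixture <- function() {
  cached("small_mols", {
    spec <- generator_spec(seed = 31)
    mol <- generate_labelled_molecules(spec, n_per_family = 15,
                                       families = scaffold_families()[1:2, ]
                                       )$molecules
    graphs <- smiles_to_graphs(mol$smiles, mol$name)
    list(molecules = mol, graphs = graphs, batch = featurize_batch(graphs))
  })
}

# Trained two-level fixture models (kept tiny; used by prediction tests).
small_model_fixture <- function() {
  cached("small_models", {
    fx <- small_molecule_fixture()
    hyper <- gin_hyper(n_layers = 2, hidden = 16, epochs = 30)
    list(
      pathway = train_level_model(fx$batch, fx$molecules$pathway, "pathway",
                                  hyper, seed = 5, k = 5),
      superclass = train_level_model(fx$batch, fx$molecules$superclass,
                                     "superclass", hyper, seed = 5, k = 5),
      class = train_level_model(fx$batch, fx$molecules$class, "class",
                                hyper, seed = 5, k = 5))
  })
}

# Independent per-record screening oracle: evaluates each rule predicate
# in isolation (its own arithmetic) and returns pass + first-failing rule.
oracle_screen_record <- function(row, config = screening_config()) {
  proton <- 1.007276
  theo <- row$calc_mw + if (row$ion_mode == "positive") proton else -proton
  checks <- c(
    db = !config$require_db_hit || nchar(row$db_hits) > 0,
    ppm = abs((row$precursor_mz - theo) / theo * 1e6) <= config$ppm_tol,
    rt = {
      w <- if (is.null(config$rt_extended)) c(config$rt_min, config$rt_max)
           else config$rt_extended
      row$rt >= w[1] && row$rt <= w[2]
    },
    area = row$peak_area >= config$area_min,
    ms2 = !config$require_ms2 || isTRUE(row$has_ms2))
  list(pass = all(checks),
       first_fail = if (all(checks)) "pass" else names(checks)[!checks][1],
       checks = checks)
}

# Brute-force average-linkage agglomeration on a sample matrix (columns =
# samples); returns the ordered merge heights.
oracle_average_linkage_heights <- function(m) {
  clusters <- as.list(seq_len(ncol(m)))
  d <- function(a, b) {
    mean(outer(a, b, Vectorize(function(i, j)
      sqrt(sum((m[, i] - m[, j])^2)))))
  }
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      h <- d(clusters[[i]], clusters[[j]])
      if (h < best[1]) best <- c(h, j, i)
    }
    heights <- c(heights, best[1])
    merged <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters <- clusters[-c(best[2], best[3])]
    clusters[[length(clusters) + 1]] <- merged
  }
  heights
}
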