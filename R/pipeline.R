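## cli/pipeline: orchestrate generate -> screen -> classify -> curate ->
## compare with a run manifest. Each stage is also callable on its own.

#' Run configuration
#'
#' @param out_dir output directory for the run.
#' @param seed master seed; all randomness (synthetic data, CV folds,
#'   weight init) flows from it.
#' @param synthetic generate all inputs with the synthetic module (the
#'   self-contained mode); otherwise `feature_tables` / `molecules` /
#'   `expert` paths must be supplied.
#' @param feature_tables named character vector species -> feature-table
#'   CSV path (non-synthetic mode).
#' @param molecules path to a molecule CSV (`name`, `smiles`, optional
#'   per-level label columns).
#' @param expert path to an expert-label CSV (`compound`, `superclass`).
#' @param dialect a [cd_dialect()].
#' @param screening a [screening_config()].
#' @param hyper a [gin_hyper()].
#' @param n_rows synthetic feature-table rows.
#' @param n_per_family synthetic molecules per scaffold family.
#' @param linkage,scaling comparative options (see [hca_abundance()],
#'   [pca_abundance()]).
#' @param verbose print stage progress.
#' @return a `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, synthetic = TRUE,
                       feature_tables = NULL, molecules = NULL, expert = NULL,
                       dialect = cd_dialect(), screening = screening_config(),
                       hyper = gin_hyper(), n_rows = 1000,
                       n_per_family = 100, linkage = "average",
                       scaling = "autoscale", verbose = TRUE) {
  cfg <- structure(list(out_dir = out_dir, seed = seed, synthetic = synthetic,
                        feature_tables = feature_tables,
                        molecules = molecules, expert = expert,
                        dialect = dialect, screening = screening,
                        hyper = hyper, n_rows = n_rows,
                        n_per_family = n_per_family, linkage = linkage,
                        scaling = scaling, verbose = verbose),
                   class = "run_config")
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (!cfg$synthetic) {
    for (p in c(cfg$feature_tables, cfg$molecules, cfg$expert))
      if (!is.null(p) && !file.exists(p))
        had_stop(paste("configured input does not exist:", p),
                 "hadmet_config_error")
    if (is.null(cfg$feature_tables))
      had_stop("non-synthetic runs need feature_tables", "hadmet_config_error")
  }
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Flat keys mirror the [run_config()] arguments; `screening:` and
#' `hyper:` sections override the respective defaults field-wise.
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  scr <- do.call(screening_config, y$screening %||% list())
  hyp <- do.call(gin_hyper, y$hyper %||% list())
  ft <- if (!is.null(y$feature_tables)) unlist(y$feature_tables) else NULL
  run_config(out_dir = out_dir %||% y$out_dir %||% "hadmet_run",
             seed = y$seed %||% 1, synthetic = isTRUE(y$synthetic %||% TRUE),
             feature_tables = ft, molecules = y$molecules,
             expert = y$expert, screening = scr, hyper = hyp,
             n_rows = y$n_rows %||% 1000,
             n_per_family = y$n_per_family %||% 100,
             linkage = y$linkage %||% "average",
             scaling = y$scaling %||% "autoscale",
             verbose = isTRUE(y$verbose %||% TRUE))
}

say <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(sprintf(...))

#' Run the full pipeline
#'
#' Executes screen -> classify -> curate -> compare (preceded by synthetic
#' generation in synthetic mode), writing per-stage CSVs with fixed names
#' (`screened.csv`, `cv_report.csv`, `predictions.csv`, `concordance.csv`,
#' `venn.csv`, `distribution.csv`, `pca_scores.csv`, `pca_variance.csv`,
#' `hca_merges.csv`, `heatmap_counts.csv`) and a `manifest.json` recording
#' the seed, a config hash, package version and per-stage counts. A stage
#' failure aborts the run with the failing stage named.
#'
#' @param cfg a [run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(cfg) {
  validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = cfg$seed, package_version =
                     as.character(utils::packageVersion("hadmet")),
                   config_hash = config_hash(cfg), stages = list())
  stage <- function(name, fun) {
    say(cfg, "[hadmet] stage %s ...", name)
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      write_manifest(manifest, cfg$out_dir)
      had_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "hadmet_stage_error")
    })
    res
  }

  ## --- inputs -------------------------------------------------------------
  if (cfg$synthetic) {
    spec <- generator_spec(seed = cfg$seed)
    gen <- stage("generate", function() {
      cd <- generate_cd_table(spec, n_rows = cfg$n_rows,
                              config = cfg$screening)
      mol <- generate_labelled_molecules(spec,
                                         n_per_family = cfg$n_per_family)
      prof <- generate_species_profiles(spec)
      utils::write.csv(cd$ledger, file.path(cfg$out_dir, "ledger_screen.csv"),
                       row.names = FALSE)
      utils::write.csv(mol$molecules, file.path(cfg$out_dir, "molecules.csv"),
                       row.names = FALSE)
      list(cd = cd, mol = mol, prof = prof)
    })
    tbl <- gen$cd$table
    molecules <- gen$mol$molecules
    profiles <- gen$prof$profiles
    manifest$stages$generate <- list(
      status = "ok", n_feature_rows = nrow(tbl),
      n_molecules = nrow(molecules),
      n_profile_compounds = sum(gen$prof$ledger$region_design),
      ledger_pass = sum(gen$cd$ledger$planted == "pass"))
  } else {
    tbl <- do.call(rbind, lapply(names(cfg$feature_tables), function(sp) {
      t <- read_feature_table(cfg$feature_tables[[sp]], cfg$dialect)
      if (all(is.na(t$species))) t$species <- sp
      t
    }))
    class(tbl) <- c("feature_table", "data.frame")
    molecules <- if (!is.null(cfg$molecules))
      utils::read.csv(cfg$molecules, stringsAsFactors = FALSE) else NULL
    profiles <- NULL
  }

  ## --- screen -------------------------------------------------------------
  rep_screen <- stage("screen", function() apply_screening(tbl, cfg$screening))
  write_feature_table(rep_screen$passed, file.path(cfg$out_dir, "screened.csv"),
                      cfg$dialect)
  manifest$stages$screen <- list(status = "ok", n_input = rep_screen$n_input,
                                 n_pass = rep_screen$n_pass,
                                 n_fail = as.list(rep_screen$n_fail_per_rule))

  ## --- classify -----------------------------------------------------------
  preds <- NULL; models <- NULL
  if (!is.null(molecules) && all(c("smiles", "superclass") %in% names(molecules))) {
    cls <- stage("classify", function() {
      graphs <- smiles_to_graphs(molecules$smiles, molecules$name)
      batch <- featurize_batch(graphs)
      models <- list(
        pathway = train_level_model(batch, molecules$pathway, "pathway",
                                    cfg$hyper, seed = cfg$seed),
        superclass = train_level_model(batch, molecules$superclass,
                                       "superclass", cfg$hyper,
                                       seed = cfg$seed),
        class = train_level_model(batch, molecules$class, "class",
                                  cfg$hyper, seed = cfg$seed))
      preds <- predict_hierarchy(models, batch)
      list(models = models, preds = preds)
    })
    models <- cls$models; preds <- cls$preds
    cvdf <- do.call(rbind, lapply(models, function(m)
      cbind(level = m$level, m$cv$per_fold)))
    utils::write.csv(cvdf, file.path(cfg$out_dir, "cv_report.csv"),
                     row.names = FALSE)
    utils::write.csv(preds, file.path(cfg$out_dir, "predictions.csv"),
                     row.names = FALSE)
    save_level_models(models, file.path(cfg$out_dir, "models"))
    manifest$stages$classify <- list(
      status = "ok", n_molecules = nrow(preds),
      cv_macro_f1 = stats::setNames(
        lapply(models, function(m) m$cv$mean_macro_f1), names(models)))
  }

  ## --- curate -------------------------------------------------------------
  if (!is.null(preds)) {
    expert <- if (cfg$synthetic)
      data.frame(compound = molecules$name, superclass = molecules$superclass)
    else if (!is.null(cfg$expert))
      utils::read.csv(cfg$expert, stringsAsFactors = FALSE) else NULL
    if (!is.null(expert)) {
      conc <- stage("curate", function() concordance(preds, expert))
      write_concordance(conc, file.path(cfg$out_dir, "concordance.csv"))
      manifest$stages$curate <- list(status = "ok",
                                     n_total = conc$n_total,
                                     n_confirmed = conc$n_confirmed,
                                     concordance_pct = conc$concordance_pct)
    }
  }

  ## --- compare ------------------------------------------------------------
  if (is.null(profiles) && !is.null(rep_screen$passed$species)) {
    profiles <- stage("profiles", function() {
      lapply(split(seq_len(nrow(rep_screen$passed)),
                   rep_screen$passed$species), function(i)
        dedupe_profile(rep_screen$passed[i, , drop = FALSE]))
    })
  }
  if (!is.null(profiles) && length(profiles) >= 2) {
    cmp <- stage("compare", function() {
      venn <- venn_regions(profiles)
      has_sc <- all(vapply(profiles, function(p)
        "superclass" %in% names(p$compounds), logical(1)))
      dist <- if (has_sc) distribution_table(profiles) else NULL
      mat <- build_abundance_matrix(profiles)
      pca <- pca_abundance(mat, cfg$scaling)
      hca <- hca_abundance(mat, cfg$linkage, cfg$scaling)
      hm <- if (has_sc) heatmap_matrix(profiles) else NULL
      list(venn = venn, dist = dist, mat = mat, pca = pca, hca = hca, hm = hm)
    })
    utils::write.csv(data.frame(region = names(cmp$venn$region_counts),
                                count = as.integer(cmp$venn$region_counts)),
                     file.path(cfg$out_dir, "venn.csv"), row.names = FALSE)
    if (!is.null(cmp$dist))
      utils::write.csv(cmp$dist, file.path(cfg$out_dir, "distribution.csv"),
                       row.names = FALSE)
    utils::write.csv(data.frame(sample = rownames(cmp$pca$scores),
                                species = cmp$pca$species,
                                cmp$pca$scores[, 1:min(4, ncol(cmp$pca$scores))]),
                     file.path(cfg$out_dir, "pca_scores.csv"), row.names = FALSE)
    utils::write.csv(data.frame(component = seq_along(cmp$pca$explained_variance_pct),
                                explained_pct = cmp$pca$explained_variance_pct),
                     file.path(cfg$out_dir, "pca_variance.csv"), row.names = FALSE)
    utils::write.csv(data.frame(a = cmp$hca$merge[, 1], b = cmp$hca$merge[, 2],
                                height = cmp$hca$height),
                     file.path(cfg$out_dir, "hca_merges.csv"), row.names = FALSE)
    if (!is.null(cmp$hm))
      utils::write.csv(data.frame(superclass = rownames(cmp$hm$counts),
                                  cmp$hm$counts, check.names = FALSE),
                       file.path(cfg$out_dir, "heatmap_counts.csv"),
                       row.names = FALSE)
    manifest$stages$compare <- list(
      status = "ok", n_union = cmp$venn$n_union,
      venn_core = unname(cmp$venn$region_counts[
        paste(cmp$venn$species, collapse = "&")]),
      pc1_pct = cmp$pca$explained_variance_pct[1],
      pc2_pct = cmp$pca$explained_variance_pct[2])
  }

  write_manifest(manifest, cfg$out_dir)
  say(cfg, "[hadmet] run complete: %s", cfg$out_dir)
  invisible(manifest)
}

## Hash of the configuration, computed on its serialized text form.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  dump <- cfg
  dump$out_dir <- NULL; dump$verbose <- NULL
  writeLines(utils::capture.output(utils::str(dump, give.attr = FALSE)), tmp)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
}
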