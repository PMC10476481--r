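# Config-driven end-to-end orchestration: generate -> extract -> variants ->
# select -> evaluate, with stage outputs on disk so each stage can be re-run
# independently (also the engine behind the inst/cli front-end).

#' Default run configuration
#'
#' @return Nested list mirroring the YAML schema accepted by
#'   [run_pipeline()]: `cohort`, `features`, `variants`, `pairs`,
#'   `selection`, `classifier`, `seed`.
#' @export
default_run_config <- function() {
  list(
    cohort = list(n_per_class = list(NC = 10, MCI = 10, AD = 10),
                  grid_shape = c(48, 48, 48), voxel_size_mm = 1.5,
                  noise_sigma = NULL),
    features = list(Z = 32, d = 1, bins = 32),
    variants = c("left", "right", "whole", "difference", "ratio"),
    pairs = c("NC-AD", "NC-MCI"),
    selection = list(max_k = 10, delta_min = 0.002, inner_folds = 5,
                     n_filter = 40),
    classifier = list(kind = "rbf", C_grid = c(0.1, 1, 10, 100),
                      outer_folds = 5, repeats = 1),
    seed = 1
  )
}

known_config_keys <- list(
  top = c("cohort", "features", "variants", "pairs", "selection",
          "classifier", "seed"),
  cohort = c("n_per_class", "grid_shape", "voxel_size_mm", "noise_sigma"),
  features = c("Z", "d", "bins"),
  selection = c("max_k", "delta_min", "inner_folds", "n_filter"),
  classifier = c("kind", "C_grid", "outer_folds", "repeats")
)

#' Validate and complete a run configuration
#'
#' Unknown keys (at the top level or within a section) are rejected before
#' any computation; missing keys take the defaults of
#' [default_run_config()].
#'
#' @param config A nested list (e.g. from [yaml::read_yaml()]), or a path to
#'   a YAML file.
#' @return The completed configuration list.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  abort_if(!is.list(config), "config must be a list or a YAML path")
  check <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    abort_if(length(bad) > 0,
             paste0("unknown config key(s) in ", where, ": ",
                    paste(bad, collapse = ", ")))
  }
  check(config, known_config_keys$top, "top level")
  for (sec in c("cohort", "features", "selection", "classifier")) {
    if (!is.null(config[[sec]])) {
      check(config[[sec]], known_config_keys[[sec]], sec)
    }
  }
  def <- default_run_config()
  out <- utils::modifyList(def, config)
  abort_if(!all(out$variants %in%
                  c("left", "right", "whole", "difference", "ratio")),
           "unknown variant in config")
  abort_if(!all(out$pairs %in% c("NC-AD", "NC-MCI")),
           "pairs must be among NC-AD, NC-MCI")
  out
}

log_line <- function(out_dir, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " | ", ...)
  message(msg)
  cat(msg, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}

cohort_config <- function(config) {
  co <- config$cohort
  args <- list(grid_shape = unlist(co$grid_shape),
               voxel_size_mm = co$voxel_size_mm)
  if (!is.null(co$noise_sigma)) args$noise_sigma <- co$noise_sigma
  do.call(phantom_config, args)
}

#' Generate the phantom cohort stage
#'
#' @param config Validated run configuration.
#' @param out_dir Output directory; volumes, legend and manifest are written
#'   under `out_dir/cohort`.
#' @param seed Master seed (default: the config's).
#' @return The manifest tibble, invisibly.
#' @export
stage_generate <- function(config, out_dir, seed = config$seed) {
  config <- validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line(out_dir, "generate: n = ",
           paste(names(config$cohort$n_per_class),
                 unlist(config$cohort$n_per_class),
                 sep = "=", collapse = ", "),
           ", grid ", paste(unlist(config$cohort$grid_shape), collapse = "x"),
           ", seed ", seed)
  co <- generate_cohort(unlist(config$cohort$n_per_class),
                        config = cohort_config(config),
                        seed = seed, dir = file.path(out_dir, "cohort"))
  invisible(co$manifest)
}

#' Read a cohort written by [stage_generate()] back into memory
#'
#' @param dir The `cohort` directory (manifest.csv, legend.json, volumes).
#' @return List of `subject_record`s.
#' @export
read_cohort <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  abort_if(!file.exists(mpath), paste0("missing manifest: ", mpath))
  lpath <- file.path(dir, "legend.json")
  abort_if(!file.exists(lpath), paste0("missing legend: ", lpath))
  manifest <- utils::read.csv(mpath, stringsAsFactors = FALSE)
  legend <- tibble::as_tibble(jsonlite::read_json(lpath, simplifyVector = TRUE))
  lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_volume(manifest$intensity_path[i])
    lab <- read_volume(manifest$label_path[i])
    structure(list(subject_id = manifest$subject_id[i],
                   class_label = manifest$class[i],
                   intensity = img,
                   labels = label_map(array(as.integer(round(lab$data)),
                                            dim(lab$data)),
                                      legend, lab$spacing_mm)),
              class = "subject_record")
  })
}

#' Feature-extraction stage
#'
#' @param config Validated run configuration.
#' @param out_dir Output directory holding `cohort/`; writes `features.csv`
#'   and a JSON sidecar recording Z, d, directions and bins.
#' @return The feature tibble, invisibly.
#' @export
stage_extract <- function(config, out_dir) {
  config <- validate_run_config(config)
  records <- read_cohort(file.path(out_dir, "cohort"))
  fs <- feature_spec(config$features$Z, config$features$d,
                     config$features$bins)
  log_line(out_dir, "extract: ", length(records), " subjects, Z = ", fs$Z,
           ", d = ", fs$d, ", bins = ", fs$bins)
  feats <- extract_features(records, fs)
  utils::write.csv(feats, file.path(out_dir, "features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(Z = fs$Z, d = fs$d, bins = fs$bins,
         directions = glcm_directions(), symmetric = TRUE),
    file.path(out_dir, "features_meta.json"), auto_unbox = TRUE)
  invisible(feats)
}

read_features <- function(out_dir) {
  fpath <- file.path(out_dir, "features.csv")
  abort_if(!file.exists(fpath),
           paste0("missing feature table (run the extract stage first): ",
                  fpath))
  tibble::as_tibble(utils::read.csv(fpath, stringsAsFactors = FALSE))
}

#' Variant-construction stage
#'
#' @param config Validated run configuration.
#' @param out_dir Output directory holding `features.csv`; writes
#'   `variant_<tag>.csv` per configured variant.
#' @return Named list of variant tibbles, invisibly.
#' @export
stage_variants <- function(config, out_dir) {
  config <- validate_run_config(config)
  feats <- read_features(out_dir)
  out <- lapply(stats::setNames(config$variants, config$variants),
                function(v) {
    tb <- build_variant(feats, v)
    utils::write.csv(tb, file.path(out_dir, paste0("variant_", v, ".csv")),
                     row.names = FALSE)
    tb
  })
  log_line(out_dir, "variants: ", paste(config$variants, collapse = ", "))
  invisible(out)
}

#' Whole-cohort feature-selection stage
#'
#' Runs the filter + wrapper selector per (pair, variant) on the full cohort
#' (for reporting; evaluation re-nests selection inside CV folds) and writes
#' `selection_<pair>_<variant>.json` plus the per-structure count table
#' mirroring the monotonicity analysis.
#'
#' @param config Validated run configuration.
#' @param out_dir Output directory holding the variant CSVs.
#' @param seed Master seed.
#' @return Named list of `ad_selection` objects, invisibly.
#' @export
stage_select <- function(config, out_dir, seed = config$seed) {
  config <- validate_run_config(config)
  feats <- read_features(out_dir)
  res <- list()
  count_rows <- list()
  for (pair_tag in config$pairs) {
    pair <- strsplit(pair_tag, "-")[[1]]
    for (v in config$variants) {
      tb <- build_variant(feats, v)
      sub <- tb[tb$class %in% pair, ]
      cfg <- do.call(selection_config, c(config$selection,
                                         list(seed = derive_seed(seed, "select",
                                                                 pair_tag, v))))
      sel <- sequential_forward_select(sub, cfg = cfg)
      mono <- monotone_flags(class_feature_means(tb))
      key <- paste(pair_tag, v, sep = "_")
      res[[key]] <- sel
      jsonlite::write_json(
        list(pair = pair_tag, variant = v, selected = sel$selected,
             step_accuracy = sel$step_accuracy,
             monotone = as.list(mono[sel$selected])),
        file.path(out_dir, paste0("selection_", key, ".json")),
        auto_unbox = TRUE, digits = NA)
      ct <- count_by_structure(sel, mono)
      ct$pair <- pair_tag; ct$variant <- v
      count_rows[[key]] <- ct
    }
  }
  counts <- dplyr::bind_rows(count_rows)
  utils::write.csv(counts, file.path(out_dir, "selected_counts.csv"),
                   row.names = FALSE)
  log_line(out_dir, "select: ", length(res), " (pair, variant) selections")
  invisible(res)
}

#' Evaluation stage: nested CV over pairs, variants and selection modes
#'
#' @param config Validated run configuration.
#' @param out_dir Output directory holding `features.csv`; writes
#'   `metrics.csv` and `metrics.json` with one row per
#'   (pair, variant, selection mode).
#' @param seed Master seed.
#' @param variants,pairs Optional subsets overriding the config.
#' @param selection_modes Logical vector of arms to run (default both
#'   `TRUE` = after selection and `FALSE` = before).
#' @return The metrics tibble, invisibly.
#' @export
stage_evaluate <- function(config, out_dir, seed = config$seed,
                           variants = NULL, pairs = NULL,
                           selection_modes = c(TRUE, FALSE)) {
  config <- validate_run_config(config)
  feats <- read_features(out_dir)
  variants <- variants %||% config$variants
  pairs <- pairs %||% config$pairs
  rows <- list()
  for (pair_tag in pairs) {
    pair <- strsplit(pair_tag, "-")[[1]]
    for (v in variants) {
      for (sel in selection_modes) {
        cfg <- do.call(selection_config,
                       c(config$selection, list(seed = seed)))
        cv <- nested_cross_validate(
          feats, pair = pair, variant = v, select = sel, cfg = cfg,
          kind = config$classifier$kind,
          C_grid = unlist(config$classifier$C_grid),
          outer_folds = config$classifier$outer_folds,
          repeats = config$classifier$repeats,
          seed = derive_seed(seed, "eval", pair_tag, v, sel))
        g <- glance(cv)
        log_line(out_dir, "evaluate: ", pair_tag, " / ", v,
                 if (sel) " (selected): " else " (all features): ",
                 sprintf("acc %.3f", g$accuracy))
        rows[[paste(pair_tag, v, sel)]] <- g
      }
    }
  }
  metrics <- dplyr::bind_rows(rows)
  utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}

#' Run the whole pipeline
#'
#' Generate -> extract -> variants -> select -> evaluate, all under one
#' master seed, writing every stage artifact beneath `out_dir`.
#'
#' @param config Run configuration (list or YAML path); see
#'   [default_run_config()].
#' @param out_dir Output directory.
#' @param seed Master seed (default: the config's).
#' @return The metrics tibble, invisibly.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         seed = NULL) {
  config <- validate_run_config(config)
  seed <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage_generate(config, out_dir, seed)
  stage_extract(config, out_dir)
  stage_variants(config, out_dir)
  stage_select(config, out_dir, seed)
  stage_evaluate(config, out_dir, seed)
}
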