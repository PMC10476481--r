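# Shared cohort fixtures, generated once per test run and cached so the
# feature-level and evaluation tests reuse them.

.fixtures <- new.env(parent = emptyenv())

# Study-condition cohort (reduced size: 48^3 grid, 30 subjects/class) with
# the shipped class effects; returns the extracted feature tibble.
cohort_features_cached <- function(seed, n = 30, grid = 48) {
  key <- paste0("cohort_", seed, "_", n, "_", grid)
  if (is.null(.fixtures[[key]])) {
    co <- generate_cohort(c(NC = n, MCI = n, AD = n),
                          config = phantom_config(grid_shape = rep(grid, 3)),
                          seed = seed)
    .fixtures[[key]] <- extract_features(co)
  }
  .fixtures[[key]]
}

# One small phantom subject per (class, seed), cached.
subject_cached <- function(class = "NC", seed = 1, grid = 48, ...) {
  key <- paste0("subj_", class, "_", seed, "_", grid, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixtures[[key]])) {
    cfg <- phantom_config(grid_shape = rep(grid, 3), ...)
    eff <- default_class_effects()[[class]]
    .fixtures[[key]] <- simulate_subject(cfg, eff, paste0(class, "_s"), seed)
  }
  .fixtures[[key]]
}

# Tabular toy data: one informative feature among noise (for selection/CV
# unit tests that do not need imaging).
toy_features <- function(n_per_class = 20, n_noise = 19, shift = 3,
                         seed = 1, classes = c("NC", "AD")) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    X <- matrix(stats::rnorm(n * n_noise), n, n_noise)
    cls <- rep(classes, each = n_per_class)
    signal <- stats::rnorm(n) + ifelse(cls == classes[2], shift, 0)
    tbl <- tibble::as_tibble(X, .name_repair = ~ sprintf("gm_left_glcm_n%02d",
                                                         seq_len(n_noise)))
    tbl$hc_left_shape_volume <- signal
    dplyr::bind_cols(tibble::tibble(subject_id = sprintf("s%03d", seq_len(n)),
                                    class = cls), tbl)
  })
}
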