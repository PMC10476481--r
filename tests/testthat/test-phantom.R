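nojit <- list(global_sd = 0, volume_sd = 0, corr_sd = 0)

test_that("identity effects give mirror-symmetric label maps", {
  cfg <- phantom_config(grid_shape = c(48, 48, 48), jitter = nojit)
  lm <- build_label_map(cfg, class_effect("NC"), seed = 1)
  for (s in c("gm", "wm", "csf", "hc")) {
    l <- structure_mask(lm, s, "left")$data
    r <- structure_mask(lm, s, "right")$data
    expect_equal(sum(l), sum(r))
    # exact reflection across the midplane
    expect_identical(l[rev(seq_len(dim(l)[1])), , ], r)
  }
  # structures pairwise disjoint and union-complete over nonzero labels
  expect_equal(sum(lm$data > 0),
               sum(sapply(seq_len(nrow(lm$legend)),
                          function(i) sum(lm$data == lm$legend$label[i]))))
})

test_that("volume_scale rasterises to the requested volume ratio", {
  cfg <- phantom_config(jitter = nojit)  # default 64^3
  eff <- class_effect("AD", volume_scale = list(hc = c(left = 0.7, right = 1)))
  lm <- build_label_map(cfg, eff, seed = 1)
  ratio <- sum(structure_mask(lm, "hc", "left")$data) /
    sum(structure_mask(lm, "hc", "right")$data)
  expect_true(abs(ratio - 0.7) < 0.05)
  # structures outside the hippocampal neighbourhood stay symmetric (the
  # voxels released by the shrunken left HC fall back to the enclosing GM)
  expect_equal(sum(structure_mask(lm, "wm", "left")$data),
               sum(structure_mask(lm, "wm", "right")$data))
  expect_equal(sum(structure_mask(lm, "csf", "left")$data),
               sum(structure_mask(lm, "csf", "right")$data))
})

test_that("label maps and textures are deterministic in the seed", {
  cfg <- phantom_config(grid_shape = c(40, 40, 40))
  eff <- default_class_effects()$MCI
  lm1 <- build_label_map(cfg, eff, seed = 5)
  lm2 <- build_label_map(cfg, eff, seed = 5)
  expect_identical(lm1$data, lm2$data)
  t1 <- synthesize_texture(lm1, cfg, eff, seed = 5)
  t2 <- synthesize_texture(lm2, cfg, eff, seed = 5)
  expect_identical(t1$data, t2$data)
  t3 <- synthesize_texture(lm1, cfg, eff, seed = 6)
  expect_false(identical(t1$data, t3$data))
})

test_that("zero texture amplitude gives piecewise-constant intensities", {
  tp <- default_texture_params()
  for (s in names(tp)) tp[[s]]$amplitude <- 0
  cfg <- phantom_config(grid_shape = c(40, 40, 40), texture_params = tp,
                        jitter = nojit, noise_sigma = 0)
  lm <- build_label_map(cfg, class_effect("NC"), 1)
  tex <- synthesize_texture(lm, cfg, class_effect("NC"), 1)
  for (s in c("gm", "wm", "csf", "hc")) {
    vals <- tex$data[structure_mask(lm, s, "left")$data]
    expect_equal(unique(vals), tp[[s]]$base_intensity)
  }
  expect_true(all(tex$data[lm$data == 0] == 0))
})

test_that("larger correlation length lowers GLCM contrast within a subject", {
  cfg <- phantom_config(grid_shape = c(40, 40, 40), jitter = nojit,
                        noise_sigma = 0)
  eff <- class_effect("NC", texture = list(
    gm = list(left = list(correlation_length_multiplier = 2))))
  s <- simulate_subject(cfg, eff, "s", seed = 2)
  gl <- glcm_features(glcm(quantize(
    s$intensity, structure_mask(s$labels, "gm", "left"), 32)))
  gr <- glcm_features(glcm(quantize(
    s$intensity, structure_mask(s$labels, "gm", "right"), 32)))
  expect_lt(gl[["contrast"]], gr[["contrast"]])
})

test_that("Rician noise matches its closed-form moments and sign", {
  v0 <- voxel_grid(array(0, c(50, 50, 50)))
  out <- add_rician_noise(v0, sigma = 1, seed = 9)
  # Rayleigh mean sqrt(pi/2) at I = 0, sigma = 1 (n = 125000 voxels)
  expect_true(abs(mean(out$data) - sqrt(pi / 2)) < 0.01)
  expect_true(all(out$data >= 0))

  v1 <- voxel_grid(array(runif(1000), c(10, 10, 10)))
  expect_identical(add_rician_noise(v1, 0, seed = 1)$data, v1$data)
  expect_error(add_rician_noise(v1, -0.1), "sigma")
  # determinism
  expect_identical(add_rician_noise(v1, 0.5, seed = 3)$data,
                   add_rician_noise(v1, 0.5, seed = 3)$data)
})

test_that("cohort generation is seeded, sized and manifest-stable", {
  cfg <- phantom_config(grid_shape = c(32, 32, 32))
  co <- generate_cohort(c(NC = 2, MCI = 1, AD = 1), cfg, seed = 4)
  expect_length(co$records, 4)
  expect_equal(nrow(co$manifest), 4)
  expect_equal(as.vector(table(co$manifest$class)[c("NC", "MCI", "AD")]),
               c(2, 1, 1))
  co2 <- generate_cohort(c(NC = 2, MCI = 1, AD = 1), cfg, seed = 4)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$records[[1]]$intensity$data,
                   co2$records[[1]]$intensity$data)
  expect_error(generate_cohort(c(NC = 0), cfg), ">= 1")
})

test_that("shipped class effects are componentwise monotone NC -> MCI -> AD", {
  eff <- default_class_effects()
  for (s in c("gm", "wm", "csf", "hc")) for (h in c("left", "right")) {
    vs <- sapply(eff, function(e) e$volume_scale[[s]][[h]])
    cl <- sapply(eff, function(e)
      e$texture[[s]][[h]]$correlation_length_multiplier)
    expect_true(all(diff(vs) <= 0) || all(diff(vs) >= 0))
    expect_true(all(diff(cl) <= 0) || all(diff(cl) >= 0))
  }
})

test_that("degenerate geometry is rejected", {
  cfg <- phantom_config(grid_shape = c(48, 48, 48), jitter = nojit)
  eff <- class_effect("AD", volume_scale = list(hc = c(left = 1e-6, right = 1)))
  expect_error(build_label_map(cfg, eff, 1), "degenerate|empty")
})
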