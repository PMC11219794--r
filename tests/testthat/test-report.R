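test_that("trajectory reports have the contracted shape and flag semantics", {
  pan <- tiny_panel(n = 5, T_ = 4, p = 2, seed = 401)
  f <- fit_dynamic_st(pan, n_iter = 150, burn_in = 50, seed = 11)
  tr <- coefficient_trajectories(f)
  expect_equal(nrow(tr), 2 * 4)                 # p components x T years
  expect_setequal(unique(tr$component), f$covariate_names)
  expect_equal(tr$significant, tr$lower > 0 | tr$upper < 0)
  vt <- variance_trajectories(f)
  expect_equal(nrow(vt), 2 * 4)                 # sigma2 and tau2, length T each
  expect_setequal(unique(vt$series), c("sigma2", "tau2"))
  expect_equal(sum(vt$series == "sigma2"), 4)
})

test_that("annual fitted layers equal the simulated surface in the noiseless limit", {
  co <- simulate_coords(5, seed = 411)
  tr <- simulate_truth(co, n_years = 4, p = 2, seed = 412,
                       nugget_var = 0, sill_var = 0.2)
  pan <- simulate_panel(tr, seed = 413)
  f <- fit_dynamic_st(pan, n_iter = 60, burn_in = 10, seed = 414)
  st <- truth_state(pan)
  for (m in seq_len(f$config$n_kept)) {
    f$draws$beta[m, , ] <- st$beta
    f$draws$spatial[m, , ] <- st$spatial
  }
  lay <- annual_fitted_layers(f)
  expect_equal(nrow(lay), 5 * 4)
  got <- matrix(lay$fitted, 5, 4)
  expect_equal(got, pan$Y, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("fitted-minus-observed residuals centre near zero on training cells", {
  co <- simulate_coords(15, seed = 421)
  tr <- simulate_truth(co, n_years = 10, p = 2, seed = 422)
  pan <- simulate_panel(tr, seed = 423)
  f <- fit_dynamic_st(pan, n_iter = 400, burn_in = 100, seed = 424)
  lay <- annual_fitted_layers(f)
  fitted <- matrix(lay$fitted, 15, 10)
  resid <- (pan$Y - fitted)[pan$mask]
  expect_lt(abs(mean(resid)), 0.05)
})

test_that("percentile classes are a permutation on distinct aggregates and pool ties low", {
  layers <- tibble::tibble(
    site_id = rep(sprintf("S%d", 1:5), each = 3),
    year = rep(2000:2002, times = 5),
    fitted = rep(c(10, 2, 7, 4, 30), each = 3) + rep(c(-1, 0, 1), times = 5))
  out <- period_percentile_layers(layers, blocks = list(c(2000, 2002)),
                                  n_bins = 5)
  expect_setequal(out$percentile_class, 1:5)
  expect_equal(out$percentile_class[order(out$aggregate)], 1:5)
  # median aggregate matches a sort-and-middle oracle
  for (s in unique(layers$site_id)) {
    v <- sort(layers$fitted[layers$site_id == s])
    expect_equal(out$aggregate[out$site_id == s], v[2])
  }
  # all-equal aggregates collapse into the lowest class
  flat <- layers; flat$fitted <- 7
  outf <- period_percentile_layers(flat, blocks = list(c(2000, 2002)))
  expect_true(all(outf$percentile_class == 1))
  expect_error(period_percentile_layers(layers, blocks = list(c(1990, 1995))),
               class = "fsndyn_error_validation")
})

test_that("percentile classes are invariant under strictly monotone transforms", {
  set.seed(431)
  layers <- tibble::tibble(site_id = rep(sprintf("S%02d", 1:20), each = 5),
                           year = rep(2000:2004, times = 20),
                           fitted = rnorm(100))
  a <- period_percentile_layers(layers, blocks = list(c(2000, 2004)))
  layers2 <- layers
  layers2$fitted <- exp(3 * layers2$fitted + 1)   # strictly monotone
  b <- period_percentile_layers(layers2, blocks = list(c(2000, 2004)))
  expect_equal(a$percentile_class, b$percentile_class)
})

test_that("a planted coefficient jump turns significance flags on late in the period", {
  co <- simulate_coords(30, seed = 441)
  T_ <- 20
  # component 2 is null until year 15, then jumps to a strong positive effect
  beta_path <- cbind(rep(2, T_), c(rep(0, 14), rep(1.5, 6)))
  tr <- simulate_truth(co, n_years = T_, p = 2, seed = 442,
                       innovation_cov = diag(1e-8, 2),
                       nugget_var = 0.25, sill_var = 0.1)
  tr$beta_path <- beta_path
  pan <- simulate_panel(tr, seed = 443)
  f <- fit_dynamic_st(pan, n_iter = 1200, burn_in = 400, seed = 444)
  traj <- coefficient_trajectories(f)
  x2 <- dplyr::filter(traj, component == "x2")
  early <- x2$significant[1:14]
  late <- x2$significant[16:20]
  expect_lt(mean(early), 0.3)
  expect_gt(mean(late), 0.7)
})

test_that("a doubled late-period sill is recovered and a constant truth shows no trend", {
  co <- simulate_coords(30, seed = 451)
  T_ <- 20
  sill_path <- c(rep(0.15, 14), rep(0.6, 6))
  tr <- simulate_truth(co, n_years = T_, p = 2, seed = 452,
                       sill_var = sill_path, nugget_var = 0.2)
  pan <- simulate_panel(tr, seed = 453)
  f <- fit_dynamic_st(pan, n_iter = 1200, burn_in = 400, seed = 454)
  vt <- variance_trajectories(f)
  s2 <- dplyr::filter(vt, series == "sigma2")
  expect_gt(mean(s2$median[16:20]), mean(s2$median[1:14]))
  # constant truth: no detectable monotone trend in >= 2/3 of seeds
  hits <- 0
  for (seed in 1:3) {
    trc <- simulate_truth(co, n_years = 12, p = 2, seed = 460 + seed,
                          sill_var = 0.2, nugget_var = 0.2)
    panc <- simulate_panel(trc, seed = 470 + seed)
    fc <- fit_dynamic_st(panc, n_iter = 600, burn_in = 200, seed = 480 + seed)
    s2c <- dplyr::filter(variance_trajectories(fc), series == "sigma2")
    kt <- suppressWarnings(stats::cor.test(s2c$median, seq_len(12),
                                           method = "kendall"))
    if (kt$p.value > 0.05) hits <- hits + 1
  }
  expect_gte(hits, 2)
})

test_that("a null truth produces few spurious significance flags", {
  co <- simulate_coords(25, seed = 491)
  tr <- simulate_truth(co, n_years = 12, p = 2, seed = 492,
                       beta0 = c(0, 0), innovation_cov = diag(1e-8, 2),
                       nugget_var = 0.3, sill_var = 0.1)
  pan <- simulate_panel(tr, seed = 493)
  f <- fit_dynamic_st(pan, n_iter = 800, burn_in = 300, seed = 494)
  traj <- coefficient_trajectories(f)
  expect_lt(mean(traj$significant), 0.2)
})

test_that("GeoJSON export is a valid point FeatureCollection", {
  layers <- tibble::tibble(block = "2000-2004",
                           site_id = c("A", "B"),
                           aggregate = c(1.5, 2.5),
                           percentile_class = c(1L, 2L))
  coords <- tibble::tibble(site_id = c("A", "B"), lon = c(10, 20),
                           lat = c(-5, 5))
  tmp <- withr::local_tempfile(fileext = ".geojson")
  write_layers_geojson(layers, coords, tmp)
  gj <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 2)
  expect_equal(gj$features[[1]]$geometry$type, "Point")
  expect_equal(unlist(gj$features[[1]]$geometry$coordinates), c(10, -5))
  expect_equal(gj$features[[2]]$properties$percentile_class, 2)
  expect_error(write_layers_geojson(dplyr::mutate(layers, site_id = "Z"),
                                    coords, tmp),
               class = "fsndyn_error_validation")
})

test_that("plot helpers return ggplot objects", {
  pan <- tiny_panel(n = 5, T_ = 4, p = 1, seed = 495)
  f <- fit_dynamic_st(pan, n_iter = 80, burn_in = 20, seed = 496)
  expect_s3_class(plot_variance_trajectories(f), "ggplot")
  lay <- annual_fitted_layers(f)
  pl <- period_percentile_layers(lay, blocks = list(c(2000, 2003)), n_bins = 2)
  co <- tibble::tibble(site_id = pan$site_ids, lon = pan$coords[, 1],
                       lat = pan$coords[, 2])
  expect_s3_class(plot_percentile_map(pl, co), "ggplot")
})

test_that("the pipeline runs end to end, reproducibly, with provenance headers", {
  tmp1 <- withr::local_tempdir()
  tmp2 <- withr::local_tempdir()
  cfg <- list(
    seed = 7,
    indicator_spec = list(n_sites = 10, n_years = 8, n_indicators = 6,
                          n_blocks = 2),
    transform = "log1p",
    truth = list(beta0 = c(8, rep(0.3, 2)), nugget_var = 0.04,
                 sill_var = 0.02, innovation_cov = diag(1e-4, 3)),
    sampler = list(n_iter = 150, burn_in = 50, thin = 1,
                   metropolis_step = 0.3, adapt = TRUE),
    blocks = list(c(2000, 2003), c(2004, 2007)))
  res1 <- run_pipeline(cfg, out_dir = tmp1)
  expect_true(file.exists(file.path(tmp1, "manifest.json")))
  man <- jsonlite::read_json(file.path(tmp1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$transform, "log1p")
  expect_equal(man$split$n_test, floor(0.3 * 80))
  # provenance header on every CSV artifact
  for (fcsv in c("scores.csv", "assessment.csv",
                 "coefficient_trajectories.csv", "period_percentile_layers.csv")) {
    first <- readLines(file.path(tmp1, fcsv), n = 1)
    expect_match(first, "^# fsndyn config=")
    expect_match(first, "transform=log1p")
  }
  # byte-identical rerun
  res2 <- run_pipeline(cfg, out_dir = tmp2)
  for (fcsv in setdiff(list.files(tmp1, pattern = "\\.csv$"), character(0))) {
    expect_identical(readLines(file.path(tmp1, fcsv)),
                     readLines(file.path(tmp2, fcsv)), label = fcsv)
  }
  # retained components match the planted block count; truth p = k + intercept
  expect_equal(res1$factor_model$n_retained, 2)
  expect_equal(res1$fit$panel$p, 3)
  expect_equal(res1$assessment$k, man$split$n_test)
})

test_that("the pipeline reads config from YAML and aborts cleanly on bad stages", {
  tmp <- withr::local_tempdir()
  yml <- file.path(tmp, "cfg.yaml")
  writeLines(c("seed: 3",
               "indicator_spec:",
               "  n_sites: 8", "  n_years: 6", "  n_indicators: 4",
               "  n_blocks: 2",
               "sampler:",
               "  n_iter: 80", "  burn_in: 20", "  thin: 1",
               "  metropolis_step: 0.3", "  adapt: true",
               "blocks:", "- [2000, 2002]", "- [2003, 2005]"), yml)
  res <- run_pipeline(yml, out_dir = file.path(tmp, "out"))
  expect_equal(res$manifest$seed, 3)
  bad <- list(seed = 1, sampler = list(n_iter = 10, burn_in = 20, thin = 1,
                                       metropolis_step = 0.3, adapt = TRUE),
              indicator_spec = list(n_sites = 8, n_years = 6,
                                    n_indicators = 4, n_blocks = 2))
  expect_error(run_pipeline(bad, out_dir = file.path(tmp, "out2")),
               regexp = "stage `fit`")
})
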