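test_that("simulate_pedigree builds the requested design deterministically", {
  cfg <- sim_config(n_sires = 2, daughters_per_sire = 3, seed = 1)
  ped <- simulate_pedigree(cfg)
  expect_equal(sum(ped$si > 0 | ped$di > 0), 6)   # 6 non-founder cows
  expect_equal(length(attr(ped, "cows")), 6)
  expect_identical(simulate_pedigree(cfg), ped)   # same seed, same pedigree

  cfg2 <- sim_config(n_sires = 4, daughters_per_sire = 4,
                     n_generations = 2, seed = 2)
  ped2 <- simulate_pedigree(cfg2)
  expect_equal(max(ped2$gen), 2)
})

test_that("gene dropping has the right first and second moments", {
  # founders: direct N(0, G) draws
  ped <- pedigree(data.frame(animal = paste0("f", 1:10000), sire = NA,
                             dam = NA))
  set.seed(41)
  bv <- simulate_breeding_values(ped, 4)
  expect_equal(var(bv[, 1]), 4, tolerance = 0.05)
  expect_equal(simulate_breeding_values(ped, matrix(0, 1, 1)),
               bv * 0, ignore_attr = TRUE)
  expect_error(simulate_breeding_values(ped, matrix(c(1, 2, 2, 1), 2)),
               "positive semidefinite")

  # 5000 independent parent-offspring pairs: cov / sigma2_a ~ 0.5
  cfg <- sim_config(n_sires = 5000, daughters_per_sire = 1, seed = 42)
  ped2 <- simulate_pedigree(cfg)
  set.seed(43)
  bv2 <- simulate_breeding_values(ped2, 4)
  off <- which(ped2$si > 0)
  expect_lt(abs(cov(bv2[off, 1], bv2[ped2$si[off], 1]) / 4 - 0.5), 0.03)
})

test_that("with only residual variance the record variance is sigma2_e", {
  v_e <- 1e6
  cfg <- sim_config(n_sires = 50, daughters_per_sire = 10, seed = 51,
                    records_per_cow = 2, milk_components = c(0, 0, v_e),
                    fixed_sd_frac = c(herd = 0, year = 0, season = 0,
                                      parity = 0),
                    lactation_slope_frac = 0)
  herd <- simulate_herd(cfg)
  expect_equal(var(herd$records$milk), v_e, tolerance = 0.1)
})

test_that("the small preset reproduces the calibrated methane variance", {
  herd <- simulate_herd(sim_config(preset = "small", seed = 4))
  rec <- herd$records
  # phenotypic variance net of fixed effects vs the component-sum target
  v_net <- var(2.73 * (rec$milk - herd$truth$fixed_part[, "milk"]))
  expect_lt(abs(v_net / 22561480 - 1), 0.10)
  expect_true(validate_records(rec))
  # records per cow within the configured parity range, mean near target
  k <- table(rec$cow)
  expect_true(all(k >= 1 & k <= 6))
  expect_equal(mean(k), 2.176, tolerance = 0.05)
})

test_that("generated trait means sit within sampling error of the targets", {
  cfg <- sim_config(preset = "small", seed = 4)
  herd <- simulate_herd(cfg)
  rec <- herd$records
  n_cows <- length(unique(rec$cow))
  for (tr in c("milk", "fat", "protein", "lactose")) {
    sdt <- cfg$trait_sds[tr]
    # SE of the overall mean, dominated by the once-per-level fixed draws
    se <- sqrt(sum(cfg$fixed_sd_frac^2 * sdt^2 /
                     c(cfg$n_herds, cfg$n_years, cfg$n_seasons,
                       cfg$max_parity)) +
               sum(cfg$sigma2[, tr]) / n_cows)
    expect_lt(abs(mean(rec[[tr]]) - cfg$trait_means[tr]), 2 * se)
  }
})

test_that("one record per cow leaves W equal to Z on recorded cows", {
  cfg <- sim_config(n_sires = 10, daughters_per_sire = 4, seed = 61,
                    records_per_cow = 1)
  herd <- simulate_herd(cfg)
  dm <- suppressMessages(
    build_design(herd$records, herd$pedigree, ~ parity + herd))
  cows <- colnames(dm$W)
  expect_equal(as.matrix(dm$Z[, cows]), as.matrix(dm$W),
               ignore_attr = TRUE)
})

test_that("same seed gives byte-identical output files", {
  cfg <- sim_config(n_sires = 5, daughters_per_sire = 3, seed = 71)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write.csv(simulate_herd(cfg)$records, f1, row.names = FALSE)
  write.csv(simulate_herd(cfg)$records, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  unlink(c(f1, f2))
})

test_that("optional methane noise breaks the unit correlation with milk", {
  cfg <- sim_config(n_sires = 30, daughters_per_sire = 5, seed = 81,
                    methane_noise_sd = 2000)
  rec <- simulate_herd(cfg)$records
  expect_lt(cor(rec$mpe1, rec$milk), 1 - 1e-4)
  cfg0 <- sim_config(n_sires = 30, daughters_per_sire = 5, seed = 81)
  expect_equal(cor(simulate_herd(cfg0)$records$mpe1,
                   simulate_herd(cfg0)$records$milk), 1)
})
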