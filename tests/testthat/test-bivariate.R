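# Two-trait REML checks.

test_that("an affine copy of a trait gives rg = rp = 1", {
  herd <- tiny_herd(seed = 11, n_sires = 40, daughters = 5)
  rec <- herd$records
  rec$y2 <- 2 * rec$mpe1 + 5
  fit <- suppressWarnings(
    animal_reml(cbind(mpe1, y2) ~ parity + herd, rec, herd$pedigree,
                maxit = 80))
  gp <- genetic_parameters(fit)
  expect_equal(gp$rg, 1, tolerance = 1e-3)
  expect_equal(gp$rp, 1, tolerance = 1e-3)
})

test_that("independent traits give a near-zero genetic correlation", {
  # 2,000 cows per replicate; single-replicate rg has sampling SD ~0.15 at
  # this design, so the mean over 6 replicates is checked
  res <- vapply(1:6, function(s) {
    cfg <- sim_config(preset = "small", seed = 810 + s, records_per_cow = 2,
                      n_herds = 1, n_years = 1, n_seasons = 1,
                      fixed_sd_frac = c(herd = 0, year = 0, season = 0,
                                        parity = 0),
                      lactation_slope_frac = 0,
                      genetic_cor = diag(5), pe_cor = diag(5),
                      residual_cor = diag(5))
    herd <- simulate_herd(cfg)
    fit <- suppressMessages(
      animal_reml(cbind(milk, lactose) ~ 1, herd$records, herd$pedigree))
    g <- genetic_parameters(fit)
    c(g$rg, g$rp)
  }, numeric(2))
  expect_lt(abs(mean(res[1, ])), 0.1)
  expect_lt(abs(mean(res[2, ])), 0.05)
})

test_that("a known genetic correlation is recovered", {
  # milk and protein are simulated with genetic correlation 0.85
  rgs <- vapply(1:4, function(s) {
    cfg <- recovery_cfg(seed = 900 + s)
    herd <- simulate_herd(cfg)
    fit <- suppressMessages(
      animal_reml(cbind(milk, protein) ~ 1, herd$records, herd$pedigree))
    genetic_parameters(fit)$rg
  }, 0)
  expect_lt(abs(mean(rgs) - 0.85), 0.05)
})

test_that("bivariate marginals match univariate fits when traits are independent", {
  cfg <- sim_config(n_sires = 80, daughters_per_sire = 8, seed = 77,
                    records_per_cow = 2, n_herds = 3, n_years = 3,
                    n_seasons = 2, genetic_cor = diag(5), pe_cor = diag(5),
                    residual_cor = diag(5))
  herd <- simulate_herd(cfg)
  rec <- herd$records; ped <- herd$pedigree
  f1 <- animal_reml(milk ~ parity + herd, rec, ped,
                    tol_logl = 1e-9, tol_theta = 1e-10)
  f2 <- animal_reml(fat ~ parity + herd, rec, ped,
                    tol_logl = 1e-9, tol_theta = 1e-10)
  fb <- animal_reml(cbind(milk, fat) ~ parity + herd, rec, ped,
                    tol_logl = 1e-9, tol_theta = 1e-10)
  th_uni <- c(f1$Ga[1, 1], f2$Ga[1, 1], f1$Gpe[1, 1], f2$Gpe[1, 1],
              f1$R0[1, 1], f2$R0[1, 1])
  th_biv <- c(fb$Ga[1, 1], fb$Ga[2, 2], fb$Gpe[1, 1], fb$Gpe[2, 2],
              fb$R0[1, 1], fb$R0[2, 2])
  expect_equal(th_biv, th_uni, tolerance = 1e-3)
})

test_that("estimated covariance blocks stay positive semidefinite", {
  herd <- tiny_herd(seed = 23, n_sires = 30, daughters = 5)
  fit <- suppressWarnings(
    animal_reml(cbind(mpe2, fat) ~ parity + herd, herd$records,
                herd$pedigree, maxit = 200))
  for (B in list(fit$Ga, fit$Gpe, fit$R0))
    expect_gte(min(eigen(B, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8 * max(abs(B)))
})
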