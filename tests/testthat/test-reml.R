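# REML engine checks against independent oracles and its own invariants.

test_that("REML equals the one-way ANOVA oracle on a balanced design", {
  set.seed(3)
  n_cow <- 150; m <- 2
  ped <- pedigree(data.frame(animal = paste0("c", 1:n_cow), sire = NA,
                             dam = NA))
  u <- rnorm(n_cow, 0, sqrt(8))
  rec <- data.frame(cow = rep(ped$animal, each = m))
  rec$y <- 10 + u[match(rec$cow, ped$animal)] + rnorm(nrow(rec), 0, sqrt(5))
  dm <- build_design(rec, ped, ~ 1)
  Ainv <- build_nrm_inverse(ped)
  fit <- reml_univariate(dm, Ainv, rec$y, trait = "y",
                         tol_logl = 1e-12, tol_theta = 1e-12, maxit = 3000)
  gm <- tapply(rec$y, rec$cow, mean)
  MSB <- m * var(as.numeric(gm))
  MSW <- sum((rec$y - ave(rec$y, rec$cow))^2) / (n_cow * (m - 1))
  between <- (MSB - MSW) / m
  # with A = I the a/pe split is unidentifiable; only the sum is checked
  expect_equal(fit$Ga[1, 1] + fit$Gpe[1, 1], between, tolerance = 1e-6)
  expect_equal(fit$R0[1, 1], MSW, tolerance = 1e-6)
})

test_that("REML log-likelihood matches a dense-matrix evaluation", {
  herd <- tiny_herd(seed = 7, n_sires = 10, daughters = 3, records = 2)
  rec <- herd$records; ped <- herd$pedigree
  fit <- animal_reml(mpe2 ~ parity + herd, rec, ped)
  dm <- build_design(rec, ped, ~ parity + herd)
  A <- build_nrm(ped)
  X <- as.matrix(dm$X); Z <- as.matrix(dm$Z); W <- as.matrix(dm$W)
  y <- rec$mpe2; n <- length(y); p <- ncol(X)
  v <- c(fit$Ga[1, 1], fit$Gpe[1, 1], fit$R0[1, 1])
  V <- v[1] * Z %*% A %*% t(Z) + v[2] * tcrossprod(W) + v[3] * diag(n)
  cV <- chol(V); Vi <- chol2inv(cV)
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  dense <- -0.5 * (2 * sum(log(diag(cV))) +
                   as.numeric(determinant(XVX)$modulus) +
                   drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
  expect_equal(fit$logL, dense, tolerance = 1e-8)
})

test_that("true zero additive variance is estimated at the floor", {
  at_floor <- vapply(1:10, function(s) {
    cfg <- sim_config(n_sires = 40, daughters_per_sire = 6, seed = 600 + s,
                      records_per_cow = 2, n_herds = 2, n_years = 2,
                      n_seasons = 2,
                      milk_components = c(0, 452375, 1666194))
    herd <- simulate_herd(cfg)
    fit <- animal_reml(milk ~ parity, herd$records, herd$pedigree)
    fit$Ga[1, 1] <= 100 * fit$floors[1]
  }, TRUE)
  expect_gte(sum(at_floor), 9)
})

test_that("pure EM iterations never decrease the log-likelihood", {
  herd <- tiny_herd(seed = 6, n_sires = 20, daughters = 5)
  fit <- suppressWarnings(
    animal_reml(mpe2 ~ parity + herd, herd$records, herd$pedigree,
                method = "em", maxit = 120))
  expect_true(all(diff(fit$trace$logL) > -1e-6 * (1 + abs(fit$trace$logL[-1]))))
  expect_true(all(fit$trace$step[-1] == "EM"))
})

test_that("estimates are invariant to record order and covariate rescaling", {
  herd <- tiny_herd(seed = 13, n_sires = 25, daughters = 4)
  rec <- herd$records; ped <- herd$pedigree
  f <- mpe2 ~ parity + herd + lactation_length
  fit <- animal_reml(f, rec, ped)
  set.seed(1)
  fit_sh <- animal_reml(f, rec[sample(nrow(rec)), ], ped)
  expect_equal(fit$theta, fit_sh$theta, tolerance = 1e-6)
  # affine rescaling of the covariate spans the same fixed space
  rec2 <- transform(rec, lactation_length = 3 * lactation_length - 500)
  fit_sc <- animal_reml(f, rec2, ped)
  expect_equal(fit$theta, fit_sc$theta, tolerance = 1e-6)
})

test_that("rescaling the response scales components by c^2, ratios unchanged", {
  herd <- tiny_herd(seed = 17, n_sires = 25, daughters = 4)
  rec <- herd$records
  fit1 <- animal_reml(mpe3 ~ parity + herd, rec, herd$pedigree)
  rec$y2 <- 10 * rec$mpe3
  fit2 <- animal_reml(y2 ~ parity + herd, rec, herd$pedigree)
  expect_equal(fit2$theta, 100 * fit1$theta, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_equal(heritability(fit1), heritability(fit2), tolerance = 1e-6)
  expect_equal(repeatability(fit1), repeatability(fit2), tolerance = 1e-6)
})

test_that("aic follows the REML convention", {
  expect_equal(aic(0, 3), 6)
  expect_equal(aic(-100, 3), 206)
  expect_equal(aic(-340238, 3), 680482)
  expect_error(aic(-10, 0))
})

test_that("non-convergence is reported, never silent", {
  herd <- tiny_herd(seed = 6, n_sires = 10, daughters = 3)
  expect_warning(
    fit <- animal_reml(mpe1 ~ parity, herd$records, herd$pedigree,
                       method = "em", maxit = 3),
    "did not converge")
  expect_false(fit$converged)
  expect_equal(fit$iterations, 3)
})

test_that("fit object methods are coherent", {
  herd <- tiny_herd(seed = 19, n_sires = 15, daughters = 4)
  fit <- animal_reml(mpe1 ~ parity + herd, herd$records, herd$pedigree)
  expect_s3_class(fit, "animal_reml")
  expect_equal(length(fitted(fit)), nrow(herd$records))
  expect_equal(fitted(fit) + residuals(fit), herd$records$mpe1,
               ignore_attr = TRUE)
  expect_equal(AIC(logLik(fit)), fit$aic)
  expect_named(ranef(fit), c("animal", "pe"))
  expect_equal(nrow(ranef(fit)$animal), nrow(herd$pedigree))
  expect_output(print(fit), "Repeatability animal model")
  expect_output(print(summary(fit)), "h2")
})
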