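## Genetic parameters derived from variance components:
##   h2 = sigma2_a / sigma2_P,  r = (sigma2_a + sigma2_pe) / sigma2_P,
##   sigma2_P = sigma2_a + sigma2_pe + sigma2_e,
##   r(g/p) = cov / sqrt(var_x * var_y).

.vc3 <- function(vc) {
  if (inherits(vc, "animal_reml")) {
    if (length(vc$traits) != 1)
      stop("heritability/repeatability need a univariate fit")
    return(c(a = vc$Ga[1, 1], pe = vc$Gpe[1, 1], e = vc$R0[1, 1]))
  }
  vc <- as.numeric(vc)
  if (length(vc) != 3) stop("need c(sigma2_a, sigma2_pe, sigma2_e)")
  c(a = vc[1], pe = vc[2], e = vc[3])
}

#' Heritability from variance components
#'
#' `h2 = sigma2_a / (sigma2_a + sigma2_pe + sigma2_e)`.
#'
#' @param vc a univariate `animal_reml` fit, or a numeric vector
#'   `c(sigma2_a, sigma2_pe, sigma2_e)`.
#' @return Heritability in `[0, 1]`.
#' @export
heritability <- function(vc) {
  v <- .vc3(vc)
  if (any(v < 0)) stop("variance components must be non-negative")
  tot <- sum(v)
  if (tot <= 0) stop("zero total variance")
  unname(v["a"] / tot)
}

#' Repeatability from variance components
#'
#' `r = (sigma2_a + sigma2_pe) / (sigma2_a + sigma2_pe + sigma2_e)`; an
#' upper bound on heritability.
#'
#' @inheritParams heritability
#' @return Repeatability in `[0, 1]`.
#' @export
repeatability <- function(vc) {
  v <- .vc3(vc)
  if (any(v < 0)) stop("variance components must be non-negative")
  tot <- sum(v)
  if (tot <= 0) stop("zero total variance")
  unname((v["a"] + v["pe"]) / tot)
}

#' Correlation from a covariance and two variances
#'
#' `cov / sqrt(var_x * var_y)`, clipped to `[-1, 1]` with a warning when the
#' raw value exceeds 1 by more than numerical noise.
#'
#' @param cov covariance between traits x and y.
#' @param var_x,var_y strictly positive variances.
#' @return Correlation in `[-1, 1]`.
#' @export
correlation <- function(cov, var_x, var_y) {
  if (any(var_x <= 0) || any(var_y <= 0))
    stop("variances must be positive")
  r <- cov / sqrt(var_x * var_y)
  if (any(abs(r) > 1 + 1e-6))
    warning("correlation outside [-1, 1]; clipped")
  pmin(pmax(r, -1), 1)
}

## first-order delta-method SE of g(theta) given cov(theta)
.delta_se <- function(grad, V) {
  if (anyNA(V)) return(NA_real_)
  sqrt(max(drop(t(grad) %*% V %*% grad), 0))
}

#' Genetic parameters (with delta-method standard errors) from a fit
#'
#' For a univariate fit: heritability and repeatability.  For a bivariate
#' fit: genetic correlation `rg` (from the additive block) and phenotypic
#' correlation `rp` (from the summed additive, permanent-environment and
#' residual blocks).  Standard errors are first-order delta-method
#' approximations based on the inverse average-information matrix.
#'
#' @param fit an `animal_reml` object.
#' @return One-row data frame of estimates and standard errors.
#' @export
genetic_parameters <- function(fit) {
  stopifnot(inherits(fit, "animal_reml"))
  V <- fit$theta_cov
  if (length(fit$traits) == 1) {
    v <- c(fit$Ga[1, 1], fit$Gpe[1, 1], fit$R0[1, 1])
    tot <- sum(v)
    h2 <- v[1] / tot
    r <- (v[1] + v[2]) / tot
    g_h2 <- c(1 / tot - v[1] / tot^2, -v[1] / tot^2, -v[1] / tot^2)
    g_r <- c((v[3]) / tot^2, (v[3]) / tot^2, -(v[1] + v[2]) / tot^2)
    data.frame(trait = fit$traits,
               sigma2_a = v[1], sigma2_pe = v[2], sigma2_e = v[3],
               h2 = h2, se_h2 = .delta_se(g_h2, V),
               repeatability = r, se_r = .delta_se(g_r, V),
               logL = fit$logL, AIC = fit$aic,
               converged = fit$converged, stringsAsFactors = FALSE)
  } else {
    Ga <- fit$Ga; P <- fit$Ga + fit$Gpe + fit$R0
    rg <- correlation(Ga[1, 2], Ga[1, 1], Ga[2, 2])
    rp <- correlation(P[1, 2], P[1, 1], P[2, 2])
    ## theta order: a11, a21, a22, pe11, pe21, pe22, e11, e21, e22
    g_rg <- c(-rg / (2 * Ga[1, 1]), 1 / sqrt(Ga[1, 1] * Ga[2, 2]),
              -rg / (2 * Ga[2, 2]), rep(0, 6))
    g_p <- c(-rp / (2 * P[1, 1]), 1 / sqrt(P[1, 1] * P[2, 2]),
             -rp / (2 * P[2, 2]))
    g_rp <- rep(g_p, 3)
    data.frame(trait_x = fit$traits[1], trait_y = fit$traits[2],
               cov_g = Ga[1, 2], rg = rg, se_rg = .delta_se(g_rg, V),
               cov_p = P[1, 2], rp = rp, se_rp = .delta_se(g_rp, V),
               logL = fit$logL, converged = fit$converged,
               stringsAsFactors = FALSE)
  }
}

#' Report tables for a collection of fits
#'
#' Renders the standard report set: trait summary statistics, univariate
#' variance components with heritability, repeatability and AIC (ranked,
#' smallest AIC preferred), and bivariate genetic/phenotypic correlations.
#' Ratios are rounded to 2 decimals at this reporting layer only; full
#' precision is kept inside the fit objects.
#'
#' @param fits list of `animal_reml` objects (univariate and/or bivariate).
#' @param records optional data frame of lactation records for the summary
#'   table.
#' @param dir optional directory; when given, the tables are written as CSV
#'   (`summary_statistics.csv`, `variance_components.csv`,
#'   `correlations.csv`).
#' @param digits decimals for reported ratios (default 2).
#' @return List of data frames `summary_statistics`, `variance_components`,
#'   `correlations` (entries may be absent when no fit of that kind was
#'   given).
#' @export
report_tables <- function(fits, records = NULL, dir = NULL, digits = 2) {
  if (inherits(fits, "animal_reml")) fits <- list(fits)
  if (!length(fits)) stop("no fits supplied")
  stopifnot(all(vapply(fits, inherits, TRUE, "animal_reml")))
  uni <- fits[vapply(fits, function(f) length(f$traits) == 1, TRUE)]
  biv <- fits[vapply(fits, function(f) length(f$traits) == 2, TRUE)]
  out <- list()

  if (!is.null(records)) {
    num <- names(records)[vapply(records, is.numeric, TRUE)]
    num <- setdiff(num, c("parity", "herd", "year", "season"))
    out$summary_statistics <- data.frame(
      variable = num,
      mean = vapply(num, function(v) mean(records[[v]]), 0),
      sd = vapply(num, function(v) stats::sd(records[[v]]), 0),
      min = vapply(num, function(v) min(records[[v]]), 0),
      max = vapply(num, function(v) max(records[[v]]), 0),
      n_records = nrow(records),
      n_cows = length(unique(records$cow)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (length(uni)) {
    tb <- do.call(rbind, lapply(uni, genetic_parameters))
    tb$h2 <- round(tb$h2, digits)
    tb$repeatability <- round(tb$repeatability, digits)
    tb$se_h2 <- round(tb$se_h2, digits)
    tb$se_r <- round(tb$se_r, digits)
    tb$aic_rank <- rank(tb$AIC, ties.method = "min")
    out$variance_components <- tb
  }
  if (length(biv)) {
    tb <- do.call(rbind, lapply(biv, genetic_parameters))
    tb$rg <- round(tb$rg, digits)
    tb$rp <- round(tb$rp, digits)
    tb$se_rg <- round(tb$se_rg, digits)
    tb$se_rp <- round(tb$se_rp, digits)
    out$correlations <- tb
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (nm in names(out))
      utils::write.csv(out[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  out
}
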