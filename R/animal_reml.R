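#' Fit a repeatability animal model by REML
#'
#' Fits the mixed model `y = Xb + Za + Wpe + e` with additive genetic effects
#' `a` (covariance `A sigma2_a`, `A` the numerator relationship matrix from
#' the pedigree), permanent-environment effects `pe` (one per cow, identity
#' covariance) and residuals `e`.  Variance components are estimated by REML
#' using EM steps with average-information acceleration on Henderson's sparse
#' mixed-model equations; an accelerated step is accepted only when it does
#' not decrease the REML log-likelihood.
#'
#' A two-trait model is requested with `cbind(trait1, trait2)` on the
#' left-hand side; the 2x2 additive, permanent-environment and residual
#' covariance blocks are then estimated jointly and kept positive
#' semidefinite.
#'
#' @param formula model formula, e.g.
#'   `mpe1 ~ parity + herd + year + season + lactation_length` or
#'   `cbind(mpe1, milk) ~ ...`.  Factors get treatment contrasts (first level
#'   dropped); numeric covariates are centred.
#' @param data data frame of lactation records (one row per cow-parity).
#' @param ped a [pedigree] containing every recorded cow.
#' @param id name of the cow identifier column (default `"cow"`).
#' @param start optional starting values: univariate, a numeric vector
#'   `c(sigma2_a, sigma2_pe, sigma2_e)`; bivariate, a list with 2x2 matrices
#'   `Ga`, `Gpe`, `R0`.
#' @param method `"ai"` (default: EM warm-up then average-information steps
#'   with EM fallback) or `"em"` (pure EM).
#' @param maxit maximum number of iterations (default 500).
#' @param tol_logl convergence tolerance on the log-likelihood change.
#' @param tol_theta convergence tolerance on the relative parameter change.
#' @param verbose print the iteration trace.
#' @return Object of class `animal_reml` with components `Ga`, `Gpe`, `R0`
#'   (estimated (co)variance blocks), `logL`, `AIC`, `converged`,
#'   `iterations`, fixed-effect solutions and BLUPs, and the iteration trace.
#'   Methods: `print`, `summary`, `coef`, `logLik`, `vcov`, `fitted`,
#'   `residuals`, `ranef`, `plot`.
#' @seealso [reml_univariate()], [reml_bivariate()] for the matrix-level
#'   interface, [genetic_parameters()] for derived ratios.
#' @export
animal_reml <- function(formula, data, ped, id = "cow", start = NULL,
                        method = c("ai", "em"), maxit = 500,
                        tol_logl = 1e-6, tol_theta = 1e-8, verbose = FALSE) {
  method <- match.arg(method)
  lhs <- formula[[2]]
  traits <- if (is.call(lhs) && identical(as.character(lhs[[1]]), "cbind")) {
    vapply(as.list(lhs)[-1], as.character, "")
  } else deparse(lhs)
  if (length(traits) > 2)
    stop("at most two traits are supported")
  miss <- setdiff(traits, names(data))
  if (length(miss)) stop("trait not in data: ", miss[1])
  Y <- as.matrix(data[, traits, drop = FALSE])
  if (!is.numeric(Y) || anyNA(Y)) stop("traits must be numeric, no NAs")

  fixed <- formula
  fixed[[2]] <- NULL  # one-sided
  dm <- build_design(data, ped, fixed = fixed, id = id)
  Ainv <- build_nrm_inverse(ped)
  fit <- .reml_engine(dm$X, dm$Z, dm$W, Y, Ainv,
                      logdetA = attr(Ainv, "logdet_A"), start = start,
                      method = method, maxit = maxit, tol_logl = tol_logl,
                      tol_theta = tol_theta, verbose = verbose)
  .as_animal_reml(fit, traits = traits, dm = dm, call = match.call(),
                  formula = formula)
}

.as_animal_reml <- function(fit, traits, dm = NULL, call = NULL,
                            formula = NULL) {
  t <- length(traits)
  dimnames(fit$Ga) <- dimnames(fit$Gpe) <- dimnames(fit$R0) <-
    list(traits, traits)
  names(fit$theta) <- .theta_names(traits)
  names(fit$se_theta) <- names(fit$theta)
  dimnames(fit$theta_cov) <- list(names(fit$theta), names(fit$theta))
  colnames(fit$fixef) <- traits
  if (!is.null(dm)) rownames(fit$fixef) <- colnames(dm$X)
  colnames(fit$u) <- colnames(fit$pe) <- traits
  if (!is.null(dm)) {
    rownames(fit$u) <- dm$animal_ids
    rownames(fit$pe) <- dm$cow_ids
  }
  colnames(fit$fitted) <- colnames(fit$residuals) <- traits
  fit$traits <- traits
  fit$design <- dm
  fit$call <- call
  fit$formula <- formula
  class(fit) <- "animal_reml"
  fit
}

#' Univariate REML fit from pre-built design matrices
#'
#' Matrix-level interface: estimate `(sigma2_a, sigma2_pe, sigma2_e)` for one
#' response given [build_design()] output and the inverse relationship matrix
#' from [build_nrm_inverse()].
#'
#' @param dm a `design_matrices` object.
#' @param Ainv sparse inverse numerator relationship matrix with a
#'   `"logdet_A"` attribute (as returned by [build_nrm_inverse()]).
#' @param y numeric response vector (one entry per record).
#' @param start optional `c(sigma2_a, sigma2_pe, sigma2_e)`.
#' @param trait trait label used in reports.
#' @inheritParams animal_reml
#' @return An `animal_reml` object.
#' @export
reml_univariate <- function(dm, Ainv, y, start = NULL, trait = "y",
                            method = c("ai", "em"), maxit = 500,
                            tol_logl = 1e-6, tol_theta = 1e-8,
                            verbose = FALSE) {
  method <- match.arg(method)
  if (!is.null(start)) stopifnot(all(start > 0))
  fit <- .reml_engine(dm$X, dm$Z, dm$W, matrix(y, ncol = 1), Ainv,
                      logdetA = attr(Ainv, "logdet_A"), start = start,
                      method = method, maxit = maxit, tol_logl = tol_logl,
                      tol_theta = tol_theta, verbose = verbose)
  .as_animal_reml(fit, traits = trait, dm = dm)
}

#' Bivariate REML fit from pre-built design matrices
#'
#' Two-trait analogue of [reml_univariate()]: both traits observed on the
#' same records; estimates 2x2 additive, permanent-environment and residual
#' covariance blocks (kept positive semidefinite).
#'
#' @inheritParams reml_univariate
#' @param y1,y2 numeric response vectors on the same records.
#' @param traits length-2 character vector of trait labels.
#' @param start optional list with 2x2 matrices `Ga`, `Gpe`, `R0`.
#' @return An `animal_reml` object with 2x2 blocks.
#' @export
reml_bivariate <- function(dm, Ainv, y1, y2, start = NULL,
                           traits = c("y1", "y2"), method = c("ai", "em"),
                           maxit = 500, tol_logl = 1e-6, tol_theta = 1e-8,
                           verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(length(y1) == length(y2))
  fit <- .reml_engine(dm$X, dm$Z, dm$W, cbind(y1, y2), Ainv,
                      logdetA = attr(Ainv, "logdet_A"), start = start,
                      method = method, maxit = maxit, tol_logl = tol_logl,
                      tol_theta = tol_theta, verbose = verbose)
  .as_animal_reml(fit, traits = traits, dm = dm)
}

#' @export
print.animal_reml <- function(x, digits = 4, ...) {
  t <- length(x$traits)
  cat("Repeatability animal model (REML",
      if (x$method == "ai") "EM + average information" else "EM", ")\n")
  cat("Trait(s):", paste(x$traits, collapse = ", "),
      sprintf("| %d records, %d animals, %d cows\n",
              x$dims$n, x$dims$q, x$dims$n_cows))
  cat(sprintf("logL = %.3f  AIC = %.3f  (%d iterations, %s)\n",
              x$logL, x$aic, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  if (t == 1) {
    v <- c(x$Ga[1, 1], x$Gpe[1, 1], x$R0[1, 1])
    cat(sprintf("sigma2_a = %.6g  sigma2_pe = %.6g  sigma2_e = %.6g\n",
                v[1], v[2], v[3]))
    cat(sprintf("h2 = %.*f   repeatability = %.*f\n",
                digits, heritability(x), digits, repeatability(x)))
  } else {
    cat("Additive block:\n"); print(signif(x$Ga, digits))
    cat("rg =", signif(correlation(x$Ga[1, 2], x$Ga[1, 1], x$Ga[2, 2]),
                       digits),
        " rp =", signif({P <- x$Ga + x$Gpe + x$R0
                         correlation(P[1, 2], P[1, 1], P[2, 2])}, digits),
        "\n")
  }
  invisible(x)
}

#' @export
summary.animal_reml <- function(object, ...) {
  out <- list(fit = object, params = genetic_parameters(object))
  class(out) <- "summary.animal_reml"
  out
}

#' @export
print.summary.animal_reml <- function(x, ...) {
  print(x$fit)
  cat("\nDerived genetic parameters:\n")
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' @export
coef.animal_reml <- function(object, ...) {
  if (length(object$traits) == 1) object$fixef[, 1] else object$fixef
}

#' @export
logLik.animal_reml <- function(object, ...) {
  structure(object$logL, df = object$n_params,
            nobs = object$dims$t * (object$dims$n - object$dims$p),
            class = "logLik")
}

#' @export
vcov.animal_reml <- function(object, ...) object$theta_cov

#' @export
fitted.animal_reml <- function(object, ...) {
  if (length(object$traits) == 1) object$fitted[, 1] else object$fitted
}

#' @export
residuals.animal_reml <- function(object, ...) {
  if (length(object$traits) == 1) object$residuals[, 1] else object$residuals
}

#' Breeding values and permanent-environment BLUPs
#'
#' @param object an `animal_reml` fit.
#' @param ... unused.
#' @return List with `animal` (additive genetic BLUPs, one row per pedigree
#'   animal) and `pe` (permanent-environment BLUPs, one row per recorded cow).
#' @export
ranef <- function(object, ...) UseMethod("ranef")

#' @export
ranef.animal_reml <- function(object, ...) {
  list(animal = object$u, pe = object$pe)
}

#' @export
plot.animal_reml <- function(x, ...) {
  plot(x$trace$iter, x$trace$logL, type = "b", pch = 16,
       xlab = "iteration", ylab = "REML log-likelihood",
       main = paste("REML convergence:", paste(x$traits, collapse = " & ")),
       ...)
  invisible(x)
}
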