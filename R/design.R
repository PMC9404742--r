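#' Build design matrices for the repeatability animal model
#'
#' Constructs the sparse fixed-effect matrix `X` (treatment contrasts, first
#' level of each factor dropped, numeric covariates centred at their sample
#' mean), the additive-genetic incidence `Z` (records x pedigree animals) and
#' the permanent-environment incidence `W` (records x recorded cows).
#'
#' Character columns are coerced to factors; factors with a single observed
#' level are dropped from the fixed part with a message (they are absorbed by
#' the intercept).
#'
#' @param data data frame of lactation records.
#' @param ped a [pedigree] containing every recorded cow.
#' @param fixed one-sided formula for the fixed effects, e.g.
#'   `~ parity + herd + year + season + lactation_length`.
#' @param id name of the column holding the cow identifier.
#' @return Object of class `design_matrices`: list with `X`, `Z`, `W`,
#'   factor levels (`xlev`), covariate centres, cow and animal id vectors.
#' @export
build_design <- function(data, ped, fixed = ~ parity + herd + year +
                           season + lactation_length, id = "cow") {
  stopifnot(is.data.frame(data), is(ped, "pedigree"))
  if (nrow(data) < 2) stop("need at least 2 records")
  if (!id %in% names(data)) stop("no column '", id, "' in data")
  ids <- as.character(data[[id]])
  aidx <- match(ids, ped$animal)
  if (anyNA(aidx))
    stop("cows not in pedigree: ", paste(head(unique(ids[is.na(aidx)]), 3),
                                         collapse = ", "))

  vars <- all.vars(fixed)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("fixed-effect variables not in data: ",
                         paste(miss, collapse = ", "))
  mf <- data[, vars, drop = FALSE]
  xlev <- list()
  centers <- numeric(0)
  drop_vars <- character(0)
  for (v in vars) {
    if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
    if (is.factor(mf[[v]])) {
      mf[[v]] <- droplevels(mf[[v]])
      if (nlevels(mf[[v]]) < 2) {
        drop_vars <- c(drop_vars, v)
      } else xlev[[v]] <- levels(mf[[v]])
    } else {
      centers[v] <- mean(mf[[v]])
      mf[[v]] <- mf[[v]] - centers[v]
    }
  }
  if (length(drop_vars)) {
    message("dropping single-level fixed effects: ",
            paste(drop_vars, collapse = ", "))
    keep <- setdiff(vars, drop_vars)
    fixed <- if (length(keep))
      stats::reformulate(keep) else ~ 1
    mf <- mf[, keep, drop = FALSE]
  }
  X <- Matrix::sparse.model.matrix(fixed, mf)
  p <- ncol(X)
  XtX <- as.matrix(Matrix::crossprod(X))
  if (qr(XtX)$rank < p)
    stop("aliased fixed effects: X is rank deficient")

  n <- nrow(data)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = aidx, x = 1,
                            dims = c(n, nrow(ped)),
                            dimnames = list(NULL, ped$animal))
  cow_ids <- ped$animal[sort(unique(aidx))]
  W <- Matrix::sparseMatrix(i = seq_len(n), j = match(ids, cow_ids), x = 1,
                            dims = c(n, length(cow_ids)),
                            dimnames = list(NULL, cow_ids))
  structure(list(X = X, Z = Z, W = W, fixed = fixed, xlev = xlev,
                 centers = centers, cow_ids = cow_ids,
                 animal_ids = ped$animal, id = id),
            class = "design_matrices")
}

#' @export
print.design_matrices <- function(x, ...) {
  cat("Design matrices: X", paste(dim(x$X), collapse = " x "),
      "| Z", paste(dim(x$Z), collapse = " x "),
      "| W", paste(dim(x$W), collapse = " x "), "\n")
  invisible(x)
}

## Fixed-effect row matrix for new records under a stored design;
## errors on factor levels unseen at fit time.
apply_design <- function(dm, newdata) {
  vars <- all.vars(dm$fixed)
  mf <- newdata[, vars, drop = FALSE]
  for (v in vars) {
    if (v %in% names(dm$xlev)) {
      f <- factor(as.character(mf[[v]]), levels = dm$xlev[[v]])
      if (anyNA(f))
        stop("unseen level in '", v, "': ",
             setdiff(unique(as.character(mf[[v]])), dm$xlev[[v]])[1])
      mf[[v]] <- f
    } else {
      mf[[v]] <- mf[[v]] - dm$centers[v]
    }
  }
  Matrix::sparse.model.matrix(dm$fixed, mf)
}
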