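#' Energy-corrected milk (kg/lactation)
#'
#' `ECM = 0.327 * milk + 12.95 * fat + 7.2 * protein`, all in kg/lactation.
#'
#' @param milk,fat,protein per-lactation yields in kg (non-negative,
#'   vectorised).
#' @return ECM in kg/lactation.
#' @export
ecm <- function(milk, fat, protein) {
  if (any(milk < 0 | fat < 0 | protein < 0, na.rm = TRUE))
    stop("yields must be non-negative")
  0.327 * milk + 12.95 * fat + 7.2 * protein
}

#' Milk protein concentration (%)
#'
#' `CPC = 100 * protein / milk` (protein yield as a percentage of milk
#' yield, both kg/lactation).
#'
#' @param milk milk yield, kg/lactation (strictly positive).
#' @param protein protein yield, kg/lactation.
#' @return Protein concentration in percent.
#' @export
cpc <- function(milk, protein) {
  if (any(milk <= 0, na.rm = TRUE)) stop("milk yield must be positive")
  if (any(protein < 0, na.rm = TRUE)) stop("protein yield must be non-negative")
  100 * protein / milk
}

#' Methane prediction equation coefficients
#'
#' The three indirect prediction equations for per-lactation methane
#' (g/lactation): from milk yield (MPE1), from energy-corrected milk (MPE2),
#' and from energy-corrected milk plus protein concentration (MPE3).
#' Standard errors of the published intercepts/slopes are carried as
#' metadata only; they are not propagated into phenotypes.
#'
#' @return Data frame of equation coefficients and their standard errors.
#' @export
methane_equations <- function() {
  data.frame(
    equation  = c("mpe1", "mpe2", "mpe3"),
    predictor = c("milk yield", "ECM", "ECM + CPC"),
    intercept = c(299, 259, 150),
    se_intercept = c(12.1, 11.1, 16.1),
    slope1    = c(2.73, 3.86, 4.31),
    se_slope1 = c(0.171, 0.167, 0.172),
    slope2    = c(NA, NA, 28.3),
    se_slope2 = c(NA, NA, 3.20),
    stringsAsFactors = FALSE
  )
}

#' Predict per-lactation methane phenotypes from milk records
#'
#' Appends `ecm` (kg/lactation), `cpc` (%), and the three indirect methane
#' phenotypes `mpe1`, `mpe2`, `mpe3` (g/lactation) to a table of lactation
#' records:
#' \deqn{MPE1 = 299 + 2.73 \cdot MY}
#' \deqn{MPE2 = 259 + 3.86 \cdot ECM}
#' \deqn{MPE3 = 150 + 4.31 \cdot ECM + 28.3 \cdot CPC}
#' Equations are applied to per-lactation totals.
#'
#' @param records data frame with columns `milk`, `fat`, `protein`
#'   (kg/lactation).
#' @return `records` with columns `ecm`, `cpc`, `mpe1`, `mpe2`, `mpe3`
#'   appended (recomputed if already present).
#' @export
predict_methane <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("milk", "fat", "protein")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  eq <- methane_equations()
  records$ecm <- ecm(records$milk, records$fat, records$protein)
  records$cpc <- cpc(records$milk, records$protein)
  records$mpe1 <- eq$intercept[1] + eq$slope1[1] * records$milk
  records$mpe2 <- eq$intercept[2] + eq$slope1[2] * records$ecm
  records$mpe3 <- eq$intercept[3] + eq$slope1[3] * records$ecm +
    eq$slope2[3] * records$cpc
  records
}

#' Convert a per-lactation total to a per-day rate
#'
#' @param total per-lactation quantity (e.g. g methane/lactation).
#' @param days lactation length in days (positive).
#' @return `total / days`.
#' @export
per_day <- function(total, days) {
  if (any(days <= 0, na.rm = TRUE)) stop("days must be positive")
  total / days
}

#' Validate lactation records
#'
#' Checks the structural invariants of a lactation phenotype table: positive
#' yields, component yields consistent with dry matter and milk
#' (`fat + protein + lactose <= dry_matter <= milk`), lactation length within
#' `[200, 400]` days and parity within 1--6.
#'
#' @param records data frame of lactation records.
#' @param tol relative slack on the yield-ordering checks.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_records <- function(records, tol = 1e-8) {
  need <- c("cow", "parity", "milk", "fat", "protein", "lactose",
            "dry_matter", "lactation_length")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  yld <- c("milk", "fat", "protein", "lactose", "dry_matter")
  for (v in yld)
    if (any(records[[v]] <= 0)) stop("non-positive ", v, " yield")
  comp <- records$fat + records$protein + records$lactose
  if (any(comp > records$dry_matter * (1 + tol)))
    stop("fat + protein + lactose exceeds dry matter for some records")
  if (any(records$dry_matter > records$milk * (1 + tol)))
    stop("dry matter exceeds milk yield for some records")
  ll <- records$lactation_length
  if (any(ll < 200 | ll > 400))
    stop("lactation length outside [200, 400] days")
  p <- as.integer(as.character(records$parity))
  if (any(is.na(p) | p < 1 | p > 6)) stop("parity outside 1-6")
  invisible(TRUE)
}
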