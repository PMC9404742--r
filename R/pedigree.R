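#' Construct a validated, topologically sorted pedigree
#'
#' A pedigree is a data frame with character columns `animal`, `sire`, `dam`
#' (`NA` = unknown parent), sorted so that every known parent appears before
#' its offspring.  Animals referenced only as parents are inserted as
#' founders.  Sorting is by generation level with stable tie-breaking by
#' input order, so the result is deterministic.
#'
#' @param x data frame with columns `animal`, `sire`, `dam` (coerced to
#'   character).
#' @param missing_parent character vector of tokens that mark an unknown
#'   parent (in addition to `NA`).
#' @return An object of class `pedigree`: the sorted data frame with integer
#'   columns `si`, `di` (parent row indices, 0 = unknown) and `gen`
#'   (generation index: 0 for founders, otherwise 1 + max parent generation).
#' @examples
#' ped <- pedigree(data.frame(animal = c("C", "A", "B"),
#'                            sire = c("A", NA, NA),
#'                            dam = c("B", NA, NA)))
#' ped$animal  # founders first
#' @export
pedigree <- function(x, missing_parent = c("0", "")) {
  x <- as.data.frame(x)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(x)))
    stop("pedigree needs columns 'animal', 'sire', 'dam'")
  x <- x[, need]
  for (v in need) {
    x[[v]] <- trimws(as.character(x[[v]]))
    x[[v]][x[[v]] %in% missing_parent | is.na(x[[v]])] <- NA_character_
  }
  if (anyNA(x$animal) || any(!nzchar(x$animal)))
    stop("animal identifiers must be non-empty")
  if (anyDuplicated(x$animal))
    stop("duplicate animal id: ", x$animal[duplicated(x$animal)][1])
  self <- !is.na(x$sire) & x$sire == x$animal |
          !is.na(x$dam)  & x$dam  == x$animal
  if (any(self))
    stop("cycle detected: animal '", x$animal[self][1], "' is its own parent")

  ## insert parents never listed as animals, as founders (input order)
  parents <- unique(c(x$sire, x$dam))
  extra <- setdiff(parents[!is.na(parents)], x$animal)
  if (length(extra))
    x <- rbind(data.frame(animal = extra, sire = NA_character_,
                          dam = NA_character_, stringsAsFactors = FALSE), x)

  n <- nrow(x)
  si <- match(x$sire, x$animal)
  di <- match(x$dam, x$animal)
  placed <- logical(n)
  ord <- integer(0)
  gen <- integer(n)
  level <- 0L
  while (length(ord) < n) {
    ok_s <- is.na(si); ok_s[!ok_s] <- placed[si[!ok_s]]
    ok_d <- is.na(di); ok_d[!ok_d] <- placed[di[!ok_d]]
    avail <- which(!placed & ok_s & ok_d)
    if (!length(avail)) {
      stop("cycle detected involving animal '",
           .name_cycle_animal(x$animal, si, di, placed), "'")
    }
    ord <- c(ord, avail)
    placed[avail] <- TRUE
    gen[avail] <- level
    level <- level + 1L
  }
  out <- x[ord, , drop = FALSE]
  rownames(out) <- NULL
  out$si <- match(out$sire, out$animal)
  out$di <- match(out$dam, out$animal)
  out$si[is.na(out$si)] <- 0L
  out$di[is.na(out$di)] <- 0L
  out$gen <- gen[ord]
  class(out) <- c("pedigree", "data.frame")
  out
}

## walk parent links among unplaced animals until one repeats
.name_cycle_animal <- function(animal, si, di, placed) {
  cur <- which(!placed)[1]
  seen <- integer(0)
  repeat {
    if (cur %in% seen) return(animal[cur])
    seen <- c(seen, cur)
    nxt <- c(si[cur], di[cur])
    nxt <- nxt[!is.na(nxt) & !placed[nxt]]
    if (!length(nxt)) return(animal[cur])  # defensive; should not happen
    cur <- nxt[1]
  }
}

#' Read a pedigree from CSV
#'
#' The file must have a header with columns `animal,sire,dam`.  Unknown
#' parents are encoded by a configurable token (default `"0"` or empty).
#'
#' @param path path to a CSV file.
#' @inheritParams pedigree
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path, missing_parent = c("0", "")) {
  df <- utils::read.csv(path, colClasses = "character")
  pedigree(df, missing_parent = missing_parent)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "animals,",
      sum(x$si == 0L & x$di == 0L), "founders, max generation", max(x$gen),
      "\n")
  invisible(x)
}

#' Prune a pedigree to a fixed number of ancestral generations
#'
#' Keeps the focal animals and every ancestor reachable within `g`
#' parent-links; parents of retained animals that fall outside the cut are
#' set to unknown.  One parent-link counts one generation.
#'
#' @param ped a [pedigree].
#' @param focal character vector of focal animal ids (non-empty subset of
#'   `ped$animal`).
#' @param g number of ancestral generations to retain (default 6).
#' @return A [pedigree] containing the retained animals in their original
#'   topological order.
#' @export
prune_generations <- function(ped, focal, g = 6) {
  stopifnot(is(ped, "pedigree"), g >= 0)
  focal <- unique(as.character(focal))
  if (!length(focal)) stop("empty focal set")
  miss <- setdiff(focal, ped$animal)
  if (length(miss)) stop("focal animals not in pedigree: ", miss[1])
  keep <- match(focal, ped$animal)
  frontier <- keep
  depth <- 0L
  while (depth < g && length(frontier)) {
    par <- c(ped$si[frontier], ped$di[frontier])
    par <- setdiff(par[par > 0L], keep)
    keep <- c(keep, par)
    frontier <- par
    depth <- depth + 1L
  }
  keep <- sort(keep)
  out <- ped[keep, c("animal", "sire", "dam"), drop = FALSE]
  out$sire[!(out$sire %in% out$animal)] <- NA_character_
  out$dam[!(out$dam %in% out$animal)] <- NA_character_
  pedigree(out)
}

#' Inbreeding coefficients
#'
#' Meuwissen--Luo algorithm; unknown parents are unrelated, non-inbred base
#' animals.
#'
#' @param ped a [pedigree].
#' @return Named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) {
  stopifnot(is(ped, "pedigree"))
  ml <- ml_inbreeding(ped$si, ped$di)
  stats::setNames(ml$F, ped$animal)
}

#' Numerator relationship matrix A (dense, tabular method)
#'
#' Recursive tabular construction: `a_ii = 1 + a_{s,d}/2`,
#' `a_ij = (a_{j,s} + a_{j,d})/2`; unknown parents contribute 0.  Intended
#' for moderate pedigrees (tests, small analyses); the mixed-model equations
#' use [build_nrm_inverse()] and never form A densely.
#'
#' @param ped a [pedigree].
#' @return Dense symmetric matrix with dimnames = animal ids and attribute
#'   `"inbreeding"` (`F_i = a_ii - 1`).
#' @export
build_nrm <- function(ped) {
  stopifnot(is(ped, "pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- ped$si[i]; d <- ped$di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  attr(A, "inbreeding") <- stats::setNames(diag(A) - 1, ped$animal)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding-corrected diagonals from the
#' Meuwissen--Luo d coefficients; never forms A densely, so it scales to
#' large pedigrees.
#'
#' @param ped a [pedigree].
#' @return Sparse symmetric matrix (`dsCMatrix`) with attribute
#'   `"logdet_A"` = log determinant of A (used by the REML likelihood).
#' @export
build_nrm_inverse <- function(ped) {
  stopifnot(is(ped, "pedigree"))
  n <- nrow(ped)
  ml <- ml_inbreeding(ped$si, ped$di)
  alpha <- 1 / ml$d
  ii <- jj <- xx <- vector("list", n)
  for (i in seq_len(n)) {
    s <- ped$si[i]; d <- ped$di[i]; a <- alpha[i]
    ri <- i; ci <- i; vi <- a
    if (s > 0L) {
      ri <- c(ri, i, s, s); ci <- c(ci, s, i, s)
      vi <- c(vi, -a / 2, -a / 2, a / 4)
    }
    if (d > 0L) {
      ri <- c(ri, i, d, d); ci <- c(ci, d, i, d)
      vi <- c(vi, -a / 2, -a / 2, a / 4)
    }
    if (s > 0L && d > 0L) {
      ri <- c(ri, s, d); ci <- c(ci, d, s)
      vi <- c(vi, a / 4, a / 4)
    }
    ii[[i]] <- ri; jj[[i]] <- ci; xx[[i]] <- vi
  }
  Ainv <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                               x = unlist(xx), dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Ainv <- as(Matrix::forceSymmetric(Ainv), "CsparseMatrix")
  attr(Ainv, "logdet_A") <- sum(log(ml$d))
  Ainv
}
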