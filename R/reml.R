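## REML for the (multi-trait) repeatability animal model
##   y = Xb + Za + Wpe + e,  V(a) = G_a (x) A,  V(pe) = G_pe (x) I,
##   V(e) = R0 (x) I,
## estimated by EM steps on Henderson's sparse mixed-model equations with
## average-information (AI) acceleration; an AI step is accepted only when it
## does not decrease the REML log-likelihood, otherwise the EM step is taken.
## All traces of the inverse coefficient matrix come from a Takahashi
## selected inverse of the sparse Cholesky factor.

.vech_pairs <- function(t) {
  which(lower.tri(diag(t), diag = TRUE), arr.ind = TRUE)
}

.theta_to_vec <- function(b) {
  t <- ncol(b$Ga)
  pr <- .vech_pairs(t)
  unlist(lapply(b[c("Ga", "Gpe", "R0")],
                function(M) M[pr]))
}

.vec_to_theta <- function(v, t) {
  pr <- .vech_pairs(t)
  np <- nrow(pr)
  mk <- function(x) {
    M <- matrix(0, t, t)
    M[pr] <- x
    M[pr[, 2:1, drop = FALSE]] <- x
    M
  }
  list(Ga = mk(v[1:np]), Gpe = mk(v[np + 1:np]), R0 = mk(v[2 * np + 1:np]))
}

.theta_names <- function(traits) {
  t <- length(traits)
  if (t == 1) return(c("sigma2_a", "sigma2_pe", "sigma2_e"))
  pr <- .vech_pairs(t)
  mk <- function(tag) paste0(tag, "_", traits[pr[, 1]], ".", traits[pr[, 2]])
  c(mk("a"), mk("pe"), mk("e"))
}

## floor diagonals, clamp block correlations, project to the PSD cone
.sanitize_block <- function(B, floor_diag, max_cor = 0.9995) {
  B <- (B + t(B)) / 2
  d <- pmax(diag(B), floor_diag)
  t <- ncol(B)
  if (t == 1) return(matrix(d, 1, 1))
  s <- sqrt(d)
  R <- B / tcrossprod(s)
  diag(R) <- 1
  off <- row(R) != col(R)
  R[off] <- pmin(pmax(R[off], -max_cor), max_cor)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-10) {
    R <- ev$vectors %*% diag(pmax(ev$values, 1e-8), t) %*% t(ev$vectors)
    R <- R / tcrossprod(sqrt(diag(R)))
  }
  tcrossprod(s) * R
}

.sanitize_theta <- function(b, floors, max_cor = 0.9995) {
  list(Ga  = .sanitize_block(b$Ga,  floors, max_cor),
       Gpe = .sanitize_block(b$Gpe, floors, max_cor),
       R0  = .sanitize_block(b$R0,  floors, max_cor))
}

.reml_engine <- function(X, Z, W, Y, Ainv, logdetA, start = NULL,
                         method = c("ai", "em"), maxit = 500,
                         tol_logl = 1e-6, tol_theta = 1e-8,
                         floor_frac = 1e-8, warmup = 2L, verbose = FALSE) {
  method <- match.arg(method)
  Y <- as.matrix(Y)
  n <- nrow(Y); t <- ncol(Y)
  p <- ncol(X); q <- ncol(Z); nc <- ncol(W)
  stopifnot(nrow(X) == n, nrow(Z) == n, nrow(W) == n, nrow(Ainv) == q)
  D <- p + q + nc
  tD <- t * D
  pr <- .vech_pairs(t)
  np <- nrow(pr)
  n_params <- 3L * np

  phenvar <- apply(Y, 2, stats::var)
  floors <- floor_frac * phenvar

  M <- cbind(X, Z, W)
  MtM <- Matrix::crossprod(M)
  MtY <- as.matrix(Matrix::crossprod(M, Y))
  YtY <- crossprod(Y)

  ## full (both-triangle) triplets of the symmetric building blocks
  gt <- function(S) {
    Tm <- as(as(S, "generalMatrix"), "TsparseMatrix")
    list(i = Tm@i + 1L, j = Tm@j + 1L, x = Tm@x)
  }
  mtm <- gt(MtM)
  ain <- gt(Ainv)
  off_u <- p
  off_pe <- p + q

  ## coefficient-matrix template: rows, cols, base values and which scalar
  ## coefficient (entry of R0^-1, Ga^-1, Gpe^-1) multiplies each entry
  ri <- ci <- xi <- ki <- vector("list", 3 * t * t)
  m <- 0L
  for (l in seq_len(t)) for (k in seq_len(t)) {
    sh_k <- (k - 1L) * D; sh_l <- (l - 1L) * D
    cid <- (l - 1L) * t + k
    m <- m + 1L
    ri[[m]] <- mtm$i + sh_k; ci[[m]] <- mtm$j + sh_l
    xi[[m]] <- mtm$x; ki[[m]] <- rep.int(cid, length(mtm$x))
    m <- m + 1L
    ri[[m]] <- ain$i + sh_k + off_u; ci[[m]] <- ain$j + sh_l + off_u
    xi[[m]] <- ain$x; ki[[m]] <- rep.int(t * t + cid, length(ain$x))
    m <- m + 1L
    ri[[m]] <- seq_len(nc) + sh_k + off_pe; ci[[m]] <- seq_len(nc) + sh_l + off_pe
    xi[[m]] <- rep.int(1, nc); ki[[m]] <- rep.int(2L * t * t + cid, nc)
  }
  Cri <- unlist(ri); Cci <- unlist(ci)
  Cxb <- unlist(xi); Ckid <- unlist(ki)

  assemble_C <- function(R0i, Gai, Gpei) {
    coefs <- c(as.vector(R0i), as.vector(Gai), as.vector(Gpei))
    Matrix::sparseMatrix(i = Cri, j = Cci, x = Cxb * coefs[Ckid],
                         dims = c(tD, tD))
  }

  ## symbolic analysis on the union pattern (made diagonally dominant)
  Cpat <- Matrix::sparseMatrix(i = Cri, j = Cci, x = abs(Cxb) + 1,
                               dims = c(tD, tD))
  Cpd <- Cpat + Matrix::Diagonal(tD, Matrix::rowSums(abs(Cpat)) + 1)
  ChS <- Matrix::Cholesky(Matrix::forceSymmetric(Cpd), LDL = FALSE,
                          super = FALSE, perm = TRUE)
  perm <- ChS@perm + 1L
  invp <- integer(tD); invp[perm] <- seq_len(tD)
  L0 <- as(ChS, "CsparseMatrix")
  Lp <- L0@p; Li <- L0@i

  pos_of <- function(I, J) {
    pi <- invp[I]; pj <- invp[J]
    r <- pmax(pi, pj) - 1L; c <- pmin(pi, pj) - 1L
    pos <- pattern_positions(Lp, Li, r, c)
    if (any(pos == 0L)) stop("internal: trace entry outside factor pattern")
    pos
  }

  ## index/weight sets for the selected-inverse traces, per trait pair
  tr_idx <- list(uu = list(), pp = list(), mm = list())
  for (a in seq_len(np)) {
    k <- pr[a, 1]; l <- pr[a, 2]
    key <- paste(k, l)
    tr_idx$uu[[key]] <- list(
      pos = pos_of((k - 1L) * D + off_u + ain$i, (l - 1L) * D + off_u + ain$j),
      w = ain$x)
    tr_idx$pp[[key]] <- list(
      pos = pos_of((k - 1L) * D + off_pe + seq_len(nc),
                   (l - 1L) * D + off_pe + seq_len(nc)),
      w = rep.int(1, nc))
    tr_idx$mm[[key]] <- list(
      pos = pos_of((k - 1L) * D + mtm$i, (l - 1L) * D + mtm$j),
      w = mtm$x)
  }
  trace_mat <- function(Sx, which) {
    Tm <- matrix(0, t, t)
    for (a in seq_len(np)) {
      k <- pr[a, 1]; l <- pr[a, 2]
      e <- tr_idx[[which]][[paste(k, l)]]
      Tm[k, l] <- Tm[l, k] <- sum(Sx[e$pos] * e$w)
    }
    Tm
  }

  ldet <- function(M2) as.numeric(determinant(M2, logarithm = TRUE)$modulus)

  Ebasis <- lapply(seq_len(np), function(a) {
    E <- matrix(0, t, t)
    E[pr[a, 1], pr[a, 2]] <- E[pr[a, 2], pr[a, 1]] <- 1
    E
  })

  eval_theta <- function(b) {
    R0i <- solve(b$R0); Gai <- solve(b$Ga); Gpei <- solve(b$Gpe)
    C <- assemble_C(R0i, Gai, Gpei)
    Ch <- Matrix::update(ChS, Matrix::forceSymmetric(C), mult = 0)
    L <- as(Ch, "CsparseMatrix")
    rhs <- MtY %*% R0i
    sol <- matrix(as.vector(Matrix::solve(Ch, as.vector(rhs), system = "A")),
                  D, t)
    fit <- as.matrix(M %*% sol)
    E <- Y - fit
    yRy <- sum(R0i * YtY)
    sPr <- sum(sol * rhs)
    ldiag <- L@x[L@p[seq_len(tD)] + 1L]
    logdetC <- 2 * sum(log(ldiag))
    logL <- -0.5 * (n * ldet(b$R0) + q * ldet(b$Ga) + t * logdetA +
                    nc * ldet(b$Gpe) + logdetC + yRy - sPr +
                    (n - p) * t * log(2 * pi))

    Sx <- takahashi_selinv(L@p, L@i, L@x, tD)
    Tuu <- trace_mat(Sx, "uu")
    Tpp <- trace_mat(Sx, "pp")
    TM  <- trace_mat(Sx, "mm")

    Umat <- sol[off_u + seq_len(q), , drop = FALSE]
    Pmat <- sol[off_pe + seq_len(nc), , drop = FALSE]
    AinvU <- as.matrix(Ainv %*% Umat)
    Uq <- crossprod(Umat, AinvU)
    Pq <- crossprod(Pmat)
    Eq <- crossprod(E)

    ## score vector
    grad <- numeric(n_params)
    for (a in seq_len(np)) {
      Eij <- Ebasis[[a]]
      H <- Gai %*% Eij %*% Gai
      grad[a] <- -0.5 * (sum(H * (q * b$Ga - Tuu)) - sum(H * Uq))
      H <- Gpei %*% Eij %*% Gpei
      grad[np + a] <- -0.5 * (sum(H * (nc * b$Gpe - Tpp)) - sum(H * Pq))
      H <- R0i %*% Eij %*% R0i
      grad[2 * np + a] <- -0.5 * ((n * sum(R0i * Eij) - sum(H * TM)) -
                                  sum(H * Eq))
    }

    ## average-information matrix
    Flist <- vector("list", n_params)
    for (a in seq_len(np)) {
      Eij <- Ebasis[[a]]
      Flist[[a]] <- as.matrix(Z %*% (Umat %*% t(Eij %*% Gai)))
      Flist[[np + a]] <- as.matrix(W %*% (Pmat %*% t(Eij %*% Gpei)))
      Flist[[2 * np + a]] <- E %*% t(Eij %*% R0i)
    }
    RHSF <- vapply(Flist,
                   function(Fm) as.vector(Matrix::crossprod(M, Fm %*% R0i)),
                   numeric(tD))
    SOLF <- as.matrix(Matrix::solve(Ch, RHSF, system = "A"))
    PFlist <- vector("list", n_params)
    for (m2 in seq_len(n_params)) {
      sm <- matrix(SOLF[, m2], D, t)
      PFlist[[m2]] <- (Flist[[m2]] - as.matrix(M %*% sm)) %*% R0i
    }
    AI <- matrix(0, n_params, n_params)
    for (a in seq_len(n_params)) for (bb in a:n_params) {
      AI[a, bb] <- AI[bb, a] <- 0.5 * sum(Flist[[a]] * PFlist[[bb]])
    }

    list(theta = b, logL = logL, sol = sol, E = E, Uq = Uq, Pq = Pq, Eq = Eq,
         Tuu = Tuu, Tpp = Tpp, TM = TM, grad = grad, AI = AI,
         Umat = Umat, Pmat = Pmat, fitted = fit)
  }

  em_update <- function(st) {
    list(Ga  = (st$Uq + st$Tuu) / q,
         Gpe = (st$Pq + st$Tpp) / nc,
         R0  = (st$Eq + st$TM) / n)
  }

  ## starting values
  if (is.null(start)) {
    s <- sqrt(phenvar)
    Rst <- if (t > 1) {
      cc <- stats::cor(Y)
      diag(t) + 0.5 * (cc - diag(diag(cc)))
    } else diag(1)
    base <- tcrossprod(s) * Rst
    start <- list(Ga = 0.30 * base, Gpe = 0.20 * base, R0 = 0.50 * base)
  }
  if (!is.list(start)) {  # univariate numeric start c(a, pe, e)
    start <- list(Ga = matrix(start[1], 1, 1), Gpe = matrix(start[2], 1, 1),
                  R0 = matrix(start[3], 1, 1))
  }
  theta <- .sanitize_theta(start, floors)

  ## parameters pinned at the variance floor or the correlation clamp are
  ## frozen out of the AI step (the AI quadratic is unreliable on the
  ## boundary); EM and the sanitizer keep them there
  pinned <- function(b) {
    out <- logical(n_params)
    blocks <- list(b$Ga, b$Gpe, b$R0)
    for (bi in 1:3) for (a in seq_len(np)) {
      i <- pr[a, 1]; j <- pr[a, 2]
      B <- blocks[[bi]]
      idx <- (bi - 1L) * np + a
      out[idx] <- if (i == j) {
        B[i, i] <= 2 * floors[i]
      } else {
        B[i, i] <= 2 * floors[i] || B[j, j] <= 2 * floors[j] ||
          abs(B[i, j]) >= 0.999 * sqrt(B[i, i] * B[j, j]) * (1 - 1e-9)
      }
    }
    out
  }

  st <- eval_theta(theta)
  trace <- data.frame(iter = 0L, step = "start", logL = st$logL)
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(maxit)) {
    iter <- it
    old <- st
    stepped <- FALSE
    if (method == "ai" && it > warmup) {
      thv <- .theta_to_vec(st$theta)
      act <- !pinned(st$theta)
      delta <- if (any(act)) tryCatch({
        d <- numeric(n_params)
        d[act] <- solve(st$AI[act, act, drop = FALSE], st$grad[act])
        d
      }, error = function(e) NULL) else NULL
      if (!is.null(delta) && all(is.finite(delta))) {
        for (frac in c(1, 0.5, 0.25, 0.1)) {  # step-halving on rejection
          cand <- .sanitize_theta(.vec_to_theta(thv + frac * delta, t),
                                  floors)
          stA <- tryCatch(eval_theta(cand), error = function(e) NULL)
          if (!is.null(stA) && is.finite(stA$logL) &&
              stA$logL >= st$logL - 1e-8 * (1 + abs(st$logL))) {
            st <- stA; step <- "AI"; stepped <- TRUE
            break
          }
        }
      }
    }
    if (!stepped) {
      cand <- .sanitize_theta(em_update(st), floors)
      st <- eval_theta(cand)
      step <- "EM"
    }
    trace <- rbind(trace, data.frame(iter = it, step = step, logL = st$logL))
    if (verbose)
      message(sprintf("it %3d [%s] logL = %.6f", it, step, st$logL))
    dl <- st$logL - old$logL
    relch <- max(abs(.theta_to_vec(st$theta) - .theta_to_vec(old$theta)) /
                 pmax(abs(.theta_to_vec(old$theta)), mean(floors)))
    if (abs(dl) < tol_logl || relch < tol_theta) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge in ", maxit, " iterations")

  theta_cov <- tryCatch(solve(st$AI), error = function(e) {
    matrix(NA_real_, n_params, n_params)
  })
  se_theta <- sqrt(pmax(diag(theta_cov), 0))

  list(Ga = st$theta$Ga, Gpe = st$theta$Gpe, R0 = st$theta$R0,
       theta = .theta_to_vec(st$theta), theta_cov = theta_cov,
       se_theta = se_theta, logL = st$logL,
       n_params = n_params, aic = -2 * st$logL + 2 * n_params,
       converged = converged, iterations = iter, trace = trace,
       fixef = st$sol[seq_len(p), , drop = FALSE],
       u = st$Umat, pe = st$Pmat,
       fitted = st$fitted, residuals = st$E,
       grad = st$grad, AI = st$AI,
       dims = list(n = n, t = t, p = p, q = q, n_cows = nc),
       floors = floors, method = method)
}

#' Akaike information criterion from a REML log-likelihood
#'
#' `AIC = -2 logL + 2 k`, with `k` the number of estimated (co)variance
#' parameters (REML convention; fixed-effect structure held constant).
#'
#' @param logL REML log-likelihood.
#' @param n_params number of estimated (co)variance parameters (>= 1).
#' @return Numeric AIC.
#' @export
aic <- function(logL, n_params) {
  stopifnot(n_params >= 1)
  -2 * logL + 2 * n_params
}
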