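# Restricted maximum likelihood for linear mixed models with one structured
# random term u ~ N(0, Sigma0 (x) A), where Sigma0 is an unstructured k x k
# coefficient covariance and A a (pedigree) relationship structure given by its
# sparse inverse (identity when Ainv is NULL). The residual is either iid
# (sigma2e I) or an unstructured n_traits x n_traits covariance applied
# per unit (animal), with units allowed to miss traits.
#
# Variance parameters are updated by Newton steps using the average-information
# matrix; the score is evaluated by central differences of the exact REML
# log-likelihood, and out-of-bounds proposals are handled by step-halving with
# clamping to the admissible region. The REML log-likelihood is computed from
# the mixed-model equations via the identity
#   log|V| + log|X'V^-1 X| = log|R| + log|G| + log|C|,
# with C the full MME coefficient matrix factored by sparse Cholesky.

# resid spec constructors -----------------------------------------------------

resid_iid <- function() list(type = "iid")

resid_unstructured <- function(unit, trait, n_traits) {
  list(type = "unstructured", unit = unit, trait = trait, n_traits = n_traits)
}

# main engine ------------------------------------------------------------------

reml_ai <- function(y, X, Z, q, k, Ainv = NULL, logdet_A = 0,
                    resid = resid_iid(), start = NULL,
                    max_iter = 200L, tol_loglik = 1e-8, tol_param = 1e-6,
                    verbose = FALSE) {
  n <- length(y)
  X <- as(X, "CsparseMatrix"); Z <- as(Z, "CsparseMatrix")
  if (nrow(X) != n || nrow(Z) != n) abort("design matrices do not match y.")
  if (ncol(Z) != k * q) abort("Z must have k * q columns.")
  p <- ncol(X)
  W <- cbind(X, Z)
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) abort("response has no variance.")
  Aq <- if (is.null(Ainv)) Matrix::Diagonal(q) else Ainv
  nS <- k * (k + 1L) / 2L
  pairsS <- vech_pairs(k)

  iid <- identical(resid$type, "iid")
  if (iid) {
    nt <- 1L
    nR <- 1L
    WtW <- Matrix::crossprod(W)
    Wty <- as.numeric(Matrix::crossprod(W, y))
    yty <- sum(y^2)
    rstruct <- NULL
  } else {
    nt <- resid$n_traits
    nR <- nt * (nt + 1L) / 2L
    pairsR <- vech_pairs(nt)
    rstruct <- build_resid_struct(resid$unit, resid$trait, nt, n)
  }
  npar <- nS + nR

  # parameter vector: vech(Sigma0) then residual (sigma2e or vech(R0))
  theta <- start %||% c(vech(diag(0.5 * vy / k, k)),
                        if (iid) 0.5 * vy else vech(diag(0.5 * vy, nt)))
  floor_v <- 1e-8 * vy

  split_theta <- function(th) {
    S0 <- unvech(th[seq_len(nS)], k)
    r <- th[nS + seq_len(nR)]
    R0 <- if (iid) r else unvech(r, nt)
    list(S0 = S0, R0 = R0)
  }

  project <- function(th) {
    pp <- split_theta(th)
    S0 <- clamp_cov(pp$S0, floor_v)
    R0 <- if (iid) max(pp$R0, floor_v) else clamp_cov(pp$R0, floor_v)
    c(vech(S0), if (iid) R0 else vech(R0))
  }

  # residual pieces for a given R0 (unstructured case)
  resid_pieces <- function(R0) {
    tri <- list(i = integer(0), j = integer(0), x = numeric(0))
    logdetR <- 0
    for (ps in rstruct$patterns) {
      S <- ps$traits
      Rs <- R0[S, S, drop = FALSE]
      dt <- det(Rs)
      if (!is.finite(dt) || dt <= 0) return(NULL)
      B <- solve(Rs)
      logdetR <- logdetR + nrow(ps$recs) * log(dt)
      for (a in seq_along(S)) for (b in seq_along(S)) {
        tri$i <- c(tri$i, ps$recs[, a]); tri$j <- c(tri$j, ps$recs[, b])
        tri$x <- c(tri$x, rep(B[a, b], nrow(ps$recs)))
      }
    }
    Rinv <- Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x, dims = c(n, n))
    list(Rinv = Rinv, logdetR = logdetR)
  }

  # returns NULL if inadmissible; otherwise list with loglik and solve pieces
  evaluate <- function(th, need_solution = FALSE) {
    pp <- split_theta(th)
    S0 <- pp$S0
    chS <- tryCatch(chol(S0), error = function(e) NULL)
    if (is.null(chS)) return(NULL)
    logdetS0 <- 2 * sum(log(diag(chS)))
    S0inv <- chol2inv(chS)
    Gaug <- Matrix::bdiag(Matrix::Matrix(0, p, p), Matrix::kronecker(S0inv, Aq))
    if (iid) {
      s2e <- pp$R0
      if (s2e <= 0) return(NULL)
      Cmat <- Matrix::forceSymmetric(WtW / s2e + Gaug)
      rhs <- Wty / s2e
      yry <- yty / s2e
      logdetR <- n * log(s2e)
      Rinv <- NULL
    } else {
      R0 <- pp$R0
      chR <- tryCatch(chol(R0), error = function(e) NULL)
      if (is.null(chR)) return(NULL)
      rp <- resid_pieces(R0)
      if (is.null(rp)) return(NULL)
      Rinv <- rp$Rinv
      logdetR <- rp$logdetR
      RW <- Rinv %*% W
      Cmat <- Matrix::forceSymmetric(Matrix::crossprod(W, RW) + Gaug)
      rhs <- as.numeric(Matrix::crossprod(W, Rinv %*% y))
      yry <- sum(y * as.numeric(Rinv %*% y))
    }
    ch <- tryCatch(Matrix::Cholesky(Cmat, LDL = FALSE, perm = TRUE),
                   error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    logdetC <- as.numeric(Matrix::determinant(ch, logarithm = TRUE, sqrt = FALSE)$modulus)
    sol <- as.numeric(Matrix::solve(ch, rhs, system = "A"))
    yPy <- yry - sum(rhs * sol)
    logdetG <- q * logdetS0 + k * logdet_A
    m2l <- (n - p) * log(2 * pi) + logdetR + logdetG + logdetC + yPy
    out <- list(loglik = -0.5 * m2l, theta = th, S0 = S0, R0 = pp$R0,
                S0inv = S0inv)
    if (need_solution) {
      out$ch <- ch; out$sol <- sol; out$Rinv <- Rinv
    }
    out
  }

  loglik_of <- function(th) {
    ev <- evaluate(th)
    if (is.null(ev)) NA_real_ else ev$loglik
  }

  fd_gradient <- function(th, l0) {
    g <- numeric(npar)
    for (j in seq_len(npar)) {
      h <- 1e-4 * (abs(th[j]) + 1e-3 * vy)
      up <- th; up[j] <- up[j] + h
      dn <- th; dn[j] <- dn[j] - h
      lu <- loglik_of(up); ld <- loglik_of(dn)
      g[j] <- if (is.finite(lu) && is.finite(ld)) (lu - ld) / (2 * h)
      else if (is.finite(lu)) (lu - l0) / h
      else if (is.finite(ld)) (l0 - ld) / h
      else 0
    }
    g
  }

  ai_matrix <- function(ev) {
    # working residual and BLUP solutions at the current parameters
    fit <- as.numeric(W %*% ev$sol)
    e <- y - fit
    Py <- if (iid) e / ev$R0 else as.numeric(ev$Rinv %*% e)
    u <- ev$sol[p + seq_len(k * q)]
    U <- matrix(u, q, k)
    T0 <- U %*% ev$S0inv
    Fmat <- matrix(0, n, npar)
    for (m in seq_len(nS)) {
      i <- pairsS[m, 1L]; j <- pairsS[m, 2L]
      E <- matrix(0, k, k); E[i, j] <- 1; E[j, i] <- 1
      Fmat[, m] <- as.numeric(Z %*% as.numeric(T0 %*% E))
    }
    if (iid) {
      Fmat[, nS + 1L] <- Py
    } else {
      for (m in seq_len(nR)) {
        i <- pairsR[m, 1L]; j <- pairsR[m, 2L]
        E <- matrix(0, nt, nt); E[i, j] <- 1; E[j, i] <- 1
        f <- numeric(n)
        for (ps in rstruct$patterns) {
          S <- ps$traits
          PyM <- matrix(Py[ps$recs], nrow(ps$recs), length(S))
          f[ps$recs] <- PyM %*% E[S, S, drop = FALSE]
        }
        Fmat[, nS + m] <- f
      }
    }
    RF <- if (iid) Fmat / ev$R0 else as.matrix(ev$Rinv %*% Fmat)
    rhsF <- as.matrix(Matrix::crossprod(W, RF))
    solF <- as.matrix(Matrix::solve(ev$ch, rhsF, system = "A"))
    PF <- RF - (if (iid) as.matrix(W %*% solF) / ev$R0
                else as.matrix(ev$Rinv %*% (W %*% solF)))
    AI <- 0.5 * crossprod(Fmat, PF)
    (AI + t(AI)) / 2
  }

  theta <- project(theta)
  ev <- evaluate(theta, need_solution = TRUE)
  if (is.null(ev)) abort("starting values are inadmissible.")
  trajectory <- ev$loglik
  converged <- FALSE
  iter <- 0L
  AI <- NULL
  stall <- 0L
  for (iter in seq_len(max_iter)) {
    g <- fd_gradient(theta, ev$loglik)
    AI <- ai_matrix(ev)
    delta <- tryCatch(solve(AI + diag(1e-10 * max(diag(AI)), npar), g),
                      error = function(e) g / max(diag(AI)))
    # cap the Newton step: a (near-)singular AI matrix can propose steps many
    # orders of magnitude beyond the parameter scale
    if (!all(is.finite(delta)) || max(abs(delta)) > 10 * vy) {
      delta <- if (all(is.finite(delta))) delta * (10 * vy / max(abs(delta)))
      else g * (0.1 * vy / max(abs(g), 1e-12))
    }
    try_direction <- function(dir) {
      step <- 1
      for (half in 1:30) {
        cand <- project(theta + step * dir)
        evc <- evaluate(cand, need_solution = TRUE)
        if (!is.null(evc) && is.finite(evc$loglik) &&
            evc$loglik >= ev$loglik - 1e-9 * (abs(ev$loglik) + 1)) {
          return(list(cand = cand, ev = evc))
        }
        step <- step / 2
      }
      NULL
    }
    acc <- try_direction(delta)
    if (is.null(acc)) {  # fall back to a scaled-gradient ascent direction
      acc <- try_direction(g * (0.1 * vy / max(abs(g), 1e-12)))
    }
    if (is.null(acc)) { converged <- TRUE; break }  # no admissible improvement left
    cand <- acc$cand; evc <- acc$ev
    dl <- evc$loglik - ev$loglik
    dpar <- max(abs(cand - theta) / (abs(theta) + 1e-3 * vy))
    theta <- cand; ev <- evc
    trajectory <- c(trajectory, ev$loglik)
    if (verbose) message(sprintf("iter %d loglik %.6f", iter, ev$loglik))
    small_dl <- abs(dl) < tol_loglik * (abs(ev$loglik) + 1)
    stall <- if (small_dl) stall + 1L else 0L
    # converged when both criteria hold, or when the likelihood has been flat
    # for several iterations (parameters drifting in a flat ridge/boundary)
    if ((small_dl && dpar < tol_param) || stall >= 3L) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf(
      "REML did not converge in %d iterations (log-likelihood trajectory: %s ...)",
      max_iter, paste(sprintf("%.4f", utils::tail(trajectory, 5)), collapse = ", ")))
  }
  AI <- ai_matrix(ev)
  acov <- tryCatch(solve(AI), error = function(e) MASS_ginv(AI))
  pp <- split_theta(theta)
  boundary <- any(diag(pp$S0) <= 2 * floor_v)
  list(
    theta = theta, Sigma0 = pp$S0, R0 = pp$R0, sigma2e = if (iid) pp$R0 else NULL,
    loglik = ev$loglik, iterations = iter, converged = converged,
    boundary = boundary, AI = AI, acov = acov, trajectory = trajectory,
    solution = ev$sol, n = n, p = p, q = q, k = k,
    fixed = ev$sol[seq_len(p)], u = matrix(ev$sol[p + seq_len(k * q)], q, k),
    npar_S = nS, npar_R = nR
  )
}

# Moore-Penrose fallback without extra dependencies
MASS_ginv <- function(M, tol = 1e-12) {
  s <- svd(M)
  pos <- s$d > tol * max(s$d)
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# clamp a symmetric covariance: variances floored, pairwise correlations
# bounded away from +-1 (full positive-definiteness is enforced by the
# likelihood evaluation itself)
clamp_cov <- function(M, floor_v, max_cor = 0.999) {
  kk <- nrow(M)
  for (i in seq_len(kk)) M[i, i] <- max(M[i, i], floor_v)
  for (i in seq_len(kk)) for (j in seq_len(kk)) {
    if (i == j) next
    lim <- max_cor * sqrt(M[i, i] * M[j, j])
    M[i, j] <- sign(M[i, j]) * min(abs(M[i, j]), lim)
  }
  (M + t(M)) / 2
}

# grouping structure for the unstructured residual: records split by unit,
# units grouped by their observed trait pattern
build_resid_struct <- function(unit, trait, nt, n) {
  if (length(unit) != n || length(trait) != n) abort("resid spec does not match y.")
  units <- split(seq_len(n), unit)
  for (ix in units) {
    if (anyDuplicated(trait[ix])) abort("a unit has duplicate records of one trait.")
  }
  key <- vapply(units, function(ix) paste(sort(trait[ix]), collapse = ","), "")
  patterns <- lapply(split(units, key), function(us) {
    S <- sort(unique(trait[us[[1L]]]))
    recs <- t(vapply(us, function(ix) ix[order(trait[ix])], integer(length(S))))
    if (length(S) == 1L) recs <- matrix(unlist(us), ncol = 1L)
    list(traits = S, recs = recs)
  })
  list(patterns = patterns)
}

# REML log-likelihood of the fixed-effects-only model (no random term), on the
# same constant scale as reml_ai, for likelihood-ratio tests of the animal
# effect
reml_null <- function(y, X, resid = resid_iid()) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (identical(resid$type, "iid")) {
    qrx <- qr(X)
    res <- qr.resid(qrx, y)
    rss <- sum(res^2)
    s2e <- rss / (n - p)
    ldXX <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
    m2l <- (n - p) * log(2 * pi) + (n - p) * log(s2e) + ldXX + (n - p)
    return(list(loglik = -0.5 * m2l, sigma2e = s2e))
  }
  nt <- resid$n_traits
  rstruct <- build_resid_struct(resid$unit, resid$trait, nt, n)
  vy <- stats::var(y)
  obj <- function(par) {
    R0 <- unvech(par, nt)
    ev <- tryCatch(eigen(R0, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) -1)
    if (min(ev) <= 1e-10 * vy) return(1e10)
    val <- null_m2l_unstr(y, X, R0, rstruct, n, p)
    if (!is.finite(val)) 1e10 else val
  }
  start <- vech(diag(vy, nt))
  opt <- stats::optim(start, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  list(loglik = -0.5 * opt$value, R0 = unvech(opt$par, nt))
}

null_m2l_unstr <- function(y, X, R0, rstruct, n, p) {
  tri_i <- integer(0); tri_j <- integer(0); tri_x <- numeric(0)
  logdetR <- 0
  for (ps in rstruct$patterns) {
    S <- ps$traits
    Rs <- R0[S, S, drop = FALSE]
    dt <- det(Rs)
    if (dt <= 0) return(NA_real_)
    B <- solve(Rs)
    logdetR <- logdetR + nrow(ps$recs) * log(dt)
    for (a in seq_along(S)) for (b in seq_along(S)) {
      tri_i <- c(tri_i, ps$recs[, a]); tri_j <- c(tri_j, ps$recs[, b])
      tri_x <- c(tri_x, rep(B[a, b], nrow(ps$recs)))
    }
  }
  Rinv <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x, dims = c(n, n))
  Xs <- as(X, "CsparseMatrix")
  XtRX <- as.matrix(Matrix::crossprod(Xs, Rinv %*% Xs))
  XtRy <- as.numeric(Matrix::crossprod(Xs, Rinv %*% y))
  b <- solve(XtRX, XtRy)
  yPy <- sum(y * as.numeric(Rinv %*% y)) - sum(XtRy * b)
  ldX <- as.numeric(determinant(XtRX, logarithm = TRUE)$modulus)
  (n - p) * log(2 * pi) + logdetR + ldX + yPy
}

# full-rank fixed-effects design from a one-sided formula; aliased columns
# (confounded levels) are dropped with a warning
build_fixed <- function(data, formula) {
  X <- stats::model.matrix(formula, data = data)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]]
    warn(sprintf("dropping %d confounded fixed-effect column(s): %s",
                 length(drop), paste(utils::head(drop, 5), collapse = ", ")))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  }
  X
}
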