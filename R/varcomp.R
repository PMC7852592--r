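# Restricted maximum likelihood with average-information (AI) updates for
# the univariate and bivariate (mixed record mode) animal models. Two
# computational routes share one update loop:
#   * dense: the phenotypic covariance V is built explicitly (small numbers
#     of observations, e.g. group records);
#   * mme: Henderson's equations are factorised sparsely; the trace terms of
#     the REML score are taken from a Takahashi partial inverse of the
#     factor, and the AI matrix from working vectors solved against the
#     factorisation.
# In both routes: score_i = -1/2 [ tr(P dV_i) - y'P dV_i P y ],
# AI_ij = 1/2 (dV_i P y)' P (dV_j P y), and the restricted log-likelihood is
# -1/2 [ log|V| + log|X'V^-1 X| + y'Py ] (constant omitted), evaluated in
# the MME route through log|V| + log|X'V^-1X| = log|C| + log|G| + log|R|.

#' Options for AI-REML
#'
#' @param maxit maximum number of iterations.
#' @param tolParam convergence threshold on the maximum relative parameter
#'   change between accepted iterations.
#' @param tolGrad convergence threshold on the score (gradient) norm.
#' @param floor lower bound at which variances are pinned.
#' @param denseLimit observation count up to which the dense covariance
#'   route is used.
#' @param verbose print iteration progress.
#' @return list of options
#' @export
remlOptions <- function(maxit = 200L, tolParam = 1e-8, tolGrad = 1e-6,
                        floor = 1e-8, denseLimit = 1500L, verbose = FALSE) {
  stopifnot(maxit > 0, tolParam > 0, tolGrad > 0, floor > 0)
  list(maxit = as.integer(maxit), tolParam = tolParam, tolGrad = tolGrad,
       floor = floor, denseLimit = as.integer(denseLimit), verbose = verbose)
}

# ---- parameter bookkeeping ------------------------------------------------

.remlParams <- function(sys) {
  nt <- sys$nt
  p <- list()
  for (e in names(sys$effects))
    for (t in seq_len(nt)) for (u in t:nt)
      p[[length(p) + 1L]] <- list(kind = "sigma", effect = e, t = t, u = u,
                                  name = sprintf("%s_%d_%d", e, t, u))
  for (t in seq_len(nt))
    p[[length(p) + 1L]] <- list(kind = "res", t = t,
                                name = sprintf("residual_%d", t))
  if (!is.null(sys$pairs) && nrow(sys$pairs) > 0)
    p[[length(p) + 1L]] <- list(kind = "rescov", name = "residual_1_2")
  p
}

.thetaToVC <- function(params, theta, nt) {
  m <- list(litter = matrix(0, nt, nt), pen = matrix(0, nt, nt),
            additive = matrix(0, nt, nt))
  res <- matrix(0, nt, nt)
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (p$kind == "sigma") {
      m[[p$effect]][p$t, p$u] <- m[[p$effect]][p$u, p$t] <- theta[i]
    } else if (p$kind == "res") {
      res[p$t, p$t] <- theta[i]
    } else res[1, 2] <- res[2, 1] <- theta[i]
  }
  new("VarianceComponents", pen = m$pen, litter = m$litter,
      additive = m$additive, residual = res)
}

.vcToTheta <- function(params, vc) {
  vapply(params, function(p) {
    if (p$kind == "sigma") .sigmaOf(vc, p$effect)[p$t, p$u]
    else if (p$kind == "res") vc@residual[p$t, p$t]
    else vc@residual[1, 2]
  }, numeric(1))
}

.startTheta <- function(params, sys) {
  nt <- sys$nt
  v <- vapply(seq_len(nt), function(t) {
    i <- sys$obsTrait == t
    var(sys$y[i] / sys$weight[i])
  }, numeric(1))
  vapply(params, function(p) {
    if (p$kind == "sigma") { if (p$t == p$u) 0.2 * v[p$t] else 0 }
    else if (p$kind == "res") 0.4 * v[p$t]
    else 0
  }, numeric(1))
}

# valid parameter vector: variances at or above floor, every modelled
# covariance within the positive semi-definite cone of its 2x2 block
.thetaValid <- function(params, theta, floor) {
  getv <- function(kind, eff, t, u) {
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (p$kind != kind) next
      if (kind == "sigma" && (p$effect != eff || p$t != t || p$u != u)) next
      if (kind == "res" && p$t != t) next
      return(theta[i])
    }
    0
  }
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (p$kind == "rescov") {
      if (theta[i]^2 > getv("res", NULL, 1, 1) * getv("res", NULL, 2, 2))
        return(FALSE)
    } else if (p$kind == "res" || p$t == p$u) {
      if (theta[i] < floor * 0.999) return(FALSE)
    } else {
      v1 <- getv("sigma", p$effect, p$t, p$t)
      v2 <- getv("sigma", p$effect, p$u, p$u)
      if (theta[i]^2 > v1 * v2) return(FALSE)
    }
  }
  TRUE
}

# observation-space basis matrix of a residual parameter (sparse)
.resBasis <- function(sys, p) {
  n <- sys$nObs
  if (p$kind == "res") {
    x <- ifelse(sys$obsTrait == p$t, sys$weight, 0)
    Matrix::Diagonal(n, x)
  } else {
    pr <- sys$pairs
    Matrix::sparseMatrix(i = c(pr[, 1], pr[, 2]), j = c(pr[, 2], pr[, 1]),
                         x = 1, dims = c(n, n))
  }
}

# ---- dense route ----------------------------------------------------------

# multiply the additive covariance K with a set of vectors
.kMultiplier <- function(eff) {
  if (is.null(eff$Kinv)) return(function(v) v)
  if (!is.null(eff$Kchol))
    return(function(v) as.matrix(Matrix::solve(eff$Kchol, as.matrix(v))))
  Kd <- solve(as.matrix(eff$Kinv))
  function(v) Kd %*% as.matrix(v)
}

# per-effect, per-trait-pair observation covariance blocks M[t,u] = Zt K Zu'
# plus the per-parameter dV basis matrices (all theta-independent)
.denseBasis <- function(sys, params) {
  nt <- sys$nt
  eff <- list()
  for (e in names(sys$effects)) {
    ef <- sys$effects[[e]]
    kmul <- .kMultiplier(ef)
    Zt <- lapply(seq_len(nt), function(t)
      ef$Z[, (t - 1L) * ef$q + seq_len(ef$q), drop = FALSE])
    M <- vector("list", nt * nt)
    dim(M) <- c(nt, nt)
    for (t in seq_len(nt)) for (u in t:nt) {
      KZu <- kmul(Matrix::t(Zt[[u]]))
      M[[t, u]] <- as.matrix(Zt[[t]] %*% KZu)
      if (u != t) M[[u, t]] <- t(M[[t, u]])
    }
    eff[[e]] <- list(M = M, Zt = Zt, kmul = kmul, q = ef$q)
  }
  B <- vector("list", length(params))
  for (i in seq_along(params)) {
    p <- params[[i]]
    if (p$kind == "sigma") {
      M <- eff[[p$effect]]$M
      B[[i]] <- if (p$t == p$u) M[[p$t, p$t]] else M[[p$t, p$u]] + M[[p$u, p$t]]
    } else B[[i]] <- as.matrix(.resBasis(sys, p))
  }
  list(eff = eff, B = B)
}

.denseEval <- function(sys, params, theta, basis, light = FALSE) {
  nt <- sys$nt
  vc <- .thetaToVC(params, theta, nt)
  n <- sys$nObs
  B <- basis$B
  V <- matrix(0, n, n)
  for (i in seq_along(params)) V <- V + theta[i] * B[[i]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE))
  Vi <- chol2inv(ch)
  X <- as.matrix(sys$X)
  XtVi <- crossprod(X, Vi)
  XtViX <- XtVi %*% X
  chX <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chX)) return(list(ok = FALSE))
  P <- Vi - crossprod(XtVi, chol2inv(chX) %*% XtVi)
  Py <- as.numeric(P %*% sys$y)
  yPy <- sum(sys$y * Py)
  loglik <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chX))) + yPy)
  if (light) return(list(ok = TRUE, loglik = loglik))
  np <- length(params)
  score <- numeric(np)
  Fm <- matrix(0, n, np)
  for (i in seq_len(np)) {
    score[i] <- -0.5 * (sum(P * B[[i]]) - sum(Py * (B[[i]] %*% Py)))
    Fm[, i] <- B[[i]] %*% Py
  }
  PF <- P %*% Fm
  AI <- 0.5 * crossprod(Fm, PF)
  list(ok = TRUE, loglik = loglik, score = score, AI = AI,
       em = .denseEM(sys, params, theta, basis, P, Py))
}

# EM-REML update from the dense pieces (used when an AI step fails)
.denseEM <- function(sys, params, theta, basis, P, Py) {
  force(P); force(Py)
  function() {
    nt <- sys$nt
    vc <- .thetaToVC(params, theta, nt)
    out <- theta
    for (i in seq_along(params)) {
      p <- params[[i]]
      if (p$kind == "sigma") {
        e <- basis$eff[[p$effect]]
        Sig <- .sigmaOf(vc, p$effect)
        q <- e$q
        g <- lapply(seq_len(nt), function(u)
          as.numeric(Matrix::t(e$Zt[[u]]) %*% Py))
        Kg <- lapply(g, function(v) as.numeric(e$kmul(v)))
        # u_t' K^-1 u_u with u_t = sum_a Sig[t,a] K g_a
        Q <- matrix(0, nt, nt)
        for (a in seq_len(nt)) for (b in seq_len(nt))
          Q[a, b] <- sum(g[[a]] * Kg[[b]])
        uKu <- as.numeric(Sig[p$t, ] %*% Q %*% Sig[, p$u])
        trTerm <- Sig[p$t, p$u] * q
        for (a in seq_len(nt)) for (b in seq_len(nt))
          trTerm <- trTerm - Sig[p$t, a] * Sig[b, p$u] *
            sum(P * e$M[[b, a]])
        out[i] <- (uKu + trTerm) / q
      } else if (p$kind == "res") {
        # sigma_new = sigma^2 * y'P D P y ... via the general identity
        Bi <- as.matrix(.resBasis(sys, p))
        nr <- sum(sys$obsTrait == p$t)
        sig <- theta[i]
        out[i] <- sig + sig^2 / nr *
          (sum(Py * (Bi %*% Py)) - sum(P * Bi))
      }
      # rescov: left unchanged by the EM fallback
    }
    out
  }
}

# ---- MME route ------------------------------------------------------------

# static pieces reused across iterations
.mmePrep <- function(sys) {
  W <- cbind(sys$X, sys$effects$litter$Z, sys$effects$pen$Z,
             sys$effects$additive$Z)
  nt <- sys$nt
  # generic-pattern template guaranteeing a parameter-independent sparsity
  genericSigma <- matrix(0.5, nt, nt) + diag(0.5, nt)
  hasPairs <- !is.null(sys$pairs) && nrow(sys$pairs) > 0
  vcGen <- new("VarianceComponents", pen = genericSigma,
               litter = genericSigma, additive = genericSigma * 2,
               residual = if (hasPairs) genericSigma
                          else diag(diag(genericSigma), nt))
  # offsets of the equation blocks
  off <- list(mean = 0L)
  o <- nt
  for (e in names(sys$effects)) {
    off[[e]] <- o
    o <- o + nt * sys$effects[[e]]$q
  }
  resBasis <- lapply(.remlParams(sys), function(p)
    if (p$kind %in% c("res", "rescov")) .resBasis(sys, p) else NULL)
  list(W = W, off = off, neq = o, resBasis = resBasis, vcGen = vcGen)
}

# equation indices of effect e, trait t
.eqIdx <- function(prep, sys, e, t) {
  q <- sys$effects[[e]]$q
  prep$off[[e]] + (t - 1L) * q + seq_len(q)
}

.mmeEval <- function(sys, params, theta, prep, pad, light = FALSE) {
  nt <- sys$nt
  vc <- .thetaToVC(params, theta, nt)
  res <- .residualMatrix(sys, vc)
  W <- prep$W
  WtRi <- Matrix::t(W) %*% res$Rinv
  C <- WtRi %*% W
  Gblocks <- list(Matrix::Matrix(0, nt, nt, sparse = TRUE))
  logdetG <- 0
  for (e in names(sys$effects)) {
    eff <- sys$effects[[e]]
    Sig <- .sigmaOf(vc, e)
    Gblocks <- c(Gblocks, list(.ginvBlock(eff, Sig)))
    logdetG <- logdetG + eff$q * determinant(Sig)$modulus + nt * eff$logdetK
  }
  C <- Matrix::forceSymmetric(C + Matrix::bdiag(Gblocks)) + pad
  ch <- tryCatch(Matrix::Cholesky(C, perm = TRUE, LDL = FALSE, super = FALSE),
                 error = function(e) NULL)
  if (is.null(ch)) return(list(ok = FALSE))
  rhs <- as.numeric(WtRi %*% sys$y)
  sol <- as.numeric(Matrix::solve(ch, rhs))
  ehat <- sys$y - as.numeric(W %*% sol)
  Py <- as.numeric(res$Rinv %*% ehat)
  yPy <- sum(sys$y * Py)
  L <- as(ch, "CsparseMatrix")
  logdetC <- 2 * sum(log(diag(L)))
  loglik <- -0.5 * (res$logdet + as.numeric(logdetG) + logdetC + yPy)
  if (light) return(list(ok = TRUE, loglik = loglik))

  ## Takahashi partial inverse of the factor
  tk <- cpp_takahashi(L@p, L@i, L@x)
  if (tk$misses > 0)
    warning("partial inverse pattern incomplete (", tk$misses, " entries)")
  pos <- Matrix::invPerm(ch@perm + 1L)
  pinvTrace <- function(i, j, x) {
    r <- cpp_trace_pinv(as.integer(i), as.integer(j), as.numeric(x),
                        pos, L@p, L@i, tk$Zx)
    r$value
  }

  ## structured traces tr(K^-1 C^kk_tu) per effect and trait pair
  effTrace <- list()
  for (e in names(sys$effects)) {
    eff <- sys$effects[[e]]
    Tm <- matrix(0, nt, nt)
    if (is.null(eff$Kinv)) {
      for (t in seq_len(nt)) for (u in t:nt) {
        Tm[t, u] <- Tm[u, t] <-
          pinvTrace(.eqIdx(prep, sys, e, t), .eqIdx(prep, sys, e, u),
                    rep(1, eff$q))
      }
    } else {
      Kt <- as(as(eff$Kinv, "generalMatrix"), "TsparseMatrix")
      for (t in seq_len(nt)) for (u in t:nt) {
        Tm[t, u] <- Tm[u, t] <-
          pinvTrace(prep$off[[e]] + (t - 1L) * eff$q + Kt@j + 1L,
                    prep$off[[e]] + (u - 1L) * eff$q + Kt@i + 1L, Kt@x)
      }
    }
    effTrace[[e]] <- Tm
  }

  ## score, AI working vectors, EM ingredients
  np <- length(params)
  score <- numeric(np)
  Fm <- matrix(0, sys$nObs, np)
  gk <- Kg <- list()
  for (e in names(sys$effects)) {
    eff <- sys$effects[[e]]
    g <- lapply(seq_len(nt), function(t)
      as.numeric(Matrix::t(eff$Z[, (t - 1L) * eff$q + seq_len(eff$q),
                                 drop = FALSE]) %*% Py))
    kmul <- .kMultiplier(eff)
    gk[[e]] <- g
    Kg[[e]] <- lapply(g, function(v) as.numeric(kmul(v)))
  }
  resTraceC <- numeric(np)   # tr(C^-1 W'R^-1 dR R^-1 W) per residual param
  for (i in seq_len(np)) {
    p <- params[[i]]
    if (p$kind == "sigma") {
      eff <- sys$effects[[p$effect]]
      Sig <- .sigmaOf(vc, p$effect)
      Si <- solve(Sig)
      E <- matrix(0, nt, nt)
      E[p$t, p$u] <- E[p$u, p$t] <- 1
      trA <- eff$q * sum(diag(E %*% Si))
      Mti <- Si %*% E %*% Si
      trB <- sum(Mti * effTrace[[p$effect]])
      g <- gk[[p$effect]]; K <- Kg[[p$effect]]
      quad <- 0
      for (t in seq_len(nt)) for (u in seq_len(nt))
        quad <- quad + E[t, u] * sum(g[[t]] * K[[u]])
      score[i] <- -0.5 * (trA - trB - quad)
      # working vector dV Py = Z (E (x) K) Z' Py
      h <- matrix(0, eff$q, nt)
      for (t in seq_len(nt)) for (u in seq_len(nt))
        h[, t] <- h[, t] + E[t, u] * K[[u]]
      Fm[, i] <- as.numeric(eff$Z %*% as.numeric(h))
    } else {
      Bobs <- prep$resBasis[[i]]
      Bt <- as(Matrix::forceSymmetric(WtRi %*% (Bobs %*% Matrix::t(WtRi))),
               "generalMatrix")
      Bt <- as(Bt, "TsparseMatrix")
      trC <- pinvTrace(Bt@i + 1L, Bt@j + 1L, Bt@x)
      resTraceC[i] <- trC
      tb <- as(as(Bobs, "generalMatrix"), "TsparseMatrix")
      trRinvB <- sum(res$Rinv[cbind(tb@i + 1L, tb@j + 1L)] * tb@x)
      BPy <- as.numeric(Bobs %*% Py)
      score[i] <- -0.5 * (trRinvB - trC - sum(Py * BPy))
      Fm[, i] <- BPy
    }
  }
  ## AI matrix from P-projected working vectors
  PF <- matrix(0, sys$nObs, np)
  for (i in seq_len(np)) {
    u <- as.numeric(Matrix::solve(ch, as.numeric(WtRi %*% Fm[, i])))
    PF[, i] <- as.numeric(res$Rinv %*% (Fm[, i] - as.numeric(W %*% u)))
  }
  AI <- 0.5 * crossprod(Fm, PF)

  em <- function() {
    out <- theta
    for (i in seq_len(np)) {
      p <- params[[i]]
      if (p$kind == "sigma") {
        eff <- sys$effects[[p$effect]]
        Sig <- .sigmaOf(vc, p$effect)
        # u_t = sum_a Sig[t,a] K g_a  (BLUP of the effect), so
        # u_t' K^-1 u_u = sum_ab Sig[t,a] Sig[b,u] g_a' K g_b
        Q <- matrix(0, nt, nt)
        for (a in seq_len(nt)) for (b in seq_len(nt))
          Q[a, b] <- sum(gk[[p$effect]][[a]] * Kg[[p$effect]][[b]])
        uKu <- as.numeric(Sig[p$t, ] %*% Q %*% Sig[, p$u])
        out[i] <- (uKu + effTrace[[p$effect]][p$t, p$u]) / eff$q
      } else if (p$kind == "res") {
        sel <- sys$obsTrait == p$t
        nr <- sum(sel)
        sig <- theta[i]
        eDe <- sum(ehat[sel]^2 / sys$weight[sel])
        out[i] <- (eDe + sig^2 * resTraceC[i]) / nr
      }
    }
    out
  }
  list(ok = TRUE, loglik = loglik, score = score, AI = AI, em = em)
}

# ---- shared update loop ---------------------------------------------------

# Parameters pinned at the variance floor whose score points further out of
# the parameter space are treated as fixed: they are excluded from the
# Newton system and from the gradient convergence check.
.airemlLoop <- function(evalFn, params, theta0, opts) {
  theta <- theta0
  ev <- evalFn(theta, FALSE)
  if (!ev$ok) stop("REML failed at the starting values")
  hist <- ev$loglik
  converged <- FALSE
  it <- 0L
  isVar <- vapply(params, function(p)
    p$kind == "res" || (p$kind == "sigma" && p$t == p$u), logical(1))
  # a variance sitting at the floor is treated as fixed unless its score
  # asks for an increase beyond the gradient tolerance
  pinned <- function(th, sc) isVar & th <= opts$floor * 1.001 &
    sc < opts$tolGrad
  lambda <- 0                       # adaptive (Levenberg-style) damping
  while (it < opts$maxit) {
    it <- it + 1L
    free <- which(!pinned(theta, ev$score))
    AIf <- ev$AI[free, free, drop = FALSE]
    step <- rep(0, length(theta))
    damp <- diag((lambda + 1e-10) * pmax(diag(AIf), 1e-12),
                 length(free))
    sf <- tryCatch(solve(AIf + damp, ev$score[free]),
                   error = function(e) NULL)
    accepted <- FALSE
    if (!is.null(sf) && length(free)) {
      step[free] <- sf
      fac <- 1
      for (h in seq_len(12L)) {
        cand <- .clampTheta(params, theta + fac * step, opts$floor)
        if (.thetaValid(params, cand, opts$floor)) {
          evl <- evalFn(cand, TRUE)
          if (evl$ok && evl$loglik >= ev$loglik - 1e-8) {
            accepted <- TRUE
            break
          }
        }
        fac <- fac / 2
      }
      lambda <- if (accepted && fac == 1) lambda / 5
                else max(lambda * 5, 1e-4)
      if (lambda < 1e-8) lambda <- 0
    }
    if (!accepted) {
      cand <- .clampTheta(params, ev$em(), opts$floor)
      if (!.thetaValid(params, cand, opts$floor))
        stop("REML: EM fallback left the parameter space")
      evl <- evalFn(cand, TRUE)
      if (!evl$ok) stop("REML: EM fallback failed")
    }
    evNew <- evalFn(cand, FALSE)
    rel <- max(abs(cand - theta) / (abs(theta) + 1e-4))
    theta <- cand
    ev <- evNew
    hist <- c(hist, ev$loglik)
    gnorm <- sqrt(sum(ev$score[!pinned(theta, ev$score)]^2))
    if (opts$verbose)
      message(sprintf("it %3d logL %.6f max rel change %.2e |score| %.2e",
                      it, ev$loglik, rel, gnorm))
    if (rel < opts$tolParam && gnorm < opts$tolGrad) {
      converged <- TRUE
      break
    }
    if (!accepted && rel < 1e-12) break   # neither AI nor EM can move
  }
  list(theta = theta, loglik = hist, converged = converged, iterations = it,
       AI = ev$AI)
}

.clampTheta <- function(params, theta, floor) {
  for (i in seq_along(params))
    if (params[[i]]$kind %in% c("sigma", "res")) {
      p <- params[[i]]
      if (p$kind == "res" || p$t == p$u) theta[i] <- max(theta[i], floor)
    }
  theta
}

# ---- public surface -------------------------------------------------------

#' Restricted log-likelihood of a model
#'
#' Evaluates the REML log-likelihood (additive constant omitted) at the
#' given variance components, either through the dense phenotypic
#' covariance or through the sparse mixed-model factorisation. The two
#' routes agree to numerical precision and are cross-checked in the test
#' suite.
#'
#' @inheritParams fitBLUP
#' @param vc a [VarianceComponents] at which to evaluate
#' @param route `"auto"`, `"dense"` or `"mme"`
#' @return scalar log-likelihood
#' @export
restrictedLogLik <- function(spec, pheno, pens = NULL, kin, vc,
                             route = c("auto", "dense", "mme"),
                             dropGenerations = integer()) {
  route <- match.arg(route)
  sys <- .buildSystem(spec, pheno, pens, kin, dropGenerations)
  params <- .remlParams(sys)
  theta <- .vcToTheta(params, vc)
  if (route == "auto")
    route <- if (sys$nObs <= 1500L) "dense" else "mme"
  if (route == "dense") {
    basis <- .denseBasis(sys, params)
    ev <- .denseEval(sys, params, theta, basis)
  } else {
    prep <- .mmePrep(sys)
    pad <- .mmePad(sys, prep)
    ev <- .mmeEval(sys, params, theta, prep, pad)
  }
  if (!ev$ok) return(-Inf)
  ev$loglik
}

# zero-valued (1e-300) padding matrix fixing the MME sparsity pattern
.mmePad <- function(sys, prep) {
  res <- .residualMatrix(sys, prep$vcGen)
  W <- prep$W
  C <- Matrix::t(W) %*% res$Rinv %*% W
  Gb <- list(Matrix::Matrix(0, sys$nt, sys$nt, sparse = TRUE))
  for (e in names(sys$effects))
    Gb <- c(Gb, list(.ginvBlock(sys$effects[[e]], .sigmaOf(prep$vcGen, e))))
  C <- Matrix::forceSymmetric(C + Matrix::bdiag(Gb))
  C@x[] <- 1e-300
  C
}

#' Estimate (co)variance components by AI-REML
#'
#' Average-information REML with exact score trace terms and an EM fallback
#' whenever an AI step would leave the parameter space or decrease the
#' restricted likelihood. Supports the univariate individual-record model,
#' the univariate group-record model, and the bivariate model with a
#' group-recorded and an individually recorded trait (for which the
#' cross-record residual covariance is not a model parameter).
#'
#' @inheritParams fitBLUP
#' @param start optional [VarianceComponents] starting values; by default
#'   40% of the per-trait phenotypic variance is assigned to the residual
#'   and 20% to each remaining component, with covariances starting at 0.
#' @param options see [remlOptions()]
#' @return a [RemlResult]
#' @export
remlEstimate <- function(spec, pheno, pens = NULL, kin, start = NULL,
                         options = remlOptions(),
                         dropGenerations = integer()) {
  sys <- .buildSystem(spec, pheno, pens, kin, dropGenerations)
  params <- .remlParams(sys)
  theta0 <- if (is.null(start)) .startTheta(params, sys)
            else .vcToTheta(params, start)
  if (sys$nObs <= options$denseLimit) {
    basis <- .denseBasis(sys, params)
    evalFn <- function(th, light = FALSE)
      .denseEval(sys, params, th, basis, light)
  } else {
    prep <- .mmePrep(sys)
    pad <- .mmePad(sys, prep)
    evalFn <- function(th, light = FALSE)
      .mmeEval(sys, params, th, prep, pad, light)
  }
  fit <- .airemlLoop(evalFn, params, theta0, options)
  se <- tryCatch(sqrt(diag(solve(fit$AI))), error = function(e)
    rep(NA_real_, length(params)))
  names(se) <- vapply(params, `[[`, character(1), "name")
  new("RemlResult", estimates = .thetaToVC(params, fit$theta, sys$nt),
      se = se, loglik = fit$loglik, converged = fit$converged,
      iterations = as.integer(fit$iterations))
}
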