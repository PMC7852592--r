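# Henderson mixed-model equations for the univariate and bivariate animal
# models with individual records y = 1*mu + Zl*l + Zc*c + Za*a + e, or their
# group-record counterparts obtained by premultiplying with the group
# incidence matrix T: Ty = T1*mu + TZl*l + TZc*c + TZa*a + Te.

#' Create a model specification
#'
#' @param records per-trait record mode: `"individual"` or `"group"`;
#'   length 1 (univariate) or 2 (bivariate).
#' @param relationship `"A"` (pedigree), `"G"` (genomic) or `"H"`
#'   (single-step).
#' @param effects random effects to include (litter, pen, additive); the
#'   full model is the default, reduced models serve closed-form checks and
#'   degenerate designs.
#' @return a [ModelSpec]
#' @export
modelSpec <- function(records = "individual", relationship = "A",
                      effects = c("litter", "pen", "additive")) {
  new("ModelSpec", records = records, relationship = relationship,
      effects = effects)
}

# Internal design/structure shared by BLUP and REML. Observations are
# stacked trait-major; equations are ordered [means | litter | pen |
# additive], trait-major within each effect block.
.buildSystem <- function(spec, pheno, pens, kin = NULL,
                         dropGenerations = integer()) {
  validObject(spec)
  f <- pheno@frame
  rec <- f$hasRecord & !(f$generation %in% dropGenerations)
  fr <- f[rec, , drop = FALSE]
  if (!nrow(fr)) stop("no records left to analyse")
  nt <- length(spec@records)
  useGroups <- any(spec@records == "group")
  pensS <- NULL
  if (useGroups) {
    if (is.null(pens)) stop("group-record mode requires a GroupIncidence")
    pensS <- subsetGroups(pens, fr$id)
  }
  useAdd <- "additive" %in% spec@effects
  litterLv <- sort(unique(fr$litter))
  penLv <- sort(unique(fr$pen))
  if (useAdd) {
    if (is.null(kin)) stop("the additive effect requires a relationship matrix")
    animLv <- kin@ids
    ai <- match(fr$id, animLv)
    if (anyNA(ai))
      stop("recorded animals missing from the relationship matrix (for GBLUP ",
           "all recorded animals must be genotyped)")
  } else {
    animLv <- integer(0)
    ai <- rep(0L, nrow(fr))
  }

  y <- numeric(0)
  obsTrait <- integer(0)
  weight <- numeric(0)
  obsUnit <- character(0)
  trip <- list(X = NULL, litter = NULL, pen = NULL, additive = NULL)
  addTrip <- function(part, i, j, x) {
    trip[[part]] <<- rbind(trip[[part]], cbind(i, j, x))
  }
  row0 <- 0L
  obsAnimal <- integer(0)   # animal id per individual observation, NA for group
  for (t in seq_len(nt)) {
    yt <- fr[[paste0("y", t)]]
    if (spec@records[t] == "individual") {
      n <- nrow(fr)
      rows <- row0 + seq_len(n)
      y <- c(y, yt)
      obsTrait <- c(obsTrait, rep(t, n))
      weight <- c(weight, rep(1, n))
      obsUnit <- c(obsUnit, as.character(fr$id))
      obsAnimal <- c(obsAnimal, fr$id)
      addTrip("X", rows, rep(t, n), rep(1, n))
      if ("litter" %in% spec@effects)
        addTrip("litter", rows, (t - 1L) * length(litterLv) + match(fr$litter, litterLv), rep(1, n))
      if ("pen" %in% spec@effects)
        addTrip("pen", rows, (t - 1L) * length(penLv) + match(fr$pen, penLv), rep(1, n))
      if (useAdd)
        addTrip("additive", rows, (t - 1L) * length(animLv) + ai, rep(1, n))
      row0 <- row0 + n
    } else {
      Tm <- as(as(pensS@incidence, "generalMatrix"), "CsparseMatrix")
      tr <- as(Tm, "TsparseMatrix")
      g <- tr@i + 1L                       # group row per membership
      m <- pensS@member[tr@j + 1L]         # member id per membership
      mi <- match(m, fr$id)
      n <- nrow(Tm)
      rows <- row0 + seq_len(n)
      y <- c(y, as.numeric(Tm %*% yt[match(pensS@member, fr$id)]))
      sizes <- as.numeric(Matrix::rowSums(Tm))
      obsTrait <- c(obsTrait, rep(t, n))
      weight <- c(weight, sizes)
      obsUnit <- c(obsUnit, pensS@group)
      obsAnimal <- c(obsAnimal, rep(NA_integer_, n))
      addTrip("X", rows, rep(t, n), sizes)
      if ("litter" %in% spec@effects)
        addTrip("litter", row0 + g, (t - 1L) * length(litterLv) + match(fr$litter[mi], litterLv), rep(1, length(g)))
      if ("pen" %in% spec@effects)
        addTrip("pen", row0 + g, (t - 1L) * length(penLv) + match(fr$pen[mi], penLv), rep(1, length(g)))
      if (useAdd)
        addTrip("additive", row0 + g, (t - 1L) * length(animLv) + match(m, animLv), rep(1, length(g)))
      row0 <- row0 + n
    }
  }
  nObs <- row0
  mk <- function(part, ncol) {
    tr <- trip[[part]]
    Matrix::sparseMatrix(i = tr[, 1], j = tr[, 2], x = tr[, 3],
                         dims = c(nObs, ncol))
  }
  X <- mk("X", nt)

  # residual pairing: both-trait individual records of the same animal
  pairs <- NULL
  if (nt == 2L && all(spec@records == "individual")) {
    i1 <- which(obsTrait == 1L)
    i2 <- which(obsTrait == 2L)
    m <- match(obsAnimal[i1], obsAnimal[i2])
    ok <- !is.na(m)
    pairs <- cbind(i1[ok], i2[m[ok]])
  }

  effects <- list()
  if ("litter" %in% spec@effects)
    effects$litter <- list(name = "litter", Z = mk("litter", nt * length(litterLv)),
                           levels = litterLv, q = length(litterLv),
                           Kinv = NULL, logdetK = 0)
  if ("pen" %in% spec@effects)
    effects$pen <- list(name = "pen", Z = mk("pen", nt * length(penLv)),
                        levels = penLv, q = length(penLv),
                        Kinv = NULL, logdetK = 0)
  if (useAdd) {
    # relationship structure for the additive effect
    if (kin@inverse) {
      Kinv <- kin@values
      Kch <- Matrix::Cholesky(Kinv, LDL = FALSE)
      logdetK <- -2 * sum(log(diag(as(Kch, "CsparseMatrix"))))
    } else {
      Kd <- as.matrix(kin@values)
      R <- chol(Kd)
      Kinv <- as(chol2inv(R), "CsparseMatrix")
      Kch <- NULL
      logdetK <- 2 * sum(log(diag(R)))
    }
    effects$additive <- list(name = "additive", Z = mk("additive", nt * length(animLv)),
                             levels = animLv, q = length(animLv),
                             Kinv = Kinv, Kchol = Kch, logdetK = logdetK)
  }

  list(spec = spec, y = y, X = X, effects = effects,
       nt = nt, nObs = nObs, obsTrait = obsTrait, weight = weight,
       obsUnit = obsUnit, pairs = pairs, pens = pensS, frame = fr)
}

#' Design matrices for a model
#'
#' Returns the stacked design of the (possibly T-premultiplied) model: the
#' fixed-effect matrix whose trait-t column is `1` (individual mode) or the
#' group-size vector `T1` (group mode), and the incidence matrices for
#' litter, pen and additive effects. The additive design spans every animal
#' of the relationship matrix, so unrecorded animals are carried by the
#' covariance structure alone.
#'
#' @param spec a [ModelSpec]
#' @param pheno a [PhenotypeSet]
#' @param pens a [GroupIncidence] (required for group mode)
#' @param kin a [RelationshipMatrix] (defines the additive levels)
#' @return list with `y`, `X`, and sparse `Z` matrices per random effect
#' @export
buildDesign <- function(spec, pheno, pens = NULL, kin) {
  sys <- .buildSystem(spec, pheno, pens, kin)
  list(y = sys$y, X = sys$X, Zl = sys$effects$litter$Z,
       Zc = sys$effects$pen$Z, Za = sys$effects$additive$Z,
       obsTrait = sys$obsTrait, groupSizes = sys$weight)
}

#' Residual covariance structure of a model
#'
#' Individual records carry residual variance `sigma_e^2`; a group record
#' that sums `n` individual records carries `n * sigma_e^2` (the groups are
#' disjoint, so `T T'` is diagonal with the group sizes). In the bivariate
#' model with one group-recorded and one individually recorded trait there
#' is no residual covariance parameter between the two record types.
#'
#' @inheritParams buildDesign
#' @param vc a [VarianceComponents]
#' @return list with the diagonal weights, per-observation trait, paired
#'   observations (both-trait individual records), and the assembled sparse
#'   residual covariance matrix
#' @export
residualStructure <- function(spec, pheno, pens = NULL, kin, vc) {
  sys <- .buildSystem(spec, pheno, pens, kin)
  R <- .residualMatrix(sys, vc)
  list(weights = sys$weight, obsTrait = sys$obsTrait, pairs = sys$pairs,
       R = R$R)
}

# residual covariance, its inverse and log-determinant from components
.residualMatrix <- function(sys, vc) {
  d <- sys$weight
  tv <- diag(vc@residual)[sys$obsTrait]
  dv <- d * tv
  cov12 <- if (sys$nt == 2L) vc@residual[1, 2] else 0
  if (is.null(sys$pairs) || cov12 == 0) {
    R <- Matrix::Diagonal(x = dv)
    Rinv <- Matrix::Diagonal(x = 1 / dv)
    logdet <- sum(log(dv))
    return(list(R = R, Rinv = Rinv, logdet = logdet))
  }
  p <- sys$pairs
  i <- c(seq_along(dv), p[, 1], p[, 2])
  j <- c(seq_along(dv), p[, 2], p[, 1])
  x <- c(dv, rep(cov12, 2 * nrow(p)))
  R <- Matrix::sparseMatrix(i = i, j = j, x = x)
  det2 <- dv[p[, 1]] * dv[p[, 2]] - cov12^2
  if (any(det2 <= 0)) stop("residual covariance block not positive definite")
  # block inversion: paired entries overwrite the diagonal entries
  invDiag <- 1 / dv
  invDiag[p[, 1]] <- dv[p[, 2]] / det2
  invDiag[p[, 2]] <- dv[p[, 1]] / det2
  Rinv <- Matrix::sparseMatrix(
    i = c(seq_along(dv), p[, 1], p[, 2]),
    j = c(seq_along(dv), p[, 2], p[, 1]),
    x = c(invDiag, rep(-cov12, 2 * nrow(p)) / rep(det2, 2)))
  unpaired <- setdiff(seq_along(dv), c(p[, 1], p[, 2]))
  logdet <- sum(log(det2)) + sum(log(dv[unpaired]))
  list(R = R, Rinv = Rinv, logdet = logdet)
}

# Sigma matrices per effect from a VarianceComponents
.sigmaOf <- function(vc, effect)
  switch(effect, litter = vc@litter, pen = vc@pen, additive = vc@additive)

# inverse covariance contribution kron(Sigma^-1, Kinv) for one effect
.ginvBlock <- function(eff, Sigma) {
  Si <- solve(Sigma)
  K <- if (is.null(eff$Kinv)) Matrix::Diagonal(eff$q) else eff$Kinv
  if (nrow(Si) == 1L) Si[1, 1] * K else Matrix::kronecker(Si, K)
}

#' Assemble the mixed-model equations
#'
#' Builds Henderson's coefficient matrix and right-hand side for the model
#' defined by `spec`, with weighted least squares for the residual structure
#' and inverse covariance blocks `Sigma_k^{-1} (x) K^{-1}` for the random
#' effects (litter, pen, additive).
#'
#' @inheritParams residualStructure
#' @return an [MMESystem]
#' @export
buildMME <- function(spec, pheno, pens = NULL, kin, vc) {
  sys <- .buildSystem(spec, pheno, pens, kin)
  .assembleMME(sys, vc)
}

.assembleMME <- function(sys, vc) {
  if (nrow(vc@pen) != sys$nt)
    stop("variance components do not match the number of traits")
  res <- .residualMatrix(sys, vc)
  W <- cbind(sys$X, sys$effects$litter$Z, sys$effects$pen$Z,
             sys$effects$additive$Z)
  WtRi <- Matrix::t(W) %*% res$Rinv
  C <- WtRi %*% W
  rhs <- as.numeric(WtRi %*% sys$y)
  nfix <- sys$nt
  blocks <- list(Matrix::Matrix(0, nfix, nfix, sparse = TRUE))
  for (e in names(sys$effects))
    blocks <- c(blocks, list(.ginvBlock(sys$effects[[e]], .sigmaOf(vc, e))))
  Ginv <- Matrix::bdiag(blocks)
  C <- Matrix::forceSymmetric(C + Ginv)
  index <- .equationIndex(sys)
  new(Class = "MMESystem", C = C, rhs = rhs, index = index,
      meta = list(system = sys, vc = vc, Rinv = res$Rinv,
                  logdetR = res$logdet, W = W))
}

.equationIndex <- function(sys) {
  idx <- data.frame(effect = "mean", trait = seq_len(sys$nt),
                    level = as.character(seq_len(sys$nt)))
  for (e in names(sys$effects)) {
    eff <- sys$effects[[e]]
    idx <- rbind(idx, data.frame(
      effect = e, trait = rep(seq_len(sys$nt), each = eff$q),
      level = rep(as.character(eff$levels), sys$nt)))
  }
  idx
}

#' Solve the mixed-model equations
#'
#' Moderate systems are solved by sparse Cholesky factorisation; large
#' systems (above `direct` equations) by Jacobi-preconditioned conjugate
#' gradients, which avoids the heavy factor fill-in of grouped-record
#' animal models. Either way the solution is verified against the
#' right-hand side and refused if the relative residual exceeds `tol`.
#'
#' @param mme an [MMESystem]
#' @param tol maximum relative residual of the solve
#' @param direct equation-count threshold up to which the direct
#'   factorisation is used
#' @param maxit iteration cap for the conjugate-gradient solver
#' @return list with `ebv` (data.frame id/trait/ebv for every animal of the
#'   relationship matrix), `fixed` (trait means), `solution` (full vector)
#'   and `index`
#' @export
solveMME <- function(mme, tol = 1e-10, direct = 20000L, maxit = 10000L) {
  n <- nrow(mme@C)
  if (n <= direct) {
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(mme@C), LDL = FALSE)
    sol <- as.numeric(Matrix::solve(ch, mme@rhs))
  } else {
    Cg <- as(as(Matrix::forceSymmetric(mme@C), "generalMatrix"),
             "CsparseMatrix")
    res <- cpp_pcg(Cg@p, Cg@i, Cg@x, mme@rhs, Matrix::diag(mme@C),
                   tol * 0.1, maxit)
    if (res$relres > tol)
      stop(sprintf("conjugate-gradient solve did not converge (rel. residual %.2e)",
                   res$relres))
    sol <- res$x
  }
  num <- sqrt(sum((as.numeric(mme@C %*% sol) - mme@rhs)^2))
  den <- sqrt(sum(mme@rhs^2))
  if (den > 0 && num / den > tol)
    stop(sprintf("mixed-model solve did not reach tolerance (rel. residual %.2e)",
                 num / den))
  idx <- mme@index
  add <- idx$effect == "additive"
  ebv <- data.frame(id = as.integer(idx$level[add]), trait = idx$trait[add],
                    ebv = sol[add])
  list(ebv = ebv, fixed = sol[idx$effect == "mean"], solution = sol,
       index = idx)
}

#' Fit BLUP breeding values
#'
#' Convenience wrapper: builds the system for `spec`, assembles Henderson's
#' equations with the supplied (true or estimated) variance components and
#' solves them.
#'
#' @inheritParams residualStructure
#' @param dropGenerations generations whose records are excluded before
#'   fitting (e.g. the validation generation for predictions without own
#'   records)
#' @param tol solver tolerance, see [solveMME()]
#' @return as [solveMME()]
#' @export
fitBLUP <- function(spec, pheno, pens = NULL, kin, vc,
                    dropGenerations = integer(), tol = 1e-10) {
  sys <- .buildSystem(spec, pheno, pens, kin, dropGenerations)
  mme <- .assembleMME(sys, vc)
  solveMME(mme, tol = tol)
}
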