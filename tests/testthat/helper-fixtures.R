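# Shared fixtures, memoised so expensive objects are built once per test run.

.fixtureEnv <- new.env(parent = emptyenv())

memoFixture <- function(name, build) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, build(), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

# small pedigreed dataset with pens (fast; ~400 animals)
tinyReplicate <- function() {
  memoFixture("tiny", function() {
    set.seed(4711)
    simulateStudyReplicate(scenarios = "S12_L2x3", rg = 0.8, litters = 20L,
                           generations = 3L, phenoGenerations = 2:3,
                           sires = 5L, histN = 40L, histGenerations = 25L,
                           chromosomes = 3L, markersPerChromosome = 0L,
                           qtlPerChromosome = 30L)
  })
}

# very small dataset suitable for dense GLS oracles (<= 60 recorded animals)
oracleReplicate <- function() {
  memoFixture("oracle", function() {
    set.seed(271)
    simulateStudyReplicate(scenarios = "S12_L2x3", rg = 0.8, litters = 4L,
                           generations = 2L, phenoGenerations = 1:2,
                           sires = 2L, histN = 20L, histGenerations = 10L,
                           chromosomes = 2L, markersPerChromosome = 0L,
                           qtlPerChromosome = 20L, attrition = 0)
  })
}

# one replicate at the full study scale (pedigree of 29,430); used by the
# structural checks on the generating design
fullReplicate <- function() {
  memoFixture("full", function() {
    set.seed(90125)
    simulateStudyReplicate(scenarios = c("S12_L2x3", "S24_L2x3"), rg = 0.8)
  })
}

# dense GLS/BLUP oracle: mixed model solved through the phenotypic
# covariance matrix, independent of the MME implementation
denseGLS <- function(spec, pheno, pens, ped, vc) {
  A <- buildA(ped)@values
  f <- pheno@frame[pheno@frame$hasRecord, ]
  nt <- length(spec@records)
  ids <- as.character(f$id)
  n <- nrow(f)
  Zl <- stats::model.matrix(~ 0 + litter, f)
  Zc <- stats::model.matrix(~ 0 + pen, f)
  Za <- matrix(0, n, nrow(A))
  Za[cbind(seq_len(n), match(f$id, ped@frame$id))] <- 1
  Tm <- NULL
  if (any(spec@records == "group")) {
    sub <- subsetGroups(pens, f$id)
    Tm <- as.matrix(sub@incidence)[, match(f$id, sub@member), drop = FALSE]
  }
  rows <- list()
  for (t in seq_len(nt)) {
    Ht <- if (spec@records[t] == "group") Tm else diag(n)
    rows[[t]] <- Ht
  }
  Sl <- vc@litter; Sc <- vc@pen; Sa <- vc@additive; Se <- vc@residual
  blocks <- function(S, M) {
    out <- vector("list", nt * nt); dim(out) <- c(nt, nt)
    for (t in seq_len(nt)) for (u in seq_len(nt))
      out[[t, u]] <- S[t, u] * (rows[[t]] %*% M %*% t(rows[[u]]))
    out
  }
  Bl <- blocks(Sl, Zl %*% t(Zl))
  Bc <- blocks(Sc, Zc %*% t(Zc))
  Ba <- blocks(Sa, Za %*% A %*% t(Za))
  mixed <- !all(spec@records == spec@records[1])
  Be <- vector("list", nt * nt); dim(Be) <- c(nt, nt)
  for (t in seq_len(nt)) for (u in seq_len(nt)) {
    s <- if (t == u) Se[t, t] else if (mixed) 0 else Se[t, u]
    Be[[t, u]] <- s * (rows[[t]] %*% t(rows[[u]]))
  }
  V <- NULL; X <- NULL; y <- NULL
  Vr <- vector("list", nt)
  for (t in seq_len(nt)) {
    Vrow <- NULL
    for (u in seq_len(nt))
      Vrow <- cbind(Vrow, Bl[[t, u]] + Bc[[t, u]] + Ba[[t, u]] + Be[[t, u]])
    V <- rbind(V, Vrow)
    X <- Matrix::bdiag(if (is.null(X)) list() else list(X))  # placeholder
    y <- c(y, as.numeric(rows[[t]] %*% f[[paste0("y", t)]]))
  }
  Xl <- lapply(seq_len(nt), function(t) rows[[t]] %*% rep(1, n))
  X <- as.matrix(Matrix::bdiag(Xl))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  resid <- y - X %*% beta
  # Cov(a_t, y_u) = Sa[t, u] * A Za' H_u'
  ebv <- matrix(0, nrow(A), nt)
  Viresid <- Vi %*% resid
  off <- 0
  parts <- vapply(rows, nrow, integer(1))
  for (t in seq_len(nt)) {
    acc <- 0
    off <- 0
    for (u in seq_len(nt)) {
      block <- Viresid[off + seq_len(parts[u]), , drop = FALSE]
      acc <- acc + Sa[t, u] * (A %*% t(Za) %*% t(rows[[u]]) %*% block)
      off <- off + parts[u]
    }
    ebv[, t] <- as.numeric(acc)
  }
  list(fixed = as.numeric(beta), ebv = ebv, ids = ped@frame$id)
}
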