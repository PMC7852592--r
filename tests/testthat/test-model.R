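# Mixed-model equations: design construction, residual structure, and
# equivalence of the Henderson solutions with a dense GLS/BLUP oracle.

test_that("group designs premultiply the individual design by T", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  pens <- rep$pens[[1]]
  des <- buildDesign(modelSpec("group", "A"), ph, pens, rep$ainv)
  # T1 is the vector of group sizes
  expect_equal(as.numeric(des$X), des$groupSizes)
  # a full pen of 12 from 4 sublitters: litter incidence row is 3,3,3,3
  full <- which(des$groupSizes == 12)
  if (length(full)) {
    row <- des$Zl[full[1], ]
    expect_equal(sort(row[row != 0]), rep(3, 4))
  }
  # additive row sums equal group sizes (one 1 per member)
  expect_equal(Matrix::rowSums(des$Za), des$groupSizes)
})

test_that("residual structure scales group records by group size", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  vc1 <- trueVarianceComponents(0.8, traits = 1)
  rs <- residualStructure(modelSpec("group", "A"), ph, rep$pens[[1]],
                          rep$ainv, vc1)
  expect_equal(Matrix::diag(rs$R), rs$weights * 50)
  # bivariate individual records: residual covariance 52.44 for paired obs
  vc2 <- trueVarianceComponents(0.8, traits = 2)
  rs2 <- residualStructure(modelSpec(c("individual", "individual"), "A"),
                           ph, NULL, rep$ainv, vc2)
  expect_equal(vc2@residual[1, 2], 0.5 * sqrt(50 * 220))
  p <- rs2$pairs
  expect_equal(unique(rs2$R[p]), vc2@residual[1, 2])
  # mixed mode: no residual covariance parameter between record types
  rsm <- residualStructure(modelSpec(c("group", "individual"), "A"),
                           ph, rep$pens[[1]], rep$ainv, vc2)
  expect_true(Matrix::isDiagonal(rsm$R))
})

test_that("MME solutions equal dense GLS on small fixtures", {
  rep <- oracleReplicate()
  ph <- rep$pheno[[1]]
  pens <- rep$pens[[1]]
  ped <- rep$pedigree
  vc1 <- trueVarianceComponents(0.8, traits = 1)
  vc2 <- trueVarianceComponents(0.8, traits = 2)
  cases <- list(list(modelSpec("group", "A"), vc1),
                list(modelSpec("individual", "A"), vc1),
                list(modelSpec(c("group", "individual"), "A"), vc2),
                list(modelSpec(c("individual", "individual"), "A"), vc2))
  for (cs in cases) {
    fit <- fitBLUP(cs[[1]], ph, pens, rep$ainv, cs[[2]])
    oracle <- denseGLS(cs[[1]], ph, pens, ped, cs[[2]])
    expect_equal(fit$fixed, oracle$fixed, tolerance = 1e-8)
    for (t in seq_along(cs[[1]]@records)) {
      got <- fit$ebv$ebv[fit$ebv$trait == t]
      expect_lt(max(abs(got - oracle$ebv[, t])), 1e-8)
    }
  }
})

test_that("singleton groups reproduce the individual model exactly", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  f <- ph@frame[ph@frame$hasRecord, ]
  single <- groupIncidence(Matrix::Diagonal(nrow(f)),
                           group = paste0("s", seq_len(nrow(f))),
                           member = f$id)
  vc1 <- trueVarianceComponents(0.8, traits = 1)
  fitS <- fitBLUP(modelSpec("group", "A"), ph, single, rep$ainv, vc1)
  fitI <- fitBLUP(modelSpec("individual", "A"), ph, NULL, rep$ainv, vc1)
  expect_equal(fitS$ebv$ebv, fitI$ebv$ebv, tolerance = 1e-9)
  expect_equal(fitS$fixed, fitI$fixed, tolerance = 1e-9)
})

test_that("a bivariate model with zero covariances decouples", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  vcD <- new("VarianceComponents",
             pen = diag(c(10, 40)), litter = diag(c(10, 40)),
             additive = diag(c(30, 100)), residual = diag(c(50, 220)))
  fit2 <- fitBLUP(modelSpec(c("individual", "individual"), "A"), ph, NULL,
                  rep$ainv, vcD)
  vc1 <- new("VarianceComponents", pen = matrix(10), litter = matrix(10),
             additive = matrix(30), residual = matrix(50))
  fit1 <- fitBLUP(modelSpec("individual", "A"), ph, NULL, rep$ainv, vc1)
  expect_equal(fit2$ebv$ebv[fit2$ebv$trait == 1], fit1$ebv$ebv,
               tolerance = 1e-8)
})

test_that("degenerate and shifted inputs behave as linear theory requires", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  vc1 <- trueVarianceComponents(0.8, traits = 1)
  # zero phenotypes: all EBVs and the mean are zero
  f0 <- ph@frame; f0$y1 <- 0
  ph0 <- new("PhenotypeSet", frame = f0, mean = ph@mean)
  fit0 <- fitBLUP(modelSpec("individual", "A"), ph0, NULL, rep$ainv, vc1)
  expect_equal(max(abs(fit0$ebv$ebv)), 0, tolerance = 1e-12)
  expect_equal(fit0$fixed, 0, tolerance = 1e-12)
  # adding a constant shifts the mean only
  fs <- ph@frame; fs$y1 <- fs$y1 + 7
  phs <- new("PhenotypeSet", frame = fs, mean = ph@mean)
  fitA <- fitBLUP(modelSpec("individual", "A"), ph, NULL, rep$ainv, vc1)
  fitB <- fitBLUP(modelSpec("individual", "A"), phs, NULL, rep$ainv, vc1)
  expect_equal(fitB$fixed, fitA$fixed + 7, tolerance = 1e-8)
  expect_equal(fitB$ebv$ebv, fitA$ebv$ebv, tolerance = 1e-8)
})

test_that("full sibs sharing sublitter and pen get identical pedigree EBVs", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  vc1 <- trueVarianceComponents(0.8, traits = 1)
  fit <- fitBLUP(modelSpec("group", "A"), ph, rep$pens[[1]], rep$ainv, vc1)
  ebv <- setNames(fit$ebv$ebv, fit$ebv$id)
  f <- ph@frame[ph@frame$hasRecord, ]
  ped <- rep$pedigree@frame
  f$litter <- paste(f$generation, ped$dam[match(f$id, ped$id)])
  # non-parent full sibs in the same pen are indistinguishable
  breeding <- ped$id[ped$breeding]
  key <- paste(f$litter, f$pen)
  groups <- split(f$id, key)
  checked <- 0L
  for (g in groups) {
    g <- setdiff(g, breeding)
    if (length(g) >= 2) {
      expect_lt(max(ebv[as.character(g)]) - min(ebv[as.character(g)]), 1e-8)
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 10L)
})

test_that("single-step equals GBLUP when everyone is genotyped", {
  rep <- oracleReplicate()
  ph <- rep$pheno[[1]]
  ped <- rep$pedigree
  f <- ph@frame[ph@frame$hasRecord, ]
  set.seed(15)
  # genotypes for every pedigree animal
  ids <- ped@frame$id
  d <- matrix(rbinom(length(ids) * 120, 2, 0.5), length(ids), 120,
              dimnames = list(ids, NULL))
  A <- buildA(ped)@values
  Gw <- blendG(rescaleG(buildG(d), A), A)
  Hinv <- assembleHinverse(rep$ainv, Gw, A)
  vc1 <- trueVarianceComponents(0.8, traits = 1)
  fitH <- fitBLUP(modelSpec("group", "H"), ph, rep$pens[[1]], Hinv, vc1)
  fitG <- fitBLUP(modelSpec("group", "G"), ph, rep$pens[[1]], Gw, vc1)
  eh <- fitH$ebv; eg <- fitG$ebv
  m <- match(paste(eg$id, eg$trait), paste(eh$id, eh$trait))
  expect_equal(eh$ebv[m], eg$ebv, tolerance = 1e-6)
})

test_that("BLUP attains the information ceiling of the generating model", {
  # breeding values drawn exactly from the pedigree model: the realised
  # accuracy must match the prediction-error-variance implied accuracy
  set.seed(31)
  rep <- memoFixture("ceiling", function() {
    set.seed(3141)
    simulateStudyReplicate(scenarios = "S12_L2x3", rg = 0.8, litters = 40L,
                           generations = 3L, phenoGenerations = 2:3,
                           sires = 8L, histN = 60L, histGenerations = 20L,
                           chromosomes = 3L, markersPerChromosome = 0L,
                           qtlPerChromosome = 40L)
  })
  ped <- rep$pedigree
  f <- ped@frame
  res <- pedigreeInbreeding(ped)
  si <- match(f$sire, f$id); di <- match(f$dam, f$id)
  a <- numeric(nrow(f))
  for (i in seq_len(nrow(f))) {
    if (f$sire[i] == 0L) a[i] <- rnorm(1, 0, sqrt(30))
    else {
      d <- 0.5 - 0.25 * (res[si[i]] + res[di[i]])
      a[i] <- 0.5 * (a[si[i]] + a[di[i]]) + rnorm(1, 0, sqrt(d * 30))
    }
  }
  tbv <- cbind(tbv1 = a, tbv2 = 0)
  rownames(tbv) <- as.character(f$id)
  ph <- simulatePhenotypes(ped, tbv, rep$pens[[1]],
                           vc = trueVarianceComponents(0.8),
                           generations = 2:3)
  ph <- applyAttrition(ph, ped, 0.2)
  vc1 <- trueVarianceComponents(0.8, traits = 1)
  fit <- fitBLUP(modelSpec("individual", "A"), ph, NULL, rep$ainv, vc1)
  v <- partitionValidation(ph, integer(), 3L)
  eb <- setNames(fit$ebv$ebv[fit$ebv$trait == 1], fit$ebv$id)
  realized <- accuracy(eb[as.character(v$all)], tbv[as.character(v$all), 1])
  # PEV-implied expectation through the dense phenotypic covariance
  fr <- ph@frame[ph@frame$hasRecord, ]
  n <- nrow(fr)
  Zl <- stats::model.matrix(~ 0 + litter, fr)
  Zc <- stats::model.matrix(~ 0 + pen, fr)
  Arr <- relationshipBlock(ped, fr$id, fr$id, ainv = rep$ainv)
  V <- 10 * tcrossprod(Zl) + 10 * tcrossprod(Zc) + 30 * Arr + diag(50, n)
  X <- matrix(1, n, 1)
  Vi <- chol2inv(chol(V))
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
  Avr <- relationshipBlock(ped, v$all, fr$id, ainv = rep$ainv)
  Avv <- relationshipBlock(ped, v$all, v$all, ainv = rep$ainv)
  C <- 30 * Avr
  varA <- 30 * diag(Avv)
  PEV <- varA - diag(C %*% P %*% t(C))
  expected <- sqrt(mean(1 - PEV / varA))
  expect_lt(abs(realized - expected), 0.1)
})

test_that("the iterative and direct solvers agree", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  vc1 <- trueVarianceComponents(0.8, traits = 1)
  mme <- buildMME(modelSpec("group", "A"), ph, rep$pens[[1]], rep$ainv, vc1)
  direct <- solveMME(mme)
  pcg <- solveMME(mme, direct = 0L)
  expect_lt(max(abs(direct$solution - pcg$solution)), 1e-6)
})
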