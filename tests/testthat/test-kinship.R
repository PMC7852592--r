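# Relationship matrices: A with inbreeding, sparse A-inverse, VanRaden G,
# Christensen rescaling, blending, single-step H.

textbookPedigree <- function() {
  new("Pedigree", frame = data.frame(
    id = 1:5, sire = c(0L, 0L, 1L, 1L, 3L), dam = c(0L, 0L, 2L, 2L, 4L),
    generation = c(0L, 0L, 1L, 1L, 2L), sex = c(1L, 2L, 1L, 2L, 1L),
    breeding = c(TRUE, TRUE, TRUE, TRUE, FALSE)))
}

test_that("A carries textbook relationships and inbreeding", {
  ped <- textbookPedigree()
  A <- buildA(ped)@values
  expect_equal(A[3, 1], 0.5)           # parent-offspring
  expect_equal(A[3, 4], 0.5)           # full sibs
  expect_equal(A[1, 1], 1)
  expect_equal(A[5, 5], 1.25)          # offspring of full-sib mating, F=0.25
  expect_equal(unname(pedigreeInbreeding(ped)), c(0, 0, 0, 0, 0.25))
})

test_that("the sparse inverse inverts A exactly", {
  ped <- textbookPedigree()
  A <- buildA(ped)@values
  Ainv <- buildAinverse(ped)
  expect_lt(max(abs(solve(as.matrix(Ainv@values)) - A)), 1e-12)

  # larger random pedigree
  rep <- tinyReplicate()
  A2 <- buildA(rep$pedigree)@values
  Ai2 <- as.matrix(rep$ainv@values)
  expect_lt(max(abs(A2 %*% Ai2 - diag(nrow(A2)))), 1e-8)
})

test_that("A matches a gene-dropping estimate of twice the kinship", {
  rep <- tinyReplicate()
  f <- rep$pedigree@frame
  A <- buildA(rep$pedigree)@values
  n <- nrow(f)
  si <- match(f$sire, f$id); di <- match(f$dam, f$id)
  founders <- which(is.na(si))
  ndrop <- 100000L
  set.seed(8)
  # drop both alleles of every animal down the pedigree, vectorised over
  # replicate drops
  pat <- mat <- matrix(0L, n, ndrop)
  for (i in seq_len(n)) {
    if (is.na(si[i])) {
      pat[i, ] <- 2L * i - 1L
      mat[i, ] <- 2L * i
    } else {
      pickS <- rbinom(ndrop, 1L, 0.5) == 1L
      pat[i, ] <- ifelse(pickS, pat[si[i], ], mat[si[i], ])
      pickD <- rbinom(ndrop, 1L, 0.5) == 1L
      mat[i, ] <- ifelse(pickD, pat[di[i], ], mat[di[i], ])
    }
  }
  # one random allele per animal estimates kinship: P(equal) = f_ij = a_ij/2
  pairs <- rbind(c(1, 2), c(n, n - 1L), c(n, si[n]), c(n - 5L, n - 20L))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    ai <- ifelse(rbinom(ndrop, 1L, 0.5) == 1L, pat[i, ], mat[i, ])
    aj <- ifelse(rbinom(ndrop, 1L, 0.5) == 1L, pat[j, ], mat[j, ])
    fhat <- mean(ai == aj)
    se <- sqrt(max(fhat * (1 - fhat), 1e-6) / ndrop)
    expect_lt(abs(2 * fhat - A[i, j]), 3 * 2 * se + 1e-9)
  }
})

test_that("relationship blocks agree with the dense recursion", {
  rep <- tinyReplicate()
  f <- rep$pedigree@frame
  A <- buildA(rep$pedigree)@values
  ids <- f$id[c(3, 10, 50, 100)]
  B <- relationshipBlock(rep$pedigree, ids, f$id[1:20], ainv = rep$ainv)
  expect_lt(max(abs(B - A[c(3, 10, 50, 100), 1:20])), 1e-8)
})

test_that("VanRaden G matches hand computation and simple invariants", {
  dos <- matrix(c(0L, 1L, 2L), 3, 1, dimnames = list(1:3, "m"))
  G <- buildG(dos)
  # p = 0.5, Z = (-1, 0, 1), denominator 0.5
  expect_equal(unname(G@values), matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3))

  expect_error(buildG(matrix(2L, 3, 2, dimnames = list(1:3, NULL))),
               "monomorphic")
  expect_error(buildG(matrix(c(0L, 3L), 2, 1, dimnames = list(1:2, NULL))),
               "0/1/2")

  # duplicated individuals give identical rows/columns
  set.seed(9)
  d <- matrix(rbinom(40, 2, 0.4), 4, 10)
  d[2, ] <- d[1, ]
  rownames(d) <- 1:4
  G2 <- buildG(d)@values
  expect_equal(G2[1, ], G2[2, ])
  expect_equal(G2[, 1], G2[, 2])

  # with in-sample frequencies the mean diagonal is near 1
  rep <- tinyReplicate()
  set.seed(10)
  mapM <- genomeMap(chromosomes = 2L, markers = 200L, qtl = 0L)
  popM <- simulateHistorical(mapM, n = 100L, generations = 20L)
  fl <- mafFilter(popM, mapM, 0.05)
  GM <- buildG(dosageMatrix(fl$population))
  expect_lt(abs(mean(diag(GM@values)) - 1), 0.1)
})

test_that("rescaling G to the A11 scale solves the moment conditions", {
  set.seed(11)
  d <- matrix(rbinom(120, 2, 0.45), 6, 20, dimnames = list(1:6, NULL))
  G <- buildG(d)
  A11 <- diag(6) + 0.2
  out <- rescaleG(G, A11)
  expect_equal(mean(diag(out@values)), mean(diag(A11)), tolerance = 1e-12)
  expect_equal(mean(out@values), mean(A11), tolerance = 1e-12)

  # closed-form oracle for (alpha, beta): solve the 2x2 linear system
  M <- rbind(c(mean(diag(G@values)), 1), c(mean(G@values), 1))
  ab <- solve(M, c(mean(diag(A11)), mean(A11)))
  expect_equal(out@values, ab[2] + ab[1] * G@values, tolerance = 1e-12)

  # fixed point: rescaling an already matched matrix changes nothing
  again <- rescaleG(out, A11)
  expect_equal(again@values, out@values, tolerance = 1e-12)
})

test_that("blending is a convex combination with weight w", {
  set.seed(12)
  d <- matrix(rbinom(60, 2, 0.5), 3, 20, dimnames = list(1:3, NULL))
  G <- buildG(d)
  A11 <- diag(3) + 0.1
  expect_equal(blendG(G, A11, 0)@values, G@values)
  expect_equal(unname(blendG(G, A11, 1)@values), A11)
  expect_equal(blendG(G, A11, 0.05)@values,
               0.95 * G@values + 0.05 * A11, ignore_attr = TRUE)
  expect_error(blendG(G, A11, 1.2), "weight")

  # blended matrix is positive definite for w in (0, 1]
  Gw <- blendG(rescaleG(G, A11), A11, 0.05)
  ev <- eigen(Gw@values, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)
})

test_that("H collapses to A or Gw in the degenerate designs", {
  rep <- oracleReplicate()
  ped <- rep$pedigree
  f <- ped@frame
  A <- buildA(ped)@values
  gid <- f$id[seq(5, 44, by = 5)]
  i1 <- as.character(gid)
  A11 <- A[i1, i1]

  # Gw = A11: H equals A exactly
  GwA <- new("RelationshipMatrix", values = A11, ids = gid, kind = "Gw",
             genotyped = gid)
  H <- assembleH(ped, GwA)
  expect_equal(H@values, A, tolerance = 1e-10)

  # all animals genotyped: H equals Gw
  set.seed(13)
  dall <- matrix(rbinom(nrow(f) * 80, 2, 0.5), nrow(f), 80,
                 dimnames = list(f$id, NULL))
  Gall <- blendG(rescaleG(buildG(dall), A), A)
  Hall <- assembleH(ped, Gall)
  expect_equal(Hall@values[as.character(f$id), as.character(f$id)],
               Gall@values[as.character(f$id), as.character(f$id)],
               tolerance = 1e-10)
})

test_that("the dense H and the sparse H inverse describe the same matrix", {
  # 20-animal pedigree, 8 genotyped
  set.seed(14)
  f <- data.frame(id = 1:20,
                  sire = c(rep(0L, 6), sample(1:3, 14, TRUE)),
                  dam = c(rep(0L, 6), sample(4:6, 14, TRUE)),
                  generation = c(rep(0L, 6), rep(1L, 14)),
                  sex = rep(1:2, 10), breeding = rep(c(TRUE, FALSE), c(6, 14)))
  ped <- new("Pedigree", frame = f)
  gid <- c(2L, 5L, 7L, 9L, 12L, 15L, 18L, 20L)
  d <- matrix(rbinom(8 * 60, 2, 0.4), 8, 60, dimnames = list(gid, NULL))
  A <- buildA(ped)@values
  A11 <- A[as.character(gid), as.character(gid)]
  Gw <- blendG(rescaleG(buildG(d), A11), A11)
  H <- assembleH(ped, Gw)@values
  Hinv <- assembleHinverse(buildAinverse(ped), Gw, A11)
  expect_lt(max(abs(solve(as.matrix(Hinv@values)) - H)), 1e-8)
  # H restricted to the genotyped animals is Gw exactly
  expect_equal(H[as.character(gid), as.character(gid)], Gw@values,
               tolerance = 1e-12)
})
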