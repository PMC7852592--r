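# Forward simulator: meiosis, historical drift, MAF filtering, population
# expansion, trait architecture, phenotypes, pens, attrition, group records.

test_that("meiosis follows the Haldane model", {
  set.seed(1)
  # zero-length map: no recombination, gamete is one parental haplotype
  m0 <- new("GenomeMap", chromosome = rep(1L, 5), position = rep(0, 5) + 0:4 * 1e-9,
            type = rep("marker", 5), mutationRate = rep(0, 5),
            chromosomeLength = 1e-8)
  parent <- cbind(rep(0L, 5), rep(1L, 5))
  g <- meiosis(parent, m0, mutate = FALSE)
  expect_true(all(g == 0L) || all(g == 1L))

  # homozygous parent, no mutation: gamete equals either haplotype
  set.seed(2)
  m <- genomeMap(chromosomes = 1L, markers = 50L, qtl = 0L, mutationRate = 0)
  hom <- cbind(rep(1L, 50), rep(1L, 50))
  expect_identical(meiosis(hom, m, mutate = FALSE), rep(1L, 50))

  # two loci 100 cM apart: recombinant fraction (1 - exp(-2)) / 2
  m2 <- new("GenomeMap", chromosome = c(1L, 1L), position = c(0, 100),
            type = c("marker", "marker"), mutationRate = c(0, 0),
            chromosomeLength = 100)
  het <- cbind(c(0L, 0L), c(1L, 1L))
  set.seed(3)
  rec <- replicate(10000, { g <- meiosis(het, m2, mutate = FALSE); g[1] != g[2] })
  expected <- (1 - exp(-2)) / 2
  expect_lt(abs(mean(rec) - expected), 3 * sqrt(expected * (1 - expected) / 10000))
})

test_that("random mating preserves fixed alleles and zero generations is identity", {
  set.seed(4)
  map <- genomeMap(chromosomes = 2L, markers = 10L, qtl = 2L, mutationRate = 0)
  pop <- simulateHistorical(map, n = 20L, generations = 0L)
  expect_identical(randomMating(pop, map, 0L), pop)

  # force one locus fixed at allele 1 and drift without mutation
  hap <- pop@haplotypes
  hap[3, ] <- as.raw(1L)
  fixedPop <- new("HaplotypePopulation", haplotypes = hap, id = pop@id,
                  generation = pop@generation, sex = pop@sex)
  out <- randomMating(fixedPop, map, 30L, mutate = FALSE)
  expect_equal(alleleFrequencies(out)[3], 1)
})

test_that("MAF filtering removes exactly the rare loci", {
  expect_error(mafFilter(tinyReplicate()$population, genomeMap(1, 100, 1, 0),
                         threshold = 0.7),
               "threshold")
  map <- new("GenomeMap", chromosome = rep(1L, 3), position = c(1, 2, 3),
             type = c("marker", "qtl", "marker"),
             mutationRate = rep(0, 3), chromosomeLength = 100)
  # locus 1 at frequency 0.5, locus 2 fixed at 0, locus 3 fixed at 1
  hap <- matrix(as.raw(c(rep(c(1L, 0L), 4), rep(0L, 8), rep(1L, 8))),
                nrow = 3, byrow = TRUE)
  pop <- new("HaplotypePopulation", haplotypes = hap, id = 1:4,
             generation = rep(0L, 4), sex = c(1L, 1L, 2L, 2L))
  f <- mafFilter(pop, map, 0.01)
  expect_equal(nLoci(f$map), 1L)
  expect_equal(unname(f$retained), c(1L, 0L))
  expect_equal(unname(f$removed), c(1L, 1L))
  # all loci at 0.5: nothing removed
  hap2 <- matrix(as.raw(rep(c(1L, 0L), 12)), nrow = 3, byrow = TRUE)
  pop2 <- new("HaplotypePopulation", haplotypes = hap2, id = 1:4,
              generation = rep(0L, 4), sex = c(1L, 1L, 2L, 2L))
  expect_equal(nLoci(mafFilter(pop2, map, 0.01)$map), 3L)
})

test_that("recent population expansion reproduces the mating design", {
  rep <- fullReplicate()
  f <- rep$pedigree@frame
  expect_equal(nrow(f), 29430L)
  expect_equal(sum(f$generation %in% 5:8), 14400L)
  expect_equal(sum(f$generation == 0L), 630L)
  # every litter: one sire, one dam, three males and three females
  lit <- f[f$generation >= 1L, ]
  key <- paste(lit$generation, lit$dam)
  expect_true(all(tapply(lit$sire, key, function(s) length(unique(s))) == 1))
  expect_true(all(tapply(lit$sex, key, function(s) sum(s == 1L)) == 3))
  expect_true(all(tapply(lit$sex, key, length) == 6))
  # each dam appears in exactly one litter per generation
  dams <- unique(data.frame(g = lit$generation, d = lit$dam))
  expect_false(anyDuplicated(dams) > 0)
  # parents precede offspring, acyclic by construction
  expect_true(validObject(rep$pedigree))
})

test_that("QTL effect architecture scales and correlates as configured", {
  rep <- tinyReplicate()
  pop <- NULL # architecture checks need haplotypes; rebuild a small pop
  set.seed(5)
  map <- genomeMap(chromosomes = 2L, markers = 0L, qtl = 100L)
  pop <- simulateHistorical(map, n = 200L, generations = 10L)
  expect_error(traitArchitecture(pop, map, rg = 1.5), "correlation")

  arch <- traitArchitecture(pop, map, rg = 0.8, targetVariances = c(30, 100))
  bv <- trueBreedingValues(pop, arch)
  expect_equal(var(bv[, 1]), 30, tolerance = 1e-10)
  expect_equal(var(bv[, 2]), 100, tolerance = 1e-10)

  # rg = 1 with proportional targets: trait-2 values proportional to trait 1
  arch1 <- traitArchitecture(pop, map, rg = 1, targetVariances = c(30, 120))
  bv1 <- trueBreedingValues(pop, arch1)
  expect_equal(cor(bv1[, 1], bv1[, 2]), 1, tolerance = 1e-10)

  # Monte-Carlo: average breeding-value correlation across architectures
  cors <- replicate(50, {
    a <- traitArchitecture(pop, map, rg = 0.8)
    b <- trueBreedingValues(pop, a)
    cor(b[, 1], b[, 2])
  })
  expect_lt(abs(mean(cors) - 0.8), 0.05)
})

test_that("phenotypes decompose into mean, litter, pen, additive, residual", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  f <- ph@frame
  expect_equal(f$y1, ph@mean[1] + f$l1 + f$c1 + f$tbv1 + f$e1)
  expect_equal(f$y2, ph@mean[2] + f$l2 + f$c2 + f$tbv2 + f$e2)

  # all variances zero: record equals mean + breeding value
  zero <- new("VarianceComponents", pen = matrix(0, 2, 2),
              litter = matrix(0, 2, 2), additive = diag(c(30, 100)),
              residual = matrix(0, 2, 2))
  ph0 <- simulatePhenotypes(rep$pedigree, rep$tbv[[1]], rep$pens[[1]],
                            vc = zero, mean = c(5, -3), generations = 2:3)
  f0 <- ph0@frame
  expect_equal(f0$y1, 5 + f0$tbv1)
  expect_equal(f0$y2, -3 + f0$tbv2)
})

test_that("simulated effect (co)variances match the generating values", {
  rep <- fullReplicate()
  f <- rep$pheno[["S12_L2x3|0.8"]]@frame
  # residual correlation over 14,400 pairs: 0.5 within sampling error
  expect_lt(abs(cor(f$e1, f$e2) - 0.5), 0.02)
  # per-class variances within 3 SE of the generating values
  se2 <- function(v, n) 3 * v * sqrt(2 / n)
  expect_lt(abs(var(f$e1) - 50), se2(50, nrow(f)))
  expect_lt(abs(var(f$e2) - 220), se2(220, nrow(f)))
  litters <- !duplicated(f$litter)
  expect_lt(abs(var(f$l1[litters]) - 10), se2(10, sum(litters)))
  pens <- !duplicated(f$pen)
  expect_lt(abs(var(f$c1[pens]) - 10), se2(10, sum(pens)))
})

test_that("pen assignment respects the grouping scenarios", {
  rep <- fullReplicate()
  f <- rep$pedigree@frame

  s12 <- rep$pens[["S12_L2x3"]]
  sizes <- groupSizes(s12)
  expect_equal(length(sizes), 1200L)         # 300 pens x 4 generations
  expect_true(all(sizes == 12))
  s24 <- rep$pens[["S24_L2x3"]]
  expect_equal(length(groupSizes(s24)), 600L)
  expect_true(all(groupSizes(s24) == 24))

  litterOf <- setNames(paste(f$generation, f$dam), f$id)
  checkSublitters <- function(pens, perPen) {
    tr <- as(pens@incidence, "TsparseMatrix")
    members <- split(pens@member[tr@j + 1L], pens@group[tr@i + 1L])
    counts <- vapply(members, function(m) {
      tab <- table(litterOf[as.character(m)])
      all(tab == 3) && length(tab) == perPen
    }, logical(1))
    all(counts)
  }
  # each pen: perPen sublitters of size 3, all from distinct litters
  expect_true(checkSublitters(s12, 4L))
  expect_true(checkSublitters(s24, 8L))
})

test_that("random pen assignment matches the combinatorial expectation", {
  # 10 litters of 6, pens of 12: expected within-pen full-sib pairs
  set.seed(6)
  ped <- new("Pedigree", frame = data.frame(
    id = 1:72, sire = c(rep(0L, 12), rep(1:2, each = 30)),
    dam = c(rep(0L, 12), rep(3:12, each = 6)),
    generation = c(rep(0L, 12), rep(1L, 60)), sex = rep(1:2, 36),
    breeding = c(rep(TRUE, 12), rep(FALSE, 60))))
  nFullSibPairs <- function(pens) {
    f <- ped@frame[ped@frame$generation == 1L, ]
    lit <- setNames(paste(f$sire, f$dam), f$id)
    tr <- as(pens@incidence, "TsparseMatrix")
    members <- split(pens@member[tr@j + 1L], pens@group[tr@i + 1L])
    sum(vapply(members, function(m) {
      tab <- table(lit[as.character(m)])
      sum(choose(tab, 2))
    }, numeric(1)))
  }
  counts <- replicate(300, nFullSibPairs(assignPens(ped, "S12_Lran", 1L)))
  # each litter has choose(6,2)=15 pairs; P(pair shares a pen) = 11/59
  expected <- 10 * 15 * 11 / 59
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(300))
})

test_that("attrition removes 20% of records among non-breeders only", {
  rep <- fullReplicate()
  ph <- rep$pheno[["S12_L2x3|0.8"]]
  f <- ph@frame
  expect_equal(sum(!f$hasRecord), round(0.2 * nrow(f)))
  breeding <- rep$pedigree@frame$breeding[match(f$id, rep$pedigree@frame$id)]
  expect_true(all(f$hasRecord[breeding]))
  # post-attrition pen sizes: mean 0.8 x 12 within sampling error, range 4-12
  sz <- groupSizes(subsetGroups(rep$pens[["S12_L2x3"]], f$id[f$hasRecord]))
  expect_lt(abs(mean(sz) - 9.6), 0.15)
  # pens below 4 survivors are possible but vanishingly rare
  expect_lt(mean(sz < 4), 0.005)
  expect_lte(max(sz), 12)
  # breeding animals are ~16.5% of the post-attrition data
  expect_lt(abs(mean(breeding[f$hasRecord]) - 0.165), 0.01)
  # fraction 0 is the identity
  expect_identical(applyAttrition(ph, rep$pedigree, 0), ph)
})

test_that("genotyping designs select the documented sets", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  ped <- rep$pedigree
  recorded <- ph@frame$id[ph@frame$hasRecord]
  expect_identical(selectGenotyped(ph, ped, 0), integer(0))
  expect_setequal(selectGenotyped(ph, ped, 100), recorded)
  g30 <- selectGenotyped(ph, ped, 30)
  expect_equal(length(g30), round(0.3 * length(recorded)))
  breeding <- intersect(recorded, ped@frame$id[ped@frame$breeding])
  expect_true(all(breeding %in% g30))
})

test_that("group records are pen sums and conserve the total", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  gr <- makeGroupRecords(ph, rep$pens[[1]])
  f <- ph@frame[ph@frame$hasRecord, ]
  expect_equal(sum(gr$y1), sum(f$y1))
  expect_equal(gr$size, vapply(strsplit(gr$members, ";"), length, numeric(1)))
  # a pen reduced to one member carries that record alone
  one <- gr[gr$size == 1, ]
  if (nrow(one)) {
    expect_equal(one$y1[1], f$y1[f$id == as.integer(one$members[1])])
  }
  # hand-computed sum
  m1 <- as.integer(strsplit(gr$members[1], ";")[[1]])
  expect_equal(gr$y1[1], sum(f$y1[match(m1, f$id)]))
})

test_that("empty pens are dropped from group records with a warning", {
  rep <- tinyReplicate()
  ph <- rep$pheno[[1]]
  f <- ph@frame
  # wipe out one entire pen
  f$hasRecord[f$pen == f$pen[1]] <- FALSE
  ph2 <- new("PhenotypeSet", frame = f, mean = ph@mean)
  expect_warning(gr <- makeGroupRecords(ph2, rep$pens[[1]]), "empty pen")
  expect_false(f$pen[1] %in% gr$pen)
})

test_that("the full-density historical phase reproduces the segregating counts and LD decay", {
  set.seed(24)
  map <- genomeMap()                       # 18 x (3100 markers + 50 QTL)
  pop <- simulateHistorical(map)           # 400 animals, 300 generations
  flt <- mafFilter(pop, map)
  # segregating loci after the MAF filter, within 10%
  expect_lt(abs(flt$retained[["marker"]] - 43638) / 43638, 0.10)
  expect_lt(abs(flt$retained[["qtl"]] - 708) / 708, 0.10)
  ld <- computeLdDecay(flt$population, flt$map, breaks = seq(0, 50, by = 5),
                       pairsPerChromosome = 5000L)
  # drift-generated LD decays with distance: non-increasing bin means (with
  # a small Monte-Carlo slack) and clearly higher for adjacent than for
  # distant markers
  expect_true(all(diff(ld$meanR2) < 0.005))
  expect_gt(ld$meanR2[1], 2 * ld$meanR2[ld$lower >= 10][1])
})

test_that("linkage disequilibrium decays with map distance", {
  # duplicated locus: r^2 = 1
  map <- new("GenomeMap", chromosome = c(1L, 1L), position = c(10, 10 + 1e-6),
             type = c("marker", "marker"), mutationRate = c(0, 0),
             chromosomeLength = 100)
  hap <- matrix(as.raw(rep(c(1L, 0L, 1L, 0L), 2)), nrow = 2, byrow = TRUE)
  pop <- new("HaplotypePopulation", haplotypes = hap, id = 1:2,
             generation = c(0L, 0L), sex = 1:2)
  ld <- computeLdDecay(pop, map, breaks = c(0, 5), loci = 1:2)
  expect_equal(ld$meanR2[1], 1)

  # independent loci: mean r^2 near the 1/(2n) sampling floor
  set.seed(7)
  n <- 200L
  m <- 60L
  mapI <- new("GenomeMap", chromosome = rep(1L, m), position = sort(runif(m, 0, 100)),
              type = rep("marker", m), mutationRate = rep(0, m),
              chromosomeLength = 100)
  hapI <- matrix(as.raw(rbinom(m * 2 * n, 1, 0.5)), nrow = m)
  popI <- new("HaplotypePopulation", haplotypes = hapI, id = seq_len(n),
              generation = rep(0L, n), sex = rep(1:2, n / 2))
  ldI <- computeLdDecay(popI, mapI, breaks = c(0, 100), loci = seq_len(m))
  expect_lt(abs(ldI$meanR2[1] - 1 / (2 * n)), 3 / (2 * n))
})
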