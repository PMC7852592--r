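# Forward-in-time simulation: historical random-mating phase that builds up
# linkage disequilibrium, minor-allele-frequency filtering, and expansion
# into the pedigreed recent population with litters and non-overlapping
# generations.

.mutationRate <- function(map) {
  if (nLoci(map) == 0) return(0)
  mu <- unique(map@mutationRate)
  if (length(mu) > 1L)
    stop("meiosis kernel requires a single common mutation rate")
  mu
}

#' Simulate the historical population
#'
#' Random mating at constant size for a number of discrete generations with
#' recurrent 0/1 mutation, starting from founders whose per-locus allele
#' frequencies are drawn uniformly on `frequencyRange`. This phase builds up
#' linkage disequilibrium by drift; the last generation is returned.
#'
#' The default founder range (0.1, 0.9) is calibrated so that, after 300
#' generations of drift at size 400 and the 1% minor-allele-frequency
#' filter, about 78% of loci remain segregating — the proportion observed
#' in the nucleus-population design this simulator emulates. A fully
#' uniform (0, 1) draw loses noticeably more loci to drift.
#'
#' @param map a [GenomeMap]
#' @param n population size (even; half of each sex)
#' @param generations number of historical generations
#' @param mutate logical; apply recurrent mutation at the map's rate
#' @param frequencyRange range of the uniform founder allele-frequency draw
#' @return a [HaplotypePopulation] (generation index = `generations`)
#' @export
simulateHistorical <- function(map, n = 400L, generations = 300L,
                               mutate = TRUE,
                               frequencyRange = c(0.1, 0.9)) {
  if (n <= 0 || n %% 2L != 0L) stop("population size must be positive and even")
  if (generations < 0) stop("generations must be >= 0")
  validObject(map)
  m <- nLoci(map)
  p <- runif(m, frequencyRange[1], frequencyRange[2])
  hap <- matrix(as.raw(rbinom(m * 2L * n, 1L, rep(p, 2L * n))), nrow = m)
  founders <- new("HaplotypePopulation", haplotypes = hap, id = seq_len(n),
                  generation = rep(0L, n), sex = rep(1:2, each = n %/% 2L))
  randomMating(founders, map, generations, mutate = mutate)
}

#' Random mating at constant size
#'
#' Advances a population by discrete generations of random mating (random
#' sire among the males, random dam among the females, per offspring) at
#' constant size and sex ratio.
#'
#' @param pop a [HaplotypePopulation]
#' @param map the matching [GenomeMap]
#' @param generations number of generations (0 returns `pop` unchanged)
#' @param mutate logical; apply recurrent mutation at the map's rate
#' @return a [HaplotypePopulation] of the final generation
#' @export
randomMating <- function(pop, map, generations, mutate = TRUE) {
  if (generations < 0) stop("generations must be >= 0")
  if (generations == 0) return(pop)
  nM <- sum(pop@sex == 1L)
  nF <- sum(pop@sex == 2L)
  ord <- order(pop@sex)            # kernel expects males first
  hap <- pop@haplotypes[, as.vector(rbind(2L * ord - 1L, 2L * ord)),
                        drop = FALSE]
  rg <- .chrRanges(map)
  mu <- if (mutate) .mutationRate(map) else 0
  hap <- cpp_random_mating(hap, nM, nF, map@position, rg$start, rg$end,
                           map@chromosomeLength, mu, as.integer(generations))
  new("HaplotypePopulation", haplotypes = hap,
      id = seq_len(nM + nF),
      generation = rep(max(pop@generation) + as.integer(generations), nM + nF),
      sex = rep(1:2, c(nM, nF)))
}

#' One meiosis
#'
#' Forms a gamete from a parent's two phased haplotypes under the Haldane
#' model: Poisson(chromosome length in Morgan) crossovers placed uniformly,
#' no interference, followed by per-locus 0/1 mutation at the map's rate.
#'
#' @param parent matrix with loci in rows and the parent's two haplotypes as
#'   columns (integer 0/1 or raw)
#' @param map a [GenomeMap]
#' @param mutate logical; apply mutation
#' @return integer 0/1 gamete of length `nLoci(map)`
#' @export
meiosis <- function(parent, map, mutate = TRUE) {
  if (ncol(parent) != 2L || nrow(parent) != nLoci(map))
    stop("parent must be a loci x 2 haplotype matrix aligned to the map")
  hap <- matrix(as.raw(as.integer(parent)), nrow = nrow(parent))
  rg <- .chrRanges(map)
  mu <- if (mutate) .mutationRate(map) else 0
  as.integer(cpp_gamete(hap, 1L, map@position, rg$start, rg$end,
                        map@chromosomeLength, mu))
}

#' Remove loci with low minor allele frequency
#'
#' Loci with minor allele frequency below `threshold` (computed from the
#' population itself) are removed from both the haplotypes and the map.
#'
#' @param pop a [HaplotypePopulation]
#' @param map the matching [GenomeMap]
#' @param threshold minimum minor allele frequency, in `[0, 0.5]`
#' @return list with elements `population`, `map`, and `retained` /
#'   `removed` counts split by locus class
#' @export
mafFilter <- function(pop, map, threshold = 0.01) {
  if (threshold < 0 || threshold > 0.5)
    stop("MAF threshold must be in [0, 0.5]")
  p <- alleleFrequencies(pop)
  maf <- pmin(p, 1 - p)
  keep <- maf >= threshold
  count <- function(w) c(marker = sum(map@type[w] == "marker"),
                         qtl = sum(map@type[w] == "qtl"))
  pop2 <- new("HaplotypePopulation",
              haplotypes = pop@haplotypes[keep, , drop = FALSE],
              id = pop@id, generation = pop@generation, sex = pop@sex)
  list(population = pop2, map = subsetMap(map, which(keep)),
       retained = count(keep), removed = count(!keep))
}

#' Expand the recent pedigreed population
#'
#' From the last historical generation, a base step mates `sires` randomly
#' chosen males to `baseDams` females (litters of `litterSize`, equal sex
#' ratio); all base females plus `sires` random base males form generation 0.
#' Each of the `generations` following non-overlapping generations then uses
#' `sires` sires and `litters` dams (each sire mated to `litters/sires` dams
#' at random), every litter consisting of `litterSize/2` males and
#' `litterSize/2` females.
#'
#' With the default sizes this yields 630 generation-0 founders plus
#' 8 x 3600 descendants: a pedigree of 29,430 individuals.
#'
#' @param founders a [HaplotypePopulation] from [simulateHistorical()]
#' @param map the matching [GenomeMap]
#' @param generations number of recent generations
#' @param litters litters (dams) per generation
#' @param litterSize offspring per litter (even)
#' @param sires sires per generation
#' @param mutate logical; apply mutation during the recent phase (off by
#'   default: mutation acts in the historical phase only)
#' @return list with elements `pedigree` (a [Pedigree]) and `population`
#'   (a [HaplotypePopulation] holding every pedigree individual)
#' @export
expandRecentPopulation <- function(founders, map, generations = 8L,
                                   litters = 600L, litterSize = 6L,
                                   sires = 30L, mutate = FALSE) {
  generations <- as.integer(generations)
  litters <- as.integer(litters)
  litterSize <- as.integer(litterSize)
  sires <- as.integer(sires)
  if (litterSize %% 2L != 0L) stop("litter size must be even")
  if (litters %% sires != 0L) stop("litters must be divisible by sires")
  nf <- nIndividuals(founders)
  males <- which(founders@sex == 1L)
  females <- which(founders@sex == 2L)
  baseDams <- ceiling(litters / (litterSize / 2L))
  if (length(males) < sires || length(females) < baseDams)
    stop("insufficient founders for the base mating step")
  rg <- .chrRanges(map)
  mu <- if (mutate) .mutationRate(map) else 0

  ## base step: litters of litterSize from baseDams dams x `sires` sires
  baseSires <- sample(males, sires)
  damPick <- sample(females, baseDams)
  litterSire <- sample(baseSires, baseDams, replace = TRUE)
  sireVec <- rep(litterSire, each = litterSize)
  damVec <- rep(damPick, each = litterSize)
  baseHap <- cpp_make_offspring(founders@haplotypes, as.integer(sireVec),
                                as.integer(damVec), map@position, rg$start,
                                rg$end, map@chromosomeLength, mu)
  nBase <- baseDams * litterSize
  baseSex <- as.integer(unlist(lapply(seq_len(baseDams), function(i)
    rep(1:2, each = litterSize / 2L))))

  ## generation 0 = all base females + `sires` random base males
  f0 <- which(baseSex == 2L)
  m0 <- sample(which(baseSex == 1L), sires)
  keep0 <- c(m0, f0)
  sex0 <- baseSex[keep0]
  n0 <- length(keep0)
  hap <- vector("list", generations + 1L)
  hap[[1]] <- baseHap[, as.vector(rbind(2L * keep0 - 1L, 2L * keep0)),
                      drop = FALSE]

  id0 <- seq_len(n0)
  ped <- data.frame(id = id0, sire = 0L, dam = 0L, generation = 0L,
                    sex = sex0, breeding = FALSE)
  prevIds <- id0
  prevSex <- sex0
  nextId <- n0 + 1L
  damsPerSire <- litters %/% sires
  litterHalf <- litterSize / 2L

  for (g in seq_len(generations)) {
    sireIds <- sample(prevIds[prevSex == 1L], sires)
    damIds <- sample(prevIds[prevSex == 2L], litters)
    litterSireIds <- rep(sireIds, each = damsPerSire)[sample.int(litters)]
    nOff <- litters * litterSize
    offSire <- rep(litterSireIds, each = litterSize)
    offDam <- rep(damIds, each = litterSize)
    # parent columns within previous generation's haplotype block
    sireCol <- match(offSire, prevIds)
    damCol <- match(offDam, prevIds)
    hap[[g + 1L]] <- cpp_make_offspring(hap[[g]], as.integer(sireCol),
                                        as.integer(damCol), map@position,
                                        rg$start, rg$end,
                                        map@chromosomeLength, mu)
    offSex <- rep(rep(1:2, each = litterHalf), litters)
    offIds <- seq.int(nextId, length.out = nOff)
    ped <- rbind(ped, data.frame(id = offIds, sire = offSire, dam = offDam,
                                 generation = g, sex = offSex,
                                 breeding = FALSE))
    ped$breeding[ped$id %in% c(sireIds, damIds)] <- TRUE
    prevIds <- offIds
    prevSex <- offSex
    nextId <- nextId + nOff
  }

  allHap <- do.call(cbind, hap)
  pop <- new("HaplotypePopulation", haplotypes = allHap, id = ped$id,
             generation = ped$generation, sex = ped$sex)
  list(pedigree = new("Pedigree", frame = ped), population = pop)
}

#' Linkage disequilibrium decay by map distance
#'
#' Computes `r^2` between pairs of marker loci on the same chromosome from
#' haplotype frequencies and averages it within map-distance bins. Pairs are
#' subsampled per chromosome when the number of possible pairs is large;
#' monomorphic loci are skipped.
#'
#' @param pop a [HaplotypePopulation]
#' @param map the matching [GenomeMap]
#' @param breaks distance bin edges in centimorgan
#' @param pairsPerChromosome pairs sampled per chromosome
#' @param loci candidate locus indices (default: the map's markers, or all
#'   loci when the map has no markers)
#' @return data.frame with bin edges, mean `r^2` and pair count
#' @export
computeLdDecay <- function(pop, map, breaks = seq(0, 50, by = 5),
                           pairsPerChromosome = 20000L, loci = NULL) {
  if (is.null(loci)) {
    loci <- markerLoci(map)
    if (!length(loci)) loci <- seq_len(nLoci(map))
  }
  H <- pop@haplotypes
  p <- alleleFrequencies(pop)
  poly <- loci[p[loci] > 0 & p[loci] < 1]
  nb <- length(breaks) - 1L
  sums <- counts <- numeric(nb)
  for (c in unique(map@chromosome[poly])) {
    idx <- poly[map@chromosome[poly] == c]
    if (length(idx) < 2L) next
    i <- sample(idx, pairsPerChromosome, replace = TRUE)
    j <- sample(idx, pairsPerChromosome, replace = TRUE)
    keep <- i < j
    i <- i[keep]; j <- j[keep]
    if (!length(i)) next
    d <- map@position[j] - map@position[i]
    bin <- findInterval(d, breaks, rightmost.closed = TRUE)
    ok <- bin >= 1L & bin <= nb
    i <- i[ok]; j <- j[ok]; bin <- bin[ok]
    if (!length(i)) next
    r2 <- .pairR2(H, i, j, p)
    for (b in unique(bin)) {
      sums[b] <- sums[b] + sum(r2[bin == b])
      counts[b] <- counts[b] + sum(bin == b)
    }
  }
  data.frame(lower = breaks[-length(breaks)], upper = breaks[-1],
             meanR2 = ifelse(counts > 0, sums / counts, NA_real_),
             nPairs = counts)
}

# r^2 from haplotype frequencies for locus pairs (rows i, j of H)
.pairR2 <- function(H, i, j, p) {
  n <- ncol(H)
  hi <- matrix(as.integer(H[i, , drop = FALSE]), nrow = length(i))
  hj <- matrix(as.integer(H[j, , drop = FALSE]), nrow = length(j))
  p11 <- rowMeans(hi * hj)
  D <- p11 - p[i] * p[j]
  D^2 / (p[i] * (1 - p[i]) * p[j] * (1 - p[j]))
}
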