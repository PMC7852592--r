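# Trait architecture, pen assignment, phenotype simulation, attrition and
# the pen-sum (group) records.

# sample n draws from N(0, Sigma), Sigma t x t (t = 1 or 2)
.rmvn <- function(n, Sigma) {
  t <- nrow(Sigma)
  z <- matrix(rnorm(n * t), n, t)
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), t) %*% t(ev$vectors)
  z %*% L
}

#' Sample a bivariate QTL effect architecture
#'
#' QTL allele-substitution effect pairs are sampled i.i.d. from a bivariate
#' normal distribution with correlation `rg` (the genetic correlation between
#' the two traits). The raw true breeding value of an individual is the sum
#' of its allele effects over both haplotypes; per-trait scaling constants
#' are then chosen so that the empirical variance of true breeding values in
#' the reference individuals equals `targetVariances` exactly.
#'
#' @param pop a [HaplotypePopulation] containing the reference individuals
#' @param map the matching [GenomeMap]
#' @param rg genetic correlation of the effect pairs, in `[-1, 1]`
#' @param targetVariances length-2 additive variances to scale to
#' @param reference indices (into `pop`) of the reference individuals whose
#'   breeding-value variance is standardised; default: all
#' @return a [TraitArchitecture]
#' @export
traitArchitecture <- function(pop, map, rg = 0.8, targetVariances = c(30, 100),
                              reference = seq_len(nIndividuals(pop))) {
  if (abs(rg) > 1) stop("genetic correlation must be in [-1, 1]")
  loci <- qtlLoci(map)
  if (!length(loci)) stop("map contains no QTL")
  Sigma <- matrix(c(1, rg, rg, 1), 2, 2)
  eff <- .rmvn(length(loci), Sigma)
  dos <- dosageMatrix(pop, loci)[reference, , drop = FALSE]
  raw <- dos %*% eff
  v <- apply(raw, 2, var)
  if (any(v <= 0)) stop("degenerate QTL genotypes: zero breeding-value variance")
  sc <- sqrt(targetVariances / v)
  new("TraitArchitecture", loci = as.integer(loci),
      effects = eff * rep(sc, each = nrow(eff)), scale = sc,
      correlation = rg, targetVariances = targetVariances)
}

#' True breeding values under an architecture
#'
#' @param pop a [HaplotypePopulation]
#' @param arch a [TraitArchitecture]
#' @return numeric matrix (individuals x 2), rownames = ids
#' @export
trueBreedingValues <- function(pop, arch) {
  dos <- dosageMatrix(pop, arch@loci)
  bv <- dos %*% arch@effects
  dimnames(bv) <- list(as.character(pop@id), c("tbv1", "tbv2"))
  bv
}

# litter label of each pedigree row (generation x dam); founders get NA
.litterLabels <- function(pedFrame) {
  ifelse(pedFrame$dam == 0L, NA_character_,
         paste0("L", pedFrame$generation, "_", pedFrame$dam))
}

#' Assign animals of each generation to pens
#'
#' Pens are constructed within generation according to the grouping
#' scenario:
#' \describe{
#'   \item{S12_L2x3}{every litter is split at random into two sublitters of
#'     half the litter size; pens of 12 are formed from 4 sublitters of 4
#'     distinct litters (the two sublitters of a litter never share a pen).}
#'   \item{S24_L2x3}{as above with pens of 24 formed from 8 sublitters.}
#'   \item{S12_Lran}{individuals are permuted uniformly into pens of up to
#'     12 (a remainder pen may be smaller).}
#' }
#'
#' @param ped a [Pedigree]
#' @param scenario grouping scenario name
#' @param generations generations to build pens for
#' @return a [GroupIncidence] over all members of those generations
#' @export
assignPens <- function(ped, scenario = c("S12_L2x3", "S12_Lran", "S24_L2x3"),
                       generations = 5:8) {
  scenario <- match.arg(scenario)
  f <- ped@frame
  penOf <- character(0)
  ids <- integer(0)
  for (g in generations) {
    sub <- f[f$generation == g, ]
    if (!nrow(sub)) next
    if (scenario == "S12_Lran") {
      perm <- sample(sub$id)
      pen <- paste0("G", g, "P", ceiling(seq_along(perm) / 12))
      ids <- c(ids, perm)
      penOf <- c(penOf, pen)
    } else {
      perPen <- if (scenario == "S12_L2x3") 4L else 8L
      asg <- .assignSublitters(sub, perPen)
      ids <- c(ids, asg$id)
      penOf <- c(penOf, paste0("G", g, "P", asg$pen))
    }
  }
  groups <- sort(unique(penOf))
  Tm <- Matrix::sparseMatrix(i = match(penOf, groups), j = seq_along(ids),
                             x = 1, dims = c(length(groups), length(ids)))
  new("GroupIncidence", incidence = Tm, group = groups, member = ids)
}

# split litters into two random sublitters and pack `perPen` sublitters per
# pen such that the two halves of a litter never meet
.assignSublitters <- function(sub, perPen) {
  litter <- .litterLabels(sub)
  byLitter <- split(sub$id, litter)
  half <- length(byLitter[[1]]) / 2L
  slMembers <- list(); slLitter <- character(0)
  for (l in names(byLitter)) {
    m <- sample(byLitter[[l]])
    if (length(m) %% 2L != 0L) stop("litter size must be even for sublitter split")
    h <- length(m) / 2L
    slMembers <- c(slMembers, list(m[seq_len(h)], m[(h + 1L):length(m)]))
    slLitter <- c(slLitter, l, l)
  }
  ns <- length(slMembers)
  if (ns %% perPen != 0L)
    stop("generation size does not divide into pens of ", perPen, " sublitters")
  nPens <- ns %/% perPen
  pen <- rep(seq_len(nPens), each = perPen)[sample.int(ns)]
  # repair clashes: both sublitters of one litter in the same pen
  for (iter in seq_len(1000L)) {
    clash <- which(vapply(split(pen, slLitter), function(p)
      anyDuplicated(p) > 0L, logical(1)))
    if (!length(clash)) break
    litters <- names(split(pen, slLitter))[clash]
    for (l in litters) {
      s <- which(slLitter == l)
      if (length(unique(pen[s])) == length(s)) next  # fixed by an earlier swap
      s1 <- s[1]
      repeat {
        s2 <- sample.int(ns, 1L)
        if (pen[s2] == pen[s1]) next
        # swapping s1 and s2 must not create a clash for either litter
        l2 <- slLitter[s2]
        otherL2 <- setdiff(which(slLitter == l2), s2)
        othersL1 <- setdiff(s, s1)
        if (pen[s1] %in% pen[otherL2]) next
        if (pen[s2] %in% pen[othersL1]) next
        tmp <- pen[s1]; pen[s1] <- pen[s2]; pen[s2] <- tmp
        break
      }
    }
  }
  if (length(clash <- which(vapply(split(pen, slLitter), function(p)
    anyDuplicated(p) > 0L, logical(1)))))
    stop("could not resolve sublitter clashes")
  data.frame(id = unlist(slMembers),
             pen = rep(pen, vapply(slMembers, length, integer(1))))
}

#' Construct a group incidence
#'
#' @param incidence 0/1 matrix (dense or sparse), groups x individuals
#' @param group group identifiers (default: rownames or G1..Gn)
#' @param member individual ids (default: integer colnames)
#' @return a [GroupIncidence]
#' @export
groupIncidence <- function(incidence, group = NULL, member = NULL) {
  M <- as(as(as(Matrix::Matrix(incidence), "generalMatrix"), "CsparseMatrix"),
          "dMatrix")
  if (is.null(group))
    group <- if (!is.null(rownames(M))) rownames(M)
             else paste0("G", seq_len(nrow(M)))
  if (is.null(member))
    member <- if (!is.null(colnames(M))) as.integer(colnames(M))
              else seq_len(ncol(M))
  new("GroupIncidence", incidence = M, group = as.character(group),
      member = as.integer(member))
}

#' Generating (co)variance components of the reference study
#'
#' The study conditions for the two traits (trait 1 heritability 0.3,
#' trait 2 heritability 0.25): pen variances 10/40, litter variances 10/40,
#' additive variances 30/100, residual variances 50/220, with between-trait
#' correlations 0.3 (pen), 0.3 (litter), `rg` (additive) and 0.5 (residual).
#'
#' @param rg additive genetic correlation
#' @param traits 1 or 2
#' @return a [VarianceComponents]
#' @export
trueVarianceComponents <- function(rg = 0.8, traits = 2L) {
  mk <- function(v1, v2, r) {
    m <- matrix(c(v1, r * sqrt(v1 * v2), r * sqrt(v1 * v2), v2), 2, 2)
    if (traits == 1L) m <- m[1, 1, drop = FALSE]
    m
  }
  new("VarianceComponents", pen = mk(10, 40, 0.3), litter = mk(10, 40, 0.3),
      additive = mk(30, 100, rg), residual = mk(50, 220, 0.5))
}

#' Simulate two-trait phenotypes for the recorded generations
#'
#' Pen, litter and residual effect pairs are drawn from bivariate normal
#' distributions with the generating (co)variances; each record is
#' `mean + litter + pen + additive + residual` per trait. Phenotypes are
#' generated only for individuals of `generations`.
#'
#' @param ped a [Pedigree]
#' @param tbv true breeding-value matrix from [trueBreedingValues()]
#' @param pens a [GroupIncidence] covering all recorded individuals
#' @param vc generating [VarianceComponents] (2 traits)
#' @param mean length-2 overall trait means
#' @param generations generations that receive records
#' @return a [PhenotypeSet]
#' @export
simulatePhenotypes <- function(ped, tbv, pens, vc = trueVarianceComponents(),
                               mean = c(0, 0), generations = 5:8) {
  f <- ped@frame[ped@frame$generation %in% generations, ]
  # map member -> pen from the incidence matrix
  memberPen <- character(length(pens@member))
  Tt <- as(pens@incidence, "TsparseMatrix")
  memberPen[Tt@j + 1L] <- pens@group[Tt@i + 1L]
  penLookup <- setNames(memberPen, as.character(pens@member))
  pen <- unname(penLookup[as.character(f$id)])
  litter <- .litterLabels(f)
  if (anyNA(pen) || anyNA(litter))
    stop("every recorded individual needs a pen and a litter label")
  litterLv <- unique(litter)
  penLv <- unique(pen)
  lEff <- .rmvn(length(litterLv), vc@litter)
  cEff <- .rmvn(length(penLv), vc@pen)
  eEff <- .rmvn(nrow(f), vc@residual)
  li <- match(litter, litterLv)
  pi <- match(pen, penLv)
  a <- tbv[as.character(f$id), , drop = FALSE]
  y1 <- mean[1] + lEff[li, 1] + cEff[pi, 1] + a[, 1] + eEff[, 1]
  y2 <- mean[2] + lEff[li, 2] + cEff[pi, 2] + a[, 2] + eEff[, 2]
  frame <- data.frame(id = f$id, generation = f$generation, litter = litter,
                      pen = pen, y1 = y1, y2 = y2, tbv1 = a[, 1],
                      tbv2 = a[, 2], l1 = lEff[li, 1], l2 = lEff[li, 2],
                      c1 = cEff[pi, 1], c2 = cEff[pi, 2], e1 = eEff[, 1],
                      e2 = eEff[, 2], hasRecord = TRUE)
  new("PhenotypeSet", frame = frame, mean = as.numeric(mean))
}

#' Random attrition of recorded animals
#'
#' Removes the records of a fraction of the recorded animals, drawn at
#' random among non-breeding animals only (all parents of later generations
#' keep their records). Removed animals stay in the pedigree; pen sizes are
#' recomputed downstream from the surviving members.
#'
#' @param pheno a [PhenotypeSet]
#' @param ped the matching [Pedigree]
#' @param fraction fraction of all recorded animals to remove
#' @param deleted optional ids to remove instead of drawing them; used to
#'   apply one common deletion set to several datasets of one replicate
#' @return the [PhenotypeSet] with `hasRecord = FALSE` for removed animals
#' @export
applyAttrition <- function(pheno, ped, fraction = 0.2, deleted = NULL) {
  if (fraction == 0 && is.null(deleted)) return(pheno)
  f <- pheno@frame
  if (is.null(deleted)) {
    breeding <- ped@frame$breeding[match(f$id, ped@frame$id)]
    candidates <- which(f$hasRecord & !breeding)
    nDel <- round(fraction * sum(f$hasRecord))
    if (nDel > length(candidates))
      stop("attrition fraction exceeds the proportion of non-breeding animals")
    deleted <- f$id[sample(candidates, nDel)]
  }
  f$hasRecord[f$id %in% deleted] <- FALSE
  new("PhenotypeSet", frame = f, mean = pheno@mean)
}

#' Restrict a group incidence to surviving members
#'
#' @param pens a [GroupIncidence]
#' @param ids ids of individuals that still have records
#' @param dropEmpty drop groups left without members
#' @return a [GroupIncidence]
#' @export
subsetGroups <- function(pens, ids, dropEmpty = TRUE) {
  keep <- pens@member %in% ids
  Tm <- pens@incidence[, keep, drop = FALSE]
  grp <- pens@group
  if (dropEmpty) {
    nz <- Matrix::rowSums(Tm) > 0
    Tm <- Tm[nz, , drop = FALSE]
    grp <- grp[nz]
  }
  new("GroupIncidence", incidence = Tm, group = grp,
      member = pens@member[keep])
}

#' Select the genotyped animals for a genotyping design
#'
#' Designs: 0% (nobody), 100% (every recorded animal), or 30% (all breeding
#' animals among the recorded generations plus a random fill-up to 30% of
#' the post-attrition data size).
#'
#' @param pheno a [PhenotypeSet] (after attrition)
#' @param ped the matching [Pedigree]
#' @param design 0, 30 or 100 (percent)
#' @return integer ids of genotyped animals
#' @export
selectGenotyped <- function(pheno, ped, design = c(0, 30, 100)) {
  design <- match.arg(as.character(design[1]), c("0", "30", "100"))
  f <- pheno@frame
  recorded <- f$id[f$hasRecord]
  if (design == "0") return(integer(0))
  if (design == "100") return(recorded)
  breeding <- ped@frame$id[ped@frame$breeding]
  core <- intersect(recorded, breeding)
  target <- round(0.30 * length(recorded))
  if (length(core) > target)
    stop("breeding animals already exceed the 30% genotyping target")
  fill <- sample(setdiff(recorded, core), target - length(core))
  sort(c(core, fill))
}

#' Pen-sum (group) records for trait 1
#'
#' One record per pen equal to the sum of the surviving members' trait-1
#' records; empty pens are excluded with a warning.
#'
#' @param pheno a [PhenotypeSet]
#' @param pens a [GroupIncidence]
#' @return data.frame with `pen`, `size`, `y1` and semicolon-joined member
#'   ids
#' @export
makeGroupRecords <- function(pheno, pens) {
  f <- pheno@frame
  alive <- f$id[f$hasRecord]
  empty <- Matrix::rowSums(subsetGroups(pens, alive, dropEmpty = FALSE)@incidence) == 0
  if (any(empty))
    warning(sum(empty), " empty pen(s) excluded from the group records")
  sub <- subsetGroups(pens, alive)
  y <- f$y1[f$hasRecord][match(sub@member, alive)]
  rec <- as.numeric(sub@incidence %*% y)
  tr <- as(sub@incidence, "TsparseMatrix")
  mem <- vapply(split(sub@member[tr@j + 1L], sub@group[tr@i + 1L]),
                function(m) paste(sort(m), collapse = ";"), character(1))
  data.frame(pen = sub@group, size = as.numeric(groupSizes(sub)),
             y1 = rec, members = unname(mem[sub@group]))
}
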