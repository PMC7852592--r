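# Core S4 containers. Haplotypes are stored as a raw matrix with loci in rows
# and two phased haplotype columns per individual, which keeps a whole-genome
# population (tens of thousands of loci) at one byte per allele.

#' Genetic map of biallelic loci
#'
#' Describes the simulated genome: chromosome assignment, within-chromosome
#' position in centimorgan, locus class (`"marker"` or `"qtl"`), per-locus
#' mutation rate, and per-chromosome length. Loci are ordered by chromosome
#' and strictly increasing position.
#'
#' @slot chromosome integer chromosome index per locus.
#' @slot position numeric position within chromosome, centimorgan.
#' @slot type character locus class, `"marker"` or `"qtl"`.
#' @slot mutationRate numeric per-locus mutation rate per meiosis.
#' @slot chromosomeLength numeric length of each chromosome in centimorgan.
#' @exportClass GenomeMap
setClass("GenomeMap",
  representation(chromosome = "integer", position = "numeric",
                 type = "character", mutationRate = "numeric",
                 chromosomeLength = "numeric"))

setValidity("GenomeMap", function(object) {
  n <- length(object@chromosome)
  if (length(object@position) != n || length(object@type) != n ||
      length(object@mutationRate) != n)
    return("chromosome, position, type and mutationRate must have equal length")
  if (!all(object@type %in% c("marker", "qtl")))
    return("locus type must be 'marker' or 'qtl'")
  if (any(object@mutationRate < 0)) return("mutation rates must be >= 0")
  for (c in unique(object@chromosome)) {
    p <- object@position[object@chromosome == c]
    if (any(diff(p) <= 0))
      return("positions must be strictly increasing within a chromosome")
    if (any(p < 0) || any(p > object@chromosomeLength[c]))
      return("positions must lie within the chromosome length")
  }
  if (is.unsorted(object@chromosome)) return("loci must be ordered by chromosome")
  TRUE
})

#' Phased haplotypes for a population
#'
#' @slot haplotypes raw matrix, loci in rows, two phased 0/1 haplotype
#'   columns per individual (columns `2i - 1` and `2i` belong to individual
#'   `i`).
#' @slot id integer individual identifiers.
#' @slot generation integer generation index per individual.
#' @slot sex integer, 1 = male, 2 = female.
#' @exportClass HaplotypePopulation
setClass("HaplotypePopulation",
  representation(haplotypes = "matrix", id = "integer",
                 generation = "integer", sex = "integer"))

setValidity("HaplotypePopulation", function(object) {
  n <- length(object@id)
  if (!is.raw(object@haplotypes)) return("haplotypes must be a raw matrix")
  if (ncol(object@haplotypes) != 2L * n)
    return("haplotype matrix must have two columns per individual")
  if (length(object@generation) != n || length(object@sex) != n)
    return("id, generation and sex must have equal length")
  if (!all(object@sex %in% 1:2)) return("sex must be 1 (male) or 2 (female)")
  TRUE
})

#' Pedigree of a simulated or recorded population
#'
#' Wraps a data frame with columns `id`, `sire`, `dam` (0 = unknown),
#' `generation`, `sex` and `breeding` (TRUE for parents of any later
#' generation). Rows are sorted parents-before-offspring.
#'
#' @slot frame data.frame with the columns above.
#' @exportClass Pedigree
setClass("Pedigree", representation(frame = "data.frame"))

setValidity("Pedigree", function(object) {
  f <- object@frame
  need <- c("id", "sire", "dam", "generation", "sex", "breeding")
  if (!all(need %in% names(f)))
    return(paste("pedigree frame must have columns:", paste(need, collapse = ", ")))
  idx <- match(c(f$sire, f$dam), f$id)
  pos <- rep(seq_len(nrow(f)), 2L)
  known <- !is.na(idx) & c(f$sire, f$dam) != 0L
  if (any(idx[known] >= pos[known]))
    return("parents must precede their offspring")
  if (anyDuplicated(f$id)) return("duplicated individual ids")
  TRUE
})

#' QTL effects for a bivariate trait architecture
#'
#' @slot loci integer indices of QTL loci in the associated [GenomeMap].
#' @slot effects numeric matrix (QTL x 2) of allele-substitution effects,
#'   already multiplied by the per-trait scaling constants.
#' @slot scale numeric length-2 scaling constants applied to the raw effects.
#' @slot correlation numeric sampling correlation of the effect pairs.
#' @slot targetVariances numeric length-2 additive variances the true
#'   breeding values were scaled to in the reference generation.
#' @exportClass TraitArchitecture
setClass("TraitArchitecture",
  representation(loci = "integer", effects = "matrix", scale = "numeric",
                 correlation = "numeric", targetVariances = "numeric"))

#' Two-trait phenotype records with simulation ground truth
#'
#' One row per individual of the recorded generations. Records decompose as
#' `y = mean + litter + pen + additive + residual` per trait; the individual
#' effect draws are retained so that tests can verify the decomposition.
#' `hasRecord` is FALSE for animals whose records were removed by attrition.
#'
#' @slot frame data.frame with columns `id`, `generation`, `litter`, `pen`,
#'   `y1`, `y2`, `tbv1`, `tbv2`, `l1`, `l2`, `c1`, `c2`, `e1`, `e2`,
#'   `hasRecord`.
#' @slot mean numeric length-2 overall means used for the two traits.
#' @exportClass PhenotypeSet
setClass("PhenotypeSet", representation(frame = "data.frame", mean = "numeric"))

setValidity("PhenotypeSet", function(object) {
  need <- c("id", "generation", "litter", "pen", "y1", "y2", "tbv1", "tbv2",
            "l1", "l2", "c1", "c2", "e1", "e2", "hasRecord")
  if (!all(need %in% names(object@frame)))
    return(paste("phenotype frame must have columns:", paste(need, collapse = ", ")))
  if (length(object@mean) != 2L) return("mean must have length 2")
  TRUE
})

#' Group (pen) incidence
#'
#' The sparse 0/1 matrix `T` with one row per group and one column per
#' recorded individual; `T[i, j] = 1` if animal `j` belongs to group `i`.
#' Groups are disjoint, so each column has exactly one 1 and row sums equal
#' group sizes.
#'
#' @slot incidence dgCMatrix, groups x recorded individuals.
#' @slot group character group (pen) identifiers, one per row.
#' @slot member integer individual ids, one per column.
#' @exportClass GroupIncidence
setClass("GroupIncidence",
  representation(incidence = "Matrix", group = "character", member = "integer"))

setValidity("GroupIncidence", function(object) {
  Tm <- object@incidence
  if (nrow(Tm) != length(object@group)) return("one group id per row required")
  if (ncol(Tm) != length(object@member)) return("one member id per column required")
  cs <- Matrix::colSums(Tm)
  if (any(cs != 1)) return("groups must be disjoint: each column sums to 1")
  if (any(object@incidence@x != 1)) return("incidence entries must be 0/1")
  TRUE
})

#' Additive relationship matrix (or its inverse)
#'
#' @slot values the matrix; dense for G-type matrices, sparse for pedigree
#'   inverses.
#' @slot ids integer individual ids indexing rows/columns.
#' @slot kind one of `"A"`, `"Ainv"`, `"G_raw"`, `"G_adjusted"`, `"Gw"`,
#'   `"H"`, `"Hinv"`.
#' @slot inverse logical, TRUE when `values` stores the inverse.
#' @slot genotyped integer ids of the genotyped subset (H-type matrices).
#' @exportClass RelationshipMatrix
setClass("RelationshipMatrix",
  representation(values = "ANY", ids = "integer", kind = "character",
                 inverse = "logical", genotyped = "integer"),
  prototype(inverse = FALSE, genotyped = integer()))

setValidity("RelationshipMatrix", function(object) {
  d <- dim(object@values)
  if (d[1] != d[2]) return("relationship matrix must be square")
  if (d[1] != length(object@ids)) return("one id per row required")
  if (!object@kind %in% c("A", "Ainv", "G_raw", "G_adjusted", "Gw", "H", "Hinv"))
    return("unknown relationship kind")
  TRUE
})

#' (Co)variance components for up to two traits
#'
#' Each slot holds a `t x t` covariance matrix (t = 1 or 2) for the pen,
#' litter, additive genetic and residual effects. For the bivariate model
#' with one group-recorded and one individually recorded trait the residual
#' covariance is structurally zero (a group sum and an individual record do
#' not share a residual covariance parameter in the model).
#'
#' @slot pen,litter,additive,residual numeric `t x t` covariance matrices.
#' @exportClass VarianceComponents
setClass("VarianceComponents",
  representation(pen = "matrix", litter = "matrix", additive = "matrix",
                 residual = "matrix"))

setValidity("VarianceComponents", function(object) {
  t <- nrow(object@pen)
  for (s in c("pen", "litter", "additive", "residual")) {
    m <- slot(object, s)
    if (!all(dim(m) == t)) return("all component matrices must have equal dimension")
    if (!isSymmetric(unname(m), tol = 1e-8)) return(paste(s, "matrix must be symmetric"))
    if (any(diag(m) < 0)) return(paste(s, "variances must be >= 0"))
    ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1))
      return(paste(s, "covariance matrix must be positive semi-definite"))
  }
  TRUE
})

#' Model specification for BLUP / REML
#'
#' @slot records character per-trait record mode, `"individual"` or
#'   `"group"`; length 1 (univariate) or 2 (bivariate).
#' @slot relationship `"A"`, `"G"` or `"H"`.
#' @slot effects random effects included in the model, a subset of
#'   `c("litter", "pen", "additive")`.
#' @slot fixed character; only `"mean"` is supported.
#' @exportClass ModelSpec
setClass("ModelSpec",
  representation(records = "character", relationship = "character",
                 effects = "character", fixed = "character"),
  prototype(effects = c("litter", "pen", "additive"), fixed = "mean"))

setValidity("ModelSpec", function(object) {
  if (!length(object@records) %in% 1:2) return("1 or 2 traits supported")
  if (!all(object@records %in% c("individual", "group")))
    return("record modes must be 'individual' or 'group'")
  if (!object@relationship %in% c("A", "G", "H"))
    return("relationship must be 'A', 'G' or 'H'")
  if (!all(object@effects %in% c("litter", "pen", "additive")))
    return("random effects must be a subset of litter/pen/additive")
  TRUE
})

#' Assembled mixed-model equations
#'
#' @slot C symmetric sparse coefficient matrix.
#' @slot rhs numeric right-hand side.
#' @slot index data.frame mapping equations to (effect, trait, level).
#' @slot meta list of design/structure objects used in assembly.
#' @exportClass MMESystem
setClass("MMESystem",
  representation(C = "ANY", rhs = "numeric", index = "data.frame",
                 meta = "list"))

#' Result of an AI-REML fit
#'
#' @slot estimates [VarianceComponents] point estimates.
#' @slot se numeric asymptotic standard errors (inverse AI matrix), named.
#' @slot loglik numeric restricted log-likelihood trace over accepted
#'   iterations.
#' @slot converged logical.
#' @slot iterations integer.
#' @exportClass RemlResult
setClass("RemlResult",
  representation(estimates = "VarianceComponents", se = "numeric",
                 loglik = "numeric", converged = "logical",
                 iterations = "integer"))

#' Scenario configuration for the simulation study
#'
#' Defaults are the study conditions: three pen-grouping scenarios, 20%
#' attrition, 0/30/100% genotyping designs, genetic correlation 0.8 between
#' the group-recorded and the individually recorded trait.
#'
#' @slot scenario `"S12_L2x3"`, `"S12_Lran"` or `"S24_L2x3"`.
#' @slot attrition fraction of recorded animals whose records are deleted.
#' @slot genotyping percent of animals genotyped (0, 30 or 100).
#' @slot rg genetic correlation used when sampling QTL effects.
#' @slot replicates number of simulation replicates.
#' @slot seed master random seed.
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
  representation(scenario = "character", attrition = "numeric",
                 genotyping = "numeric", rg = "numeric",
                 replicates = "integer", seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  if (!object@scenario %in% c("S12_L2x3", "S12_Lran", "S24_L2x3"))
    return("unknown grouping scenario")
  if (object@attrition < 0 || object@attrition >= 1)
    return("attrition fraction must be in [0, 1)")
  if (!object@genotyping %in% c(0, 30, 100))
    return("genotyping design must be 0, 30 or 100 percent")
  if (abs(object@rg) > 1) return("genetic correlation must be in [-1, 1]")
  TRUE
})

#' Aggregated results of a replicated experiment
#'
#' @slot replicates data.frame of per-replicate cell values.
#' @slot summary data.frame of mean and SD per cell.
#' @slot seed integer master seed.
#' @exportClass ExperimentSummary
setClass("ExperimentSummary",
  representation(replicates = "data.frame", summary = "data.frame",
                 seed = "integer"))
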