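# Generics and small accessors shared across modules.

#' Number of loci
#' @param x a [GenomeMap] or [HaplotypePopulation]
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Number of individuals
#' @param x a population-like object
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' Group sizes of a [GroupIncidence]
#' @param x a [GroupIncidence]
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @describeIn GenomeMap number of loci
#' @param x a `GenomeMap`
#' @export
setMethod("nLoci", "GenomeMap", function(x) length(x@chromosome))

#' @describeIn HaplotypePopulation number of loci
#' @export
setMethod("nLoci", "HaplotypePopulation", function(x) nrow(x@haplotypes))

#' @describeIn HaplotypePopulation number of individuals
#' @export
setMethod("nIndividuals", "HaplotypePopulation", function(x) length(x@id))

#' @describeIn Pedigree number of individuals
#' @export
setMethod("nIndividuals", "Pedigree", function(x) nrow(x@frame))

#' @describeIn GroupIncidence sizes of the groups (row sums of T)
#' @export
setMethod("groupSizes", "GroupIncidence", function(x)
  setNames(Matrix::rowSums(x@incidence), x@group))

#' Extract the underlying data frame
#' @param x a [Pedigree] or [PhenotypeSet]
#' @param ... unused
#' @export
setMethod("as.data.frame", "Pedigree", function(x, ...) x@frame)

#' @rdname as.data.frame-Pedigree-method
#' @export
setMethod("as.data.frame", "PhenotypeSet", function(x, ...) x@frame)

#' QTL indices of a genome map
#' @param map a [GenomeMap]
#' @return integer locus indices
#' @export
qtlLoci <- function(map) which(map@type == "qtl")

#' Marker indices of a genome map
#' @param map a [GenomeMap]
#' @export
markerLoci <- function(map) which(map@type == "marker")

#' Allele-1 frequencies per locus
#' @param pop a [HaplotypePopulation]
#' @export
alleleFrequencies <- function(pop) {
  rowMeans(matrix(as.integer(pop@haplotypes), nrow = nrow(pop@haplotypes)))
}

#' Dosage matrix (0/1/2) for selected loci
#'
#' @param pop a [HaplotypePopulation]
#' @param loci integer locus indices (default: all)
#' @return integer matrix, individuals x loci, rownames = individual ids
#' @export
dosageMatrix <- function(pop, loci = seq_len(nLoci(pop))) {
  d <- cpp_dosage(pop@haplotypes, as.integer(loci))
  rownames(d) <- as.character(pop@id)
  d
}

setMethod("show", "GenomeMap", function(object) {
  cat("GenomeMap:", length(unique(object@chromosome)), "chromosomes,",
      nLoci(object), "loci (", sum(object@type == "marker"), "markers,",
      sum(object@type == "qtl"), "QTL )\n")
})

setMethod("show", "HaplotypePopulation", function(object) {
  cat("HaplotypePopulation:", nIndividuals(object), "individuals,",
      nLoci(object), "loci, generation(s)",
      paste(range(object@generation), collapse = "-"), "\n")
})

setMethod("show", "Pedigree", function(object) {
  f <- object@frame
  cat("Pedigree:", nrow(f), "individuals, generations",
      paste(range(f$generation), collapse = "-"), ";",
      sum(f$breeding), "breeding animals\n")
})

setMethod("show", "PhenotypeSet", function(object) {
  f <- object@frame
  cat("PhenotypeSet:", nrow(f), "individuals,", sum(f$hasRecord),
      "with records, generations", paste(range(f$generation), collapse = "-"), "\n")
})

setMethod("show", "GroupIncidence", function(object) {
  s <- groupSizes(object)
  cat("GroupIncidence:", length(s), "groups,", ncol(object@incidence),
      "individuals; sizes", min(s), "-", max(s),
      sprintf("(mean %.2f)\n", mean(s)))
})

setMethod("show", "RelationshipMatrix", function(object) {
  cat("RelationshipMatrix (", object@kind, "): ", length(object@ids), " x ",
      length(object@ids), if (object@inverse) ", stored as inverse" else "",
      "\n", sep = "")
})

setMethod("show", "VarianceComponents", function(object) {
  t <- nrow(object@pen)
  cat("VarianceComponents for", t, if (t == 1) "trait:\n" else "traits:\n")
  for (s in c("pen", "litter", "additive", "residual")) {
    m <- slot(object, s)
    if (t == 1) cat(sprintf("  %-8s %8.3f\n", s, m[1, 1]))
    else cat(sprintf("  %-8s var1 %8.3f  var2 %8.3f  cov %8.3f\n",
                     s, m[1, 1], m[2, 2], m[1, 2]))
  }
})

setMethod("show", "RemlResult", function(object) {
  cat("RemlResult:", if (object@converged) "converged" else "NOT converged",
      "after", object@iterations, "iterations; logL =",
      sprintf("%.4f", utils::tail(object@loglik, 1)), "\n")
  show(object@estimates)
})

setMethod("show", "ExperimentSummary", function(object) {
  cat("ExperimentSummary:", length(unique(object@replicates$replicate)),
      "replicates,", nrow(object@summary), "cells\n")
  print(utils::head(object@summary, 20))
})
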