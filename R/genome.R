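#' Construct a genetic map
#'
#' Builds a [GenomeMap] with loci placed uniformly at random along each
#' chromosome. Defaults describe the simulated pig genome used throughout the
#' package: 18 chromosomes of 100 cM, each carrying 3100 biallelic markers
#' and 50 biallelic QTL, with a per-locus mutation rate of 2.5e-5 per
#' meiosis. Positions are drawn with the current RNG state.
#'
#' @param chromosomes number of chromosomes.
#' @param length chromosome length in centimorgan (recycled).
#' @param markers markers per chromosome.
#' @param qtl QTL per chromosome.
#' @param mutationRate per-locus mutation rate per meiosis.
#' @return a [GenomeMap]
#' @examples
#' set.seed(1)
#' genomeMap(chromosomes = 2, markers = 10, qtl = 2)
#' @export
genomeMap <- function(chromosomes = 18L, length = 100, markers = 3100L,
                      qtl = 50L, mutationRate = 2.5e-5) {
  if (chromosomes < 1 || markers < 0 || qtl < 0)
    stop("invalid genome configuration")
  len <- rep_len(length, chromosomes)
  perChr <- markers + qtl
  chr <- rep(seq_len(chromosomes), each = perChr)
  pos <- type <- vector("list", chromosomes)
  for (c in seq_len(chromosomes)) {
    p <- sort(runif(perChr, 0, len[c]))
    while (any(diff(p) <= 0))                 # enforce strict ordering
      p <- sort(p + c(0, cumsum(rep(1e-9, perChr - 1L))))
    pos[[c]] <- p
    ty <- rep("marker", perChr)
    ty[sample.int(perChr, qtl)] <- "qtl"
    type[[c]] <- ty
  }
  new("GenomeMap", chromosome = as.integer(chr), position = unlist(pos),
      type = unlist(type), mutationRate = rep(mutationRate, length(chr)),
      chromosomeLength = len)
}

# 0-based inclusive index ranges per chromosome (empty: end < start)
.chrRanges <- function(map) {
  nChr <- length(map@chromosomeLength)
  start <- end <- integer(nChr)
  for (c in seq_len(nChr)) {
    idx <- which(map@chromosome == c)
    if (length(idx)) {
      start[c] <- idx[1] - 1L
      end[c] <- idx[length(idx)] - 1L
    } else {
      start[c] <- 0L
      end[c] <- -1L
    }
  }
  list(start = start, end = end)
}

#' Subset a genome map to selected loci
#' @param map a [GenomeMap]
#' @param loci integer locus indices to keep
#' @export
subsetMap <- function(map, loci) {
  new("GenomeMap", chromosome = map@chromosome[loci],
      position = map@position[loci], type = map@type[loci],
      mutationRate = map@mutationRate[loci],
      chromosomeLength = map@chromosomeLength)
}
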