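# Plain-text interchange formats: pedigree CSV, 0/1/2 genotype TSV,
# phenotype CSV, group-record CSV, relationship-matrix triplet TSV, and a
# YAML scenario configuration.

#' Read / write a pedigree CSV
#'
#' Columns `id, sire, dam, generation, sex, breeding`; 0 marks an unknown
#' parent.
#'
#' @param file path
#' @return a [Pedigree]
#' @export
readPedigree <- function(file) {
  f <- utils::read.csv(file)
  f$breeding <- as.logical(f$breeding)
  new("Pedigree", frame = f)
}

#' @rdname readPedigree
#' @param ped a [Pedigree]
#' @export
writePedigree <- function(ped, file) {
  utils::write.csv(ped@frame, file, row.names = FALSE, quote = FALSE)
}

#' Read / write a genotype dosage table
#'
#' Tab-separated: first column `id`, then one 0/1/2 dosage column per
#' marker.
#'
#' @param file path
#' @return integer dosage matrix with ids as rownames
#' @export
readGenotypes <- function(file) {
  t <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(t[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- t[[1]]
  m
}

#' @rdname readGenotypes
#' @param dosages integer matrix, individuals x markers
#' @export
writeGenotypes <- function(dosages, file) {
  utils::write.table(data.frame(id = rownames(dosages), dosages,
                                check.names = FALSE),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read / write a phenotype CSV
#'
#' Columns `id, litter, pen, y1, y2, tbv1, tbv2, has_record` (plus any
#' extra columns, which are preserved on write).
#'
#' @param file path
#' @param pheno a [PhenotypeSet]
#' @export
writePhenotypes <- function(pheno, file) {
  f <- pheno@frame
  out <- data.frame(id = f$id, litter = f$litter, pen = f$pen, y1 = f$y1,
                    y2 = f$y2, tbv1 = f$tbv1, tbv2 = f$tbv2,
                    has_record = f$hasRecord)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
}

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(file) {
  f <- utils::read.csv(file)
  frame <- data.frame(id = f$id, generation = if ("generation" %in% names(f))
                        f$generation else NA_integer_,
                      litter = f$litter, pen = f$pen, y1 = f$y1, y2 = f$y2,
                      tbv1 = f$tbv1, tbv2 = f$tbv2,
                      l1 = NA_real_, l2 = NA_real_, c1 = NA_real_,
                      c2 = NA_real_, e1 = NA_real_, e2 = NA_real_,
                      hasRecord = as.logical(f$has_record))
  new("PhenotypeSet", frame = frame, mean = c(0, 0))
}

#' Write group records
#'
#' One row per pen: `pen, group_size, y1_sum, member_ids` (semicolon
#' joined).
#'
#' @param records data.frame from [makeGroupRecords()]
#' @param file path
#' @export
writeGroupRecords <- function(records, file) {
  out <- data.frame(pen = records$pen, group_size = records$size,
                    y1_sum = records$y1, member_ids = records$members)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
}

#' Write a relationship matrix as text triplets
#'
#' Tab-separated `i, j, value` (1-based ids, lower triangle of symmetric
#' matrices).
#'
#' @param kin a [RelationshipMatrix]
#' @param file path
#' @export
writeRelationshipTriplets <- function(kin, file) {
  m <- as(as(Matrix::Matrix(kin@values, sparse = TRUE), "generalMatrix"),
          "TsparseMatrix")
  keep <- m@i >= m@j
  utils::write.table(data.frame(i = kin@ids[m@i[keep] + 1L],
                                j = kin@ids[m@j[keep] + 1L],
                                value = m@x[keep]),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Read a scenario configuration from YAML
#'
#' Fields `scenario`, `attrition`, `genotyping`, `rg`, `replicates`,
#' `seed`; missing fields take the defaults of [scenarioConfig()].
#'
#' @param file path
#' @return a [ScenarioConfig]
#' @export
readScenarioConfig <- function(file) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading YAML configurations requires the 'yaml' package")
  y <- yaml::read_yaml(file)
  do.call(scenarioConfig, y[intersect(names(y),
    c("scenario", "attrition", "genotyping", "rg", "replicates", "seed"))])
}
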