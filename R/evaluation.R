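# Scoring of estimated against true breeding values, validation partitions,
# and the replicated simulation-study driver.

#' Accuracy of estimated breeding values
#'
#' Pearson correlation between estimated and true breeding values over a
#' validation set.
#'
#' @param ebv,tbv aligned numeric vectors (at least 3 animals)
#' @return correlation, or `NA` with a warning when either vector has zero
#'   variance
#' @export
accuracy <- function(ebv, tbv) {
  if (length(ebv) < 3L || length(ebv) != length(tbv))
    stop("need at least 3 aligned pairs")
  if (sd(ebv) == 0 || sd(tbv) == 0) {
    warning("zero variance: accuracy undefined")
    return(NA_real_)
  }
  cor(ebv, tbv)
}

#' Dispersion bias of estimated breeding values
#'
#' Ordinary least-squares regression coefficient of true on estimated
#' breeding values; 1 indicates no over- or under-dispersion of the
#' estimates.
#'
#' @inheritParams accuracy
#' @return regression slope, or `NA` with a warning when the estimates have
#'   zero variance
#' @export
biasRegression <- function(ebv, tbv) {
  if (length(ebv) < 3L || length(ebv) != length(tbv))
    stop("need at least 3 aligned pairs")
  if (sd(ebv) == 0) {
    warning("zero variance in EBV: slope undefined")
    return(NA_real_)
  }
  sum((tbv - mean(tbv)) * (ebv - mean(ebv))) / sum((ebv - mean(ebv))^2)
}

#' Validation partition of the last generation
#'
#' The validation animals are the post-attrition recorded animals of the
#' validation generation. Group I / Group II split them by membership of the
#' 30%-design genotyped set, which is frozen once per replicate so that all
#' genotyping designs score identical animal sets.
#'
#' @param pheno a [PhenotypeSet] after attrition
#' @param genotyped ids of the 30%-design genotyped animals (possibly empty)
#' @param generation validation generation
#' @return list with `all`, `groupI`, `groupII` id vectors
#' @export
partitionValidation <- function(pheno, genotyped = integer(),
                                generation = 8L) {
  f <- pheno@frame
  ids <- f$id[f$generation == generation & f$hasRecord]
  gI <- intersect(ids, genotyped)
  list(all = ids, groupI = gI, groupII = setdiff(ids, gI))
}

#' Scenario configuration
#'
#' @param scenario grouping scenario
#' @param attrition fraction of records removed
#' @param genotyping percent of animals genotyped (0, 30, 100)
#' @param rg additive genetic correlation between the traits
#' @param replicates number of replicates
#' @param seed master seed
#' @return a [ScenarioConfig]
#' @export
scenarioConfig <- function(scenario = "S12_L2x3", attrition = 0.2,
                           genotyping = 0, rg = 0.8, replicates = 10L,
                           seed = 1L) {
  new("ScenarioConfig", scenario = scenario, attrition = attrition,
      genotyping = genotyping, rg = rg, replicates = as.integer(replicates),
      seed = as.integer(seed))
}

#' Default grid of study cells
#'
#' The pedigree-based cells of the simulation study: univariate
#' group/individual BLUP in the three grouping scenarios, the bivariate
#' model with group-recorded trait 1 and individually recorded trait 2
#' (records kept and removed in the validation generation), the
#' reduced-genetic-correlation variant, and the two REML cells (univariate
#' group records; bivariate mixed mode).
#'
#' @param reml include the REML cells
#' @return data.frame of cells understood by [runExperiment()]
#' @export
defaultStudyGrid <- function(reml = TRUE) {
  g <- data.frame(
    scenario = c("S12_L2x3", "S12_L2x3", "S12_Lran", "S24_L2x3",
                 "S12_L2x3", "S12_L2x3", "S12_L2x3"),
    rg = c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.5),
    records = c("group", "individual", "group", "group",
                "mixed", "mixed", "mixed"),
    validation = c("Valid_R", "Valid_R", "Valid_R", "Valid_R",
                   "Valid_R", "Valid_nR", "Valid_R"),
    relationship = "A",
    analysis = "blup")
  if (reml)
    g <- rbind(g, data.frame(
      scenario = "S12_L2x3", rg = 0.8, records = c("group", "mixed"),
      validation = "Valid_R", relationship = "A", analysis = "reml"))
  g
}

# model spec from a grid row ("mixed" = group trait 1 + individual trait 2)
.cellSpec <- function(records, relationship) {
  recs <- switch(records,
                 group = "group",
                 individual = "individual",
                 mixed = c("group", "individual"),
                 bivariate_individual = c("individual", "individual"),
                 stop("unknown record mode: ", records))
  modelSpec(records = recs, relationship = relationship)
}

#' Simulate one replicate of the study
#'
#' Runs the full generating pipeline under the current RNG state: genome
#' and historical population, MAF filtering, expansion into the pedigreed
#' recent population, QTL effect architectures (one per requested genetic
#' correlation), pen assignment per grouping scenario, phenotypes,
#' attrition, and the frozen 30%-design genotyped set.
#'
#' @param scenarios grouping scenarios to build pens for
#' @param rg genetic correlations to build architectures for
#' @param litters litters per recent generation
#' @param generations recent generations
#' @param phenoGenerations generations that receive records
#' @param sires sires per generation
#' @param histN,histGenerations historical population size and length
#' @param chromosomes,markersPerChromosome,qtlPerChromosome genome layout
#' @param attrition fraction of records removed
#' @param keepHaplotypes keep the haplotype population in the result (needed
#'   for genomic relationship matrices)
#' @return list with `pedigree`, `ainv`, per-scenario `pens`, per
#'   (scenario, rg) phenotype sets, `tbv` per rg, `genotyped30`, and
#'   `validation` ids
#' @export
simulateStudyReplicate <- function(scenarios = "S12_L2x3", rg = 0.8,
                                   litters = 600L, generations = 8L,
                                   phenoGenerations = 5:8, sires = 30L,
                                   histN = 400L, histGenerations = 300L,
                                   chromosomes = 18L,
                                   markersPerChromosome = 0L,
                                   qtlPerChromosome = 50L, attrition = 0.2,
                                   keepHaplotypes = FALSE) {
  map <- genomeMap(chromosomes = chromosomes, markers = markersPerChromosome,
                   qtl = qtlPerChromosome)
  hist <- simulateHistorical(map, n = histN, generations = histGenerations)
  flt <- mafFilter(hist, map)
  rm(hist)
  exp <- expandRecentPopulation(flt$population, flt$map,
                                generations = generations, litters = litters,
                                sires = sires)
  ped <- exp$pedigree
  pop <- exp$population
  gen0 <- which(pop@generation == 0L)
  tbv <- list()
  for (r in unique(rg))
    tbv[[as.character(r)]] <-
      trueBreedingValues(pop, traitArchitecture(pop, flt$map, rg = r,
                                                reference = gen0))
  pens <- list()
  for (s in unique(scenarios))
    pens[[s]] <- assignPens(ped, s, generations = phenoGenerations)
  # one common deletion set per replicate: every scenario / correlation
  # variant then scores identical validation animals
  deleted <- NULL
  pheno <- list()
  for (s in unique(scenarios)) for (r in unique(rg)) {
    ph <- simulatePhenotypes(ped, tbv[[as.character(r)]], pens[[s]],
                             vc = trueVarianceComponents(r),
                             generations = phenoGenerations)
    if (attrition > 0 && is.null(deleted)) {
      ph <- applyAttrition(ph, ped, attrition)
      deleted <- ph@frame$id[!ph@frame$hasRecord]
    } else if (!is.null(deleted)) {
      ph <- applyAttrition(ph, ped, attrition, deleted = deleted)
    }
    pheno[[paste(s, r, sep = "|")]] <- ph
  }
  first <- pheno[[1]]
  genotyped30 <- selectGenotyped(first, ped, 30)
  out <- list(pedigree = ped, map = flt$map, ainv = buildAinverse(ped),
              tbv = tbv, pens = pens, pheno = pheno,
              genotyped30 = genotyped30,
              validation = partitionValidation(first, genotyped30,
                                               max(phenoGenerations)))
  if (keepHaplotypes) out$population <- pop
  out
}

# score one BLUP fit over the validation subsets; long format
.scoreFit <- function(fit, tbv, traits, valid) {
  out <- NULL
  for (t in traits) {
    eb <- fit$ebv[fit$ebv$trait == t, ]
    ebv <- setNames(eb$ebv, eb$id)
    for (sub in c("All", "GroupI", "GroupII")) {
      ids <- switch(sub, All = valid$all, GroupI = valid$groupI,
                    GroupII = valid$groupII)
      if (length(ids) < 3L) next
      tb <- tbv[as.character(ids), t]
      out <- rbind(out, data.frame(
        trait = t, subset = sub,
        measure = c("accuracy", "bias"),
        value = c(accuracy(ebv[as.character(ids)], tb),
                  biasRegression(ebv[as.character(ids)], tb))))
    }
  }
  out
}

#' Run a replicated simulation experiment
#'
#' For every replicate: simulate a dataset, build the relationship
#' structure, fit every cell of `grid` (BLUP with the generating variance
#' components, or AI-REML), and score accuracy and dispersion bias on the
#' validation generation. Results are aggregated as mean and SD per cell.
#'
#' @param grid data.frame of cells, see [defaultStudyGrid()]
#' @param replicates number of replicates
#' @param seed master seed; one child seed per replicate is spawned
#' @param remlOpts options for the REML cells, see [remlOptions()]
#' @param progress print per-replicate progress
#' @param ... sizing arguments passed to [simulateStudyReplicate()]
#' @return an [ExperimentSummary]; the `replicates` slot holds one row per
#'   cell x trait x subset (accuracy/bias) or cell x parameter (REML)
#' @export
runExperiment <- function(grid = defaultStudyGrid(), replicates = 10L,
                          seed = 1L,
                          remlOpts = remlOptions(tolParam = 1e-6,
                                                 tolGrad = 1e-3,
                                                 floor = 0.01, maxit = 30L),
                          progress = FALSE, ...) {
  set.seed(seed)
  childSeeds <- sample.int(2^31 - 2, replicates)
  rows <- NULL
  for (r in seq_len(replicates)) {
    set.seed(childSeeds[r])
    rep <- simulateStudyReplicate(scenarios = unique(grid$scenario),
                                  rg = unique(grid$rg), ...)
    for (i in seq_len(nrow(grid))) {
      cell <- grid[i, ]
      ph <- rep$pheno[[paste(cell$scenario, cell$rg, sep = "|")]]
      pens <- rep$pens[[cell$scenario]]
      tbv <- rep$tbv[[as.character(cell$rg)]]
      spec <- .cellSpec(cell$records, cell$relationship)
      kin <- .cellKinship(cell$relationship, rep)
      vc <- trueVarianceComponents(cell$rg,
                                   traits = length(spec@records))
      drop <- if (cell$validation == "Valid_nR")
        max(ph@frame$generation) else integer()
      if (cell$analysis == "blup") {
        fit <- fitBLUP(spec, ph, pens, kin, vc, dropGenerations = drop)
        sc <- .scoreFit(fit, tbv, seq_along(spec@records), rep$validation)
      } else {
        # start at the generating components: the converged optimum is the
        # same, quadratic convergence just sets in sooner
        est <- remlEstimate(spec, ph, pens, kin, start = vc,
                            options = remlOpts, dropGenerations = drop)
        sys <- .buildSystem(spec, ph, pens, kin, drop)
        params <- .remlParams(sys)
        sc <- data.frame(
          trait = NA_integer_, subset = NA_character_,
          measure = vapply(params, `[[`, character(1), "name"),
          value = .vcToTheta(params, est@estimates))
        if (!est@converged)
          warning("REML cell did not reach the convergence thresholds ",
                  "(replicate ", r, ")")
      }
      rows <- rbind(rows, cbind(replicate = r, cell, sc, row.names = NULL))
    }
    if (progress) message("replicate ", r, " done")
  }
  keys <- c("scenario", "rg", "records", "validation", "relationship",
            "analysis", "trait", "subset", "measure")
  km <- rows[keys]
  km$trait[is.na(km$trait)] <- 0L
  km$subset[is.na(km$subset)] <- ""
  agg <- stats::aggregate(list(mean = rows$value), km, mean)
  aggS <- stats::aggregate(list(sd = rows$value), km, function(x)
    if (length(x) > 1) sd(x) else NA_real_)
  agg <- merge(agg, aggS, by = keys)
  new("ExperimentSummary", replicates = rows, summary = agg,
      seed = as.integer(seed))
}

#' Run the package's reference simulation study
#'
#' Replicates the pedigree-based (no genotyping) evaluation study at its
#' default desk-scale settings: the accuracy/bias cells and the univariate
#' group-record REML cell run on full-sized populations (600 litters per
#' generation, pedigree of 29,430); the bivariate mixed-mode REML cell runs
#' on a size-reduced population (100 litters per generation, 5 sires, same
#' litter size, pen structure and attrition), whose pen-covariance
#' behaviour depends on the within-pen structure rather than on population
#' size.
#'
#' @param seed master seed
#' @param replicates replicates per cell
#' @param progress print progress
#' @return list with two [ExperimentSummary] objects: `main` and `bivReml`
#' @export
runReferenceStudy <- function(seed, replicates = 10L, progress = FALSE) {
  grid <- defaultStudyGrid(reml = TRUE)
  gridMain <- grid[!(grid$analysis == "reml" & grid$records == "mixed"), ]
  gridBiv <- grid[grid$analysis == "reml" & grid$records == "mixed", ]
  main <- runExperiment(gridMain, replicates = replicates, seed = seed,
                        progress = progress)
  bivReml <- runExperiment(gridBiv, replicates = replicates,
                           seed = seed + 1L, litters = 100L, sires = 5L,
                           progress = progress)
  list(main = main, bivReml = bivReml)
}

#' Extract one summary cell from an experiment
#'
#' @param summary an [ExperimentSummary]
#' @param measure measure name (`"accuracy"`, `"bias"`, or a variance
#'   parameter such as `"additive_1_1"`)
#' @param scenario,rg,records,validation,relationship,analysis cell
#'   coordinates
#' @param trait trait index (0 for REML rows)
#' @param subset validation subset (empty for REML rows)
#' @return list with `mean`, `sd` and `n`
#' @export
summaryCell <- function(summary, measure, scenario = "S12_L2x3", rg = 0.8,
                        records = "group", validation = "Valid_R",
                        relationship = "A", analysis = "blup", trait = 1L,
                        subset = "All") {
  if (analysis == "reml") { trait <- 0L; subset <- "" }
  s <- summary@summary
  row <- s[s$scenario == scenario & s$rg == rg & s$records == records &
           s$validation == validation & s$relationship == relationship &
           s$analysis == analysis &
           s$measure == measure & s$trait == trait & s$subset == subset, ]
  if (nrow(row) != 1L) stop("cell not found (or not unique)")
  r <- summary@replicates
  n <- sum(r$scenario == scenario & r$rg == rg & r$records == records &
           r$validation == validation & r$relationship == relationship &
           r$analysis == analysis & r$measure == measure &
           (analysis == "reml" | (r$trait == trait & r$subset == subset)),
           na.rm = TRUE)
  list(mean = row$mean, sd = row$sd, n = n)
}

.cellKinship <- function(relationship, rep) {
  if (relationship == "A") return(rep$ainv)
  if (is.null(rep$population))
    stop("genomic relationship requires keepHaplotypes = TRUE")
  gid <- if (relationship == "G") {
    f <- rep$pheno[[1]]@frame
    f$id[f$hasRecord]
  } else rep$genotyped30
  dos <- dosageMatrix(rep$population, markerLoci(rep$map))
  dos <- dos[as.character(gid), , drop = FALSE]
  G <- buildG(dos)
  A11 <- relationshipBlock(rep$pedigree, gid, ainv = rep$ainv)
  Gw <- blendG(rescaleG(G, A11), A11)
  if (relationship == "G") {
    Gw
  } else {
    assembleHinverse(rep$ainv, Gw, A11)
  }
}
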