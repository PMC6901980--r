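# Synthetic-data generator.  Emulates the replicated in vivo / in vitro
# exposure design the scoring statistics assume: two cohorts of
# n-per-cohort samples (default 5, the study's cohort size), i.i.d.
# Gaussian noise on the log-expression scale, and "planted" injury
# modules whose genes are shifted in the treatment cohort by a known
# effect size delta, with a configurable fraction of responders and a
# configurable up/down direction mix.

#' Describe a planted module
#'
#' A planted module is a gene set whose responding genes are shifted by
#' \code{+delta} or \code{-delta} (on the natural-log scale) in the
#' treatment cohort.  \code{directionMix = 0.5} (the default) splits the
#' responders evenly between up- and down-regulation, the regime in which
#' an absolute-value activation statistic detects what a signed pathway
#' statistic cancels away.
#'
#' @param name unique module name.
#' @param size number of genes (ignored when \code{genes} is given).
#' @param effectSize mean log-FC magnitude delta per responding gene
#'   (>= 0; 0 makes the module a pure decoy).
#' @param responderFraction fraction of the module's genes that respond,
#'   in (0, 1].
#' @param directionMix fraction of responders shifted up (the rest down),
#'   in [0, 1].
#' @param genes optional explicit character vector of gene identifiers;
#'   when \code{NULL} the genes are drawn from the synthetic universe.
#' @return an object of class \code{"PlantedModule"}.
#' @seealso [simulationConfig()], [simulateExperiment()]
#' @export
plantedModule <- function(name, size = 30L, effectSize = 0,
                          responderFraction = 1, directionMix = 0.5,
                          genes = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  .assertScalarNumber(effectSize, "effectSize", lower = 0)
  .assertScalarNumber(responderFraction, "responderFraction", lower = 0, upper = 1)
  if (responderFraction == 0) stop("'responderFraction' must be in (0, 1]")
  .assertScalarNumber(directionMix, "directionMix", lower = 0, upper = 1)
  if (!is.null(genes)) {
    genes <- unique(as.character(genes))
    size <- length(genes)
  }
  size <- .assertCount(size, "size", 1L)
  structure(list(name = name, size = size, effectSize = effectSize,
                 responderFraction = responderFraction,
                 directionMix = directionMix, genes = genes),
            class = "PlantedModule")
}

#' Decoy modules
#'
#' Convenience constructor for \code{n} planted modules with zero effect
#' size, used as the inactive background against which a planted signal
#' must be ranked.
#'
#' @param n number of decoys.
#' @param size genes per decoy.
#' @param prefix name prefix (names are \code{prefix1 ... prefixN}).
#' @return list of \code{"PlantedModule"} objects.
#' @export
decoyModules <- function(n, size = 30L, prefix = "decoy") {
  lapply(seq_len(n), function(i) {
    plantedModule(paste0(prefix, i), size = size, effectSize = 0)
  })
}

#' Simulation configuration
#'
#' Bundles the parameters of one synthetic treatment/control experiment.
#' Defaults mirror the study design the statistics were built for: five
#' samples per cohort and i.i.d. Gaussian noise on log-scale expression.
#'
#' @param nGenes size of the gene universe.
#' @param nPerCohort samples per cohort (>= 2; default 5).
#' @param baselineMean log-expression location of unperturbed genes.
#' @param noiseSd per-gene Gaussian standard deviation on the log scale
#'   (> 0).
#' @param modules list of [plantedModule()] objects (disjoint by default).
#' @param seed integer root seed; all sub-streams (universe assignment,
#'   expression noise) are derived deterministically from it.
#' @param conditionId condition label stamped on the simulated samples.
#' @return an object of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(nGenes = 2000L, nPerCohort = 5L,
                             baselineMean = 5, noiseSd = 0.5,
                             modules = list(), seed = 1L,
                             conditionId = "sim") {
  nGenes <- .assertCount(nGenes, "nGenes", 1L)
  nPerCohort <- .assertCount(nPerCohort, "nPerCohort", 2L)
  .assertScalarNumber(baselineMean, "baselineMean")
  .assertScalarNumber(noiseSd, "noiseSd")
  if (noiseSd <= 0) stop("'noiseSd' must be > 0")
  seed <- .assertCount(seed, "seed", 0L)
  stopifnot(is.character(conditionId), length(conditionId) == 1L)
  if (!all(vapply(modules, inherits, logical(1), "PlantedModule"))) {
    stop("'modules' must be a list of plantedModule() objects")
  }
  nms <- vapply(modules, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("module names must be unique")
  structure(list(nGenes = nGenes, nPerCohort = nPerCohort,
                 baselineMean = baselineMean, noiseSd = noiseSd,
                 modules = modules, seed = seed, conditionId = conditionId),
            class = "SimulationConfig")
}

#' Assign module genes from a synthetic universe
#'
#' Draws disjoint gene sets for the configured modules, without
#' replacement, from the synthetic universe \code{g0001 ... gN}.  Modules
#' that carry explicit gene lists keep them (they must lie inside the
#' universe).  Deterministic given the config seed.
#'
#' @param config a [simulationConfig()].
#' @return a \linkS4class{GeneSetList} (source \code{"synthetic"}).
#' @export
generateUniverse <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  width <- max(4L, nchar(as.character(config$nGenes)))
  universe <- sprintf(paste0("g%0", width, "d"), seq_len(config$nGenes))
  fixed <- unlist(lapply(config$modules, `[[`, "genes"))
  if (length(fixed)) {
    if (anyDuplicated(fixed)) stop("explicit module gene lists overlap")
    if (!all(fixed %in% universe)) {
      stop("explicit module genes outside the synthetic universe g1..gN")
    }
  }
  needed <- sum(vapply(config$modules,
                       function(m) if (is.null(m$genes)) m$size else 0L,
                       numeric(1)))
  pool <- setdiff(universe, fixed)
  if (needed > length(pool)) {
    stop(sprintf("requested module sizes (%d genes) exceed the universe (%d available)",
                 needed, length(pool)))
  }
  drawn <- .withSeed(.subSeed(config$seed, "universe"),
                     sample(pool, needed, replace = FALSE))
  sets <- list()
  offset <- 0L
  for (m in config$modules) {
    if (is.null(m$genes)) {
      sets[[m$name]] <- drawn[(offset + 1L):(offset + m$size)]
      offset <- offset + m$size
    } else {
      sets[[m$name]] <- m$genes
    }
  }
  GeneSetList(sets, descriptions = rep("planted synthetic module", length(sets)),
              source = "synthetic")
}

#' Simulate a treatment/control expression experiment
#'
#' Control samples are \code{Normal(baselineMean, noiseSd)} i.i.d. per
#' gene and sample; treatment samples add the planted per-gene shift.
#' For each module the first \code{ceiling(responderFraction * size)}
#' genes respond; of those, the first \code{round(directionMix * n)} are
#' shifted by \code{+delta}, the remainder by \code{-delta}.  The truth
#' object records the exact planted per-gene log fold change.
#'
#' @param config a [simulationConfig()].
#' @return list with components \code{experiment}
#'   (\linkS4class{ToxExperiment}), \code{geneSets}
#'   (\linkS4class{GeneSetList}), and \code{truth} (list with
#'   \code{geneLfc}, a named numeric vector of planted log fold changes,
#'   and \code{modules}, a data.frame of per-module planted parameters).
#' @examples
#' cfg <- simulationConfig(nGenes = 200, modules = list(
#'   plantedModule("fibrosis", size = 10, effectSize = log(2))), seed = 42)
#' sim <- simulateExperiment(cfg)
#' dim(logExpr(sim$experiment))
#' @export
simulateExperiment <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  gsl <- generateUniverse(config)
  width <- max(4L, nchar(as.character(config$nGenes)))
  universe <- sprintf(paste0("g%0", width, "d"), seq_len(config$nGenes))

  lfc <- setNames(numeric(config$nGenes), universe)
  modRows <- list()
  for (m in config$modules) {
    genes <- gsl[[m$name]]
    nResp <- ceiling(m$responderFraction * length(genes))
    responders <- genes[seq_len(nResp)]
    nUp <- round(m$directionMix * nResp)
    signs <- c(rep(1, nUp), rep(-1, nResp - nUp))
    lfc[responders] <- signs * m$effectSize
    modRows[[m$name]] <- data.frame(
      module = m$name, effect_size = m$effectSize,
      responder_fraction = m$responderFraction,
      direction_mix = m$directionMix,
      n_responders = nResp,
      activated = m$effectSize > 0,
      stringsAsFactors = FALSE)
  }

  n <- config$nPerCohort
  sampleIds <- c(paste0(config$conditionId, "_t", seq_len(n)),
                 paste0(config$conditionId, "_c", seq_len(n)))
  vals <- .withSeed(.subSeed(config$seed, "expression"), {
    matrix(rnorm(config$nGenes * 2L * n, mean = config$baselineMean,
                 sd = config$noiseSd),
           nrow = config$nGenes, ncol = 2L * n,
           dimnames = list(universe, sampleIds))
  })
  vals[, seq_len(n)] <- vals[, seq_len(n)] + lfc

  meta <- data.frame(
    sample_id = sampleIds,
    condition_id = config$conditionId,
    cohort = rep(c("treatment", "control"), each = n),
    stringsAsFactors = FALSE)

  truth <- list(
    geneLfc = lfc,
    modules = if (length(modRows)) do.call(rbind, c(modRows, list(make.row.names = FALSE)))
              else data.frame())
  list(experiment = ToxExperiment(vals, meta), geneSets = gsl, truth = truth)
}
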