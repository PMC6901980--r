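#' @import methods
#' @importFrom stats pt pchisq sd cor cov var p.adjust rnorm setNames
#' @importFrom utils combn read.delim write.table head adist packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
NULL

#' GeneSetList: a collection of named gene sets
#'
#' Container for gene sets such as histopathology-linked injury modules or
#' KEGG pathways.  Gene identifiers are opaque, case-sensitive strings;
#' within each set they are de-duplicated preserving first occurrence.
#'
#' @slot sets named list of character vectors (gene identifiers per set).
#' @slot descriptions character vector parallel to \code{sets} (the GMT
#'   description column).
#' @slot source single string: the file the collection was read from, or
#'   \code{"synthetic"}.
#'
#' @seealso [readGmt()], [writeGmt()], [generateUniverse()]
#' @export
setClass("GeneSetList",
         slots = c(sets = "list",
                   descriptions = "character",
                   source = "character"))

setValidity("GeneSetList", function(object) {
  msgs <- character(0)
  nm <- names(object@sets)
  if (length(object@sets) == 0L) nm <- character(0)
  if (length(object@sets) > 0L && (is.null(nm) || any(!nzchar(nm)))) {
    msgs <- c(msgs, "all gene sets must have non-empty names")
  } else if (anyDuplicated(nm)) {
    msgs <- c(msgs, sprintf("duplicate gene-set names: %s",
                            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (length(object@descriptions) != length(object@sets)) {
    msgs <- c(msgs, "descriptions must be parallel to sets")
  }
  for (i in seq_along(object@sets)) {
    g <- object@sets[[i]]
    if (!is.character(g) || length(g) == 0L) {
      msgs <- c(msgs, sprintf("set '%s' has no genes", nm[i]))
    } else if (any(!nzchar(g))) {
      msgs <- c(msgs, sprintf("set '%s' contains empty gene identifiers", nm[i]))
    } else if (anyDuplicated(g)) {
      msgs <- c(msgs, sprintf("set '%s' contains duplicate genes after construction", nm[i]))
    }
  }
  if (length(object@source) != 1L) msgs <- c(msgs, "source must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSetList
#'
#' @param sets named list of character vectors of gene identifiers.
#'   Duplicate genes within a set are removed, keeping the first occurrence.
#' @param descriptions optional character vector of free-text descriptions
#'   (recycled empty when missing).
#' @param source provenance label, default \code{"synthetic"}.
#' @return a \linkS4class{GeneSetList}.
#' @examples
#' gsl <- GeneSetList(list(fibrosis = c("g1", "g2"), necrosis = c("g3")))
#' length(gsl)
#' gsl[["fibrosis"]]
#' @export
GeneSetList <- function(sets, descriptions = NULL, source = "synthetic") {
  if (!is.list(sets)) stop("'sets' must be a named list of character vectors")
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  new("GeneSetList", sets = sets,
      descriptions = as.character(descriptions), source = source)
}

#' @describeIn GeneSetList number of sets in the collection
#' @param x a GeneSetList
#' @export
setMethod("length", "GeneSetList", function(x) length(x@sets))

#' @describeIn GeneSetList set names
#' @export
setMethod("names", "GeneSetList", function(x) names(x@sets))

#' @describeIn GeneSetList extract one set's gene identifiers
#' @param i set name or index
#' @export
setMethod("[[", "GeneSetList", function(x, i) x@sets[[i]])

#' @describeIn GeneSetList subset the collection by name or index
#' @export
setMethod("[", "GeneSetList", function(x, i) {
  new("GeneSetList", sets = x@sets[i],
      descriptions = x@descriptions[if (is.character(i)) match(i, names(x@sets)) else i],
      source = x@source)
})

setMethod("show", "GeneSetList", function(object) {
  sz <- lengths(object@sets)
  cat(sprintf("GeneSetList with %d set(s), sizes %d-%d, source: %s\n",
              length(object@sets),
              if (length(sz)) min(sz) else 0L,
              if (length(sz)) max(sz) else 0L,
              object@source))
  shown <- head(names(object@sets), 5L)
  if (length(shown)) cat("  ", paste(shown, collapse = ", "),
                         if (length(object@sets) > 5L) ", ..." else "", "\n", sep = "")
})

#' Gene-set sizes
#' @param x a \linkS4class{GeneSetList}
#' @return named integer vector of set sizes.
#' @export
geneSetSizes <- function(x) {
  stopifnot(is(x, "GeneSetList"))
  lengths(x@sets)
}

#' Gene-set descriptions
#' @param x a \linkS4class{GeneSetList}
#' @return named character vector of GMT descriptions.
#' @export
geneSetDescriptions <- function(x) {
  stopifnot(is(x, "GeneSetList"))
  setNames(x@descriptions, names(x@sets))
}

#' ToxExperiment: replicated treatment/control log-expression
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' (\code{"logexpr"}) holds gene x sample log-scale expression, and whose
#' column data carries \code{sample_id}, \code{condition_id} (tissue /
#' dose / time encoding) and \code{cohort} (\code{"treatment"} or
#' \code{"control"}).  Every condition must have at least two samples in
#' each cohort so the per-gene t-test is defined.
#'
#' @seealso [readExpression()], [simulateExperiment()], [computeFoldChanges()]
#' @export
setClass("ToxExperiment", contains = "SummarizedExperiment")

setValidity("ToxExperiment", function(object) {
  msgs <- character(0)
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "condition_id", "cohort")
  if (!all(need %in% colnames(cd))) {
    return(sprintf("colData must contain columns: %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(cd$sample_id)) msgs <- c(msgs, "sample_id values must be unique")
  bad <- setdiff(unique(cd$cohort), c("treatment", "control"))
  if (length(bad)) {
    msgs <- c(msgs, sprintf("cohort must be 'treatment' or 'control' (found: %s)",
                            paste(bad, collapse = ", ")))
  }
  tab <- table(cd$condition_id, cd$cohort)
  if (!all(c("treatment", "control") %in% colnames(tab)) || any(tab < 2L)) {
    msgs <- c(msgs, "every condition needs >= 2 treatment and >= 2 control samples")
  }
  m <- SummarizedExperiment::assay(object)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    msgs <- c(msgs, "gene identifiers (rownames) must be present and unique")
  }
  if (!all(is.finite(m))) msgs <- c(msgs, "expression values must be finite")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ToxExperiment
#'
#' @param values numeric matrix, genes x samples, log-scale expression with
#'   gene identifiers as rownames.
#' @param sampleData data.frame with columns \code{sample_id},
#'   \code{condition_id}, \code{cohort}; rows match the matrix columns by
#'   \code{sample_id}.
#' @return a \linkS4class{ToxExperiment}.
#' @export
ToxExperiment <- function(values, sampleData) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  sampleData <- as.data.frame(sampleData, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition_id", "cohort")
  if (!all(need %in% colnames(sampleData))) {
    stop("sampleData must contain columns: ", paste(need, collapse = ", "))
  }
  if (is.null(colnames(values))) stop("'values' must have sample identifiers as colnames")
  missMeta <- setdiff(colnames(values), sampleData$sample_id)
  missMat <- setdiff(sampleData$sample_id, colnames(values))
  if (length(missMeta)) {
    stop("samples present in the matrix but missing from metadata: ",
         paste(missMeta, collapse = ", "))
  }
  if (length(missMat)) {
    stop("samples present in metadata but missing from the matrix: ",
         paste(missMat, collapse = ", "))
  }
  sampleData <- sampleData[match(colnames(values), sampleData$sample_id), , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(logexpr = values),
    colData = S4Vectors::DataFrame(sampleData, row.names = sampleData$sample_id))
  new("ToxExperiment", se)
}

#' Log-expression matrix of a ToxExperiment
#' @param x a \linkS4class{ToxExperiment}
#' @return numeric gene x sample matrix.
#' @export
logExpr <- function(x) {
  stopifnot(is(x, "ToxExperiment"))
  SummarizedExperiment::assay(x, "logexpr")
}

#' Sample metadata of a ToxExperiment
#' @param x a \linkS4class{ToxExperiment}
#' @return data.frame with sample_id, condition_id, cohort.
#' @export
sampleInfo <- function(x) {
  stopifnot(is(x, "ToxExperiment"))
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Condition identifiers present in a ToxExperiment
#' @param x a \linkS4class{ToxExperiment}
#' @return character vector of unique condition ids.
#' @export
conditionNames <- function(x) {
  unique(sampleInfo(x)$condition_id)
}

#' NullEngine: permutation-null configuration
#'
#' Describes how the random-gene-set null distribution of a set statistic
#' is generated: the number of Monte-Carlo draws (the headline analysis
#' uses 10,000), the seed, and whether to enumerate all same-size subsets
#' exhaustively instead of sampling.  Exhaustive mode is only permitted
#' when \code{choose(universe, set size)} does not exceed
#' \code{exhaustiveCap}.
#'
#' @slot nPerm integer, number of Monte-Carlo draws.
#' @slot seed integer root seed.
#' @slot mode \code{"montecarlo"} or \code{"exhaustive"}.
#' @slot exhaustiveCap numeric cap on the number of enumerated subsets.
#' @seealso [nullEngine()], [aafcScore()], [afcScore()]
#' @export
setClass("NullEngine",
         slots = c(nPerm = "integer", seed = "integer",
                   mode = "character", exhaustiveCap = "numeric"))

setValidity("NullEngine", function(object) {
  msgs <- character(0)
  if (length(object@nPerm) != 1L || is.na(object@nPerm) || object@nPerm < 1L) {
    msgs <- c(msgs, "nPerm must be a single integer >= 1")
  }
  if (!object@mode %in% c("montecarlo", "exhaustive")) {
    msgs <- c(msgs, "mode must be 'montecarlo' or 'exhaustive'")
  }
  if (length(object@exhaustiveCap) != 1L || object@exhaustiveCap < 1) {
    msgs <- c(msgs, "exhaustiveCap must be a single number >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a NullEngine
#'
#' @param nPerm number of Monte-Carlo permutations (default 10000).
#' @param seed integer root seed for the null draws.
#' @param mode \code{"montecarlo"} (default) or \code{"exhaustive"}.
#' @param exhaustiveCap maximum number of subsets enumerated in exhaustive
#'   mode (default 2e5).
#' @return a \linkS4class{NullEngine}.
#' @examples
#' ne <- nullEngine(nPerm = 1000, seed = 7)
#' @export
nullEngine <- function(nPerm = 10000L, seed = 1L, mode = c("montecarlo", "exhaustive"),
                       exhaustiveCap = 2e5) {
  mode <- match.arg(mode)
  nPerm <- .assertCount(nPerm, "nPerm", 1L)
  seed <- .assertCount(seed, "seed", 0L)
  new("NullEngine", nPerm = nPerm, seed = seed, mode = mode,
      exhaustiveCap = exhaustiveCap)
}

setMethod("show", "NullEngine", function(object) {
  cat(sprintf("NullEngine: mode=%s, nPerm=%d, seed=%d\n",
              object@mode, object@nPerm, object@seed))
})
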