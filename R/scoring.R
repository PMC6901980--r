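# Gene-set scoring: the signed aggregated fold-change (AFC) pathway
# statistic and the absolute aggregated fold-change (AAFC) injury-module
# activation statistic, each tested against a null of random same-size
# gene subsets drawn without replacement from the measured universe.

# Match a set's genes to the fold-change table, preserving set order.
.measuredGenes <- function(fct, genes) {
  genes[genes %in% fct$gene]
}

# Null sums of `x` over subsets of size k.  Monte-Carlo mode draws
# null@nPerm subsets without replacement; exhaustive mode enumerates all
# choose(n, k) subsets (only when that count is within the cap).
.nullSums <- function(x, k, null) {
  n <- length(x)
  if (null@mode == "exhaustive") {
    nComb <- choose(n, k)
    if (nComb > null@exhaustiveCap) {
      stop(sprintf("exhaustive null needs %s subsets, above the cap of %s; use montecarlo",
                   format(nComb, big.mark = ","), format(null@exhaustiveCap)))
    }
    idx <- combn(n, k)
    list(sums = colSums(matrix(x[idx], nrow = k)), n = nComb, exhaustive = TRUE)
  } else {
    sums <- .withSeed(null@seed,
      vapply(seq_len(null@nPerm),
             function(i) sum(x[sample.int(n, k)]), numeric(1)))
    list(sums = sums, n = null@nPerm, exhaustive = FALSE)
  }
}

.setPreamble <- function(fct, genes, setName, minCoverage) {
  stopifnot(is.data.frame(fct), all(c("gene", "fc", "p") %in% colnames(fct)),
            nrow(fct) >= 2L)
  genes <- unique(as.character(genes))
  measured <- .measuredGenes(fct, genes)
  if (length(measured) == 0L) {
    stop("gene set '", setName, "' has no genes in the measured universe")
  }
  if (length(measured) == nrow(fct)) {
    stop("gene set '", setName,
         "' covers the whole measured universe; the permutation null is degenerate")
  }
  coverage <- length(measured) / length(genes)
  if (coverage < minCoverage) {
    warning(sprintf("gene set '%s': only %d of %d genes measured (%.0f%% < %.0f%% coverage)",
                    setName, length(measured), length(genes),
                    100 * coverage, 100 * minCoverage))
  }
  list(measured = measured, coverage = coverage)
}

#' Signed aggregated fold-change (AFC) pathway score
#'
#' The pathway score is the sum of the per-gene log fold changes over the
#' set's measured genes; its sign gives the direction of regulation.
#' Significance is a one-sided permutation p-value in the observed
#' direction, against the scores of random same-size gene subsets drawn
#' without replacement from the measured universe.  Null values exactly
#' equal to the observed score count as as-or-more extreme.  The add-one
#' corrected p-value \code{(1 + extreme) / (draws + 1)} is reported as
#' \code{p_perm}; the plain proportion is reported as \code{p_plain}.
#'
#' @param fct fold-change table from [computeFoldChanges()].
#' @param genes character vector of the set's gene identifiers.
#' @param null a [nullEngine()].
#' @param setName label for the result row.
#' @param minCoverage minimum fraction of set genes that must be measured
#'   before a warning is raised (default 0.5; genes absent from the
#'   matrix are dropped and counted via \code{n_measured}).
#' @return one-row data.frame with \code{set_name}, \code{n_measured},
#'   \code{coverage}, \code{score}, \code{direction} (\code{"up"},
#'   \code{"down"} or \code{"none"} at score 0), \code{p_perm},
#'   \code{p_plain}, and \code{z}, the signed score standardised against
#'   the null mean and spread (0 when the null is degenerate).
#' @export
afcScore <- function(fct, genes, null = nullEngine(), setName = "set",
                     minCoverage = 0.5) {
  pre <- .setPreamble(fct, genes, setName, minCoverage)
  fcv <- fct$fc[match(pre$measured, fct$gene)]
  score <- sum(fcv)
  nd <- .nullSums(fct$fc, length(pre$measured), null)
  extreme <- if (score >= 0) sum(nd$sums >= score) else sum(nd$sums <= score)
  sdv <- sd(nd$sums)
  data.frame(set_name = setName,
             n_measured = length(pre$measured),
             coverage = pre$coverage,
             score = score,
             direction = if (score > 0) "up" else if (score < 0) "down" else "none",
             p_perm = (1 + extreme) / (nd$n + 1),
             p_plain = extreme / nd$n,
             z = if (!is.finite(sdv) || sdv == 0) 0 else (score - mean(nd$sums)) / sdv,
             stringsAsFactors = FALSE)
}

#' Absolute aggregated fold-change (AAFC) module activation score
#'
#' The activation score aggregates the absolute values of the per-gene
#' log fold changes over the set's measured genes (mean by default; the
#' z-score and permutation p-value are identical under sum aggregation
#' because the null preserves set size).  The null is the same statistic
#' on random same-size gene subsets of the measured universe; the
#' z-score is the number of null standard deviations separating the
#' observed score from the null mean.  A Fisher combined p-value over
#' the set's per-gene t-test p-values is reported as an indicator of the
#' reliability of the member genes.
#'
#' @inheritParams afcScore
#' @param aggregate \code{"mean"} (default) or \code{"sum"}.
#' @return one-row data.frame with \code{set_name}, \code{n_measured},
#'   \code{coverage}, \code{score}, \code{p_perm}, \code{p_plain},
#'   \code{z}, \code{degenerate} (TRUE when the null has zero spread, in
#'   which case z = 0 and p_perm = 1), \code{p_fisher}.
#' @examples
#' fct <- data.frame(gene = paste0("g", 1:5), fc = c(0.1, 0.2, 0.3, 0.4, 0.5),
#'                   t = 0, p = 0.5)
#' aafcScore(fct, c("g4", "g5"), nullEngine(mode = "exhaustive"), "top2")
#' @export
aafcScore <- function(fct, genes, null = nullEngine(), setName = "set",
                      minCoverage = 0.5, aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  pre <- .setPreamble(fct, genes, setName, minCoverage)
  k <- length(pre$measured)
  absfc <- abs(fct$fc)
  obsSum <- sum(absfc[match(pre$measured, fct$gene)])
  nd <- .nullSums(absfc, k, null)
  div <- if (aggregate == "mean") k else 1
  obs <- obsSum / div
  # the z-score and p-value are computed on the subset sums: because the
  # null preserves set size, mean and sum aggregation give the same tail
  # counts and the same standardised distance, here bit-identically
  extreme <- sum(nd$sums >= obsSum)
  mu <- mean(nd$sums)
  sdv <- sd(nd$sums)
  degenerate <- !is.finite(sdv) || sdv == 0
  if (degenerate) {
    z <- 0
    pPerm <- 1
    pPlain <- 1
  } else {
    z <- (obsSum - mu) / sdv
    pPerm <- (1 + extreme) / (nd$n + 1)
    pPlain <- extreme / nd$n
  }
  pf <- fisherCombined(fct$p[match(pre$measured, fct$gene)])
  data.frame(set_name = setName, n_measured = k, coverage = pre$coverage,
             score = obs, p_perm = pPerm, p_plain = pPlain, z = z,
             degenerate = degenerate, p_fisher = pf,
             stringsAsFactors = FALSE)
}

#' Fisher's combined probability
#'
#' Combines k independent p-values via \code{X = -2 * sum(log(p))},
#' referred to the upper tail of a chi-squared distribution with 2k
#' degrees of freedom.  Input p-values of exactly 0 are clamped to the
#' smallest positive double with a warning; values outside [0, 1] are an
#' error.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return combined p-value in (0, 1].
#' @examples
#' fisherCombined(c(0.05, 0.05))  # ~0.0175
#' @export
fisherCombined <- function(pvals) {
  if (length(pvals) == 0L) stop("'pvals' must be non-empty")
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be finite and lie in [0, 1]")
  }
  if (any(pvals == 0)) {
    warning("p-value(s) of exactly 0 clamped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals), lower.tail = FALSE)
}

#' Score every set in a collection
#'
#' Applies [aafcScore()] or [afcScore()] to each set of a collection
#' against one fold-change table.  Each set's permutation null is seeded
#' by a deterministic sub-seed derived from the engine's root seed and
#' the set name, so results are reproducible and invariant to the order
#' of sets in the collection.  Sets with no measured genes, or with
#' measured coverage below \code{minCoverage}, yield a flagged row
#' (\code{passed_coverage = FALSE}) rather than being dropped; a set with
#' no measured genes has \code{NA} statistics.
#'
#' @param fct fold-change table from [computeFoldChanges()].
#' @param gsl a \linkS4class{GeneSetList}.
#' @param statistic \code{"aafc"} (module activation, default) or
#'   \code{"afc"} (signed pathway score).
#' @param null a [nullEngine()]; per-set seeds are derived from its seed.
#' @param minCoverage coverage gate, as in [aafcScore()].
#' @return data.frame with one row per set, columns as in the per-set
#'   scorer plus \code{passed_coverage}.
#' @export
scoreCollection <- function(fct, gsl, statistic = c("aafc", "afc"),
                            null = nullEngine(), minCoverage = 0.5) {
  statistic <- match.arg(statistic)
  stopifnot(is(gsl, "GeneSetList"))
  if (length(gsl) == 0L) stop("gene-set collection is empty")
  scorer <- if (statistic == "aafc") aafcScore else afcScore
  lowCov <- character(0)
  rows <- lapply(names(gsl), function(nm) {
    subNull <- null
    subNull@seed <- .subSeed(null@seed, c("score", nm))
    genes <- gsl[[nm]]
    measured <- .measuredGenes(fct, genes)
    if (length(measured) == 0L) {
      lowCov <<- c(lowCov, nm)
      row <- if (statistic == "aafc") {
        data.frame(set_name = nm, n_measured = 0L, coverage = 0,
                   score = NA_real_, p_perm = NA_real_, p_plain = NA_real_,
                   z = NA_real_, degenerate = NA, p_fisher = NA_real_,
                   stringsAsFactors = FALSE)
      } else {
        data.frame(set_name = nm, n_measured = 0L, coverage = 0,
                   score = NA_real_, direction = NA_character_,
                   p_perm = NA_real_, p_plain = NA_real_, z = NA_real_,
                   stringsAsFactors = FALSE)
      }
      row$passed_coverage <- FALSE
      return(row)
    }
    row <- withCallingHandlers(
      scorer(fct, genes, subNull, setName = nm, minCoverage = minCoverage),
      warning = function(w) {
        if (grepl("coverage", conditionMessage(w))) {
          lowCov <<- c(lowCov, nm)
          invokeRestart("muffleWarning")
        }
      })
    row$passed_coverage <- row$coverage >= minCoverage
    row
  })
  if (length(lowCov)) {
    warning("set(s) below the coverage gate, flagged not dropped: ",
            paste(lowCov, collapse = ", "))
  }
  do.call(rbind, rows)
}
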