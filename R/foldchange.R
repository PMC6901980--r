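# Per-gene fold changes, significance, and DEG calling.
#
# The fold change of a gene is the difference of cohort means on the
# log-expression scale (treatment minus control); significance is a
# two-sample pooled-variance Student's t-test per gene, Benjamini-
# Hochberg adjusted across genes for DEG calling.

# Vectorised pooled-variance two-sample t-test over matrix rows.
# Degenerate rows (pooled variance 0) follow the documented convention:
# equal means -> t = 0, p = 1; unequal means -> p = smallest positive
# double, t = signed Inf, with a warning.
.rowTTest <- function(tm, cm) {
  nt <- ncol(tm); nc <- ncol(cm)
  mt <- rowMeans(tm); mc <- rowMeans(cm)
  sst <- rowSums((tm - mt)^2)
  ssc <- rowSums((cm - mc)^2)
  df <- nt + nc - 2L
  sp2 <- (sst + ssc) / df
  se <- sqrt(sp2 * (1 / nt + 1 / nc))
  fc <- mt - mc
  t <- fc / se
  p <- 2 * pt(abs(t), df = df, lower.tail = FALSE)
  degenerate <- se == 0
  if (any(degenerate)) {
    eq <- degenerate & fc == 0
    ne <- degenerate & fc != 0
    t[eq] <- 0; p[eq] <- 1
    if (any(ne)) {
      warning(sum(ne), " gene(s) with zero variance in both cohorts but ",
              "unequal means; p set to the smallest positive double")
      t[ne] <- sign(fc[ne]) * Inf
      p[ne] <- .Machine$double.xmin
    }
  }
  list(fc = fc, t = t, p = p)
}

#' Per-gene fold changes and t-test significance
#'
#' For one condition, computes each gene's fold change as the difference
#' between the mean log-transformed expression of the treatment and
#' control cohorts, and its significance by a two-sample pooled-variance
#' Student's t-test.  On natural-log input the fold change is the
#' natural-log effect size (beta).
#'
#' @param te a \linkS4class{ToxExperiment}.
#' @param condition condition identifier to analyse; may be omitted when
#'   the experiment holds a single condition.
#' @return data.frame (one row per gene) with columns \code{gene},
#'   \code{fc}, \code{t}, \code{p}.
#' @seealso [callDegs()], [aafcScore()], [afcScore()]
#' @export
computeFoldChanges <- function(te, condition = NULL) {
  stopifnot(is(te, "ToxExperiment"))
  info <- sampleInfo(te)
  if (is.null(condition)) {
    conds <- unique(info$condition_id)
    if (length(conds) != 1L) {
      stop("experiment holds ", length(conds),
           " conditions; specify 'condition'")
    }
    condition <- conds
  }
  sel <- info$condition_id == condition
  if (!any(sel)) stop("condition not found: ", condition)
  info <- info[sel, , drop = FALSE]
  m <- logExpr(te)[, info$sample_id, drop = FALSE]
  tCols <- info$sample_id[info$cohort == "treatment"]
  cCols <- info$sample_id[info$cohort == "control"]
  if (length(tCols) < 2L || length(cCols) < 2L) {
    stop("condition '", condition, "' needs >= 2 samples in each cohort")
  }
  res <- .rowTTest(m[, tCols, drop = FALSE], m[, cCols, drop = FALSE])
  data.frame(gene = rownames(m), fc = res$fc, t = res$t, p = res$p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' Adjusts the per-gene t-test p-values by Benjamini-Hochberg and flags a
#' gene as differentially expressed when its adjusted p-value (q) is at
#' most \code{qMax} and the magnitude of its natural-log effect size is
#' at least \code{betaMin}.  The default \code{betaMin = 0.41} is the
#' natural-log bound corresponding to a 1.5-fold change
#' (\code{round(log(1.5), 2)}).
#'
#' @param fct fold-change table from [computeFoldChanges()].
#' @param qMax FDR threshold in [0, 1] (default 0.05).
#' @param betaMin minimum absolute natural-log effect size (default 0.41).
#' @return the input data.frame with added columns \code{q} and
#'   \code{is_deg}; all genes are returned, not only the DEGs.
#' @export
callDegs <- function(fct, qMax = 0.05, betaMin = 0.41) {
  stopifnot(is.data.frame(fct), nrow(fct) > 0L,
            all(c("gene", "fc", "p") %in% colnames(fct)))
  .assertScalarNumber(qMax, "qMax", lower = 0, upper = 1)
  .assertScalarNumber(betaMin, "betaMin", lower = 0)
  fct$q <- p.adjust(fct$p, method = "BH")
  fct$is_deg <- fct$q <= qMax & abs(fct$fc) >= betaMin
  fct
}

#' Overlap and fold-change concordance of two DEG lists
#'
#' Counts the genes called DEG in both, only the first, and only the
#' second table, and reports the squared Pearson correlation of the fold
#' changes over the shared DEGs together with the least-squares slope
#' (R-squared alone cannot distinguish concordant from anti-concordant
#' change).  With fewer than 3 shared DEGs, or zero variance in either
#' fold-change vector, the correlation is reported as \code{NA}.
#'
#' @param a,b DEG tables from [callDegs()] over comparable gene universes.
#' @return list of class \code{"OverlapSummary"} with \code{n_a},
#'   \code{n_b}, \code{n_shared}, \code{n_a_only}, \code{n_b_only},
#'   \code{r_squared}, \code{slope}.
#' @export
degOverlap <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b),
            all(c("gene", "fc", "is_deg") %in% colnames(a)),
            all(c("gene", "fc", "is_deg") %in% colnames(b)))
  degsA <- a$gene[a$is_deg]
  degsB <- b$gene[b$is_deg]
  shared <- intersect(degsA, degsB)
  r2 <- NA_real_; slope <- NA_real_
  if (length(shared) >= 3L) {
    fa <- a$fc[match(shared, a$gene)]
    fb <- b$fc[match(shared, b$gene)]
    if (var(fa) > 0 && var(fb) > 0) {
      r2 <- cor(fa, fb)^2
      slope <- cov(fa, fb) / var(fa)
    }
  }
  structure(list(n_a = length(degsA), n_b = length(degsB),
                 n_shared = length(shared),
                 n_a_only = length(setdiff(degsA, degsB)),
                 n_b_only = length(setdiff(degsB, degsA)),
                 r_squared = r2, slope = slope),
            class = "OverlapSummary")
}

#' @export
print.OverlapSummary <- function(x, ...) {
  cat(sprintf("DEG overlap: %d shared, %d only-A, %d only-B\n",
              x$n_shared, x$n_a_only, x$n_b_only))
  if (is.na(x$r_squared)) {
    cat("fold-change correlation over shared DEGs: not defined\n")
  } else {
    cat(sprintf("fold-change R^2 over shared DEGs: %.3f (slope %.3f)\n",
                x$r_squared, x$slope))
  }
  invisible(x)
}
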