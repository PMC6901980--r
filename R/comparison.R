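# Cross-condition analysis: ranking modules within a condition,
# correlating activation between conditions (the in vitro / in vivo
# concordance question), aggregating over exposure conditions by maximum
# activation score, and classifying toxicant risk against a target
# injury module such as fibrosis.

#' Rank module activation results within a condition
#'
#' Orders activation results by descending z-score — from the most to
#' the least likely injury endpoint — breaking ties by ascending
#' permutation p-value and then set name.  A module is flagged
#' significant when its permutation p-value is below \code{alpha}
#' (default 0.01).
#'
#' @param results data.frame of AAFC results, e.g. from
#'   [scoreCollection()] (needs \code{set_name}, \code{z}, \code{p_perm}).
#' @param alpha significance threshold on the permutation p-value.
#' @return the input rows sorted, with added columns \code{rank}
#'   (1..K) and \code{significant}; \code{alpha} is recorded as an
#'   attribute.
#' @export
rankModules <- function(results, alpha = 0.01) {
  stopifnot(is.data.frame(results), nrow(results) > 0L,
            all(c("set_name", "z", "p_perm") %in% colnames(results)))
  .assertScalarNumber(alpha, "alpha", lower = 0, upper = 1)
  if (anyDuplicated(results$set_name)) {
    stop("duplicate set names: ",
         paste(unique(results$set_name[duplicated(results$set_name)]),
               collapse = ", "))
  }
  ord <- order(-results$z, results$p_perm, results$set_name)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$significant <- !is.na(out$p_perm) & out$p_perm < alpha
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Correlate module activation between two conditions
#'
#' Pairs the z-scores of modules shared by two ranked (or unranked)
#' result tables and reports their squared Pearson correlation together
#' with the least-squares slope of b on a.  R-squared is sign-blind, so
#' the slope is what distinguishes concordant from anti-concordant
#' activation.  At least 3 shared modules are required; zero variance in
#' either z-vector yields an \code{NA} correlation with a warning.
#'
#' @param a,b data.frames with columns \code{set_name} and \code{z}
#'   (e.g. from [rankModules()] or [scoreCollection()]).
#' @param conditionA,conditionB labels for the report.
#' @return list of class \code{"CrossConditionCorrelation"} with
#'   \code{condition_a}, \code{condition_b}, \code{n_shared},
#'   \code{r_squared}, \code{slope}.
#' @export
correlateConditions <- function(a, b, conditionA = "a", conditionB = "b") {
  stopifnot(is.data.frame(a), is.data.frame(b),
            all(c("set_name", "z") %in% colnames(a)),
            all(c("set_name", "z") %in% colnames(b)))
  shared <- intersect(a$set_name, b$set_name)
  if (length(shared) < 3L) {
    stop("need >= 3 shared modules to correlate; found ", length(shared))
  }
  za <- a$z[match(shared, a$set_name)]
  zb <- b$z[match(shared, b$set_name)]
  r2 <- NA_real_; slope <- NA_real_
  if (var(za) == 0 || var(zb) == 0) {
    warning("zero variance in a z-score vector; correlation not defined")
  } else {
    r2 <- cor(za, zb)^2
    slope <- cov(za, zb) / var(za)
  }
  structure(list(condition_a = conditionA, condition_b = conditionB,
                 n_shared = length(shared), r_squared = r2, slope = slope),
            class = "CrossConditionCorrelation")
}

#' @export
print.CrossConditionCorrelation <- function(x, ...) {
  cat(sprintf("Cross-condition module activation: %s vs %s (%d shared modules)\n",
              x$condition_a, x$condition_b, x$n_shared))
  if (is.na(x$r_squared)) {
    cat("R^2: not defined (zero variance)\n")
  } else {
    cat(sprintf("R^2 = %.3f, slope = %.3f\n", x$r_squared, x$slope))
  }
  invisible(x)
}

#' Maximum activation over exposure conditions
#'
#' For a compound scored under several conditions (doses x time points),
#' keeps, per module, the result row with the maximal activation score
#' and records which condition produced it.  The z and p reported are
#' those of the selected row, not the per-column maxima.  Ties go to the
#' earliest condition in the list.
#'
#' @param perCondition named list of AAFC result data.frames, one per
#'   condition, all scoring the same module collection.
#' @return data.frame with one row per module plus a \code{condition}
#'   column naming the provenance of each row.
#' @export
maxOverConditions <- function(perCondition) {
  stopifnot(is.list(perCondition), length(perCondition) > 0L)
  if (is.null(names(perCondition)) || any(!nzchar(names(perCondition)))) {
    stop("'perCondition' must be a named list (condition ids as names)")
  }
  ref <- sort(perCondition[[1L]]$set_name)
  for (nm in names(perCondition)) {
    df <- perCondition[[nm]]
    stopifnot(is.data.frame(df), all(c("set_name", "score") %in% colnames(df)))
    if (!identical(sort(df$set_name), ref)) {
      stop("condition '", nm, "' scores a different module set")
    }
  }
  rows <- lapply(ref, function(mod) {
    best <- NULL; bestCond <- NULL
    for (nm in names(perCondition)) {
      df <- perCondition[[nm]]
      row <- df[df$set_name == mod, , drop = FALSE]
      if (is.null(best) ||
          (!is.na(row$score) && (is.na(best$score) || row$score > best$score))) {
        best <- row; bestCond <- nm
      }
    }
    best$condition <- bestCond
    best
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify toxicant risk from maximum module activation
#'
#' A compound is called high-risk for the injury encoded by
#' \code{targetModule} (e.g. fibrosis) when that module's permutation
#' p-value, in the max-over-conditions table, is below \code{alpha}.
#'
#' @param maxed data.frame from [maxOverConditions()].
#' @param targetModule module name to test (must be present).
#' @param alpha significance threshold (default 0.01).
#' @param compoundId label for the report.
#' @return list of class \code{"RiskCall"} with \code{compound_id},
#'   \code{target_module}, \code{max_score_condition}, \code{max_score},
#'   \code{max_z}, \code{p_perm}, \code{significant}, \code{call}
#'   (\code{"high_risk"} or \code{"low_risk"}).
#' @export
classifyRisk <- function(maxed, targetModule, alpha = 0.01,
                         compoundId = "compound") {
  stopifnot(is.data.frame(maxed),
            all(c("set_name", "score", "p_perm", "condition") %in% colnames(maxed)))
  .assertScalarNumber(alpha, "alpha", lower = 0, upper = 1)
  row <- maxed[maxed$set_name == targetModule, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop("target module '", targetModule, "' not present in the scored collection")
  }
  significant <- !is.na(row$p_perm) && row$p_perm < alpha
  structure(list(compound_id = compoundId,
                 target_module = targetModule,
                 max_score_condition = row$condition,
                 max_score = row$score,
                 max_z = if ("z" %in% colnames(row)) row$z else NA_real_,
                 p_perm = row$p_perm,
                 significant = significant,
                 call = if (significant) "high_risk" else "low_risk"),
            class = "RiskCall")
}

#' @export
print.RiskCall <- function(x, ...) {
  cat(sprintf("%s: %s (module '%s', max score %.3f at condition '%s', p_perm = %.3g)\n",
              x$compound_id, x$call, x$target_module, x$max_score,
              x$max_score_condition, x$p_perm))
  invisible(x)
}
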