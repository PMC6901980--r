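# Readers and writers for the plain-text formats the pipeline touches:
# GMT gene-set collections, TSV expression matrices with sample metadata,
# and TSV/JSON result tables.  All TSV is tab-separated UTF-8, unquoted.

#' Read a GMT gene-set file
#'
#' Parses the Broad/MSigDB GMT dialect: one set per line,
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.  Duplicate genes
#' within a set are removed preserving first occurrence; duplicate set
#' names are an error.  Empty trailing fields (a common artifact of
#' trailing tabs) are dropped.
#'
#' @param path path to a GMT file.
#' @return a \linkS4class{GeneSetList} with \code{source} set to \code{path}.
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("FIB\tfibrosis\tg1\tg2\tg2", f)
#' readGmt(f)[["FIB"]]
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("GMT file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  sets <- vector("list", length(fields))
  descriptions <- character(length(fields))
  nms <- character(length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (length(f) < 3L || !nzchar(f[1L]) || length(genes) == 0L) {
      stop(sprintf("malformed GMT line %d in %s: need name, description and >= 1 gene",
                   i, path))
    }
    nms[i] <- f[1L]
    descriptions[i] <- f[2L]
    sets[[i]] <- unique(genes)
  }
  if (anyDuplicated(nms)) {
    stop("duplicate gene-set names in ", path, ": ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(sets) <- nms
  GeneSetList(sets, descriptions, source = path)
}

#' Write a GeneSetList to GMT
#'
#' @param gsl a \linkS4class{GeneSetList}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(gsl, path) {
  stopifnot(is(gsl, "GeneSetList"))
  lines <- vapply(seq_along(gsl@sets), function(i) {
    paste(c(names(gsl@sets)[i], gsl@descriptions[i], gsl@sets[[i]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix and sample metadata
#'
#' The matrix TSV has gene identifiers in the first column and one column
#' per sample; the metadata TSV has columns \code{sample_id},
#' \code{condition_id}, \code{cohort}.  Every matrix sample must appear in
#' the metadata and vice versa.  Missing (\code{NA} or \code{.}) and
#' non-numeric cells are rejected with the offending gene and sample
#' named: the scoring statistics assume complete matrices.
#'
#' @param matrixPath path to the expression TSV.
#' @param metadataPath path to the sample-metadata TSV.
#' @param logTransform \code{"none"} (default: values already log-scale),
#'   \code{"natural"} (apply \code{log(x + 1)}), or \code{"log2"}
#'   (apply \code{log2(x + 1)}) for count-like input.
#' @return a \linkS4class{ToxExperiment}.
#' @export
readExpression <- function(matrixPath, metadataPath,
                           logTransform = c("none", "natural", "log2")) {
  logTransform <- match.arg(logTransform)
  if (!file.exists(matrixPath)) stop("expression matrix not found: ", matrixPath)
  if (!file.exists(metadataPath)) stop("sample metadata not found: ", metadataPath)

  raw <- read.delim(matrixPath, sep = "\t", header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    na.strings = NULL, quote = "")
  if (ncol(raw) < 2L) stop("expression matrix must have a gene column and >= 1 sample column")
  genes <- raw[[1L]]
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifiers in ", matrixPath, ": ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.finite(num) | col %in% c("NA", "", "."))
    if (length(bad)) {
      stop(sprintf("non-numeric or missing cell in %s: gene '%s', sample '%s' (value '%s')",
                   matrixPath, genes[bad[1L]], samples[j], col[bad[1L]]))
    }
    vals[, j] <- num
  }
  vals <- switch(logTransform,
                 none = vals,
                 natural = log(vals + 1),
                 log2 = log2(vals + 1))

  meta <- read.delim(metadataPath, sep = "\t", header = TRUE,
                     colClasses = "character", check.names = FALSE,
                     na.strings = NULL, quote = "")
  need <- c("sample_id", "condition_id", "cohort")
  if (!all(need %in% colnames(meta))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  ToxExperiment(vals, meta[, need, drop = FALSE])
}

#' Write a ToxExperiment to matrix + metadata TSV
#'
#' @param te a \linkS4class{ToxExperiment}.
#' @param matrixPath,metadataPath output paths.
#' @return invisibly, a character vector of the two paths.
#' @export
writeExpression <- function(te, matrixPath, metadataPath) {
  stopifnot(is(te, "ToxExperiment"))
  m <- logExpr(te)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sampleInfo(te)[, c("sample_id", "condition_id", "cohort")],
              metadataPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(matrixPath, metadataPath))
}

#' Write a result table as TSV
#'
#' @param x data.frame of results (fold changes, DEG calls, set scores...).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultsTsv <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write results as machine-readable JSON
#'
#' @param x list or data.frame to serialise.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeResultsJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
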