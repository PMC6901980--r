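# Shared fixtures: tiny fold-change tables, on-disk TSV/GMT fixtures
# built in code, and standard simulation setups.

makeFct <- function(fc, p = 0.5, genes = paste0("g", seq_along(fc))) {
  data.frame(gene = genes, fc = fc, t = 0, p = rep_len(p, length(fc)),
             stringsAsFactors = FALSE)
}

# 4-gene x 10-sample experiment written to temp TSV files; returns paths.
writeTinyExperiment <- function(dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(11)
  m <- matrix(rnorm(40, 5, 0.5), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  matrixPath <- file.path(dir, "expr.tsv")
  metaPath <- file.path(dir, "meta.tsv")
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = paste0("s", 1:10),
                     condition_id = "liver_hi_24h",
                     cohort = rep(c("treatment", "control"), each = 5))
  write.table(meta, metaPath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(matrix = matrixPath, metadata = metaPath, values = m, meta = meta)
}

# One planted module among decoys: the parameter-recovery workhorse.
recoveryConfig <- function(seed, delta = log(2), directionMix = 0.5,
                           responderFraction = 1, nGenes = 2000,
                           nDecoys = 8, size = 30, noiseSd = 0.5,
                           nPerCohort = 5, conditionId = "sim") {
  simulationConfig(
    nGenes = nGenes, nPerCohort = nPerCohort, noiseSd = noiseSd,
    modules = c(list(plantedModule("planted", size = size, effectSize = delta,
                                   responderFraction = responderFraction,
                                   directionMix = directionMix)),
                decoyModules(nDecoys, size = size)),
    seed = seed, conditionId = conditionId)
}
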