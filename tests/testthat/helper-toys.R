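# small in-code fixtures shared across test files

# random long-format response table
randomResponses <- function(nCells, nDrugs, sparsity = 0, seed = 1,
                            sd = 1) {
  set.seed(seed)
  cells <- sprintf("c%03d", seq_len(nCells))
  drugs <- sprintf("d%02d", seq_len(nDrugs))
  df <- expand.grid(cell_line = cells, drug = drugs,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  df$ln_ic50 <- rnorm(nrow(df), sd = sd)
  if (sparsity > 0)
    df <- df[-sample.int(nrow(df), floor(sparsity * nrow(df))), ]
  df[order(df$cell_line, df$drug), ]
}

# omics matrix with iid features for the given cell lines
toyOmics <- function(cells, nFeatures = 3, modality = "rnaseq", seed = 1) {
  set.seed(seed)
  v <- matrix(rnorm(length(cells) * nFeatures), length(cells), nFeatures,
              dimnames = list(cells, sprintf("f%02d", seq_len(nFeatures))))
  omicsMatrix(v, modality)
}

# paired dataset straight from a response table
toyPaired <- function(responses, nFeatures = 3, seed = 1,
                      vocabulary = sort(unique(responses$drug))) {
  om <- toyOmics(sort(unique(responses$cell_line)), nFeatures, seed = seed)
  buildPairs(om, responses, vocabulary = vocabulary)
}
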