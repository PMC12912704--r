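# Shared fixtures: all data is generated in code at test time.

randomEM <- function(n = 5, g = 4, seed = 1, modality = "scrna",
                     genes = sprintf("g%02d", seq_len(g))) {
  withr::with_seed(seed, {
    v <- matrix(stats::rexp(n * g), n, g, dimnames = list(NULL, genes))
    ExpressionMatrix(v, genes, paste0("c", seq_len(n)), modality)
  })
}

# The desk-scale model profile used for end-to-end checks: 2 blocks, 4 heads,
# width 64, T = 200, 1-layer BiLSTM of width 32, batch 32, lr 1e-3.
tinyModelConfig <- function(nGenes = 50L, ablation = "full", ...) {
  modelConfig(nGenes = nGenes, width = 64L, nBlocks = 2L, nHeads = 4L,
              lstmHidden = 32L, lstmLayers = 1L, T = 200L, batchSize = 32L,
              learningRate = 1e-3, ablation = ablation, ...)
}

# A very small regime for fast smoke tests of the training/imputation loop.
microSim <- function(seed = 1, ...) {
  simulatePair(simConfig(nRefCells = 60L, nStCells = 30L, nGenes = 14L,
                         nModules = 2L, sharedFraction = 0.7, seed = seed,
                         ...))
}

microModelConfig <- function(nGenes = 14L, ablation = "full", ...) {
  modelConfig(nGenes = nGenes, width = 16L, nBlocks = 1L, nHeads = 2L,
              lstmHidden = 8L, lstmLayers = 1L, T = 50L, batchSize = 16L,
              learningRate = 1e-3, ablation = ablation, ...)
}

meanSortedJS <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == ncol(B))
  mean(vapply(seq_len(ncol(A)),
              function(j) jsGene(sort(A[, j]), sort(B[, j])), numeric(1)))
}

heldOutSpcc <- function(imp, stTruth, heldGenes) {
  pred <- exprValues(imp)
  truth <- exprValues(stTruth)
  mean(vapply(heldGenes, function(g) spccGene(pred[, g], truth[, g]),
              numeric(1)))
}
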