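# Run configuration, schema validation, and provenance manifests.

defaultRunConfig <- function() {
  list(
    seed = 0L,
    outDir = ".",
    normalization = "lognorm",
    model = list(width = NULL, nBlocks = 6L, nHeads = 16L, lstmHidden = 128L,
                 lstmLayers = 2L, T = 1000L, scheduleOffset = 0.008,
                 perturbSd = 0.1, ablation = "full", peephole = TRUE,
                 ffnMult = 2L),
    train = list(epochs = 1200L, batchSize = NULL, learningRate = 1e-4,
                 weightDecay = 0.01, klWeight = NULL, nIter = NULL),
    sim = list(nRefCells = 200L, nStCells = 100L, nGenes = 50L, nModules = 4L,
               sharedFraction = 0.7, batchShift = 0, dropoutRate = 0,
               noiseSd = 0.05, nCelltypes = 3L),
    metrics = list(resolution = 1, nPCs = 50L, kNN = 15L, ssimC1 = 0.01,
                   ssimC2 = 0.03),
    impute = list(nSteps = NULL, nDraws = 1L)
  )
}

mergeConfig <- function(base, override, path = "") {
  for (nm in names(override)) {
    if (!nm %in% names(base)) {
      valid <- names(base)
      near <- valid[utils::adist(nm, valid) == min(utils::adist(nm, valid))]
      stop(sprintf("unknown config key '%s%s'; nearest valid key: '%s'",
                   path, nm, near[1]))
    }
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]],
                                paste0(path, nm, "."))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Parse a run configuration
#'
#' Reads a YAML or JSON config file (by extension), validates every key
#' against the schema (unknown keys are rejected with the nearest valid key
#' named), fills defaults, and applies `overrides` last so explicit flags win
#' over file values. Called with neither argument it returns the full default
#' set.
#'
#' @param path optional path to a `.yaml`/`.yml`/`.json` config file.
#' @param overrides named list applied after the file (e.g.
#'   `list(train = list(epochs = 10))`).
#' @return A validated `RunConfig` list with a `configHash` attribute.
#' @export
parseConfig <- function(path = NULL, overrides = list()) {
  cfg <- defaultRunConfig()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    fromFile <- if (grepl("\\.ya?ml$", path)) {
      yaml::read_yaml(path)
    } else if (grepl("\\.json$", path)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else stop("config must be .yaml/.yml or .json")
    cfg <- mergeConfig(cfg, fromFile)
  }
  cfg <- mergeConfig(cfg, overrides)
  attr(cfg, "configHash") <- configHash(cfg)
  cfg
}

sortTree <- function(x) {
  if (is.list(x) && !is.null(names(x))) {
    x <- x[order(names(x))]
    lapply(x, sortTree)
  } else x
}

# 32-bit FNV-1a over a string; returned as 8 hex digits. Self-contained so
# provenance hashing needs no extra dependency.
fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 2166136261
  for (b in bytes) {
    # xor on 16-bit halves to stay in exact double range
    hi <- h %/% 65536; lo <- h %% 65536
    bhi <- b %/% 65536; blo <- b %% 65536
    h <- bitwXor(as.integer(hi), as.integer(bhi)) * 65536 +
      bitwXor(as.integer(lo), as.integer(blo))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

configHash <- function(cfg) {
  attr(cfg, "configHash") <- NULL
  fnv1a(as.character(jsonlite::toJSON(sortTree(cfg), auto_unbox = TRUE,
                                      digits = NA, null = "null")))
}

#' Write a provenance manifest for a run
#'
#' Records the config hash, seed, package and R versions, and a checksum of
#' every input file. Two runs with identical configuration and inputs produce
#' identical manifests (no timestamps inside the hashed content).
#'
#' @param cfg a config list from [parseConfig()].
#' @param inputs character vector of input file paths to checksum.
#' @param outDir directory to write `manifest.json` into (`NULL` to skip
#'   writing).
#' @return The manifest list, invisibly; its own hash is in
#'   `manifest$manifestHash`.
#' @export
runProvenance <- function(cfg, inputs = character(), outDir = cfg$outDir) {
  checksums <- vapply(inputs, function(p) {
    if (!file.exists(p)) stop("input file not found: ", p)
    fnv1a(rawToChar(readBin(p, "raw", file.size(p))))
  }, character(1))
  manifest <- list(
    configHash = configHash(cfg),
    seed = cfg$seed,
    package = "diffuseST",
    packageVersion = as.character(utils::packageVersion("diffuseST")),
    rVersion = paste(R.version$major, R.version$minor, sep = "."),
    inputChecksums = as.list(checksums)
  )
  manifest$manifestHash <- fnv1a(as.character(
    jsonlite::toJSON(sortTree(manifest), auto_unbox = TRUE, digits = NA)))
  if (!is.null(outDir)) {
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(manifest)
}
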