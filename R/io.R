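#' Experiment configuration
#'
#' A complete, serialisable description of a simulation experiment: model
#' kind, all process parameters, initial population, run lengths, the
#' master seed and summary options. Configurations round-trip losslessly
#' through the YAML dialect written by [writeExperimentConfig()].
#'
#' @slot model `"onetype"` or `"multitype"`.
#' @slot lambdas,alphas,betas per-genotype parameter vectors (length 1 for
#'   the one-type model).
#' @slot mutation a [MutationMatrix-class] (`matrix(1)` for one-type).
#' @slot x0 initial genotype counts.
#' @slot nGenerations,nReplicates,masterSeed run controls.
#' @slot quantileLevels quantile levels for the summary.
#' @slot includeExtinct whether extinct replicates count as zeros in
#'   quantiles.
#' @slot deterministicOnly skip the stochastic ensemble.
#' @slot cltThreshold opt-in normal-approximation threshold for the
#'   offspring sampler (`Inf` = exact sampling).
#' @seealso [readExperimentConfig()], [runExperiment()]
#' @export
setClass("ExperimentConfig",
  representation(model = "character", lambdas = "numeric",
                 alphas = "numeric", betas = "numeric",
                 mutation = "MutationMatrix", x0 = "numeric",
                 nGenerations = "integer", nReplicates = "integer",
                 masterSeed = "integer", quantileLevels = "numeric",
                 includeExtinct = "logical", deterministicOnly = "logical",
                 cltThreshold = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (!object@model %in% c("onetype", "multitype"))
      msg <- c(msg, "model must be 'onetype' or 'multitype'")
    k <- nrow(object@mutation)
    if (object@model == "onetype" && k != 1L)
      msg <- c(msg, "one-type model must have a 1x1 mutation matrix")
    if (length(object@lambdas) != k || length(object@alphas) != k ||
        length(object@betas) != k || length(object@x0) != k)
      msg <- c(msg, "lambdas, alphas, betas and x0 must have one entry per genotype")
    if (any(object@lambdas <= 0)) msg <- c(msg, "lambdas must be positive")
    if (any(object@alphas <= 0)) msg <- c(msg, "alphas must be positive")
    if (any(object@betas < 0)) msg <- c(msg, "betas must be non-negative")
    if (any(object@x0 < 0) || sum(object@x0) < 1)
      msg <- c(msg, "x0 must be non-negative with at least one individual")
    if (object@nGenerations < 1L) msg <- c(msg, "nGenerations must be >= 1")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (any(object@quantileLevels <= 0) || any(object@quantileLevels >= 1))
      msg <- c(msg, "quantileLevels must lie strictly inside (0, 1)")
    if (is.null(msg)) TRUE else msg
  })

#' Construct an experiment configuration
#'
#' @param model `"onetype"` or `"multitype"`.
#' @param lambdas,alphas,betas per-genotype parameter vectors (scalars are
#'   recycled to the number of genotypes).
#' @param mutation mutation matrix (full, or off-diagonal with `NA`
#'   diagonal, auto-completed); defaults to `matrix(1)` for one-type.
#' @param x0 initial genotype counts.
#' @param nGenerations,nReplicates,masterSeed run controls.
#' @param quantileLevels summary quantile levels.
#' @param includeExtinct count extinct replicates as zeros (default TRUE).
#' @param deterministicOnly skip the stochastic ensemble (default FALSE).
#' @param cltThreshold normal-approximation threshold (default `Inf`).
#' @return a validated [ExperimentConfig-class].
#' @export
ExperimentConfig <- function(model, lambdas, alphas = 2, betas = 0,
                             mutation = NULL, x0,
                             nGenerations, nReplicates = 1L,
                             masterSeed = 101L,
                             quantileLevels = c(0.05, 0.25, 0.5, 0.75, 0.95),
                             includeExtinct = TRUE,
                             deterministicOnly = FALSE,
                             cltThreshold = Inf) {
  if (is.null(mutation)) {
    if (model != "onetype")
      stop("'mutation' is required for the multitype model")
    mutation <- MutationMatrix(matrix(1))
  } else if (!is(mutation, "MutationMatrix")) {
    mutation <- as.matrix(mutation)
    mutation <- if (anyNA(diag(mutation))) completeMutationMatrix(mutation)
                else MutationMatrix(mutation)
  }
  k <- nrow(mutation)
  new("ExperimentConfig", model = model,
      lambdas = rep_len(as.numeric(lambdas), k),
      alphas = rep_len(as.numeric(alphas), k),
      betas = rep_len(as.numeric(betas), k),
      mutation = mutation, x0 = rep_len(as.numeric(x0), k),
      nGenerations = as.integer(nGenerations),
      nReplicates = as.integer(nReplicates),
      masterSeed = as.integer(masterSeed),
      quantileLevels = sort(as.numeric(quantileLevels)),
      includeExtinct = isTRUE(includeExtinct),
      deterministicOnly = isTRUE(deterministicOnly),
      cltThreshold = as.numeric(cltThreshold))
}

setMethod("show", "ExperimentConfig", function(object) {
  cat("ExperimentConfig (", object@model, "):",
      nrow(object@mutation), "genotype(s),",
      object@nReplicates, "replicates x", object@nGenerations,
      "generations, master seed", object@masterSeed, "\n")
})

#' Extract multitype parameters from a configuration
#'
#' @param config an [ExperimentConfig-class].
#' @return a [MultitypeParams-class] (one-type configs yield k = 1).
#' @export
configParams <- function(config) {
  stopifnot(is(config, "ExperimentConfig"))
  MultitypeParams(config@lambdas, config@alphas, config@betas,
                  config@mutation)
}

#' Read an experiment configuration from YAML
#'
#' Parses and validates a YAML configuration. Scientific notation is
#' supported throughout (mutation probabilities in the preset span 1e-17
#' to 1). The `mutation` entry may be a full row-stochastic matrix (list
#' of rows) or carry `.na` / `null` diagonal entries, in which case the
#' diagonal is completed so each row sums to 1. All domain invariants are
#' enforced at parse time with named errors.
#'
#' @param path path to a YAML file.
#' @return a validated [ExperimentConfig-class].
#' @examples
#' cfg <- readExperimentConfig(system.file("extdata", "section5.yaml",
#'                                         package = "SRBranching"))
#' configParams(cfg)
#' @export
readExperimentConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  need <- c("model", "lambdas", "x0", "nGenerations")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("config is missing required key(s): ", paste(miss, collapse = ", "))
  mut <- raw$mutation
  if (!is.null(mut)) {
    mut <- do.call(rbind, lapply(mut, function(row)
      vapply(row, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))))
  }
  ExperimentConfig(
    model = raw$model,
    lambdas = as.numeric(raw$lambdas),
    alphas = if (is.null(raw$alphas)) 2 else as.numeric(raw$alphas),
    betas = if (is.null(raw$betas)) 0 else as.numeric(raw$betas),
    mutation = mut,
    x0 = as.numeric(raw$x0),
    nGenerations = raw$nGenerations,
    nReplicates = if (is.null(raw$nReplicates)) 1L else raw$nReplicates,
    masterSeed = if (is.null(raw$masterSeed)) 101L else raw$masterSeed,
    quantileLevels = if (is.null(raw$quantileLevels))
      c(0.05, 0.25, 0.5, 0.75, 0.95) else as.numeric(raw$quantileLevels),
    includeExtinct = if (is.null(raw$includeExtinct)) TRUE
      else isTRUE(raw$includeExtinct),
    deterministicOnly = isTRUE(raw$deterministicOnly),
    cltThreshold = if (is.null(raw$cltThreshold)) Inf
      else as.numeric(raw$cltThreshold))
}

#' Write an experiment configuration to YAML
#'
#' Inverse of [readExperimentConfig()]: `readExperimentConfig(
#' writeExperimentConfig(cfg, path))` reconstructs an identical object.
#' Numbers are written with 17 significant digits so doubles survive the
#' round trip exactly.
#'
#' @param config an [ExperimentConfig-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExperimentConfig <- function(config, path) {
  stopifnot(is(config, "ExperimentConfig"))
  lst <- list(
    model = config@model,
    lambdas = config@lambdas,
    alphas = config@alphas,
    betas = config@betas,
    mutation = lapply(seq_len(nrow(config@mutation)),
                      function(i) config@mutation@.Data[i, ]),
    x0 = config@x0,
    nGenerations = config@nGenerations,
    nReplicates = config@nReplicates,
    masterSeed = config@masterSeed,
    quantileLevels = config@quantileLevels,
    includeExtinct = config@includeExtinct,
    deterministicOnly = config@deterministicOnly,
    cltThreshold = if (is.finite(config@cltThreshold))
      config@cltThreshold else NULL)
  yaml::write_yaml(lst, path, precision = 17L)
  invisible(path)
}

#' Write trajectories as long-format CSV
#'
#' Long format with columns `replicate`, `generation`, `genotype`,
#' `count`. Deterministic trajectories use the literal token `DET` in the
#' replicate column; stochastic replicates are numbered from 1.
#'
#' @param x a [BranchingEnsemble-class], [DetTrajectory-class] or
#'   [OneTypeTrajectory-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCSV <- function(x, path) {
  df <- trajectoryToLong(x)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a trajectory or ensemble to a long data frame
#'
#' @inheritParams writeTrajectoryCSV
#' @return `data.frame` with columns `replicate`, `generation`, `genotype`,
#'   `count`.
#' @export
trajectoryToLong <- function(x) {
  if (is(x, "BranchingEnsemble")) {
    d <- dim(x@counts)
    data.frame(
      replicate = rep(seq_len(d[1L]), times = d[2L] * d[3L]),
      generation = rep(rep(0:(d[2L] - 1L), each = d[1L]), times = d[3L]),
      genotype = rep(seq_len(d[3L]), each = d[1L] * d[2L]),
      count = as.vector(x@counts))
  } else if (is(x, "DetTrajectory")) {
    s <- x@states
    data.frame(
      replicate = "DET",
      generation = rep(0:(nrow(s) - 1L), times = ncol(s)),
      genotype = rep(seq_len(ncol(s)), each = nrow(s)),
      count = as.vector(s))
  } else if (is(x, "OneTypeTrajectory")) {
    data.frame(replicate = 1L,
               generation = 0:(length(x@counts) - 1L),
               genotype = 1L, count = x@counts)
  } else {
    stop("cannot convert objects of class ", class(x)[1L])
  }
}

#' Read a long-format trajectory CSV back into an array
#'
#' Inverse of [writeTrajectoryCSV()] for stochastic ensembles: rebuilds
#' the replicate x generation x genotype array.
#'
#' @param path CSV path.
#' @return numeric array.
#' @export
readTrajectoryArray <- function(path) {
  df <- utils::read.csv(path)
  reps <- sort(unique(df$replicate))
  gens <- sort(unique(df$generation))
  gts <- sort(unique(df$genotype))
  arr <- array(NA_real_,
               dim = c(length(reps), length(gens), length(gts)))
  arr[cbind(match(df$replicate, reps), match(df$generation, gens),
            match(df$genotype, gts))] <- df$count
  arr
}

#' Write a quantile/DET summary CSV
#'
#' Columns `generation`, `genotype`, `statistic`, `value`, with one
#' statistic row per quantile level (`Q05`, `Q50`, ...), the ensemble
#' `mean`, and `DET` rows when a deterministic trajectory is supplied.
#'
#' @param q a [QuantileTrajectory-class].
#' @param path output CSV path.
#' @param ens optional [BranchingEnsemble-class] for the mean rows.
#' @param det optional [DetTrajectory-class] for the DET rows.
#' @return `path`, invisibly.
#' @export
writeSummaryCSV <- function(q, path, ens = NULL, det = NULL) {
  stopifnot(is(q, "QuantileTrajectory"))
  d <- dim(q@values)
  lab <- sprintf("Q%02d", round(q@levels * 100))
  rows <- list()
  for (l in seq_along(q@levels)) {
    rows[[l]] <- data.frame(
      generation = rep(0:(d[1L] - 1L), times = d[2L]),
      genotype = rep(seq_len(d[2L]), each = d[1L]),
      statistic = lab[l],
      value = as.vector(q@values[, , l]))
  }
  if (!is.null(ens)) {
    m <- apply(ens@counts, c(2L, 3L), mean)
    rows[[length(rows) + 1L]] <- data.frame(
      generation = rep(0:(d[1L] - 1L), times = d[2L]),
      genotype = rep(seq_len(d[2L]), each = d[1L]),
      statistic = "mean", value = as.vector(m))
  }
  if (!is.null(det)) {
    s <- det@states
    rows[[length(rows) + 1L]] <- data.frame(
      generation = rep(0:(nrow(s) - 1L), times = ncol(s)),
      genotype = rep(seq_len(ncol(s)), each = nrow(s)),
      statistic = "DET", value = as.vector(s))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run a configured experiment and write its outputs
#'
#' Runs the deterministic model and (unless `deterministicOnly`) the
#' stochastic ensemble described by `config`, then writes
#' `trajectories.csv` (long format; `DET` rows included),
#' `summary.csv` (quantiles, mean, DET) and `metadata.json` (full
#' parameters, seed policy, quantile convention, package version) into
#' `outDir`.
#'
#' @param config an [ExperimentConfig-class].
#' @param outDir output directory, created if needed.
#' @param progress log progress every 10% of replicates.
#' @return invisibly, a list with elements `det`, `ensemble` (or `NULL`),
#'   `quantiles` (or `NULL`) and the output file paths.
#' @export
runExperiment <- function(config, outDir, progress = FALSE) {
  stopifnot(is(config, "ExperimentConfig"))
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  params <- configParams(config)
  det <- multitypeDetTrajectory(config@x0, params, config@nGenerations)
  ens <- NULL
  q <- NULL
  if (!config@deterministicOnly) {
    ens <- runEnsemble(config@x0, params, config@nGenerations,
                       config@nReplicates, config@masterSeed,
                       cltThreshold = config@cltThreshold,
                       progress = progress)
    q <- quantileTrajectories(ens, config@quantileLevels,
                              includeExtinct = config@includeExtinct)
  }
  trajPath <- file.path(outDir, "trajectories.csv")
  detDf <- trajectoryToLong(det)
  if (!is.null(ens)) {
    df <- rbind(transform(trajectoryToLong(ens),
                          replicate = as.character(replicate)), detDf)
  } else {
    df <- detDf
  }
  utils::write.csv(df, trajPath, row.names = FALSE, quote = FALSE)
  sumPath <- NULL
  if (!is.null(q)) {
    sumPath <- file.path(outDir, "summary.csv")
    writeSummaryCSV(q, sumPath, ens = ens, det = det)
  }
  metaPath <- file.path(outDir, "metadata.json")
  meta <- list(
    model = config@model,
    lambdas = config@lambdas, alphas = config@alphas, betas = config@betas,
    mutation = config@mutation@.Data,
    x0 = config@x0,
    nGenerations = config@nGenerations, nReplicates = config@nReplicates,
    masterSeed = config@masterSeed,
    seedDerivation = "child = (master + r*48271) mod (2^31-1); set.seed(child) per replicate",
    quantileLevels = config@quantileLevels,
    quantileEstimator = "linear interpolation of order statistics (type 7)",
    includeExtinct = config@includeExtinct,
    package = as.character(utils::packageVersion("SRBranching")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(meta, metaPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(det = det, ensemble = ens, quantiles = q,
                 files = c(trajectories = trajPath, summary = sumPath,
                           metadata = metaPath)))
}
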