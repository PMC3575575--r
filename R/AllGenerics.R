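#' @import methods
NULL

#' Extract simulated counts
#'
#' Accessor for the genotype-count data held by a trajectory or ensemble
#' object.
#'
#' @param object a trajectory or ensemble object.
#' @return For a [OneTypeTrajectory-class], the integer-valued count vector
#'   \eqn{X(0..T)}. For a [BranchingEnsemble-class], the
#'   replicate x generation x genotype array.
#' @export
setGeneric("counts", function(object) standardGeneric("counts"))

#' @rdname modelParams
#' @export
setGeneric("modelParams", function(object) standardGeneric("modelParams"))

#' @rdname nGenotypes
#' @export
setGeneric("nGenotypes", function(object) standardGeneric("nGenotypes"))

#' @rdname nGenerations
#' @export
setGeneric("nGenerations", function(object) standardGeneric("nGenerations"))

#' @rdname nReplicates
#' @export
setGeneric("nReplicates", function(object) standardGeneric("nReplicates"))

#' @rdname mutationMatrix
#' @export
setGeneric("mutationMatrix", function(object) standardGeneric("mutationMatrix"))

#' @rdname detStates
#' @export
setGeneric("detStates", function(object) standardGeneric("detStates"))

#' @rdname convergedAt
#' @export
setGeneric("convergedAt", function(object) standardGeneric("convergedAt"))
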