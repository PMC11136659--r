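#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the data containers: number of trials and
#' neurons, the trial table, the activity tensor, neuron centroids, animal and
#' day identity, and the sessions of a cohort.
#'
#' @param x an object.
#' @return The corresponding slot content; see the class documentation.
#' @name accessors
#' @aliases nTrials nNeurons trialTable activityTensor centroids animalId
#'   dayIndex sessions groundTruth
NULL

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' @rdname accessors
#' @export
setGeneric("trialTable", function(x) standardGeneric("trialTable"))

#' @rdname accessors
#' @export
setGeneric("activityTensor", function(x) standardGeneric("activityTensor"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("animalId", function(x) standardGeneric("animalId"))

#' @rdname accessors
#' @export
setGeneric("dayIndex", function(x) standardGeneric("dayIndex"))

#' @rdname accessors
#' @export
setGeneric("sessions", function(x) standardGeneric("sessions"))

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))
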