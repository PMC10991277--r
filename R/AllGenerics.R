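#' @rdname ThermoCorpus-class
#' @param x,object an object.
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @rdname ThermoCorpus-class
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @rdname ThermoCorpus-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname OrthologClusters-class
#' @param x an object.
#' @export
setGeneric("clusterIds", function(x) standardGeneric("clusterIds"))

#' @rdname OrthologClusters-class
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' @rdname SplitPlan-class
#' @param x an object.
#' @export
setGeneric("foldOfCluster", function(x) standardGeneric("foldOfCluster"))

#' @rdname SplitPlan-class
#' @export
setGeneric("foldOfProtein", function(x) standardGeneric("foldOfProtein"))

#' @rdname SplitPlan-class
#' @export
setGeneric("trainIds", function(x) standardGeneric("trainIds"))

#' @rdname SplitPlan-class
#' @export
setGeneric("testIds", function(x) standardGeneric("testIds"))

#' @rdname OptTempCNN-class
#' @param x an object.
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))

#' @rdname OptTempCNN-class
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))

#' Predict per-protein optimal temperatures
#'
#' Returns one finite prediction in degrees Celsius per input protein, named
#' by protein id and order-aligned with the input. Dropout is inactive at
#' inference.
#'
#' @param model a trained \linkS4class{OptTempCNN}, or (for stub/oracle use)
#'   a plain R function mapping a named character vector of sequences to a
#'   numeric vector of temperatures.
#' @param x sequences: a named character vector, an
#'   \link[Biostrings]{AAStringSet}, a \linkS4class{ThermoCorpus}, or a
#'   pre-encoded 3-d array from \code{\link{encodeBatch}}.
#' @param ... passed to methods.
#' @return named numeric vector of predicted temperatures (degrees Celsius).
#' @export
setGeneric("predictOptTemp", function(model, x, ...) standardGeneric("predictOptTemp"))
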