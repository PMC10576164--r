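#' @rdname RhythmDataset-accessors
#' @export
setGeneric("obsTimes", function(x) standardGeneric("obsTimes"))

#' @rdname RhythmDataset-accessors
#' @export
setGeneric("obsValues", function(x) standardGeneric("obsValues"))

#' @rdname RhythmDataset-accessors
#' @export
setGeneric("noiseVar", function(x) standardGeneric("noiseVar"))

#' @rdname RhythmDataset-accessors
#' @export
setGeneric("datasetLabel", function(x) standardGeneric("datasetLabel"))

#' @rdname RhythmDataset-accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))

#' @rdname RhythmDataset-accessors
#' @export
setGeneric("nTimePoints", function(x) standardGeneric("nTimePoints"))

#' Kernel covariance matrix over a set of times
#'
#' Dispatches on the hyperparameter class: diagonal, non-stationary
#' Gibbs-cosine, or spectral mixture.
#'
#' @param times numeric vector of input locations (hours).
#' @param hp a hyperparameter object.
#' @return the covariance matrix (epsilon^2 included on the diagonal).
#' @export
setGeneric("covMatrix", function(times, hp) standardGeneric("covMatrix"))

#' Kernel cross-covariance between two sets of times
#'
#' Covariance of the latent signal (no epsilon^2 noise term) between
#' `times1` (rows) and `times2` (columns); used by the posterior predictor.
#'
#' @param times1,times2 numeric vectors of input locations (hours).
#' @param hp a hyperparameter object.
#' @export
setGeneric("crossCovMatrix",
           function(times1, times2, hp) standardGeneric("crossCovMatrix"))

#' @rdname GPFit-accessors
#' @export
setGeneric("mll", function(x) standardGeneric("mll"))

#' @rdname GPFit-accessors
#' @export
setGeneric("kernelFamily", function(x) standardGeneric("kernelFamily"))

#' @rdname GPFit-accessors
#' @export
setGeneric("hyperparams", function(x) standardGeneric("hyperparams"))

#' @rdname OscillationCall-accessors
#' @export
setGeneric("bfValue", function(x) standardGeneric("bfValue"))

#' @rdname OscillationCall-accessors
#' @export
setGeneric("log10BF", function(x) standardGeneric("log10BF"))

#' @rdname OscillationCall-accessors
#' @export
setGeneric("posteriorOdds", function(x) standardGeneric("posteriorOdds"))

#' @rdname OscillationCall-accessors
#' @export
setGeneric("callLabel", function(x) standardGeneric("callLabel"))

#' @rdname ROCResult-accessors
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))
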