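# Accessor generics for the S4 containers. Slot access from user code should
# go through these.

#' Extract the event table from a TrialEvents object
#' @param x a \linkS4class{TrialEvents} object.
#' @return data.frame with columns `time_s`, `event`, `trial_index`.
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname eventTable
setMethod("eventTable", "TrialEvents", function(x) x@events)

#' Times of a given event type
#' @param x a \linkS4class{TrialEvents} object.
#' @param type one of the event codes (e.g. "cue_on", "reward").
#' @return numeric vector of times in seconds.
#' @export
setGeneric("eventTimes", function(x, type) standardGeneric("eventTimes"))

#' @rdname eventTimes
setMethod("eventTimes", "TrialEvents", function(x, type) {
  x@events$time_s[x@events$event == type]
})

#' Number of trials in an event stream
#' @param x a \linkS4class{TrialEvents} object.
#' @return integer trial count.
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname nTrials
setMethod("nTrials", "TrialEvents", function(x) {
  if (!nrow(x@events)) return(0L)
  as.integer(max(x@events$trial_index))
})

#' Photometry channel accessors
#' @param x a \linkS4class{PhotometryRecording}.
#' @return numeric vector (channel), scalar (samplingRate), or list
#'   (groundTruth).
#' @export
setGeneric("signalChannel", function(x) standardGeneric("signalChannel"))
#' @rdname signalChannel
setMethod("signalChannel", "PhotometryRecording", function(x) x@signal470)

#' @rdname signalChannel
#' @export
setGeneric("isoChannel", function(x) standardGeneric("isoChannel"))
#' @rdname signalChannel
setMethod("isoChannel", "PhotometryRecording", function(x) x@iso405)

#' @rdname signalChannel
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname signalChannel
setMethod("samplingRate", "PhotometryRecording", function(x) x@fs)

#' Planted ground truth attached to a synthetic object
#' @param x a synthetic-data container.
#' @return list of generator metadata (empty for real data).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname groundTruth
setMethod("groundTruth", "PhotometryRecording", function(x) x@groundTruth)

#' Spike session accessors
#' @param x a \linkS4class{SpikeSession}.
#' @return list of spike-time vectors, character vector, or scalar.
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname spikeTimes
setMethod("spikeTimes", "SpikeSession", function(x) x@spikes)

#' @rdname spikeTimes
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))
#' @rdname spikeTimes
setMethod("unitIds", "SpikeSession", function(x) names(x@spikes))

#' @rdname spikeTimes
#' @export
setGeneric("sessionDuration", function(x) standardGeneric("sessionDuration"))
#' @rdname spikeTimes
setMethod("sessionDuration", "SpikeSession", function(x) x@duration)

#' @rdname spikeTimes
#' @export
setGeneric("unitProfiles", function(x) standardGeneric("unitProfiles"))
#' @rdname spikeTimes
setMethod("unitProfiles", "SpikeSession", function(x) x@profiles)

#' Tensor accessors
#' @param x a \linkS4class{TrialTensor}.
#' @return the underlying array, unit metadata, or time axis.
#' @export
setGeneric("tensorData", function(x) standardGeneric("tensorData"))
#' @rdname tensorData
setMethod("tensorData", "TrialTensor", function(x) x@data)

#' @rdname tensorData
#' @export
setGeneric("unitInfo", function(x) standardGeneric("unitInfo"))
#' @rdname tensorData
setMethod("unitInfo", "TrialTensor", function(x) x@unitInfo)

#' @rdname tensorData
#' @export
setGeneric("timeAxis", function(x) standardGeneric("timeAxis"))
#' @rdname tensorData
setMethod("timeAxis", "TrialTensor", function(x) x@timeAxis)

#' CP model accessors
#' @param x a \linkS4class{CPModel}.
#' @return a factor matrix, the rank, or the objective trace.
#' @export
setGeneric("unitFactors", function(x) standardGeneric("unitFactors"))
#' @rdname unitFactors
setMethod("unitFactors", "CPModel", function(x) x@W)

#' @rdname unitFactors
#' @export
setGeneric("trialFactors", function(x) standardGeneric("trialFactors"))
#' @rdname unitFactors
setMethod("trialFactors", "CPModel", function(x) x@B)

#' @rdname unitFactors
#' @export
setGeneric("timeFactors", function(x) standardGeneric("timeFactors"))
#' @rdname unitFactors
setMethod("timeFactors", "CPModel", function(x) x@A)

#' @rdname unitFactors
#' @export
setGeneric("cpRank", function(x) standardGeneric("cpRank"))
#' @rdname unitFactors
setMethod("cpRank", "CPModel", function(x) x@rank)

#' @rdname unitFactors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname unitFactors
setMethod("objectiveTrace", "CPModel", function(x) x@objective)

#' Reconstruct a tensor from its CP factors
#' @param x a \linkS4class{CPModel}.
#' @return numeric array U x T x P.
#' @export
setGeneric("reconstruct", function(x) standardGeneric("reconstruct"))

#' @rdname reconstruct
setMethod("reconstruct", "CPModel", function(x) {
  U <- nrow(x@W); Tt <- nrow(x@B); P <- nrow(x@A)
  # mode-1 unfolding: W %*% t(khatriRao(A, B)) has columns ordered t fastest
  X1 <- x@W %*% t(khatriRao(x@A, x@B))
  array(X1, dim = c(U, Tt, P))
})

#' Demand fit accessors
#' @param x a \linkS4class{DemandFit}.
#' @return named numeric vector of fitted and derived parameters.
#' @export
setGeneric("demandParameters", function(x) standardGeneric("demandParameters"))

#' @rdname demandParameters
setMethod("demandParameters", "DemandFit", function(x) {
  c(Q0 = x@Q0, alpha = x@alpha, k = x@k, EV = x@EV, Pmax = x@Pmax, r2 = x@r2)
})

#' Cluster model accessors
#' @param x a \linkS4class{ClusterModel}.
#' @return assignments vector, centroid matrix, or final k.
#' @export
setGeneric("clusterAssignments", function(x) standardGeneric("clusterAssignments"))
#' @rdname clusterAssignments
setMethod("clusterAssignments", "ClusterModel", function(x) x@assignments)

#' @rdname clusterAssignments
#' @export
setGeneric("clusterCentroids", function(x) standardGeneric("clusterCentroids"))
#' @rdname clusterAssignments
setMethod("clusterCentroids", "ClusterModel", function(x) x@centroids)

#' @rdname clusterAssignments
#' @export
setGeneric("finalK", function(x) standardGeneric("finalK"))
#' @rdname clusterAssignments
setMethod("finalK", "ClusterModel", function(x) x@k)
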