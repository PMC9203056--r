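#' Accessors for recording and epoch containers
#'
#' Small accessor API over the S4 containers so downstream code never touches
#' slots directly.
#'
#' @param x a [ContinuousRecording-class] or [EpochSet-class] object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("recordingDuration",
           function(x) standardGeneric("recordingDuration"))

#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname accessors
#' @export
setGeneric("handMap", function(x) standardGeneric("handMap"))

#' @rdname accessors
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("epochTime", function(x) standardGeneric("epochTime"))

#' @rdname accessors
#' @export
setGeneric("processingStage", function(x) standardGeneric("processingStage"))

#' @rdname accessors
#' @export
setGeneric("trialInfo", function(x) standardGeneric("trialInfo"))

#' @rdname accessors
#' @export
setGeneric("rejectedReasons", function(x) standardGeneric("rejectedReasons"))

#' @rdname accessors
#' @export
setMethod("samplingRate", "ContinuousRecording", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@rate)

#' @rdname accessors
#' @export
setMethod("recordingDuration", "ContinuousRecording",
          function(x) ncol(x@samples) / x@rate)

#' @rdname accessors
#' @export
setMethod("channelLabels", "ContinuousRecording", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("handMap", "ContinuousRecording", function(x) x@hands)

#' @rdname accessors
#' @export
setMethod("eventTable", "ContinuousRecording", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("epochData", "EpochSet", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("epochTime", "EpochSet", function(x) x@time)

#' @rdname accessors
#' @export
setMethod("processingStage", "EpochSet", function(x) x@stage)

#' @rdname accessors
#' @export
setMethod("trialInfo", "EpochSet", function(x) x@trials)

#' @rdname accessors
#' @export
setMethod("rejectedReasons", "EpochSet", function(x) x@rejected)

# internal: enforce the documented stage order on transitions
.advanceStage <- function(epochs, from, to) {
  if (!identical(epochs@stage, from))
    stop(sprintf("stage must be '%s' (is '%s'); stages advance %s",
                 from, epochs@stage, paste(.EPOCH_STAGES, collapse = " -> ")),
         call. = FALSE)
  epochs@stage <- to
  epochs
}

# internal: channel samples for a hand, erroring if the map does not cover it
.handChannel <- function(recording, hand) {
  hit <- names(recording@hands)[recording@hands == hand]
  if (!length(hit))
    stop(sprintf("no channel assigned to hand '%s'", hand), call. = FALSE)
  recording@samples[match(hit[1], recording@channels), ]
}
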