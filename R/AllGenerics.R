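#' @include AllClasses.R
NULL

#' Accessors for cortmag classes
#'
#' Small accessor generics for the package's S4 containers; use these rather
#' than reaching into slots.
#'
#' @param object a cortmag S4 object.
#' @name cortmag-accessors
NULL

#' @rdname cortmag-accessors
#' @export
setGeneric("nVertices", function(object) standardGeneric("nVertices"))
#' @rdname cortmag-accessors
#' @export
setGeneric("vertexAreas", function(object) standardGeneric("vertexAreas"))
#' @rdname cortmag-accessors
#' @export
setGeneric("polarAngles", function(object) standardGeneric("polarAngles"))
#' @rdname cortmag-accessors
#' @export
setGeneric("eccentricities", function(object) standardGeneric("eccentricities"))
#' @rdname cortmag-accessors
#' @export
setGeneric("hemisphere", function(object) standardGeneric("hemisphere"))
#' @rdname cortmag-accessors
#' @export
setGeneric("meshDepth", function(object) standardGeneric("meshDepth"))
#' @rdname cortmag-accessors
#' @export
setGeneric("meshFaces", function(object) standardGeneric("meshFaces"))
#' @rdname cortmag-accessors
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))
#' @rdname cortmag-accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname cortmag-accessors
#' @export
setGeneric("inclusionFlags", function(object) standardGeneric("inclusionFlags"))
#' @rdname cortmag-accessors
#' @export
setGeneric("observerIds", function(object) standardGeneric("observerIds"))
#' @rdname cortmag-accessors
#' @export
setGeneric("contrastSensitivities",
           function(object) standardGeneric("contrastSensitivities"))
#' @rdname cortmag-accessors
#' @export
setGeneric("wedgeAreas", function(object) standardGeneric("wedgeAreas"))
#' @rdname cortmag-accessors
#' @export
setGeneric("v1Areas", function(object) standardGeneric("v1Areas"))
#' @rdname cortmag-accessors
#' @export
setGeneric("cortexAreas", function(object) standardGeneric("cortexAreas"))
#' @rdname cortmag-accessors
#' @export
setGeneric("nullPercentile", function(object) standardGeneric("nullPercentile"))
#' @rdname cortmag-accessors
#' @export
setGeneric("observedRho", function(object) standardGeneric("observedRho"))

#' @rdname cortmag-accessors
#' @export
setMethod("nVertices", "CorticalMesh", function(object) nrow(object@vertices))
#' @rdname cortmag-accessors
#' @export
setMethod("vertexAreas", "CorticalMesh", function(object) object@vertexArea)
#' @rdname cortmag-accessors
#' @export
setMethod("polarAngles", "CorticalMesh", function(object) object@polarAngle)
#' @rdname cortmag-accessors
#' @export
setMethod("eccentricities", "CorticalMesh",
          function(object) object@eccentricity)
#' @rdname cortmag-accessors
#' @export
setMethod("hemisphere", "CorticalMesh", function(object) object@hemisphere)
#' @rdname cortmag-accessors
#' @export
setMethod("meshDepth", "CorticalMesh", function(object) object@depth)
#' @rdname cortmag-accessors
#' @export
setMethod("meshFaces", "CorticalMesh", function(object) object@faces)
#' @rdname cortmag-accessors
#' @export
setMethod("meshVertices", "CorticalMesh", function(object) object@vertices)

#' @rdname cortmag-accessors
#' @export
setMethod("nFrames", "StimulusAperture", function(object) nrow(object@frames))

#' @rdname cortmag-accessors
#' @export
setMethod("polarAngles", "RetinotopyMap", function(object) object@polarAngle)
#' @rdname cortmag-accessors
#' @export
setMethod("eccentricities", "RetinotopyMap",
          function(object) object@eccentricity)
#' @rdname cortmag-accessors
#' @export
setMethod("inclusionFlags", "RetinotopyMap", function(object) object@included)

#' @rdname cortmag-accessors
#' @export
setMethod("observerIds", "CohortTable", function(object) object@observerId)
#' @rdname cortmag-accessors
#' @export
setMethod("contrastSensitivities", "CohortTable", function(object) object@cs)
#' @rdname cortmag-accessors
#' @export
setMethod("wedgeAreas", "CohortTable", function(object) object@wedgeArea)
#' @rdname cortmag-accessors
#' @export
setMethod("v1Areas", "CohortTable", function(object) object@v1Area)
#' @rdname cortmag-accessors
#' @export
setMethod("cortexAreas", "CohortTable", function(object) object@cortexArea)

#' @rdname cortmag-accessors
#' @export
setMethod("nullPercentile", "NullDistributionResult",
          function(object) object@x95)
#' @rdname cortmag-accessors
#' @export
setMethod("observedRho", "NullDistributionResult",
          function(object) object@observedRho)

setMethod("show", "CorticalMesh", function(object) {
  cat(sprintf(
    "CorticalMesh: %s hemisphere, %s depth\n  %d vertices, %d faces, total area %.1f mm^2\n  eccentricity %.2f-%.2f deg\n",
    object@hemisphere, object@depth, nVertices(object), nrow(object@faces),
    sum(object@vertexArea), min(object@eccentricity), max(object@eccentricity)
  ))
})

setMethod("show", "StimulusAperture", function(object) {
  cat(sprintf(
    "StimulusAperture: %d frames of %.3g s, %dx%d grid (%.3f deg/px), radius %.1f deg\n  %d blank frames\n",
    nFrames(object), object@frameDuration, object@gridSize, object@gridSize,
    object@degPerPix, object@radius, sum(object@schedule$blank)
  ))
})

setMethod("show", "RetinotopyMap", function(object) {
  cat(sprintf(
    "RetinotopyMap: %d vertices, %d included (R^2 > 10%%), median R^2 %.3f\n",
    length(object@x), sum(object@included), stats::median(object@r2)
  ))
})

setMethod("show", "CohortTable", function(object) {
  cat(sprintf(
    "CohortTable: %d observers x 4 locations\n  mean CS %.1f, mean wedge area %.0f mm^2, mean V1 %.0f mm^2\n",
    length(object@observerId), mean(object@cs), mean(object@wedgeArea),
    mean(object@v1Area)
  ))
})

setMethod("show", "NullDistributionResult", function(object) {
  cat(sprintf(
    "NullDistributionResult (%s): observed rho %.3f, x0.95 %.3f over %d iterations\n",
    object@mode, object@observedRho, object@x95, length(object@rho)
  ))
})

#' Coerce a RetinotopyMap to a data.frame
#'
#' @param x a `RetinotopyMap`.
#' @param row.names,optional,... passed through for S3 consistency; unused.
#' @return data.frame with columns `vertex_id, x, y, sigma, gain, r2, angle,
#'   ecc, included`.
#' @export
as.data.frame.RetinotopyMap <- function(x, row.names = NULL,
                                        optional = FALSE, ...) {
  data.frame(
    vertex_id = seq_along(x@x),
    x = x@x, y = x@y, sigma = x@sigma, gain = x@gain, r2 = x@r2,
    angle = x@polarAngle, ecc = x@eccentricity, included = x@included
  )
}
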