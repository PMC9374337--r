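# Accessor generics and show methods.

#' @name accessors
#' @title Accessors for smdmr S4 objects
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object an smdmr S4 object.
#' @return the corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("radius", function(object) standardGeneric("radius"))
#' @rdname accessors
#' @export
setGeneric("totalLength", function(object) standardGeneric("totalLength"))
#' @rdname accessors
#' @export
setGeneric("cylinderHalfLength",
           function(object) standardGeneric("cylinderHalfLength"))
#' @rdname accessors
#' @export
setGeneric("dHat", function(object) standardGeneric("dHat"))
#' @rdname accessors
#' @export
setGeneric("kHat", function(object) standardGeneric("kHat"))
#' @rdname accessors
#' @export
setGeneric("nObs", function(object) standardGeneric("nObs"))
#' @rdname accessors
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
#' @rdname accessors
#' @export
setGeneric("displacements", function(object) standardGeneric("displacements"))
#' @rdname accessors
#' @export
setGeneric("rotationAngle", function(object) standardGeneric("rotationAngle"))
#' @rdname accessors
#' @export
setGeneric("cellLength", function(object) standardGeneric("cellLength"))
#' @rdname accessors
#' @export
setGeneric("cellWidth", function(object) standardGeneric("cellWidth"))
#' @rdname accessors
#' @export
setGeneric("qcStatus", function(object) standardGeneric("qcStatus"))
#' @rdname accessors
#' @export
setGeneric("regionCounts", function(object) standardGeneric("regionCounts"))

#' @rdname accessors
#' @export
setMethod("radius", "Spherocylinder", function(object) object@radius)
#' @rdname accessors
#' @export
setMethod("totalLength", "Spherocylinder", function(object) object@totalLength)
#' @rdname accessors
#' @export
setMethod("cylinderHalfLength", "Spherocylinder",
          function(object) (object@totalLength - 2 * object@radius) / 2)

#' @rdname accessors
#' @export
setMethod("dHat", "FitResult", function(object) object@dHat)
#' @rdname accessors
#' @export
setMethod("kHat", "FitResult", function(object) object@kHat)
#' @rdname accessors
#' @export
setMethod("nObs", "FitResult", function(object) object@n)
#' @rdname accessors
#' @export
setMethod("converged", "FitResult", function(object) object@converged)
#' @rdname accessors
#' @export
setMethod("logLik", "FitResult", function(object, ...) object@logLik)

#' @rdname accessors
#' @export
setMethod("displacements", "CellRecord", function(object) object@displacements)
#' @rdname accessors
#' @export
setMethod("rotationAngle", "CellRecord", function(object) object@rotationAngle)
#' @rdname accessors
#' @export
setMethod("cellLength", "CellRecord", function(object) object@length)
#' @rdname accessors
#' @export
setMethod("cellWidth", "CellRecord", function(object) object@width)
#' @rdname accessors
#' @export
setMethod("qcStatus", "CellRecord",
          function(object) c(qc = object@qc, reason = object@qcReason))

#' @rdname accessors
#' @export
setMethod("regionCounts", "RegionPartition", function(object)
  c(left = nrow(object@left), center = nrow(object@center),
    right = nrow(object@right)))

setMethod("show", "Spherocylinder", function(object) {
  cat(sprintf("Spherocylinder: radius %.3f um, total length %.3f um (cyl. %.3f um)\n",
              object@radius, object@totalLength,
              object@totalLength - 2 * object@radius))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: D = %.4g um^2/s, k = %.3g nm^-2%s, n = %d, logLik = %.2f, %s\n",
              object@dHat, object@kHat,
              if (object@kFixed) " (fixed)" else "",
              object@n, object@logLik,
              if (object@converged) "converged" else "NOT converged"))
})

setMethod("show", "CellRecord", function(object) {
  cat(sprintf("CellRecord %d: %d displacements, angle %.2f deg, %.2f x %.2f um, QC %s%s\n",
              object@id, nrow(object@displacements),
              object@rotationAngle * 180 / pi, object@length, object@width,
              object@qc,
              if (nzchar(object@qcReason)) paste0(" (", object@qcReason, ")")
              else ""))
})

setMethod("show", "DiffusionMap", function(object) {
  cat(sprintf("DiffusionMap: %d x %d pixels of %g nm, %d fitted, %s\n",
              nrow(object@d), ncol(object@d), object@pixelSize,
              sum(!is.na(object@d)),
              if (object@complete) "complete"
              else sprintf("incomplete (try %g nm)",
                           object@recommendedPixelSize)))
})

setMethod("show", "RegionPartition", function(object) {
  n <- regionCounts(object)
  cat(sprintf("RegionPartition: left %d | center %d | right %d (pole fraction %.2f)\n",
              n["left"], n["center"], n["right"], object@poleFraction))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: D = %.3g * M^%.3f (SE alpha %.3g, beta %.3f)%s\n",
              object@alpha, object@beta, object@seAlpha, object@seBeta,
              if (object@weighted) ", SD-weighted" else ""))
})
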