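# accessor generics: user code should not reach into slots directly

#' Accessors for xlmod S4 containers
#'
#' Small read-only accessors for the core containers: residue/coordinate
#' table and chains of a [StructureModel-class], eigenvalues/eigenvectors of
#' a [ModeSet-class], the columns of a [SAXSCurve-class], the peak table of
#' a [SpectrumRecord-class], and the headline numbers of the SAXS result
#' objects.
#'
#' @param object the container
#' @return the requested component (see the individual method)
#' @name accessors
#' @aliases caAtoms chains modelId eigenValues eigenVectors qValues
#'   intensities sigmas peakTable radiusOfGyration forwardScattering
#'   porodVol subunits
NULL

#' @rdname accessors
#' @export
setGeneric("caAtoms", function(object) standardGeneric("caAtoms"))
#' @rdname accessors
#' @export
setMethod("caAtoms", "StructureModel", function(object) object@atoms)

#' @rdname accessors
#' @export
setGeneric("chains", function(object) standardGeneric("chains"))
#' @rdname accessors
#' @export
setMethod("chains", "StructureModel",
          function(object) unique(object@atoms$chain))

#' @rdname accessors
#' @export
setGeneric("modelId", function(object) standardGeneric("modelId"))
#' @rdname accessors
#' @export
setMethod("modelId", "StructureModel", function(object) object@id)

#' @rdname accessors
#' @export
setGeneric("eigenValues", function(object) standardGeneric("eigenValues"))
#' @rdname accessors
#' @export
setMethod("eigenValues", "ModeSet", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("eigenVectors", function(object) standardGeneric("eigenVectors"))
#' @rdname accessors
#' @export
setMethod("eigenVectors", "ModeSet", function(object) object@vectors)

#' @rdname accessors
#' @export
setGeneric("qValues", function(object) standardGeneric("qValues"))
#' @rdname accessors
#' @export
setMethod("qValues", "SAXSCurve", function(object) object@q)

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "SAXSCurve", function(object) object@I)

#' @rdname accessors
#' @export
setGeneric("sigmas", function(object) standardGeneric("sigmas"))
#' @rdname accessors
#' @export
setMethod("sigmas", "SAXSCurve", function(object) object@sigma)

#' @rdname accessors
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))
#' @rdname accessors
#' @export
setMethod("peakTable", "SpectrumRecord", function(object)
  data.frame(mz = object@mz, intensity = object@intensity))

#' @rdname accessors
#' @export
setGeneric("radiusOfGyration",
           function(object) standardGeneric("radiusOfGyration"))
#' @rdname accessors
#' @export
setMethod("radiusOfGyration", "GuinierResult", function(object) object@rg)
#' @rdname accessors
#' @export
setMethod("radiusOfGyration", "PrResult", function(object) object@rg)

#' @rdname accessors
#' @export
setGeneric("forwardScattering",
           function(object) standardGeneric("forwardScattering"))
#' @rdname accessors
#' @export
setMethod("forwardScattering", "GuinierResult", function(object) object@i0)

#' @rdname accessors
#' @export
setGeneric("porodVol", function(object) standardGeneric("porodVol"))
#' @rdname accessors
#' @export
setMethod("porodVol", "PorodResult", function(object) object@volume)

#' @rdname accessors
#' @export
setGeneric("subunits", function(object) standardGeneric("subunits"))
#' @rdname accessors
#' @export
setMethod("subunits", "SizeEstimate",
          function(object) as.integer(object@subunits))
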