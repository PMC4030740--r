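#' @rdname Molecule-class
#' @param x a \code{Molecule}.
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))

#' @rdname Molecule-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname Molecule-class
#' @export
setGeneric("atomCoords", function(x) standardGeneric("atomCoords"))

#' @rdname Molecule-class
#' @export
setGeneric("atomCharges", function(x) standardGeneric("atomCharges"))

#' @rdname Molecule-class
#' @export
setGeneric("atomLabels", function(x) standardGeneric("atomLabels"))

#' @rdname ChargeAutocorrelation-class
#' @param x a \code{ChargeAutocorrelation}.
#' @export
setGeneric("positivePairs", function(x) standardGeneric("positivePairs"))

#' @rdname ChargeAutocorrelation-class
#' @export
setGeneric("negativePairs", function(x) standardGeneric("negativePairs"))

#' @rdname ChargeDescriptor-class
#' @param x a \code{ChargeDescriptor}.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname ChargeDescriptor-class
#' @export
setGeneric("lbacPlus", function(x) standardGeneric("lbacPlus"))

#' @rdname ChargeDescriptor-class
#' @export
setGeneric("lbacMinus", function(x) standardGeneric("lbacMinus"))

#' @rdname RocCurve-class
#' @param x a \code{RocCurve}.
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname RocCurve-class
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname Molecule-class
setMethod("molName", "Molecule", function(x) x@name)

#' @rdname Molecule-class
setMethod("nAtoms", "Molecule", function(x) nrow(x@coords))

#' @rdname Molecule-class
setMethod("atomCoords", "Molecule", function(x) x@coords)

#' @rdname Molecule-class
setMethod("atomCharges", "Molecule", function(x) x@charges)

#' @rdname Molecule-class
setMethod("atomLabels", "Molecule", function(x) x@labels)

#' @rdname ChargeAutocorrelation-class
setMethod("positivePairs", "ChargeAutocorrelation",
          function(x) x@positivePairs)

#' @rdname ChargeAutocorrelation-class
setMethod("negativePairs", "ChargeAutocorrelation",
          function(x) x@negativePairs)

#' @rdname ChargeDescriptor-class
setMethod("binWidth", "ChargeDescriptor", function(x) x@dx)

#' @rdname ChargeDescriptor-class
setMethod("lbacPlus", "ChargeDescriptor", function(x) x@lbacPlus)

#' @rdname ChargeDescriptor-class
setMethod("lbacMinus", "ChargeDescriptor", function(x) x@lbacMinus)

#' @rdname RocCurve-class
setMethod("auc", "RocCurve", function(x) x@auc)

#' @rdname RocCurve-class
setMethod("rocPoints", "RocCurve",
          function(x) data.frame(fpr = x@fpr, tpr = x@tpr))
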