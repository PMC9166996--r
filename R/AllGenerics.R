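#' @title Generics for CTdenoise classes
#' @name CTdenoise-generics
#' @keywords internal
NULL

#' Pixel matrix of an image
#'
#' @param object a \linkS4class{GrayImage}.
#' @return A numeric matrix of intensities (rows x cols).
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' Replace the pixel matrix of an image
#'
#' @param object a \linkS4class{GrayImage}.
#' @param value a numeric matrix with the same dimensions.
#' @return The modified object.
#' @export
setGeneric("pixels<-", function(object, value) standardGeneric("pixels<-"))

#' Gray-value range of an image
#'
#' The maximum representable intensity L (255 for 8-bit data, 65535 for
#' 16-bit). Carried as metadata because peak signal-to-noise ratio needs it
#' explicitly.
#'
#' @param object a \linkS4class{GrayImage} or \linkS4class{QualityReport}.
#' @return A positive scalar.
#' @export
setGeneric("grayRange", function(object) standardGeneric("grayRange"))

#' Provenance tag of an image
#'
#' @param object a \linkS4class{GrayImage}.
#' @return A character scalar describing where the image came from.
#' @export
setGeneric("origin", function(object) standardGeneric("origin"))

#' Unmixing component vectors of a fitted ICA model
#'
#' @param object an \linkS4class{ICAModel}.
#' @return A matrix whose rows are unit-norm component vectors in whitened
#'   space.
#' @export
setGeneric("icaComponents", function(object) standardGeneric("icaComponents"))

#' Per-component convergence flags of a fitted ICA model
#'
#' @param object an \linkS4class{ICAModel}.
#' @return A logical vector, one flag per extracted component.
#' @export
setGeneric("converged", function(object) standardGeneric("converged"))
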