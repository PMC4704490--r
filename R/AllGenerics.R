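#' @name orcall-generics
#' @title Accessor generics for orcall classes
#' @description Small accessor generics shared by the simulation containers.
#' @param x an orcall object.
#' @param ... passed to methods.
NULL

#' @rdname orcall-generics
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname orcall-generics
#' @export
setGeneric("geneBiotype", function(x, ...) standardGeneric("geneBiotype"))

#' @rdname orcall-generics
#' @export
setGeneric("markerClass", function(x, ...) standardGeneric("markerClass"))

#' @rdname orcall-generics
#' @export
setGeneric("homologGroup", function(x, ...) standardGeneric("homologGroup"))

#' @rdname orcall-generics
#' @export
setGeneric("exonRanges", function(x, ...) standardGeneric("exonRanges"))

#' @rdname orcall-generics
#' @export
setGeneric("cdsRanges", function(x, ...) standardGeneric("cdsRanges"))

#' @rdname orcall-generics
#' @export
setGeneric("cellIds", function(x, ...) standardGeneric("cellIds"))

#' @rdname orcall-generics
#' @export
setGeneric("cellData", function(x, ...) standardGeneric("cellData"))

#' @rdname orcall-generics
#' @export
setGeneric("chosenReceptors", function(x, ...) standardGeneric("chosenReceptors"))

#' @rdname orcall-generics
#' @export
setGeneric("trueTpm", function(x, ...) standardGeneric("trueTpm"))
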