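#' @title Generics used across the package
#' @description Small set of S4 generics shared by the container classes.
#' @name stabmark-generics
#' @keywords internal
NULL

#' Feature identifiers of an object
#'
#' @param x an object carrying feature identifiers.
#' @return Character vector of feature identifiers.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' Canberra distance between two ranked lists
#'
#' @param t1,t2 \linkS4class{RankedList} objects (or character vectors of
#'   ordered feature identifiers) over the same feature universe.
#' @return Non-negative numeric scalar.
#' @seealso [normalizedCanberra()], [topkCanberra()]
#' @export
setGeneric("canberra", function(t1, t2) standardGeneric("canberra"))
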