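#' Accessors for tickPI classes
#'
#' Standard accessor generics: `recordIds()` returns record identifiers,
#' `sequences()` the underlying `AAStringSet`, `speciesCode()` the species
#' code(s), `libraryIds()` the per-record library memberships,
#' `annotationHint()` the optional free-text family hints, and `familyId()`
#' the family token of a model or cluster.
#'
#' @param x a tickPI object.
#' @return the corresponding slot content.
#' @name tickPI-accessors
#' @aliases recordIds sequences speciesCode libraryIds annotationHint familyId
#' @examples
#' p <- PISet(c(r1 = "MKTAYIAK"), species = "aam", libraries = list("L1"))
#' recordIds(p)
#' speciesCode(p)
NULL

#' @rdname tickPI-accessors
#' @export
setGeneric("recordIds", function(x) standardGeneric("recordIds"))

#' @rdname tickPI-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname tickPI-accessors
#' @export
setGeneric("speciesCode", function(x) standardGeneric("speciesCode"))

#' @rdname tickPI-accessors
#' @export
setGeneric("libraryIds", function(x) standardGeneric("libraryIds"))

#' @rdname tickPI-accessors
#' @export
setGeneric("annotationHint", function(x) standardGeneric("annotationHint"))

#' @rdname tickPI-accessors
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))

#' @rdname percentIdentity
#' @export
setGeneric("percentIdentity",
    function(r, convention = c("columns", "shorter"))
        standardGeneric("percentIdentity"))

#' @rdname marginalTotal
#' @export
setGeneric("marginalTotal",
    function(matrix, side = c("left", "right")) standardGeneric("marginalTotal"))
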