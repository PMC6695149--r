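#' @name zsens-generics
#' @title Generics for SensitivityStudy objects
#' @description Accessor and transformation generics implemented for
#'   [SensitivityStudy-class] objects.
#' @param x a `SensitivityStudy`
#' @param ... passed to methods
NULL

#' @rdname zsens-generics
#' @export
setGeneric("measureNames", function(x, ...) standardGeneric("measureNames"))

#' @rdname zsens-generics
#' @export
setGeneric("subjectIDs", function(x, ...) standardGeneric("subjectIDs"))

#' @rdname zsens-generics
#' @export
setGeneric("nSessions", function(x, ...) standardGeneric("nSessions"))

#' @rdname zsens-generics
#' @export
setGeneric("isBalanced", function(x, ...) standardGeneric("isBalanced"))

#' @rdname zsens-generics
#' @export
setGeneric("isStandardized", function(x, ...) standardGeneric("isStandardized"))

#' @rdname zsens-generics
#' @export
setGeneric("filterCompleteCases", function(x, ...)
  standardGeneric("filterCompleteCases"))

#' @rdname zsens-generics
#' @export
setGeneric("measureMatrix", function(x, measure, ...)
  standardGeneric("measureMatrix"))

#' @rdname zsens-generics
#' @export
setGeneric("studyCube", function(x, ...) standardGeneric("studyCube"))

#' @rdname zsens-generics
#' @export
setGeneric("asLongDataFrame", function(x, ...)
  standardGeneric("asLongDataFrame"))

#' @rdname zsens-generics
#' @export
setGeneric("standardizeMeasures", function(x, ...)
  standardGeneric("standardizeMeasures"))

#' @rdname zsens-generics
#' @export
setGeneric("standardization", function(x, ...)
  standardGeneric("standardization"))
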