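#' @include AllClasses.R
NULL

#' @export
setGeneric("drawings", function(x) standardGeneric("drawings"))

#' @export
setGeneric("trialData", function(x) standardGeneric("trialData"))

#' @export
setGeneric("electrodeCoords", function(x) standardGeneric("electrodeCoords"))

#' @export
setGeneric("coefTable", function(x) standardGeneric("coefTable"))

#' @export
setGeneric("modelAIC", function(x) standardGeneric("modelAIC"))

#' @export
setGeneric("modelBIC", function(x) standardGeneric("modelBIC"))
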