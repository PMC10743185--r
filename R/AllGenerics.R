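#' @include AllClasses.R
NULL

#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' @export
setGeneric("wavelengthUnit", function(x) standardGeneric("wavelengthUnit"))

#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @export
setGeneric("concentrations<-", function(x, value) standardGeneric("concentrations<-"))

#' @export
setGeneric("regressionVector", function(object) standardGeneric("regressionVector"))

#' @export
setGeneric("nLatent", function(object) standardGeneric("nLatent"))
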