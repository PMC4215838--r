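#' @rdname OtuExperiment-accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname OtuExperiment-accessors
#' @export
setGeneric("otuLineages", function(x) standardGeneric("otuLineages"))

#' @rdname relativeAbundance
#' @export
setGeneric("relativeAbundance", function(x) standardGeneric("relativeAbundance"))

#' @rdname rarefy
#' @export
setGeneric("rarefy", function(x, depth, seed = NULL) standardGeneric("rarefy"))
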