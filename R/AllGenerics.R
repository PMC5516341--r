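#' @rdname MethylRawSet-class
#' @param object a \linkS4class{MethylRawSet} or \linkS4class{MethylBetaSet}.
#' @export
setGeneric("getMeth", function(object) standardGeneric("getMeth"))

#' @rdname MethylRawSet-class
#' @export
setGeneric("getUnmeth", function(object) standardGeneric("getUnmeth"))

#' @rdname MethylBetaSet-class
#' @param object a \linkS4class{MethylBetaSet}.
#' @export
setGeneric("getBeta", function(object) standardGeneric("getBeta"))

#' @rdname MethylRawSet-class
#' @export
setGeneric("negativeControls",
    function(object) standardGeneric("negativeControls"))

#' @rdname MethylRawSet-class
#' @export
setGeneric("sampleGroups", function(object) standardGeneric("sampleGroups"))

#' @rdname MethylRawSet-class
#' @export
setGeneric("probeManifest", function(object) standardGeneric("probeManifest"))
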