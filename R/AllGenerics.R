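#' @rdname TestBattery-accessors
#' @export
setGeneric("testNames", function(x) standardGeneric("testNames"))

#' @rdname TestBattery-accessors
#' @export
setGeneric("isHigherBetter", function(x) standardGeneric("isHigherBetter"))

#' @rdname TestBattery-accessors
#' @export
setGeneric("domainsOf", function(x, test) standardGeneric("domainsOf"))

#' @rdname TestBattery-accessors
#' @export
setGeneric("domainMembers", function(x, domain) standardGeneric("domainMembers"))

#' @rdname CognitiveGraph-accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))

#' @rdname CognitiveGraph-accessors
#' @export
setGeneric("nodeNames", function(x) standardGeneric("nodeNames"))

#' @rdname CognitiveCohort-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname CognitiveCohort-accessors
#' @export
setGeneric("batteryOf", function(x) standardGeneric("batteryOf"))

#' @rdname CognitiveCohort-accessors
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' @rdname CognitiveCohort-accessors
#' @export
setGeneric("subsetGroup", function(x, group) standardGeneric("subsetGroup"))
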