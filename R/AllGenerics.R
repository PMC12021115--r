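#' @rdname GenotypeData-accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("hapA", function(x) standardGeneric("hapA"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("hapB", function(x) standardGeneric("hapB"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("isPhased", function(x) standardGeneric("isPhased"))

#' @rdname GenotypeData-accessors
#' @export
setGeneric("sampleMeta", function(x) standardGeneric("sampleMeta"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname HaplotypePanel-accessors
#' @export
setGeneric("population", function(x) standardGeneric("population"))
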