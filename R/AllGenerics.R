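#' Accessors for ldstructure classes
#'
#' \code{dosage} returns the SNPs x individuals integer dosage matrix;
#' \code{markers} the marker-map \code{GRanges}; \code{individuals} the
#' individual identifiers; \code{haplotypes}, \code{carriers} and
#' \code{origins} the haplotype matrix and its row tags;
#' \code{nHaplotypes} the chromosome sample size n; \code{pedigreeTable}
#' the pedigree as a data.frame; \code{neByGeneration} the realized
#' per-generation population size of a simulation.
#'
#' @param x an object of the documented class.
#' @return see details per accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname accessors
#' @export
setGeneric("markers", function(x) standardGeneric("markers"))

#' @rdname accessors
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))

#' @rdname accessors
#' @export
setGeneric("carriers", function(x) standardGeneric("carriers"))

#' @rdname accessors
#' @export
setGeneric("origins", function(x) standardGeneric("origins"))

#' @rdname accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))

#' @rdname accessors
#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))

#' @rdname accessors
#' @export
setGeneric("neByGeneration", function(x) standardGeneric("neByGeneration"))

#' @rdname accessors
#' @export
setMethod("dosage", "SnpGenotypes", function(x)
    SummarizedExperiment::assay(x, "dosage"))

#' @rdname accessors
#' @export
setMethod("markers", "SnpGenotypes", function(x)
    SummarizedExperiment::rowRanges(x))

#' @rdname accessors
#' @export
setMethod("markers", "HaplotypeSet", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("markers", "SimTruth", function(x) x@markers)

#' @rdname accessors
#' @export
setMethod("individuals", "SnpGenotypes", function(x)
    colnames(SummarizedExperiment::assay(x, "dosage")))

#' @rdname accessors
#' @export
setMethod("haplotypes", "HaplotypeSet", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setMethod("haplotypes", "SimTruth", function(x) x@haplotypes)

#' @rdname accessors
#' @export
setMethod("carriers", "HaplotypeSet", function(x) x@carrier)

#' @rdname accessors
#' @export
setMethod("origins", "HaplotypeSet", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("nHaplotypes", "HaplotypeSet", function(x) nrow(x@haplotypes))

#' @rdname accessors
#' @export
setMethod("pedigreeTable", "Pedigree", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("neByGeneration", "SimTruth", function(x) x@neByGeneration)
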