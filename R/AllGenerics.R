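#' Autosome names of a genome model
#' @param x A [GenomeModel-class].
#' @return Character vector of autosome names.
#' @export
setGeneric("autosomes", function(x) standardGeneric("autosomes"))

#' @rdname autosomes
#' @export
setMethod("autosomes", "GenomeModel", function(x) x@autosomes)

#' Total autosomal genome size in bp
#'
#' The denominator `D` of the enrichment fold: the sum of the autosome
#' lengths (analogue of summing chromosomes 1-29 of the bovine genome).
#'
#' @param x A [GenomeModel-class].
#' @return Numeric bp count.
#' @export
setGeneric("autosomalBp", function(x) standardGeneric("autosomalBp"))

#' @rdname autosomalBp
#' @export
setMethod("autosomalBp", "GenomeModel", function(x) {
  sum(as.numeric(GenomeInfoDb::seqlengths(x@seqinfo)[x@autosomes]))
})

#' Shape class of a peak set
#' @param x A [PeakSet-class].
#' @return `"narrow"` or `"broad"`.
#' @export
setGeneric("shapeClass", function(x) standardGeneric("shapeClass"))

#' @rdname shapeClass
#' @export
setMethod("shapeClass", "PeakSet", function(x) x@shapeClass)

#' Label of a peak or SNP set
#' @param x A [PeakSet-class] or [SnpRanges-class].
#' @return Character label.
#' @export
setGeneric("setLabel", function(x) standardGeneric("setLabel"))

#' @rdname setLabel
#' @export
setMethod("setLabel", "PeakSet", function(x) x@label)

#' @rdname setLabel
#' @export
setMethod("setLabel", "SnpRanges", function(x) x@label)

#' Convert an enrichment result to a one-row data.frame
#'
#' @param x An [EnrichmentResult-class].
#' @param row.names,optional,... Ignored; present for generic consistency.
#' @return A one-row `data.frame` with columns `regionLabel`, `snpLabel`,
#'   `A`, `B`, `C`, `D`, `fold`, `pEnrich`, `pDeplete`, `defined`.
#' @export
as.data.frame.EnrichmentResult <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  data.frame(
    regionLabel = x@regionLabel, snpLabel = x@snpLabel,
    A = x@A, B = x@B, C = x@C, D = x@D,
    fold = x@fold, pEnrich = x@pEnrich, pDeplete = x@pDeplete,
    defined = x@defined, stringsAsFactors = FALSE
  )
}
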