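#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @export
setGeneric("labelOrder", function(x) standardGeneric("labelOrder"))

#' @export
setGeneric("labelMaxima", function(x) standardGeneric("labelMaxima"))

#' @export
setGeneric("corrected", function(x) standardGeneric("corrected"))

#' @export
setGeneric("reconstructed", function(x) standardGeneric("reconstructed"))

#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))

#' @export
setGeneric("residual", function(x) standardGeneric("residual"))

## masks base::addNA (factor helper); the field's name for the forward
## contamination operator wins here
#' @export
setGeneric("addNA", function(x, ...) standardGeneric("addNA"))

#' @export
setGeneric("solvePass", function(x, ...) standardGeneric("solvePass"))

#' @export
setGeneric("correctNA", function(x, ...) standardGeneric("correctNA"))
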