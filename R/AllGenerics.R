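#' Accessors for SL reference and control sets
#'
#' @param x An \linkS4class{SLReferenceSet} or \linkS4class{RandomControlSet}.
#' @return \code{slSequences} returns a \link[Biostrings]{DNAStringSet};
#'   \code{slCategories} a character vector parallel to the sequences;
#'   \code{controlLength} the integer control length (nt).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">SL1", "GGTTTAATTACCCAAGTTTGAG"), fa)
#' refs <- loadSLReferences(fa)
#' slSequences(refs)
#' slCategories(refs)
#' controlLength(refs)
#' @name sl-accessors
NULL

#' @rdname sl-accessors
#' @export
setGeneric("slSequences", function(x) standardGeneric("slSequences"))

#' @rdname sl-accessors
#' @export
setGeneric("slCategories", function(x) standardGeneric("slCategories"))

#' @rdname sl-accessors
#' @export
setGeneric("controlLength", function(x) standardGeneric("controlLength"))

#' @rdname sl-accessors
#' @export
setMethod("slSequences", "SLReferenceSet", function(x) x@sequences)

#' @rdname sl-accessors
#' @export
setMethod("slCategories", "SLReferenceSet", function(x) {
  stats::setNames(x@category, names(x@sequences))
})

#' @rdname sl-accessors
#' @export
setMethod("controlLength", "SLReferenceSet", function(x) x@controlLength)

#' @rdname sl-accessors
#' @export
setMethod("slSequences", "RandomControlSet", function(x) x@sequences)

setMethod("show", "SLReferenceSet", function(object) {
  cat("SLReferenceSet with", length(object@sequences), "references (",
      sum(object@category == "SL1"), "SL1,",
      sum(object@category == "SL2"), "SL2 )\n")
  cat("  control length:", object@controlLength, "nt\n")
  cat("  names:", paste(utils::head(names(object@sequences), 6),
                        collapse = ", "),
      if (length(object@sequences) > 6) "...\n" else "\n")
})

setMethod("show", "RandomControlSet", function(object) {
  cat("RandomControlSet:", length(object@sequences), "sequences of",
      Biostrings::width(object@sequences)[1], "nt (seed",
      object@seed, ")\n")
})

setMethod("show", "CutoffCurve", function(object) {
  cat("CutoffCurve over", length(object@scores), "distinct scores;",
      "fold =", object@fold, "\n")
  cat("  candidate reads:", max(object@nSL), "\n")
  cat("  dynamic cutoff:",
      if (is.na(object@cutoff)) "none" else format(object@cutoff), "\n")
})
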