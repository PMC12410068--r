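#' @import methods
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom Biostrings DNAStringSet
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' SLReferenceSet: spliced-leader reference sequences
#'
#' Holds the spliced-leader (SL) reference sequences for a species together
#' with their type category (SL1 or SL2-family) and the length used for the
#' random background controls, defined as the rounded mean length of the
#' references (round half up).
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet} of SL reference
#'   sequences (DNA alphabet; U in input FASTA is mapped to T on load).
#' @slot category Character vector, one of \code{"SL1"} or \code{"SL2"} per
#'   reference, parallel to \code{sequences}.
#' @slot controlLength Integer scalar, the length (nt) of the random control
#'   sequences derived from this set.
#'
#' @seealso \code{\link{loadSLReferences}}, \code{\link{randomControls}}
#' @export
setClass("SLReferenceSet",
  representation(
    sequences = "DNAStringSet",
    category = "character",
    controlLength = "integer"
  )
)

setValidity("SLReferenceSet", function(object) {
  msg <- character()
  if (length(object@sequences) < 1L)
    msg <- c(msg, "at least one SL reference is required")
  if (length(object@category) != length(object@sequences))
    msg <- c(msg, "'category' must be parallel to 'sequences'")
  if (!all(object@category %in% c("SL1", "SL2")))
    msg <- c(msg, "categories must be 'SL1' or 'SL2'")
  if (any(Biostrings::width(object@sequences) == 0L))
    msg <- c(msg, "SL reference sequences must be non-empty")
  expect <- as.integer(floor(mean(Biostrings::width(object@sequences)) + 0.5))
  if (length(object@controlLength) != 1L || is.na(object@controlLength) ||
      object@controlLength != expect)
    msg <- c(msg, "controlLength must be the rounded mean reference length")
  if (length(msg)) msg else TRUE
})

#' RandomControlSet: background control sequences
#'
#' A fixed number of i.i.d.-uniform random DNA sequences of identical length,
#' used as the score background against which SL alignments are judged.
#' Regeneration with the same seed is bit-identical.
#'
#' @slot sequences A \link[Biostrings]{DNAStringSet}; all members have the
#'   same width.
#' @slot seed Integer scalar, the RNG seed the set was generated from.
#'
#' @seealso \code{\link{randomControls}}
#' @export
setClass("RandomControlSet",
  representation(
    sequences = "DNAStringSet",
    seed = "integer"
  )
)

setValidity("RandomControlSet", function(object) {
  msg <- character()
  w <- Biostrings::width(object@sequences)
  if (length(w) < 1L) msg <- c(msg, "no control sequences")
  if (length(unique(w)) > 1L)
    msg <- c(msg, "control sequences must share one length")
  if (length(msg)) msg else TRUE
})

#' CutoffCurve: cumulative SL vs random score curves
#'
#' Cumulative count curves of candidate reads whose best-SL (respectively
#' best-random) SL score is at least each score threshold, plus the fold
#' factor and the dynamic cutoff derived from them. The cutoff is the
#' smallest score at which SL-aligned reads outnumber random-aligned reads by
#' the fold factor (NA when no score qualifies, as for species without SLs).
#'
#' @slot scores Numeric, sorted distinct score thresholds.
#' @slot nSL Integer, number of candidate reads with best-SL score >= s.
#' @slot nRandom Integer, number of candidate reads with best-random
#'   score >= s.
#' @slot fold Numeric scalar, the required fold difference.
#' @slot cutoff Numeric scalar, the dynamic cutoff, or NA if none exists.
#'
#' @seealso \code{\link{buildCutoffCurve}}, \code{\link{computeCutoff}}
#' @export
setClass("CutoffCurve",
  representation(
    scores = "numeric",
    nSL = "integer",
    nRandom = "integer",
    fold = "numeric",
    cutoff = "numeric"
  )
)

setValidity("CutoffCurve", function(object) {
  msg <- character()
  n <- length(object@scores)
  if (n < 1L) msg <- c(msg, "empty curve")
  if (length(object@nSL) != n || length(object@nRandom) != n)
    msg <- c(msg, "counts must be parallel to scores")
  if (is.unsorted(object@scores, strictly = TRUE))
    msg <- c(msg, "scores must be sorted strictly increasing")
  if (any(diff(object@nSL) > 0L) || any(diff(object@nRandom) > 0L))
    msg <- c(msg, "cumulative counts must be non-increasing in the score")
  if (length(msg)) msg else TRUE
})
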