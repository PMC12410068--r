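#' Build cumulative SL vs random score curves
#'
#' For every distinct score s observed among the candidate reads (union of
#' best-SL and best-random scores), counts the candidate reads whose best-SL
#' score is >= s and those whose best-random score is >= s. At the minimum
#' observed score both counts equal the number of candidate reads analyzed;
#' the gap between the two curves at higher scores is what the dynamic
#' cutoff exploits.
#'
#' @param calls Scored read table from \code{\link{scoreReads}}.
#' @param fold Fold factor stored with the curve (default 4); the cutoff is
#'   computed lazily by \code{\link{computeCutoff}}.
#' @return A \linkS4class{CutoffCurve} (with \code{cutoff} still NA).
#' @export
buildCutoffCurve <- function(calls, fold = 4) {
  calls <- as.data.frame(calls)
  if (nrow(calls) == 0L) stop("no candidate reads")
  s <- sort(unique(c(calls$sl_score, calls$best_random)))
  nSL <- vapply(s, function(x) sum(calls$sl_score >= x), integer(1))
  nRD <- vapply(s, function(x) sum(calls$best_random >= x), integer(1))
  new("CutoffCurve", scores = s, nSL = nSL, nRandom = nRD,
      fold = fold, cutoff = NA_real_)
}

#' Compute the dynamic score cutoff
#'
#' The dynamic cutoff s_c is the smallest observed score s at which the
#' cumulative count of reads aligned to the SL references is at least
#' \code{fold} times the cumulative count aligned to the random controls:
#' \code{s_c = min\{s : N_SL(s) / N_random(s) >= f\}}. A zero random count
#' with a positive SL count satisfies the condition (the ratio is
#' unbounded). When no score qualifies -- as for a species without SLs,
#' where the two curves coincide -- the cutoff is NA and a warning is
#' raised; no reads can then be promoted.
#'
#' @param curve A \linkS4class{CutoffCurve}.
#' @param fold Required fold difference (default: the curve's own fold).
#' @return The updated \linkS4class{CutoffCurve} with \code{cutoff} set
#'   (possibly NA).
#' @export
computeCutoff <- function(curve, fold = curve@fold) {
  stopifnot(fold > 0)
  ok <- (curve@nRandom == 0L & curve@nSL > 0L) |
    (curve@nRandom > 0L & curve@nSL / curve@nRandom >= fold)
  sc <- if (any(ok)) min(curve@scores[ok]) else NA_real_
  if (is.na(sc))
    warning("no score satisfies the fold condition; ",
            "no dynamic cutoff established")
  initialize(curve, fold = fold, cutoff = sc)
}

#' Promote potential SL reads above the dynamic cutoff
#'
#' Potential SL reads (best SL score strictly above best random score) whose
#' SL score is >= the dynamic cutoff become high-confidence SL reads. Other
#' categories are never promoted; with no cutoff (NA) nothing is promoted.
#'
#' @param calls Scored read table from \code{\link{scoreReads}}.
#' @param cutoff The dynamic cutoff (a number, or a
#'   \linkS4class{CutoffCurve} whose cutoff slot is used).
#' @return The calls table with \code{category} updated.
#' @export
selectHighConfidence <- function(calls, cutoff) {
  if (is(cutoff, "CutoffCurve")) cutoff <- cutoff@cutoff
  if (is.na(cutoff)) {
    warning("no dynamic cutoff; zero reads promoted")
    return(calls)
  }
  promote <- calls$category == "potential_SL" & calls$sl_score >= cutoff
  calls$category[promote] <- "high_confidence_SL"
  calls
}

#' Area-under-curve separation between SL and random curves
#'
#' Trapezoidal area under the cumulative SL count curve divided by the area
#' under the cumulative random count curve, over the common score range. A
#' larger ratio means the SL score separates genuine SL alignments from
#' background better; identical curves give exactly 1.
#'
#' @param curve A \linkS4class{CutoffCurve}.
#' @return A positive number, possibly \code{Inf} (with a warning) when the
#'   random curve has zero area.
#' @export
aucSeparation <- function(curve) {
  s <- curve@scores
  if (length(s) < 2L) stop("need at least two distinct scores")
  trapz <- function(y) sum(diff(s) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  a_sl <- trapz(as.numeric(curve@nSL))
  a_rd <- trapz(as.numeric(curve@nRandom))
  if (a_rd == 0) {
    warning("random curve has zero area; separation is infinite")
    return(Inf)
  }
  a_sl / a_rd
}

#' Export the cutoff curve as a data frame
#'
#' @param x A \linkS4class{CutoffCurve}.
#' @param row.names,optional,... Passed on per the generic contract
#'   (unused).
#' @return A data.frame with columns \code{score}, \code{n_sl_cum},
#'   \code{n_random_cum}.
#' @method as.data.frame CutoffCurve
#' @export
as.data.frame.CutoffCurve <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  data.frame(score = x@scores, n_sl_cum = x@nSL, n_random_cum = x@nRandom)
}
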