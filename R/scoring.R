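#' Scoring parameters for SL detection
#'
#' Bundles the Smith-Waterman (SW) alignment parameters and the weights of
#' the SL-specific score terms. The SW scheme is match = +1 with unit
#' mismatch, gap-open and gap-extend penalties; a k-base gap costs
#' \code{gapOpen + k * gapExtend}. On top of the optimal local alignment the
#' SL score adds a continuity bonus of \code{continuityWeight} per sliding
#' \code{window}-column stretch with at most \code{maxWindowMismatch}
#' mismatching columns (gap columns count as mismatches), then scales by
#' reference 3'-proximity and query 5'-proximity factors and normalizes to
#' [0, 1].
#'
#' @param match Match reward (default 1).
#' @param mismatch Mismatch penalty, given as a positive number (default 1).
#' @param gapOpen Gap opening penalty (default 1).
#' @param gapExtend Per-base gap extension penalty (default 1).
#' @param window Continuity window width in alignment columns (default 5).
#' @param maxWindowMismatch Maximum mismatching columns per qualifying
#'   window (default 1).
#' @param continuityWeight Score units added per qualifying window
#'   (default 0.5).
#' @return A list of class \code{"sl_scoring_params"}.
#' @export
scoringParams <- function(match = 1, mismatch = 1, gapOpen = 1,
                          gapExtend = 1, window = 5L,
                          maxWindowMismatch = 1L, continuityWeight = 0.5) {
  stopifnot(match > 0, mismatch >= 0, gapOpen >= 0, gapExtend >= 0,
            window >= 1, maxWindowMismatch >= 0, continuityWeight >= 0)
  structure(list(match = match, mismatch = mismatch, gapOpen = gapOpen,
                 gapExtend = gapExtend, window = as.integer(window),
                 maxWindowMismatch = as.integer(maxWindowMismatch),
                 continuityWeight = continuityWeight),
            class = "sl_scoring_params")
}

#' Smith-Waterman local alignment
#'
#' Optimal local alignment of a query against a reference under the unit
#' match/mismatch/gap scheme used for SL detection (affine gaps: a k-base
#' gap costs \code{gapOpen + k * gapExtend}). Ties between equal-scoring
#' optima are broken deterministically by the canonical row-major
#' convention (first optimum scanning query then reference positions); the
#' same neutral rule is applied to SL references and random controls, so
#' coincidental short matches are not pushed toward the positionally
#' most favourable placement.
#'
#' @param query,ref DNA sequences as character strings (ACGT).
#' @param params A \code{\link{scoringParams}} object.
#' @return A list with \code{sw_score}; 0-based half-open region bounds
#'   \code{query_start}, \code{query_end}, \code{ref_start}, \code{ref_end};
#'   and \code{status}, an integer vector over alignment columns
#'   (0 match, 1 mismatch, 2 query-base-vs-gap, 3 gap-vs-ref-base). A score
#'   of 0 yields an empty region.
#' @examples
#' smithWaterman("ACGT", "ACGT")$sw_score  # 4
#' smithWaterman("AAAA", "TTTT")$sw_score  # 0
#' @export
smithWaterman <- function(query, ref, params = scoringParams()) {
  if (!nzchar(query) || !nzchar(ref))
    stop("query and ref must be non-empty")
  if (grepl("[^ACGT]", query) || grepl("[^ACGT]", ref))
    stop("query and ref must be ACGT only")
  res <- sw_align_cpp(query, ref, params$match, params$mismatch,
                      params$gapOpen, params$gapExtend)
  names(res)[names(res) == "score"] <- "sw_score"
  res
}

#' Normalized SL detection score for a clip against one reference
#'
#' Scores a candidate 5' clip against one SL reference. Starting from the
#' SW-optimal local region, the raw score is
#' \code{sw + w_c * C}, where C counts sliding window-column stretches with
#' at most one mismatch (gap columns count as mismatches). The raw score is
#' scaled by \code{f3 = ref_end / length(ref)} (regions ending at the
#' reference 3' end are worth most, since trans-splicing joins the SL 3' end
#' to the mRNA) and \code{f5 = 1 - query_start / length(clip)} (the SL
#' residue should sit at the very 5' end of the clip), then normalized by
#' the maximum score the whole clip could attain,
#' \code{M = n * match + w_c * max(0, n - window + 1)} with
#' \code{n = length(clip)}, and clamped to [0, 1]. Clip bases outside the
#' local alignment therefore count against the SL hypothesis; a clip that
#' aligns perfectly end-to-end against a reference 3' end scores exactly 1,
#' while a short coincidental k-mer match tops out near \code{k/n}. A SW
#' score of 0 yields an SL score of 0 with an empty region.
#'
#' @param clip Candidate clip sequence (read 5'->3'), character.
#' @param ref SL reference sequence, character.
#' @param params A \code{\link{scoringParams}} object.
#' @return A list: \code{sw_score}, \code{sl_score} in [0, 1],
#'   \code{aligned_len} (aligned query bases L), and the region fields of
#'   \code{\link{smithWaterman}}.
#' @examples
#' ref <- "GGTTTAATTACCCAAGTTTGAG"
#' slScore(ref, ref)$sl_score                      # 1: perfect full match
#' slScore(substr(ref, 15, 22), ref)$sl_score      # 1: 3'-anchored residue
#' @export
slScore <- function(clip, ref, params = scoringParams()) {
  aln <- smithWaterman(clip, ref, params)
  if (aln$sw_score <= 0) {
    return(c(aln, list(sl_score = 0, aligned_len = 0L)))
  }
  st <- aln$status
  w <- params$window
  C <- 0L
  if (length(st) >= w) {
    bad <- as.integer(st != 0L)
    cs <- cumsum(bad)
    mism <- cs[w:length(st)] - c(0L, cs)[seq_len(length(st) - w + 1L)]
    C <- sum(mism <= params$maxWindowMismatch)
  }
  raw <- aln$sw_score + params$continuityWeight * C
  f3 <- aln$ref_end / nchar(ref)
  f5 <- 1 - aln$query_start / nchar(clip)
  L <- aln$query_end - aln$query_start
  # normalize by the best score the whole clip could achieve; clip bases
  # left out of the local alignment count against the SL hypothesis, which
  # keeps short coincidental matches on random controls well below 1
  nc <- nchar(clip)
  M <- nc * params$match +
    params$continuityWeight * max(0L, nc - w + 1L)
  score <- raw * f3 * f5 / M
  c(aln, list(sl_score = min(max(score, 0), 1), aligned_len = L))
}

#' Assign an SL label from per-reference scores
#'
#' Picks the SL label given the SL score of one read against every
#' reference. A unique maximum yields that reference's name; a tie for the
#' maximum spanning SL1 and any SL2 variant yields \code{"SL_unknown"}
#' (cannot be placed between the two SL classes); a tie among SL2 variants
#' only yields \code{"SL2_unknown"} (SL2-class but no specific variant).
#'
#' @param scores Named numeric vector of SL scores, one per reference.
#' @param categories Character vector (\code{"SL1"}/\code{"SL2"}) parallel
#'   to \code{scores}, e.g. \code{slCategories(refs)}.
#' @return A list with \code{label} (reference name, \code{"SL_unknown"} or
#'   \code{"SL2_unknown"}) and \code{class} (\code{"SL1"}, \code{"SL2"} or
#'   \code{NA} when the class itself is ambiguous).
#' @export
classifyLabel <- function(scores, categories) {
  stopifnot(length(scores) >= 1L, length(scores) == length(categories))
  top <- which(scores == max(scores))
  if (length(top) == 1L) {
    return(list(label = names(scores)[top],
                class = unname(categories[top])))
  }
  cls <- unique(categories[top])
  if (length(cls) > 1L) list(label = "SL_unknown", class = NA_character_)
  else if (cls == "SL2") list(label = "SL2_unknown", class = "SL2")
  else list(label = names(scores)[top[1L]], class = "SL1")
}

#' Score candidate reads against SL references and random controls
#'
#' Computes the best SL score of each candidate clip over all SL references
#' and over all random controls, labels each read, and classifies it on the
#' confidence ladder: a candidate becomes a \code{potential_SL} read iff its
#' best SL score strictly exceeds its best random-control score (ties fail).
#' Promotion to \code{high_confidence_SL} happens later, once the dynamic
#' cutoff is known (\code{\link{selectHighConfidence}}).
#'
#' @param candidates A \code{DataFrame}/\code{data.frame} with columns
#'   \code{read_id}, \code{clip_seq}, \code{clip_len}, as produced by
#'   \code{\link{extractCandidates}}.
#' @param refs An \linkS4class{SLReferenceSet}.
#' @param controls A \linkS4class{RandomControlSet}.
#' @param params A \code{\link{scoringParams}} object.
#' @return A \link[S4Vectors]{DataFrame} with one row per candidate:
#'   \code{read_id}, \code{clip_len}, \code{sw_score}, \code{sl_score},
#'   \code{sl_label}, \code{sl_class}, \code{aligned_len},
#'   \code{best_random}, \code{category}.
#' @export
scoreReads <- function(candidates, refs, controls,
                       params = scoringParams()) {
  cand <- as.data.frame(candidates)
  refseq <- as.character(slSequences(refs))
  cats <- slCategories(refs)
  ctrlseq <- as.character(slSequences(controls))
  n <- nrow(cand)
  out <- data.frame(
    read_id = character(n), clip_len = integer(n), sw_score = numeric(n),
    sl_score = numeric(n), sl_label = character(n), sl_class = character(n),
    aligned_len = integer(n), best_random = numeric(n),
    category = character(n), stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    clip <- cand$clip_seq[i]
    hits <- lapply(refseq, function(r) slScore(clip, r, params))
    sl_scores <- vapply(hits, `[[`, numeric(1), "sl_score")
    names(sl_scores) <- names(refseq)
    best_i <- which.max(sl_scores)
    lab <- classifyLabel(sl_scores, cats)
    best_rand <- max(vapply(ctrlseq, function(r)
      slScore(clip, r, params)$sl_score, numeric(1)))
    best <- hits[[best_i]]
    out$read_id[i] <- cand$read_id[i]
    out$clip_len[i] <- cand$clip_len[i]
    out$sw_score[i] <- best$sw_score
    out$sl_score[i] <- sl_scores[[best_i]]
    out$sl_label[i] <- lab$label
    out$sl_class[i] <- lab$class
    out$aligned_len[i] <- best$aligned_len
    out$best_random[i] <- best_rand
    out$category[i] <-
      if (sl_scores[[best_i]] > best_rand) "potential_SL" else "candidate"
  }
  S4Vectors::DataFrame(out)
}
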