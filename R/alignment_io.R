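#' Read spliced long-read alignments
#'
#' Loads primary alignments (secondary, supplementary and unmapped records
#' are dropped) from a BAM or SAM file, keeping the query sequence and CIGAR
#' needed for 5' clip extraction and the junction structure needed for gene
#' assignment. SAM input is converted on the fly.
#'
#' @param file Path to a BAM or SAM file.
#' @return A \link[GenomicAlignments]{GAlignments} object named by read id,
#'   with metadata columns \code{flag} and \code{seq}.
#' @export
readSplicedAlignments <- function(file) {
  if (!file.exists(file)) stop("alignment file not found: ", file)
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("flag", "seq"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  GenomicAlignments::readGAlignments(file, use.names = TRUE, param = param)
}

# first and last CIGAR op/length ignoring hard clips (their bases are not in
# SEQ, so they never contribute clip sequence)
.end_softclips <- function(cig) {
  ops <- GenomicAlignments::explodeCigarOps(cig)
  lens <- GenomicAlignments::explodeCigarOpLengths(cig)
  lead <- integer(length(cig))
  trail <- integer(length(cig))
  for (i in seq_along(cig)) {
    o <- ops[[i]]
    l <- lens[[i]]
    keep <- o != "H"
    o <- o[keep]; l <- l[keep]
    if (length(o)) {
      if (o[1L] == "S") lead[i] <- l[1L]
      if (o[length(o)] == "S") trail[i] <- l[length(l)]
    }
  }
  list(lead = lead, trail = trail)
}

#' Extract 5' soft-clipped candidate fragments
#'
#' Walks primary alignments and extracts, for each read, the soft-clipped
#' fragment at the read's 5' end in read orientation: the leading soft clip
#' of SEQ for plus-strand alignments, and the reverse complement of the
#' trailing soft clip for minus-strand alignments (SAM stores SEQ in
#' reference orientation). Reads whose 5' clip is shorter than
#' \code{minClip} (or absent) are tallied as \code{"other"}; the rest are
#' the candidate reads that may carry an SL residue. Records whose CIGAR has
#' no aligned (M/=/X) operation are skipped with a warning.
#'
#' @param alignments A BAM/SAM path or a
#'   \link[GenomicAlignments]{GAlignments} from
#'   \code{\link{readSplicedAlignments}}.
#' @param minClip Minimum 5' clip length in nt (default 5).
#' @return A list with \code{candidates}, a \link[S4Vectors]{DataFrame} of
#'   \code{read_id}, \code{clip_seq} (read 5'->3'), \code{clip_len};
#'   \code{tally}, a named integer vector \code{c(other, candidate)}; and
#'   \code{alignments}, the primary alignments processed.
#' @examples
#' \dontrun{
#' res <- extractCandidates("aln.bam")
#' res$tally
#' }
#' @export
extractCandidates <- function(alignments, minClip = 5L) {
  galn <- if (is.character(alignments)) readSplicedAlignments(alignments)
          else alignments
  cig <- GenomicAlignments::cigar(galn)
  has_match <- grepl("[M=X]", cig)
  if (any(!has_match)) {
    warning(sum(!has_match), " record(s) without any aligned operation ",
            "skipped")
    galn <- galn[has_match]
    cig <- cig[has_match]
  }
  str <- as.character(GenomicAlignments::strand(galn))
  clips <- .end_softclips(cig)
  seqs <- S4Vectors::mcols(galn)$seq
  n <- length(galn)
  clip_seq <- character(n)
  clip_len <- integer(n)
  for (i in seq_len(n)) {
    if (str[i] == "-") {
      len <- clips$trail[i]
      if (len > 0L) {
        w <- Biostrings::width(seqs)[i]
        frag <- Biostrings::subseq(seqs[i], w - len + 1L, w)
        clip_seq[i] <- as.character(Biostrings::reverseComplement(frag))
      }
      clip_len[i] <- len
    } else {
      len <- clips$lead[i]
      if (len > 0L)
        clip_seq[i] <- as.character(Biostrings::subseq(seqs[i], 1L, len))
      clip_len[i] <- len
    }
  }
  is_cand <- clip_len >= minClip
  cand <- S4Vectors::DataFrame(
    read_id = names(galn)[is_cand],
    clip_seq = clip_seq[is_cand],
    clip_len = clip_len[is_cand]
  )
  list(candidates = cand,
       tally = c(other = sum(!is_cand), candidate = sum(is_cand)),
       alignments = galn)
}

#' Residual SL length histogram
#'
#' Tabulates, over high-confidence SL reads, the length of the clip region
#' locally aligned to the winning SL reference -- i.e. the SL residue that
#' survived 5' degradation. In direct RNA sequencing this distribution is
#' typically concentrated at short residues (about 5-9 nt).
#'
#' @param calls A scored read table (see \code{\link{scoreReads}}) after
#'   \code{\link{selectHighConfidence}}.
#' @return A named integer vector mapping residue length (nt) to read
#'   count; empty for empty input.
#' @export
residualLengthHistogram <- function(calls) {
  calls <- as.data.frame(calls)
  hc <- calls[calls$category == "high_confidence_SL", , drop = FALSE]
  if (nrow(hc) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(hc$aligned_len)
  stats::setNames(as.integer(tab), names(tab))
}
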