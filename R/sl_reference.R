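#' Load spliced-leader reference sequences from FASTA
#'
#' Reads a FASTA file of mature spliced-leader (SL) sequences, normalizes the
#' alphabet (U is mapped to T so RNA-alphabet files work, case is folded to
#' upper), assigns each reference to the SL1 or SL2 category and derives the
#' control length as the rounded mean reference length (half-up). By default
#' the category is taken from the record name: names beginning with
#' \code{"SL1"} (case-insensitive) are SL1 and everything else is SL2, which
#' matches the conventional naming of the \emph{C. elegans} SL1 sequence and
#' its SL2-family variants (SL2..SL13 etc.). Supply \code{categoryMap} to
#' override this for other species.
#'
#' @param fasta Path to a FASTA file of SL references.
#' @param categoryMap Optional named character vector mapping record names to
#'   \code{"SL1"}/\code{"SL2"}; unmapped names fall back to the prefix rule.
#' @return An \linkS4class{SLReferenceSet}.
#' @examples
#' fa <- system.file("extdata", "celegans_sl_synthetic.fasta",
#'                   package = "SLcallR")
#' refs <- loadSLReferences(fa)
#' controlLength(refs)  # 22 for the C. elegans set
#' @export
loadSLReferences <- function(fasta, categoryMap = NULL) {
  if (!file.exists(fasta)) stop("FASTA file not found: ", fasta)
  seqs <- Biostrings::readBStringSet(fasta)
  if (length(seqs) == 0L) stop("no SL references in ", fasta)
  chr <- toupper(as.character(seqs))
  chr <- gsub("U", "T", chr, fixed = TRUE)
  bad <- grepl("[^ACGT]", chr)
  if (any(bad))
    stop("non-ACGT/U character in SL reference record(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  if (any(nchar(chr) == 0L))
    stop("empty sequence in SL reference record(s): ",
         paste(names(seqs)[nchar(chr) == 0L], collapse = ", "))
  nms <- names(seqs)
  if (is.null(nms) || any(nms == ""))
    stop("all SL reference records must be named")
  # "SL1" prefix not followed by another digit, so SL10..SL13 stay SL2
  category <- ifelse(grepl("^SL1([^0-9]|$)", nms, ignore.case = TRUE),
                     "SL1", "SL2")
  if (!is.null(categoryMap)) {
    hit <- nms %in% names(categoryMap)
    category[hit] <- unname(categoryMap[nms[hit]])
    if (!all(category %in% c("SL1", "SL2")))
      stop("categoryMap values must be 'SL1' or 'SL2'")
  }
  dna <- Biostrings::DNAStringSet(chr)
  names(dna) <- nms
  new("SLReferenceSet",
      sequences = dna,
      category = category,
      controlLength = round_half_up(mean(nchar(chr))))
}

#' Generate random background control sequences
#'
#' Generates \code{count} i.i.d.-uniform DNA sequences of exactly
#' \code{length} nt. Candidate 5' clips are scored against these controls in
#' the same way as against the SL references; the best control score per read
#' forms the background distribution from which the dynamic cutoff is
#' derived. Generation is deterministic for a given seed and leaves the
#' caller's RNG state untouched.
#'
#' @param length Control sequence length in nt, normally
#'   \code{controlLength(refs)}.
#' @param seed Integer RNG seed.
#' @param count Number of control sequences (default 10).
#' @return A \linkS4class{RandomControlSet}.
#' @examples
#' ctrl <- randomControls(22, seed = 1)
#' Biostrings::width(slSequences(ctrl))
#' @export
randomControls <- function(length, seed, count = 10L) {
  if (length < 1L) stop("control length must be >= 1")
  if (count < 1L) stop("count must be >= 1")
  seqs <- with_seed(seed, {
    vapply(seq_len(count), function(i) random_dna(length), character(1))
  })
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- paste0("random_", seq_len(count))
  new("RandomControlSet", sequences = dna, seed = as.integer(seed))
}
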