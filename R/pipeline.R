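#' Run the SL detection workflow
#'
#' End-to-end SL detection: extract 5' soft-clipped candidates from the
#' alignments, score each candidate against the SL references and the
#' random controls, build the cumulative score curves, derive the dynamic
#' cutoff and promote reads above it to high confidence. Writes a per-read
#' TSV, the curve TSV and a summary JSON with the category tallies and all
#' effective parameters. When no cutoff can be established (e.g. data from
#' a species without SLs) the run completes with zero high-confidence reads
#' and a warning.
#'
#' @param alignments BAM/SAM path or \link[GenomicAlignments]{GAlignments}.
#' @param refs An \linkS4class{SLReferenceSet} or path to the SL FASTA.
#' @param outdir Output directory; NULL suppresses file output.
#' @param fold Dynamic cutoff fold factor (default 4).
#' @param minClip Minimum 5' clip length (default 5).
#' @param seed Seed for the random control set (default 1).
#' @param params \code{\link{scoringParams}}.
#' @param mode Library type, \code{"rna"} or \code{"cdna"}; extraction and
#'   scoring rely on the alignment strand and are identical in both modes
#'   (recorded in the summary for provenance).
#' @return A list: \code{calls} (scored, promoted read table),
#'   \code{curve} (\linkS4class{CutoffCurve} with cutoff),
#'   \code{cutoff}, \code{tally} (counts of other/candidate/potential/
#'   high-confidence), \code{alignments}, and \code{files}.
#' @export
runDetect <- function(alignments, refs, outdir = NULL, fold = 4,
                      minClip = 5L, seed = 1L,
                      params = scoringParams(), mode = c("rna", "cdna")) {
  mode <- match.arg(mode)
  if (is.character(refs)) refs <- loadSLReferences(refs)
  controls <- randomControls(controlLength(refs), seed = seed)
  ex <- extractCandidates(alignments, minClip = minClip)
  if (nrow(as.data.frame(ex$candidates)) == 0L)
    stop("no candidate reads with a 5' clip >= ", minClip, " nt")
  calls <- scoreReads(ex$candidates, refs, controls, params)
  curve <- computeCutoff(buildCutoffCurve(calls, fold = fold))
  calls <- selectHighConfidence(calls, curve)
  tally <- c(other = unname(ex$tally["other"]),
             candidate = sum(calls$category == "candidate"),
             potential_SL = sum(calls$category == "potential_SL"),
             high_confidence_SL = sum(calls$category == "high_confidence_SL"))
  files <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files$reads_tsv <- file.path(outdir, "sl_reads.tsv")
    df <- as.data.frame(calls)
    utils::write.table(
      df[, c("read_id", "clip_len", "sw_score", "sl_score", "sl_label",
             "category")],
      files$reads_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    files$curve_tsv <- file.path(outdir, "cutoff_curve.tsv")
    utils::write.table(as.data.frame(curve), files$curve_tsv, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$summary_json <- file.path(outdir, "detect_summary.json")
    jsonlite::write_json(
      list(mode = mode, fold = fold, min_clip = minClip,
           random_seed = seed, control_length = controlLength(refs),
           cutoff = if (is.na(curve@cutoff)) NULL else curve@cutoff,
           tally = as.list(tally)),
      files$summary_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(calls = calls, curve = curve, cutoff = curve@cutoff, tally = tally,
       alignments = ex$alignments, files = files)
}

#' Run the operon prediction workflow
#'
#' Assigns reads to genes (one-third symmetric exon overlap), aggregates
#' high-confidence SL1/SL2 evidence per gene (with fusion-read
#' propagation), classifies upstream/downstream/both roles, groups genes
#' into promoter-span clusters and calls operons from the role pattern and
#' the downstream read support, plus the fusion-read rule. Writes the
#' operon GFF3 and a per-gene role TSV.
#'
#' @param detect Result of \code{\link{runDetect}}, or a list with
#'   \code{calls} and \code{alignments}.
#' @param annotation GFF3 path or output of
#'   \code{\link{readGeneAnnotation}}.
#' @param outdir Output directory; NULL suppresses file output.
#' @param span Gene grouping span in bp (default 5000).
#' @param minSupport Minimum SL2 reads per downstream gene (default 3).
#' @param fusionMinReads Minimum identical fusion reads for fusion
#'   evidence (default 4).
#' @return A list: \code{operons} (GRanges), \code{genes} (role table),
#'   \code{assignments}, and \code{files}.
#' @export
runOperon <- function(detect, annotation, outdir = NULL, span = 5000,
                      minSupport = 3L, fusionMinReads = 4L) {
  if (is.character(annotation)) annotation <- readGeneAnnotation(annotation)
  asn <- assignGenes(detect$alignments, annotation)
  summ <- propagateSLToGenes(asn, detect$calls, annotation)
  summ <- classifyGeneRoles(summ)
  clusters <- groupGenes(annotation, span = span)
  ops <- callOperons(clusters, summ, asn, annotation,
                     minSupport = minSupport,
                     fusionMinReads = fusionMinReads)
  files <- list()
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files$operons_gff <- file.path(outdir, "operons.gff3")
    writeOperonsGFF(ops, files$operons_gff)
    files$genes_tsv <- file.path(outdir, "gene_roles.tsv")
    utils::write.table(summ, files$genes_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  message(sprintf(
    "genes: %d upstream, %d downstream, %d both, %d without SL; %d operons",
    sum(summ$role == "upstream"), sum(summ$role == "downstream"),
    sum(summ$role == "both"), sum(summ$role == "none"), length(ops)))
  list(operons = ops, genes = summ, assignments = asn, files = files)
}
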