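#' Read a gene annotation from GFF3
#'
#' Imports \code{gene} and \code{exon} features from a GFF3 file and links
#' exons to their gene via Parent attributes (directly, or through an
#' intermediate mRNA/transcript feature). Genes without annotated exons are
#' treated as single-exon genes spanning their full extent.
#'
#' @param gff Path to a GFF3 annotation.
#' @return A list with \code{genes}, a \link[GenomicRanges]{GRanges} with
#'   metadata column \code{gene_id}, and \code{exons}, a
#'   \link[GenomicRanges]{GRangesList} of (reduced) exons indexed by
#'   gene_id.
#' @export
readGeneAnnotation <- function(gff) {
  if (!file.exists(gff)) stop("annotation not readable: ", gff)
  gr <- rtracklayer::import(gff, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", gff)
  gid <- genes$ID
  if (is.null(gid) || anyNA(gid)) stop("gene features must carry ID")
  genes$gene_id <- gid
  # map transcript-level IDs to their gene
  tx <- gr[gr$type %in% c("mRNA", "transcript")]
  tx2gene <- character(0)
  if (length(tx)) {
    par <- as.character(S4Vectors::unstrsplit(tx$Parent, ","))
    tx2gene <- stats::setNames(par, tx$ID)
  }
  ex <- gr[gr$type == "exon"]
  exons <- GenomicRanges::GRangesList(lapply(
    stats::setNames(seq_along(genes), gid), function(i)
      GenomicRanges::granges(genes[i])))
  if (length(ex)) {
    par <- as.character(S4Vectors::unstrsplit(ex$Parent, ","))
    owner <- ifelse(par %in% names(tx2gene), tx2gene[par], par)
    keep <- owner %in% gid
    ex <- ex[keep]; owner <- owner[keep]
    got <- S4Vectors::split(GenomicRanges::granges(ex),
                            factor(owner, levels = gid))
    has <- lengths(got) > 0L
    exons[has] <- GenomicRanges::reduce(got[has])
  }
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(gene_id = gid)
  list(genes = genes, exons = exons)
}

#' Assign reads to genes by exonic overlap
#'
#' A gene is assigned to a read when the exonic intersection covers at least
#' one-third of the read's exonic span \emph{and} at least one-third of the
#' gene's exonic span (both fractions must reach 1/3; this symmetric rule
#' keeps short reads from claiming long genes and vice versa). Only
#' same-chromosome, same-strand genes are considered. Reads assigned two or
#' more genes are fusion reads: single molecules spanning adjacent genes,
#' the signature of a partially processed polycistronic transcript. Genes
#' are reported in the read's 5'->3' transcription order.
#'
#' @param alignments A \link[GenomicAlignments]{GAlignments} (e.g. from
#'   \code{\link{extractCandidates}}) or BAM/SAM path.
#' @param annotation Output of \code{\link{readGeneAnnotation}}.
#' @return A \link[S4Vectors]{DataFrame} with \code{read_id}, \code{genes}
#'   (a CharacterList in transcription order) and \code{is_fusion}; reads
#'   matching no gene are omitted.
#' @export
assignGenes <- function(alignments, annotation) {
  galn <- if (is.character(alignments)) readSplicedAlignments(alignments)
          else alignments
  blocks <- GenomicAlignments::grglist(galn)  # exon blocks, N-split
  exons <- annotation$exons
  genes <- annotation$genes
  gene_len <- sum(GenomicRanges::width(exons))
  read_len <- sum(GenomicRanges::width(GenomicRanges::reduce(blocks)))
  ov <- GenomicRanges::findOverlaps(blocks, exons)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  keep_pair <- logical(length(qh))
  for (k in seq_along(qh)) {
    O <- sum(GenomicRanges::width(GenomicRanges::intersect(
      blocks[[qh[k]]], exons[[sh[k]]])))
    keep_pair[k] <- (3 * O >= read_len[qh[k]]) && (3 * O >= gene_len[sh[k]])
  }
  qh <- qh[keep_pair]; sh <- sh[keep_pair]
  if (length(qh) == 0L) {
    return(S4Vectors::DataFrame(
      read_id = character(0),
      genes = IRanges::CharacterList(),
      is_fusion = logical(0)))
  }
  ids <- names(galn)
  res <- lapply(split(sh, qh), function(gi) {
    g <- genes[gi]
    o <- if (as.character(GenomicRanges::strand(g))[1] == "-")
      order(GenomicRanges::end(g), decreasing = TRUE)
    else order(GenomicRanges::start(g))
    g$gene_id[o]
  })
  ridx <- as.integer(names(res))
  S4Vectors::DataFrame(
    read_id = ids[ridx],
    genes = IRanges::CharacterList(unname(res)),
    is_fusion = lengths(res) >= 2L
  )
}

#' Aggregate SL-type evidence per gene
#'
#' Counts, per gene, the high-confidence SL1-type and SL2-type reads
#' assigned to it (SL2 variants are pooled; \code{SL2_unknown} counts as
#' SL2; \code{SL_unknown} reads are excluded since their class is
#' ambiguous), plus the total assigned reads of any SL status. For fusion
#' reads the SL type is credited to the first gene in transcription order
#' and to any downstream gene whose transcription-direction start lies
#' within half the first gene's length of the first gene's start -- the SL
#' of a polycistronic molecule marks the promoter-proximal genes, not
#' everything the read happens to span.
#'
#' @param assignments Output of \code{\link{assignGenes}}.
#' @param calls Scored read table after \code{\link{selectHighConfidence}}.
#' @param annotation Output of \code{\link{readGeneAnnotation}}.
#' @return A data.frame with \code{gene_id}, \code{n_SL1}, \code{n_SL2},
#'   \code{n_total} covering every annotated gene.
#' @export
propagateSLToGenes <- function(assignments, calls, annotation) {
  genes <- annotation$genes
  gid <- genes$gene_id
  tab <- data.frame(gene_id = gid,
                    n_SL1 = 0L, n_SL2 = 0L, n_total = 0L,
                    stringsAsFactors = FALSE)
  rownames(tab) <- gid
  gstart <- stats::setNames(GenomicRanges::start(genes), gid)
  gend <- stats::setNames(GenomicRanges::end(genes), gid)
  gstrand <- stats::setNames(as.character(GenomicRanges::strand(genes)), gid)
  glen <- stats::setNames(GenomicRanges::width(genes), gid)
  calls <- as.data.frame(calls)
  hc <- calls[calls$category == "high_confidence_SL" &
                !is.na(calls$sl_class), , drop = FALSE]
  cls <- stats::setNames(hc$sl_class, hc$read_id)
  asn <- as.data.frame(assignments)
  gl <- assignments$genes
  for (i in seq_len(nrow(asn))) {
    gs <- gl[[i]]
    tab[gs, "n_total"] <- tab[gs, "n_total"] + 1L
    rc <- cls[asn$read_id[i]]
    if (is.na(rc)) next
    col <- if (rc == "SL1") "n_SL1" else "n_SL2"
    first <- gs[1L]
    credit <- first
    if (length(gs) > 1L) {
      half <- glen[first] / 2
      for (g in gs[-1L]) {
        d <- if (gstrand[first] == "-") gend[first] - gend[g]
             else gstart[g] - gstart[first]
        if (d <= half) credit <- c(credit, g)
      }
    }
    tab[credit, col] <- tab[credit, col] + 1L
  }
  tab
}

#' Classify operon roles of genes
#'
#' A gene with more SL1-type than SL2-type reads is an \code{upstream}
#' (operon-initial or monocistronic trans-spliced) gene; otherwise it is
#' \code{downstream}. Independently of that majority, a gene whose SL2-type
#' reads exceed one-fourth of its total assigned reads \emph{and} number
#' more than five takes the dual role \code{both} -- it can terminate one
#' operon segment and start another. Genes with no SL-typed reads get role
#' \code{none}.
#'
#' @param summary Output of \code{\link{propagateSLToGenes}}.
#' @return The summary with a \code{role} column added.
#' @export
classifyGeneRoles <- function(summary) {
  role <- character(nrow(summary))
  for (i in seq_len(nrow(summary))) {
    s1 <- summary$n_SL1[i]; s2 <- summary$n_SL2[i]
    tot <- summary$n_total[i]
    role[i] <- if (s1 == 0L && s2 == 0L) "none"
    else if (tot > 0L && s2 > tot / 4 && s2 > 5L) "both"
    else if (s1 > s2) "upstream"
    else "downstream"
  }
  summary$role <- role
  summary
}

#' Group genes into candidate operon clusters
#'
#' Consecutive genes on the same chromosome and strand are clustered when
#' the gap between the upstream gene's end and the downstream gene's start
#' is at most \code{span} bp (default 5000, a typical upper bound on the
#' promoter span of an operon). Singleton clusters are allowed; opposite
#' strands never share a cluster, since operons are co-directional.
#'
#' @param annotation Output of \code{\link{readGeneAnnotation}} (or a
#'   GRanges of genes with \code{gene_id}).
#' @param span Maximum intergenic gap in bp (default 5000).
#' @return A list of character vectors of gene ids, each in transcription
#'   order.
#' @export
groupGenes <- function(annotation, span = 5000) {
  genes <- if (is.list(annotation)) annotation$genes else annotation
  df <- data.frame(gene_id = genes$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(genes)),
                   strand = as.character(GenomicRanges::strand(genes)),
                   start = GenomicRanges::start(genes),
                   end = GenomicRanges::end(genes),
                   stringsAsFactors = FALSE)
  out <- list()
  for (key in split(seq_len(nrow(df)),
                    paste(df$chrom, df$strand))) {
    sub <- df[key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    gap_new <- c(TRUE, sub$start[-1L] - sub$end[-nrow(sub)] > span)
    cl <- cumsum(gap_new)
    for (ids in split(sub$gene_id, cl)) {
      if (identical(unique(sub$strand), "-")) ids <- rev(ids)
      out[[length(out) + 1L]] <- ids
    }
  }
  out
}

#' Call operons from gene roles and read support
#'
#' Within each cluster (genes in transcription order) the maximal runs in
#' which the first gene has role \code{upstream}/\code{both} and every
#' subsequent gene has role \code{downstream}/\code{both} are operon
#' candidates; a candidate is confirmed when every downstream gene is
#' supported by at least \code{minSupport} SL2-type reads. Independently,
#' any multi-gene combination observed in more than three fusion reads
#' (\code{>= fusionMinReads}) that contains an SL2-classified
#' (downstream/both) gene is called an operon with \code{fusion} evidence;
#' combinations already called by adjacency are not duplicated.
#'
#' @param clusters Output of \code{\link{groupGenes}}.
#' @param summary Role-annotated gene table from
#'   \code{\link{classifyGeneRoles}}.
#' @param assignments Output of \code{\link{assignGenes}} (for fusion
#'   evidence); may be NULL to skip the fusion rule.
#' @param annotation Output of \code{\link{readGeneAnnotation}}.
#' @param minSupport Minimum SL2-type reads per downstream gene (default 3).
#' @param fusionMinReads Minimum identical fusion reads for the fusion rule
#'   (default 4, i.e. "more than three").
#' @return A \link[GenomicRanges]{GRanges} of operon calls with metadata
#'   columns \code{operon_id}, \code{gene_ids} (CharacterList),
#'   \code{downstream_support} and \code{evidence}.
#' @export
callOperons <- function(clusters, summary, assignments, annotation,
                        minSupport = 3L, fusionMinReads = 4L) {
  genes <- annotation$genes
  gid <- genes$gene_id
  role <- stats::setNames(summary$role, summary$gene_id)
  nSL2 <- stats::setNames(summary$n_SL2, summary$gene_id)
  ops <- list()   # each: list(genes=, support=, evidence=)
  for (cl in clusters) {
    n <- length(cl)
    i <- 1L
    while (i < n) {
      if (role[cl[i]] %in% c("upstream", "both")) {
        j <- i + 1L
        while (j <= n && role[cl[j]] %in% c("downstream", "both")) j <- j + 1L
        if (j - i >= 2L) {
          run <- cl[i:(j - 1L)]
          down <- run[-1L]
          if (all(nSL2[down] >= minSupport)) {
            ops[[length(ops) + 1L]] <- list(
              genes = run, support = sum(nSL2[down]),
              evidence = "adjacency")
          }
          i <- j
        } else i <- i + 1L
      } else i <- i + 1L
    }
  }
  if (!is.null(assignments) && nrow(as.data.frame(assignments)) > 0L) {
    fus <- assignments[assignments$is_fusion, , drop = FALSE]
    if (nrow(as.data.frame(fus)) > 0L) {
      keys <- vapply(as.list(fus$genes), paste, character(1), collapse = "\t")
      cnt <- table(keys)
      seen <- vapply(ops, function(o) paste(o$genes, collapse = "\t"),
                     character(1))
      for (k in names(cnt)) {
        if (cnt[[k]] < fusionMinReads) next
        gs <- strsplit(k, "\t", fixed = TRUE)[[1L]]
        if (!any(role[gs] %in% c("downstream", "both"))) next
        if (k %in% seen) next
        ops[[length(ops) + 1L]] <- list(genes = gs,
                                        support = as.integer(cnt[[k]]),
                                        evidence = "fusion")
      }
    }
  }
  if (length(ops) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      operon_id = character(0), gene_ids = IRanges::CharacterList(),
      downstream_support = integer(0), evidence = character(0))
    return(gr)
  }
  idx <- match(unlist(lapply(ops, function(o) o$genes[1L])), gid)
  gr <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(genes)[idx],
    ranges = IRanges::IRanges(
      start = vapply(ops, function(o)
        min(GenomicRanges::start(genes)[match(o$genes, gid)]), numeric(1)),
      end = vapply(ops, function(o)
        max(GenomicRanges::end(genes)[match(o$genes, gid)]), numeric(1))),
    strand = GenomicRanges::strand(genes)[idx])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    operon_id = sprintf("operon_%04d", seq_along(ops)),
    gene_ids = IRanges::CharacterList(lapply(ops, `[[`, "genes")),
    downstream_support = vapply(ops, function(o) as.integer(o$support),
                                integer(1)),
    evidence = vapply(ops, `[[`, character(1), "evidence"))
  gr[order(as.character(GenomicRanges::seqnames(gr)),
           GenomicRanges::start(gr))]
}

#' Write operon calls to GFF3
#'
#' One \code{operon} feature per call, 1-based inclusive coordinates,
#' attributes carrying the ordered gene list, the downstream read support
#' and the evidence type. Output is byte-deterministic for identical calls.
#'
#' @param calls Operon GRanges from \code{\link{callOperons}}.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
writeOperonsGFF <- function(calls, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(calls)) {
    genes <- vapply(as.list(calls$gene_ids), paste, character(1),
                    collapse = ",")
    lines <- sprintf(
      "%s\tSLcallR\toperon\t%d\t%d\t.\t%s\t.\tID=%s;genes=%s;downstream_support=%d;evidence=%s",
      as.character(GenomicRanges::seqnames(calls)),
      GenomicRanges::start(calls), GenomicRanges::end(calls),
      as.character(GenomicRanges::strand(calls)),
      calls$operon_id, genes, calls$downstream_support, calls$evidence)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read operon calls from GFF3
#'
#' Parses \code{operon} features written by \code{\link{writeOperonsGFF}}
#' (or any GFF3 whose operon features carry a \code{genes} attribute with a
#' comma-separated ordered gene list).
#'
#' @param path GFF3 file path.
#' @return A GRanges in the layout of \code{\link{callOperons}}.
#' @export
readOperonsGFF <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  ln <- ln[vapply(strsplit(ln, "\t"), function(f) f[3] == "operon",
                  logical(1))]
  if (length(ln) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      operon_id = character(0), gene_ids = IRanges::CharacterList(),
      downstream_support = integer(0), evidence = character(0))
    return(gr)
  }
  f <- do.call(rbind, strsplit(ln, "\t"))
  attr1 <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))
    vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_,
           character(1))
  }
  support <- suppressWarnings(as.integer(attr1(f[, 9], "downstream_support")))
  evid <- attr1(f[, 9], "evidence")
  gr <- GenomicRanges::GRanges(
    seqnames = f[, 1],
    ranges = IRanges::IRanges(start = as.integer(f[, 4]),
                              end = as.integer(f[, 5])),
    strand = f[, 7])
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    operon_id = attr1(f[, 9], "ID"),
    gene_ids = IRanges::CharacterList(
      strsplit(attr1(f[, 9], "genes"), ",", fixed = TRUE)),
    downstream_support = ifelse(is.na(support), 0L, support),
    evidence = ifelse(is.na(evid), "adjacency", evid))
  gr
}

#' Evaluate predicted operons against a reference annotation
#'
#' Gene-level metrics treat each operon-member gene as a unit: precision is
#' the fraction of predicted operon genes present in the reference operon
#' gene set, recall the fraction of reference operon genes recovered.
#' Structure-level metrics require a predicted operon's ordered gene list to
#' equal a reference operon's exactly (fully concordant structures).
#'
#' @param predicted Operon GRanges (\code{\link{callOperons}}) or GFF3 path.
#' @param reference Reference operon GRanges or GFF3 path.
#' @return A named list: \code{gene_precision}, \code{gene_recall},
#'   \code{structure_precision}, \code{structure_recall}. Empty predicted
#'   set yields NaN precisions with a warning.
#' @export
evaluateOperons <- function(predicted, reference) {
  if (is.character(predicted)) predicted <- readOperonsGFF(predicted)
  if (is.character(reference)) reference <- readOperonsGFF(reference)
  pg <- unique(unlist(as.list(predicted$gene_ids)))
  rg <- unique(unlist(as.list(reference$gene_ids)))
  if (length(pg) == 0L)
    warning("empty predicted operon set; precision undefined")
  pkey <- vapply(as.list(predicted$gene_ids), paste, character(1),
                 collapse = "\t")
  rkey <- vapply(as.list(reference$gene_ids), paste, character(1),
                 collapse = "\t")
  list(
    gene_precision = length(intersect(pg, rg)) / length(pg),
    gene_recall = length(intersect(pg, rg)) / length(rg),
    structure_precision = sum(pkey %in% rkey) / length(pkey),
    structure_recall = sum(rkey %in% pkey) / length(rkey)
  )
}
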