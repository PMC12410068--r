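#' Simulation configuration
#'
#' Parameters of the synthetic dataset generator. The defaults describe a
#' compact but realistic direct-RNA experiment on a trans-splicing
#' nematode-like genome: 20 operons of 3 genes (60 genes), 10 reads per
#' gene, 3\% substitutions and 1\% insertions/deletions per base
#' (nanopore-like), and a 5' truncation model -- a fixed offset plus a
#' geometric tail -- that leaves a modal SL residue of 9 nt and most
#' residues between 5 and 9 nt, as observed for direct RNA reads where the
#' 5' end is sequenced last and often lost.
#'
#' @param seed Integer RNG seed; the whole dataset is a deterministic
#'   function of it.
#' @param nGenes Total genes; genes beyond \code{nOperons * genesPerOperon}
#'   are monocistronic singletons.
#' @param nOperons Number of operons.
#' @param genesPerOperon Genes per operon.
#' @param geneLenRange Gene length range in bp.
#' @param intergenicGapRange Gap range between genes inside one operon, bp;
#'   must stay within the operon grouping span.
#' @param unitSpacing Spacing between operons/singleton units, bp; must
#'   exceed the grouping span so distinct units never merge.
#' @param readsPerGene Reads simulated per gene.
#' @param noneProb Probability a read carries no SL at all.
#' @param sl2Weights Optional named weights over SL2 variant names for
#'   downstream-gene reads; default uniform.
#' @param truncationOffset,truncationProb 5' loss is
#'   \code{offset + rgeom(truncationProb)} bases (SL bases are lost first);
#'   \code{truncationProb <= 0} disables truncation entirely.
#' @param subRate,insRate,delRate Per-base error probabilities.
#' @param fusionReadRate Probability a downstream-gene read extends into the
#'   preceding gene (a partially processed polycistronic molecule).
#' @param junkClipProb Probability that a read without an SL still carries a
#'   short non-SL 5' clip (drawn uniformly from \code{junkClipRange} nt of
#'   random sequence), mimicking transcription start site scatter and
#'   unannotated 5' ends seen in real alignments.
#' @param junkClipRange Length range of such junk clips, nt.
#' @param minusStrandFrac Fraction of units placed on the minus strand.
#' @param chromName Chromosome name of the synthetic genome.
#' @return A list of class \code{"sl_sim_config"}.
#' @export
simulationConfig <- function(seed = 1L,
                             nGenes = 60L, nOperons = 20L,
                             genesPerOperon = 3L,
                             geneLenRange = c(1000L, 2000L),
                             intergenicGapRange = c(200L, 800L),
                             unitSpacing = 8000L,
                             readsPerGene = 10L,
                             noneProb = 0.1,
                             sl2Weights = NULL,
                             truncationOffset = 13L,
                             truncationProb = 0.3,
                             subRate = 0.03, insRate = 0.01,
                             delRate = 0.01,
                             fusionReadRate = 0.1,
                             junkClipProb = 0.3,
                             junkClipRange = c(5L, 12L),
                             minusStrandFrac = 0.4,
                             chromName = "chrS") {
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              nOperons = as.integer(nOperons),
              genesPerOperon = as.integer(genesPerOperon),
              geneLenRange = as.integer(geneLenRange),
              intergenicGapRange = as.integer(intergenicGapRange),
              unitSpacing = as.integer(unitSpacing),
              readsPerGene = as.integer(readsPerGene),
              noneProb = noneProb, sl2Weights = sl2Weights,
              truncationOffset = as.integer(truncationOffset),
              truncationProb = truncationProb,
              subRate = subRate, insRate = insRate, delRate = delRate,
              fusionReadRate = fusionReadRate,
              junkClipProb = junkClipProb,
              junkClipRange = as.integer(junkClipRange),
              minusStrandFrac = minusStrandFrac,
              chromName = chromName)
  rates <- c(cfg$noneProb, cfg$subRate, cfg$insRate, cfg$delRate,
             cfg$fusionReadRate, cfg$junkClipProb, cfg$minusStrandFrac)
  if (any(rates < 0 | rates > 1))
    stop("probabilities/rates must lie in [0, 1]")
  if (cfg$nGenes < cfg$nOperons * cfg$genesPerOperon)
    stop("nGenes smaller than the genes required by the operons")
  if (cfg$genesPerOperon < 2L) stop("operons need at least two genes")
  if (diff(cfg$geneLenRange) < 0L || cfg$geneLenRange[1] < 200L)
    stop("invalid geneLenRange")
  if (cfg$intergenicGapRange[1] < 1L ||
      diff(cfg$intergenicGapRange) < 0L)
    stop("invalid intergenicGapRange")
  structure(cfg, class = "sl_sim_config")
}

# apply substitution/indel noise to a bare sequence (used for the clip,
# which has no CIGAR footprint); returns possibly empty string
.mutate_seq <- function(seq, sub, ins, del) {
  if (!nzchar(seq)) return("")
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  keep <- stats::runif(n) >= del
  do_sub <- stats::runif(n) < sub & keep
  if (any(do_sub))
    b[do_sub] <- vapply(b[do_sub], function(x)
      sample(setdiff(DNA_BASES4, x), 1L), character(1))
  do_ins <- stats::runif(n) < ins & keep
  out <- character(0)
  for (i in seq_len(n)) {
    if (keep[i]) out <- c(out, b[i])
    if (do_ins[i]) out <- c(out, sample(DNA_BASES4, 1L))
  }
  paste(out, collapse = "")
}

# one aligned gene-body walk: given exon segments (transcription order,
# each c(gstart, gend)), the strand and the genome, emit the CIGAR runs in
# transcription order plus the read bases, with per-base errors
.walk_segments <- function(segs, strand, genome_chars,
                           sub, ins, del) {
  runs_op <- character(0); runs_len <- integer(0)
  bases <- character(0)
  nseg <- length(segs)
  for (si in seq_len(nseg)) {
    gs <- segs[[si]][1]; ge <- segs[[si]][2]
    ref <- genome_chars[gs:ge]
    if (strand == "-") ref <- rev(chartr("ACGT", "TGCA", ref))
    k <- length(ref)
    dd <- stats::runif(k) < del
    ss <- stats::runif(k) < sub
    ii <- stats::runif(k) < ins
    # keep the alignment boundaries clean: terminal bases are matches and
    # the final column is never an insertion
    if (si == 1L) { dd[1L] <- FALSE; }
    if (si == nseg) { dd[k] <- FALSE; ii[k] <- FALSE }
    ii <- ii & !dd
    rb <- ref
    subi <- which(ss & !dd)
    if (length(subi))
      rb[subi] <- vapply(rb[subi], function(x)
        sample(setdiff(DNA_BASES4, x), 1L), character(1))
    op1 <- ifelse(dd, "D", "M")
    insPos <- which(ii)
    allops <- c(op1, rep("I", length(insPos)))
    allb <- c(ifelse(dd, NA_character_, rb),
              sample(DNA_BASES4, length(insPos), replace = TRUE))
    ord <- order(c(seq_len(k), insPos + 0.5))
    allops <- allops[ord]; allb <- allb[ord]
    r <- rle(allops)
    runs_op <- c(runs_op, r$values)
    runs_len <- c(runs_len, r$lengths)
    bases <- c(bases, allb[!is.na(allb)])
    if (si < nseg) {
      nxt <- segs[[si + 1L]]
      gap <- if (strand == "-") gs - nxt[2] - 1L else nxt[1] - ge - 1L
      runs_op <- c(runs_op, "N")
      runs_len <- c(runs_len, as.integer(gap))
    }
  }
  list(op = runs_op, len = runs_len, read = paste(bases, collapse = ""))
}

#' Simulate a trans-splicing long-read dataset
#'
#' Generates, deterministically from the config seed, a synthetic genome,
#' a gene/operon annotation, trans-spliced long reads with 5' SL residues,
#' their alignments with exact soft clips, a per-read truth table and the
#' true operon structures. First genes of operons and singleton genes
#' receive SL1; downstream operon genes receive SL2 variants. Each read
#' loses a truncation-model number of 5' bases (SL first), then nanopore-
#' like substitution/indel noise is applied; the SAM soft clip is exactly
#' the surviving, noise-bearing SL residue. A configurable fraction of
#' downstream-gene reads are fusion reads also spanning the preceding gene.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param refs An \linkS4class{SLReferenceSet} providing the SL sequences.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the output paths (\code{genome},
#'   \code{annotation}, \code{reads}, \code{alignments}, \code{truth},
#'   \code{operons}) and the truth \code{data.frame}.
#' @export
simulateDataset <- function(config, refs, outdir) {
  stopifnot(inherits(config, "sl_sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  slseq <- as.character(slSequences(refs))
  slcat <- slCategories(refs)
  sl2names <- names(slcat)[slcat == "SL2"]
  sl1names <- names(slcat)[slcat == "SL1"]
  if (length(sl1names) == 0L) stop("reference set lacks an SL1 sequence")
  w2 <- config$sl2Weights
  if (is.null(w2)) w2 <- stats::setNames(rep(1, length(sl2names)), sl2names)
  w2 <- w2 / sum(w2)
  with_seed(config$seed, {
    ## ---- gene layout -------------------------------------------------
    nSingle <- config$nGenes - config$nOperons * config$genesPerOperon
    unit_kind <- sample(c(rep("operon", config$nOperons),
                          rep("single", nSingle)))
    genes <- list()
    pos <- 1001L
    gidx <- 0L
    for (u in seq_along(unit_kind)) {
      ngu <- if (unit_kind[u] == "operon") config$genesPerOperon else 1L
      ustrand <- if (stats::runif(1) < config$minusStrandFrac) "-" else "+"
      unit_ids <- character(ngu)
      for (g in seq_len(ngu)) {
        gidx <- gidx + 1L
        len <- sample(config$geneLenRange[1]:config$geneLenRange[2], 1L)
        e1 <- as.integer(floor(len * 0.4))
        intr <- as.integer(min(300L, floor(len * 0.2)))
        gene <- list(
          gene_id = sprintf("gene_%03d", gidx),
          chrom = config$chromName, strand = ustrand,
          start = pos, end = pos + len - 1L,
          exons = list(c(pos, pos + e1 - 1L),
                       c(pos + e1 + intr, pos + len - 1L)),
          unit = u,
          pos_in_unit = g, unit_kind = unit_kind[u], unit_size = ngu)
        genes[[gidx]] <- gene
        unit_ids[g] <- gene$gene_id
        pos <- pos + len - 1L +
          sample(config$intergenicGapRange[1]:config$intergenicGapRange[2],
                 1L)
      }
      pos <- pos + config$unitSpacing
    }
    glen <- pos + 1000L
    genome <- Biostrings::DNAStringSet(random_dna(glen))
    names(genome) <- config$chromName
    genome_chars <- strsplit(as.character(genome[[1]]), "")[[1]]

    ## genes within one unit in genomic order; transcription order for "-"
    ## units is the reverse
    by_unit <- split(genes, vapply(genes, `[[`, integer(1), "unit"))
    tx_order <- lapply(by_unit, function(gg) {
      if (gg[[1]]$strand == "-") rev(gg) else gg
    })

    ## ---- annotation + truth operons ----------------------------------
    gff <- c("##gff-version 3")
    for (g in genes) {
      at_g <- sprintf("ID=%s", g$gene_id)
      gff <- c(gff, sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\t%s",
                            g$chrom, g$start, g$end, g$strand, at_g))
      tid <- paste0(g$gene_id, ".t1")
      gff <- c(gff, sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                            g$chrom, g$start, g$end, g$strand, tid,
                            g$gene_id))
      for (e in seq_along(g$exons)) {
        ex <- g$exons[[e]]
        gff <- c(gff, sprintf(
          "%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
          g$chrom, ex[1], ex[2], g$strand, tid, e, tid))
      }
    }
    f_ann <- file.path(outdir, "annotation.gff3")
    writeLines(gff, f_ann)

    op_units <- tx_order[vapply(by_unit, function(gg)
      gg[[1]]$unit_kind == "operon", logical(1))]
    op_gr <- GenomicRanges::GRanges(
      seqnames = config$chromName,
      ranges = IRanges::IRanges(
        start = vapply(op_units, function(gg)
          min(vapply(gg, `[[`, integer(1), "start")), integer(1)),
        end = vapply(op_units, function(gg)
          max(vapply(gg, `[[`, integer(1), "end")), integer(1))),
      strand = vapply(op_units, function(gg) gg[[1]]$strand, character(1)))
    S4Vectors::mcols(op_gr) <- S4Vectors::DataFrame(
      operon_id = sprintf("true_operon_%03d", seq_along(op_units)),
      gene_ids = IRanges::CharacterList(lapply(op_units, function(gg)
        vapply(gg, `[[`, character(1), "gene_id"))),
      downstream_support = rep(0L, length(op_units)),
      evidence = rep("truth", length(op_units)))
    op_gr <- op_gr[order(GenomicRanges::start(op_gr))]
    f_ops <- file.path(outdir, "operons_truth.gff3")
    writeOperonsGFF(op_gr, f_ops)

    ## ---- reads -------------------------------------------------------
    sam <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", config$chromName, glen))
    fastq <- character(0)
    truth <- list()
    ridx <- 0L
    for (ut in tx_order) {
      for (k in seq_along(ut)) {
        gene <- ut[[k]]
        downstream <- gene$unit_kind == "operon" && k > 1L
        for (r in seq_len(config$readsPerGene)) {
          ridx <- ridx + 1L
          rid <- sprintf("read_%05d", ridx)
          fusion <- downstream &&
            stats::runif(1) < config$fusionReadRate
          span <- if (fusion) ut[k - 1L:0] else ut[k]
          first <- span[[1L]]
          first_down <- first$unit_kind == "operon" &&
            !identical(first$gene_id, ut[[1L]]$gene_id)
          # SL class follows the first spanned gene: operon-first and
          # singleton genes carry SL1, downstream genes SL2
          if (stats::runif(1) < config$noneProb) {
            sl_name <- "none"
          } else if (first_down) {
            sl_name <- sample(names(w2), 1L, prob = w2)
          } else {
            sl_name <- sl1names[1L]
          }
          sl_s <- if (sl_name == "none") "" else slseq[[sl_name]]
          # segments: exons of spanned genes in transcription order
          segs <- list()
          for (g in span) {
            ex <- g$exons
            if (g$strand == "-") ex <- rev(ex)
            segs <- c(segs, ex)
          }
          tlen <- sum(vapply(segs, function(s) s[2] - s[1] + 1L,
                             integer(1)))
          loss <- 0L
          if (config$truncationProb > 0)
            loss <- config$truncationOffset +
              stats::rgeom(1L, config$truncationProb)
          loss <- min(loss, nchar(sl_s) + tlen - 50L)
          residual <- max(0L, nchar(sl_s) - loss)
          extra <- max(0L, loss - nchar(sl_s))
          # trim extra bases off the transcription 5' end
          while (extra > 0L && length(segs)) {
            sl1 <- segs[[1L]][2] - segs[[1L]][1] + 1L
            if (extra >= sl1) { segs <- segs[-1L]; extra <- extra - sl1 }
            else {
              if (first$strand == "-") segs[[1L]][2] <-
                  segs[[1L]][2] - extra
              else segs[[1L]][1] <- segs[[1L]][1] + extra
              extra <- 0L
            }
          }
          clip0 <- if (residual > 0L)
            substr(sl_s, nchar(sl_s) - residual + 1L, nchar(sl_s)) else ""
          clip <- .mutate_seq(clip0, config$subRate, config$insRate,
                              config$delRate)
          if (sl_name == "none" && config$junkClipProb > 0 &&
              stats::runif(1) < config$junkClipProb) {
            clip <- random_dna(sample(
              config$junkClipRange[1]:config$junkClipRange[2], 1L))
          }
          wk <- .walk_segments(segs, first$strand, genome_chars,
                               config$subRate, config$insRate,
                               config$delRate)
          read_seq <- paste0(clip, wk$read)
          # CIGAR in genomic (left-to-right) order
          if (first$strand == "-") {
            op <- rev(wk$op); ln <- rev(wk$len)
            if (nchar(clip) > 0L) { op <- c(op, "S"); ln <- c(ln, nchar(clip)) }
            seq_sam <- revcomp_chr(read_seq)
            gpos <- min(vapply(segs, `[[`, integer(1), 1L))
            flag <- 16L
          } else {
            op <- wk$op; ln <- wk$len
            if (nchar(clip) > 0L) { op <- c("S", op); ln <- c(nchar(clip), ln) }
            seq_sam <- read_seq
            gpos <- segs[[1L]][1]
            flag <- 0L
          }
          cigar <- paste0(ln, op, collapse = "")
          sam <- c(sam, sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                                rid, flag, config$chromName, gpos, cigar,
                                seq_sam))
          fastq <- c(fastq, paste0("@", rid), read_seq, "+",
                     strrep("I", nchar(read_seq)))
          truth[[ridx]] <- data.frame(
            read_id = rid, true_sl = sl_name,
            true_class = if (sl_name == "none") "none"
                         else unname(slcat[sl_name]),
            residual_sl_len = residual,
            clip_seq = clip,
            genes = paste(vapply(span, `[[`, character(1), "gene_id"),
                          collapse = ","),
            is_fusion = fusion, stringsAsFactors = FALSE)
        }
      }
    }
    f_genome <- file.path(outdir, "genome.fasta")
    Biostrings::writeXStringSet(genome, f_genome)
    f_sam <- file.path(outdir, "alignments.sam")
    writeLines(sam, f_sam)
    f_fq <- file.path(outdir, "reads.fastq")
    writeLines(fastq, f_fq)
    truth_df <- do.call(rbind, truth)
    f_truth <- file.path(outdir, "truth.tsv")
    utils::write.table(truth_df, f_truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(list(genome = f_genome, annotation = f_ann,
                   reads = f_fq, alignments = f_sam,
                   truth_file = f_truth, operons = f_ops,
                   truth = truth_df))
  })
}
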