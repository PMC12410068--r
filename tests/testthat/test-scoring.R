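test_that("local alignment scores match simple cases and the reference DP", {
  expect_identical(smithWaterman("ACGT", "ACGT")$sw_score, 4)
  expect_identical(smithWaterman("ACGT", "AGGT")$sw_score, 2)
  expect_identical(smithWaterman("AAAA", "TTTT")$sw_score, 0)
  # a 1-base gap costs gapOpen + gapExtend = 2
  expect_identical(smithWaterman("ACGTACGT", "ACGTTACGT")$sw_score, 6)
  expect_error(smithWaterman("", "ACGT"))
  expect_error(smithWaterman("ACGT", "ACGN"))

  set.seed(101)
  for (i in 1:200) {
    q <- random_seq(sample(1:15, 1))
    r <- random_seq(sample(1:15, 1))
    expect_identical(smithWaterman(q, r)$sw_score, sw_score_oracle(q, r),
                     info = paste(q, r))
  }
})

test_that("alignment regions are consistent with the reported score", {
  set.seed(77)
  for (i in 1:50) {
    q <- random_seq(sample(5:15, 1))
    r <- random_seq(sample(5:20, 1))
    a <- smithWaterman(q, r)
    if (a$sw_score == 0) next
    # rescore the aligned columns independently
    st <- a$status
    qb <- strsplit(q, "")[[1]][(a$query_start + 1):a$query_end]
    rb <- strsplit(r, "")[[1]][(a$ref_start + 1):a$ref_end]
    sc <- 0; qi <- 0; ri <- 0; k <- 1
    while (k <= length(st)) {
      if (st[k] %in% c(0, 1)) {
        qi <- qi + 1; ri <- ri + 1
        sc <- sc + if (qb[qi] == rb[ri]) 1 else -1
        k <- k + 1
      } else {
        gap <- st[k]
        len <- 0
        while (k <= length(st) && st[k] == gap) { len <- len + 1; k <- k + 1 }
        if (gap == 2) qi <- qi + len else ri <- ri + len
        sc <- sc - 1 - len
      }
    }
    expect_equal(qi, length(qb))
    expect_equal(ri, length(rb))
    expect_equal(sc, a$sw_score, info = paste(q, r))
  }
})

test_that("SL score saturates exactly for perfect 3'-anchored residues", {
  ref <- "GGTTTAATTACCCAAGTTTGAG"
  expect_identical(slScore(ref, ref)$sl_score, 1)
  # 8 nt surviving residue, 3'-anchored, clip fully aligned from position 0:
  # raw = 8 + 0.5*4 = 10 = M(8)
  s <- slScore(substr(ref, 15, 22), ref)
  expect_identical(s$sl_score, 1)
  expect_identical(s$aligned_len, 8L)
  expect_identical(s$ref_end, 22L)
})

test_that("the reference 3'-proximity factor scales the score", {
  kmer <- "AATTCCAA"
  ref_end22 <- paste0(strrep("G", 14), kmer)              # match at 15..22
  ref_end12 <- paste0(strrep("G", 4), kmer, strrep("G", 10))  # match at 5..12
  expect_identical(slScore(kmer, ref_end22)$sl_score, 1)
  expect_equal(slScore(kmer, ref_end12)$sl_score, 12 / 22, tolerance = 1e-12)
})

test_that("SL scores stay within [0, 1] on random inputs", {
  set.seed(55)
  for (i in 1:2000) {
    clip <- random_seq(sample(1:30, 1))
    ref <- random_seq(sample(10:25, 1))
    s <- slScore(clip, ref)$sl_score
    expect_true(s >= 0 && s <= 1, info = paste(clip, ref))
  }
})

test_that("a mismatch in a perfect residue strictly lowers the score", {
  ref <- "GGTTTAATTACCCAAGTTTGAG"
  clip <- substr(ref, 15, 22)  # AGTTTGAG
  base <- slScore(clip, ref)$sl_score
  for (pos in c(2L, 5L, 7L)) {
    mut <- clip
    substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                     substr(clip, pos, pos))[1]
    expect_lt(slScore(mut, ref)$sl_score, base)
  }
})

test_that("moving the match off the 3' end or burying it lowers the score", {
  kmer <- "AATTCCAA"
  anchored <- paste0(strrep("G", 14), kmer)
  shifted <- paste0(strrep("G", 13), kmer, "G")
  expect_lt(slScore(kmer, shifted)$sl_score,
            slScore(kmer, anchored)$sl_score)
  # unmatched clip bases ahead of the residue cost score twice: f5 and the
  # clip-length normalizer
  buried <- paste0("C", kmer)
  expect_lt(slScore(buried, anchored)$sl_score,
            slScore(kmer, anchored)$sl_score)
})

test_that("zero-score alignments yield empty regions and SL score 0", {
  s <- slScore("AAAAA", "TTTTTTTTTT")
  expect_identical(s$sl_score, 0)
  expect_identical(s$aligned_len, 0L)
})

test_that("labels resolve unique maxima and flag ambiguous ties", {
  cats <- c(SL1 = "SL1", SL2a = "SL2", SL2b = "SL2")
  u <- classifyLabel(c(SL1 = 0.9, SL2a = 0.7, SL2b = 0.6), cats)
  expect_identical(u$label, "SL1")
  expect_identical(u$class, "SL1")
  t1 <- classifyLabel(c(SL1 = 0.8, SL2a = 0.8, SL2b = 0.1), cats)
  expect_identical(t1$label, "SL_unknown")
  expect_true(is.na(t1$class))
  t2 <- classifyLabel(c(SL1 = 0.6, SL2a = 0.8, SL2b = 0.8), cats)
  expect_identical(t2$label, "SL2_unknown")
  expect_identical(t2$class, "SL2")
})

test_that("potential SL status requires strictly beating every control", {
  refs <- celegans_refs()
  clip <- substr("GGTTTAATTACCCAAGTTTGAG", 15, 22)
  cand <- S4Vectors::DataFrame(read_id = "r1", clip_seq = clip,
                               clip_len = nchar(clip))
  ctrl <- randomControls(22, seed = 5)
  calls <- scoreReads(cand, refs, ctrl)
  expect_identical(calls$category, "potential_SL")
  expect_identical(calls$sl_label, "SL1")
  expect_identical(calls$sl_class, "SL1")
  # controls that contain the SL sequences themselves force exact ties,
  # which must NOT count as potential
  sl1 <- as.character(slSequences(refs))[["SL1"]]
  tie_ctrl <- new("RandomControlSet",
                  sequences = Biostrings::DNAStringSet(rep(sl1, 10)),
                  seed = 0L)
  calls2 <- scoreReads(cand, refs, tie_ctrl)
  expect_identical(calls2$sl_score, calls2$best_random)
  expect_identical(calls2$category, "candidate")
})
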