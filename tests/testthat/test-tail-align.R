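p8 <- align_params(min_match_len = 8)

test_that("exact fragments, tails, and crosslink deletions are recovered", {
  ref <- toy_ref()
  a <- align_read("CGATTTTTTAA", ref, p8)
  expect_true(a$aligned)
  expect_equal(a[c("ref_start", "ref_end", "tail", "deletions")],
               data.frame(ref_start = 6L, ref_end = 14L, tail = "AA",
                          deletions = ""),
               ignore_attr = TRUE)

  b <- align_read("CGATTTTT", ref, p8)
  expect_equal(c(b$ref_start, b$ref_end), c(6L, 13L))
  expect_equal(b$tail, "")

  # read lacking the A at ref position 8: one deletion beats both the
  # mismatch alignment (mismatch fraction too high) and the clipped
  # truncated exact match (segment too short)
  d <- align_read("CGTTTTTTAA", ref, p8)
  expect_true(d$aligned)
  expect_equal(c(d$ref_start, d$ref_end), c(6L, 14L))
  expect_equal(d$deletions, "8")
  expect_equal(d$tail, "AA")
})

test_that("templated/non-templated boundary uses maximal genomic extension", {
  # reference ends ...TTA: the last read A matches ref and is templated
  ref <- bare_reference("TACGTCAGGCGCTTA")
  a <- align_read("CAGGCGCTTAAA", ref, p8)
  expect_equal(a$ref_end, 15L)
  expect_equal(a$tail, "AA")

  # ref ends ...TTT: no tail base can extend
  ref2 <- bare_reference("TACGTCAGGCGCTTT")
  b <- align_read("CAGGCGCTTTAA", ref2, p8)
  expect_equal(b$ref_end, 15L)
  expect_equal(b$tail, "AA")

  # identity: read equal to a reference substring has no tail
  c0 <- align_read("ACGTCAGGCG", ref, p8)
  expect_equal(c0$tail, "")
  expect_equal(c(c0$ref_start, c0$ref_end), c(2L, 11L))

  # resolve_tail_boundary normalizes a hand-built candidate the same way
  cand <- data.frame(ref_end = 13L, tail = "AAA", stringsAsFactors = FALSE)
  fixed <- resolve_tail_boundary(cand, bare_reference("TACGTCAGGCGCTAA"))
  expect_equal(fixed$ref_end, 15L)
  expect_equal(fixed$tail, "A")
})

test_that("antisense alignments are reported without a tail", {
  set.seed(3)
  ref <- rand_tref(60L)
  frag <- ref_segment(ref, 10L, 40L)
  a <- align_read(revcomp_chr(paste0(frag, "AAAA")), ref, align_params())
  expect_true(a$aligned)
  expect_equal(a$strand, "-")
  expect_equal(a$tail, "")
  expect_equal(c(a$ref_start, a$ref_end), c(10L, 40L))
})

test_that("output is deterministic and independent of read order", {
  set.seed(5)
  ref <- rand_tref(60L)
  reads <- data.frame(
    id = sprintf("r%d", 1:30),
    seq = replicate(30, {
      s <- sample(40, 1)
      paste0(ref_segment(ref, s, min(60L, s + sample(15:25, 1))),
             strrep("A", sample(0:3, 1)))
    }),
    stringsAsFactors = FALSE)
  al1 <- align_reads(reads, ref, p8)
  perm <- sample(nrow(reads))
  al2 <- align_reads(reads[perm, ], ref, p8)
  expect_equal(al2[match(reads$id, al2$read_id), ], al1,
               ignore_attr = TRUE)
  expect_identical(align_reads(reads, ref, p8), al1)
})

test_that("aligner agrees with exhaustive path enumeration", {
  p <- align_params(min_match_len = 8, max_tail_len = 6)
  set.seed(2024)
  for (i in 1:60) {
    inst <- rand_align_instance()
    ref <- bare_reference(inst$refseq)
    got <- align_read(inst$read, ref, p)
    exp <- oracle_align(inst$read, inst$refseq, p)
    if (is.null(exp)) {
      expect_false(got$aligned, label = paste("instance", i))
    } else {
      expect_true(got$aligned, label = paste("instance", i))
      expect_equal(
        list(got$ref_start, got$ref_end, got$tail, got$score,
             got$n_mismatch, got$strand),
        list(exp$ref_start, exp$ref_end, exp$tail, exp$score,
             exp$n_mismatch, exp$strand),
        label = paste("instance", i, inst$read, inst$refseq))
    }
  }
})

test_that("emitted alignments always satisfy the tail-boundary invariant", {
  set.seed(9)
  ref <- rand_tref(50L)
  for (i in 1:80) {
    read <- if (i %% 3 == 0) rand_seq(sample(15:30, 1)) else {
      s <- sample(30, 1)
      paste0(ref_segment(ref, s, min(50L, s + 19L)), rand_seq(sample(0:5, 1)))
    }
    a <- align_read(read, ref, align_params())
    if (!a$aligned || a$strand != "+" || !nzchar(a$tail)) next
    if (a$ref_end < ref$length)
      expect_false(substring(a$tail, 1, 1) ==
                     ref_segment(ref, a$ref_end + 1L, a$ref_end + 1L))
    # length bookkeeping: clip + (span - deletions) + tail = read length
    ndel <- length(parse_deletions(a$deletions)[[1L]])
    span <- a$ref_end - a$ref_start + 1L
    expect_lte(span - ndel + nchar(a$tail), nchar(read))
    expect_gte(span - ndel + nchar(a$tail) + align_params()$max_clip5,
               nchar(read))
  }
})
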