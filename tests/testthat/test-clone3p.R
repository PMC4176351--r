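test_that("strip_adapter finds the 3'-most adapter match", {
  ad <- adapter_set()
  insert <- substring(CLONE_REF_SEQ, 1, 44)
  exact <- strip_adapter(paste0(insert, ad$adapters[1]), ad)
  expect_true(exact$found)
  expect_equal(exact$insert, insert)
  expect_equal(exact$n_mismatch, 0L)

  mut <- ad$adapters[2]
  substr(mut, 5, 5) <- "C"   # one substitution in the adapter
  one <- strip_adapter(paste0(insert, mut), ad)
  expect_true(one$found)
  expect_equal(one$insert, insert)
  expect_equal(one$adapter_used, 2L)
  expect_equal(one$n_mismatch, 1L)

  none <- strip_adapter(paste0(insert, "CCCCCCCCCCCCCC"), ad)
  expect_false(none$found)
  expect_match(none$reason, "no adapter")
})

test_that("clone 3' ends are classified as mature/trimmed/truncated/extended", {
  ref <- clone_ref()  # L = 46, terminator 41..46
  mature <- annotate_clone(substring(CLONE_REF_SEQ, 1, 44), ref)
  expect_equal(mature$ref_end, 44L)
  expect_equal(mature$terminal_u_count, 4L)
  expect_equal(mature$end_class, "mature")
  expect_false(mature$adenylated)

  trimmed <- annotate_clone(paste0(substring(CLONE_REF_SEQ, 1, 42), "AAA"),
                            ref)
  expect_equal(trimmed$ref_end, 42L)
  expect_equal(trimmed$terminal_u_count, 2L)
  expect_equal(trimmed$nontemplated_tail, "AAA")
  expect_equal(trimmed$nontemplated_a_count, 3L)
  expect_equal(trimmed$end_class, "trimmed")
  expect_true(trimmed$adenylated)

  truncated <- annotate_clone(substring(CLONE_REF_SEQ, 1, 40), ref)
  expect_equal(truncated$end_class, "truncated")
  expect_equal(truncated$terminal_u_count, 0L)

  extended <- annotate_clone(substring(CLONE_REF_SEQ, 1, 46), ref)
  expect_equal(extended$ref_end, 46L)
  expect_equal(extended$terminal_u_count, 6L)
  expect_equal(extended$end_class, "extended")

  unmapped <- annotate_clone("GGGGGCCCCCGGGGGCCCCCGGGGG", ref)
  expect_equal(unmapped$end_class, "unmapped")
})

test_that("annotation recovers every generating state on the full grid", {
  ref <- clone_ref()
  ad <- adapter_set()
  for (trunc in c(FALSE, TRUE)) {
    ends <- if (trunc) 25L else 46L - 0:6
    for (end_pos in ends) {
      for (a in 0:4) {
        insert <- paste0(substring(CLONE_REF_SEQ, 1, end_pos),
                         strrep("A", a))
        anns <- lapply(ad$adapters, function(adp) {
          st <- strip_adapter(paste0(insert, adp), ad)
          expect_true(st$found)
          expect_equal(st$insert, insert)
          annotate_clone(st$insert, ref)
        })
        # both ligation oligos give identical annotations
        expect_equal(anns[[1]], anns[[2]])
        ann <- anns[[1]]
        expect_equal(ann$ref_end, end_pos,
                     label = sprintf("end=%d a=%d", end_pos, a))
        expect_equal(ann$terminal_u_count, count_terminal_u(end_pos, ref))
        expect_equal(ann$nontemplated_a_count, a)
        expect_lte(ann$terminal_u_count, ref$terminator_len)
        if (trunc) expect_equal(ann$end_class, "truncated")
      }
    }
  }
})

test_that("clone set summaries tally classes, adenylation and U lengths", {
  ref <- clone_ref()
  model <- genotype_preset("lhp1d")
  model$p_subst <- 0
  sim <- simulate_clones(model, ref, n = 24, seed = 5, anchor_start = 1L)
  ann <- annotate_clones(sim$clones, ref)
  s <- summarize_clone_set(ann, label = "lhp1d-like")
  expect_equal(s$n, 24L)
  # zero-error annotation reproduces the generator's ground truth exactly
  expect_equal(unname(s$class_counts[c("mature", "extended", "trimmed",
                                       "truncated")]),
               unname(as.integer(table(factor(sim$truth$end_class,
                                              levels = c("mature", "extended",
                                                         "trimmed",
                                                         "truncated"))))))
  expect_equal(s$n_adenylated, sum(sim$truth$adenylated))
  expect_equal(s$n_u45, sum(sim$truth$u_count %in% c(4L, 5L)))
  expect_equal(unname(s$a_count_dist),
               unname(as.integer(table(factor(pmin(sim$truth$a_count, 4L),
                                              levels = 0:4)))))

  empty <- summarize_clone_set(ann[0, ])
  expect_equal(empty$n, 0L)
  expect_equal(sum(empty$class_counts), 0L)
})
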