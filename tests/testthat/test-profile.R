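# build a minimal alignment table by hand
mk_aln <- function(ref_start, ref_end, deletions = "", tail = "",
                   strand = "+") {
  n <- length(ref_start)
  data.frame(read_id = sprintf("m%d", seq_len(n)), ref_start = ref_start,
             ref_end = ref_end, strand = strand, n_mismatch = 0L,
             deletions = deletions, tail = tail, score = 0L, aligned = TRUE,
             stringsAsFactors = FALSE)
}

mk_calls <- function(al, is_oligoA = FALSE) {
  data.frame(read_id = al$read_id, tail = al$tail,
             tail_len = nchar(al$tail), a_count = 0L, non_a_frac = 0,
             is_oligoA = is_oligoA, terminal_u_count = 0L,
             stringsAsFactors = FALSE)
}

test_that("densities are counts over an explicit per-million denominator", {
  ref <- bare_reference("ACGTACGATTTTTT")
  al <- mk_aln(c(1L, 3L), c(5L, 8L))
  prof <- build_profile(al, mk_calls(al), ref, n_aligned_denominator = 4L)
  expect_equal(prof$count_total[3], 2L)
  expect_equal(prof$density_total[3], 5e5)
  expect_equal(prof$count_total[9:14], rep(0L, 6))
  expect_error(build_profile(al, mk_calls(al), ref, 1L), "denominator")
})

test_that("deleted positions are not covered", {
  ref <- bare_reference("ACGTACGATTTTTT")
  al <- mk_aln(6L, 14L, deletions = "8")
  prof <- build_profile(al, mk_calls(al), ref)
  expect_equal(prof$count_total[8], 0L)
  expect_equal(prof$count_total[7], 1L)
  expect_equal(sum(prof$count_total), (14 - 6 + 1) - 1)
})

test_that("coverage is conserved and the oligoA track is dominated", {
  set.seed(31)
  ref <- rand_tref(120L)
  model <- genotype_preset("lhp1d")
  sim <- simulate_crac_reads(model, ref, n = 250, seed = 77)
  al <- align_reads(sim$reads, ref)
  calls <- call_tails(al, ref)
  prof <- build_profile(al, calls, ref)
  ok <- al[al$aligned, ]
  spans <- sum(ok$ref_end - ok$ref_start + 1L) -
    sum(lengths(parse_deletions(ok$deletions)))
  expect_identical(sum(prof$count_total), as.integer(spans))
  expect_true(all(prof$count_oligoA <= prof$count_total))
  expect_true(all(prof$density_oligoA <= prof$density_total))

  # doubling every read and the denominator leaves densities unchanged
  al2 <- rbind(ok, transform(ok, read_id = paste0(read_id, "_dup")))
  calls2 <- call_tails(al2, ref)
  prof2 <- build_profile(al2, calls2, ref,
                         n_aligned_denominator = 2L * nrow(ok))
  prof1 <- build_profile(ok, calls, ref, n_aligned_denominator = nrow(ok))
  expect_equal(prof2$density_total, prof1$density_total)
  expect_equal(prof2$density_oligoA, prof1$density_oligoA)
})

test_that("a 5'-biased library peaks in the 5' third of the reference", {
  set.seed(41)
  ref <- rand_tref(150L)
  model <- end_state_model(fragment_start_bias = 6, p_adenylate = 0.2)
  sim <- simulate_crac_reads(model, ref, n = 400, seed = 13)
  al <- align_reads(sim$reads, ref)
  calls <- call_tails(al, ref)
  prof <- build_profile(al, calls, ref)
  expect_lt(which.max(prof$count_total), ref$length / 3)
})

test_that("truncation histogram reports the modal internal end", {
  ref <- toy_ref()  # terminator at 9..14
  al <- mk_aln(rep(1L, 6), c(14L, 14L, 12L, 8L, 8L, 8L))
  h <- truncation_end_histogram(al, ref)
  expect_equal(h$modal_internal_end, 8L)
  expect_equal(h$ends$count[h$ends$ref_end == 14L], 2L)

  al2 <- mk_aln(rep(1L, 3), c(14L, 13L, 12L))
  expect_true(is.na(truncation_end_histogram(al2, ref)$modal_internal_end))
})

test_that("simulated truncation point mass is recovered as the modal end", {
  set.seed(51)
  ref <- rand_tref(150L)
  site <- 101L
  model <- end_state_model(p_truncate = 0.5, truncation_sites = site,
                           truncation_site_probs = 1, p_subst = 0,
                           p_crosslink_del = 0,
                           read_len_dist = 1, read_len_min = 160L)
  sim <- simulate_crac_reads(model, ref, n = 300, seed = 19)
  al <- align_reads(sim$reads, ref)
  h <- truncation_end_histogram(al, ref)
  expect_equal(h$modal_internal_end, site)
})
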