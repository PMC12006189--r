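# Synthetic cohort generator: validation, determinism, and recovery of the
# coupling structure by the downstream estimators.

test_that("cohort and coupling specs validate their inputs", {
  expect_error(coupling_spec(c("O1", "O1")), "distinct")
  expect_error(coupling_spec(c("O1", "O2"), phase_lag = 4), "phase_lag")
  expect_error(coupling_spec(c("O1", "O2"), mixing_weight = 1.2), "mixing")
  expect_error(cohort_spec(duration = 3), "duration")
  expect_error(cohort_spec(n_subjects_per_group = 0), "subject")
  expect_error(cohort_spec(montage = letters[1:19]), "unknown channel")
  gc <- list(a = list(coupling_spec(c("Zz", "O2"))), b = list())
  expect_error(cohort_spec(group_couplings = gc), "unknown channel")
})

test_that("same spec and seed reproduce recordings bit-for-bit", {
  sp <- cohort_spec(duration = 5, n_subjects_per_group = 1, seed = 9)
  r1 <- generate_recording(sp, "case", 123)
  r2 <- generate_recording(sp, "case", 123)
  expect_identical(r1$data, r2$data)
  r3 <- generate_recording(sp, "case", 124)
  expect_false(identical(r1$data, r3$data))
})

test_that("generate_cohort yields labeled subjects per group", {
  sp <- cohort_spec(duration = 5, n_subjects_per_group = 3, seed = 4)
  coh <- generate_cohort(sp)
  expect_length(coh, 6L)
  labs <- vapply(coh, `[[`, integer(1), "label")
  expect_identical(sort(labs), c(0L, 0L, 0L, 1L, 1L, 1L))
  ids <- vapply(coh, `[[`, character(1), "subject_id")
  expect_false(anyDuplicated(ids) > 0)
  # cohorts are reproducible end to end
  coh2 <- generate_cohort(sp)
  expect_identical(coh[[5]]$recording$data, coh2[[5]]$recording$data)
})

test_that("a fully mixed constant-lag sinusoid pair gives PLI of 1", {
  gc <- list(a = list(coupling_spec(c("O1", "O2"), phase_lag = pi / 2,
                                    mixing_weight = 1,
                                    envelope_coupling = 0)),
             b = list())
  sp <- cohort_spec(duration = 5, n_subjects_per_group = 1,
                    group_couplings = gc, noise_sd = 0,
                    oscillator = "sinusoid", seed = 3)
  seg <- segment_recording(generate_recording(sp, "a", 42), label = 1L,
                           subject_id = "x")[[1]]
  expect_equal(pli_matrix(seg)$values["O1", "O2"], 1, tolerance = 1e-6)
})

test_that("uncoupled channels show vanishing phase locking at long duration", {
  gc <- list(a = list(), b = list())
  sp <- cohort_spec(duration = 60, n_subjects_per_group = 1,
                    group_couplings = gc, seed = 5)
  rec <- generate_recording(sp, "a", 7)
  p <- pli_matrix(rec$data)$values
  # effective sample count ~ duration x bandwidth; Monte-Carlo tolerance
  expect_lt(mean(p[upper.tri(p)]), 0.25)
  expect_lt(max(p[upper.tri(p)]), 0.5)
})

test_that("measured PLI increases with the mixing weight", {
  ws <- c(0, 0.25, 0.5, 0.75, 1)
  avg <- vapply(ws, function(w) {
    vals <- vapply(1:20, function(s) {
      gc <- list(a = list(coupling_spec(c("O1", "O2"), mixing_weight = w,
                                        envelope_coupling = 0)),
                 b = list())
      sp <- cohort_spec(duration = 10, n_subjects_per_group = 1,
                        group_couplings = gc, seed = s)
      rec <- generate_recording(sp, "a", 1000L + 13L * s)
      pli_matrix(rec$data)$values["O1", "O2"]
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(avg) > -0.05))  # monotone up to Monte-Carlo jitter
  expect_true(all(diff(avg[3:5]) > 0))  # clearly increasing once coupled
  expect_gt(avg[5], avg[1] + 0.3)
})

test_that("identical group couplings give a null Mann-Whitney in most replicates", {
  gc0 <- default_group_couplings()
  nonsig <- vapply(1:10, function(r) {
    sp <- cohort_spec(duration = 10, n_subjects_per_group = 2,
                      group_couplings = list(control = gc0$control,
                                             case = gc0$control),
                      seed = 100L + r)
    segs <- segments_from_cohort(generate_cohort(sp))
    labs <- vapply(segs, function(s) s$label, integer(1))
    pc <- lapply(segs, segment_pcoh)
    mann_whitney_connectivity(pc[labs == 0], pc[labs == 1])$p > 0.05
  }, logical(1))
  expect_gte(sum(nonsig), 9L)
})

test_that("group-average fused connectivity peaks at the coupled pairs", {
  sp <- cohort_spec(duration = 15, n_subjects_per_group = 2, seed = 11)
  segs <- segments_from_cohort(generate_cohort(sp))
  labs <- vapply(segs, function(s) s$label, integer(1))
  pc <- lapply(segs, segment_pcoh)
  av <- group_average_connectivity(split(pc, labs))
  d <- av[[2]]$values - av[[1]]$values
  # strongest case-minus-control elevation must be a case-coupled pair
  idx <- arrayInd(which.max(d), dim(d))
  case_pairs <- c("Fp1-Fp2", "Fp2-Fp1", "Fp1-Fz", "Fz-Fp1", "Fp2-Fz",
                  "Fz-Fp2", "F3-F7", "F7-F3", "F4-F8", "F8-F4",
                  "C3-T3", "T3-C3")
  got <- paste(canonical_montage()[idx[1]], canonical_montage()[idx[2]],
               sep = "-")
  expect_true(got %in% case_pairs)
  # and the reverse direction a control-coupled pair
  idx2 <- arrayInd(which.min(d), dim(d))
  ctrl_pairs <- c("O1-O2", "O2-O1", "O1-P3", "P3-O1", "O2-P3", "P3-O2",
                  "P4-T6", "T6-P4")
  got2 <- paste(canonical_montage()[idx2[1]], canonical_montage()[idx2[2]],
                sep = "-")
  expect_true(got2 %in% ctrl_pairs)
})
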