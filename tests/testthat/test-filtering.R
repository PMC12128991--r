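test_that("per-round matched filter applies all four thresholds", {
  p <- filter_params()
  buffy0 <- obs_row(sample_id = "P01_buffy", alt_reads = 0)

  # below the 5-read floor
  r <- filter_matched_round(obs_row(alt_reads = 4), buffy0, p)
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "rejected")$reason, "few_alt_reads")

  # 8/700 (VAF 1.14%), base quality 30, clean buffy: kept
  r <- filter_matched_round(obs_row(alt_reads = 8), buffy0, p)
  expect_equal(nrow(r), 1)
  expect_equal(r$vaf, 8 / 700)

  # buffy signal 2/700 = 0.29% >= 0.01%: rejected
  r <- filter_matched_round(obs_row(alt_reads = 8),
                            obs_row(sample_id = "P01_buffy", alt_reads = 2), p)
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "rejected")$reason, "buffy_signal")

  # VAF below 1% despite enough reads (7/1000)
  r <- filter_matched_round(obs_row(alt_reads = 7, total_reads = 1000),
                            buffy0, p)
  expect_equal(nrow(r), 0)

  # base quality below 25
  r <- filter_matched_round(obs_row(alt_reads = 8, mean_base_quality = 20),
                            buffy0, p)
  expect_equal(nrow(r), 0)
  expect_equal(attr(r, "rejected")$reason, "base_quality")

  # absent from buffy counts as zero signal
  r <- filter_matched_round(obs_row(alt_reads = 8), buffy0[0, ], p)
  expect_equal(nrow(r), 1)

  expect_error(filter_matched_round(obs_row(), NULL, p), "buffy")
})

test_that("round concordance requires the full filter in enough rounds", {
  p <- filter_params()
  both <- rbind(cbind(obs_row(round = 1), vaf = 8 / 700, buffy_vaf = 0),
                cbind(obs_row(round = 2), vaf = 9 / 700, buffy_vaf = 0))
  one <- both[1, ]

  v <- require_round_concordance(both, p, available_rounds = 1:2)
  expect_equal(nrow(v), 1)
  expect_equal(v$samples_validated, "P01_s1")

  v <- require_round_concordance(one, p, available_rounds = 1:2)
  expect_equal(nrow(v), 0)

  # a mutation may validate via any single sample of the patient
  other <- both
  other$sample_id <- "P01_s4"
  mixed <- rbind(one, other)
  v <- require_round_concordance(mixed, p, available_rounds = 1:2)
  expect_equal(nrow(v), 1)
  expect_equal(v$samples_validated, "P01_s4")

  # single-round dataset can never satisfy require_rounds = 2
  expect_error(require_round_concordance(one, p, available_rounds = 1),
               "round")
})

test_that("germline removal needs ~50% VAF in every covered sample", {
  p <- filter_params()
  meta <- tiny_meta(nseg = 4)
  val <- data.frame(patient = "P01", chrom = "chr1", pos = 1000L,
                    ref = "A", alt = "T", samples_validated = "P01_s1")
  mk_obs <- function(vafs_by_sample) {
    do.call(rbind, lapply(names(vafs_by_sample), function(s)
      obs_row(sample_id = s, alt_reads = round(700 * vafs_by_sample[[s]]))))
  }
  # ~50% everywhere including buffy: removed
  obs <- mk_obs(list(P01_s1 = 0.5, P01_s2 = 0.48, P01_s3 = 0.52,
                     P01_s4 = 0.5, P01_buffy = 0.5))
  out <- remove_germline(val, obs, p)
  expect_equal(nrow(out), 0)
  expect_equal(nrow(attr(out, "removed")), 1)

  # 50% in one sample but 2% in another: retained
  obs <- mk_obs(list(P01_s1 = 0.5, P01_s2 = 0.02, P01_buffy = 0.5))
  out <- remove_germline(val, obs, p)
  expect_equal(nrow(out), 1)

  # samples without coverage do not veto the rule
  obs <- rbind(mk_obs(list(P01_s1 = 0.5, P01_buffy = 0.5)),
               obs_row(sample_id = "P01_s2", alt_reads = 0, total_reads = 0))
  out <- remove_germline(val, obs, p)
  expect_equal(nrow(out), 0)
})

test_that("cross-patient recurrent variants are excluded from every patient", {
  val <- data.frame(patient = c("P01", "P02", "P02"),
                    chrom = "chr3", pos = c(500L, 500L, 900L),
                    ref = "G", alt = "A",
                    samples_validated = c("P01_s1", "P02_s1", "P02_s1"))
  out <- exclude_cross_patient(val)
  expect_equal(nrow(out), 1)
  expect_equal(out$pos, 900L)
  exc <- attr(out, "excluded")
  expect_equal(nrow(exc), 2)
  expect_true(all(exc$shared_with == "P01,P02"))

  # unique per patient: identity
  out2 <- exclude_cross_patient(out[, names(out) != "shared_with"])
  expect_equal(nrow(out2), 1)
})

test_that("the cascade is monotone and its stages idempotent", {
  sim <- small_sim(seed = 61)
  res <- run_filter_cascade(sim$obs, sim$truth$meta)
  expect_true(all(diff(res$funnel$n_variants) <= 0))

  # re-applying the last two stages to their own output changes nothing
  again <- remove_germline(res$validated, sim$obs, res$params)
  expect_equal(again, res$validated, ignore_attr = TRUE)
  again2 <- exclude_cross_patient(res$validated)
  expect_equal(again2, res$validated, ignore_attr = TRUE)

  # validated variants are a subset of planted somatic mutations
  tr <- sim$truth$mutations
  planted <- paste(tr$chrom, tr$pos, tr$ref, tr$alt)
  got <- paste(res$validated$chrom, res$validated$pos, res$validated$ref,
               res$validated$alt)
  expect_true(all(got %in% planted))
})

test_that("a patient without buffy-coat data is a hard error", {
  sim <- small_sim(seed = 62, n_patients = 2)
  obs <- sim$obs[!(sim$obs$patient == "P02" &
                     grepl("buffy", sim$obs$sample_id)), ]
  expect_error(run_filter_cascade(obs, sim$truth$meta), "P02")
})
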