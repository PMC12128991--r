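chip_ann <- function(chrom = "chr4", pos = 1000L, gene = "TET2",
                     consequence = "loss_of_function", gnomad_maf = NA,
                     cadd_phred = 30, votes = 5L, clinvar = FALSE) {
  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T", gene = gene,
             consequence = consequence, gnomad_maf = gnomad_maf,
             cadd_phred = cadd_phred, dbnsfp_damaging_votes = votes,
             clinvar_damaging = clinvar)
}

buffy_obs <- function(alt = 20, total = 650, pos = 1000L, chrom = "chr4",
                      patient = "P01") {
  obs_row(patient = patient, sample_id = paste0(patient, "_buffy"),
          chrom = chrom, pos = pos, alt_reads = alt, total_reads = total)
}

test_that("the tumor-only cascade keeps listed damaging rare variants", {
  meta <- tiny_meta()
  # TET2 frameshift, depth 650, VAF 3%, absent from gnomAD: kept
  out <- screen_buffy(buffy_obs(alt = 20), meta, chip_ann())
  expect_equal(nrow(out), 1)
  expect_equal(out$gene, "TET2")
  expect_equal(out$buffy_vaf, 20 / 650)
  expect_equal(out$buffy_ccf, 2 * 20 / 650)

  # same variant in a non-list gene: rejected
  out <- screen_buffy(buffy_obs(), meta, chip_ann(gene = "NOTALISTGENE"))
  expect_equal(nrow(out), 0)

  # missense with CADD 21, 3 votes, no ClinVar: fails the damaging criterion
  out <- screen_buffy(buffy_obs(), meta,
                      chip_ann(consequence = "missense", cadd_phred = 21,
                               votes = 3L))
  expect_equal(nrow(out), 0)
  # ...but any single damaging evidence suffices
  for (ann in list(chip_ann(consequence = "missense", cadd_phred = 24,
                            votes = 0L),
                   chip_ann(consequence = "missense", cadd_phred = 10,
                            votes = 4L),
                   chip_ann(consequence = "missense", cadd_phred = 10,
                            votes = 0L, clinvar = TRUE))) {
    expect_equal(nrow(screen_buffy(buffy_obs(), meta, ann)), 1)
  }

  # common gnomAD variants fail; missing MAF passes as rare
  out <- screen_buffy(buffy_obs(), meta, chip_ann(gnomad_maf = 0.05))
  expect_equal(nrow(out), 0)

  # depth below 20 reads fails
  out <- screen_buffy(buffy_obs(alt = 2, total = 15), meta, chip_ann())
  expect_equal(nrow(out), 0)

  # ~50% VAF in every covered sample is residual germline, excluded
  g_obs <- rbind(buffy_obs(alt = 325, total = 650),
                 obs_row(sample_id = "P01_s1", chrom = "chr4",
                         alt_reads = 350))
  out <- screen_buffy(g_obs, meta, chip_ann())
  expect_equal(nrow(out), 0)
})

test_that("force-calling reports zeros and no-coverage distinctly, excluding recurrences", {
  meta <- rbind(tiny_meta("P01"), tiny_meta("P02", sex = "female"))
  ann <- chip_ann()
  obs <- rbind(
    buffy_obs(alt = 20, patient = "P01"),
    obs_row(patient = "P01", sample_id = "P01_s1", chrom = "chr4",
            alt_reads = 15),
    # P02 buffy covered with zero alt reads; P02_s1 has no row at the site
    buffy_obs(alt = 0, patient = "P02"))
  carriers <- screen_buffy(obs, meta, ann)
  expect_equal(carriers$patient, "P01")
  fc <- force_call(carriers, obs, meta)
  expect_equal(nrow(fc), 4)
  p2b <- fc[fc$sample_id == "P02_buffy", ]
  expect_true(p2b$covered)
  expect_equal(p2b$alt_reads, 0L)
  p2s <- fc[fc$sample_id == "P02_s1", ]
  expect_false(p2s$covered)
  expect_true(is.na(p2s$vaf))

  # the same substitution qualifying in both patients is dropped from both
  obs2 <- rbind(obs, buffy_obs(alt = 25, patient = "P02"))
  carriers2 <- screen_buffy(obs2, meta, ann)
  expect_equal(sort(carriers2$patient), c("P01", "P02"))
  fc2 <- force_call(carriers2, obs2, meta)
  expect_equal(nrow(fc2), 0)
  expect_equal(nrow(attr(fc2, "excluded")), 2)
})

test_that("blood-only CHIP clones show no tissue infiltration", {
  meta <- tiny_meta(nseg = 3)
  ann <- chip_ann()
  obs <- rbind(buffy_obs(alt = 30, total = 700),
               do.call(rbind, lapply(1:3, function(s)
                 obs_row(sample_id = paste0("P01_s", s), chrom = "chr4",
                         alt_reads = 0))))
  res <- run_chip_screen(obs, meta, ann)
  inf <- res$infiltration
  expect_equal(nrow(inf$per_sample), 3)
  expect_true(all(!inf$per_sample$detected))
  expect_equal(inf$per_patient$frac_positive, 0)
  expect_equal(inf$per_patient$n_plaque_samples, 3)
})

test_that("planted CHIP clones are recovered with their infiltration pattern", {
  # a high blood fraction with infiltration into every segment, in the style
  # of a NOTCH2-like carrier: blood ~21.6%, tissue 13%-18% of cells
  cfg <- sim_config(n_patients = 2, segments_per_plaque = 4,
                    n_clones = 0, n_germline = 4, n_error_sites = 0,
                    chip = chip_spec(n_carriers = 1,
                                     blood_fraction = 0.216,
                                     mutations_per_carrier = 1,
                                     infiltration_prob = 1,
                                     infiltration_fraction = c(0.134, 0.184)),
                    seed = 14)
  sim <- simulate_dataset(cfg)
  res <- run_chip_screen(sim$obs, sim$truth$meta, sim$truth$annotations)
  expect_equal(nrow(res$carriers), 1)
  carrier <- res$carriers$patient
  truth_clone <- sim$truth$clones[sim$truth$clones$class == "chip", ]
  expect_equal(carrier, truth_clone$patient)
  # blood clonal cell frequency near the planted 21.6%
  expect_lt(abs(res$carriers$buffy_ccf - 0.216), 0.05)
  inf <- res$infiltration$per_sample
  expect_true(all(inf$detected))
  truth_fr <- sim$truth$fractions[!grepl("buffy",
                                         sim$truth$fractions$sample_id), ]
  got <- inf$ccf[match(truth_fr$sample_id, inf$sample_id)]
  expect_true(all(abs(got - truth_fr$fraction) < 0.05))
})
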