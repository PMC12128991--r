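test_that("truth generation handles empty, fixed and infeasible clone configs", {
  # no clones at all: only germline variants remain
  cfg0 <- sim_config(n_patients = 2, n_clones = 0, n_germline = 5,
                     chip = NULL, seed = 1)
  t0 <- simulate_truth(cfg0)
  expect_equal(nrow(t0$clones), 0)
  expect_true(all(t0$mutations$class == "germline"))
  expect_equal(nrow(t0$mutations), 10)

  # one clone at fraction 0.20 in every segment: expected autosomal VAF 0.10
  cfg1 <- sim_config(n_patients = 1, segments_per_plaque = 4,
                     clone_spec = list(list(patient = 1, segments = 1:4,
                                            fraction = 0.2, chrom = "chr5")),
                     n_germline = 0, n_error_sites = 0, chip = NULL, seed = 2)
  t1 <- simulate_truth(cfg1)
  ev <- t1$expected_vaf
  expect_equal(nrow(ev), 4)
  expect_true(all(ev$expected_vaf == 0.10))

  # two disjoint clones at 0.6 and 0.5 sharing a sample: infeasible
  cfg2 <- sim_config(n_patients = 1, segments_per_plaque = 2,
                     clone_spec = list(
                       list(patient = 1, segments = 1:2, fraction = 0.6),
                       list(patient = 1, segments = 1:2, fraction = 0.5)),
                     n_germline = 0, chip = NULL, seed = 3)
  expect_error(simulate_truth(cfg2), "infeasible")
})

test_that("clone occupancy is contiguous and multi-mutation clones share fractions", {
  truth <- small_sim(seed = 7)$truth
  for (cid in truth$clones$clone_id[truth$clones$class == "somatic"]) {
    cl <- truth$clones[truth$clones$clone_id == cid, ]
    fr <- truth$fractions[truth$fractions$clone_id == cid, ]
    segs <- match(fr$sample_id,
                  truth$meta$sample_id[truth$meta$patient == cl$patient &
                                         truth$meta$tissue_class == "plaque"])
    expect_equal(sort(segs), seq(cl$seg_first, cl$seg_last))
    # member mutations inherit identical per-sample cell fractions; their
    # expected VAFs differ only by the sex-chromosome multiplier
    members <- truth$mutations$id[which(truth$mutations$clone_id == cid)]
    sex <- unique(truth$meta$sex[truth$meta$patient == cl$patient])
    fracs <- lapply(members, function(id) {
      m <- truth$mutations[truth$mutations$id == id, ]
      mult <- if (m$chrom %in% c("chrX", "chrY") && sex == "male") 1 else 0.5
      e <- truth$expected_vaf[truth$expected_vaf$id == id, ]
      e <- e[order(e$sample_id), ]
      data.frame(sample_id = e$sample_id, fraction = e$expected_vaf / mult)
    })
    for (f in fracs[-1]) expect_equal(f, fracs[[1]], ignore_attr = TRUE)
  }
  # per-sample sums of disjoint-clone fractions never exceed 1
  sums <- tapply(truth$fractions$fraction, truth$fractions$sample_id, sum)
  expect_true(all(sums <= 1 + 1e-12))
})

test_that("read draws are binomial with the expected VAF", {
  # 1000 planted mutations at expected VAF 0.10, two rounds, constant depth:
  # 2000 replicate binomial draws
  spec <- lapply(1:100, function(i)
    list(patient = i, segments = 1, fraction = 0.2, n_mutations = 10,
         chrom = "chr7"))
  cfg <- sim_config(n_patients = 100, segments_per_plaque = 1,
                    clone_spec = spec, n_germline = 0, n_error_sites = 0,
                    chip = NULL, error_rate = 0, depth_model = "constant",
                    seed = 11)
  sim <- simulate_dataset(cfg)
  tis <- sim$obs[!grepl("buffy", sim$obs$sample_id), ]
  expect_equal(nrow(tis), 2000)
  expect_true(all(tis$total_reads == 700))
  vaf <- tis$alt_reads / tis$total_reads
  se <- sqrt(0.1 * 0.9 / 700) / sqrt(2000)
  expect_lt(abs(mean(vaf) - 0.10), 3 * se)

  # goodness of fit of the alt-read distribution against Binomial(700, 0.1)
  qs <- qbinom(seq(0.1, 0.9, by = 0.1), 700, 0.1)
  breaks <- c(-1, unique(qs), 700)
  obs_counts <- table(cut(tis$alt_reads, breaks))
  p_bins <- diff(pbinom(breaks, 700, 0.1))
  gof <- suppressWarnings(chisq.test(as.vector(obs_counts), p = p_bins,
                                     rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
})

test_that("zero error rate yields zero alt reads at non-variant sites", {
  cfg <- sim_config(n_patients = 1, segments_per_plaque = 2,
                    clone_spec = list(list(patient = 1, segments = 1,
                                           fraction = 0.2)),
                    n_germline = 0, n_error_sites = 50, chip = NULL,
                    error_rate = 0, seed = 4)
  sim <- simulate_dataset(cfg)
  key <- paste(sim$obs$chrom, sim$obs$pos)
  ekey <- paste(sim$truth$error_sites$chrom, sim$truth$error_sites$pos)
  expect_true(all(sim$obs$alt_reads[key %in% ekey] == 0))
  # the clone's unoccupied segment is also error-free
  mut <- sim$truth$mutations
  s2 <- sim$obs[key %in% paste(mut$chrom, mut$pos) &
                  grepl("_s2$", sim$obs$sample_id), ]
  expect_true(all(s2$alt_reads == 0))
})

test_that("germline draws stay near 50% VAF at 700x as the binomial tail predicts", {
  cfg <- sim_config(n_patients = 4, segments_per_plaque = 4, n_clones = 0,
                    n_germline = 50, n_error_sites = 0, chip = NULL,
                    error_rate = 0, depth_model = "constant", seed = 12)
  sim <- simulate_dataset(cfg)
  vaf <- sim$obs$alt_reads / sim$obs$total_reads
  inside <- mean(vaf > 0.4 & vaf < 0.6)
  # exact binomial oracle for P(0.4 < X/700 < 0.6)
  p_inside <- pbinom(ceiling(0.6 * 700) - 1, 700, 0.5) -
    pbinom(floor(0.4 * 700), 700, 0.5)
  expect_gt(p_inside, 0.99)
  expect_gt(inside, 0.99)
})

test_that("simulation is deterministic in the seed", {
  a <- small_sim(seed = 21)
  b <- small_sim(seed = 21)
  expect_identical(a$obs, b$obs)
  expect_identical(a$truth$mutations, b$truth$mutations)
  c <- small_sim(seed = 22)
  expect_false(identical(a$obs, c$obs))
})

test_that("datasets round-trip through disk byte-stably", {
  sim <- small_sim(seed = 31, n_patients = 2)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(sim, d1, overwrite = TRUE)
  write_dataset(sim, d2, overwrite = TRUE)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # refuse to clobber without the explicit flag
  expect_error(write_dataset(sim, d1), "overwrite")

  rb <- read_dataset(d1)
  ord <- function(x) {
    x <- x[order(x$sample_id, x$round, x$chrom, x$pos, x$alt), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(rb$obs), ord(sim$obs))
  expect_equal(rb$meta, sim$truth$meta, ignore_attr = TRUE)

  # truth bookkeeping: one mutation row per planted variant
  tr <- read.delim(file.path(d1, "truth", "mutations.tsv"))
  expect_equal(nrow(tr),
               sum(sim$truth$clones$n_mutations[
                 sim$truth$clones$class == "somatic"]) +
                 2 * sim$config$n_germline +
                 sum(sim$truth$mutations$class == "chip"))
})
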