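geom4 <- data.frame(sample_id = paste0("s", 1:4),
                    start_mm = c(0, 6, 12, 18), end_mm = c(2, 8, 14, 20))

test_that("mutation matrices are complete, ordered and zero-filled", {
  meta <- tiny_meta(nseg = 4)
  val <- data.frame(patient = "P01",
                    chrom = c("chr1", "chr2", "chr3"),
                    pos = c(100L, 200L, 300L), ref = "A", alt = "T",
                    samples_validated = "P01_s1")
  obs <- do.call(rbind, lapply(1:3, function(i) rbind(
    obs_row(chrom = val$chrom[i], pos = val$pos[i], alt_reads = 70,
            sample_id = "P01_s1"),
    obs_row(chrom = val$chrom[i], pos = val$pos[i],
            alt_reads = if (i == 1) 35 else 0, sample_id = "P01_s2"),
    obs_row(chrom = val$chrom[i], pos = val$pos[i], alt_reads = 0,
            sample_id = "P01_buffy"))))
  m <- build_matrix(quantify_mutations(val, obs, meta), meta, "P01")
  expect_equal(dim(m), c(3, 4))
  expect_equal(colnames(m), paste0("P01_s", 1:4))
  expect_equal(unname(m[1, 1]), 0.2)
  expect_equal(unname(m[1, 2]), 0.1)
  expect_true(all(m[, 3:4] == 0))

  # single-sample plaque gives a single-column matrix
  meta1 <- tiny_meta(nseg = 1)
  m1 <- build_matrix(quantify_mutations(val[1, ], obs[obs$sample_id !=
    "P01_s2", ], meta1), meta1, "P01")
  expect_equal(ncol(m1), 1)

  # plaque sample without geometry is an error
  metab <- meta
  metab$start_mm[1] <- NA
  metab$end_mm[1] <- NA
  expect_error(build_matrix(quantify_mutations(val, obs, meta), metab, "P01"),
               "geometry")
})

test_that("extent bounds follow nearest/farthest-edge arithmetic", {
  g2 <- data.frame(start_mm = c(0, 6), end_mm = c(2, 8))
  expect_equal(unname(clone_extent(c(TRUE, FALSE), g2)), c(0, 2))
  expect_equal(unname(clone_extent(c(TRUE, TRUE), g2)), c(4, 8))
  g3 <- data.frame(start_mm = c(0, 6, 12), end_mm = c(2, 8, 14))
  expect_equal(unname(clone_extent(c(TRUE, TRUE, TRUE), g3)), c(10, 14))
  expect_error(clone_extent(c(FALSE, FALSE), g2), "positive")
})

test_that("extent bounds match the exhaustive pairwise oracle on all patterns", {
  set.seed(3)
  widths <- runif(6, 2, 5)
  gaps <- runif(5, 4, 10)
  starts <- cumsum(c(0, widths[-6] + gaps))
  g6 <- data.frame(start_mm = starts, end_mm = starts + widths)
  for (mask in 1:63) {
    pos <- as.logical(bitwAnd(mask, 2^(0:5)))
    got <- unname(clone_extent(pos, g6))
    expect_equal(got, oracle_extent(pos, g6))
  }
})

test_that("grouping links equal-pattern, similar-frequency mutations", {
  # co-travelling profiles in the style of a media-intima spanning clone
  m <- rbind(a = c(0.05, 0.31, 0.10), b = c(0.05, 0.30, 0.10))
  colnames(m) <- paste0("s", 1:3)
  g <- group_into_clones(m)
  expect_equal(unname(g$membership["a"]), unname(g$membership["b"]))
  expect_equal(nrow(g$groups), 1)
  expect_equal(unname(g$profiles[1, ]), c(0.05, 0.305, 0.10))

  # presence-pattern mismatch separates
  m2 <- rbind(a = c(0.05, 0, 0.10), b = c(0.05, 0.31, 0.10))
  colnames(m2) <- paste0("s", 1:3)
  g2 <- group_into_clones(m2)
  expect_equal(nrow(g2$groups), 2)

  # frequencies too far apart separate even with equal patterns
  m3 <- rbind(a = c(0.05, 0.05), b = c(0.30, 0.30))
  g3 <- group_into_clones(m3, rel_tol = 0.5)
  expect_equal(nrow(g3$groups), 2)
  g3b <- group_into_clones(m3, rel_tol = 1)
  expect_equal(nrow(g3b$groups), 1)
})

test_that("grouping equals the brute-force pairwise oracle on random matrices", {
  skip_if_not_installed("igraph")
  set.seed(4)
  for (rep in 1:10) {
    m <- matrix(0, 12, 5, dimnames = list(paste0("m", 1:12), paste0("s", 1:5)))
    for (i in 1:12) {
      on <- sample(5, sample(1:4, 1))
      m[i, on] <- runif(length(on), 0.02, 0.4)
    }
    # seed some deliberate near-duplicates so links actually occur
    m[2, ] <- m[1, ] * runif(1, 0.8, 1.2) * (m[1, ] > 0)
    m[7, ] <- m[6, ] * runif(1, 0.9, 1.1) * (m[6, ] > 0)
    got <- group_into_clones(m)$membership
    want <- oracle_group(m)
    expect_equal(rand_index(got, want), 1)
  }
})

test_that("grouping is invariant to row permutation", {
  set.seed(5)
  m <- matrix(runif(40, 0, 0.3), 8, 5,
              dimnames = list(paste0("m", 1:8), paste0("s", 1:5)))
  m[m < 0.1] <- 0
  g <- group_into_clones(m)
  perm <- sample(8)
  gp <- group_into_clones(m[perm, ])
  for (i in 1:7) for (j in (i + 1):8) {
    same <- g$membership[paste0("m", i)] == g$membership[paste0("m", j)]
    same_p <- gp$membership[paste0("m", i)] == gp$membership[paste0("m", j)]
    expect_equal(unname(same), unname(same_p))
  }
})

test_that("gap-tolerant mode forgives one interior dropout only", {
  m <- rbind(full = c(0.2, 0.2, 0.2, 0.2),
             gap  = c(0.2, 0.0, 0.2, 0.2),
             edge = c(0.0, 0.2, 0.2, 0.2))
  colnames(m) <- paste0("s", 1:4)
  strict <- group_into_clones(m)
  expect_equal(length(unique(strict$membership)), 3)
  lenient <- group_into_clones(m, gap_tolerant = TRUE)
  # the interior dropout links, the edge mismatch still separates
  expect_equal(unname(lenient$membership["full"]),
               unname(lenient$membership["gap"]))
  expect_false(lenient$membership["full"] == lenient$membership["edge"])
})

test_that("samples with frequency sums above 1 are flagged as multi-mutation", {
  m <- rbind(a = c(0.6, 0.3), b = c(0.6, 0.3))
  colnames(m) <- c("s1", "s2")
  f <- flag_multimutation_samples(m)
  expect_true(f[["s1"]])
  expect_false(f[["s2"]])
})

test_that("a planted 2-mutation clone at 0.6 flags its sample and groups as one", {
  cfg <- sim_config(n_patients = 1, segments_per_plaque = 2,
                    clone_spec = list(list(patient = 1, segments = 1,
                                           fraction = 0.6, n_mutations = 2,
                                           chrom = "chr9")),
                    n_germline = 4, n_error_sites = 0, chip = NULL,
                    error_rate = 0, seed = 9)
  sim <- simulate_dataset(cfg)
  fit <- plaque_clonality(sim$obs, sim$truth$meta, chip = NULL)
  flags <- fit$multimutation_flags$P01
  first <- colnames(fit$matrices$P01)[1]
  expect_true(flags[[first]])
  g <- fit$clone_groups$P01
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$groups$n_members, 2)
})
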