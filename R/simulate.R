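#' Generate the planted ground truth for a synthetic cohort
#'
#' Draws patient/segment geometry, somatic clones with contiguous 1-D
#' spatial occupancy, multi-mutation clone memberships, heterozygous
#' germline variants, CHIP blood clones with optional tissue infiltration,
#' and the per-sample expected VAF of every planted mutation. The truth set
#' is the reference against which recovery by the downstream pipeline is
#' judged.
#'
#' Expected VAFs follow the diploid heterozygous model: an autosomal (or
#' female chrX) mutation carried by a fraction f of cells has expected VAF
#' f/2; a chrX mutation in a male has expected VAF f. Germline heterozygous
#' variants sit at VAF 0.5 in every sample. Disjoint clones sharing a sample
#' may not sum to more than 100% of its cells; configurations that force
#' this are rejected as infeasible.
#'
#' @param config a [sim_config()].
#' @return an object of class `truth_set`: a list with elements `meta`
#'   (sample metadata), `mutations`, `clones`, `fractions` (clone x sample
#'   cell fractions), `expected_vaf` (mutation x sample), `annotations`,
#'   `error_sites` and `config`.
#' @export
#' @examples
#' truth <- simulate_truth(sim_config(n_patients = 2, n_germline = 5, seed = 3))
#' truth
simulate_truth <- function(config) {
  stop_if(!inherits(config, "sim_config"), "'config' must be a sim_config()")
  set.seed(config$seed)
  npat <- config$n_patients
  patients <- sprintf("P%02d", seq_len(npat))
  sex <- if (!is.null(config$sex)) rep(config$sex, length.out = npat)
         else sample(c("male", "female"), npat, replace = TRUE)

  ## ---- sample metadata with 1-D segment geometry --------------------------
  meta <- do.call(rbind, lapply(seq_len(npat), function(i) {
    nseg <- draw_int(1L, config$segments_per_plaque)
    widths <- round(draw_unif(nseg, config$segment_width_mm), 2)
    gaps <- if (nseg > 1) round(draw_unif(nseg - 1L, config$inter_segment_gap_mm), 2)
            else numeric(0)
    starts <- cumsum(c(0, widths[-nseg] + gaps))
    yields <- round(stats::rlnorm(nseg, log(6.6e5), 0.5))
    rbind(
      data.frame(patient = patients[i],
                 sample_id = sprintf("%s_s%d", patients[i], seq_len(nseg)),
                 sex = sex[i], tissue_class = "plaque",
                 start_mm = starts, end_mm = starts + widths,
                 dna_yield_pg = yields),
      data.frame(patient = patients[i],
                 sample_id = paste0(patients[i], "_buffy"),
                 sex = sex[i], tissue_class = "buffy",
                 start_mm = NA_real_, end_mm = NA_real_,
                 dna_yield_pg = NA_real_)
    )
  }))
  rownames(meta) <- NULL

  ## ---- unique variant site allocator --------------------------------------
  used_keys <- character(0)
  bases <- c("A", "C", "G", "T")
  new_sites <- function(n, chroms) {
    if (n == 0)
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), alt = character()))
    got <- NULL
    while (is.null(got) || nrow(got) < n) {
      k <- n - if (is.null(got)) 0L else nrow(got)
      chrom <- sample(chroms, k, replace = TRUE)
      pos <- sample.int(2e8L, k, replace = TRUE) + 1e5L
      ri <- sample.int(4L, k, replace = TRUE)
      ai <- (ri + sample.int(3L, k, replace = TRUE) - 1L) %% 4L + 1L
      cand <- data.frame(chrom = chrom, pos = pos,
                         ref = bases[ri], alt = bases[ai])
      key <- variant_key(cand$chrom, cand$pos, cand$ref, cand$alt)
      ok <- !key %in% used_keys & !duplicated(key)
      used_keys <<- c(used_keys, key[ok])
      got <- rbind(got, cand[ok, , drop = FALSE])
    }
    rownames(got) <- NULL
    got
  }
  autosomes <- paste0("chr", 1:22)
  somatic_chroms <- c(autosomes, "chrX")

  mut_rows <- list(); clone_rows <- list(); frac_rows <- list()
  mut_counter <- 0L; clone_counter <- 0L

  chip <- config$chip
  carriers <- character(0)
  if (!is.null(chip) && chip$n_carriers > 0)
    carriers <- sample(patients, min(chip$n_carriers, npat))
  chip_genes <- if (!is.null(chip)) (chip$genes %||% chip_default_genes())

  ## ---- clones, per patient, with feasibility rejection --------------------
  for (i in seq_len(npat)) {
    p <- patients[i]
    psamp <- meta[meta$patient == p & meta$tissue_class == "plaque", ]
    nseg <- nrow(psamp)
    explicit <- !is.null(config$clone_spec)

    draw_patient <- function() {
      # returns list(clones = list of list(segments, fractions, n_mut, chrom))
      cl <- list()
      if (explicit) {
        for (cs in config$clone_spec) {
          if (patients[cs$patient %||% 1L] != p) next
          segs <- as.integer(cs$segments %||% seq_len(nseg))
          stop_if(any(segs < 1 | segs > nseg) || !all(diff(segs) == 1L),
                  "clone_spec segments must be a contiguous range within the plaque")
          fr <- rep(cs$fraction, length.out = length(segs))
          cl[[length(cl) + 1L]] <- list(segments = segs, fractions = fr,
                                        n_mut = as.integer(cs$n_mutations %||% 1L),
                                        chrom = cs$chrom)
        }
      } else {
        for (k in seq_len(draw_int(1L, config$n_clones))) {
          first <- sample.int(nseg, 1L)
          len <- sample.int(nseg - first + 1L, 1L)
          segs <- first:(first + len - 1L)
          cl[[length(cl) + 1L]] <- list(
            segments = segs,
            fractions = draw_unif(len, config$clone_fractions),
            n_mut = draw_int(1L, config$mutations_per_clone),
            chrom = NULL)
        }
      }
      # CHIP infiltration fractions for this patient (if carrier)
      ch <- list()
      if (p %in% carriers) {
        for (k in seq_len(draw_int(1L, chip$mutations_per_carrier))) {
          infil <- runif(nseg) < chip$infiltration_prob
          ch[[length(ch) + 1L]] <- list(
            blood = draw_unif(1L, chip$blood_fraction),
            segments = which(infil),
            fractions = draw_unif(sum(infil), chip$infiltration_fraction))
        }
      }
      list(clones = cl, chip = ch)
    }

    feasible <- function(d) {
      load <- numeric(nseg)
      for (cl in d$clones) load[cl$segments] <- load[cl$segments] + cl$fractions
      for (ch in d$chip) load[ch$segments] <- load[ch$segments] + ch$fractions
      blood <- sum(vapply(d$chip, `[[`, numeric(1), "blood"))
      all(load <= 1) && blood <= 1
    }

    d <- draw_patient()
    if (explicit) {
      stop_if(!feasible(d),
              "infeasible clonal architecture: summed clone fractions exceed 1 ",
              "in a sample of patient ", p)
    } else {
      tries <- 1L
      while (!feasible(d)) {
        tries <- tries + 1L
        stop_if(tries > 200L,
                "infeasible clonal architecture: could not place clones for ",
                "patient ", p, " with summed fractions <= 1")
        d <- draw_patient()
      }
    }

    for (cl in d$clones) {
      clone_counter <- clone_counter + 1L
      cid <- sprintf("C%03d", clone_counter)
      segs <- cl$segments
      clone_rows[[cid]] <- data.frame(
        clone_id = cid, patient = p, class = "somatic",
        n_mutations = cl$n_mut,
        seg_first = segs[1], seg_last = segs[length(segs)],
        start_mm = psamp$start_mm[segs[1]],
        end_mm = psamp$end_mm[segs[length(segs)]])
      frac_rows[[cid]] <- data.frame(clone_id = cid,
                                     sample_id = psamp$sample_id[segs],
                                     fraction = cl$fractions)
      sites <- new_sites(cl$n_mut,
                         if (is.null(cl$chrom)) somatic_chroms else cl$chrom)
      ids <- sprintf("M%05d", mut_counter + seq_len(cl$n_mut))
      mut_counter <- mut_counter + cl$n_mut
      mut_rows[[cid]] <- cbind(
        data.frame(id = ids, patient = p, clone_id = cid, class = "somatic"),
        sites,
        data.frame(gene = sprintf("GENE%s", substr(ids, 2, 6))))
    }
    for (ch in d$chip) {
      clone_counter <- clone_counter + 1L
      cid <- sprintf("H%03d", clone_counter)
      clone_rows[[cid]] <- data.frame(
        clone_id = cid, patient = p, class = "chip", n_mutations = 1L,
        seg_first = NA_integer_, seg_last = NA_integer_,
        start_mm = NA_real_, end_mm = NA_real_)
      frac_rows[[cid]] <- data.frame(
        clone_id = cid,
        sample_id = c(paste0(p, "_buffy"), psamp$sample_id[ch$segments]),
        fraction = c(ch$blood, ch$fractions))
      sites <- new_sites(1L, autosomes)
      ids <- sprintf("M%05d", mut_counter + 1L)
      mut_counter <- mut_counter + 1L
      mut_rows[[cid]] <- cbind(
        data.frame(id = ids, patient = p, clone_id = cid, class = "chip"),
        sites,
        data.frame(gene = sample(chip_genes, 1L)))
    }
  }

  ## ---- germline variants (autosomal heterozygous, every sample) -----------
  for (i in seq_len(npat)) {
    p <- patients[i]
    if (config$n_germline == 0) next
    sites <- new_sites(config$n_germline, autosomes)
    ids <- sprintf("M%05d", mut_counter + seq_len(config$n_germline))
    mut_counter <- mut_counter + config$n_germline
    mut_rows[[paste0("g", p)]] <- cbind(
      data.frame(id = ids, patient = p, clone_id = NA_character_,
                 class = "germline"),
      sites,
      data.frame(gene = sprintf("GENE%s", substr(ids, 2, 6))))
  }

  mutations <- if (length(mut_rows)) do.call(rbind, mut_rows) else
    data.frame(id = character(), patient = character(), clone_id = character(),
               class = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), gene = character())
  rownames(mutations) <- NULL
  clones <- if (length(clone_rows)) do.call(rbind, clone_rows) else
    data.frame(clone_id = character(), patient = character(),
               class = character(), n_mutations = integer(),
               seg_first = integer(), seg_last = integer(),
               start_mm = numeric(), end_mm = numeric())
  rownames(clones) <- NULL
  fractions <- if (length(frac_rows)) do.call(rbind, frac_rows) else
    data.frame(clone_id = character(), sample_id = character(),
               fraction = numeric())
  rownames(fractions) <- NULL

  ## ---- error-only sites ----------------------------------------------------
  error_sites <- NULL
  if (config$n_error_sites > 0) {
    error_sites <- do.call(rbind, lapply(patients, function(p) {
      cbind(data.frame(patient = p),
            new_sites(config$n_error_sites, autosomes))
    }))
    rownames(error_sites) <- NULL
  }

  ## ---- expected VAF per (mutation, sample) --------------------------------
  ev <- list()
  sex_of <- setNames(sex, patients)
  for (j in seq_len(nrow(mutations))) {
    m <- mutations[j, ]
    mult <- if (m$chrom %in% c("chrX", "chrY") && sex_of[[m$patient]] == "male")
      1 else 0.5
    if (m$class == "germline") {
      sids <- meta$sample_id[meta$patient == m$patient]
      ev[[j]] <- data.frame(id = m$id, sample_id = sids, expected_vaf = 0.5)
    } else {
      fr <- fractions[fractions$clone_id == m$clone_id, ]
      if (nrow(fr))
        ev[[j]] <- data.frame(id = m$id, sample_id = fr$sample_id,
                              expected_vaf = pmin(1, fr$fraction * mult))
    }
  }
  expected_vaf <- if (length(ev)) do.call(rbind, ev) else
    data.frame(id = character(), sample_id = character(),
               expected_vaf = numeric())
  rownames(expected_vaf) <- NULL

  annotations <- sim_annotations(mutations, error_sites)

  structure(list(meta = meta, mutations = mutations, clones = clones,
                 fractions = fractions, expected_vaf = expected_vaf,
                 annotations = annotations, error_sites = error_sites,
                 config = config),
            class = "truth_set")
}

# annotation table for planted mutations and error sites; CHIP mutations are
# guaranteed to satisfy the damaging criterion, germline variants carry a
# common gnomAD frequency so the tumor-only MAF filter removes them
sim_annotations <- function(mutations, error_sites) {
  ann_one <- function(class) {
    switch(class,
      somatic = {
        cons <- sample(c("missense", "synonymous", "loss_of_function", "other"),
                       1L, prob = c(0.6, 0.15, 0.15, 0.1))
        data.frame(consequence = cons,
                   gnomad_maf = if (runif(1) < 0.9) NA_real_ else runif(1, 0, 1e-3),
                   cadd_phred = round(runif(1, 0, 40), 1),
                   dbnsfp_damaging_votes = sample(0:5, 1L),
                   clinvar_damaging = FALSE)
      },
      germline = data.frame(
        consequence = sample(c("missense", "synonymous", "other"), 1L),
        gnomad_maf = round(runif(1, 0.05, 0.5), 4),
        cadd_phred = round(runif(1, 0, 20), 1),
        dbnsfp_damaging_votes = sample(0:2, 1L),
        clinvar_damaging = FALSE),
      chip = {
        lof <- runif(1) < 0.5
        data.frame(consequence = if (lof) "loss_of_function" else "missense",
                   gnomad_maf = NA_real_,
                   cadd_phred = round(runif(1, 24, 40), 1),
                   dbnsfp_damaging_votes = sample(4:5, 1L),
                   clinvar_damaging = runif(1) < 0.3)
      },
      error = data.frame(consequence = "other",
                         gnomad_maf = NA_real_,
                         cadd_phred = round(runif(1, 0, 20), 1),
                         dbnsfp_damaging_votes = 0L,
                         clinvar_damaging = FALSE))
  }
  rows <- list()
  if (nrow(mutations))
    rows$mut <- cbind(mutations[, c("chrom", "pos", "ref", "alt", "gene")],
                      do.call(rbind, lapply(mutations$class, ann_one)))
  if (!is.null(error_sites) && nrow(error_sites)) {
    es <- error_sites
    rows$err <- data.frame(
      chrom = es$chrom, pos = es$pos, ref = es$ref, alt = es$alt,
      gene = sprintf("GENE%05d", sample.int(99999L, nrow(es), replace = TRUE)),
      consequence = "other", gnomad_maf = NA_real_,
      cadd_phred = round(runif(nrow(es), 0, 20), 1),
      dbnsfp_damaging_votes = 0L, clinvar_damaging = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw binomially sampled read counts for a planted truth set
#'
#' Emits candidate variant observation rows for every sequencing round.
#' Alt-read counts at a site with expected VAF v are Binomial(depth, p) with
#' p = v + (1 - v) * error_rate; per-site depth is Poisson(depth) truncated
#' at 1 (or constant, per the config). Tissue samples carry rows for all of
#' the patient's somatic, germline and error sites (zero-VAF sites included,
#' so coverage is explicit); the buffy coat carries germline, CHIP and
#' error-only sites but never tissue-restricted somatic sites, mirroring a
#' UMI-error-corrected matched reference in which sub-0.1% noise at somatic
#' sites is suppressed. CHIP sites are emitted in every sample of every
#' patient so that force-calling has cohort-wide coverage.
#'
#' @param truth a [simulate_truth()] result.
#' @param config the same [sim_config()] the truth was generated from.
#' @return a variant observation `data.frame` (one row per variant, sample
#'   and round) with columns `patient`, `sample_id`, `round`, `chrom`,
#'   `pos`, `ref`, `alt`, `alt_reads`, `total_reads`, `mean_base_quality`.
#' @export
simulate_reads <- function(truth, config) {
  stop_if(!inherits(truth, "truth_set"), "'truth' must be a truth_set")
  stop_if(!identical(truth$config$seed, config$seed),
          "'truth' was generated from a different config (seed mismatch)")
  set.seed(if (config$seed < 2147483646L) config$seed + 1L else 1L)
  meta <- truth$meta
  mut <- truth$mutations

  targets <- list()
  if (nrow(mut)) {
    for (j in seq_len(nrow(mut))) {
      m <- mut[j, ]
      sids <- switch(m$class,
        somatic = meta$sample_id[meta$patient == m$patient &
                                 meta$tissue_class != "buffy"],
        germline = meta$sample_id[meta$patient == m$patient],
        chip = meta$sample_id)
      targets[[j]] <- data.frame(chrom = m$chrom, pos = m$pos, ref = m$ref,
                                 alt = m$alt, sample_id = sids)
    }
  }
  if (!is.null(truth$error_sites) && nrow(truth$error_sites)) {
    for (p in unique(truth$error_sites$patient)) {
      es <- truth$error_sites[truth$error_sites$patient == p, , drop = FALSE]
      sids <- meta$sample_id[meta$patient == p]
      idx <- rep(seq_len(nrow(es)), times = length(sids))
      targets[[length(targets) + 1L]] <-
        data.frame(chrom = es$chrom[idx], pos = es$pos[idx],
                   ref = es$ref[idx], alt = es$alt[idx],
                   sample_id = rep(sids, each = nrow(es)))
    }
  }
  if (!length(targets)) {
    return(check_obs(data.frame(
      patient = character(), sample_id = character(), round = integer(),
      chrom = character(), pos = integer(), ref = character(),
      alt = character(), alt_reads = integer(), total_reads = integer(),
      mean_base_quality = numeric())))
  }
  tg <- do.call(rbind, targets)
  tg$patient <- meta$patient[match(tg$sample_id, meta$sample_id)]

  # expected VAF lookup (0 where the site is covered but the clone is absent)
  ev <- truth$expected_vaf
  mut_key <- variant_key(mut$chrom, mut$pos, mut$ref, mut$alt)
  ev$key <- mut_key[match(ev$id, mut$id)]
  tg$key <- variant_key(tg$chrom, tg$pos, tg$ref, tg$alt)
  idx <- match(paste(tg$key, tg$sample_id), paste(ev$key, ev$sample_id))
  tg$vaf <- ifelse(is.na(idx), 0, ev$expected_vaf[idx])

  rounds <- lapply(seq_len(config$n_rounds), function(r) {
    n <- nrow(tg)
    depth <- if (config$depth_model == "constant") rep(round(config$depth), n)
             else pmax(1L, rpois(n, config$depth))
    p <- pmin(1, tg$vaf + (1 - tg$vaf) * config$error_rate)
    alt <- rbinom(n, depth, p)
    mbq <- round(pmin(60, pmax(2, rnorm(n, config$base_quality_mean,
                                        config$base_quality_sd))), 1)
    data.frame(patient = tg$patient, sample_id = tg$sample_id, round = r,
               chrom = tg$chrom, pos = tg$pos, ref = tg$ref, alt = tg$alt,
               alt_reads = alt, total_reads = depth, mean_base_quality = mbq)
  })
  obs <- do.call(rbind, rounds)
  obs <- obs[order(obs$patient, obs$sample_id, obs$chrom, obs$pos, obs$alt,
                   obs$round), ]
  rownames(obs) <- NULL
  check_obs(obs)
}

#' Simulate a complete dataset in one call
#'
#' Convenience wrapper running [simulate_truth()] then [simulate_reads()].
#'
#' @param config a [sim_config()].
#' @return an object of class `plaque_sim`: list with `truth`, `obs`,
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_truth(config)
  obs <- simulate_reads(truth, config)
  structure(list(truth = truth, obs = obs, config = config),
            class = "plaque_sim")
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Planted truth set: ", length(unique(x$meta$patient)), " patients, ",
      sum(x$meta$tissue_class == "plaque"), " plaque segments\n", sep = "")
  tab <- table(factor(x$mutations$class,
                      levels = c("somatic", "germline", "chip")))
  cat("  mutations: ", tab[["somatic"]], " somatic, ", tab[["germline"]],
      " germline, ", tab[["chip"]], " CHIP\n", sep = "")
  cat("  clones: ", sum(x$clones$class == "somatic"), " somatic, ",
      sum(x$clones$class == "chip"), " CHIP\n", sep = "")
  invisible(x)
}

#' @export
print.plaque_sim <- function(x, ...) {
  print(x$truth)
  cat("  observation rows: ", nrow(x$obs), " (", x$config$n_rounds,
      " rounds)\n", sep = "")
  invisible(x)
}
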