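#' Pool read counts across sequencing rounds
#'
#' The round-pooled VAF weights each round by its read count:
#' `sum(alt) / sum(total)`. It always lies between the smallest and largest
#' per-round VAF, and equals the simple mean of round VAFs when depths are
#' equal.
#'
#' @param alt_reads,total_reads alternate and total read counts per round.
#' @return the pooled VAF, or `NA` if no round has coverage.
#' @export
#' @examples
#' pool_rounds(c(7, 14), c(700, 700))   # 21/1400 = 0.015
pool_rounds <- function(alt_reads, total_reads) {
  stop_if(length(alt_reads) != length(total_reads),
          "'alt_reads' and 'total_reads' must have the same length")
  stop_if(any(alt_reads > total_reads, na.rm = TRUE),
          "alt_reads cannot exceed total_reads")
  tot <- sum(total_reads, na.rm = TRUE)
  if (tot == 0) return(NA_real_)
  sum(alt_reads, na.rm = TRUE) / tot
}

#' Convert VAF to clonal cell frequency
#'
#' Under diploidy and mutation heterozygosity, a mutation carried by a
#' fraction f of cells is seen on one of two autosomal copies, so its
#' expected VAF is f/2 and the clonal cell frequency is 2 x VAF. Males have
#' a single X (and Y), so chrX/chrY VAFs in male patients convert with
#' multiplier 1. Female chrX variants are heterozygous on one of two X's
#' and convert like autosomes. The result is capped at 1; the uncapped
#' value is available via `cap = FALSE`.
#'
#' @param vaf numeric VAF(s) in `[0, 1]`.
#' @param chrom chromosome label(s), recycled; normalized with
#'   [normalize_chrom()].
#' @param sex `"male"` or `"female"`, recycled. Required (no default) when
#'   any variant lies on chrX/chrY.
#' @param cap cap frequencies at 1 (default `TRUE`).
#' @return clonal cell frequencies in `[0, 1]` (or uncapped in `[0, 2]`).
#' @export
#' @examples
#' vaf_to_ccf(0.013, "chr2", "female")  # 0.026
#' vaf_to_ccf(0.10, "chrX", "male")     # 0.10
vaf_to_ccf <- function(vaf, chrom = "chr1", sex = NA_character_, cap = TRUE) {
  stop_if(any(vaf < 0 | vaf > 1, na.rm = TRUE), "'vaf' must lie in [0, 1]")
  n <- max(length(vaf), length(chrom), length(sex))
  vaf <- rep_len(vaf, n)
  chrom <- normalize_chrom(rep_len(chrom, n))
  sex <- rep_len(as.character(sex), n)
  sexchrom <- chrom %in% c("chrX", "chrY")
  bad_sex <- sexchrom & (is.na(sex) | !sex %in% c("male", "female"))
  stop_if(any(bad_sex),
          "sex must be 'male' or 'female' for chrX/chrY variants")
  stop_if(any(chrom == "chrY" & sex == "female", na.rm = TRUE),
          "chrY variant in a female patient is an input error")
  mult <- ifelse(sexchrom & sex == "male", 1, 2)
  ccf <- vaf * mult
  if (cap) pmin(ccf, 1) else ccf
}

#' Estimate sample cell count from DNA yield
#'
#' Assumes an average diploid DNA content of 6.6 pg per cell.
#'
#' @param dna_yield_pg DNA yield(s) in picograms; must be positive. `NA`
#'   yields propagate as `NA` (metric unavailable, never zero).
#' @return `data.frame` with `dna_yield_pg`, `cells` (real-valued estimate)
#'   and `cells_rounded`.
#' @export
#' @examples
#' estimate_cell_count(6600)  # 1000 cells
estimate_cell_count <- function(dna_yield_pg) {
  stop_if(any(dna_yield_pg <= 0, na.rm = TRUE),
          "'dna_yield_pg' must be positive")
  cells <- dna_yield_pg / 6.6
  data.frame(dna_yield_pg = dna_yield_pg, cells = cells,
             cells_rounded = round(cells))
}

#' Quantify validated mutations in every sample of their patient
#'
#' For each patient-validated mutation and each sample of that patient,
#' pools alternate/total reads over sequencing rounds, computes the pooled
#' VAF, applies the per-sample presence rule (pooled alt reads >= 5 and
#' pooled VAF >= 1%, reusing the discovery thresholds), and converts
#' present VAFs to clonal cell frequencies with sex-chromosome handling.
#' Absent or below-threshold entries get frequency 0 for mapping purposes.
#'
#' @param validated validated-mutation table from [run_filter_cascade()].
#' @param obs full observation table.
#' @param meta sample metadata.
#' @param params a [filter_params()] (presence thresholds).
#' @param annotations optional annotation table; adds `gene` and
#'   `consequence` columns.
#' @return `data.frame` of class `somatic_mutations`: one row per
#'   (mutation, sample) with pooled counts, `vaf`, `detected`, `ccf` and
#'   `ccf_uncapped`.
#' @export
quantify_mutations <- function(validated, obs, meta,
                               params = filter_params(),
                               annotations = NULL) {
  check_obs(obs); check_meta(meta)
  empty <- data.frame(patient = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      sample_id = character(), tissue_class = character(),
                      alt_reads = integer(), total_reads = integer(),
                      vaf = numeric(), detected = logical(),
                      ccf = numeric(), ccf_uncapped = numeric(),
                      gene = character(), consequence = character())
  if (nrow(validated) == 0)
    return(structure(empty, class = c("somatic_mutations", "data.frame")))
  obs$chrom <- normalize_chrom(obs$chrom)
  okey <- paste(obs$patient, variant_key(obs$chrom, obs$pos, obs$ref, obs$alt))
  vk <- paste(validated$patient,
              variant_key(validated$chrom, validated$pos, validated$ref,
                          validated$alt))
  sub <- obs[okey %in% vk, , drop = FALSE]
  skey <- paste(sub$patient,
                variant_key(sub$chrom, sub$pos, sub$ref, sub$alt))
  by_key <- split(seq_len(nrow(sub)), skey)
  out <- list()
  for (i in seq_len(nrow(validated))) {
    v <- validated[i, ]
    sx <- patient_sex(meta, v$patient)
    samples <- meta[meta$patient == v$patient, , drop = FALSE]
    rows <- sub[by_key[[vk[i]]], , drop = FALSE]
    per <- lapply(seq_len(nrow(samples)), function(s) {
      sid <- samples$sample_id[s]
      r <- rows[rows$sample_id == sid, , drop = FALSE]
      alt <- sum(r$alt_reads); tot <- sum(r$total_reads)
      vaf <- if (tot > 0) alt / tot else NA_real_
      det <- !is.na(vaf) && alt >= params$min_alt_reads &&
        vaf >= params$min_vaf
      ccf_u <- if (det) vaf_to_ccf(vaf, v$chrom, sx, cap = FALSE) else 0
      data.frame(patient = v$patient, chrom = v$chrom, pos = v$pos,
                 ref = v$ref, alt = v$alt, sample_id = sid,
                 tissue_class = samples$tissue_class[s],
                 alt_reads = alt, total_reads = tot,
                 vaf = ifelse(is.na(vaf), NA_real_, vaf),
                 detected = det, ccf = min(ccf_u, 1), ccf_uncapped = ccf_u)
    })
    out[[i]] <- do.call(rbind, per)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  if (!is.null(annotations)) {
    akey <- variant_key(annotations$chrom, annotations$pos,
                        annotations$ref, annotations$alt)
    idx <- match(variant_key(out$chrom, out$pos, out$ref, out$alt), akey)
    out$gene <- annotations$gene[idx]
    out$consequence <- annotations$consequence[idx]
  } else {
    out$gene <- NA_character_
    out$consequence <- NA_character_
  }
  structure(out, class = c("somatic_mutations", "data.frame"))
}

#' Summaries of clonal cell frequencies
#'
#' Per-patient and per-sample summaries (count, median, IQR, range) of
#' clonal cell frequencies over detected (mutation, sample) pairs in plaque
#' tissue, plus Spearman rank correlations of per-sample mutation count and
#' median frequency against the estimated number of sample cells (from DNA
#' yield at 6.6 pg/cell). Patients with zero mutations are reported with
#' count 0, not dropped.
#'
#' @param mutations a [quantify_mutations()] table.
#' @param meta sample metadata (enumerates patients/samples and provides
#'   DNA yields).
#' @return list with `patient`, `sample` and `correlations` data frames.
#' @export
summarize_frequencies <- function(mutations, meta) {
  check_meta(meta)
  det <- mutations[mutations$detected & mutations$tissue_class == "plaque", ,
                   drop = FALSE]
  summ <- function(x) {
    if (length(x) == 0)
      return(data.frame(n_detections = 0L, median_ccf = NA_real_,
                        q25 = NA_real_, q75 = NA_real_,
                        min_ccf = NA_real_, max_ccf = NA_real_))
    q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
    data.frame(n_detections = length(x), median_ccf = q[2],
               q25 = q[1], q75 = q[3], min_ccf = min(x), max_ccf = max(x))
  }
  patients <- unique(meta$patient)
  pat <- do.call(rbind, lapply(patients, function(p) {
    d <- det[det$patient == p, , drop = FALSE]
    cbind(data.frame(
      patient = p,
      n_mutations = length(unique(variant_key(d$chrom, d$pos, d$ref, d$alt)))),
      summ(d$ccf))
  }))
  plaque <- meta[meta$tissue_class == "plaque", , drop = FALSE]
  samp <- do.call(rbind, lapply(seq_len(nrow(plaque)), function(s) {
    sid <- plaque$sample_id[s]
    d <- det[det$sample_id == sid, , drop = FALSE]
    cells <- if (is.na(plaque$dna_yield_pg[s])) NA_real_ else
      estimate_cell_count(plaque$dna_yield_pg[s])$cells
    cbind(data.frame(patient = plaque$patient[s], sample_id = sid,
                     est_cells = cells),
          summ(d$ccf))
  }))
  cors <- data.frame(metric = c("n_detections_vs_cells",
                                "median_ccf_vs_cells"),
                     spearman_rho = NA_real_, n = NA_integer_)
  ok <- !is.na(samp$est_cells)
  if (sum(ok) >= 3) {
    cors$spearman_rho[1] <- cor(samp$n_detections[ok], samp$est_cells[ok],
                                method = "spearman")
    cors$n[1] <- sum(ok)
    ok2 <- ok & !is.na(samp$median_ccf)
    if (sum(ok2) >= 3) {
      cors$spearman_rho[2] <- cor(samp$median_ccf[ok2], samp$est_cells[ok2],
                                  method = "spearman")
      cors$n[2] <- sum(ok2)
    }
  }
  list(patient = pat, sample = samp, correlations = cors)
}
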