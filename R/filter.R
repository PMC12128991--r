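#' Somatic filtering thresholds
#'
#' Parameters of the matched tissue-vs-buffy filtering cascade. Defaults are
#' the discovery settings of the targeted study design: a variant is
#' accepted in a sample/round when it has at least 5 alternate reads, a VAF
#' of 1% or more, a mean base quality of at least 25, and no or very low
#' signal in the patient's buffy coat (VAF < 0.01%; at 700x this effectively
#' demands zero alternate reads, and absence from the buffy calls counts as
#' zero). A mutation is validated for a patient when it passes the full
#' per-round filter in at least `require_rounds` independent sequencing
#' rounds in at least one sample. Variants whose VAF is ~50% in every
#' covered sample of the patient are removed as germline, and variants
#' validated in more than one patient are excluded as artifacts.
#'
#' @param min_alt_reads minimum alternate reads per sample/round.
#' @param min_vaf minimum VAF per sample/round.
#' @param max_buffy_vaf strict upper bound on the matched buffy-coat VAF.
#' @param min_base_quality minimum mean base quality (Phred).
#' @param require_rounds independent rounds that must pass.
#' @param germline_vaf_low,germline_vaf_high VAF window operationalizing
#'   "approximately 50% in all samples"; must contain 0.5.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(min_alt_reads = 5,
                          min_vaf = 0.01,
                          max_buffy_vaf = 1e-4,
                          min_base_quality = 25,
                          require_rounds = 2,
                          germline_vaf_low = 0.40,
                          germline_vaf_high = 0.60) {
  stop_if(min_alt_reads < 1, "'min_alt_reads' must be >= 1")
  check_range(min_vaf, "min_vaf", 0, 1, len = 1L)
  check_range(max_buffy_vaf, "max_buffy_vaf", 0, 1, len = 1L)
  stop_if(require_rounds < 1, "'require_rounds' must be >= 1")
  stop_if(germline_vaf_low > 0.5 || germline_vaf_high < 0.5,
          "germline VAF window must contain 0.5")
  structure(list(min_alt_reads = min_alt_reads, min_vaf = min_vaf,
                 max_buffy_vaf = max_buffy_vaf,
                 min_base_quality = min_base_quality,
                 require_rounds = as.integer(require_rounds),
                 germline_vaf_low = germline_vaf_low,
                 germline_vaf_high = germline_vaf_high),
            class = "filter_params")
}

#' Per-round matched filter against the buffy coat
#'
#' Applies the per-sample/per-round acceptance rule to tissue observations
#' of one patient and one sequencing round, using the same round's
#' buffy-coat observations as the matched reference. A variant absent from
#' the buffy table is treated as buffy VAF 0.
#'
#' @param tissue_obs observation rows for the patient's tissue samples in
#'   one round.
#' @param buffy_obs observation rows for the same patient's buffy coat in
#'   the same round; missing buffy data is a hard error (the matched design
#'   is mandatory).
#' @param params a [filter_params()].
#' @return the kept subset of `tissue_obs`, with columns `vaf` and
#'   `buffy_vaf` appended; rejected rows with their failure reason are
#'   attached as attribute `"rejected"`.
#' @export
filter_matched_round <- function(tissue_obs, buffy_obs, params = filter_params()) {
  stop_if(is.null(buffy_obs),
          "matched buffy-coat observations are missing for this patient")
  check_obs(tissue_obs)
  if (nrow(tissue_obs) == 0) {
    out <- cbind(tissue_obs, vaf = numeric(0), buffy_vaf = numeric(0))
    attr(out, "rejected") <- cbind(tissue_obs, reason = character(0))
    return(out)
  }
  key <- variant_key(tissue_obs$chrom, tissue_obs$pos, tissue_obs$ref,
                     tissue_obs$alt)
  bvaf <- rep(0, nrow(tissue_obs))
  if (nrow(buffy_obs) > 0) {
    bkey <- variant_key(buffy_obs$chrom, buffy_obs$pos, buffy_obs$ref,
                        buffy_obs$alt)
    bv <- ifelse(buffy_obs$total_reads > 0,
                 buffy_obs$alt_reads / buffy_obs$total_reads, 0)
    idx <- match(key, bkey)
    bvaf[!is.na(idx)] <- bv[idx[!is.na(idx)]]
  }
  vaf <- ifelse(tissue_obs$total_reads > 0,
                tissue_obs$alt_reads / tissue_obs$total_reads, 0)
  pass_alt <- tissue_obs$alt_reads >= params$min_alt_reads
  pass_vaf <- vaf >= params$min_vaf
  pass_bq <- !is.na(tissue_obs$mean_base_quality) &
    tissue_obs$mean_base_quality >= params$min_base_quality
  pass_buffy <- bvaf < params$max_buffy_vaf
  keep <- pass_alt & pass_vaf & pass_bq & pass_buffy

  out <- cbind(tissue_obs[keep, , drop = FALSE],
               vaf = vaf[keep], buffy_vaf = bvaf[keep])
  reason <- rep(NA_character_, nrow(tissue_obs))
  reason[!pass_buffy] <- "buffy_signal"
  reason[!pass_bq] <- "base_quality"
  reason[!pass_vaf] <- "low_vaf"
  reason[!pass_alt] <- "few_alt_reads"
  rej <- cbind(tissue_obs[!keep, , drop = FALSE],
               reason = reason[!keep])
  rownames(out) <- rownames(rej) <- NULL
  attr(out, "rejected") <- rej
  out
}

#' Two-round concordance rule
#'
#' A mutation is validated for a patient when it independently passes the
#' full per-round filter in at least `require_rounds` sequencing rounds in
#' at least one sample of that patient. A dataset that does not carry
#' enough rounds to ever satisfy the rule is an explicit error, never a
#' silent pass-through.
#'
#' @param candidates row-bound output of [filter_matched_round()] across
#'   patients, samples and rounds.
#' @param params a [filter_params()].
#' @param available_rounds the sequencing rounds present in the dataset
#'   (defaults to the rounds seen among the candidates).
#' @return `data.frame` of validated mutations: `patient`, `chrom`, `pos`,
#'   `ref`, `alt`, and `samples_validated` (comma-separated sample ids in
#'   which the rule held).
#' @export
require_round_concordance <- function(candidates, params = filter_params(),
                                      available_rounds = NULL) {
  if (is.null(available_rounds))
    available_rounds <- sort(unique(candidates$round))
  stop_if(length(available_rounds) < params$require_rounds,
          "dataset has ", length(available_rounds),
          " sequencing round(s) but require_rounds = ",
          params$require_rounds,
          "; the concordance rule can never be satisfied")
  empty <- data.frame(patient = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      samples_validated = character())
  if (nrow(candidates) == 0) return(empty)
  key <- variant_key(candidates$chrom, candidates$pos, candidates$ref,
                     candidates$alt)
  grp <- paste(candidates$patient, candidates$sample_id, key, sep = "\r")
  nrounds <- tapply(candidates$round, grp, function(r) length(unique(r)))
  ok <- names(nrounds)[nrounds >= params$require_rounds]
  if (length(ok) == 0) return(empty)
  parts <- do.call(rbind, strsplit(ok, "\r", fixed = TRUE))
  hit <- data.frame(patient = parts[, 1], sample_id = parts[, 2],
                    key = parts[, 3])
  agg <- stats::aggregate(sample_id ~ patient + key, data = hit,
                          FUN = function(s) paste(sort(unique(s)),
                                                  collapse = ","))
  kp <- strsplit(agg$key, ":", fixed = TRUE)
  out <- data.frame(patient = agg$patient,
                    chrom = vapply(kp, `[`, "", 1),
                    pos = as.integer(vapply(kp, `[`, "", 2)),
                    ref = vapply(kp, `[`, "", 3),
                    alt = vapply(kp, `[`, "", 4),
                    samples_validated = agg$sample_id)
  out <- out[order(out$patient, out$chrom, out$pos, out$alt), ]
  rownames(out) <- NULL
  out
}

#' Remove germline variants
#'
#' Drops validated variants whose round-pooled VAF lies within the germline
#' window (default 0.40-0.60, operationalizing "approximately 50%") in
#' every sample of the patient that has coverage at the site, including the
#' buffy coat.
#'
#' @param validated validated-mutation table
#'   (see [require_round_concordance()]).
#' @param obs full observation table of the cohort (all samples, all
#'   rounds).
#' @param params a [filter_params()].
#' @return `validated` without germline rows; removed rows are attached as
#'   attribute `"removed"`.
#' @export
remove_germline <- function(validated, obs, params = filter_params()) {
  if (nrow(validated) == 0) {
    attr(validated, "removed") <- validated
    return(validated)
  }
  check_obs(obs)
  vkey <- paste(validated$patient,
                variant_key(validated$chrom, validated$pos, validated$ref,
                            validated$alt))
  okey <- paste(obs$patient,
                variant_key(obs$chrom, obs$pos, obs$ref, obs$alt))
  sub <- obs[okey %in% vkey, , drop = FALSE]
  is_germ <- rep(FALSE, nrow(validated))
  if (nrow(sub) > 0) {
    skey <- paste(sub$patient,
                  variant_key(sub$chrom, sub$pos, sub$ref, sub$alt))
    # pool rounds per (patient-variant, sample), then ask whether every
    # covered sample of the patient sits inside the germline VAF window
    g <- paste(skey, sub$sample_id, sep = "\r")
    alt <- tapply(sub$alt_reads, g, sum)
    tot <- tapply(sub$total_reads, g, sum)
    covered <- tot > 0
    pooled <- alt[covered] / tot[covered]
    pk <- sub("\r.*$", "", names(pooled))
    in_window <- pooled >= params$germline_vaf_low &
      pooled <= params$germline_vaf_high
    all_in <- tapply(in_window, pk, all)
    hit <- names(all_in)[all_in]
    is_germ <- vkey %in% hit
  }
  out <- validated[!is_germ, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- validated[is_germ, , drop = FALSE]
  out
}

#' Exclude cross-patient recurrent variants
#'
#' A substitution validated in more than one patient is almost certainly a
#' platform artifact rather than independent somatic events at the same
#' base; such variants are removed from every patient. Requires a
#' multi-patient cohort.
#'
#' @param validated validated-mutation table across all patients.
#' @return `validated` without recurrent rows; excluded rows (with the list
#'   of patients sharing them) attached as attribute `"excluded"`.
#' @export
exclude_cross_patient <- function(validated) {
  if (nrow(validated) == 0) {
    attr(validated, "excluded") <- validated
    return(validated)
  }
  key <- variant_key(validated$chrom, validated$pos, validated$ref,
                     validated$alt)
  npat <- tapply(validated$patient, key, function(p) length(unique(p)))
  recurrent <- names(npat)[npat > 1]
  drop <- key %in% recurrent
  out <- validated[!drop, , drop = FALSE]
  rownames(out) <- NULL
  exc <- validated[drop, , drop = FALSE]
  if (nrow(exc) > 0)
    exc$shared_with <- vapply(
      variant_key(exc$chrom, exc$pos, exc$ref, exc$alt),
      function(k) paste(sort(unique(validated$patient[key == k])),
                        collapse = ","), "")
  attr(out, "excluded") <- exc
  out
}

#' Run the full somatic filtering cascade
#'
#' Applies, in order: the per-round matched filter for every patient and
#' round, the round-concordance rule, germline removal, and cross-patient
#' recurrence exclusion. Every stage only removes variants (the output of
#' each stage is a subset of its input) and the per-stage funnel counts are
#' returned for reporting.
#'
#' @param obs observation table (tissue and buffy, all rounds).
#' @param meta sample metadata.
#' @param params a [filter_params()].
#' @return list of class `filter_result` with elements `validated` (final
#'   somatic mutation set), `funnel` (per-stage distinct-variant counts),
#'   `candidates` (per-round accepted rows), `germline_removed`,
#'   `cross_patient_excluded`, `params`.
#' @export
run_filter_cascade <- function(obs, meta, params = filter_params()) {
  check_obs(obs); check_meta(meta)
  obs$chrom <- normalize_chrom(obs$chrom)
  patients <- unique(meta$patient[meta$tissue_class != "buffy"])
  buffy_ids <- meta$sample_id[meta$tissue_class == "buffy"]
  rounds <- sort(unique(obs$round))

  cand <- list()
  for (p in patients) {
    pobs <- obs[obs$patient == p, , drop = FALSE]
    bid <- meta$sample_id[meta$patient == p & meta$tissue_class == "buffy"]
    stop_if(length(bid) == 0 || !any(pobs$sample_id %in% bid),
            "no buffy-coat observations for patient ", p,
            " (matched design is mandatory)")
    for (r in rounds) {
      tiss <- pobs[pobs$round == r & !pobs$sample_id %in% buffy_ids, ,
                   drop = FALSE]
      buff <- pobs[pobs$round == r & pobs$sample_id %in% buffy_ids, ,
                   drop = FALSE]
      cand[[paste(p, r)]] <- filter_matched_round(tiss, buff, params)
    }
  }
  candidates <- do.call(rbind, lapply(cand, function(x) {
    attr(x, "rejected") <- NULL; x
  }))
  rownames(candidates) <- NULL

  validated <- require_round_concordance(candidates, params,
                                         available_rounds = rounds)
  n_cand <- length(unique(paste(
    candidates$patient,
    variant_key(candidates$chrom, candidates$pos, candidates$ref,
                candidates$alt))))
  somatic <- remove_germline(validated, obs, params)
  final <- if (length(patients) > 1) exclude_cross_patient(somatic)
           else { attr(somatic, "excluded") <- somatic[0, ]; somatic }

  funnel <- data.frame(
    stage = c("per_round_candidates", "round_concordant", "non_germline",
              "patient_unique"),
    n_variants = c(n_cand, nrow(validated), nrow(somatic), nrow(final)))
  structure(list(validated = final, funnel = funnel,
                 candidates = candidates,
                 germline_removed = attr(somatic, "removed"),
                 cross_patient_excluded = attr(final, "excluded"),
                 params = params),
            class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("Somatic filtering cascade\n")
  for (i in seq_len(nrow(x$funnel)))
    cat(sprintf("  %-22s %6d\n", x$funnel$stage[i], x$funnel$n_variants[i]))
  invisible(x)
}
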