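#' Bundled CHIP gene list
#'
#' Reads the 78-gene clonal-hematopoiesis driver list shipped with the
#' package (`extdata/chip_genes.txt`, one symbol per line, `#` comments).
#' The list is a plain editable text file; supply your own via
#' [chip_params()].
#'
#' @return character vector of gene symbols.
#' @export
chip_default_genes <- function() {
  path <- system.file("extdata", "chip_genes.txt", package = "plaqueclone")
  read_gene_list(path)
}

read_gene_list <- function(path) {
  stop_if(!nzchar(path) || !file.exists(path),
          "CHIP gene list file not found: ", path)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  stop_if(length(x) == 0, "CHIP gene list is empty: ", path)
  unique(x)
}

#' CHIP screening thresholds
#'
#' Parameters of the tumor-only screening cascade applied to buffy-coat
#' calls: the variant must fall in a listed CHIP gene, be covered by at
#' least 20 reads, have a VAF of at least 1%, a gnomAD minor allele
#' frequency below 1% (absence from gnomAD counts as rare and passes), and
#' carry known or predicted damaging evidence - a ClinVar pathogenic flag,
#' a loss-of-function consequence, a CADD Phred score above 23, or at
#' least 4 of the 5 dbNSFP predictors voting damaging.
#'
#' @param gene_list character vector of CHIP gene symbols, or a path to a
#'   one-symbol-per-line file; defaults to the bundled 78-gene list.
#' @param min_depth minimum total reads at the site (pooled over rounds).
#' @param max_gnomad_maf gnomAD MAF upper bound.
#' @param min_cadd CADD Phred score above which a variant counts as
#'   damaging.
#' @param min_votes dbNSFP damaging votes (out of 5) that count as damaging.
#' @param min_vaf minimum buffy-coat VAF.
#' @param germline_window VAF window of the approximately-50%-everywhere
#'   germline exclusion applied on top of the MAF filter.
#' @return object of class `chip_params`.
#' @export
chip_params <- function(gene_list = NULL,
                        min_depth = 20,
                        max_gnomad_maf = 0.01,
                        min_cadd = 23,
                        min_votes = 4,
                        min_vaf = 0.01,
                        germline_window = c(0.40, 0.60)) {
  genes <- if (is.null(gene_list)) chip_default_genes()
           else if (is.character(gene_list) && length(gene_list) == 1 &&
                    file.exists(gene_list)) read_gene_list(gene_list)
           else as.character(gene_list)
  stop_if(length(genes) == 0, "CHIP gene list is empty")
  stop_if(min_depth < 1, "'min_depth' must be >= 1")
  check_range(max_gnomad_maf, "max_gnomad_maf", 0, 1, len = 1L)
  stop_if(min_votes < 0 || min_votes > 5, "'min_votes' must be in 0-5")
  check_range(min_vaf, "min_vaf", 0, 1, len = 1L)
  stop_if(germline_window[1] > 0.5 || germline_window[2] < 0.5,
          "'germline_window' must contain 0.5")
  structure(list(gene_list = genes, min_depth = min_depth,
                 max_gnomad_maf = max_gnomad_maf, min_cadd = min_cadd,
                 min_votes = min_votes, min_vaf = min_vaf,
                 germline_window = germline_window),
            class = "chip_params")
}

#' Screen buffy-coat calls for CHIP mutations
#'
#' Applies the tumor-only cascade of [chip_params()] to round-pooled
#' buffy-coat observations joined to the annotation table, then removes
#' candidates whose VAF is ~50% in every covered sample of the patient
#' (residual germline heterozygotes that slipped past the MAF filter).
#'
#' @param obs full observation table (all samples; the buffy rows are
#'   selected via `meta`, the tissue rows feed the germline rule).
#' @param meta sample metadata.
#' @param annotations annotation table ([read_annotations()] format).
#' @param params a [chip_params()].
#' @return `data.frame` of candidate CHIP mutations with buffy pooled
#'   counts, VAF and clonal cell frequency.
#' @export
screen_buffy <- function(obs, meta, annotations, params = chip_params()) {
  check_obs(obs); check_meta(meta)
  stop_if(is.null(annotations), "CHIP screening requires an annotation table")
  obs$chrom <- normalize_chrom(obs$chrom)
  buffy_ids <- meta$sample_id[meta$tissue_class == "buffy"]
  b <- obs[obs$sample_id %in% buffy_ids, , drop = FALSE]
  empty <- data.frame(patient = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      gene = character(), consequence = character(),
                      buffy_alt_reads = integer(),
                      buffy_total_reads = integer(),
                      buffy_vaf = numeric(), buffy_ccf = numeric())
  if (nrow(b) == 0) return(empty)

  g <- paste(b$patient, variant_key(b$chrom, b$pos, b$ref, b$alt), sep = "\r")
  alt <- tapply(b$alt_reads, g, sum)
  tot <- tapply(b$total_reads, g, sum)
  first <- b[!duplicated(g), , drop = FALSE]
  first <- first[match(names(alt), paste(first$patient,
                                         variant_key(first$chrom, first$pos,
                                                     first$ref, first$alt),
                                         sep = "\r")), ]
  pooled <- data.frame(patient = first$patient, chrom = first$chrom,
                       pos = first$pos, ref = first$ref, alt = first$alt,
                       buffy_alt_reads = as.integer(alt),
                       buffy_total_reads = as.integer(tot))
  pooled$buffy_vaf <- ifelse(pooled$buffy_total_reads > 0,
                             pooled$buffy_alt_reads / pooled$buffy_total_reads,
                             NA_real_)

  akey <- variant_key(annotations$chrom, annotations$pos, annotations$ref,
                      annotations$alt)
  idx <- match(variant_key(pooled$chrom, pooled$pos, pooled$ref, pooled$alt),
               akey)
  pooled$gene <- annotations$gene[idx]
  pooled$consequence <- annotations$consequence[idx]
  maf <- annotations$gnomad_maf[idx]
  cadd <- annotations$cadd_phred[idx]
  votes <- annotations$dbnsfp_damaging_votes[idx]
  clinvar <- annotations$clinvar_damaging[idx]

  damaging <- (!is.na(clinvar) & clinvar) |
    (!is.na(pooled$consequence) & pooled$consequence == "loss_of_function") |
    (!is.na(cadd) & cadd > params$min_cadd) |
    (!is.na(votes) & votes >= params$min_votes)
  keep <- !is.na(pooled$gene) & pooled$gene %in% params$gene_list &
    pooled$buffy_total_reads >= params$min_depth &
    !is.na(pooled$buffy_vaf) & pooled$buffy_vaf >= params$min_vaf &
    (is.na(maf) | maf < params$max_gnomad_maf) &
    damaging
  out <- pooled[keep, , drop = FALSE]
  if (nrow(out) > 0) {
    # residual-germline exclusion: ~50% VAF in every covered sample
    fp <- filter_params(germline_vaf_low = params$germline_window[1],
                        germline_vaf_high = params$germline_window[2])
    out <- remove_germline(out, obs, fp)
    attr(out, "removed") <- NULL
    sexes <- vapply(out$patient, function(p) patient_sex(meta, p), "")
    out$buffy_ccf <- if (nrow(out)) vaf_to_ccf(out$buffy_vaf, out$chrom, sexes)
                     else numeric(0)
  } else out$buffy_ccf <- numeric(0)
  rownames(out) <- NULL
  out[, c("patient", "chrom", "pos", "ref", "alt", "gene", "consequence",
          "buffy_alt_reads", "buffy_total_reads", "buffy_vaf", "buffy_ccf")]
}

#' Force-call CHIP sites across all samples of all patients
#'
#' Reports round-pooled read support at every screened CHIP site in every
#' sample of every patient, whether or not the variant was called there.
#' A site with no observation rows in a sample is recorded as no-coverage
#' (`covered = FALSE`, VAF `NA`), never as zero. CHIP variants screened in
#' more than one patient are platform noise by the recurrence argument and
#' are excluded from all patients first.
#'
#' @param chip_muts a [screen_buffy()] table.
#' @param obs full cohort observation table.
#' @param meta sample metadata.
#' @return `data.frame` with one row per (CHIP mutation, sample); excluded
#'   recurrent variants attached as attribute `"excluded"`.
#' @export
force_call <- function(chip_muts, obs, meta) {
  check_obs(obs); check_meta(meta)
  obs$chrom <- normalize_chrom(obs$chrom)
  key <- variant_key(chip_muts$chrom, chip_muts$pos, chip_muts$ref,
                     chip_muts$alt)
  npat <- tapply(chip_muts$patient, key, function(p) length(unique(p)))
  recurrent <- names(npat)[npat > 1]
  excluded <- chip_muts[key %in% recurrent, , drop = FALSE]
  cm <- chip_muts[!key %in% recurrent, , drop = FALSE]
  key <- key[!key %in% recurrent]

  okey <- variant_key(obs$chrom, obs$pos, obs$ref, obs$alt)
  sub <- obs[okey %in% key, , drop = FALSE]
  sg <- paste(variant_key(sub$chrom, sub$pos, sub$ref, sub$alt),
              sub$sample_id, sep = "\r")
  alt <- tapply(sub$alt_reads, sg, sum)
  tot <- tapply(sub$total_reads, sg, sum)

  rows <- list()
  for (i in seq_len(nrow(cm))) {
    k <- key[i]
    g <- paste(k, meta$sample_id, sep = "\r")
    a <- unname(alt[g]); t <- unname(tot[g])
    covered <- !is.na(t) & t > 0
    rows[[i]] <- data.frame(
      carrier = cm$patient[i], chrom = cm$chrom[i], pos = cm$pos[i],
      ref = cm$ref[i], alt = cm$alt[i], gene = cm$gene[i],
      patient = meta$patient, sample_id = meta$sample_id,
      tissue_class = meta$tissue_class,
      alt_reads = ifelse(covered, as.integer(a), NA_integer_),
      total_reads = ifelse(covered, as.integer(t), NA_integer_),
      vaf = ifelse(covered, a / t, NA_real_),
      covered = covered)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(carrier = character(), chrom = character(), pos = integer(),
               ref = character(), alt = character(), gene = character(),
               patient = character(), sample_id = character(),
               tissue_class = character(), alt_reads = integer(),
               total_reads = integer(), vaf = numeric(), covered = logical())
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Quantify CHIP-clone infiltration into plaque tissue
#'
#' For each CHIP mutation and each plaque sample of its carrier, reports
#' the pooled VAF, the clonal cell frequency, and a detection flag (at
#' least 5 alternate reads and VAF >= 1%); per (carrier, mutation) the
#' fraction of the carrier's covered plaque samples that are positive.
#'
#' @param fc a [force_call()] table.
#' @param meta sample metadata.
#' @param params a [filter_params()] providing the detection thresholds.
#' @return list with `per_sample` and `per_patient` data frames.
#' @export
quantify_infiltration <- function(fc, meta, params = filter_params()) {
  check_meta(meta)
  ts <- fc[fc$patient == fc$carrier & fc$tissue_class == "plaque", ,
           drop = FALSE]
  if (nrow(ts) > 0) {
    sexes <- vapply(ts$carrier, function(p) patient_sex(meta, p), "")
    ts$detected <- ts$covered & !is.na(ts$vaf) &
      ts$alt_reads >= params$min_alt_reads & ts$vaf >= params$min_vaf
    ts$ccf <- ifelse(ts$detected,
                     vaf_to_ccf(ifelse(is.na(ts$vaf), 0, ts$vaf),
                                ts$chrom, sexes),
                     ifelse(ts$covered, 0, NA_real_))
  } else {
    ts$detected <- logical(0); ts$ccf <- numeric(0)
  }
  g <- paste(ts$carrier, variant_key(ts$chrom, ts$pos, ts$ref, ts$alt),
             sep = "\r")
  per_patient <- if (nrow(ts)) {
    agg <- do.call(rbind, lapply(split(seq_len(nrow(ts)), g), function(j) {
      data.frame(carrier = ts$carrier[j[1]], chrom = ts$chrom[j[1]],
                 pos = ts$pos[j[1]], ref = ts$ref[j[1]], alt = ts$alt[j[1]],
                 gene = ts$gene[j[1]],
                 n_plaque_samples = sum(ts$covered[j]),
                 n_positive = sum(ts$detected[j]),
                 frac_positive = if (sum(ts$covered[j]) > 0)
                   sum(ts$detected[j]) / sum(ts$covered[j]) else NA_real_)
    }))
    rownames(agg) <- NULL
    agg
  } else data.frame(carrier = character(), chrom = character(),
                    pos = integer(), ref = character(), alt = character(),
                    gene = character(), n_plaque_samples = integer(),
                    n_positive = integer(), frac_positive = numeric())
  rownames(ts) <- NULL
  list(per_sample = ts, per_patient = per_patient)
}

#' Run the complete CHIP screen
#'
#' [screen_buffy()], then [force_call()] across the cohort, then
#' [quantify_infiltration()] in the carriers' plaque samples.
#'
#' @param obs full observation table.
#' @param meta sample metadata.
#' @param annotations annotation table.
#' @param params a [chip_params()].
#' @param presence a [filter_params()] with the tissue detection thresholds.
#' @return list of class `chip_result` with `carriers`, `force_call`,
#'   `infiltration`, `excluded_recurrent`.
#' @export
run_chip_screen <- function(obs, meta, annotations, params = chip_params(),
                            presence = filter_params()) {
  carriers <- screen_buffy(obs, meta, annotations, params)
  fc <- force_call(carriers, obs, meta)
  inf <- quantify_infiltration(fc, meta, presence)
  structure(list(carriers = carriers, force_call = fc,
                 infiltration = inf,
                 excluded_recurrent = attr(fc, "excluded"),
                 params = params),
            class = "chip_result")
}

#' @export
print.chip_result <- function(x, ...) {
  cat("CHIP screen: ", nrow(x$carriers), " mutation(s) in ",
      length(unique(x$carriers$patient)), " carrier(s)\n", sep = "")
  if (nrow(x$infiltration$per_patient)) {
    cat("Plaque infiltration (per carrier mutation):\n")
    print(x$infiltration$per_patient, row.names = FALSE)
  }
  invisible(x)
}
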