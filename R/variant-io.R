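#' Write a simulated dataset to disk
#'
#' Emits one single-sample VCF 4.2 file per sample per sequencing round
#' (read support in the standard `AD`/`DP` FORMAT fields, mean base quality
#' in the `MBQ` INFO field), a TSV annotation table, a JSON sample-metadata
#' manifest with segment geometry, and the planted-truth tables as TSV.
#' Output is byte-stable for a fixed config/seed.
#'
#' @param sim a [simulate_dataset()] result (or a list with `obs` and
#'   `truth`).
#' @param dir output directory.
#' @param overwrite logical; refuse to write into a non-empty directory
#'   unless `TRUE`.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(sim, dir, overwrite = FALSE) {
  stop_if(is.null(sim$obs) || is.null(sim$truth),
          "'sim' must carry 'obs' and 'truth' (see simulate_dataset())")
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("directory '", dir, "' is not empty; pass overwrite = TRUE",
         call. = FALSE)
  dir.create(file.path(dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  obs <- check_obs(sim$obs)
  meta <- check_meta(sim$truth$meta)

  manifest <- list()
  for (sid in meta$sample_id) {
    srows <- meta[meta$sample_id == sid, ]
    files <- list()
    for (r in sort(unique(obs$round))) {
      fn <- file.path("vcf", sprintf("%s_r%d.vcf", sid, r))
      write_vcf(obs[obs$sample_id == sid & obs$round == r, , drop = FALSE],
                file.path(dir, fn), sid)
      files[[as.character(r)]] <- fn
    }
    manifest[[length(manifest) + 1L]] <- c(
      as.list(srows[1, META_COLS]), list(files = files))
  }
  jsonlite::write_json(list(samples = manifest),
                       file.path(dir, "samples.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null",
                       digits = NA)

  write_annotations(sim$truth$annotations, file.path(dir, "annotations.tsv"))
  wt <- function(x, f) write.table(x, file.path(dir, "truth", f), sep = "\t",
                                   quote = FALSE, row.names = FALSE)
  wt(sim$truth$mutations, "mutations.tsv")
  wt(sim$truth$clones, "clones.tsv")
  wt(sim$truth$fractions, "fractions.tsv")
  wt(sim$truth$expected_vaf, "expected_vaf.tsv")
  invisible(dir)
}

# single-sample VCF 4.2 writer; AD is (ref, alt) with ref = DP - alt
write_vcf <- function(obs, path, sample_id) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=plaqueclone",
    paste0("##INFO=<ID=MBQ,Number=1,Type=Float,",
           "Description=\"Mean base quality of alternate-allele reads\">"),
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t"))
  body <- character(0)
  if (nrow(obs)) {
    o <- obs[order(obs$chrom, obs$pos, obs$alt), , drop = FALSE]
    body <- paste(o$chrom, o$pos, ".", o$ref, o$alt, ".", ".",
                  sprintf("MBQ=%.1f", o$mean_base_quality), "AD:DP",
                  sprintf("%d,%d:%d", o$total_reads - o$alt_reads,
                          o$alt_reads, o$total_reads),
                  sep = "\t")
  }
  writeLines(c(hdr, body), path)
}

#' Read candidate variant calls into an observation table
#'
#' Parses VCF 4.x (via \pkg{vcfR}) or TSV files into the long observation
#' format used by the pipeline: one row per (variant, sample, round).
#' Multiallelic VCF records are split into one row per alternate allele,
#' each keeping the site's total `DP`. Chromosome names are normalized with
#' [normalize_chrom()]. Parsing is strict: a VCF record without `AD` or
#' `DP`, or a file mapped to a sample id absent from the metadata, is a hard
#' error rather than a silent drop.
#'
#' @param manifest `data.frame` with columns `path`, `patient`, `sample_id`,
#'   `round`, one row per input file.
#' @param meta sample metadata table (see [read_dataset()] for the format).
#' @return observation `data.frame`.
#' @export
read_variants <- function(manifest, meta) {
  stop_if(!all(c("path", "patient", "sample_id", "round") %in% names(manifest)),
          "'manifest' needs columns path, patient, sample_id, round")
  check_meta(meta)
  unknown <- setdiff(manifest$sample_id, meta$sample_id)
  stop_if(length(unknown) > 0,
          "sample id(s) not in metadata: ", paste(unknown, collapse = ", "))
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    stop_if(!file.exists(m$path), "input file not found: ", m$path)
    tab <- if (grepl("\\.tsv$", m$path)) read_obs_tsv(m$path)
           else read_obs_vcf(m$path)
    if (nrow(tab) == 0) return(NULL)
    data.frame(patient = m$patient, sample_id = m$sample_id,
               round = as.integer(m$round), tab)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(patient = character(), sample_id = character(),
                      round = integer(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      alt_reads = integer(), total_reads = integer(),
                      mean_base_quality = numeric())
  rownames(out) <- NULL
  check_obs(out)
}

read_obs_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  if (is.null(fix) || nrow(fix) == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), alt_reads = integer(),
                      total_reads = integer(), mean_base_quality = numeric()))
  ad <- vcfR::extract.gt(v, "AD")[, 1]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, "DP")[, 1]))
  mbq <- suppressWarnings(vcfR::extract.info(v, "MBQ", as.numeric = TRUE))
  rows <- list()
  for (j in seq_len(nrow(fix))) {
    rec <- paste0(fix[j, "CHROM"], ":", fix[j, "POS"])
    stop_if(is.na(ad[j]) || is.na(dp[j]),
            "record ", rec, " in ", path, " lacks AD or DP")
    alts <- strsplit(fix[j, "ALT"], ",", fixed = TRUE)[[1]]
    counts <- suppressWarnings(as.integer(
      strsplit(ad[j], ",", fixed = TRUE)[[1]]))
    stop_if(anyNA(counts) || length(counts) != length(alts) + 1L,
            "record ", rec, " in ", path, " has a malformed AD field")
    rows[[j]] <- data.frame(
      chrom = normalize_chrom(unname(fix[j, "CHROM"])),
      pos = as.integer(unname(fix[j, "POS"])),
      ref = unname(fix[j, "REF"]), alt = unname(alts),
      alt_reads = unname(counts[-1L]), total_reads = unname(dp[j]),
      mean_base_quality = if (length(mbq)) unname(mbq[j]) else NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

read_obs_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "alt_reads", "total_reads",
            "mean_base_quality")
  miss <- setdiff(need, names(tab))
  stop_if(length(miss) > 0, "TSV ", path, " is missing columns: ",
          paste(miss, collapse = ", "))
  tab$chrom <- normalize_chrom(tab$chrom)
  tab[, need]
}

ANN_COLS <- c("chrom", "pos", "ref", "alt", "gene", "consequence",
              "gnomad_maf", "cadd_phred", "dbnsfp_damaging_votes",
              "clinvar_damaging")

#' Read / write the per-variant annotation table
#'
#' The annotation table carries externally computed evidence consumed by the
#' CHIP screen: gene symbol, consequence class (`missense`,
#' `loss_of_function`, `synonymous`, `other`), gnomAD population MAF, CADD
#' Phred score, the number of damaging verdicts among the five dbNSFP
#' predictors (0-5), and a ClinVar pathogenicity flag. Missing values stay
#' missing (`NA`) and are never coerced to 0; a malformed row is reported
#' with its row number.
#'
#' @param path TSV path.
#' @return annotation `data.frame` with one row per (chrom, pos, ref, alt).
#' @export
read_annotations <- function(path) {
  stop_if(!file.exists(path), "annotation file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  miss <- setdiff(ANN_COLS, names(tab))
  stop_if(length(miss) > 0, "annotation table is missing columns: ",
          paste(miss, collapse = ", "))
  tab <- tab[, ANN_COLS]
  tab$chrom <- normalize_chrom(tab$chrom)
  tab$clinvar_damaging <- as.logical(tab$clinvar_damaging)
  bad <- which(!is.na(tab$dbnsfp_damaging_votes) &
                 (tab$dbnsfp_damaging_votes < 0 |
                  tab$dbnsfp_damaging_votes > 5))
  stop_if(length(bad) > 0,
          "malformed annotation row ", bad[1],
          ": dbnsfp_damaging_votes outside 0-5")
  bad <- which(!is.na(tab$gnomad_maf) &
                 (tab$gnomad_maf < 0 | tab$gnomad_maf > 1))
  stop_if(length(bad) > 0,
          "malformed annotation row ", bad[1], ": gnomad_maf outside [0, 1]")
  bad <- which(!tab$consequence %in%
                 c("missense", "loss_of_function", "synonymous", "other"))
  stop_if(length(bad) > 0,
          "malformed annotation row ", bad[1], ": unknown consequence '",
          tab$consequence[bad[1]], "'")
  tab
}

#' @rdname read_annotations
#' @param annotations annotation `data.frame` to write.
#' @export
write_annotations <- function(annotations, path) {
  miss <- setdiff(ANN_COLS, names(annotations))
  stop_if(length(miss) > 0, "annotation table is missing columns: ",
          paste(miss, collapse = ", "))
  write.table(annotations[, ANN_COLS], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory containing `samples.json`, `vcf/` and
#'   `annotations.tsv`.
#' @return list with `obs` (observation table), `meta` (sample metadata) and
#'   `annotations`.
#' @export
read_dataset <- function(dir) {
  sj <- file.path(dir, "samples.json")
  stop_if(!file.exists(sj), "no samples.json in ", dir)
  cfg <- jsonlite::read_json(sj)
  meta <- do.call(rbind, lapply(cfg$samples, function(s) {
    data.frame(patient = s$patient, sample_id = s$sample_id, sex = s$sex,
               tissue_class = s$tissue_class,
               start_mm = s$start_mm %||% NA_real_,
               end_mm = s$end_mm %||% NA_real_,
               dna_yield_pg = s$dna_yield_pg %||% NA_real_)
  }))
  manifest <- do.call(rbind, lapply(cfg$samples, function(s) {
    data.frame(path = file.path(dir, unlist(s$files)),
               patient = s$patient, sample_id = s$sample_id,
               round = as.integer(names(s$files)))
  }))
  obs <- read_variants(manifest, meta)
  ann_path <- file.path(dir, "annotations.tsv")
  annotations <- if (file.exists(ann_path)) read_annotations(ann_path) else NULL
  list(obs = obs, meta = check_meta(meta), annotations = annotations)
}
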