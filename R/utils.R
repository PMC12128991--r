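`%||%` <- function(x, y) if (is.null(x)) y else x

#' Canonical chromosome names
#'
#' Normalizes chromosome labels to the `chr`-prefixed convention used
#' throughout the package: `"X"`, `"23"` and `"chrX"` all become `"chrX"`,
#' `"1"` becomes `"chr1"`, `"MT"`/`"M"` become `"chrM"`.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of canonical labels.
#' @export
#' @examples
#' normalize_chrom(c("X", "23", "chrX", "1", "MT"))
normalize_chrom <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom))
  x[x == "23"] <- "X"
  x[x == "24"] <- "Y"
  x[x %in% c("MT", "M")] <- "M"
  paste0("chr", x)
}

# "chrom:pos:ref:alt" identifier used as the mutation key everywhere
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# draw n values from a scalar (constant) or length-2 range (uniform)
draw_unif <- function(n, r) {
  if (length(r) == 1L) rep(as.numeric(r), n) else runif(n, r[1], r[2])
}

# draw n integers from a scalar or inclusive length-2 range
draw_int <- function(n, r) {
  if (length(r) == 1L) return(rep(as.integer(r), n))
  lo <- as.integer(r[1]); hi <- as.integer(r[2])
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

check_range <- function(x, name, lo = -Inf, hi = Inf, len = c(1L, 2L)) {
  stop_if(!is.numeric(x) || !length(x) %in% len || anyNA(x),
          sprintf("'%s' must be numeric of length %s", name,
                  paste(len, collapse = " or ")))
  stop_if(any(x < lo) || any(x > hi),
          sprintf("'%s' must lie in [%s, %s]", name, lo, hi))
  stop_if(length(x) == 2L && x[2] < x[1],
          sprintf("'%s' range must be nondecreasing", name))
  invisible(x)
}

# columns an observation table must carry
OBS_COLS <- c("patient", "sample_id", "round", "chrom", "pos", "ref", "alt",
              "alt_reads", "total_reads", "mean_base_quality")

check_obs <- function(obs) {
  miss <- setdiff(OBS_COLS, names(obs))
  stop_if(length(miss) > 0,
          "observation table is missing columns: ", paste(miss, collapse = ", "))
  stop_if(any(obs$alt_reads < 0 | obs$alt_reads > obs$total_reads, na.rm = TRUE),
          "alt_reads must satisfy 0 <= alt_reads <= total_reads")
  stop_if(any(obs$pos < 1, na.rm = TRUE), "positions must be 1-based (>= 1)")
  invisible(obs)
}

META_COLS <- c("patient", "sample_id", "sex", "tissue_class",
               "start_mm", "end_mm", "dna_yield_pg")

check_meta <- function(meta) {
  miss <- setdiff(META_COLS, names(meta))
  stop_if(length(miss) > 0,
          "sample metadata is missing columns: ", paste(miss, collapse = ", "))
  stop_if(!all(meta$tissue_class %in% c("plaque", "buffy", "control_artery")),
          "tissue_class must be 'plaque', 'buffy' or 'control_artery'")
  geom <- meta[!is.na(meta$start_mm), , drop = FALSE]
  stop_if(any(geom$end_mm <= geom$start_mm),
          "segment intervals must satisfy end_mm > start_mm")
  # intervals of one patient's samples must be pairwise disjoint
  for (p in unique(geom$patient)) {
    g <- geom[geom$patient == p, , drop = FALSE]
    g <- g[order(g$start_mm), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start_mm[-1] < g$end_mm[-nrow(g)]))
      stop("overlapping segment intervals for patient ", p, call. = FALSE)
  }
  invisible(meta)
}

patient_sex <- function(meta, patient) {
  sx <- unique(meta$sex[meta$patient == patient])
  sx <- sx[!is.na(sx)]
  stop_if(length(sx) > 1, "inconsistent sex for patient ", patient)
  if (length(sx) == 0) NA_character_ else sx
}
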