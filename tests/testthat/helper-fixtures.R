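# In-code fixtures shared across test files.

# minimal two-sample metadata for one patient (one plaque segment + buffy)
tiny_meta <- function(patient = "P01", sex = "male", nseg = 1,
                      width = 2, gap = 4) {
  starts <- (width + gap) * (seq_len(nseg) - 1)
  rbind(
    data.frame(patient = patient,
               sample_id = sprintf("%s_s%d", patient, seq_len(nseg)),
               sex = sex, tissue_class = "plaque",
               start_mm = starts, end_mm = starts + width,
               dna_yield_pg = 6.6e5),
    data.frame(patient = patient, sample_id = paste0(patient, "_buffy"),
               sex = sex, tissue_class = "buffy",
               start_mm = NA_real_, end_mm = NA_real_,
               dna_yield_pg = NA_real_))
}

# one observation row builder
obs_row <- function(patient = "P01", sample_id = "P01_s1", round = 1,
                    chrom = "chr1", pos = 1000, ref = "A", alt = "T",
                    alt_reads = 8, total_reads = 700,
                    mean_base_quality = 30) {
  data.frame(patient = patient, sample_id = sample_id, round = round,
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             alt_reads = alt_reads, total_reads = total_reads,
             mean_base_quality = mean_base_quality)
}

# a small deterministic simulated cohort reused by several files
small_sim <- function(seed = 42, n_patients = 3, ...) {
  simulate_dataset(sim_config(
    n_patients = n_patients, segments_per_plaque = 4,
    n_clones = c(1, 3), clone_fractions = c(0.08, 0.30),
    mutations_per_clone = c(1, 3), n_germline = 8, n_error_sites = 30,
    chip = NULL, seed = seed, ...))
}
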