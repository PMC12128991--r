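#' Simulation configuration
#'
#' Describes a synthetic plaque/blood whole-exome dataset with planted clonal
#' structure. The defaults emulate the study design the package targets:
#' a cohort of 13 patients, plaques divided into 4 frozen segments of 2-5 mm
#' separated by 4-10 mm gaps (alternate segments go to histology and are not
#' sequenced), ~700x mean depth, two independent sequencing rounds starting
#' from raw DNA, per-base miscall rate 1e-3, somatic clones with cell
#' fractions between 1% and 31%, heterozygous germline variants at ~50% VAF,
#' and CHIP clones in roughly half the cohort's blood.
#'
#' @param n_patients number of patients.
#' @param segments_per_plaque frozen plaque segments per patient (scalar or
#'   inclusive integer range).
#' @param segment_width_mm segment width in mm (scalar or range).
#' @param inter_segment_gap_mm unsequenced gap between consecutive frozen
#'   segments, in mm (scalar or range).
#' @param depth mean total reads per site (default 700).
#' @param depth_model `"poisson"` draws per-site depth from a Poisson
#'   truncated at >= 1; `"constant"` uses `depth` everywhere.
#' @param n_rounds independent sequencing rounds per sample (default 2).
#' @param error_rate per-base miscall probability, in `[0, 0.01)`.
#' @param n_clones somatic clones per patient (scalar or range).
#' @param clone_fractions support of the uniform clone cell-fraction
#'   distribution, within `[0.01, 0.35]` by default.
#' @param mutations_per_clone mutations carried by one clone (scalar or
#'   range); all members share the clone's per-sample fractions.
#' @param n_germline heterozygous germline variants per patient (~50% VAF in
#'   every sample including the buffy coat).
#' @param n_error_sites sequencing-error-only sites per patient, emitted in
#'   every sample of that patient including the buffy coat.
#' @param base_quality_mean,base_quality_sd mean base quality per variant is
#'   drawn from a normal with these parameters (Phred scale), truncated to
#'   `[2, 60]`.
#' @param chip a [chip_spec()] describing planted CHIP clones, or `NULL` for
#'   none.
#' @param clone_spec optional explicit clone list overriding random clone
#'   placement; a list of lists with elements `patient` (index), `segments`
#'   (contiguous segment indices), `fraction` (scalar, or one value per
#'   occupied segment), and optionally `n_mutations` and `chrom`.
#' @param sex optional character vector of patient sexes (recycled);
#'   `NULL` draws `"male"`/`"female"` at random.
#' @param seed integer seed; together with the other fields it fully
#'   determines the simulated dataset.
#'
#' @return an object of class `sim_config`.
#' @seealso [simulate_truth()], [simulate_reads()], [write_dataset()]
#' @export
#' @examples
#' cfg <- sim_config(n_patients = 2, n_clones = 1, n_germline = 5, seed = 7)
#' cfg
sim_config <- function(n_patients = 13,
                       segments_per_plaque = 4,
                       segment_width_mm = c(2, 5),
                       inter_segment_gap_mm = c(4, 10),
                       depth = 700,
                       depth_model = c("poisson", "constant"),
                       n_rounds = 2,
                       error_rate = 1e-3,
                       n_clones = c(1, 6),
                       clone_fractions = c(0.01, 0.31),
                       mutations_per_clone = c(1, 4),
                       n_germline = 30,
                       n_error_sites = 200,
                       base_quality_mean = 35,
                       base_quality_sd = 2,
                       chip = chip_spec(),
                       clone_spec = NULL,
                       sex = NULL,
                       seed = 1L) {
  depth_model <- match.arg(depth_model)
  check_range(n_patients, "n_patients", 1, len = 1L)
  check_range(segments_per_plaque, "segments_per_plaque", 1)
  check_range(segment_width_mm, "segment_width_mm", 0.1)
  check_range(inter_segment_gap_mm, "inter_segment_gap_mm", 0)
  check_range(depth, "depth", 1, len = 1L)
  check_range(n_rounds, "n_rounds", 1, len = 1L)
  stop_if(!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.01,
          "'error_rate' must lie in [0, 0.01)")
  check_range(n_clones, "n_clones", 0)
  check_range(clone_fractions, "clone_fractions", 0, 1)
  check_range(mutations_per_clone, "mutations_per_clone", 1)
  check_range(n_germline, "n_germline", 0, len = 1L)
  check_range(n_error_sites, "n_error_sites", 0, len = 1L)
  stop_if(!is.null(chip) && !inherits(chip, "chip_spec"),
          "'chip' must be NULL or a chip_spec()")
  stop_if(!is.null(sex) && !all(sex %in% c("male", "female")),
          "'sex' entries must be 'male' or 'female'")
  seed <- as.integer(seed)
  stop_if(is.na(seed), "'seed' must be an integer")

  structure(list(
    n_patients = as.integer(n_patients),
    segments_per_plaque = as.integer(segments_per_plaque),
    segment_width_mm = segment_width_mm,
    inter_segment_gap_mm = inter_segment_gap_mm,
    depth = depth, depth_model = depth_model,
    n_rounds = as.integer(n_rounds),
    error_rate = error_rate,
    n_clones = n_clones,
    clone_fractions = clone_fractions,
    mutations_per_clone = mutations_per_clone,
    n_germline = as.integer(n_germline),
    n_error_sites = as.integer(n_error_sites),
    base_quality_mean = base_quality_mean,
    base_quality_sd = base_quality_sd,
    chip = chip, clone_spec = clone_spec, sex = sex, seed = seed
  ), class = "sim_config")
}

#' CHIP clone specification for the simulator
#'
#' Describes the clonal-hematopoiesis component of a simulated cohort: a
#' subset of patients carry expanded blood clones with mutations in CHIP
#' genes; each clone may additionally infiltrate individual plaque segments
#' at a fraction drawn independently of its blood fraction (tissue and blood
#' fractions of the same clone differ in real data).
#'
#' Defaults reflect the study conditions: about 6 of 13 patients are
#' carriers, with blood clonal cell fractions between 2.6% and 34%
#' (equivalently, buffy-coat VAFs of 1.3%-17% for autosomal heterozygous
#' mutations).
#'
#' @param n_carriers number of CHIP-carrier patients (capped at the cohort
#'   size).
#' @param blood_fraction blood clonal cell fraction (scalar or range).
#' @param mutations_per_carrier CHIP mutations per carrier (scalar or range);
#'   each CHIP mutation is its own blood clone.
#' @param infiltration_prob probability that a CHIP clone infiltrates a given
#'   plaque segment of its carrier.
#' @param infiltration_fraction cell fraction of an infiltrating CHIP clone
#'   in a tissue sample (scalar or range), drawn independently per sample.
#' @param genes CHIP gene symbols to draw from; `NULL` uses the bundled
#'   78-gene list ([chip_default_genes()]).
#' @return an object of class `chip_spec`.
#' @export
chip_spec <- function(n_carriers = 6,
                      blood_fraction = c(0.026, 0.34),
                      mutations_per_carrier = c(1, 3),
                      infiltration_prob = 0.5,
                      infiltration_fraction = c(0.02, 0.20),
                      genes = NULL) {
  check_range(n_carriers, "n_carriers", 0, len = 1L)
  check_range(blood_fraction, "blood_fraction", 0, 1)
  check_range(mutations_per_carrier, "mutations_per_carrier", 1)
  check_range(infiltration_prob, "infiltration_prob", 0, 1, len = 1L)
  check_range(infiltration_fraction, "infiltration_fraction", 0, 1)
  structure(list(n_carriers = as.integer(n_carriers),
                 blood_fraction = blood_fraction,
                 mutations_per_carrier = mutations_per_carrier,
                 infiltration_prob = infiltration_prob,
                 infiltration_fraction = infiltration_fraction,
                 genes = genes),
            class = "chip_spec")
}

#' @export
print.sim_config <- function(x, ...) {
  fmt <- function(r) if (length(r) == 1) format(r) else
    paste0(format(r[1]), "-", format(r[2]))
  cat("Simulation configuration (seed ", x$seed, ")\n", sep = "")
  cat("  patients: ", x$n_patients,
      ", segments/plaque: ", fmt(x$segments_per_plaque),
      " (", fmt(x$segment_width_mm), " mm wide, gaps ",
      fmt(x$inter_segment_gap_mm), " mm)\n", sep = "")
  cat("  depth: ", x$depth, "x (", x$depth_model, "), rounds: ", x$n_rounds,
      ", error rate: ", format(x$error_rate), "\n", sep = "")
  cat("  clones/patient: ", fmt(x$n_clones), " at fractions ",
      fmt(x$clone_fractions), ", ", fmt(x$mutations_per_clone),
      " mutations each\n", sep = "")
  cat("  germline variants: ", x$n_germline,
      ", error-only sites: ", x$n_error_sites, "\n", sep = "")
  if (!is.null(x$chip))
    cat("  CHIP: ", x$chip$n_carriers, " carriers, blood fractions ",
        fmt(x$chip$blood_fraction), "\n", sep = "")
  invisible(x)
}
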