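#' Reconstruct the clonal architecture of a plaque cohort
#'
#' End-to-end driver: runs the matched somatic filtering cascade
#' ([run_filter_cascade()]), quantifies every validated mutation in every
#' sample of its patient ([quantify_mutations()]), builds per-patient
#' mutation-by-segment frequency matrices, groups co-travelling mutations
#' into putative clones with physical-extent bounds
#' ([group_into_clones()]), flags samples whose frequency sums imply
#' multi-mutation clones, summarizes clonal cell frequencies, and - when an
#' annotation table is supplied - screens the buffy coats for CHIP
#' mutations and quantifies their infiltration into plaque tissue
#' ([run_chip_screen()]).
#'
#' @param obs observation table (one row per variant, sample, round); see
#'   [read_variants()].
#' @param meta sample metadata with segment geometry; see [read_dataset()].
#' @param annotations optional annotation table; enables the CHIP screen
#'   and gene/consequence columns.
#' @param params a [filter_params()].
#' @param chip a [chip_params()], or `NULL` to skip the CHIP screen even
#'   when annotations are present.
#' @param rel_tol relative-difference tolerance for clone grouping.
#' @param gap_tolerant gap-tolerant clone grouping (see
#'   [group_into_clones()]).
#' @return object of class `plaque_clonality`; see
#'   [print.plaque_clonality()], [summary.plaque_clonality()],
#'   [plot.plaque_clonality()] and [write_report()].
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_patients = 2, n_germline = 5,
#'                                    n_error_sites = 20, chip = NULL,
#'                                    seed = 11))
#' fit <- plaque_clonality(sim$obs, sim$truth$meta, sim$truth$annotations)
#' fit
plaque_clonality <- function(obs, meta, annotations = NULL,
                             params = filter_params(),
                             chip = if (!is.null(annotations)) chip_params(),
                             rel_tol = 0.5, gap_tolerant = FALSE) {
  check_obs(obs); check_meta(meta)
  cascade <- run_filter_cascade(obs, meta, params)
  mutations <- quantify_mutations(cascade$validated, obs, meta, params,
                                  annotations)
  patients <- unique(meta$patient[meta$tissue_class == "plaque"])
  matrices <- list(); groups <- list(); flags <- list()
  for (p in patients) {
    m <- build_matrix(mutations, meta, p)
    matrices[[p]] <- m
    groups[[p]] <- group_into_clones(m, rel_tol, gap_tolerant)
    flags[[p]] <- flag_multimutation_samples(m)
  }
  chip_res <- NULL
  if (!is.null(chip) && !is.null(annotations))
    chip_res <- run_chip_screen(obs, meta, annotations, chip, params)
  freq <- summarize_frequencies(mutations, meta)
  structure(list(mutations = mutations, cascade = cascade,
                 matrices = matrices, clone_groups = groups,
                 multimutation_flags = flags, frequency_summary = freq,
                 chip = chip_res, meta = meta, params = params),
            class = "plaque_clonality")
}

#' @describeIn plaque_clonality compact overview of the fitted architecture.
#' @param x,object a `plaque_clonality` object.
#' @param ... ignored.
#' @export
print.plaque_clonality <- function(x, ...) {
  ps <- x$frequency_summary$patient
  cat("Plaque clonal architecture: ", nrow(ps), " patient(s), ",
      sum(x$meta$tissue_class == "plaque"), " plaque segment(s)\n", sep = "")
  cat("  validated somatic mutations: ", sum(ps$n_mutations),
      " (", sum(ps$n_mutations > 0), "/", nrow(ps),
      " patients positive)\n", sep = "")
  det <- x$mutations$ccf[x$mutations$detected &
                           x$mutations$tissue_class == "plaque"]
  if (length(det))
    cat(sprintf("  clonal cell frequencies: %.1f%%-%.1f%% (median %.1f%%)\n",
                100 * min(det), 100 * max(det), 100 * median(det)))
  ngrp <- sum(vapply(x$clone_groups, function(g) nrow(g$groups), 0L))
  cat("  putative clone groups: ", ngrp, "\n", sep = "")
  if (!is.null(x$chip))
    cat("  CHIP: ", nrow(x$chip$carriers), " mutation(s) in ",
        length(unique(x$chip$carriers$patient)), "/", nrow(ps),
        " carrier(s)\n", sep = "")
  invisible(x)
}

#' @describeIn plaque_clonality per-patient tables (mutation counts,
#'   frequency summaries, clone groups, CHIP carriers).
#' @export
summary.plaque_clonality <- function(object, ...) {
  out <- list(patient = object$frequency_summary$patient,
              sample = object$frequency_summary$sample,
              correlations = object$frequency_summary$correlations,
              funnel = object$cascade$funnel,
              clone_groups = do.call(rbind, lapply(
                names(object$clone_groups), function(p) {
                  g <- object$clone_groups[[p]]$groups
                  if (nrow(g)) cbind(patient = p, g) else NULL
                })),
              chip = if (!is.null(object$chip)) object$chip$carriers)
  class(out) <- "summary.plaque_clonality"
  out
}

#' @export
print.summary.plaque_clonality <- function(x, ...) {
  cat("Filter funnel:\n"); print(x$funnel, row.names = FALSE)
  cat("\nPer-patient summary:\n"); print(x$patient, row.names = FALSE)
  if (!is.null(x$clone_groups) && NROW(x$clone_groups)) {
    cat("\nPutative clone groups:\n")
    print(x$clone_groups, row.names = FALSE)
  }
  if (!is.null(x$chip) && nrow(x$chip)) {
    cat("\nCHIP carrier mutations:\n"); print(x$chip, row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn plaque_clonality spatial dot plot of one patient's mutations
#'   along the plaque axis (frequency vs segment midpoint, one line per
#'   mutation).
#' @param patient patient to plot (default: first with mutations).
#' @export
plot.plaque_clonality <- function(x, patient = NULL, ...) {
  has <- names(Filter(function(m) nrow(m) > 0, x$matrices))
  stop_if(length(has) == 0, "no patient with validated mutations to plot")
  patient <- patient %||% has[1]
  m <- x$matrices[[patient]]
  stop_if(is.null(m), "unknown patient: ", patient)
  geom <- attr(m, "geometry")
  mid <- (geom$start_mm + geom$end_mm) / 2
  cols <- grDevices::hcl.colors(max(2, nrow(m)), "Dark 3")
  plot.new()
  plot.window(xlim = range(geom$start_mm, geom$end_mm),
              ylim = c(0, max(0.05, max(m)) * 1.1))
  axis(1); axis(2)
  title(xlab = "position along plaque axis (mm)",
        ylab = "clonal cell frequency",
        main = paste("Clonal architecture of", patient))
  for (s in seq_len(nrow(geom)))
    graphics::rect(geom$start_mm[s], 0, geom$end_mm[s],
                   max(0.05, max(m)) * 1.1,
                   col = "grey95", border = "grey80")
  for (i in seq_len(nrow(m))) {
    on <- m[i, ] > 0
    if (any(on)) {
      graphics::lines(mid[on], m[i, on], col = cols[i], lty = 3)
      points(mid[on], m[i, on], col = cols[i], pch = 19)
    }
  }
  invisible(x)
}

#' Write the analysis report to disk
#'
#' Emits TSV tables (per-sample mutation quantifications, per-patient and
#' per-sample frequency summaries, filter funnel, clone groups, CHIP
#' carriers and infiltration) and a JSON overview.
#'
#' @param fit a [plaque_clonality()] object.
#' @param dir output directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(fit, dir, overwrite = FALSE) {
  stop_if(!inherits(fit, "plaque_clonality"),
          "'fit' must be a plaque_clonality object")
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("directory '", dir, "' is not empty; pass overwrite = TRUE",
         call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) if (!is.null(x))
    write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                row.names = FALSE)
  s <- summary(fit)
  wt(as.data.frame(fit$mutations), "mutations.tsv")
  wt(s$patient, "patient_summary.tsv")
  wt(s$sample, "sample_summary.tsv")
  wt(s$funnel, "filter_funnel.tsv")
  wt(s$clone_groups, "clone_groups.tsv")
  if (!is.null(fit$chip)) {
    wt(fit$chip$carriers, "chip_carriers.tsv")
    wt(fit$chip$force_call, "chip_force_call.tsv")
    wt(fit$chip$infiltration$per_sample, "chip_infiltration.tsv")
  }
  det <- fit$mutations[fit$mutations$detected &
                         fit$mutations$tissue_class == "plaque", ]
  overview <- list(
    n_patients = nrow(s$patient),
    n_patients_positive = sum(s$patient$n_mutations > 0),
    n_validated_mutations = sum(s$patient$n_mutations),
    ccf_range = if (nrow(det)) range(det$ccf) else NULL,
    ccf_median = if (nrow(det)) median(det$ccf) else NULL,
    n_chip_mutations = if (!is.null(fit$chip)) nrow(fit$chip$carriers),
    n_chip_carriers = if (!is.null(fit$chip))
      length(unique(fit$chip$carriers$patient)))
  jsonlite::write_json(overview, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
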