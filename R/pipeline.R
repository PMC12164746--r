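#' Manifest for a reproducible pipeline run
#'
#' Bundles the cohort specification, the analysis configuration and the
#' output directory; [run_pipeline()] executes the full simulate ->
#' profile -> analyze -> classify -> report chain from it. Re-running the
#' same manifest reproduces byte-identical output files (the written
#' manifest records only relative file names and their checksums, never
#' timestamps or absolute paths).
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if missing).
#' @param alpha,covariates,control_policy,multiplicity Analysis settings,
#'   see [comparison_grid()].
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(spec, out_dir, alpha = 0.05, covariates = NULL,
                         control_policy = c("pool", "subject-mean"),
                         multiplicity = c("none", "BH")) {
  stopifnot(inherits(spec, "cohort_spec"))
  control_policy <- match.arg(control_policy)
  multiplicity <- match.arg(multiplicity)
  structure(
    list(spec = spec, out_dir = out_dir,
         analysis = list(alpha = alpha, covariates = covariates,
                         control_policy = control_policy,
                         multiplicity = multiplicity),
         version = as.character(packageVersion("epitract"))),
    class = "run_manifest"
  )
}

log_stage <- function(stage, ...) {
  inform(paste0("[", stage, "] ", sprintf(...)))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", stage, "` failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline from a manifest
#'
#' Stages: simulate the cohort; write the subject and profile tables;
#' summarise profiles; compute comparison grids (pre and, when operated
#' patients exist, post; diagnosis-wise, combined, and outcome groupings);
#' classify abnormalities; write the taxonomy report, cohort summary and a
#' manifest JSON with per-file checksums. Progress is logged to stderr with
#' row counts; any stage failure aborts with the stage name.
#'
#' @param manifest A [run_manifest()].
#' @return Invisibly, a list with the output `files` (named md5 checksums)
#'   and the key tables (`subjects`, `grids`, `labels`, `report`).
#' @export
run_pipeline <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  spec <- manifest$spec
  cfg <- manifest$analysis
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(manifest$out_dir, f)

  cohort <- run_stage("simulate", simulate_cohort(spec))
  log_stage("simulate", "%d subjects, %d profile rows",
            nrow(cohort$subjects), nrow(cohort$profiles))
  run_stage("simulate", {
    write_subjects(cohort$subjects, path("subjects.csv"))
    write_tract_profiles(cohort$profiles, path("profile_nodes.csv"),
                         path("profile_tracts.csv"))
  })

  summaries <- run_stage("profile", summarize_profiles(cohort$profiles,
                                                       spec$n_segments))
  log_stage("profile", "%d summary rows", nrow(summaries))

  has_post <- any(cohort$subjects$has_post)
  outcome_ok <- {
    op <- cohort$subjects |> filter(.data$operated)
    any(op$engel_class == "I") && any(op$engel_class %in% c("II", "III", "IV"))
  }
  grids <- list()
  run_stage("analyze", {
    for (grp in c("diagnosis", "combined")) {
      for (tp in c("pre", if (has_post) "post")) {
        g <- comparison_grid(summaries, cohort$subjects, grouping = grp,
                             timepoint = tp, alpha = cfg$alpha,
                             covariates = cfg$covariates,
                             control_policy = cfg$control_policy,
                             multiplicity = cfg$multiplicity,
                             n_segments = spec$n_segments)
        nm <- paste0(grp, "_", tp)
        grids[[nm]] <- g
        write_comparison_grid(g, path(paste0("grid_", nm, ".tsv")))
        log_stage("analyze", "%s: %d rows, %d significant", nm, nrow(g),
                  sum(g$significant, na.rm = TRUE))
      }
    }
    if (outcome_ok) {
      for (tp in c("pre", "post")) {
        g <- comparison_grid(summaries, cohort$subjects, grouping = "outcome",
                             timepoint = tp, alpha = cfg$alpha,
                             covariates = cfg$covariates,
                             control_policy = cfg$control_policy,
                             multiplicity = cfg$multiplicity,
                             n_segments = spec$n_segments)
        nm <- paste0("outcome_", tp)
        grids[[nm]] <- g
        write_comparison_grid(g, path(paste0("grid_", nm, ".tsv")))
        log_stage("analyze", "%s: %d rows, %d significant", nm, nrow(g),
                  sum(g$significant, na.rm = TRUE))
      }
    } else {
      log_stage("analyze", "outcome grouping skipped (need operated patients in both Engel classes)")
    }
  })

  labels <- run_stage("classify", {
    bind_rows(
      classify_abnormalities(grids$diagnosis_pre,
                             grids$diagnosis_post, spec$n_segments),
      classify_abnormalities(grids$combined_pre,
                             grids$combined_post, spec$n_segments)
    )
  })
  fingerprint <- attr(grids$diagnosis_pre, "config_fingerprint")
  run_stage("classify", write_labels(labels, path("labels.tsv"), fingerprint))
  log_stage("classify", "%d abnormality labels", nrow(labels))

  report <- run_stage("report", taxonomy_report(labels))
  run_stage("report", {
    write_labels(report, path("taxonomy_report.tsv"), fingerprint)
    write_tsv(cohort_summary(cohort$subjects), path("cohort_summary.tsv"))
  })
  log_stage("report", "%d report rows", nrow(report))

  files <- setdiff(list.files(manifest$out_dir), "manifest.json")
  checksums <- tools::md5sum(file.path(manifest$out_dir, files))
  names(checksums) <- files
  manifest_json <- list(
    spec = serialize_spec(spec),
    analysis = cfg,
    version = manifest$version,
    files = as.list(checksums)
  )
  jsonlite::write_json(manifest_json, path("manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  log_stage("manifest", "%d files written", length(files) + 1L)

  invisible(list(files = checksums, subjects = cohort$subjects,
                 grids = grids, labels = labels, report = report))
}

serialize_spec <- function(spec) {
  out <- unclass(spec)
  out$effects <- map(spec$effects, unclass)
  out
}
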