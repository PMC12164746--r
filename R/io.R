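#' Write and read tract-profile tables
#'
#' The on-disk dialect follows AFQ-style nodes tables: a nodes CSV with
#' columns `subject_id`, `timepoint`, `tract`, `side`, `node` (1..100),
#' `FA`, `MD`, `VOL`, and a companion per-tract CSV with `subject_id`,
#' `timepoint`, `tract`, `side`, `FIB`, `valid`. UTF-8, dot decimal,
#' headers mandatory. Reading validates the schema strictly (missing
#' columns, node gaps or duplicates, FA outside [0,1], non-positive MD,
#' negative Vol) and reports the offending subject/tract and line numbers.
#'
#' @param profiles A tract-profile tibble.
#' @param nodes_path,tracts_path CSV paths for the node-wise table and the
#'   per-tract companion table.
#' @return `write_tract_profiles()` returns the paths invisibly;
#'   `read_tract_profiles()` returns a tract-profile tibble equal (up to
#'   numeric serialisation) to the one written.
#' @export
write_tract_profiles <- function(profiles, nodes_path, tracts_path) {
  nodes <- profiles |>
    select("subject_id", "timepoint", "tract", "side", "node",
           "FA", "MD", VOL = "Vol")
  tracts <- profiles |>
    distinct(.data$subject_id, .data$timepoint, .data$tract, .data$side,
             FIB = .data$Fib, valid = .data$valid)
  write_csv(nodes, nodes_path)
  write_csv(tracts, tracts_path)
  invisible(c(nodes = nodes_path, tracts = tracts_path))
}

profile_error <- function(msg, rows, where) {
  abort(paste0("profile validation error: ", msg, " at ", where,
               " (line ", paste(head(rows, 5) + 1L, collapse = ", "),
               if (length(rows) > 5) ", ..." else "", ")"))
}

#' @rdname write_tract_profiles
#' @export
read_tract_profiles <- function(nodes_path, tracts_path) {
  nodes <- read_csv(nodes_path, col_types = cols(
    subject_id = col_character(), timepoint = col_character(),
    tract = col_character(), side = col_character(),
    node = col_integer(), FA = col_double(), MD = col_double(),
    VOL = col_double()
  ))
  need <- c("subject_id", "timepoint", "tract", "side", "node", "FA", "MD", "VOL")
  miss <- setdiff(need, names(nodes))
  if (length(miss) > 0) {
    abort(paste0("profile validation error: nodes table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  tracts <- read_csv(tracts_path, col_types = cols(
    subject_id = col_character(), timepoint = col_character(),
    tract = col_character(), side = col_character(),
    FIB = col_integer(), valid = col_logical()
  ))
  misst <- setdiff(c("subject_id", "timepoint", "tract", "side", "FIB", "valid"),
                   names(tracts))
  if (length(misst) > 0) {
    abort(paste0("profile validation error: tracts table is missing column(s): ",
                 paste(misst, collapse = ", ")))
  }
  if (nrow(nodes) == 0) {
    return(as_tract_profiles(tibble(
      subject_id = character(), timepoint = character(), tract = character(),
      side = character(), node = integer(), FA = double(), MD = double(),
      Vol = double(), Fib = integer(), valid = logical()
    )))
  }

  where <- paste0(nodes$subject_id, "/", nodes$tract, " (", nodes$side, ", ",
                  nodes$timepoint, ")")
  bad <- which(!is.na(nodes$FA) & (nodes$FA < 0 | nodes$FA > 1))
  if (length(bad)) profile_error("FA outside [0,1]", bad, where[bad[1]])
  bad <- which(!is.na(nodes$MD) & nodes$MD <= 0)
  if (length(bad)) profile_error("non-positive MD", bad, where[bad[1]])
  bad <- which(!is.na(nodes$VOL) & nodes$VOL < 0)
  if (length(bad)) profile_error("negative Vol", bad, where[bad[1]])

  key <- paste(nodes$subject_id, nodes$timepoint, nodes$tract, nodes$side, sep = "\r")
  n_nodes <- max(nodes$node)
  by_inst <- split(seq_len(nrow(nodes)), key)
  for (rows in by_inst) {
    got <- sort(nodes$node[rows])
    if (!identical(got, seq_len(n_nodes))) {
      profile_error(sprintf("node sequence is not 1..%d (gap or duplicate)", n_nodes),
                    rows, where[rows[1]])
    }
  }

  out <- nodes |>
    rename(Vol = "VOL") |>
    left_join(tracts |> rename(Fib = "FIB"),
              by = c("subject_id", "timepoint", "tract", "side"))
  if (anyNA(out$Fib) || anyNA(out$valid)) {
    miss_inst <- out |> filter(is.na(.data$Fib) | is.na(.data$valid)) |>
      distinct(.data$subject_id, .data$tract)
    abort(paste0("profile validation error: tract instance(s) missing from the ",
                 "per-tract table: ",
                 paste(paste0(miss_inst$subject_id, "/", miss_inst$tract),
                       collapse = ", ")))
  }
  as_tract_profiles(arrange(out, .data$subject_id, .data$timepoint,
                            factor(.data$tract, levels = tract_names()),
                            .data$side, .data$node))
}

#' Write and read the subject table
#'
#' CSV with columns subject_id, group, operated, ioz_side, engel_class,
#' age, sex, duration (plus timepoint availability flags).
#'
#' @param subjects Subject tibble.
#' @param path CSV path.
#' @return The path invisibly / the subject tibble.
#' @export
write_subjects <- function(subjects, path) {
  write_csv(subjects, path)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  subj <- read_csv(path, col_types = cols(
    subject_id = col_character(), group = col_character(),
    operated = col_logical(), ioz_side = col_character(),
    engel_class = col_character(), age = col_double(),
    sex = col_character(), duration = col_double()
  ))
  need <- c("subject_id", "group", "operated", "ioz_side", "engel_class",
            "age", "sex", "duration")
  miss <- setdiff(need, names(subj))
  if (length(miss) > 0) {
    abort(paste0("subject table is missing column(s): ", paste(miss, collapse = ", ")))
  }
  ctrl <- subj$group == "control"
  if (any(ctrl & (subj$ioz_side != "none" | subj$engel_class != "none" | subj$operated))) {
    abort("subject validation error: controls must have ioz_side = none, engel_class = none, operated = FALSE")
  }
  if (any(subj$engel_class != "none" & !subj$operated)) {
    abort("subject validation error: an Engel class implies operated = TRUE")
  }
  subj
}

#' Write and read streamline bundles as JSON lines
#'
#' One record per fiber: subject_id, timepoint, tract, side, fiber index,
#' the ordered xyz polyline and the per-point FA/MD samples.
#'
#' @param bundles Long streamline-point tibble (see [simulate_cohort()]).
#' @param path Output `.jsonl` path.
#' @return The path invisibly / the bundles tibble.
#' @export
write_bundles_jsonl <- function(bundles, path) {
  key <- paste(bundles$subject_id, bundles$timepoint, bundles$tract,
               bundles$side, bundles$fiber, sep = "\r")
  parts <- split(bundles, factor(key, levels = unique(key)))
  lines <- map_chr(parts, function(f) {
    jsonlite::toJSON(list(
      subject_id = f$subject_id[1], timepoint = f$timepoint[1],
      tract = f$tract[1], side = f$side[1], fiber = f$fiber[1],
      points = unname(as.matrix(f[, c("x", "y", "z")])),
      fa = f$FA, md = f$MD
    ), auto_unbox = TRUE, digits = NA)
  })
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bundles_jsonl
#' @export
read_bundles_jsonl <- function(path) {
  lines <- readLines(path)
  list_rbind(map(lines, function(ln) {
    rec <- jsonlite::fromJSON(ln)
    pts <- rec$points
    tibble(
      subject_id = rec$subject_id, timepoint = rec$timepoint,
      tract = rec$tract, side = rec$side, fiber = rec$fiber,
      point = seq_len(nrow(pts)),
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      FA = rec$fa, MD = rec$md
    )
  }))
}

#' Write abnormality labels and taxonomy reports
#'
#' TSV outputs carrying the analysis configuration fingerprint of the grids
#' they were derived from.
#'
#' @param labels An `abnormality_labels` tibble (or a report tibble).
#' @param path Output TSV path.
#' @param fingerprint Optional configuration fingerprint string recorded in
#'   a `config_fingerprint` column.
#' @return The path, invisibly.
#' @export
write_labels <- function(labels, path, fingerprint = NULL) {
  out <- as_tibble(labels)
  out$config_fingerprint <- fingerprint %||% NA_character_
  out$software_version <- as.character(packageVersion("epitract"))
  write_tsv(out, path)
  invisible(path)
}
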