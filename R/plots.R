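#' Plot node-wise tract profiles
#'
#' One line per subject along the 100 nodes, coloured by group when a
#' subject table is supplied, faceted by tract and side.
#'
#' @param profiles Tract-profile tibble.
#' @param subjects Optional subject table for group colouring.
#' @param variable One of `"FA"`, `"MD"`, `"Vol"`.
#' @param timepoint Timepoint to show (default `"pre"`).
#' @return A ggplot object.
#' @export
plot_tract_profiles <- function(profiles, subjects = NULL, variable = "FA",
                                timepoint = "pre") {
  variable <- match.arg(variable, nodewise_variables())
  dat <- profiles |> filter(.data$timepoint == .env$timepoint, .data$valid)
  if (!is.null(subjects)) {
    dat <- dat |> left_join(subjects |> select("subject_id", "group"),
                            by = "subject_id")
  } else {
    dat$group <- "all"
  }
  ggplot(dat, aes(x = .data$node, y = .data[[variable]],
                  group = .data$subject_id, colour = .data$group)) +
    geom_line(alpha = 0.4) +
    facet_grid(vars(.data$side), vars(.data$tract)) +
    labs(x = "node (1-100)", y = variable, colour = NULL) +
    theme_minimal()
}

#' @export
autoplot.tract_grid <- function(object, ...) {
  dat <- as_tibble(object) |>
    mutate(instance = paste(.data$tract, .data$laterality),
           neglogp = -log10(pmax(.data$p_adjusted, 1e-16)))
  ggplot(dat, aes(x = .data$scope, y = .data$instance, fill = .data$neglogp)) +
    geom_tile() +
    geom_point(data = dat |> filter(!is.na(.data$significant), .data$significant),
               shape = 8, size = 1, colour = "white") +
    facet_grid(vars(.data$cohort_scope), vars(.data$variable)) +
    scale_fill_viridis_c(na.value = "grey85") +
    labs(x = NULL, y = NULL, fill = "-log10 p",
         title = "Comparison grid (stars: significant)") +
    theme_minimal()
}

#' @export
autoplot.abnormality_labels <- function(object, ...) {
  counts <- taxonomy_report(object, by = "cohort_scope")
  p <- ggplot(counts, aes(x = .data$category, y = .data$n)) +
    geom_col() +
    labs(x = NULL, y = "labels") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("cohort_scope" %in% names(counts)) {
    p <- p + facet_wrap(vars(.data$cohort_scope))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
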