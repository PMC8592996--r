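# broom-style tidiers and ggplot2 autoplot methods.

#' Tidy a recruitment solution
#'
#' @param x A `spineload_recruitment`.
#' @param ... Unused.
#' @return Per-fascicle tibble of forces and activities.
#' @export
tidy.spineload_recruitment <- function(x, ...) x$forces

#' One-row summary of a recruitment solution
#'
#' @param x A `spineload_recruitment`.
#' @param ... Unused.
#' @return Tibble with the objective, IAP, residual and status flags.
#' @export
glance.spineload_recruitment <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, iap_kpa = x$iap_kpa,
    max_residual = max(x$residuals$norm),
    n_active = sum(x$forces$activity > 1e-6),
    feasible = x$feasible, converged = x$converged
  )
}

#' Tidy a battery comparison report
#'
#' @param x A `spineload_comparison`.
#' @param ... Unused.
#' @return The per-task comparison tibble.
#' @export
tidy.spineload_comparison <- function(x, ...) x$per_task

#' One-row summary of a battery comparison report
#'
#' @param x A `spineload_comparison`.
#' @param ... Unused.
#' @return The across-task means (equal task weighting).
#' @export
glance.spineload_comparison <- function(x, ...) x$overall

#' Plot L5-S1 loads across the task battery
#'
#' @param object A `spineload_battery`.
#' @param measure Column to plot (default `"compression"`).
#' @param ... Unused.
#' @return A ggplot object: load by task, coloured by model variant.
#' @export
autoplot.spineload_battery <- function(object, measure = "compression", ...) {
  df <- tibble::as_tibble(object)
  df$task <- factor(df$task, levels = paste0("T", 1:12))
  ggplot2::ggplot(df[df$feasible, ],
                  ggplot2::aes(x = .data$task, y = .data[[measure]], fill = .data$variant)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "task", y = paste0("L5-S1 ", measure),
                  fill = "model variant") +
    ggplot2::theme_minimal()
}

#' Plot muscle activities of a recruitment solution
#'
#' @param object A `spineload_recruitment`.
#' @param ... Unused.
#' @return A ggplot bar chart of fascicle activities by side.
#' @export
autoplot.spineload_recruitment <- function(object, ...) {
  ggplot2::ggplot(object$forces,
                  ggplot2::aes(x = .data$muscle, y = .data$activity, fill = .data$side)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "activity (force / strength)") +
    ggplot2::theme_minimal()
}

#' @export
print.spineload_recruitment <- function(x, ...) {
  cat("<spineload recruitment solution>\n")
  cat(sprintf("  feasible: %s   objective: %.4g   IAP: %.2f kPa   max residual: %.2e N*m\n",
              x$feasible, x$objective, x$iap_kpa, max(x$residuals$norm)))
  active <- x$forces[x$forces$activity > 1e-6, ]
  cat(sprintf("  active fascicles: %d of %d\n", nrow(active), nrow(x$forces)))
  invisible(x)
}

#' @export
print.spineload_comparison <- function(x, ...) {
  cat("<spineload battery comparison> measure:", x$measure, "\n")
  print(x$per_task)
  cat("across-task means (equal weighting):\n")
  print(x$overall)
  cat(x$note, "\n")
  invisible(x)
}
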