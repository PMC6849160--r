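#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a subtype confusion
#'
#' @param x A `subtype_confusion` object.
#' @param ... Unused.
#' @return A tibble of gold x source x call counts.
#' @method tidy subtype_confusion
#' @export
tidy.subtype_confusion <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of a subtype confusion
#'
#' @param x A `subtype_confusion` object.
#' @param ... Unused.
#' @return A one-row tibble: gold totals, patients classified by each
#'   source, and per-source concordance.
#' @method glance subtype_confusion
#' @export
glance.subtype_confusion <- function(x, ...) {
  tot <- attr(x, "gold_totals")
  st <- subtype_concordance(x, "structured")
  ft <- subtype_concordance(x, "freetext")
  tibble::tibble(
    n_stemi = unname(tot["STEMI"]),
    n_nstemi = unname(tot["NSTEMI"]),
    n_structured = st$n, n_freetext = ft$n,
    concordance_structured = st$point,
    concordance_freetext = ft$point
  )
}

#' Plot a subtype confusion
#'
#' Tile plot of gold subtype against call, faceted by primary-care source.
#'
#' @param object A `subtype_confusion` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot subtype_confusion
#' @export
autoplot.subtype_confusion <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$call, y = .data$gold,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::facet_wrap(~source) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "Primary care call", y = "Registry gold standard",
                  fill = "Patients") +
    ggplot2::theme_minimal()
}

#' Tidy a cause-of-death concordance report
#'
#' @param x A `death_concordance` object.
#' @param ... Unused.
#' @return The match-level tibble (cumulative proportions with CIs).
#' @method tidy death_concordance
#' @export
tidy.death_concordance <- function(x, ...) {
  x$matching
}

#' One-row summary of a cause-of-death concordance report
#'
#' @param x A `death_concordance` object.
#' @param ... Unused.
#' @return A one-row tibble with cohort size, cases with a recorded cause,
#'   and the pooled exact-code and same-chapter proportions.
#' @method glance death_concordance
#' @export
glance.death_concordance <- function(x, ...) {
  p <- x$pooled
  tibble::tibble(
    n_cases = x$n_cases,
    n_with_cause = x$n_with_cause,
    exact_match = p$point[p$level == "same_underlying_cause"],
    same_chapter = p$point[p$level == "same_chapter"]
  )
}

#' Plot cause-of-death match levels
#'
#' Cumulative match-level proportions by source with Wilson intervals.
#'
#' @param object A `death_concordance` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot death_concordance
#' @export
autoplot.death_concordance <- function(object, ...) {
  df <- object$matching %>%
    dplyr::mutate(level = factor(.data$level, levels = c(
      "same_underlying_cause", "same_category", "same_chapter")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$point,
                                   colour = .data$source, group = .data$source)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           width = 0.15,
                           position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "Agreement level (cumulative)",
                  y = "Proportion of deaths", colour = "Source") +
    ggplot2::theme_minimal()
}

#' Plot the symptom recording comparison
#'
#' Paired bars of patients recorded via structured data only versus either
#' source, per symptom/investigation item.
#'
#' @param symptoms Output of [symptom_recording_table()].
#' @return A ggplot object.
#' @export
plot_symptom_recording <- function(symptoms) {
  df <- symptoms %>%
    tidyr::pivot_longer(c("n_structured", "n_either"), names_to = "mode",
                        values_to = "n") %>%
    dplyr::mutate(mode = ifelse(.data$mode == "n_structured",
                                "Structured only", "Structured or free text"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$item, y = .data$n,
                                   fill = .data$mode)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Patients with a record", fill = NULL) +
    ggplot2::theme_minimal()
}
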