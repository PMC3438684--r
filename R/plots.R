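# ggplot2 displays for scan, cross-validation and composition results.

#' Plot a phase-I ranking
#'
#' Log Bayes factor against SNP rank, colored by assigned model.
#'
#' @param object a `pleio_scan`.
#' @param ... unused.
#' @export
autoplot.pleio_scan <- function(object, ...) {
  rk <- object$ranking
  ggplot2::ggplot(rk, ggplot2::aes(x = .data$rank, y = .data$ln_bf,
                                   color = .data$model)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "SNP rank", y = "ln Bayes factor vs null",
                  color = "model") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation metric curves
#'
#' Pooled out-of-fold AUC against nested set size `r`, one line per
#' method, with the selected `r*` marked.
#'
#' @param object a `pleio_cv`.
#' @param ... unused.
#' @export
autoplot.pleio_cv <- function(object, ...) {
  sel <- glance(object)
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$r, y = .data$auc,
                               color = .data$method)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(data = sel,
                        ggplot2::aes(xintercept = .data$r_star,
                                     color = .data$method),
                        linetype = "dashed", show.legend = FALSE) +
    ggplot2::labs(x = "number of ranked SNPs (r)",
                  y = "cross-validated AUC") +
    ggplot2::theme_minimal()
}

#' Plot model composition by rank
#'
#' Stacked-area display of the composition of the nested SNP sets: correct
#' model by causal type, mismodeled causal SNPs, and non-causal SNPs.
#'
#' @param composition output of [composition_by_rank()].
#' @export
plot_composition <- function(composition) {
  long <- tidyr::pivot_longer(
    dplyr::select(composition, -"causal_at_rank"), -"r",
    names_to = "category", values_to = "fraction")
  long$category <- factor(long$category,
                          levels = c("pleio_correct", "da_correct",
                                     "db_correct", "mismodeled",
                                     "non_causal"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$r, y = .data$fraction,
                                     fill = .data$category)) +
    ggplot2::geom_area() +
    ggplot2::scale_fill_manual(values = c(
      pleio_correct = "#08306b", da_correct = "#2171b5",
      db_correct = "#9ecae1", mismodeled = "#8c510a",
      non_causal = "grey90")) +
    ggplot2::labs(x = "SNP rank cutoff (r)", y = "fraction of nested set") +
    ggplot2::theme_minimal()
}
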