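#' Paired pre/post burden plot
#'
#' One panel per body site; each line links a patient's pre- and
#' post-course mutation burden, the classic paired-measurement display for
#' treatment-induced burden increase.
#'
#' @param cohort a [uvb_cohort()].
#' @return A ggplot object.
#' @examples
#' plot_burden_change(nbuvb_cohort())
#' @export
plot_burden_change <- function(cohort) {
  validate_cohort(cohort)
  long <- cohort$measurements %>%
    tidyr::pivot_longer(c("burden_pre", "burden_post"),
                        names_to = "phase", values_to = "burden") %>%
    dplyr::mutate(phase = factor(.data$phase,
                                 levels = c("burden_pre", "burden_post"),
                                 labels = c("pre", "post")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$phase, y = .data$burden,
                                     group = .data$patient_id)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 1.8) +
    ggplot2::facet_wrap(~site, scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = "Mutation burden (substitutions per Mb)") +
    ggplot2::theme_minimal()
}
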