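# Report figures: trajectory spaghetti with WHO reference lines, the two
# leading components, and score histograms.

#' Spaghetti plot of fitted HAZ trajectories with WHO reference lines
#'
#' @param cohort A [haz_cohort()] (one sex).
#' @param model Fitted `fpca_model`.
#' @param ref A `reference_system` (horizontal constant-z reference lines).
#' @param max_children Cap on the number of individual curves drawn.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(cohort, model, ref, max_children = 150L) {
  scores <- estimate_scores(cohort, model)
  fitted <- scores$fitted
  ids <- rownames(fitted)
  if (length(ids) > max_children) {
    ids <- ids[seq_len(max_children)]
    fitted <- fitted[ids, , drop = FALSE]
  }
  long <- data.frame(
    child_id = rep(ids, each = length(model$grid)),
    age = rep(model$grid, times = length(ids)),
    haz = as.vector(t(fitted))
  )
  mean_df <- data.frame(age = model$grid, haz = model$mean)
  ref_df <- data.frame(percentile = ref$ref_scores$percentile,
                       haz = ref$ref_scores$ref_z)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$haz)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$child_id),
                       alpha = 0.25, linewidth = 0.3, colour = "steelblue") +
    ggplot2::geom_hline(data = ref_df,
                        ggplot2::aes(yintercept = .data$haz),
                        colour = "black", linewidth = 0.3) +
    ggplot2::geom_line(data = mean_df, colour = "red", linewidth = 1) +
    ggplot2::labs(x = "Age (months)", y = "HAZ",
                  title = paste0("Fitted HAZ trajectories (",
                                 model$sex, ")"),
                  subtitle = "Horizontal lines: WHO percentile references; red: cohort mean") +
    ggplot2::theme_minimal()
}

#' Plot the two leading functional principal components
#'
#' @param model Fitted `fpca_model`.
#' @return A ggplot object.
#' @export
plot_components <- function(model) {
  k <- min(2L, ncol(model$eigenfunctions))
  share <- round(100 * c(model$fve[1], diff(model$fve))[seq_len(k)], 1)
  long <- data.frame(
    age = rep(model$grid, times = k),
    value = as.vector(model$eigenfunctions[, seq_len(k)]),
    component = rep(sprintf("FPC%d (%.1f%%)", seq_len(k), share),
                    each = length(model$grid))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value,
                                     colour = .data$component)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Age (months)", y = "Eigenfunction",
                  title = paste0("Leading components (", model$sex, ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histograms of FPC1, FPC2 and adj-FPC2 scores
#'
#' @param results A `faltering_result`.
#' @return A ggplot object (faceted).
#' @export
plot_score_histograms <- function(results) {
  long <- data.frame(
    value = c(results$s1, results$s2, results$adj_fpc2),
    score = rep(c("FPC1", "FPC2", "adj-FPC2"),
                each = nrow(results))
  )
  long$score <- factor(long$score, levels = c("FPC1", "FPC2", "adj-FPC2"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~score, scales = "free") +
    ggplot2::labs(x = "Score", y = "Children") +
    ggplot2::theme_minimal()
}
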