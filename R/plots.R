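# ggplot2 displays for the main result types.

#' @describeIn km_curve Kaplan-Meier step plot (one step curve per
#'   group when present).
#' @param object A `km_fit`.
#' @param ... Unused.
#' @method autoplot km_fit
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- as_tibble(object)
  pad <- function(dd) {
    dplyr::bind_rows(tibble(time = 0, surv = 1), dd[c("time", "surv")])
  }
  if ("group" %in% names(d)) {
    d <- dplyr::group_modify(dplyr::group_by(d, .data$group), ~ pad(.x)) |>
      dplyr::ungroup()
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$surv,
                                         colour = .data$group))
  } else {
    p <- ggplot2::ggplot(pad(d), ggplot2::aes(.data$time, .data$surv))
  }
  p + ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time", y = "Survival probability")
}

#' @describeIn roc_cutoff ROC curve with the Youden-optimal point marked.
#' @param object A `roc_result`.
#' @param ... Unused.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  d <- object$curve
  d <- d[order(1 - d$specificity, d$sensitivity), ]
  d <- dplyr::bind_rows(tibble(cutoff = NA, sensitivity = 0, specificity = 1),
                        d,
                        tibble(cutoff = NA, sensitivity = 1, specificity = 0))
  ggplot2::ggplot(d, ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_path() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::annotate("point", x = 1 - object$specificity,
                      y = object$sensitivity, colour = "red") +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("AUC = %.4f, cutoff = %g",
                                  object$auc, object$cutoff))
}

#' Plot an A/B compartment track
#'
#' Bar track of the compartment eigenvector, filled by A/B call.
#'
#' @param track A [compartment_track()] tibble.
#' @return A ggplot.
#' @export
plot_compartments <- function(track) {
  d <- track[!is.na(track$eigen), ]
  ggplot2::ggplot(d, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$eigen,
                                  fill = .data$compartment)) +
    ggplot2::geom_col(width = max(d$end - d$start)) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(A = "#d73027", B = "#4575b4"),
                               na.value = "grey70") +
    ggplot2::labs(x = "Genomic position (bp)", y = "Leading eigenvector")
}

#' Plot an insulation track with called TAD boundaries
#'
#' @param track An [insulation_track()] tibble.
#' @param tads Optional [call_tads()] result; retained internal
#'   boundaries are drawn as vertical lines.
#' @return A ggplot.
#' @export
plot_insulation <- function(track, tads = NULL) {
  p <- ggplot2::ggplot(track[!is.na(track$insulation), ],
                       ggplot2::aes((.data$start + .data$end) / 2,
                                    .data$insulation)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Genomic position (bp)", y = "Insulation score (log2)")
  if (!is.null(tads)) {
    b <- tad_boundaries_of(tads)
    if (nrow(b) > 0) {
      p <- p + ggplot2::geom_vline(data = b,
                                   ggplot2::aes(xintercept = .data$pos),
                                   linetype = "dotted", colour = "red")
    }
  }
  p
}

#' Volcano-style plot of marker statistics
#'
#' @param markers A [rank_sum_markers()] tibble.
#' @param padj_max,lfc_min Highlight thresholds.
#' @return A ggplot, faceted by group.
#' @export
plot_markers <- function(markers, padj_max = 0.01, lfc_min = 1) {
  d <- dplyr::mutate(markers,
                     hit = .data$adjusted_p < padj_max &
                       abs(.data$log_fc) > lfc_min)
  ggplot2::ggplot(d, ggplot2::aes(.data$log_fc,
                                  -log10(pmax(.data$adjusted_p, 1e-300)),
                                  colour = .data$hit)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#d73027",
                                            `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 adjusted p")
}
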