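# broom-style accessors and ggplot2 autoplot methods for the result types.

#' @method tidy acyl_classification
#' @export
tidy.acyl_classification <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- setdiff(class(out), "acyl_classification")
  out
}

#' @method glance acyl_classification
#' @export
glance.acyl_classification <- function(x, ...) {
  tibble(
    n = nrow(x),
    n_called = sum(x$status == "called"),
    n_gdpat_like = sum(x$status == "gdpat_like"),
    n_partial = sum(x$status == "partial"),
    n_ambiguous = sum(x$status == "ambiguous"),
    n_none = sum(x$status == "none"),
    n_pts1_positive = sum(x$pts1_positive)
  )
}

#' @method tidy acyl_survey
#' @export
tidy.acyl_survey <- function(x, ...) {
  x$log
}

#' @method glance acyl_survey
#' @export
glance.acyl_survey <- function(x, ...) {
  tibble(
    families = length(x$iterations),
    validated = nrow(x$validated),
    max_iterations = max(x$iterations),
    proteomes_hit = length(unique(x$validated$proteome))
  )
}

#' @method tidy acyl_presence
#' @export
tidy.acyl_presence <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), -"subclass",
                      names_to = "proteome", values_to = "present")
}

#' @method tidy acyl_pssm
#' @export
tidy.acyl_pssm <- function(x, ...) {
  cols <- bind_rows(map(x$columns, as_tibble))
  bind_cols(
    cols[rep(seq_len(nrow(cols)), each = 20), ],
    tibble(residue = rep(rownames(x$scores), ncol(x$scores)),
           score = as.vector(x$scores))
  )
}

#' Plot a presence/absence matrix
#'
#' Tile plot of subclass detections across proteomes, the standard visual
#' summary of a comparative survey.
#'
#' @param object An `acyl_presence`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acyl_presence
#' @export
autoplot.acyl_presence <- function(object, ...) {
  long <- tidy.acyl_presence(object)
  long$subclass <- factor(long$subclass,
                          levels = rev(unique(object$subclass)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$proteome, y = .data$subclass,
                                     fill = .data$present)) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2c7fb8",
                                          `FALSE` = "grey92"),
                               name = "present") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-subclass chain scores of a classification
#'
#' @param object An `acyl_classification`.
#' @param ... Unused.
#' @return A ggplot object (proteins x subclasses score tiles).
#' @method autoplot acyl_classification
#' @export
autoplot.acyl_classification <- function(object, ...) {
  score_cols <- grep("^score_", names(object), value = TRUE)
  long <- tidyr::pivot_longer(as_tibble(object)[, c("id", score_cols)],
                              -"id", names_to = "subclass",
                              values_to = "score")
  long$subclass <- sub("^score_", "", long$subclass)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$subclass, y = .data$id,
                                     fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey95") +
    ggplot2::labs(x = NULL, y = NULL, fill = "chain score") +
    ggplot2::theme_minimal()
}

#' Plot a placed motif chain
#'
#' Draws the four motif windows along the protein with the inter-motif
#' distances annotated.
#'
#' @param object An `acyl_chain` from [scan_chain()].
#' @param seq_length Optional protein length for the x scale.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot acyl_chain
#' @export
autoplot.acyl_chain <- function(object, seq_length = NULL, ...) {
  df <- as_tibble(object)
  df$end <- df$offset + df$length - 1
  dbm <- chain_dbm(object)
  mids <- (df$end[-nrow(df)] + df$offset[-1]) / 2
  ann <- tibble(x = mids, label = as.character(dbm))
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = 1,
                                       xend = seq_length %||% (max(df$end) + 20),
                                       y = 1, yend = 1), colour = "grey70") +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$offset, xmax = .data$end,
                                    ymin = 0.9, ymax = 1.1,
                                    fill = .data$motif)) +
    ggplot2::geom_text(data = ann,
                       ggplot2::aes(x = .data$x, y = 1.25,
                                    label = .data$label), size = 3) +
    ggplot2::scale_y_continuous(limits = c(0.6, 1.5), breaks = NULL) +
    ggplot2::labs(x = "residue", y = NULL, fill = "motif",
                  subtitle = paste0(attr(object, "subclass"), " chain, score ",
                                    round(chain_score(object), 1))) +
    ggplot2::theme_minimal()
}
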