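# ggplot2 views of the corpus statistics.

#' Plot a token frequency distribution
#'
#' @param object a tibble from [token_distribution()].
#' @param top show only the most frequent tokens.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ts_token_distribution
#' @export
autoplot.ts_token_distribution <- function(object, top = 25L, ...) {
  df <- utils::head(object, top)
  df$token <- factor(df$token, levels = rev(df$token))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$token)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "frequency", y = NULL,
                  title = "Token distribution") +
    ggplot2::theme_minimal()
}

#' Plot a nesting-depth profile
#'
#' @param object a `ts_nesting` from [nesting_profile()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ts_nesting
#' @export
autoplot.ts_nesting <- function(object, ...) {
  ggplot2::ggplot(object$bands,
                  ggplot2::aes(x = .data$band, y = .data$prop)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "maximum nesting depth", y = "proportion of strings",
                  title = "Parenthesis nesting depth") +
    ggplot2::theme_minimal()
}

#' Plot per-descriptor Wasserstein distances of a report
#'
#' @param object a `ts_report` from [distribution_report()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ts_report
#' @export
autoplot.ts_report <- function(object, ...) {
  df <- object$descriptors
  ggplot2::ggplot(df, ggplot2::aes(x = .data$property, y = .data$wasserstein)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::labs(x = NULL, y = "1-Wasserstein distance",
                  title = "Property distribution distances") +
    ggplot2::theme_minimal()
}

#' Overlayed property distributions of two molecule sets
#'
#' Density overlays per descriptor, generated vs training.
#'
#' @inheritParams distribution_report
#' @return a ggplot object (faceted by descriptor).
#' @export
plot_property_distributions <- function(generated, training,
                                        properties = ts_property_set()) {
  if (is.data.frame(generated)) generated <- generated$smiles
  if (is.data.frame(training)) training <- training$smiles
  gp <- ts_properties(generated, properties)
  tp <- ts_properties(training, properties)
  gp$set <- "generated"; tp$set <- "training"
  df <- dplyr::bind_rows(gp, tp)
  long <- tidyr::pivot_longer(df, -"set", names_to = "property",
                              values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, fill = .data$set)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(~property, scales = "free") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_minimal()
}
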