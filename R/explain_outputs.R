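#' Summarize explanations for one class
#'
#' Global feature-importance view over a set of explained instances:
#' features are ranked by mean absolute Shapley value (descending, ties by
#' original feature order), and a per-instance scatter of (feature value,
#' Shapley value) pairs is kept for the `top_k` ranked features — the data
#' behind a SHAP summary (beeswarm) plot.
#'
#' @param explanations List of per-instance explanation lists as returned by
#'   [explain_instances()], or a flat list of `shap_explanation` objects.
#' @param class_index Class to summarize (1-based).
#' @param top_k Number of ranked features to keep (default 10, capped at M).
#' @return An object of class `shap_summary`: list with `class_index`,
#'   `class_name`, `ranking` (data frame `feature`, `mean_abs_shap`, top_k
#'   rows), `scatter` (data frame `instance`, `feature`, `feature_value`,
#'   `shap_value`) and `top_k`.
#' @export
shap_summarize <- function(explanations, class_index = 1, top_k = 10) {
  if (!length(explanations)) stop_input("empty explanation list")
  pick <- lapply(explanations, function(e) {
    if (inherits(e, "shap_explanation")) {
      if (e$class_index == class_index) e else NULL
    } else {
      hit <- Filter(function(z) z$class_index == class_index, e)
      if (length(hit)) hit[[1L]] else NULL
    }
  })
  pick <- Filter(Negate(is.null), pick)
  if (!length(pick)) stop_input("no explanations for class_index ", class_index)
  M <- length(pick[[1L]]$shap_values)
  feat <- names(pick[[1L]]$shap_values)
  shap_mat <- t(vapply(pick, function(e) unname(e$shap_values), numeric(M)))
  val_mat <- t(vapply(pick, function(e) unname(e$feature_values), numeric(M)))
  imp <- colMeans(abs(shap_mat))
  ord <- order(-imp, seq_along(imp))           # stable: ties keep feature order
  top_k <- as.integer(min(top_k, M))
  keep <- ord[seq_len(top_k)]
  ranking <- data.frame(feature = feat[keep], mean_abs_shap = unname(imp[keep]),
                        row.names = NULL)
  n <- nrow(shap_mat)
  scatter <- data.frame(
    instance = rep(seq_len(n), times = top_k),
    feature = rep(feat[keep], each = n),
    feature_value = as.vector(val_mat[, keep]),
    shap_value = as.vector(shap_mat[, keep]),
    row.names = NULL
  )
  structure(list(class_index = class_index,
                 class_name = pick[[1L]]$class_name,
                 ranking = ranking, scatter = scatter, top_k = top_k),
            class = "shap_summary")
}

#' Decompose one explanation into force-plot data
#'
#' Splits the Shapley values of a single explanation by sign — features
#' pushing the output above the base value versus below it — each group
#' sorted by decreasing absolute contribution; zero contributions go to a
#' residual group. Additivity (`base_value + sum(shap) = fx`) is re-verified.
#'
#' @param explanation A `shap_explanation`.
#' @param instance_id Optional identifier carried into the output.
#' @param tolerance Additivity tolerance (default 1e-6).
#' @return An object of class `shap_force`: list with `instance_id`,
#'   `class_index`, `class_name`, `base_value`, `fx` and data frames
#'   `positive`, `negative`, `zero` (columns `feature`, `feature_value`,
#'   `shap_value`).
#' @export
force_decompose <- function(explanation, instance_id = NULL, tolerance = 1e-6) {
  stopifnot(inherits(explanation, "shap_explanation"))
  phi <- explanation$shap_values
  gap <- abs(explanation$base_value + sum(phi) - explanation$fx)
  if (gap > tolerance) {
    stop_input("explanation violates additivity by ", format(gap))
  }
  df <- data.frame(feature = names(phi),
                   feature_value = unname(explanation$feature_values),
                   shap_value = unname(phi), row.names = NULL)
  grab <- function(rows) {
    out <- df[rows, , drop = FALSE]
    out[order(-abs(out$shap_value)), , drop = FALSE]
  }
  structure(list(instance_id = instance_id,
                 class_index = explanation$class_index,
                 class_name = explanation$class_name,
                 base_value = explanation$base_value, fx = explanation$fx,
                 positive = grab(df$shap_value > 0),
                 negative = grab(df$shap_value < 0),
                 zero = df[df$shap_value == 0, , drop = FALSE]),
            class = "shap_force")
}

#' Write summary or force data to disk
#'
#' JSON and CSV are lossless serializations (full double precision); PNG is
#' a best-effort static chart (requires ggplot2): a jittered
#' beeswarm-style summary or a horizontal contribution bar chart.
#'
#' @param x A `shap_summary` or `shap_force`.
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"png"`.
#' @return Invisibly, `path`.
#' @export
render_shap <- function(x, path, format = c("json", "csv", "png")) {
  format <- match.arg(format)
  if (!dir.exists(dirname(path))) stop_input("unwritable path: ", dirname(path))
  switch(format,
    json = jsonlite::write_json(.shap_to_list(x), path, auto_unbox = TRUE,
                                digits = NA, null = "null"),
    csv = utils::write.csv(.shap_to_frame(x), path, row.names = FALSE),
    png = .shap_to_png(x, path)
  )
  invisible(path)
}

.shap_to_list <- function(x) {
  out <- unclass(x)
  out$kind <- if (inherits(x, "shap_summary")) "summary" else "force"
  out
}

.shap_to_frame <- function(x) {
  if (inherits(x, "shap_summary")) {
    rk <- x$ranking
    rk$rank <- seq_len(nrow(rk))
    out <- merge(x$scatter, rk, by = "feature", sort = FALSE)
    out <- out[order(out$rank, out$instance),
               c("rank", "feature", "mean_abs_shap", "instance",
                 "feature_value", "shap_value")]
    out$class_index <- x$class_index
    rownames(out) <- NULL
    out
  } else {
    parts <- rbind(
      cbind(x$positive, sign = rep_len("positive", nrow(x$positive))),
      cbind(x$negative, sign = rep_len("negative", nrow(x$negative))),
      cbind(x$zero, sign = rep_len("zero", nrow(x$zero)))
    )
    parts$base_value <- x$base_value
    parts$fx <- x$fx
    parts$class_index <- x$class_index
    rownames(parts) <- NULL
    parts
  }
}

.shap_to_png <- function(x, path) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_config("png rendering requires the ggplot2 package")
  }
  if (inherits(x, "shap_summary")) {
    d <- x$scatter
    d$feature <- factor(d$feature, levels = rev(x$ranking$feature))
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$shap_value, y = .data$feature,
                                         colour = .data$feature_value)) +
      ggplot2::geom_jitter(height = 0.2, width = 0, alpha = 0.7, size = 1) +
      ggplot2::scale_colour_gradient(low = "blue", high = "red") +
      ggplot2::labs(x = "Shapley value", y = NULL, colour = "feature value",
                    title = paste("Summary:", x$class_name))
  } else {
    d <- rbind(x$positive, x$negative)
    d <- d[order(d$shap_value), , drop = FALSE]
    d$feature <- factor(d$feature, levels = d$feature)
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$shap_value, y = .data$feature,
                                         fill = .data$shap_value > 0)) +
      ggplot2::geom_col(show.legend = FALSE) +
      ggplot2::scale_fill_manual(values = c(`TRUE` = "red", `FALSE` = "blue")) +
      ggplot2::labs(x = "contribution", y = NULL,
                    title = sprintf("%s: base %.3f -> f(x) %.3f",
                                    x$class_name, x$base_value, x$fx))
  }
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120)
}

#' Read summary data back from JSON
#'
#' Inverse of [render_shap()] with `format = "json"` for `shap_summary`
#' objects.
#'
#' @param path JSON file written by [render_shap()].
#' @return A `shap_summary`.
#' @export
read_shap_summary <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(class_index = raw$class_index, class_name = raw$class_name,
                 ranking = as.data.frame(raw$ranking),
                 scatter = as.data.frame(raw$scatter), top_k = raw$top_k),
            class = "shap_summary")
}
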