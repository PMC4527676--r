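# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fold-check result
#'
#' @param x A `fold_check` from [check_mb_fold()].
#' @param ... Unused.
#' @return One row per template position: `label`, `helix`, `role`,
#'   `reference_residue`, `column`, `residue` (`NA` at gaps), `hydrophobic`.
#' @method tidy fold_check
#' @export
tidy.fold_check <- function(x, ...) {
  x$positions
}

#' One-row summary of a fold-check result
#'
#' @param x A `fold_check` from [check_mb_fold()].
#' @param ... Unused.
#' @return Tibble with `candidate_id`, `verdict`, `f8_his`,
#'   `helices_present`, `hydrophobic_fraction`, `fugue_z`.
#' @method glance fold_check
#' @export
glance.fold_check <- function(x, ...) {
  tibble::tibble(
    candidate_id = x$candidate_id,
    verdict = x$verdict,
    f8_his = x$f8_his,
    helices_present = paste(x$helices_present, collapse = ""),
    hydrophobic_fraction = x$hydrophobic_fraction,
    fugue_z = x$fugue_z %||% NA_real_
  )
}

#' Tidy a per-site dRMSD profile
#'
#' @param x A `site_profile` from [per_site_drmsd()] or
#'   [average_profiles()].
#' @param ... Unused.
#' @return One row per alignment column: `column`, `drmsd` (`NA` at gaps),
#'   `gap`, and `confidence` when available.
#' @method tidy site_profile
#' @export
tidy.site_profile <- function(x, ...) {
  out <- tibble::tibble(
    column = seq_along(x$values),
    drmsd = x$values,
    gap = is.na(x$values)
  )
  if (!is.null(x$confidence)) out$confidence <- x$confidence
  if (!is.null(x$helix_labels)) out$helix <- x$helix_labels
  out
}

#' One-row summary of a per-site dRMSD profile
#'
#' @param x A `site_profile`.
#' @param ... Unused.
#' @return Tibble with the pair of structure ids, `n_aligned`,
#'   `overall_rmsd` and `mean_square`.
#' @method glance site_profile
#' @export
glance.site_profile <- function(x, ...) {
  tibble::tibble(
    structure_a = x$pair[[1]],
    structure_b = x$pair[[2]],
    n_aligned = x$n_aligned,
    overall_rmsd = x$overall_rmsd,
    mean_square = x$mean_square
  )
}

#' Plot a per-site dRMSD profile
#'
#' Draws the per-column deviation profile: bars for per-site dRMSD, grey
#' marks over gap columns, a dashed line at the overall RMSD, and (when
#' present) the per-column alignment confidence as a shaded band along the
#' baseline.
#'
#' @param object A `site_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot site_profile
#' @export
autoplot.site_profile <- function(object, ...) {
  df <- tidy(object)
  ymax <- max(df$drmsd, na.rm = TRUE)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$column, y = .data$drmsd)) +
    ggplot2::geom_col(fill = "grey25", na.rm = TRUE, width = 1)
  gaps <- df[df$gap, , drop = FALSE]
  if (nrow(gaps) > 0) {
    p <- p + ggplot2::geom_tile(
      data = gaps,
      ggplot2::aes(x = .data$column, y = ymax / 2),
      height = ymax, width = 1, fill = "grey80", alpha = 0.6
    )
  }
  if ("confidence" %in% names(df)) {
    p <- p + ggplot2::geom_area(
      ggplot2::aes(y = .data$confidence * ymax * 0.25),
      fill = "steelblue", alpha = 0.4
    )
  }
  p +
    ggplot2::geom_hline(yintercept = object$overall_rmsd,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(
      x = "alignment column",
      y = "per-site dRMSD (Å)",
      title = sprintf("%s vs %s (n = %d, overall %.2f Å)",
                      object$pair[[1]], object$pair[[2]],
                      object$n_aligned, object$overall_rmsd)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
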