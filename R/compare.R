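# Measure-comparison harness: molecules x measures score tables, pairwise
# squared Pearson correlations, distribution summaries, plots.

#' Assemble a molecules-by-measures score table
#'
#' Validates a data frame (or reads a TSV) of one row per molecule with an
#' `id` column and numeric measure columns. External measures (SAscore,
#' SPS, nSPS, FCFP4 bit counts, ...) are consumed as precomputed columns —
#' they are prior work, not reimplemented here — and can be joined onto a
#' [mc_score()] result by `id`. Missing scores stay `NA` and are excluded
#' pairwise downstream; no silent NaN.
#'
#' @param x A data frame of scores, or the path of a TSV file.
#' @param id_col Name of the identifier column (default `"id"`).
#' @param external Optional second data frame or TSV path of precomputed
#'   external measures, joined on `id_col`.
#' @return A tibble of class `score_table`: `id` plus numeric columns.
#' @export
score_table <- function(x, id_col = "id", external = NULL) {
  read_in <- function(obj) {
    if (is.character(obj) && length(obj) == 1) {
      readr::read_tsv(obj, show_col_types = FALSE, comment = "#")
    } else {
      tibble::as_tibble(obj)
    }
  }
  tbl <- read_in(x)
  if (!id_col %in% names(tbl)) {
    rlang::abort(sprintf("score table needs an identifier column '%s'", id_col),
                 class = "molcomplex_input_error")
  }
  if (!is.null(external)) {
    ext <- read_in(external)
    if (!id_col %in% names(ext)) {
      rlang::abort(sprintf("external scores need an identifier column '%s'", id_col),
                   class = "molcomplex_input_error")
    }
    ext[[id_col]] <- as.character(ext[[id_col]])
    tbl[[id_col]] <- as.character(tbl[[id_col]])
    tbl <- dplyr::left_join(tbl, ext, by = id_col)
  }
  tbl <- dplyr::rename(tbl, id = dplyr::all_of(id_col))
  tbl$id <- as.character(tbl$id)
  num <- names(tbl)[vapply(tbl, is.numeric, logical(1))]
  if (length(num) < 1) {
    rlang::abort("score table has no numeric measure columns",
                 class = "molcomplex_input_error")
  }
  out <- dplyr::select(tbl, "id", dplyr::all_of(num))
  class(out) <- c("score_table", class(out))
  out
}

#' Pairwise squared Pearson correlations between measures
#'
#' Computes the symmetric matrix of r-squared values over every pair of
#' numeric measure columns, using pairwise-complete observations. The
#' diagonal is 1 by definition wherever the column varies; a constant
#' column, or a pair with fewer than `min_pairs` complete observations,
#' yields `NA` (an explicit undefined marker) rather than a number.
#'
#' @param t A `score_table` (or any data frame; numeric columns are used).
#' @param columns Optional character vector restricting the measures.
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return An object of class `mc_r2`: the r-squared matrix with an `n`
#'   attribute holding the per-cell complete-pair counts.
#' @examples
#' \donttest{
#' fixture_score_table(10) |> pairwise_r2()
#' }
#' @export
pairwise_r2 <- function(t, columns = NULL, min_pairs = 3L) {
  t <- tibble::as_tibble(t)
  num <- names(t)[vapply(t, is.numeric, logical(1))]
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, num)
    if (length(missing_cols) > 0) {
      rlang::abort(paste("not numeric columns of the table:",
                         paste(missing_cols, collapse = ", ")),
                   class = "molcomplex_input_error")
    }
    num <- columns
  }
  if (length(num) < 2) {
    rlang::abort("need at least two numeric measure columns",
                 class = "molcomplex_input_error")
  }
  p <- length(num)
  r2 <- matrix(NA_real_, p, p, dimnames = list(num, num))
  npair <- matrix(0L, p, p, dimnames = list(num, num))
  for (i in seq_len(p)) {
    for (j in i:p) {
      x <- t[[num[i]]]; y <- t[[num[j]]]
      ok <- stats::complete.cases(x, y)
      npair[i, j] <- npair[j, i] <- sum(ok)
      if (sum(ok) < min_pairs) next
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next  # undefined
      if (i == j) {
        r2[i, j] <- 1
      } else {
        r2[i, j] <- r2[j, i] <- stats::cor(x[ok], y[ok])^2
      }
    }
  }
  structure(r2, n = npair, class = c("mc_r2", "matrix", "array"))
}

#' @export
print.mc_r2 <- function(x, digits = 3, ...) {
  cat("<mc_r2> pairwise squared Pearson correlations\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Tidy a pairwise r-squared matrix
#'
#' @param x An `mc_r2` object from [pairwise_r2()].
#' @param ... Unused.
#' @return A long tibble with `measure1`, `measure2`, `r_squared`, `n`
#'   (complete pairs), one row per unordered pair including the diagonal.
#' @export
tidy.mc_r2 <- function(x, ...) {
  nm <- rownames(x)
  n <- attr(x, "n")
  pairs <- which(upper.tri(x, diag = TRUE), arr.ind = TRUE)
  tibble::tibble(
    measure1 = nm[pairs[, "row"]],
    measure2 = nm[pairs[, "col"]],
    r_squared = x[pairs],
    n = n[pairs]
  )
}

#' Summarize a pairwise r-squared matrix
#'
#' @param x An `mc_r2` object.
#' @param ... Unused.
#' @return A one-row tibble: number of measures, molecules (max pair
#'   count), and the mean / max off-diagonal r-squared over defined cells.
#' @export
glance.mc_r2 <- function(x, ...) {
  off <- unclass(x)[upper.tri(x)]
  tibble::tibble(
    n_measures = nrow(x),
    n_molecules = max(attr(x, "n")),
    n_undefined = sum(is.na(off)),
    mean_r_squared = mean(off, na.rm = TRUE),
    max_r_squared = if (all(is.na(off))) NA_real_ else max(off, na.rm = TRUE)
  )
}

#' Heatmap of a pairwise r-squared matrix
#'
#' @param object An `mc_r2` object from [pairwise_r2()].
#' @param ... Unused.
#' @return A ggplot object (tile heatmap, undefined cells blank).
#' @export
autoplot.mc_r2 <- function(object, ...) {
  long <- tidy.mc_r2(object)
  long2 <- dplyr::bind_rows(
    long,
    dplyr::filter(long, .data$measure1 != .data$measure2) |>
      dplyr::rename(measure1 = "measure2", measure2 = "measure1")
  )
  ggplot2::ggplot(long2, ggplot2::aes(.data$measure1, .data$measure2,
                                      fill = .data$r_squared)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r_squared)),
                       size = 3, na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90",
                                  name = expression(r^2)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Pairwise squared Pearson correlation between measures") +
    ggplot2::theme_minimal()
}

#' Per-measure distribution summaries
#'
#' Deterministic five-number summaries (type-7 quantiles) plus histogram
#' bins for each measure column — the tabular backbone of a violin or
#' density plot of score distributions.
#'
#' @param t A `score_table` or data frame; numeric columns are summarized.
#' @param columns Optional character vector restricting the measures.
#' @param bins Number of histogram bins (default 20).
#' @return A tibble with one row per measure: `measure`, `n`, `min`, `q1`,
#'   `median`, `q3`, `max`, and list-columns `bin_mid`, `bin_count`.
#' @export
distribution_summary <- function(t, columns = NULL, bins = 20L) {
  t <- tibble::as_tibble(t)
  num <- names(t)[vapply(t, is.numeric, logical(1))]
  if (!is.null(columns)) num <- intersect(columns, num)
  if (length(num) == 0) {
    rlang::abort("no numeric measure columns to summarize",
                 class = "molcomplex_input_error")
  }
  purrr::map(num, function(col) {
    v <- t[[col]][!is.na(t[[col]])]
    if (length(v) == 0) {
      rlang::abort(sprintf("measure '%s' has no values", col),
                   class = "molcomplex_input_error")
    }
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), names = FALSE, type = 7)
    rng <- range(v)
    if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    tibble::tibble(measure = col, n = length(v),
                   min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
                   bin_mid = list(h$mids), bin_count = list(h$counts))
  }) |>
    dplyr::bind_rows()
}

#' Violin plot of per-measure score distributions
#'
#' @param t A `score_table` or data frame of scores.
#' @param columns Optional character vector restricting the measures.
#' @return A ggplot object: one violin (probability density) per measure,
#'   free y scales since measures live on different scales.
#' @export
plot_score_distributions <- function(t, columns = NULL) {
  t <- tibble::as_tibble(t)
  num <- names(t)[vapply(t, is.numeric, logical(1))]
  if (!is.null(columns)) num <- intersect(columns, num)
  long <- tidyr::pivot_longer(dplyr::select(t, dplyr::all_of(num)),
                              dplyr::everything(),
                              names_to = "measure", values_to = "score") |>
    dplyr::filter(!is.na(.data$score))
  ggplot2::ggplot(long, ggplot2::aes(x = "", y = .data$score)) +
    ggplot2::geom_violin(fill = "steelblue", alpha = 0.6, na.rm = TRUE) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Probability density of each complexity measure") +
    ggplot2::theme_minimal()
}
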