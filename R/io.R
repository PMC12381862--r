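# Structure-file ingestion and deterministic TSV output.

#' Read structures from a file
#'
#' Supported layouts: a SMILES line file (`smiles`, one molecule per line,
#' optionally `SMILES<TAB>id`), a delimited table (`csv`/`tsv`) with a
#' named SMILES column, or an SDF (V2000, `sdf`) file of one or more
#' records. Attachment points must use the standard dummy-atom token
#' (`[*]` or `*`).
#'
#' @param path Input file path.
#' @param format `"smiles"`, `"csv"`, `"tsv"` or `"sdf"`.
#' @param smiles_col SMILES column name for `csv`/`tsv` input.
#' @param id_col Optional id column name for `csv`/`tsv` input.
#' @return A tibble with columns `id`, `input` (SMILES string or SDF
#'   record text) and `fmt` (`"smiles"` or `"sdf_record"`), one row per
#'   molecule in file order.
#' @export
read_structures <- function(path, format = c("smiles", "csv", "tsv", "sdf"),
                            smiles_col = "smiles", id_col = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(sprintf("input file not found: %s", path),
                 class = "molcomplex_input_error")
  }
  out <- switch(format,
    smiles = {
      lines <- readr::read_lines(path)
      lines <- lines[nzchar(trimws(lines))]
      parts <- stringr::str_split_fixed(lines, "\t", 2)
      ids <- ifelse(nzchar(parts[, 2]), parts[, 2], as.character(seq_along(lines)))
      tibble::tibble(id = ids, input = trimws(parts[, 1]), fmt = "smiles")
    },
    csv = ,
    tsv = {
      reader <- if (format == "csv") readr::read_csv else readr::read_tsv
      tbl <- reader(path, show_col_types = FALSE)
      if (!smiles_col %in% names(tbl)) {
        rlang::abort(sprintf("column '%s' not found in %s", smiles_col, path),
                     class = "molcomplex_input_error")
      }
      ids <- if (!is.null(id_col)) {
        if (!id_col %in% names(tbl)) {
          rlang::abort(sprintf("column '%s' not found in %s", id_col, path),
                       class = "molcomplex_input_error")
        }
        as.character(tbl[[id_col]])
      } else as.character(seq_len(nrow(tbl)))
      tibble::tibble(id = ids, input = as.character(tbl[[smiles_col]]), fmt = "smiles")
    },
    sdf = {
      lines <- readr::read_lines(path)
      ends <- which(trimws(lines) == "$$$$")
      if (length(ends) == 0 && length(lines) > 0) ends <- length(lines)
      starts <- c(1L, utils::head(ends, -1) + 1L)
      recs <- purrr::map2(starts, ends, function(s, e) lines[s:e])
      recs <- purrr::keep(recs, function(r) any(grepl("V2000", r, fixed = TRUE)))
      ids <- purrr::map_chr(recs, function(r) trimws(r[1]))
      ids <- ifelse(nzchar(ids), ids, as.character(seq_along(recs)))
      tibble::tibble(id = ids,
                     input = purrr::map_chr(recs, paste, collapse = "\n"),
                     fmt = "sdf_record")
    }
  )
  if (nrow(out) == 0) {
    rlang::abort(sprintf("no molecules found in %s", path),
                 class = "molcomplex_input_error")
  }
  out
}

# Fixed-format numeric rendering so identical runs are byte-identical.
format_fixed <- function(x, decimals) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", decimals, "f"), x))
}

#' Write complexity records as a TSV
#'
#' Deterministic column order and float formatting: MC1 and FDV are
#' printed with a configurable number of decimals (default 2, the
#' precision complexity values are conventionally reported at); pass
#' `full_precision = TRUE` to append full-precision columns. A `# key=value`
#' header echoes the effective run configuration.
#'
#' @param records A tibble from [mc_score()].
#' @param path Output path.
#' @param decimals Decimals for `fdv`/`mc1` (default 2).
#' @param full_precision Also write `fdv_full`, `mc1_full` at full precision.
#' @param config Optional named list echoed as `# key=value` header lines.
#' @return `path`, invisibly.
#' @export
write_score_tsv <- function(records, path, decimals = 2L, full_precision = FALSE,
                            config = NULL) {
  out <- tibble::tibble(
    id = records$id, smiles = records$smiles, hac = records$hac,
    fdv = format_fixed(records$fdv, decimals),
    mc1 = format_fixed(records$mc1, decimals),
    mc2 = records$mc2, n_excluded = records$n_excluded,
    n_attachments = records$n_attachments, status = records$status,
    message = records$message
  )
  if (full_precision) {
    out$fdv_full <- ifelse(is.na(records$fdv), "NA", sprintf("%.12g", records$fdv))
    out$mc1_full <- ifelse(is.na(records$mc1), "NA", sprintf("%.12g", records$mc1))
  }
  header <- if (!is.null(config)) {
    sprintf("# %s=%s", names(config), vapply(config, as.character, character(1)))
  } else character(0)
  body <- c(paste(names(out), collapse = "\t"),
            do.call(paste, c(as.list(out), sep = "\t")))
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Write an r-squared matrix as a TSV
#'
#' @param r2 An `mc_r2` object from [pairwise_r2()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_r2_tsv <- function(r2, path) {
  m <- unclass(r2)
  lines <- c(paste(c("measure", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(rownames(m)[i],
                       ifelse(is.na(m[i, ]), "NA", sprintf("%.12g", m[i, ]))),
                     collapse = "\t")
             }, character(1)))
  readr::write_lines(lines, path)
  invisible(path)
}
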