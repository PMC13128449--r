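#' Read and validate a plot-metadata table
#'
#' Reads a delimited text file describing the chronosequence design: one row
#' per plot with its land-use category and, for recovering plots, the time
#' since agricultural use was abandoned. Active plots sit at age 0 and
#' old-growth reference plots carry no age.
#'
#' The delimiter is auto-detected from the header line (tab if present,
#' otherwise comma) unless given explicitly.
#'
#' @param path Path to a TSV/CSV file with columns `plot_id`, `category`
#'   and `age_years`. `category` must be one of `active_cacao`,
#'   `active_pasture`, `secondary_cacao`, `secondary_pasture`, `old_growth`.
#' @param delim Field delimiter; `NULL` (default) auto-detects.
#' @return A tibble with columns `plot_id`, `category`, `legacy`
#'   (`cacao`, `pasture` or `none`) and `age_years` (`NA` for old growth),
#'   validated against the design invariants.
#' @export
read_plot_table <- function(path, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  tbl <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  required <- c("plot_id", "category", "age_years")
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(paste0(
      "Plot table is missing required column(s): ",
      paste(missing, collapse = ", ")
    ), class = "regrow_format_error")
  }
  tbl <- tibble::tibble(
    plot_id = tbl$plot_id,
    category = tbl$category,
    age_years = suppressWarnings(as.numeric(tbl$age_years))
  )
  validate_plot_table(tbl)
}

#' Validate a plot-metadata table
#'
#' Enforces the design invariants: categories are known, plot ids unique,
#' active plots have age 0, old-growth plots no age, and secondary plots a
#' strictly positive age. Adds the derived `legacy` column.
#'
#' @param plots A data frame with columns `plot_id`, `category`, `age_years`.
#' @return The validated tibble with a `legacy` column.
#' @export
validate_plot_table <- function(plots) {
  plots <- tibble::as_tibble(plots)
  if (nrow(plots) == 0) {
    return(tibble::tibble(
      plot_id = character(), category = character(),
      legacy = character(), age_years = numeric()
    ))
  }
  unknown <- setdiff(unique(plots$category), PLOT_CATEGORIES)
  if (length(unknown) > 0) {
    abort(paste0("Unknown plot category: ", paste(unknown, collapse = ", ")),
          class = "regrow_validation_error")
  }
  if (anyDuplicated(plots$plot_id)) {
    abort("Duplicate plot_id in plot table.", class = "regrow_validation_error")
  }
  is_active <- plots$category %in% c("active_cacao", "active_pasture")
  is_og <- plots$category == "old_growth"
  is_sec <- plots$category %in% c("secondary_cacao", "secondary_pasture")

  bad_og <- is_og & !is.na(plots$age_years)
  if (any(bad_og)) {
    abort(paste0(
      "Old-growth plot(s) must not carry an age: ",
      paste(plots$plot_id[bad_og], collapse = ", ")
    ), class = "regrow_validation_error")
  }
  bad_active <- is_active & (is.na(plots$age_years) | plots$age_years != 0)
  if (any(bad_active)) {
    abort(paste0(
      "Active plot(s) must have age_years = 0: ",
      paste(plots$plot_id[bad_active], collapse = ", ")
    ), class = "regrow_validation_error")
  }
  bad_sec <- is_sec & (is.na(plots$age_years) | plots$age_years <= 0)
  if (any(bad_sec)) {
    abort(paste0(
      "Secondary plot(s) must have a positive age_years: ",
      paste(plots$plot_id[bad_sec], collapse = ", ")
    ), class = "regrow_validation_error")
  }
  tibble::tibble(
    plot_id = plots$plot_id,
    category = plots$category,
    legacy = legacy_of_category(plots$category),
    age_years = plots$age_years
  )
}

#' Read a species-by-plot abundance matrix
#'
#' Reads a delimited file whose first column holds species ids and whose
#' remaining columns are plot ids, and aligns it against a validated plot
#' table. Counts must be finite and non-negative. Species observed nowhere
#' are kept but recorded in the `zero_species` attribute; the metric layer
#' drops them before computing diversity.
#'
#' @param path Path to the delimited file.
#' @param plots A validated plot table (see [read_plot_table()]).
#' @param taxon Name of the organism group the matrix belongs to.
#' @param strict If `TRUE` (default) a column not present in `plots` is an
#'   error naming the column; if `FALSE` it is dropped with a warning.
#' @param delim Field delimiter; `NULL` auto-detects.
#' @return A wide tibble (first column `species_id`, one column per plot)
#'   with attributes `taxon` and `zero_species`.
#' @export
read_abundance_matrix <- function(path, plots, taxon = "taxon",
                                  strict = TRUE, delim = NULL) {
  delim <- delim %||% detect_delim(path)
  tbl <- readr::read_delim(
    path, delim = delim, progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      readr::col_character(), .default = readr::col_double()
    )
  )
  names(tbl)[1] <- "species_id"
  as_abundance_table(tbl, plots, taxon = taxon, strict = strict)
}

#' Coerce a wide data frame to a validated abundance table
#'
#' @param x Data frame with first column `species_id` and one numeric column
#'   per plot.
#' @inheritParams read_abundance_matrix
#' @return See [read_abundance_matrix()].
#' @export
as_abundance_table <- function(x, plots, taxon = "taxon", strict = TRUE) {
  tbl <- tibble::as_tibble(x)
  if (names(tbl)[1] != "species_id") names(tbl)[1] <- "species_id"
  if (anyDuplicated(tbl$species_id)) {
    abort("Duplicate species ids in abundance matrix.",
          class = "regrow_validation_error")
  }
  plot_cols <- names(tbl)[-1]
  if (anyDuplicated(plot_cols)) {
    abort("Duplicate plot columns in abundance matrix.",
          class = "regrow_validation_error")
  }
  stray <- setdiff(plot_cols, plots$plot_id)
  if (length(stray) > 0) {
    if (strict) {
      abort(paste0(
        "Abundance matrix has plot column(s) absent from the plot table: ",
        paste(stray, collapse = ", ")
      ), class = "regrow_validation_error")
    }
    warn(paste0("Dropping unknown plot column(s): ",
                paste(stray, collapse = ", ")))
    tbl <- tbl[, c("species_id", setdiff(plot_cols, stray))]
    plot_cols <- setdiff(plot_cols, stray)
  }
  m <- as.matrix(tbl[, plot_cols, drop = FALSE])
  if (any(!is.finite(m))) {
    abort("Abundance matrix contains missing or non-finite counts.",
          class = "regrow_validation_error")
  }
  if (any(m < 0)) {
    abort("Abundance matrix contains negative counts.",
          class = "regrow_validation_error")
  }
  zero_species <- tbl$species_id[rowSums(m) == 0]
  if (length(zero_species) > 0) {
    inform(paste0(
      taxon, ": ", length(zero_species),
      " species with zero total abundance will be ignored in metrics."
    ))
  }
  structure(tbl, taxon = taxon, zero_species = zero_species,
            class = class(tbl))
}

# species x plot numeric matrix from a wide abundance tibble,
# zero-total species removed
abundance_matrix <- function(abundance) {
  m <- as.matrix(abundance[, -1, drop = FALSE])
  rownames(m) <- abundance$species_id
  m[rowSums(m) > 0, , drop = FALSE]
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Write a resilience summary table
#'
#' Writes one row per taxon, metric and legacy with resistance (%), return
#' rate (in units of 10^-3 per year), relative recovery after the evaluation
#' horizon (%) and recovery time (years), each accompanied by its jackknife
#' CI when present. Formatted cells mirror the conventional presentation:
#' arrested recovery renders as `">cap"` and an instantaneous recovery
#' leaves the return-rate cell empty. Raw numeric columns are written
#' alongside the formatted cells so the file round-trips losslessly apart
#' from the stated cell rounding.
#'
#' @param summaries A summary tibble as returned by [summarize_resilience()]
#'   (optionally augmented with `*_lo`/`*_hi` CI columns).
#' @param path Output file path (TSV).
#' @param cap_years Recovery-time cap used for the `">cap"` rendering.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(summaries, path, cap_years = 300) {
  summaries <- tibble::as_tibble(summaries)
  if (nrow(summaries) == 0) {
    empty <- tibble::tibble(
      taxon = character(), metric = character(), legacy = character(),
      resistance = character(), return_rate_e3 = character(),
      relative_recovery = character(), recovery_time = character()
    )
    readr::write_tsv(empty, path)
    return(invisible(path))
  }
  fmt_time <- function(t, classification) {
    dplyr::case_when(
      classification == "arrested" ~ paste0(">", cap_years),
      is.infinite(t) ~ paste0(">", cap_years),
      TRUE ~ as.character(round(t))
    )
  }
  fmt_ci <- function(cell, lo, hi, digits = 0) {
    ifelse(
      is.na(lo) | is.na(hi), cell,
      paste0(cell, " (", round(lo, digits), "-",
             ifelse(is.infinite(hi), paste0(">", cap_years), round(hi, digits)),
             ")")
    )
  }
  col_or_na <- function(nm) {
    if (nm %in% names(summaries)) summaries[[nm]] else rep(NA_real_, nrow(summaries))
  }
  out <- dplyr::mutate(
    summaries,
    resistance_cell = fmt_ci(
      as.character(round(.data$resistance_pct)),
      col_or_na("resistance_pct_lo"), col_or_na("resistance_pct_hi")
    ),
    return_rate_cell = ifelse(
      .data$classification == "instant" | is.na(.data$return_rate),
      "",
      fmt_ci(as.character(round(.data$return_rate * 1e3)),
             col_or_na("return_rate_lo") * 1e3,
             col_or_na("return_rate_hi") * 1e3)
    ),
    relative_recovery_cell = fmt_ci(
      as.character(round(.data$relative_recovery_pct)),
      col_or_na("relative_recovery_pct_lo"),
      col_or_na("relative_recovery_pct_hi")
    ),
    recovery_time_cell = fmt_ci(
      fmt_time(.data$recovery_time_years, .data$classification),
      col_or_na("recovery_time_years_lo"),
      col_or_na("recovery_time_years_hi")
    )
  )
  readr::write_tsv(out, path)
  invisible(path)
}
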