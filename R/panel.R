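#' Monthly expression panels
#'
#' An `expression_panel` is a tibble of monthly relative expression values
#' keyed by `(gene_id, individual_id, year, month)`, the basic data container
#' for the whole pipeline.  Panels carry two state flags as attributes:
#' `normalized` (per-series z-scoring has been applied) and `winter_masked`
#' (dormant-season months have been set to zero and filled in so that every
#' individual covers whole calendar years).
#'
#' @param records data frame with columns `gene_id`, `individual_id`,
#'   `year`, `month` (integer 1-12) and `value` (numeric).
#' @param normalized,winter_masked logical state flags; normally left at
#'   `FALSE` and set by [normalize_panel()] / [apply_winter_mask()].
#' @param mask_months integer months treated as dormant (default November
#'   through May).
#'
#' @return A tibble of class `expression_panel`, ordered by
#'   `(gene_id, individual_id, year, month)`, with a derived `month_index`
#'   column (consecutive month number counted from January of the earliest
#'   study year).
#' @export
expression_panel <- function(records,
                             normalized = FALSE,
                             winter_masked = FALSE,
                             mask_months = c(11L, 12L, 1L, 2L, 3L, 4L, 5L)) {
  required <- c("gene_id", "individual_id", "year", "month", "value")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(records$value)) {
    stop("panel 'value' column must be numeric", call. = FALSE)
  }
  records <- tibble::tibble(gene_id = as.character(records$gene_id),
                            individual_id = as.character(records$individual_id),
                            year = as.integer(records$year),
                            month = as.integer(records$month),
                            value = as.numeric(records$value))
  bad_month <- which(is.na(records$month) | records$month < 1L | records$month > 12L)
  if (length(bad_month) > 0L) {
    stop("invalid month (must be 1-12) at record(s): ",
         paste(utils::head(bad_month, 5L), collapse = ", "), call. = FALSE)
  }
  key <- paste(records$gene_id, records$individual_id, records$year,
               records$month, sep = "\r")
  if (anyDuplicated(key) > 0L) {
    d <- records[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf(
      "duplicate timestamp for gene '%s', individual '%s' at %d-%02d",
      d$gene_id, d$individual_id, d$year, d$month), call. = FALSE)
  }
  records <- records[order(records$gene_id, records$individual_id,
                           records$year, records$month), ]
  base_year <- min(records$year)
  records$month_index <- (records$year - base_year) * 12L + records$month
  structure(records,
            class = c("expression_panel", class(tibble::tibble())),
            normalized = normalized,
            winter_masked = winter_masked,
            mask_months = as.integer(mask_months))
}

panel_flags <- function(panel) {
  list(normalized = isTRUE(attr(panel, "normalized")),
       winter_masked = isTRUE(attr(panel, "winter_masked")),
       mask_months = attr(panel, "mask_months") %||% c(11L, 12L, 1:5))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an expression panel from disk
#'
#' Long TSV layout has columns `gene_id individual_id year month value`.
#' Wide CSV layout has one row per gene and one column per
#' `<individual>:<YYYY-MM>` combination.
#'
#' @param path file path.
#' @param format `"long_tsv"` (default) or `"wide_csv"`.
#' @return An [expression_panel()].
#' @export
read_panel <- function(path, format = c("long_tsv", "wide_csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "long_tsv") {
    raw <- utils::read.delim(path, colClasses = "character",
                             check.names = FALSE, stringsAsFactors = FALSE)
    required <- c("gene_id", "individual_id", "year", "month", "value")
    missing_cols <- setdiff(required, names(raw))
    if (length(missing_cols) > 0L) {
      stop("input file is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    value <- suppressWarnings(as.numeric(raw$value))
    bad <- which(is.na(value) & !(trimws(raw$value) %in% c("NA", "")))
    if (length(bad) > 0L) {
      stop("non-numeric value at data row ", bad[1L],
           ": '", raw$value[bad[1L]], "'", call. = FALSE)
    }
    records <- tibble::tibble(
      gene_id = raw$gene_id,
      individual_id = raw$individual_id,
      year = suppressWarnings(as.integer(raw$year)),
      month = suppressWarnings(as.integer(raw$month)),
      value = value)
    if (anyNA(records$year) || anyNA(records$month)) {
      stop("non-integer year or month in input file", call. = FALSE)
    }
  } else {
    raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (names(raw)[1L] != "gene_id") {
      stop("wide CSV must have 'gene_id' as its first column", call. = FALSE)
    }
    cols <- names(raw)[-1L]
    parts <- regmatches(cols, regexec("^(.+):([0-9]{4})-([0-9]{2})$", cols))
    bad <- which(lengths(parts) != 4L)
    if (length(bad) > 0L) {
      stop("malformed wide column header (expect '<individual>:<YYYY-MM>'): ",
           cols[bad[1L]], call. = FALSE)
    }
    meta <- do.call(rbind, parts)
    long <- tidyr::pivot_longer(raw, -"gene_id",
                                names_to = "column", values_to = "value")
    idx <- match(long$column, cols)
    records <- tibble::tibble(
      gene_id = long$gene_id,
      individual_id = meta[idx, 2L],
      year = as.integer(meta[idx, 3L]),
      month = as.integer(meta[idx, 4L]),
      value = as.numeric(long$value))
  }
  expression_panel(records)
}

#' Write an expression panel as long TSV
#'
#' @param panel an [expression_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  out <- panel[c("gene_id", "individual_id", "year", "month", "value")]
  readr::write_tsv(tibble::as_tibble(out), path)
  invisible(path)
}

#' Z-score every (gene, individual) series
#'
#' Each series is centred and scaled using its own mean and sample standard
#' deviation (denominator n - 1), computed from the observations present in
#' the panel.  Called before [apply_winter_mask()] this normalizes on
#' growing-season values only, which is the default analysis order.
#'
#' @param panel an [expression_panel()].
#' @return The normalized panel (flag `normalized` set).
#' @export
normalize_panel <- function(panel) {
  flags <- panel_flags(panel)
  df <- tibble::as_tibble(panel)
  grp <- paste(df$gene_id, df$individual_id, sep = "\r")
  split_idx <- split(seq_len(nrow(df)), grp)
  for (idx in split_idx) {
    v <- df$value[idx]
    if (length(v) < 2L) {
      stop(sprintf("series too short to normalize (gene '%s', individual '%s')",
                   df$gene_id[idx[1L]], df$individual_id[idx[1L]]), call. = FALSE)
    }
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) {
      stop(sprintf("constant series cannot be normalized (gene '%s', individual '%s')",
                   df$gene_id[idx[1L]], df$individual_id[idx[1L]]), call. = FALSE)
    }
    df$value[idx] <- (v - mean(v)) / s
  }
  expression_panel(df, normalized = TRUE,
                   winter_masked = flags$winter_masked,
                   mask_months = flags$mask_months)
}

#' Zero out dormant-season months and complete the monthly grid
#'
#' Expression during leafless months (November-May by default) is set to
#' exactly zero; missing dormant months are created as zero records so each
#' individual contributes 12 consecutive points per calendar year of the
#' study window (2 years of observations become a 24-point series).  Missing
#' growing-season observations are an error, not imputed.
#'
#' @param panel an [expression_panel()].
#' @param mask_months integer months to zero; defaults to the panel's own
#'   mask attribute (November-May).
#' @return The masked panel (flag `winter_masked` set).
#' @export
apply_winter_mask <- function(panel, mask_months = NULL) {
  flags <- panel_flags(panel)
  if (flags$winter_masked) {
    stop("winter mask already applied to this panel", call. = FALSE)
  }
  mask_months <- as.integer(mask_months %||% flags$mask_months)
  df <- tibble::as_tibble(panel)
  years <- min(df$year):max(df$year)
  grid <- tidyr::expand_grid(
    gene_id = unique(df$gene_id),
    individual_id = unique(df$individual_id),
    year = years,
    month = 1:12)
  grid <- dplyr::left_join(grid, df[c("gene_id", "individual_id", "year",
                                      "month", "value")],
                           by = c("gene_id", "individual_id", "year", "month"))
  growing <- setdiff(1:12, mask_months)
  miss <- grid$month %in% growing & is.na(grid$value)
  if (any(miss)) {
    m <- grid[miss, ][1L, ]
    stop(sprintf(
      "missing growing-season observation: gene '%s', individual '%s', %d-%02d",
      m$gene_id, m$individual_id, m$year, m$month), call. = FALSE)
  }
  grid$value[grid$month %in% mask_months] <- 0
  expression_panel(grid, normalized = flags$normalized,
                   winter_masked = TRUE, mask_months = mask_months)
}

#' Extract one gene's pooled series across individuals
#'
#' Returns the gene's values in a fixed canonical order (individuals sorted,
#' then time), together with segment ids and calendar months, the layout the
#' embedding and cross-mapping functions operate on.  All individuals must
#' cover the same set of time points.
#'
#' @param panel an [expression_panel()].
#' @param gene gene id.
#' @return list with `values`, `segment` (integer individual index),
#'   `individuals`, `month` (calendar month) and `month_index`.
#' @export
panel_series <- function(panel, gene) {
  df <- tibble::as_tibble(panel)
  df <- df[df$gene_id == gene, ]
  if (nrow(df) == 0L) stop("gene not present in panel: ", gene, call. = FALSE)
  inds <- sort(unique(df$individual_id))
  cover <- lapply(inds, function(i) sort(df$month_index[df$individual_id == i]))
  ref <- cover[[1L]]
  same <- vapply(cover, function(x) identical(x, ref), logical(1L))
  if (!all(same)) {
    stop("individuals differ in time coverage for gene '", gene, "': ",
         paste(inds[!same], collapse = ", "), call. = FALSE)
  }
  if (any(diff(ref) != 1L)) {
    stop("series for gene '", gene,
         "' is not a contiguous monthly sequence; apply_winter_mask() first",
         call. = FALSE)
  }
  df <- df[order(match(df$individual_id, inds), df$month_index), ]
  list(values = df$value,
       segment = rep(seq_along(inds), each = length(ref)),
       individuals = inds,
       month = df$month,
       month_index = df$month_index)
}
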