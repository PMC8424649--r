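#' Construct a peak table
#'
#' A peak table is the unit of fragment-analysis data handled by the package:
#' the sized, height-annotated electropherogram peaks observed for one sample
#' at one locus, as exported from genotyping software (GeneMapper-style
#' "Genotypes table" export).
#'
#' @param sample_id Sample identifier (non-empty string).
#' @param locus Locus label, e.g. `"HTT"` or `"BAT-25"` (non-empty string).
#' @param peaks A data.frame with numeric columns `size_bp` (> 0) and
#'   `height` (>= 0), and optionally `area` (>= 0). Rows are sorted by
#'   `size_bp` on construction.
#' @param day Optional time-course day (non-negative number) or `NA`.
#'
#' @return An object of class `peak_table`: a list with elements
#'   `sample_id`, `locus`, `day` and `peaks` (sorted data.frame).
#' @export
peak_table <- function(sample_id, locus, peaks, day = NA_real_) {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id))
    stop("`sample_id` must be a non-empty string", call. = FALSE)
  if (!is.character(locus) || length(locus) != 1L || !nzchar(locus))
    stop("`locus` must be a non-empty string", call. = FALSE)
  if (!is.data.frame(peaks) || !all(c("size_bp", "height") %in% names(peaks)))
    stop("`peaks` must be a data.frame with columns size_bp and height",
         call. = FALSE)
  peaks <- as.data.frame(peaks)[, intersect(c("size_bp", "height", "area"),
                                            names(peaks)), drop = FALSE]
  if (nrow(peaks) > 0) {
    if (!is.numeric(peaks$size_bp) || any(!is.finite(peaks$size_bp)) ||
        any(peaks$size_bp <= 0))
      stop("peak sizes must be finite and > 0", call. = FALSE)
    if (!is.numeric(peaks$height) || any(!is.finite(peaks$height)) ||
        any(peaks$height < 0))
      stop("peak heights must be finite and >= 0", call. = FALSE)
    peaks <- peaks[order(peaks$size_bp), , drop = FALSE]
    rownames(peaks) <- NULL
  }
  structure(list(sample_id = sample_id, locus = locus,
                 day = as.numeric(day)[1L], peaks = peaks),
            class = "peak_table")
}

#' @export
print.peak_table <- function(x, ...) {
  cat(sprintf("<peak_table> sample=%s locus=%s%s, %d peaks\n",
              x$sample_id, x$locus,
              if (is.finite(x$day)) sprintf(" day=%g", x$day) else "",
              nrow(x$peaks)))
  if (nrow(x$peaks)) print(utils::head(x$peaks, 10))
  invisible(x)
}

#' Column mapping for peak-table files
#'
#' The native dialect is tab-delimited with one row per peak. Real exports
#' with different header names can be adapted by overriding the mapping.
#'
#' @param sample,locus,size,height,area,day Header names in the file for the
#'   corresponding fields; `area` and `day` are optional columns.
#' @return A named list used by [read_peak_table()] / [write_peak_table()].
#' @export
fragio_dialect <- function(sample = "sample", locus = "locus",
                           size = "size_bp", height = "height",
                           area = "area", day = "day") {
  list(sample = sample, locus = locus, size = size, height = height,
       area = area, day = day)
}

#' Read peak tables from a tab-delimited export
#'
#' Parses a GeneMapper-style tab-delimited peak export into one [peak_table()]
#' per (sample, locus) pair. Rows with non-numeric size or height are reported
#' with their line numbers and dropped (or are fatal in strict mode); peaks
#' are returned sorted by size regardless of file order.
#'
#' @param path Path to a tab-delimited file with a header line.
#' @param dialect Column mapping, see [fragio_dialect()].
#' @param strict If `TRUE`, malformed rows are an error instead of a warning.
#' @return A list of `peak_table` objects, ordered by (sample, locus) first
#'   appearance.
#' @export
read_peak_table <- function(path, dialect = fragio_dialect(), strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE)
  mandatory <- c(dialect$sample, dialect$locus, dialect$size, dialect$height)
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(raw) == 0L) {
    warning("no data rows in ", path, call. = FALSE)
    return(list())
  }
  size <- suppressWarnings(as.numeric(raw[[dialect$size]]))
  height <- suppressWarnings(as.numeric(raw[[dialect$height]]))
  bad <- which(is.na(size) | is.na(height) | size <= 0 | height < 0)
  if (length(bad)) {
    msg <- sprintf("%d malformed row(s) at line(s) %s of %s",
                   length(bad),
                   paste(bad + 1L, collapse = ", "), # +1 for header line
                   path)
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  raw <- raw[keep, , drop = FALSE]
  size <- size[keep]; height <- height[keep]
  area <- if (dialect$area %in% names(raw))
    suppressWarnings(as.numeric(raw[[dialect$area]])) else NULL
  day <- if (dialect$day %in% names(raw))
    suppressWarnings(as.numeric(raw[[dialect$day]])) else rep(NA_real_, nrow(raw))

  key <- paste(raw[[dialect$sample]], raw[[dialect$locus]], sep = "\r")
  out <- lapply(unique(key), function(k) {
    idx <- which(key == k)
    pk <- data.frame(size_bp = size[idx], height = height[idx])
    if (!is.null(area)) pk$area <- area[idx]
    peak_table(sample_id = raw[[dialect$sample]][idx[1L]],
               locus = raw[[dialect$locus]][idx[1L]],
               peaks = pk,
               day = day[idx[1L]])
  })
  out
}

#' Write peak tables to a tab-delimited file
#'
#' Inverse of [read_peak_table()]: `read_peak_table(write_peak_table(x))`
#' reproduces `x` up to float formatting (>= 6 significant digits are
#' preserved). The `area` column is only written when at least one table
#' carries areas; the `day` column only when at least one day is set.
#'
#' @param tables A `peak_table` or list of them.
#' @param path Output path.
#' @param dialect Column mapping, see [fragio_dialect()].
#' @return `path`, invisibly.
#' @export
write_peak_table <- function(tables, path, dialect = fragio_dialect()) {
  if (inherits(tables, "peak_table")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, logical(1), "peak_table")))
  rows <- lapply(tables, function(tb) {
    n <- nrow(tb$peaks)
    if (n == 0L) return(NULL)
    df <- data.frame(sample = rep(tb$sample_id, n),
                     locus = rep(tb$locus, n),
                     day = rep(tb$day, n),
                     size_bp = tb$peaks$size_bp,
                     height = tb$peaks$height,
                     area = if ("area" %in% names(tb$peaks)) tb$peaks$area
                            else rep(NA_real_, n),
                     stringsAsFactors = FALSE)
    df
  })
  df <- do.call(rbind, rows)
  has_area <- !is.null(df) && any(!is.na(df$area))
  has_day <- !is.null(df) && any(!is.na(df$day))
  cols <- c(dialect$sample, dialect$locus,
            if (has_day) dialect$day,
            dialect$size, dialect$height,
            if (has_area) dialect$area)
  if (is.null(df)) {
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  out <- data.frame(df$sample, df$locus, stringsAsFactors = FALSE)
  names(out) <- c(dialect$sample, dialect$locus)
  if (has_day) out[[dialect$day]] <- fmt_num(df$day)
  out[[dialect$size]] <- fmt_num(df$size_bp)
  out[[dialect$height]] <- fmt_num(df$height)
  if (has_area) out[[dialect$area]] <- fmt_num(df$area)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

# fixed 10-significant-digit formatting so writes are byte-stable across
# platforms and round-trips are lossless at the precision the sizer reports
fmt_num <- function(x) {
  out <- formatC(x, digits = 10, format = "g")
  out[is.na(x)] <- NA_character_
  trimws(out)
}

#' Read / write a sample manifest
#'
#' The manifest maps samples to their experimental coordinates: columns
#' `sample_id`, `genotype`, `replicate`, `day` (and optionally `file`,
#' `seed`). Stored as CSV.
#'
#' @param path CSV path.
#' @return `read_manifest()`: a data.frame; `write_manifest()`: `path`,
#'   invisibly.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- data.table::fread(path, data.table = FALSE)
  need <- c("sample_id", "genotype", "replicate", "day")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_manifest
#' @param manifest A data.frame with at least `sample_id`, `genotype`,
#'   `replicate`, `day`.
#' @export
write_manifest <- function(manifest, path) {
  data.table::fwrite(as.data.frame(manifest), path, quote = FALSE)
  invisible(path)
}
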