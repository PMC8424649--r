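#' Size-to-repeat calibration
#'
#' Fragment sizes in bp are converted to repeat units against a calibrator
#' allele of known repeat count (for the HTT assay, the endogenous 20-CAG
#' allele). Calibration is required because the non-repeat flank length of
#' the amplicon is assay-specific and capillary sizing carries a small
#' systematic offset.
#'
#' @param reference_repeat Known repeat count of the calibrator allele
#'   (integer >= 1).
#' @param reference_size_bp Its observed fragment size in bp (> 0).
#' @param repeat_unit_bp Repeat unit length in bp; 3 for CAG.
#' @return An object of class `calibration`.
#' @export
calibration <- function(reference_repeat, reference_size_bp,
                        repeat_unit_bp = 3) {
  if (!is.numeric(reference_repeat) || reference_repeat < 1 ||
      reference_repeat != round(reference_repeat))
    stop("`reference_repeat` must be a positive integer", call. = FALSE)
  if (!is.numeric(reference_size_bp) || reference_size_bp <= 0)
    stop("`reference_size_bp` must be > 0", call. = FALSE)
  if (!is.numeric(repeat_unit_bp) || repeat_unit_bp < 1)
    stop("`repeat_unit_bp` must be >= 1", call. = FALSE)
  structure(list(reference_repeat = as.integer(reference_repeat),
                 reference_size_bp = as.numeric(reference_size_bp),
                 repeat_unit_bp = as.numeric(repeat_unit_bp)),
            class = "calibration")
}

#' Convert fragment sizes to repeat counts
#'
#' `repeats = reference_repeat + round((size_bp - reference_size_bp) /
#' repeat_unit_bp)`, with half-unit offsets rounded half-up so the mapping is
#' deterministic. Vectorised over `size_bp`.
#'
#' @param size_bp Fragment size(s) in bp.
#' @param cal A [calibration()].
#' @return Integer repeat count(s), each >= 1.
#' @export
size_to_repeats <- function(size_bp, cal) {
  stopifnot(inherits(cal, "calibration"))
  delta <- (size_bp - cal$reference_size_bp) / cal$repeat_unit_bp
  r <- cal$reference_repeat + as.integer(floor(delta + 0.5))
  if (any(r < 1L))
    stop("calibration maps size(s) ",
         paste(signif(size_bp[r < 1L], 6), collapse = ", "),
         " to repeat count < 1", call. = FALSE)
  r
}

#' Split a biallelic peak table into per-allele windows
#'
#' Peaks are partitioned at the arithmetic midpoint (in repeat units) between
#' the expected allele positions; a peak exactly at the midpoint goes to the
#' shorter allele. With a single expected allele this is the identity
#' partition. Expected alleles closer than twice the stutter-ladder depth are
#' refused as unresolvable.
#'
#' @param table A [peak_table()].
#' @param expected_alleles Numeric vector of 1 or 2 expected allele positions
#'   in repeat units (e.g. `c(20, 118)` for the U2OS HTT assay).
#' @param cal A [calibration()].
#' @param stutter_depth Assumed maximal stutter ladder depth (repeat units)
#'   used for the ambiguity guard.
#' @return A named list of `peak_table` objects, one per expected allele
#'   (names `"allele_<repeat>"`), whose peak sets are disjoint and union to
#'   the input.
#' @export
split_alleles <- function(table, expected_alleles, cal, stutter_depth = 3) {
  stopifnot(inherits(table, "peak_table"), inherits(cal, "calibration"))
  expected_alleles <- sort(as.numeric(expected_alleles))
  if (!length(expected_alleles) %in% c(1L, 2L))
    stop("1 or 2 expected allele positions required", call. = FALSE)
  if (length(expected_alleles) == 2L &&
      diff(expected_alleles) < 2 * stutter_depth)
    stop("expected alleles ", expected_alleles[1L], " and ",
         expected_alleles[2L], " are closer than 2 x stutter depth (",
         2 * stutter_depth, " units); windows would overlap", call. = FALSE)
  mk <- function(idx) peak_table(table$sample_id, table$locus,
                                 table$peaks[idx, , drop = FALSE], table$day)
  if (length(expected_alleles) == 1L) {
    out <- list(mk(seq_len(nrow(table$peaks))))
  } else {
    mid <- mean(expected_alleles)
    rep_real <- cal$reference_repeat +
      (table$peaks$size_bp - cal$reference_size_bp) / cal$repeat_unit_bp
    lower <- rep_real <= mid
    out <- list(mk(which(lower)), mk(which(!lower)))
  }
  names(out) <- paste0("allele_", expected_alleles)
  out
}

# aggregate peak heights per integer repeat unit (two jittered peaks that
# size into the same unit are summed)
bin_repeats <- function(table, cal) {
  if (nrow(table$peaks) == 0L)
    return(data.frame(repeat_len = integer(), height = numeric()))
  r <- size_to_repeats(table$peaks$size_bp, cal)
  h <- tapply(table$peaks$height, r, sum)
  data.frame(repeat_len = as.integer(names(h)), height = as.numeric(h),
             row.names = NULL)
}

#' Call the modal allele of a peak-table window
#'
#' The modal repeat is the repeat unit with maximal summed peak height. A
#' height tie breaks to the smaller repeat and raises a warning so the table
#' can be reviewed manually.
#'
#' @param table A `peak_table` restricted to one allele window (see
#'   [split_alleles()]).
#' @param cal A [calibration()].
#' @return A list with `modal_repeat` (integer) and `modal_height` (numeric).
#' @export
call_modal <- function(table, cal) {
  binned <- bin_repeats(table, cal)
  if (nrow(binned) == 0L)
    stop("cannot call modal allele of an empty window", call. = FALSE)
  top <- which(binned$height == max(binned$height))
  if (length(top) > 1L)
    warning("modal height tie at repeats ",
            paste(binned$repeat_len[top], collapse = ", "),
            "; taking the smallest -- review this table", call. = FALSE)
  i <- top[1L] # binned is sorted by repeat_len, so [1] is the smallest
  list(modal_repeat = binned$repeat_len[i], modal_height = binned$height[i])
}

#' Apply the inclusion threshold to an allele window
#'
#' Keeps peaks whose height is at least `fraction` of the modal peak height
#' (inclusive at the boundary), the mechanism used to suppress PCR stutter
#' before index computation. Default fraction is 0.20.
#'
#' @param table A `peak_table` restricted to one allele window.
#' @param cal A [calibration()].
#' @param modal_height Modal peak height of the window (see [call_modal()]).
#' @param fraction Inclusion threshold as a fraction of modal height,
#'   in (0, 1].
#' @return A data.frame with columns `repeat_len`, `height` of the included
#'   peaks, in repeat order.
#' @export
threshold_peaks <- function(table, cal, modal_height, fraction = 0.20) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction > 0, fraction <= 1)
  if (!is.numeric(modal_height) || modal_height <= 0)
    stop("`modal_height` must be > 0", call. = FALSE)
  binned <- bin_repeats(table, cal)
  binned[binned$height >= fraction * modal_height, , drop = FALSE]
}

#' Full allele call for one window
#'
#' Convenience wrapper running [call_modal()] then [threshold_peaks()] and
#' bundling the result.
#'
#' @inheritParams threshold_peaks
#' @param window Optional `[min_repeat, max_repeat]` annotation of the
#'   analysed window; defaults to the observed repeat range.
#' @return An object of class `allele_call` with fields `allele_window`,
#'   `modal_repeat`, `modal_height`, `included_peaks` (data.frame
#'   `repeat_len`, `height`) and `threshold_fraction`.
#' @export
allele_call <- function(table, cal, fraction = 0.20, window = NULL) {
  modal <- call_modal(table, cal)
  inc <- threshold_peaks(table, cal, modal$modal_height, fraction)
  if (is.null(window)) {
    binned <- bin_repeats(table, cal)
    window <- range(binned$repeat_len)
  }
  new_allele_call(window, modal$modal_repeat, modal$modal_height, inc,
                  fraction)
}

# internal constructor; also the entry point for tests that build calls
# directly from (repeat, height) pairs
new_allele_call <- function(window, modal_repeat, modal_height,
                            included_peaks, threshold_fraction) {
  stopifnot(modal_repeat >= window[1L], modal_repeat <= window[2L])
  stopifnot(all(included_peaks$height >=
                  threshold_fraction * modal_height - 1e-9))
  if (!modal_repeat %in% included_peaks$repeat_len)
    stop("modal peak must be in the included set", call. = FALSE)
  structure(list(allele_window = as.integer(window),
                 modal_repeat = as.integer(modal_repeat),
                 modal_height = as.numeric(modal_height),
                 included_peaks = included_peaks,
                 threshold_fraction = threshold_fraction),
            class = "allele_call")
}

#' @export
print.allele_call <- function(x, ...) {
  cat(sprintf(
    "<allele_call> window [%d, %d], modal %d (height %g), %d peak(s) >= %g%%\n",
    x$allele_window[1L], x$allele_window[2L], x$modal_repeat, x$modal_height,
    nrow(x$included_peaks), 100 * x$threshold_fraction))
  invisible(x)
}
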