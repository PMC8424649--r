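#' Instability index of an allele call
#'
#' The signed, height-weighted mean change from the modal allele over the
#' threshold-included peaks:
#' \deqn{I = \sum_i \frac{h_i}{\sum_j h_j} (r_i - r_{modal})}
#' Contractions contribute negatively. A call whose included set is only the
#' modal peak scores 0.
#'
#' @param call An [allele_call()].
#' @return Signed instability index in repeat units.
#' @export
instability_index <- function(call) {
  stopifnot(inherits(call, "allele_call"))
  pk <- call$included_peaks
  if (nrow(pk) == 0L) stop("included peak set is empty", call. = FALSE)
  sum(pk$height * (pk$repeat_len - call$modal_repeat)) / sum(pk$height)
}

#' Expansion index of an allele call
#'
#' The expansion-direction component of the instability index: the weighted
#' sum runs only over included peaks longer than the modal allele. By default
#' the normaliser is the total height of *all* included peaks (one consistent
#' normaliser with [instability_index()]); set
#' `normalizer = "expansion"` to normalise by expansion-side height only.
#'
#' @param call An [allele_call()].
#' @param normalizer `"all"` (default) or `"expansion"`.
#' @return Non-negative expansion index in repeat units.
#' @export
expansion_index <- function(call, normalizer = c("all", "expansion")) {
  stopifnot(inherits(call, "allele_call"))
  normalizer <- match.arg(normalizer)
  pk <- call$included_peaks
  if (nrow(pk) == 0L) stop("included peak set is empty", call. = FALSE)
  up <- pk$repeat_len > call$modal_repeat
  num <- sum(pk$height[up] * (pk$repeat_len[up] - call$modal_repeat))
  den <- if (normalizer == "all") sum(pk$height) else sum(pk$height[up])
  if (den == 0) return(0)
  num / den
}

#' Modal change from a baseline call
#'
#' @param call,baseline_call [allele_call()] objects for the same allele
#'   window at two time points.
#' @return Integer repeat-unit change `modal(call) - modal(baseline)`.
#' @export
modal_change <- function(call, baseline_call) {
  stopifnot(inherits(call, "allele_call"),
            inherits(baseline_call, "allele_call"))
  if (!identical(call$allele_window, baseline_call$allele_window))
    stop("calls are from different allele windows ([",
         paste(call$allele_window, collapse = ", "), "] vs [",
         paste(baseline_call$allele_window, collapse = ", "), "])",
         call. = FALSE)
  call$modal_repeat - baseline_call$modal_repeat
}

#' Assemble per-replicate time courses
#'
#' Joins an indices table to a sample manifest and produces one time course
#' per (genotype, replicate) for the chosen metric. Replicates with fewer
#' than two distinct days are dropped with a warning.
#'
#' @param indices A data.frame with a `sample_id` column and the metric
#'   column; typically the output of [index_samples()] or the CLI `index`
#'   step. If it already carries `genotype`, `replicate` and `day`, the
#'   manifest may be `NULL`.
#' @param manifest A manifest data.frame (see [read_manifest()]) or `NULL`.
#' @param metric Name of the metric column: one of `"modal_repeat"`,
#'   `"instability_index"`, `"expansion_index"` (or any numeric column
#'   present).
#' @return A list of `time_course` objects: each a list with `genotype`,
#'   `replicate`, `metric` and `points` (data.frame `day`, `value`, sorted by
#'   day).
#' @export
build_time_courses <- function(indices, manifest = NULL,
                               metric = "modal_repeat") {
  indices <- as.data.frame(indices)
  if (!is.null(manifest)) {
    manifest <- as.data.frame(manifest)
    keep <- setdiff(names(manifest), setdiff(names(indices), "sample_id"))
    indices <- merge(indices, manifest[, keep, drop = FALSE],
                     by = "sample_id", sort = FALSE)
  }
  need <- c("genotype", "replicate", "day", metric)
  missing_cols <- setdiff(need, names(indices))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  key <- interaction(indices$genotype, indices$replicate, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    sub <- indices[key == k, , drop = FALSE]
    sub <- sub[order(sub$day), , drop = FALSE]
    if (length(unique(sub$day)) < 2L) {
      warning("replicate ", sub$genotype[1L], "/", sub$replicate[1L],
              " has < 2 distinct days; dropped", call. = FALSE)
      next
    }
    out[[length(out) + 1L]] <- time_course(
      genotype = as.character(sub$genotype[1L]),
      replicate = sub$replicate[1L],
      metric = metric,
      points = data.frame(day = sub$day, value = sub[[metric]]))
  }
  out
}

#' @rdname build_time_courses
#' @param genotype,replicate,points See return value description.
#' @export
time_course <- function(genotype, replicate, metric, points) {
  stopifnot(is.data.frame(points), all(c("day", "value") %in% names(points)))
  points <- points[order(points$day), c("day", "value"), drop = FALSE]
  if (anyDuplicated(points$day))
    stop("time course days must be distinct", call. = FALSE)
  if (nrow(points) < 2L)
    stop("a time course needs >= 2 distinct days", call. = FALSE)
  rownames(points) <- NULL
  structure(list(genotype = genotype, replicate = replicate,
                 metric = metric, points = points),
            class = "time_course")
}

#' Index every allele window of a set of peak tables
#'
#' Pipeline helper: for each peak table, split the expected alleles, call
#' each window and compute indices. Baseline modal repeats (for
#' `modal_change`) are taken per (genotype, replicate, allele) at the
#' earliest day when a manifest is supplied.
#'
#' @param tables List of [peak_table()] objects.
#' @param expected_alleles Expected allele positions in repeat units.
#' @param cal A [calibration()].
#' @param fraction Inclusion threshold fraction (default 0.20).
#' @param manifest Optional manifest data.frame with `sample_id`, `genotype`,
#'   `replicate`, `day`.
#' @return A data.frame with one row per (sample, allele window): columns
#'   `sample_id`, `locus`, `allele`, `day`, `modal_repeat`, `modal_height`,
#'   `n_included`, `instability_index`, `expansion_index` and, when a
#'   manifest is given, `genotype`, `replicate`, `modal_change`.
#' @export
index_samples <- function(tables, expected_alleles, cal, fraction = 0.20,
                          manifest = NULL) {
  rows <- lapply(tables, function(tb) {
    wins <- split_alleles(tb, expected_alleles, cal)
    do.call(rbind, lapply(names(wins), function(w) {
      sub <- wins[[w]]
      if (nrow(sub$peaks) == 0L) return(NULL)
      ac <- allele_call(sub, cal, fraction)
      data.frame(sample_id = tb$sample_id, locus = tb$locus, allele = w,
                 day = tb$day, modal_repeat = ac$modal_repeat,
                 modal_height = ac$modal_height,
                 n_included = nrow(ac$included_peaks),
                 instability_index = instability_index(ac),
                 expansion_index = expansion_index(ac),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(manifest)) {
    manifest <- as.data.frame(manifest)
    keep <- c("sample_id", setdiff(c("genotype", "replicate", "day"),
                                   names(out)))
    out <- merge(out, manifest[, keep, drop = FALSE], by = "sample_id",
                 sort = FALSE)
    key <- interaction(out$genotype, out$replicate, out$allele, drop = TRUE)
    out$modal_change <- NA_integer_
    for (k in levels(key)) {
      idx <- which(key == k)
      base <- idx[which.min(out$day[idx])]
      out$modal_change[idx] <- out$modal_repeat[idx] - out$modal_repeat[base]
    }
  }
  out
}
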