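#' The default microsatellite-instability marker panel
#'
#' Eighteen loci: six mononucleotide, five dinucleotide and five
#' tetranucleotide markers plus the two stable pentanucleotide control loci
#' (Penta C, Penta D). Instability at tetranucleotide markers corresponds to
#' the EMAST phenotype (elevated microsatellite alterations at selected
#' tetranucleotide repeats).
#'
#' @return A data.frame with columns `name`, `unit_bp`, `role`
#'   (`"marker"`/`"control"`).
#' @export
msi_panel <- function() {
  data.frame(
    name = c("NR-21", "NR-24", "BAT-25", "BAT-26", "MONO-27", "NR-27",
             "D2S123", "D5S346", "D17S250", "D18S64", "D18S69",
             "D8S321", "D20S82", "D9S242", "MYCL1", "D20S85",
             "Penta C", "Penta D"),
    unit_bp = c(rep(1L, 6L), rep(2L, 5L), rep(4L, 5L), rep(5L, 2L)),
    role = c(rep("marker", 16L), rep("control", 2L)),
    stringsAsFactors = FALSE)
}

#' Read / write a panel configuration
#'
#' Panels are stored as YAML: a list of loci each with `unit_bp` and `role`.
#'
#' @param path YAML path.
#' @return `read_panel()`: a panel data.frame as from [msi_panel()];
#'   `write_panel()`: `path`, invisibly.
#' @export
read_panel <- function(path) {
  cfg <- yaml::read_yaml(path)
  df <- do.call(rbind, lapply(cfg$loci, function(l)
    data.frame(name = l$name, unit_bp = as.integer(l$unit_bp),
               role = l$role, stringsAsFactors = FALSE)))
  validate_panel(df)
  df
}

#' @rdname read_panel
#' @param panel A panel data.frame.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  yaml::write_yaml(list(loci = lapply(seq_len(nrow(panel)), function(i)
    list(name = panel$name[i], unit_bp = panel$unit_bp[i],
         role = panel$role[i]))), path)
  invisible(path)
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel),
            all(c("name", "unit_bp", "role") %in% names(panel)))
  if (!all(panel$unit_bp %in% c(1L, 2L, 4L, 5L)))
    stop("unknown repeat unit size(s): ",
         paste(unique(setdiff(panel$unit_bp, c(1, 2, 4, 5))), collapse = ", "),
         " (panel units must be 1, 2, 4 or 5 nt)", call. = FALSE)
  if (!all(panel$role %in% c("marker", "control")))
    stop("locus role must be 'marker' or 'control'", call. = FALSE)
  invisible(panel)
}

#' Call up to two alleles at a microsatellite locus
#'
#' The same inclusion-threshold machinery used for repeat indexing, applied
#' in bp space: peaks below the noise floor are ignored, peaks below the
#' threshold fraction of the tallest peak are discarded as PCR stutter
#' (stutter echoes run at ~10-15% of their parent and fall under the default
#' 20% cutoff), and the surviving peaks are read as alleles -- greedily, by
#' descending height, requiring each new allele to sit at least one repeat
#' unit (minus the sizing tolerance) away from those already accepted, up to
#' `max_alleles`.
#'
#' @param table A [peak_table()] for one sample at this locus.
#' @param locus One row of a panel data.frame ([msi_panel()]) or a list with
#'   `name` and `unit_bp`.
#' @param threshold_fraction Stutter-suppression threshold as a fraction of
#'   the tallest peak (default 0.20).
#' @param noise_floor Absolute minimal peak height (fluorescence units).
#' @param max_alleles Maximal number of alleles reported (default 2).
#' @param tolerance_bp Sizing tolerance in bp used for the minimal allele
#'   spacing (default 0.5).
#' @return A list with `locus`, `status` (`"ok"` or `"failed"`) and
#'   `alleles` (numeric vector of up to `max_alleles` sizes in bp,
#'   ascending).
#' @export
call_locus_alleles <- function(table, locus, threshold_fraction = 0.20,
                               noise_floor = 50, max_alleles = 2,
                               tolerance_bp = 0.5) {
  stopifnot(inherits(table, "peak_table"))
  unit <- as.numeric(locus$unit_bp)
  pk <- table$peaks[table$peaks$height >= noise_floor, , drop = FALSE]
  if (nrow(pk) == 0L)
    return(list(locus = locus$name, status = "failed", alleles = numeric()))
  pk <- pk[pk$height >= threshold_fraction * max(pk$height), , drop = FALSE]
  pk <- pk[order(pk$height, decreasing = TRUE), , drop = FALSE]
  alleles <- numeric()
  for (i in seq_len(nrow(pk))) {
    if (length(alleles) >= max_alleles) break
    if (all(abs(pk$size_bp[i] - alleles) >= unit - tolerance_bp))
      alleles <- c(alleles, pk$size_bp[i])
  }
  list(locus = locus$name, status = "ok", alleles = sort(alleles))
}

#' Classify one locus as stable or unstable against a matched baseline
#'
#' A locus is unstable when any follow-up allele differs from *every*
#' baseline allele by at least one repeat unit (allowing a sizing tolerance:
#' `|delta| >= unit_bp - tolerance_bp`). The shift is reported in rounded
#' repeat units relative to the nearest baseline allele.
#'
#' @param sample_alleles,baseline_alleles Numeric allele sizes (bp) from
#'   [call_locus_alleles()].
#' @param locus One panel row (needs `name`, `unit_bp`; `role` optional).
#' @param tolerance_bp Sizing tolerance in bp (default 0.5, half the
#'   smallest panel unit).
#' @return An object of class `msi_call`: list with `locus`, `unit_bp`,
#'   `role`, `status` (`"stable"`, `"unstable"` or `"failed"`),
#'   `shifted_units` (0 when stable) and `evidence` (baseline/sample allele
#'   sizes).
#' @export
classify_msi <- function(sample_alleles, baseline_alleles, locus,
                         tolerance_bp = 0.5) {
  unit <- as.numeric(locus$unit_bp)
  role <- if (!is.null(locus$role)) locus$role else "marker"
  mk <- function(status, shift) structure(
    list(locus = locus$name, unit_bp = unit, role = role, status = status,
         shifted_units = as.integer(shift),
         evidence = list(baseline = baseline_alleles,
                         sample = sample_alleles)),
    class = "msi_call")
  if (length(sample_alleles) == 0L || length(baseline_alleles) == 0L)
    return(mk("failed", 0L))
  deltas <- vapply(sample_alleles, function(a) {
    d <- a - baseline_alleles
    d[which.min(abs(d))] # signed distance to the nearest baseline allele
  }, numeric(1))
  novel <- abs(deltas) >= unit - tolerance_bp
  if (!any(novel)) return(mk("stable", 0L))
  d <- deltas[novel][which.max(abs(deltas[novel]))]
  shift <- max(1, round(abs(d) / unit)) * sign(d)
  mk("unstable", shift)
}

#' Summarise MSI calls across the panel for one sample
#'
#' @param calls A list of `msi_call` objects (one per locus).
#' @return A list with `n_informative`, `n_failed`, `unstable_by_unit`
#'   (named integer vector over unit sizes 1/2/4/5, marker loci only),
#'   `unstable_loci` (character), `emast` (TRUE iff >= 1 tetranucleotide
#'   marker is unstable) and `qc_fail` (TRUE iff any control locus is
#'   unstable).
#' @export
panel_summary <- function(calls) {
  stopifnot(length(calls) > 0,
            all(vapply(calls, inherits, logical(1), "msi_call")))
  status <- vapply(calls, `[[`, character(1), "status")
  if (all(status == "failed"))
    stop("all loci failed; no informative call", call. = FALSE)
  ok <- status != "failed"
  unit <- vapply(calls, `[[`, numeric(1), "unit_bp")
  role <- vapply(calls, `[[`, character(1), "role")
  name <- vapply(calls, `[[`, character(1), "locus")
  unstable <- status == "unstable"
  marker_unstable <- unstable & role == "marker"
  counts <- vapply(c(1, 2, 4, 5), function(u)
    sum(marker_unstable & unit == u), integer(1))
  names(counts) <- c("mono", "di", "tetra", "penta")
  list(n_informative = sum(ok), n_failed = sum(!ok),
       unstable_by_unit = counts,
       unstable_loci = name[unstable],
       emast = any(marker_unstable & unit == 4),
       qc_fail = any(unstable & role == "control"))
}

#' Run the MSI pipeline over baseline and follow-up peak tables
#'
#' @param tables,baseline_tables Named lists of [peak_table()]s keyed by
#'   locus name (follow-up and matched baseline, e.g. day-0/parental line).
#' @param panel A panel data.frame ([msi_panel()]).
#' @param tolerance_bp,threshold_fraction,noise_floor Passed through.
#' @return A list with `calls` (list of `msi_call`) and `summary`
#'   ([panel_summary()]).
#' @export
msi_classify_sample <- function(tables, baseline_tables, panel = msi_panel(),
                                tolerance_bp = 0.5, threshold_fraction = 0.20,
                                noise_floor = 50) {
  validate_panel(panel)
  calls <- lapply(seq_len(nrow(panel)), function(i) {
    loc <- panel[i, ]
    tb <- tables[[loc$name]]; bt <- baseline_tables[[loc$name]]
    if (is.null(tb) || is.null(bt))
      return(classify_msi(numeric(), numeric(), loc, tolerance_bp))
    s <- call_locus_alleles(tb, loc, threshold_fraction, noise_floor)
    b <- call_locus_alleles(bt, loc, threshold_fraction, noise_floor)
    classify_msi(s$alleles, b$alleles, loc, tolerance_bp)
  })
  list(calls = calls, summary = panel_summary(calls))
}
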