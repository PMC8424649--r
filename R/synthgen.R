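#' Parameters of the stochastic repeat-expansion model
#'
#' Each cell carries the configured founder alleles; every day each allele
#' independently gains one repeat unit with probability `p_expand`, loses one
#' with probability `p_contract`, and is otherwise unchanged -- a per-day
#' biased unit-step random walk, the simplest process reproducing the linear
#' modal drift (slope `p_expand - p_contract` units/day) and gradual
#' broadening seen in repeat-expansion time courses.
#'
#' @param p_expand,p_contract Per-cell per-day step probabilities. Scalar, or
#'   one value per founder allele (the biallelic HTT assay has a stable short
#'   allele and an expanding long allele).
#' @param n_cells Population size (>= 1).
#' @param days Strictly increasing non-negative sampling days.
#' @param founder_repeats Starting repeat length of each allele (>= 1).
#' @param seed Integer RNG seed.
#' @return An object of class `expansion_model_params`.
#' @export
expansion_model_params <- function(p_expand, p_contract = 0,
                                   n_cells = 10000,
                                   days = c(0, 14, 28, 42),
                                   founder_repeats = c(20, 118),
                                   seed = 1) {
  n_alleles <- length(founder_repeats)
  p_expand <- rep_len(as.numeric(p_expand), n_alleles)
  p_contract <- rep_len(as.numeric(p_contract), n_alleles)
  if (any(p_expand < 0) || any(p_contract < 0) ||
      any(p_expand + p_contract > 1))
    stop("need 0 <= p_expand, p_contract and p_expand + p_contract <= 1",
         call. = FALSE)
  if (n_cells < 1 || n_cells != round(n_cells))
    stop("`n_cells` must be a positive integer", call. = FALSE)
  days <- as.numeric(days)
  if (any(days < 0) || any(diff(days) <= 0))
    stop("`days` must be non-negative and strictly increasing", call. = FALSE)
  if (any(founder_repeats < 1))
    stop("founder repeat lengths must be >= 1", call. = FALSE)
  structure(list(p_expand = p_expand, p_contract = p_contract,
                 n_cells = as.integer(n_cells), days = days,
                 founder_repeats = as.integer(founder_repeats),
                 seed = as.integer(seed)),
            class = "expansion_model_params")
}

#' Simulate repeat-length dynamics of a cell population
#'
#' Evolves the per-allele repeat-length histogram day by day under the
#' random-walk model of [expansion_model_params()] and records it at each
#' sampling day. The whole population is simulated (histogram counts sum to
#' `n_cells` at every day); evolution is multinomial per length bin, so run
#' time is independent of `n_cells` up to RNG cost.
#'
#' @param params An [expansion_model_params()].
#' @return An object of class `repeat_population`: a list keyed by day (as
#'   character) whose elements are lists of per-allele histograms (named
#'   integer vectors: repeat length -> cell count). Reproducible for a fixed
#'   seed.
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "expansion_model_params"))
  set.seed(params$seed)
  n_alleles <- length(params$founder_repeats)
  # current histogram per allele, named by repeat length
  hist <- lapply(seq_len(n_alleles), function(a)
    stats::setNames(params$n_cells, params$founder_repeats[a]))
  out <- stats::setNames(vector("list", length(params$days)),
                         as.character(params$days))
  record <- function(day) out[[as.character(day)]] <<- lapply(hist, identity)
  if (params$days[1L] == 0) record(0)
  max_day <- max(params$days)
  if (max_day >= 1) for (day in seq_len(max_day)) {
    for (a in seq_len(n_alleles)) {
      pe <- params$p_expand[a]; pc <- params$p_contract[a]
      if (pe == 0 && pc == 0) next
      h <- hist[[a]]
      lens <- as.integer(names(h))
      acc <- new.env(parent = emptyenv())
      add <- function(len, n) {
        if (n == 0L) return()
        key <- as.character(len)
        prev <- acc[[key]]
        acc[[key]] <- if (is.null(prev)) n else prev + n
      }
      for (i in seq_along(lens)) {
        moves <- stats::rmultinom(1L, h[i], c(pc, 1 - pe - pc, pe))[, 1L]
        add(max(1L, lens[i] - 1L), moves[1L]) # repeat length floor at 1
        add(lens[i], moves[2L])
        add(lens[i] + 1L, moves[3L])
      }
      keys <- sort(as.integer(ls(acc)))
      hist[[a]] <- stats::setNames(
        vapply(as.character(keys), function(k) acc[[k]], numeric(1)), keys)
    }
    if (day %in% params$days) record(day)
  }
  structure(out, class = "repeat_population", params = params)
}

#' Rendering parameters for synthetic peak tables
#'
#' Controls how a repeat-length histogram is turned into a capillary
#' electrophoresis peak table: PCR stutter (a geometric minus-one-repeat
#' ladder, the dominant stutter direction for CAG amplicons), Gaussian
#' sizing jitter, and multiplicative height noise.
#'
#' @param stutter_ratio Fraction of a peak's signal echoed per -1 repeat
#'   stutter step (0 <= s < 1; default 0.15).
#' @param stutter_steps Maximal stutter ladder depth (default 3).
#' @param size_noise_sd Gaussian sizing jitter in bp (default 0.15,
#'   typical capillary sizing precision).
#' @param height_noise_cv Coefficient of variation of multiplicative
#'   (log-normal, mean 1) height noise (default 0.10).
#' @param repeat_unit_bp Repeat unit length in bp (3 for CAG).
#' @param flank_bp Amplicon length minus repeat tract (default 87; an
#'   arbitrary but realistic flank -- downstream analysis calibrates against
#'   a known allele, so the absolute value is immaterial).
#' @param peak_height_scale Height of the tallest rendered peak, in
#'   arbitrary fluorescence units (only height ratios matter downstream).
#' @return An object of class `trace_render_params`.
#' @export
trace_render_params <- function(stutter_ratio = 0.15, stutter_steps = 3,
                                size_noise_sd = 0.15, height_noise_cv = 0.10,
                                repeat_unit_bp = 3, flank_bp = 87,
                                peak_height_scale = 8000) {
  if (stutter_ratio < 0 || stutter_ratio >= 1)
    stop("`stutter_ratio` must be in [0, 1)", call. = FALSE)
  if (stutter_steps < 0 || stutter_steps != round(stutter_steps))
    stop("`stutter_steps` must be a non-negative integer", call. = FALSE)
  if (size_noise_sd < 0 || height_noise_cv < 0)
    stop("noise parameters must be >= 0", call. = FALSE)
  if (repeat_unit_bp < 1) stop("`repeat_unit_bp` must be >= 1", call. = FALSE)
  structure(list(stutter_ratio = stutter_ratio,
                 stutter_steps = as.integer(stutter_steps),
                 size_noise_sd = size_noise_sd,
                 height_noise_cv = height_noise_cv,
                 repeat_unit_bp = repeat_unit_bp, flank_bp = flank_bp,
                 peak_height_scale = peak_height_scale),
            class = "trace_render_params")
}

#' Default calibration matching the renderer
#'
#' Maps the renderer's size model back to repeat units: a `reference_repeat`
#' allele sizes at `flank_bp + reference_repeat * repeat_unit_bp`.
#'
#' @param render A [trace_render_params()].
#' @param reference_repeat Calibrator repeat count (default 20, the
#'   endogenous HTT allele).
#' @return A [calibration()].
#' @export
render_calibration <- function(render, reference_repeat = 20) {
  calibration(reference_repeat,
              render$flank_bp + reference_repeat * render$repeat_unit_bp,
              render$repeat_unit_bp)
}

#' Render a repeat-length histogram as a peak table
#'
#' Peaks sit at `flank_bp + repeat * repeat_unit_bp` plus sizing jitter.
#' Each true peak contributes `stutter_ratio^k` of its signal at the `-k`
#' repeat position for `k = 1..stutter_steps`; contributions landing on the
#' same repeat add. Heights are scaled so the tallest true peak (before
#' noise) equals `peak_height_scale`, then multiplied by log-normal noise.
#' Rendering consumes the current RNG stream; seed before calling for
#' reproducibility.
#'
#' @param histograms A list of per-allele histograms (named numeric vectors,
#'   repeat length -> count) -- one day's entry of a `repeat_population` --
#'   or a single named vector.
#' @param render A [trace_render_params()].
#' @param sample_id,locus,day Passed to [peak_table()].
#' @return A [peak_table()] with all alleles rendered into one table (single
#'   dye), peaks sorted by size.
#' @export
render_peak_table <- function(histograms, render, sample_id,
                              locus = "HTT", day = NA_real_) {
  stopifnot(inherits(render, "trace_render_params"))
  if (!is.list(histograms)) histograms <- list(histograms)
  if (length(histograms) == 0L ||
      any(vapply(histograms, length, integer(1)) == 0L))
    stop("empty histogram", call. = FALSE)
  scale <- render$peak_height_scale /
    max(vapply(histograms, max, numeric(1)))
  rows <- lapply(histograms, function(h) {
    lens <- as.integer(names(h))
    signal <- as.numeric(h) * scale
    acc <- stats::setNames(signal, lens)
    if (render$stutter_ratio > 0 && render$stutter_steps > 0) {
      for (k in seq_len(render$stutter_steps)) {
        contrib <- signal * render$stutter_ratio^k
        at <- lens - k
        keep <- at >= 1L
        for (i in which(keep)) {
          key <- as.character(at[i])
          acc[key] <- if (is.na(acc[key])) contrib[i] else acc[key] + contrib[i]
        }
      }
    }
    lens2 <- as.integer(names(acc))
    data.frame(repeat_len = lens2, height = as.numeric(acc))
  })
  df <- do.call(rbind, rows)
  size <- render$flank_bp + df$repeat_len * render$repeat_unit_bp
  if (render$size_noise_sd > 0)
    size <- size + stats::rnorm(length(size), 0, render$size_noise_sd)
  height <- df$height
  if (render$height_noise_cv > 0) {
    sdlog <- sqrt(log(1 + render$height_noise_cv^2))
    height <- height * stats::rlnorm(length(height), -sdlog^2 / 2, sdlog)
  }
  peak_table(sample_id, locus,
             data.frame(size_bp = size, height = height), day)
}

derive_seed <- function(base, ...) {
  idx <- c(...)
  as.integer((as.numeric(base) * 7919 + sum(idx * 104729^seq_along(idx))) %%
               2147483647)
}

#' Default genotype set of the U2OS-like fixture
#'
#' Three genotype archetypes spanning the phenotypes of interest: a
#' full-length-protected slow expander, a knockout-like fast expander, and
#' an MMR-null non-expander (expansion requires functional mismatch repair).
#' Probabilities apply to the long (118-repeat) exogenous allele; the short
#' endogenous 20-repeat allele is stable in all genotypes, as in the assay.
#'
#' @return Named numeric vector of per-day `p_expand` for the long allele.
#' @export
u2os_genotypes <- function() {
  c(FAN1_FL = 0.05, FAN1_KO = 0.15, MMR_null = 0)
}

#' Generate the packaged U2OS-like expansion fixture
#'
#' Simulates biallelic (20/118 CAG) fragment data for three genotypes x
#' `replicates` replicates x `days`, renders each (genotype, replicate, day)
#' as a peak-table TSV, and writes a sample manifest (CSV) and the full
#' configuration (YAML) next to them. Deterministic (byte-identical files)
#' for a fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param seed Base integer seed; per-replicate seeds are derived from it
#'   and logged in the manifest.
#' @param genotypes Named `p_expand` vector, see [u2os_genotypes()].
#' @param replicates Replicates per genotype (default 3).
#' @param days Sampling days (default `c(0, 14, 28, 42)`, a six-week
#'   course).
#' @param n_cells Cells per population (default 10000).
#' @param render A [trace_render_params()].
#' @return An object of class `fixture_manifest`: list with `manifest`
#'   (data.frame: sample_id, genotype, replicate, day, seed, file), `dir`,
#'   `config_path`, `manifest_path`, `genotypes`, `render`, `cal`.
#' @export
make_fixture_u2os <- function(dir = tempfile("u2os_fixture"), seed = 1,
                              genotypes = u2os_genotypes(), replicates = 3,
                              days = c(0, 14, 28, 42), n_cells = 10000,
                              render = trace_render_params()) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir, call. = FALSE)
  if (file.access(dir, mode = 2L) != 0L)
    stop("output directory ", dir, " is not writable", call. = FALSE)
  rows <- list()
  for (gi in seq_along(genotypes)) {
    g <- names(genotypes)[gi]
    for (r in seq_len(replicates)) {
      rep_seed <- derive_seed(seed, gi, r)
      params <- expansion_model_params(
        p_expand = c(0, genotypes[[gi]]), p_contract = 0,
        n_cells = n_cells, days = days, founder_repeats = c(20, 118),
        seed = rep_seed)
      pop <- simulate_population(params)
      for (d in days) {
        sample_id <- sprintf("%s_rep%d_d%02d", g, r, d)
        set.seed(derive_seed(rep_seed, match(d, days)))
        tb <- render_peak_table(pop[[as.character(d)]], render,
                                sample_id = sample_id, locus = "HTT",
                                day = d)
        file <- file.path(dir, paste0(sample_id, ".tsv"))
        write_peak_table(tb, file)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sample_id, genotype = g, replicate = r, day = d,
          seed = rep_seed, file = basename(file), stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(manifest, manifest_path)
  cal <- render_calibration(render)
  config <- list(
    seed = seed, n_cells = n_cells, days = days, replicates = replicates,
    founder_repeats = c(20L, 118L),
    genotypes = as.list(genotypes),
    render = unclass(render),
    calibration = unclass(cal))
  config_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, config_path)
  structure(list(manifest = manifest, dir = dir,
                 manifest_path = manifest_path, config_path = config_path,
                 genotypes = genotypes, render = render, cal = cal),
            class = "fixture_manifest")
}

#' Generate a synthetic MSI panel fixture
#'
#' Builds baseline peak tables for every panel locus and follow-up tables in
#' which the loci named in `shifts` gain a novel allele displaced by the
#' given number of repeat units; every other locus reproduces its baseline
#' allele. Baselines are single-allele, emulating a clonal cell line (the
#' within-line time-course design the classifier targets). Ground-truth
#' labels are returned. Control (pentanucleotide) loci may not be shifted.
#'
#' @param panel A panel data.frame ([msi_panel()]).
#' @param shifts Named integer vector: locus name -> shift in repeat units
#'   (non-zero). Empty for an all-stable fixture.
#' @param seed Integer seed.
#' @param render_stutter Stutter ratio used when rendering each allele's
#'   small ladder.
#' @return A list with `baseline` and `followup` (named lists of
#'   [peak_table()] keyed by locus), `truth` (data.frame `locus`, `status`,
#'   `shift_units`) and `panel`.
#' @export
make_msi_fixture <- function(panel = msi_panel(), shifts = integer(),
                             seed = 1, render_stutter = 0.12) {
  validate_panel(panel)
  if (length(shifts)) {
    if (is.null(names(shifts)) || any(!nzchar(names(shifts))))
      stop("`shifts` must be named by locus", call. = FALSE)
    unknown <- setdiff(names(shifts), panel$name)
    if (length(unknown))
      stop("unknown locus/loci in `shifts`: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    ctrl <- intersect(names(shifts),
                      panel$name[panel$role == "control"])
    if (length(ctrl))
      stop("control loci cannot be shifted: ",
           paste(ctrl, collapse = ", "), call. = FALSE)
    if (any(shifts == 0))
      stop("shifts must be non-zero", call. = FALSE)
  }
  set.seed(seed)
  render_locus <- function(alleles, unit, sample_id, locus) {
    rows <- lapply(alleles, function(a) {
      # main peak + a short minus-one-unit stutter ladder
      k <- 0:2
      data.frame(size_bp = a - k * unit +
                   stats::rnorm(length(k), 0, 0.08),
                 height = 1000 * render_stutter^k *
                   stats::rlnorm(length(k), 0, 0.05))
    })
    peak_table(sample_id, locus, do.call(rbind, rows))
  }
  baseline <- list(); followup <- list(); truth <- list()
  for (i in seq_len(nrow(panel))) {
    loc <- panel[i, ]
    # deterministic per-seed clonal baseline on the locus unit grid
    alleles <- 90 + 4 * i + loc$unit_bp * sample.int(10, 1)
    baseline[[loc$name]] <- render_locus(alleles, loc$unit_bp,
                                         "baseline", loc$name)
    shift <- if (loc$name %in% names(shifts)) shifts[[loc$name]] else 0L
    fu_alleles <- if (shift != 0L)
      c(alleles, max(alleles) + shift * loc$unit_bp) else alleles
    followup[[loc$name]] <- render_locus(fu_alleles, loc$unit_bp,
                                         "followup", loc$name)
    truth[[loc$name]] <- data.frame(
      locus = loc$name,
      status = if (shift != 0L) "unstable" else "stable",
      shift_units = as.integer(shift), stringsAsFactors = FALSE)
  }
  list(baseline = baseline, followup = followup,
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
       panel = panel)
}

#' Generate a synthetic crosslink + toy-structure fixture
#'
#' Writes (a) a tab-delimited crosslink identification table whose scores
#' straddle the validation cutoff of 20 (including one record at exactly
#' 20), with all residue letters drawn from the crosslinkable set, and whose
#' above-cutoff unique pair counts are 3 for FAN1-MLH1 and 6 for FAN1-PMS2
#' (plus duplicates and sub-threshold decoys that must not change the
#' counts); and (b) a toy two-chain PDB file with known inter-residue
#' distances, including two Calpha atoms exactly 5.0 Angstrom apart (the
#' 3-4-5 triangle). All content is synthetic.
#'
#' @param dir Output directory.
#' @param seed Unused randomness placeholder (the fixture is fully
#'   deterministic); kept so call sites can thread a seed uniformly.
#' @return A list with `links_path`, `structure_path`, `records` (the
#'   data.frame as written) and `coords`.
#' @export
make_xlink_fixture <- function(dir = tempfile("xlink_fixture"), seed = 1) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory ", dir, call. = FALSE)
  rec <- function(p1, r1, l1, p2, r2, l2, score)
    data.frame(protein1 = p1, residue1 = r1, letter1 = l1,
               protein2 = p2, residue2 = r2, letter2 = l2,
               score = score, stringsAsFactors = FALSE)
  records <- rbind(
    # FAN1-MLH1: 3 unique pairs above cutoff (two N-terminal, one TPR-region)
    rec("FAN1", 146, "K", "MLH1", 377, "K", 28.5),
    rec("FAN1", 151, "S", "MLH1", 413, "T", 25.1),
    rec("FAN1", 794, "K", "MLH1", 618, "K", 22.3),
    rec("MLH1", 377, "K", "FAN1", 146, "K", 21.7), # duplicate, swapped order
    rec("FAN1", 131, "Y", "MLH1", 394, "S", 19.9), # decoy below cutoff
    rec("FAN1", 128, "Y", "MLH1", 401, "K", 20.0), # decoy exactly at cutoff
    # FAN1-PMS2: 6 unique pairs above cutoff (four N-terminal, two TPR-side)
    rec("FAN1", 120, "S", "PMS2", 563, "K", 30.2),
    rec("FAN1", 127, "T", "PMS2", 571, "K", 26.8),
    rec("FAN1", 146, "K", "PMS2", 602, "S", 24.4),
    rec("FAN1", 168, "K", "PMS2", 563, "K", 23.9),
    rec("FAN1", 794, "K", "PMS2", 610, "T", 22.0),
    rec("FAN1", 810, "S", "PMS2", 622, "Y", 21.2),
    # FAN1 intra-protein: the structured-region pair plus one low scorer
    rec("FAN1", 539, "K", "FAN1", 646, "S", 31.2),
    rec("FAN1", 539, "K", "FAN1", 882, "K", 18.0),
    # N-terminal amino acid is linkable regardless of letter
    rec("FAN1", 1, "M", "MLH1", 1, "M", 17.5))
  links_path <- file.path(dir, "links.tsv")
  data.table::fwrite(records, links_path, sep = "\t", quote = FALSE)
  coords <- data.frame(
    chain = c("A", "A", "A", "B", "B"),
    resid = c(10L, 20L, 30L, 20L, 40L),
    resname = c("LYS", "SER", "LYS", "SER", "TYR"),
    atom = "CA",
    x = c(0, 3, 10, 3, 0), y = c(0, 4, 0, 4, 30), z = c(0, 0, 0, 10, 0),
    stringsAsFactors = FALSE)
  structure_path <- file.path(dir, "toy_structure.pdb")
  write_pdb(coords, structure_path)
  list(links_path = links_path, structure_path = structure_path,
       records = records, coords = coords)
}
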