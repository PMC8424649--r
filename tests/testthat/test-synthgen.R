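test_that("parameter validation enforces the model invariants", {
  expect_error(expansion_model_params(p_expand = -0.1), "p_expand")
  expect_error(expansion_model_params(p_expand = 0.6, p_contract = 0.5),
               "<= 1")
  expect_error(expansion_model_params(0.1, n_cells = 0), "positive integer")
  expect_error(expansion_model_params(0.1, days = c(0, 14, 14)),
               "strictly increasing")
  expect_error(expansion_model_params(0.1, founder_repeats = 0), ">= 1")
  expect_error(trace_render_params(stutter_ratio = 1), "stutter_ratio")
  expect_error(trace_render_params(size_noise_sd = -1), ">= 0")
})

test_that("no dynamics means a point mass at the founder length forever", {
  params <- expansion_model_params(p_expand = 0, p_contract = 0,
                                   n_cells = 250, days = c(0, 20, 40),
                                   founder_repeats = c(20, 118), seed = 1)
  pop <- simulate_population(params)
  for (day in names(pop)) for (a in 1:2) {
    h <- pop[[day]][[a]]
    expect_length(h, 1L)
    expect_equal(as.integer(names(h)), params$founder_repeats[a])
    expect_equal(unname(h), 250)
  }
})

test_that("histograms conserve cells and drift at t x (p_expand - p_contract)", {
  params <- expansion_model_params(p_expand = 0.1, p_contract = 0,
                                   n_cells = 10000, days = c(0, 40),
                                   founder_repeats = 100, seed = 99)
  pop <- simulate_population(params)
  h <- pop[["40"]][[1]]
  expect_equal(sum(h), 10000) # every cell accounted for
  gain <- sum((as.integer(names(h)) - 100) * h) / sum(h)
  # binomial mean 40 x 0.1 = 4, SE = sqrt(40 x 0.1 x 0.9 / 10000)
  se <- sqrt(40 * 0.1 * 0.9 / 10000)
  expect_lt(abs(gain - 4.0), 3 * se)
})

test_that("equal seeds give identical histograms, different seeds differ", {
  params <- expansion_model_params(p_expand = 0.1, n_cells = 500,
                                   days = c(0, 10), founder_repeats = 50,
                                   seed = 7)
  expect_identical(simulate_population(params), simulate_population(params))
  params2 <- expansion_model_params(p_expand = 0.1, n_cells = 500,
                                    days = c(0, 10), founder_repeats = 50,
                                    seed = 8)
  expect_false(identical(simulate_population(params)[["10"]],
                         simulate_population(params2)[["10"]]))
})

test_that("noise-free rendering places peaks exactly and builds the stutter ladder", {
  render0 <- trace_render_params(stutter_ratio = 0, stutter_steps = 0,
                                 size_noise_sd = 0, height_noise_cv = 0,
                                 flank_bp = 87, peak_height_scale = 100)
  tb <- render_peak_table(setNames(50, 20), render0, "s1")
  expect_equal(nrow(tb$peaks), 1L)
  expect_equal(tb$peaks$size_bp, 87 + 60) # flank + 20 x 3 bp
  expect_equal(tb$peaks$height, 100)

  ladder <- trace_render_params(stutter_ratio = 0.2, stutter_steps = 2,
                                size_noise_sd = 0, height_noise_cv = 0,
                                flank_bp = 87, peak_height_scale = 100)
  tb2 <- render_peak_table(setNames(50, 20), ladder, "s1")
  expect_equal(tb2$peaks$size_bp, 87 + 3 * c(18, 19, 20))
  expect_equal(tb2$peaks$height, c(4, 20, 100)) # geometric 100 x 0.2^k
  expect_error(render_peak_table(list(), ladder, "s1"), "empty")
})

test_that("total stutter signal per allele is main x sum of s^k (conservation)", {
  for (s in c(0.1, 0.15, 0.3)) for (K in 0:3) {
    render <- trace_render_params(stutter_ratio = s, stutter_steps = K,
                                  size_noise_sd = 0, height_noise_cv = 0,
                                  peak_height_scale = 1000)
    tb <- render_peak_table(setNames(100, 40), render, "s1")
    expect_equal(sum(tb$peaks$height), 1000 * sum(s^(0:K)), tolerance = 1e-9)
  }
})

test_that("make_fixture_u2os writes the full grid deterministically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  fx1 <- make_fixture_u2os(dir = dir1, seed = 42, n_cells = 400)
  expect_equal(nrow(fx1$manifest), 3 * 3 * 4) # genotypes x reps x days
  expect_false(anyDuplicated(fx1$manifest[c("genotype", "replicate",
                                            "day")]) > 0)
  expect_true(all(file.exists(file.path(dir1, fx1$manifest$file))))
  # byte-identical on re-generation with the same seed
  fx2 <- make_fixture_u2os(dir = dir2, seed = 42, n_cells = 400)
  for (f in fx1$manifest$file)
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  # config records the genotype expansion rates
  cfg <- yaml::read_yaml(fx1$config_path)
  expect_equal(unlist(cfg$genotypes), u2os_genotypes())
})

test_that("the MMR-null genotype never moves its modal repeat", {
  dir <- withr::local_tempdir()
  fx <- make_fixture_u2os(dir = dir, seed = 11, n_cells = 400)
  null_rows <- fx$manifest[fx$manifest$genotype == "MMR_null", ]
  for (r in unique(null_rows$replicate)) {
    rows <- null_rows[null_rows$replicate == r, ]
    modals <- vapply(rows$file, function(f) {
      tb <- read_peak_table(file.path(dir, f))[[1]]
      long <- split_alleles(tb, c(20, 118), fx$cal)$allele_118
      call_modal(long, fx$cal)$modal_repeat
    }, integer(1))
    expect_true(all(modals == modals[1]))
  }
})

test_that("make_msi_fixture injects labelled shifts and protects controls", {
  fx <- make_msi_fixture(shifts = c(D20S85 = 1L), seed = 3)
  expect_equal(fx$truth$status[fx$truth$locus == "D20S85"], "unstable")
  expect_true(all(fx$truth$status[fx$truth$locus != "D20S85"] == "stable"))
  expect_error(make_msi_fixture(shifts = c(`Penta C` = 1L)),
               "control loci")
  expect_error(make_msi_fixture(shifts = c(NOPE = 1L)), "unknown locus")
  expect_error(make_msi_fixture(shifts = c(D20S85 = 0L)), "non-zero")
  none <- make_msi_fixture(seed = 4)
  expect_true(all(none$truth$status == "stable"))
})

test_that("make_xlink_fixture writes a boundary-rich table and a 3-4-5 structure", {
  dir <- withr::local_tempdir()
  fx <- make_xlink_fixture(dir = dir)
  records <- read_crosslinks(fx$links_path)
  expect_true(any(records$score == 20)) # boundary record present
  expect_true(any(records$score < 20) && any(records$score > 20))
  linkable <- records$letter_a %in% c("K", "S", "T", "Y") | records$res_a == 1L
  expect_true(all(linkable))
  stru <- read_structure(fx$structure_path)
  m <- structure_map(chains = c(P1 = "A"))
  d <- map_distance(list(protein_a = "P1", res_a = 10,
                         protein_b = "P1", res_b = 20), stru, m)
  expect_equal(d$distance, 5.0) # (0,0,0) to (3,4,0)
})
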