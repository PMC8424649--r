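# Independent oracles and small builders shared across the suite.
# The oracles deliberately re-derive each quantity by the most direct route
# (explicit loops, textbook formulas) so they share no code with the package.

# build an allele_call directly from (repeat, height) pairs
make_call <- function(repeats, heights, modal_repeat = NULL,
                      fraction = NULL) {
  stopifnot(length(repeats) == length(heights))
  if (is.null(modal_repeat)) modal_repeat <- repeats[which.max(heights)]
  # the included set is given; pick a fraction that admits all of it
  if (is.null(fraction)) fraction <- min(heights) / max(heights)
  repeatlens:::new_allele_call(
    window = range(repeats), modal_repeat = modal_repeat,
    modal_height = max(heights),
    included_peaks = data.frame(repeat_len = as.integer(repeats),
                                height = as.numeric(heights)),
    threshold_fraction = fraction)
}

# direct-summation index oracles (explicit loop, no vectorisation)
oracle_instability <- function(repeats, heights, modal) {
  total <- 0
  for (h in heights) total <- total + h
  s <- 0
  for (i in seq_along(repeats)) s <- s + (heights[i] / total) * (repeats[i] - modal)
  s
}
oracle_expansion <- function(repeats, heights, modal) {
  total <- 0
  for (h in heights) total <- total + h
  s <- 0
  for (i in seq_along(repeats))
    if (repeats[i] > modal) s <- s + (heights[i] / total) * (repeats[i] - modal)
  s
}

# textbook sum-of-squares one-way ANOVA oracle
oracle_anova_F <- function(groups) {
  all_values <- unlist(groups)
  grand <- mean(all_values)
  ssb <- 0; ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - grand)^2
    for (v in g) ssw <- ssw + (v - mean(g))^2
  }
  k <- length(groups); n <- length(all_values)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# textbook pooled-variance t statistic
oracle_t <- function(a, b) {
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
}

# quick single-allele peak table in bp space
bp_table <- function(sizes, heights, sample_id = "s1", locus = "L") {
  peak_table(sample_id, locus, data.frame(size_bp = sizes, height = heights))
}

# calibration used throughout: 20 repeats at 147 bp, CAG unit
test_cal <- function() calibration(20, 147, 3)

# random rigid-body transform (rotation from QR decomposition + translation)
rigid_transform <- function(coords) {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  shift <- rnorm(3, sd = 50)
  m <- as.matrix(coords[, c("x", "y", "z")]) %*% q
  coords$x <- m[, 1] + shift[1]
  coords$y <- m[, 2] + shift[2]
  coords$z <- m[, 3] + shift[3]
  coords
}
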