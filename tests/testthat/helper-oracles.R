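# Independent reference implementations used as oracles. These deliberately
# take a different computational route from the package code they check.

# Box count by explicit enumeration of the floor-index triples as strings.
bruteCountBoxes <- function(mask, s) {
  keys <- character(0)
  d <- dim(mask)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3]))
    if (mask[i, j, k])
      keys <- c(keys, paste(floor((i - 1) / s), floor((j - 1) / s),
                            floor((k - 1) / s)))
  length(unique(keys))
}

# F-beta via the weighted-harmonic-mean form rather than the closed form.
fbetaRef <- function(p, r, beta) {
  if (p == 0 && r == 0) return(0)
  w <- beta^2 / (1 + beta^2)
  1 / (w / r + (1 - w) / p)
}

# Random sparse label mask for oracle-equivalence runs.
randomMask <- function(n, p, seed) {
  withSeed(seed, array(stats::runif(n^3) < p, c(n, n, n)))
}

# Two-class synthetic (volume, fd) features: dementia shifted by volShift
# mm^3 and fdShift dimensionless units.
makeFeatures <- function(n, volShift, fdShift, seed) {
  withSeed(seed, {
    cls <- rep(c("control", "dementia"), each = n / 2)
    data.frame(
      subject_id = sprintf("S%04d", seq_len(n)),
      region_name = "brain_stem",
      volume = stats::rnorm(n, 5000, 500) + (cls == "dementia") * volShift,
      fd = stats::rnorm(n, 2.5, 0.1) + (cls == "dementia") * fdShift,
      class_label = cls, stringsAsFactors = FALSE)
  })
}

# Synthetic CDR registry with known decidable truth: every MRI session lies
# strictly between two same-score CDR visits.
makeDecidableRegistry <- function(nSubjects, seed) {
  withSeed(seed, {
    sessions <- NULL; cdr <- NULL
    for (i in seq_len(nSubjects)) {
      sid <- sprintf("SUB%04d", i)
      score <- sample(c(0, 0.5, 1, 2, 3), 1)
      mri <- sample(100:1000, 1)
      gap <- sample(10:400, 2)
      sessions <- rbind(sessions, data.frame(
        subject_id = sid, session_id = formatSessionId(sid, mri),
        day = mri, truth = score, stringsAsFactors = FALSE))
      cdr <- rbind(cdr,
        data.frame(subject_id = sid, day = c(mri - gap[1], mri + gap[2]),
                   cdr = score))
    }
    list(sessions = sessions, cdr = cdr)
  })
}
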