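randomLabelVolume <- function(seed, labels = c(0L, 23L, 24L, 26L),
                              n = 12L, spacing = c(1, 1, 1)) {
  withSeed(seed,
    labelVolume(array(sample(labels, n^3, TRUE), c(n, n, n)),
                spacing = spacing))
}

test_that("region extraction selects exactly the labeled voxels", {
  vol <- randomLabelVolume(21)
  m <- extractRegion(vol, 26)
  expect_identical(m, volumeData(vol) == 26L)
  expect_warning(m27 <- extractRegion(vol, 27), "not present")
  expect_identical(sum(m27), 0L)
  expect_error(extractRegion(vol, 0), "1..40")
})

test_that("region masks partition the whole-brain mask", {
  vol <- randomLabelVolume(22)
  whole <- wholeBrainMask(vol)
  total <- array(0L, dim(vol))
  for (lab in 1:40) {
    m <- suppressWarnings(extractRegion(vol, lab))
    total <- total + m
  }
  expect_true(all(total <= 1L))              # disjoint
  expect_identical(total == 1L, whole)       # union
  expect_identical(sum(whole), sum(volumeData(vol) > 0L))
  expect_gte(sum(whole), sum(extractRegion(vol, 26)))
})

test_that("whole-brain mask is the union of positive labels", {
  data <- array(0L, c(6, 6, 6))
  data[1:2, , ] <- 23L
  data[5:6, , ] <- 24L
  vol <- labelVolume(data)
  expect_identical(wholeBrainMask(vol), data > 0L)
})

test_that("a session measure reports whole plus per-region rows", {
  sp <- makePhantom("menger_sponge", level = 3)
  vol <- embedPhantom(sp, c(32, 32, 32), label = 26)
  ses <- parseSessionId("OAS30001_MR_d0129")
  m <- suppressWarnings(
    measureSession(vol, ses, labels = c(26, 27)))
  expect_identical(m$region_name,
                   c("whole_volume", "third_ventricle", "right_putamen"))
  expect_identical(m$voxel_count, c(8000L, 8000L, 0L))
  # single-region volume: whole mask coincides with the region mask
  expect_equal(m$fd[1], m$fd[2])
  expect_true(is.na(m$fd[3]))
  expect_equal(m$volume_mm3[2], 8000)
  expect_identical(m$session_id[1], "OAS30001_MR_d0129")
  # deterministic
  m2 <- suppressWarnings(measureSession(vol, ses, labels = c(26, 27)))
  expect_identical(m, m2)
  # labels outside the default map are addressable by number
  m3 <- suppressWarnings(measureSession(vol, ses, labels = 30))
  expect_identical(m3$region_name[2], "label_30")
})

test_that("physical volume scales with the cube of the spacing", {
  data <- withSeed(31, array(sample(c(0L, 26L), 8^3, TRUE), c(8, 8, 8)))
  m1 <- measureSession(labelVolume(data), labels = 26,
                       schedule = scaleSchedule(5, 0.1, 0.8))
  m2 <- measureSession(labelVolume(data, spacing = c(2, 2, 2)),
                       labels = 26, schedule = scaleSchedule(5, 0.1, 0.8))
  expect_equal(m2$volume_mm3, 8 * m1$volume_mm3)
  expect_equal(m2$fd, m1$fd)  # FD is grid-based, spacing-free
  expect_warning(
    measureSession(labelVolume(data, spacing = c(1, 1, 2)), labels = 26,
                   schedule = scaleSchedule(5, 0.1, 0.8)),
    "anisotropic")
})

test_that("session comparison pivots wide and reports relative variation", {
  mk <- function(sid, fdw, fdr) data.frame(
    session_id = sid, subject_id = "OAS30109",
    day = parseSessionId(sid)$day,
    region_label = c(NA, 26L), region_name = c("whole_volume",
                                               "third_ventricle"),
    voxel_count = c(100L, 50L), volume_mm3 = c(100, 50),
    fd = c(fdw, fdr), rmse = 0.01, r2 = 0.99, n_points = 20L,
    stringsAsFactors = FALSE)
  meas <- rbind(mk("OAS30109_MR_d0432", 2.2, 2.30),
                mk("OAS30109_MR_d0270", 2.0, 2.30))
  comp <- compareSessions(meas)
  # rows sorted by day
  expect_identical(comp$fd$session_id,
                   c("OAS30109_MR_d0270", "OAS30109_MR_d0432"))
  expect_equal(comp$fd$whole_volume, c(2.0, 2.2))
  # (max-min)/mean as percent: (0.2)/(2.1)*100
  expect_equal(unname(comp$variation["whole_volume"]), 100 * 0.2 / 2.1)
  expect_equal(unname(comp$variation["third_ventricle"]), 0)
  # identical sessions: zero variation everywhere
  same <- rbind(mk("OAS30109_MR_d0270", 2.0, 2.3),
                mk("OAS30109_MR_d0432", 2.0, 2.3))
  expect_true(all(compareSessions(same)$variation == 0))
  # single session: variation undefined
  single <- compareSessions(mk("OAS30109_MR_d0270", 2.0, 2.3))
  expect_true(all(is.na(single$variation)))
  expect_equal(nrow(single$fd), 1L)
  # inconsistent region sets refuse to tabulate
  broken <- rbind(mk("OAS30109_MR_d0270", 2.0, 2.3)[1, ],
                  mk("OAS30109_MR_d0432", 2.0, 2.3))
  expect_error(compareSessions(broken), "different region sets")
})

test_that("embedded phantoms keep their dimension through the pipeline", {
  slab <- makePhantom("slab", size = 48)
  vol <- embedPhantom(slab, c(54, 54, 5), label = 23)
  m <- measureSession(vol, labels = 23)
  expect_equal(m$fd[m$region_name == "right_thalamus_proper"], 2,
               tolerance = 0.1)
})
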