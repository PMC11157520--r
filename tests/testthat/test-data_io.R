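test_that("NIfTI round-trip is the identity on voxel arrays", {
  spec <- tiny_spec()
  v <- generate_phantom(spec, "nc001", 1L, 0L)
  sum_at_gen <- sum(v$voxels)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path, list(subject_id = "nc001", scan_id = "nc001_t01",
                               label = 0), grid_shape = spec$grid_shape)
  expect_identical(v2$voxels, v$voxels)
  expect_equal(sum(v2$voxels), sum_at_gen)
  expect_equal(v2$subject_id, "nc001")
})

test_that("full-scale gray-matter grid is accepted", {
  spec <- phantom_spec(grid_shape = c(84L, 102L, 84L),
                       n_subjects_per_class = 1L)
  v <- generate_phantom(spec, "nc001", 1L, 0L)
  expect_identical(dim(v$voxels), c(84L, 102L, 84L))
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  v2 <- read_volume(path, list(subject_id = "nc001", scan_id = "s",
                               label = 0), grid_shape = c(84L, 102L, 84L))
  expect_identical(dim(v2$voxels), c(84L, 102L, 84L))
})

test_that("I/O errors are typed: missing file, grid mismatch", {
  expect_error(read_volume(tempfile(), list(subject_id = "x", scan_id = "y",
                                            label = 0)),
               class = "mcigate_io_error")
  spec <- tiny_spec()
  v <- generate_phantom(spec, "nc001", 1L, 0L)
  path <- tempfile(fileext = ".nii.gz")
  write_volume(v, path)
  expect_error(read_volume(path, list(subject_id = "nc001", scan_id = "s",
                                      label = 0),
                           grid_shape = c(8L, 8L, 8L)),
               class = "mcigate_validation_error")
})

test_that("cohort invariants: conflicting labels and duplicate paths rejected", {
  rec <- data.frame(subject_id = c("a", "a", "b"),
                    scan_id = c("a1", "a2", "b1"),
                    label = c(0, 1, 1),
                    path = c("p1", "p2", "p3"))
  expect_error(new_cohort(rec, tiny_grid), class = "mcigate_validation_error")
  rec$label <- c(0, 0, 1)
  expect_silent(new_cohort(rec, tiny_grid))
  rec$path <- c("p1", "p1", "p3")
  expect_error(new_cohort(rec, tiny_grid), class = "mcigate_validation_error")
})

test_that("manifest TSV round-trips", {
  cohort <- fake_cohort(3, scans = 2)
  path <- tempfile(fileext = ".tsv")
  write_cohort(cohort, path)
  back <- read_cohort(path, grid_shape = tiny_grid)
  expect_equal(back$records$subject_id, cohort$records$subject_id)
  expect_equal(back$records$label, cohort$records$label)
  expect_equal(nrow(back$records), 12)
})

test_that("subject split keeps all scans of a subject on one side", {
  cohort <- fake_cohort(4, scans = 3)
  sp <- subject_split(cohort, 0.25, seed = 0)
  # forced by rounding: exactly 1 test subject per class, all its scans
  test_subj <- unique(sp$test$records$subject_id)
  expect_length(test_subj, 2)
  expect_equal(sort(unique(sp$test$records$label)), c(0L, 1L))
  expect_equal(nrow(sp$test$records), 6)   # 2 subjects x 3 scans
  expect_equal(nrow(sp$train$records) + nrow(sp$test$records),
               nrow(cohort$records))
  for (s in test_subj)
    expect_equal(sum(cohort$records$subject_id == s),
                 sum(sp$test$records$subject_id == s))
})

test_that("splits are leakage-free for every seed and deterministic", {
  cohort <- fake_cohort(50, scans = 2)
  memberships <- lapply(0:4, function(seed) {
    sp <- subject_split(cohort, 0.25, seed = seed)
    expect_length(intersect(sp$train$records$subject_id,
                            sp$test$records$subject_id), 0)
    sort(unique(sp$test$records$subject_id))
  })
  expect_identical(memberships[[1]],
                   sort(unique(subject_split(cohort, 0.25,
                                             seed = 0)$test$records$subject_id)))
  expect_false(identical(memberships[[1]], memberships[[2]]))
  # per-class allocation is round(fraction * count)
  sp <- subject_split(cohort, 0.25, seed = 1)
  tsub <- unique(sp$test$records[, c("subject_id", "label")])
  expect_equal(as.vector(table(tsub$label)), c(12, 12))
})

test_that("split refuses cohorts it cannot allocate", {
  expect_error(subject_split(fake_cohort(1), 0.25, seed = 0),
               class = "mcigate_config_error")
  expect_error(subject_split(fake_cohort(4), 1.5, seed = 0),
               class = "mcigate_config_error")
})
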