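test_that("volume + mask round-trip through NIfTI and NRRD", {
  vol <- array(rnorm(64, 0, 50), c(4, 4, 4))
  msk <- array(0, c(4, 4, 4)); msk[2:3, 2:3, 2:3] <- 1

  for (ext in c(".nii", ".nii.gz", ".nrrd")) {
    vp <- withr::local_tempfile(fileext = ext)
    mp <- withr::local_tempfile(fileext = ext)
    wr <- if (ext == ".nrrd") write_nrrd else write_nifti
    wr(vol, vp, spacing = c(0.9, 0.9, 3))
    wr(msk, mp, spacing = c(0.9, 0.9, 3))
    roi <- read_volume_roi(vp, mp)
    expect_s3_class(roi, "volume_roi")
    expect_equal(sum(roi$mask), 8)
    expect_equal(roi$volume, vol, tolerance = 1e-6)  # float32 storage
    expect_equal(roi$voxel_spacing, c(0.9, 0.9, 3), tolerance = 1e-6)
  }
})

test_that("volume reader rejects invariant-violating inputs", {
  vol <- array(rnorm(64), c(4, 4, 4))
  vp <- withr::local_tempfile(fileext = ".nii")
  write_nifti(vol, vp)

  bad_dim <- withr::local_tempfile(fileext = ".nii")
  write_nifti(array(1, c(4, 4, 3)), bad_dim)
  expect_error(read_volume_roi(vp, bad_dim), "4x4x3|dimensions differ")

  empty <- withr::local_tempfile(fileext = ".nii")
  write_nifti(array(0, c(4, 4, 4)), empty)
  expect_error(read_volume_roi(vp, empty), "at least 2 foreground")

  one_voxel <- array(0, c(4, 4, 4)); one_voxel[1] <- 1
  ovp <- withr::local_tempfile(fileext = ".nii")
  write_nifti(one_voxel, ovp)
  expect_error(read_volume_roi(vp, ovp), "at least 2 foreground")

  expect_error(read_volume_roi("absent.nii", vp), "not found")
})

test_that("mask values are coerced to binary by value > 0", {
  vol <- array(rnorm(27), c(3, 3, 3))
  msk <- array(c(0, 0.5, 2, rep(0, 24)), c(3, 3, 3))
  roi <- volume_roi(vol, msk)
  expect_setequal(unique(as.vector(roi$mask)), c(0L, 1L))
  expect_equal(sum(roi$mask), 2)
})

test_that("feature tables round-trip through ARFF and CSV", {
  g <- generate_feature_table(n = 5, p = 3, k_informative = 1, d = 1,
                              seed = 4)
  tab <- g$table
  for (ext in c(".arff", ".csv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_feature_table(tab, path)
    back <- read_feature_table(path)
    expect_identical(table_feature_names(back), table_feature_names(tab))
    expect_identical(back$patient_id, tab$patient_id)
    expect_identical(as.character(back$class), as.character(tab$class))
    for (f in table_feature_names(tab)) {
      expect_equal(back[[f]], tab[[f]], tolerance = 1e-9)
    }
  }
})

test_that("ARFF writer emits one attribute per feature plus id and class", {
  spec <- cohort_spec(volume_dim = 32L)
  phs <- list(generate_phantom("adaptive", spec, seed = 2),
              generate_phantom("non-adaptive", spec, seed = 3))
  tab <- extract_cohort(lapply(phs, `[[`, "roi"),
                        c("adaptive", "non-adaptive"),
                        lapply(phs, `[[`, "semantic"))
  path <- withr::local_tempfile(fileext = ".arff")
  write_feature_table(tab, path)
  # independent text parse: count @attribute lines
  lines <- readLines(path)
  n_attr <- sum(grepl("^@attribute", lines))
  expect_equal(n_attr, 251 + 2)  # features + patient_id + class
  expect_equal(sum(grepl("^@data", lines)), 1)
})

test_that("readers reject malformed label structure", {
  # CSV with three label values
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(f1 = 1:3, class = c("a", "b", "c")), path)
  expect_error(read_feature_table(path), "exactly 2 values")

  # ARFF with a 3-valued class
  path2 <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation t", "@attribute f1 numeric",
               "@attribute class {a,b,c}", "@data", "1,a", "2,b"), path2)
  expect_error(read_feature_table(path2), "2 values")

  # non-numeric value in a numeric attribute
  path3 <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation t", "@attribute f1 numeric",
               "@attribute class {a,b}", "@data", "x,a", "2,b"), path3)
  expect_error(read_feature_table(path3), "Non-numeric")

  # missing value in a radiomic column
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(stat_mean = c(1, NA),
                                  class = c("a", "b")), path4)
  expect_error(read_feature_table(path4), "Missing values in radiomic")
})

test_that("nominal non-class ARFF attributes are integer-coded with coding recorded", {
  path <- withr::local_tempfile(fileext = ".arff")
  writeLines(c("@relation t",
               "@attribute sem_histology {adeno,squamous,NOS}",
               "@attribute f2 real",
               "@attribute class {yes,no}",
               "@data",
               "squamous,1.5,yes", "adeno,2.5,no", "NOS,0.5,yes"), path)
  tab <- read_feature_table(path)
  expect_equal(tab$sem_histology, c(1, 0, 2))
  expect_equal(attr(tab, "codings")$sem_histology, c("adeno", "squamous", "NOS"))
  expect_identical(table_feature_names(tab), c("sem_histology", "f2"))
})

test_that("quoted ARFF attribute names survive a round-trip byte-for-byte", {
  tab <- feature_table(
    data.frame(`glcm_absolute_-1,1,-1` = c(1.25, 2.5),
               `stat name` = c(0.1, 0.2), check.names = FALSE),
    c("adaptive", "non-adaptive")
  )
  path <- withr::local_tempfile(fileext = ".arff")
  write_feature_table(tab, path)
  back <- read_feature_table(path)
  expect_identical(table_feature_names(back),
                   c("glcm_absolute_-1,1,-1", "stat name"))
})

test_that("empty feature list is rejected on write", {
  tab <- tibble::tibble(patient_id = c("a", "b"),
                        class = c("adaptive", "non-adaptive"))
  expect_error(write_feature_table(tab, withr::local_tempfile(fileext = ".arff")),
               "at least one feature")
})
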