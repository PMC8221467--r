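test_that("constructors validate configurations and datasets", {
  expect_error(landmark_config("a", matrix(1:4, 2, 2)), "k x 3")
  expect_error(landmark_config("a", matrix(c(1, 2, NA, 4, 5, 6, 7, 8, 9), 3, 3)),
               "non-finite")
  expect_error(landmark_config("a", matrix(1:6, 2, 3)), "at least 3")
  m <- matrix(rnorm(9), 3, 3)
  expect_error(landmark_config("a", m, labels = c("p", "p", "q")), "unique")

  c1 <- landmark_config("s1", matrix(rnorm(9), 3, 3))
  c2 <- landmark_config("s2", matrix(rnorm(12), 4, 3))
  expect_error(shape_dataset(list(c1, c2)), "s2")
  expect_error(shape_dataset(list(c1, c1)), "unique")
})

test_that("metadata join is validated by specimen id", {
  set.seed(11)
  configs <- lapply(1:3, function(i) rand_config(4, paste0("s", i)))
  meta <- data.frame(specimen_id = c("s1", "s2", "s3"),
                     group = c("DANISH", "DANISH", "EARLY_AS"),
                     sex = c("F", "M", "F"))
  ds <- shape_dataset(configs, meta = meta)
  expect_identical(ds$meta$role, c("SOURCE", "SOURCE", "TARGET"))
  expect_error(shape_dataset(configs, meta = meta[1:2, ]), "no metadata")
  bad <- rbind(meta, data.frame(specimen_id = "ghost", group = "DANISH", sex = "F"))
  expect_error(shape_dataset(configs, meta = bad), "unknown specimen")
})

test_that("a small CSV fixture parses to the expected dataset", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "specimen_id,group,sex,lm1_x,lm1_y,lm1_z,lm2_x,lm2_y,lm2_z,lm3_x,lm3_y,lm3_z",
    "a,DANISH,F,0,0,0,1,0,0,0,1,0",
    "b,PREMED_BRITISH,M,0,0,1,1,0,1,0,1,1"
  ), path)
  ds <- read_landmarks(path, dialect = "csv")
  expect_equal(n_specimens(ds), 2L)
  expect_equal(n_landmarks(ds), 3L)
  expect_equal(ds$coords[2, , "a"], c(x = 1, y = 0, z = 0))
  expect_equal(ds$meta$group, c("DANISH", "PREMED_BRITISH"))
})

test_that("write/read round-trips are lossless in every dialect", {
  set.seed(21)
  configs <- lapply(1:4, function(i) rand_config(6, paste0("sp", i)))
  meta <- data.frame(specimen_id = paste0("sp", 1:4),
                     group = c("DANISH", "DANISH", "EARLY_AS", "MIDDLE_AS"),
                     sex = c("F", "M", "F", "M"))
  ds <- shape_dataset(configs, meta = meta)
  for (dialect in c("csv", "whitespace", "tps", "morphologika")) {
    path <- withr::local_tempfile(fileext = ".txt")
    write_landmarks(ds, path, dialect = dialect)
    back <- read_landmarks(path, dialect = dialect)
    expect_equal(unname(back$coords), unname(ds$coords),
                 tolerance = 0, label = dialect)
    expect_identical(specimen_ids(back), specimen_ids(ds))
  }
  # metadata survives the CSV dialect and external join for the others
  path <- withr::local_tempfile(fileext = ".txt")
  mpath <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(ds, path, dialect = "tps")
  write_metadata(ds, mpath)
  back <- read_landmarks(path, dialect = "tps", metadata_path = mpath)
  expect_identical(back$meta$group, ds$meta$group)
  expect_identical(back$meta$sex, ds$meta$sex)
})

test_that("whitespace dialect supports both row layouts", {
  path <- withr::local_tempfile()
  writeLines(c("a 0 0 0 1 0 0 0 1 0", "b 0 0 1 1 0 1 0 1 1"), path)
  wide <- read_landmarks(path, dialect = "whitespace", layout = "specimen")
  expect_equal(n_landmarks(wide), 3L)

  path2 <- withr::local_tempfile()
  writeLines(c("a 0 0 0", "a 1 0 0", "a 0 1 0",
               "b 0 0 1", "b 1 0 1", "b 0 1 1"), path2)
  long <- read_landmarks(path2, dialect = "whitespace", layout = "landmark")
  expect_equal(unname(long$coords), unname(wide$coords))
})

test_that("subsetting filters by sex and group, preserves order, idempotent", {
  p <- small_params(seed = 7, sizes = c(3L, 2L, 4L, 2L))
  ds <- simulate_study(p)$dataset
  f <- subset_specimens(ds, sex = "F")
  expect_true(all(f$meta$sex == "F"))
  expect_equal(n_specimens(f), sum(p$group_sizes[, "F"]))
  expect_identical(subset_specimens(f, sex = "F"), f)

  src <- subset_specimens(ds, groups = SOURCE_GROUPS)
  expect_setequal(unique(src$meta$group), SOURCE_GROUPS)
  expect_identical(specimen_ids(src),
                   specimen_ids(ds)[ds$meta$group %in% SOURCE_GROUPS])

  expect_identical(subset_specimens(ds), ds)
  expect_error(subset_specimens(ds, groups = "VIKINGS"), "not present")
  expect_warning(subset_specimens(subset_specimens(ds, sex = "F"), sex = "M"),
                 "empty")
})

test_that("the default synthetic study matches the published design size", {
  ds <- simulate_study(simulation_params(seed = 4))$dataset
  expect_equal(n_specimens(ds), 236L)
  expect_equal(n_landmarks(ds), 34L)
  expect_equal(n_specimens(subset_specimens(ds, sex = "F")), 99L)
  expect_equal(n_specimens(subset_specimens(ds, sex = "M")), 137L)
  # a full-size study written out and re-read is intact
  path <- withr::local_tempfile(fileext = ".csv")
  write_landmarks(ds, path, dialect = "csv")
  back <- read_landmarks(path, dialect = "csv")
  expect_equal(n_specimens(back), 236L)
  expect_equal(n_landmarks(back), 34L)
})
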