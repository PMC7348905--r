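test_that("save/load round-trips the epoch bundle", {
  x <- tiny_epochs(4, 2, 10)
  p <- file.path(tempdir(), "bundle_rt")
  save_epochs(x, p)
  y <- load_epochs(p)
  # float32 quantization on the first write; bit-exact thereafter
  expect_equal(y$data, x$data, tolerance = 1e-6)
  expect_identical(y$labels, x$labels)
  expect_identical(y$srate, x$srate)
  expect_identical(y$t0_ms, x$t0_ms)
  expect_identical(y$channel_names, x$channel_names)
  p2 <- file.path(tempdir(), "bundle_rt2")
  save_epochs(y, p2)
  z <- load_epochs(p2)
  expect_identical(z$data, y$data)
  unlink(c(p, p2), recursive = TRUE)
})

test_that("bundle payload size and write determinism", {
  x <- tiny_epochs(40, 3, 25)
  p <- file.path(tempdir(), "bundle_sz")
  save_epochs(x, p)
  expect_identical(file.info(file.path(p, "data.bin"))$size, 40 * 3 * 25 * 4)
  bytes1 <- readBin(file.path(p, "data.bin"), "raw",
                    n = file.info(file.path(p, "data.bin"))$size)
  save_epochs(x, p)
  bytes2 <- readBin(file.path(p, "data.bin"), "raw", n = length(bytes1))
  expect_identical(bytes1, bytes2)
  unlink(p, recursive = TRUE)
})

test_that("degenerate empty-trial bundle round-trips", {
  x <- epoch_set(array(0, c(0, 2, 5)), labels = integer(0), srate = 100,
                 t0_ms = 0, channel_names = c("C3", "C4"))
  p <- file.path(tempdir(), "bundle_empty")
  save_epochs(x, p)
  y <- load_epochs(p)
  expect_identical(dim(y$data), c(0L, 2L, 5L))
  expect_identical(y$labels, integer(0))
  unlink(p, recursive = TRUE)
})

test_that("metadata/payload inconsistencies raise format errors", {
  x <- tiny_epochs(3, 2, 8)
  p <- file.path(tempdir(), "bundle_bad")
  save_epochs(x, p)
  meta <- jsonlite::read_json(file.path(p, "metadata.json"),
                              simplifyVector = TRUE)
  meta$n_channels <- 3
  meta$channel_names <- c(meta$channel_names, "CZ")
  jsonlite::write_json(meta, file.path(p, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_epochs(p), "size mismatch")
  meta$n_channels <- NULL
  jsonlite::write_json(meta, file.path(p, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_epochs(p), "n_channels")
  expect_error(load_epochs(file.path(tempdir(), "no_such_dir_xyz")),
               "missing")
  unlink(p, recursive = TRUE)
})

test_that("independently written bundles load with matching values", {
  # write the documented format by hand: json metadata + float32 LE payload
  # in trial-major, channel-major, sample order
  p <- file.path(tempdir(), "bundle_xwriter")
  dir.create(p, showWarnings = FALSE)
  vals <- array(seq(0.25, by = 0.25, length.out = 2 * 2 * 3), c(2, 2, 3))
  writeLines(paste0(
    '{"n_trials":2,"n_channels":2,"n_samples":3,"srate_hz":100,',
    '"t0_ms":-10,"channel_names":["C3","C4"],"labels":[1,-1]}'),
    file.path(p, "metadata.json"))
  con <- file(file.path(p, "data.bin"), "wb")
  for (tr in 1:2) for (ch in 1:2)
    writeBin(as.numeric(vals[tr, ch, ]), con, size = 4, endian = "little")
  close(con)
  y <- load_epochs(p)
  expect_equal(y$data, vals, tolerance = 1e-7)
  expect_identical(y$labels, c(1L, -1L))
  expect_identical(y$channel_names, c("C3", "C4"))
  unlink(p, recursive = TRUE)
})

test_that("CSV payload fallback is accepted on read", {
  p <- file.path(tempdir(), "bundle_csv")
  dir.create(p, showWarnings = FALSE)
  writeLines(paste0(
    '{"n_trials":2,"n_channels":1,"n_samples":3,"srate_hz":100,',
    '"t0_ms":0,"channel_names":["CZ"],"labels":[1,-1]}'),
    file.path(p, "metadata.json"))
  writeLines(c("1,2,3", "4,5,6"), file.path(p, "data.csv"))
  y <- load_epochs(p)
  expect_equal(y$data[1, 1, ], c(1, 2, 3))
  expect_equal(y$data[2, 1, ], c(4, 5, 6))
  unlink(p, recursive = TRUE)
})

test_that("select restricts channels, window and labels as requested", {
  x <- epoch_set(array(rnorm(4 * 20 * 600), c(4, 20, 600)),
                 labels = c(1, 1, -1, -1), srate = 200, t0_ms = -500,
                 channel_names = c(central_channels(), "FP1", "FP2"))
  # identity selection
  same <- select_epochs(x)
  expect_identical(same$data, x$data)
  # the canonical DCPM window holds exactly 70 samples at 200 Hz
  w <- select_epochs(x, window = window_spec(500, 850))
  expect_identical(n_samples(w), 70L)
  expect_identical(w$t0_ms, 500)
  # 18 listed channels, output order follows the request
  req <- rev(central_channels())
  ch <- select_epochs(x, channels = req)
  expect_identical(ch$channel_names, req)
  expect_identical(n_channels(ch), 18L)
  # case-insensitive matching
  lc <- select_epochs(x, channels = c("cz", "cpz"))
  expect_identical(lc$channel_names, c("CZ", "CPZ"))
  expect_identical(lc$data[, 1, ], x$data[, which(x$channel_names == "CZ"), ])
  # label filtering
  lab <- select_epochs(x, labels = 1)
  expect_identical(n_trials(lab), 2L)
  expect_error(select_epochs(x, channels = "BOGUS"), "unknown channel")
  expect_error(select_epochs(x, labels = 0), "empty selection")
})

test_that("select is idempotent and half-open windows tile", {
  x <- tiny_epochs(4, 3, 200, srate = 200, t0_ms = -100)
  w <- window_spec(0, 500)
  once <- select_epochs(x, channels = c("CH2", "CH1"), window = w)
  twice <- select_epochs(once, channels = c("CH2", "CH1"), window = w)
  expect_identical(once$data, twice$data)
  expect_identical(once$t0_ms, twice$t0_ms)
  # [a,b) and [b,c) tile [a,c)
  n_ab <- n_samples(select_epochs(x, window = window_spec(-100, 300)))
  n_bc <- n_samples(select_epochs(x, window = window_spec(300, 700)))
  n_ac <- n_samples(select_epochs(x, window = window_spec(-100, 700)))
  expect_identical(n_ab + n_bc, n_ac)
})

test_that("constructor enforces the container invariants", {
  expect_error(epoch_set(array(0, c(2, 2, 3)), labels = c(1, -1, 1),
                         srate = 100, t0_ms = 0,
                         channel_names = c("A", "B")), "labels length")
  expect_error(epoch_set(array(0, c(2, 2, 3)), labels = c(1, -1),
                         srate = 100, t0_ms = 0, channel_names = "A"),
               "channel_names")
  expect_error(epoch_set(array(0, c(2, 2, 3)), labels = c(1, -1),
                         srate = -1, t0_ms = 0,
                         channel_names = c("A", "B")), "srate")
  bad <- array(0, c(2, 2, 3)); bad[1] <- NA
  expect_error(epoch_set(bad, labels = c(1, -1), srate = 100, t0_ms = 0,
                         channel_names = c("A", "B")), "finite")
})
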