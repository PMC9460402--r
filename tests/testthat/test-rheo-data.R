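# Readers, writers, domain-type invariants.

write_fixture_csv <- function(df, name, meta = NULL) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta))
    jsonlite::write_json(meta, sub("\\.csv$", ".meta.json", path),
                         auto_unbox = TRUE)
  path
}

test_that("frequency sweep reads a 5-row table with its metadata sidecar", {
  df <- data.frame(omega_rad_per_s = c(0.1, 1, 10, 100, 1000),
                   g_prime_pa = c(1, 50, 400, 800, 950),
                   g_double_prime_pa = c(10, 120, 420, 300, 150))
  path <- write_fixture_csv(df, "sweep.csv",
                            meta = list(temperature_c = 23, mode = "CS",
                                        amplitude = 300, gap_mm = 0.5,
                                        sample_id = "collagen_4wt"))
  sw <- read_sweep(path, "frequency")
  expect_s3_class(sw, "frequency_sweep")
  expect_length(sw$omega, 5L)
  expect_equal(sw$temperature, 23)
  expect_equal(sw$mode, "CS")
  expect_equal(sw$amplitude, 300)
  expect_equal(sw$gap, 0.5)
})

test_that("rows in descending frequency are reordered ascending, idempotently", {
  df <- data.frame(omega_rad_per_s = c(100, 10, 1, 0.1),
                   g_prime_pa = c(800, 400, 50, 1),
                   g_double_prime_pa = c(300, 420, 120, 10))
  path <- write_fixture_csv(df, "desc.csv", meta = list(temperature_c = 23))
  sw <- read_sweep(path, "frequency")
  expect_equal(sw$omega, c(0.1, 1, 10, 100))
  expect_equal(sw$g_prime, c(1, 50, 400, 800))
  sw2 <- frequency_sweep(sw$omega, sw$g_prime, sw$g_double_prime, 23)
  expect_equal(sw2$omega, sw$omega)
})

test_that("validation errors name the offending row and column", {
  df <- data.frame(omega_rad_per_s = c(0.1, 1, 10),
                   g_prime_pa = c(1, -1, 400),
                   g_double_prime_pa = c(10, 120, 420))
  path <- write_fixture_csv(df, "neg.csv", meta = list(temperature_c = 23))
  expect_error(read_sweep(path, "frequency"), "row 2.*g_prime")
  df$g_prime_pa <- NULL
  path2 <- write_fixture_csv(df, "miss.csv", meta = list(temperature_c = 23))
  expect_error(read_sweep(path2, "frequency"), "missing column")
  path3 <- write_fixture_csv(df[1:2, ], "short.csv")
  expect_error(read_sweep(path3, "frequency"), "fewer than 3")
})

test_that("a frequency column in Hz is converted to rad/s on read", {
  df <- data.frame(frequency_hz = c(0.1, 1, 10),
                   g_prime_pa = c(1, 50, 400),
                   g_double_prime_pa = c(10, 120, 420))
  path <- write_fixture_csv(df, "hz.csv", meta = list(temperature_c = 23))
  expect_message(sw <- read_sweep(path, "frequency"), "2\\*pi")
  expect_equal(sw$omega, 2 * pi * c(0.1, 1, 10))
})

test_that("result types round-trip through disk to 12 significant digits", {
  dir <- withr::local_tempdir()
  dist <- collagen_truth()
  p1 <- file.path(dir, "mwd.csv")
  write_result(dist, p1)
  back <- read_result(p1, "mwd")
  expect_equal(back$w, dist$w, tolerance = 1e-12)
  expect_equal(back$Mw, dist$Mw, tolerance = 1e-12)

  cs <- continuous_spectrum(log_grid(1e-3, 1e2, 10),
                            dnorm(log(log_grid(1e-3, 1e2, 10)), 0, 1) * 100)
  p2 <- file.path(dir, "spec.csv")
  write_result(cs, p2)
  back2 <- read_result(p2, "spectrum")
  expect_equal(back2$H, cs$H, tolerance = 1e-12)
  expect_equal(back2$lambda_grid, cs$lambda_grid, tolerance = 1e-12)
})

test_that("writing a payload containing NaN is refused", {
  rc <- relaxation_curve(c(1, 2, 3), c(3, 2, 1))
  rc$modulus[2] <- NaN
  expect_error(write_result(rc, file.path(withr::local_tempdir(), "bad.csv")),
               "NaN")
})

test_that("run_config validates grids and round-trips through JSON", {
  expect_error(run_config(lambda_grid = list(min = 1, max = 0.1,
                                             points_per_decade = 10)),
               "min < max")
  cfg <- run_config(seed = 42L)
  path <- file.path(withr::local_tempdir(), "cfg.json")
  write_result(cfg, path)
  cfg2 <- read_run_config(path)
  expect_equal(cfg2$seed, 42L)
  expect_equal(cfg2$reptation$G_N, cfg$reptation$G_N)
  expect_equal(cfg2$lambda_grid$min, cfg$lambda_grid$min)
})

test_that("amplitude and temperature sweeps enforce their invariants", {
  expect_error(amplitude_sweep(c(0, 0.1, 1), c(1, 1, 1), c(1, 1, 1), 23, 1),
               "positive")
  expect_error(temperature_sweep(c(23, 30, 40), c(10, -1, 5), c(1, 1, 1)),
               "viscosity")
  ts <- temperature_sweep(c(40, 23, 30), c(1, 10, 5), c(0.3, 0.2, 0.25))
  expect_equal(ts$temperature, c(23, 30, 40))
})
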