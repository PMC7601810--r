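test_that("spheroid initialization seeds the expected disk", {
  pa <- tiny_ca()
  set.seed(1)
  single <- init_spheroid(pa, radius_sites = 0)
  expect_equal(sum(single$grid > 0), 1)
  pos <- which(single$grid == 1L, arr.ind = TRUE)
  expect_true(all(abs(pos - 30.5) <= 1))  # at the lattice center
  set.seed(1)
  disk <- init_spheroid(pa, radius_sites = 10)
  count <- sum(disk$grid > 0)
  expect_lt(abs(count - pi * 100) / (pi * 100), 0.05)
  expect_true(all(disk$oxygen == pa$c_inf))
  set.seed(7); a <- init_spheroid(pa, radius_sites = 6)
  set.seed(7); b <- init_spheroid(pa, radius_sites = 6)
  expect_identical(a$grid, b$grid)
  expect_identical(a$clock, b$clock)
  expect_error(init_spheroid(pa, radius_sites = 50), "fit")
})

test_that("oxygen solve matches a direct sparse solve in the linear regime", {
  skip_if_not_installed("Matrix")
  # consumption weak enough that every cell stays proliferating, so the
  # self-consistent solve reduces to one linear Dirichlet problem
  pa <- ca_params(lattice_n = 40, uptake_P = 2e-5 / (0.18 / 0.018)^2)
  set.seed(2)
  st <- init_spheroid(pa, radius_sites = 10)
  st <- ca_update_oxygen(st, pa)
  n <- pa$lattice_n
  g <- st$grid
  interior <- which(row(g) > 1 & row(g) < n & col(g) > 1 & col(g) < n)
  idx <- matrix(0L, n, n); idx[interior] <- seq_along(interior)
  trip <- list(i = integer(), j = integer(), x = numeric())
  b <- numeric(length(interior))
  for (kk in seq_along(interior)) {
    ij <- interior[kk]
    i <- ((ij - 1) %% n) + 1; j <- ((ij - 1) %/% n) + 1
    trip$i <- c(trip$i, kk); trip$j <- c(trip$j, kk); trip$x <- c(trip$x, -4)
    b[kk] <- if (g[i, j] == 1) pa$uptake_P else 0
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (idx[ii, jj] > 0) {
        trip$i <- c(trip$i, kk); trip$j <- c(trip$j, idx[ii, jj])
        trip$x <- c(trip$x, 1)
      } else b[kk] <- b[kk] - pa$c_inf
    }
  }
  A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x)
  oracle <- matrix(pa$c_inf, n, n)
  oracle[interior] <- as.numeric(Matrix::solve(A, b))
  expect_lt(max(abs(oracle - st$oxygen)), 1e-3)
  expect_true(min(st$oxygen) < pa$c_inf)  # consumption depresses the field
})

test_that("oxygen field properties: empty lattice and point sink", {
  pa <- tiny_ca()
  empty <- list(grid = matrix(0L, 60, 60), oxygen = matrix(0.3, 60, 60),
                clock = matrix(0, 60, 60), cyclen = matrix(24, 60, 60), t = 0)
  out <- ca_update_oxygen(empty, pa)
  expect_equal(max(abs(out$oxygen - pa$c_inf)), 0, tolerance = 1e-4)
  single <- empty
  single$grid[30, 30] <- 1L
  out1 <- ca_update_oxygen(single, pa)
  expect_equal(which.min(out1$oxygen), (30 - 1) * 60 + 30)  # unique minimum
  expect_true(all(out1$oxygen >= 0))
})

test_that("classification follows the oxygen thresholds, necrosis irreversibly", {
  pa <- tiny_ca()
  st <- list(grid = matrix(0L, 60, 60), oxygen = matrix(1, 60, 60),
             clock = matrix(0, 60, 60), cyclen = matrix(24, 60, 60), t = 0)
  st$grid[10, 10] <- 1L; st$grid[20, 20] <- 1L; st$grid[30, 30] <- 2L
  st$grid[40, 40] <- 3L
  st$oxygen[10, 10] <- 0.9           # above c_Q -> P
  st$oxygen[20, 20] <- 0.55          # between -> Q
  st$oxygen[30, 30] <- 0.2           # below c_N -> N
  st$oxygen[40, 40] <- 0.99          # necrotic stays necrotic
  out <- ca_classify(st, pa)
  expect_equal(out$grid[10, 10], 1L)
  expect_equal(out$grid[20, 20], 2L)
  expect_equal(out$grid[30, 30], 3L)
  expect_equal(out$grid[40, 40], 3L)
})

test_that("cell stepping respects occupancy bookkeeping and lysis statistics", {
  pa <- tiny_ca(p_lysis = 0.2)
  # grid of isolated necrotic cells: expected lysed fraction = p_lysis
  st <- list(grid = matrix(0L, 60, 60), oxygen = matrix(1, 60, 60),
             clock = matrix(0, 60, 60), cyclen = matrix(24, 60, 60), t = 0)
  sites <- expand.grid(i = seq(5, 55, by = 3), j = seq(5, 55, by = 3))
  for (r in seq_len(nrow(sites))) st$grid[sites$i[r], sites$j[r]] <- 3L
  n0 <- sum(st$grid == 3L)
  set.seed(123)
  lysed <- replicate(30, {
    out <- ca_step(st, pa)
    n0 - sum(out$grid == 3L)
  })
  expect_lt(abs(mean(lysed) - 0.2 * n0),
            3 * sqrt(0.2 * 0.8 * n0 / 30))
  # with p_lysis = 0 the necrotic count never decreases
  pa0 <- tiny_ca(p_lysis = 0)
  out0 <- ca_step(st, pa0)
  expect_equal(sum(out0$grid == 3L), n0)
  expect_true(all(out0$grid %in% c(0L, 3L)))  # nothing else appeared
})

test_that("radiation kill is binomial with the LQ survival fraction", {
  pa <- tiny_ca()
  st <- list(grid = matrix(1L, 60, 60), oxygen = matrix(1, 60, 60),
             clock = matrix(0, 60, 60), cyclen = matrix(24, 60, 60), t = 0)
  n_live <- 3600
  # alpha = beta = 0: nothing happens
  pa0 <- tiny_ca(radio = radiosensitivity(0, 0))
  expect_identical(ca_apply_rt(st, 2, pa0)$grid, st$grid)
  # enormous dose: everything dies
  set.seed(1)
  out_inf <- ca_apply_rt(st, 1e4, pa)
  expect_true(all(out_inf$grid == 3L))
  # 2 Gy at high radiosensitivity: killed fraction within 3 binomial sd
  sf <- exp(-0.84)
  set.seed(2)
  out <- ca_apply_rt(st, 2, pa)
  killed <- sum(out$grid == 3L)
  expect_lt(abs(killed - (1 - sf) * n_live),
            3 * sqrt(sf * (1 - sf) * n_live))
})

test_that("measurement applies the ellipsoid conversion", {
  pa <- tiny_ca()
  st <- list(grid = matrix(0L, 60, 60), oxygen = matrix(1, 60, 60),
             clock = matrix(0, 60, 60), cyclen = matrix(24, 60, 60), t = 0)
  expect_equal(ca_measure(st, pa)$total_volume, 0)
  st$grid[30:32, 40:42] <- 1L  # 3x3 block
  m <- ca_measure(st, pa)
  expect_equal(m$h_mm, 3 * pa$dx_mm)
  expect_equal(m$v_mm, 3 * pa$dx_mm)
  expect_equal(m$total_volume, 0.5 * (3 * pa$dx_mm)^3)
  expect_equal(m$necrotic_volume, 0)
  # half the block necrotic: necrotic volume scales by area fraction
  st$grid[30, 40:42] <- 3L
  m2 <- ca_measure(st, pa)
  expect_equal(m2$necrotic_volume, m2$total_volume * 3 / 9)
  # circular tumor: h and v agree
  set.seed(3)
  disk <- init_spheroid(pa, radius_sites = 12)
  md <- ca_measure(disk, pa)
  expect_lt(abs(md$h_mm - md$v_mm) / md$h_mm, 0.1)
})

test_that("well-oxygenated uninhibited growth doubles at the cell-cycle rate", {
  pa <- ca_params(lattice_n = 80, uptake_P = 1e-8, cycle_hours = 24,
                  contact_inhibition = FALSE)
  tr <- run_ca(pa, build_schedule(n_weeks = 0), seed = 5, horizon = 7)
  counts <- tr$n_p + tr$n_q + tr$n_n
  rate <- coef(lm(log(counts) ~ tr$day))[2]
  expect_lt(abs(rate - log(2) / 1), 0.1 * log(2))  # per-day rate, 24 h cycle
})

test_that("scenario runs are reproducible and ordered by radiosensitivity", {
  pa <- tiny_ca()
  sched <- build_schedule(8, 2, 2)
  a <- run_scenario("high", sched, seed = 11, params = pa, horizon = 21)
  b <- run_scenario("high", sched, seed = 11, params = pa, horizon = 21)
  expect_identical(a, b)
  untreated <- run_ca(ca_params(lattice_n = 60,
                                radio = scenario_radiosensitivity("high")),
                      build_schedule(n_weeks = 0), seed = 11, horizon = 21)
  low <- run_scenario("low", sched, seed = 11, params = pa, horizon = 21)
  # radiation only removes: end-of-course ordering high <= low <= untreated
  expect_lt(tail(a$tumor_volume, 1), tail(low$tumor_volume, 1) + 1e-9)
  expect_lt(tail(low$tumor_volume, 1), tail(untreated$tumor_volume, 1))
  expect_error(run_scenario("extreme"), "arg")
})
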