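test_that("buffer background enumerates the cells within reach", {
  st <- small_stack()   # 10-km cells
  p1 <- data.frame(lon = 55, lat = 55, year = 2015, month = 7)
  ## radius smaller than a cell: background is that cell only
  bg <- buffer_background(p1, st, radius_km = 4, variables = "MINTEMP")
  expect_equal(nrow(bg), 1)
  expect_equal(bg$cell_id, cell_from_xy(st, 55, 55))
  ## two distant presences: sizes add over disjoint buffers
  p2 <- data.frame(lon = c(25, 215), lat = c(25, 215), year = 2015, month = 7)
  bg2 <- buffer_background(p2, st, radius_km = 30, variables = "MINTEMP")
  cc <- cell_centers(st)
  n1 <- sum(sqrt((cc$x - 25)^2 + (cc$y - 25)^2) <= 30)
  n2 <- sum(sqrt((cc$x - 215)^2 + (cc$y - 215)^2) <= 30)
  expect_equal(nrow(bg2), n1 + n2)
  ## every returned cell lies within the radius of some presence
  dmin <- pmin(sqrt((bg2$lon - 25)^2 + (bg2$lat - 25)^2),
               sqrt((bg2$lon - 215)^2 + (bg2$lat - 215)^2))
  expect_true(all(dmin <= 30))
})

test_that("niche space axes reproduce a hand eigendecomposition", {
  x <- data.frame(a = c(1, 2, 4, 7), b = c(0, 1, 3, 5), c = c(2, -1, 0, 1))
  sp <- fit_niche_space(x)
  ev <- eigen(cor(x))
  expect_equal(sp$explained, ev$values / 3, tolerance = 1e-10)
  ## loadings match up to sign
  for (k in 1:2)
    expect_equal(abs(unname(sp$rotation[, k])), abs(ev$vectors[, k]),
                 tolerance = 1e-8)
  expect_equal(sum(sp$explained), 1)
})

test_that("perfectly correlated variables load on a single axis", {
  set.seed(13)
  a <- rnorm(50)
  d <- data.frame(a = a, b = 2 * a + 3)
  sp <- fit_niche_space(d)
  expect_equal(sp$explained[1], 1, tolerance = 1e-12)
  expect_warning(fit_niche_space(data.frame(a = a, b = 1, c = rnorm(50))),
                 "constant")
})

test_that("occurrence density integrates to one over the window", {
  set.seed(14)
  occ <- cbind(rnorm(40), rnorm(40))
  bg <- cbind(rnorm(500, 0, 2), rnorm(500, 0, 2))
  g <- density_grid(occ, bg, R = 60)
  cell <- diff(g$x[1:2]) * diff(g$y[1:2])
  expect_equal(sum(g$z) * cell, 1, tolerance = 1e-9)
  expect_true(all(g$z >= 0) && all(g$zbg >= 0))
  expect_error(density_grid(occ[1, , drop = FALSE], bg), ">= 2")
})

test_that("density grid matches a direct kernel-sum oracle", {
  occ <- cbind(c(-1, 0, 0.5, 1, 2), c(0, 1, -0.5, 0.3, -1))
  bg <- cbind(seq(-3, 3, length.out = 50), seq(-3, 3, length.out = 50))
  h <- c(1.2, 0.9)
  g <- density_grid(occ, bg, R = 25, h = h)
  ## the kernel estimator evaluates a product-Gaussian with sd = h/4 at
  ## each grid node (rows index the x axis); renormalize the oracle too
  oracle <- outer(seq_along(g$x), seq_along(g$y), Vectorize(function(i, j)
    mean(dnorm(g$x[i], occ[, 1], h[1] / 4) *
           dnorm(g$y[j], occ[, 2], h[2] / 4))))
  cell <- diff(g$x[1:2]) * diff(g$y[1:2])
  expect_equal(g$z, oracle / (sum(oracle) * cell), tolerance = 1e-8)
})

test_that("near-zero bandwidth reduces to histogram counting on the nodes", {
  ## occurrence points placed exactly on grid nodes, with multiplicities
  nodes_x <- seq(-3, 3, length.out = 20)
  nodes_y <- seq(-3, 3, length.out = 20)
  occ <- cbind(nodes_x[c(3, 3, 8, 8, 15)], nodes_y[c(4, 4, 10, 10, 18)])
  bg <- cbind(seq(-3, 3, length.out = 30), seq(-3, 3, length.out = 30))
  g <- density_grid(occ, bg, R = 20, h = c(1e-3, 1e-3),
                    lims = c(-3, 3, -3, 3))
  cell <- diff(g$x[1:2]) * diff(g$y[1:2])
  mass <- g$z * cell
  ## binning oracle: each point contributes 1/n at its node, 0 elsewhere
  expect_equal(mass[3, 4], 2 / 5, tolerance = 1e-6)
  expect_equal(mass[8, 10], 2 / 5, tolerance = 1e-6)
  expect_equal(mass[15, 18], 1 / 5, tolerance = 1e-6)
  expect_equal(sum(mass > 1e-9), 3)
})

test_that("niche dynamics identities hold on constructed grids", {
  z <- matrix(0, 10, 10); z[3:6, 3:6] <- 1
  id <- niche_dynamics(z, z, occupancy_quantile = 0)
  expect_equal(id$stability, 1); expect_equal(id$expansion, 0)
  expect_equal(id$unfilled, 0)
  z2 <- matrix(0, 10, 10); z2[8:9, 8:9] <- 1
  dj <- niche_dynamics(z, z2, occupancy_quantile = 0)
  expect_equal(dj$stability, 0); expect_equal(dj$expansion, 1)
  expect_equal(dj$unfilled, 1)
})

test_that("indices equal brute-force pixel counting (50/34/44 case)", {
  ## non-outbreak occupies 50 cells, 34 shared, outbreak occupies 44
  ref <- matrix(0, 10, 10); comp <- matrix(0, 10, 10)
  ref[1:50] <- 1                     # 50 reference cells
  comp[17:60] <- 1                   # 44 comparison cells; 17..50 shared = 34
  dyn <- niche_dynamics(ref, comp, occupancy_quantile = 0)
  expect_equal(dyn$stability, 34 / 50)   # 0.68
  expect_equal(dyn$expansion, 16 / 50)   # 0.32
  expect_equal(dyn$unfilled, 10 / 44)    # ~0.227
  expect_equal(dyn$stability, 0.68)
  expect_equal(dyn$expansion, 0.32)
})

test_that("stability + expansion = 1 on random inputs, and the analog mask bites", {
  set.seed(15)
  for (i in 1:10) {
    a <- matrix(runif(100), 10, 10) * rbinom(100, 1, 0.6)
    b <- matrix(runif(100), 10, 10) * rbinom(100, 1, 0.6)
    if (sum(a) == 0 || sum(b) == 0) next
    dyn <- niche_dynamics(a, b, occupancy_quantile = 0)
    expect_equal(dyn$stability + dyn$expansion, 1)
    expect_true(all(c(dyn$stability, dyn$expansion, dyn$unfilled) >= 0))
    expect_true(all(c(dyn$stability, dyn$expansion, dyn$unfilled) <= 1))
  }
  ## cells outside the shared background are excluded from the counts
  g1 <- list(z = matrix(1, 4, 4), zbg = matrix(1, 4, 4))
  g2 <- list(z = matrix(1, 4, 4), zbg = matrix(c(1, 1, 0, 0), 4, 4))
  class(g1) <- class(g2) <- "niche_grid"
  dyn <- niche_dynamics(g1, g2, occupancy_quantile = 0)
  expect_equal(sum(dyn$mask), 8)
  expect_equal(dyn$stability, 1)
})

test_that("occupancy binarization drops the thinnest density mass", {
  z <- matrix(0, 5, 5)
  z[1, 1] <- 100; z[2, 2] <- 10; z[3, 3] <- 0.1
  occ <- seasonsdm:::occupied_cells(z, matrix(TRUE, 5, 5), quantile = 0.05)
  expect_true(occ[1, 1] && occ[2, 2])
  expect_false(occ[3, 3])   # the thin 0.1% tail is dropped
})

test_that("variable occupancy curves are rescaled and match a kernel-sum oracle", {
  set.seed(16)
  vals <- c(rnorm(30, 0), rnorm(30, 3))
  months <- rep(c(1, 7), each = 30)
  pres <- data.frame(month = months, MINTEMP = vals)
  bg <- data.frame(month = rep(c(1, 7), each = 100),
                   MINTEMP = c(rnorm(100, 0, 2), rnorm(100, 3, 2)))
  vo <- variable_occupancy(pres, bg, "MINTEMP",
                           periods = list(non_outbreak = 1, outbreak = 7),
                           n_grid = 128)
  expect_setequal(unique(vo$period), c("non_outbreak", "outbreak"))
  for (p in unique(vo$period)) {
    expect_equal(max(vo$occupancy[vo$period == p]), 1)
    expect_equal(max(vo$availability[vo$period == p]), 1)
  }
  ## kernel-sum oracle at the grid nodes for one period
  pv <- pres$MINTEMP[pres$month == 1]
  dd <- density(pv, from = min(c(bg$MINTEMP, pres$MINTEMP)),
                to = max(c(bg$MINTEMP, pres$MINTEMP)), n = 128)
  manual <- vapply(dd$x, function(x0) mean(dnorm(x0, pv, dd$bw)), numeric(1))
  got <- vo$occupancy[vo$period == "non_outbreak"]
  expect_equal(got, manual / max(manual), tolerance = 0.02)
  ## identical periods give coincident curves
  pres2 <- data.frame(month = rep(c(1, 7), each = 30),
                      MINTEMP = rep(vals[1:30], 2))
  bg2 <- data.frame(month = rep(c(1, 7), each = 100),
                    MINTEMP = rep(bg$MINTEMP[1:100], 2))
  vo2 <- variable_occupancy(pres2, bg2, "MINTEMP",
                            periods = list(non_outbreak = 1, outbreak = 7))
  expect_equal(vo2$occupancy[vo2$period == "non_outbreak"],
               vo2$occupancy[vo2$period == "outbreak"])
  expect_error(variable_occupancy(
    data.frame(month = months, MINTEMP = 1), bg, "MINTEMP",
    periods = list(non_outbreak = 1, outbreak = 7)), "degenerate")
})

test_that("a season-shifted niche expands; a season-constant niche is stable", {
  ## stability ~ 1 for a season-constant species presumes that the
  ## environment it occupies is available in every month (aseasonal
  ## availability) and enough records that kernel-region sampling noise is
  ## controlled; both samples then estimate the same occupied region.  The
  ## shifted species moves its thermal optimum upward in the outbreak
  ## months, which must register as expansion plus unfilling.
  base_cfg <- function(seed) {
    vp <- default_var_params()
    vp$MINTEMP$amplitude <- 0     # availability identical across periods
    vp$NDVI$amplitude <- 0
    landscape_config(n_rows = 16, n_cols = 16, cell_size_km = 10,
                     years = 2015, var_params = vp, seed = seed)
  }
  sp_const <- virtual_species(coefs = list(MINTEMP = c(2 * 12 / (2 * 3.5^2),
                                                       -1 / (2 * 3.5^2))))
  sp_shift <- virtual_species(coefs = sp_const$coefs, shift_months = 6:9,
                              shift_delta = c(MINTEMP = 6))
  vars2 <- c("MINTEMP", "NDVI")
  stab_const <- stab_shift <- exp_shift <- unf_shift <- numeric(0)
  for (seed in 1:10) {
    st <- generate_env_stack(base_cfg(seed))
    run_one <- function(sp) {
      pres <- sample_occurrences(sp, st, 100, seed = 1000 + seed)
      bg <- buffer_background(pres, st, 60, vars2)
      pe <- extract_env(st, pres, vars2)
      per <- list(non_outbreak = c(1:5, 10:12), outbreak = 6:9)
      bsc <- as.matrix(bg[, vars2])
      lims <- c(range(bsc[, 1]), range(bsc[, 2]))
      h <- 2.5 * c(MASS::bandwidth.nrd(bsc[, 1]),
                   MASS::bandwidth.nrd(bsc[, 2]))
      grids <- lapply(per, function(m) density_grid(
        as.matrix(pe[pe$month %in% m, vars2]),
        bsc[bg$month %in% m, , drop = FALSE], R = 50, h = h, lims = lims))
      niche_dynamics(grids[[1]], grids[[2]])
    }
    dc <- run_one(sp_const); ds <- run_one(sp_shift)
    stab_const <- c(stab_const, dc$stability)
    stab_shift <- c(stab_shift, ds$stability)
    exp_shift <- c(exp_shift, ds$expansion)
    unf_shift <- c(unf_shift, ds$unfilled)
  }
  expect_gte(median(stab_const), 0.95)
  expect_gt(median(exp_shift), 0)
  expect_gt(median(unf_shift), 0)
  expect_lt(median(stab_shift), median(stab_const))
})
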