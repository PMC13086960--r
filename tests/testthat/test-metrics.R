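# Trajectory observables against hand values and exhaustive oracles.

make_traj <- function(frames, times = seq_along(frames) - 1, box = c(6, 6, 20)) {
  trajectory(frames, times, box)
}

water_at <- function(z, x = 3, y = 3, id = 1L) {
  data.frame(molecule_id = id, species = "water", charge = 0L, element = "O",
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

test_that("deepest-water depth averages the per-frame minima", {
  reg <- pore_region(c(3, 3), 0.8)
  traj <- make_traj(list(water_at(-0.4), water_at(-0.5), water_at(-0.6)))
  expect_equal(deepest_water_depth(traj, reg), -0.5, tolerance = 1e-12)

  # a single water above the pore mouth still counts (lateral gate only)
  traj1 <- make_traj(list(water_at(0.3)))
  expect_equal(deepest_water_depth(traj1, reg), 0.3, tolerance = 1e-12)

  # discard fraction drops initial frames
  expect_equal(deepest_water_depth(traj, reg, discard = 0.34), -0.55,
               tolerance = 1e-12)
})

test_that("penetration traces take the species minimum and anchor at t = 0", {
  reg <- pore_region(c(3, 3), 0.8)
  two <- data.frame(molecule_id = 1:2, species = "surfactant", charge = 0L,
                    element = "C", x = 3, y = 3, z = c(-1, -2),
                    stringsAsFactors = FALSE)
  traj <- make_traj(list(two, two))
  tr <- penetration_trace(traj, "surfactant", reg)
  expect_equal(tr$depths, c(-2, -2))
  expect_equal(tr$z0, -2)
  expect_error(penetration_trace(traj, "ai", reg), "absent")

  # noise-free generator round trip
  sim <- simulate_penetration(kinetics_truth(), times = 0:20)
  tr2 <- penetration_trace(sim$trajectory, "surfactant",
                           pore_region(c(3, 3), 0.8))
  expect_equal(tr2$depths, sim$trace$depths, tolerance = 1e-12)
})

test_that("occupancy, net charge, depth and clusters match exhaustive oracles", {
  species <- c("water", "Na", "Cl", "Ca", "ai", "surfactant")
  for (seed in 1:30) {
    f <- random_frame(seed, n_molecules = 60)
    box <- c(6, 6, 20)
    traj <- trajectory(list(f), 0, box)
    reg <- pore_region(c(runif(1, 1, 5), runif(1, 1, 5)),
                       radius = runif(1, 0.5, 2.5),
                       z_top = 0, z_bottom = -10)
    expect_equal(unname(occupancy_counts(traj, reg, species, time = 0)),
                 unname(oracle_occupancy(f, reg, box, species)))
    expect_equal(net_charge_in_region(traj, reg, time = 0),
                 oracle_net_charge(f, reg, box))
    om <- oracle_min_water_z(f, reg, box)
    if (!is.na(om)) {
      expect_equal(deepest_water_depth(traj, reg), om, tolerance = 1e-12)
    }
    cs <- water_clusters(f, cutoff = 0.8, box = box)
    expect_identical(canon_partition(cs$clusters),
                     canon_partition(oracle_clusters(f, cutoff = 0.8, box = box)))
  }
})

test_that("region metrics are invariant under rigid lateral translation", {
  f <- random_frame(99, n_molecules = 80)
  box <- c(6, 6, 20)
  reg <- pore_region(c(3, 3), 1.2, z_bottom = -10)
  traj <- trajectory(list(f), 0, box)
  shift <- c(1.3, -0.7)
  f2 <- f
  f2$x <- (f$x + shift[1]) %% box[1]
  f2$y <- (f$y + shift[2]) %% box[2]
  reg2 <- pore_region(c(3 + shift[1], 3 + shift[2]), 1.2, z_bottom = -10)
  traj2 <- trajectory(list(f2), 0, box)
  sp <- c("water", "Na", "Cl")
  expect_equal(occupancy_counts(traj, reg, sp), occupancy_counts(traj2, reg2, sp))
  expect_equal(net_charge_in_region(traj, reg), net_charge_in_region(traj2, reg2))
  expect_equal(deepest_water_depth(traj, reg), deepest_water_depth(traj2, reg2),
               tolerance = 1e-12)
})

test_that("cluster partition is permutation-invariant and transitive", {
  # a chain of oxygens 0.3 nm apart is one cluster by transitive closure
  n <- 8
  chain <- data.frame(molecule_id = seq_len(n), species = "water",
                      charge = 0L, element = "O",
                      x = 0.3 * seq_len(n), y = 3, z = -2,
                      stringsAsFactors = FALSE)
  cs <- water_clusters(chain, cutoff = 0.35)
  expect_length(cs$clusters, 1)
  expect_length(cs$clusters[[1]], n)

  # spacings straddling the cutoff: {2, 1} pattern
  three <- data.frame(molecule_id = 1:3, species = "water", charge = 0L,
                      element = "O", x = c(0, 0.3, 1.0), y = 0, z = 0,
                      stringsAsFactors = FALSE)
  cs3 <- water_clusters(three, cutoff = 0.35)
  expect_equal(sort(lengths(cs3$clusters)), c(1L, 2L))

  f <- random_frame(7, n_molecules = 120)
  perm <- sample(nrow(f))
  cs1 <- water_clusters(f, cutoff = 0.8, box = c(6, 6, 20))
  cs2 <- water_clusters(f[perm, ], cutoff = 0.8, box = c(6, 6, 20))
  expect_identical(canon_partition(cs1$clusters), canon_partition(cs2$clusters))
})

test_that("bulk connectivity distinguishes discrete pore clusters", {
  pore_cluster <- data.frame(molecule_id = 1:3, species = "water",
                             charge = 0L, element = "O",
                             x = 3, y = 3, z = c(-2.0, -2.3, -2.6),
                             stringsAsFactors = FALSE)
  bulk <- data.frame(molecule_id = 4:5, species = "water", charge = 0L,
                     element = "O", x = 3, y = 3, z = c(0.2, 0.5),
                     stringsAsFactors = FALSE)
  cs <- water_clusters(rbind(pore_cluster, bulk), cutoff = 0.35)
  flags <- cs$bulk_connected[order(vapply(cs$clusters, min, 0L))]
  expect_identical(flags, c(FALSE, TRUE))
})

test_that("density scans conserve counts and localize stationary molecules", {
  one <- data.frame(molecule_id = 1L, species = "ai", charge = 0L,
                    element = "C", x = 2.05, y = 3.55, z = -1,
                    stringsAsFactors = FALSE)
  traj <- make_traj(rep(list(one), 10))
  dm <- density_scan(traj, plane = "top_view", bin_width = 0.1)
  expect_equal(sum(dm$counts$ai), 10)
  expect_equal(max(dm$counts$ai), 10)  # a single occupied bin

  f <- random_frame(3, n_molecules = 100)
  traj2 <- make_traj(list(f, f, f))
  dm2 <- density_scan(traj2, plane = "side_view", bin_width = 0.25)
  expect_equal(sum(vapply(dm2$counts, sum, 0)), 3 * 100)

  # uniform lateral positions spread across bins within 5 sigma
  set.seed(41)
  nb <- 6; npts <- 6000
  u <- data.frame(molecule_id = seq_len(npts), species = "water",
                  charge = 0L, element = "O",
                  x = runif(npts, 0, 6), y = runif(npts, 0, 6), z = 0,
                  stringsAsFactors = FALSE)
  dmu <- density_scan(trajectory(list(u), 0, c(6, 6, 20)),
                      plane = "top_view", bin_width = 1)
  p <- 1 / 36
  sigma <- sqrt(npts * p * (1 - p))
  expect_true(all(abs(dmu$counts$water - npts * p) < 5 * sigma))
})

test_that("metric error contracts: absent species, bad times, empty input", {
  reg <- pore_region(c(3, 3), 0.8)
  traj <- make_traj(list(water_at(-0.4)))
  expect_error(occupancy_counts(traj, reg, "water", time = 99), "outside")
  expect_error(net_charge_in_region(traj, reg, time = -5), "outside")
  nowater <- data.frame(molecule_id = 1L, species = "Na", charge = 1L,
                        element = "Na", x = 3, y = 3, z = 0,
                        stringsAsFactors = FALSE)
  expect_error(deepest_water_depth(make_traj(list(nowater)), reg), "no water")
})
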