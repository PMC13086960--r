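# Wax slab construction: chain geometry, lattice tiling, pore carving,
# carboxylate functionalization.

test_that("all-trans chain geometry follows the bond/angle closed forms", {
  lat <- lattice_spec()
  rise <- 0.154 * sin(114 / 2 * pi / 180)
  expect_equal(axial_rise(lat), rise, tolerance = 1e-12)

  xyz <- build_chain(lat)
  expect_equal(nrow(xyz), 30)
  # axial rise between consecutive carbons and end-to-end backbone length
  expect_equal(abs(diff(xyz[, 3])), rep(rise, 29), tolerance = 1e-12)
  expect_equal(unname(abs(xyz[30, 3] - xyz[1, 3])), 29 * rise,
               tolerance = 1e-9)
  expect_equal(29 * rise, 3.745, tolerance = 1e-3)
  # every bond has the nominal C-C length
  bonds <- sqrt(rowSums((xyz[-1, , drop = FALSE] - xyz[-30, , drop = FALSE])^2))
  expect_equal(bonds, rep(0.154, 29), tolerance = 1e-12)

  # degenerate single-site chain and the two-carbon bond identity
  one <- build_chain(lattice_spec(carbons_per_chain = 1))
  expect_equal(dim(one), c(1L, 3L))
  expect_equal(max(one) - min(one), 0)
  two <- build_chain(lattice_spec(carbons_per_chain = 2))
  expect_equal(sqrt(sum((two[2, ] - two[1, ])^2)), 0.154, tolerance = 1e-12)
})

test_that("non-physical bond lengths and angles are rejected", {
  expect_error(lattice_spec(cc_bond = 0), "positive")
  expect_error(lattice_spec(ccc_angle = 0), "between 0 and 180")
  expect_error(lattice_spec(ccc_angle = 180), "between 0 and 180")
})

test_that("slab tiling rounds the lateral target to whole subcells", {
  slab <- default_flat_slab()
  expect_equal(slab$provenance$nx, 8)
  expect_equal(slab$provenance$ny, 12)
  expect_equal(length(unique(slab$atoms$chain_id)), 192)
  expect_equal(slab$box[1], 5.936, tolerance = 1e-9)
  expect_equal(slab$box[2], 5.952, tolerance = 1e-9)

  small <- build_crystal_slab(c(3, 3))
  expect_equal(small$provenance$nx, 4)
  expect_equal(small$provenance$ny, 6)
  expect_equal(length(unique(small$atoms$chain_id)), 48)

  one <- build_crystal_slab(c(0.742, 0.496))
  expect_equal(length(unique(one$atoms$chain_id)), 2)

  expect_error(build_crystal_slab(c(0.1, 0.1)), "smaller than one subcell")
})

test_that("chains are perpendicular, CH3-terminated, and define z = 0", {
  slab <- default_flat_slab()
  a <- slab$atoms
  expect_equal(max(a$z), 0, tolerance = 1e-12)
  expect_true(all(a$z <= 1e-12))
  # terminal carbons labeled CH3, interior CH2, 2 + 28 per chain
  per_chain <- table(a$group_label, a$chain_id)
  expect_true(all(per_chain["CH3", ] == 2))
  expect_true(all(per_chain["CH2", ] == 28))
  # lateral extent of each chain stays within the zig-zag amplitude
  amp <- 0.154 * cos(114 / 2 * pi / 180)
  spread <- tapply(a$x, a$chain_id, function(v) max(v) - min(v))
  expect_true(all(spread <= amp + 1e-9))
})

test_that("chain areal density and nearest-neighbor spacing match the subcell", {
  slab <- default_flat_slab()
  ax <- slab$provenance$chain_axes
  density <- nrow(ax) / (slab$box[1] * slab$box[2])
  expect_equal(density, 2 / (0.742 * 0.496), tolerance = 1e-12)
  # nearest neighbor of every chain axis is the herringbone half-diagonal
  d_expect <- sqrt((0.742 / 2)^2 + (0.496 / 2)^2)
  nn <- vapply(seq_len(nrow(ax)), function(i) {
    d <- oracle_lat_dist(ax$x[-i], ax$y[-i], c(ax$x[i], ax$y[i]), slab$box)
    min(d)
  }, 0)
  expect_equal(nn, rep(d_expect, nrow(ax)), tolerance = 1e-9)
})

test_that("by-count carving removes the 14 nearest chains in every layer", {
  carved <- carve_pore(default_pore_slab(), pore_spec())
  expect_equal(carved$removed, rep(14L, 4))
  expect_equal(length(unique(carved$model$atoms$chain_id)),
               4 * 192 - 4 * 14)
})

test_that("carving is a pure deletion and n_remove = 0 is the identity", {
  slab <- default_pore_slab()
  carved <- carve_pore(slab, pore_spec())$model
  kept <- slab$atoms$chain_id %in% unique(carved$atoms$chain_id)
  expect_identical(carved$atoms[, c("x", "y", "z", "chain_id", "group_label")],
                   {
                     d <- slab$atoms[kept, c("x", "y", "z", "chain_id", "group_label")]
                     rownames(d) <- NULL
                     d
                   })
  intact <- carve_pore(slab, pore_spec(n_remove = 0))
  expect_equal(intact$removed, rep(0L, 4))
  expect_identical(intact$model$atoms, slab$atoms)
})

test_that("by-radius carving matches brute-force enumeration of chain axes", {
  slab <- default_flat_slab()
  ax <- slab$provenance$chain_axes
  # zero accessible radius centered between lattice sites removes nothing
  center <- c(ax$x[1] + 0.18, ax$y[1] + 0.12)
  none <- carve_pore(slab, pore_spec(mode = "by_radius", accessible_radius = 0,
                                     methyl_radius = 0, center = center,
                                     depth = 4))
  expect_equal(none$removed, 0L)

  # cut radius 0.95 nm centered on a chain site: exhaustive distance check
  center <- c(ax$x[25], ax$y[25])
  cut <- 0.95
  spec <- pore_spec(mode = "by_radius", accessible_radius = cut - 0.20,
                    methyl_radius = 0.20, center = center, depth = 4)
  got <- carve_pore(slab, spec)
  expected <- sum(oracle_lat_dist(ax$x, ax$y, center, slab$box) <= cut)
  expect_equal(got$removed, expected)
  expect_gt(expected, 0)
})

test_that("removed-chain count is monotone in the accessible radius", {
  slab <- default_flat_slab()
  center <- slab$box[1:2] / 2
  radii <- seq(0, 1.6, by = 0.08)
  counts <- vapply(radii, function(r) {
    carve_pore(slab, pore_spec(mode = "by_radius", accessible_radius = r,
                               center = center, depth = 4))$removed
  }, 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("pore depth must not exceed the slab thickness", {
  expect_error(carve_pore(default_flat_slab(), pore_spec(depth = 15)),
               "exceeds slab thickness")
  expect_error(carve_pore(default_pore_slab(), pore_spec(n_remove = 200)),
               "chains per layer")
})

test_that("COO- replacement counts and charges follow the carbon fraction", {
  slab <- default_flat_slab()  # 192 C30 chains = 5760 carbons
  f15 <- functionalize_surface(slab, functionalization_spec(fraction = 0.015))
  expect_equal(sum(f15$atoms$group_label == "COO"), 86)
  expect_equal(total_charge(f15), -86L)

  f05 <- functionalize_surface(slab, functionalization_spec(fraction = 0.005))
  expect_equal(sum(f05$atoms$group_label == "COO"), 29)
  expect_equal(total_charge(f05), -29L)

  # identity at zero fraction
  f0 <- functionalize_surface(slab, functionalization_spec(fraction = 0))
  expect_identical(f0$atoms, slab$atoms)

  # COOH replacement never changes the total charge
  fh <- functionalize_surface(slab, functionalization_spec(
    group = "COOH", fraction = 0.015))
  expect_equal(sum(fh$atoms$group_label == "COOH"), 86)
  expect_equal(total_charge(fh), 0L)
})

test_that("functionalization respects face capacity and the seed", {
  slab <- default_flat_slab()
  expect_error(
    functionalize_surface(slab, functionalization_spec(fraction = 0.05)),
    "only .* terminal CH3 sites"
  )
  a <- functionalize_surface(slab, functionalization_spec(fraction = 0.01, seed = 9))
  b <- functionalize_surface(slab, functionalization_spec(fraction = 0.01, seed = 9))
  c <- functionalize_surface(slab, functionalization_spec(fraction = 0.01, seed = 10))
  expect_identical(a$atoms, b$atoms)
  expect_false(identical(a$atoms$group_label, c$atoms$group_label))
  # replacements sit on the top face only
  repl <- a$atoms[a$atoms$group_label == "COO", ]
  expect_true(all(repl$z > -0.01))
})

test_that("pore-wall functionalization stays near the pore axis", {
  carved <- carve_pore(default_pore_slab(), pore_spec())$model
  fw <- functionalize_surface(carved, functionalization_spec(
    fraction = 0.0005, face = "pore_wall", seed = 2))
  repl <- fw$atoms[fw$atoms$group_label == "COO", ]
  expect_gt(nrow(repl), 0)
  center <- carved$provenance$pore$center
  d <- oracle_lat_dist(repl$x, repl$y, center, carved$box)
  expect_true(all(d <= 0.775 + 0.20 + 0.5 + 1e-9))
})
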