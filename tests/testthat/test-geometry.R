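test_that("two-sinusoid perturbation follows the analytic rule", {
  ref <- const_ref(r0 = 2)
  # zero amplitudes and offsets leave the baseline untouched
  expect_identical(perturb_radius(ref, perturbation_params()), ref$r0)
  # single sinusoid a=0.1, f=1, phi=0: at s = L/4 the bracket is 1.1
  p <- perturbation_params(a = c(0.1, 0), f = c(1, 1))
  wide <- list(a_max = 0.1, d_max = 0.03, f_min = 0.5, f_max = 2.5)
  r <- perturb_radius(ref, p, bounds = wide)
  i_quarter <- which.min(abs(ref$s - ref$length / 4))
  expect_equal(r[i_quarter], 1.1 * 2, tolerance = 1e-12)
  expect_true(all(r > 0))
})

test_that("radius deviation is bounded by the parameter magnitudes", {
  ref <- coarse_refs(1L, n_ax = 201L)[[1L]]
  bounds <- perturbation_bounds()
  set.seed(11)
  for (i in 1:100) {
    p <- draw_perturbation(bounds)
    r <- perturb_radius(ref, p, bounds)
    bound <- sum(abs(p$a)) + sum(abs(p$d))
    expect_lte(max(abs(r / ref$r0 - 1)), bound + 1e-12)
  }
})

test_that("invalid perturbations are rejected", {
  ref <- const_ref()
  expect_error(perturb_radius(ref, perturbation_params(a = c(0.5, 0))),
               "outside bounds")
  expect_error(perturb_radius(ref, perturbation_params(f = c(10, 1))),
               "outside bounds")
  # parameters within (artificially loose) bounds but driving r <= 0
  loose <- list(a_max = 2, d_max = 2, f_min = 0.5, f_max = 2.5)
  expect_error(
    perturb_radius(ref, perturbation_params(d = c(-0.8, -0.4)), bounds = loose),
    "non-positive")
  expect_error(perturbation_bounds(a_max = 0.3, d_max = 0.3), "too large")
})

test_that("structured tube meshing has the frozen counts and ordering", {
  ref <- reference_vessel("T", c(0, 1, 2), c(1, 1, 1), n_circ = 4L, n_rad = 1L)
  g <- build_mesh(ref$r0, ref)
  expect_equal(g$n_surface, 12L)
  expect_equal(g$n_volume, 15L)
  expect_equal(dim(g$surface), c(12L, 3L))
  expect_equal(dim(g$volume), c(15L, 3L))
  # every surface node sits at its station radius from the x-axis
  d <- sqrt(g$surface[, 2]^2 + g$surface[, 3]^2)
  expect_equal(d, rep(1, 12L), tolerance = 1e-12)
  # station-major ordering
  expect_equal(g$surface_station, rep(1:3, each = 4L))
  expect_equal(g$volume_station, rep(1:3, each = 5L))
  # volume block per station: axis node first, then the interior ring
  expect_equal(g$volume[1, ], c(x = 0, y = 0, z = 0))
  ring_r <- sqrt(g$volume[2:5, 2]^2 + g$volume[2:5, 3]^2)
  expect_equal(ring_r, rep(0.5, 4L), tolerance = 1e-12)  # r * 1/(n_rad+1)
})

test_that("topology is constant across geometries at one resolution", {
  ref <- coarse_refs(1L)[[1L]]
  set.seed(3)
  g1 <- build_mesh(perturb_radius(ref, draw_perturbation()), ref, "a")
  g2 <- build_mesh(perturb_radius(ref, draw_perturbation()), ref, "b")
  expect_identical(dim(g1$surface), dim(g2$surface))
  expect_identical(dim(g1$volume), dim(g2$volume))
  expect_identical(g1$surface_station, g2$surface_station)
  expect_identical(g1$volume_station, g2$volume_station)
  expect_error(build_mesh(rep(-1, ref$n_ax), ref), "positive")
  expect_error(build_mesh(c(1, 2), ref), "match")
})

test_that("dataset generation counts and reproducibility", {
  refs <- coarse_refs(2L)
  ds <- generate_dataset(refs, 3L, seed = 9L)
  expect_length(ds, 8L)            # |refs| * (n_perturb + 1)
  expect_s3_class(ds[[1L]], "vessel_geometry")
  # each reference's first entry is the unperturbed original
  expect_equal(ds[[1L]]$r, refs[[1L]]$r0)
  expect_equal(ds[[5L]]$r, refs[[2L]]$r0)
  # n_perturb = 0 returns just the references
  ds0 <- generate_dataset(refs[1L], 0L, seed = 9L)
  expect_length(ds0, 1L)
  expect_equal(ds0[[1L]]$r, refs[[1L]]$r0)
  # bitwise reproducibility from the seed
  ds2 <- generate_dataset(refs, 3L, seed = 9L)
  expect_identical(lapply(ds, `[[`, "r"), lapply(ds2, `[[`, "r"))
  expect_identical(dataset_params(ds), dataset_params(ds2))
  ds3 <- generate_dataset(refs, 3L, seed = 10L)
  expect_false(identical(lapply(ds, `[[`, "r"), lapply(ds3, `[[`, "r")))
  # parameter log covers every mesh
  expect_equal(dataset_params(ds)$mesh_id,
               vapply(ds, `[[`, "", "mesh_id"))
})

test_that("profile-only datasets carry no coordinates but full topology", {
  ds <- generate_dataset(coarse_refs(1L), 2L, seed = 5L, nodes = FALSE)
  expect_null(ds[[1L]]$surface)
  expect_length(ds[[2L]]$surface_station, ds[[2L]]$n_surface)
  sol <- solve_flow(ds[[2L]])   # solver works without coordinates
  expect_length(sol$pressure, ds[[2L]]$n_volume)
})

test_that("geometry exports round-trip", {
  g <- build_mesh(const_ref()$r0, const_ref(), "t")
  tmp <- withr::local_tempdir()
  csv <- file.path(tmp, "r.csv")
  write_radius_csv(g, csv)
  back <- read.csv(csv)
  expect_equal(back$r_mm, g$r)
  expect_equal(back$s_mm, g$s)
  vtk_s <- file.path(tmp, "s.vtk")
  write_vtk_surface(g, vtk_s, point_data = list(wss_Pa = seq_len(g$n_surface)))
  lines <- readLines(vtk_s)
  expect_equal(lines[4], "DATASET POLYDATA")
  expect_equal(lines[5], sprintf("POINTS %d double", g$n_surface))
  expect_true(any(grepl("SCALARS wss_Pa", lines)))
  vtk_v <- file.path(tmp, "v.vtk")
  write_vtk_volume(g, vtk_v)
  expect_true(any(grepl(sprintf("POINTS %d double", g$n_volume),
                        readLines(vtk_v))))
})
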