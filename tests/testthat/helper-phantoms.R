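# Shared fixtures, built in code at test time.

# small parallel-plate phantom: quick to register and measure
small_plate <- function(extent = c(10, 10), gap = 3, spacing = 1,
                        seed = 1L, jitter = 0.2) {
  make_cartilage_phantom(phantom_spec(
    "parallel_plate", list(extent = extent, gap = gap, spacing = spacing,
                           jitter = jitter),
    seed = seed))
}

small_paraboloid <- function(spacing = 0.5, seed = 1L, jitter = 0.2) {
  make_cartilage_phantom(phantom_spec(
    "paraboloid_cartilage",
    list(extent = c(30, 30), spacing = spacing, apex = 4, R = 20,
         floor_mm = 0.2, jitter = jitter),
    seed = seed))
}

expect_transform_equal <- function(a, b, tol = 1e-6) {
  expect_lt(max(abs(a$rotation - b$rotation)), tol)
  expect_lt(max(abs(a$translation - b$translation)), tol)
}
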