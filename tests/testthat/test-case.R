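test_that("case configuration rejects degenerate geometry", {
  expect_error(case_config(pocket_width = 0), "pocket")
  expect_error(case_config(pocket_length = 0), "pocket")
  expect_error(case_config(h = -1), "spacing")
  expect_error(case_config(h = 0.0007), "does not divide")
  expect_error(case_config(dt_max = 2), "dt_max")
  expect_error(case_config(n_inlets = 0), "n_inlets")
  # both NA is a legitimate pocket-free channel
  expect_s3_class(channel_case(), "case_config")
})

test_that("mesh counts, patches and region tags match the configuration", {
  cfg <- case_config(chamber_length = 0.04, chamber_height = 0.02,
                     h = 0.001)
  m <- build_mesh(cfg)
  expect_equal(sum(m$region == "chamber"), 800)
  expect_gt(sum(m$region == "pocket"), 0)
  expect_setequal(unique(m$bpatch),
                  c(m$inlet_patches, "outlet", "wall"))
  for (p in m$inlet_patches) expect_gt(sum(m$bpatch == p), 0)
  # equal inlet areas
  areas <- vapply(m$inlet_patches,
                  function(p) sum(m$barea[m$bpatch == p]), numeric(1))
  expect_true(all(abs(areas - areas[1]) < 1e-15))
})

test_that("mesh closure and normalization invariants hold", {
  for (cfg in list(case_config(), toy_case(), channel_case())) {
    m <- build_mesh(cfg)
    expect_true(check_mesh(m))
    expect_lt(abs(sum(m$bnx * m$barea)), 1e-10)
    expect_lt(abs(sum(m$bny * m$barea)), 1e-10)
    expect_lt(max(abs(m$bnx^2 + m$bny^2 - 1)), 1e-12)
  }
})

test_that("pocket cells are disjoint from the chamber and edge-connected", {
  m <- build_mesh(toy_case())
  pocket <- which(m$region == "pocket")
  chamber <- which(m$region == "chamber")
  expect_length(intersect(pocket, chamber), 0)
  expect_equal(sort(c(pocket, chamber)), seq_len(m$n_cells))
  # connectivity via interior-face adjacency restricted to pocket cells
  inpocket <- m$fo %in% pocket & m$fn %in% pocket
  reach <- pocket[1]
  repeat {
    grow <- unique(c(m$fn[inpocket & m$fo %in% reach],
                     m$fo[inpocket & m$fn %in% reach]))
    new <- union(reach, grow)
    if (length(new) == length(reach)) break
    reach <- new
  }
  expect_setequal(reach, pocket)
})

test_that("outlet waveform scales linearly, is periodic, and integrates to the stroke volume", {
  cfg <- case_config()
  tt <- seq(0, cfg$period, length.out = 211)
  expect_equal(mv_waveform(tt, 1.0, cfg) * 2, mv_waveform(tt, 2, cfg) |>
                 suppressWarnings())
  expect_identical(mv_waveform(0, 0.7, cfg), mv_waveform(cfg$period, 0.7, cfg))
  q <- stats::integrate(function(t) mv_waveform(t, 1, cfg), 0, cfg$period,
                        subdivisions = 2000L, rel.tol = 1e-10)
  expect_equal(q$value, cfg$stroke_volume, tolerance = 1e-8)
  # closed phase before the opening time, pulse afterwards
  expect_equal(mv_waveform(0.3 * cfg$period, 1, cfg), 0)
  expect_gt(mv_waveform(0.7 * cfg$period, 1, cfg), 0)
  expect_warning(mv_waveform(0.5, 2, cfg), "outside")
})

test_that("inflow is split equally across inlets and conserves the total", {
  m <- build_mesh(case_config(n_inlets = 4))
  sp <- inlet_split(4e-5, m)
  expect_equal(nrow(sp), 4)
  expect_true(all(sp$rate == 1e-5))
  expect_lt(abs(sum(sp$rate) - 4e-5) / 4e-5, 1e-15)
  m1 <- build_mesh(case_config(n_inlets = 1))
  expect_equal(inlet_split(4e-5, m1)$rate, 4e-5)
})
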