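# minimal fixture: a short wall segment and a few membrane points
adh_fixture <- function(cell_y = um(0.6)) {
  wall <- data.frame(id = 1:9, x = um(0:8), y = 0,
                     tag = "wall_bottom", outer = FALSE)
  cell <- data.frame(id = 1:3, x = um(c(2.1, 4.0, 6.2)), y = cell_y,
                     tag = "cortex", outer = TRUE)
  list(cell = cell, wall = wall)
}

test_that("links form only within the capture radius, to the nearest wall point", {
  fx <- adh_fixture(cell_y = um(0.6))
  p <- adhesion_params(r_on = um(0.75), L_A = um(0.5))
  st <- update_adhesions(fx$cell, fx$wall, adhesion_state(), p, t = 0)
  # y gap 0.6 < 0.75: the points directly above a wall point bind
  expect_equal(nrow(st$links), 3)
  expect_equal(st$links$wall, c(3, 5, 7))  # nearest in x (wall ids at 2,4,6 um)
  expect_true(all(st$events$event == "create"))
  # far cell: nothing happens
  fx2 <- adh_fixture(cell_y = um(3))
  st2 <- update_adhesions(fx2$cell, fx2$wall, adhesion_state(), p, t = 0)
  expect_equal(nrow(st2$links), 0)
  expect_equal(nrow(st2$events), 0)
})

test_that("a pair links at most once and per-point link count is capped", {
  fx <- adh_fixture()
  p <- adhesion_params(r_on = um(0.75), L_A = um(0.5), max_links = 1)
  st <- update_adhesions(fx$cell, fx$wall, adhesion_state(), p, t = 0)
  st <- update_adhesions(fx$cell, fx$wall, st, p, t = 1e-4)
  expect_equal(nrow(st$links), 3)
  expect_false(any(duplicated(st$links[c("cell", "wall")])))
  expect_lte(max(tabulate(st$links$cell)), 1)
})

test_that("links break exactly above the strain threshold and are logged", {
  p <- adhesion_params(r_on = um(0.75), lambda_break = 2, L_A = um(0.5))
  thresh <- 2 * um(0.5)
  wall <- data.frame(id = 1L, x = 0, y = 0, tag = "wall_bottom")
  mk_cell <- function(len) data.frame(id = 1L, x = 0, y = len,
                                      tag = "cortex", outer = TRUE)
  st0 <- adhesion_state()
  st0$links <- data.frame(cell = 1L, wall = 1L, birth = 0)
  eps <- um(0.01)
  kept <- update_adhesions(mk_cell(thresh - eps), wall, st0, p, t = 1)
  expect_equal(nrow(kept$links), 1)
  gone <- update_adhesions(mk_cell(thresh + eps), wall, st0, p, t = 1)
  expect_equal(nrow(gone$links), 0)
  expect_equal(gone$events$event, "break")
  expect_equal(gone$events$length, thresh + eps)
  expect_equal(gone$events$time, 1)
})

test_that("adhesive forces are Hookean action-reaction pairs", {
  wall <- data.frame(id = 1L, x = 0, y = 0, tag = "wall_bottom")
  cell <- data.frame(id = 1L, x = 0, y = 1e-4, tag = "cortex",
                     outer = TRUE)
  st <- adhesion_state()
  # empty state: zero forces
  f0 <- adhesion_forces(st, cell, wall, S_A = 50, L_A = 0)
  expect_equal(max(abs(f0$cell), abs(f0$wall)), 0)
  st$links <- data.frame(cell = 1L, wall = 1L, birth = 0)
  # stretched zero-rest-length link: S * length, pulling together
  f <- adhesion_forces(st, cell, wall, S_A = 50, L_A = 0)
  expect_equal(f$cell[1, ], c(0, -5e-3))
  expect_equal(f$wall[1, ], c(0, 5e-3))
  expect_equal(f$cell + f$wall, matrix(0, 1, 2))
  # at rest length: no force
  fr <- adhesion_forces(st, cell, wall, S_A = 50, L_A = 1e-4)
  expect_equal(max(abs(fr$cell)), 0)
  # dangling reference errors out
  st$links$wall <- 5L
  expect_error(adhesion_forces(st, cell, wall, 50, 0), "missing point")
})

test_that("cortex softens near focal adhesions and recovers on release", {
  cell <- default_cell()
  st <- adhesion_state()
  # no links: everything at base stiffness
  net <- remodel_cortex(cell$cortex, cell$points, st)
  expect_true(all(net$mult == 1))
  # adhere the lowest outer point
  low <- which.min(cell$points$y + ifelse(cell$points$outer, 0, 1))
  st$links <- data.frame(cell = low, wall = 1L, birth = 0)
  net1 <- remodel_cortex(cell$cortex, cell$points, st, m_soft = 1 / 3,
                         r_soft = um(1.5))
  soft <- net1$mult < 1
  expect_gt(sum(soft), 0)
  expect_lt(sum(soft), nrow(net1))
  # exactly the springs with an endpoint within r_soft are softened
  d_i <- sqrt((cell$points$x[net1$i] - cell$points$x[low])^2 +
              (cell$points$y[net1$i] - cell$points$y[low])^2)
  d_j <- sqrt((cell$points$x[net1$j] - cell$points$x[low])^2 +
              (cell$points$y[net1$j] - cell$points$y[low])^2)
  expect_equal(soft, d_i < um(1.5) | d_j < um(1.5))
  # idempotent
  expect_equal(remodel_cortex(net1, cell$points, st), net1)
  # broken adhesion: stiffness restored immediately
  st$links <- st$links[0, ]
  expect_true(all(remodel_cortex(net1, cell$points, st)$mult == 1))
})

test_that("bond bookkeeping keeps event times ordered", {
  fx <- adh_fixture()
  p <- adhesion_params(r_on = um(0.75), L_A = um(0.5))
  st <- update_adhesions(fx$cell, fx$wall, adhesion_state(), p, t = 0)
  # drag the cell away in stages; breaks must carry later times
  cell <- fx$cell
  cell$y <- cell$y + um(1)
  st <- update_adhesions(cell, fx$wall, st, p, t = 2e-4)
  expect_true(all(diff(st$events$time) >= 0))
  br <- st$events[st$events$event == "break", ]
  for (k in seq_len(nrow(br))) {
    cr <- st$events$time[st$events$event == "create" &
                         st$events$cell == br$cell[k]]
    expect_true(all(br$time[k] > cr))
  }
})
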