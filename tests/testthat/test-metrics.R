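circle_xy <- function(n = 128, r = 1, ctr = c(0, 0)) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(ctr[1] + r * cos(th), ctr[2] + r * sin(th))
}

test_that("shape metrics recover circle, square, and ellipse benchmarks", {
  m <- shape_metrics(circle_xy(128))
  expect_equal(m$circularity, 1, tolerance = 1e-3)
  expect_equal(m$area, pi, tolerance = 1e-3)
  expect_equal(m$major, 2, tolerance = 1e-2)
  expect_equal(m$aspect, 1, tolerance = 1e-6)
  # unit square with points along the edges: 4 pi / 16
  s <- seq(0, 1, by = 0.05); s1 <- s[-length(s)]
  sq <- rbind(cbind(s1, 0), cbind(1, s1), cbind(1 - s1, 1),
              cbind(0, 1 - s1))
  ms <- shape_metrics(sq)
  expect_equal(ms$circularity, pi / 4, tolerance = 1e-9)
  # 2:1 ellipse: perimeter by quadrature ~ 9.6884, circ = 4 pi A / P^2
  th <- 2 * pi * (seq_len(4096) - 1) / 4096
  el <- cbind(2 * cos(th), sin(th))
  me <- shape_metrics(el)
  p_exact <- 9.688448
  expect_equal(me$perimeter, p_exact, tolerance = 1e-5)
  expect_equal(me$circularity, 4 * pi * (2 * pi) / p_exact^2,
               tolerance = 1e-4)
  expect_equal(me$aspect, 2, tolerance = 1e-2)
})

test_that("shape metrics are rigid-motion invariant and stretch-sensitive", {
  set.seed(12)
  xy <- circle_xy(100, r = 5e-4, ctr = c(1e-3, 2e-3))
  m0 <- shape_metrics(xy)
  for (k in 1:5) {
    th <- runif(1, 0, 2 * pi); tr <- runif(2, -1e-3, 1e-3)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    m1 <- shape_metrics(sweep(xy %*% t(R), 2, -tr))
    expect_equal(m1$area, m0$area, tolerance = 1e-12)
    expect_equal(m1$perimeter, m0$perimeter, tolerance = 1e-12)
    expect_equal(m1$circularity, m0$circularity, tolerance = 1e-12)
  }
  # area-preserving stretch strictly lowers circularity, monotonically
  circ_of <- function(s) shape_metrics(
    cbind(xy[, 1] * s, xy[, 2] / s))$circularity
  cs <- vapply(c(1, 1.2, 1.5, 2, 3), circ_of, numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("self-intersecting contours are flagged and can be rejected", {
  bow <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(shape_metrics(bow, check_simple = TRUE), "self-intersect")
  expect_true(shape_metrics(bow)$clasmatosis_flag)
  expect_false(shape_metrics(circle_xy(64))$clasmatosis_flag)
})

# synthetic trajectory: a marked ring rigidly transformed between snapshots
synthetic_traj <- function(angles, shifts = NULL, n = 48) {
  r <- um(5); ctr0 <- c(um(20), um(15))
  if (is.null(shifts)) shifts <- rep(0, length(angles))
  snaps <- lapply(seq_along(angles), function(k) {
    th <- 2 * pi * (seq_len(n) - 1) / n
    x <- ctr0[1] + shifts[k] + r * cos(th + angles[k])
    y <- ctr0[2] + r * sin(th + angles[k])
    data.frame(time = (k - 1) * 1e-3, id = seq_len(n), tag = "cortex",
               x = x, y = y, outer = TRUE,
               marker = seq_len(n) <= 4, structure_group = "cell",
               adh = 0L)
  })
  structure(list(times = (seq_along(angles) - 1) * 1e-3,
                 snapshots = snaps,
                 links = rep(0L, length(angles)),
                 events = NULL, config = sim_config()),
            class = "ctc_trajectory")
}

test_that("marker rotation tracks rigid rotation and ignores translation", {
  traj <- synthetic_traj(angles = rep(0, 5), shifts = um(c(0, 2, 4, 6, 8)))
  expect_equal(marker_rotation(traj), 0, tolerance = 1e-9)
  rot <- synthetic_traj(angles = seq(0, pi / 2, length.out = 9))
  expect_equal(marker_rotation(rot), pi / 2, tolerance = 1e-6)
  # unwrapping across many turns, in the negative direction
  spin <- synthetic_traj(angles = seq(0, -3 * pi, length.out = 25))
  expect_equal(marker_rotation(spin), -3 * pi, tolerance = 1e-6)
})

test_that("mode classification is deterministic and labels clear regimes", {
  # free drift at the local flow speed, no adhesion at all -> floating
  cfg <- sim_config()
  u <- cfg$fluid$u_max
  drift <- synthetic_traj(angles = rep(0, 9),
                          shifts = u * (0:8) * 1e-3)
  drift$config$adhesion$enabled <- FALSE
  md <- classify_mode(drift)
  expect_equal(md$label, "floating")
  expect_identical(classify_mode(drift), md)
  # pinned cell with persistent links -> anchoring
  anchored <- synthetic_traj(angles = rep(0, 9))
  anchored$links <- rep(5L, 9)
  expect_equal(classify_mode(anchored)$label, "anchoring")
})

test_that("stiffness signature reports per-mode effective stiffness", {
  base <- sim_config()
  mk <- function(kC, kN, S_A_on, mult_soft = NULL) {
    tr <- synthetic_traj(angles = rep(0, 5))
    tr$config$stiffness$kC <- kC
    tr$config$stiffness$kN <- kN
    tr$multipliers <- lapply(1:5, function(i) {
      mv <- rep(1, 50)
      if (!is.null(mult_soft)) mv[1:10] <- mult_soft
      mv
    })
    if (S_A_on) tr$links <- rep(3L, 5)
    tr
  }
  runs <- list(floating = mk(3, 3, FALSE),
               rolling = mk(6, 6, TRUE),
               crawling = mk(3, 6, TRUE, mult_soft = 1 / 3))
  expect_warning(tab <- stiffness_signature(runs), "anchoring")
  expect_equal(tab$cortex_S[tab$mode == "rolling"], 300)
  expect_equal(tab$adhesion_S[tab$mode == "floating"], 0)
  crw <- tab[tab$mode == "crawling", ]
  expect_lt(crw$cortex_near_adhesion_S, crw$cortex_S)
})
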