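test_that("preprocessing recentres, trims to onset, and resamples to 21 points", {
  # radii 2, 4, 6, ...: onset at the first sample beyond 5 px (radius 6)
  raw <- data.frame(x = seq(0, 20, by = 2), y = 0)
  pp <- preprocess_trajectory(raw)
  expect_equal(nrow(pp), 21L)
  expect_false(attr(pp, "no_movement"))
  expect_equal(pp$x[1], 6)               # trajectory starts at onset
  expect_equal(pp$x[21], 20)
  # recentring: an offset start position changes nothing
  pp2 <- preprocess_trajectory(transform(raw, x = x + 300, y = y - 100))
  expect_equal(pp2$x, pp$x)
  expect_equal(pp2$y, pp$y)
  # a cursor that never leaves the 5 px radius is flagged
  still <- preprocess_trajectory(data.frame(x = c(0, 1, 2), y = c(0, 1, 0)))
  expect_true(attr(still, "no_movement"))
  expect_true(all(is.na(still$x)))
})

test_that("timestamps drive time normalization when present", {
  # same path, uneven sampling in time: late samples compressed
  raw <- data.frame(x = c(0, seq(10, 100, by = 10)), y = 0,
                    t_ms = c(0, 10, 20, 30, 40, 50, 60, 70, 80, 90, 1000))
  pp <- preprocess_trajectory(raw)
  # at 50% of wall-clock time the cursor is already near x = 100
  expect_gt(pp$x[11], 90)
  ppi <- preprocess_trajectory(raw[, c("x", "y")])
  expect_lt(ppi$x[11], 70)
})

test_that("destination vectors recover headings on the arc", {
  # straight ray toward point p: all 20 destinations equal p
  for (p in c(10, 45, 72)) {
    pp <- preprocess_trajectory(straight_traj(p))
    dv <- destination_vectors(pp)
    expect_length(dv, 20L)
    expect_true(all(abs(dv - p) < 1e-9))
  }
  # step along +x heads at the scale midpoint 45.5
  pp <- preprocess_trajectory(data.frame(x = seq(0, 200, length.out = 22),
                                         y = 0))
  dv <- destination_vectors(pp)
  expect_true(all(abs(dv - 45.5) < 1e-9))
  # heading away from the scale (leftwards) gives missing values
  away <- preprocess_trajectory(data.frame(x = seq(0, -200, length.out = 22),
                                           y = 0))
  expect_true(all(is.na(destination_vectors(away))))
})

test_that("destinations are equivariant under joint rotation", {
  # rotating the trajectory by delta degrees (staying on the scale)
  # shifts every destination by delta/2 confidence points
  p <- 30; delta <- 20
  rot <- function(df, deg) {
    a <- deg * pi / 180  # clockwise
    data.frame(x = df$x * cos(a) + df$y * sin(a),
               y = -df$x * sin(a) + df$y * cos(a))
  }
  base <- straight_traj(p)
  dv0 <- destination_vectors(preprocess_trajectory(base))
  dv1 <- destination_vectors(preprocess_trajectory(rot(base, delta)))
  expect_equal(dv1, dv0 + delta / 2, tolerance = 1e-9)
})

test_that("zero-length steps carry the previous destination forward", {
  tr <- straight_traj(60)
  tr[10:12, ] <- tr[10, ]                # stall mid-flight
  dv <- destination_vectors(preprocess_trajectory(tr))
  expect_length(dv, 20L)
  expect_true(all(abs(dv - 60) < 1e-6))
})

test_that("two-phase synthetic trajectories shift their modal destination at the switch", {
  trials <- data.frame(subject_id = "s1", group = "experienced",
                       condition = "short_first", pathology = "abnormal",
                       rating = 88L,
                       trajectory_id = sprintf("t%02d", 1:30))
  td <- trajectory_design(early_target = 50, late_target = 88,
                          switch_time = 0.5, heading_noise = 2,
                          samples_per_trial = 81L, seed = 9L)
  tj <- simulate_trajectories(td, trials)
  fields <- destination_fields(tj)
  early <- fields$conf[fields$step <= 9]
  late <- fields$conf[fields$step >= 12]
  expect_equal(median(early, na.rm = TRUE), 50, tolerance = 0.1)
  expect_gt(median(late, na.rm = TRUE), 80)
  # modal confidence bin jumps across the switch (the transition ray
  # itself may re-aim off-scale and yields an empty row)
  m <- aggregate_distributions(fields)
  expect_lt(which.max(m[9, ]), which.max(m[11, ]))
  filled <- rowSums(m) > 0
  expect_true(all(filled[c(1:9, 11:20)]))
  expect_equal(unname(rowSums(m)[filled]), rep(1, sum(filled)),
               tolerance = 1e-12)
})

test_that("aggregation gives point-mass rows for identical trajectories", {
  tj <- do.call(rbind, lapply(1:5, function(i)
    cbind(trial_id = paste0("t", i), sample_index = 1:21,
          straight_traj(64))))
  fields <- destination_fields(tj)
  m <- aggregate_distributions(fields, n_conf_bins = 18L)
  expect_true(all(apply(m, 1, max) == 1))
  expect_error(aggregate_distributions(fields[0, ]), "empty")
})

test_that("interaction map is zero for identical cells and localized for a known injection", {
  lv <- list(group = c("experienced", "inexperienced"),
             pathology = c("abnormal", "normal"),
             condition = c("long_second", "short_first"))
  combos <- expand.grid(lv, stringsAsFactors = FALSE)
  nm <- with(combos, paste(group, pathology, condition, sep = "."))
  base <- matrix(1 / 18, 20, 18)
  cells <- setNames(rep(list(base), 8), nm)
  m0 <- interaction_map(cells)
  expect_true(all(m0$grid == 0))
  expect_false(any(m0$contour_mask))
  # inject extra late/high-confidence mass only in experienced x abnormal
  # x long_second: the mask should concentrate there
  inj <- base
  inj[16:20, 16:18] <- inj[16:20, 16:18] + 0.4
  inj <- inj / rowSums(inj)
  cells[["experienced.abnormal.long_second"]] <- inj
  m1 <- interaction_map(cells)
  hot <- which(m1$contour_mask, arr.ind = TRUE)
  expect_gt(nrow(hot), 0)
  expect_true(all(hot[, 1] >= 16 & hot[, 2] >= 16))
  # row-normalized matrices: the grid's total is the triple difference
  # of totals, which vanishes
  expect_equal(sum(m1$grid), 0, tolerance = 1e-12)
  # swapping the two levels of one factor negates the grid
  swap <- cells
  for (pth in c("abnormal", "normal")) for (cnd in lv$condition) {
    a <- paste("experienced", pth, cnd, sep = ".")
    b <- paste("inexperienced", pth, cnd, sep = ".")
    tmp <- swap[[a]]; swap[[a]] <- swap[[b]]; swap[[b]] <- tmp
  }
  m2 <- interaction_map(swap)
  expect_equal(m2$grid, -m1$grid, tolerance = 1e-12)
  expect_equal(m2$contour_mask, m1$contour_mask)
  expect_error(interaction_map(cells[-1]), "missing cell")
})
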