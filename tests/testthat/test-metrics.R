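test_that("Euclidean errors match hand values and a naive loop oracle", {
  set.seed(41)
  mocap <- rand_stream3d(nf = 6, frame_tag = "mocap")
  mask <- all_true_mask(mocap)
  zero <- euclid_errors(mocap, mocap, mask)
  expect_true(all(zero$e == 0))
  # single known offset
  dm <- tibble::as_tibble(mocap)
  dm$x <- dm$x + 3; dm$y <- dm$y + 4; dm$z <- dm$z + 12
  shifted <- stream3d(dm, fps = 30, coordinate_frame = "aligned")
  expect_true(all(abs(euclid_errors(shifted, mocap, mask)$e - 13) < 1e-12))
  # random streams vs explicit loop
  a <- rand_stream3d(nf = 6, frame_tag = "aligned")
  tab <- euclid_errors(a, mocap, mask, participant = 1, method = "m")
  for (i in sample(nrow(tab), 10)) {
    fr <- tab$frame[i]; kp <- as.character(tab$keypoint[i])
    ra <- a[a$frame == fr & a$keypoint == kp, ]
    rm_ <- mocap[mocap$frame == fr & mocap$keypoint == kp, ]
    expect_equal(tab$e[i],
                 sqrt((ra$x - rm_$x)^2 + (ra$y - rm_$y)^2 + (ra$z - rm_$z)^2))
  }
  expect_equal(nrow(tab), sum(mask$valid))
})

test_that("error tables are invariant under a common rigid motion of both streams", {
  set.seed(42)
  mocap <- rand_stream3d(nf = 5, frame_tag = "mocap")
  a <- rand_stream3d(nf = 5, frame_tag = "aligned")
  mask <- all_true_mask(mocap)
  tf <- rigid_transform(R = rand_rotation(), t = c(100, -50, 20))
  move <- function(s) {
    d <- tibble::as_tibble(s)
    p <- apply_rigid(cbind(d$x, d$y, d$z), tf)
    d$x <- p[, 1]; d$y <- p[, 2]; d$z <- p[, 3]
    stream3d(d, fps = 30, coordinate_frame = attr(s, "coordinate_frame"))
  }
  e1 <- euclid_errors(a, mocap, mask)$e
  e2 <- euclid_errors(move(a), move(mocap), mask)$e
  expect_lt(max(abs(e1 - e2)), 1e-9)
})

test_that("aggregation uses unweighted cell means and participant-mean overall means", {
  tab <- structure(tibble::tibble(
    participant = c(1, 1, 1, 2, 2, 2),
    method = "m", sequence = 1,
    group = factor("wrist_R", levels = hpeval:::group_levels()),
    keypoint = "wrist_right", frame = 0:5,
    e = c(10, 30, 20, 40, 40, 40)
  ), class = c("error_table", class(tibble::tibble())))
  agg <- aggregate_participant_means(tab)
  expect_equal(agg$cell_means$mean_error_mm, c(20, 40))
  # overall: mean of participant means (20 and 40), not pooled-frame mean
  expect_equal(agg$overall$mean_error_mm, 30)
  # constant table: every mean equals the constant
  tab$e <- 10
  expect_true(all(aggregate_participant_means(tab)$cell_means$mean_error_mm == 10))
  set.seed(43)
  tab$e <- runif(6, 0, 50)
  agg <- aggregate_participant_means(tab)
  expect_equal(agg$cell_means$mean_error_mm,
               c(mean(tab$e[1:3]), mean(tab$e[4:6])))
})

test_that("voxelization floors indices, including negatives, with set semantics", {
  v <- voxelize(matrix(c(25, 25, 25), 1), 50)
  expect_equal(c(v$ix, v$iy, v$iz), c(0L, 0L, 0L))
  v2 <- voxelize(matrix(c(-1, 0, 0), 1), 50)
  expect_equal(v2$ix, -1L)
  dup <- voxelize(rbind(c(10, 10, 10), c(10, 10, 10), c(12, 12, 12)), 50)
  expect_equal(nrow(dup), 1L)
})

test_that("Dice matches its formula, is symmetric and bounded", {
  A <- voxelize(rbind(c(10, 10, 10), c(60, 10, 10)), 50)
  expect_equal(dice(A, A), 1)
  B <- voxelize(rbind(c(210, 10, 10), c(260, 10, 10)), 50)
  expect_equal(dice(A, B), 0)
  C <- voxelize(rbind(c(10, 10, 10), c(210, 10, 10)), 50)
  expect_equal(dice(A, C), 0.5)  # |A|=|B|=2, overlap 1
  expect_error(dice(voxelize(matrix(0, 0, 3), 50),
                    voxelize(matrix(0, 0, 3), 50)), "empty")
  set.seed(44)
  for (i in 1:10) {
    P <- matrix(runif(60, -200, 200), ncol = 3)
    Q <- matrix(runif(60, -200, 200), ncol = 3)
    a <- voxelize(P, 80); b <- voxelize(Q, 80)
    d1 <- dice(a, b)
    expect_equal(d1, dice(b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
  }
})

test_that("dice agrees with a brute-force voxel enumeration oracle", {
  set.seed(45)
  for (i in 1:5) {
    P <- matrix(runif(90, -300, 300), ncol = 3)
    Q <- P + matrix(rep(c(25, 0, 0), each = 30), ncol = 3)  # half-voxel shift
    v <- 50
    key <- function(M) unique(apply(floor(M / v), 1, paste, collapse = ","))
    ka <- key(P); kb <- key(Q)
    expected <- 2 * length(intersect(ka, kb)) / (length(ka) + length(kb))
    expect_equal(dice(voxelize(P, v), voxelize(Q, v)), expected)
  }
})

test_that("shifting both point sets by whole voxels leaves Dice unchanged", {
  set.seed(46)
  P <- matrix(runif(90, -200, 200), ncol = 3)
  Q <- matrix(runif(90, -200, 200), ncol = 3)
  v <- 50
  d0 <- dice(voxelize(P, v), voxelize(Q, v))
  shift <- matrix(rep(c(3 * v, -2 * v, 7 * v), each = 30), ncol = 3)
  d1 <- dice(voxelize(P + shift, v), voxelize(Q + shift, v))
  expect_equal(d0, d1)
  # and the index sets shift exactly
  expect_equal(sort(voxelize(P + shift, v)$ix), sort(voxelize(P, v)$ix + 3L))
})

test_that("the dice curve is 1 for identical sets and respects the sweep", {
  set.seed(47)
  P <- matrix(runif(150, -300, 300), ncol = 3)
  dc <- dice_curve(P, P, c(10, 50, 100))
  expect_equal(dc$dice, rep(1, 3))
  expect_error(dice_curve(P, P, c(-5, 10)), "positive")
})

test_that("low-confidence breakdown tabulates categories with NA when no events", {
  nf <- 10
  base <- tibble::tibble(
    frame = rep(seq_len(nf) - 1L, each = 13L),
    keypoint = factor(rep(target_keypoints(), nf), levels = target_keypoints()),
    x = 0, y = 0, z = 0, missing = FALSE
  )
  a <- stream3d(dplyr::mutate(base, confidence = 0.9), 30, "camera1")
  b <- stream3d(dplyr::mutate(base, confidence = 0.1), 30, "camera1")
  out <- low_confidence_breakdown(a, b, tau = 0.3)
  expect_true(all(out$N[out$group != "shoulder"] > 0))
  expect_true(all(out$pct_b_only[out$N > 0] == 100))
  # no events at all -> N = 0 and NA percentages
  none <- low_confidence_breakdown(a, a, tau = 0.3)
  expect_true(all(none$N == 0))
  expect_true(all(is.na(none$pct_a_only)))
  expect_equal(as.character(none$group), hpeval:::group_levels())
})

test_that("breakdown percentages sum to 100 and match a counting oracle", {
  set.seed(48)
  nf <- 40
  mk <- function() {
    stream3d(tibble::tibble(
      frame = rep(seq_len(nf) - 1L, each = 13L),
      keypoint = factor(rep(target_keypoints(), nf), levels = target_keypoints()),
      x = 0, y = 0, z = 0, confidence = runif(nf * 13), missing = FALSE
    ), 30, "camera1")
  }
  a <- mk(); b <- mk()
  out <- low_confidence_breakdown(a, b, tau = 0.3)
  has <- out$N > 0
  expect_equal(out$pct_a_only[has] + out$pct_b_only[has] + out$pct_both[has],
               rep(100, sum(has)))
  # counting oracle for one group
  grp <- keypoint_groups()
  kps <- grp$keypoint[grp$group == "face"]
  sel <- as.character(a$keypoint) %in% kps
  ba <- a$confidence[sel] < 0.3; bb <- b$confidence[sel] < 0.3
  N <- sum(ba | bb)
  expect_equal(out$N[out$group == "face"], N)
  expect_equal(out$pct_both[out$group == "face"], 100 * sum(ba & bb) / N)
})
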