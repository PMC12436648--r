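test_that("optimal assignment matches the brute-force oracle", {
  set.seed(10)
  for (r in 1:40) {
    n <- sample(2:6, 1)
    cost <- matrix(runif(n * n), n, n)
    a <- solve_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]),
                 brute_force_assignment(cost), tolerance = 1e-10)
  }
  ## rectangular case: every row assigned a distinct column
  cost <- matrix(runif(12), 3, 4)
  a <- solve_assignment(cost)
  expect_equal(length(unique(a)), 3L)
})

test_that("frame linking builds the expected tracks", {
  ## one stationary spot over n frames -> one track of length n
  s1 <- data.frame(frame = 0:9, x = 5, y = 5)
  t1 <- link_frames(s1, link_params())
  expect_equal(length(unique(t1$track_id)), 1L)
  expect_equal(nrow(t1), 10L)

  ## two far-apart parallel movers: no identity swaps
  s2 <- rbind(data.frame(frame = 0:9, x = (0:9) * 0.5, y = 2),
              data.frame(frame = 0:9, x = (0:9) * 0.5, y = 40))
  t2 <- link_frames(s2, link_params(max_disp_px = 3))
  expect_equal(length(unique(t2$track_id)), 2L)
  ys <- tapply(t2$y, t2$track_id, function(v) length(unique(v)))
  expect_true(all(ys == 1))

  ## frame-pair assignment cost is globally optimal (5-spot instances)
  set.seed(11)
  for (r in 1:10) {
    xy1 <- matrix(runif(10, 0, 10), 5, 2)
    xy2 <- xy1 + matrix(rnorm(10, 0, 1), 5, 2)
    m <- smtrack:::link_pair(xy1, xy2, max_disp = 30)
    got <- sum((xy1 - xy2[m, ])^2)
    d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 +
      outer(xy1[, 2], xy2[, 2], "-")^2
    expect_equal(got, brute_force_assignment(d2), tolerance = 1e-10)
  }
})

test_that("tracking conserves spots and ignores input order", {
  set.seed(12)
  spots <- data.frame(frame = rep(0:7, each = 4),
                      x = rep(c(3, 13, 23, 33), 8) + rnorm(32, 0, 0.3),
                      y = rep(c(3, 13, 23, 33), 8) + rnorm(32, 0, 0.3))
  tr <- link_frames(spots, link_params())
  expect_equal(nrow(tr), nrow(spots))          # every spot in one track
  expect_false(anyNA(tr$track_id))
  perm <- spots[sample(nrow(spots)), ]
  tr2 <- link_frames(perm, link_params())
  ## same partition of spots into tracks (ids may differ)
  key <- function(d) sort(vapply(
    split(paste(d$frame, round(d$x, 6), sep = ":"), d$track_id),
    function(v) paste(sort(v), collapse = "|"), ""))
  expect_equal(unname(key(tr)), unname(key(tr2)))
})

test_that("gap closing joins fragments but never overlapping tracks", {
  base <- data.frame(frame = c(0:4, 6:9), x = 5, y = 5)
  tr <- link_frames(base, link_params(max_gap_frames = 1L))
  expect_equal(length(unique(tr$track_id)), 2L)
  joined <- close_gaps(tr, link_params(max_gap_frames = 1L))
  expect_equal(length(unique(joined$track_id)), 1L)
  ## disabled gap closing is the identity
  expect_identical(close_gaps(tr, link_params(max_gap_frames = 0L)), tr)
  ## temporally overlapping tracks stay separate
  two <- rbind(make_track(1L, "mrna", 0:9, 5, 5),
               make_track(2L, "mrna", 5:14, 5.2, 5))
  out <- close_gaps(two, link_params(max_gap_frames = 3L))
  expect_equal(length(unique(out$track_id)), 2L)
})

test_that("dropped detections are repaired to the true track count", {
  set.seed(13)
  n_mol <- 12
  frames <- 0:29
  rows <- list()
  for (i in seq_len(n_mol)) {
    keep <- runif(length(frames)) > 0.05   # 5% missed detections
    keep[c(1, length(frames))] <- TRUE
    rows[[i]] <- data.frame(frame = frames[keep],
                            x = 8 * ((i - 1) %% 4) + 4 + rnorm(sum(keep), 0, 0.2),
                            y = 8 * ((i - 1) %/% 4) + 4 + rnorm(sum(keep), 0, 0.2))
  }
  spots <- do.call(rbind, rows)
  tr <- close_gaps(link_frames(spots, link_params(max_gap_frames = 2L)),
                   link_params(max_gap_frames = 2L))
  expect_equal(length(unique(tr$track_id)), n_mol)
})

test_that("track filters implement the keep/discard boundaries", {
  p <- link_params(frame_interval_s = 2)
  t24 <- make_track(1L, "mrna", 0:23, 1, 1)
  t25 <- make_track(2L, "mrna", 0:24, 10, 10)
  t3 <- make_track(3L, "protein", 0:2, 20, 20)
  t4 <- make_track(4L, "protein", 0:3, 30, 30)
  tr <- rbind(t24, t25, t3, t4)[, c("track_id", "channel", "frame",
                                    "x", "y", "cell", "t_s")]
  f <- filter_tracks(tr, p)
  st <- unique(f[, c("track_id", "status", "reason")])
  expect_equal(st$status[st$track_id == 1], "discarded")  # 24 frames
  expect_equal(st$reason[st$track_id == 1], "too_short")
  ## a 25-frame mRNA track spans 50 s < 120 s -> discarded as too brief
  expect_equal(st$reason[st$track_id == 2], "too_brief")
  expect_equal(st$status[st$track_id == 3], "discarded")  # 3-frame protein
  expect_equal(st$status[st$track_id == 4], "kept")       # 4-frame protein
  ## 61 frames at 2 s = 122 s: passes both mRNA rules
  long <- make_track(5L, "mrna", 0:60, 40, 40)[, names(tr)]
  fl <- filter_tracks(long, p)
  expect_true(all(fl$status == "kept"))
  ## idempotence
  expect_identical(filter_tracks(f, p), f)
})

test_that("crossing mRNA tracks are flagged pairwise", {
  p <- link_params()
  a <- make_track(1L, "mrna", 0:30, 5, 5)
  b <- make_track(2L, "mrna", 0:30, 20, 5)
  cc <- make_track(3L, "mrna", 0:30, 40, 5)
  ## far apart: nothing flagged
  none <- flag_crossings(rbind(a, b, cc), 2.6)
  expect_true(all(none$status == "kept"))
  ## b drifts through a at one frame: exactly that pair flagged
  b2 <- b
  b2$x <- seq(20, 3, length.out = 31)
  out <- flag_crossings(rbind(a, b2, cc), 2.6)
  st <- unique(out[, c("track_id", "status")])
  expect_equal(st$status[st$track_id %in% c(1, 2)], c("discarded",
                                                      "discarded"))
  expect_equal(st$status[st$track_id == 3], "kept")
})
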