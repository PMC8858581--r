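# 2-s block featurization: the 43-feature contract, moment conventions
# against closed forms and an independent oracle, the 3/5 labeling rule and
# the exclusion filter with its validity report.

test_that("the feature vector has exactly 43 named features", {
  expect_length(block_feature_names(), 43)
  win <- data.frame(depth_m = rnorm(20, 20), depth_rate_ms = rnorm(20),
                    speed_ms = rnorm(20, 1.5), odba_ms2 = abs(rnorm(20)),
                    pitch_post_deg = rnorm(20), roll_post_deg = rnorm(20, 40),
                    roll_rate_dps = abs(rnorm(20)), fsr_hz = runif(20, 0, .4))
  f <- compute_block_features(win)
  expect_length(f, 43)
  expect_identical(names(f), block_feature_names())
})

test_that("moment conventions match closed forms and e1071", {
  const <- data.frame(depth_m = rep(5, 20), depth_rate_ms = 0, speed_ms = 1,
                      odba_ms2 = 0, pitch_post_deg = 0, roll_post_deg = 0,
                      roll_rate_dps = 0, fsr_hz = 0)
  f <- compute_block_features(const)
  expect_equal(unname(f["depth_var"]), 0)
  expect_equal(unname(f["depth_skew"]), 0) # degenerate moments flagged as 0
  expect_equal(unname(f["depth_kurt"]), 0)

  x <- 1:20
  win <- const
  win$depth_m <- x
  f <- compute_block_features(win)
  expect_equal(unname(f["depth_mean"]), 10.5)
  expect_equal(unname(f["depth_min"]), 1)
  expect_equal(unname(f["depth_max"]), 20)
  expect_equal(unname(f["depth_var"]), var(x)) # n-1: 35
  expect_equal(unname(f["depth_var"]), 35)
  expect_equal(unname(f["depth_skew"]), 0, tolerance = 1e-12) # symmetric
  # non-excess kurtosis of the discrete uniform 1..20: m4/m2^2
  m2 <- mean((x - mean(x))^2)
  m4 <- mean((x - mean(x))^4)
  expect_equal(unname(f["depth_kurt"]), m4 / m2^2)

  skip_if_not_installed("e1071")
  set.seed(11)
  y <- rnorm(20)
  win$depth_m <- y
  f <- compute_block_features(win)
  expect_equal(unname(f["depth_skew"]), e1071::skewness(y, type = 1),
               tolerance = 1e-12)
  expect_equal(unname(f["depth_kurt"]), e1071::kurtosis(y, type = 1) + 3,
               tolerance = 1e-12)
})

test_that("roll features use the absolute roll", {
  win <- data.frame(depth_m = 10, depth_rate_ms = 0, speed_ms = 1,
                    odba_ms2 = 0, pitch_post_deg = 0,
                    roll_post_deg = rep(c(-50, -40), 10),
                    roll_rate_dps = 0, fsr_hz = 0)
  f <- compute_block_features(win)
  expect_equal(unname(f["abs_roll_mean"]), 45)
  expect_equal(unname(f["abs_roll_min"]), 40)
  expect_equal(unname(f["abs_roll_max"]), 50)
})

test_that("min <= mean <= max and var >= 0 on random windows", {
  set.seed(21)
  for (rep in 1:20) {
    win <- data.frame(depth_m = rnorm(20, 15, 5), depth_rate_ms = rnorm(20),
                      speed_ms = runif(20, 0.5, 2), odba_ms2 = abs(rnorm(20)),
                      pitch_post_deg = rnorm(20, 0, 20),
                      roll_post_deg = rnorm(20, 0, 60),
                      roll_rate_dps = abs(rnorm(20)), fsr_hz = runif(20))
    f <- compute_block_features(win)
    for (ch in c("depth", "speed", "abs_roll", "pitch")) {
      expect_lte(f[[paste0(ch, "_min")]], f[[paste0(ch, "_mean")]])
      expect_lte(f[[paste0(ch, "_mean")]], f[[paste0(ch, "_max")]])
      expect_gte(f[[paste0(ch, "_var")]], 0)
    }
  }
})

test_that("the 3/5 labeling boundary is inclusive", {
  n <- 400
  # event covering exactly 12 of the 20 samples of block [0, 2)
  ev12 <- behavior_events(start_s = 0, stop_s = 1.2)
  expect_equal(label_block(0, 2, ev12, n = n), "suckling")
  ev11 <- behavior_events(start_s = 0, stop_s = 1.1)
  expect_equal(label_block(0, 2, ev11, n = n), "non-suckling")
  evfull <- behavior_events(start_s = 0, stop_s = 2)
  expect_equal(label_block(0, 2, evfull, n = n), "suckling")
})

test_that("label rule agrees with a brute-force overlap counter", {
  set.seed(31)
  n <- 2000 # 200 s
  s <- sort(runif(6, 0, 180))
  ev <- behavior_events(start_s = s, stop_s = s + runif(6, 3, 15))
  ev <- ev[c(TRUE, ev$start_s[-1] > cummax(ev$stop_s)[-6]), ]
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(ev))) { # brute force, sample by sample
    tt <- (seq_len(n) - 1) / 10
    mask <- mask | (tt >= ev$start_s[i] & tt < ev$stop_s[i])
  }
  for (b in 1:100) {
    idx <- ((b - 1) * 20 + 1):(b * 20)
    oracle <- if (sum(mask[idx]) >= 12) "suckling" else "non-suckling"
    expect_equal(label_block((b - 1) * 2, b * 2, ev, n = n), oracle)
  }
})

test_that("make_blocks windows the record and drops the partial tail", {
  kin100 <- manual_kin(1000, depth = 20)
  phases <- list(labels = rep("bottom", 1000))
  none <- behavior_events(numeric(0), numeric(0))
  blocks <- make_blocks(kin100, none, phases)
  expect_equal(nrow(blocks), 50)
  expect_true(all(blocks$label == "non-suckling"))
  kin101 <- manual_kin(1010, depth = 20)
  phases101 <- list(labels = rep("bottom", 1010))
  expect_equal(nrow(make_blocks(kin101, none, phases101)), 50)
  expect_error(make_blocks(manual_kin(10), none,
                           list(labels = rep("surface", 10))),
               "shorter than one block")
})

test_that("block features equal a naive recomputation from the channels", {
  fix <- tiny_deployment()
  blocks <- make_blocks(fix$kin, fix$dep$truth_events, fix$phases)
  chan <- as.data.frame(fix$kin)
  set.seed(5)
  for (b in sample(nrow(blocks), 12)) {
    idx <- ((b - 1) * 20 + 1):(b * 20)
    expect_equal(blocks$depth_mean[b], mean(chan$depth_m[idx]))
    expect_equal(blocks$speed_max[b], max(chan$speed_ms[idx]))
    expect_equal(blocks$abs_roll_mean[b], mean(abs(chan$roll_post_deg[idx])))
    expect_equal(blocks$fsr_mean[b], mean(chan$fsr_hz[idx]))
    d <- chan$odba_ms2[idx] - mean(chan$odba_ms2[idx])
    expect_equal(blocks$odba_skew[b], mean(d^3) / mean(d^2)^1.5)
  }
})

test_that("the exclusion filter drops shallow/fast blocks and validates", {
  fix <- tiny_deployment()
  blocks <- make_blocks(fix$kin, fix$dep$truth_events, fix$phases)
  # planted violations
  shallow <- blocks[1, ]; shallow$depth_mean <- 1.0
  shallow$label <- "non-suckling"
  fast <- blocks[1, ]; fast$speed_mean <- 2.5
  fast$label <- "non-suckling"
  fl <- filter_blocks(rbind(blocks, shallow, fast))
  expect_equal(fl$report$n_before, nrow(blocks) + 2)
  expect_false(fl$blocks$retained[nrow(blocks) + 1])
  expect_false(fl$blocks$retained[nrow(blocks) + 2])
  # simulator safety invariant: no suckling block is ever removed
  expect_equal(fl$report$n_suckling_removed, 0)
  expect_true(fl$report$pass)
  expect_true(all(fl$retained$depth_mean >= 1.5))
  expect_true(all(fl$retained$speed_mean <= 2))
})
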