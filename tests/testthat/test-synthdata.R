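test_that("gen_assemblages: determinism, degenerate SD, shrink injection", {
  specs <- toy_specs()
  s1 <- gen_assemblages(specs, seed = 4)
  s2 <- gen_assemblages(specs, seed = 4)
  expect_identical(series_summary(s1), series_summary(s2))

  degen <- specs; degen$sd_area <- 0
  sd0 <- gen_assemblages(degen, seed = 1)
  for (i in seq_along(sd0))
    expect_true(all(sd0[[i]]$areas == sd0[[i]]$mean_area))

  bad <- specs; bad$n[1] <- 0L
  expect_error(gen_assemblages(bad, seed = 1), "n >= 1")

  # factor 0.25 at the middle event, mean 8 -> truth from the sidecar
  sp <- data.frame(locality = c("O", "Y"), age_ma = c(430, 425),
                   n = 100L, mean_area = 8, sd_area = 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  gen_assemblages(sp, event_shrink = list(age_ma = 428, factor = 0.25),
                  seed = 6, path = f)
  truth <- jsonlite::read_json(paste0(f, ".truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$true_mean, c(8, 2))
  ser <- read_measurements(f)
  d <- event_delta(ser, event_window("E", "O", "Y"))
  expect_lt(abs(d - (truth$true_mean[1] - truth$true_mean[2])),
            3 * 0.5 * sqrt(2 / 100))
  # header carries the seed
  expect_match(readLines(f, n = 1), "seed: 6")
})

test_that("gen_fbd_record boundaries and exponential-duration oracle", {
  st <- data.frame(name = "S", start_ma = 30, end_ma = 0,
                   lambda = 0, mu = 0, psi = 0)
  rec <- gen_fbd_record(st, n_founders = 20, seed = 2)
  expect_equal(nrow(rec$taxa), 20L)
  expect_false(any(rec$taxa$extinct))
  expect_true(all(rec$taxa$n_occ == 0L))

  # lambda = 0, mu > 0: duration is Exp(mu); mean over many founders
  st2 <- data.frame(name = "S", start_ma = 60, end_ma = 0,
                    lambda = 0, mu = 2, psi = 0)
  rec2 <- gen_fbd_record(st2, n_founders = 4000, seed = 3)
  dur <- 60 - rec2$taxa$extinction_ma[rec2$taxa$extinct]
  expect_lt(abs(mean(dur) - 0.5), 3 * 0.5 / sqrt(length(dur)))

  # budding keeps the mother: founders never vanish at speciation
  st3 <- data.frame(name = "S", start_ma = 10, end_ma = 0,
                    lambda = 0.3, mu = 0.1, psi = 0.5)
  rec3 <- gen_fbd_record(st3, n_founders = 50, seed = 9)
  expect_true(all(rec3$taxa$origin_ma >= rec3$taxa$extinction_ma, na.rm = TRUE))
  expect_true(all(is.na(rec3$taxa$parent[1:50])))
  expect_error(gen_fbd_record(st3, n_founders = 50, seed = 9,
                              taxon_cap = 10L), "cap")
})

test_that("gen_fbd_record matches the completeness closed form", {
  st <- data.frame(name = "S", start_ma = 40, end_ma = 0,
                   lambda = 0, mu = 1, psi = 1)
  rec <- gen_fbd_record(st, n_founders = 4000, seed = 13)
  ext <- rec$taxa[rec$taxa$extinct, ]
  phat <- mean(ext$n_occ > 0)
  p0 <- completeness(1, 1)
  expect_lt(abs(phat - p0), 3 * sqrt(p0 * (1 - p0) / nrow(ext)))
})

test_that("gen_tree_sample hits the requested AD fraction exactly", {
  smp <- gen_tree_sample(4, paste0("t", 1:5), 0.75, seed = 21)
  expect_equal(ad_posterior(smp, "t1", "t2"), 0.75)
  all_ad <- gen_tree_sample(6, paste0("t", 1:5), 1, seed = 22)
  expect_equal(ad_posterior(all_ad, "t1", "t2"), 1)
  none <- gen_tree_sample(6, paste0("t", 1:5), 0, seed = 23)
  expect_equal(ad_posterior(none, "t1", "t2"), 0)
  expect_error(gen_tree_sample(4, "t1", 0.5, seed = 1), "taxa")

  f1 <- withr::local_tempfile(fileext = ".nwk")
  f2 <- withr::local_tempfile(fileext = ".nwk")
  gen_tree_sample(5, paste0("t", 1:6), 0.4, seed = 30, path = f1)
  gen_tree_sample(5, paste0("t", 1:6), 0.4, seed = 30, path = f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
})

test_that("gen_occurrences determinism and boundary behavior", {
  st <- toy_stages(6L)
  o1 <- gen_occurrences(40, st, 0.5, seed = 5)
  o2 <- gen_occurrences(40, st, 0.5, seed = 5)
  expect_identical(o1$presence, o2$presence)

  # p = 1 everywhere: every defined interior interval estimates 1
  full <- gen_occurrences(60, st, 1, seed = 6)
  tt <- three_timer(full)
  expect_true(all(tt$p_sample[2:5] == 1, na.rm = TRUE))
  expect_error(gen_occurrences(10, st[0, ], 0.5, seed = 1), "nrow")
})

test_that("three_timer recovers the generating probability", {
  st <- toy_stages(8L)
  occ <- gen_occurrences(500, st, 0.5, seed = 8)
  tt <- three_timer(occ)
  idx <- which(!is.na(tt$p_sample))
  for (i in idx) {
    denom <- tt$three_timer[i] + tt$part_timer[i]
    expect_lt(abs(tt$p_sample[i] - 0.5), 3 * sqrt(0.25 / denom))
  }
})
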