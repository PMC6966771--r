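make_raw <- function(sj) sj  # readability alias for synth subjects

test_that("the band-pass filter attenuates out-of-band tones", {
  t <- (0:9999) / 1000
  x50 <- sin(2 * pi * 50 * t)
  y50 <- mtenet:::fft_bandpass(x50, 1000, 0.5, 30, 4)
  mid <- 2000:8000
  att_db <- 20 * log10(stats::sd(y50[mid]) / stats::sd(x50[mid]))
  expect_lte(att_db, -20)
  # in-band tone passes nearly untouched
  x10 <- sin(2 * pi * 10 * t)
  y10 <- mtenet:::fft_bandpass(x10, 1000, 0.5, 30, 4)
  expect_equal(stats::sd(y10[mid]) / stats::sd(x10[mid]), 1, tolerance = 0.05)
})

test_that("preprocessing yields 1-s baseline-corrected target epochs", {
  sj <- generate_subject("hc", paradigm = small_paradigm(seed = 3), seed = 21)
  ep <- preprocess_eeg(sj$series, sj$events)
  expect_identical(dim(ep$data)[3], 1000L)             # 1-s epoch at 1,000 Hz
  expect_identical(dim(ep$data)[2], 16L)
  expect_identical(dim(ep$data)[1],
                   sum(sj$events$label == "target"))
  base <- apply(ep$data[, , ep$times < 0], c(1, 2), mean)
  expect_lte(max(abs(base)), 1e-9)                     # baseline removed
  expect_equal(ep$times[1], -200)
  # average reference: channels sum to ~0 at every sample
  expect_lte(max(abs(apply(ep$data, c(1, 3), sum))), 1e-6)
})

test_that("edge events are dropped with a message, not an error", {
  sj <- generate_subject("hc", paradigm = small_paradigm(seed = 4), seed = 22)
  ev <- rbind(sj$events,
              data.frame(run = 1, time_ms = 50, label = "target"))
  expect_message(ep <- preprocess_eeg(sj$series, ev), "dropped")
  expect_identical(dim(ep$data)[1], sum(sj$events$label == "target"))
})

test_that("artifact rejection drops exactly the supra-threshold trials", {
  sj <- generate_subject("hc", paradigm = small_paradigm(seed = 5), seed = 23)
  inj <- inject_artifacts(sj, rate = 0.5, amplitude_uv = 400, seed = 31)
  ep <- preprocess_eeg(inj$subject$series, inj$subject$events)
  # quiet epochs all pass
  clean_ep <- preprocess_eeg(sj$series, sj$events)
  kept0 <- reject_artifacts(clean_ep, 100)
  expect_true(all(kept0$kept))
  rej <- reject_artifacts(ep, 100)
  expect_identical(which(!rej$kept), inj$injected)
  # idempotent at the rejection step
  rej2 <- reject_artifacts(rej, 100)
  expect_identical(rej$kept, rej2$kept)
  expect_error(reject_artifacts(ep, -5), "positive")
})

test_that("a 150 uV excursion is rejected at the default threshold", {
  sj <- generate_subject("hc", paradigm = small_paradigm(seed = 6), seed = 24)
  inj <- inject_artifacts(sj, rate = 0.3, amplitude_uv = 150, seed = 32)
  ep <- preprocess_eeg(inj$subject$series, inj$subject$events)
  rej <- reject_artifacts(ep)
  expect_true(all(inj$injected %in% which(!rej$kept)))
})

test_that("subject networks are 16 x 16 with zero diagonal", {
  sj <- generate_subject("hc", paradigm = small_paradigm(seed = 7), seed = 25)
  ep <- reject_artifacts(preprocess_eeg(sj$series, sj$events))
  net <- subject_network(ep, "gca", inference_params(max_order = 2, seed = 1))
  expect_identical(dim(net$weights), c(16L, 16L))
  expect_true(all(diag(net$weights) == 0))
  expect_identical(net$labels, default_montage())
})

test_that("a single kept trial returns that trial's network", {
  sj <- generate_subject("hc", paradigm = small_paradigm(seed = 8), seed = 26)
  ep <- reject_artifacts(preprocess_eeg(sj$series, sj$events))
  ep1 <- ep; ep1$kept[-1] <- FALSE
  p <- inference_params(max_order = 2, seed = 5)
  net1 <- subject_network(ep1, "gca", p)
  s <- multichannel_series(ep$data[1, , seq(1, 1000, by = 4)],
                           ep$channels, ep$sample_rate / 4)
  p2 <- p; p2$seed <- mtenet:::derive_seed(5, "trial", 1L)
  direct <- infer_gca_network(s, p2)
  expect_equal(net1$weights, direct$weights)
  ep0 <- ep; ep0$kept[] <- FALSE
  expect_error(subject_network(ep0, "gca", p), "no kept trials")
})

test_that("the planted coupling ranks among the strongest weights", {
  sj <- generate_subject("hc", paradigm = small_paradigm(seed = 9, n_runs = 2L),
                         seed = 27)
  ep <- reject_artifacts(preprocess_eeg(sj$series, sj$events))
  net <- subject_network(ep, "gca", inference_params(max_order = 5, seed = 2))
  w <- net$weights
  off <- w[row(w) != col(w)]
  expect_gte(w["F3", "P3"], stats::quantile(off, 0.9))  # top 10%
})

test_that("identical groups produce no significant edges", {
  withr::with_seed(41, {
    nets <- lapply(1:4, function(i) matrix(rnorm(256), 16, 16,
      dimnames = list(default_montage(), default_montage())))
    cmp <- group_difference(nets, nets, 0.05)
    expect_identical(sum(cmp$significant), 0L)
  })
  expect_error(group_difference(list(matrix(0, 2, 2)), list(), 0.05),
               "2 subjects")
})

test_that("direction masks are disjoint and FDR is monotone in alpha", {
  withr::with_seed(42, {
    hc <- lapply(1:8, function(i) {
      m <- matrix(rnorm(256, 0.5), 16, 16); m[1, 2] <- 5 + rnorm(1, sd = 0.1)
      m[3, 4] <- -4 + rnorm(1, sd = 0.1); diag(m) <- 0; m
    })
    scz <- lapply(1:8, function(i) {
      m <- matrix(rnorm(256, 0.5), 16, 16); diag(m) <- 0; m
    })
    c05 <- group_difference(hc, scz, 0.05)
    expect_identical(sum(c05$hc_gt_scz * c05$scz_gt_hc), 0L)
    expect_true(all(c05$significant[c05$hc_gt_scz == 1] == 1))
    c01 <- group_difference(hc, scz, 0.01)
    expect_true(all(c01$significant <= c05$significant))  # monotone
  })
})

test_that("out-degree counts outgoing edges under row = source", {
  m <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_identical(unname(out_degree(m)), rep(0L, 4))
  m["b", "a"] <- 1; m["b", "d"] <- 1; m["c", "a"] <- 1
  od <- out_degree(m)
  expect_identical(od[["b"]], 2L)   # matches the paper's maximum HC out-degree
  expect_identical(sum(od), sum(m != 0))  # handshake identity
})
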