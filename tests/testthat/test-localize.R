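# Functional localization: evoked potentials, short-latency detection and
# the two-criterion pmHG/alHG assignment.

test_that("evoked amplitude of pure noise shrinks as one over sqrt(N)", {
  set.seed(5)
  amp_at <- function(n) {
    ep <- noise_epochs(n, t_range = c(-0.2, 0.3))
    ev <- averaged_evoked_potential(ep)
    sd(ev$data[1, ev$times > 0])
  }
  r <- mean(replicate(8, amp_at(25) / amp_at(100)))
  expect_equal(r, 2, tolerance = 0.25)
})

test_that("a constructed 12 ms component is detected at its latency", {
  fs <- 1000
  tt <- seq(-0.2, by = 1 / fs, length.out = 500)
  set.seed(8)
  base <- rnorm(500, 0, 0.1)
  x <- base
  x[tt >= 0.012 & tt < 0.016] <- 1.0        # 10x the baseline SD
  data <- array(rep(x, each = 12), c(12, 1, 500))
  ep <- epoched_recording(data, fs, tt)
  ev <- averaged_evoked_potential(ep)
  det <- detect_short_latency(ev)
  expect_true(det$short_latency)
  expect_lt(abs(det$latency - 0.012), 0.002)
})

test_that("components outside the 20 ms window or absent are not detected", {
  fs <- 1000
  tt <- seq(-0.2, by = 1 / fs, length.out = 500)
  set.seed(9)
  late <- rnorm(500, 0, 0.1)
  late[tt >= 0.030 & tt < 0.035] <- 1.0
  flat <- rnorm(500, 0, 0.1)
  data <- array(NA_real_, c(12, 2, 500))
  for (i in 1:12) { data[i, 1, ] <- late; data[i, 2, ] <- flat }
  ep <- epoched_recording(data, fs, tt)
  det <- detect_short_latency(averaged_evoked_potential(ep))
  expect_false(det$short_latency[1])
  expect_false(det$short_latency[2])
  expect_true(all(is.na(det$latency)))
})

test_that("constant offsets vanish after baseline subtraction", {
  fs <- 1000
  tt <- seq(-0.2, by = 1 / fs, length.out = 400)
  data <- array(7, c(10, 1, 400))
  ev <- averaged_evoked_potential(epoched_recording(data, fs, tt))
  expect_equal(max(abs(ev$data)), 0)
  expect_error(detect_short_latency(ev), "zero baseline variance")
})

test_that("evoked averaging enforces the minimum trial count", {
  ep <- noise_epochs(5, t_range = c(-0.2, 0.3))
  expect_error(averaged_evoked_potential(ep), "at least 10")
})

test_that("classification is the conjunction of the two criteria", {
  # three synthetic HG contacts: locked+fast, locked+slow, unlocked+fast
  mk_itpc <- function(vals100) {
    structure(list(values = matrix(vals100, 3, 1), freqs = 100,
                   window = c(0, 0.2), n_trials = 50,
                   contact_ids = c("c1", "c2", "c3")),
              class = "itpc_result")
  }
  chance <- structure(list(mean = matrix(0.12, 3, 1),
                           sd = matrix(0.02, 3, 1), freqs = 100,
                           n_surrogates = 100,
                           contact_ids = c("c1", "c2", "c3")),
                      class = "itpc_chance")
  fs <- 1000
  tt <- seq(-0.2, by = 1 / fs, length.out = 400)
  set.seed(10)
  mk_trace <- function(lat) {
    x <- rnorm(400, 0, 0.05)
    x[tt >= lat & tt < lat + 0.004] <- 1
    x
  }
  ev <- structure(list(
    data = rbind(mk_trace(0.010), mk_trace(0.030), mk_trace(0.008)),
    times = tt, fs = fs, contact_ids = c("c1", "c2", "c3")
  ), class = "evoked_potential")
  contacts <- data.frame(contact_id = c("c1", "c2", "c3"),
                         hemisphere_id = "H1", hg = c(TRUE, TRUE, TRUE))
  itpc <- mk_itpc(c(0.8, 0.8, 0.125))
  rep1 <- classify_contacts(itpc, chance, ev, contacts)
  expect_equal(rep1$assigned, c("pmHG", "alHG", "alHG"))
  # deterministic given identical inputs
  rep2 <- classify_contacts(itpc, chance, ev, contacts)
  expect_identical(rep1, rep2)
  # non-HG contacts are never classified
  contacts$hg[3] <- FALSE
  rep3 <- classify_contacts(itpc, chance, ev, contacts)
  expect_true(is.na(rep3$assigned[3]))
  # contact mismatch errors
  expect_error(classify_contacts(itpc, chance, ev,
                                 data.frame(contact_id = "cX",
                                            hemisphere_id = "H1", hg = TRUE)),
               "match")
})

test_that("simulated hemispheres are localized perfectly across seeds", {
  p <- small_params()
  ct <- make_contact_set(p)
  for (s in c(101, 202, 303)) {
    hc <- ct[ct$hemisphere_id == "H1", ]
    rec <- simulate_hemisphere(p, hc, s)
    click <- rec$click
    c100 <- subset_trials(click, click$conditions == "100")
    itpc <- compute_itpc(c100)
    ch <- surrogate_chance_level(c100, n_surrogates = 40, seed = s + 1)
    ev <- averaged_evoked_potential(click)
    loc <- classify_contacts(itpc, ch, ev, hc)
    expect_equal(loc$assigned[hc$hg], hc$zone[hc$hg])
  }
})
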