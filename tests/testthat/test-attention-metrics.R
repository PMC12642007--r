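geom <- screen_geometry()

test_that("per-AOI metrics aggregate fixations and censor the rest", {
  aois <- tiny_aois(geom)
  fx <- tibble::tibble(
    participant_id = "P01", ad_id = "Ad1",
    onset_ms = c(500, 2000, 1200),
    duration_ms = c(300, 400, 250),
    cx_px = c(900, 950, 160), cy_px = c(500, 450, 130))
  fx <- assign_fixations(fx, aois)        # Pic, Pic, Cta
  st <- compute_aoi_metrics(fx, aois[aois$ad_id == "Ad1", ], geometry = geom)
  expect_equal(nrow(st), 3)               # one record per AOI, always
  pic <- st[st$aoi_id == "Pic", ]
  expect_equal(pic$ttff_ms, 500)
  expect_equal(pic$fc, 2)
  expect_equal(pic$fd_ms, 700)
  head_rec <- st[st$aoi_id == "Head", ]   # never fixated
  expect_true(head_rec$censored)
  expect_equal(head_rec$ttff_ms, 10000)
  expect_equal(head_rec$fc, 0)
  expect_equal(head_rec$fd_ms, 0)
})

test_that("fixations outside every AOI contribute to no record", {
  aois <- tiny_aois(geom)
  fx <- tibble::tibble(participant_id = "P01", ad_id = "Ad1",
                       onset_ms = c(100, 600), duration_ms = c(150, 200),
                       cx_px = c(1900, 900), cy_px = c(1000, 500))
  fx <- assign_fixations(fx, aois)
  st <- compute_aoi_metrics(fx, aois[aois$ad_id == "Ad1", ], geometry = geom)
  expect_equal(sum(st$fc), 1)             # only the Pic hit counts
  expect_equal(st$ttff_ms[st$aoi_id == "Pic"], 600)
})

test_that("unknown AOI references are rejected", {
  aois <- tiny_aois(geom)
  fx <- tibble::tibble(participant_id = "P01", ad_id = "Ad1",
                       onset_ms = 100, duration_ms = 100,
                       cx_px = 0, cy_px = 0, aoi_id = "Ghost")
  expect_error(compute_aoi_metrics(fx, aois, geometry = geom),
               "Ghost", class = "gazedominion_validation_error")
})

test_that("first hit is the arg-min over uncensored TTFF", {
  rec <- make_records("P01", aoi_id = c("A", "B", "C"),
                      category = c("Text", "Image", "Symbol"),
                      ttff_ms = c(29, 188, 10000), fc = c(1, 1, 0),
                      fd_ms = c(100, 100, 0))
  fh <- first_hits(rec)
  expect_equal(fh$aoi_id, "A")
  expect_equal(fh$ttff_ms, 29)

  all_cens <- make_records("P01", aoi_id = c("A", "B"),
                           category = c("Text", "Image"),
                           ttff_ms = 10000, fc = 0, fd_ms = 0)
  fh2 <- first_hits(all_cens)
  expect_true(is.na(fh2$aoi_id))

  # exact tie broken by overlap-priority category order
  tie <- make_records("P01", aoi_id = c("Cta", "Head"),
                      category = c("Website/CTA", "Text"),
                      ttff_ms = c(41, 41), fc = 1, fd_ms = 100)
  expect_equal(first_hits(tie)$aoi_id, "Cta")

  expect_error(first_hits(tie[0, ]), class = "gazedominion_validation_error")
})

test_that("first hit agrees with an exhaustive scan on random inputs", {
  set.seed(13)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    cens <- runif(k) < 0.4
    rec <- make_records("P01", aoi_id = sprintf("A%02d", 1:k),
                        category = "Text",
                        ttff_ms = ifelse(cens, 10000,
                                         sample(50:5000, k)),
                        fc = ifelse(cens, 0, 1),
                        fd_ms = ifelse(cens, 0, 100))
    fh <- first_hits(rec)
    un <- rec[!rec$censored, ]
    if (nrow(un) == 0) {
      expect_true(is.na(fh$aoi_id))
    } else {
      expect_equal(fh$aoi_id, un$aoi_id[which.min(un$ttff_ms)])
    }
  }
})

test_that("first-hit distributions reproduce counted shares and sum to 100", {
  hits <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:30), ad_id = "Ad1",
    aoi_id = "x",
    category = rep(c("Image/Visual", "Symbol", "Text"), c(10, 19, 1)),
    ttff_ms = 100)
  d <- first_hit_distribution(hits, "category")
  expect_equal(round(d$pct[match(c("Image/Visual", "Symbol", "Text"),
                                 d$category)], 1),
               c(33.3, 63.3, 3.3))
  expect_equal(sum(d$pct), 100, tolerance = 1e-9)

  solo <- dplyr::mutate(hits, category = "Text")
  expect_equal(first_hit_distribution(solo, "category")$pct, 100)
})

test_that("no-hit trials leave the denominator and are reported", {
  hits <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:10), ad_id = "Ad1",
    aoi_id = c(rep("A", 8), NA, NA),
    category = c(rep("Text", 8), NA, NA),
    ttff_ms = c(rep(100, 8), NA, NA))
  d <- first_hit_distribution(hits, "aoi")
  expect_equal(d$n_trials, 8)
  expect_equal(d$n_no_hit, 2)
  expect_equal(d$pct, 100)
  all_na <- dplyr::mutate(hits, aoi_id = NA_character_)
  expect_error(first_hit_distribution(all_na, "aoi"),
               class = "gazedominion_compute_error")
})

test_that("benchmark medians include censored latencies by convention", {
  rec <- dplyr::bind_rows(
    make_records(c("P01", "P02", "P03"), aoi_id = "A", category = "Text",
                 ttff_ms = c(1, 2, 3) * 1000, fc = c(1, 2, 3),
                 fd_ms = c(1, 2, 3) * 100),
    make_records(c("P01", "P02"), aoi_id = "B", category = "Image",
                 ttff_ms = c(100, 10000), fc = c(1, 0), fd_ms = c(50, 0)),
    make_records(c("P01", "P02"), aoi_id = "C", category = "Symbol",
                 ttff_ms = 10000, fc = 0, fd_ms = 0))
  b <- benchmark_table(rec, "aoi")
  expect_equal(b$median_fc[b$aoi_id == "A"], 2)
  expect_equal(b$median_ttff_ms[b$aoi_id == "A"], 2000)
  # censored value enters the median: midpoint of 100 and 10000
  expect_equal(b$median_ttff_ms[b$aoi_id == "B"], 5050)
  # never fixated by anyone: median latency is the censor value
  expect_equal(b$median_ttff_ms[b$aoi_id == "C"], 10000)
  expect_equal(b$n_censored[b$aoi_id == "C"], 2)
})

test_that("category-level benchmarks aggregate within participant first", {
  rec <- make_records("P01", aoi_id = c("T1", "T2", "Pic"),
                      category = c("Text", "Text", "Image"),
                      ttff_ms = c(300, 700, 150), fc = c(1, 2, 1),
                      fd_ms = c(300, 200, 400))
  b <- benchmark_table(rec, "category")
  expect_equal(b$median_fd_ms[b$category == "Text"], 500)  # 300 + 200
  expect_equal(b$median_ttff_ms[b$category == "Text"], 300)
  expect_equal(b$median_fc[b$category == "Text"], 3)
})

test_that("per-trial total dwell never exceeds the exposure", {
  sim <- generate_study(test_config(n_participants = 8), seed = 4,
                        emit_samples = FALSE)
  tot <- tibble::as_tibble(sim$study) |>
    dplyr::group_by(participant_id, ad_id) |>
    dplyr::summarise(fd = sum(fd_ms), .groups = "drop")
  expect_true(all(tot$fd <= 10000))
})

test_that("mean_ci matches the closed-form t-interval", {
  x <- c(3.1, 4.5, 2.2, 5.0, 3.8, 4.1)
  got <- mean_ci(x)
  tt <- t.test(x)
  expect_equal(got$mean, unname(tt$estimate))
  expect_equal(c(got$ci_low, got$ci_high), as.numeric(tt$conf.int),
               tolerance = 1e-12)
})
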