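make_hits <- function(categories, participant_ids = NULL, ad_id = "Ad1") {
  n <- length(categories)
  tibble::tibble(
    participant_id = participant_ids %||% sprintf("P%02d", seq_len(n)),
    ad_id = ad_id,
    aoi_id = ifelse(is.na(categories), NA_character_,
                    paste0("aoi_", seq_len(n))),
    category = categories, ttff_ms = 100)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a stratum containing everyone reproduces the overall shares", {
  hits <- make_hits(rep(c("Text", "Image/Visual"), c(6, 4)))
  strata <- tibble::tibble(participant_id = hits$participant_id,
                           age_band = "40-45")
  s <- stratified_first_hit(hits, strata, by = "age_band")
  o <- first_hit_distribution(hits, "category")
  expect_equal(s$pct[match(o$category, s$category)], o$pct)
  expect_equal(unique(s$level), "40-45")
})

test_that("per-level shares follow the counting oracle", {
  hits <- make_hits(rep(c("Source/Authority", "Text"), c(6, 3)))
  strata <- tibble::tibble(participant_id = hits$participant_id,
                           education = "Postgraduate")
  s <- stratified_first_hit(hits, strata, by = "education")
  expect_equal(round(s$pct[s$category == "Source/Authority"], 1), 66.7)
  expect_equal(round(s$pct[s$category == "Text"], 1), 33.3)
  expect_equal(unique(s$n_trials), 9)
})

test_that("participants missing from the strata map are an error", {
  hits <- make_hits(c("Text", "Image/Visual"))
  strata <- tibble::tibble(participant_id = "P01", age_band = "40-45")
  expect_error(stratified_first_hit(hits, strata, by = "age_band"),
               "P02", class = "gazedominion_validation_error")
  expect_error(stratified_first_hit(hits, strata, by = "nope"),
               class = "gazedominion_schema_error")
})

test_that("delta matrices subtract overall from subgroup in pp", {
  sub <- tibble::tibble(ad_id = "Ad2", category = "Source/Authority",
                        pct = 66.7)
  ove <- tibble::tibble(ad_id = "Ad2",
                        category = c("Source/Authority", "Text"),
                        pct = c(50.0, 50.0))
  d <- delta_matrix(sub, ove)
  expect_equal(d$delta_pp[d$category == "Source/Authority"], 16.7)
  expect_equal(d$delta_pp[d$category == "Text"], -50)  # missing = 0%

  # identical distributions give all-zero deltas; antisymmetry
  d0 <- delta_matrix(ove, ove)
  expect_true(all(d0$delta_pp == 0))
  dxy <- delta_matrix(sub, ove)$delta_pp
  dyx <- delta_matrix(ove, sub)$delta_pp
  expect_equal(dxy, -dyx)
})

test_that("delta columns cancel when both distributions sum to 100", {
  set.seed(41)
  hits <- make_hits(sample(c("Text", "Image/Visual", "Symbol"), 24,
                           replace = TRUE))
  strata <- tibble::tibble(participant_id = hits$participant_id,
                           age_band = sample(c("40-45", "56-60"), 24,
                                             replace = TRUE))
  dd <- first_hit_deltas(hits, strata, by = "age_band")
  sums <- dd |>
    dplyr::group_by(level) |>
    dplyr::summarise(s = sum(delta_pp))
  expect_true(all(abs(sums$s) < 1e-9))
})

test_that("stratified shares recompose the overall distribution", {
  set.seed(43)
  hits <- make_hits(sample(c("Text", "Image/Visual", "Logo"), 30,
                           replace = TRUE))
  strata <- tibble::tibble(participant_id = hits$participant_id,
                           household = sample(c("a", "b", "c"), 30,
                                              replace = TRUE))
  s <- stratified_first_hit(hits, strata, by = "household")
  o <- first_hit_distribution(hits, "category")
  # weighted by level sizes, per-level shares rebuild the overall shares
  lvl_sizes <- dplyr::distinct(s, level, n_trials)
  total <- sum(lvl_sizes$n_trials)
  rec2 <- s |>
    dplyr::group_by(category) |>
    dplyr::summarise(pct = sum(pct * n_trials) / total)
  expect_equal(rec2$pct[match(o$category, rec2$category)], o$pct,
               tolerance = 1e-9)
})

test_that("quadrants cross first-hit share with dominance score", {
  dist <- tibble::tibble(ad_id = "Ad1",
                         aoi_id = c("Ribbon", "Cta", "Head"),
                         n = c(18, 6, 6), n_trials = 30,
                         pct = c(60, 20, 20), n_no_hit = 0)
  rk <- tibble::tibble(ad_id = "Ad1",
                       aoi_id = c("Ribbon", "Cta", "Head", "Pic"),
                       s = c(0.08, 0.3, -0.2, -0.1))
  q <- classify_quadrants(dist, rk)
  expect_equal(nrow(q), 4)              # never-hit Pic included at 0%
  expect_equal(q$first_hit_pct[q$aoi_id == "Pic"], 0)
  expect_equal(q$quadrant[q$aoi_id == "Ribbon"], "early_sticky")
  expect_equal(q$action[q$aoi_id == "Ribbon"], "protect")
  expect_equal(q$quadrant[q$aoi_id == "Cta"], "early_sticky")
  expect_equal(q$quadrant[q$aoi_id == "Head"], "early_not_sticky")
  expect_equal(q$quadrant[q$aoi_id == "Pic"], "neither")
  expect_equal(q$action[q$aoi_id == "Pic"], "reconsider")
  # late + sticky promotes
  rk2 <- dplyr::mutate(rk, s = c(0.08, 0.3, -0.2, 0.4))
  dist2 <- dplyr::mutate(dist, pct = c(80, 10, 10))
  q2 <- classify_quadrants(dist2, rk2)
  expect_equal(q2$action[q2$aoi_id == "Pic"], "promote")
})

test_that("boundary rule: at the median is early, s = 0 is not sticky", {
  dist <- tibble::tibble(ad_id = "Ad1", aoi_id = c("A", "B", "C"),
                         n = c(10, 10, 10), n_trials = 30,
                         pct = c(40, 33.3333, 26.6667), n_no_hit = 0)
  rk <- tibble::tibble(ad_id = "Ad1", aoi_id = c("A", "B", "C"),
                       s = c(0.2, 0, -0.2))
  q <- classify_quadrants(dist, rk)
  expect_equal(q$quadrant[q$aoi_id == "B"], "early_not_sticky")
  expect_equal(attr(q, "median_first_hit_pct"), 33.3333)
})

test_that("each AOI gets exactly one quadrant and one action", {
  set.seed(47)
  for (rep in 1:10) {
    k <- sample(4:9, 1)
    dist <- tibble::tibble(ad_id = "Ad1",
                           aoi_id = sprintf("A%02d", 1:k),
                           n = 1, n_trials = k,
                           pct = as.numeric(rmultinom(1, 100, runif(k))),
                           n_no_hit = 0)
    rk <- tibble::tibble(ad_id = "Ad1", aoi_id = dist$aoi_id,
                         s = runif(k, -1, 1))
    q <- classify_quadrants(dist, rk)
    expect_equal(nrow(q), k)
    expect_true(all(q$quadrant %in% c("early_sticky", "late_sticky",
                                      "early_not_sticky", "neither")))
    expect_true(all(table(q$aoi_id) == 1))
    expect_equal(unname(c(early_sticky = "protect", late_sticky = "promote",
                          early_not_sticky = "unclutter",
                          neither = "reconsider")[q$quadrant]),
                 q$action)
  }
})

test_that("mismatched quadrant keys are an error", {
  dist <- tibble::tibble(ad_id = "Ad1", aoi_id = "Ghost", n = 1,
                         n_trials = 1, pct = 100, n_no_hit = 0)
  rk <- tibble::tibble(ad_id = "Ad1", aoi_id = c("A", "B"), s = c(0.1, -0.1))
  expect_error(classify_quadrants(dist, rk), "Ghost",
               class = "gazedominion_validation_error")
})
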