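test_that("tie-aware win probabilities count ties as one half", {
  dm <- rbind(c(500, 300), c(400, 400), c(200, 600))
  colnames(dm) <- c("A", "B")
  m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  expect_equal(m$P["A", "B"], 0.5)      # (1 + 0.5 + 0) / 3
  expect_equal(m$N["A", "B"], 3)
  expect_equal(diag(m$P), c(A = 0.5, B = 0.5))
})

test_that("participants lacking one of the pair are excluded", {
  dm <- rbind(c(500, 300), c(400, NA), c(200, 600))
  colnames(dm) <- c("A", "B")
  m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  expect_equal(m$N["A", "B"], 2)
  expect_equal(m$P["A", "B"], 0.5)      # one win, one loss
  expect_equal(m$N["A", "A"], 3)        # diagonal support = observers of A
})

test_that("all-tie comparisons and undefined pairs behave as specified", {
  dm <- rbind(c(400, 400), c(250, 250))
  colnames(dm) <- c("A", "B")
  m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  expect_equal(m$P["A", "B"], 0.5)

  disjoint <- rbind(c(500, NA), c(NA, 300))
  colnames(disjoint) <- c("A", "B")
  m2 <- pairwise_dwell_matrix(dwell_records(disjoint), "aoi")
  expect_true(is.na(m2$P["A", "B"]))
  expect_equal(m2$N["A", "B"], 0)

  one <- dwell_records(matrix(c(500), 1, 1, dimnames = list(NULL, "A")))
  expect_error(pairwise_dwell_matrix(one, "aoi"),
               class = "gazedominion_validation_error")
})

test_that("dominance scores rescale mean win probabilities to [-1, 1]", {
  # engineered so row means (excl. diagonal) are 0.75, 0.40, 0.35
  P <- rbind(c(0.5, 0.8, 0.7),
             c(0.2, 0.5, 0.6),
             c(0.3, 0.4, 0.5))
  keys <- c("A", "B", "C")
  m <- gazedominion:::new_pairwise_matrix("Ad1", keys, P,
                                          matrix(10, 3, 3), "dwell", "aoi")
  rk <- dominance_scores(m)
  expect_equal(rk$s, c(0.5, -0.2, -0.3))
  expect_equal(sum(rk$s), 0, tolerance = 1e-12)
  expect_equal(rk$rank, c(1, 2, 3))
})

test_that("a key winning every contest without ties scores exactly 1", {
  dm <- cbind(A = c(900, 800, 700, 950, 850),
              B = c(100, 200, 300, 250, 150),
              C = c(400, 300, 350, 500, 450))
  m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  rk <- dominance_scores(m)
  expect_equal(rk$s[rk$aoi_id == "A"], 1)
  # all-tie matrix scores everyone 0
  tie <- matrix(400, 4, 3, dimnames = list(NULL, c("A", "B", "C")))
  rk0 <- dominance_scores(pairwise_dwell_matrix(dwell_records(tie), "aoi"))
  expect_equal(rk0$s, c(0, 0, 0))
})

test_that("isolated keys yield NA scores with a warning", {
  dm <- rbind(c(500, 300, NA), c(400, 350, NA))
  colnames(dm) <- c("A", "B", "C")
  m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  expect_warning(rk <- dominance_scores(m), "Isolated")
  expect_true(is.na(rk$s[rk$aoi_id == "C"]))
})

test_that("category dominance aggregates dwell within participant", {
  rec <- dplyr::bind_rows(
    make_records("P01", aoi_id = c("Text1", "Text2", "Pic"),
                 category = c("Text", "Text", "Image"),
                 ttff_ms = c(100, 200, 300), fc = 1,
                 fd_ms = c(300, 200, 400)),
    make_records("P02", aoi_id = c("Text1", "Text2", "Pic"),
                 category = c("Text", "Text", "Image"),
                 ttff_ms = c(100, 200, 300), fc = 1,
                 fd_ms = c(100, 50, 600)))
  m <- category_dominance(rec)
  # P01: Text 500 > Image 400; P02: Text 150 < Image 600
  expect_equal(m$P["Text", "Image/Visual"], 0.5)
  expect_equal(m$N["Text", "Image/Visual"], 2)
  expect_equal(sort(m$keys), sort(c("Text", "Image/Visual")))

  single <- make_records("P01", aoi_id = c("T1", "T2"), category = "Text",
                         ttff_ms = c(100, 200), fc = 1, fd_ms = c(10, 20))
  expect_error(category_dominance(single),
               class = "gazedominion_validation_error")

  # equal totals for one participant tie at 0.5
  eq <- make_records("P01", aoi_id = c("T1", "Pic"),
                     category = c("Text", "Image"),
                     ttff_ms = c(100, 200), fc = 1, fd_ms = c(400, 400))
  expect_equal(category_dominance(eq)$P["Text", "Image/Visual"], 0.5)
})

test_that("precedence: earlier wins, censoring loses, both-censored drop", {
  rec <- dplyr::bind_rows(
    make_records("P01", aoi_id = c("T", "P"), category = c("Text", "Image"),
                 ttff_ms = c(100, 400), fc = 1, fd_ms = 100),
    make_records("P02", aoi_id = c("T", "P"), category = c("Text", "Image"),
                 ttff_ms = c(200, 300), fc = 1, fd_ms = 100))
  m <- ttff_precedence_matrix(rec, "category")
  expect_equal(m$P["Text", "Image/Visual"], 1.0)
  expect_equal(m$N["Text", "Image/Visual"], 2)

  rec2 <- dplyr::bind_rows(
    make_records("P01", aoi_id = c("T", "P"), category = c("Text", "Image"),
                 ttff_ms = c(100, 10000), fc = c(1, 0), fd_ms = c(100, 0)),
    make_records("P02", aoi_id = c("T", "P"), category = c("Text", "Image"),
                 ttff_ms = 10000, fc = 0, fd_ms = 0))
  m2 <- ttff_precedence_matrix(rec2, "category")
  expect_equal(m2$N["Text", "Image/Visual"], 1)  # both-censored excluded
  expect_equal(m2$P["Text", "Image/Visual"], 1)  # uncensored beats censored

  rec3 <- make_records("P01", aoi_id = c("T", "P"),
                       category = c("Text", "Image"),
                       ttff_ms = c(500, 500), fc = 1, fd_ms = 100)
  expect_equal(ttff_precedence_matrix(rec3, "category")$P["Text", "Image/Visual"],
               0.5)
})

test_that("support masking flags display cells but changes no number", {
  dm <- matrix(rnorm(40, 500, 100), 10, 4,
               dimnames = list(NULL, c("A", "B", "C", "D")))
  dm[1:8, 4] <- NA                      # pair support with D drops to 2
  m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  masked <- apply_support_mask(m, threshold = 5)
  expect_true(masked$mask["A", "D"])
  expect_false(masked$mask["A", "B"])
  expect_equal(masked$P, m$P)
  expect_equal(suppressWarnings(dominance_scores(masked))$s,
               suppressWarnings(dominance_scores(m))$s)
  none <- apply_support_mask(m, threshold = 1)
  expect_false(any(none$mask))
})

test_that("axiom checks pass on constructed matrices and catch tampering", {
  set.seed(31)
  dm <- matrix(rgamma(60, 2, scale = 300), 15, 4,
               dimnames = list(NULL, c("A", "B", "C", "D")))
  dm[runif(60) < 0.2] <- NA
  m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  ax <- verify_axioms(m)
  expect_true(ax$pass)
  expect_equal(ax$max_offdiag_dev, 0)

  bad <- m
  bad$P["A", "B"] <- bad$P["A", "B"] + 0.01
  ax2 <- verify_axioms(bad)
  expect_false(ax2$pass)
  expect_equal(ax2$max_offdiag_dev, 0.01, tolerance = 1e-12)

  bad2 <- m
  bad2$P["A", "A"] <- 0.6
  ax3 <- verify_axioms(bad2)
  expect_false(ax3$pass)
  expect_equal(ax3$max_diag_dev, 0.1, tolerance = 1e-12)
})

test_that("pairwise counting matches the brute-force oracle", {
  set.seed(17)
  for (rep in 1:15) {
    n_p <- sample(3:20, 1); k <- sample(2:6, 1)
    dm <- matrix(sample(c(NA, 100, 200, 200, 350, 500), n_p * k,
                        replace = TRUE), n_p, k)
    colnames(dm) <- LETTERS[1:k]
    keep <- colSums(!is.na(dm)) > 0      # drop all-censored keys
    dm <- dm[, keep, drop = FALSE]
    if (ncol(dm) < 2) next
    m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
    want <- oracle_pairwise(dm)
    expect_equal(unname(m$P), want$P)
    expect_equal(unname(m$N), want$N)
  }
})

test_that("zero-sum holds whenever every pair is defined", {
  set.seed(19)
  for (rep in 1:10) {
    n_p <- sample(5:15, 1); k <- sample(3:6, 1)
    dm <- matrix(rgamma(n_p * k, 2, scale = 200), n_p, k,
                 dimnames = list(NULL, LETTERS[1:k]))
    rk <- dominance_scores(pairwise_dwell_matrix(dwell_records(dm), "aoi"))
    expect_equal(sum(rk$s), 0, tolerance = 1e-12)
  }
})

test_that("raising one participant's dwell on a key never lowers its wins", {
  set.seed(23)
  dm <- matrix(rgamma(30, 2, scale = 200), 10, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  m0 <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  for (p in 1:10) {
    dm2 <- dm
    dm2[p, "A"] <- dm2[p, "A"] + 500
    m1 <- pairwise_dwell_matrix(dwell_records(dm2), "aoi")
    expect_true(all(m1$P["A", -1] >= m0$P["A", -1]))
  }
})

test_that("relabelling keys permutes P, N, and scores consistently", {
  set.seed(29)
  dm <- matrix(rgamma(40, 2, scale = 200), 10, 4,
               dimnames = list(NULL, c("A", "B", "C", "D")))
  m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  relabel <- c(A = "Z", B = "Y", C = "X", D = "W")
  dm2 <- dm; colnames(dm2) <- unname(relabel[colnames(dm)])
  m2 <- pairwise_dwell_matrix(dwell_records(dm2), "aoi")
  perm <- match(m$keys, names(relabel))
  expect_equal(m2$P[relabel[m$keys], relabel[m$keys]], m$P,
               ignore_attr = TRUE)
  rk <- dominance_scores(m); rk2 <- dominance_scores(m2)
  expect_equal(rk2$s[match(relabel[rk$aoi_id], rk2$aoi_id)], rk$s)
})

test_that("estimated win probability converges to the generating truth", {
  set.seed(37)
  n <- 200
  # dwell A ~ gamma with higher mean; true P(A > B) from the beta identity
  a1 <- 4; a2 <- 2; sc <- 100
  p_true <- pbeta(0.5, a2, a1)
  dm <- cbind(A = rgamma(n, a1, scale = sc), B = rgamma(n, a2, scale = sc))
  m <- pairwise_dwell_matrix(dwell_records(dm), "aoi")
  tol <- 3 * sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(m$P["A", "B"] - p_true), tol)
})

test_that("concordance recovers monotone agreement and needs 3 keys", {
  rk <- tibble::tibble(ad_id = "Ad1", aoi_id = c("A", "B", "C", "D"),
                       s = c(-0.5, -0.1, 0.2, 0.6))
  bench <- tibble::tibble(ad_id = "Ad1", aoi_id = c("A", "B", "C", "D"),
                          median_fd_ms = c(100, 300, 500, 900))
  cc <- concordance(rk, bench)
  expect_equal(cc$spearman_rho, 1)
  expect_gt(cc$pearson_r, 0.9)

  dec <- dplyr::mutate(bench, median_fd_ms = rev(median_fd_ms))
  expect_equal(concordance(rk, dec)$spearman_rho, -1)

  expect_error(concordance(rk[1:2, ], bench[1:2, ]),
               class = "gazedominion_validation_error")
  flat <- dplyr::mutate(bench, median_fd_ms = 500)
  expect_warning(cc2 <- concordance(rk, flat), "variance")
  expect_true(is.na(cc2$pearson_r))
})

test_that("tidy and glance expose the matrix in long and summary form", {
  dm <- matrix(rgamma(30, 2, scale = 200), 10, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  m <- apply_support_mask(pairwise_dwell_matrix(dwell_records(dm), "aoi"))
  td <- tidy(m)
  expect_equal(nrow(td), 9)
  expect_equal(td$p[td$key_i == "A" & td$key_j == "B"], m$P["A", "B"])
  g <- glance(m)
  expect_true(g$axioms_pass)
  expect_equal(g$n_keys, 3)
})
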