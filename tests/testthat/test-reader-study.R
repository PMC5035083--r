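# Frozen expected values for the published pilot-study tables were
# verified by direct computation from the printed counts before being
# asserted here.

test_that("build_confusion binarizes one-vs-rest and drops missing", {
  gold <- data.frame(image_id = c("i1", "i2", "i3"),
                     referral = c("red", "green", "yellow"))
  resp <- data.frame(
    reader_id = rep(c("a", "b"), each = 3),
    image_id = rep(c("i1", "i2", "i3"), 2),
    referral = c("red", "green", "yellow",   # reader a matches gold
                 "red", "green", NA))        # reader b misses one
  ds <- study_dataset(gold, resp)
  t_red <- build_confusion(ds, "red")
  expect_identical(t_red$n, 5)               # 6 cells minus 1 missing
  expect_identical(t_red$d, 2)               # both readers flag i1 red
  expect_identical(t_red$b + t_red$c, 0)     # perfect agreement
  t_yellow <- build_confusion(ds, "yellow")
  expect_identical(t_yellow$d, 1)

  expect_error(build_confusion(study_dataset(
    gold, data.frame(reader_id = "a", image_id = "i1",
                     referral = NA_character_)), "red"),
    "no non-missing responses")
  expect_error(study_dataset(gold, data.frame(
    reader_id = "a", image_id = "nope", referral = "red")),
    "absent from gold")
})

test_that("Cohen's kappa reproduces the published pilot-study values", {
  tabs <- table2_confusions()
  expect_identical(unname(vapply(tabs, function(t) t$n, numeric(1))),
                   rep(4780, 3))
  k_red <- cohens_kappa(tabs$red)
  expect_equal(round(k_red$kappa, 3), 0.696)
  expect_equal(round(k_red$se_kappa, 3), 0.010)
  expect_identical(k_red$band, "substantial agreement")
  expect_equal(round(cohens_kappa(tabs$yellow)$kappa, 3), 0.462)
  expect_equal(round(cohens_kappa(tabs$green)$kappa, 3), 0.532)

  perfect <- confusion_2x2(10, 0, 0, 10)
  expect_equal(cohens_kappa(perfect)$kappa, 1.0)
  expect_error(cohens_kappa(confusion_2x2(10, 0, 0, 0)), "degenerate")
})

test_that("kappa properties hold on random tables", {
  set.seed(410)
  for (i in 1:1000) {
    cells <- stats::rmultinom(1, size = sample(20:500, 1),
                              prob = stats::runif(4, 0.05, 1))
    if (any(colSums(matrix(cells, 2)) == 0) || any(rowSums(matrix(cells, 2)) == 0)) next
    t <- confusion_2x2(cells[1], cells[2], cells[3], cells[4])
    k <- cohens_kappa(t)
    expect_lte(k$kappa, k$po + 1e-12)
    expect_identical(k$kappa == 1, t$b == 0 && t$c == 0)
    expect_identical(k$band, kappa_band(k$kappa))
  }
})

test_that("agreement bands follow the stated cutoffs after 2 d.p. rounding", {
  expect_identical(kappa_band(0.696), "substantial agreement")
  expect_identical(kappa_band(0.462), "moderate agreement")
  expect_identical(kappa_band(0.405), "moderate agreement")  # rounds to 0.41
  expect_identical(kappa_band(0.15), "slight agreement")
  expect_identical(kappa_band(0.30), "fair agreement")
  expect_identical(kappa_band(0.90), "almost perfect agreement")
  expect_identical(kappa_band(0.004), "unclassified")
  expect_identical(kappa_band(0.995), "unclassified")  # rounds to 1.00
  expect_identical(kappa_band(-0.2), "unclassified")
})

test_that("diagnostics reproduce the published sensitivity/specificity", {
  tabs <- table2_confusions()
  d_red <- diagnostics(tabs$red)
  expect_equal(d_red$percent_correct, 91.5)
  expect_identical(trunc(100 * d_red$sensitivity), 91)
  expect_identical(trunc(100 * d_red$specificity), 78)
  expect_equal(diagnostics(tabs$yellow)$percent_correct, 62.5)
  expect_equal(diagnostics(tabs$green)$percent_correct, 51.2)

  perfect <- diagnostics(confusion_2x2(10, 0, 0, 10))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  expect_equal(perfect$auc, 1)

  expect_error(diagnostics(confusion_2x2(5, 5, 0, 0)), "gold-positive")
  expect_error(diagnostics(confusion_2x2(0, 0, 5, 5)), "gold-negative")
})

test_that("Wilson intervals are ordered, bounded, and cover at nominal rate", {
  ci <- wilson_ci(91, 100)
  expect_true(ci["low"] < 0.91 && 0.91 < ci["high"])
  expect_true(all(wilson_ci(0, 50) >= 0) && all(wilson_ci(50, 50) <= 1))
  # narrower than Wald away from the boundary is not guaranteed; coverage is
  set.seed(411)
  p_true <- 0.8
  x <- stats::rbinom(2000, 200, p_true)
  cover <- vapply(x, function(xi) {
    ci <- wilson_ci(xi, 200)
    ci["low"] <= p_true && p_true <= ci["high"]
  }, logical(1))
  expect_gte(mean(cover), 0.93)
})

test_that("stratification partitions responses and counts are additive", {
  set.seed(412)
  cfg <- simulation_config(n_images = 20, n_readers = 8, seed = 99)
  ds <- simulate_reader_study(cfg)
  by_group <- stratify(ds, "group")
  expect_named(by_group, c("student", "working"))
  expect_length(intersect(unique(by_group$student$responses$reader_id),
                          unique(by_group$working$responses$reader_id)), 0)
  for (cat in c("green", "yellow", "red")) {
    pooled <- build_confusion(ds, cat)
    parts <- lapply(by_group, build_confusion, category = cat)
    for (cell in c("a", "b", "c", "d")) {
      expect_identical(sum(vapply(parts, function(t) t[[cell]], numeric(1))),
                       pooled[[cell]])
    }
  }
  blocks <- stratify(ds, "image-block=10")
  expect_length(blocks, 2)
  expect_identical(nrow(blocks[[1]]$gold), 10L)
  expect_error(stratify(ds, "image-block=7"), "divisor")
  expect_error(stratify(ds, "shoe_size"), "unknown reader attribute")
})

test_that("statistics are invariant to reader relabeling", {
  set.seed(413)
  ds <- simulate_reader_study(simulation_config(n_images = 25, n_readers = 6,
                                                seed = 5))
  perm <- sample(unique(ds$responses$reader_id))
  relabel <- stats::setNames(sprintf("z%02d", seq_along(perm)), perm)
  resp2 <- ds$responses
  resp2$reader_id <- unname(relabel[resp2$reader_id])
  ds2 <- study_dataset(ds$gold, resp2)
  for (cat in c("green", "yellow", "red")) {
    t1 <- build_confusion(ds, cat)
    t2 <- build_confusion(ds2, cat)
    expect_identical(unclass(t1)[c("a", "b", "c", "d")],
                     unclass(t2)[c("a", "b", "c", "d")])
  }
})

test_that("compare_auc is symmetric, null on identical groups, and close to a permutation oracle", {
  tabs <- table2_confusions()
  d <- diagnostics(tabs$red)
  same <- compare_auc(d, d)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  d2 <- diagnostics(tabs$yellow)
  ab <- compare_auc(d, d2)
  ba <- compare_auc(d2, d)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)

  # permutation oracle on a small synthetic study: shuffle reader group
  # labels, recompute the red-category AUC difference
  set.seed(414)
  ds <- simulate_reader_study(simulation_config(n_images = 30, n_readers = 20,
                                                missing_rate = 0, seed = 77))
  groups <- stratify(ds, "group")
  diag_of <- function(d) diagnostics(build_confusion(d, "red"))
  obs <- compare_auc(diag_of(groups[[1]]), diag_of(groups[[2]]))

  # per-reader cell counts let each shuffle be a table sum
  readers <- unique(ds$responses$reader_id)
  gold_of <- stats::setNames(as.character(ds$gold$referral), ds$gold$image_id)
  per_reader <- t(vapply(readers, function(r) {
    rs <- ds$responses[ds$responses$reader_id == r, ]
    gpos <- gold_of[rs$image_id] == "red"
    rpos <- as.character(rs$referral) == "red"
    c(a = sum(!gpos & !rpos), b = sum(!gpos & rpos),
      c = sum(gpos & !rpos), d = sum(gpos & rpos))
  }, numeric(4)))
  auc_of <- function(m) {
    cs <- colSums(m)
    (cs["d"] / (cs["c"] + cs["d"]) + cs["a"] / (cs["a"] + cs["b"])) / 2
  }
  idx1 <- which(readers %in% unique(groups[[1]]$responses$reader_id))
  n1 <- length(idx1)
  obs_diff <- auc_of(per_reader[idx1, , drop = FALSE]) -
    auc_of(per_reader[-idx1, , drop = FALSE])
  perm_diffs <- replicate(10000, {
    idx <- sample(length(readers), n1)
    auc_of(per_reader[idx, , drop = FALSE]) -
      auc_of(per_reader[-idx, , drop = FALSE])
  })
  p_perm <- mean(abs(perm_diffs) >= abs(obs_diff) - 1e-12)
  expect_equal(obs$auc_diff, unname(obs_diff))
  # the large-sample z-test should land near the exact permutation p
  expect_lt(abs(obs$p_value - p_perm), 0.15)
})

test_that("chi-square sample size matches the closed form and scales as 1/w^2", {
  expect_identical(sample_size_chisq(0.05, 0.3, 0.85, df = 1), 100L)
  closed <- ceiling((stats::qnorm(0.975) + stats::qnorm(0.85))^2 / 0.3^2)
  expect_identical(closed, 100)
  n_small <- sample_size_chisq(0.05, 0.3, 0.85, 1)
  n_big <- sample_size_chisq(0.05, 0.6, 0.85, 1)
  expect_lt(abs(n_small / n_big - 4), 0.3)
  expect_gt(sample_size_chisq(0.05, 0.3, 0.85, df = 2),
            sample_size_chisq(0.05, 0.3, 0.85, df = 1))
  expect_error(sample_size_chisq(1.2, 0.3, 0.85), "alpha")
})

test_that("evaluate_study formats a per-category report with display precision", {
  set.seed(415)
  profiles <- lapply(1:5, function(i) {
    reader_profile(diag(3), group = if (i <= 2) "student" else "working")
  })
  ds <- simulate_reader_study(simulation_config(
    n_images = 40, n_readers = 5, profiles = profiles, seed = 11))
  rep <- evaluate_study(ds)
  expect_identical(nrow(rep), 3L)
  expect_identical(rep$category, c("red", "yellow", "green"))
  expect_true(all(rep$kappa == 1))
  expect_true(all(rep$kappa_display == "1.000"))
  expect_true(all(rep$sens_pct == 100L & rep$spec_pct == 100L))

  by_group <- evaluate_study(ds, by = "group")
  expect_identical(nrow(by_group), 9L)
  expect_setequal(unique(by_group$group), c("all", "student", "working"))

  tmp_csv <- withr::local_tempfile(fileext = ".csv")
  tmp_json <- withr::local_tempfile(fileext = ".json")
  write_report(rep, tmp_csv, tmp_json)
  back <- utils::read.csv(tmp_csv)
  expect_equal(back$kappa, rep$kappa)
  expect_identical(nrow(jsonlite::fromJSON(tmp_json)), 3L)
})

test_that("study CSVs round-trip", {
  ds <- simulate_reader_study(simulation_config(n_images = 15, n_readers = 4,
                                                seed = 3))
  g <- withr::local_tempfile(fileext = ".csv")
  r <- withr::local_tempfile(fileext = ".csv")
  rd <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(ds, g, r, rd)
  back <- read_study_csv(g, r, rd)
  expect_identical(back$gold, ds$gold)
  expect_identical(back$responses, ds$responses)
  expect_identical(back$readers, ds$readers)
})
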