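lm_od <- fundus_landmarks(c(200, 100), c(100, 100), 50, "OD")

test_that("quadrant assignment matches the hand-computed fixtures", {
  # fovea side is temporal by construction
  expect_true(quadrant_of(lm_od$fovea_center, lm_od) %in% c(1L, 2L))
  expect_identical(quadrant_of(c(150, 80), lm_od), 1L)   # superior-temporal
  expect_identical(quadrant_of(c(50, 150), lm_od), 4L)   # inferior-nasal
  expect_identical(quadrant_label(1L), "superior-temporal")
})

test_that("degenerate landmarks are rejected", {
  expect_error(fundus_landmarks(c(100, 100), c(100, 100), 50), "degenerate")
  expect_error(fundus_landmarks(c(1, 2), c(3, 4), 0), "positive")
  expect_error(fundus_landmarks(c(1, 2), c(3, 4), 50, "XX"), "laterality")
})

test_that("dividing-line ties go to the temporal and superior sides", {
  # on the horizontal (fovea-disc) line, temporal side -> quadrant 1
  expect_identical(quadrant_of(c(150, 100), lm_od), 1L)
  # on the horizontal line, nasal side -> quadrant 3
  expect_identical(quadrant_of(c(50, 100), lm_od), 3L)
  # on the perpendicular line -> temporal, so quadrant 1 or 2 by side
  expect_identical(quadrant_of(c(100, 60), lm_od), 1L)
  expect_identical(quadrant_of(c(100, 140), lm_od), 2L)
  # disc center itself: both ties -> quadrant 1
  expect_identical(quadrant_of(c(100, 100), lm_od), 1L)
})

test_that("10,000 random points agree with the brute-force half-plane oracle", {
  set.seed(402)
  for (rep in 1:10) {
    lm <- random_landmarks()
    pts <- cbind(stats::runif(1000, 0, 1024), stats::runif(1000, 0, 1024))
    got <- quadrant_of(pts, lm)
    expect_true(all(got %in% 1:4))
    want <- vapply(seq_len(nrow(pts)), function(i) {
      oracle_quadrant(pts[i, ], lm)
    }, integer(1))
    expect_identical(got, want)
  }
})

test_that("macular zones are a monotone step function of fovea distance", {
  expect_identical(macular_zone_of(lm_od$fovea_center, lm_od), "inner")
  expect_identical(macular_zone_of(c(200, 175), lm_od), "mid")    # r = 75, DD = 50
  expect_identical(macular_zone_of(c(200, 200), lm_od), "outer")  # r = 2DD boundary
  expect_identical(macular_zone_of(c(200, 150), lm_od), "mid")    # r = 1DD boundary
  set.seed(403)
  lm <- random_landmarks()
  r <- sort(stats::runif(500, 0, 5 * lm$disc_diameter))
  theta <- stats::runif(1, 0, 2 * pi)
  pts <- cbind(lm$fovea_center[1] + r * cos(theta),
               lm$fovea_center[2] + r * sin(theta))
  zones <- macular_zone_of(pts, lm)
  idx <- match(zones, c("inner", "mid", "outer"))
  expect_true(all(diff(idx) >= 0))
  expect_identical(unique(zones[r < lm$disc_diameter]), "inner")
})

test_that("mirroring the image and swapping laterality preserves labels", {
  set.seed(404)
  w <- 1024
  for (rep in 1:20) {
    lm <- random_landmarks()
    mirror_lm <- fundus_landmarks(
      c(w - lm$fovea_center[1], lm$fovea_center[2]),
      c(w - lm$disc_center[1], lm$disc_center[2]),
      lm$disc_diameter, if (lm$laterality == "OD") "OS" else "OD",
      lm$image_width, lm$image_height)
    pts <- cbind(stats::runif(200, 0, w), stats::runif(200, 0, w))
    mirrored <- cbind(w - pts[, 1], pts[, 2])
    expect_identical(quadrant_of(pts, lm), quadrant_of(mirrored, mirror_lm))
    expect_identical(macular_zone_of(pts, lm),
                     macular_zone_of(mirrored, mirror_lm))
  }
})

test_that("build_form aggregates lesions into the expected counts", {
  expect_identical(build_form(list(), lm_od),
                   eye_grading_form(laterality = "OD"))

  # 21 red dots constructed in each quadrant, verified back by the oracle
  set.seed(405)
  lesions <- list()
  for (q in 1:4) {
    for (i in 1:21) {
      p <- drtriage:::point_in_quadrant(lm_od, q,
                                        stats::runif(1, 10, 40),
                                        stats::runif(1, 130, 180))
      expect_identical(oracle_quadrant(p, lm_od), q)
      lesions[[length(lesions) + 1L]] <- annotated_lesion("red_dots_blots", p)
    }
  }
  f <- build_form(lesions, lm_od)
  counts <- vapply(f$quadrants, function(q) q$red_dot_count, integer(1))
  expect_identical(counts, rep(21L, 4))
  expect_identical(sum(counts), 84L)  # conservation

  # hard exudate at 0.5 DD from fovea: inner macular zone + its quadrant
  p <- lm_od$fovea_center + c(0, 25)
  f2 <- build_form(list(annotated_lesion("hard_exudates", p)), lm_od)
  expect_true(f2$macula$inner_hard_exudates)
  q <- quadrant_of(p, lm_od)
  expect_true(f2$quadrants[[q]]$hard_exudates)

  # microaneurysms_only only when every red dot in the quadrant is flagged
  p1 <- drtriage:::point_in_quadrant(lm_od, 1, 20, 150)
  p2 <- drtriage:::point_in_quadrant(lm_od, 1, 30, 160)
  f3 <- build_form(list(
    annotated_lesion("red_dots_blots", p1, microaneurysm = TRUE),
    annotated_lesion("red_dots_blots", p2, microaneurysm = FALSE)), lm_od)
  expect_false(f3$quadrants[[1]]$microaneurysms_only)
  f4 <- build_form(list(
    annotated_lesion("red_dots_blots", p1, microaneurysm = TRUE)), lm_od)
  expect_true(f4$quadrants[[1]]$microaneurysms_only)

  # global lesions set global flags only
  f5 <- build_form(list(annotated_lesion("vitreous_preretinal_hemorrhage"),
                        annotated_lesion("detached_retina")), lm_od)
  expect_true(f5$vitreous_preretinal_hemorrhage)
  expect_true(f5$detached_retina)
})

test_that("red-dot conservation holds for random lesion sets", {
  set.seed(406)
  for (rep in 1:25) {
    lm <- random_landmarks()
    n <- sample(0:60, 1)
    lesions <- lapply(seq_len(n), function(i) {
      annotated_lesion("red_dots_blots",
                       c(stats::runif(1, 0, 1024), stats::runif(1, 0, 1024)),
                       microaneurysm = stats::runif(1) < 0.5)
    })
    f <- build_form(lesions, lm)
    expect_identical(sum(vapply(f$quadrants, function(q) q$red_dot_count,
                                integer(1))), n)
  }
})

test_that("localizable lesions require a location", {
  expect_error(annotated_lesion("hard_exudates"), "requires a location")
  expect_error(annotated_lesion("bogus_type", c(1, 2)), "unknown lesion_type")
  # global lesions drop any supplied location
  l <- annotated_lesion("detached_retina", c(1, 2))
  expect_null(l$location)
})

test_that("annotation files round-trip and zone tables are correct", {
  set.seed(407)
  lm <- random_landmarks()
  lesions <- list(
    annotated_lesion("red_dots_blots", c(300, 300), microaneurysm = TRUE),
    annotated_lesion("irma", c(500, 200), prominent = TRUE),
    annotated_lesion("vitreous_preretinal_hemorrhage"))
  ann <- list(landmarks = lm, lesions = lesions, va = visual_acuity(20, 30))
  tmp <- withr::local_tempfile(fileext = ".json")
  write_annotations_json(ann, tmp)
  back <- read_annotations_json(tmp)
  # JSON text carries ~15 significant digits, so landmark doubles round-trip
  # to within relative 1e-12, not bit-exactly
  expect_equal(back$landmarks, lm, tolerance = 1e-12)
  expect_identical(back$lesions, lesions)
  expect_identical(back$va, ann$va)

  tab <- lesion_zone_table(lesions, lm)
  expect_identical(nrow(tab), 3L)
  expect_true(is.na(tab$quadrant_id[3]))
  expect_identical(tab$quadrant_id[1], quadrant_of(c(300, 300), lm))
  expect_identical(tab$zone[2], macular_zone_of(c(500, 200), lm))
})
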