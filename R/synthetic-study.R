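# Simulators: multi-reader referral studies with known per-reader
# confusion matrices and a stated missing-response rate, and fundus
# annotation sets whose expected triage outcome is a certificate by
# construction. These make every other module testable without any
# external data.

#' Reader error profile
#'
#' A reader is modeled as a 3x3 row-stochastic confusion matrix
#' P(response | gold) over the referral categories, plus a probability of
#' leaving a response blank. Readers are conditionally independent given
#' the gold label; an optional per-image difficulty weight (see
#' [simulation_config()]) mixes each row toward uniform guessing.
#'
#' @param confusion 3x3 matrix with rows and columns in the order green,
#'   yellow, red; each row must sum to 1 (tolerance 1e-12).
#' @param missing_rate Probability in [0, 1) of a missing response.
#' @param group,prior_grading Reader attributes used for stratification.
#' @return Object of class `reader_profile`.
#' @export
reader_profile <- function(confusion = default_reader_confusion(),
                           missing_rate = 0,
                           group = "working", prior_grading = FALSE) {
  confusion <- as.matrix(confusion)
  if (!all(dim(confusion) == c(3L, 3L)) || any(confusion < 0)) {
    stop("confusion must be a non-negative 3x3 matrix")
  }
  if (any(abs(rowSums(confusion) - 1) > 1e-12)) {
    stop("confusion rows must each sum to 1")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)")
  }
  dimnames(confusion) <- list(gold = referral_tokens,
                              response = referral_tokens)
  structure(list(confusion = confusion, missing_rate = missing_rate,
                 group = group, prior_grading = isTRUE(prior_grading)),
            class = "reader_profile")
}

#' Default reader confusion matrix
#'
#' Derived from the validation study's published one-vs-rest margins. The
#' three 2x2 tables pin the full 3x3 reader-vs-gold joint table down to
#' one free parameter; it is fixed so that misgrades of immediate-referral
#' images fall entirely in the adjacent 6-month category. The resulting
#' rates reproduce all published margins in expectation.
#'
#' @return 3x3 row-stochastic matrix, categories ordered green, yellow,
#'   red.
#' @export
default_reader_confusion <- function() {
  counts <- rbind(green = c(583, 339, 216),
                  yellow = c(159, 776, 306),
                  red = c(0, 204, 2197))
  m <- counts / rowSums(counts)
  dimnames(m) <- list(gold = referral_tokens, response = referral_tokens)
  m
}

#' Default gold-label mix of study images
#'
#' Inferred from the validation study's response margins (2401 red, 1241
#' yellow, 1138 green of 4780): the per-image mix is not published, so
#' these proportions are the response-margin estimate.
#'
#' @return Named proportions over green, yellow, red summing to 1.
#' @export
default_gold_proportions <- function() {
  p <- c(green = 1138, yellow = 1241, red = 2401) / 4780
  p
}

#' Simulation configuration for a reader study
#'
#' Defaults restate the validation study's design: 50 images, 99 readers,
#' missing responses at rate 170/4950, reader behavior from
#' [default_reader_confusion()] and gold mix from
#' [default_gold_proportions()]. Roughly half the readers are labeled
#' students, and one in ten carries prior grading experience, matching the
#' published cohort description.
#'
#' @param n_images Number of images.
#' @param n_readers Number of readers (ignored when `profiles` is given).
#' @param gold_proportions Length-3 proportions (green, yellow, red)
#'   summing to 1.
#' @param profiles A single [reader_profile()] applied to all readers, or
#'   a list of one profile per reader.
#' @param missing_rate Convenience override applied to all profiles.
#' @param difficulty Optional per-image weights in [0, 1]; weight d mixes
#'   each reader's confusion row toward uniform: (1-d) P + d/3. Default
#'   `NULL` (off).
#' @param seed Integer random seed; the simulation is fully reproducible
#'   from it.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_images = 50L,
                              n_readers = 99L,
                              gold_proportions = default_gold_proportions(),
                              profiles = NULL,
                              missing_rate = 170 / 4950,
                              difficulty = NULL,
                              seed = 1L) {
  stopifnot(n_images > 0, n_readers > 0)
  gold_proportions <- as.numeric(gold_proportions)
  if (length(gold_proportions) != 3L || any(gold_proportions < 0) ||
      abs(sum(gold_proportions) - 1) > 1e-9) {
    stop("gold_proportions must be 3 non-negative values summing to 1")
  }
  if (is.null(profiles)) {
    half <- seq_len(n_readers) <= ceiling(n_readers / 2)
    profiles <- lapply(seq_len(n_readers), function(i) {
      reader_profile(default_reader_confusion(), missing_rate,
                     group = if (half[i]) "student" else "working",
                     prior_grading = (i %% 10L == 0L))
    })
  } else if (inherits(profiles, "reader_profile")) {
    profiles <- lapply(seq_len(n_readers), function(i) {
      p <- profiles
      p$missing_rate <- missing_rate
      p
    })
  } else {
    stopifnot(all(vapply(profiles, inherits, logical(1), "reader_profile")))
    n_readers <- length(profiles)
  }
  if (!is.null(difficulty)) {
    stopifnot(length(difficulty) == n_images,
              all(difficulty >= 0 & difficulty <= 1))
  }
  structure(list(n_images = as.integer(n_images),
                 n_readers = as.integer(n_readers),
                 gold_proportions = stats::setNames(gold_proportions,
                                                    referral_tokens),
                 profiles = profiles, difficulty = difficulty,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-reader referral study
#'
#' Gold labels are drawn from the configured proportions; each reader's
#' response to each image is drawn from the reader's confusion row for the
#' image's gold label (optionally mixed toward uniform by the image's
#' difficulty weight) and then dropped with the reader's missing rate.
#' Identical seeds give identical datasets.
#'
#' @param cfg A [simulation_config()].
#' @return A [study_dataset()].
#' @export
simulate_reader_study <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  image_ids <- sprintf("img%04d", seq_len(cfg$n_images))
  reader_ids <- sprintf("r%03d", seq_len(cfg$n_readers))
  gold <- sample(referral_tokens, cfg$n_images, replace = TRUE,
                 prob = cfg$gold_proportions)
  gold_idx <- match(gold, referral_tokens)
  rows <- vector("list", cfg$n_readers)
  for (r in seq_len(cfg$n_readers)) {
    prof <- cfg$profiles[[r]]
    resp <- character(cfg$n_images)
    for (g in 1:3) {
      sel <- which(gold_idx == g)
      if (!length(sel)) next
      if (is.null(cfg$difficulty)) {
        resp[sel] <- sample(referral_tokens, length(sel), replace = TRUE,
                            prob = prof$confusion[g, ])
      } else {
        for (i in sel) {
          d <- cfg$difficulty[i]
          p <- (1 - d) * prof$confusion[g, ] + d / 3
          resp[i] <- sample(referral_tokens, 1L, prob = p)
        }
      }
    }
    if (prof$missing_rate > 0) {
      resp[stats::runif(cfg$n_images) < prof$missing_rate] <- NA_character_
    }
    rows[[r]] <- data.frame(reader_id = reader_ids[r], image_id = image_ids,
                            referral = resp, stringsAsFactors = FALSE)
  }
  readers <- data.frame(
    reader_id = reader_ids,
    group = vapply(cfg$profiles, function(p) p$group, character(1)),
    prior_grading = vapply(cfg$profiles, function(p) p$prior_grading,
                           logical(1)),
    stringsAsFactors = FALSE)
  study_dataset(
    gold = data.frame(image_id = image_ids, referral = gold,
                      stringsAsFactors = FALSE),
    responses = do.call(rbind, rows),
    readers = readers)
}

# Deterministic placement of a lesion inside quadrant `q` that is
# guaranteed to fall in the outer macular zone (distance from fovea at
# least 2.5 DD because the perpendicular offset alone exceeds it).
outer_zone_point <- function(lm, q) {
  dd <- lm$disc_diameter
  point_in_quadrant(lm, q, a_off = stats::runif(1, 0.3, 0.9) * dd,
                    s_off = stats::runif(1, 2.6, 3.4) * dd)
}

#' Simulate one fundus annotation case with a known triage outcome
#'
#' Builds a lesion set that provably triages to `target` by instantiating
#' one rule of the decision matrix (chosen at random among the target's
#' rules): green via a few microaneurysm-flagged red dots, yellow via e.g.
#' a cotton-wool spot, hard exudates, non-prominent IRMA or single-quadrant
#' venous beading, red via the 4-2-1 criteria, new vessels, global
#' lesions, or an inner-zone macular lesion. The returned `expected`
#' fields are the construction's certificate.
#'
#' @param target Referral token green/yellow/red.
#' @param lm A [fundus_landmarks()].
#' @param seed Optional integer seed.
#' @return List: `lesions`, `expected_referral` (a [referral_category()]),
#'   `recipe` (which rule was instantiated).
#' @export
simulate_fundus_case <- function(target, lm, seed = NULL) {
  stopifnot(inherits(lm, "fundus_landmarks"))
  target <- as.character(referral_category(target))
  if (!is.null(seed)) set.seed(seed)
  dd <- lm$disc_diameter
  rd <- function(q, ma) annotated_lesion("red_dots_blots", outer_zone_point(lm, q),
                                         microaneurysm = ma)
  recipe <- switch(target,
    green = sample(c("ma_only", "ma_only_multi"), 1L),
    yellow = sample(c("cotton_wool", "hard_exudates", "red_dots",
                      "irma_nonprominent", "venous_beading_1q",
                      "macula_mid"), 1L),
    red = sample(c("hemorrhages_4q", "venous_beading_2q", "irma_prominent",
                   "nvd", "nve", "vitreous_hemorrhage", "detached_retina",
                   "macula_inner"), 1L))
  lesions <- switch(recipe,
    ma_only = lapply(seq_len(sample(1:3, 1L)), function(i) {
      rd(sample(1:4, 1L), ma = TRUE)
    }),
    ma_only_multi = unlist(lapply(sample(1:4, 2L), function(q) {
      lapply(seq_len(sample(1:2, 1L)), function(i) rd(q, ma = TRUE))
    }), recursive = FALSE),
    cotton_wool = list(annotated_lesion("cotton_wool_spots",
                                        outer_zone_point(lm, sample(1:4, 1L)))),
    hard_exudates = list(annotated_lesion("hard_exudates",
                                          outer_zone_point(lm, sample(1:4, 1L)))),
    red_dots = lapply(seq_len(sample(2:6, 1L)), function(i) {
      rd(sample(1:4, 1L), ma = FALSE)
    }),
    irma_nonprominent = list(annotated_lesion("irma",
                                              outer_zone_point(lm, sample(1:4, 1L)),
                                              prominent = FALSE)),
    venous_beading_1q = list(annotated_lesion("venous_abnormality",
                                              outer_zone_point(lm, sample(1:4, 1L)))),
    macula_mid = {
      theta <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 1.2, 1.8) * dd
      list(annotated_lesion("hard_exudates",
                            lm$fovea_center + r * c(cos(theta), sin(theta))))
    },
    hemorrhages_4q = unlist(lapply(1:4, function(q) {
      lapply(1:21, function(i) rd(q, ma = FALSE))
    }), recursive = FALSE),
    venous_beading_2q = lapply(sample(1:4, 2L), function(q) {
      annotated_lesion("venous_abnormality", outer_zone_point(lm, q))
    }),
    irma_prominent = list(annotated_lesion("irma",
                                           outer_zone_point(lm, sample(1:4, 1L)),
                                           prominent = TRUE)),
    nvd = list(annotated_lesion("nvd",
                                point_in_quadrant(lm, sample(1:4, 1L),
                                                  0.2 * dd, 0.2 * dd))),
    nve = list(annotated_lesion("nve", outer_zone_point(lm, sample(1:4, 1L)))),
    vitreous_hemorrhage = list(annotated_lesion("vitreous_preretinal_hemorrhage")),
    detached_retina = list(annotated_lesion("detached_retina")),
    macula_inner = {
      theta <- stats::runif(1, 0, 2 * pi)
      r <- stats::runif(1, 0.2, 0.8) * dd
      list(annotated_lesion(sample(c("hard_exudates", "red_dots_blots"), 1L),
                            lm$fovea_center + r * c(cos(theta), sin(theta))))
    })
  list(lesions = lesions,
       expected_referral = referral_category(target),
       recipe = recipe)
}
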