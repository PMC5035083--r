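# Independent oracles and random-case generators shared across test files.
# Each oracle is a deliberately naive reimplementation kept separate from
# the package's own code path.

# Brute-force half-plane quadrant oracle: classify by explicit side tests
# (nearest-axis-endpoint comparison for temporal/nasal, cross-product sign
# for superior/inferior) rather than signed axis coordinates.
oracle_quadrant <- function(p, lm) {
  f <- lm$fovea_center
  dc <- lm$disc_center
  u <- (f - dc) / sqrt(sum((f - dc)^2))
  # temporal iff p is closer to a probe point on the fovea side of the
  # perpendicular line than to its mirror on the nasal side
  probe <- dc + u
  mirror <- dc - u
  d_t <- sum((p - probe)^2)
  d_n <- sum((p - mirror)^2)
  temporal <- d_t <= d_n
  # superior via the sign of the z cross product of (fovea - disc) x (p - disc)
  cr <- (f[1] - dc[1]) * (p[2] - dc[2]) - (f[2] - dc[2]) * (p[1] - dc[1])
  superior <- if (lm$laterality == "OD") cr <= 0 else cr >= 0
  if (temporal && superior) 1L else if (temporal) 2L else if (superior) 3L else 4L
}

# Flat truth-table color oracle: the decision matrix written as direct
# logical expressions over a form, independent of the rule-table
# interpreter in mark_boxes().
oracle_color <- function(form) {
  cnt <- vapply(form$quadrants, function(q) q$red_dot_count, integer(1))
  ma <- vapply(form$quadrants, function(q) q$microaneurysms_only, logical(1))
  he <- vapply(form$quadrants, function(q) q$hard_exudates, logical(1))
  cw <- vapply(form$quadrants, function(q) q$cotton_wool, logical(1))
  vb <- vapply(form$quadrants, function(q) q$venous_beading, logical(1))
  ip <- vapply(form$quadrants, function(q) q$irma_present, logical(1))
  ipr <- vapply(form$quadrants, function(q) q$irma_prominent, logical(1))
  nvd <- vapply(form$quadrants, function(q) q$nvd, logical(1))
  nve <- vapply(form$quadrants, function(q) q$nve, logical(1))
  mac <- form$macula
  if (all(cnt > 20) ||
      sum(vb) >= 2 ||
      any(ipr) ||
      any(nvd) || any(nve) ||
      form$vitreous_preretinal_hemorrhage ||
      form$detached_retina ||
      mac$inner_hard_exudates || mac$inner_red_dots) {
    return("red")
  }
  if (any(cnt > 0 & !ma) ||
      any(he) || any(cw) ||
      sum(vb) == 1 ||
      any(ip & !ipr) ||
      mac$mid_hard_exudates || mac$mid_red_dots) {
    return("yellow")
  }
  "green"
}

oracle_referral <- function(form) {
  col <- oracle_color(form)
  if (col == "yellow" && !is.null(form$visual_acuity) &&
      form$visual_acuity$snellen_numerator /
        form$visual_acuity$snellen_denominator < 0.5) {
    col <- "red"
  }
  col
}

# Random valid grading form. Sparse by default so all referral classes
# appear with useful frequency.
random_form <- function(p_flag = 0.08) {
  quads <- lapply(1:4, function(i) {
    cnt <- sample(c(0L, 0L, 0L, 1L, 3L, 21L, 25L), 1L)
    irma <- stats::runif(1) < p_flag
    quadrant_findings(
      i, red_dot_count = cnt,
      microaneurysms_only = cnt > 0L && stats::runif(1) < 0.5,
      hard_exudates = stats::runif(1) < p_flag,
      cotton_wool = stats::runif(1) < p_flag,
      venous_beading = stats::runif(1) < p_flag,
      irma_present = irma,
      irma_prominent = irma && stats::runif(1) < 0.4,
      nvd = stats::runif(1) < p_flag / 2,
      nve = stats::runif(1) < p_flag / 2)
  })
  mac <- macular_findings(
    inner_hard_exudates = stats::runif(1) < p_flag / 2,
    inner_red_dots = stats::runif(1) < p_flag / 2,
    mid_hard_exudates = stats::runif(1) < p_flag,
    mid_red_dots = stats::runif(1) < p_flag,
    outer_hard_exudates = stats::runif(1) < p_flag,
    outer_red_dots = stats::runif(1) < p_flag)
  va <- if (stats::runif(1) < 0.5) NULL else
    visual_acuity(20, sample(c(20, 30, 40, 60, 100, 200), 1L))
  eye_grading_form(sample(c("OD", "OS"), 1L), quads, mac,
                   vitreous_preretinal_hemorrhage = stats::runif(1) < 0.02,
                   detached_retina = stats::runif(1) < 0.02,
                   visual_acuity = va)
}

# Apply 1-3 random augmenting edits to a form: strictly more findings,
# more quadrants, more central macular involvement, or worse acuity.
# Every edit preserves validity and can only push the referral upward.
augment_form <- function(form) {
  for (k in seq_len(sample(1:3, 1L))) {
    op <- sample(c("dots", "flag", "macula", "va", "global"), 1L)
    if (op == "dots") {
      i <- sample(1:4, 1L)
      q <- form$quadrants[[i]]
      add <- sample(c(1L, 21L), 1L)
      if (q$red_dot_count == 0L) {
        q$red_dot_count <- add
        q$microaneurysms_only <- stats::runif(1) < 0.5
      } else {
        q$red_dot_count <- q$red_dot_count + add
        # grader may withdraw the microaneurysms-only assertion, never add it
        if (q$microaneurysms_only && stats::runif(1) < 0.5) {
          q$microaneurysms_only <- FALSE
        }
      }
      form$quadrants[[i]] <- q
    } else if (op == "flag") {
      i <- sample(1:4, 1L)
      q <- form$quadrants[[i]]
      fl <- sample(c("hard_exudates", "cotton_wool", "venous_beading",
                     "irma_present", "irma_prominent", "nvd", "nve"), 1L)
      q[[fl]] <- TRUE
      if (fl == "irma_prominent") q$irma_present <- TRUE
      form$quadrants[[i]] <- q
    } else if (op == "macula") {
      fl <- sample(names(unclass(form$macula)), 1L)
      form$macula[[fl]] <- TRUE
    } else if (op == "va") {
      cur <- form$visual_acuity
      if (is.null(cur)) {
        form$visual_acuity <- visual_acuity(20, sample(c(60, 100, 200), 1L))
      } else {
        form$visual_acuity <- visual_acuity(
          cur$snellen_numerator, cur$snellen_denominator * sample(2:4, 1L))
      }
    } else {
      fl <- sample(c("vitreous_preretinal_hemorrhage", "detached_retina"), 1L)
      form[[fl]] <- TRUE
    }
  }
  form
}

# Enumerate the discretized quadrant-state space for the truth-table
# check: red-dot counts in {0, 1, 21} x valid microaneurysm flag x all
# boolean combinations of the remaining findings, laid out either in one
# quadrant or in all four.
enumerate_matrix_forms <- function() {
  states <- list()
  for (cnt in c(0L, 1L, 21L)) {
    mas <- if (cnt > 0L) c(FALSE, TRUE) else FALSE
    for (ma in mas) for (he in c(FALSE, TRUE)) for (cw in c(FALSE, TRUE)) {
      for (vb in c(FALSE, TRUE)) for (irma in c("none", "present", "prominent")) {
        for (nvd in c(FALSE, TRUE)) for (nve in c(FALSE, TRUE)) {
          states[[length(states) + 1L]] <- list(
            cnt = cnt, ma = ma, he = he, cw = cw, vb = vb,
            ip = irma != "none", ipr = irma == "prominent",
            nvd = nvd, nve = nve)
        }
      }
    }
  }
  make_q <- function(i, s) {
    quadrant_findings(i, s$cnt, s$ma, s$he, s$cw, s$vb, s$ip, s$ipr,
                      s$nvd, s$nve)
  }
  forms <- list()
  empty <- list(cnt = 0L, ma = FALSE, he = FALSE, cw = FALSE, vb = FALSE,
                ip = FALSE, ipr = FALSE, nvd = FALSE, nve = FALSE)
  for (s in states) {
    forms[[length(forms) + 1L]] <- eye_grading_form(
      quadrants = c(list(make_q(1L, s)), lapply(2:4, make_q, empty)))
    forms[[length(forms) + 1L]] <- eye_grading_form(
      quadrants = lapply(1:4, make_q, s))
  }
  # macular-zone and global-flag space over empty quadrants
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 8))
  names(grid) <- c("ihe", "ird", "mhe", "mrd", "ohe", "ord", "vph", "det")
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    forms[[length(forms) + 1L]] <- eye_grading_form(
      macula = macular_findings(g$ihe, g$ird, g$mhe, g$mrd, g$ohe, g$ord),
      vitreous_preretinal_hemorrhage = g$vph, detached_retina = g$det)
  }
  forms
}

referral_of <- function(form) as.character(eye_referral(form)$referral)

random_landmarks <- function() {
  dd <- stats::runif(1, 30, 80)
  disc <- c(stats::runif(1, 200, 800), stats::runif(1, 200, 800))
  theta <- stats::runif(1, 0, 2 * pi)
  fovea <- disc + stats::runif(1, 2, 3) * dd * c(cos(theta), sin(theta))
  fundus_landmarks(fovea, disc, dd, sample(c("OD", "OS"), 1L),
                   image_width = 1024, image_height = 1024)
}
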