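# The red-green-yellow decision matrix and the referral logic built on it.
#
# Every colored cell of the triage chart lives in one declarative table
# (default_color_matrix()), so an alternate reconstruction of the chart is
# a config swap, not a code change. mark_boxes() interprets that table
# against a grading form; eye_referral() adds the acuity escalation and
# patient_referral() combines the two eyes.

# Per-quadrant predicates the matrix rules can count. Returns a 4 x p
# logical matrix, rows in quadrant-id order.
quadrant_predicates <- function(form) {
  m <- t(vapply(form$quadrants, function(q) {
    c(red_gt20 = q$red_dot_count > 20L,
      red_not_ma_only = q$red_dot_count > 0L && !q$microaneurysms_only,
      red_ma_only = q$red_dot_count > 0L && q$microaneurysms_only,
      hard_exudates = q$hard_exudates,
      cotton_wool = q$cotton_wool,
      venous_beading = q$venous_beading,
      irma_prominent = q$irma_prominent,
      irma_nonprominent = q$irma_present && !q$irma_prominent,
      nvd = q$nvd,
      nve = q$nve)
  }, logical(10)))
  rownames(m) <- vapply(form$quadrants, function(q) as.character(q$quadrant_id),
                        character(1))
  m
}

#' The default red-green-yellow decision matrix
#'
#' One row per colored box of the triage chart. `kind` selects the
#' evaluator: `quadrant_count` counts quadrants where the per-quadrant
#' predicate named by `finding` holds and fires when the count is in
#' `[min_quadrants, max_quadrants]` (NA max means 4); `global` tests a
#' per-eye flag; `macula` fires when the zone named by `finding` has hard
#' exudates or red dots/blots.
#'
#' Red boxes encode severe non-proliferative disease (the 4-2-1 rule:
#' more than 20 hemorrhages in all 4 quadrants, venous beading in 2 or
#' more quadrants, prominent IRMA in any quadrant), proliferative disease
#' (new vessels, vitreous/preretinal hemorrhage, detachment) and the
#' macular-edema surrogate (lesions within 1 DD of the fovea). Yellow
#' boxes encode moderate disease: any finding beyond microaneurysms that
#' falls short of a red box. The single green box is the
#' microaneurysms-only (mild) row.
#'
#' @return Data frame with columns `rule_id`, `color`, `kind`, `finding`,
#'   `min_quadrants`, `max_quadrants`, `description`.
#' @export
default_color_matrix <- function() {
  r <- function(rule_id, color, kind, finding, min_q = NA, max_q = NA, desc) {
    data.frame(rule_id = rule_id, color = color, kind = kind,
               finding = finding, min_quadrants = min_q, max_quadrants = max_q,
               description = desc, stringsAsFactors = FALSE)
  }
  rbind(
    r("R1", "red", "quadrant_count", "red_gt20", 4, NA,
      "more than 20 intraretinal hemorrhages in each of 4 quadrants"),
    r("R2", "red", "quadrant_count", "venous_beading", 2, NA,
      "definite venous beading in 2+ quadrants"),
    r("R3", "red", "quadrant_count", "irma_prominent", 1, NA,
      "prominent IRMA in 1+ quadrant"),
    r("R4", "red", "quadrant_count", "nvd", 1, NA,
      "neovascularization at the disc"),
    r("R5", "red", "quadrant_count", "nve", 1, NA,
      "neovascularization elsewhere"),
    r("R6", "red", "global", "vitreous_preretinal_hemorrhage", NA, NA,
      "vitreous or preretinal hemorrhage"),
    r("R7", "red", "global", "detached_retina", NA, NA,
      "tractional or combined retinal detachment"),
    r("R8", "red", "macula", "inner", NA, NA,
      "macular edema surrogate: lesions within 1 DD of fovea"),
    r("Y1", "yellow", "quadrant_count", "red_not_ma_only", 1, NA,
      "red dots/blots beyond microaneurysms in 1+ quadrant"),
    r("Y2", "yellow", "quadrant_count", "hard_exudates", 1, NA,
      "hard exudates in any quadrant"),
    r("Y3", "yellow", "quadrant_count", "cotton_wool", 1, NA,
      "cotton wool spots in any quadrant"),
    r("Y4", "yellow", "quadrant_count", "venous_beading", 1, 1,
      "venous beading in exactly 1 quadrant"),
    r("Y5", "yellow", "quadrant_count", "irma_nonprominent", 1, NA,
      "IRMA present but not prominent"),
    r("Y6", "yellow", "macula", "mid",  NA, NA,
      "macular lesions between 1 and 2 DD of fovea"),
    r("G1", "green", "quadrant_count", "red_ma_only", 1, NA,
      "microaneurysms only (mild NPDR)")
  )
}

#' Load / save a color matrix as JSON
#'
#' For sensitivity analysis the decision matrix can be serialized and an
#' alternate reconstruction loaded at run time (`triage --matrix`).
#'
#' @param path JSON file path.
#' @return `read_color_matrix`: the matrix data frame.
#' @export
read_color_matrix <- function(path) {
  df <- jsonlite::fromJSON(path)
  needed <- c("rule_id", "color", "kind", "finding")
  if (!all(needed %in% names(df))) {
    stop("color matrix JSON must provide columns: ",
         paste(needed, collapse = ", "))
  }
  if (is.null(df$min_quadrants)) df$min_quadrants <- NA_real_
  if (is.null(df$max_quadrants)) df$max_quadrants <- NA_real_
  if (is.null(df$description)) df$description <- df$rule_id
  df
}

#' @rdname read_color_matrix
#' @param matrix A color matrix data frame.
#' @export
write_color_matrix <- function(matrix, path) {
  writeLines(jsonlite::toJSON(matrix, dataframe = "rows", pretty = TRUE,
                              na = "null", digits = NA), path)
  invisible(path)
}

color_mark <- function(color, rule_id, finding, description,
                       quadrants = integer(0), zone = NULL) {
  structure(
    list(color = color, rule_id = rule_id, finding = finding,
         description = description, quadrants = quadrants, zone = zone),
    class = "color_mark"
  )
}

#' @export
print.color_mark <- function(x, ...) {
  where <- if (length(x$quadrants)) {
    paste0(" [Q", paste(x$quadrants, collapse = ",Q"), "]")
  } else if (!is.null(x$zone)) paste0(" [macula ", x$zone, "]") else ""
  cat(sprintf("%-6s %s: %s%s\n", toupper(x$color), x$rule_id,
              x$description, where))
  invisible(x)
}

#' Mark the colored boxes for a grading form
#'
#' Evaluates every rule of the decision matrix against the form and
#' returns the marks that fire, each carrying an audit trail (rule id,
#' finding, quadrants or macular zone). A form with no findings at all
#' yields a single green "no DR" mark.
#'
#' @param form A valid [eye_grading_form()].
#' @param matrix Decision matrix; defaults to [default_color_matrix()].
#' @return List of `color_mark` objects.
#' @export
mark_boxes <- function(form, matrix = default_color_matrix()) {
  stop_if_invalid(form)
  preds <- quadrant_predicates(form)
  marks <- list()
  for (i in seq_len(nrow(matrix))) {
    rule <- matrix[i, ]
    if (rule$kind == "quadrant_count") {
      if (!(rule$finding %in% colnames(preds))) {
        stop("unknown quadrant predicate in matrix: ", rule$finding)
      }
      hit <- preds[, rule$finding]
      nq <- sum(hit)
      max_q <- if (is.na(rule$max_quadrants)) 4 else rule$max_quadrants
      if (nq >= rule$min_quadrants && nq <= max_q) {
        marks[[length(marks) + 1L]] <- color_mark(
          rule$color, rule$rule_id, rule$finding, rule$description,
          quadrants = as.integer(rownames(preds)[hit]))
      }
    } else if (rule$kind == "global") {
      if (isTRUE(form[[rule$finding]])) {
        marks[[length(marks) + 1L]] <- color_mark(
          rule$color, rule$rule_id, rule$finding, rule$description)
      }
    } else if (rule$kind == "macula") {
      zone <- rule$finding
      he <- isTRUE(form$macula[[paste0(zone, "_hard_exudates")]])
      rd <- isTRUE(form$macula[[paste0(zone, "_red_dots")]])
      if (he || rd) {
        src <- c("hard_exudates", "red_dots_blots")[c(he, rd)]
        marks[[length(marks) + 1L]] <- color_mark(
          rule$color, rule$rule_id, paste(src, collapse = "+"),
          rule$description, zone = zone)
      }
    } else {
      stop("unknown rule kind in matrix: ", rule$kind)
    }
  }
  if (length(marks) == 0L) {
    marks[[1L]] <- color_mark("green", "G0", "none",
                              "no evidence of clinical signs of DR")
  }
  marks
}

#' Severity on the international 5-step scale
#'
#' Derived from the same findings as the color marks: proliferative
#' disease if new vessels, vitreous/preretinal hemorrhage or detachment;
#' severe NPDR if any 4-2-1 criterion holds; moderate NPDR for any lesser
#' finding beyond microaneurysms (including mid-zone macular lesions);
#' mild NPDR for microaneurysms only; otherwise no DR. Macular edema is
#' carried separately as `dme_present` (inner-zone finding).
#'
#' @param form A valid [eye_grading_form()].
#' @return List with `severity` (a [severity_level()]) and `dme_present`.
#' @export
classify_severity <- function(form) {
  stop_if_invalid(form)
  preds <- quadrant_predicates(form)
  nq <- colSums(preds)
  dme <- isTRUE(form$macula$inner_hard_exudates) ||
    isTRUE(form$macula$inner_red_dots)
  mid <- isTRUE(form$macula$mid_hard_exudates) ||
    isTRUE(form$macula$mid_red_dots)
  sev <- if (nq["nvd"] >= 1 || nq["nve"] >= 1 ||
             form$vitreous_preretinal_hemorrhage || form$detached_retina) {
    "pdr"
  } else if (nq["red_gt20"] >= 4 || nq["venous_beading"] >= 2 ||
             nq["irma_prominent"] >= 1) {
    "severe_npdr"
  } else if (nq["red_not_ma_only"] >= 1 || nq["hard_exudates"] >= 1 ||
             nq["cotton_wool"] >= 1 || nq["venous_beading"] >= 1 ||
             nq["irma_nonprominent"] >= 1 || mid || dme) {
    "moderate_npdr"
  } else if (nq["red_ma_only"] >= 1) {
    "mild_npdr"
  } else {
    "no_dr"
  }
  list(severity = severity_level(sev), dme_present = dme)
}

#' Triage one eye
#'
#' Marks the boxes, classifies severity, and derives the referral: red if
#' any red box, else yellow if any yellow box, else green. A yellow eye
#' whose acuity is worse than 20/40 escalates to red (`va_escalated`),
#' with an extra audit mark; a green eye with poor acuity stays green but
#' the result carries a warning note.
#'
#' @param form A valid [eye_grading_form()].
#' @param matrix Decision matrix override.
#' @return Object of class `triage_result` with elements `marks`,
#'   `severity`, `dme_present`, `referral`, `va_escalated`, `notes`.
#' @export
eye_referral <- function(form, matrix = default_color_matrix()) {
  marks <- mark_boxes(form, matrix)
  cls <- classify_severity(form)
  colors <- vapply(marks, function(m) m$color, character(1))
  base <- if (any(colors == "red")) "red" else
    if (any(colors == "yellow")) "yellow" else "green"
  va_escalated <- FALSE
  notes <- character(0)
  poor_va <- va_worse_than_20_40(form$visual_acuity)
  if (base == "yellow" && poor_va) {
    va_escalated <- TRUE
    marks[[length(marks) + 1L]] <- color_mark(
      "red", "VA", "visual_acuity",
      "visual acuity worse than 20/40 escalates a 6-month review")
    base <- "red"
  } else if (base == "green" && poor_va) {
    notes <- "visual acuity worse than 20/40 but no yellow box: no escalation"
  }
  structure(
    list(marks = marks, severity = cls$severity, dme_present = cls$dme_present,
         referral = referral_category(base), va_escalated = va_escalated,
         notes = notes),
    class = "triage_result"
  )
}

#' @export
print.triage_result <- function(x, ...) {
  cat(sprintf("<triage_result> referral: %s (%s)\n",
              toupper(as.character(x$referral)),
              referral_interval(x$referral)))
  cat(sprintf("  severity: %s%s%s\n", as.character(x$severity),
              if (x$dme_present) " + DME" else "",
              if (x$va_escalated) " (VA escalated)" else ""))
  for (m in x$marks) {
    cat("  ")
    print(m)
  }
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}

#' Combine two eyes into a patient-level referral
#'
#' The patient follows the worse eye: the maximum of the two referral
#' categories under green < yellow < red.
#'
#' @param od,os `triage_result` objects (or bare referral categories).
#' @return A [referral_category()] of length 1.
#' @export
patient_referral <- function(od, os) {
  get_ref <- function(x) {
    if (inherits(x, "triage_result")) x$referral else referral_category(x)
  }
  max(get_ref(od), get_ref(os))
}
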