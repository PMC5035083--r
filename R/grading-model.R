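# Domain vocabulary: lesion taxonomy, referral categories, severity scale,
# visual acuity, and the per-eye grading form shared by all other modules.

#' Lesion types recognized on the grading form
#'
#' The nine lesion headings a grader can record on a single-field fundus
#' photograph. `red_dots_blots` deliberately pools microaneurysms, dot-blot
#' and flame-shaped hemorrhages: single-field photographs offer no reliable
#' counting rule to separate them, so the mild-vs-moderate distinction is
#' carried by a grader-asserted `microaneurysms_only` flag per quadrant
#' (see [quadrant_findings()]), not by the lesion taxonomy.
#'
#' @return Character vector of the nine lesion type tokens.
#' @export
lesion_types <- function() {
  c("red_dots_blots", "hard_exudates", "cotton_wool_spots",
    "venous_abnormality", "irma", "nvd", "nve",
    "vitreous_preretinal_hemorrhage", "detached_retina")
}

#' Lesion types that carry a point location
#'
#' Vitreous/preretinal hemorrhage and retinal detachment are global findings
#' recorded per eye, not per quadrant; every other lesion is localizable.
#'
#' @return Character vector of localizable lesion tokens.
#' @export
localizable_lesion_types <- function() {
  setdiff(lesion_types(), c("vitreous_preretinal_hemorrhage", "detached_retina"))
}

referral_tokens <- c("green", "yellow", "red")
severity_tokens <- c("no_dr", "mild_npdr", "moderate_npdr", "severe_npdr", "pdr")
macular_zone_tokens <- c("inner", "mid", "outer")

#' Referral category as an ordered factor
#'
#' The triage outcome: `green` (review in 1 year) < `yellow` (review in
#' 6 months) < `red` (immediate referral). Being an ordered factor, `max()`
#' over any set of categories is the patient-level combination rule.
#'
#' @param x Character vector of tokens among `"green"`, `"yellow"`, `"red"`
#'   (case-insensitive).
#' @return Ordered factor with levels green < yellow < red.
#' @examples
#' max(referral_category(c("green", "red", "yellow")))  # red
#' @export
referral_category <- function(x) {
  x <- tolower(as.character(x))
  bad <- !is.na(x) & !(x %in% referral_tokens)
  if (any(bad)) {
    stop("unknown referral token(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = referral_tokens, ordered = TRUE)
}

#' Follow-up interval label for a referral category
#' @param x Referral token(s) or [referral_category()] factor.
#' @return Character vector: "review_1_year", "review_6_months", "immediate".
#' @export
referral_interval <- function(x) {
  x <- as.character(x)
  c(green = "review_1_year", yellow = "review_6_months",
    red = "immediate")[x]
}

#' Severity level on the 5-step international clinical scale
#'
#' @param x Token(s) among `"no_dr"`, `"mild_npdr"`, `"moderate_npdr"`,
#'   `"severe_npdr"`, `"pdr"`.
#' @return Ordered factor no_dr < mild_npdr < moderate_npdr < severe_npdr < pdr.
#' @export
severity_level <- function(x) {
  x <- tolower(as.character(x))
  bad <- !is.na(x) & !(x %in% severity_tokens)
  if (any(bad)) {
    stop("unknown severity token(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  factor(x, levels = severity_tokens, ordered = TRUE)
}

#' Snellen visual acuity
#'
#' Stored as a Snellen fraction; compared on the decimal scale
#' (numerator/denominator) so that 6/12 is exactly equivalent to 20/40.
#'
#' @param numerator,denominator Positive integers of the Snellen fraction.
#' @return Object of class `visual_acuity`.
#' @export
visual_acuity <- function(numerator, denominator) {
  if (length(numerator) != 1L || length(denominator) != 1L ||
      !is.finite(numerator) || !is.finite(denominator) ||
      numerator <= 0 || denominator <= 0) {
    stop("visual acuity requires positive finite numerator and denominator")
  }
  dec <- numerator / denominator
  if (dec > 2.5) {
    stop("implausible visual acuity: decimal value ", format(dec), " > 2.5")
  }
  structure(
    list(snellen_numerator = as.numeric(numerator),
         snellen_denominator = as.numeric(denominator)),
    class = "visual_acuity"
  )
}

#' @export
print.visual_acuity <- function(x, ...) {
  cat(sprintf("VA %g/%g (decimal %.3f)\n", x$snellen_numerator,
              x$snellen_denominator, va_decimal(x)))
  invisible(x)
}

#' Decimal value of a Snellen acuity
#' @param va A [visual_acuity()] object.
#' @return Numerator/denominator as a plain number.
#' @export
va_decimal <- function(va) {
  stopifnot(inherits(va, "visual_acuity"))
  va$snellen_numerator / va$snellen_denominator
}

#' Is acuity strictly worse than 20/40?
#'
#' The escalation threshold of the triage rule: a 6-month-review eye with
#' acuity worse than 20/40 is referred immediately to look for other causes
#' of reduced vision. The boundary itself (20/40, decimal 0.5) does not
#' escalate; absent acuity (`NULL`) is treated as not worse than 20/40,
#' because the validation study graded images without acuities.
#'
#' @param va A [visual_acuity()] object, or `NULL` for unmeasured.
#' @return `TRUE` iff the decimal value is strictly below 0.5.
#' @export
va_worse_than_20_40 <- function(va) {
  if (is.null(va)) return(FALSE)
  va_decimal(va) < 0.5
}

#' Per-quadrant findings
#'
#' One record per anatomical quadrant (see [quadrant_of()] for the 1..4
#' convention). `red_dot_count` pools microaneurysms, dot-blot and flame
#' hemorrhages; `microaneurysms_only` is the grader's assertion that every
#' red dot in this quadrant is a microaneurysm (the mild-NPDR criterion).
#'
#' @param quadrant_id Integer 1..4.
#' @param red_dot_count Non-negative count of red dots/blots.
#' @param microaneurysms_only,hard_exudates,cotton_wool,venous_beading,irma_present,irma_prominent,nvd,nve
#'   Logical flags.
#' @return Object of class `quadrant_findings`.
#' @export
quadrant_findings <- function(quadrant_id,
                              red_dot_count = 0L,
                              microaneurysms_only = FALSE,
                              hard_exudates = FALSE,
                              cotton_wool = FALSE,
                              venous_beading = FALSE,
                              irma_present = FALSE,
                              irma_prominent = FALSE,
                              nvd = FALSE,
                              nve = FALSE) {
  structure(
    list(quadrant_id = as.integer(quadrant_id),
         red_dot_count = as.integer(red_dot_count),
         microaneurysms_only = isTRUE(microaneurysms_only),
         hard_exudates = isTRUE(hard_exudates),
         cotton_wool = isTRUE(cotton_wool),
         venous_beading = isTRUE(venous_beading),
         irma_present = isTRUE(irma_present),
         irma_prominent = isTRUE(irma_prominent),
         nvd = isTRUE(nvd),
         nve = isTRUE(nve)),
    class = "quadrant_findings"
  )
}

#' Macular findings per concentric zone
#'
#' Three mutually exclusive zones around the fovea center: `inner`
#' (radius < 1 disc diameter), `mid` (1-2 DD), `outer` (>= 2 DD), each
#' recording presence of hard exudates and of red dots/blots. Inner-zone
#' findings are the photographic surrogate for macular edema.
#'
#' @param inner_hard_exudates,inner_red_dots,mid_hard_exudates,mid_red_dots,outer_hard_exudates,outer_red_dots
#'   Logical flags.
#' @return Object of class `macular_findings`.
#' @export
macular_findings <- function(inner_hard_exudates = FALSE,
                             inner_red_dots = FALSE,
                             mid_hard_exudates = FALSE,
                             mid_red_dots = FALSE,
                             outer_hard_exudates = FALSE,
                             outer_red_dots = FALSE) {
  structure(
    list(inner_hard_exudates = isTRUE(inner_hard_exudates),
         inner_red_dots = isTRUE(inner_red_dots),
         mid_hard_exudates = isTRUE(mid_hard_exudates),
         mid_red_dots = isTRUE(mid_red_dots),
         outer_hard_exudates = isTRUE(outer_hard_exudates),
         outer_red_dots = isTRUE(outer_red_dots)),
    class = "macular_findings"
  )
}

#' Per-eye grading form
#'
#' The self-contained input of the triage rule: four quadrant records, the
#' macular zone findings, the two global lesion flags, and optionally the
#' eye's visual acuity.
#'
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @param quadrants List of exactly four [quadrant_findings()] with distinct
#'   ids 1..4 (any order; stored sorted by id).
#' @param macula A [macular_findings()] object.
#' @param vitreous_preretinal_hemorrhage,detached_retina Global lesion flags.
#' @param visual_acuity A [visual_acuity()] object or `NULL`.
#' @return Object of class `eye_grading_form`.
#' @export
eye_grading_form <- function(laterality = "OD",
                             quadrants = lapply(1:4, quadrant_findings),
                             macula = macular_findings(),
                             vitreous_preretinal_hemorrhage = FALSE,
                             detached_retina = FALSE,
                             visual_acuity = NULL) {
  ids <- vapply(quadrants, function(q) q$quadrant_id, integer(1))
  quadrants <- quadrants[order(ids)]
  structure(
    list(laterality = toupper(as.character(laterality)),
         quadrants = quadrants,
         macula = macula,
         vitreous_preretinal_hemorrhage = isTRUE(vitreous_preretinal_hemorrhage),
         detached_retina = isTRUE(detached_retina),
         visual_acuity = visual_acuity),
    class = "eye_grading_form"
  )
}

#' @export
print.eye_grading_form <- function(x, ...) {
  cat(sprintf("<eye_grading_form %s>\n", x$laterality))
  for (q in x$quadrants) {
    flags <- c("HE", "CWS", "VB", "IRMA", "IRMA+", "NVD", "NVE")[
      c(q$hard_exudates, q$cotton_wool, q$venous_beading,
        q$irma_present, q$irma_prominent, q$nvd, q$nve)]
    cat(sprintf("  Q%d: red dots %d%s%s\n", q$quadrant_id, q$red_dot_count,
                if (q$microaneurysms_only) " (MA only)" else "",
                if (length(flags)) paste0("; ", paste(flags, collapse = ",")) else ""))
  }
  mz <- unlist(x$macula)
  if (any(mz)) cat("  macula:", paste(names(mz)[mz], collapse = ", "), "\n")
  if (x$vitreous_preretinal_hemorrhage) cat("  vitreous/preretinal hemorrhage\n")
  if (x$detached_retina) cat("  detached retina\n")
  if (!is.null(x$visual_acuity)) {
    cat(sprintf("  VA %g/%g\n", x$visual_acuity$snellen_numerator,
                x$visual_acuity$snellen_denominator))
  }
  invisible(x)
}

#' Validate a grading form
#'
#' Checks every structural invariant of the form and reports violations as
#' human-readable strings naming the field and the rule. Validation never
#' raises; an empty return value means the form is well formed.
#'
#' @param form An [eye_grading_form()].
#' @return Character vector of violation descriptions (length 0 if valid).
#' @export
validate_form <- function(form) {
  v <- character(0)
  if (!inherits(form, "eye_grading_form")) {
    return("form: not an eye_grading_form object")
  }
  if (!(form$laterality %in% c("OD", "OS"))) {
    v <- c(v, sprintf("laterality: '%s' is not OD or OS", form$laterality))
  }
  if (length(form$quadrants) != 4L) {
    v <- c(v, sprintf("quadrants: expected exactly 4, got %d",
                      length(form$quadrants)))
  }
  ids <- vapply(form$quadrants, function(q) q$quadrant_id, integer(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    v <- c(v, sprintf("quadrants: duplicate quadrant_id %s",
                      paste(dup, collapse = ",")))
  }
  if (length(form$quadrants) == 4L && !setequal(ids, 1:4)) {
    v <- c(v, sprintf("quadrants: ids {%s} are not {1,2,3,4}",
                      paste(sort(ids), collapse = ",")))
  }
  for (q in form$quadrants) {
    tag <- sprintf("quadrant %d", q$quadrant_id)
    if (is.na(q$red_dot_count) || q$red_dot_count < 0) {
      v <- c(v, sprintf("%s: red_dot_count must be a non-negative integer", tag))
    }
    if (q$irma_prominent && !q$irma_present) {
      v <- c(v, sprintf("%s: irma_prominent implies irma_present", tag))
    }
    if (q$microaneurysms_only && (is.na(q$red_dot_count) || q$red_dot_count <= 0)) {
      v <- c(v, sprintf("%s: microaneurysms_only implies red_dot_count > 0", tag))
    }
  }
  if (!inherits(form$macula, "macular_findings")) {
    v <- c(v, "macula: not a macular_findings object")
  }
  if (!is.null(form$visual_acuity) &&
      !inherits(form$visual_acuity, "visual_acuity")) {
    v <- c(v, "visual_acuity: not a visual_acuity object (or NULL)")
  }
  v
}

stop_if_invalid <- function(form) {
  v <- validate_form(form)
  if (length(v)) {
    stop("invalid grading form:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(form)
}
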