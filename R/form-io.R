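# JSON and flat-CSV serialization of grading forms. Field names in the
# JSON schema match the constructor arguments exactly.

form_to_list <- function(form) {
  stopifnot(inherits(form, "eye_grading_form"))
  list(
    laterality = form$laterality,
    quadrants = lapply(form$quadrants, function(q) unclass(q)),
    macula = unclass(form$macula),
    vitreous_preretinal_hemorrhage = form$vitreous_preretinal_hemorrhage,
    detached_retina = form$detached_retina,
    visual_acuity = if (is.null(form$visual_acuity)) NULL else
      unclass(form$visual_acuity)
  )
}

form_from_list <- function(x) {
  va <- if (is.null(x$visual_acuity)) NULL else
    visual_acuity(x$visual_acuity$snellen_numerator,
                  x$visual_acuity$snellen_denominator)
  eye_grading_form(
    laterality = x$laterality,
    quadrants = lapply(x$quadrants, function(q) do.call(quadrant_findings, q)),
    macula = do.call(macular_findings, x$macula),
    vitreous_preretinal_hemorrhage = isTRUE(x$vitreous_preretinal_hemorrhage),
    detached_retina = isTRUE(x$detached_retina),
    visual_acuity = va
  )
}

#' Serialize grading forms to JSON
#'
#' One eye serializes to an object; a named list of forms (e.g.
#' `list(OD = ..., OS = ...)`) to an object of objects.
#'
#' @param form An [eye_grading_form()] or a list of them.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly, if written to `path`).
#' @export
write_form_json <- function(form, path = NULL) {
  x <- if (inherits(form, "eye_grading_form")) form_to_list(form) else
    lapply(form, form_to_list)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Parse grading forms from JSON
#'
#' @param path File path, or a JSON string.
#' @return An [eye_grading_form()] if the JSON is a single form, otherwise a
#'   named list of forms.
#' @export
read_form_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.null(x$quadrants)) form_from_list(x) else lapply(x, form_from_list)
}

#' Flatten a grading form to a one-row data frame
#'
#' Columns: `laterality`, per-quadrant `q<i>_<field>`, macular flags, global
#' flags and acuity. The inverse is [form_from_row()].
#'
#' @param form An [eye_grading_form()].
#' @return A one-row data frame.
#' @export
form_to_row <- function(form) {
  stopifnot(inherits(form, "eye_grading_form"))
  row <- list(laterality = form$laterality)
  for (q in form$quadrants) {
    p <- sprintf("q%d_", q$quadrant_id)
    f <- unclass(q)
    f$quadrant_id <- NULL
    names(f) <- paste0(p, names(f))
    row <- c(row, f)
  }
  row <- c(row, unclass(form$macula),
           list(vitreous_preretinal_hemorrhage = form$vitreous_preretinal_hemorrhage,
                detached_retina = form$detached_retina,
                va_numerator = if (is.null(form$visual_acuity)) NA_real_ else
                  form$visual_acuity$snellen_numerator,
                va_denominator = if (is.null(form$visual_acuity)) NA_real_ else
                  form$visual_acuity$snellen_denominator))
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Rebuild a grading form from a flat row
#' @param row A one-row data frame as produced by [form_to_row()].
#' @return An [eye_grading_form()].
#' @export
form_from_row <- function(row) {
  quadrants <- lapply(1:4, function(i) {
    g <- function(f) row[[sprintf("q%d_%s", i, f)]]
    quadrant_findings(i, g("red_dot_count"), g("microaneurysms_only"),
                      g("hard_exudates"), g("cotton_wool"),
                      g("venous_beading"), g("irma_present"),
                      g("irma_prominent"), g("nvd"), g("nve"))
  })
  mac <- macular_findings(row$inner_hard_exudates, row$inner_red_dots,
                          row$mid_hard_exudates, row$mid_red_dots,
                          row$outer_hard_exudates, row$outer_red_dots)
  va <- if (is.na(row$va_numerator)) NULL else
    visual_acuity(row$va_numerator, row$va_denominator)
  eye_grading_form(row$laterality, quadrants, mac,
                   row$vitreous_preretinal_hemorrhage, row$detached_retina, va)
}
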