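# Geometry of the single-field 45-degree posterior-pole photograph:
# four anatomical quadrants defined by the fovea-disc axis and its
# perpendicular through the disc center, and three concentric macular
# zones at radii 1 DD and 2 DD around the fovea center.
#
# Coordinates are continuous image pixels: origin top-left, x rightward,
# y downward; sub-pixel positions allowed.

#' Fundus landmarks
#'
#' The grader-supplied geometry of one photograph: fovea center, disc
#' center, disc diameter (the DD distance unit, judged visually by the
#' grader, not estimated from pixels) and eye laterality.
#'
#' @param fovea_center,disc_center Numeric length-2 vectors `c(x, y)` in
#'   pixels (y grows downward).
#' @param disc_diameter Disc diameter in pixels; must be positive.
#' @param laterality `"OD"` or `"OS"`.
#' @param image_width,image_height Optional image extent in pixels.
#' @return Object of class `fundus_landmarks`.
#' @export
fundus_landmarks <- function(fovea_center, disc_center, disc_diameter,
                             laterality = "OD",
                             image_width = NA_real_, image_height = NA_real_) {
  fovea_center <- as.numeric(fovea_center)
  disc_center <- as.numeric(disc_center)
  if (length(fovea_center) != 2L || length(disc_center) != 2L ||
      !all(is.finite(fovea_center)) || !all(is.finite(disc_center))) {
    stop("fovea_center and disc_center must be finite (x, y) pairs")
  }
  if (!is.finite(disc_diameter) || disc_diameter <= 0) {
    stop("disc_diameter must be a positive length in pixels")
  }
  if (all(fovea_center == disc_center)) {
    stop("degenerate landmarks: fovea_center equals disc_center")
  }
  laterality <- toupper(laterality)
  if (!(laterality %in% c("OD", "OS"))) stop("laterality must be OD or OS")
  structure(
    list(fovea_center = fovea_center, disc_center = disc_center,
         disc_diameter = as.numeric(disc_diameter), laterality = laterality,
         image_width = as.numeric(image_width),
         image_height = as.numeric(image_height)),
    class = "fundus_landmarks"
  )
}

#' @export
print.fundus_landmarks <- function(x, ...) {
  cat(sprintf("<fundus_landmarks %s> fovea (%g, %g), disc (%g, %g), DD %g px\n",
              x$laterality, x$fovea_center[1], x$fovea_center[2],
              x$disc_center[1], x$disc_center[2], x$disc_diameter))
  invisible(x)
}

# Signed coordinates of points on the (u, v) axes: u is the unit vector
# from disc center toward fovea center, v is u rotated by +90 degrees
# ((-uy, ux); visually clockwise in the y-down image frame). Returns a
# two-column matrix (a, b). `pts` is an n x 2 matrix or a length-2 vector.
axis_coords <- function(pts, lm) {
  if (is.null(dim(pts))) pts <- matrix(as.numeric(pts), ncol = 2L)
  u <- lm$fovea_center - lm$disc_center
  u <- u / sqrt(sum(u^2))
  v <- c(-u[2], u[1])
  d <- cbind(pts[, 1] - lm$disc_center[1], pts[, 2] - lm$disc_center[2])
  cbind(a = d %*% u, b = d %*% v)
}

#' Anatomical quadrant of a point
#'
#' The photograph is divided by the fovea-disc line and its perpendicular
#' through the disc center. Quadrant ids follow a fixed convention:
#' 1 = superior-temporal, 2 = inferior-temporal, 3 = superior-nasal,
#' 4 = inferior-nasal. Temporal is the fovea side of the perpendicular;
#' superior/inferior is resolved laterality-aware so that mirroring an
#' image left-right and swapping OD/OS preserves every anatomical label.
#' Points exactly on a dividing line (within `1e-9 * DD`) go to the
#' temporal and superior sides.
#'
#' @param p A length-2 `c(x, y)` point, or an n x 2 matrix of points.
#' @param lm A [fundus_landmarks()] object.
#' @return Integer quadrant id(s) in 1..4.
#' @examples
#' lm <- fundus_landmarks(c(200, 100), c(100, 100), 50, "OD")
#' quadrant_of(c(150, 80), lm)  # 1, superior-temporal
#' @export
quadrant_of <- function(p, lm) {
  stopifnot(inherits(lm, "fundus_landmarks"))
  ab <- axis_coords(p, lm)
  tol <- 1e-9 * lm$disc_diameter
  temporal <- ab[, 1] >= -tol
  # b measured along v; image "up" for the convention is -v for OD, +v for OS
  s <- if (lm$laterality == "OD") -ab[, 2] else ab[, 2]
  superior <- s >= -tol
  ids <- ifelse(temporal, ifelse(superior, 1L, 2L), ifelse(superior, 3L, 4L))
  as.integer(ids)
}

#' Human-readable quadrant labels
#' @param id Integer quadrant id(s) 1..4.
#' @return Character labels.
#' @export
quadrant_label <- function(id) {
  c("superior-temporal", "inferior-temporal",
    "superior-nasal", "inferior-nasal")[id]
}

#' Macular zone of a point
#'
#' Concentric circles of radius 1 DD and 2 DD around the fovea center
#' partition the image into `inner` (r < 1 DD), `mid` (1 DD <= r < 2 DD)
#' and `outer` (r >= 2 DD). Intervals are half-open, closed at the lower
#' radius, so each boundary circle belongs to the outer of the two zones
#' it separates.
#'
#' @inheritParams quadrant_of
#' @return Character zone token(s): `"inner"`, `"mid"` or `"outer"`.
#' @export
macular_zone_of <- function(p, lm) {
  stopifnot(inherits(lm, "fundus_landmarks"))
  if (is.null(dim(p))) p <- matrix(as.numeric(p), ncol = 2L)
  r <- sqrt((p[, 1] - lm$fovea_center[1])^2 + (p[, 2] - lm$fovea_center[2])^2)
  dd <- lm$disc_diameter
  ifelse(r < dd, "inner", ifelse(r < 2 * dd, "mid", "outer"))
}

# Inverse of axis_coords for one point: the pixel location at signed
# coordinates (a, b) on the (u, v) axes. Used by tests and the simulator
# to construct points with a known quadrant.
point_at <- function(lm, a, b) {
  u <- lm$fovea_center - lm$disc_center
  u <- u / sqrt(sum(u^2))
  v <- c(-u[2], u[1])
  lm$disc_center + a * u + b * v
}

# A pixel location guaranteed to lie in quadrant `qid`, at temporal/nasal
# offset `a_off` > 0 and superior/inferior offset `s_off` > 0 (in pixels).
point_in_quadrant <- function(lm, qid, a_off, s_off) {
  stopifnot(qid %in% 1:4, a_off > 0, s_off > 0)
  a <- if (qid %in% c(1L, 2L)) a_off else -a_off
  s <- if (qid %in% c(1L, 3L)) s_off else -s_off
  b <- if (lm$laterality == "OD") -s else s
  point_at(lm, a, b)
}

#' Point lesion annotation
#'
#' A single lesion marked by the grader on the photograph. Global lesions
#' (vitreous/preretinal hemorrhage, detached retina) carry no location;
#' every other type must.
#'
#' @param lesion_type One of [lesion_types()].
#' @param location `c(x, y)` in pixels, or `NULL` for global lesions.
#' @param microaneurysm For `red_dots_blots` only: the grader asserts this
#'   red dot is a microaneurysm.
#' @param prominent For `irma` only: the IRMA is prominent.
#' @return Object of class `annotated_lesion`.
#' @export
annotated_lesion <- function(lesion_type, location = NULL,
                             microaneurysm = FALSE, prominent = FALSE) {
  lesion_type <- tolower(lesion_type)
  if (!(lesion_type %in% lesion_types())) {
    stop("unknown lesion_type: ", lesion_type)
  }
  localizable <- lesion_type %in% localizable_lesion_types()
  if (localizable && is.null(location)) {
    stop("lesion '", lesion_type, "' requires a location")
  }
  if (!localizable) location <- NULL
  if (!is.null(location)) {
    location <- as.numeric(location)
    if (length(location) != 2L || !all(is.finite(location))) {
      stop("location must be a finite (x, y) pair")
    }
  }
  structure(
    list(lesion_type = lesion_type, location = location,
         microaneurysm = isTRUE(microaneurysm) && lesion_type == "red_dots_blots",
         prominent = isTRUE(prominent) && lesion_type == "irma"),
    class = "annotated_lesion"
  )
}

#' Aggregate lesion annotations into a grading form
#'
#' Applies [quadrant_of()] and [macular_zone_of()] to every localizable
#' lesion and fills an [eye_grading_form()]: per-quadrant red-dot counts and
#' presence flags, macular-zone flags for hard exudates and red dots/blots
#' (a lesion contributes to both its quadrant and its macular zone), and
#' the global flags. A quadrant's `microaneurysms_only` is set when it has
#' red dots and every one of them carries the grader's microaneurysm flag.
#'
#' @param lesions List of [annotated_lesion()] objects.
#' @param lm A [fundus_landmarks()] object.
#' @param va Optional [visual_acuity()].
#' @return An [eye_grading_form()].
#' @export
build_form <- function(lesions, lm, va = NULL) {
  stopifnot(inherits(lm, "fundus_landmarks"))
  for (l in lesions) {
    if (!inherits(l, "annotated_lesion")) stop("lesions must be annotated_lesion objects")
  }
  red_count <- integer(4)
  red_all_ma <- rep(TRUE, 4)
  flags <- matrix(FALSE, nrow = 4, ncol = 7,
                  dimnames = list(NULL, c("hard_exudates", "cotton_wool",
                                          "venous_beading", "irma_present",
                                          "irma_prominent", "nvd", "nve")))
  mac <- macular_findings()
  mac <- unclass(mac)
  global_vh <- FALSE
  global_dr <- FALSE
  for (l in lesions) {
    if (l$lesion_type == "vitreous_preretinal_hemorrhage") {
      global_vh <- TRUE
      next
    }
    if (l$lesion_type == "detached_retina") {
      global_dr <- TRUE
      next
    }
    q <- quadrant_of(l$location, lm)
    zone <- macular_zone_of(l$location, lm)
    switch(l$lesion_type,
      red_dots_blots = {
        red_count[q] <- red_count[q] + 1L
        if (!l$microaneurysm) red_all_ma[q] <- FALSE
        mac[[paste0(zone, "_red_dots")]] <- TRUE
      },
      hard_exudates = {
        flags[q, "hard_exudates"] <- TRUE
        mac[[paste0(zone, "_hard_exudates")]] <- TRUE
      },
      cotton_wool_spots = flags[q, "cotton_wool"] <- TRUE,
      venous_abnormality = flags[q, "venous_beading"] <- TRUE,
      irma = {
        flags[q, "irma_present"] <- TRUE
        if (l$prominent) flags[q, "irma_prominent"] <- TRUE
      },
      nvd = flags[q, "nvd"] <- TRUE,
      nve = flags[q, "nve"] <- TRUE
    )
  }
  quadrants <- lapply(1:4, function(i) {
    quadrant_findings(
      quadrant_id = i,
      red_dot_count = red_count[i],
      microaneurysms_only = red_count[i] > 0L && red_all_ma[i],
      hard_exudates = flags[i, "hard_exudates"],
      cotton_wool = flags[i, "cotton_wool"],
      venous_beading = flags[i, "venous_beading"],
      irma_present = flags[i, "irma_present"],
      irma_prominent = flags[i, "irma_prominent"],
      nvd = flags[i, "nvd"],
      nve = flags[i, "nve"]
    )
  })
  eye_grading_form(
    laterality = lm$laterality,
    quadrants = quadrants,
    macula = do.call(macular_findings, mac),
    vitreous_preretinal_hemorrhage = global_vh,
    detached_retina = global_dr,
    visual_acuity = va
  )
}

#' Per-lesion quadrant and macular-zone table
#'
#' The tabular view behind the `zones` command-line subcommand: one row per
#' lesion with its assigned quadrant (NA for global lesions) and macular
#' zone.
#'
#' @param lesions List of [annotated_lesion()] objects.
#' @param lm A [fundus_landmarks()] object.
#' @return Data frame with columns `lesion_type`, `x`, `y`, `quadrant_id`,
#'   `quadrant`, `zone`.
#' @export
lesion_zone_table <- function(lesions, lm) {
  rows <- lapply(lesions, function(l) {
    if (is.null(l$location)) {
      data.frame(lesion_type = l$lesion_type, x = NA_real_, y = NA_real_,
                 quadrant_id = NA_integer_, quadrant = NA_character_,
                 zone = NA_character_, stringsAsFactors = FALSE)
    } else {
      q <- quadrant_of(l$location, lm)
      data.frame(lesion_type = l$lesion_type,
                 x = l$location[1], y = l$location[2],
                 quadrant_id = q, quadrant = quadrant_label(q),
                 zone = macular_zone_of(l$location, lm),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Read an annotation file (landmarks plus lesion list)
#'
#' JSON schema: an object with a `landmarks` block (`fovea_center`,
#' `disc_center` as `[x, y]`, `disc_diameter`, `laterality`, optional
#' `image_width`/`image_height`), a `lesions` array (`lesion_type`, `x`,
#' `y`, optional `microaneurysm`, `prominent`; omit `x`/`y` for global
#' lesions) and an optional `visual_acuity` block.
#'
#' @param path Path to the annotation JSON.
#' @return List with elements `landmarks`, `lesions`, `va`.
#' @export
read_annotations_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lmx <- x$landmarks
  lm <- fundus_landmarks(
    fovea_center = unlist(lmx$fovea_center),
    disc_center = unlist(lmx$disc_center),
    disc_diameter = lmx$disc_diameter,
    laterality = if (is.null(lmx$laterality)) "OD" else lmx$laterality,
    image_width = if (is.null(lmx$image_width)) NA_real_ else lmx$image_width,
    image_height = if (is.null(lmx$image_height)) NA_real_ else lmx$image_height
  )
  lesions <- lapply(x$lesions, function(l) {
    loc <- if (is.null(l$x) || is.null(l$y)) NULL else c(l$x, l$y)
    annotated_lesion(l$lesion_type, loc,
                     microaneurysm = isTRUE(l$microaneurysm),
                     prominent = isTRUE(l$prominent))
  })
  va <- if (is.null(x$visual_acuity)) NULL else
    visual_acuity(x$visual_acuity$snellen_numerator,
                  x$visual_acuity$snellen_denominator)
  list(landmarks = lm, lesions = lesions, va = va)
}

#' Write an annotation file
#' @param ann List as returned by [read_annotations_json()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(ann, path) {
  lm <- ann$landmarks
  x <- list(
    landmarks = list(
      fovea_center = lm$fovea_center, disc_center = lm$disc_center,
      disc_diameter = lm$disc_diameter, laterality = lm$laterality,
      image_width = lm$image_width, image_height = lm$image_height
    ),
    lesions = lapply(ann$lesions, function(l) {
      out <- list(lesion_type = l$lesion_type)
      if (!is.null(l$location)) {
        out$x <- l$location[1]
        out$y <- l$location[2]
      }
      if (l$microaneurysm) out$microaneurysm <- TRUE
      if (l$prominent) out$prominent <- TRUE
      out
    }),
    visual_acuity = if (is.null(ann$va)) NULL else unclass(ann$va)
  )
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null",
                              na = "null", digits = NA, pretty = TRUE), path)
  invisible(path)
}
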