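# Validation statistics for a multi-reader referral study: one-vs-rest
# confusion tables against the specialist's gold labels, Cohen's kappa
# with the large-sample standard error and agreement bands, sensitivity /
# specificity with Wilson score intervals, single-operating-point AUC,
# subgroup stratification and comparison, and the chi-square effect-size
# sample-size estimate.

#' Assemble a reader study dataset
#'
#' @param gold Data frame with columns `image_id`, `referral` (tokens
#'   green/yellow/red): the specialist's label per image.
#' @param responses Data frame with columns `reader_id`, `image_id`,
#'   `referral` (`NA` for a missing response).
#' @param readers Optional data frame with column `reader_id` plus reader
#'   attributes (e.g. `group`, `prior_grading`) for stratification.
#' @return Object of class `study_dataset`. Rows are stored sorted by
#'   (reader_id, image_id) so every downstream report is byte-stable.
#' @export
study_dataset <- function(gold, responses, readers = NULL) {
  stopifnot(all(c("image_id", "referral") %in% names(gold)),
            all(c("reader_id", "image_id", "referral") %in% names(responses)))
  gold <- data.frame(image_id = as.character(gold$image_id),
                     referral = referral_category(gold$referral),
                     stringsAsFactors = FALSE)
  if (anyDuplicated(gold$image_id)) stop("duplicate image_id in gold labels")
  if (any(is.na(gold$referral))) stop("gold labels must not be missing")
  responses <- data.frame(reader_id = as.character(responses$reader_id),
                          image_id = as.character(responses$image_id),
                          referral = referral_category(responses$referral),
                          stringsAsFactors = FALSE)
  unknown <- setdiff(responses$image_id, gold$image_id)
  if (length(unknown)) {
    stop("responses reference image_id(s) absent from gold: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  gold <- gold[order(gold$image_id), , drop = FALSE]
  responses <- responses[order(responses$reader_id, responses$image_id), ,
                         drop = FALSE]
  rownames(gold) <- rownames(responses) <- NULL
  if (!is.null(readers)) {
    stopifnot("reader_id" %in% names(readers))
    readers$reader_id <- as.character(readers$reader_id)
    readers <- readers[order(readers$reader_id), , drop = FALSE]
    rownames(readers) <- NULL
  }
  structure(list(gold = gold, responses = responses, readers = readers),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  n_readers <- length(unique(x$responses$reader_id))
  n_images <- nrow(x$gold)
  n_missing <- sum(is.na(x$responses$referral))
  cat(sprintf(
    "<study_dataset> %d images, %d readers, %d responses (%d missing)\n",
    n_images, n_readers, nrow(x$responses), n_missing))
  invisible(x)
}

#' One-vs-rest confusion table for a referral category
#'
#' Binarizes the three-way labels: positive iff equal to `category`, for
#' gold and reader alike, and cross-tabulates reader against gold over all
#' non-missing responses. Cell names follow the screening convention:
#' `a` (gold-, reader-), `b` (gold-, reader+), `c` (gold+, reader-),
#' `d` (gold+, reader+).
#'
#' @param ds A [study_dataset()].
#' @param category Referral token (`"red"`, `"yellow"`, `"green"`).
#' @return Object of class `confusion_2x2` (list a, b, c, d, n, category).
#' @export
build_confusion <- function(ds, category) {
  stopifnot(inherits(ds, "study_dataset"))
  category <- as.character(referral_category(category))
  resp <- ds$responses[!is.na(ds$responses$referral), , drop = FALSE]
  if (nrow(resp) == 0L) stop("no non-missing responses in dataset")
  gold_of <- stats::setNames(as.character(ds$gold$referral), ds$gold$image_id)
  gpos <- gold_of[resp$image_id] == category
  rpos <- as.character(resp$referral) == category
  confusion_2x2(a = sum(!gpos & !rpos), b = sum(!gpos & rpos),
                c = sum(gpos & !rpos), d = sum(gpos & rpos),
                category = category)
}

#' Construct a 2x2 confusion table from counts
#' @param a,b,c,d Cell counts: gold-/reader-, gold-/reader+, gold+/reader-,
#'   gold+/reader+.
#' @param category Optional label of the positive category.
#' @return Object of class `confusion_2x2`.
#' @export
confusion_2x2 <- function(a, b, c, d, category = NA_character_) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("confusion counts must be non-negative")
  }
  n <- as.numeric(sum(counts))
  if (n == 0) stop("empty confusion table (n = 0)")
  structure(list(a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
                 d = as.numeric(d), n = n, category = category),
            class = "confusion_2x2")
}

#' @export
print.confusion_2x2 <- function(x, ...) {
  cat(sprintf("<confusion_2x2%s> n = %g\n",
              if (is.na(x$category)) "" else paste0(" ", x$category), x$n))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(gold = c("-", "+"), reader = c("-", "+")))
  print(m)
  invisible(x)
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement kappa = (po - pe) / (1 - pe) with observed
#' agreement po = (a + d)/n and expected agreement pe from the marginal
#' products. The standard error is the large-sample form
#' sqrt(po (1 - po) / (n (1 - pe)^2)).
#'
#' @param t A [confusion_2x2()].
#' @return Object of class `agreement_result`: `kappa`, `se_kappa`, `po`,
#'   `pe`, `band` (see [kappa_band()]).
#' @export
cohens_kappa <- function(t) {
  stopifnot(inherits(t, "confusion_2x2"))
  n <- t$n
  po <- (t$a + t$d) / n
  pe <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / n^2
  if (pe >= 1) stop("degenerate marginals: expected agreement is 1")
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  structure(list(kappa = kappa, se_kappa = se, po = po, pe = pe,
                 band = kappa_band(kappa)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("kappa = %.3f +/- %.3f (%s; po = %.3f, pe = %.3f)\n",
              x$kappa, x$se_kappa, x$band, x$po, x$pe))
  invisible(x)
}

#' Agreement band for a kappa value
#'
#' The conventional labels, applied to the kappa rounded to two decimals:
#' 0.01-0.20 slight, 0.21-0.40 fair, 0.41-0.60 moderate, 0.61-0.80
#' substantial, 0.81-0.99 almost perfect agreement. Values outside
#' 0.01-0.99 after rounding are reported as unclassified.
#'
#' @param kappa Numeric in [-1, 1] (vectorized).
#' @return Character label(s).
#' @export
kappa_band <- function(kappa) {
  stopifnot(all(kappa >= -1 & kappa <= 1))
  k <- round(kappa, 2)
  out <- rep("unclassified", length(k))
  out[k >= 0.01 & k <= 0.20] <- "slight agreement"
  out[k >= 0.21 & k <= 0.40] <- "fair agreement"
  out[k >= 0.41 & k <= 0.60] <- "moderate agreement"
  out[k >= 0.61 & k <= 0.80] <- "substantial agreement"
  out[k >= 0.81 & k <= 0.99] <- "almost perfect agreement"
  out
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(low = max(0, center - half), high = min(1, center + half))
}

wald_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  half <- z * sqrt(p * (1 - p) / n)
  c(low = max(0, p - half), high = min(1, p + half))
}

# Hanley-McNeil standard error of an AUC given the positive/negative
# group sizes; used for the AUC interval and the subgroup z-test.
auc_se_hanley <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Diagnostic statistics for a 2x2 table
#'
#' Sensitivity d/(c+d), specificity a/(a+b), the percentage of
#' gold-positive images correctly referred (sensitivity as a one-decimal
#' percentage), 95% confidence intervals (Wilson score by default, Wald as
#' an option), and the single-operating-point AUC (sensitivity +
#' specificity)/2 with a Hanley-McNeil interval. A binary rating gives one
#' point on the ROC curve, so the trapezoidal area reduces to this mean.
#'
#' @param t A [confusion_2x2()].
#' @param ci_method `"wilson"` (default) or `"wald"`.
#' @return Object of class `diagnostic_result`.
#' @export
diagnostics <- function(t, ci_method = c("wilson", "wald")) {
  stopifnot(inherits(t, "confusion_2x2"))
  ci_method <- match.arg(ci_method)
  n_pos <- t$c + t$d
  n_neg <- t$a + t$b
  if (n_pos == 0) stop("undefined metric: no gold-positive responses (c + d = 0)")
  if (n_neg == 0) stop("undefined metric: no gold-negative responses (a + b = 0)")
  ci_fun <- if (ci_method == "wilson") wilson_ci else wald_ci
  se <- t$d / n_pos
  sp <- t$a / n_neg
  auc <- (se + sp) / 2
  auc_se <- auc_se_hanley(auc, n_pos, n_neg)
  z <- stats::qnorm(0.975)
  structure(
    list(sensitivity = se, sensitivity_ci = ci_fun(t$d, n_pos),
         specificity = sp, specificity_ci = ci_fun(t$a, n_neg),
         percent_correct = round(100 * se, 1),
         auc = auc, auc_se = auc_se,
         auc_ci = c(low = max(0, auc - z * auc_se),
                    high = min(1, auc + z * auc_se)),
         n_pos = n_pos, n_neg = n_neg, n = t$n,
         ci_method = ci_method, category = t$category),
    class = "diagnostic_result"
  )
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat(sprintf(
    "Se %d%% [%d-%d], Sp %d%% [%d-%d], AUC %.3f [%.3f-%.3f], correct %.1f%%\n",
    trunc(100 * x$sensitivity), round(100 * x$sensitivity_ci[1]),
    round(100 * x$sensitivity_ci[2]),
    trunc(100 * x$specificity), round(100 * x$specificity_ci[1]),
    round(100 * x$specificity_ci[2]),
    x$auc, x$auc_ci[1], x$auc_ci[2], x$percent_correct))
  invisible(x)
}

#' Split a study dataset into subgroups
#'
#' `by` may name a reader attribute column of the `readers` table (e.g.
#' `"group"` or `"prior_grading"`), or `"image-block=K"` to split the
#' image set (in sorted image_id order) into consecutive blocks of K
#' images. The returned datasets partition the responses exactly: pooling
#' their confusion tables reproduces the unstratified counts.
#'
#' @param ds A [study_dataset()].
#' @param by Attribute name or `"image-block=K"` rule.
#' @return Named list of [study_dataset()] objects.
#' @export
stratify <- function(ds, by) {
  stopifnot(inherits(ds, "study_dataset"), is.character(by), length(by) == 1L)
  if (grepl("^image-block=", by)) {
    k <- as.integer(sub("^image-block=", "", by))
    ids <- sort(ds$gold$image_id)
    if (is.na(k) || k <= 0 || length(ids) %% k != 0) {
      stop("image-block size must be a positive divisor of the image count")
    }
    block <- rep(seq_len(length(ids) / k), each = k)
    groups <- split(ids, sprintf("block%d", block))
    out <- lapply(groups, function(im) {
      study_dataset(ds$gold[ds$gold$image_id %in% im, , drop = FALSE],
                    ds$responses[ds$responses$image_id %in% im, , drop = FALSE],
                    ds$readers)
    })
    return(out)
  }
  if (is.null(ds$readers) || !(by %in% names(ds$readers))) {
    stop("unknown reader attribute: ", by)
  }
  attr_of <- stats::setNames(as.character(ds$readers[[by]]),
                             ds$readers$reader_id)
  resp_readers <- unique(ds$responses$reader_id)
  undefined <- resp_readers[is.na(attr_of[resp_readers]) |
                              !(resp_readers %in% names(attr_of))]
  if (length(undefined)) {
    stop("attribute '", by, "' undefined for reader(s): ",
         paste(utils::head(undefined, 5), collapse = ", "))
  }
  groups <- split(names(attr_of), attr_of)
  out <- lapply(groups, function(rd) {
    study_dataset(ds$gold,
                  ds$responses[ds$responses$reader_id %in% rd, , drop = FALSE],
                  ds$readers[ds$readers$reader_id %in% rd, , drop = FALSE])
  })
  out[order(names(out))]
}

#' Compare two groups' AUCs
#'
#' Two-sided z-test on the difference of two single-operating-point AUCs
#' from independent groups, with Hanley-McNeil standard errors. The paper
#' behind this design reports subgroup p-values from an unnamed chi-square
#' procedure; this documented z-test is the package's stand-in, and the
#' method name is recorded in the output.
#'
#' @param d1,d2 [diagnostics()] results for the two groups.
#' @return List: `auc_diff`, `se_diff`, `statistic` (z), `p_value`,
#'   `method`.
#' @export
compare_auc <- function(d1, d2) {
  stopifnot(inherits(d1, "diagnostic_result"), inherits(d2, "diagnostic_result"))
  se1 <- d1$auc_se
  se2 <- d2$auc_se
  se_diff <- sqrt(se1^2 + se2^2)
  if (se_diff == 0) stop("zero-variance groups: AUC difference has no SE")
  z <- (d1$auc - d2$auc) / se_diff
  list(auc_diff = d1$auc - d2$auc, se_diff = se_diff, statistic = z,
       p_value = 2 * stats::pnorm(-abs(z)),
       method = "independent-groups z-test with Hanley-McNeil SEs")
}

#' Sample size for a chi-square test at effect size w
#'
#' The smallest N such that a chi-square test with `df` degrees of freedom
#' at level `alpha` reaches the target power against noncentrality
#' lambda = N * w^2 (Cohen's effect size w). For df = 1 this agrees with
#' the normal-approximation closed form
#' ceiling((z_(1-alpha/2) + z_power)^2 / w^2).
#'
#' @param alpha Significance level in (0, 1).
#' @param effect_size_w Cohen's w > 0.
#' @param power Target power in (0, 1).
#' @param df Degrees of freedom >= 1.
#' @return Integer sample size.
#' @examples
#' sample_size_chisq(0.05, 0.3, 0.85, df = 1)  # 100
#' @export
sample_size_chisq <- function(alpha, effect_size_w, power, df = 1) {
  stopifnot(alpha > 0, alpha < 1, effect_size_w > 0, power > 0, power < 1,
            df >= 1)
  crit <- stats::qchisq(1 - alpha, df)
  pow <- function(n) {
    stats::pchisq(crit, df, ncp = n * effect_size_w^2, lower.tail = FALSE)
  }
  hi <- 2
  while (pow(hi) < power) {
    hi <- hi * 2
    if (hi > 1e9) stop("unattainable power for the given effect size")
  }
  lo <- 1
  while (hi - lo > 1) {
    mid <- (lo + hi) %/% 2
    if (pow(mid) >= power) hi <- mid else lo <- mid
  }
  as.integer(hi)
}

# Integer percentage by truncation toward zero; matches the printed
# sensitivity/specificity rounding of the validation study's tables.
pct_trunc <- function(p) trunc(100 * p)

#' Evaluate a reader study
#'
#' The full per-category report: for each referral category (and
#' optionally for each subgroup under `by`), the one-vs-rest confusion
#' counts, Cohen's kappa with SE and band, sensitivity/specificity with
#' 95% intervals, the percent of gold-positive images correctly referred,
#' and the single-operating-point AUC. Display columns follow the
#' conventional precisions (kappa 3 d.p.; Se/Sp integer percent by
#' truncation; percent correct 1 d.p.); the underlying full-precision
#' values are also returned.
#'
#' @param ds A [study_dataset()].
#' @param by Optional stratification rule passed to [stratify()];
#'   the pooled rows are always included (group `"all"`).
#' @param ci_method Passed to [diagnostics()].
#' @return Data frame of class `study_report`, one row per group x
#'   category.
#' @export
evaluate_study <- function(ds, by = NULL, ci_method = "wilson") {
  groups <- list(all = ds)
  if (!is.null(by)) groups <- c(groups, stratify(ds, by))
  rows <- list()
  for (g in names(groups)) {
    for (cat in rev(referral_tokens)) {  # red, yellow, green: worst first
      t <- build_confusion(groups[[g]], cat)
      k <- cohens_kappa(t)
      d <- diagnostics(t, ci_method = ci_method)
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, category = cat, interval = unname(referral_interval(cat)),
        a = t$a, b = t$b, c = t$c, d = t$d, n = t$n,
        kappa = k$kappa, se_kappa = k$se_kappa, band = k$band,
        sensitivity = d$sensitivity, specificity = d$specificity,
        auc = d$auc, auc_se = d$auc_se,
        sens_ci_low = d$sensitivity_ci[1], sens_ci_high = d$sensitivity_ci[2],
        spec_ci_low = d$specificity_ci[1], spec_ci_high = d$specificity_ci[2],
        percent_correct = d$percent_correct,
        kappa_display = sprintf("%.3f", k$kappa),
        sens_pct = pct_trunc(d$sensitivity),
        spec_pct = pct_trunc(d$specificity),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("study_report", class(out))
  out
}

#' Write a study report as CSV and/or JSON
#' @param report An [evaluate_study()] data frame.
#' @param csv_path,json_path Output paths (`NULL` to skip).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    utils::write.csv(report, csv_path, row.names = FALSE, na = "NA")
  }
  if (!is.null(json_path)) {
    writeLines(jsonlite::toJSON(as.data.frame(report), dataframe = "rows",
                                digits = NA, pretty = TRUE), json_path)
  }
  invisible(report)
}

#' Read study CSV inputs
#'
#' Gold: `image_id, referral`; responses: `reader_id, image_id, referral`
#' (token `NA` or empty = missing); readers: `reader_id` plus attributes.
#' Referral tokens green/yellow/red, case-insensitive.
#'
#' @param gold_path,responses_path CSV paths.
#' @param readers_path Optional CSV path.
#' @return A [study_dataset()].
#' @export
read_study_csv <- function(gold_path, responses_path, readers_path = NULL) {
  gold <- utils::read.csv(gold_path, stringsAsFactors = FALSE)
  responses <- utils::read.csv(responses_path, stringsAsFactors = FALSE,
                               na.strings = c("NA", ""))
  readers <- if (!is.null(readers_path)) {
    utils::read.csv(readers_path, stringsAsFactors = FALSE)
  }
  study_dataset(gold, responses, readers)
}

#' Write study CSV files
#' @param ds A [study_dataset()].
#' @param gold_path,responses_path,readers_path Output CSV paths
#'   (`readers_path` ignored when the dataset has no reader table).
#' @return `ds`, invisibly.
#' @export
write_study_csv <- function(ds, gold_path, responses_path,
                            readers_path = NULL) {
  g <- ds$gold
  g$referral <- as.character(g$referral)
  utils::write.csv(g, gold_path, row.names = FALSE)
  r <- ds$responses
  r$referral <- as.character(r$referral)
  utils::write.csv(r, responses_path, row.names = FALSE, na = "NA")
  if (!is.null(readers_path) && !is.null(ds$readers)) {
    utils::write.csv(ds$readers, readers_path, row.names = FALSE)
  }
  invisible(ds)
}

#' Packaged one-vs-rest confusion tables of the validation study
#'
#' The published pilot study's reader-vs-specialist counts for the three
#' referral categories (99 readers x 50 images, 4780 non-missing
#' responses), shipped as a plain-text fixture. Categories: `red`
#' (immediate referral), `yellow` (review after 6 months), `green`
#' (review after 1 year).
#'
#' @return Named list of [confusion_2x2()] tables.
#' @export
table2_confusions <- function() {
  path <- system.file("extdata", "pilot_confusion_tables.csv",
                      package = "drtriage", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    confusion_2x2(df$a[i], df$b[i], df$c[i], df$d[i], category = df$category[i])
  })
  stats::setNames(out, df$category)
}
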