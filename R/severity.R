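#' Work-severity scales
#'
#' Builds one of the built-in occupational work-severity scales:
#' \describe{
#'   \item{\code{"daily"}}{Lehmann bands on 24-h energy expenditure
#'     (kcal/24 h): Light 2300–2800, Moderate 2800–3300, Moderate hard
#'     3300–3800, Hard 3800–4300, Very hard 4300–4800, Extremely hard
#'     from 4800.}
#'   \item{\code{"shift"}}{Lehmann bands on energy expenditure per 8-h
#'     work shift (kcal/8 h): Light to 500, Moderate 500–1000, Moderate
#'     hard 1000–1500, Hard 1500–2000, Very hard 2000–2800, Extremely
#'     hard from 2800.}
#'   \item{\code{"rate"}}{Christensen bands on instantaneous energy
#'     expenditure (kcal/min): Light 2.5–5.0, Moderate 5.0–7.5, Hard
#'     7.5–10.0, Very hard 10.0–12.5, Extremely hard from 12.5. The
#'     classic scale states each threshold as a lower bound.}
#' }
#' All touching band boundaries are resolved left-closed/right-open
#' \verb{[lower, upper)}, which makes classification deterministic and
#' monotone. Inputs below the lowest band are labelled with the scale's
#' bottom label ("Light") and flagged as below-scale.
#'
#' Scales are also shipped as a versioned JSON config
#' (\code{system.file("extdata", "severity_scales.json", package = "crewEE")})
#' so alternative scales can be swapped in via [read_severity_scale()].
#'
#' @param basis one of \code{"daily"}, \code{"shift"}, \code{"rate"}.
#' @return an object of class \code{severity_scale}: a data frame of
#'   ordered bands (\code{label}, \code{lower}, \code{upper}) with
#'   attributes \code{basis}, \code{unit}, \code{below_scale_label}.
#' @export
severity_scale <- function(basis = c("daily", "shift", "rate")) {
  basis <- match.arg(basis)
  cfg <- jsonlite::fromJSON(
    system.file("extdata", "severity_scales.json", package = "crewEE"),
    simplifyVector = TRUE
  )
  sc <- cfg$scales[[basis]]
  bands <- sc$bands
  bands$upper[is.na(bands$upper)] <- Inf
  as_severity_scale(bands, basis = sc$basis, unit = sc$unit,
                    below_scale_label = sc$below_scale_label)
}

as_severity_scale <- function(bands, basis, unit, below_scale_label) {
  stopifnot(all(c("label", "lower", "upper") %in% names(bands)))
  bands <- bands[order(bands$lower), , drop = FALSE]
  rownames(bands) <- NULL
  if (any(bands$lower >= bands$upper)) stop("bands must satisfy lower < upper")
  if (nrow(bands) > 1L &&
      any(abs(bands$lower[-1L] - bands$upper[-nrow(bands)]) > 1e-9)) {
    stop("bands must tile their range without gaps or overlaps")
  }
  structure(bands, class = c("severity_scale", "data.frame"),
            basis = basis, unit = unit,
            below_scale_label = below_scale_label)
}

#' Read a severity scale from a JSON config
#'
#' @param file path to a JSON file in the format of the shipped
#'   \code{severity_scales.json}.
#' @param scale which named scale to extract.
#' @return a \code{severity_scale} object.
#' @export
read_severity_scale <- function(file, scale) {
  cfg <- jsonlite::fromJSON(file, simplifyVector = TRUE)
  if (!scale %in% names(cfg$scales)) {
    stop("no scale named '", scale, "' in ", file)
  }
  sc <- cfg$scales[[scale]]
  bands <- sc$bands
  bands$upper[is.na(bands$upper)] <- Inf
  as_severity_scale(bands, basis = sc$basis, unit = sc$unit,
                    below_scale_label = sc$below_scale_label)
}

#' Classify energy expenditure on a severity scale
#'
#' Returns the band label whose half-open interval \verb{[lower, upper)}
#' contains the value. Values below the lowest band receive the scale's
#' bottom label with attribute \code{below_scale = TRUE}.
#'
#' @param x non-negative energy expenditure value(s), in the scale's unit.
#' @param scale a \code{severity_scale}.
#' @return character vector of labels; attribute \code{below_scale} is a
#'   logical vector marking values under the scale's lowest bound.
#' @export
classify_severity <- function(x, scale) {
  stopifnot(inherits(scale, "severity_scale"))
  if (any(!is.finite(x)) || any(x < 0)) stop("energy expenditure must be non-negative")
  lab <- character(length(x))
  below <- x < scale$lower[1L]
  lab[below] <- attr(scale, "below_scale_label")
  for (j in which(!below)) {
    i <- findInterval(x[j], scale$lower)  # left-closed by construction
    lab[j] <- scale$label[i]
  }
  structure(lab, below_scale = below)
}

severity_rank <- function(label, scale) match(label, scale$label)

#' @rdname classify_severity
#' @param kcal_per_day 24-h energy expenditure, kcal.
#' @export
classify_daily <- function(kcal_per_day, scale = severity_scale("daily")) {
  classify_severity(kcal_per_day, scale)
}

#' @rdname classify_severity
#' @param kcal_per_8h energy expenditure per 8-h work shift, kcal.
#' @export
classify_shift <- function(kcal_per_8h, scale = severity_scale("shift")) {
  classify_severity(kcal_per_8h, scale)
}

#' @rdname classify_severity
#' @param kcal_per_min instantaneous energy expenditure, kcal/min.
#' @export
classify_rate <- function(kcal_per_min, scale = severity_scale("rate")) {
  classify_severity(kcal_per_min, scale)
}

#' Describe a range of work intensities
#'
#' Classifies the two endpoints of an intensity range on the per-minute
#' (Christensen) scale and renders the usual "light to moderate" style
#' descriptor.
#'
#' @param min_rate,max_rate endpoints of the kcal/min range.
#' @param scale a per-minute \code{severity_scale}.
#' @return a string such as \code{"light to moderate"}; when both
#'   endpoints fall in one band, just that band's name.
#' @examples
#' classify_rate_range(2.17, 5.61)
#' @export
classify_rate_range <- function(min_rate, max_rate,
                                scale = severity_scale("rate")) {
  if (min_rate > max_rate) stop("min_rate must not exceed max_rate")
  lo <- tolower(as.character(classify_rate(min_rate, scale)))
  hi <- tolower(as.character(classify_rate(max_rate, scale)))
  if (identical(lo, hi)) lo else paste(lo, "to", hi)
}

#' @export
print.severity_scale <- function(x, ...) {
  cat(sprintf("Work-severity scale (%s, %s), left-closed bands:\n",
              attr(x, "basis"), attr(x, "unit")))
  for (i in seq_len(nrow(x))) {
    up <- if (is.infinite(x$upper[i])) "and above" else paste0("to ", x$upper[i])
    cat(sprintf("  %-15s %s %s\n", x$label[i], x$lower[i], up))
  }
  cat("values below", x$lower[1L], "map to",
      attr(x, "below_scale_label"), "(flagged below-scale)\n")
  invisible(x)
}
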