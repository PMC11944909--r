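#' Fit an individual heart-rate / oxygen-uptake calibration
#'
#' Heart-rate based energy-expenditure estimation rests on the linear
#' relationship between heart rate (HR) and oxygen uptake (VO2) during
#' exercise. This fits, per subject, the ordinary least-squares line
#' \deqn{\dot{V}O_2 = a + b\,\mathrm{HR}}
#' over the exercise calibration points, and derives the quantities the
#' flex-HR convention needs:
#' \itemize{
#'   \item \code{flex_hr}: the heart rate above which the regression is
#'     trusted. With resting points, the midpoint between the highest
#'     resting HR and the lowest exercise HR; without them, the lowest
#'     exercise HR.
#'   \item \code{resting_ee}: energy expenditure (kcal/min) assumed below
#'     \code{flex_hr}. With resting points, the caloric equivalent times
#'     their mean VO2; otherwise the predicted VO2 at \code{flex_hr},
#'     floored at zero (a message notes the fallback).
#' }
#' Predicted VO2 is converted to kcal/min with the caloric equivalent of
#' oxygen (default 4.85 kcal per litre O2, the standard
#' indirect-calorimetry value for a mixed diet).
#'
#' @param hr heart rate, beats/min; or a data frame with columns
#'   \code{hr_bpm}, \code{vo2_l_min} and optionally \code{phase}
#'   (\code{"rest"}/\code{"exercise"}), as produced by
#'   [read_calibration()].
#' @param vo2 oxygen uptake, L/min (omit when \code{hr} is a data frame).
#' @param phase optional character vector marking each point
#'   \code{"rest"} or \code{"exercise"}; points default to exercise.
#' @param caloric_equivalent kcal per litre O2.
#' @return an object of class \code{hr_calibration} with components
#'   \code{slope} (L/min per bpm), \code{intercept} (L/min),
#'   \code{flex_hr} (bpm), \code{resting_ee} (kcal/min),
#'   \code{caloric_equivalent}, \code{fit} (the underlying \code{lm}),
#'   and the calibration \code{data}.
#' @seealso [predict.hr_calibration()], [ee_from_trace()]
#' @examples
#' cal <- fit_calibration(hr = c(90, 120, 150, 180),
#'                        vo2 = c(0.4, 0.7, 1.0, 1.3))
#' coef(cal)
#' predict(cal, newdata = data.frame(hr = 130))
#' @export
fit_calibration <- function(hr, vo2 = NULL, phase = NULL,
                            caloric_equivalent = 4.85) {
  if (is.data.frame(hr)) {
    df <- hr
    stopifnot(all(c("hr_bpm", "vo2_l_min") %in% names(df)))
    phase <- if ("phase" %in% names(df)) df$phase else NULL
    vo2 <- df$vo2_l_min
    hr <- df$hr_bpm
  }
  hr <- as.numeric(hr); vo2 <- as.numeric(vo2)
  if (length(hr) != length(vo2)) stop("hr and vo2 lengths differ")
  if (any(hr <= 0) || any(vo2 < 0)) {
    stop("calibration points need hr > 0 and vo2 >= 0")
  }
  if (is.null(phase)) phase <- rep("exercise", length(hr))
  phase <- tolower(as.character(phase))
  if (!all(phase %in% c("rest", "exercise"))) {
    stop("phase must be 'rest' or 'exercise'")
  }
  if (caloric_equivalent <= 0) stop("caloric_equivalent must be positive")

  ex <- phase == "exercise"
  if (length(unique(hr[ex])) < 2L) {
    stop("underdetermined fit: need >= 2 exercise points with distinct HR")
  }
  dat <- data.frame(hr = hr, vo2 = vo2, phase = phase)
  fit <- stats::lm(vo2 ~ hr, data = dat[ex, , drop = FALSE])
  slope <- unname(stats::coef(fit)[["hr"]])
  intercept <- unname(stats::coef(fit)[["(Intercept)"]])

  if (any(!ex)) {
    flex_hr <- (max(hr[!ex]) + min(hr[ex])) / 2
    resting_ee <- caloric_equivalent * mean(vo2[!ex])
  } else {
    flex_hr <- min(hr[ex])
    resting_ee <- max(0, caloric_equivalent * (intercept + slope * flex_hr))
    message("no resting calibration points: resting EE set from the ",
            "regression at flex HR (", round(resting_ee, 2), " kcal/min)")
  }

  structure(list(
    slope = slope, intercept = intercept,
    flex_hr = flex_hr, resting_ee = resting_ee,
    caloric_equivalent = caloric_equivalent,
    fit = fit, data = dat
  ), class = "hr_calibration")
}

#' Read a calibration-points file
#'
#' CSV with columns \code{hr_bpm}, \code{vo2_l_min} and optional
#' \code{phase} (\code{rest}|\code{exercise}).
#'
#' @param file path to the CSV file.
#' @return a data frame suitable for [fit_calibration()].
#' @export
read_calibration <- function(file) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("hr_bpm", "vo2_l_min")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("calibration file lacks column(s): ",
                         paste(miss, collapse = ", "))
  raw
}

#' @export
coef.hr_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict oxygen uptake or energy expenditure from heart rate
#'
#' Below \code{flex_hr} the resting energy expenditure is returned (for
#' \code{type = "ee"}); above it the calibration line is evaluated, with
#' negative predicted VO2 clamped to zero.
#'
#' @param object an \code{hr_calibration} fit.
#' @param newdata data frame with an \code{hr} column, or a numeric HR
#'   vector. Defaults to the calibration data.
#' @param type \code{"vo2"} for L/min or \code{"ee"} for kcal/min (the
#'   flex-HR rule applies only to \code{"ee"}).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.hr_calibration <- function(object, newdata = NULL,
                                   type = c("ee", "vo2"), ...) {
  type <- match.arg(type)
  hr <- if (is.null(newdata)) object$data$hr
        else if (is.data.frame(newdata)) newdata$hr
        else as.numeric(newdata)
  vo2 <- object$intercept + object$slope * hr
  if (type == "vo2") return(vo2)
  ee <- object$caloric_equivalent * pmax(vo2, 0)
  ee[hr < object$flex_hr] <- object$resting_ee
  ee
}

#' @export
residuals.hr_calibration <- function(object, ...) stats::residuals(object$fit)

#' @export
print.hr_calibration <- function(x, ...) {
  cat("Individual HR-VO2 calibration (OLS over exercise points)\n")
  cat(sprintf("  vo2 [L/min] = %.5f + %.6f x HR [bpm]\n", x$intercept, x$slope))
  cat(sprintf("  flex HR %.1f bpm; resting EE %.2f kcal/min; %.2f kcal/L O2\n",
              x$flex_hr, x$resting_ee, x$caloric_equivalent))
  cat(sprintf("  %d exercise / %d resting points\n",
              sum(x$data$phase == "exercise"), sum(x$data$phase == "rest")))
  invisible(x)
}

#' @export
summary.hr_calibration <- function(object, ...) {
  s <- summary(object$fit)
  cat("Individual HR-VO2 calibration\n")
  print(object)
  cat(sprintf("  residual SD %.4f L/min, R^2 %.4f\n", s$sigma, s$r.squared))
  invisible(s)
}

#' Plot a calibration fit
#'
#' Calibration points (resting points open, exercise points filled), the
#' fitted line over the exercise HR range, and the flex-HR threshold.
#'
#' @param x an \code{hr_calibration} fit.
#' @param ... passed to \code{plot.default}.
#' @export
plot.hr_calibration <- function(x, ...) {
  ex <- x$data$phase == "exercise"
  graphics::plot(x$data$hr, x$data$vo2, pch = ifelse(ex, 19, 1),
                 xlab = "heart rate [bpm]", ylab = "VO2 [L/min]",
                 main = "HR-VO2 calibration", ...)
  rng <- range(x$data$hr[ex])
  graphics::segments(rng[1], x$intercept + x$slope * rng[1],
                     rng[2], x$intercept + x$slope * rng[2])
  graphics::abline(v = x$flex_hr, lty = 2)
  graphics::mtext(sprintf("flex HR = %.0f bpm", x$flex_hr), side = 3,
                  line = 0, adj = 1, cex = 0.8)
  invisible(x)
}

#' Simulate calibration measurements from a fitted line
#'
#' Draws new exercise calibration points from the fitted relationship
#' plus Gaussian measurement noise at the fit's residual SD — useful for
#' parametric-bootstrap checks of calibration uncertainty.
#'
#' @param object an \code{hr_calibration} fit.
#' @param nsim number of replicate data sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a list of data frames with columns \code{hr}, \code{vo2}.
#' @export
simulate.hr_calibration <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  ex <- object$data[object$data$phase == "exercise", , drop = FALSE]
  sig <- summary(object$fit)$sigma
  if (!is.finite(sig)) sig <- 0
  lapply(seq_len(nsim), function(i) {
    data.frame(hr = ex$hr,
               vo2 = pmax(0, object$intercept + object$slope * ex$hr +
                            stats::rnorm(nrow(ex), 0, sig)))
  })
}
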