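#' Construct a daily food ration
#'
#' @param energy energy value, kcal/day (may be \code{NA} to have it
#'   computed from the macronutrients by [atwater_energy()]).
#' @param protein,fat,carb macronutrient content, g/day.
#' @param provenance one of \code{"planned"} (the menu as designed),
#'   \code{"served"} (given for consumption) or \code{"standard"} (a
#'   normative food standard).
#' @param name optional label.
#' @return an object of class \code{ration}.
#' @export
ration <- function(energy = NA, protein, fat, carb,
                   provenance = c("planned", "served", "standard"),
                   name = NULL) {
  provenance <- match.arg(provenance)
  vals <- c(energy = energy, protein = protein, fat = fat, carb = carb)
  if (any(!is.na(vals) & vals < 0)) stop("ration fields must be non-negative")
  if (is.na(energy)) vals[["energy"]] <- atwater_energy(protein, fat, carb)
  structure(as.list(vals), provenance = provenance, name = name,
            class = "ration")
}

#' @export
print.ration <- function(x, ...) {
  cat(sprintf("Food ration%s (%s): %.1f kcal; protein %.1f g, fat %.1f g, carbohydrate %s g\n",
              if (is.null(attr(x, "name"))) "" else paste0(" '", attr(x, "name"), "'"),
              attr(x, "provenance"), x$energy, x$protein, x$fat,
              if (is.na(x$carb)) "NA" else sprintf("%.1f", x$carb)))
  invisible(x)
}

#' Atwater energy of a macronutrient composition
#'
#' The general Atwater factors — 4 kcal/g protein, 9 kcal/g fat,
#' 4 kcal/g carbohydrate — convert macronutrient masses to metabolisable
#' energy:
#' \deqn{E = 4P + 9F + 4C \;\mathrm{kcal}.}
#'
#' @param protein,fat,carb grams/day.
#' @param factors kcal/g conversion factors, in protein/fat/carbohydrate
#'   order.
#' @return kcal, vectorised.
#' @examples
#' atwater_energy(149.3, 147.4, 547.5)
#' @export
atwater_energy <- function(protein, fat, carb, factors = c(4, 9, 4)) {
  if (length(factors) != 3L || any(factors <= 0)) {
    stop("factors must be three positive kcal/g values")
  }
  if (any(c(protein, fat, carb) < 0, na.rm = TRUE)) {
    stop("macronutrient masses must be non-negative")
  }
  factors[1] * protein + factors[2] * fat + factors[3] * carb
}

#' Percentage of energy from each macronutrient
#'
#' Shares of the Atwater-computed energy contributed by protein, fat and
#' carbohydrate; always normalised so the three shares sum to 100.
#'
#' @param x a [ration()], or protein g when giving raw masses.
#' @param fat,carb grams (when \code{x} is numeric protein grams).
#' @param factors Atwater factors, kcal/g.
#' @return an object of class \code{macro_shares}: named numeric
#'   \code{pct_protein}, \code{pct_fat}, \code{pct_carb}.
#' @examples
#' energy_shares(ration(protein = 149.3, fat = 147.4, carb = 547.5,
#'                      provenance = "served"))
#' @export
energy_shares <- function(x, fat = NULL, carb = NULL, factors = c(4, 9, 4)) {
  if (inherits(x, "ration")) {
    protein <- x$protein; fat <- x$fat; carb <- x$carb
  } else {
    protein <- x
  }
  if (any(is.na(c(protein, fat, carb)))) {
    stop("all three macronutrient masses are needed for energy shares")
  }
  kcal <- factors * c(protein, fat, carb)
  total <- sum(kcal)
  if (total <= 0) stop("all-zero macronutrients: shares undefined")
  shares <- kcal / total * 100
  structure(c(pct_protein = shares[1], pct_fat = shares[2], pct_carb = shares[3]),
            total_kcal = total, class = "macro_shares")
}

#' @export
print.macro_shares <- function(x, ...) {
  cat(sprintf("Energy shares (Atwater total %.1f kcal): protein %.1f%%, fat %.1f%%, carbohydrate %.1f%%\n",
              attr(x, "total_kcal"), x[["pct_protein"]], x[["pct_fat"]],
              x[["pct_carb"]]))
  invisible(x)
}

#' Audit a ration against a reference
#'
#' Per-field comparison of a ration with a reference composition (a food
#' standard, or a planned ration when auditing implementation quality).
#' For each of energy, protein, fat and carbohydrate the report gives the
#' delta (ration \eqn{-} reference, same unit), the ration as a percent
#' of the reference, and the delta as a percent of the reference (the
#' shortfall/excess share). Fields that are \code{NA} in either operand
#' are reported as \code{NA}.
#'
#' @param x the audited [ration()].
#' @param reference the reference [ration()] (all compared fields > 0).
#' @return an object of class \code{adequacy_report}: a data frame with
#'   rows energy/protein/fat/carb and columns \code{ration},
#'   \code{reference}, \code{delta}, \code{pct_of_reference},
#'   \code{delta_pct_of_reference}.
#' @examples
#' std <- food_standard()
#' served <- ration(4120.0, 149.3, 147.4, 547.5, provenance = "served")
#' compare_to_standard(served, std)
#' @export
compare_to_standard <- function(x, reference) {
  stopifnot(inherits(x, "ration"), inherits(reference, "ration"))
  fields <- c("energy", "protein", "fat", "carb")
  a <- unlist(x[fields]); b <- unlist(reference[fields])
  cmp <- !is.na(a) & !is.na(b)
  if (any(b[cmp] <= 0)) stop("reference fields must be positive")
  delta <- pct <- dpct <- rep(NA_real_, 4)
  delta[cmp] <- a[cmp] - b[cmp]
  pct[cmp] <- a[cmp] / b[cmp] * 100
  dpct[cmp] <- delta[cmp] / b[cmp] * 100
  out <- data.frame(
    field = fields, unit = c("kcal", "g", "g", "g"),
    ration = unname(a), reference = unname(b), delta = delta,
    pct_of_reference = pct, delta_pct_of_reference = dpct,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("adequacy_report", "data.frame"),
            ration_provenance = attr(x, "provenance"),
            reference_provenance = attr(reference, "provenance"))
}

#' @rdname compare_to_standard
#' @param planned,served planned and as-served [ration()]s; the planned
#'   ration is the reference, so negative deltas mean the galley served
#'   less than the menu promised.
#' @export
compare_planned_vs_served <- function(planned, served) {
  compare_to_standard(served, planned)
}

#' @export
print.adequacy_report <- function(x, ...) {
  cat(sprintf("Ration adequacy audit (%s vs %s reference):\n",
              attr(x, "ration_provenance"), attr(x, "reference_provenance")))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 1)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' The packaged navy food standard (reconstructed)
#'
#' The normative ration composition used as the default audit reference.
#' No composition table for the standard is published; this fixture is
#' reconstructed arithmetically from the reported ration-versus-standard
#' differences (energy 4532 kcal, protein 164.6 g, fat 145.3 g;
#' carbohydrate not reconstructible, left \code{NA}). A second stated
#' energy figure of 4520 kcal exists in the source discussion but is
#' inconsistent with those differences; the reconstructed 4532 kcal is
#' the self-consistent choice. Supply your own standard to override.
#'
#' @param file optional path to a JSON file with fields
#'   \code{energy_kcal}, \code{protein_g}, \code{fat_g}, \code{carb_g}.
#' @return a [ration()] with provenance \code{"standard"}.
#' @export
food_standard <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "food_standard_reconstructed.json",
                        package = "crewEE")
  }
  cfg <- jsonlite::fromJSON(file)
  ration(energy = cfg$energy_kcal, protein = cfg$protein_g, fat = cfg$fat_g,
         carb = if (is.null(cfg$carb_g)) NA else cfg$carb_g,
         provenance = "standard",
         name = if (is.null(cfg$name)) "food standard" else cfg$name)
}

#' Read a ration from JSON or CSV
#'
#' JSON files carry fields \code{energy_kcal}, \code{protein_g},
#' \code{fat_g}, \code{carb_g} (and optional \code{provenance},
#' \code{name}); CSV files carry those columns, one ration per row.
#'
#' @param file path to the file.
#' @return a [ration()] (JSON) or list of rations (CSV with several rows).
#' @export
read_ration <- function(file) {
  if (grepl("\\.json$", file, ignore.case = TRUE)) {
    cfg <- jsonlite::fromJSON(file)
    return(ration(
      energy = if (is.null(cfg$energy_kcal)) NA else cfg$energy_kcal,
      protein = cfg$protein_g, fat = cfg$fat_g,
      carb = if (is.null(cfg$carb_g)) NA else cfg$carb_g,
      provenance = if (is.null(cfg$provenance)) "planned" else cfg$provenance,
      name = cfg$name
    ))
  }
  raw <- utils::read.csv(file, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("energy_kcal", "protein_g", "fat_g", "carb_g")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("ration file lacks column(s): ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(raw)), function(i) {
    ration(raw$energy_kcal[i], raw$protein_g[i], raw$fat_g[i], raw$carb_g[i],
           provenance = if ("provenance" %in% names(raw)) raw$provenance[i] else "planned",
           name = if ("name" %in% names(raw)) raw$name[i] else NULL)
  })
  if (length(out) == 1L) out[[1L]] else out
}
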