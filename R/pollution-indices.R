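#' Geoaccumulation index (Igeo)
#'
#' `Igeo = log2(Cn / (1.5 * Bn))`, where Cn is the measured soil
#' concentration and Bn the geochemical background; the factor 1.5 damps
#' natural lithogenic variation in the baseline. Vectorised over `cn`/`bn`.
#'
#' @param cn Measured concentration(s), mg/kg; must be > 0.
#' @param bn Background value(s), mg/kg; must be > 0.
#' @return Dimensionless Igeo value(s).
#' @export
igeo <- function(cn, bn) {
  if (any(!is.finite(cn)) || any(cn <= 0)) {
    stop_domain("igeo: cn must be positive and finite")
  }
  if (any(!is.finite(bn)) || any(bn <= 0)) {
    stop_domain("igeo: bn must be positive and finite")
  }
  log2(cn / (1.5 * bn))
}

#' Monomial potential ecological risk index (E)
#'
#' Hakanson's single-metal index `E = Tn * Cn / Bn`, the toxic response
#' coefficient times the contamination factor. For Cr the conventional
#' `Tn = 2`.
#'
#' @param cn Measured concentration(s), mg/kg; > 0.
#' @param bn Background value(s), mg/kg; > 0.
#' @param tn Toxic response coefficient; > 0, default 2 (Cr).
#' @return Dimensionless E value(s).
#' @export
ecological_risk <- function(cn, bn, tn = 2) {
  if (any(!is.finite(cn)) || any(cn <= 0)) {
    stop_domain("ecological_risk: cn must be positive and finite")
  }
  if (any(!is.finite(bn)) || any(bn <= 0)) {
    stop_domain("ecological_risk: bn must be positive and finite")
  }
  if (any(!is.finite(tn)) || any(tn <= 0)) {
    stop_domain("ecological_risk: tn must be positive and finite")
  }
  tn * cn / bn
}

.igeo_labels <- c("unpolluted",
                  "unpolluted to moderately polluted",
                  "moderately polluted",
                  "moderately to heavily polluted",
                  "heavily polluted",
                  "heavily to extremely polluted",
                  "extremely polluted")

.e_labels <- c("low", "moderate", "considerable", "high", "significant high")
.e_breaks_default <- c(40, 80, 160, 320)

#' Classify Igeo values into the seven Muller classes
#'
#' Class 0 (`Igeo <= 0`, unpolluted) through class 6 (`Igeo > 5`, extremely
#' polluted); intermediate classes are the unit intervals `(k-1, k]`, i.e.
#' upper-closed.
#'
#' @param x Finite Igeo value(s).
#' @param labels If `TRUE` return the textual pollution level instead of the
#'   integer class.
#' @return Integer class 0..6 (or character labels).
#' @export
classify_igeo <- function(x, labels = FALSE) {
  if (any(!is.finite(x))) stop_domain("classify_igeo: Igeo must be finite")
  cls <- ifelse(x <= 0, 0L, ifelse(x > 5, 6L, as.integer(ceiling(x))))
  if (labels) .igeo_labels[cls + 1L] else cls
}

#' Classify E values into Hakanson risk levels
#'
#' Lower-closed intervals: low `< 40`; moderate `[40, 80)`; considerable
#' `[80, 160)`; high `[160, 320)`; significant high `>= 320`. Break points
#' can be overridden for sensitivity analyses.
#'
#' @param x Non-negative E value(s).
#' @param breaks Ascending numeric vector of 4 class boundaries.
#' @return Character risk labels.
#' @export
classify_e <- function(x, breaks = .e_breaks_default) {
  if (any(!is.finite(x) | x < 0)) {
    stop_domain("classify_e: E must be finite and non-negative")
  }
  if (length(breaks) != 4 || is.unsorted(breaks, strictly = TRUE)) {
    stop_config("classify_e: breaks must be 4 strictly increasing numbers")
  }
  .e_labels[findInterval(x, breaks) + 1L]
}

#' Compute pollution and ecological-risk indices for every region
#'
#' Resolves each region's background value from its province (falling back
#' to the national default), then computes Igeo, E, and their classes. The
#' background actually used is recorded per region (`bn_used`) so the
#' provincial-vs-national choice stays auditable.
#'
#' @param regions Region data frame.
#' @param background A [background_table()].
#' @param tn Toxic response coefficient (default 2 for Cr).
#' @return Data frame with columns `region_id`, `igeo`, `igeo_class`,
#'   `e_value`, `e_class`, `bn_used`.
#' @export
assess_regions <- function(regions, background = background_table(), tn = 2) {
  regions <- validate_regions(regions)
  bn <- lookup_background(background, regions$province)
  ig <- igeo(regions$cr_conc, bn)
  ev <- ecological_risk(regions$cr_conc, bn, tn)
  data.frame(
    region_id = regions$region_id,
    igeo = ig,
    igeo_class = classify_igeo(ig),
    e_value = ev,
    e_class = classify_e(ev),
    bn_used = bn,
    stringsAsFactors = FALSE
  )
}

.class_fractions <- function(values, levels) {
  tab <- table(factor(values, levels = levels))
  as.numeric(tab) / length(values)
}

#' Summarise index results by industry type
#'
#' Arithmetic mean Igeo and E per type plus the class-distribution
#' fractions (which sum to 1 within each type). Types with no regions are
#' dropped with a warning.
#'
#' @param results Output of [assess_regions()], row-aligned with `regions`.
#' @param regions The region data frame the results were computed from.
#' @return List with `means` (data frame: `industry_type`, `n`, `mean_igeo`,
#'   `mean_e`), `igeo_class_fractions` and `e_class_fractions` (data frames,
#'   one row per type, one column per class).
#' @export
summarize_by_type <- function(results, regions) {
  regions <- validate_regions(regions)
  if (nrow(results) != nrow(regions)) {
    stop_input("results and regions must be row-aligned")
  }
  present <- intersect(industry_types, unique(regions$industry_type))
  absent <- setdiff(industry_types, present)
  if (length(absent) > 0) {
    warning(sprintf("no regions for industry type(s): %s",
                    paste(absent, collapse = ", ")))
  }
  means <- data.frame(industry_type = present,
                      n = NA_integer_, mean_igeo = NA_real_, mean_e = NA_real_,
                      stringsAsFactors = FALSE)
  igeo_fr <- matrix(NA_real_, length(present), 7,
                    dimnames = list(present, paste0("class", 0:6)))
  e_fr <- matrix(NA_real_, length(present), 5,
                 dimnames = list(present, gsub(" ", "_", .e_labels)))
  for (i in seq_along(present)) {
    idx <- regions$industry_type == present[i]
    means$n[i] <- sum(idx)
    means$mean_igeo[i] <- mean(results$igeo[idx])
    means$mean_e[i] <- mean(results$e_value[idx])
    igeo_fr[i, ] <- .class_fractions(results$igeo_class[idx], 0:6)
    e_fr[i, ] <- .class_fractions(results$e_class[idx], .e_labels)
  }
  list(means = means,
       igeo_class_fractions = data.frame(industry_type = present,
                                         igeo_fr, row.names = NULL,
                                         check.names = FALSE),
       e_class_fractions = data.frame(industry_type = present,
                                      e_fr, row.names = NULL,
                                      check.names = FALSE))
}
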