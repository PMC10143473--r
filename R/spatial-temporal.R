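#' Hotspot areas
#'
#' The five priority industrial clusters plus the catch-all `"other"`.
#' Ordered by the precedence used to resolve provinces a user map places in
#' two areas: delta/rim labels outrank basin labels.
#'
#' @format Character vector of length 6.
#' @export
hotspot_areas <- c("Yangtze River Delta", "Bohai Rim", "Pearl River Delta",
                   "Yangtze River Basin", "Yellow River Basin", "other")

# Default provincial membership of each area. Deliberately coarse: deltas
# and rims take their core provinces; basins take standard riparian
# provinces not already claimed by a delta/rim.
.area_provinces <- list(
  "Yangtze River Delta" = c("Shanghai", "Jiangsu", "Zhejiang", "Anhui"),
  "Bohai Rim" = c("Beijing", "Tianjin", "Hebei", "Shandong", "Liaoning"),
  "Pearl River Delta" = c("Guangdong"),
  "Yangtze River Basin" = c("Sichuan", "Chongqing", "Hubei", "Hunan",
                            "Jiangxi"),
  "Yellow River Basin" = c("Qinghai", "Gansu", "Ningxia", "Inner Mongolia",
                           "Shaanxi", "Shanxi", "Henan"),
  "other" = c("Fujian", "Guizhou", "Yunnan", "Guangxi", "Hainan", "Jilin",
              "Heilongjiang", "Xinjiang", "Tibet")
)

#' Default province-to-hotspot-area map
#'
#' @return Named character vector, province -> area label. Fully
#'   user-overridable; provinces absent from a map are assigned `"other"`.
#' @export
default_area_map <- function() {
  stats::setNames(rep(names(.area_provinces),
                      lengths(.area_provinces)),
                  unlist(.area_provinces, use.names = FALSE))
}

#' Assign each region to a hotspot area
#'
#' Deterministic province -> area lookup. Unknown provinces fall back to
#' `"other"`. If a user-supplied map lists the same province under two
#' areas (duplicate names), the area earlier in [hotspot_areas()] wins and
#' a warning is issued.
#'
#' @param regions Region data frame.
#' @param area_map Named character vector, province -> area (default
#'   [default_area_map()]).
#' @return Data frame with columns `region_id`, `area`.
#' @export
assign_areas <- function(regions, area_map = default_area_map()) {
  regions <- validate_regions(regions)
  bad_areas <- setdiff(unique(area_map), hotspot_areas)
  if (length(bad_areas) > 0) {
    stop_config("area_map contains unknown area label(s): %s",
                paste(bad_areas, collapse = ", "))
  }
  dup <- unique(names(area_map)[duplicated(names(area_map))])
  if (length(dup) > 0) {
    warning(sprintf("province(s) %s listed in more than one area; using the higher-priority area",
                    paste(dup, collapse = ", ")))
    # keep, per province, the entry whose area ranks earliest
    ord <- order(match(area_map, hotspot_areas))
    area_map <- area_map[ord]
    area_map <- area_map[!duplicated(names(area_map))]
  }
  area <- unname(area_map[regions$province])
  area[is.na(area)] <- "other"
  data.frame(region_id = regions$region_id, area = area,
             stringsAsFactors = FALSE)
}

#' Class distribution of Igeo and E per hotspot area
#'
#' Per area, the fraction of regions in each Igeo class (0-6) and each E
#' risk level; fractions sum to 1 within an area. Areas with no regions are
#' omitted.
#'
#' @param assignments Output of [assign_areas()].
#' @param results Output of [assess_regions()], matched by `region_id`.
#' @return List with `igeo_class_fractions` and `e_class_fractions` (data
#'   frames, one row per area) and `n` (named region counts).
#' @export
area_class_distribution <- function(assignments, results) {
  m <- match(assignments$region_id, results$region_id)
  if (anyNA(m)) stop_input("assignments contain region_ids absent from results")
  results <- results[m, ]
  present <- intersect(hotspot_areas, unique(assignments$area))
  igeo_fr <- matrix(NA_real_, length(present), 7,
                    dimnames = list(present, paste0("class", 0:6)))
  e_fr <- matrix(NA_real_, length(present), 5,
                 dimnames = list(present, gsub(" ", "_", .e_labels)))
  n <- integer(length(present))
  for (i in seq_along(present)) {
    idx <- assignments$area == present[i]
    n[i] <- sum(idx)
    igeo_fr[i, ] <- .class_fractions(results$igeo_class[idx], 0:6)
    e_fr[i, ] <- .class_fractions(results$e_class[idx], .e_labels)
  }
  list(igeo_class_fractions = data.frame(area = present, igeo_fr,
                                         row.names = NULL, check.names = FALSE),
       e_class_fractions = data.frame(area = present, e_fr,
                                      row.names = NULL, check.names = FALSE),
       n = stats::setNames(n, present))
}

#' Screening-value exceedances per hotspot area
#'
#' Counts the regions whose concentration strictly exceeds the screening
#' value in each area and each area's share of the total exceedance count.
#' With zero exceedances overall, shares are reported as 0.
#'
#' @param regions Region data frame.
#' @param assignments Output of [assign_areas()] (default: computed with the
#'   default area map).
#' @param screening Screening value, mg/kg (default 2500).
#' @return Data frame with columns `area`, `n_regions`, `n_exceed`,
#'   `share_pct`.
#' @export
exceedance_by_area <- function(regions, assignments = assign_areas(regions),
                               screening = 2500) {
  regions <- validate_regions(regions)
  m <- match(regions$region_id, assignments$region_id)
  if (anyNA(m)) stop_input("assignments are missing some region_ids")
  area <- assignments$area[m]
  exceed <- regions$cr_conc > screening
  total <- sum(exceed)
  present <- intersect(hotspot_areas, unique(area))
  out <- do.call(rbind, lapply(present, function(a) {
    idx <- area == a
    ne <- sum(exceed[idx])
    data.frame(area = a, n_regions = sum(idx), n_exceed = ne,
               share_pct = if (total > 0) 100 * ne / total else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Median soil Cr concentration per sampling year
#'
#' Sample medians (mean of the two middle values for even counts), ordered
#' by year. Records without a sampling year are dropped; if none remain an
#' empty result is returned with a warning.
#'
#' @param regions Region data frame.
#' @return Data frame with columns `year`, `n`, `median`.
#' @export
yearly_medians <- function(regions) {
  regions <- validate_regions(regions)
  keep <- !is.na(regions$sampling_year)
  if (!any(keep)) {
    warning("no records carry a sampling year")
    return(data.frame(year = integer(0), n = integer(0), median = numeric(0)))
  }
  regions <- regions[keep, ]
  years <- sort(unique(regions$sampling_year))
  data.frame(
    year = years,
    n = vapply(years, function(y) sum(regions$sampling_year == y), integer(1)),
    median = vapply(years, function(y)
      stats::median(regions$cr_conc[regions$sampling_year == y]), numeric(1))
  )
}
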