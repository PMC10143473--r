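#' Receptor exposure profile
#'
#' Behavioural and physiological parameters of one receptor group for the
#' USEPA soil exposure model. Units follow the conventional handbook forms:
#' IngR mg soil/day, InhR m3 air/day, SA exposed skin cm2, AF soil-to-skin
#' adherence mg/(cm2 day), ABS dermal absorption fraction, EF days/year, ED
#' years, BW kg, AT days, PEF m3/kg, CF kg/mg (1e-6 converts mg soil to kg).
#'
#' @param group One of `"child"`, `"adult_male"`, `"adult_female"`.
#' @param IngR,InhR,SA,AF,ABS,EF,ED,BW,AT,PEF,CF Positive numbers (see
#'   Description); `ABS <= 1`.
#' @return Object of class `cr_receptor` (named list).
#' @export
receptor_profile <- function(group, IngR, InhR, SA, AF, ABS, EF, ED, BW, AT,
                             PEF = 1.36e9, CF = 1e-6) {
  group <- match.arg(group, c("child", "adult_male", "adult_female"))
  p <- list(group = group, IngR = IngR, InhR = InhR, SA = SA, AF = AF,
            ABS = ABS, EF = EF, ED = ED, BW = BW, AT = AT, PEF = PEF, CF = CF)
  num <- p[setdiff(names(p), "group")]
  bad <- names(num)[!vapply(num, function(v)
    is.numeric(v) && all(is.finite(v)) && all(v > 0), logical(1))]
  if (length(bad) > 0) {
    stop_domain("receptor_profile: %s must be positive and finite",
                paste(bad, collapse = ", "))
  }
  if (any(p$ABS > 1)) stop_domain("receptor_profile: ABS must be <= 1")
  structure(p, class = "cr_receptor")
}

#' Default receptor profiles
#'
#' Repository-default exposure parameters for the three receptor groups,
#' drawn from the USEPA Exposure Factors Handbook / HJ 25.3 conventions
#' (e.g. child soil ingestion 200 mg/day, body weight 15 kg, particulate
#' emission factor 1.36e9 m3/kg). These are the package defaults, not
#' values asserted by any particular survey; every field is overridable via
#' [receptor_profile()] or the YAML config.
#'
#' @return Named list of three [receptor_profile()] objects.
#' @export
default_receptors <- function() {
  list(
    child = receptor_profile("child", IngR = 200, InhR = 7.6, SA = 2800,
                             AF = 0.2, ABS = 0.001, EF = 350, ED = 6,
                             BW = 15, AT = 2190),
    adult_male = receptor_profile("adult_male", IngR = 100, InhR = 19,
                                  SA = 5700, AF = 0.07, ABS = 0.001,
                                  EF = 350, ED = 24, BW = 70, AT = 8760),
    adult_female = receptor_profile("adult_female", IngR = 100, InhR = 14.5,
                                    SA = 5700, AF = 0.07, ABS = 0.001,
                                    EF = 350, ED = 24, BW = 57, AT = 8760)
  )
}

#' Toxicity (reference dose) parameters
#'
#' Non-carcinogenic reference doses per pathway, mg/(kg day). Defaults are
#' the conventional total-Cr-as-Cr(VI) values: oral RfD 3e-3; dermal RfD =
#' oral x gastrointestinal absorption fraction 0.025 = 7.5e-5; inhalation
#' RfD 2.86e-5 derived from the Cr(VI) particulate RfC (1e-4 mg/m3 scaled by
#' 20 m3/day / 70 kg).
#'
#' @param rfd_ing,rfd_derm,rfd_inh Positive reference doses, mg/(kg day).
#' @return Object of class `cr_toxicity`.
#' @export
toxicity_params <- function(rfd_ing = 3e-3, rfd_derm = 7.5e-5,
                            rfd_inh = 2.86e-5) {
  vals <- c(rfd_ing = rfd_ing, rfd_derm = rfd_derm, rfd_inh = rfd_inh)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop_domain("toxicity_params: all reference doses must be positive")
  }
  structure(as.list(vals), class = "cr_toxicity")
}

#' Average daily dose via incidental soil ingestion
#'
#' `ADD_ing = Cn * IngR * EF * ED * CF / (BW * AT)`, mg/(kg day). Linear in
#' the soil concentration. Vectorised over `cn` and over numeric profile
#' fields (used by the Monte Carlo engine).
#'
#' @param cn Soil concentration(s), mg/kg.
#' @param p A [receptor_profile()].
#' @return Dose(s) in mg/(kg day).
#' @export
add_ingestion <- function(cn, p) {
  .check_cn(cn)
  cn * p$IngR * p$EF * p$ED * p$CF / (p$BW * p$AT)
}

#' Average daily dose via dermal contact
#'
#' `ADD_derm = Cn * SA * AF * ABS * EF * ED * CF / (BW * AT)`, mg/(kg day).
#'
#' @inheritParams add_ingestion
#' @return Dose(s) in mg/(kg day).
#' @export
add_dermal <- function(cn, p) {
  .check_cn(cn)
  cn * p$SA * p$AF * p$ABS * p$EF * p$ED * p$CF / (p$BW * p$AT)
}

#' Average daily dose via inhalation of resuspended particulates
#'
#' `ADD_inh = Cn * InhR * EF * ED / (PEF * BW * AT)`, mg/(kg day); the
#' particulate emission factor PEF converts the soil concentration to an
#' airborne one, so the dose is inversely proportional to PEF.
#'
#' @inheritParams add_ingestion
#' @return Dose(s) in mg/(kg day).
#' @export
add_inhalation <- function(cn, p) {
  .check_cn(cn)
  cn * p$InhR * p$EF * p$ED / (p$PEF * p$BW * p$AT)
}

.check_cn <- function(cn) {
  if (any(!is.finite(cn) | cn < 0)) {
    stop_domain("soil concentration must be non-negative and finite")
  }
}

#' Hazard quotients for one concentration and receptor
#'
#' Computes the three pathway doses, divides each by its reference dose
#' (HQ = ADD / RfD), and sums them into the reported total HQ (a
#' single-metal hazard index). `HQ > 1` marks a potential non-carcinogenic
#' health effect and sets `exceeds_1`. `pathways` restricts the total to a
#' subset (e.g. ingestion-only variants of the model).
#'
#' @param cn Soil concentration(s), mg/kg; vectorised.
#' @param p A [receptor_profile()] (fields may be equal-length vectors, as
#'   used by the Monte Carlo engine).
#' @param tox A [toxicity_params()].
#' @param region_id Optional identifier(s) carried through to the output.
#' @param pathways Character subset of `c("ing", "derm", "inh")`.
#' @return Data frame with columns `region_id`, `group`, `add_ing`,
#'   `add_derm`, `add_inh`, `hq_ing`, `hq_derm`, `hq_inh`, `hq_total`,
#'   `exceeds_1`.
#' @export
hazard_quotients <- function(cn, p, tox = toxicity_params(),
                             region_id = NA_character_,
                             pathways = c("ing", "derm", "inh")) {
  stopifnot(inherits(p, "cr_receptor"), inherits(tox, "cr_toxicity"))
  pathways <- match.arg(pathways, several.ok = TRUE)
  a_ing <- add_ingestion(cn, p)
  a_derm <- add_dermal(cn, p)
  a_inh <- add_inhalation(cn, p)
  hq <- list(ing = a_ing / tox$rfd_ing,
             derm = a_derm / tox$rfd_derm,
             inh = a_inh / tox$rfd_inh)
  total <- Reduce(`+`, hq[pathways])
  data.frame(region_id = region_id, group = p$group,
             add_ing = a_ing, add_derm = a_derm, add_inh = a_inh,
             hq_ing = hq$ing, hq_derm = hq$derm, hq_inh = hq$inh,
             hq_total = total, exceeds_1 = total > 1,
             stringsAsFactors = FALSE)
}

#' Health-risk assessment of a region table
#'
#' Evaluates [hazard_quotients()] for every region under every receptor
#' profile.
#'
#' @param regions Region data frame.
#' @param receptors List of [receptor_profile()]s (default
#'   [default_receptors()]).
#' @param tox A [toxicity_params()].
#' @param pathways Pathways included in the total HQ.
#' @return Long data frame, one row per region x receptor group.
#' @export
assess_health_risk <- function(regions, receptors = default_receptors(),
                               tox = toxicity_params(),
                               pathways = c("ing", "derm", "inh")) {
  regions <- validate_regions(regions)
  out <- lapply(receptors, function(p)
    hazard_quotients(regions$cr_conc, p, tox,
                     region_id = regions$region_id, pathways = pathways))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise hazard quotients by receptor group (and industry type)
#'
#' Arithmetic mean HQ and the proportion of regions with HQ strictly above 1
#' per receptor group; when `regions` is supplied, also per industry type
#' within each group together with the ratio of the type mean to the
#' all-region (national) mean of that group. Ratios are computed from the
#' unrounded means.
#'
#' @param results Output of [assess_health_risk()] (or any data frame with
#'   `region_id`, `group`, `hq_total`).
#' @param regions Optional region data frame for the per-type breakdown.
#' @return List with `by_group` (data frame: `group`, `n`, `mean_hq`,
#'   `pct_above_1`) and, when `regions` is given, `by_type` (data frame:
#'   `group`, `industry_type`, `n`, `mean_hq`, `pct_above_1`,
#'   `ratio_to_national`).
#' @export
summarize_hq <- function(results, regions = NULL) {
  if (nrow(results) == 0) stop_input("no health-risk results to summarise")
  groups <- unique(results$group)
  by_group <- do.call(rbind, lapply(groups, function(g) {
    hq <- results$hq_total[results$group == g]
    data.frame(group = g, n = length(hq), mean_hq = mean(hq),
               pct_above_1 = 100 * mean(hq > 1), stringsAsFactors = FALSE)
  }))
  out <- list(by_group = by_group)
  if (!is.null(regions)) {
    regions <- validate_regions(regions)
    type_of <- stats::setNames(regions$industry_type, regions$region_id)
    rows <- list()
    for (g in groups) {
      sub <- results[results$group == g, ]
      nat_mean <- mean(sub$hq_total)
      types <- intersect(industry_types, unique(type_of[sub$region_id]))
      empty <- setdiff(industry_types, types)
      if (length(empty) > 0 && g == groups[1]) {
        warning(sprintf("no regions for industry type(s): %s",
                        paste(empty, collapse = ", ")))
      }
      for (ty in types) {
        hq <- sub$hq_total[type_of[sub$region_id] == ty]
        rows[[length(rows) + 1L]] <- data.frame(
          group = g, industry_type = ty, n = length(hq),
          mean_hq = mean(hq), pct_above_1 = 100 * mean(hq > 1),
          ratio_to_national = mean(hq) / nat_mean,
          stringsAsFactors = FALSE)
      }
    }
    out$by_type <- do.call(rbind, rows)
  }
  out
}
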