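# Programmatic fixtures shared across test files.

# Minimal region table builder: recycles scalar arguments.
make_regions <- function(cr, province = "Hunan", type = "M", year = 2010,
                         id = NULL) {
  n <- length(cr)
  data.frame(
    region_id = if (is.null(id)) sprintf("R%03d", seq_len(n)) else id,
    province = rep_len(province, n),
    city = rep_len(NA_character_, n),
    industry_type = rep_len(type, n),
    sampling_year = rep_len(year, n),
    depth_cm = rep_len(20, n),
    cr_conc = cr,
    source = rep_len(NA_character_, n),
    stringsAsFactors = FALSE
  )
}

# A 506-region table in which exactly 21 regions exceed 2500 mg/kg and 8 of
# those 21 sit in Yangtze-River-Delta provinces: the layout of the national
# compilation's exceedance bookkeeping, built deterministically.
fixture_506 <- function() {
  prov_exceed <- c(rep("Zhejiang", 5), rep("Jiangsu", 3),   # 8 in the YRD
                   rep("Hunan", 6), rep("Shandong", 4),
                   rep("Gansu", 3))                         # 13 elsewhere
  prov_rest <- rep(c("Hunan", "Hubei", "Shandong", "Guangdong", "Zhejiang",
                     "Shaanxi", "Fujian"), length.out = 485)
  rbind(
    make_regions(rep(3000, 21), province = prov_exceed, type = "C",
                 id = sprintf("E%03d", 1:21)),
    make_regions(rep(500, 485), province = prov_rest, type = "M",
                 id = sprintf("N%03d", 1:485))
  )
}
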