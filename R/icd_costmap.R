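# ICD-10 disease-group classification, stratum inclusion rule and the DRG
# cost model (cost weight x cantonal base rate).

#' The 21-group ICD-10 disease classification
#'
#' Mutually exclusive disease groups following the main ICD-10 chapters, with
#' diabetes, Alzheimer's/dementia and COPD separated out because of their
#' known heat sensitivity. `priority` resolves the deliberate overlaps: the
#' specific groups (priority 1) win over the general chapter ranges, e.g.
#' the Alzheimer's G-code ranges over the nervous-system chapter, and E10
#' belongs to diabetes, not to the endocrine group.
#'
#' @return A data.frame with columns `disease_group`, `icd10_ranges`
#'   (semicolon-separated `start-end` pairs) and `priority`.
#' @export
disease_group_map <- function() {
  path <- system.file("extdata", "disease_groups.csv", package = "heatcost")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Names of the 21 disease groups, in classification order
#' @export
disease_group_names <- function() disease_group_map()$disease_group

# Normalize an ICD-10 code to a comparable string: uppercase, dot removed.
# Errors on anything not matching letter + 2 digits + optional subcode.
normalize_icd10 <- function(code) {
  code <- toupper(trimws(code))
  ok <- grepl("^[A-Z][0-9]{2}(\\.?[0-9A-Z]{0,4})$", code)
  if (any(!ok))
    stop("malformed ICD-10 code(s): ", paste(code[!ok], collapse = ", "))
  gsub(".", "", code, fixed = TRUE)
}

# Prefix-inclusive range membership on normalized codes: a code is in
# start-end iff its prefix of the endpoint's length lies between them. This
# is the conventional reading of printed ICD-10 ranges (G30-G31.1 contains
# every G31.1x subcode).
icd10_in_range <- function(code_norm, start_norm, end_norm) {
  substr(code_norm, 1, nchar(start_norm)) >= start_norm &
    substr(code_norm, 1, nchar(end_norm)) <= end_norm
}

parse_ranges <- function(spec) {
  parts <- strsplit(spec, ";", fixed = TRUE)[[1]]
  t(vapply(parts, function(p) {
    se <- strsplit(p, "-", fixed = TRUE)[[1]]
    if (length(se) == 1L) se <- c(se, se)
    se <- normalize_icd10(se)
    if (se[1] > se[2]) stop("range start after end: ", p)
    se
  }, character(2)))
}

#' Map ICD-10 codes to disease groups
#'
#' @param code character vector of ICD-10 codes (letter + two digits,
#'   optional subcode, dot optional). Malformed codes are rejected.
#' @return Character vector: the matching disease group, or `"unmapped"` for
#'   codes outside every configured range.
#' @examples
#' map_icd10(c("E11", "J42", "G31.2", "U07"))
#' @export
map_icd10 <- function(code) {
  cn <- normalize_icd10(code)
  map <- disease_group_map()
  map <- map[order(map$priority), ]
  out <- rep("unmapped", length(cn))
  todo <- rep(TRUE, length(cn))
  for (i in seq_len(nrow(map))) {
    rg <- parse_ranges(map$icd10_ranges[i])
    hit <- rep(FALSE, length(cn))
    for (r in seq_len(nrow(rg)))
      hit <- hit | icd10_in_range(cn, rg[r, 1], rg[r, 2])
    sel <- todo & hit
    out[sel] <- map$disease_group[i]
    todo <- todo & !hit
  }
  out
}

#' Flag strata for inclusion by total observation count
#'
#' Canton x disease x age strata with fewer than `min_obs` admissions over
#' the whole study period are excluded from model fitting (too sparse for a
#' stable first-stage estimate); a threshold of 100 excludes the expected
#' empty combinations such as pregnancy outside childbearing ages and
#' newborn groups outside infancy.
#'
#' @param totals data.frame with columns `canton`, `disease_group`,
#'   `age_group`, `total` (non-negative integers over the study period).
#' @param min_obs inclusion threshold (included iff `total >= min_obs`).
#' @return `totals` with a logical `include` column appended.
#' @export
stratum_inclusion <- function(totals, min_obs = 100) {
  stopifnot(all(c("canton", "disease_group", "age_group", "total")
                %in% names(totals)))
  if (any(totals$total < 0) || any(totals$total != round(totals$total)))
    stop("totals must be non-negative integers")
  totals$include <- totals$total >= min_obs
  totals
}

#' DRG cost table
#'
#' @param cost_weight data.frame with columns `year`, `disease_group`,
#'   `age_group`, `cost_weight` (unitless, > 0).
#' @param base_rate data.frame with columns `year`, `canton`, `base_rate`
#'   (CHF per unit cost weight, > 0); one cantonal rate per year, already
#'   averaged across the canton's hospitals (see [cantonal_base_rates()]).
#' @return An object of class `cost_table`.
#' @export
cost_table <- function(cost_weight, base_rate) {
  stopifnot(all(c("year", "disease_group", "age_group", "cost_weight")
                %in% names(cost_weight)),
            all(c("year", "canton", "base_rate") %in% names(base_rate)))
  if (any(cost_weight$cost_weight <= 0)) stop("cost weights must be > 0")
  if (any(base_rate$base_rate <= 0)) stop("base rates must be > 0")
  structure(list(cost_weight = cost_weight, base_rate = base_rate),
            class = "cost_table")
}

#' Cantonal base rates from hospital-level rates
#'
#' Averages negotiated per-hospital base rates within each canton, then takes
#' a trailing mean over a window of years (default 5) to smooth negotiation
#' cycles.
#'
#' @param hospital_rates data.frame with columns `year`, `canton`,
#'   `hospital`, `base_rate`.
#' @param window trailing window length in years.
#' @return data.frame with columns `year`, `canton`, `base_rate`.
#' @export
cantonal_base_rates <- function(hospital_rates, window = 5) {
  stopifnot(all(c("year", "canton", "base_rate") %in% names(hospital_rates)))
  ann <- stats::aggregate(base_rate ~ year + canton, hospital_rates, mean)
  out <- do.call(rbind, lapply(split(ann, ann$canton), function(d) {
    d <- d[order(d$year), ]
    d$base_rate <- vapply(seq_len(nrow(d)), function(i) {
      mean(d$base_rate[max(1, i - window + 1):i])
    }, numeric(1))
    d
  }))
  rownames(out) <- NULL
  out
}

#' Per-admission cost for a stratum
#'
#' The DRG cost model: cost weight of the (year, disease group, age group)
#' cell times the cantonal base rate of the (year, canton) cell.
#'
#' @param table a [cost_table()].
#' @param year,disease_group,age_group,canton scalar keys.
#' @return CHF per admission.
#' @export
stratum_cost <- function(table, year, disease_group, age_group, canton) {
  stopifnot(inherits(table, "cost_table"))
  cw <- table$cost_weight
  w <- cw$cost_weight[cw$year == year & cw$disease_group == disease_group &
                        cw$age_group == age_group]
  if (length(w) != 1L)
    stop("no cost weight for (year=", year, ", disease_group=", disease_group,
         ", age_group=", age_group, ")")
  br <- table$base_rate
  r <- br$base_rate[br$year == year & br$canton == canton]
  if (length(r) != 1L)
    stop("no base rate for (year=", year, ", canton=", canton, ")")
  w * r
}
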