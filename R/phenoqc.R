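#' Somatic cell score from somatic cell count
#'
#' SCS = log2(SCC / 100) + 3, with SCC in units of 1,000 cells/mL (the DHI
#' convention), so SCC = 100 maps to a score of 3.
#'
#' @param scc Somatic cell count, 1,000 cells/mL; must be positive.
#' @return Somatic cell score.
#' @export
compute_scs <- function(scc) {
  if (any(!is.na(scc) & scc <= 0)) stop("scc must be positive (log transform)")
  log2(scc / 100) + 3
}

# inverse of compute_scs, used by the simulator and in round-trip checks
.scs_to_scc <- function(scs) 100 * 2^(scs - 3)

#' Fat and protein yield from milk yield and component percentages
#'
#' FY = FP * MY / 100 and PY = PP * MY / 100 (kg/day).
#'
#' @param my Milk yield, kg/day (non-negative).
#' @param fp Fat percentage.
#' @param pp Protein percentage.
#' @return Data frame with columns `fy` and `py`.
#' @export
compute_component_yields <- function(my, fp, pp) {
  if (any(!is.na(my) & my < 0)) stop("my must be non-negative")
  data.frame(fy = fp * my / 100, py = pp * my / 100)
}

#' Populate the derived trait columns of a record table
#'
#' Fills `scs`, `fy` and `py` from `scc`, `my`, `fp`, `pp` where missing.
#'
#' @param records Test-day record data frame.
#' @return The records with derived columns populated.
#' @export
derive_traits <- function(records) {
  ok <- !is.na(records$scc) & records$scc > 0
  records$scs <- NA_real_
  records$scs[ok] <- compute_scs(records$scc[ok])
  yields <- compute_component_yields(records$my, records$fp, records$pp)
  if (is.null(records$fy)) records$fy <- yields$fy
  records$fy[is.na(records$fy)] <- yields$fy[is.na(records$fy)]
  if (is.null(records$py)) records$py <- yields$py
  records$py[is.na(records$py)] <- yields$py[is.na(records$py)]
  records
}

#' Age at first calving in whole calendar months
#'
#' Calendar-month difference between birth and calving; the day of month is
#' ignored.
#'
#' @param birth_date,calving_date `Date` vectors.
#' @return Integer months.
#' @export
age_at_calving_months <- function(birth_date, calving_date) {
  b <- as.POSIXlt(birth_date); cdt <- as.POSIXlt(calving_date)
  12L * (cdt$year - b$year) + (cdt$mon - b$mon)
}

.filter_report <- function(records_in, records_out, cows_in, cows_out, rules) {
  structure(list(records_in = records_in, records_out = records_out,
                 cows_in = cows_in, cows_out = cows_out,
                 per_rule_rejections = rules),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("records %d -> %d, cows %d -> %d\n", x$records_in,
              x$records_out, x$cows_in, x$cows_out))
  for (r in names(x$per_rule_rejections)) {
    cat(sprintf("  %-22s %d\n", r, x$per_rule_rejections[[r]]))
  }
  invisible(x)
}

#' Record-level inclusion criteria
#'
#' Retains records with age at first calving 19-37 months (inclusive),
#' DIM 5-305, milk yield 1.0-65 kg, fat 0.5-8.5\%, protein 0.5-7.5\%, and
#' SCC strictly below 2,000 (1,000 cells/mL, i.e. 2 million cells/mL). All
#' bounds are inclusive except the SCC cap. Records with missing required
#' fields are rejected under rule `missing_field` rather than crashing.
#'
#' @param records Test-day record data frame with dates populated.
#' @return List with elements `records` (survivors) and `report`
#'   (a `filter_report`; a record may fail several rules).
#' @export
apply_record_filters <- function(records) {
  n0 <- nrow(records)
  cows0 <- length(unique(records$cow_id))
  afc <- age_at_calving_months(records$birth_date, records$calving_date)
  need <- cbind(dim = records$dim, my = records$my, fp = records$fp,
                pp = records$pp, scc = records$scc, afc = afc)
  miss <- rowSums(is.na(need)) > 0
  fail <- list(
    missing_field = miss,
    afc_range = !miss & (afc < 19 | afc > 37),
    dim_range = !miss & (records$dim < 5 | records$dim > 305),
    my_range  = !miss & (records$my < 1.0 | records$my > 65),
    fp_range  = !miss & (records$fp < 0.5 | records$fp > 8.5),
    pp_range  = !miss & (records$pp < 0.5 | records$pp > 7.5),
    scc_cap   = !miss & (records$scc >= 2000))
  drop <- Reduce(`|`, fail)
  kept <- records[!drop, , drop = FALSE]
  rep <- .filter_report(n0, nrow(kept), cows0, length(unique(kept$cow_id)),
                        vapply(fail, sum, integer(1)))
  list(records = kept, report = rep)
}

#' Cow-level inclusion criteria
#'
#' Drops every record of cows with fewer than three surviving records, no
#' record before DIM 45, or a calving date on/after the cutoff.
#'
#' @param records Record-filtered test-day records.
#' @param max_calving_date Calving-date cutoff (default `"2019-12-01"`,
#'   i.e. calvings must precede December 2019).
#' @return List with `records` and `report` as in [apply_record_filters()].
#' @export
apply_cow_filters <- function(records, max_calving_date = as.Date("2019-12-01")) {
  n0 <- nrow(records)
  cows0 <- length(unique(records$cow_id))
  max_calving_date <- as.Date(max_calving_date)
  sp <- split(seq_len(n0), records$cow_id)
  bad_n <- bad_early <- bad_calv <- character(0)
  for (cw in names(sp)) {
    idx <- sp[[cw]]
    if (length(idx) < 3L) bad_n <- c(bad_n, cw)
    if (!any(records$dim[idx] < 45)) bad_early <- c(bad_early, cw)
    if (any(records$calving_date[idx] >= max_calving_date)) bad_calv <- c(bad_calv, cw)
  }
  bad <- unique(c(bad_n, bad_early, bad_calv))
  keep <- !(records$cow_id %in% bad)
  kept <- records[keep, , drop = FALSE]
  count_rec <- function(cws) sum(records$cow_id %in% cws)
  rep <- .filter_report(n0, nrow(kept), cows0, length(unique(kept$cow_id)),
                        c(min_records = count_rec(bad_n),
                          no_early_test = count_rec(bad_early),
                          calving_cutoff = count_rec(bad_calv)))
  list(records = kept, report = rep)
}

#' Assign fixed-effect factor levels
#'
#' Herd-test-date is the herd x test-date cell; the age class crosses the
#' calving month with a binned age at first calving; the season class
#' crosses the calving year with its season (calendar quarters by default).
#'
#' @param records Filtered records with dates populated.
#' @param season_rule Either `"quarter"` or a function mapping a `Date`
#'   vector to season labels.
#' @param age_breaks Breakpoints (months) for age-at-first-calving bins.
#' @return Records with columns `htd`, `age_class`, `season_class`.
#' @export
assign_factor_levels <- function(records, season_rule = "quarter",
                                 age_breaks = c(19, 25, 30, 37)) {
  if (any(is.na(records$test_date)) || any(is.na(records$calving_date))) {
    stop("unparsable or missing dates in records")
  }
  records$htd <- paste(records$herd, format(records$test_date, "%Y%m%d"),
                       sep = ":")
  afc <- age_at_calving_months(records$birth_date, records$calving_date)
  bin <- cut(afc, breaks = age_breaks, include.lowest = TRUE, labels = FALSE)
  records$age_class <- paste0("M", format(records$calving_date, "%m"),
                              "_A", bin)
  season <- if (is.function(season_rule)) {
    season_rule(records$calving_date)
  } else if (identical(season_rule, "quarter")) {
    paste0("Q", (as.integer(format(records$calving_date, "%m")) - 1L) %/% 3L + 1L)
  } else stop("unknown season_rule")
  records$season_class <- paste(format(records$calving_date, "%Y"), season,
                                sep = "_")
  records
}

#' Descriptive statistics per trait
#'
#' One row per trait: record and animal counts, mean, sample SD, min, max
#' and the coefficient of variation CV = SD / mean.
#'
#' @param records Records with derived traits populated.
#' @param traits Trait columns to summarize.
#' @return Data frame, one row per trait with any data (empty traits are
#'   dropped with a warning).
#' @export
summarize_traits <- function(records,
                             traits = c("my", "fy", "py", "fp", "pp", "scs")) {
  rows <- lapply(traits, function(tr) {
    x <- records[[tr]]
    ok <- !is.na(x)
    if (!any(ok)) {
      warning("no records for trait ", tr, "; row omitted")
      return(NULL)
    }
    data.frame(trait = tr, n_records = sum(ok),
               n_animals = length(unique(records$cow_id[ok])),
               mean = mean(x[ok]), sd = stats::sd(x[ok]),
               min = min(x[ok]), max = max(x[ok]),
               cv = coef_variation(x[ok]))
  })
  do.call(rbind, rows)
}

#' Coefficient of variation
#'
#' CV = SD / mean (sample SD). Supply `mean` and `sd` directly to reproduce
#' a CV from printed summary statistics.
#'
#' @param x Numeric vector (ignored when `mean` and `sd` are given).
#' @param mean,sd Optional pre-computed summary statistics.
#' @return CV as a plain ratio (multiply by 100 for percent).
#' @export
coef_variation <- function(x = NULL, mean = NULL, sd = NULL) {
  if (is.null(mean)) mean <- base::mean(x, na.rm = TRUE)
  if (is.null(sd)) sd <- stats::sd(x, na.rm = TRUE)
  if (mean == 0) return(ifelse(sd == 0, 0, NA_real_))
  if (sd == 0) return(0)
  sd / mean
}
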