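# Phenotype processing for multi-location trials: average tuber weight as a
# derived trait, additive location adjustment by check-cultivar means, and
# AUDPC from repeated disease severity scores.

#' Derive average tuber weight (ATW) records
#'
#' ATW = TW / TN per plot, pairing tuber weight (kg) and tuber number
#' records by genotype, location and replicate. Plots with TN = 0 yield a
#' missing ATW and a warning.
#'
#' @param pheno long-format phenotype `data.frame` with `genotype_id`,
#'   `location`, `replicate`, `trait`, `value`.
#' @param tw_trait,tn_trait,atw_trait trait labels.
#' @return `pheno` with ATW rows appended.
#' @export
derive_atw <- function(pheno, tw_trait = "TW", tn_trait = "TN",
                       atw_trait = "ATW") {
  tw <- pheno[pheno$trait == tw_trait, ]
  tn <- pheno[pheno$trait == tn_trait, ]
  if (!nrow(tw) || !nrow(tn))
    stop("both TW and TN records are required to derive ATW")
  key <- c("genotype_id", "location", "replicate")
  m <- merge(tw, tn[, c(key, "value")], by = key,
             suffixes = c("", ".tn"), sort = FALSE)
  zero <- !is.na(m$value.tn) & m$value.tn == 0
  if (any(zero))
    warning(sprintf("%d plot(s) with TN = 0; ATW set to missing", sum(zero)))
  atw <- m
  atw$trait <- atw_trait
  atw$value <- ifelse(zero, NA_real_, m$value / m$value.tn)
  atw$value.tn <- NULL
  rbind(pheno, atw[, names(pheno)])
}

#' Adjust phenotypes by location using check-cultivar means
#'
#' Additive centering: each record is shifted by the deviation of its
#' location's check mean from the grand check mean (the unweighted mean of
#' the per-location check means), trait by trait:
#' `adjusted = raw - (check_mean_location - grand_check_mean)`.
#' Within-location differences between genotypes are preserved exactly and
#' between-location differences in check means are removed.
#'
#' @param pheno long-format phenotype `data.frame`.
#' @param check_ids genotype ids of the check cultivars.
#' @param traits traits to adjust; defaults to every trait present except
#'   late-blight scores (`LB`, `LB_score`), which are recorded on a
#'   per-plant basis only.
#' @return `pheno` with adjusted values and a logical `adjusted` column.
#' @export
adjust_by_location <- function(pheno, check_ids,
                               traits = setdiff(unique(pheno$trait),
                                                c("LB", "LB_score"))) {
  stopifnot(length(check_ids) >= 1)
  out <- pheno
  if (!"adjusted" %in% names(out)) out$adjusted <- FALSE
  for (tr in traits) {
    rows <- out$trait == tr
    chk <- out[rows & out$genotype_id %in% check_ids & !is.na(out$value), ]
    locs <- unique(out$location[rows])
    missing_loc <- setdiff(locs, unique(chk$location))
    if (length(missing_loc))
      stop(sprintf("no check records for trait '%s' at location(s): %s",
                   tr, paste(missing_loc, collapse = ", ")))
    loc_means <- tapply(chk$value, chk$location, mean)
    grand <- mean(loc_means)
    shift <- loc_means[out$location[rows]] - grand
    out$value[rows] <- out$value[rows] - as.numeric(shift)
    out$adjusted[rows] <- TRUE
  }
  out
}

#' Area under the disease progress curve
#'
#' Trapezoidal integration of repeated severity scores over observation
#' times: `sum_i (y_i + y_(i+1))/2 * (t_(i+1) - t_i)`, in score-days.
#'
#' @param times strictly increasing observation times (days).
#' @param scores severity scores at those times.
#' @return the AUDPC value (non-negative for non-negative scores).
#' @export
audpc <- function(times, scores) {
  stopifnot(length(times) == length(scores))
  if (length(times) < 2) stop("AUDPC needs at least two time points")
  if (any(diff(times) <= 0))
    stop("observation times must be strictly increasing")
  dt <- diff(times)
  sum((scores[-length(scores)] + scores[-1]) / 2 * dt)
}

#' AUDPC per genotype from a long-format score table
#'
#' @param scores `data.frame` with `genotype_id`, `time` (days) and `value`
#'   columns; one repeated-score series per genotype.
#' @return `data.frame` with `genotype_id` and `audpc`.
#' @export
audpc_records <- function(scores) {
  stopifnot(all(c("genotype_id", "time", "value") %in% names(scores)))
  ids <- unique(scores$genotype_id)
  vals <- vapply(ids, function(g) {
    s <- scores[scores$genotype_id == g, ]
    s <- s[order(s$time), ]
    audpc(s$time, s$value)
  }, numeric(1))
  data.frame(genotype_id = ids, audpc = as.numeric(vals),
             stringsAsFactors = FALSE)
}

#' Per-genotype means of (adjusted) phenotype records
#'
#' @param pheno long-format phenotype `data.frame`.
#' @param trait trait to summarise.
#' @return named numeric vector of genotype means.
#' @export
genotype_means <- function(pheno, trait) {
  rows <- pheno$trait == trait & !is.na(pheno$value)
  if (!any(rows)) stop("no records for trait '", trait, "'")
  tapply(pheno$value[rows], pheno$genotype_id[rows], mean)
}
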