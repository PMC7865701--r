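#' Stratify patients by an anchor/partner gene pair
#'
#' The patient-cohort analogue of [partition_by_pair()]: each patient is
#' labelled by the disruption status of the anchor gene (e.g. TP53) and one
#' SC partner. `both_mut` is the reference level, so hazard ratios above 1
#' for the other groups mean worse survival than the double-mutant group.
#'
#' @param m A `disruption_matrix` over patients.
#' @param anchor,partner Gene symbols present in `m`.
#' @return Named factor (levels `both_mut`, `anchor_only`, `partner_only`,
#'   `wild_type`; reference `both_mut`), one label per patient.
#' @export
stratify_pair_groups <- function(m, anchor, partner) {
  part <- partition_by_pair(m, anchor, partner)
  lab <- rep(NA_character_, nrow(m))
  names(lab) <- rownames(m)
  lab[part$both] <- "both_mut"
  lab[part$a_only] <- "anchor_only"
  lab[part$b_only] <- "partner_only"
  lab[part$neither] <- "wild_type"
  factor(lab, levels = c("both_mut", "anchor_only", "partner_only",
                         "wild_type"))
}

#' Partner-disruption burden by anchor stratum
#'
#' Counts, per patient, how many of the anchor gene's SC partners are
#' disrupted, and records whether the patient carries the anchor disruption
#' — the cumulative-disruption stratification used for the with/without
#' anchor survival contrast.
#'
#' @param m A `disruption_matrix` over patients.
#' @param anchor Anchor gene symbol.
#' @param partners Non-empty character vector of partner gene symbols.
#' @return A `data.frame` with `patient_id`, `partner_burden` (0..number of
#'   partners) and `anchor_mut` (0/1).
#' @export
partner_burden <- function(m, anchor, partners) {
  if (length(partners) == 0L) stop("partners must be non-empty")
  for (g in c(anchor, partners))
    if (!g %in% colnames(m)) stop("gene not in matrix: ", g)
  data.frame(patient_id = rownames(m),
             partner_burden = as.integer(rowSums(m[, partners, drop = FALSE])),
             anchor_mut = as.integer(m[, anchor]),
             stringsAsFactors = FALSE)
}

#' Encode tumour stage as an ordinal covariate
#'
#' @param stage Character vector with values `I`..`IV` (a `Stage ` prefix is
#'   tolerated); `NA` passes through.
#' @param dummies If `TRUE`, return an indicator matrix (stages II--IV
#'   against reference I) instead of the single ordinal code.
#' @return Numeric vector 1..4 (or an indicator matrix).
#' @export
encode_stage <- function(stage, dummies = FALSE) {
  s <- sub("^[Ss]tage[ _]?", "", as.character(stage))
  code <- match(s, c("I", "II", "III", "IV"))
  if (any(!is.na(stage) & is.na(code)))
    stop("unrecognised stage value(s): ",
         paste(unique(stage[!is.na(stage) & is.na(code)]), collapse = ", "))
  if (!dummies) return(as.numeric(code))
  out <- sapply(2:4, function(k) as.numeric(code == k))
  colnames(out) <- c("stage_II", "stage_III", "stage_IV")
  out
}

#' Kaplan-Meier curves with a risk table
#'
#' Product-limit survival estimates per group, `S(t) = prod(1 - d_i/n_i)`
#' over event times up to `t`; subjects censored at `t` remain at risk at
#' `t`. A risk table (patients still at risk) is evaluated at `risk_times`.
#'
#' @param time Non-negative follow-up times.
#' @param event 0/1 event indicators.
#' @param group Optional grouping vector (one curve per level; a single
#'   curve when omitted).
#' @param risk_times Times at which to tabulate the numbers at risk;
#'   defaults to quartiles of follow-up.
#' @return A list of class `km_curve` with `curves` (`data.frame`: `group`,
#'   `time`, `n_risk`, `n_event`, `survival`) and `risk_table`
#'   (`data.frame`: `group`, `time`, `at_risk`).
#' @export
kaplan_meier <- function(time, event, group = NULL, risk_times = NULL) {
  if (any(time < 0)) stop("negative survival time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  g <- if (is.null(group)) factor(rep("all", length(time))) else factor(group)
  if (any(table(g) == 0L)) g <- droplevels(g)
  if (is.null(risk_times))
    risk_times <- unique(round(stats::quantile(time, c(0, .25, .5, .75, 1))))
  curves <- list()
  risk <- list()
  for (lev in levels(g)) {
    i <- g == lev
    sf <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    ev <- sf$n.event > 0  # the curve steps only at event times
    curves[[lev]] <- data.frame(group = rep(lev, sum(ev)), time = sf$time[ev],
                                n_risk = sf$n.risk[ev],
                                n_event = sf$n.event[ev],
                                survival = sf$surv[ev],
                                stringsAsFactors = FALSE)
    sm <- summary(sf, times = risk_times, extend = TRUE)
    risk[[lev]] <- data.frame(group = lev, time = sm$time,
                              at_risk = sm$n.risk, stringsAsFactors = FALSE)
  }
  structure(list(curves = do.call(rbind, curves),
                 risk_table = do.call(rbind, risk)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  ngrp <- length(unique(x$curves$group))
  cat("Kaplan-Meier estimate:", ngrp, "group(s),",
      nrow(x$curves), "step(s)\n")
  for (lev in unique(x$curves$group)) {
    cc <- x$curves[x$curves$group == lev, ]
    cat("  ", lev, ": final S(t) = ",
        format(cc$survival[nrow(cc)], digits = 4), " at t = ",
        format(cc$time[nrow(cc)]), "\n", sep = "")
  }
  invisible(x)
}

#' @export
plot.km_curve <- function(x, col = NULL, lwd = 2, xlab = "time",
                          ylab = "survival probability", ...) {
  groups <- unique(x$curves$group)
  if (is.null(col)) col <- seq_along(groups)
  graphics::plot(NA, xlim = c(0, max(x$curves$time)), ylim = c(0, 1),
                 xlab = xlab, ylab = ylab, ...)
  for (k in seq_along(groups)) {
    cc <- x$curves[x$curves$group == groups[k], ]
    graphics::lines(c(0, cc$time), c(1, cc$survival), type = "s",
                    col = col[k], lwd = lwd)
  }
  graphics::legend("bottomleft", legend = groups, col = col, lwd = lwd,
                   bty = "n")
  invisible(x)
}

#' Interpolate a KM curve at arbitrary times
#'
#' @param x A `km_curve`.
#' @param times Times at which to read off the step function.
#' @param group Group label (needed when several curves are present).
#' @return Numeric survival probabilities (right-continuous step values).
#' @export
km_survival_at <- function(x, times, group = NULL) {
  cc <- x$curves
  if (!is.null(group)) cc <- cc[cc$group == group, , drop = FALSE]
  if (length(unique(cc$group)) > 1L) stop("specify a group")
  vapply(times, function(t) {
    below <- cc$time <= t
    if (!any(below)) 1 else cc$survival[max(which(below))]
  }, numeric(1))
}

#' Write KM coordinates and risk table as TSV
#'
#' @param x A `km_curve`.
#' @param path Output TSV path for the curve coordinates; the risk table is
#'   written to `<path>.risk.tsv`.
#' @export
write_km_curve <- function(x, path) {
  utils::write.table(x$curves, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(x$risk_table, paste0(path, ".risk.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a Firth Cox regression table as TSV
#'
#' @param fit A `firth_coxph` object.
#' @param path Output TSV path.
#' @export
write_regression_table <- function(fit, path) {
  tab <- data.frame(covariate = names(coef(fit)), beta = unname(coef(fit)),
                    hazard_ratio = unname(fit$hazard_ratio),
                    p_value = unname(fit$p_value),
                    n = fit$n, events = fit$n_events,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
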