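#' Fit a variable-slope sigmoidal dose-response curve
#'
#' Fits a three-parameter logistic inhibition model
#' \deqn{y(d) = A_{max} / (1 + (EC_{50}/d)^{h})}
#' by least squares, where the lower plateau is fixed at 0% inhibition
#' (untreated growth) and \eqn{A_{max}} is the upper plateau of % inhibition.
#' \eqn{EC_{50}} is the inflection dose (half-\eqn{A_{max}} inhibition) and
#' \eqn{IC_{50}} the dose where the fitted curve crosses 50% inhibition;
#' when the fitted \eqn{A_{max}} is below 50%, \eqn{IC_{50}} is set to the
#' maximum tested dose. Fitting uses Levenberg-Marquardt least squares with
#' multiple starts taken from data quantiles.
#'
#' @param doses Strictly ascending positive doses (molar); at least 3.
#' @param inhibition Percent inhibition at each dose (0 = untreated growth,
#'   100 = total kill). Values outside \[0, 100\] are allowed (assay noise).
#' @return An object of class `sigmoid_fit`: list with `a_max`, `ec50`,
#'   `ic50`, `hill`, `converged`, `ec50_extrapolated`, `max_dose`.
#' @export
fit_dose_response <- function(doses, inhibition) {
  stopifnot(is.numeric(doses), is.numeric(inhibition))
  if (length(doses) < 3 || length(unique(doses)) < 3) {
    stop("at least 3 distinct doses are required for curve fitting")
  }
  if (length(doses) != length(inhibition)) {
    stop("doses and inhibition must have equal length")
  }
  if (any(!is.finite(doses)) || any(doses <= 0)) stop("doses must be positive")
  if (is.unsorted(doses)) stop("doses must be ascending")
  if (any(!is.finite(inhibition))) stop("inhibition values must be finite")

  max_dose <- max(doses)
  out <- list(a_max = NA_real_, ec50 = NA_real_, ic50 = NA_real_,
              hill = NA_real_, converged = FALSE,
              ec50_extrapolated = FALSE, max_dose = max_dose)
  class(out) <- "sigmoid_fit"

  # Degenerate flat curve: no dose dependence to fit.
  if (diff(range(inhibition)) < 1e-8) {
    out$a_max <- mean(inhibition)
    out$converged <- TRUE
    out$ic50 <- if (out$a_max < 50) max_dose else max_dose
    return(out)
  }

  df <- data.frame(d = doses, y = inhibition)
  top0 <- max(inhibition)
  # EC50 starts: dose nearest the half-max crossing, plus range quantiles
  half <- top0 / 2
  cross <- doses[which.min(abs(inhibition - half))]
  starts_ec <- unique(c(cross, exp(quantile(log(doses), c(0.25, 0.5, 0.75)))))
  best <- NULL
  for (ec0 in starts_ec) {
    for (h0 in c(0.5, 1, 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ amax / (1 + (ec50 / d)^hill),
          data = df,
          start = list(amax = max(top0, 1), ec50 = ec0, hill = h0),
          lower = c(amax = -Inf, ec50 = min(doses) * 1e-6, hill = 1e-3),
          upper = c(amax = Inf, ec50 = max_dose * 1e6, hill = 100),
          control = minpack.lm::nls.lm.control(maxiter = 200)
        ),
        error = function(e) NULL, warning = function(w) NULL
      )
      if (!is.null(fit)) {
        sse <- sum(stats::resid(fit)^2)
        if (is.null(best) || sse < best$sse - 1e-12) {
          best <- list(fit = fit, sse = sse)
        }
      }
    }
  }

  if (is.null(best)) {
    # non-convergence fallback: report the empirical maximum inhibition
    out$a_max <- max(inhibition)
    out$ic50 <- if (out$a_max < 50) max_dose else max_dose
    return(out)
  }

  cf <- stats::coef(best$fit)
  out$a_max <- unname(cf["amax"])
  out$ec50 <- unname(cf["ec50"])
  out$hill <- unname(cf["hill"])
  out$converged <- TRUE
  out$ec50_extrapolated <- out$ec50 < min(doses) || out$ec50 > max_dose
  if (out$a_max < 50) {
    out$ic50 <- max_dose
  } else {
    # solve amax / (1 + (ec50/d)^h) = 50
    d50 <- out$ec50 / (out$a_max / 50 - 1)^(1 / out$hill)
    out$ic50 <- min(d50, max_dose)
  }
  out
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid fit: Amax = %.1f%%, EC50 = %.3g M, IC50 = %.3g M, hill = %.2f%s\n",
    x$a_max, x$ec50, x$ic50, x$hill,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Three-class sensitivity call from Amax
#'
#' Classifies maximum inhibition into sensitive (\eqn{A_{max} \ge 70}),
#' insensitive (\eqn{A_{max} \le 50}) or intermediate (the open interval
#' between). The boundary values 70 and 50 belong to sensitive and
#' insensitive respectively.
#'
#' @param a_max Numeric vector of maximum % inhibition values.
#' @return Character vector with values `"sensitive"`, `"intermediate"`,
#'   `"insensitive"`.
#' @export
call_sensitivity <- function(a_max) {
  stopifnot(is.numeric(a_max), all(is.finite(a_max)))
  ifelse(a_max >= 70, "sensitive",
         ifelse(a_max <= 50, "insensitive", "intermediate"))
}

#' Majority-vote consensus of per-screen sensitivity calls
#'
#' Aggregates one cell line's per-screen calls by strict majority vote over
#' the non-missing calls. An exact tie among distinct calls (including the
#' two-screen sensitive/insensitive pattern) yields `"conflict"`. The result
#' is invariant to the ordering of the input.
#'
#' @param calls Character vector of per-screen calls
#'   (`"sensitive"`/`"intermediate"`/`"insensitive"`, `NA` allowed).
#' @return A single call: one of `"sensitive"`, `"intermediate"`,
#'   `"insensitive"`, `"conflict"`.
#' @export
consensus_call <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) stop("at least one non-missing call is required")
  bad <- setdiff(unique(calls), c("sensitive", "intermediate", "insensitive"))
  if (length(bad) > 0) stop("invalid call(s): ", paste(bad, collapse = ", "))
  tab <- table(calls)
  top <- max(tab)
  winners <- names(tab)[tab == top]
  if (length(winners) > 1) "conflict" else winners
}

#' Consensus calls for a table of per-screen calls
#'
#' @param calls_df Data frame with columns `cell_line_id`, `screen_id`,
#'   `call`.
#' @return Data frame with one row per cell line: `cell_line_id`, `call`,
#'   `n_screens`.
#' @export
consensus_calls <- function(calls_df) {
  stopifnot(all(c("cell_line_id", "call") %in% names(calls_df)))
  ids <- sort(unique(calls_df$cell_line_id))
  res <- lapply(ids, function(id) {
    cc <- calls_df$call[calls_df$cell_line_id == id]
    cc <- cc[!is.na(cc)]
    data.frame(cell_line_id = id, call = consensus_call(cc),
               n_screens = length(cc), stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Lineage enrichment of sensitivity by Fisher's exact test
#'
#' For each lineage with at least `min_n` lines among the
#' sensitive/insensitive consensus calls, tests enrichment of sensitivity
#' and of insensitivity with one-sided Fisher's exact tests on the 2x2
#' table (lineage vs rest) x (sensitive vs insensitive).
#'
#' @param consensus Data frame with columns `cell_line_id`, `call`; only
#'   `"sensitive"`/`"insensitive"` rows are used (others dropped).
#' @param lineages Named character vector mapping cell_line_id to lineage.
#' @param min_n Minimum lines per lineage to be tested (default 10).
#' @return Data frame: `lineage`, `n`, `n_sensitive`, `response_rate`,
#'   `p_sensitive`, `p_insensitive`. Lineages below `min_n` are excluded
#'   (reported via a message).
#' @export
lineage_enrichment <- function(consensus, lineages, min_n = 10) {
  keep <- consensus$call %in% c("sensitive", "insensitive")
  consensus <- consensus[keep, , drop = FALSE]
  lin <- unname(lineages[consensus$cell_line_id])
  if (anyNA(lin)) stop("missing lineage for some cell lines")
  sens <- consensus$call == "sensitive"
  res <- list()
  for (L in sort(unique(lin))) {
    in_l <- lin == L
    n <- sum(in_l)
    if (n < min_n) {
      message("lineage ", L, " excluded (n = ", n, " < ", min_n, ")")
      next
    }
    a <- sum(in_l & sens)          # sensitive in lineage
    b <- n - a                     # insensitive in lineage
    c_ <- sum(!in_l & sens)
    d <- sum(!in_l & !sens)
    res[[L]] <- data.frame(
      lineage = L, n = n, n_sensitive = a, response_rate = a / n,
      p_sensitive = fisher_exact_p(a, b, c_, d, "greater"),
      p_insensitive = fisher_exact_p(a, b, c_, d, "less"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Xenograft anti-tumor response from arm-level tumor volumes
#'
#' Computes %T/C = 100 x dT/dC when the treated arm grew (dT >= 0), or
#' %Regression = 100 x dT/T_i when it shrank (dT < 0), where
#' dT = T_final - T_initial and dC = C_final - C_initial are the mean
#' tumor-volume changes of the treated and control arms. A model is a
#' responder on tumor stasis (%T/C < 10) or regression (%REG < 10).
#'
#' @param model_id Model identifier.
#' @param tv_treated_initial,tv_treated_final Mean treated-arm tumor volume
#'   (mm^3) at start and end.
#' @param tv_control_initial,tv_control_final Mean control-arm tumor volume
#'   (mm^3) at start and end.
#' @return Data frame row: `model_id`, `t_over_c`, `regression`,
#'   `responder`, `valid` (`FALSE` when the control arm did not grow, which
#'   leaves %T/C undefined).
#' @export
in_vivo_response <- function(model_id, tv_treated_initial, tv_treated_final,
                             tv_control_initial, tv_control_final) {
  dT <- tv_treated_final - tv_treated_initial
  dC <- tv_control_final - tv_control_initial
  if (dC <= 0) {
    return(data.frame(model_id = model_id, t_over_c = NA_real_,
                      regression = NA_real_, responder = NA, valid = FALSE,
                      stringsAsFactors = FALSE))
  }
  if (dT >= 0) {
    toc <- 100 * dT / dC
    reg <- NA_real_
    responder <- toc < 10
  } else {
    toc <- NA_real_
    reg <- 100 * dT / tv_treated_initial
    responder <- reg < 10
  }
  data.frame(model_id = model_id, t_over_c = toc, regression = reg,
             responder = responder, valid = TRUE, stringsAsFactors = FALSE)
}

#' Process a long-format dose-response table into sensitivity calls
#'
#' Averages replicate inhibition values per dose (the default replicate
#' policy), fits a sigmoidal curve per cell line per screen, extracts Amax
#' and calls sensitivity, then aggregates per-line consensus calls by
#' majority vote.
#'
#' @param dr Data frame with columns `cell_line_id`, `screen_id`, `dose`,
#'   `inhibition` and optionally `replicate`.
#' @param average_replicates Average replicates per dose before fitting
#'   (default `TRUE`); if `FALSE`, all points enter the fit jointly.
#' @return List with `fits` (per line/screen data frame: `cell_line_id`,
#'   `screen_id`, `a_max`, `ec50`, `ic50`, `converged`, `call`) and
#'   `consensus` (per line consensus calls).
#' @export
process_screens <- function(dr, average_replicates = TRUE) {
  stopifnot(all(c("cell_line_id", "screen_id", "dose", "inhibition") %in% names(dr)))
  keys <- unique(dr[, c("cell_line_id", "screen_id")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- dr[dr$cell_line_id == keys$cell_line_id[i] &
              dr$screen_id == keys$screen_id[i], ]
    if (average_replicates) {
      agg <- stats::aggregate(inhibition ~ dose, data = sub, FUN = mean)
    } else {
      agg <- sub[, c("dose", "inhibition")]
    }
    agg <- agg[order(agg$dose), ]
    fit <- fit_dose_response(agg$dose, agg$inhibition)
    data.frame(cell_line_id = keys$cell_line_id[i],
               screen_id = keys$screen_id[i],
               a_max = fit$a_max, ec50 = fit$ec50, ic50 = fit$ic50,
               converged = fit$converged,
               call = call_sensitivity(fit$a_max),
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  list(fits = fits, consensus = consensus_calls(fits))
}
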