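## Kinetic model of protein turnover under heavy-water labeling.
##
## The model: d[P]/dt = ksyn - kdeg.[P], zero-order synthesis and first-order
## degradation. At homeostasis [P] = ksyn/kdeg. After the free amino-acid
## pool is deuterated at t = 0, pre-existing (unlabeled) protein decays as
## (ksyn/kdeg) e^(-kdeg t) and labeled protein accumulates as its complement,
## so the measurable labeled fraction follows 1 - e^(-kdeg t).

#' Steady-state protein abundance
#'
#' Under zero-order synthesis and first-order degradation the homeostatic
#' concentration is the ratio of the two rates, \code{ksyn / kdeg}.
#'
#' @param ksyn zero-order synthesis rate (concentration units per day), > 0.
#' @param kdeg first-order degradation rate constant (per day), > 0.
#' @return steady-state concentration (same units as \code{ksyn / kdeg}).
#' @examples
#' steadyStateAbundance(10, 2) # 5
#' @export
steadyStateAbundance <- function(ksyn, kdeg) {
    if (any(!is.finite(ksyn)) || any(!is.finite(kdeg)) ||
        any(ksyn <= 0) || any(kdeg <= 0)) {
        stop("invalid parameters: ksyn and kdeg must be finite and > 0")
    }
    ksyn / kdeg
}

#' Closed-form labeling kinetics
#'
#' Concentrations of unlabeled and labeled protein, and the measurable
#' labeled ("fraction new") fraction, at times \code{t} after the start of
#' labeling. The unlabeled pool decays exponentially, the labeled pool
#' accumulates, and their sum equals the steady-state abundance at every
#' time point.
#'
#' @inheritParams steadyStateAbundance
#' @param t labeling time(s) in days, >= 0.
#' @return data.frame with columns \code{time_days}, \code{unlabeled},
#'   \code{labeled}, \code{fraction_new}.
#' @examples
#' labelingCurves(10, log(2), t = c(0, 1, 2))$fraction_new # 0, 0.5, 0.75
#' @export
labelingCurves <- function(ksyn, kdeg, t) {
    ss <- steadyStateAbundance(ksyn, kdeg)
    if (any(!is.finite(t)) || any(t < 0)) {
        stop("labeling times must be finite and non-negative")
    }
    decay <- exp(-kdeg * t)
    data.frame(
        time_days = t,
        unlabeled = ss * decay,
        labeled = ss * (1 - decay),
        fraction_new = 1 - decay
    )
}

#' Turnover rate as the mean of per-molar synthesis and degradation
#'
#' Defined as \code{(ksyn/P + kdeg) / 2}. At homeostasis
#' (\code{P = ksyn/kdeg}) the per-molar synthesis rate equals \code{kdeg}
#' and the turnover rate reduces to \code{kdeg} itself; away from
#' homeostasis the mean keeps both processes in view.
#'
#' @inheritParams steadyStateAbundance
#' @param P protein concentration, > 0.
#' @param ksyn synthesis rate, >= 0.
#' @return turnover rate in per day.
#' @examples
#' turnoverRate(10, P = 5, kdeg = 2) # homeostasis: returns kdeg
#' @export
turnoverRate <- function(ksyn, P, kdeg) {
    if (any(P <= 0) || any(kdeg <= 0) || any(ksyn < 0)) {
        stop("require P > 0, kdeg > 0, ksyn >= 0")
    }
    (ksyn / P + kdeg) / 2
}

.rejectedFit <- function(reason) {
    list(k = NA_real_, rsq = NA_real_, deviation = NA_real_,
         accepted = FALSE, reason = reason)
}

## SSE of the labeling curve at rate k against points (t, y)
.labelSSE <- function(k, t, y) sum((1 - exp(-k * t) - y)^2)

## Newton polish of the SSE minimizer on the gradient; keeps within bounds.
.polishRate <- function(k, t, y, lower, upper) {
    for (i in seq_len(12L)) {
        e <- exp(-k * t)
        r <- (1 - e) - y
        g <- 2 * sum(r * t * e)
        h <- 2 * sum((t * e)^2 - r * t^2 * e)
        if (!is.finite(g) || !is.finite(h) || h <= 0) break
        step <- g / h
        k_new <- min(max(k - step, lower), upper)
        if (abs(k_new - k) < 1e-14 * max(k, 1)) {
            k <- k_new
            break
        }
        k <- k_new
    }
    k
}

#' Fit a turnover rate to one peptide labeling time course
#'
#' Nonlinear least squares of \code{fraction_new = 1 - exp(-k t)} with the
#' asymptote fixed at 1, by bounded one-dimensional minimization of the sum
#' of squared residuals (golden-section/parabolic search followed by a
#' Newton polish on the gradient). Replicate measurements at the same time
#' point all enter the objective unweighted.
#'
#' Quality control: the fit is rejected (\code{accepted = FALSE} with a
#' \code{reason}) when fewer than \code{min_timepoints} distinct non-zero
#' labeling times carry a measurement (\code{"min-timepoints"}), when the
#' root-mean-square residual reaches \code{max_deviation}
#' (\code{"deviation"}), or when the optimizer is pinned at a bound of the
#' search interval, as happens for all-zero labeling signals
#' (\code{"non-converged"}).
#'
#' @param time_days numeric, labeling times in days (6 h = 0.25).
#' @param fraction_new numeric, measured labeled fraction; noisy values
#'   slightly outside [0, 1] are admitted.
#' @param min_timepoints minimum distinct non-zero time points (default 3).
#' @param max_deviation rejection threshold on the RMS residual
#'   (default 0.1, on the fraction scale).
#' @param k_bounds search interval for k in per day.
#' @return list with \code{k}, \code{rsq} (coefficient of determination over
#'   all points), \code{deviation} (RMS residual), \code{accepted},
#'   \code{reason} (NA when accepted).
#' @examples
#' t <- c(0, 0.25, 1, 4, 16, 32)
#' fitPeptideRate(t, 1 - exp(-0.2 * t))$k
#' @export
fitPeptideRate <- function(time_days, fraction_new, min_timepoints = 3L,
                           max_deviation = 0.1, k_bounds = c(1e-6, 50)) {
    if (length(time_days) != length(fraction_new)) {
        stop("time_days and fraction_new must have equal length")
    }
    if (any(time_days < 0, na.rm = TRUE)) stop("negative labeling time")
    ok <- is.finite(time_days) & is.finite(fraction_new)
    t <- time_days[ok]
    y <- fraction_new[ok]
    if (length(unique(t[t > 0])) < min_timepoints) {
        return(.rejectedFit("min-timepoints"))
    }
    opt <- stats::optimize(.labelSSE, interval = k_bounds, t = t, y = y,
                           tol = 1e-10)
    k <- .polishRate(opt$minimum, t, y, k_bounds[1], k_bounds[2])
    if (.labelSSE(opt$minimum, t, y) < .labelSSE(k, t, y)) k <- opt$minimum
    if (k <= k_bounds[1] * (1 + 1e-6) || k >= k_bounds[2] * (1 - 1e-6)) {
        return(.rejectedFit("non-converged"))
    }
    res <- (1 - exp(-k * t)) - y
    sstot <- sum((y - mean(y))^2)
    rsq <- if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_
    deviation <- sqrt(mean(res^2))
    if (deviation >= max_deviation) {
        return(list(k = k, rsq = rsq, deviation = deviation,
                    accepted = FALSE, reason = "deviation"))
    }
    list(k = k, rsq = rsq, deviation = deviation,
         accepted = TRUE, reason = NA_character_)
}

#' Combine accepted peptide fits into one protein-level rate
#'
#' The protein rate is the median of the accepted peptide rates (robust to a
#' single aberrant peptide); the quality metrics are recomputed by pooling
#' all accepted peptide points and evaluating the fixed-asymptote curve at
#' the combined rate: \code{rsq} is the coefficient of determination of that
#' pooled evaluation and \code{deviation} its RMS residual.
#'
#' @param peptide_ks numeric vector of accepted per-peptide rates.
#' @param time_days,fraction_new pooled points of the accepted peptides.
#' @param peptide_ids identifiers of the accepted peptides (distinct values
#'   are counted as unique peptides).
#' @param protein_id protein identifier carried into the result.
#' @return one-row data.frame: \code{protein_id}, \code{rate_per_day},
#'   \code{rsq}, \code{n_unique_peptides}, \code{asymptote} (1),
#'   \code{deviation}.
#' @export
.combineCore <- function(peptide_ks, time_days, fraction_new, peptide_ids) {
    k <- stats::median(peptide_ks)
    res <- (1 - exp(-k * time_days)) - fraction_new
    sstot <- sum((fraction_new - mean(fraction_new))^2)
    list(k = k,
         rsq = if (sstot > 0) 1 - sum(res^2) / sstot else NA_real_,
         n_unique_peptides = length(unique(peptide_ids)),
         deviation = sqrt(mean(res^2)))
}

combineProteinRate <- function(peptide_ks, time_days, fraction_new,
                               peptide_ids, protein_id = NA_character_) {
    if (length(peptide_ks) == 0L) stop("no accepted peptide fits to combine")
    cc <- .combineCore(peptide_ks, time_days, fraction_new, peptide_ids)
    data.frame(
        protein_id = protein_id,
        rate_per_day = cc$k,
        rsq = cc$rsq,
        n_unique_peptides = cc$n_unique_peptides,
        asymptote = 1,
        deviation = cc$deviation,
        stringsAsFactors = FALSE
    )
}

#' Fit protein turnover rates from peptide labeling time courses
#'
#' Runs [fitPeptideRate()] on every peptide of every protein, keeps the
#' accepted peptide fits, and combines them per protein with
#' [combineProteinRate()]. Proteins with no accepted peptide fit are
#' dropped and reported in the \code{"peptide_rejections"} and
#' \code{"n_proteins_dropped"} attributes of the result.
#'
#' @param timecourses data.frame with columns \code{protein_id},
#'   \code{peptide_id}, \code{time_days}, \code{fraction_new} and
#'   optionally \code{n_value}.
#' @param min_n_value optional lower bound on the peptide deuterium-site
#'   count (\code{n_value}); peptides at or below it are excluded before
#'   fitting. Off (\code{NULL}) by default.
#' @inheritParams fitPeptideRate
#' @return data.frame with one row per protein that has at least one
#'   accepted peptide fit, in the columns of [combineProteinRate()].
#' @seealso [filterRateFits()] for the protein-level quality filter.
#' @export
fitProteinRates <- function(timecourses, min_timepoints = 3L,
                            max_deviation = 0.1, k_bounds = c(1e-6, 50),
                            min_n_value = NULL) {
    need <- c("protein_id", "peptide_id", "time_days", "fraction_new")
    miss <- setdiff(need, names(timecourses))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    if (!is.null(min_n_value)) {
        if (!"n_value" %in% names(timecourses)) {
            stop("min_n_value given but no n_value column present")
        }
        timecourses <- timecourses[timecourses$n_value > min_n_value, ,
                                   drop = FALSE]
    }
    key <- paste(timecourses$protein_id, timecourses$peptide_id, sep = "\r")
    idx <- split(seq_len(nrow(timecourses)), key)
    rej <- c("min-timepoints" = 0L, "deviation" = 0L, "non-converged" = 0L)
    n_g <- length(idx)
    pep_protein <- character(n_g)
    pep_k <- numeric(n_g)
    pep_ok <- logical(n_g)
    tt <- timecourses$time_days
    yy <- timecourses$fraction_new
    for (i in seq_len(n_g)) {
        rows <- idx[[i]]
        fit <- fitPeptideRate(tt[rows], yy[rows],
                              min_timepoints = min_timepoints,
                              max_deviation = max_deviation,
                              k_bounds = k_bounds)
        if (fit$accepted) {
            pep_protein[i] <- timecourses$protein_id[rows[1]]
            pep_k[i] <- fit$k
            pep_ok[i] <- TRUE
        } else {
            rej[fit$reason] <- rej[fit$reason] + 1L
        }
    }
    all_proteins <- unique(timecourses$protein_id)
    acc <- which(pep_ok)
    by_protein <- split(acc, pep_protein[acc])
    n_p <- length(by_protein)
    out_k <- out_rsq <- out_dev <- numeric(n_p)
    out_npep <- integer(n_p)
    pid <- timecourses$peptide_id
    for (p in seq_len(n_p)) {
        g <- by_protein[[p]]
        rows <- unlist(idx[g], use.names = FALSE)
        cc <- .combineCore(pep_k[g], tt[rows], yy[rows], pid[rows])
        out_k[p] <- cc$k
        out_rsq[p] <- cc$rsq
        out_dev[p] <- cc$deviation
        out_npep[p] <- cc$n_unique_peptides
    }
    out <- data.frame(
        protein_id = names(by_protein),
        rate_per_day = out_k,
        rsq = out_rsq,
        n_unique_peptides = out_npep,
        asymptote = rep(1, n_p),
        deviation = out_dev,
        row.names = NULL, stringsAsFactors = FALSE
    )
    attr(out, "peptide_rejections") <- rej
    attr(out, "n_proteins_dropped") <-
        length(setdiff(all_proteins, out$protein_id))
    out
}

#' Quality filter for protein-level rate fits
#'
#' Keeps exactly the fits with \code{rsq >= 0.6}, more than one unique
#' peptide, and a strictly positive combined rate. Rejections are counted by
#' the first criterion failed, in that order.
#'
#' @param fits data.frame as produced by [fitProteinRates()] (columns
#'   \code{rsq}, \code{n_unique_peptides}, \code{rate_per_day}).
#' @param min_rsq minimum coefficient of determination (default 0.6).
#' @param min_unique_peptides unique-peptide count must exceed this
#'   (default 1).
#' @return list with \code{accepted} (data.frame), \code{rejected}
#'   (data.frame with a \code{rejection_reason} column) and \code{counts}
#'   (named integer vector over \code{rsq}, \code{unique-peptides},
#'   \code{rate-positivity}).
#' @export
filterRateFits <- function(fits, min_rsq = 0.6, min_unique_peptides = 1L) {
    reason <- rep(NA_character_, nrow(fits))
    bad_rsq <- is.na(fits$rsq) | fits$rsq < min_rsq
    reason[bad_rsq] <- "rsq"
    bad_pep <- is.na(reason) & fits$n_unique_peptides <= min_unique_peptides
    reason[bad_pep] <- "unique-peptides"
    bad_rate <- is.na(reason) &
        (is.na(fits$rate_per_day) | fits$rate_per_day <= 0)
    reason[bad_rate] <- "rate-positivity"
    counts <- c("rsq" = sum(reason == "rsq", na.rm = TRUE),
                "unique-peptides" = sum(reason == "unique-peptides",
                                        na.rm = TRUE),
                "rate-positivity" = sum(reason == "rate-positivity",
                                        na.rm = TRUE))
    rejected <- fits[!is.na(reason), , drop = FALSE]
    if (nrow(rejected)) rejected$rejection_reason <- reason[!is.na(reason)]
    list(accepted = fits[is.na(reason), , drop = FALSE],
         rejected = rejected,
         counts = counts)
}

#' Turnover-rate fold changes between two cohorts
#'
#' For every protein with accepted rates in both cohorts, averages the rate
#' within each cohort (a protein measured in several datasets contributes
#' one mean per cohort) and takes the difference of the log2 rates.
#' Proteins present in only one cohort are excluded and counted in the
#' \code{"n_excluded"} attribute.
#'
#' @param rates_exp,rates_ctrl data.frames of accepted fits (columns
#'   \code{protein_id}, \code{rate_per_day}); several rows per protein are
#'   allowed and averaged.
#' @return data.frame with \code{protein_id}, \code{log2_rate_fc},
#'   \code{n_datasets_exp}, \code{n_datasets_ctrl}, ordered by protein.
#'   Apply [autoScale()] to \code{log2_rate_fc} across the cohort to obtain
#'   \code{scaled_fc}.
#' @export
computeTurnoverFC <- function(rates_exp, rates_ctrl) {
    if (any(rates_exp$rate_per_day <= 0, na.rm = TRUE) ||
        any(rates_ctrl$rate_per_day <= 0, na.rm = TRUE)) {
        stop("non-positive rate reached fold-change computation")
    }
    agg <- function(d) {
        s <- split(d$rate_per_day, d$protein_id)
        data.frame(protein_id = names(s),
                   k = vapply(s, mean, numeric(1)),
                   n = lengths(s), stringsAsFactors = FALSE)
    }
    e <- agg(rates_exp)
    c0 <- agg(rates_ctrl)
    shared <- intersect(e$protein_id, c0$protein_id)
    shared <- sort(shared)
    ei <- match(shared, e$protein_id)
    ci <- match(shared, c0$protein_id)
    out <- data.frame(
        protein_id = shared,
        log2_rate_fc = log2(e$k[ei]) - log2(c0$k[ci]),
        n_datasets_exp = e$n[ei],
        n_datasets_ctrl = c0$n[ci],
        stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    attr(out, "n_excluded") <- c(
        exp_only = length(setdiff(e$protein_id, shared)),
        ctrl_only = length(setdiff(c0$protein_id, shared)))
    out
}

#' Auto scaling (unit-variance standardization)
#'
#' \code{(x - mean(x)) / sd(x)} with the sample (n - 1) standard deviation.
#' Applied to a cohort of turnover fold changes before ontology
#' aggregation; the scaled vector has mean 0 and sample standard
#' deviation 1.
#'
#' @param values numeric vector, length >= 2, non-constant.
#' @return scaled numeric vector.
#' @examples
#' autoScale(c(1, 2, 3)) # -1 0 1
#' @export
autoScale <- function(values) {
    if (length(values) < 2L) stop("auto scaling requires at least 2 values")
    s <- stats::sd(values)
    if (!is.finite(s) || s == 0) {
        stop("degenerate input: zero variance, auto scaling undefined")
    }
    (values - mean(values)) / s
}
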