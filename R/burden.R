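## Per-cell mutation burden, exposure covariates, robust dose-response fits,
## the Jonckheere-Terpstra ordered trend test and ageing-equivalent summaries.

#' Estimate mutation burden per Mb per cell
#'
#' At duplex depths every mutation is observed in a small fraction of the
#' sequenced cells; summing twice the variant allele frequencies over all
#' mutations and dividing by the effectively sequenced megabases estimates the
#' mutations carried per megabase per cell:
#' beta = 2 * sum_j VAF_j / L_Mb.
#'
#' @param variants Filtered somatic variant table for one sample.
#' @param panel A \linkS4class{Panel} (supplies L_Mb), or a numeric L_Mb.
#' @param exposureRow Optional named exposure-fraction vector for the sample;
#'   when given, per-signature burden components (beta * exposure) are
#'   attached.
#' @param genomeMb Haploid genome size in Mb used for the per-genome scaling
#'   (default 3000; the factor 2 for diploidy is already inside beta).
#' @return list(sample_id, beta_per_mb, beta_genome, n_variants, l_mb,
#'   per_signature).
#' @export
estimateBurden <- function(variants, panel, exposureRow = NULL,
                           genomeMb = 3000) {
  v <- asVariantTable(variants)
  l_mb <- if (is.numeric(panel)) panel else effectiveLengthMb(panel)
  if (l_mb <= 0) stop("effective panel length must be positive")
  beta <- 2 * sum(v$vaf) / l_mb
  per_sig <- NULL
  if (!is.null(exposureRow)) {
    per_sig <- beta * exposureRow
  }
  list(sample_id = if (nrow(v)) v$sample_id[1] else NA_character_,
       beta_per_mb = beta,
       beta_genome = beta * genomeMb,
       n_variants = nrow(v),
       l_mb = l_mb,
       per_signature = per_sig)
}

#' Pack years of smoking
#' @param packs_per_day Packs (20 cigarettes) smoked per day.
#' @param years Years smoked.
#' @return packs_per_day * years.
#' @export
packYears <- function(packs_per_day, years) {
  if (any(packs_per_day < 0) || any(years < 0)) stop("inputs must be >= 0")
  packs_per_day * years
}

#' Drink years of alcohol consumption
#'
#' One drink year is 14 units of alcohol a week for one year. When \code{years}
#' is not supplied it defaults to \code{age - 18}, under the assumption of
#' approximately constant drinking from age 18.
#'
#' @param units_per_week Self-reported weekly alcohol units.
#' @param years Years of drinking; default \code{age - 18}.
#' @param age Age in years (used only for the default).
#' @return (units_per_week / 14) * years.
#' @export
drinkYears <- function(units_per_week, years = NULL, age = NULL) {
  if (is.null(years)) {
    if (is.null(age)) stop("supply years or age")
    years <- pmax(age - 18, 0)
  }
  if (any(units_per_week < 0) || any(years < 0)) stop("inputs must be >= 0")
  (units_per_week / 14) * years
}

#' Robust dose-response fit
#'
#' Huber M-estimated linear fit (tuning constant 1.345, 95% Gaussian
#' efficiency) of per-patient burden against an exposure covariate, with a 95%
#' confidence interval from the asymptotic covariance. When a patient
#' contributes several samples their median burden is used, with the min/max
#' retained for reporting.
#'
#' @param burden Per-sample burden values (mutations per cell, or per Mb).
#' @param exposure Per-sample exposure covariate (years, pack years, cycles,
#'   drink years).
#' @param patient Per-sample patient identifiers.
#' @param tissue Label recorded in the result.
#' @param process Label recorded in the result.
#' @param ci_method "bootstrap" (default; percentile interval from seeded
#'   case resampling of patients, honest under the heteroscedastic burden
#'   noise typical of exposure refitting) or "asymptotic" (M-estimation
#'   covariance).
#' @param boot_reps,boot_seed Bootstrap replicates and seed; the global RNG
#'   state is restored afterwards.
#' @return list(tissue, process, slope, intercept, ci95, se, n_patients,
#'   estimator, points) where points holds the per-patient medians/min/max.
#' @export
robustDoseResponse <- function(burden, exposure, patient,
                               tissue = NA_character_,
                               process = NA_character_,
                               ci_method = c("bootstrap", "asymptotic"),
                               boot_reps = 400, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(burden) == length(exposure),
            length(burden) == length(patient))
  df <- data.frame(burden = burden, exposure = exposure, patient = patient)
  agg <- do.call(rbind, lapply(split(df, df$patient), function(d) {
    data.frame(patient = d$patient[1],
               exposure = stats::median(d$exposure),
               burden = stats::median(d$burden),
               burden_min = min(d$burden), burden_max = max(d$burden))
  }))
  if (nrow(agg) < 4) stop("need >= 4 patients with exposure values")
  if (stats::var(agg$exposure) == 0) stop("zero exposure variance")
  rfit <- function(d) {
    MASS::rlm(burden ~ exposure, data = d, psi = MASS::psi.huber,
              k = 1.345, maxit = 100)
  }
  fit <- rfit(agg)
  co <- summary(fit)$coefficients
  slope <- co["exposure", "Value"]
  se <- co["exposure", "Std. Error"]
  if (ci_method == "asymptotic") {
    ci <- slope + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    set.seed(boot_seed)
    boots <- rep(NA_real_, boot_reps)
    n_pat <- nrow(agg)
    for (b in seq_len(boot_reps)) {
      ix <- sample.int(n_pat, replace = TRUE)
      xb <- agg$exposure[ix]
      if (stats::var(xb) == 0) next
      boots[b] <- tryCatch(
        stats::coef(suppressWarnings(
          MASS::rlm(cbind(1, xb), agg$burden[ix], psi = MASS::psi.huber,
                    k = 1.345, maxit = 100)))[2],
        error = function(e) NA_real_)
    }
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    # expanded percentile interval (Hesterberg): plain percentile intervals
    # undercover at a few dozen patients; widen the quantile levels by the
    # t-versus-normal ratio at n - 1 degrees of freedom
    alpha_adj <- stats::pnorm(-stats::qt(0.975, n_pat - 1) *
                                sqrt(n_pat / (n_pat - 1)))
    ci <- unname(stats::quantile(boots, c(alpha_adj, 1 - alpha_adj),
                                 na.rm = TRUE))
    se <- stats::sd(boots, na.rm = TRUE)
  }
  list(tissue = tissue, process = process, slope = slope,
       intercept = co["(Intercept)", "Value"], ci95 = ci, se = se,
       n_patients = nrow(agg),
       estimator = paste0("huber_m_1.345_", ci_method), points = agg)
}

## JT statistic: sum over ordered group pairs of Mann-Whitney counts,
## ties counting one half.
.jt_statistic <- function(groups) {
  k <- length(groups)
  stat <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      for (x in groups[[i]]) {
        stat <- stat + sum(groups[[j]] > x) + 0.5 * sum(groups[[j]] == x)
      }
    }
  }
  stat
}

#' Jonckheere-Terpstra trend test
#'
#' Tests for a monotone increasing trend across groups ordered by exposure
#' category. The statistic is the sum of pairwise Mann-Whitney counts over
#' ordered group pairs (ties count one half). The one-sided p-value is exact
#' (full enumeration of group-label permutations) when the total sample size
#' is at most \code{exact_max}, otherwise a normal approximation with
#' tie-corrected variance is used; \code{n_perm} draws a seeded Monte-Carlo
#' permutation p-value instead.
#'
#' @param groups list of numeric vectors, ordered by increasing exposure.
#' @param exact_max Maximum total n for exhaustive enumeration (default 10).
#' @param n_perm Number of Monte-Carlo permutations (0 disables).
#' @param seed Seed for the permutation option.
#' @return list(statistic, p_value, method).
#' @export
jonckheereTerpstra <- function(groups, exact_max = 10, n_perm = 0,
                               seed = NULL) {
  if (length(groups) < 2) stop("need at least two ordered groups")
  if (any(!vapply(groups, length, 1L))) stop("every group needs >= 1 value")
  stat <- .jt_statistic(groups)
  sizes <- vapply(groups, length, 1L)
  n <- sum(sizes)
  values <- unlist(groups)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    labels <- rep(seq_along(groups), sizes)
    ge <- 0L
    for (b in seq_len(n_perm)) {
      perm <- sample(values)
      g <- split(perm, labels)
      if (.jt_statistic(g) >= stat - 1e-12) ge <- ge + 1L
    }
    return(list(statistic = stat, p_value = (ge + 1) / (n_perm + 1),
                method = "permutation"))
  }
  if (n <= exact_max) {
    # exhaustive enumeration over all distinct assignments of the pooled
    # values to the ordered groups
    perms <- .multiset_assignments(values, sizes)
    stats_all <- vapply(perms, .jt_statistic, numeric(1))
    p <- mean(stats_all >= stat - 1e-12)
    return(list(statistic = stat, p_value = p, method = "exact"))
  }
  # normal approximation with tie correction
  mu <- (n^2 - sum(sizes^2)) / 4
  tie_tab <- table(values)
  t1 <- sum(tie_tab * (tie_tab - 1) * (2 * tie_tab + 5))
  s1 <- sum(sizes * (sizes - 1) * (2 * sizes + 5))
  var_jt <- (n * (n - 1) * (2 * n + 5) - s1 - t1) / 72 +
    (sum(sizes * (sizes - 1) * (sizes - 2)) *
       sum(tie_tab * (tie_tab - 1) * (tie_tab - 2))) /
      (36 * n * (n - 1) * (n - 2)) +
    (sum(sizes * (sizes - 1)) * sum(tie_tab * (tie_tab - 1))) /
      (8 * n * (n - 1))
  z <- (stat - mu) / sqrt(var_jt)
  list(statistic = stat, p_value = stats::pnorm(z, lower.tail = FALSE),
       method = "normal")
}

## All assignments of `values` (by index) into ordered groups of the given
## sizes: one entry per way of choosing which observations land in which
## group (n! / prod(sizes!) assignments, each equally likely under the null).
.multiset_assignments <- function(values, sizes) {
  assign_rec <- function(idx, sizes) {
    if (length(sizes) == 1L) return(list(list(idx)))
    choices <- utils::combn(idx, sizes[1], simplify = FALSE)
    out <- list()
    for (ch in choices) {
      for (rest in assign_rec(setdiff(idx, ch), sizes[-1])) {
        out[[length(out) + 1L]] <- c(list(ch), rest)
      }
    }
    out
  }
  lapply(assign_rec(seq_along(values), sizes), function(grp_idx) {
    lapply(grp_idx, function(ix) values[ix])
  })
}

#' Ageing-equivalent years of a mutational process
#'
#' Divides the process slope times a reference exposure by the tissue's
#' clock-like (SBS5) slope, expressing the process's contribution as years of
#' ageing. Default reference exposures: 40 pack years (heavy smoker), 6
#' platinum cycles, 50 drink years.
#'
#' @param process_slope Mutations per cell per exposure unit.
#' @param exposure Exposure amount (defaults above apply to the caller).
#' @param sbs5_slope Clock-like mutations per cell per year for the tissue.
#' @return Equivalent ageing years.
#' @export
ageingEquivalents <- function(process_slope, exposure, sbs5_slope) {
  if (sbs5_slope <= 0) stop("sbs5 slope must be positive")
  (process_slope * exposure) / sbs5_slope
}

#' Treatment mutagenesis summaries without a fitted slope
#'
#' Fallback for treatments whose slope cannot be estimated: the
#' treatment-attributed mutation count divided by the treatment duration gives
#' a rate, and dividing the count by the tissue ageing rate gives the
#' equivalent ageing years of the (punctuated) burst.
#'
#' @param treatment_mutations Treatment-attributed mutations per cell.
#' @param duration_years Time between treatment start and end, in years.
#' @param sbs5_slope Clock-like mutations per cell per year.
#' @return list(rate_per_year, ageing_years).
#' @export
ageingEquivalentsFromDuration <- function(treatment_mutations, duration_years,
                                          sbs5_slope) {
  if (sbs5_slope <= 0) stop("sbs5 slope must be positive")
  if (duration_years <= 0) stop("duration must be positive")
  list(rate_per_year = treatment_mutations / duration_years,
       ageing_years = treatment_mutations / sbs5_slope)
}
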