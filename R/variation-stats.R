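# evaluate expr with a private RNG stream (restores .Random.seed on exit)
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Build distance-constrained between-individual pairs
#'
#' All unordered pairs of individuals whose breeding colonies are within
#' `constraint_km` of each other AND whose wintering centroids are within
#' `constraint_km` (both boundary inclusive). For each pair, one season per
#' individual is selected uniformly at random (pairs need not share years).
#'
#' @param individuals data frame with columns `individual_id`, `colony_lon`,
#'   `colony_lat`, `winter_lon`, `winter_lat`.
#' @param seasons_by_individual named list mapping individual id to its
#'   vector of season labels.
#' @param constraint_km the pairing constraint (default 250).
#' @param seed integer seed controlling the season selection.
#' @return a `pair_set` data frame: `id_a`, `id_b`, `season_a`, `season_b`,
#'   `colony_km`, `winter_km`, `mean_distance_km` is left to the caller.
#'   Empty (with a warning) when no pair satisfies the constraints.
#' @export
build_pairs <- function(individuals, seasons_by_individual,
                        constraint_km = 250, seed = 1) {
  n <- nrow(individuals)
  out <- NULL
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      ck <- great_circle_km(individuals$colony_lon[i], individuals$colony_lat[i],
                            individuals$colony_lon[j], individuals$colony_lat[j])
      wk <- great_circle_km(individuals$winter_lon[i], individuals$winter_lat[i],
                            individuals$winter_lon[j], individuals$winter_lat[j])
      if (ck <= constraint_km && wk <= constraint_km)
        out <- rbind(out, data.frame(
          id_a = individuals$individual_id[i],
          id_b = individuals$individual_id[j],
          colony_km = ck, winter_km = wk, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    warning("no valid pairs under the ", constraint_km, "-km constraint")
    out <- data.frame(id_a = character(), id_b = character(),
                      season_a = character(), season_b = character(),
                      colony_km = numeric(), winter_km = numeric(),
                      stringsAsFactors = FALSE)
    class(out) <- c("pair_set", "data.frame")
    return(out)
  }
  with_local_seed(seed, {
    out$season_a <- vapply(out$id_a, function(id) {
      ss <- seasons_by_individual[[id]]
      ss[sample.int(length(ss), 1L)]
    }, character(1))
    out$season_b <- vapply(out$id_b, function(id) {
      ss <- seasons_by_individual[[id]]
      ss[sample.int(length(ss), 1L)]
    }, character(1))
  })
  class(out) <- c("pair_set", "data.frame")
  out
}

#' Randomization test of within- vs between-individual variation
#'
#' The observed statistic is the difference of group medians,
#' `median(between) - median(within)`. Group labels are shuffled `n_perm`
#' times preserving group sizes, and the one-sided p-value is the add-one
#' permutation probability of a difference at least as large as observed:
#' `p = (1 + #{perm >= obs}) / (n_perm + 1)`.
#'
#' @param within,between numeric vectors of variation values (for overlap
#'   metrics, pass variation as e.g. `1 - BA` or use `alternative` to flip).
#' @param n_perm number of randomizations (default 10,000).
#' @param seed integer seed.
#' @return list with `p`, `observed`, `n_perm`.
#' @export
randomization_test <- function(within, between, n_perm = 10000, seed = 1) {
  stopifnot(length(within) > 0, length(between) > 0)
  obs <- stats::median(between) - stats::median(within)
  pool <- c(between, within)
  nb <- length(between)
  N <- length(pool)
  with_local_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(N, nb)
      stat <- stats::median(pool[idx]) - stats::median(pool[-idx])
      if (stat >= obs - 1e-12) exceed <- exceed + 1L
    }
    list(p = (1 + exceed) / (n_perm + 1), observed = obs, n_perm = n_perm)
  })
}

#' Variance components and repeatability of a trait
#'
#' REML linear mixed model of the trait with migration distance as a fixed
#' effect (optional) and colony and individual as random intercepts. Year is
#' deliberately not a random effect, so year-to-year plasticity contributes
#' to the within-individual (residual) variance. Repeatability is
#' `R = s_a^2 / (s_a^2 + s_eps^2)` with `s_a^2` the among-individual variance
#' and `s_eps^2` the residual variance.
#'
#' @param data data frame with columns `value`, `individual`, `colony`,
#'   `distance` (the individual's median migration distance, km).
#' @param include_distance keep the migration-distance fixed effect
#'   (default TRUE; set FALSE to aid convergence, as for winter arrival).
#' @return a `repeatability_result`: list with `s_a2`, `s_col2`, `s_eps2`,
#'   `R`, `fixef`, `singular`, `model`, `data`, `include_distance`.
#' @export
fit_variance_components <- function(data, include_distance = TRUE) {
  stopifnot(all(c("value", "individual", "colony") %in% names(data)))
  data$individual <- factor(data$individual)
  data$colony <- factor(data$colony)
  # the colony random intercept needs at least two colonies
  col_term <- if (nlevels(data$colony) > 1L) "(1 | colony) + " else ""
  fix_term <- if (include_distance && length(unique(data$distance)) > 1L)
    "distance + " else ""
  form <- stats::as.formula(paste0("value ~ ", fix_term, col_term,
                                   "(1 | individual)"))
  fit <- lme4::lmer(form, data = data, REML = TRUE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s_a2 <- vc$vcov[vc$grp == "individual"]
  s_col2 <- if (any(vc$grp == "colony")) vc$vcov[vc$grp == "colony"] else NA_real_
  s_eps2 <- vc$vcov[vc$grp == "Residual"]
  structure(list(s_a2 = s_a2, s_col2 = s_col2, s_eps2 = s_eps2,
                 R = s_a2 / (s_a2 + s_eps2),
                 fixef = lme4::fixef(fit),
                 singular = lme4::isSingular(fit),
                 model = fit, data = data,
                 include_distance = include_distance),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("repeatability R = %.3f (s_a2 = %.3f, s_eps2 = %.3f, colony var = %.3f)%s\n",
              x$R, x$s_a2, x$s_eps2, x$s_col2,
              if (x$singular) " [singular fit]" else ""))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.3f, %.3f] (%d bootstraps)\n",
                                  x$ci[1], x$ci[2], x$n_boot))
  invisible(x)
}

#' Parametric bootstrap confidence interval for repeatability
#'
#' Simulates responses from the fitted mixed model, refits, and takes the
#' 2.5/97.5 percentiles of the bootstrap repeatability distribution.
#' Deterministic given the seed; refit failures are skipped and counted.
#'
#' @param result a `repeatability_result`.
#' @param n_boot bootstrap iterations (default 1,000).
#' @param seed integer seed.
#' @return the input with `ci` (length-2), `boot_R`, `n_boot`,
#'   `n_boot_failed` added.
#' @export
bootstrap_ci <- function(result, n_boot = 1000, seed = 1) {
  sims <- with_local_seed(seed,
    stats::simulate(result$model, nsim = n_boot))
  boot_R <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    boot_R[b] <- tryCatch({
      m <- suppressWarnings(suppressMessages(lme4::refit(result$model, sims[[b]])))
      vc <- as.data.frame(lme4::VarCorr(m))
      a <- vc$vcov[vc$grp == "individual"]
      e <- vc$vcov[vc$grp == "Residual"]
      if (a + e <= 0) 1 else a / (a + e)
    }, error = function(e) NA_real_)
  }
  ok <- !is.na(boot_R)
  result$ci <- unname(stats::quantile(boot_R[ok], c(0.025, 0.975)))
  result$boot_R <- boot_R
  result$n_boot <- n_boot
  result$n_boot_failed <- sum(!ok)
  result
}

#' Individual-level repeatability
#'
#' Substitutes the residual variance of individual i,
#' `s_i^2 = sum(res_i^2) / (n_i - 1)` over its conditional residuals, for
#' the population residual variance: `R_i = s_a^2 / (s_a^2 + s_i^2)`.
#' Individuals with fewer than 2 observations are skipped. Wintering-area
#' switchers should be excluded from `data` before fitting.
#'
#' @param result a `repeatability_result`.
#' @return data frame with `individual`, `n`, `s_i2`, `R_i`.
#' @export
individual_repeatability <- function(result) {
  res <- stats::residuals(result$model)  # conditional residuals
  ind <- result$data$individual
  out <- NULL
  for (id in levels(ind)) {
    r <- res[ind == id]
    if (length(r) < 2L) next
    s_i2 <- sum(r^2) / (length(r) - 1L)
    out <- rbind(out, data.frame(
      individual = id, n = length(r), s_i2 = s_i2,
      R_i = result$s_a2 / (result$s_a2 + s_i2),
      stringsAsFactors = FALSE))
  }
  out
}

#' Linear model of a variation metric against migration distance
#'
#' Ordinary least squares of the values on the per-individual median
#' migration distance, compared against the intercept-only model both by the
#' F test (the form the results are reported in) and the likelihood ratio
#' test (equivalent for nested Gaussian linear models).
#'
#' @param values numeric response (switchers excluded by the caller).
#' @param distances per-individual median migration distance, km.
#' @return a `distance_model`: list with `intercept`, `slope`, `F`, `df1`,
#'   `df2`, `p`, `lrt_chisq`, `lrt_p`, `r_squared`, `n`, `model`.
#' @export
distance_model <- function(values, distances) {
  ok <- !is.na(values) & !is.na(distances)
  values <- values[ok]; distances <- distances[ok]
  if (length(values) < 3L) stop("need at least 3 observations")
  if (stats::var(distances) == 0) stop("zero variance in migration distance")
  fit <- stats::lm(values ~ distances)
  null <- stats::lm(values ~ 1)
  sm <- suppressWarnings(summary(fit))
  fs <- sm$fstatistic
  lrt <- as.numeric(2 * (stats::logLik(fit) - stats::logLik(null)))
  structure(list(
    intercept = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    F = unname(fs[1]), df1 = unname(fs[2]), df2 = unname(fs[3]),
    p = unname(stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
    lrt_chisq = lrt,
    lrt_p = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
    r_squared = sm$r.squared,
    n = length(values), model = fit), class = "distance_model")
}

#' @export
print.distance_model <- function(x, ...) {
  cat(sprintf("value = %.4g + %.4g * distance_km; F(%d,%d) = %.3f, p = %.4g (n = %d)\n",
              x$intercept, x$slope, x$df1, x$df2, x$F, x$p, x$n))
  invisible(x)
}

#' Distance-corrected intra-individual variation
#'
#' Short-distance migrants are spatially constrained, so the between-pair
#' relationship of variation with migration distance serves as a null model
#' for the variation expected at a given distance. The null prediction is
#' subtracted from each individual's observed intra-individual value, and a
#' second distance model on the corrected values tests whether
#' intra-individual variation changes with distance more or less than
#' expected.
#'
#' @param observed intra-individual variation values.
#' @param distances the individuals' median migration distances, km.
#' @param between_model a `distance_model` fitted to between-pair values
#'   against pair mean distance.
#' @return list with `corrected` (observed minus null prediction) and
#'   `model` (the `distance_model` on corrected values).
#' @export
residual_variation <- function(observed, distances, between_model) {
  predicted <- between_model$intercept + between_model$slope * distances
  corrected <- observed - predicted
  list(corrected = corrected,
       model = distance_model(corrected, distances))
}
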