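#' Build the finite-element model of a synthetic subject
#'
#' Meshes the subject's profile, labels compartments and sub-tendons, and
#' embeds the requested fascicle twist either through the full continuum
#' pipeline (cloud -> Euler-angle field fit -> Gauss evaluation, the
#' default) or directly from the analytic helix.
#'
#' @param subject A `synthetic_subject` from [draw_subject()].
#' @param twist_deg Twist angle; defaults to the subject's own.
#' @param n_axial,n_circ,n_radial Mesh resolution (defaults 8 x 4 x 4, the
#'   cohort-study scale).
#' @param scheme Sub-tendon labeling scheme, or `"none"` to skip labeling
#'   (e.g. for calibration meshes loaded uniformly).
#' @param fractions Optional sub-tendon area fractions (see
#'   [label_subtendons()]).
#' @param fiber `"fitted"` or `"analytic"`.
#' @param csa_scale Optional free-form mid-section CSA scale factor.
#' @return List with `mesh`, `fiber_field`, `params`, `twist_deg`.
#' @export
subject_model <- function(subject, twist_deg = subject$twist_deg,
                          n_axial = 8, n_circ = 4, n_radial = 4,
                          scheme = "three_way", fractions = NULL,
                          fiber = c("fitted", "analytic"),
                          csa_scale = 1) {
  fiber <- match.arg(fiber)
  mesh <- build_tendon_mesh(subject$profile, n_axial, n_circ, n_radial)
  if (!identical(scheme, "none"))
    mesh <- label_compartments(label_subtendons(mesh, scheme, fractions))
  if (csa_scale != 1) mesh <- ffd_scale_csa(mesh, csa_scale)
  ff <- suppressWarnings(
    if (twist_deg == 0) straight_fiber_field(mesh)
    else if (fiber == "fitted") embed_twist_field(mesh, twist_deg)
    else analytic_twist_field(mesh, twist_deg))
  list(mesh = mesh, fiber_field = ff, params = subject$params,
       twist_deg = twist_deg)
}

#' One-at-a-time sensitivity of the rupture load
#'
#' Perturbs each of the three factors -- mid-section cross-sectional area
#' (via free-form mesh morphing), straightened-collagen stiffness `c5`, and
#' fascicle twist angle -- by plus and minus one population standard
#' deviation around each subject's baseline, reruns the rupture experiment,
#' and reports the percent change in rupture load. Factors are ranked by
#' mean absolute percent change across subjects.
#'
#' @param subjects List of `synthetic_subject` objects.
#' @param population The [population_model()] supplying the sigma of each
#'   factor.
#' @param n_axial,n_circ,n_radial Mesh resolution for the runs.
#' @param fractions Sub-tendon area fractions for the labeling (see
#'   [label_subtendons()]).
#' @param fiber Fiber embedding method (see [subject_model()]).
#' @param split,increment,threshold,run_length,max_load Rupture settings
#'   (see [run_rupture()]).
#' @param control Solver control overrides.
#' @return A `sensitivity_result`: per-run table `(subject, factor,
#'   direction, rupture_load, percent_change)`, the baseline loads, and the
#'   factor ranking by mean |% change|. Failed runs are recorded as `NA`
#'   with a warning and their subject is excluded from the ranking.
#' @export
run_sensitivity <- function(subjects, population,
                            n_axial = 8, n_circ = 4, n_radial = 4,
                            fractions = NULL,
                            fiber = "fitted", split = load_split(),
                            increment = 100, threshold = 100,
                            run_length = 15, max_load = 10000,
                            control = list()) {
  rupt <- function(subject, twist, csa_scale, params) {
    mod <- subject_model(subject, twist_deg = twist, n_axial = n_axial,
                         n_circ = n_circ, n_radial = n_radial,
                         fractions = fractions, fiber = fiber,
                         csa_scale = csa_scale)
    rr <- run_rupture(mod$mesh, mod$fiber_field, params, split = split,
                      increment = increment, threshold = threshold,
                      run_length = run_length, max_load = max_load,
                      control = control)
    rr$rupture_load
  }
  perturb <- expand.grid(factor = c("csa", "c5", "twist"),
                         direction = c(-1, 1), stringsAsFactors = FALSE)
  rows <- list()
  baselines <- numeric(length(subjects))
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    base <- tryCatch(rupt(sub, sub$twist_deg, 1, sub$params),
                     error = function(e) {
                       warning("subject ", si, " baseline failed: ",
                               conditionMessage(e)); NA_real_
                     })
    baselines[si] <- base
    for (k in seq_len(nrow(perturb))) {
      fac <- perturb$factor[k]; dir <- perturb$direction[k]
      twist <- sub$twist_deg; csa_scale <- 1; params <- sub$params
      if (fac == "twist") {
        twist <- max(0, min(90, twist + dir * population$twist_sd))
      } else if (fac == "csa") {
        csa_scale <- (sub$csa + dir * population$csa_sd) / sub$csa
      } else {
        params <- material_params(
          c1 = params$c1, c3 = params$c3, c4 = params$c4,
          c5 = max(1e-6, params$c5 + dir * population$c5_sd),
          lambda_star = params$lambda_star, kappa = params$kappa)
      }
      rl <- if (is.na(base)) NA_real_ else
        tryCatch(rupt(sub, twist, csa_scale, params),
                 error = function(e) {
                   warning("subject ", si, " ", fac, dir, " failed: ",
                           conditionMessage(e)); NA_real_
                 })
      rows[[length(rows) + 1]] <- data.frame(
        subject = si, factor = fac, direction = dir, rupture_load = rl,
        percent_change = if (is.na(base) || is.na(rl)) NA_real_
                         else (rl - base) / base * 100)
    }
  }
  tab <- do.call(rbind, rows)
  ok_subj <- tapply(!is.na(tab$percent_change), tab$subject, all)
  keep <- tab$subject %in% as.integer(names(ok_subj)[ok_subj])
  if (!all(keep))
    warning("excluding ", sum(!ok_subj), " subject(s) with failed runs ",
            "from the factor ranking")
  ranking <- sort(tapply(abs(tab$percent_change[keep]), tab$factor[keep],
                         mean), decreasing = TRUE)
  structure(list(table = tab, baselines = baselines,
                 ranking = ranking, sigma = c(
                   csa = population$csa_sd, c5 = population$c5_sd,
                   twist = population$twist_sd)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("sensitivity_result: mean |% rupture-load change| per factor\n")
  for (n in names(x$ranking))
    cat(sprintf("  %-6s %.1f%%\n", n, x$ranking[n]))
  invisible(x)
}

#' Classical one-way analysis of variance
#'
#' Between/within mean-square F ratio with its F-distribution p-value
#' (equal-variance one-way ANOVA, via [stats::oneway.test()]). The
#' degenerate case of identical constant groups is reported as `F = 0`,
#' `p = 1` with `degenerate = TRUE`.
#'
#' @param groups List of numeric vectors (>= 2 groups, each with >= 2
#'   observations).
#' @return List with `F`, `p`, `df` (between, within), the sums of squares
#'   `ss` and mean squares `ms`, and `degenerate`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least 2 observations")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  df <- c(between = length(groups) - 1L,
          within = length(y) - length(groups))
  gm <- tapply(y, g, mean)
  ss <- c(between = sum(tabulate(g) * (gm - mean(y))^2),
          within = sum((y - gm[g])^2))
  ms <- ss / df
  if (stats::var(y) == 0)
    return(list(F = 0, p = 1, df = df, ss = ss, ms = ms,
                degenerate = TRUE))
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value), df = df,
       ss = ss, ms = ms, degenerate = FALSE)
}

#' Write a classical ANOVA table as CSV
#'
#' @param result An [anova_oneway()] result.
#' @param path CSV path (columns: source, SS, df, MS, F, p).
#' @export
write_anova_csv <- function(result, path) {
  df <- data.frame(
    source = c("between", "within"),
    SS = unname(result$ss), df = unname(result$df),
    MS = unname(result$ms),
    F = c(result$F, NA), p = c(result$p, NA))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
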