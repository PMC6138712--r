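#' Configuration of the full in-silico study
#'
#' Bundles every setting of the end-to-end pipeline. The protocol defaults
#' are the study's reference values: five twist angles (0/15/30/45/60
#' degrees), the 6:2:1 soleus:MG:LG load split, 100 N load increments, a
#' 100 MPa von Mises rupture threshold over 15 consecutive axial Gauss
#' points.
#'
#' @param n_subjects Number of synthetic subjects (default 10).
#' @param twist_angles Twist angles in degrees.
#' @param seed Base RNG seed; all subject draws, noise and optimizer starts
#'   derive from it.
#' @param population A [population_model()].
#' @param noise_sd Marker noise, mm.
#' @param protocol Stretch-experiment protocol (peak stress or force, and
#'   number of levels; see [simulate_experiment()]).
#' @param calib Calibration-stage settings: mesh resolution and optimizer
#'   effort.
#' @param rupture Rupture-stage settings: mesh resolution and criterion.
#' @param split Load split (see [load_split()]).
#' @param area_fractions Sub-tendon cross-section area fractions used for
#'   the rupture-stage labeling. The default follows cadaveric morphometry
#'   (soleus about half the section, MG about a third, LG the rest), which
#'   deliberately differs from the 6:2:1 force split: the force-to-area
#'   mismatch is what makes the triceps-surae loading differential.
#' @param ref_load Load (N) at which the compartment stress contrast is
#'   tabulated.
#' @param fiber Fiber embedding method (`"fitted"` or `"analytic"`).
#' @param outdir Optional output directory for CSV results.
#' @return A `study_config` list.
#' @export
study_config <- function(n_subjects = 10,
                         twist_angles = c(0, 15, 30, 45, 60),
                         seed = 1,
                         population = population_model(),
                         noise_sd = 0.1,
                         protocol = list(peak_stress = 80, n_levels = 10),
                         calib = list(n_axial = 4, n_circ = 2, n_radial = 2,
                                      n_starts = 2, maxit = 60),
                         rupture = list(n_axial = 8, n_circ = 4,
                                        n_radial = 4, increment = 100,
                                        threshold = 100, run_length = 15,
                                        max_load = 10000),
                         split = load_split(),
                         area_fractions = c(SOL = 0.52, MG = 0.35,
                                            LG = 0.13),
                         ref_load = 1000,
                         fiber = "fitted", outdir = NULL) {
  cfg <- list(n_subjects = n_subjects, twist_angles = twist_angles,
              seed = seed, population = population, noise_sd = noise_sd,
              protocol = protocol, calib = calib, rupture = rupture,
              split = split, area_fractions = area_fractions,
              ref_load = ref_load, fiber = fiber,
              outdir = outdir)
  class(cfg) <- "study_config"
  cfg
}

# Deterministic short hash of a config (for provenance headers).
config_hash <- function(cfg) {
  s <- paste(deparse(cfg[setdiff(names(cfg), "outdir")]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full synthetic study
#'
#' For every synthetic subject: simulate the bench stretch experiment on the
#' subject's own (true-twist) model, estimate the straightened-collagen
#' modulus from the terminal stress-strain gradient, then for every twist
#' angle calibrate (c1, c3, c4) against the recorded markers and run the
#' in-silico rupture experiment with the fitted parameters. Failures are
#' isolated per subject x angle case and logged in the `status` column.
#'
#' @param config A [study_config()].
#' @param verbose Print per-case progress.
#' @return A `study_result` with data frames `coefficients` (subject x
#'   angle calibration results), `rupture` (rupture loads and compartment
#'   stress contrast), `summary_by_angle`, plus the config, its hash and
#'   the subjects used. If `config$outdir` is set the tables are also
#'   written as CSV with provenance headers.
#' @export
run_full_study <- function(config = study_config(), verbose = FALSE) {
  cfg <- config
  hash <- config_hash(cfg)
  coef_rows <- list(); rupt_rows <- list()
  subjects <- list()
  say <- function(...) if (verbose) message(...)
  for (i in seq_len(cfg$n_subjects)) {
    subj <- draw_subject(cfg$population, cfg$seed * 1000L + i)
    subjects[[i]] <- subj
    say(sprintf("subject %d: twist %.1f deg, CSA %.1f mm^2", i,
                subj$twist_deg, subj$csa))
    cal_mod <- try(subject_model(
      subj, n_axial = cfg$calib$n_axial, n_circ = cfg$calib$n_circ,
      n_radial = cfg$calib$n_radial, scheme = "none",
      fiber = cfg$fiber), silent = TRUE)
    rec <- if (inherits(cal_mod, "try-error")) NULL else
      tryCatch(simulate_experiment(
        cal_mod$mesh, cal_mod$fiber_field, subj$params,
        protocol = cfg$protocol, noise_sd = cfg$noise_sd,
        seed = cfg$seed * 1000L + i), error = function(e) NULL)
    c5_est <- if (is.null(rec)) NA_real_ else
      tryCatch(estimate_c5(rec), error = function(e) NA_real_)
    for (ang in cfg$twist_angles) {
      status <- "ok"; fitted <- NULL; rms <- NA_real_
      if (is.null(rec) || is.na(c5_est)) {
        status <- "experiment_failed"
      } else {
        ffa <- suppressWarnings(
          if (ang == 0) straight_fiber_field(cal_mod$mesh)
          else if (cfg$fiber == "fitted")
            embed_twist_field(cal_mod$mesh, ang)
          else analytic_twist_field(cal_mod$mesh, ang))
        cal <- tryCatch(optimize_material(
          rec, cal_mod$mesh, ffa, c5 = c5_est,
          lambda_star = subj$params$lambda_star,
          n_starts = cfg$calib$n_starts, maxit = cfg$calib$maxit,
          seed = cfg$seed * 1000L + i), error = function(e) NULL)
        if (is.null(cal)) status <- "calibration_failed"
        else { fitted <- cal$fitted_params; rms <- cal$rms_error }
      }
      coef_rows[[length(coef_rows) + 1]] <- data.frame(
        subject = i, angle = ang,
        c1 = if (is.null(fitted)) NA else fitted$c1,
        c3 = if (is.null(fitted)) NA else fitted$c3,
        c4 = if (is.null(fitted)) NA else fitted$c4,
        c5 = c5_est, rms_mm = rms, status = status)
      say(sprintf("  angle %2d: %s (rms %.3g mm)", ang, status, rms))
      rl <- NA_real_; pd_ref <- NA_real_; r_status <- status
      if (status == "ok") {
        rp <- tryCatch({
          mod <- subject_model(subj, twist_deg = ang,
                               n_axial = cfg$rupture$n_axial,
                               n_circ = cfg$rupture$n_circ,
                               n_radial = cfg$rupture$n_radial,
                               fractions = cfg$area_fractions,
                               fiber = cfg$fiber)
          run_rupture(mod$mesh, mod$fiber_field, fitted,
                      split = cfg$split,
                      increment = cfg$rupture$increment,
                      threshold = cfg$rupture$threshold,
                      run_length = cfg$rupture$run_length,
                      max_load = cfg$rupture$max_load)
        }, error = function(e) NULL)
        if (is.null(rp)) r_status <- "rupture_failed" else {
          rl <- rp$rupture_load
          hist <- rp$load_history
          k <- which(hist$load_N == cfg$ref_load)
          if (length(k)) pd_ref <- hist$percent_difference[k]
          if (is.na(rl)) r_status <- rp$status
        }
      }
      rupt_rows[[length(rupt_rows) + 1]] <- data.frame(
        subject = i, angle = ang, rupture_load_N = rl,
        medlat_pct_at_ref = pd_ref, status = r_status)
      say(sprintf("  angle %2d: rupture %s N", ang, format(rl)))
    }
  }
  coefficients <- do.call(rbind, coef_rows)
  rupture <- do.call(rbind, rupt_rows)
  summary_by_angle <- do.call(rbind, lapply(
    split(rupture, rupture$angle), function(d) data.frame(
      angle = d$angle[1],
      mean_rupture_N = mean(d$rupture_load_N, na.rm = TRUE),
      mean_medlat_pct = mean(d$medlat_pct_at_ref, na.rm = TRUE),
      n_ok = sum(!is.na(d$rupture_load_N)))))
  res <- structure(list(coefficients = coefficients, rupture = rupture,
                        summary_by_angle = summary_by_angle,
                        subjects = subjects, config = cfg,
                        config_hash = hash), class = "study_result")
  if (!is.null(cfg$outdir)) write_study_csv(res, cfg$outdir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d subjects x %d angles (config %s, seed %d)\n",
              x$config$n_subjects, length(x$config$twist_angles),
              x$config_hash, x$config$seed))
  print(x$summary_by_angle, row.names = FALSE)
  invisible(x)
}

# Write the study tables as CSV with provenance headers.
write_study_csv <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# tendontwist study; seed=%d; config_hash=%s",
                 res$config$seed, res$config_hash)
  wr <- function(df, name) {
    path <- file.path(outdir, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    path
  }
  wr(res$coefficients, "coefficients.csv")
  wr(res$rupture, "rupture.csv")
  wr(res$summary_by_angle, "summary_by_angle.csv")
  invisible(outdir)
}

#' Parse a packaged printed-reference table
#'
#' Reads the subject-by-angle reference CSVs shipped under `extdata`
#' (marker-RMS fit errors and optimized coefficients of ten cadaver
#' specimens) and separates the per-subject value matrix from the printed
#' Average/SD summary rows.
#'
#' @param table_csv Path to the CSV (see
#'   `system.file("extdata", "reference_marker_rms.csv", package =
#'   "tendontwist")`).
#' @return For a plain table: list with `values` (subject x angle matrix),
#'   `printed_average`, `printed_sd` (named by angle column). For the
#'   coefficients table (a `coefficient` column present): a named list of
#'   such lists, one per coefficient.
#' @export
parse_printed_tables <- function(table_csv) {
  df <- utils::read.csv(table_csv, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("empty reference table")
  if (!"subject" %in% names(df))
    stop("malformed reference table: no 'subject' column ",
         "(transposed or wrong file?)")
  angle_cols <- grep("^angle_", names(df), value = TRUE)
  if (length(angle_cols) < 2)
    stop("malformed reference table: expected angle_* columns")
  parse_block <- function(d) {
    subj <- suppressWarnings(as.integer(d$subject))
    vals <- as.matrix(d[!is.na(subj), angle_cols, drop = FALSE])
    rownames(vals) <- d$subject[!is.na(subj)]
    if (nrow(vals) == 0) stop("reference table has no subject rows")
    pick <- function(tag) {
      k <- which(d$subject == tag)
      if (length(k)) unlist(d[k[1], angle_cols]) else NULL
    }
    list(values = vals, printed_average = pick("Average"),
         printed_sd = pick("SD"))
  }
  if ("coefficient" %in% names(df))
    lapply(split(df, df$coefficient), parse_block)
  else
    parse_block(df)
}
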