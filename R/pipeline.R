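# Orchestration of the full comparison study: instantiate/calibrate the
# three material models, simulate the protocol per model instance, compute
# cohort statistics, and compare against the synthetic validation cohort.

#' Default study configuration
#'
#' The packaged configuration carrying every reference constant: geometry
#' (8 mm wide section, 1.305 mm mean thickness), the two-step loading
#' protocol (ramp to 1.225 MPa, cyclic 0.75--1.7 MPa at 1 Hz), the per-model
#' mesh densities (50/100/200 µm for linear / Ogden / Neo-Hookean), the four
#' regional Neo-Hookean constants, the reference third-order Ogden constants,
#' and the synthetic cohort sizes (10 model-building, 6 validation).
#'
#' @param seed RNG seed for cohort generation.
#' @param backend `"homogeneous"` (default; lateral-locked closed form, the
#'   idealisation the plane-stress solver converges to under platen boundary
#'   conditions) or `"fem"`.
#' @return A nested list of class `"study_config"`, YAML-serialisable.
#' @export
default_study_config <- function(seed = 42L, backend = c("homogeneous", "fem")) {
  backend <- match.arg(backend)
  structure(list(
    seed = as.integer(seed),
    backend = backend,
    mode = "lateral_locked",
    geometry = list(width_mm = 8, thickness_mm = 1.305, diameter_mm = 8),
    protocol = list(p_mean_MPa = 1.225, amplitude_MPa = 0.475,
                    alt_amplitude_MPa = 0.388, frequency_Hz = 1,
                    ramp_duration_s = 1, cyclic_duration_s = 1,
                    sample_interval_s = 0.005),
    mesh = list(linear_um = 50, ogden3_um = 100, neo_hookean_um = 200),
    solver = list(n_incr_ramp = 20, n_incr_cyclic = 40, tol_rel = 1e-8,
                  penalty_factor = 1000, integration = "full"),
    cohorts = list(n_model = 10, n_validation = 6),
    materials = list(
      linear = list(type = "linear", fit_from_model_cohort = TRUE,
                    poisson_ratio = 0.45),
      neo_hookean = list(type = "neo_hookean",
                         c10_MPa = as.list(neo_hookean_regional_c10()),
                         convention = "standard_c10"),
      ogden3 = local({
        m <- ogden_reference_material()
        list(type = "ogden3", mu_MPa = m$mu, alpha = m$alpha)
      }))),
    class = "study_config")
}

#' Read or write a study configuration as YAML
#'
#' @param config A `study_config` list.
#' @param file Path to a YAML document.
#' @return `write_study_config()` returns `file` invisibly;
#'   `read_study_config()` returns a `study_config`.
#' @export
write_study_config <- function(config, file) {
  yaml::write_yaml(unclass(config), file)
  invisible(file)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(file) {
  structure(yaml::read_yaml(file), class = "study_config")
}

config_protocol <- function(config, amplitude = NULL) {
  p <- config$protocol
  loading_protocol(p_mean = p$p_mean_MPa,
                   amplitude = amplitude %||% p$amplitude_MPa,
                   frequency = p$frequency_Hz,
                   ramp_duration = p$ramp_duration_s,
                   cyclic_duration = p$cyclic_duration_s,
                   sample_interval = p$sample_interval_s)
}

simulate_instance <- function(model, config, protocol, mesh_um) {
  if (config$backend == "fem") {
    opts <- fe_options(n_incr_ramp = config$solver$n_incr_ramp,
                       n_incr_cyclic = config$solver$n_incr_cyclic,
                       tol_rel = config$solver$tol_rel,
                       penalty_factor = config$solver$penalty_factor,
                       integration = config$solver$integration,
                       store_field = FALSE)
    mesh <- build_mesh(config$geometry$width_mm, config$geometry$thickness_mm,
                       mesh_um)
    fe_simulate(model, mesh, protocol, bc = "platen", options = opts)$trace
  } else {
    simulate_protocol(model, protocol, config$geometry$thickness_mm,
                      mode = config$mode)
  }
}

#' Run the full comparison study
#'
#' Generates the synthetic model-building and validation cohorts, calibrates
#' the per-specimen linear models from the model cohort's ramp curves,
#' instantiates the Neo-Hookean (regional constants) and Ogden (reference
#' constants) models, simulates the loading protocol for every model
#' instance at mean geometry with the configured backend, computes the
#' headline metrics, and compares per-model means against the validation
#' cohort's statistics.  Per-specimen instabilities are reported in the
#' metrics table (`status` column), not fatal.  Fully reproducible from
#' `config` (including its seed).
#'
#' @param config A [default_study_config()]-shaped list.
#' @return An object of class `"study_report"`.
#' @examples
#' \donttest{
#' rep <- run_study(default_study_config())
#' print(rep)
#' }
#' @export
run_study <- function(config = default_study_config()) {
  stopifnot(is.list(config))
  protocol <- config_protocol(config)
  truth <- default_validation_truth()
  truth$seed <- as.integer(config$seed)

  model_cohort <- generate_cohort(config$cohorts$n_model, "model", truth)
  valid_cohort <- generate_cohort(config$cohorts$n_validation, "validation", truth)

  # validation metrics from synthetic DMA traces
  vtraces <- lapply(seq_len(nrow(valid_cohort)), function(i)
    generate_dma_trace(valid_cohort[i, ], truth, protocol))
  names(vtraces) <- valid_cohort$id
  vtab <- metrics_table(vtraces, model = "validation")

  # material instances per model family
  instances <- list()
  if (isTRUE(config$materials$linear$fit_from_model_cohort)) {
    for (i in seq_len(nrow(model_cohort))) {
      cv <- generate_ramp_curve(model_cohort[i, ], truth)
      ft <- fit_material(cv, "linear",
                         poisson_ratio = config$materials$linear$poisson_ratio)
      instances[[paste0("linear/", model_cohort$id[i])]] <-
        list(family = "linear", model = ft$model, mesh_um = config$mesh$linear_um)
    }
  }
  for (nm in names(config$materials$neo_hookean$c10_MPa)) {
    c10 <- config$materials$neo_hookean$c10_MPa[[nm]]
    instances[[paste0("neo_hookean/", nm)]] <-
      list(family = "neo_hookean",
           model = neo_hookean_material(c10, config$materials$neo_hookean$convention,
                                        label = paste0("neo_hookean_", nm)),
           mesh_um = config$mesh$neo_hookean_um)
  }
  instances[["ogden3/reference"]] <-
    list(family = "ogden3",
         model = ogden_material(unlist(config$materials$ogden3$mu_MPa),
                                unlist(config$materials$ogden3$alpha),
                                label = "ogden3_reference"),
         mesh_um = config$mesh$ogden3_um)

  rows <- list(); traces <- list()
  for (nm in names(instances)) {
    inst <- instances[[nm]]
    tr <- tryCatch(simulate_instance(inst$model, config, protocol, inst$mesh_um),
                   cartdyn_stability_error = function(e) e)
    if (inherits(tr, "cartdyn_stability_error")) {
      rows[[nm]] <- data.frame(specimen = nm, model = inst$family,
                               ramp_um = NA_real_, dynamp_um = NA_real_,
                               hysteresis_J_m2 = NA_real_,
                               status = paste("unstable:", conditionMessage(tr)),
                               stringsAsFactors = FALSE)
    } else {
      traces[[nm]] <- tr
      m <- metrics_table(list(tr), model = inst$family)
      m$specimen <- nm; m$status <- "ok"
      rows[[nm]] <- m
    }
  }
  mtab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  summarise <- function(tab, metric) {
    fam <- unique(tab$model)
    do.call(rbind, lapply(fam, function(f) {
      v <- tab[tab$model == f & is.finite(tab[[metric]]), metric]
      st <- if (length(v)) cohort_stats(v) else
        c(mean = NA_real_, sd = NA_real_, n = 0)
      data.frame(model = f, metric = metric, mean = st["mean"], sd = st["sd"],
                 n = st["n"], row.names = NULL)
    }))
  }
  summary_tab <- rbind(summarise(mtab, "ramp_um"), summarise(mtab, "dynamp_um"))
  vstats <- list(ramp = cohort_stats(vtab$ramp_um),
                 dynamp = cohort_stats(vtab$dynamp_um))

  comp <- do.call(rbind, lapply(split(summary_tab, seq_len(nrow(summary_tab))),
    function(r) {
      tgt <- if (r$metric == "ramp_um") vstats$ramp else vstats$dynamp
      data.frame(r, validation_mean = tgt["mean"], validation_sd = tgt["sd"],
                 ratio = r$mean / tgt["mean"],
                 within_one_sd = abs(r$mean - tgt["mean"]) <= tgt["sd"],
                 row.names = NULL)
    }))

  structure(list(config = config, metrics = mtab, summary = comp,
                 validation = vtab, validation_stats = vstats,
                 traces = traces),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study report>\n")
  cat(sprintf("  backend: %s, seed: %s\n", x$config$backend, format(x$config$seed)))
  v <- x$validation_stats
  cat(sprintf("  validation cohort (n=%.0f): ramp %.1f +/- %.1f um, dynamic amplitude %.1f +/- %.1f um\n",
              v$ramp["n"], v$ramp["mean"], v$ramp["sd"],
              v$dynamp["mean"], v$dynamp["sd"]))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s %-10s mean %8.1f um (ratio %5.2f, %s one validation SD)\n",
                s$model[i], sub("_um", "", s$metric[i]), s$mean[i], s$ratio[i],
                ifelse(s$within_one_sd[i], "within", "outside")))
  invisible(x)
}

#' Write a study report to a directory
#'
#' Serialises the report as a YAML document (config + summary + validation
#' statistics) plus the flat metrics table as TSV.  Regenerating the study
#' from the serialised config reproduces the report.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(list(config = unclass(report$config),
                        summary = report$summary,
                        validation_stats = lapply(report$validation_stats,
                                                  as.list)),
                   file.path(dir, "report.yaml"))
  utils::write.table(report$metrics, file.path(dir, "metrics.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Render the study's comparison figures
#'
#' Writes (1) a six-panel bar chart (three model families by two metrics,
#' each with the validation mean and SD), (2) overall compression-versus-time
#' curves for the hyperelastic models, and (3) pressure--displacement loops
#' for the final cycle, as PNG files.
#'
#' @param report A [run_study()] result.
#' @param outdir Output directory.
#' @return Character vector of the files written.
#' @export
make_figures <- function(report, outdir) {
  stopifnot(inherits(report, "study_report"))
  if (!nrow(report$summary)) stop("empty report: nothing to plot")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  f1 <- file.path(outdir, "comparison_panel.png")
  grDevices::png(f1, width = 1400, height = 900, res = 140)
  fams <- unique(report$summary$model)
  graphics::par(mfrow = c(2, length(fams)), mar = c(3, 4, 2, 1))
  for (metric in c("ramp_um", "dynamp_um")) {
    for (f in fams) {
      r <- report$summary[report$summary$model == f &
                            report$summary$metric == metric, ]
      v <- if (metric == "ramp_um") report$validation_stats$ramp
      else report$validation_stats$dynamp
      hs <- c(r$mean, v["mean"]); ses <- c(r$sd, v["sd"])
      bp <- graphics::barplot(hs, names.arg = c(f, "validation"),
                              ylab = paste(sub("_um", "", metric), "(um)"),
                              ylim = c(0, max(hs + ses) * 1.2), col = c("grey70", "grey30"))
      nz <- ses > 0                        # single-instance bars carry no SD
      if (any(nz))
        graphics::arrows(bp[nz], hs[nz] - ses[nz], bp[nz], hs[nz] + ses[nz],
                         angle = 90, code = 3, length = 0.04)
    }
  }
  grDevices::dev.off(); files <- c(files, f1)

  if (length(report$traces)) {
    f2 <- file.path(outdir, "compression_curves.png")
    grDevices::png(f2, width = 1200, height = 700, res = 140)
    graphics::par(mar = c(4, 4, 1, 1))
    ylim <- c(0, max(vapply(report$traces, function(t)
      max(t$displacement_um), numeric(1))))
    plot(NA, xlim = c(0, 2), ylim = ylim, xlab = "time (s)",
         ylab = "compression (um)")
    cols <- seq_along(report$traces)
    for (i in cols)
      graphics::lines(report$traces[[i]]$time_s,
                      report$traces[[i]]$displacement_um, col = i)
    graphics::legend("topleft", legend = names(report$traces), col = cols,
                     lty = 1, cex = 0.5, bty = "n")
    grDevices::dev.off(); files <- c(files, f2)

    f3 <- file.path(outdir, "hysteresis_loops.png")
    grDevices::png(f3, width = 1200, height = 700, res = 140)
    graphics::par(mar = c(4, 4, 1, 1))
    plot(NA, xlim = range(vapply(report$traces, function(t)
      range(t$displacement_um[t$step == "cyclic"]), numeric(2))),
      ylim = c(0, 2), xlab = "compression (um)", ylab = "pressure (MPa)")
    for (i in seq_along(report$traces)) {
      cyc <- report$traces[[i]][report$traces[[i]]$step == "cyclic", ]
      graphics::lines(cyc$displacement_um, cyc$pressure_MPa, col = i)
    }
    grDevices::dev.off(); files <- c(files, f3)
  }
  files
}
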