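# Pipeline driver: run every montage on one phantom and collect the full
# metric suite into report tables.

#' Comparison-run configuration
#'
#' @param phantom A [phantom_config()].
#' @param conductivity_set `"primary"` or `"weighted_mean"`.
#' @param montages Character vector of montage presets (default all seven).
#' @param current_mA Total injected current per montage (mA).
#' @param tol,max_iter Solver settings.
#' @param out_dir Optional directory for CSV / JSON outputs.
#' @param seed Seed recorded in the provenance block (the default pipeline
#'   is deterministic; the seed governs optional phantom jitter and
#'   bootstrap resampling).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(phantom = phantom_config(),
                       conductivity_set = "primary",
                       montages = paste0("montage", 1:7),
                       current_mA = 1,
                       tol = 1e-6,
                       max_iter = 20000L,
                       out_dir = NULL,
                       seed = 42L) {
  if (!length(montages)) stop("montage list must be non-empty")
  if (current_mA <= 0) stop("current must be > 0")
  structure(list(phantom = phantom, conductivity_set = conductivity_set,
                 montages = montages, current_mA = current_mA, tol = tol,
                 max_iter = as.integer(max_iter), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Metrics for one solved montage on a phantom with vestibular ROIs.
.montage_metrics <- function(vol, ef, current_mA) {
  sides <- c("left", "right")
  comp_stats <- list()
  for (side in sides) {
    for (comp in c("network", "vestibule", "scc")) {
      labs <- roi_labels(vol, side, comp)
      st <- roi_statistics(ef, labs, vol)
      if (comp == "network")
        st$current_uA <- roi_inflow_current(ef, roi_surface(vol, labs))
      comp_stats[[paste(side, comp, sep = "_")]] <- st
    }
  }
  sym <- symmetricity(comp_stats$left_network, comp_stats$right_network)
  cran <- cranial_current_fraction(ef, inner_skull_surface(vol), current_mA, vol)
  list(stats = comp_stats, symmetricity = sym, cranial_fraction_pct = cran)
}

#' Run the full montage comparison
#'
#' Builds the phantom once and, for each montage: stamps the pads, assembles
#' and solves the volume-conduction problem, derives the field, and computes
#' the metric suite for the left/right vestibular network, vestibule and
#' SCC, plus symmetricity, cranial current fraction and inter-electrode
#' separations. Deterministic given the configuration. A montage whose
#' pipeline fails is recorded in `failures` without aborting the others.
#'
#' @param config A [run_config()].
#' @return A list of class `"report_bundle"` with `network_table`
#'   (per-montage left/right mean/sd/p99/current + symmetricity),
#'   `subregion_table`, `montage_table` (separation, cranial fraction,
#'   electrode current density), `starplot_table`, `solver_reports`,
#'   `failures` and a `provenance` block. CSVs are written when
#'   `config$out_dir` is set.
#' @export
run_comparison <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  ct <- conductivity_table(config$conductivity_set)
  base <- build_phantom(config$phantom, ct)
  net_rows <- list(); sub_rows <- list(); mon_rows <- list()
  reports <- list(); failures <- list()
  for (mname in config$montages) {
    res <- tryCatch({
      sol <- solve_montage(base, mname, I_total_mA = config$current_mA,
                           tol = config$tol, max_iter = config$max_iter,
                           conductivities = ct)
      mm <- .montage_metrics(sol$vol, sol$efield, config$current_mA)
      sep <- electrode_separation(sol$vol$montage, sol$vol)
      list(sol = sol, mm = mm, sep = sep)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[mname]] <- conditionMessage(res)
      next
    }
    st <- res$mm$stats
    net_rows[[mname]] <- data.frame(
      montage = mname,
      left_mean = st$left_network$mean_V_per_m,
      left_sd = st$left_network$sd_V_per_m,
      left_p99 = st$left_network$p99_V_per_m,
      left_current_uA = st$left_network$current_uA,
      right_mean = st$right_network$mean_V_per_m,
      right_sd = st$right_network$sd_V_per_m,
      right_p99 = st$right_network$p99_V_per_m,
      right_current_uA = st$right_network$current_uA,
      sym_mean = res$mm$symmetricity$mean_ratio,
      sym_max = res$mm$symmetricity$max_ratio,
      stringsAsFactors = FALSE)
    sub_rows[[mname]] <- data.frame(
      montage = mname,
      left_vestibule_mean = st$left_vestibule$mean_V_per_m,
      left_scc_mean = st$left_scc$mean_V_per_m,
      right_vestibule_mean = st$right_vestibule$mean_V_per_m,
      right_scc_mean = st$right_scc$mean_V_per_m,
      stringsAsFactors = FALSE)
    pads <- res$sol$vol$pads
    pad_area_m2 <- pi * (pads$diameter_mm[1] / 2 / 1000)^2
    n_anodes <- sum(pads$polarity == "anode")
    an_cat <- res$sep[res$sep$polarity_a != res$sep$polarity_b, ]
    mon_rows[[mname]] <- data.frame(
      montage = mname,
      electrode_current_density_A_per_m2 =
        (config$current_mA / 1000) / (n_anodes * pad_area_m2),
      min_separation_mm = min(an_cat$separation_mm),
      max_separation_mm = max(an_cat$separation_mm),
      cranial_fraction_pct = res$mm$cranial_fraction_pct,
      delivered_current_mA =
        unname(res$sol$potential$report$delivered_current_mA["anode"]),
      cg_iterations = res$sol$potential$report$iterations,
      stringsAsFactors = FALSE)
    reports[[mname]] <- res$sol$potential$report
  }
  net <- do.call(rbind, net_rows)
  sub <- do.call(rbind, sub_rows)
  mon <- do.call(rbind, mon_rows)
  star <- NULL
  if (!is.null(net) && nrow(net) > 0) {
    star_in <- cbind(net[, c("montage", "left_mean", "left_sd", "left_p99",
                             "right_mean", "right_sd", "right_p99")],
                     sub[, c("left_vestibule_mean", "left_scc_mean",
                             "right_vestibule_mean", "right_scc_mean")])
    star <- starplot_normalize(star_in)
  }
  bundle <- structure(list(
    network_table = net, subregion_table = sub, montage_table = mon,
    starplot_table = star, solver_reports = reports, failures = failures,
    provenance = list(
      package_version = as.character(utils::packageVersion("vestibflow")),
      config = config,
      conductivity_set = config$conductivity_set,
      timestamp = NULL  # deliberately omitted: outputs must be byte-identical
    )
  ), class = "report_bundle")
  if (!is.null(config$out_dir)) write_report_bundle(bundle, config$out_dir)
  bundle
}

#' Write a report bundle to CSV / JSON
#'
#' @param bundle A `"report_bundle"` from [run_comparison()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    table1 = file.path(out_dir, "table1_analogue.csv"),
    table2 = file.path(out_dir, "table2_analogue.csv"),
    table3 = file.path(out_dir, "table3_analogue.csv"),
    star = file.path(out_dir, "starplot.csv"),
    worked = file.path(out_dir, "worked_examples.csv"),
    prov = file.path(out_dir, "provenance.json")
  )
  write.csv(bundle$network_table, paths["table1"], row.names = FALSE)
  write.csv(bundle$subregion_table, paths["table2"], row.names = FALSE)
  write.csv(bundle$montage_table, paths["table3"], row.names = FALSE)
  if (!is.null(bundle$starplot_table))
    write.csv(bundle$starplot_table, paths["star"], row.names = FALSE)
  write.csv(paper_worked_examples(), paths["worked"], row.names = FALSE)
  prov <- bundle$provenance
  prov$config$phantom$roi_spec <- lapply(prov$config$phantom$roi_spec, unclass)
  jsonlite::write_json(
    list(package_version = prov$package_version,
         conductivity_set = prov$conductivity_set,
         montages = prov$config$montages,
         current_mA = prov$config$current_mA,
         tol = prov$config$tol,
         voxel_mm = prov$config$phantom$voxel_mm,
         seed = prov$config$seed,
         failures = bundle$failures),
    paths["prov"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle> ", nrow(x$network_table %||% data.frame()),
      " montage(s)\n", sep = "")
  if (!is.null(x$network_table)) {
    df <- x$network_table
    df[-1] <- lapply(df[-1], signif, 4)
    print(df, row.names = FALSE)
  }
  if (length(x$failures)) {
    cat("failures:\n")
    for (nm in names(x$failures)) cat("  ", nm, ": ", x$failures[[nm]], "\n")
  }
  invisible(x)
}
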