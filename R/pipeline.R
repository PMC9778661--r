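# Configuration-driven pipeline: simulate -> analyze -> report.
#
# The config is a flat key = value text file; every analysis threshold is a
# key with the standard default (3.5 A / 120 deg hydrogen-bond criterion,
# 75% occupancy threshold, 3.0 A water cutoff, 0.6 trailing window, 5
# clusters, 40 ps cluster stride, 0.2 A histogram bins).

.default_config <- function() {
  list(
    hbond_dmax = 3.5, hbond_angle_min = 120, occupancy_threshold = 0.75,
    water_cutoff = 3.0, window = 0.6, n_clusters = 5, stride_ps = 40,
    bin_width = 0.2, resid_t37 = 37, resid_g62 = 62, gtp_resname = "GTP",
    seed = 42, n_frames = 500, system = "wt", n_replicates = 3,
    energy_tables = "", trajectories = "", out_dir = "."
  )
}

#' Read a flat key = value run configuration
#'
#' Unknown keys are kept verbatim; known numeric keys are coerced.  Missing
#' keys take the documented defaults.
#'
#' @param path config file path, or `NULL` for pure defaults.
#' @return named list of class `"run_config"`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- .default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) < 2L) stop("malformed config line: '", ln, "'")
      key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
      num <- suppressWarnings(as.numeric(val))
      cfg[[key]] <- if (!is.na(num)) num else val
    }
  }
  for (k in c("hbond_dmax", "hbond_angle_min", "water_cutoff", "window",
              "bin_width")) {
    if (cfg[[k]] <= 0) stop("config value must be positive: ", k)
  }
  structure(cfg, class = "run_config")
}

.cfg_criterion <- function(cfg) {
  hbond_criterion(d_max = cfg$hbond_dmax, angle_min = cfg$hbond_angle_min)
}

#' Simulate replicate trajectories to disk
#'
#' Writes, per replicate, a multi-model PDB trajectory plus a ground-truth
#' table, and a manifest file with md5 checksums of every artifact.
#' Deterministic for a given seed.
#'
#' @param config a `run_config` (or path to one); keys used: `system`,
#'   `n_frames`, `n_replicates`, `seed`, `out_dir`.
#' @param spec optional explicit [synthetic_spec()] overriding
#'   `system`/`n_frames` (the per-replicate seed is still derived from
#'   `config$seed`).
#' @return invisibly, the manifest data.frame (`file`, `md5`).
#' @export
run_simulate <- function(config = read_run_config(), spec = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (r in seq_len(config$n_replicates)) {
    sp <- if (is.null(spec)) {
      preset_spec(config$system, n_frames = as.integer(config$n_frames),
                  seed = as.integer(config$seed) + 1000L * r)
    } else {
      sp0 <- spec; sp0$seed <- as.integer(config$seed) + 1000L * r; sp0
    }
    sim <- simulate_trajectory(sp)
    tf <- file.path(config$out_dir, sprintf("traj_rep%d.pdb", r))
    gf <- file.path(config$out_dir, sprintf("truth_rep%d.tsv", r))
    write_structure(sim$trajectory, tf)
    write_ground_truth(sim$truth, gf)
    files <- c(files, tf, gf)
  }
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  mf <- file.path(config$out_dir, "manifest.tsv")
  utils::write.table(manifest, mf, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(manifest)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run every analysis stage on replicate trajectories
#'
#' Stages: per-frame state classification and populations, characteristic
#' hydrogen-bond occupancies, GTP SASA (LCPO), gamma-phosphate water counts,
#' conformational clustering, per-residue RMSF, secondary-structure
#' propensities, and (when energy tables are configured) the MM/GBSA ledger.
#' Each stage writes a delimited table into `out_dir`; a failing stage is
#' reported but does not abort the others.
#'
#' @param config a `run_config` or path; `trajectories` holds
#'   comma-separated PDB paths (defaults to the files `run_simulate` wrote
#'   into `out_dir`).
#' @return list with every stage result (`states`, `populations`,
#'   `occupancy`, `sasa`, `waters`, `clusters`, `rmsf`, `propensity`,
#'   `bfe`, `errors`), invisibly.
#' @export
run_analyze <- function(config = read_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  paths <- if (nzchar(config$trajectories)) {
    trimws(strsplit(config$trajectories, ",")[[1]])
  } else {
    list.files(config$out_dir, pattern = "^traj_rep[0-9]+\\.pdb$",
               full.names = TRUE)
  }
  if (!length(paths)) stop("no trajectory files to analyze")
  trajs <- lapply(paths, read_structure)
  crit <- .cfg_criterion(config)
  out <- list(errors = character())
  res <- function(name, expr) {
    v <- tryCatch(expr, error = function(e) {
      out$errors <<- c(out$errors, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
    out[[name]] <<- v
    v
  }

  states <- res("states", lapply(trajs, state_series,
                                 resid_t37 = config$resid_t37,
                                 resid_g62 = config$resid_g62,
                                 gtp_resname = config$gtp_resname,
                                 criterion = crit))
  if (!is.null(states)) {
    pop <- state_populations(states, window = config$window)
    out$populations <- pop
    .write_tsv(data.frame(replicate = rownames(pop), pop),
               file.path(config$out_dir, "state_populations.tsv"))
    .write_tsv(do.call(rbind, lapply(seq_along(states), function(r) {
      cbind(replicate = r, states[[r]])
    })), file.path(config$out_dir, "state_series.tsv"))
    for (wh in c("d1", "d2")) {
      hist <- distance_histogram(do.call(rbind, states), wh,
                                 bin_width = config$bin_width)
      .write_tsv(hist, file.path(config$out_dir,
                                 paste0("histogram_", wh, ".tsv")))
    }
  }

  res("occupancy", {
    at <- trajs[[1]]$atoms
    gammaO <- which(at$resname == config$gtp_resname &
                      at$name %in% c("O1G", "O2G", "O3G"))
    occ <- rbind(
      hbond_occupancy(trajs, which(at$resid == config$resid_t37 &
                                     at$name == "N"), gammaO,
                      window = config$window, criterion = crit,
                      label = "T37.N-gammaO"),
      hbond_occupancy(trajs, which(at$resid == config$resid_g62 &
                                     at$name == "N"), gammaO,
                      window = config$window, criterion = crit,
                      label = "G62.N-gammaO"))
    .write_tsv(occ, file.path(config$out_dir, "hbond_occupancy.tsv"))
    occ
  })

  res("sasa", {
    s <- selection_sasa_series(trajs,
                               sel_query = paste("resname",
                                                 config$gtp_resname),
                               window = config$window, method = "lcpo")
    .write_tsv(data.frame(replicate = seq_along(s$replicate_means),
                          mean_sasa = s$replicate_means),
               file.path(config$out_dir, "sasa_gtp.tsv"))
    s
  })

  res("waters", {
    w <- water_count_summary(trajs, window = config$window,
                             cutoff = config$water_cutoff)
    .write_tsv(data.frame(count = w$levels, prob = w$histogram),
               file.path(config$out_dir, "water_counts.tsv"))
    w
  })

  res("clusters", {
    stride <- max(1L, round(config$stride_ps / trajs[[1]]$dt))
    pm <- pairwise_rmsd_matrix(trajs, stride = stride)
    cl <- average_linkage(pm, n_clusters = min(config$n_clusters,
                                               nrow(pm$matrix)))
    summ <- cluster_summary(cl, pm)
    .write_tsv(cbind(summ, pm$frames[summ$representative, ]),
               file.path(config$out_dir, "clusters.tsv"))
    list(matrix = pm, result = cl, summary = summ)
  })

  res("rmsf", {
    prof <- rmsf_profile(trajs)
    .write_tsv(prof, file.path(config$out_dir, "rmsf.tsv"))
    prof
  })

  res("propensity", {
    pr <- ss_propensity(trajs)
    .write_tsv(pr, file.path(config$out_dir, "ss_propensity.tsv"))
    pr
  })

  if (nzchar(config$energy_tables)) {
    res("bfe", {
      tabs <- lapply(trimws(strsplit(config$energy_tables, ",")[[1]]),
                     read_energy_table)
      b <- bfe_combine(tabs, window = config$window)
      .write_tsv(data.frame(term = c(names(b$components), "dG_binding",
                                     "sd"),
                            value = c(b$components, b$total, b$sd)),
                 file.path(config$out_dir, "bfe_summary.tsv"))
      pr <- tryCatch(bfe_per_residue(tabs, window = config$window),
                     error = function(e) NULL)
      if (!is.null(pr)) {
        .write_tsv(pr, file.path(config$out_dir, "bfe_per_residue.tsv"))
      }
      b
    })
  } else {
    message("no energy tables configured; MM/GBSA stage skipped")
  }

  # headline summary
  lines <- c(
    sprintf("system: %s", config$system),
    sprintf("replicates: %d", length(trajs)),
    if (!is.null(out$populations)) {
      pooled <- out$populations["pooled", ]
      sprintf("pooled state populations: %s",
              paste(sprintf("%s=%.3f", names(pooled), pooled),
                    collapse = " "))
    },
    if (!is.null(out$sasa)) sprintf("mean GTP SASA: %.2f A^2",
                                    out$sasa$mean),
    if (!is.null(out$waters)) sprintf("mean gamma-phosphate waters: %.2f",
                                      out$waters$mean),
    if (!is.null(out$clusters)) sprintf(
      "top cluster population: %.3f",
      out$clusters$summary$population[1]),
    if (length(out$errors)) paste("stage errors:", length(out$errors))
  )
  writeLines(lines, file.path(config$out_dir, "summary.txt"))
  invisible(out)
}

#' Compare analysis outputs across systems and render a report
#'
#' Reads the tables written by [run_analyze()] from one result directory per
#' system, lists hydrogen bonds whose mean occupancy exceeds the threshold
#' in any system, tabulates state populations side by side, and reports the
#' percent change in mean GTP SASA of each system against the first
#' (reference) system, rounded to the nearest percent.
#'
#' @param dirs named character vector of result directories; the first entry
#'   is the reference system.
#' @param threshold occupancy threshold (default 0.75).
#' @return list (`sasa`, `occupancy`, `populations`, `text`); the `text`
#'   element is the rendered report, also written to `report.txt` in the
#'   first directory.
#' @export
run_report <- function(dirs, threshold = 0.75) {
  if (is.null(names(dirs))) names(dirs) <- paste0("system", seq_along(dirs))
  need <- function(d, f) {
    p <- file.path(d, f)
    if (!file.exists(p)) stop("missing analysis table: ", p)
    utils::read.delim(p, check.names = FALSE)
  }
  sasa <- do.call(rbind, lapply(names(dirs), function(s) {
    tab <- need(dirs[[s]], "sasa_gtp.tsv")
    data.frame(system = s, mean_sasa = mean(tab$mean_sasa))
  }))
  ref <- sasa$mean_sasa[1]
  sasa$pct_change_vs_ref <- round(percent_decrease(ref, sasa$mean_sasa))
  occ <- do.call(rbind, lapply(names(dirs), function(s) {
    tab <- need(dirs[[s]], "hbond_occupancy.tsv")
    cbind(system = s, tab)
  }))
  hi <- high_occupancy(occ, threshold)
  pops <- do.call(rbind, lapply(names(dirs), function(s) {
    tab <- need(dirs[[s]], "state_populations.tsv")
    cbind(system = s, tab[tab$replicate == "pooled", -1, drop = FALSE])
  }))
  txt <- c(
    "== GTP SASA ==",
    sprintf("%s: %.2f A^2 (%+d%% vs %s)", sasa$system, sasa$mean_sasa,
            -sasa$pct_change_vs_ref, sasa$system[1]),
    "", sprintf("== hydrogen bonds with occupancy > %g%% in any system ==",
                100 * threshold),
    if (nrow(hi)) sprintf("%s [%s]: mean %.2f", hi$pair, hi$system, hi$mean)
    else "(none)",
    "", "== pooled state populations ==",
    vapply(seq_len(nrow(pops)), function(k) {
      paste(pops$system[k], paste(sprintf("%s=%.3f", names(pops)[-1],
                                          as.numeric(pops[k, -1])),
                                  collapse = " "))
    }, character(1))
  )
  writeLines(txt, file.path(dirs[[1]], "report.txt"))
  invisible(list(sasa = sasa, occupancy = hi, populations = pops,
                 text = txt))
}
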