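#' Study configuration
#'
#' Describes a replica of the experiment: a roster of experiments (each an
#' animal/session with its group, per-block evoked suppression, sonicated
#' side and focal displacement peak), the block schedule, and analysis
#' parameters for every stage. `ActiveSham` experiments carry no
#' suppression (factor 1) and an off-target, low-displacement focus,
#' emulating sonication that missed the target.
#'
#' @param seed Master seed; per-experiment seeds are derived from it.
#' @param experiments Data.frame with columns `experiment`, `group`
#'   (`"LGN-TUS"` / `"ActiveSham"`), `suppression`, `side`,
#'   `displacement_peak_um`; `NULL` builds the default roster (6 LGN-TUS,
#'   5 sham) with suppression near 0.5 and displacement peaks coupled
#'   linearly to suppression depth.
#' @param blocks Block schedule for every experiment.
#' @param n_sections Sections per sonication block (20 = full-length
#'   blocks).
#' @param n_keep Trials retained per cell by [equalize_trials()].
#' @param reject_uV Amplitude-rejection threshold.
#' @param noise_scale_uV Background-noise RMS passed to the generator.
#' @param wavelet Named list overriding [build_wavelets()] arguments.
#' @param n_perm Permutations for difference maps.
#' @param spectra_decim Time decimation of stored spectrograms/maps.
#' @param run_ica Run component cleaning on TUS-containing conditions.
#' @param arfi_tau_s Motion-encoding lobe duration, s.
#' @param arfi_noise_sd_rad Phase noise per ARFI acquisition.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L, experiments = NULL,
                         blocks = c("Baseline", "LGN1", "Ctrl1"),
                         n_sections = 20, n_keep = 250, reject_uV = 100,
                         noise_scale_uV = 5,
                         wavelet = list(), n_perm = 1000,
                         spectra_decim = 10L, run_ica = TRUE,
                         arfi_tau_s = 3e-3, arfi_noise_sd_rad = 0.005) {
  if (is.null(experiments)) {
    experiments <- data.frame(
      experiment = sprintf("exp%02d", 1:11),
      group = c(rep("LGN-TUS", 6), rep("ActiveSham", 5)),
      suppression = c(0.35, 0.45, 0.5, 0.55, 0.6, 0.65, rep(1, 5)),
      side = rep(c("left", "right"), length.out = 11),
      stringsAsFactors = FALSE
    )
    # displacement scales with suppression depth: deeper suppression at the
    # target goes with larger focal displacement (better transmission)
    experiments$displacement_peak_um <-
      ifelse(experiments$group == "LGN-TUS",
             0.5 + 2.5 * (1 - experiments$suppression), 0.1)
  }
  stopifnot(all(c("experiment", "group", "suppression", "side",
                  "displacement_peak_um") %in% names(experiments)),
            nrow(experiments) > 0)
  structure(
    list(seed = as.integer(seed), experiments = experiments, blocks = blocks,
         n_sections = n_sections, n_keep = n_keep, reject_uV = reject_uV,
         noise_scale_uV = noise_scale_uV, wavelet = wavelet, n_perm = n_perm,
         spectra_decim = as.integer(spectra_decim), run_ica = run_ica,
         arfi_tau_s = arfi_tau_s, arfi_noise_sd_rad = arfi_noise_sd_rad),
    class = "study_config"
  )
}

# preprocess one simulated experiment up to clean epochs
preprocess_experiment <- function(raw, events, cfg, seed) {
  filt <- eeg_bandpass(raw)
  epochs <- eeg_epoch(filt, events)
  epochs <- reject_amplitude_artifacts(epochs, cfg$reject_uV)
  epochs <- suppressWarnings(equalize_trials(epochs, n = cfg$n_keep))
  if (cfg$run_ica && any(epochs$labels$tus_on & epochs$accepted)) {
    tus_ep <- epoch_subset(epochs, condition = c("tus", "light+tus"))
    dec <- decompose_components(tus_ep, seed = seed)
    dec <- score_and_flag_components(dec, tus_ep)
    if (any(dec$flagged) && !all(dec$flagged)) {
      cleaned <- remove_components(epochs, dec)
      sel <- epochs$labels$tus_on
      epochs$data[sel, , ] <- cleaned$data[sel, , ]
    }
  }
  epochs
}

#' Run the end-to-end study replica
#'
#' For every experiment in the roster: simulate the EEG and event schedule,
#' preprocess (filter, epoch, reject, equalize, component-clean TUS
#' conditions), quantify light-only VEPs per block with baseline
#' normalization and laterality, decompose total/NPL/PL spectra for the
#' light and light+TUS conditions, and compute the NPL permutation
#' difference map. Simulates each experiment's MR-ARFI acquisition, extracts
#' the maximum focal displacement, and correlates it with VEP suppression
#' across experiments. Group-level t-tests and the dose-response table are
#' written alongside a manifest with per-file checksums.
#'
#' @param cfg A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param spectra Also compute and store spectrograms / difference maps
#'   (the slowest stage).
#' @param arfi Simulate and analyse ARFI acquisitions; when `FALSE` the
#'   dose-response stage is skipped with a warning.
#' @return Invisibly, a list with the main tables (`vep`, `ttests`,
#'   `arfi`, `dose_response`, `manifest`).
#' @export
run_study <- function(cfg, out_dir, spectra = TRUE, arfi = TRUE) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character()
  exps <- cfg$experiments
  vep_rows <- list()
  norm_rows <- list()
  lat_rows <- list()
  arfi_rows <- list()
  son_blocks <- setdiff(cfg$blocks, "Baseline")
  lgn_block <- if (length(son_blocks)) son_blocks[1] else NULL

  fam_args <- utils::modifyList(
    list(fs_hz = 1000, f_range = c(2, 55), n_freqs = 50,
         cycle_range = c(3, 10)), cfg$wavelet)
  family <- do.call(build_wavelets, fam_args)

  for (i in seq_len(nrow(exps))) {
    ex <- exps[i, ]
    seed_i <- cfg$seed + 1000L * i
    supp <- stats::setNames(rep(ex$suppression, length(son_blocks)),
                            son_blocks)
    sim <- sim_config(seed = seed_i, noise_scale_uV = cfg$noise_scale_uV,
                      suppression = supp)
    events <- make_event_table(cfg$blocks, n_sections = cfg$n_sections)
    raw <- simulate_eeg(events, sim)
    epochs <- preprocess_experiment(raw, events, cfg, seed_i)

    measures <- list()
    for (b in cfg$blocks) {
      erp <- average_evoked(epochs, block = b, condition = "light")
      m <- peak_to_peak(erp)
      measures[[b]] <- m
      for (j in seq_len(nrow(m$per_electrode))) {
        vep_rows[[length(vep_rows) + 1L]] <- cbind(
          data.frame(experiment = ex$experiment, group = ex$group,
                     block = b, condition = "light"),
          m$per_electrode[j, ], row.names = NULL)
      }
    }
    norm <- normalize_to_baseline(measures)
    norm$experiment <- ex$experiment
    norm$group <- ex$group
    norm_rows[[i]] <- norm

    if (!is.null(lgn_block)) {
      lat_rows[[i]] <- data.frame(
        experiment = ex$experiment, group = ex$group,
        laterality_pct = laterality_index(measures[[lgn_block]],
                                          epochs$montage, ex$side))
    }

    if (spectra && !is.null(lgn_block)) {
      occ <- epochs$montage$name[epochs$montage$region == "occipital"]
      x_light <- channel_matrix(
        epoch_subset(epochs, block = lgn_block, condition = "light"), occ)
      x_both <- channel_matrix(
        epoch_subset(epochs, block = lgn_block, condition = "light+tus"), occ)
      spec_set <- function(x) {
        tot <- total_power(x, family, epochs$time_ms, decim = cfg$spectra_decim)
        npl <- npl_power(x, family, epochs$time_ms, decim = cfg$spectra_decim)
        list(total = tot, npl = npl, pl = pl_power(tot, npl))
      }
      specs <- list(light = spec_set(x_light), light_tus = spec_set(x_both))
      saveRDS(specs, file.path(out_dir,
                               sprintf("spectra_%s.rds", ex$experiment)))
      dm <- permutation_diff_map(x_both, x_light, family, epochs$time_ms,
                                 n_perm = cfg$n_perm, seed = seed_i,
                                 decim = cfg$spectra_decim, kind = "npl")
      saveRDS(dm, file.path(out_dir,
                            sprintf("diffmap_npl_%s.rds", ex$experiment)))
    }

    if (arfi) {
      enc <- encoding_params(tau_s = cfg$arfi_tau_s)
      field <- gaussian_focus(dim = c(25, 25, 25), spacing_mm = 1,
                              center_mm = c(12, 12, 12), fwhm_mm = 4,
                              peak = ex$displacement_peak_um)
      pair <- simulate_arfi_pair(field, enc,
                                 noise_sd_rad = cfg$arfi_noise_sd_rad,
                                 seed = seed_i + 1L)
      dmap <- displacement_map(phase_difference(pair), enc, spacing_mm = 1)
      roi <- array(FALSE, dim = c(25, 25, 25))
      roi[7:19, 7:19, 7:19] <- TRUE
      mx <- max_displacement(dmap, roi)
      arfi_rows[[i]] <- data.frame(
        experiment = ex$experiment, group = ex$group,
        max_um = mx$max_um, x = mx$index[1], y = mx$index[2],
        z = mx$index[3], detectable = mx$detectable)
    }
  }

  vep_table <- do.call(rbind, vep_rows)
  vep_norm <- do.call(rbind, norm_rows)
  utils::write.csv(vep_table, file.path(out_dir, "vep.csv"),
                   row.names = FALSE)
  utils::write.csv(vep_norm, file.path(out_dir, "vep_normalized.csv"),
                   row.names = FALSE)
  lat_table <- do.call(rbind, lat_rows)
  if (!is.null(lat_table)) {
    utils::write.csv(lat_table, file.path(out_dir, "laterality.csv"),
                     row.names = FALSE)
  }

  ttests <- NULL
  if (!is.null(lgn_block)) {
    tt <- vep_norm[, c("experiment", "group", "block", "p2p_norm")]
    rows <- list()
    for (dsn in c("baseline_vs_lgn_paired", "lgn_vs_sham_unpaired")) {
      rows[[dsn]] <- tryCatch(
        vep_t_tests(tt, dsn, lgn_block = lgn_block),
        error = function(e) {
          msg <- sprintf("t-test %s skipped: %s", dsn, conditionMessage(e))
          warnings_log <<- c(warnings_log, msg)
          warning(msg, call. = FALSE)
          NULL
        })
    }
    ttests <- do.call(rbind, rows)
    if (!is.null(ttests)) {
      rownames(ttests) <- NULL
      utils::write.csv(ttests, file.path(out_dir, "ttests.csv"),
                       row.names = FALSE)
    }
  }

  arfi_table <- NULL
  dr <- NULL
  if (arfi) {
    arfi_table <- do.call(rbind, arfi_rows)
    utils::write.csv(arfi_table, file.path(out_dir, "arfi.csv"),
                     row.names = FALSE)
    lgn_norm <- vep_norm[vep_norm$block == lgn_block, ]
    dd <- merge(arfi_table, lgn_norm, by = c("experiment", "group"))
    dr <- dose_response(dd$max_um, dd$p2p_norm)
    utils::write.csv(dr, file.path(out_dir, "dose_response.csv"),
                     row.names = FALSE)
  } else {
    msg <- "ARFI inputs disabled; dose-response stage skipped"
    warnings_log <- c(warnings_log, msg)
    warning(msg, call. = FALSE)
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_file)
  files <- sort(setdiff(list.files(out_dir, full.names = TRUE),
                        file.path(out_dir, "manifest.json")))
  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_file)),
    version = as.character(utils::packageVersion("tusvep")),
    timestamp = format(Sys.time(), tz = "UTC"),
    warnings = warnings_log,
    checksums = as.list(tools::md5sum(files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(vep = vep_table, vep_norm = vep_norm,
                 laterality = lat_table, ttests = ttests,
                 arfi = arfi_table, dose_response = dr,
                 manifest = manifest))
}

#' Render summary figures from a study output tree
#'
#' ERP overlays (display-smoothed), block-wise normalized amplitude lines,
#' NPL difference maps with significance contours, and the
#' displacement-vs-amplitude scatter. Panels whose inputs are missing are
#' skipped with a warning. Requires ggplot2.
#'
#' @param out_dir Directory written by [run_study()].
#' @param file Output PDF path (default inside `out_dir`).
#' @return Invisibly, the paths of the panels rendered.
#' @export
report_study <- function(out_dir, file = file.path(out_dir, "report.pdf")) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("report_study requires ggplot2", call. = FALSE)
  }
  g <- ggplot2::ggplot
  aes <- ggplot2::aes
  panels <- list()

  f_norm <- file.path(out_dir, "vep_normalized.csv")
  if (file.exists(f_norm)) {
    d <- utils::read.csv(f_norm)
    panels$amplitude <- g(d, aes(x = block, y = p2p_norm,
                                 group = experiment, colour = group)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(y = "normalized peak-to-peak", title = "VEP amplitude by block")
  } else warning("vep_normalized.csv missing; amplitude panel skipped")

  dmf <- list.files(out_dir, "^diffmap_npl_.*\\.rds$", full.names = TRUE)
  if (length(dmf) > 0) {
    dm <- readRDS(dmf[1])
    dd <- expand.grid(time_ms = dm$time_ms, freq_hz = dm$freqs_hz)
    dd$dB <- as.vector(t(dm$diff))
    dd$sig <- as.vector(t(dm$mask))
    panels$diffmap <- g(dd, aes(time_ms, freq_hz, fill = dB)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_gradient2(low = "blue", high = "red") +
      ggplot2::geom_point(data = dd[dd$sig, ], size = 0.1) +
      ggplot2::labs(title = "NPL difference map (light+TUS - light)")
  } else warning("no difference maps found; map panel skipped")

  f_dr <- file.path(out_dir, "dose_response.csv")
  f_ar <- file.path(out_dir, "arfi.csv")
  if (file.exists(f_dr) && file.exists(f_ar)) {
    ar <- utils::read.csv(f_ar)
    nv <- utils::read.csv(file.path(out_dir, "vep_normalized.csv"))
    blocks <- unique(nv$block)
    lgn_block <- setdiff(blocks, "Baseline")[1]
    dd <- merge(ar, nv[nv$block == lgn_block, ], by = c("experiment", "group"))
    panels$dose <- g(dd, aes(max_um, p2p_norm, colour = group)) +
      ggplot2::geom_point() +
      ggplot2::geom_smooth(method = "lm", se = FALSE,
                           ggplot2::aes(group = 1), colour = "black") +
      ggplot2::labs(x = "max displacement (um)",
                    y = "normalized peak-to-peak",
                    title = "Dose-response")
  } else warning("dose-response inputs missing; scatter panel skipped")

  if (length(panels) == 0) {
    warning("nothing to render")
    return(invisible(character()))
  }
  grDevices::pdf(file, width = 7, height = 5)
  on.exit(grDevices::dev.off())
  for (p in panels) print(p)
  invisible(file)
}
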