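pipeline_defaults <- function() list(
  template = "HO",              # ground-truth template for simulated input
  paired_template = NULL,       # second condition for a paired contrast
  n_subjects = 12,
  seed = 1,
  n_modes = 4,
  freqs = c(4, 48),             # Hz, 1 Hz resolution
  crop = c(-1000, 0),           # ms analysis window
  dt = 10,                      # ms model time step
  baseline_power = c(-1000, -833),
  baseline_trials = c(-2180, -1700),
  bandpass = c(1, 50),
  onset_max_diff = 500,         # ms; >= excludes
  onset_comparator = ">=",
  artifact_p2p = 150,           # microvolts
  p_threshold = 0.005,
  coupling_fwhm = 8,            # Hz
  spectrogram_fwhm = c(8, 96),  # Hz, ms
  input_peak = -400,            # ms
  input_dispersion = 400,       # ms
  tau = 1,                      # s
  models = c("m06", "m12"),     # model subset to invert (full per family)
  fit_max_iter = 128,
  noise_frac = 0.1,
  coupling_mean = 0.4,
  subject_sd_frac = 0.2,
  bms_samples = 1e6,
  out_dir = NULL
)

#' Validate and normalize a pipeline configuration
#'
#' Fills in defaults (the analysis chain's standard values: 4-48 Hz grid,
#' -1000..0 ms window, p < 0.005 uncorrected, 500 ms onset rule, gamma input
#' peaking 400 ms before EMG onset), rejects unknown keys, and checks
#' bounds/units before any computation.
#'
#' @param cfg a named list, a YAML file path, or `NULL` for pure defaults.
#' @return the normalized configuration list (class `run_config`).
#' @export
validate_config <- function(cfg = NULL) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg) %||% list()
  cfg <- cfg %||% list()
  stopifnot(is.list(cfg))
  def <- pipeline_defaults()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- utils::modifyList(def, cfg)
  with(out, {
    stopifnot(p_threshold > 0, p_threshold < 1,
              n_subjects >= 2, n_modes >= 1,
              freqs[1] < freqs[2], crop[1] < crop[2], dt > 0,
              bandpass[1] > 0, bandpass[1] < bandpass[2],
              onset_max_diff > 0, tau > 0, noise_frac >= 0)
  })
  if (!out$onset_comparator %in% c(">=", ">"))
    stop("onset_comparator must be \">=\" or \">\"", call. = FALSE)
  if (out$onset_comparator == ">")
    warning("onset rule comparator overridden to \">\" (default is \">=\")")
  structure(out, class = c("run_config", "list"))
}

write_table_file <- function(df, path) {
  con <- file(path, open = "wb")   # fixed EOL so tables are byte-stable
  on.exit(close(con))
  utils::write.csv(df, con, row.names = FALSE, eol = "\n")
  invisible(path)
}

run_condition <- function(cfg, template, log) {
  gt <- make_population(template = template, n_subjects = cfg$n_subjects,
                        seed = cfg$seed, coupling_mean = cfg$coupling_mean,
                        subject_sd_frac = cfg$subject_sd_frac,
                        noise_frac = cfg$noise_frac,
                        times = seq(cfg$crop[1], cfg$crop[2], by = cfg$dt),
                        freqs = seq(cfg$freqs[1], cfg$freqs[2]))
  study <- simulate_study(gt)
  log("simulate", sprintf("condition %s: %d subjects", template,
                          cfg$n_subjects))
  ms <- build_model_space(gt$network, M = cfg$n_modes,
                          input = list(peak_ms = cfg$input_peak,
                                       dispersion_ms = cfg$input_dispersion),
                          tau = cfg$tau)
  models <- ms$models[cfg$models]
  if (any(vapply(models, is.null, TRUE)))
    stop("unknown model id(s): ",
         paste(setdiff(cfg$models, names(ms$models)), collapse = ", "),
         call. = FALSE)
  names(models) <- cfg$models
  mds <- lapply(study$specs, reduce_to_modes, M = cfg$n_modes)
  fits <- list()
  lev <- matrix(0, cfg$n_subjects, length(models),
                dimnames = list(NULL, names(models)))
  for (s in seq_len(cfg$n_subjects)) {
    for (m in names(models)) {
      fit <- fit_dcm(models[[m]], mds[[s]]$g[[1]], gt$times,
                     max_iter = cfg$fit_max_iter)
      lev[s, m] <- fit$free_energy
      fits[[m]][[s]] <- fit
    }
    log("fit", sprintf("subject %d/%d done", s, cfg$n_subjects))
  }
  ev <- evidence_table(lev, family_map = ms$families[names(models)])
  bms <- if (length(unique(ms$families[names(models)])) > 1)
    family_inference(ev, n_samples = cfg$bms_samples, seed = cfg$seed)
  else rfx_bms(ev, n_samples = cfg$bms_samples, seed = cfg$seed)
  win <- if (inherits(bms, "family_bms"))
    names(which.max(bms$within$exceedance)) else
      names(which.max(bms$exceedance))
  log("bms", sprintf("winning model: %s", win))
  maps <- coupling_to_frequency(fits[[win]], mds, models[[win]],
                                fwhm = cfg$coupling_fwhm)
  stat_maps <- lapply(maps, one_sample_tmap, freqs = attr(maps, "freqs"),
                      p_threshold = cfg$p_threshold)
  tab <- cluster_table(stat_maps)
  list(gt = gt, mds = mds, fits = fits, ev = ev, bms = bms,
       winning_model = win, model = models[[win]], maps = maps,
       stat_maps = stat_maps, table = tab)
}

#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate -> mode reduction -> per-model inversion -> Bayesian
#' model selection -> group coupling statistics, writing all artifacts to a
#' run directory: per-condition evidence CSVs, BMS results (JSON), cluster
#' tables (CSV), a paired-contrast table when two conditions are configured,
#' and a JSON-lines log. Every artifact set is stamped with the config hash;
#' identical config + seed reproduces byte-identical tables.
#'
#' @param cfg a configuration ([validate_config()] is applied).
#' @param out_dir output directory (overrides `cfg$out_dir`; required if
#'   neither is set).
#' @return (invisibly) a list with per-condition results, the config and its
#'   hash, and paths of written artifacts.
#' @export
run_pipeline <- function(cfg = NULL, out_dir = NULL) {
  cfg <- validate_config(cfg)
  out_dir <- out_dir %||% cfg$out_dir
  if (is.null(out_dir)) stop("no output directory configured", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- object_hash(unclass(cfg))
  log_path <- file.path(out_dir, "run_log.jsonl")
  unlink(log_path)
  log <- function(stage, msg) {
    cat(jsonlite::toJSON(list(stage = stage, message = msg,
                              config_hash = hash), auto_unbox = TRUE),
        "\n", file = log_path, append = TRUE)
  }
  conds <- c(cfg$template, cfg$paired_template)
  results <- list()
  paths <- character(0)
  for (cd in conds) {
    res <- tryCatch(run_condition(cfg, cd, log),
                    error = function(e)
                      stop("pipeline stage failed in condition ", cd, ": ",
                           conditionMessage(e), call. = FALSE))
    results[[cd]] <- res
    p1 <- file.path(out_dir, paste0("evidence_", cd, ".csv"))
    write_evidence_csv(res$ev, p1)
    p2 <- file.path(out_dir, paste0("cluster_table_", cd, ".csv"))
    tab <- res$table
    if (nrow(tab)) tab$config_hash <- hash
    write_table_file(tab, p2)
    p3 <- file.path(out_dir, paste0("bms_", cd, ".json"))
    bm <- res$bms
    jsonlite::write_json(
      if (inherits(bm, "family_bms"))
        list(config_hash = hash,
             family_exceedance = as.list(bm$family_exceedance),
             winning_family = bm$winning_family,
             within_exceedance = as.list(bm$within$exceedance),
             winning_model = res$winning_model)
      else list(config_hash = hash, exceedance = as.list(bm$exceedance),
                winning_model = res$winning_model),
      p3, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p1, p2, p3)
  }
  if (length(conds) == 2) {
    a <- results[[conds[1]]]; b <- results[[conds[2]]]
    shared <- intersect(names(a$maps), names(b$maps))
    pstats <- lapply(shared, function(cn)
      paired_tmap(a$maps[[cn]], b$maps[[cn]], freqs = attr(a$maps, "freqs"),
                  p_threshold = cfg$p_threshold))
    names(pstats) <- shared
    ptab <- cluster_table(pstats)
    if (nrow(ptab)) ptab$config_hash <- hash
    p4 <- file.path(out_dir, paste0("cluster_table_paired_", conds[1], "_vs_",
                                    conds[2], ".csv"))
    write_table_file(ptab, p4)
    paths <- c(paths, p4)
    results$paired <- list(stat_maps = pstats, table = ptab)
  }
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(c(list(config_hash = hash), unclass(cfg)), cfg_path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  log("done", paste("artifacts:", paste(basename(paths), collapse = ", ")))
  invisible(list(results = results, config = cfg, config_hash = hash,
                 paths = c(paths, cfg_path)))
}
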