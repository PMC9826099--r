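# Recording container and the pipeline driver. Recordings round-trip through
# an RDS container (schema-versioned, bitwise lossless) with a JSON sidecar
# carrying the channel table, seeds and config hash.

RECORDING_SCHEMA <- "triaxmeg-recording-1"

#' Write a recording to disk
#'
#' Serializes the full recording (data, triggers, motion, array, provenance)
#' to an RDS container and writes a JSON sidecar (\code{<path>.json}) with
#' the channel table, seeds and config hash.
#'
#' @param rec a \code{recording}.
#' @param path output path (conventionally \code{.rds}).
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  obj <- unclass(rec)
  obj$.schema <- RECORDING_SCHEMA
  saveRDS(obj, path)
  sidecar <- list(schema = RECORDING_SCHEMA,
                  fs = rec$fs,
                  n_channels = nrow(rec$data),
                  n_samples = ncol(rec$data),
                  config_hash = rec$provenance$config_hash,
                  seed = rec$provenance$seed,
                  channels = channel_table(rec$array))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Read a recording from disk
#'
#' @param path path written by \code{write_recording}.
#' @return the \code{recording}, bitwise identical to what was written.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("unreadable or truncated recording file: ",
                                           conditionMessage(e)))
  if (is.null(obj$.schema))
    stop("not a recording container (missing schema tag)")
  if (!identical(obj$.schema, RECORDING_SCHEMA))
    stop(sprintf("schema mismatch: file has '%s', this package reads '%s'",
                 obj$.schema, RECORDING_SCHEMA))
  obj$.schema <- NULL
  class(obj) <- "recording"
  obj
}

#' Default run configuration
#'
#' All knobs of the simulate / null / beamform / connect / fingerprint
#' pipeline in one list. Every stochastic stage draws its seed from
#' \code{seed} deterministically.
#'
#' @param seed master integer seed.
#' @param n_sensors triaxial sensor count (default 30).
#' @param trials_per_block trials per block (default 20).
#' @param fs sampling rate, Hz (default 1200).
#' @param n_regions parcellation size (default 78).
#' @param b0_nT,g_nT_per_m background-field scale (defaults 3.0 and 3.4,
#'   split over components).
#' @param noise_fT sensor noise density (default 15 fT/rtHz).
#' @param interference_pT interference amplitude at the helmet (default 1 pT).
#' @param band analysis band (default c(13, 30)).
#' @param mu covariance regularization (default 0.05).
#' @param grid_mm imaging voxel size in mm (default 4).
#' @param n_perm fingerprint permutations (default 100000).
#' @return a named list (class \code{run_config}).
#' @export
run_config <- function(seed = 1L, n_sensors = 30, trials_per_block = 20,
                       fs = 1200, n_regions = 78, b0_nT = 3.0,
                       g_nT_per_m = 3.4, noise_fT = 15,
                       interference_pT = 1, band = c(13, 30), mu = 0.05,
                       grid_mm = 4, n_perm = 100000) {
  structure(list(seed = seed, n_sensors = n_sensors,
                 trials_per_block = trials_per_block, fs = fs,
                 n_regions = n_regions, b0_nT = b0_nT,
                 g_nT_per_m = g_nT_per_m, noise_fT = noise_fT,
                 interference_pT = interference_pT, band = band, mu = mu,
                 grid_mm = grid_mm, n_perm = n_perm),
            class = "run_config")
}

# background field with given coefficient norms, direction split fixed
.scaled_background <- function(b0_nT, g_nT_per_m) {
  b0 <- c(1, 1, 1) / sqrt(3) * b0_nT
  g <- c(1, -0.5, 0.3, 0.2, -0.1)
  background_field(b0, g / sqrt(sum(g^2)) * g_nT_per_m)
}

#' Run the full pipeline on a configuration
#'
#' Sequences the stages in acquisition order: field nulling, synthetic
#' acquisition, preprocessing, beamformer imaging, connectomics, and summary
#' statistics, writing JSON/CSV reports under \code{out_dir}. Deterministic
#' for a fixed config.
#'
#' @param cfg a \code{run_config}.
#' @param out_dir output directory (created if needed); NULL writes nothing.
#' @param stages subset of c("null", "simulate", "beamform", "connect") to
#'   run; later stages require earlier ones.
#' @return list of stage results (\code{nulling}, \code{recording},
#'   \code{images}, \code{connectomes}, \code{summary}).
#' @export
run_pipeline <- function(cfg = run_config(), out_dir = NULL,
                         stages = c("null", "simulate", "beamform",
                                    "connect")) {
  all_stages <- c("null", "simulate", "beamform", "connect")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  need <- function(s) s %in% stages
  if ((need("beamform") || need("connect")) && !need("simulate"))
    stop("stage dependency violated: beamform/connect require simulate")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list(config = cfg)
  array <- build_helmet_array(cfg$n_sensors)
  head <- head_model()
  env <- .scaled_background(cfg$b0_nT, cfg$g_nT_per_m)
  nm <- noise_model(cfg$noise_fT, derive_seed(cfg$seed, 11))

  if (need("null")) {
    coils <- default_coil_system(seed = derive_seed(cfg$seed, 12))
    res$nulling <- run_nulling(env, coils, array, nm = nm, iterations = 2,
                               seed = derive_seed(cfg$seed, 13))
    env <- res$nulling$true_residual
    if (!is.null(out_dir)) {
      rep <- list(pre = as.list(res$nulling$pre_norms),
                  post = as.list(res$nulling$post_norms),
                  currents = res$nulling$currents)
      jsonlite::write_json(rep, file.path(out_dir, "nulling.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }

  if (need("simulate")) {
    p <- generate_participant(1L, seed = derive_seed(cfg$seed, 14),
                              n_regions = cfg$n_regions, head = head)
    prd <- paradigm(trials_per_block = cfg$trials_per_block, fs = cfg$fs)
    intf <- interference_source(amplitude = cfg$interference_pT * 1e-12)
    res$participant <- p
    res$recording <- generate_recording(
      p, prd, array = array, env = env, interference = intf, nm = nm,
      motion = "task", seed = derive_seed(cfg$seed, 15))
    if (!is.null(out_dir))
      write_recording(res$recording, file.path(out_dir, "recording.rds"))
  }

  if (need("beamform")) {
    seg <- preprocess(res$recording)
    grid <- voxel_grid(head, spacing = cfg$grid_mm / 1000)
    res$images <- lapply(names(seg$trials), function(cond)
      pseudo_t_image(seg, cond, grid = grid, head = head, band = cfg$band,
                     mu = cfg$mu))
    names(res$images) <- names(seg$trials)
    if (!is.null(out_dir))
      for (cond in names(res$images))
        write_source_image(res$images[[cond]],
                           file.path(out_dir, sprintf("pseudo_t_%s.csv", cond)))
    res$seg <- seg
  }

  if (need("connect")) {
    p <- res$participant
    res$connectomes <- lapply(names(res$seg$trials), function(cond) {
      tcs <- region_timecourses(res$seg, cond, p$centroids, head,
                                band = cfg$band, mu = cfg$mu)
      aec_connectome(tcs, res$seg$fs, condition = cond)
    })
    names(res$connectomes) <- names(res$seg$trials)
    res$summary <- lapply(res$connectomes, function(cm)
      connectivity_summaries(cm, node = p$sm_right))
    if (!is.null(out_dir)) {
      for (cond in names(res$connectomes))
        write_connectome(res$connectomes[[cond]],
                         file.path(out_dir, sprintf("connectome_%s.csv", cond)))
      jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  res
}
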