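#' Run configuration
#'
#' Assembles and validates the configuration of a single-subject run:
#' baseline (pre-activity) scan, serial post-activity scans with their
#' nominal time labels (scan-end times, minutes), grid and fit options.
#'
#' @param pre list(`bone` = path, `cartilage` = path) for the baseline
#'   scan.
#' @param post list of post-activity scans, each
#'   list(`bone`, `cartilage`, `time_min`).
#' @param grid list of grid options: `radius` (mm), `split_axis`,
#'   `split_at` (optional).
#' @param fit list of fit options: `offset` (logical).
#' @param out_dir output directory.
#' @param seed integer seed recorded in the log and used for any
#'   stochastic option (e.g. ICP subsampling).
#' @return A validated `run_config` object.
#' @export
run_config <- function(pre, post, grid = list(), fit = list(),
                       out_dir = ".", seed = 1L) {
  grid <- utils::modifyList(list(radius = 2.5, split_axis = "x",
                                 split_at = NULL), grid)
  fit <- utils::modifyList(list(offset = FALSE), fit)
  cfg <- structure(list(pre = pre, post = post, grid = grid, fit = fit,
                        out_dir = out_dir, seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  need_file <- function(path, what) {
    if (is.null(path) || !file.exists(path))
      stop(sprintf("%s file not found: %s", what,
                   if (is.null(path)) "<missing>" else path),
           call. = FALSE)
  }
  need_file(cfg$pre$bone, "pre-activity bone")
  need_file(cfg$pre$cartilage, "pre-activity cartilage")
  if (!length(cfg$post))
    stop("config lists no post-activity scans", call. = FALSE)
  for (i in seq_along(cfg$post)) {
    p <- cfg$post[[i]]
    if (is.null(p$time_min) || !is.finite(as.numeric(p$time_min)))
      stop(sprintf("post scan %d lacks a time_min label", i),
           call. = FALSE)
    need_file(p$bone, sprintf("post scan %d (t=%s min) bone", i,
                              p$time_min))
    need_file(p$cartilage, sprintf("post scan %d (t=%s min) cartilage", i,
                                   p$time_min))
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Relative paths in the file are resolved against the file's directory.
#'
#' @param path YAML file with keys `pre`, `post`, and optionally `grid`,
#'   `fit`, `out_dir`, `seed`.
#' @return A `run_config` object (see [run_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) if (is.null(p) || file.exists(p)) p
                     else file.path(base, p)
  y$pre$bone <- fix(y$pre$bone); y$pre$cartilage <- fix(y$pre$cartilage)
  y$post <- lapply(y$post, function(p) {
    p$bone <- fix(p$bone); p$cartilage <- fix(p$cartilage); p
  })
  cfg <- run_config(y$pre, y$post, y$grid %||% list(), y$fit %||% list(),
                    y$out_dir %||% dirname(path), y$seed %||% 1L)
  attr(cfg, "config_file") <- path
  cfg
}

config_hash <- function(cfg) {
  path <- attr(cfg, "config_file")
  if (is.null(path)) {
    path <- tempfile(fileext = ".yaml")
    on.exit(unlink(path))
    yaml::write_yaml(unclass(cfg), path)
  }
  unname(tools::md5sum(path))
}

#' Run the full recovery pipeline for one subject
#'
#' Mirrors the study workflow: build the sampling grid on the
#' pre-activity cartilage; for each post-activity scan, register its bone
#' model to the pre-activity bone model (ICP) and carry the cartilage
#' along; measure site thickness on every scan; convert to per-site
#' strain against baseline; average the 18 sites into the subject's mean
#' strain per time point; fit the Kelvin-Voigt recovery model. Writes
#' `thickness.csv`, `strain.csv`, `fit.json` and `run_log.txt` (package
#' version, config hash, seed) into `out_dir`; every CSV/JSON carries the
#' config hash so outputs of different runs cannot be mixed silently.
#'
#' @param cfg a [run_config()] (or path handled by [read_run_config()]).
#' @return Invisibly, a report list: `thickness` and `strain`
#'   data.frames, `trajectory` ([strain_trajectory()]), `fit`
#'   ([fit_kelvin_voigt()] result), `registrations`, `config_hash`.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  if (!inherits(cfg, "run_config"))
    stop("`cfg` must be a run_config or a YAML path", call. = FALSE)
  validate_run_config(cfg)
  hash <- config_hash(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  pre_bone <- stage("read", read_mesh(cfg$pre$bone, "bone"))
  pre_cart <- stage("read", read_mesh(cfg$pre$cartilage, "cartilage"))
  grid <- stage("grid", build_sampling_grid(
    pre_cart, split_axis = cfg$grid$split_axis,
    split_at = cfg$grid$split_at, radius = cfg$grid$radius))

  pre_sites <- stage("thickness",
                     scan_site_thickness(pre_cart, pre_bone, grid, "pre"))
  all_sites <- list(pre_sites)
  registrations <- list()
  strain_rows <- list()

  for (i in seq_along(cfg$post)) {
    p <- cfg$post[[i]]
    sid <- sprintf("post_%gmin", as.numeric(p$time_min))
    bone <- stage("read", read_mesh(p$bone, "bone"))
    cart <- stage("read", read_mesh(p$cartilage, "cartilage"))
    tf <- stage("register",
                icp_register(bone, pre_bone, seed = cfg$seed))
    bone_al <- apply_transform(tf, bone)
    cart_al <- apply_transform(tf, cart)
    registrations[[sid]] <- tf
    sites <- stage("thickness",
                   scan_site_thickness(cart_al, bone_al, grid, sid))
    all_sites[[i + 1]] <- sites

    ok <- !pre_sites$missing & !sites$missing
    strain_rows[[i]] <- data.frame(
      scan_id = sid, time_min = as.numeric(p$time_min),
      site_id = sites$site_id[ok],
      strain_pct = compute_strain(pre_sites$thickness_mm[ok],
                                  sites$thickness_mm[ok]),
      stringsAsFactors = FALSE)
  }

  thickness <- do.call(rbind, all_sites)
  strain <- do.call(rbind, strain_rows)
  mean_strain <- stats::aggregate(strain_pct ~ time_min, strain, mean)
  mean_strain <- mean_strain[order(mean_strain$time_min), ]
  traj <- strain_trajectory(mean_strain$time_min, mean_strain$strain_pct)
  fit <- stage("fit", fit_kelvin_voigt(traj, offset = cfg$fit$offset))

  # outputs, each stamped with the config hash
  th_path <- file.path(cfg$out_dir, "thickness.csv")
  st_path <- file.path(cfg$out_dir, "strain.csv")
  write_stamped_csv(thickness, th_path, hash)
  write_stamped_csv(strain, st_path, hash)
  jsonlite::write_json(
    list(A = fit$A, B = fit$B,
         characteristic_recovery_time_min = fit$characteristic_recovery_time,
         rmse = fit$rmse, converged = fit$converged,
         n_points = fit$n_points, config_hash = hash),
    file.path(cfg$out_dir, "fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  writeLines(c(sprintf("cartrec %s",
                       as.character(utils::packageVersion("cartrec"))),
               sprintf("config_hash %s", hash),
               sprintf("seed %d", cfg$seed),
               sprintf("scans %d", length(cfg$post))),
             file.path(cfg$out_dir, "run_log.txt"))

  invisible(list(thickness = thickness, strain = strain, trajectory = traj,
                 fit = fit, registrations = registrations, grid = grid,
                 config_hash = hash))
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash %s", hash), con)
  write.csv(df, con, row.names = FALSE)
}

#' Read a strain trajectory from CSV
#'
#' @param path CSV with columns `time_min` and `strain_pct` (comment
#'   lines starting with `#` are skipped).
#' @return A [strain_trajectory()].
#' @export
read_strain_trajectory <- function(path) {
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_min", "strain_pct") %in% names(df)))
    stop("CSV needs columns time_min and strain_pct", call. = FALSE)
  agg <- stats::aggregate(strain_pct ~ time_min, df, mean)
  agg <- agg[order(agg$time_min), ]
  strain_trajectory(agg$time_min, agg$strain_pct)
}

#' Fit the cohort-mean recovery trajectory
#'
#' Aggregates per-subject trajectories into the cohort mean
#' ([cohort_mean_trajectory()]) and fits the Kelvin-Voigt model to it —
#' the headline analysis: the cohort's characteristic recovery time is
#' the `1/B` of this fit.
#'
#' @param subject_trajs list of subject [strain_trajectory()] objects.
#' @param ... passed to [fit_kelvin_voigt()].
#' @return list(`trajectory`, `fit`).
#' @export
fit_cohort_recovery <- function(subject_trajs, ...) {
  traj <- cohort_mean_trajectory(subject_trajs)
  list(trajectory = traj, fit = fit_kelvin_voigt(traj, ...))
}
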