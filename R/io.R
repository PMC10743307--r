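#' Load a run configuration file
#'
#' Reads the flat `[section] key = value` run-configuration dialect:
#'
#' ```
#' [model]
#' n = 128
#' beta = 99.52
#' eta = 0.5
#' [run]
#' steps = 4000
#' transient = 1000
#' ```
#'
#' Defaults `v0 = 1`, `r0 = 0.472`, `seed = 1`, `transient = 0` are applied;
#' unknown keys are rejected by name; all constraint violations are listed
#' at once.
#'
#' @param path Path to the configuration file.
#' @return List with `params` ([hcvm_params()]) plus `seed`, `steps`,
#'   `transient`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  section <- ""
  kv <- list()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) {
      stop(sprintf("parse error at line %d: expected key = value, got %s",
                   i, sQuote(lines[i])), call. = FALSE)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    kv[[paste0(section, ".", key)]] <- val
  }
  known <- c("model.n", "model.v0", "model.beta", "model.eta", "model.r0",
             "model.seed", "model.force_convention",
             "run.steps", "run.transient")
  unknown <- setdiff(names(kv), known)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("non-numeric value for ", key, call. = FALSE)
    v
  }
  if (is.null(kv[["model.n"]]) || is.null(kv[["model.beta"]])) {
    stop("config must set model.n and model.beta", call. = FALSE)
  }
  params <- hcvm_params(
    n = num("model.n"), beta = num("model.beta"),
    eta = num("model.eta", 0), v0 = num("model.v0", 1),
    r0 = num("model.r0", 0.472),
    force_convention = if (is.null(kv[["model.force_convention"]]))
      "focal_once" else kv[["model.force_convention"]])
  list(params = params,
       seed = as.integer(num("model.seed", 1)),
       steps = as.integer(num("run.steps", 4000)),
       transient = as.integer(num("run.transient", 1000)))
}

#' Scenario presets
#'
#' Ready-to-run parameter sets for the model's canonical regimes: the
#' deterministic attractor gallery at `N = 5000`, the noise-induced-chaos
#' point `N = 128, beta = 99.52`, the critical-curve points at
#' `N = 500, eta = 0.5`, the deterministic bifurcation diagram, and the
#' phase-diagram grid.
#'
#' @param name One of `"fig1_gallery"`, `"fig2_bifurcation"`,
#'   `"fig5_noise_chaos"`, `"fig6_phase"`, `"fig7_critical"`.
#' @return List with `name`, `n`, `eta` (or `eta_grid`), `beta_values` (or
#'   `beta_grid`), `r0`, `v0`, suggested `steps`/`transient`, and a `note`
#'   describing the expected qualitative outcome.
#' @export
scenario_preset <- function(name) {
  registry <- list(
    fig1_gallery = list(
      n = 5000, eta = 0, beta_values = c(1e9, 2e5, 1e4, 500, 0.1),
      steps = 2000, transient = 1000,
      note = paste("deterministic attractor gallery: period-2 pulsation at",
                   "beta = 1e9 and 2e5, period-4 at 1e4, large-period",
                   "orbits at 500, chaos at 0.1")),
    fig2_bifurcation = list(
      n = 128, eta = 0, beta_grid = 10^seq(-2, 9, length.out = 100),
      steps = 1500, transient = 1000,
      note = "center-of-mass bifurcation diagram: P2, P4, P6 cascades into chaos"),
    fig5_noise_chaos = list(
      n = 128, beta = 99.52, eta_values = c(0, 0.25, 0.5),
      steps = 21000, transient = 1000,
      note = paste("noise-induced chaos: period-14 at eta = 0, noisy",
                   "quasiperiodic at 0.25, noisy chaos with lambda1 ~ 0.02",
                   "at 0.5")),
    fig6_phase = list(
      n = 500, eta_grid = seq(0, 2, by = 0.25),
      beta_grid = 10^seq(-4, 9, length.out = 14),
      steps = 3000, transient = 1000,
      note = "phase diagram on the (beta, eta) plane"),
    fig7_critical = list(
      n = 500, eta = 0.5, beta_values = c(0.1, 3e-4, 1e-5),
      steps = 5000, transient = 1000,
      note = paste("critical curve: multicluster chaos at beta = 0.1,",
                   "scale-free transition near beta_c = 3e-4,",
                   "single-cluster chaos at 1e-5")))
  if (!name %in% names(registry)) {
    stop("unknown preset ", sQuote(name), "; available: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  }
  c(list(name = name, r0 = 0.472, v0 = 1), registry[[name]])
}

#' Write / read a trajectory as CSV
#'
#' Columnar text with header `step,id,x,y,theta` (ids 1-based, steps
#' 0-based). Center-of-mass series go through [write_cm_csv()] with header
#' `step,X,Y,x_sum`.
#'
#' @param traj An `hcvm_trajectory` recorded with states.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "hcvm_trajectory"))
  if (is.null(traj$positions)) {
    stop("trajectory has no recorded states", call. = FALSE)
  }
  T <- dim(traj$positions)[1]; n <- dim(traj$positions)[2]
  df <- data.frame(
    step = rep(0:(T - 1), times = n),
    id = rep(seq_len(n), each = T),
    x = as.vector(traj$positions[, , 1]),
    y = as.vector(traj$positions[, , 2]),
    theta = as.vector(traj$headings))
  df <- df[order(df$step, df$id), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param params The [hcvm_params()] the file was produced with (stored on
#'   the rebuilt trajectory).
#' @param transient Transient marker to attach.
#' @export
read_trajectory_csv <- function(path, params, transient = 0) {
  df <- utils::read.csv(path)
  stopifnot(all(c("step", "id", "x", "y", "theta") %in% names(df)))
  steps <- sort(unique(df$step))
  ids <- sort(unique(df$id))
  T <- length(steps); n <- length(ids)
  df <- df[order(df$id, df$step), ]
  pos <- array(c(df$x, df$y), dim = c(T, n, 2))
  th <- matrix(df$theta, nrow = T)
  cm <- data.frame(step = steps,
                   X = rowMeans(pos[, , 1, drop = FALSE]),
                   Y = rowMeans(pos[, , 2, drop = FALSE]))
  cm$x_sum <- cm$X + cm$Y
  structure(list(params = params, seed = NA_integer_, n_steps = T - 1L,
                 transient = as.integer(transient), cm = cm,
                 positions = pos, headings = th),
            class = "hcvm_trajectory")
}

#' @rdname write_trajectory_csv
#' @export
write_cm_csv <- function(traj, path) {
  utils::write.csv(cm_series(traj, drop_transient = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record for a run: configuration hash, master seed and derived
#' substreams, package version. Identical manifests imply bit-identical
#' outputs.
#'
#' @param params An [hcvm_params()] object.
#' @param seed Master seed.
#' @param steps,transient Run lengths.
#' @return List suitable for `jsonlite::write_json()`.
#' @export
run_manifest <- function(params, seed, steps, transient) {
  cfg <- paste(params$n, params$v0, params$beta, params$eta, params$r0,
               params$force_convention, steps, transient, sep = "|")
  list(config = unclass(params)[c("n", "beta", "eta", "v0", "r0",
                                  "force_convention")],
       steps = steps, transient = transient,
       seed = seed, substreams = as.list(seed_streams(seed)),
       config_hash = sprintf("%08x", sum(utf8ToInt(cfg) *
                                           seq_along(utf8ToInt(cfg)))),
       package_version = as.character(utils::packageVersion("swarmchaos")))
}
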